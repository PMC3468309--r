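## Scenario engine: the six built-in initiation/cessation scenarios as
## parameter transforms, and attributable deaths by reference-vs-
## counterfactual contrast.

#' Build a smoking scenario
#'
#' The six built-ins:
#' \describe{
#'   \item{1}{Reference, calibrated 2004 rates (period mode).}
#'   \item{2}{Counterfactual: smoking has no effect on mortality — all
#'     relative risks set to 1 (period mode).}
#'   \item{3}{100\% initiation, 0\% cessation ("always smokers"; cohort).}
#'   \item{4}{55\% (women) / 80\% (men) initiation, cessation at half the
#'     2004 hazards (mid-1900s rates; cohort).}
#'   \item{5}{2004 initiation and cessation rates (cohort).}
#'   \item{6}{0\% initiation ("never smokers"; cohort).}
#' }
#'
#' @param spec A built-in id (`1`..`6`, or `"s4"` style), or a list with
#'   any of `name`, `mode` (`"cohort"`/`"period"`), `cumulative_initiation`
#'   (named `female`/`male` or `NULL` for no change), `cessation_multiplier`,
#'   `cessation_absolute` (data frame as in [smoking_rates()]), `rr_null`
#'   (logical).
#' @return A `scenario` object (list of overrides).
#' @export
build_scenario <- function(spec) {
  if (is.numeric(spec) || (is.character(spec) && length(spec) == 1L &&
                           grepl("^s?[1-6]$", spec))) {
    id <- as.integer(sub("^s", "", as.character(spec)))
    spec <- switch(id,
      list(name = "reference", mode = "period"),
      list(name = "rr_null", mode = "period", rr_null = TRUE),
      list(name = "all_smokers", mode = "cohort",
           cumulative_initiation = c(female = 1, male = 1),
           cessation_multiplier = 0),
      list(name = "rates_1950s", mode = "cohort",
           cumulative_initiation = c(female = 0.55, male = 0.80),
           cessation_multiplier = 0.5),
      list(name = "rates_2004", mode = "cohort"),
      list(name = "no_smoking", mode = "cohort",
           cumulative_initiation = c(female = 0, male = 0)))
    spec$id <- id
  } else if (!is.list(spec)) {
    stop("unknown scenario spec: ", deparse(spec))
  }
  defaults <- list(id = NA_integer_, name = "custom", mode = "cohort",
                   cumulative_initiation = NULL, cessation_multiplier = NULL,
                   cessation_absolute = NULL, rr_null = FALSE)
  unknown <- setdiff(names(spec), names(defaults))
  if (length(unknown))
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  spec <- utils::modifyList(defaults, spec)
  if (!spec$mode %in% c("cohort", "period"))
    stop("scenario mode must be 'cohort' or 'period'")
  if (!is.null(spec$cumulative_initiation)) {
    ci <- spec$cumulative_initiation
    if (!all(sexes() %in% names(ci)) || any(ci < 0 | ci > 1))
      stop("cumulative_initiation override must be named female/male in [0, 1]")
  }
  structure(spec, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %s ('%s', %s mode)\n",
              ifelse(is.na(x$id), "custom", x$id), x$name, x$mode))
  if (!is.null(x$cumulative_initiation))
    cat(sprintf("  initiation -> F %.2f / M %.2f\n",
                x$cumulative_initiation["female"],
                x$cumulative_initiation["male"]))
  if (!is.null(x$cessation_multiplier))
    cat(sprintf("  cessation hazards x %.2f\n", x$cessation_multiplier))
  if (isTRUE(x$rr_null)) cat("  all relative risks set to 1\n")
  invisible(x)
}

#' Apply a scenario's overrides to rates and relative risks
#'
#' Idempotent: applying the same scenario twice equals applying it once.
#'
#' @param scenario A [build_scenario()] object.
#' @param rates A [smoking_rates()].
#' @param rr An [rr_table()].
#' @return List with transformed `rates` and `rr`.
#' @export
apply_scenario <- function(scenario, rates, rr) {
  stopifnot(inherits(scenario, "scenario"))
  init <- vapply(sexes(), function(s) rates[[s]]$p, numeric(1))
  if (!is.null(scenario$cumulative_initiation))
    init[sexes()] <- scenario$cumulative_initiation[sexes()]
  ces <- do.call(rbind, lapply(sexes(), function(s) {
    cs <- rates[[s]]$cessation
    cbind(sex = s, cs[c("age_lo", "age_hi")], hazard = cs$hazard)
  }))
  if (!is.null(scenario$cessation_absolute)) {
    ces <- scenario$cessation_absolute
  } else if (!is.null(scenario$cessation_multiplier)) {
    ces$hazard <- ces$hazard * scenario$cessation_multiplier
  }
  rates2 <- smoking_rates(initiation = init,
                          start_age = rates[[1]]$start_age,
                          end_age = rates[[1]]$end_age,
                          cessation = ces)
  list(rates = rates2, rr = if (isTRUE(scenario$rr_null)) rr_null(rr) else rr)
}

#' Run a scenario
#'
#' Applies the scenario overrides and delegates to the engine: cohort
#' mode returns a simulated birth cohort, period mode expected deaths in
#' the supplied cross-sectional population.
#'
#' @param scenario A [build_scenario()] object (or a spec accepted by it).
#' @param rates,h,rr Baseline inputs.
#' @param n Cohort size (cohort mode).
#' @param seed Master seed (cohort mode / sampled period mode).
#' @param population Period population (period mode; see
#'   [simulate_period_deaths()]).
#' @param causes Optional [cause_list()].
#' @param ... Passed on to the engine.
#' @return A `cohort_result` or a `period_deaths` table.
#' @export
run_scenario <- function(scenario, rates, h, rr, n = 10000L, seed = 1L,
                         population = NULL, causes = NULL, ...) {
  if (!inherits(scenario, "scenario")) scenario <- build_scenario(scenario)
  tr <- apply_scenario(scenario, rates, rr)
  if (scenario$mode == "cohort") {
    simulate_cohort(n, tr$rates, h, tr$rr, seed = seed, causes = causes,
                    scenario = scenario$name, ...)
  } else {
    if (is.null(population))
      stop("period-mode scenario '", scenario$name,
           "' requires a period population")
    simulate_period_deaths(population, h, tr$rr, causes = causes, ...)
  }
}

#' Deaths by cause and sex
#'
#' @param x A `cohort_result` or `period_deaths` object.
#' @return Data frame `cause`, `sex`, `deaths`.
#' @export
deaths_by_cause <- function(x) {
  if (inherits(x, "period_deaths")) return(as.data.frame(x))
  if (is.data.frame(x) && !inherits(x, "cohort_result")) {
    if (!all(c("cause", "sex", "deaths") %in% names(x)))
      stop("death table needs columns cause, sex, deaths")
    return(as.data.frame(x)[c("cause", "sex", "deaths")])
  }
  stopifnot(inherits(x, "cohort_result"))
  causes <- attr(x, "causes")
  out <- expand.grid(cause = as.character(causes), sex = sexes(),
                     stringsAsFactors = FALSE)
  tab <- table(factor(x$cause, levels = as.character(causes)),
               factor(x$sex, levels = sexes()))
  out$deaths <- as.numeric(tab[cbind(out$cause, out$sex)])
  out
}

#' Attributable deaths from a reference/counterfactual contrast
#'
#' Per-cause deaths avoided are reference minus counterfactual deaths;
#' percent reduction is relative to the reference. Negative values
#' (competing-risk reshuffling toward a cause when smoking is removed)
#' are reported as negative.
#'
#' @param reference,counterfactual Objects accepted by
#'   [deaths_by_cause()], on the same cause list and population basis.
#' @return An `attribution_result` data frame: `cause`, `sex`,
#'   `reference`, `counterfactual`, `avoided`, `pct_reduction`, with a
#'   `totals` attribute (per-sex sums).
#' @export
attributable_deaths <- function(reference, counterfactual) {
  ref <- deaths_by_cause(reference)
  cf <- deaths_by_cause(counterfactual)
  if (!identical(sort(unique(ref$cause)), sort(unique(cf$cause))))
    stop("reference and counterfactual cause lists differ")
  key <- paste(ref$cause, ref$sex)
  m <- match(key, paste(cf$cause, cf$sex))
  if (anyNA(m)) stop("counterfactual is missing cause/sex strata")
  out <- data.frame(cause = ref$cause, sex = ref$sex,
                    reference = ref$deaths,
                    counterfactual = cf$deaths[m])
  out$avoided <- out$reference - out$counterfactual
  out$pct_reduction <- ifelse(out$reference > 0,
                              out$avoided / out$reference * 100, 0)
  totals <- do.call(rbind, lapply(sexes(), function(s) {
    sel <- out$sex == s
    data.frame(sex = s, reference = sum(out$reference[sel]),
               avoided = sum(out$avoided[sel]),
               pct_reduction = if (sum(out$reference[sel]) > 0)
                 sum(out$avoided[sel]) / sum(out$reference[sel]) * 100 else 0)
  }))
  structure(out, class = c("attribution_result", "data.frame"),
            totals = totals)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("Attributable deaths (reference - counterfactual)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  tt <- attr(x, "totals")
  cat(sprintf("Totals: %s %.4g avoided (%.1f%%)\n",
              tt$sex, tt$avoided, tt$pct_reduction), sep = "")
  invisible(x)
}

#' Summary shares of an attribution result
#'
#' @param object An `attribution_result`.
#' @param ... Unused.
#' @return List with `total_avoided`, per-sex totals and attributable
#'   shares (percent of that sex's reference deaths), and each cause's
#'   percent share of all avoided deaths (summed over sexes).
#' @export
summary.attribution_result <- function(object, ...) {
  tt <- attr(object, "totals")
  total <- sum(object$avoided)
  by_cause <- stats::aggregate(avoided ~ cause, data = object, FUN = sum)
  by_cause$share_of_avoided_pct <-
    if (total != 0) by_cause$avoided / total * 100 else 0
  list(total_avoided = total, by_sex = tt,
       cause_shares = by_cause[order(-by_cause$avoided), ])
}
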