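## Reported statistics: life expectancy, direct age standardization,
## cause-of-death distributions, age-adjusted smoking prevalence,
## quit-age gain curves and lifespan gain curves (area = delta LE),
## and cross-scenario reports.

#' Construct a standard population
#'
#' Per-sex age-band weights used for direct standardization; weights are
#' normalized to sum to 1 within sex.
#'
#' @param data Data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `weight` (counts or proportions, >= 0).
#' @return A `standard_population` data frame with normalized weights.
#' @export
standard_population <- function(data) {
  need <- c("sex", "age_lo", "age_hi", "weight")
  if (!all(need %in% names(data)))
    stop("standard population needs columns: ", paste(need, collapse = ", "))
  data <- as.data.frame(data)[need]
  if (any(data$weight < 0)) stop("weights must be >= 0")
  for (s in unique(data$sex)) {
    sel <- data$sex == s
    tot <- sum(data$weight[sel])
    if (tot <= 0) stop("weights for sex '", s, "' sum to zero")
    data$weight[sel] <- data$weight[sel] / tot
  }
  structure(data[order(data$sex, data$age_lo), ],
            class = c("standard_population", "data.frame"))
}

#' Life expectancy of a simulated cohort
#'
#' Mean simulated death age with its Monte-Carlo standard error, overall
#' and by sex.
#'
#' @param cohort A `cohort_result`.
#' @return Data frame `sex` (including `"all"`), `n`, `le`, `se`.
#' @export
life_expectancy <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_result"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  grp <- c(list(all = rep(TRUE, nrow(cohort))),
           lapply(stats::setNames(sexes(), sexes()),
                  function(s) cohort$sex == s))
  do.call(rbind, lapply(names(grp), function(g) {
    x <- cohort$death_age[grp[[g]]]
    data.frame(sex = g, n = length(x), le = mean(x),
               se = stats::sd(x) / sqrt(length(x)))
  }))
}

## deaths and person-years by age band from a cohort, per sex
cohort_band_exposure <- function(cohort, bands) {
  out <- expand.grid(sex = sexes(), band = seq_len(nrow(bands)),
                     stringsAsFactors = FALSE)
  out$age_lo <- bands$age_lo[out$band]
  out$age_hi <- bands$age_hi[out$band]
  out$deaths <- 0; out$py <- 0
  hi_top <- max(bands$age_hi)
  for (s in sexes()) {
    d <- cohort$death_age[cohort$sex == s]
    for (b in seq_len(nrow(bands))) {
      lo <- bands$age_lo[b]; hi <- bands$age_hi[b]
      sel <- out$sex == s & out$band == b
      ## residual deaths at the age cap are counted in the top band
      out$deaths[sel] <- sum(d >= lo & (d < hi | (hi >= hi_top & d == hi)))
      out$py[sel] <- sum(pmax(pmin(d, hi) - lo, 0))
    }
  }
  out[c("sex", "age_lo", "age_hi", "deaths", "py")]
}

#' Directly age-standardized mortality rate
#'
#' `sum_a w_a * (deaths_a / person_years_a) * 100000`, with the standard
#' population's per-sex weights. Accepts either a precomputed
#' deaths/exposure table or a `cohort_result` (exposure computed from the
#' simulated lifetimes).
#'
#' @param x Data frame `sex`, `age_lo`, `age_hi`, `deaths`, `py`, or a
#'   `cohort_result`.
#' @param std A [standard_population()]; its bands must match the data's.
#' @return Data frame `sex`, `rate_per_100k`.
#' @export
age_adjusted_mortality <- function(x, std) {
  stopifnot(inherits(std, "standard_population"))
  if (inherits(x, "cohort_result")) {
    bands <- unique(std[c("age_lo", "age_hi")])
    x <- cohort_band_exposure(x, bands[order(bands$age_lo), ])
  }
  sxs <- intersect(intersect(sexes(), unique(std$sex)), unique(x$sex))
  do.call(rbind, lapply(sxs, function(s) {
    w <- std[std$sex == s, ]
    d <- x[x$sex == s, ]
    m <- match(paste(w$age_lo, w$age_hi), paste(d$age_lo, d$age_hi))
    if (anyNA(m))
      stop("age bands of data and standard population do not match for sex '",
           s, "'")
    rate <- ifelse(d$py[m] > 0, d$deaths[m] / d$py[m], 0)
    data.frame(sex = s, rate_per_100k = sum(w$weight * rate) * 1e5)
  }))
}

#' Cause-of-death distribution
#'
#' @param cohort A `cohort_result` (or `period_deaths`).
#' @return Data frame `cause`, `sex`, `percent`; percentages sum to 100
#'   within sex, ordered by the cause list.
#' @export
cause_distribution <- function(cohort) {
  d <- deaths_by_cause(cohort)
  for (s in unique(d$sex)) {
    sel <- d$sex == s
    tot <- sum(d$deaths[sel])
    if (tot <= 0) stop("no deaths for sex '", s, "'")
    d$deaths[sel] <- d$deaths[sel] / tot * 100
  }
  names(d)[names(d) == "deaths"] <- "percent"
  d
}

#' Age-adjusted smoking prevalence among adult survivors
#'
#' Cross-sectional current/former/never proportions among survivors in
#' each adult age band — computed from each individual's person-time in
#' each smoking state within the band — then directly standardized with
#' the per-sex standard-population weights renormalized over the adult
#' bands.
#'
#' @param cohort A `cohort_result` retaining smoking histories.
#' @param std A [standard_population()].
#' @param adult_age Lower age cut (default 18); bands at or above it are
#'   used.
#' @return Data frame `sex`, `current_pct`, `former_pct`, `never_pct`
#'   (each summing to 100 with the others).
#' @export
adjusted_smoking_prevalence <- function(cohort, std, adult_age = 18) {
  stopifnot(inherits(cohort, "cohort_result"),
            inherits(std, "standard_population"))
  out <- do.call(rbind, lapply(intersect(sexes(), unique(std$sex)),
                               function(s) {
    w <- std[std$sex == s & std$age_lo >= adult_age, ]
    if (nrow(w) == 0L) stop("no adult bands in standard population")
    w$weight <- w$weight / sum(w$weight)
    ch <- cohort[cohort$sex == s, ]
    cur <- fmr <- nvr <- numeric(nrow(w))
    seen <- logical(nrow(w))
    for (b in seq_len(nrow(w))) {
      lo <- w$age_lo[b]; hi <- w$age_hi[b]
      alive <- pmax(pmin(ch$death_age, hi) - lo, 0)       # PY alive in band
      tot <- sum(alive)
      if (tot <= 0) next                  # band empty in this cohort
      seen[b] <- TRUE
      init <- ifelse(is.na(ch$initiation_age), Inf, ch$initiation_age)
      quit <- ifelse(is.na(ch$quit_age), Inf, ch$quit_age)
      end <- pmin(ch$death_age, hi)
      t_cur <- pmax(pmin(end, quit) - pmax(lo, init), 0)
      t_fmr <- pmax(end - pmax(lo, quit), 0)
      cur[b] <- sum(t_cur) / tot
      fmr[b] <- sum(t_fmr) / tot
      nvr[b] <- 1 - cur[b] - fmr[b]
    }
    wt <- w$weight * seen
    wt <- wt / sum(wt)                    # renormalize over observed bands
    data.frame(sex = s, current_pct = 100 * sum(wt * cur),
               former_pct = 100 * sum(wt * fmr),
               never_pct = 100 * sum(wt * nvr))
  }))
  rownames(out) <- NULL
  out
}

#' Life-years gained by quitting at a given age
#'
#' Deterministic-oracle comparison of a smoker who quits at age `q`
#' against a lifetime smoker with the same initiation age: the
#' difference in (unconditional) life expectancy.
#'
#' @param h,rr Hazard and relative-risk tables.
#' @param sex `"female"` or `"male"`.
#' @param quit_ages Numeric vector of quit ages.
#' @param initiation_age Common initiation age (default 17).
#' @return Data frame `quit_age`, `gain_years`.
#' @export
quit_age_gain <- function(h, rr, sex, quit_ages, initiation_age = 17) {
  stopifnot(all(quit_ages > initiation_age),
            all(quit_ages < max_age(h)))
  always <- survival_curve(h, rr, sex, initiation_age, NA,
                           grid_step = max_age(h))
  gains <- vapply(quit_ages, function(q) {
    survival_curve(h, rr, sex, initiation_age, q,
                   grid_step = max_age(h))$le - always$le
  }, numeric(1))
  data.frame(quit_age = quit_ages, gain_years = gains)
}

#' Lifespan gain curve between two scenarios
#'
#' Per-age expected life-years gained for a birth cohort of fixed size:
#' for each one-year (by default) age cell, `cohort_size` times the
#' integral of the survivor-proportion difference `S_A - S_B` over the
#' cell. In oracle mode the cell integrals are exact, so the total area
#' equals `cohort_size * (LE_A - LE_B)` up to rounding; with empirical
#' cohorts the cell integrals are trapezoidal.
#'
#' @param a,b Either `survival_curve` objects or `cohort_result`s on the
#'   same age cap.
#' @param cohort_size Cohort size the curve is scaled to (default 10000).
#' @param grid_step Age-cell width in years (default 1).
#' @return A `gain_curve`: data frame `age` (cell start), `gain`
#'   (life-years gained in the cell), with attributes `area` and
#'   `delta_le` (`area / cohort_size`).
#' @export
gain_curve <- function(a, b, cohort_size = 10000, grid_step = 1) {
  mage <- if (inherits(a, "survival_curve")) a$max_age
  else max(a$death_age, b$death_age)
  edges <- seq(0, mage, by = grid_step)
  if (edges[length(edges)] < mage) edges <- c(edges, mage)
  int_S <- function(x) {
    if (inherits(x, "survival_curve")) {
      vapply(seq_len(length(edges) - 1L), function(k)
        curve_surv_integral(x, edges[k], edges[k + 1L]), numeric(1))
    } else {
      ## empirical survivor proportion, trapezoid on the cell edges
      Se <- vapply(edges, function(t) mean(x$death_age > t), numeric(1))
      (Se[-1] + Se[-length(Se)]) / 2 * diff(edges)
    }
  }
  gain <- cohort_size * (int_S(a) - int_S(b))
  area <- sum(gain)
  structure(data.frame(age = edges[-length(edges)], gain = gain),
            class = c("gain_curve", "data.frame"),
            area = area, delta_le = area / cohort_size,
            cohort_size = cohort_size)
}

#' @export
print.gain_curve <- function(x, ...) {
  cat(sprintf("Gain curve: area %.2f life-years for a cohort of %g (delta LE %.4f y)\n",
              attr(x, "area"), attr(x, "cohort_size"), attr(x, "delta_le")))
  invisible(x)
}

#' Life-expectancy decomposition across the standard scenario set
#'
#' The three comparisons reported for the cohort analysis, per sex and
#' sex-averaged:
#' \describe{
#'   \item{realized}{reference minus scenario 4 (gains since the
#'     mid-1900s already realized).}
#'   \item{pending}{scenario 5 minus reference (still to come at 2004
#'     rates).}
#'   \item{elimination}{scenario 6 minus scenario 5 (from eliminating
#'     smoking).}
#'   \item{total_potential}{scenario 6 minus scenario 4.}
#' }
#'
#' @param le Data frame with columns `scenario` (containing at least
#'   `"reference"`, `"s4"`, `"s5"`, `"s6"`; `"1"`/`"4"`-style labels are
#'   accepted), `female`, `male` (life expectancies in years).
#' @return Data frame `component`, `female`, `male`, `average`.
#' @export
le_decomposition <- function(le) {
  lab <- as.character(le$scenario)
  lab[lab %in% c("1", "s1", "ref")] <- "reference"
  lab[lab %in% c("4", "rates_1950s")] <- "s4"
  lab[lab %in% c("5", "rates_2004")] <- "s5"
  lab[lab %in% c("6", "no_smoking")] <- "s6"
  need <- c("reference", "s4", "s5", "s6")
  if (!all(need %in% lab))
    stop("le table must contain scenarios: ", paste(need, collapse = ", "))
  g <- function(sc, sex) le[[sex]][match(sc, lab)]
  comp <- function(nm, a, b) data.frame(
    component = nm, female = g(a, "female") - g(b, "female"),
    male = g(a, "male") - g(b, "male"))
  out <- rbind(comp("realized", "reference", "s4"),
               comp("pending", "s5", "reference"),
               comp("elimination", "s6", "s5"),
               comp("total_potential", "s6", "s4"))
  out$average <- (out$female + out$male) / 2
  out
}

#' Cross-scenario report
#'
#' Per-scenario life expectancy, age-adjusted mortality, cause-of-death
#' distribution and age-adjusted smoking prevalence, plus the
#' [le_decomposition()] when the required scenarios are present.
#'
#' @param results Named list of `cohort_result`s keyed by scenario label.
#' @param std A [standard_population()].
#' @param reference_le Optional data frame `scenario`, `female`, `male`
#'   of externally supplied life expectancies that replace/augment the
#'   simulated ones in the decomposition (e.g. a period reference).
#' @return A `scenario_report` list with elements `life_expectancy`,
#'   `age_adjusted_mortality`, `cause_distribution`, `smoking_prevalence`
#'   and (when possible) `le_decomposition`.
#' @export
scenario_report <- function(results, std, reference_le = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  le <- do.call(rbind, lapply(names(results), function(nm) {
    l <- life_expectancy(results[[nm]])
    data.frame(scenario = nm,
               female = l$le[l$sex == "female"],
               male = l$le[l$sex == "male"])
  }))
  aam <- do.call(rbind, lapply(names(results), function(nm)
    cbind(scenario = nm, age_adjusted_mortality(results[[nm]], std))))
  cdist <- do.call(rbind, lapply(names(results), function(nm)
    cbind(scenario = nm, cause_distribution(results[[nm]]))))
  prev <- do.call(rbind, lapply(names(results), function(nm)
    cbind(scenario = nm, adjusted_smoking_prevalence(results[[nm]], std))))
  le_all <- if (is.null(reference_le)) le else {
    keep <- !(le$scenario %in% reference_le$scenario)
    rbind(reference_le, le[keep, ])
  }
  dec <- tryCatch(le_decomposition(le_all), error = function(e) NULL)
  structure(list(life_expectancy = le, age_adjusted_mortality = aam,
                 cause_distribution = cdist, smoking_prevalence = prev,
                 le_decomposition = dec),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario report\n\nLife expectancy (y):\n")
  print.data.frame(x$life_expectancy, row.names = FALSE, digits = 4)
  if (!is.null(x$le_decomposition)) {
    cat("\nLife-expectancy decomposition (y):\n")
    print.data.frame(x$le_decomposition, row.names = FALSE, digits = 3)
  }
  cat("\nAge-adjusted mortality (per 100,000):\n")
  print.data.frame(x$age_adjusted_mortality, row.names = FALSE, digits = 4)
  cat("\nAge-adjusted adult smoking prevalence (%):\n")
  print.data.frame(x$smoking_prevalence, row.names = FALSE, digits = 3)
  invisible(x)
}
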