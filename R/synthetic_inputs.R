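## Synthetic-input generator: Gompertz baseline hazard tables, smoking
## relative-risk tables with monotone quit-duration decay, a stylized
## standard population with smoking-state composition, and linked
## survey-like mortality follow-up records.

#' Specification for the synthetic input generator
#'
#' The default emulates the structure of the real study inputs at desk
#' scale: five named causes spanning the qualitative contrasts (an
#' ischemic-heart-disease-like cause with moderate smoking RR, a
#' lung-cancer-like and a COPD-like cause with large RRs, an injury-like
#' cause with a flat age profile and no smoking effect, an other-cancer-
#' like cause) plus a residual, each with a Gompertz age gradient
#' `level * exp(slope * age-band midpoint)` tabulated on 5-year bands.
#' Former-smoker relative risks decay monotonically toward 1 with time
#' since quitting.
#'
#' @param seed Integer seed stored with the spec.
#' @param max_age Age cap in years (default 110).
#' @param band_width Hazard age-band width in years (default 5).
#' @param causes Data frame with columns `cause`, `level_female`,
#'   `level_male`, `slope`, `rr_current`, and `rr_former_1` ..
#'   `rr_former_4` (quit-bin RRs); `NULL` for the built-in six-cause set.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, max_age = 110, band_width = 5,
                           causes = NULL) {
  if (is.null(causes)) {
    causes <- data.frame(
      cause = c("Ischemic heart disease", "Lung cancer", "COPD",
                "Injuries", "Other cancers", "All other causes"),
      level_female = c(4.2e-6, 1.1e-6, 7.0e-7, 9.0e-5, 1.1e-5, 1.25e-5),
      level_male   = c(8.0e-6, 1.6e-6, 9.0e-7, 2.5e-4, 1.4e-5, 1.8e-5),
      slope        = c(0.098, 0.092, 0.102, 0.004, 0.075, 0.095),
      rr_current   = c(2.2, 20, 12, 1, 1.6, 1.3),
      rr_former_1  = c(1.8, 9, 8, 1, 1.4, 1.2),
      rr_former_2  = c(1.5, 5, 5, 1, 1.25, 1.1),
      rr_former_3  = c(1.2, 2, 2.5, 1, 1.1, 1.05),
      rr_former_4  = c(1.05, 1.2, 1.3, 1, 1, 1))
  }
  need <- c("cause", "level_female", "level_male", "slope", "rr_current",
            paste0("rr_former_", 1:4))
  if (!all(need %in% names(causes)))
    stop("causes spec needs columns: ", paste(need, collapse = ", "))
  rrcols <- as.matrix(causes[c("rr_current", paste0("rr_former_", 1:4))])
  if (any(rrcols < 1 - 1e-12))
    stop("synthetic RRs must be >= 1")
  if (any(rrcols[, -1] > rrcols[, -5] + 1e-12))
    stop("former-smoker RRs must decay monotonically from the current RR")
  structure(list(seed = as.integer(seed), max_age = max_age,
                 band_width = band_width, causes = causes),
            class = "synthetic_spec")
}

#' Cause list of a synthetic spec
#' @param spec A [synthetic_spec()].
#' @return A [cause_list()] with "All other causes" (or the last cause)
#'   as residual.
#' @export
spec_causes <- function(spec) {
  cz <- spec$causes$cause
  resid <- if ("All other causes" %in% cz) "All other causes" else
    cz[length(cz)]
  cause_list(cz, resid)
}

#' Generate a Gompertz baseline hazard table
#'
#' `h0(cause, sex, band) = level * exp(slope * band midpoint)` on
#' half-open bands of width `spec$band_width` up to `spec$max_age`.
#' Deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated [hazard_table()].
#' @export
make_hazards <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  edges <- seq(0, spec$max_age, by = spec$band_width)
  if (edges[length(edges)] < spec$max_age) edges <- c(edges, spec$max_age)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  rows <- do.call(rbind, lapply(seq_len(nrow(spec$causes)), function(i) {
    cz <- spec$causes[i, ]
    do.call(rbind, lapply(sexes(), function(s) {
      lev <- if (s == "female") cz$level_female else cz$level_male
      data.frame(cause = cz$cause, sex = s,
                 age_lo = edges[-length(edges)], age_hi = edges[-1],
                 rate_per_py = lev * exp(cz$slope * mid))
    }))
  }))
  hazard_table(rows, max_age = spec$max_age)
}

#' Generate a smoking relative-risk table
#'
#' Emits the spec's current- and former-smoker multipliers (identical
#' for both sexes), RR(never) = 1. `null = TRUE` gives the all-ones
#' table used for counterfactual and null tests.
#'
#' @param spec A [synthetic_spec()].
#' @param null Set every RR to 1 (default `FALSE`).
#' @return A validated [rr_table()].
#' @export
make_rr <- function(spec, null = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  states <- smoking_states()
  rows <- do.call(rbind, lapply(seq_len(nrow(spec$causes)), function(i) {
    cz <- spec$causes[i, ]
    rrv <- c(1, cz$rr_current, cz$rr_former_1, cz$rr_former_2,
             cz$rr_former_3, cz$rr_former_4)
    do.call(rbind, lapply(sexes(), function(s)
      data.frame(cause = cz$cause, sex = s, state = states,
                 rr = if (null) rep(1, 6) else rrv)))
  }))
  rr_table(rows)
}

#' Generate a standard population and period composition
#'
#' The standard population uses a stylized 2004-like age pyramid (flat
#' through early middle age, tapering at older ages) on 5-year bands by
#' sex. The period composition assigns each (sex, band) the smoking-state
#' probabilities of [prevalence_components()] at the band midpoint, with
#' the quit-duration split induced by the cessation law (no mortality
#' adjustment).
#'
#' @param spec A [synthetic_spec()].
#' @param rates A [smoking_rates()] defining the composition.
#' @param total Total population count per sex (default 1e6).
#' @return List with `std` (a [standard_population()]) and `composition`
#'   (data frame `sex`, `age`, `state`, `count`, `time_since_quit`).
#' @export
make_population <- function(spec, rates = smoking_rates(), total = 1e6) {
  stopifnot(inherits(spec, "synthetic_spec"))
  edges <- seq(0, spec$max_age, by = spec$band_width)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  mid <- (lo + hi) / 2
  ## stylized pyramid: constant to 40, then smooth decline
  w <- ifelse(mid <= 40, 1, exp(-((mid - 40) / 32)^2))
  std <- standard_population(data.frame(
    sex = rep(sexes(), each = length(mid)),
    age_lo = rep(lo, 2), age_hi = rep(hi, 2), weight = rep(w, 2)))
  comp <- do.call(rbind, lapply(sexes(), function(s) {
    pc <- prevalence_components(rates, s, mid)
    wgt <- std$weight[std$sex == s]
    do.call(rbind, lapply(seq_along(mid), function(b) {
      pr <- as.numeric(pc[b, c("never", "current", smoking_states()[3:6])])
      data.frame(sex = s, age = mid[b], state = c("never", "current",
                                                  smoking_states()[3:6]),
                 count = total * wgt[b] * pr,
                 time_since_quit = c(NA, NA, 2.5, 7.5, 15,
                                     max(mid[b] - rates[[s]]$start_age - 20,
                                         20) / 2 + 20))
    }))
  }))
  list(std = std, composition = comp[comp$count > 0, ])
}

#' Generate linked survey-like mortality follow-up records
#'
#' Samples individuals from the life-course model, keeps those alive at
#' their survey entry age (left truncation by construction: entry ages
#' are assigned and individuals dying earlier are resampled from the
#' model, i.e. simple random sampling among survivors), and follows them
#' for a fixed horizon, recording the event cause or censoring.
#'
#' @param spec A [synthetic_spec()] (its seed is combined with `seed`).
#' @param rates,h,rr Model inputs; ground truth `rr` is retained in the
#'   `truth` attribute.
#' @param n Number of records.
#' @param entry_ages Vector of candidate entry ages sampled uniformly
#'   (default 40 to 70 by 5).
#' @param horizon Follow-up in years (default 10).
#' @param seed Seed.
#' @return Data frame `id`, `sex`, `entry_age`, `exit_age`,
#'   `event_cause` (`NA` = censored), `initiation_age`, `quit_age`;
#'   attribute `truth` holds `rr`.
#' @export
make_linked_records <- function(spec, rates, h, rr, n = 50000L,
                                entry_ages = seq(40, 70, by = 5),
                                horizon = 10, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed) + spec$seed)
  out <- NULL
  draw <- max(2L * n, 1000L)
  guard <- 0L
  while ((is.null(out) || nrow(out) < n) && guard < 20L) {
    guard <- guard + 1L
    coh <- simulate_cohort(draw, rates, h, rr,
                           seed = sample.int(2^31 - 2, 1))
    entry <- entry_ages[sample.int(length(entry_ages), nrow(coh),
                                   replace = TRUE)]
    keep <- coh$death_age > entry
    rec <- data.frame(sex = coh$sex[keep], entry_age = entry[keep],
                      death_age = coh$death_age[keep],
                      cause = coh$cause[keep],
                      initiation_age = coh$initiation_age[keep],
                      quit_age = coh$quit_age[keep])
    out <- rbind(out, rec)
  }
  out <- out[seq_len(n), ]
  died <- out$death_age <= out$entry_age + horizon
  out$exit_age <- pmin(out$death_age, out$entry_age + horizon)
  out$event_cause <- ifelse(died, out$cause, NA_character_)
  out$id <- seq_len(n)
  rownames(out) <- NULL
  structure(out[c("id", "sex", "entry_age", "exit_age", "event_cause",
                  "initiation_age", "quit_age")],
            truth = rr, horizon = horizon)
}
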