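## Data model for baseline cause-specific mortality hazards and smoking
## relative risks, and effective-hazard lookups.

#' Smoking state labels
#'
#' The six smoking states used throughout the package: never smoker, current
#' smoker, and former smoker by years since quitting in half-open bins
#' \[0,5), \[5,10), \[10,20), \[20,Inf).
#'
#' @return Character vector of the six state labels, in canonical order.
#' @export
smoking_states <- function() {
  c("never", "current", "former_0_4", "former_5_9", "former_10_19",
    "former_20plus")
}

## lower edges (years since quitting) of the four former-smoker bins
.former_bin_lo <- c(0, 5, 10, 20)

#' Sexes recognised by the model
#' @return Character vector `c("female", "male")`.
#' @export
sexes <- function() c("female", "male")

#' Construct a smoking state label
#'
#' @param category One of `"never"`, `"current"`, `"former"`.
#' @param years_since_quit Years since quitting; required iff
#'   `category == "former"`. The boundary instant belongs to the higher bin
#'   (e.g. exactly 20 years maps to `former_20plus`).
#' @return One of the six labels from [smoking_states()].
#' @export
smoking_state <- function(category, years_since_quit = NULL) {
  category <- match.arg(category, c("never", "current", "former"))
  if (category != "former") {
    if (!is.null(years_since_quit))
      stop("years_since_quit must be omitted unless category is 'former'")
    return(category)
  }
  if (is.null(years_since_quit))
    stop("years_since_quit is required for former smokers")
  quit_bin_state(years_since_quit)
}

## vectorised: years since quit -> former-bin label
quit_bin_state <- function(d) {
  stopifnot(all(d >= 0))
  idx <- findInterval(d, c(.former_bin_lo, Inf))
  smoking_states()[2L + idx]
}

#' Construct a cause list
#'
#' An ordered set of cause-of-death identifiers, exactly one of which is
#' flagged as the residual ("all other causes") that absorbs survivors at
#' the maximum age.
#'
#' @param causes Character vector of unique cause identifiers.
#' @param residual The identifier of the residual cause (must be in
#'   `causes`).
#' @return A `cause_list` object (character vector with a `residual`
#'   attribute).
#' @export
cause_list <- function(causes, residual) {
  causes <- as.character(causes)
  if (length(causes) < 1L) stop("cause list must contain at least one cause")
  if (anyDuplicated(causes)) stop("cause identifiers must be unique")
  if (length(residual) != 1L || !residual %in% causes)
    stop("exactly one residual cause must be named and present in 'causes'")
  structure(causes, residual = residual, class = "cause_list")
}

#' @export
print.cause_list <- function(x, ...) {
  cat("Cause list (", length(x), " causes, residual = '",
      attr(x, "residual"), "')\n", sep = "")
  cat(paste0("  ", unclass(x)), sep = "\n")
  invisible(x)
}

#' Residual cause of a cause list
#' @param causes A [cause_list()].
#' @return The residual cause identifier.
#' @export
residual_cause <- function(causes) attr(causes, "residual")

#' Construct a baseline hazard table
#'
#' Cause-, sex- and age-band-specific mortality hazards in deaths per
#' person-year. Age bands are half-open `[age_lo, age_hi)` and must
#' partition `[0, max_age)` for every (cause, sex) combination.
#'
#' @param data Data frame with columns `cause`, `sex`, `age_lo`, `age_hi`,
#'   `rate_per_py`.
#' @param max_age Simulation age cap in years (default 110). Survivors at
#'   `max_age` die of the residual cause at that instant.
#' @return A validated `hazard_table` (the data frame, ordered, with a
#'   `max_age` attribute).
#' @export
hazard_table <- function(data, max_age = 110) {
  need <- c("cause", "sex", "age_lo", "age_hi", "rate_per_py")
  if (!all(need %in% names(data)))
    stop("hazard table needs columns: ", paste(need, collapse = ", "))
  data <- as.data.frame(data)[need]
  data$cause <- as.character(data$cause)
  data$sex <- as.character(data$sex)
  if (!all(data$sex %in% sexes()))
    stop("sex must be one of: ", paste(sexes(), collapse = ", "))
  if (any(!is.finite(data$rate_per_py)) || any(data$rate_per_py < 0))
    stop("hazard rates must be finite and non-negative")
  data <- data[order(data$cause, data$sex, data$age_lo), , drop = FALSE]
  rownames(data) <- NULL
  obj <- structure(data, max_age = max_age, class = c("hazard_table", "data.frame"))
  validate_hazard_table(obj)
  obj
}

#' Validate a hazard table
#'
#' Checks that for every (cause, sex) the age bands partition
#' `[0, max_age)` with no gaps or overlaps, and that every cause is
#' covered for both sexes.
#'
#' @param h A `hazard_table`.
#' @param causes Optional [cause_list()]; if given, coverage of exactly
#'   these causes is enforced.
#' @return `h`, invisibly; errors name the offending rows.
#' @export
validate_hazard_table <- function(h, causes = NULL) {
  max_age <- attr(h, "max_age")
  if (!is.numeric(max_age) || max_age <= 0) stop("invalid max_age")
  for (cs in split(h, list(h$cause, h$sex), drop = TRUE)) {
    cs <- cs[order(cs$age_lo), , drop = FALSE]
    lab <- paste0("cause '", cs$cause[1], "', sex '", cs$sex[1], "'")
    if (cs$age_lo[1] != 0)
      stop("age bands for ", lab, " must start at 0 (first band starts at ",
           cs$age_lo[1], ")")
    if (any(cs$age_hi <= cs$age_lo))
      stop("empty or inverted age band in ", lab, " at age_lo = ",
           cs$age_lo[which(cs$age_hi <= cs$age_lo)[1]])
    k <- length(cs$age_lo)
    if (k > 1L) {
      bad <- which(cs$age_lo[-1] != cs$age_hi[-k])
      if (length(bad)) {
        if (cs$age_lo[bad[1] + 1L] > cs$age_hi[bad[1]])
          stop("gap in age bands for ", lab, " at age ", cs$age_hi[bad[1]])
        stop("overlapping age bands for ", lab, " at age ",
             cs$age_lo[bad[1] + 1L])
      }
    }
    if (cs$age_hi[k] < max_age)
      stop("age bands for ", lab, " end at ", cs$age_hi[k],
           " but must cover [0, ", max_age, ")")
  }
  tab_causes <- sort(unique(h$cause))
  if (!is.null(causes)) {
    miss <- setdiff(as.character(causes), tab_causes)
    if (length(miss))
      stop("hazard table missing causes: ", paste(miss, collapse = ", "))
  }
  for (cz in tab_causes) {
    have <- unique(h$sex[h$cause == cz])
    if (!all(sexes() %in% have))
      stop("cause '", cz, "' not covered for both sexes")
  }
  invisible(h)
}

#' Maximum simulated age of a hazard table
#' @param h A `hazard_table`.
#' @return `max_age` in years.
#' @export
max_age <- function(h) attr(h, "max_age")

#' Construct a relative-risk table
#'
#' Dimensionless multipliers RR(cause, sex, smoking state) applied to the
#' baseline hazards. Must be complete over causes x sexes x the six
#' smoking states, with RR = 1 for never smokers.
#'
#' @param data Data frame with columns `cause`, `sex`, `state`, `rr`.
#' @return A validated `rr_table`.
#' @export
rr_table <- function(data) {
  need <- c("cause", "sex", "state", "rr")
  if (!all(need %in% names(data)))
    stop("rr table needs columns: ", paste(need, collapse = ", "))
  data <- as.data.frame(data)[need]
  data$cause <- as.character(data$cause)
  data$sex <- as.character(data$sex)
  data$state <- as.character(data$state)
  obj <- structure(data[order(data$cause, data$sex,
                              match(data$state, smoking_states())), ,
                        drop = FALSE],
                   class = c("rr_table", "data.frame"))
  rownames(obj) <- NULL
  validate_rr_table(obj)
  obj
}

#' Validate a relative-risk table
#'
#' @param rr An `rr_table`.
#' @param causes Optional [cause_list()] whose coverage is enforced.
#' @return `rr`, invisibly; errors name the offending row.
#' @export
validate_rr_table <- function(rr, causes = NULL) {
  bad <- which(!rr$state %in% smoking_states())
  if (length(bad))
    stop("unknown smoking state '", rr$state[bad[1]], "' in rr table row ",
         bad[1])
  bad <- which(!is.finite(rr$rr) | rr$rr <= 0)
  if (length(bad))
    stop("rr must be finite and > 0; violated in row ", bad[1],
         " (cause '", rr$cause[bad[1]], "', state '", rr$state[bad[1]], "')")
  bad <- which(rr$state == "never" & rr$rr != 1)
  if (length(bad))
    stop("RR(never) must equal 1; violated in row ", bad[1],
         " (cause '", rr$cause[bad[1]], "', sex '", rr$sex[bad[1]], "')")
  cnt <- table(rr$cause, rr$sex)
  if (any(cnt != length(smoking_states())))
    stop("rr table must contain exactly one row per cause x sex x state; ",
         "incomplete for cause '",
         rownames(cnt)[which(cnt != 6, arr.ind = TRUE)[1, 1]], "'")
  if (!is.null(causes)) {
    miss <- setdiff(as.character(causes), unique(rr$cause))
    if (length(miss))
      stop("rr table missing causes: ", paste(miss, collapse = ", "))
  }
  invisible(rr)
}

#' Null relative-risk table (all RR = 1)
#'
#' Used for the counterfactual in which smoking has no effect on
#' mortality.
#'
#' @param rr An `rr_table` to nullify.
#' @return An `rr_table` of the same shape with every RR set to 1.
#' @export
rr_null <- function(rr) {
  rr$rr <- 1
  rr_table(rr)
}

#' Effective cause-specific hazard
#'
#' Baseline hazard for the age band containing `age` multiplied by the
#' relative risk of the given smoking state.
#'
#' @param h A [hazard_table()].
#' @param rr An [rr_table()].
#' @param cause Cause identifier.
#' @param sex `"female"` or `"male"`.
#' @param age Age in years, `0 <= age < max_age(h)`.
#' @param state A smoking-state label (see [smoking_states()]).
#' @return Hazard in deaths per person-year.
#' @export
effective_hazard <- function(h, rr, cause, sex, age, state) {
  if (any(age < 0) || any(age >= max_age(h)))
    stop("age must lie in [0, ", max_age(h), ")")
  hs <- h[h$cause == cause & h$sex == sex, , drop = FALSE]
  if (nrow(hs) == 0L) stop("unknown cause '", cause, "' or sex '", sex, "'")
  if (!state %in% smoking_states()) stop("unknown smoking state '", state, "'")
  band <- findInterval(age, hs$age_lo)
  r <- rr$rr[rr$cause == cause & rr$sex == sex & rr$state == state]
  if (length(r) != 1L) stop("rr table has no entry for cause '", cause,
                            "', sex '", sex, "', state '", state, "'")
  hs$rate_per_py[band] * r
}

#' Total (all-cause) effective hazard
#'
#' Sum of [effective_hazard()] over all causes in the table.
#'
#' @inheritParams effective_hazard
#' @return Hazard in deaths per person-year.
#' @export
total_hazard <- function(h, rr, sex, age, state) {
  causes <- unique(h$cause)
  out <- 0
  for (cz in causes) out <- out + effective_hazard(h, rr, cz, sex, age, state)
  out
}

## ---------------------------------------------------------------------------
## Internal "basis": per-sex precomputation used by the engine and oracle.
## Refines all causes' bands onto one common edge grid and tabulates
## per-state total hazards and their cumulative integrals at the edges.
hazard_basis <- function(h, rr, sex, causes = NULL) {
  hs <- h[h$sex == sex, , drop = FALSE]
  if (nrow(hs) == 0L) stop("hazard table has no rows for sex '", sex, "'")
  if (is.null(causes)) causes <- sort(unique(hs$cause))
  mage <- max_age(h)
  edges <- sort(unique(c(0, mage, hs$age_lo, hs$age_hi)))
  edges <- edges[edges <= mage]
  K <- length(edges) - 1L
  mid <- (edges[-1] + edges[-(K + 1L)]) / 2
  nc <- length(causes)
  H0 <- matrix(0, K, nc, dimnames = list(NULL, causes))
  for (j in seq_len(nc)) {
    hc <- hs[hs$cause == causes[j], , drop = FALSE]
    hc <- hc[order(hc$age_lo), , drop = FALSE]
    H0[, j] <- hc$rate_per_py[findInterval(mid, hc$age_lo)]
  }
  states <- smoking_states()
  RRm <- matrix(1, nc, length(states), dimnames = list(causes, states))
  rrs <- rr[rr$sex == sex, , drop = FALSE]
  for (s in states) {
    v <- rrs$rr[rrs$state == s][match(causes, rrs$cause[rrs$state == s])]
    if (anyNA(v)) stop("rr table incomplete for sex '", sex, "'")
    RRm[, s] <- v
  }
  Tband <- H0 %*% RRm                       # K x 6 per-state total hazards
  len <- diff(edges)
  Cedge <- rbind(0, apply(Tband * len, 2, cumsum))  # (K+1) x 6
  list(edges = edges, len = len, H0 = H0, RRm = RRm, Tband = Tband,
       Cedge = Cedge, causes = causes, max_age = mage, sex = sex)
}

## G_s(t): cumulative state-s total hazard from age 0 to t, vectorised in t.
## t must lie in [0, max_age].
basis_cumhaz_state <- function(basis, s, t) {
  k <- findInterval(t, basis$edges, rightmost.closed = TRUE, all.inside = TRUE)
  basis$Cedge[k, s] + (t - basis$edges[k]) * basis$Tband[k, s]
}

## Personal breakpoints of a smoking history, capped at max_age.
## init/quit may be NA (never / never quits). Returns n x 5 matrix with
## columns a1 (initiation), a2 (quit), b1, b2, b3 (quit + 5/10/20).
history_breaks <- function(init, quit, mage) {
  n <- max(length(init), length(quit))
  init <- rep_len(as.numeric(init), n)
  quit <- rep_len(as.numeric(quit), n)
  a1 <- pmin(ifelse(is.na(init), Inf, init), mage)
  a2 <- pmin(ifelse(is.na(quit), Inf, quit), mage)
  a2 <- pmax(a2, a1)
  cbind(a1 = a1, a2 = a2,
        b1 = pmin(a2 + 5, mage), b2 = pmin(a2 + 10, mage),
        b3 = pmin(a2 + 20, mage))
}

## Lambda_i(t): cumulative total effective hazard along each individual's
## smoking history. init, quit, t recycled to common length.
history_cumhaz <- function(basis, init, quit, t) {
  n <- max(length(init), length(quit), length(t))
  t <- pmin(pmax(rep_len(as.numeric(t), n), 0), basis$max_age)
  B <- history_breaks(rep_len(init, n), rep_len(quit, n), basis$max_age)
  starts <- cbind(0, B)                    # segment starts per state 1..6
  ends <- cbind(B, basis$max_age)          # segment ends
  out <- numeric(n)
  for (s in seq_len(6L)) {
    lo <- starts[, s]
    hi <- pmin(pmax(t, lo), ends[, s])
    live <- hi > lo
    if (any(live))
      out[live] <- out[live] +
        basis_cumhaz_state(basis, s, hi[live]) -
        basis_cumhaz_state(basis, s, lo[live])
  }
  out
}

## Smoking state index (1..6) at age t given breakpoints, with the tie rule
## that an instant exactly at a breakpoint uses the pre-breakpoint state.
history_state_index <- function(B, t) {
  1L + (t > B[, "a1"]) + (t > B[, "a2"]) + (t > B[, "b1"]) +
    (t > B[, "b2"]) + (t > B[, "b3"])
}
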