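## Piecewise-exponential proportional-hazards estimation of smoking
## relative risks: person-period expansion and a profiled-baseline
## Newton solver (the Poisson-equivalent of an age-stratified Cox fit).

#' Expand survey-like records into a person-period table
#'
#' Splits each follow-up record at every age-band edge and smoking-state
#' breakpoint (initiation, quit, quit + 5/10/20 years), then aggregates
#' exposure person-years and per-cause event counts by stratum
#' (sex x age band) and smoking state. Exposure and events are conserved
#' exactly.
#'
#' @param records Data frame with columns `id`, `sex`, `entry_age`,
#'   `exit_age`, `event_cause` (`NA`/`""` = censored), `initiation_age`,
#'   `quit_age` (`NA` = never).
#' @param band_edges Increasing age-band edges covering all follow-up
#'   (e.g. `seq(0, 110, by = 5)`); bands are half-open.
#' @return A `person_period_table` data frame: `sex`, `age_lo`, `age_hi`,
#'   `state`, `py`, and an `events` matrix column (one column per
#'   observed cause).
#' @export
expand_person_periods <- function(records, band_edges = seq(0, 110, by = 5)) {
  need <- c("sex", "entry_age", "exit_age", "event_cause",
            "initiation_age", "quit_age")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$exit_age <= records$entry_age))
    stop("exit_age must exceed entry_age (row ",
         which(records$exit_age <= records$entry_age)[1], ")")
  band_edges <- sort(unique(band_edges))
  if (min(records$entry_age) < band_edges[1] ||
      max(records$exit_age) > band_edges[length(band_edges)])
    stop("band_edges must cover all follow-up")
  ev <- as.character(records$event_cause)
  ev[is.na(ev) | ev == ""] <- NA_character_
  causes <- sort(unique(ev[!is.na(ev)]))
  n <- nrow(records)
  ## per-record cut points: band edges + personal smoking breakpoints
  cuts <- lapply(seq_len(n), function(i) {
    en <- records$entry_age[i]; ex <- records$exit_age[i]
    br <- c(records$initiation_age[i], records$quit_age[i],
            records$quit_age[i] + c(5, 10, 20))
    sort(unique(c(en, ex, band_edges[band_edges > en & band_edges < ex],
                  br[!is.na(br) & br > en & br < ex])))
  })
  nseg <- lengths(cuts) - 1L
  pp <- data.frame(
    row = rep(seq_len(n), nseg),
    lo = unlist(lapply(cuts, function(x) x[-length(x)]), use.names = FALSE),
    hi = unlist(lapply(cuts, function(x) x[-1]), use.names = FALSE))
  mid <- (pp$lo + pp$hi) / 2
  pp$sex <- records$sex[pp$row]
  pp$state <- state_at(records$initiation_age[pp$row],
                       records$quit_age[pp$row], mid)
  bi <- findInterval(mid, band_edges)
  pp$age_lo <- band_edges[bi]
  pp$age_hi <- band_edges[bi + 1L]
  pp$py <- pp$hi - pp$lo
  ## events land in the terminal piece of their record
  is_last <- pp$hi == records$exit_age[pp$row]
  pp$ev <- ifelse(is_last, ev[pp$row], NA_character_)
  key <- paste(pp$sex, pp$age_lo, pp$state, sep = "\r")
  ukey <- sort(unique(key))
  idx <- match(key, ukey)
  py <- as.numeric(tapply(pp$py, idx, sum))
  evmat <- matrix(0L, length(ukey), length(causes),
                  dimnames = list(NULL, causes))
  has_ev <- !is.na(pp$ev)
  if (any(has_ev)) {
    tt <- table(idx[has_ev], factor(pp$ev[has_ev], levels = causes))
    evmat[as.integer(rownames(tt)), ] <- as.matrix(tt)
  }
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  out <- data.frame(sex = parts[, 1], age_lo = as.numeric(parts[, 2]),
                    state = parts[, 3], py = py)
  out$age_hi <- band_edges[findInterval(out$age_lo, band_edges) + 1L]
  out <- out[c("sex", "age_lo", "age_hi", "state", "py")]
  out$events <- evmat
  structure(out[order(out$sex, out$age_lo,
                      match(out$state, smoking_states())), ],
            class = c("person_period_table", "data.frame"),
            causes = causes)
}

#' Fit a piecewise-exponential proportional-hazards model for one cause
#'
#' Maximizes the Poisson-equivalent piecewise-exponential likelihood
#' with one free baseline rate per stratum (sex x age band), profiled
#' out analytically, and five free log relative risks for the
#' non-reference smoking states (never = reference, log-RR fixed at 0).
#' Newton-Raphson with step-halving; converged when the gradient
#' infinity-norm drops below `grad_tol`. A state with positive exposure
#' but no events anywhere (complete separation toward 0) is reported as
#' a boundary estimate (`log_rr = -Inf`) with a flag rather than an
#' error.
#'
#' @param table A [expand_person_periods()] result.
#' @param cause Cause identifier (must have >= 1 event).
#' @param grad_tol Convergence tolerance on the gradient infinity norm
#'   (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return An `rr_fit`: data frame `state`, `log_rr`, `se`, `rr`,
#'   `rr_lo`, `rr_hi` (95\% Wald), `flag`; attributes `converged`,
#'   `loglik`, `iterations`, `cause`.
#' @export
fit_piecewise_ph <- function(table, cause, grad_tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(table, "person_period_table"))
  if (!cause %in% colnames(table$events))
    stop("no events observed for cause '", cause, "'")
  d <- as.numeric(table$events[, cause])
  py <- table$py
  keep <- py > 0
  d <- d[keep]; py <- py[keep]
  if (any(as.numeric(table$events[!keep, cause]) > 0))
    stop("events recorded in rows with zero exposure")
  stratum <- factor(paste(table$sex, table$age_lo, sep = ":"))[keep]
  state <- factor(table$state[keep], levels = smoking_states())
  nonref <- smoking_states()[-1]
  ## boundary states: positive exposure, zero events everywhere
  tot_ev <- tapply(d, state, sum, default = 0)
  tot_py <- tapply(py, state, sum, default = 0)
  boundary <- nonref[tot_ev[nonref] == 0 & tot_py[nonref] > 0]
  absent <- nonref[is.na(tot_py[nonref]) | tot_py[nonref] == 0]
  free <- setdiff(nonref, c(boundary, absent))
  X <- matrix(0, length(state), length(free), dimnames = list(NULL, free))
  for (s in free) X[, s] <- as.numeric(state == s)
  ## drop rows of boundary/absent states: their fitted rate is 0 and they
  ## contribute no information about the free coefficients
  use <- !(as.character(state) %in% c(boundary, absent))
  Xu <- X[use, , drop = FALSE]
  du <- d[use]; pyu <- py[use]; su <- droplevels(stratum[use])
  beta <- rep(0, length(free))
  H <- matrix(0, length(free), length(free))
  prof <- function(beta) {
    eta <- as.numeric(Xu %*% beta)
    w <- pyu * exp(eta)
    Ej <- tapply(w, su, sum)
    Dj <- tapply(du, su, sum)
    ok <- Dj > 0
    ll <- sum(du * eta) + sum(Dj[ok] * (log(Dj[ok] / Ej[ok]) - 1))
    list(ll = ll, w = w, Ej = Ej, Dj = Dj)
  }
  iter <- 0L; converged <- length(free) == 0L
  p <- prof(beta)
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    ## gradient and Hessian of the profile likelihood
    wn <- p$w / as.numeric(p$Ej[su])          # within-stratum weights
    Dw <- as.numeric(p$Dj[su]) * wn
    grad <- colSums(du * Xu) - colSums(Dw * Xu)
    H <- matrix(0, length(free), length(free))
    for (j in levels(su)) {
      sel <- su == j
      Dj <- p$Dj[[j]]
      if (Dj == 0) next
      wj <- wn[sel]
      Xj <- Xu[sel, , drop = FALSE]
      xbar <- colSums(wj * Xj)
      H <- H - Dj * (crossprod(Xj, wj * Xj) - tcrossprod(xbar))
    }
    if (max(abs(grad)) < grad_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, -grad), error = function(e) -grad * 0.1)
    ## step-halving: never decrease the likelihood
    for (half in 0:20) {
      cand <- beta + step / 2^half
      pc <- prof(cand)
      if (pc$ll >= p$ll - 1e-12) { beta <- cand; p <- pc; break }
    }
  }
  se <- rep(NA_real_, length(free))
  if (length(free)) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
  }
  res <- data.frame(state = nonref, log_rr = NA_real_, se = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  res$log_rr[match(free, res$state)] <- beta
  res$se[match(free, res$state)] <- se
  res$log_rr[res$state %in% boundary] <- -Inf
  res$flag[res$state %in% boundary] <- "boundary"
  res$flag[res$state %in% absent] <- "no_exposure"
  res$rr <- exp(res$log_rr)
  res$rr_lo <- exp(res$log_rr - 1.96 * res$se)
  res$rr_hi <- exp(res$log_rr + 1.96 * res$se)
  structure(res, class = c("rr_fit", "data.frame"),
            converged = converged, loglik = p$ll, iterations = iter,
            cause = cause)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf("Piecewise-exponential PH fit for '%s' (%s, %d iterations)\n",
              attr(x, "cause"),
              if (attr(x, "converged")) "converged" else "not converged",
              attr(x, "iterations")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
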