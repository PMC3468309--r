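## Calibration of initiation/cessation rates to cross-sectional
## current-smoker prevalence among survivors, accounting for smokers'
## excess mortality.

#' Smoking prevalence among survivors
#'
#' `P(state | alive at age)`, combining the analytic no-mortality state
#' law with state-specific survival. The deterministic estimator
#' discretises the initiation age (exact probability masses on a
#' sub-interval grid) and the quit age (exact conditional masses on a
#' step grid), evaluates survival for every lattice history through the
#' segment-exact cumulative hazard, and mixes. With all relative risks
#' equal to 1 it reduces exactly to [prevalence_no_mortality()].
#'
#' @param rates A [smoking_rates()].
#' @param h,rr Hazard and relative-risk tables.
#' @param sex `"female"` or `"male"`.
#' @param age Numeric vector of ages.
#' @param init_grid Number of initiation-age sub-intervals (default 24).
#' @param quit_step Quit-age grid step in years (default 1).
#' @param method `"deterministic"` (default) or `"montecarlo"`.
#' @param n Monte-Carlo sample size (montecarlo method only).
#' @param seed Seed for the Monte-Carlo method.
#' @return Data frame `age`, `never`, `current`, `former` (probabilities
#'   among survivors, rows sum to 1).
#' @export
survivor_prevalence <- function(rates, h, rr, sex, age,
                                init_grid = 24L, quit_step = 1,
                                method = c("deterministic", "montecarlo"),
                                n = 100000L, seed = 1L) {
  sex <- match.arg(sex, sexes())
  method <- match.arg(method)
  if (method == "montecarlo")
    return(.survivor_prevalence_mc(rates, h, rr, sex, age, n, seed))
  r <- rates[[sex]]
  basis <- hazard_basis(h, rr, sex)
  out <- data.frame(age = age, never = NA_real_, current = NA_real_,
                    former = NA_real_)
  ## initiation lattice: exact mass per sub-interval, node at midpoint
  s0 <- r$start_age; s1 <- r$end_age
  if (r$p > 0) {
    se <- seq(s0, s1, length.out = init_grid + 1L)
    if (r$p >= 1) {
      imass <- c(1, rep(0, init_grid - 1L))
      inode <- rep(s0, init_grid)
    } else {
      lam <- initiation_hazard(r$p, s0, s1)
      Fi <- -expm1(-lam * (se - s0))
      imass <- diff(Fi)
      inode <- (se[-1] + se[-length(se)]) / 2
    }
  } else {
    imass <- numeric(0); inode <- numeric(0)
  }
  for (i in seq_along(age)) {
    a <- age[i]
    S_never <- exp(-history_cumhaz(basis, NA, NA, a))
    ## exact state totals from the closed-form no-mortality law; the
    ## lattice below only distributes the survival weighting within state
    pn <- prevalence_no_mortality(rates, sex, a)
    w_never <- pn$never * S_never
    w_current <- 0; w_former <- 0
    if (r$p > 0 && a > s0) {
      keep <- inode < a
      nodes <- inode[keep]; masses <- imass[keep]
      if (length(nodes)) {
        ## still-current mass: quit after a (exact tail), survival of a
        ## continuous smoker from each initiation node
        tail_mass <- exp(-(cessation_cumhaz(r, a) -
                             cessation_cumhaz(r, nodes)))
        S_cur <- exp(-history_cumhaz(basis, nodes, NA, rep(a, length(nodes))))
        mcur <- masses * tail_mass
        if (sum(mcur) > 0)
          w_current <- pn$current * sum(mcur * S_cur) / sum(mcur)
        ## former: quit-age lattice between each node and a
        qe <- sort(unique(c(seq(min(nodes), a, by = quit_step), a,
                            r$cessation$age_lo[r$cessation$age_lo < a])))
        mf_tot <- 0; wf_raw <- 0
        for (j in seq_along(nodes)) {
          qq <- qe[qe >= nodes[j]]
          if (length(qq) < 2L) next
          cq <- cessation_cumhaz(r, qq) - cessation_cumhaz(r, nodes[j])
          qmass <- exp(-cq[-length(cq)]) - exp(-cq[-1])
          qnode <- (qq[-1] + qq[-length(qq)]) / 2
          live <- qmass > 0
          if (!any(live)) next
          S_f <- exp(-history_cumhaz(basis, rep(nodes[j], sum(live)),
                                     qnode[live], rep(a, sum(live))))
          wf_raw <- wf_raw + masses[j] * sum(qmass[live] * S_f)
          mf_tot <- mf_tot + masses[j] * sum(qmass[live])
        }
        if (mf_tot > 0) w_former <- pn$former * wf_raw / mf_tot
      }
    }
    tot <- w_never + w_current + w_former
    out$never[i] <- w_never / tot
    out$current[i] <- w_current / tot
    out$former[i] <- w_former / tot
  }
  out
}

.survivor_prevalence_mc <- function(rates, h, rr, sex, age, n, seed) {
  coh <- simulate_cohort(n, rates, h, rr, seed = seed, sex = sex)
  out <- data.frame(age = age, never = NA_real_, current = NA_real_,
                    former = NA_real_)
  for (i in seq_along(age)) {
    alive <- coh$death_age > age[i]
    st <- state_at(coh$initiation_age[alive], coh$quit_age[alive], age[i])
    out$never[i] <- mean(st == "never")
    out$current[i] <- mean(st == "current")
    out$former[i] <- 1 - out$never[i] - out$current[i]
  }
  out
}

#' Prevalence calibration targets
#'
#' @param data Data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `current_prev` and optionally `weight` (default 1). The band
#'   midpoint is the evaluation age.
#' @return A validated `prevalence_target` data frame with an added
#'   `age` column.
#' @export
prevalence_target <- function(data) {
  need <- c("sex", "age_lo", "age_hi", "current_prev")
  if (!all(need %in% names(data)))
    stop("targets need columns: ", paste(need, collapse = ", "))
  data <- as.data.frame(data)
  if (is.null(data$weight)) data$weight <- 1
  if (any(data$current_prev < 0 | data$current_prev > 1))
    stop("target proportions must lie in [0, 1]")
  data$age <- (data$age_lo + data$age_hi) / 2
  for (s in unique(data$sex)) {
    d <- data[data$sex == s, ]
    d <- d[order(d$age_lo), ]
    if (nrow(d) > 1L && any(d$age_lo[-1] < d$age_hi[-nrow(d)]))
      stop("target bands overlap for sex '", s, "'")
  }
  structure(data[order(data$sex, data$age), ],
            class = c("prevalence_target", "data.frame"))
}

#' Calibrate initiation and cessation rates to survivor prevalence
#'
#' Iterative proportional fitting: each pass rescales the cumulative
#' initiation probability toward the youngest-band target and each
#' cessation-band hazard toward the target log-decline across the ages
#' it governs, recomputing the deterministic [survivor_prevalence()]
#' estimator after every pass. Multiplicative updates in rate space with
#' geometric damping 0.8. Stops when the maximum absolute prevalence
#' error drops below `tol`, when the weighted residual stops improving,
#' or after `max_iter` passes; non-convergence is flagged in the result,
#' not raised.
#'
#' @param targets A [prevalence_target()] (or data frame accepted by it).
#' @param initial Starting [smoking_rates()].
#' @param h,rr Hazard and relative-risk tables.
#' @param max_iter Maximum passes (default 100).
#' @param tol Absolute prevalence tolerance (default 1e-3).
#' @param damping Geometric damping exponent in (0, 1\] (default 0.8).
#' @param ... Passed to [survivor_prevalence()].
#' @return A `calibration_result`: list with `rates`, `converged`,
#'   `iterations`, `residuals` (per-pass weighted max residuals) and
#'   `final` (per-target model vs target).
#' @export
calibrate <- function(targets, initial, h, rr, max_iter = 100L, tol = 1e-3,
                      damping = 0.8, ...) {
  if (!inherits(targets, "prevalence_target"))
    targets <- prevalence_target(targets)
  rates <- initial
  resid_hist <- numeric(0)
  best <- list(rates = rates, resid = Inf, final = NULL)
  for (it in seq_len(max_iter)) {
    model <- .model_prevalence(targets, rates, h, rr, ...)
    resid <- max(abs(model - targets$current_prev) * targets$weight)
    resid_hist <- c(resid_hist, resid)
    if (resid < best$resid)
      best <- list(rates = rates, resid = resid,
                   final = data.frame(targets[c("sex", "age")],
                                      target = targets$current_prev,
                                      model = model))
    if (resid < tol) break
    if (it > 1L && resid > resid_hist[it - 1L]) break  # stop at best
    rates <- .calibration_pass(targets, model, rates, damping)
  }
  structure(list(rates = best$rates, converged = best$resid < tol,
                 iterations = length(resid_hist), residuals = resid_hist,
                 final_residual = best$resid, final = best$final),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration %s after %d pass(es); max residual %.3g\n",
              if (x$converged) "converged" else "did NOT converge",
              x$iterations, x$final_residual))
  if (!is.null(x$final)) print.data.frame(x$final, row.names = FALSE,
                                          digits = 4)
  invisible(x)
}

.model_prevalence <- function(targets, rates, h, rr, ...) {
  out <- numeric(nrow(targets))
  for (s in unique(targets$sex)) {
    sel <- targets$sex == s
    sp <- survivor_prevalence(rates, h, rr, s, targets$age[sel], ...)
    out[sel] <- sp$current
  }
  out
}

## one damped multiplicative update of p24 and the cessation hazards
.calibration_pass <- function(targets, model, rates, damping) {
  eps <- 1e-12
  init <- vapply(sexes(), function(s) rates[[s]]$p, numeric(1))
  ces <- do.call(rbind, lapply(sexes(), function(s) {
    cs <- rates[[s]]$cessation
    cbind(sex = s, cs[c("age_lo", "age_hi")], hazard = cs$hazard)
  }))
  for (s in intersect(sexes(), unique(targets$sex))) {
    sel <- which(targets$sex == s)
    tv <- targets$current_prev[sel]
    mv <- model[sel]
    ## youngest band drives cumulative initiation
    if (mv[1] > eps && tv[1] > eps) {
      ratio <- tv[1] / mv[1]
      init[s] <- min(max(init[s] * ratio^damping, 0), 0.999)
    } else if (tv[1] <= eps) {
      init[s] <- init[s] * (1 - damping)
      if (init[s] < 1e-6) init[s] <- 0
    }
    if (length(sel) < 2L) next
    cs <- rates[[s]]$cessation
    for (k in 2:length(sel)) {
      a0 <- targets$age[sel[k - 1L]]; a1 <- targets$age[sel[k]]
      band <- findInterval((a0 + a1) / 2, cs$age_lo)
      if (band < 1L) next
      if (tv[k] <= eps || tv[k - 1L] <= eps || mv[k] <= eps ||
          mv[k - 1L] <= eps) next
      Lt <- log(tv[k - 1L] / tv[k])
      Lm <- log(mv[k - 1L] / mv[k])
      if (Lm <= eps || Lt < 0) next
      ratio <- Lt / Lm
      rowsel <- ces$sex == s & ces$age_lo == cs$age_lo[band]
      ces$hazard[rowsel] <- min(cs$hazard[band] * ratio^damping, 1)
    }
  }
  smoking_rates(initiation = init, start_age = rates[[1]]$start_age,
                end_age = rates[[1]]$end_age, cessation = ces)
}
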