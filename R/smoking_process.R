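## Smoking life-course process: initiation through age 24, age-banded
## cessation (absorbing, no relapse), state bookkeeping and analytic
## no-mortality prevalence.

#' Construct smoking initiation/cessation rates
#'
#' Initiation is a constant hazard on `[start_age, end_age)` chosen so the
#' cumulative probability of ever smoking by `end_age` equals
#' `initiation[sex]`; initiation after `end_age` is negligible. Cessation
#' is a piecewise-constant hazard of successful quitting on half-open age
#' bands (zero below the first band); quitting is absorbing (no relapse).
#'
#' Defaults are the 1980-birth-cohort values: cumulative initiation 35%
#' (women) / 39% (men) by the 24th birthday, and annual cessation hazards
#' 4.2/3.1/2.5/4.5% (women) and 4.0/2.8/2.1/6.0% (men) for ages 15-27,
#' 28-32, 33-47 and 48+.
#'
#' @param initiation Named numeric `c(female=, male=)`: cumulative
#'   initiation probability by `end_age`, in `[0, 1]`. The value 1 is the
#'   degenerate limit in which everyone initiates at `start_age`.
#' @param start_age,end_age Initiation window in years (default 12 to 24).
#' @param cessation Data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `hazard` (per year); per sex the bands must partition
#'   `[first age_lo, Inf)`.
#' @return A `smoking_rates` object.
#' @export
smoking_rates <- function(initiation = c(female = 0.35, male = 0.39),
                          start_age = 12, end_age = 24,
                          cessation = default_cessation()) {
  stopifnot(all(sexes() %in% names(initiation)),
            end_age > start_age)
  if (any(initiation < 0 | initiation > 1))
    stop("cumulative initiation must lie in [0, 1]")
  cessation <- as.data.frame(cessation)
  need <- c("sex", "age_lo", "age_hi", "hazard")
  if (!all(need %in% names(cessation)))
    stop("cessation needs columns: ", paste(need, collapse = ", "))
  obj <- list()
  for (s in sexes()) {
    cs <- cessation[cessation$sex == s, need, drop = FALSE]
    cs <- cs[order(cs$age_lo), , drop = FALSE]
    if (nrow(cs) == 0L) stop("no cessation bands for sex '", s, "'")
    if (any(!is.finite(cs$hazard)) || any(cs$hazard < 0))
      stop("cessation hazards must be finite and >= 0")
    k <- nrow(cs)
    if (k > 1L && any(cs$age_lo[-1] != cs$age_hi[-k]))
      stop("cessation bands for sex '", s, "' must be contiguous")
    if (is.finite(cs$age_hi[k]))
      stop("last cessation band for sex '", s, "' must be open-ended (Inf)")
    rownames(cs) <- NULL
    obj[[s]] <- list(p = unname(initiation[s]), start_age = start_age,
                     end_age = end_age, cessation = cs)
  }
  structure(obj, class = "smoking_rates")
}

#' Default cessation bands (1980 cohort)
#' @return Data frame of per-sex cessation hazard bands.
#' @export
default_cessation <- function() {
  data.frame(
    sex = rep(sexes(), each = 4),
    age_lo = rep(c(15, 28, 33, 48), 2),
    age_hi = rep(c(28, 33, 48, Inf), 2),
    hazard = c(0.042, 0.031, 0.025, 0.045,
               0.040, 0.028, 0.021, 0.060))
}

#' @export
print.smoking_rates <- function(x, ...) {
  cat("Smoking rates\n")
  for (s in sexes()) {
    r <- x[[s]]
    cat(sprintf("  %s: cumulative initiation %.3f on [%g, %g)\n",
                s, r$p, r$start_age, r$end_age))
    with(r$cessation, cat(sprintf("    cessation %.4f/y on [%g, %g)\n",
                                  hazard, age_lo, age_hi), sep = ""))
  }
  invisible(x)
}

#' Constant initiation hazard from a cumulative probability
#'
#' Inverts `1 - exp(-lambda * (end_age - start_age)) = p`.
#'
#' @param p Cumulative initiation probability, `0 <= p < 1`.
#' @param start_age,end_age Initiation window (years).
#' @return Hazard per year.
#' @export
initiation_hazard <- function(p, start_age = 12, end_age = 24) {
  if (end_age <= start_age) stop("end_age must exceed start_age")
  if (any(p < 0) || any(p >= 1))
    stop("cumulative initiation probability must lie in [0, 1)")
  -log1p(-p) / (end_age - start_age)
}

## cumulative cessation hazard from age 0 to t for one sex (vectorised)
cessation_cumhaz <- function(rates_sex, t) {
  cs <- rates_sex$cessation
  haz <- c(0, cs$hazard)
  fe <- c(0, cs$age_lo)
  cumfe <- c(0, cumsum(haz[-length(haz)] * diff(fe)))
  k <- findInterval(t, fe, rightmost.closed = FALSE, all.inside = FALSE)
  k[k < 1L] <- 1L
  cumfe[k] + (pmax(t, 0) - fe[k]) * haz[k]
}

## invert cessation: earliest q > s with C(q) - C(s) = e, Inf if never.
## s, e vectors of equal length.
cessation_invert <- function(rates_sex, s, e) {
  cs <- rates_sex$cessation
  fe <- c(0, cs$age_lo)                    # finite edges
  haz <- c(0, cs$hazard)
  cumfe <- c(0, cumsum(haz[-length(haz)] * diff(fe)))
  target <- cessation_cumhaz(rates_sex, s) + e
  ## band containing the target cumulative hazard; plateaus (hazard 0) are
  ## skipped because findInterval returns the last edge with cumfe <= target
  k <- findInterval(target, cumfe)
  q <- rep(Inf, length(s))
  ok <- k <= length(haz) & haz[pmin(k, length(haz))] > 0
  q[ok] <- fe[k[ok]] + (target[ok] - cumfe[k[ok]]) / haz[k[ok]]
  ## if target falls beyond the last cumulative value but the open-ended
  ## band has zero hazard, the person never quits (q stays Inf)
  q
}

#' Sample smoking histories
#'
#' Draws initiation age from the truncated-exponential initiation law on
#' `[start_age, end_age)` (with total mass equal to the cumulative
#' initiation probability) and, conditional on initiation, a quit age from
#' the piecewise-exponential cessation law. No relapse ever occurs.
#'
#' @param rates A [smoking_rates()] object.
#' @param sex `"female"` or `"male"`.
#' @param n Number of histories.
#' @param u Optional `2 x n` matrix of uniforms (row 1: initiation, row 2:
#'   cessation); drawn from the current RNG stream when `NULL`.
#' @return Data frame with columns `initiation_age`, `quit_age` (`NA` for
#'   never smokers / never quitters).
#' @export
sample_history <- function(rates, sex, n, u = NULL) {
  r <- rates[[match.arg(sex, sexes())]]
  if (is.null(u)) u <- matrix(stats::runif(2L * n), nrow = 2L)
  stopifnot(nrow(u) >= 2L, ncol(u) == n)
  init <- rep(NA_real_, n)
  quit <- rep(NA_real_, n)
  smoker <- u[1L, ] < r$p
  if (any(smoker)) {
    if (r$p >= 1) {
      init[smoker] <- r$start_age        # degenerate limit of the law
    } else {
      lam <- initiation_hazard(r$p, r$start_age, r$end_age)
      init[smoker] <- r$start_age - log1p(-u[1L, smoker]) / lam
    }
    e <- -log(u[2L, smoker])
    q <- cessation_invert(r, init[smoker], e)
    q[!is.finite(q)] <- NA_real_
    quit[smoker] <- q
  }
  data.frame(initiation_age = init, quit_age = quit)
}

#' Smoking state at a given age
#'
#' @param initiation_age,quit_age Event ages (`NA` = event never occurs);
#'   vectors are recycled.
#' @param age Age in years (>= 0).
#' @return Character vector of state labels (see [smoking_states()]).
#'   An individual is `never` before the initiation age, `current` from
#'   initiation (inclusive) to quitting, and `former` from the quit age
#'   (inclusive) onward, binned by completed years since quitting with the
#'   boundary instant in the higher bin.
#' @export
state_at <- function(initiation_age, quit_age, age) {
  n <- max(length(initiation_age), length(quit_age), length(age))
  init <- rep_len(as.numeric(initiation_age), n)
  quit <- rep_len(as.numeric(quit_age), n)
  age <- rep_len(as.numeric(age), n)
  stopifnot(all(age >= 0))
  out <- rep("never", n)
  cur <- !is.na(init) & age >= init
  out[cur] <- "current"
  fmr <- cur & !is.na(quit) & age >= quit
  if (any(fmr)) out[fmr] <- quit_bin_state(age[fmr] - quit[fmr])
  out
}

#' Analytic smoking-state prevalence ignoring mortality
#'
#' Closed-form probabilities of being a never, current or former smoker at
#' each age under the initiation/cessation law, with no mortality. The
#' current-smoker probability integrates the initiation density against
#' the piecewise-exponential cessation survival (exact piecewise closed
#' form, no quadrature).
#'
#' @param rates A [smoking_rates()].
#' @param sex `"female"` or `"male"`.
#' @param age Numeric vector of ages (years, >= 0).
#' @return Data frame with columns `age`, `never`, `current`, `former`;
#'   rows sum to 1.
#' @export
prevalence_no_mortality <- function(rates, sex, age) {
  r <- rates[[match.arg(sex, sexes())]]
  stopifnot(all(age >= 0))
  pc <- vapply(age, function(a) .p_current(r, a), numeric(1))
  pe <- .p_ever(r, age)
  data.frame(age = age, never = 1 - pe, current = pc, former = pe - pc)
}

## P(initiated by age a)
.p_ever <- function(r, a) {
  if (r$p >= 1) return(as.numeric(a >= r$start_age))
  lam <- initiation_hazard(r$p, r$start_age, r$end_age)
  span <- pmin(pmax(a, r$start_age), r$end_age) - r$start_age
  -expm1(-lam * span)
}

## P(current smoker at age a), exact piecewise closed form:
##   integral over initiation age s of  lam exp(-lam (s - s0)) *
##   exp(-(Cq(a) - Cq(s)))  for s in [s0, min(a, 24))
.p_current <- function(r, a) {
  s0 <- r$start_age
  if (a <= s0 || r$p == 0) return(0)
  if (r$p >= 1) {                           # all initiate at s0
    return(exp(-(cessation_cumhaz(r, a) - cessation_cumhaz(r, s0))))
  }
  lam <- initiation_hazard(r$p, s0, r$end_age)
  hi <- min(a, r$end_age)
  knots <- sort(unique(c(s0, hi, r$cessation$age_lo[
    r$cessation$age_lo > s0 & r$cessation$age_lo < hi])))
  cqa <- cessation_cumhaz(r, a)
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    x1 <- knots[i]; x2 <- knots[i + 1L]
    cband <- .cess_rate_at(r, (x1 + x2) / 2)
    ## A = survival-to-piece-start factors
    A <- exp(-lam * (x1 - s0)) * exp(-(cqa - cessation_cumhaz(r, x1)))
    L <- x2 - x1
    d <- lam - cband
    piece <- if (abs(d) < 1e-12) lam * L else lam / d * -expm1(-d * L)
    total <- total + A * piece
  }
  total
}

## cessation hazard at a single age
.cess_rate_at <- function(r, a) {
  cs <- r$cessation
  k <- findInterval(a, cs$age_lo)
  if (k < 1L) 0 else cs$hazard[k]
}

#' Former-smoker prevalence by years-since-quit bin (no mortality)
#'
#' Splits the former-smoker probability at each age into the four
#' years-since-quit bins by integrating the quit-time density
#' `c(q) * P(current at q)` (adaptive Simpson on the smooth pieces).
#'
#' @inheritParams prevalence_no_mortality
#' @return Data frame with columns `age`, `never`, `current`,
#'   `former_0_4`, `former_5_9`, `former_10_19`, `former_20plus`.
#' @export
prevalence_components <- function(rates, sex, age) {
  r <- rates[[match.arg(sex, sexes())]]
  base <- prevalence_no_mortality(rates, sex, age)
  bins <- matrix(0, length(age), 4,
                 dimnames = list(NULL, smoking_states()[3:6]))
  pcur <- function(q) vapply(q, function(qq) .p_current(r, qq), numeric(1))
  breaks <- c(r$start_age, r$cessation$age_lo, r$end_age)
  edges_d <- c(.former_bin_lo, Inf)
  for (i in seq_along(age)) {
    a <- age[i]
    for (b in 1:4) {
      qlo <- max(if (is.finite(edges_d[b + 1])) a - edges_d[b + 1] else 0, 0)
      qhi <- max(a - edges_d[b], 0)
      if (qhi <= qlo) next
      ## the cessation hazard is constant on each smooth piece: factor it
      ## out and Simpson-integrate the continuous current-smoker law
      knots <- sort(unique(c(qlo, qhi, breaks[breaks > qlo & breaks < qhi])))
      for (k in seq_len(length(knots) - 1L)) {
        cband <- .cess_rate_at(r, (knots[k] + knots[k + 1L]) / 2)
        if (cband > 0)
          bins[i, b] <- bins[i, b] + cband *
            .simpson_piecewise(pcur, knots[k], knots[k + 1L], numeric(0))
      }
    }
  }
  cbind(base[c("age", "never", "current")], as.data.frame(bins))
}

## composite Simpson with subdivision at given breakpoints (smooth pieces)
.simpson_piecewise <- function(f, lo, hi, breaks, n_sub = 32L) {
  knots <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    x <- seq(a, b, length.out = 2L * n_sub + 1L)
    y <- f(x)
    hstep <- (b - a) / (2 * n_sub)
    total <- total + hstep / 3 *
      (y[1] + y[2 * n_sub + 1] + 4 * sum(y[seq(2, 2 * n_sub, by = 2)]) +
         2 * sum(y[seq(3, 2 * n_sub - 1, by = 2)]))
  }
  total
}
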