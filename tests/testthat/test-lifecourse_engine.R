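test_that("death ages follow the exponential law under a constant hazard", {
  h <- const_hazard(0.02, cap = 5000)
  rr <- unit_rr("X")
  set.seed(5)
  d <- simulate_death(h, rr, "female", u = matrix(runif(2e5), nrow = 2))
  expect_equal(mean(d$death_age), 50, tolerance = 0.5 / 50)
  sc <- survival_curve(h, rr, "female", grid_step = 50)
  expect_equal(curve_surv_at(sc, 50), exp(-1), tolerance = 1e-12)
  expect_equal(sc$surv[1], 1)
  expect_true(all(diff(sc$surv) <= 0))
  expect_equal(sc$le, 50, tolerance = 1e-9)
})

test_that("competing exponentials split causes as lambda_i over the total", {
  h <- two_cause_hazard(0.01, 0.03)
  rr <- unit_rr(c("A", "B"))
  set.seed(6)
  d <- simulate_death(h, rr, "male", u = matrix(runif(2e5), nrow = 2),
                      causes = cause_list(c("A", "B"), "B"))
  shareB <- mean(d$cause == "B")
  expect_lt(abs(shareB - 0.75), 4 * sqrt(0.75 * 0.25 / 1e5))
})

test_that("doubling the hazard via RR halves the mean lifetime", {
  h <- const_hazard(0.002, cap = 50000)
  rr <- current_rr("X", "X", 2)
  n <- 1e5
  set.seed(7)
  u <- matrix(runif(2 * n), nrow = 2)
  never <- simulate_death(h, rr, "female", NA, NA, u = u)
  always <- simulate_death(h, rr, "female", 0, NA, u = u)
  ratio <- mean(always$death_age) / mean(never$death_age)
  expect_equal(ratio, 0.5, tolerance = 0.01)
})

test_that("event-time inversion is exact on re-integration", {
  w <- synth_world()
  n <- 2000
  for (s in sexes()) {
    set.seed(17)
    hist <- sample_history(w$rates, s, n)
    u <- matrix(runif(2 * n), nrow = 2)
    d <- simulate_death(w$h, w$rr, s, hist$initiation_age, hist$quit_age,
                        causes = w$causes, u = u)
    basis <- smokesim:::hazard_basis(w$h, w$rr, s, as.character(w$causes))
    E <- -log(u[1, ])
    L <- smokesim:::history_cumhaz(basis, hist$initiation_age,
                                   hist$quit_age, d$death_age)
    hit <- d$death_age < max_age(w$h)
    expect_true(any(hit))
    expect_lt(max(abs(L[hit] - E[hit]) / E[hit]), 1e-10)
  }
})

test_that("stochastic engine matches the deterministic oracle", {
  # battery: three histories x three hazard tables
  w <- synth_world()
  tables <- list(
    list(h = const_hazard(0.02, cap = 110), rr = unit_rr("X")),
    list(h = two_cause_hazard(0.005, 0.015, cap = 110),
         rr = current_rr(c("A", "B"), "A", 3, former = c(2.5, 2, 1.5, 1.1))),
    list(h = w$h, rr = w$rr))
  histories <- list(never = c(NA, NA), always = c(17, NA), quit40 = c(17, 40))
  n <- 1e5
  seed <- 23
  for (tb in tables) {
    for (hs in histories) {
      set.seed(seed <- seed + 1)
      u <- matrix(runif(2 * n), nrow = 2)
      d <- simulate_death(tb$h, tb$rr, "male", hs[1], hs[2], u = u)
      sc <- survival_curve(tb$h, tb$rr, "male", hs[1], hs[2],
                           grid_step = 110)
      for (a in c(40, 60, 80)) {
        S <- curve_surv_at(sc, a)
        emp <- mean(d$death_age > a)
        expect_lt(abs(emp - S), 4 * sqrt(S * (1 - S) / n) + 1e-9)
      }
      # cause shares vs oracle cumulative incidence at the cap
      ci <- smokesim:::.curve_ci_at(sc, max_age(tb$h))
      resid <- residual_cause(smokesim:::.default_causes(tb$h, NULL))
      ci[resid] <- ci[resid] + curve_surv_at(sc, max_age(tb$h))
      for (cz in names(ci)) {
        emp <- mean(d$cause == cz)
        expect_lt(abs(emp - ci[[cz]]),
                  4 * sqrt(ci[[cz]] * (1 - ci[[cz]]) / n) + 1e-9)
      }
    }
  }
})

test_that("cohort simulation is reproducible and append-stable", {
  w <- synth_world()
  c1 <- simulate_cohort(800, w$rates, w$h, w$rr, seed = 99)
  c2 <- simulate_cohort(800, w$rates, w$h, w$rr, seed = 99)
  expect_identical(c1, c2)
  # growing the cohort appends individuals without disturbing earlier ones
  c3 <- simulate_cohort(1000, w$rates, w$h, w$rr, seed = 99)
  expect_equal(as.data.frame(c3)[1:800, ], as.data.frame(c1),
               ignore_attr = TRUE)
  # zero initiation: every record is a never smoker
  r0 <- smoking_rates(initiation = c(female = 0, male = 0))
  c0 <- simulate_cohort(500, r0, w$h, w$rr, seed = 1)
  expect_true(all(is.na(c0$initiation_age)))
  # smoking events never at/after death
  expect_true(all(c1$initiation_age < c1$death_age, na.rm = TRUE))
  expect_true(all(c1$quit_age < c1$death_age, na.rm = TRUE))
})

test_that("with all RR = 1 the death-age law is independent of smoking", {
  w <- synth_world()
  n <- 1e5
  chA <- simulate_cohort(n, w$rates, w$h, w$rr0, seed = 31)
  chB <- simulate_cohort(n, no_cessation_rates(c(female = 1, male = 1)),
                         w$h, w$rr0, seed = 32)
  ks <- suppressWarnings(stats::ks.test(chA$death_age, chB$death_age))
  expect_gt(ks$p.value, 0.01)
  # null RR: never-smoker cohort LE equals smoking cohort LE within MC error
  le <- life_expectancy(chA)$le[1]
  c0 <- simulate_cohort(n, smoking_rates(initiation = c(female = 0, male = 0)),
                        w$h, w$rr0, seed = 33)
  le0 <- life_expectancy(c0)$le[1]
  se <- sqrt(var(chA$death_age) / n + var(c0$death_age) / n)
  expect_lt(abs(le - le0), 4 * se)
})

test_that("life expectancy is non-increasing in initiation when RRs >= 1", {
  w <- synth_world()
  les <- vapply(c(0, 0.35, 1), function(p) {
    r <- smoking_rates(initiation = c(female = p, male = p))
    life_expectancy(simulate_cohort(3e4, r, w$h, w$rr, seed = 77))$le[1]
  }, numeric(1))
  expect_true(all(diff(les) < 0))
})

test_that("expected period deaths match closed forms", {
  h <- const_hazard(0.01, cap = 200)
  rr <- unit_rr("X")
  pop <- data.frame(sex = "female", age = 40, state = "never", count = 1e4)
  pd <- simulate_period_deaths(pop, h, rr)
  expect_equal(pd$deaths[pd$sex == "female"], 1e4 * (1 - exp(-0.01)),
               tolerance = 1e-12)
  expect_equal(sum(pd$deaths[pd$sex == "male"]), 0)
  # with RR = 1 the smoking-state composition is irrelevant
  popA <- data.frame(sex = "female", age = 40,
                     state = c("never", "current", "former_5_9"),
                     count = c(5000, 3000, 2000))
  pdA <- simulate_period_deaths(popA, h, rr)
  expect_equal(sum(pdA$deaths), 1e4 * (1 - exp(-0.01)), tolerance = 1e-12)
  # monotone bracketing: 50/50 current (RR 2) vs never lies between extremes
  rr2 <- current_rr("X", "X", 2)
  mix <- simulate_period_deaths(
    data.frame(sex = "male", age = 40, state = c("never", "current"),
               count = c(5000, 5000)), h, rr2)
  all_never <- simulate_period_deaths(
    data.frame(sex = "male", age = 40, state = "never", count = 1e4), h, rr2)
  all_cur <- simulate_period_deaths(
    data.frame(sex = "male", age = 40, state = "current", count = 1e4),
    h, rr2)
  expect_gt(sum(mix$deaths), sum(all_never$deaths))
  expect_lt(sum(mix$deaths), sum(all_cur$deaths))
})

test_that("cohorts persist to CSV with a metadata sidecar", {
  w <- synth_world()
  coh <- simulate_cohort(400, w$rates, w$h, w$rr, seed = 3,
                         causes = w$causes, scenario = "demo")
  p <- file.path(tempdir(), "cohort.csv")
  write_cohort(coh, p, input_hashes = c(hazards = "abc"))
  expect_true(file.exists(paste0(p, ".meta.json")))
  back <- read_cohort(p)
  expect_equal(as.data.frame(back)$death_age, coh$death_age)
  expect_equal(attr(back, "seed"), 3L)
  expect_equal(attr(back, "scenario"), "demo")
  expect_equal(as.character(attr(back, "causes")),
               as.character(w$causes))
})
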