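test_that("life expectancy is the mean death age with its MC error", {
  coh <- structure(data.frame(id = 1:3, sex = c("female", "female", "female"),
                              initiation_age = NA_real_, quit_age = NA_real_,
                              death_age = c(70, 80, 90), cause = "X"),
                   class = c("cohort_result", "data.frame"),
                   seed = 1L, n = 3L, scenario = NA_character_,
                   causes = cause_list("X", "X"))
  le <- life_expectancy(coh)
  expect_equal(le$le[le$sex == "all"], 80)
  expect_equal(le$le[le$sex == "female"], 80)
  expect_equal(le$se[le$sex == "all"], stats::sd(c(70, 80, 90)) / sqrt(3))
  expect_error(life_expectancy(coh[0, ]))
})

test_that("direct standardization weights stratum rates", {
  std <- standard_population(data.frame(
    sex = rep(sexes(), each = 2), age_lo = rep(c(0, 50), 2),
    age_hi = rep(c(50, 110), 2), weight = 0.5))
  x <- data.frame(sex = rep("female", 2), age_lo = c(0, 50),
                  age_hi = c(50, 110), deaths = c(10, 100),
                  py = c(10000, 10000))
  # hand weighted sum: 0.5 * 0.001 + 0.5 * 0.01 = 0.0055
  out <- age_adjusted_mortality(x, std)
  expect_equal(out$rate_per_100k[out$sex == "female"], 550)
  # single band: crude rate times 1e5
  std1 <- standard_population(data.frame(sex = sexes(), age_lo = 0,
                                         age_hi = 110, weight = 1))
  x1 <- data.frame(sex = "male", age_lo = 0, age_hi = 110, deaths = 7,
                   py = 1000)
  expect_equal(age_adjusted_mortality(x1, std1)$rate_per_100k, 700)
  # equal stratum rates: adjusted equals crude whatever the weights
  stdw <- standard_population(data.frame(
    sex = rep(sexes(), each = 2), age_lo = rep(c(0, 50), 2),
    age_hi = rep(c(50, 110), 2), weight = rep(c(0.9, 0.1), 2)))
  xe <- data.frame(sex = rep("female", 2), age_lo = c(0, 50),
                   age_hi = c(50, 110), deaths = c(5, 50),
                   py = c(1000, 10000))
  expect_equal(age_adjusted_mortality(xe, stdw)$rate_per_100k[1], 500)
  # band mismatch errors
  xb <- data.frame(sex = "female", age_lo = 0, age_hi = 60, deaths = 1,
                   py = 100)
  expect_error(age_adjusted_mortality(xb, std), "match")
})

test_that("cause distribution sums to 100 percent per sex", {
  w <- synth_world()
  coh <- simulate_cohort(20000, w$rates, w$h, w$rr, seed = 13,
                         causes = w$causes)
  cd <- cause_distribution(coh)
  for (s in sexes())
    expect_equal(sum(cd$percent[cd$sex == s]), 100, tolerance = 1e-9)
  # two equal constant hazards split 50/50
  h <- two_cause_hazard(0.01, 0.01)
  c2 <- simulate_cohort(20000, w$rates, h, unit_rr(c("A", "B")), seed = 14)
  cd2 <- cause_distribution(c2)
  expect_equal(cd2$percent[cd2$cause == "A" & cd2$sex == "female"], 50,
               tolerance = 4 * sqrt(0.25 / 10000) * 100 / 50)
  # a heavily smoking-loaded cause takes a larger share among smokers
  all_smoke <- run_scenario(3, w$rates, w$h, w$rr, n = 20000, seed = 15,
                            causes = w$causes)
  never_smoke <- run_scenario(6, w$rates, w$h, w$rr, n = 20000, seed = 15,
                              causes = w$causes)
  cds <- cause_distribution(all_smoke)
  cdn <- cause_distribution(never_smoke)
  lung <- function(x, s) x$percent[x$cause == "Lung cancer" & x$sex == s]
  for (s in sexes()) expect_gt(lung(cds, s), lung(cdn, s))
})

test_that("age-adjusted smoking prevalence respects structural extremes", {
  w <- synth_world()
  std <- make_population(w$spec, w$rates)$std
  # zero initiation: all zero
  c6 <- run_scenario(6, w$rates, w$h, w$rr, n = 4000, seed = 16,
                     causes = w$causes)
  p6 <- adjusted_smoking_prevalence(c6, std)
  expect_equal(p6$current_pct, c(0, 0))
  expect_equal(p6$former_pct, c(0, 0))
  # full initiation, no cessation: 100% current among adults
  c3 <- run_scenario(3, w$rates, w$h, w$rr, n = 4000, seed = 16,
                     causes = w$causes)
  p3 <- adjusted_smoking_prevalence(c3, std)
  expect_equal(p3$current_pct, c(100, 100), tolerance = 1e-9)
  # conservation
  c5 <- run_scenario(5, w$rates, w$h, w$rr, n = 4000, seed = 16,
                     causes = w$causes)
  p5 <- adjusted_smoking_prevalence(c5, std)
  expect_equal(p5$current_pct + p5$former_pct + p5$never_pct, c(100, 100),
               tolerance = 1e-9)
})

test_that("quitting earlier yields larger life-years gains", {
  w <- synth_world()
  rr_tables <- list(
    w$rr,
    current_rr(as.character(w$causes), "Lung cancer", 15,
               former = c(8, 4, 2, 1.1)),
    current_rr(as.character(w$causes), "Ischemic heart disease", 2,
               former = c(1.6, 1.4, 1.2, 1.05)))
  for (rrt in rr_tables) {
    g <- quit_age_gain(w$h, rrt, "male", seq(30, 80, by = 10))
    expect_true(all(g$gain_years >= 0))
    expect_true(all(diff(g$gain_years) <= 1e-9))
  }
  # no effect, no gain
  g0 <- quit_age_gain(w$h, w$rr0, "female", c(30, 50, 70))
  expect_equal(g0$gain_years, rep(0, 3), tolerance = 1e-12)
  # quitting just before the cap leaves no time to benefit
  glate <- quit_age_gain(w$h, w$rr, "female", c(30, 109.9))
  expect_lt(glate$gain_years[2], 0.01)
  expect_gt(glate$gain_years[1], glate$gain_years[2])
})

test_that("gain-curve area equals the life-expectancy difference", {
  w <- synth_world()
  pairs <- list(
    c(NA, NA, 17, NA),     # never vs always
    c(17, 40, 17, NA),     # quit-at-40 vs always
    c(NA, NA, 17, 40))     # never vs quit-at-40
  for (s in sexes()) {
    for (p in pairs) {
      a <- survival_curve(w$h, w$rr, s, p[1], p[2], grid_step = 110)
      b <- survival_curve(w$h, w$rr, s, p[3], p[4], grid_step = 110)
      gc <- gain_curve(a, b)
      expect_equal(attr(gc, "delta_le"), a$le - b$le, tolerance = 1e-3)
      expect_equal(attr(gc, "area"), 10000 * (a$le - b$le),
                   tolerance = 1e-3 * 10000)
    }
  }
  # identical scenarios give the zero curve
  sc <- survival_curve(w$h, w$rr, "female", 17, NA, grid_step = 110)
  g0 <- gain_curve(sc, sc)
  expect_true(all(g0$gain == 0))
  expect_equal(attr(g0, "area"), 0)
  # survival dominance: never-vs-always curve is non-negative everywhere
  a <- survival_curve(w$h, w$rr, "male", NA, NA, grid_step = 110)
  b <- survival_curve(w$h, w$rr, "male", 12, NA, grid_step = 110)
  expect_true(all(gain_curve(a, b)$gain >= -1e-12))
})

test_that("the published scenario life expectancies decompose as reported", {
  le <- utils::read.csv(extdata("us2004_scenario_le.csv"))
  dec <- le_decomposition(le)
  g <- function(comp, col) dec[[col]][dec$component == comp]
  # gains already realized since the mid-1900s
  expect_equal(g("realized", "female"), 0.6, tolerance = 1e-9)
  expect_equal(g("realized", "male"), 1.2, tolerance = 1e-9)
  # gains still to come at 2004 rates
  expect_equal(g("pending", "female"), 0.9, tolerance = 1e-9)
  expect_equal(g("pending", "male"), 1.3, tolerance = 1e-9)
  # gains from full elimination
  expect_equal(g("elimination", "female"), 1.2, tolerance = 1e-9)
  expect_equal(g("elimination", "male"), 1.6, tolerance = 1e-9)
  # sex-averaged total potential
  expect_equal(g("total_potential", "average"), 3.4, tolerance = 1e-9)
  expect_error(le_decomposition(le[le$scenario != "s4", ]), "must contain")
})

test_that("scenario_report assembles all summary tables", {
  w <- synth_world()
  std <- make_population(w$spec, w$rates)$std
  res <- list()
  for (id in c("s4", "s5", "s6"))
    res[[id]] <- run_scenario(as.integer(sub("s", "", id)), w$rates, w$h,
                              w$rr, n = 6000, seed = 21, causes = w$causes)
  rep <- scenario_report(res, std,
                         reference_le = data.frame(scenario = "reference",
                                                   female = 80.2,
                                                   male = 75.1))
  expect_named(rep, c("life_expectancy", "age_adjusted_mortality",
                      "cause_distribution", "smoking_prevalence",
                      "le_decomposition"))
  expect_equal(nrow(rep$life_expectancy), 3)
  expect_false(is.null(rep$le_decomposition))
  # single scenario: pairwise decomposition unavailable but no crash
  rep1 <- scenario_report(res["s5"], std)
  expect_null(rep1$le_decomposition)
})
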