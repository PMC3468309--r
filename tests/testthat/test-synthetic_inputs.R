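test_that("generated hazards follow the Gompertz form and validate", {
  spec <- synthetic_spec()
  h <- make_hazards(spec)
  expect_s3_class(h, "hazard_table")
  expect_silent(validate_hazard_table(h, spec_causes(spec)))
  # hand evaluation: level 1e-5, slope 0.09 at band midpoint 80
  spec2 <- synthetic_spec(causes = data.frame(
    cause = "Z", level_female = 1e-5, level_male = 1e-5, slope = 0.09,
    rr_current = 1, rr_former_1 = 1, rr_former_2 = 1, rr_former_3 = 1,
    rr_former_4 = 1))
  h2 <- make_hazards(spec2)
  mid <- (h2$age_lo + h2$age_hi) / 2
  expect_equal(h2$rate_per_py, 1e-5 * exp(0.09 * mid), tolerance = 1e-12)
  expect_equal(1e-5 * exp(0.09 * 80), 0.0134, tolerance = 1e-3)
  # zero slope gives a flat profile
  spec3 <- synthetic_spec(causes = transform(spec2$causes, slope = 0))
  h3 <- make_hazards(spec3)
  expect_equal(length(unique(h3$rate_per_py)), 1)
  # determinism
  expect_identical(make_hazards(synthetic_spec()), make_hazards(spec))
})

test_that("generated RR tables respect the monotone decay constraints", {
  spec <- synthetic_spec()
  rr <- make_rr(spec)
  expect_s3_class(rr, "rr_table")
  expect_silent(validate_rr_table(rr, spec_causes(spec)))
  # echo of the requested decay sequence, in quit-bin order
  spec2 <- synthetic_spec(causes = data.frame(
    cause = "Z", level_female = 1e-5, level_male = 1e-5, slope = 0.08,
    rr_current = 20, rr_former_1 = 9, rr_former_2 = 5, rr_former_3 = 2,
    rr_former_4 = 1.2))
  rr2 <- make_rr(spec2)
  v <- rr2$rr[rr2$sex == "female"][match(smoking_states(),
                                         rr2$state[rr2$sex == "female"])]
  expect_equal(v, c(1, 20, 9, 5, 2, 1.2))
  # null table is all ones
  expect_true(all(make_rr(spec, null = TRUE)$rr == 1))
  # non-monotone decay is rejected
  expect_error(synthetic_spec(causes = transform(spec2$causes,
                                                 rr_former_2 = 10)),
               "monotonically")
})

test_that("generated populations normalize and track the smoking law", {
  spec <- synthetic_spec()
  rates <- smoking_rates()
  pop <- make_population(spec, rates, total = 1e5)
  for (s in sexes())
    expect_equal(sum(pop$std$weight[pop$std$sex == s]), 1, tolerance = 1e-12)
  # composition proportions per (sex, age) sum to the band total
  comp <- pop$composition
  for (s in sexes()) {
    cs <- comp[comp$sex == s, ]
    band_tot <- tapply(cs$count, cs$age, sum)
    w <- pop$std$weight[pop$std$sex == s]
    mid <- (pop$std$age_lo + pop$std$age_hi)[pop$std$sex == s] / 2
    expect_equal(as.numeric(band_tot[as.character(sort(unique(cs$age)))]),
                 1e5 * w[match(sort(unique(cs$age)), mid)],
                 tolerance = 1e-9)
  }
  # zero initiation: all-never composition
  r0 <- smoking_rates(initiation = c(female = 0, male = 0))
  pop0 <- make_population(spec, r0, total = 1e4)
  expect_true(all(pop0$composition$state == "never"))
})

test_that("linked records respect left truncation and the event law", {
  w <- synth_world()
  rec <- make_linked_records(w$spec, w$rates, w$h, w$rr, n = 20000,
                             seed = 12, entry_ages = 60, horizon = 5)
  expect_true(all(rec$exit_age > rec$entry_age))
  expect_true(all(rec$exit_age <= rec$entry_age + 5 + 1e-12))
  # zero horizon: everyone censored at entry is impossible (exit > entry),
  # so use a tiny horizon: event count matches the oracle expectation
  died <- !is.na(rec$event_cause)
  # oracle: mixture over smoking states of conditional death probability
  states <- state_at(rec$initiation_age, rec$quit_age, 60)
  pr <- vapply(seq_len(nrow(rec)), function(i) {
    sc <- survival_curve(w$h, w$rr, rec$sex[i], rec$initiation_age[i],
                         rec$quit_age[i], grid_step = 110)
    1 - curve_surv_at(sc, 65) / curve_surv_at(sc, 60)
  }, numeric(1))
  expected <- sum(pr)
  se <- sqrt(sum(pr * (1 - pr)))
  expect_lt(abs(sum(died) - expected), 4 * se)
  # under null RRs, event rates are independent of smoking state
  rec0 <- make_linked_records(w$spec, w$rates, w$h, w$rr0, n = 20000,
                              seed = 13, entry_ages = 60, horizon = 5)
  st0 <- ifelse(state_at(rec0$initiation_age, rec0$quit_age, 60) == "never",
                "never", "ever")
  tab <- table(st0, !is.na(rec0$event_cause))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
  # determinism
  recA <- make_linked_records(w$spec, w$rates, w$h, w$rr, n = 500, seed = 5)
  recB <- make_linked_records(w$spec, w$rates, w$h, w$rr, n = 500, seed = 5)
  expect_identical(recA, recB)
})

test_that("survey survivors match the conditional death-age law", {
  # left-truncation correctness: among survivors to 60, death ages follow
  # the oracle's conditional distribution (KS test on a never-smoker world)
  h <- const_hazard(0.02, cap = 1000)
  rr <- unit_rr("X")
  spec <- synthetic_spec()
  r0 <- smoking_rates(initiation = c(female = 0, male = 0))
  rec <- make_linked_records(spec, r0, h, rr, n = 15000, seed = 30,
                             entry_ages = 60, horizon = 900)
  d <- rec$exit_age[!is.na(rec$event_cause)]
  # memoryless law: death age - 60 ~ Exp(0.02)
  ks <- suppressWarnings(stats::ks.test(d - 60, "pexp", 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("the fixture emitter writes a complete, reproducible file set", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  cmd_make_fixtures(d1, seed = 4, n_records = 300, quiet = TRUE)
  cmd_make_fixtures(d2, seed = 4, n_records = 300, quiet = TRUE)
  files <- c("hazards.csv", "rr.csv", "rr_null.csv", "smoking_rates.csv",
             "std_population.csv", "population_composition.csv",
             "records.csv", "scenarios.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # everything passes its consumer's validator
  expect_silent(validate_hazard_table(read_hazard_table(
    file.path(d1, "hazards.csv"))))
  expect_silent(validate_rr_table(read_rr_table(file.path(d1, "rr.csv"))))
  expect_s3_class(read_smoking_rates(file.path(d1, "smoking_rates.csv")),
                  "smoking_rates")
  expect_s3_class(read_std_population(file.path(d1, "std_population.csv")),
                  "standard_population")
  expect_length(read_scenarios(file.path(d1, "scenarios.json")), 6)
})
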