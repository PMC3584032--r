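test_that("discounting and mortality conversion follow their closed forms", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 0.970873786408, tolerance = 1e-10)
  expect_equal(discount_factor(c(0, 5, 10), 0), rep(1, 3))
  lt <- make_life_table(list(male = c(a = -log(1 - 0.19), b = 0, g = 0),
                             female = c(a = -log(1 - 0.19), b = 0, g = 0)))
  # q = 0.19 annually -> 0.1 per semester
  expect_equal(mortality_probability(lt, 40, TRUE), 0.1, tolerance = 1e-12)
  expect_equal(mortality_probability(zero_life_table(), 40, TRUE), 0)
  # MRR doubling doubles the hazard, so probability less than doubles
  lt2 <- make_life_table(list(male = c(a = -log(1 - 0.19), b = 0, g = 0),
                              female = c(a = -log(1 - 0.19), b = 0, g = 0)),
                         mrr = 2)
  p1 <- mortality_probability(lt, 40, TRUE)
  p2 <- mortality_probability(lt2, 40, TRUE)
  expect_equal(log(1 - p2), 2 * log(1 - p1), tolerance = 1e-12)
  expect_lt(p2, 2 * p1)
})

test_that("the CKD ramp hits its endpoints and freezes on second line", {
  expect_equal(ckd_probability(1, "lpvr"), 0.0012, tolerance = 1e-12)
  expect_equal(ckd_probability(40, "lpvr"), 0.029, tolerance = 1e-12)
  expect_equal(ckd_probability(1, "atvr1"), 0.0012, tolerance = 1e-12)
  expect_equal(ckd_probability(40, "atvr2"), 0.233, tolerance = 1e-12)
  expect_equal(ckd_probability(20, "lpvr"), 0.00566312403667,
               tolerance = 1e-10)
  # monotone on first line, constant after cycle 40
  risks_path <- ckd_probability(1:60, "atvr1")
  expect_true(all(diff(risks_path[1:40]) > 0))
  expect_equal(risks_path[41:60], rep(0.233, 20), tolerance = 1e-12)
  # second line returns the frozen value untouched
  expect_equal(ckd_probability(55, "lpvr", "second", frozen = 0.0042),
               0.0042)
  expect_error(ckd_probability(55, "lpvr", "second"), "frozen")
})

test_that("CHD risk combines stratum, cholesterol effect and line", {
  p <- default_parameters()
  pat <- list(prior_dm = FALSE, prior_chd = FALSE, chd_history = FALSE,
              line = 1L)
  expect_equal(chd_probability(pat, p$arms$lpvr, p$risks), 0.00165954,
               tolerance = 1e-12)
  pat2 <- pat; pat2$line <- 2L
  expect_equal(chd_probability(pat2, p$arms$lpvr, p$risks), 0.0017)
  pat3 <- list(prior_dm = TRUE, prior_chd = TRUE, chd_history = FALSE,
               line = 2L)
  expect_equal(chd_probability(pat3, p$arms$lpvr, p$risks), 0.0494)
  # a CHD event history moves the patient into the prior-CHD stratum
  pat4 <- list(prior_dm = FALSE, prior_chd = FALSE, chd_history = TRUE,
               line = 2L)
  expect_equal(chd_probability(pat4, p$arms$lpvr, p$risks), 0.0375)
  # the ATV+r arms carry the larger cholesterol benefit
  expect_equal(chd_probability(pat, p$arms$atvr1, p$risks),
               0.0017 * (1 - 0.14 * 0.40), tolerance = 1e-12)
})

test_that("cycle utility takes the worst applicable column and discounts", {
  p <- default_parameters()
  expect_equal(cycle_utility(1, cycle = 1),
               0.9440 * 0.5 * discount_factor(0.25, 0.03),
               tolerance = 1e-12)
  expect_equal(cycle_utility(3, cycle = 1, chd_history = TRUE),
               0.5996 * 0.5 * discount_factor(0.25, 0.03),
               tolerance = 1e-12)
  expect_equal(cycle_utility(2, cycle = 1, line = 2L),
               0.7810 * 0.5 * discount_factor(0.25, 0.03),
               tolerance = 1e-12)
  # an OI in state 1 dominates the baseline weight
  expect_equal(cycle_utility(1, cycle = 1, events = "oi"),
               0.6200 * 0.5 * discount_factor(0.25, 0.03),
               tolerance = 1e-12)
  # later cycles discount more
  expect_lt(cycle_utility(1, cycle = 20), cycle_utility(1, cycle = 1))
})

test_that("cycle cost accrues half the annual state cost plus events", {
  p <- default_parameters()
  expect_equal(cycle_cost(1, cycle = 1),
               11423.24 / 2 * discount_factor(0.25, 0.03),
               tolerance = 1e-9)
  expect_equal(cycle_cost(1, cycle = 1, events = "aids"),
               (11423.24 / 2 + 4684.00) * discount_factor(0.25, 0.03),
               tolerance = 1e-9)
  expect_equal(cycle_cost(1, cycle = 1, alive = FALSE), 0)
  # ATV+r arms use their own state-cost column and AE cost
  expect_equal(cycle_cost(8, cycle = 1, arm = "atvr1", events = "ae"),
               (11425.94 / 2 + 27.61) * discount_factor(0.25, 0.03),
               tolerance = 1e-9)
})

test_that("a cycle with nothing happening only ages the patient", {
  p <- params_events_off()
  pat <- new_patient_record(age = 40, start_state = 3L)
  res <- step_patient(pat, "lpvr", p, matrices = identity_matrices(),
                      lt = zero_life_table())
  expect_true(res$patient$alive)
  expect_equal(res$patient$state, 3L)
  expect_equal(res$patient$age, 40.5)
  expect_equal(res$patient$surv_years, 0.5)
  expect_equal(sum(res$outcome$events), 0)
  expect_gt(res$patient$qaly, 0)   # state utility still accrues
})

test_that("an adverse event switches the line and freezes the CKD risk", {
  p <- params_fixed_demog(params_events_off())
  p$arms$lpvr$ae_risk <- 1      # AE certain
  pat <- new_patient_record(age = 40, start_state = 1L)
  set.seed(5)
  res <- step_patient(pat, "lpvr", p, matrices = identity_matrices(),
                      lt = zero_life_table())
  expect_equal(res$patient$line, 2L)
  expect_true(res$outcome$switched)
  # the frozen risk equals the first-line CKD risk of the switch cycle
  expect_equal(res$patient$frozen_ckd_risk,
               ckd_probability(1, "lpvr", risks = p$risks))
  expect_equal(unname(res$patient$events["ae"]), 1)
})

test_that("two consecutive detectable semesters trigger the switch", {
  p <- params_fixed_demog(params_events_off())
  pat <- new_patient_record(age = 40, start_state = 2L)  # detectable
  tm <- identity_matrices()                              # stays in state 2
  lt <- zero_life_table()
  set.seed(6)
  res1 <- step_patient(pat, "lpvr", p, matrices = tm, lt = lt)
  # entry does not count: after one detectable cycle, still first line
  expect_equal(res1$patient$line, 1L)
  expect_equal(res1$patient$consecutive_detectable, 1L)
  res2 <- step_patient(res1$patient, "lpvr", p, matrices = tm, lt = lt)
  expect_equal(res2$patient$line, 2L)
  expect_true(res2$outcome$events[["two_detectable"]])
  expect_equal(res2$patient$consecutive_detectable, 0L)
  # a suppressed cycle resets the counter
  pat3 <- new_patient_record(age = 40, start_state = 1L)
  res3 <- step_patient(pat3, "lpvr", p, matrices = tm, lt = lt)
  expect_equal(res3$patient$consecutive_detectable, 0L)
  expect_error(step_patient(local({x <- pat; x$alive <- FALSE; x}),
                            "lpvr", p, tm, lt), "dead")
})

test_that("simulation is reproducible under a fixed seed", {
  p <- default_parameters()
  s1 <- simulate_arm("atvr1", n = 400, params = p, seed = 123)
  s2 <- simulate_arm("atvr1", n = 400, params = p, seed = 123)
  expect_identical(s1, s2)
  s3 <- simulate_arm("atvr1", n = 400, params = p, seed = 124)
  expect_false(identical(s1$mean_qaly, s3$mean_qaly))
})

test_that("QALYs equal survival under unit utilities and zero discount", {
  p <- params_unit_utility(params_events_off())
  set.seed(77)
  cohort <- generate_baseline_cohort(2000, p$demographics)
  res <- run_microsim("lpvr", cohort, p)
  expect_equal(res$patients$qaly, res$patients$surv_years,
               tolerance = 1e-12)
})

test_that("discounted QALY <= undiscounted QALY <= survival per patient", {
  s <- simulate_arm("lpvr", n = 3000, seed = 42)
  expect_lt(s$mean_qaly, s$mean_qaly_undiscounted)
  expect_lt(s$mean_qaly_undiscounted, s$mean_survival)
  # and the summary identities hold
  expect_equal(s$cost_per_qaly, s$mean_lifetime_cost / s$mean_qaly)
  expect_equal(s$per_capita_annual_cost,
               s$mean_lifetime_cost / s$mean_survival)
})

test_that("with all risks off, survival matches the life-table oracle", {
  p <- params_fixed_demog(params_events_off())
  n <- 30000
  s <- simulate_arm("lpvr", n = n, params = p, seed = 2718)
  le <- life_expectancy(life_table_from_params(p),
                        p$demographics$age_mean, "male")
  # binomial-ish spread of individual lifetimes
  se <- sqrt(90) / sqrt(n)  # crude upper bound on sd(years)/sqrt(n)
  expect_lt(abs(s$mean_survival - le), 3 * se)
})

test_that("the OI event rate is a constant-hazard property, life-table free", {
  p <- params_fixed_demog(default_parameters())
  lt_alt <- make_life_table(
    list(male = c(a = 5e-4, b = 5e-5, g = 0.085),
         female = c(a = 3e-4, b = 2e-5, g = 0.09)), mrr = 5)
  s1 <- simulate_arm("lpvr", n = 20000, params = p, seed = 31)
  s2 <- simulate_arm("lpvr", n = 20000, params = p, seed = 31, lt = lt_alt)
  expect_lt(abs(s1$oi_per_1000py - s2$oi_per_1000py), 1.5)
  expect_lt(abs(s1$oi_per_1000py - 35.2), 1.5)
})

test_that("CKD risk freezing shows up in the event rates", {
  # ATV+r first line ramps to 23.3%/semester; patients forced to switch
  # early keep a tiny frozen risk instead
  p <- params_fixed_demog(params_events_off())
  p$risks$ckd_ramp$atvr[c("start", "end")] <- c(0.0012, 0.233)
  early <- p
  early$arms$atvr1$ae_risk <- 1      # switch at cycle 1, freeze at 0.0012
  s_stay <- simulate_arm("atvr1", n = 4000, params = p, seed = 8)
  s_early <- simulate_arm("atvr1", n = 4000, params = early, seed = 8)
  expect_gt(s_stay$ckd_per_1000py, 10 * s_early$ckd_per_1000py)
  expect_lt(abs(s_early$ckd_per_1000py - 1000 * 0.0012 / 0.5), 1.0)
})
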