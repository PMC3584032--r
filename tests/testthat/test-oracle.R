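test_that("mass is conserved and death mass never shrinks", {
  p <- default_parameters()
  traj <- occupancy_recursion(p, "lpvr", n_cycles = 60)
  total <- rowSums(traj$occ1) + rowSums(traj$occ2) + traj$dead
  expect_equal(total, rep(1, 60), tolerance = 1e-12)
  expect_true(all(diff(traj$dead) >= -1e-15))
})

test_that("identity matrix and no mortality keep the mass in place", {
  p <- params_fixed_demog(params_events_off())
  start <- c(0, 0, 0, 1, 0, 0, 0, 0)  # state 4, detectable
  traj <- occupancy_recursion(p, "lpvr", n_cycles = 5,
                              start_state_probs = start,
                              matrices = identity_matrices(),
                              lt = zero_life_table())
  # cycle 1: entry counter is 0, no switch yet; from cycle 2 the
  # detectable-detectable rule moves everyone to second line at once
  expect_equal(traj$occ1[1, ], start, tolerance = 1e-12)
  expect_equal(traj$occ2[2, ], start, tolerance = 1e-12)
  expect_equal(traj$occ2[5, ], start, tolerance = 1e-12)
  expect_equal(traj$dead, rep(0, 5), tolerance = 1e-15)
  # a suppressed state never switches and never moves
  start_odd <- c(0, 0, 1, 0, 0, 0, 0, 0)
  traj2 <- occupancy_recursion(p, "lpvr", n_cycles = 5,
                               start_state_probs = start_odd,
                               matrices = identity_matrices(),
                               lt = zero_life_table())
  expect_equal(traj2$occ1[5, ], start_odd, tolerance = 1e-12)
})

test_that("a two-state chain converges geometrically to its closed form", {
  # embed a two-state chain on the suppressed states 1 and 3 (odd states
  # cannot trigger the detectable-VL switch), no mortality
  a <- 0.3; b <- 0.2
  m <- diag(8)
  m[1, 1] <- 1 - a; m[1, 3] <- a
  m[3, 3] <- 1 - b; m[3, 1] <- b
  tm <- identity_matrices()
  for (k in names(tm$matrices)) tm$matrices[[k]] <- m
  p <- params_fixed_demog(params_events_off())
  traj <- occupancy_recursion(p, "lpvr", n_cycles = 30,
                              start_state_probs = c(1, 0, 0, 0, 0, 0, 0, 0),
                              matrices = tm, lt = zero_life_table())
  # closed form: x_t(1) = pi1 + (1 - a - b)^t (1 - pi1), pi1 = b/(a+b)
  pi1 <- b / (a + b)
  for (t in c(1, 2, 5, 10, 30)) {
    expect_equal(traj$occ1[t, 1], pi1 + (1 - a - b)^t * (1 - pi1),
                 tolerance = 1e-12)
    expect_equal(traj$occ1[t, 3], 1 - traj$occ1[t, 1], tolerance = 1e-12)
  }
})

test_that("expected outcomes are the expected linear functionals", {
  p <- params_fixed_demog(params_events_off())
  traj <- occupancy_recursion(p, "lpvr", n_cycles = 120)
  # zero costs give zero expected cost
  p0 <- p
  p0$costs$hs_annual[] <- 0
  p0$costs$event[] <- 0
  expect_equal(expected_outcomes(traj, p0)$cost, 0)
  # unit utilities and no discounting collapse QALY onto survival
  pu <- params_unit_utility(p)
  eo <- expected_outcomes(traj, pu)
  expect_equal(eo$qaly, eo$survival, tolerance = 1e-10)
  expect_error(occupancy_recursion(p, events = "chd"), "does not support")
})

test_that("oracle matches the microsimulation with OI and AE processes on", {
  p <- params_fixed_demog(params_events_off())
  p$risks$oi <- 0.0176
  p$arms$lpvr$ae_risk <- 0.0176
  tm <- build_arm_matrices(p)
  lt <- life_table_from_params(p)
  n <- 40000
  set.seed(1234)
  cohort <- generate_baseline_cohort(n, p$demographics)
  res <- run_microsim("lpvr", cohort, p, tm, lt, occupancy = TRUE)
  traj <- occupancy_recursion(p, "lpvr", n_cycles = res$cycles,
                              events = c("oi", "ae"),
                              matrices = tm, lt = lt)
  for (cyc in c(1, 10, 40)) {
    sim <- res$occupancy[cyc, ] / n
    ora <- c(traj$occ1[cyc, ], traj$occ2[cyc, ], traj$dead[cyc])
    se <- sqrt(pmax(ora * (1 - ora), 1e-12) / n)
    expect_true(all(abs(sim - ora) < 3.5 * se + 1e-9),
                label = sprintf("occupancy at cycle %d", cyc))
  }
  eo <- expected_outcomes(traj, p)
  for (v in list(c("survival", "surv_years"), c("qaly", "qaly"),
                 c("cost", "cost"))) {
    sim_v <- res$patients[[v[2]]]
    se <- sd(sim_v) / sqrt(n)
    expect_lt(abs(mean(sim_v) - eo[[v[1]]]), 3.5 * se,
              label = paste("mean", v[1]))
  }
})

test_that("occupancy trajectories export to CSV", {
  traj <- occupancy_recursion(default_parameters(), n_cycles = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occupancy(traj, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 10)
  expect_equal(df$alive + df$dead, rep(1, 10), tolerance = 1e-9)
})
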