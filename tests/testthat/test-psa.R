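test_that("distribution draws have the right support and moments", {
  draw <- hivcea:::.draw_spec
  set.seed(99)
  n <- 20000
  # Beta(8, 448): mean alpha/(alpha+beta)
  x <- replicate(n, draw(list(family = "beta", shape1 = 8, shape2 = 448)))
  expect_lt(abs(mean(x) - 8 / 456), 3 * sd(x) / sqrt(n))
  expect_true(all(x > 0 & x < 1))
  # Uniform(0.254, 0.454): mean at the base-case CHD fatality
  y <- replicate(n, draw(list(family = "uniform", min = 0.254, max = 0.454)))
  expect_true(all(y >= 0.254 & y <= 0.454))
  expect_lt(abs(mean(y) - 0.354), 3 * sd(y) / sqrt(n))
  # truncated normal never exceeds its upper bound, mean below raw mean
  z <- replicate(n, draw(list(family = "normal", mean = -0.17, sd = 1.56,
                              upper = 0)))
  expect_true(all(z <= 0))
  expect_lt(mean(z), -0.17)
  # relative-uniform multiplier
  m <- replicate(n, draw(list(family = "uniform_rel", rel = 0.10)))
  expect_true(all(m >= 0.9 & m <= 1.1))
})

test_that("sampled parameter sets stay valid and keep ties", {
  base <- default_parameters()
  set.seed(7)
  for (i in 1:25) {
    p <- sample_parameter_set(base)
    expect_length(validate_parameters(p), 0)
    # second-line utility re-tied to the sampled state-7 weight
    expect_equal(p$utilities$second_line, p$utilities$hs[7])
    # shared draws: the two ATV+r arms move together
    expect_equal(p$arms$atvr1$ae_risk, p$arms$atvr2$ae_risk)
    expect_equal(p$arms$atvr1$tc_hdl_effect, p$arms$atvr2$tc_hdl_effect)
    expect_lte(p$arms$lpvr$tc_hdl_effect, 0)
    expect_true(p$arms$atvr2$vl_reduction >= 0.09 &&
                p$arms$atvr2$vl_reduction <= 0.29)
    # unlisted parameters untouched
    expect_equal(p$risks$aids, base$risks$aids)
    expect_equal(p$costs$event[["aids"]], base$costs$event[["aids"]])
  }
  # with no specs the base case comes back unchanged
  expect_equal(unclass(sample_parameter_set(base, list())), unclass(base))
})

test_that("ICER-plane classification covers every quadrant", {
  cl <- function(...) classify_icer_point(...)
  expect_equal(cl(-100, 0.1)$category, "dominant")
  expect_true(cl(-100, 0.1)$cost_effective)
  r <- cl(2000, 0.1, wtp = 25000)
  expect_equal(r$icer, 20000)
  expect_equal(r$category, "ne_icer_below_wtp")
  expect_true(r$cost_effective)
  expect_equal(cl(4000, 0.1, wtp = 25000)$category, "ne_icer_above_wtp")
  expect_equal(cl(100, -0.1)$category, "dominated")
  expect_false(cl(100, -0.1)$cost_effective)
  # south-west: paying less, losing little -> acceptable above WTP
  sw <- cl(-4000, -0.1, wtp = 25000)
  expect_equal(sw$category, "sw_icer_above_wtp")
  expect_true(sw$cost_effective)
  expect_equal(cl(-1000, -0.1, wtp = 25000)$category, "sw_icer_below_wtp")
  expect_equal(cl(0, 0)$category, "indifferent")
  expect_true(is.na(cl(500, 0)$icer))
})

test_that("PSA runs are reproducible and category fractions sum to one", {
  base <- default_parameters()
  r1 <- run_psa(base, n_outer = 5, n_inner = 150, seed = 11)
  r2 <- run_psa(base, n_outer = 5, n_inner = 150, seed = 11)
  expect_identical(r1$points, r2$points)
  expect_equal(sum(r1$summary$category_fractions), 1, tolerance = 1e-12)
  expect_equal(nrow(r1$points), 5)
  expect_equal(
    r1$summary$fraction_cost_effective,
    sum(r1$summary$category_fractions[c("dominant", "ne_icer_below_wtp",
                                        "sw_icer_above_wtp")]),
    tolerance = 1e-12)
})

test_that("an arm compared against itself is centred on zero", {
  base <- default_parameters()
  r <- run_psa(base, specs = list(), intervention = "lpvr",
               comparator = "lpvr", n_outer = 8, n_inner = 200,
               seed = 21, crn = TRUE)
  # common random numbers + identical arm: deltas vanish exactly
  expect_equal(r$points$delta_cost, rep(0, 8))
  expect_equal(r$points$delta_qaly, rep(0, 8))
})

test_that("common random numbers shrink the incremental variance", {
  base <- default_parameters()
  crn <- run_psa(base, specs = list(), n_outer = 12, n_inner = 250,
                 seed = 5, crn = TRUE)
  ind <- run_psa(base, specs = list(), n_outer = 12, n_inner = 250,
                 seed = 5, crn = FALSE)
  # with no parameter uncertainty the spread of deltas is pure inner-loop
  # noise; pairing the streams must reduce it
  expect_lt(var(crn$points$delta_qaly), var(ind$points$delta_qaly))
  expect_lt(var(crn$points$delta_cost), var(ind$points$delta_cost))
})

test_that("the CEAC is a proper acceptability curve", {
  pts <- data.frame(delta_cost = c(2000, -500, 1000),
                    delta_qaly = c(0.1, 0.05, 0.2))
  grid <- seq(0, 50000, by = 1000)
  curve <- ceac_curve(pts, grid)
  # all delta_qaly > 0: non-decreasing in WTP, reaching 1
  expect_true(all(diff(curve$prob_cost_effective) >= 0))
  expect_equal(curve$prob_cost_effective[length(grid)], 1)
  # at WTP 0 only the cost-saving draw is acceptable
  expect_equal(curve$prob_cost_effective[1], 1 / 3)
  # single point steps from 0 to 1 exactly at its ICER
  single <- data.frame(delta_cost = 2000, delta_qaly = 0.1)
  expect_equal(ceac_curve(single, c(19999, 20001))$prob_cost_effective,
               c(0, 1))
})
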