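# Probabilistic sensitivity analysis: parameter sampling, outer/inner
# Monte-Carlo loops with common random numbers, ICER-plane classification
# and cost-effectiveness acceptability curves.

#' Default PSA distribution specifications
#'
#' One entry per varied parameter. Families: `uniform` (min/max),
#' `uniform_rel` (multiplier drawn from `1 +- rel` applied to the base
#' value), `normal` (mean/sd, optionally truncated above at `upper`),
#' `beta` (shape1/shape2). A spec whose `paths` field lists several
#' parameter paths applies one common draw to all of them (the two ATV+r
#' arms share their adverse-event risk, cholesterol effect, and the two
#' CKD ramps are varied jointly).
#'
#' Defaults: CHD case fatality Uniform(0.254, 0.454); diarrhoea risk
#' Beta(8, 448); hyperbilirubinemia risk Beta(3, 189); OI risk
#' Beta(11, 637); CKD risk +-10%; TC:HDL effects Normal(-0.17, 1.56) and
#' Normal(-0.40, 2.82), truncated at 0 (a positive "effect" would invert
#' the 14%-per-unit reduction); detectable-VL reduction of the
#' trial-adjusted arm Uniform(0.09, 0.29) in magnitude; state utility
#' weights +-5%; CHD and event utility columns +-10%; state costs +-3%;
#' CHD cost +-20%; CKD cost +-5%; OI cost +-10%.
#'
#' @return A named list of spec lists with fields `paths`, `family` and the
#'   family's parameters.
#' @export
default_psa_specs <- function() {
  sp <- function(paths, family, ...)
    c(list(paths = paths, family = family), list(...))
  list(
    chd_fatal = sp("risks.chd_fatal", "uniform", min = 0.254, max = 0.454),
    diarrhoea_risk = sp("arms.lpvr.ae_risk", "beta",
                        shape1 = 8, shape2 = 448),
    hyperbilirubinemia_risk = sp(c("arms.atvr1.ae_risk",
                                   "arms.atvr2.ae_risk"), "beta",
                                 shape1 = 3, shape2 = 189),
    oi_risk = sp("risks.oi", "beta", shape1 = 11, shape2 = 637),
    ckd_risk = sp(c("risks.ckd_ramp.lpvr", "risks.ckd_ramp.atvr"),
                  "uniform_rel", rel = 0.10),
    tc_hdl_lpvr = sp("arms.lpvr.tc_hdl_effect", "normal",
                     mean = -0.17, sd = 1.56, upper = 0),
    tc_hdl_atvr = sp(c("arms.atvr1.tc_hdl_effect",
                       "arms.atvr2.tc_hdl_effect"), "normal",
                     mean = -0.40, sd = 2.82, upper = 0),
    vl_reduction = sp("arms.atvr2.vl_reduction", "uniform",
                      min = 0.09, max = 0.29),
    hs_utility = sp("utilities.hs", "uniform_rel", rel = 0.05),
    chd_utility = sp("utilities.hs_chd", "uniform_rel", rel = 0.10),
    diarrhoea_utility = sp("utilities.event.diarrhoea", "uniform_rel",
                           rel = 0.10),
    hyperbilirubinemia_utility = sp("utilities.event.hyperbilirubinemia",
                                    "uniform_rel", rel = 0.10),
    ckd_utility = sp("utilities.event.ckd", "uniform_rel", rel = 0.10),
    aids_utility = sp("utilities.event.aids", "uniform_rel", rel = 0.10),
    oi_utility = sp("utilities.event.oi", "uniform_rel", rel = 0.10),
    hs_cost = sp("costs.hs_annual", "uniform_rel", rel = 0.03),
    chd_cost = sp("costs.event.chd", "uniform_rel", rel = 0.20),
    ckd_cost = sp("costs.event.ckd", "uniform_rel", rel = 0.05),
    oi_cost = sp("costs.event.oi", "uniform_rel", rel = 0.10)
  )
}

.draw_spec <- function(spec) {
  switch(spec$family,
    uniform = runif(1, spec$min, spec$max),
    uniform_rel = runif(1, 1 - spec$rel, 1 + spec$rel),
    beta = rbeta(1, spec$shape1, spec$shape2),
    normal = {
      lo <- if (is.null(spec$lower)) 0 else pnorm(spec$lower, spec$mean,
                                                  spec$sd)
      hi <- if (is.null(spec$upper)) 1 else pnorm(spec$upper, spec$mean,
                                                  spec$sd)
      qnorm(runif(1, lo, hi), spec$mean, spec$sd)  # truncated normal
    },
    stop("unknown distribution family: ", spec$family)
  )
}

.apply_draw <- function(p, spec, value) {
  for (path in spec$paths) {
    keys <- strsplit(path, ".", fixed = TRUE)[[1]]
    cur <- .get_path(p, keys)
    new <- if (spec$family == "uniform_rel") cur * value else value
    if (is.numeric(cur) && length(cur) > 0 &&
        !is.matrix(cur) && all(cur >= 0) && all(cur <= 1) &&
        spec$family == "uniform_rel")
      new <- pmin(pmax(new, 0), 1)   # clip sampled probabilities/weights
    p <- .set_path(p, keys, new)
  }
  p
}

#' Draw one parameter set for the PSA
#'
#' Redraws every parameter listed in `specs` from its distribution; all
#' other parameters keep their base-case values. Sampled probabilities and
#' utility weights are clipped to \[0, 1\]; the flat second-line utility is
#' re-tied to the (sampled) state-7 weight. If the sampled set fails
#' validation it is redrawn, up to `retries` times.
#'
#' @param base the base `cea_params`.
#' @param specs list of distribution specs (see [default_psa_specs()]).
#' @param retries bounded number of resampling attempts.
#' @return A validated `cea_params`.
#' @export
#' @examples
#' set.seed(1)
#' p <- sample_parameter_set(default_parameters())
sample_parameter_set <- function(base, specs = default_psa_specs(),
                                 retries = 20) {
  for (att in seq_len(retries)) {
    p <- base
    for (spec in specs) p <- .apply_draw(p, spec, .draw_spec(spec))
    p$utilities$second_line <- p$utilities$hs[7]
    p$utilities$hs[8] <- p$utilities$hs[7]
    viol <- validate_parameters(p)
    if (!length(viol)) return(p)
  }
  stop("could not draw a valid parameter set after ", retries,
       " attempts:\n  - ", paste(viol, collapse = "\n  - "))
}

#' Classify a point on the incremental cost-effectiveness plane
#'
#' Classifies the incremental cost and QALY of an intervention against its
#' comparator at a willingness-to-pay (WTP) threshold. Categories:
#' `dominant` (cheaper, more effective); `ne_icer_below_wtp` /
#' `ne_icer_above_wtp` (more effective, more costly, ICER below/above WTP);
#' `sw_icer_above_wtp` / `sw_icer_below_wtp` (less effective, cheaper —
#' acceptable when the savings per QALY forgone exceed WTP); `dominated`
#' (more costly, less effective); `indifferent` (both deltas zero). The
#' intervention is cost-effective when dominant, in the north-east with
#' ICER < WTP, or in the south-west with ICER > WTP.
#'
#' @param delta_cost incremental cost (euro), vectorised.
#' @param delta_qaly incremental QALYs, vectorised.
#' @param wtp willingness-to-pay threshold (euro/QALY, > 0).
#' @return A data frame with `delta_cost`, `delta_qaly`, `icer` (`NA` when
#'   `delta_qaly` is 0), `category` and `cost_effective`.
#' @export
#' @examples
#' classify_icer_point(2000, 0.1, 25000)  # ICER 20000, cost-effective
classify_icer_point <- function(delta_cost, delta_qaly, wtp = 25000) {
  stopifnot(wtp > 0)
  icer <- ifelse(delta_qaly == 0, NA_real_, delta_cost / delta_qaly)
  category <- rep("indifferent", length(icer))
  category[delta_qaly > 0 & delta_cost <= 0] <- "dominant"
  category[delta_qaly > 0 & delta_cost > 0 & icer < wtp] <- "ne_icer_below_wtp"
  category[delta_qaly > 0 & delta_cost > 0 & icer >= wtp] <- "ne_icer_above_wtp"
  category[delta_qaly < 0 & delta_cost < 0 & icer > wtp] <- "sw_icer_above_wtp"
  category[delta_qaly < 0 & delta_cost < 0 & icer <= wtp] <- "sw_icer_below_wtp"
  category[delta_qaly < 0 & delta_cost >= 0] <- "dominated"
  category[delta_qaly == 0 & delta_cost < 0] <- "dominant"
  category[delta_qaly == 0 & delta_cost > 0] <- "dominated"
  ce <- category %in% c("dominant", "ne_icer_below_wtp", "sw_icer_above_wtp")
  data.frame(delta_cost = delta_cost, delta_qaly = delta_qaly, icer = icer,
             category = category, cost_effective = ce,
             stringsAsFactors = FALSE)
}

#' Run the probabilistic sensitivity analysis
#'
#' Outer loop: draw a parameter set from `specs`. Inner loop: simulate both
#' arms on the sampled set; with `crn = TRUE` both arms share the same
#' random-number stream (same cohort, same event uniforms), which removes
#' between-arm sampling noise from the incremental estimates. Each outer
#' draw yields one point on the ICER plane.
#'
#' @param base the base `cea_params`.
#' @param specs distribution specs; [default_psa_specs()] by default.
#' @param intervention,comparator arm keys for the comparison (deltas are
#'   intervention minus comparator).
#' @param n_outer number of parameter draws (200 in the full analysis).
#' @param n_inner patients per simulation (5000 in the full analysis).
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @param seed integer seed governing all randomness.
#' @param crn use common random numbers across the two arms of each draw.
#' @return A list of class `cea_psa` with `points` (one row per draw:
#'   deltas, ICER, category), `summary` (fraction per category and fraction
#'   cost-effective at `wtp`), and the run settings.
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), n_outer = 4, n_inner = 100, seed = 1)
#' psa$summary$fraction_cost_effective
run_psa <- function(base, specs = default_psa_specs(),
                    intervention = "lpvr", comparator = "atvr1",
                    n_outer = 200, n_inner = 5000,
                    wtp = base$economics$wtp_threshold, seed = 1L,
                    crn = TRUE) {
  stopifnot(n_outer >= 1, n_inner >= 1)
  set.seed(seed)
  # derive per-draw seeds below 2^31
  draw_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_outer)
  rows <- vector("list", n_outer)
  for (i in seq_len(n_outer)) {
    set.seed(draw_seeds[i])
    p_i <- sample_parameter_set(base, specs)
    tm_i <- build_arm_matrices(p_i)
    lt_i <- life_table_from_params(p_i)
    s_a <- draw_seeds[n_outer + i]
    s_b <- if (crn) s_a else s_a + 1L
    sum_a <- simulate_arm(intervention, n_inner, p_i, seed = s_a,
                          matrices = tm_i, lt = lt_i)
    sum_b <- simulate_arm(comparator, n_inner, p_i, seed = s_b,
                          matrices = tm_i, lt = lt_i)
    rows[[i]] <- data.frame(
      draw = i,
      delta_cost = sum_a$mean_lifetime_cost - sum_b$mean_lifetime_cost,
      delta_qaly = sum_a$mean_qaly - sum_b$mean_qaly
    )
  }
  pts <- do.call(rbind, rows)
  cls <- classify_icer_point(pts$delta_cost, pts$delta_qaly, wtp)
  pts <- cbind(pts["draw"], cls)
  cats <- c("dominant", "ne_icer_below_wtp", "ne_icer_above_wtp",
            "sw_icer_above_wtp", "sw_icer_below_wtp", "dominated",
            "indifferent")
  frac <- vapply(cats, function(k) mean(pts$category == k), numeric(1))
  out <- list(
    points = pts,
    summary = list(category_fractions = frac,
                   fraction_cost_effective = mean(pts$cost_effective)),
    intervention = intervention, comparator = comparator,
    n_outer = n_outer, n_inner = n_inner, wtp = wtp, seed = seed, crn = crn
  )
  class(out) <- "cea_psa"
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws in which the intervention has positive net
#' monetary benefit (`delta_qaly * wtp - delta_cost > 0`) at each
#' willingness-to-pay value.
#'
#' @param points data frame with `delta_cost` and `delta_qaly` (e.g.
#'   `run_psa(...)$points`), or a `cea_psa` object.
#' @param wtp_grid vector of willingness-to-pay values (euro/QALY).
#' @return A data frame with `wtp` and `prob_cost_effective`.
#' @export
ceac_curve <- function(points, wtp_grid = seq(0, 100000, by = 2500)) {
  if (inherits(points, "cea_psa")) points <- points$points
  stopifnot(nrow(points) >= 1)
  prob <- vapply(wtp_grid, function(w)
    mean(points$delta_qaly * w - points$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %s vs %s: %d draws x %d patients (WTP %s, %s)\n",
              x$intervention, x$comparator, x$n_outer, x$n_inner,
              format(x$wtp, big.mark = ","),
              if (x$crn) "common random numbers" else "independent streams"))
  fr <- x$summary$category_fractions
  for (k in names(fr)) if (fr[[k]] > 0)
    cat(sprintf("  %-20s %5.1f%%\n", k, 100 * fr[[k]]))
  cat(sprintf("  cost-effective at WTP: %.1f%%\n",
              100 * x$summary$fraction_cost_effective))
  invisible(x)
}
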