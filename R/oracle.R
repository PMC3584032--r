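# Deterministic cohort-level Markov recursion: the independent test oracle
# for the stochastic engine. It computes exact expectations of the
# microsimulation for a cohort of identical patients (one age, one sex)
# under a restricted event model:
#   - background mortality, state transitions and line switching (both the
#     two-consecutive-detectable rule and the AE switch hazard) are exact;
#   - OI and AIDS events (with zero AIDS case fatality) enter expectations
#     exactly because their draws are independent of patient history;
#   - CHD (whose history changes future risk and utility) and CKD (whose
#     second-line risk is frozen at the switch cycle) are deliberately
#     omitted: the oracle must be provably exact where it is used, so
#     equivalence tests disable them.
# The two-consecutive-detectable switch is Markov in (state, line): a
# first-line patient's detectable-cycle counter is 1 exactly when the
# current state is detectable (a counter of 2 would already have switched),
# except on entry, where the counter starts at 0.

#' Deterministic occupancy recursion
#'
#' Propagates the exact state-occupancy distribution of a cohort of
#' identical patients through the semestral model, tracking first line (8
#' states), second line (8 states) and death, with the switching rules
#' applied in expectation.
#'
#' @param params a `cea_params` list.
#' @param arm arm key (`"lpvr"`, `"atvr1"`, `"atvr2"`).
#' @param n_cycles number of cycles to run (>= 1).
#' @param age,sex the cohort's common age and sex.
#' @param start_state_probs initial distribution over the 8 states.
#' @param events character vector among `"oi"`, `"aids"`, `"ae"` naming the
#'   event processes to include; everything else is off.
#' @param matrices,lt optional prebuilt transition matrices / life table.
#' @return A list of class `cea_occupancy`: per-cycle end-of-cycle masses
#'   `occ1`, `occ2` (matrices `n_cycles` x 8), `dead`, `alive`, the accrual
#'   decomposition (`stay1`, `to2_two`, `to2_ae`, `occ2_cont`), and the run
#'   settings.
#' @export
#' @examples
#' traj <- occupancy_recursion(default_parameters(), n_cycles = 10)
#' rowSums(traj$occ1) + rowSums(traj$occ2) + traj$dead  # all 1
occupancy_recursion <- function(params, arm = "lpvr", n_cycles = 40,
                                age = params$demographics$age_mean,
                                sex = "male",
                                start_state_probs =
                                  params$demographics$start_state_probs,
                                events = character(),
                                matrices = NULL, lt = NULL) {
  stopifnot(n_cycles >= 1, length(start_state_probs) == 8,
            abs(sum(start_state_probs) - 1) < 1e-9)
  bad <- setdiff(events, c("oi", "aids", "ae"))
  if (length(bad))
    stop("oracle does not support event process(es): ",
         paste(bad, collapse = ", "))
  if ("aids" %in% events && params$risks$aids_case_fatality > 0)
    stop("oracle supports AIDS events only with zero case fatality")
  if (is.null(matrices)) matrices <- build_arm_matrices(params)
  if (is.null(lt)) lt <- life_table_from_params(params)
  M1 <- matrices$matrices[[arm]]
  M2 <- matrices$matrices$second
  ae_risk <- if ("ae" %in% events) params$arms[[arm]]$ae_risk else 0
  det <- state_is_detectable(1:8)
  male <- sex == "male"

  occ1 <- start_state_probs
  occ2 <- numeric(8)
  dead <- 0
  Z <- function() matrix(0, n_cycles, 8)
  out <- list(occ1 = Z(), occ2 = Z(), stay1 = Z(), to2_two = Z(),
              to2_ae = Z(), occ2_cont = Z(),
              dead = numeric(n_cycles), alive = numeric(n_cycles))

  for (cyc in seq_len(n_cycles)) {
    p_mort <- mortality_probability(lt, age + (cyc - 1) * 0.5, male)
    a1 <- occ1 * (1 - p_mort)            # first-line survivors of mortality
    a2 <- occ2 * (1 - p_mort)
    dead <- dead + (sum(occ1) + sum(occ2)) * p_mort
    # flows by (source, destination); det-det flows switch with certainty
    # from cycle 2 onward (counter is 1 in any detectable state after the
    # first cycle; on entry it is 0)
    Fl <- a1 * M1                         # rows scaled by source mass
    mask <- if (cyc >= 2) outer(det, det, `&`) else matrix(FALSE, 8, 8)
    flow_two <- colSums(Fl * mask)        # switch regardless of AE
    flow_rest <- colSums(Fl * !mask)
    stay1 <- flow_rest * (1 - ae_risk)
    to2_ae <- (flow_two + flow_rest) * ae_risk
    to2_two <- flow_two * (1 - ae_risk)
    occ2_cont <- as.numeric(crossprod(M2, a2))
    occ1 <- stay1
    occ2 <- occ2_cont + to2_two + to2_ae
    out$occ1[cyc, ] <- occ1
    out$occ2[cyc, ] <- occ2
    out$stay1[cyc, ] <- stay1
    out$to2_two[cyc, ] <- to2_two
    out$to2_ae[cyc, ] <- to2_ae
    out$occ2_cont[cyc, ] <- occ2_cont
    out$dead[cyc] <- dead
    out$alive[cyc] <- sum(occ1) + sum(occ2)
  }
  out$n_cycles <- n_cycles
  out$arm <- arm
  out$events <- events
  out$age <- age
  out$sex <- sex
  class(out) <- "cea_occupancy"
  out
}

# Expected utility weight for a group with pre-event weight w0 in state s,
# under independent OI and AIDS draws combined by minimum.
.expected_weight <- function(w0, u, p_oi, p_aids) {
  (1 - p_oi) * (1 - p_aids) * w0 +
    p_oi * (1 - p_aids) * pmin(w0, u$event$oi) +
    (1 - p_oi) * p_aids * pmin(w0, u$event$aids) +
    p_oi * p_aids * pmin(w0, u$event$oi, u$event$aids)
}

#' Expected outcomes from an occupancy trajectory
#'
#' Deterministic linear functionals of the occupancy: expected discounted
#' cost, expected discounted QALY and expected (undiscounted) survival,
#' under the same accrual conventions as the microsimulation.
#'
#' @param traj a `cea_occupancy` from [occupancy_recursion()].
#' @param params the `cea_params` the trajectory was built from.
#' @return A list with `cost`, `qaly`, `survival`.
#' @export
expected_outcomes <- function(traj, params) {
  u <- params$utilities
  if (!identical(u$combine, "minimum"))
    stop("the oracle implements the minimum utility combination only")
  arm <- traj$arm
  hs_cost <- params$costs$hs_annual[, if (arm == "lpvr") "lpvr" else "atvr"]
  ev_cost <- params$costs$event
  ae_name <- params$arms[[arm]]$primary_ae
  p_oi <- if ("oi" %in% traj$events) params$risks$oi else 0
  p_aids <- if ("aids" %in% traj$events) params$risks$aids else rep(0, 8)
  w_first <- .expected_weight(u$hs, u, p_oi, p_aids)
  w_second <- .expected_weight(rep(u$second_line, 8), u, p_oi, p_aids)
  w_ae <- .expected_weight(pmin(u$second_line, u$event[[ae_name]]),
                           u, p_oi, p_aids)
  cost <- qaly <- survival <- 0
  rate <- params$economics$annual_discount_rate
  for (cyc in seq_len(traj$n_cycles)) {
    disc <- discount_factor((cyc - 0.5) * 0.5, rate)
    g1 <- traj$stay1[cyc, ]
    g2 <- traj$occ2_cont[cyc, ] + traj$to2_two[cyc, ]
    gae <- traj$to2_ae[cyc, ]
    acc <- g1 + g2 + gae                       # all accruers, by state
    qaly <- qaly + disc * 0.5 *
      (sum(g1 * w_first) + sum(g2 * w_second) + sum(gae * w_ae))
    cost <- cost + disc * (
      sum(acc * 0.5 * hs_cost) +
        p_oi * sum(acc) * ev_cost[["oi"]] +
        sum(acc * p_aids) * ev_cost[["aids"]] +
        sum(gae) * ev_cost[[ae_name]])
    survival <- survival + 0.5 * traj$alive[cyc]
  }
  list(cost = cost, qaly = qaly, survival = survival)
}

#' Dump an occupancy trajectory to CSV
#'
#' One row per cycle: first-line and second-line occupancy by state, dead
#' mass and total alive mass.
#' @param traj a `cea_occupancy`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(traj, path) {
  df <- data.frame(cycle = seq_len(traj$n_cycles))
  colnames(traj$occ1) <- paste0("first_HS", 1:8)
  colnames(traj$occ2) <- paste0("second_HS", 1:8)
  df <- cbind(df, traj$occ1, traj$occ2,
              dead = traj$dead, alive = traj$alive)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cea_occupancy <- function(x, ...) {
  cat(sprintf(
    "<cea_occupancy> arm %s, %d cycles, age %.1f %s, events: %s\n",
    x$arm, x$n_cycles, x$age, x$sex,
    if (length(x$events)) paste(x$events, collapse = ", ") else "none"))
  cat(sprintf("  alive mass after final cycle: %.4f\n",
              x$alive[x$n_cycles]))
  invisible(x)
}
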