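# Patient-level semestral cycle engine.
#
# Cycle order (one documented convention; the source gives none):
#   1. background mortality draw (life table with MRR)
#   2. health-state transition
#   3. AIDS draw (per-state probability; case fatality configurable)
#   4. CHD draw (fatal with configured probability)
#   5. OI draw
#   6. CKD draw (first line: cycle ramp; second line: frozen risk)
#   7. adverse-event draw (first line only, the arm's primary AE)
#   8. switching update (AE fired, or second consecutive detectable cycle)
#   9. accrual of discounted cost/QALY and survival
# Death in a cycle (any cause) suppresses that cycle's accrual; events drawn
# before an event death are still counted. Accrual uses the post-switch
# line, discounted at the cycle midpoint t = (cycle - 0.5) * 0.5 years.

#' Discount factor
#'
#' @param t time in years (>= 0, vectorised).
#' @param annual_rate annual discount rate (fraction).
#' @return `(1 + annual_rate)^(-t)`.
#' @export
#' @examples
#' discount_factor(1, 0.03)  # 0.9709
discount_factor <- function(t, annual_rate) {
  stopifnot(all(t >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-t)
}

#' Semestral background mortality probability
#'
#' Converts the annual death probability from a life table (MRR already
#' applied on the hazard scale) to a semestral probability under a constant
#' hazard within the year: `1 - (1 - q)^(1/2)`.
#'
#' @param lt a `life_table`.
#' @param age age in years (vectorised).
#' @param male logical, `TRUE` for male (vectorised).
#' @return Semestral death probability.
#' @export
#' @examples
#' # q = 0.19 annually -> 0.1 per semester
#' lt <- make_life_table()
#' mortality_probability(lt, 40, TRUE)
mortality_probability <- function(lt, age, male) {
  1 - sqrt(1 - .lt_q(lt, age, male))
}

#' Semestral chronic-kidney-disease risk
#'
#' On first line the CKD risk ramps geometrically (log-linearly) from the
#' cycle-1 value to the cycle-40 value and stays constant thereafter. On
#' switching, the risk freezes at its last first-line value; second-line
#' patients keep that frozen value for life.
#'
#' @param cycle cycle index (>= 1, vectorised).
#' @param arm arm key (`"lpvr"`, `"atvr1"`, `"atvr2"`); the two ATV+r arms
#'   share one ramp.
#' @param line `"first"` or `"second"`.
#' @param frozen the frozen risk carried from first line (required when
#'   `line = "second"`).
#' @param risks the `risks` block of a `cea_params` list.
#' @return Semestral CKD probability.
#' @export
#' @examples
#' ckd_probability(1, "lpvr")    # 0.0012
#' ckd_probability(40, "atvr1")  # 0.233
ckd_probability <- function(cycle, arm = "lpvr", line = c("first", "second"),
                            frozen = NULL,
                            risks = default_parameters()$risks) {
  line <- match.arg(line)
  if (line == "second") {
    if (is.null(frozen) || any(is.na(frozen)))
      stop("second-line CKD risk requires the frozen first-line value")
    return(frozen)
  }
  stopifnot(all(cycle >= 1))
  ramp <- risks$ckd_ramp[[if (arm == "lpvr") "lpvr" else "atvr"]]
  if (ramp[["start"]] <= 0 || ramp[["end"]] <= 0)
    return(rep(0, length(cycle)))  # risk disabled
  nc <- risks$ckd_ramp$n_cycles
  k <- pmin(cycle, nc)
  ramp[["start"]] * (ramp[["end"]] / ramp[["start"]])^((k - 1) / (nc - 1))
}

#' Semestral coronary-heart-disease risk
#'
#' Base risk from the (prior diabetes, prior CHD) stratum — a CHD event
#' history moves the patient into a prior-CHD stratum permanently —
#' multiplied on first line by `1 - 0.14 * |TC:HDL effect|` for the
#' cholesterol-lowering effect of treatment (each unit decrement of the
#' TC:HDL ratio reduces CHD risk by 14%). The effect is null on second
#' line.
#'
#' @param patient a list with logical `prior_dm`, `prior_chd`,
#'   `chd_history`, and `line` (1 or 2).
#' @param arm an arm specification (element of `params$arms`).
#' @param risks the `risks` block of a `cea_params` list.
#' @return Semestral CHD probability.
#' @export
#' @examples
#' p <- default_parameters()
#' pat <- list(prior_dm = FALSE, prior_chd = FALSE, chd_history = FALSE,
#'             line = 1L)
#' chd_probability(pat, p$arms$lpvr, p$risks)  # 0.0017 * (1 - 0.14*0.17)
chd_probability <- function(patient, arm, risks = default_parameters()$risks) {
  stratum <- 1L + as.integer(patient$prior_dm) +
    2L * as.integer(patient$prior_chd | isTRUE(patient$chd_history))
  base <- risks$chd_base[[stratum]]
  mult <- if (patient$line == 1L && arm$tc_hdl_effect < 0)
    1 - risks$chd_rr_per_unit_tc_hdl * abs(arm$tc_hdl_effect) else 1
  base * mult
}

# Precomputed per-arm simulation context.
.arm_context <- function(arm_key, p, tm, lt) {
  arm_key <- match.arg(arm_key, .ARM_KEYS)
  arm <- p$arms[[arm_key]]
  cum <- function(m) {
    cm <- t(apply(m, 1, cumsum))
    cm[, 8] <- 1
    cm
  }
  list(
    arm_key = arm_key, arm = arm,
    cum1 = cum(tm$matrices[[arm_key]]), cum2 = cum(tm$matrices$second),
    lt = lt, rate = p$economics$annual_discount_rate,
    aids_p = p$risks$aids, aids_cf = p$risks$aids_case_fatality,
    chd_base = unname(p$risks$chd_base), chd_fatal = p$risks$chd_fatal,
    chd_mult = if (arm$tc_hdl_effect < 0)
      1 - p$risks$chd_rr_per_unit_tc_hdl * abs(arm$tc_hdl_effect) else 1,
    oi_risk = p$risks$oi, ae_risk = arm$ae_risk,
    risks = p$risks,
    hs_cost = p$costs$hs_annual[, if (arm_key == "lpvr") "lpvr" else "atvr"],
    cost_ev = p$costs$event, ae_cost = p$costs$event[[arm$primary_ae]],
    u_hs = p$utilities$hs, u_hs_ref = p$utilities$hs,
    u_chd = p$utilities$hs_chd, u_second = p$utilities$second_line,
    u_aids = p$utilities$event$aids, u_oi = p$utilities$event$oi,
    u_ckd = p$utilities$event$ckd,
    u_ae = p$utilities$event[[arm$primary_ae]],
    combine = p$utilities$combine
  )
}

.combine_utility <- function(state, line, chd_hist, aids, oi, ckd, ae, ctx) {
  base <- ifelse(line == 1L, ctx$u_hs[state], ctx$u_second)
  if (ctx$combine == "minimum") {
    w <- base
    w <- ifelse(chd_hist, pmin(w, ctx$u_chd[state]), w)
    w <- ifelse(aids, pmin(w, ctx$u_aids[state]), w)
    w <- ifelse(oi, pmin(w, ctx$u_oi[state]), w)
    w <- ifelse(ckd, pmin(w, ctx$u_ckd[state]), w)
    ifelse(ae, pmin(w, ctx$u_ae[state]), w)
  } else {
    rel <- function(col) col[state] / ctx$u_hs_ref[state]
    w <- base *
      ifelse(chd_hist, rel(ctx$u_chd), 1) * ifelse(aids, rel(ctx$u_aids), 1) *
      ifelse(oi, rel(ctx$u_oi), 1) * ifelse(ckd, rel(ctx$u_ckd), 1) *
      ifelse(ae, rel(ctx$u_ae), 1)
    pmin(pmax(w, 0), 1)
  }
}

# One vectorised model cycle over all patients. S is the list of per-patient
# state vectors; U an n x 9 matrix of uniforms (one column per draw).
.advance_cycle <- function(S, cyc, ctx, U) {
  alive0 <- S$alive
  disc <- discount_factor((cyc - 0.5) * 0.5, ctx$rate)

  p_mort <- mortality_probability(ctx$lt, S$age, S$male)
  dies_bg <- alive0 & U[, 1] < p_mort
  act <- alive0 & !dies_bg

  news <- S$state
  i1 <- which(act & S$line == 1L)
  if (length(i1))
    news[i1] <- rowSums(U[i1, 2] > ctx$cum1[S$state[i1], , drop = FALSE]) + 1L
  i2 <- which(act & S$line == 2L)
  if (length(i2))
    news[i2] <- rowSums(U[i2, 2] > ctx$cum2[S$state[i2], , drop = FALSE]) + 1L

  aids <- act & U[, 3] < ctx$aids_p[news]
  aids_death <- aids & U[, 4] < ctx$aids_cf
  stratum <- 1L + S$prior_dm + 2L * (S$prior_chd | S$chd_history)
  p_chd <- ctx$chd_base[stratum] * ifelse(S$line == 1L, ctx$chd_mult, 1)
  chd <- act & U[, 5] < p_chd
  chd_death <- chd & U[, 6] < ctx$chd_fatal
  oi <- act & U[, 7] < ctx$oi_risk
  ckd1 <- ckd_probability(cyc, ctx$arm_key, "first", risks = ctx$risks)
  p_ckd <- ifelse(S$line == 1L, ckd1, S$frozen_ckd)
  p_ckd[is.na(p_ckd)] <- 0
  ckd <- act & U[, 8] < p_ckd
  ae <- act & S$line == 1L & U[, 9] < ctx$ae_risk

  dies_ev <- aids_death | chd_death
  surv <- act & !dies_ev

  S$chd_history <- S$chd_history | chd
  S$n_aids <- S$n_aids + aids
  S$n_chd <- S$n_chd + chd
  S$n_oi <- S$n_oi + oi
  S$n_ckd <- S$n_ckd + ckd
  S$n_ae <- S$n_ae + ae

  det <- state_is_detectable(news)
  two <- surv & S$line == 1L & det & S$consec >= 1L
  sw <- surv & S$line == 1L & (ae | two)
  S$n_detect2 <- S$n_detect2 + two
  S$frozen_ckd[sw] <- ckd1
  stay1 <- surv & S$line == 1L & !sw
  S$consec[stay1] <- ifelse(det[stay1], S$consec[stay1] + 1L, 0L)
  S$line[sw] <- 2L
  S$consec[sw] <- 0L

  ev_cost <- aids * ctx$cost_ev[["aids"]] + chd * ctx$cost_ev[["chd"]] +
    oi * ctx$cost_ev[["oi"]] + ckd * ctx$cost_ev[["ckd"]] + ae * ctx$ae_cost
  cyc_cost <- 0.5 * ctx$hs_cost[news] + ev_cost
  w <- .combine_utility(news, S$line, S$chd_history, aids, oi, ckd, ae, ctx)

  S$cost <- S$cost + ifelse(surv, disc * cyc_cost, 0)
  S$qaly <- S$qaly + ifelse(surv, disc * 0.5 * w, 0)
  S$qaly_raw <- S$qaly_raw + ifelse(surv, 0.5 * w, 0)
  S$surv_years <- S$surv_years + 0.5 * surv
  S$first_years <- S$first_years + 0.5 * (surv & S$line == 1L)
  S$age <- S$age + 0.5 * surv
  S$state[act] <- news[act]

  died <- alive0 & !surv
  S$alive[died] <- FALSE
  S$end_line[died] <- S$line[died]
  S$death_cycle[died] <- cyc

  attr(S, "last") <- list(
    dies_bg = dies_bg, aids = aids, aids_death = aids_death, chd = chd,
    chd_death = chd_death, oi = oi, ckd = ckd, ae = ae, switched = sw,
    two_detectable = two, state = news, disc = disc,
    cost = ifelse(surv, disc * cyc_cost, 0),
    qaly = ifelse(surv, disc * 0.5 * w, 0)
  )
  S
}

.init_sim_state <- function(cohort) {
  n <- nrow(cohort)
  list(
    state = as.integer(cohort$start_state), line = rep(1L, n),
    age = cohort$age, male = cohort$male,
    prior_dm = cohort$prior_dm, prior_chd = cohort$prior_chd,
    chd_history = rep(FALSE, n), consec = rep(0L, n),
    frozen_ckd = rep(NA_real_, n), alive = rep(TRUE, n),
    cost = numeric(n), qaly = numeric(n), qaly_raw = numeric(n),
    surv_years = numeric(n), first_years = numeric(n),
    n_aids = numeric(n), n_chd = numeric(n), n_oi = numeric(n),
    n_ckd = numeric(n), n_ae = numeric(n), n_detect2 = numeric(n),
    end_line = rep(NA_integer_, n), death_cycle = rep(NA_integer_, n)
  )
}

#' Run the microsimulation for one cohort
#'
#' Low-level engine: advances every patient of `cohort` through semestral
#' cycles until all have died (or `max_cycles` is reached). Draws come from
#' the current RNG stream; see [simulate_arm()] for the seeded front end.
#'
#' @param arm arm key: `"lpvr"`, `"atvr1"` or `"atvr2"`.
#' @param cohort a `baseline_cohort` data frame.
#' @param params a `cea_params` list.
#' @param matrices optional `cea_matrices` (built from `params` if `NULL`).
#' @param lt optional `life_table` (built from `params` if `NULL`).
#' @param max_cycles safety cap on the number of cycles.
#' @param trace if `TRUE`, keep a per-cycle per-patient trace (memory-heavy;
#'   for small cohorts only).
#' @param occupancy if `TRUE`, record end-of-cycle occupancy counts by
#'   (line, state) plus dead — cheap, for comparison against
#'   [occupancy_recursion()].
#' @return A list with `patients` (data frame of per-patient accumulators
#'   and event counts), `cycles` (number of cycles run), and optionally
#'   `trace` and `occupancy` (matrix cycles x 17: first-line states 1..8,
#'   second-line states 1..8, dead).
#' @export
run_microsim <- function(arm, cohort, params, matrices = NULL, lt = NULL,
                         max_cycles = 600, trace = FALSE,
                         occupancy = FALSE) {
  if (is.null(matrices)) matrices <- build_arm_matrices(params)
  if (is.null(lt)) lt <- life_table_from_params(params)
  ctx <- .arm_context(arm, params, matrices, lt)
  S <- .init_sim_state(cohort)
  n <- nrow(cohort)
  traces <- if (trace) vector("list", max_cycles)
  occ <- if (occupancy) matrix(0, 0, 17,
    dimnames = list(NULL, c(paste0("first_HS", 1:8),
                            paste0("second_HS", 1:8), "dead")))
  cyc <- 0L
  while (any(S$alive) && cyc < max_cycles) {
    cyc <- cyc + 1L
    U <- matrix(runif(n * 9L), n, 9L)
    S <- .advance_cycle(S, cyc, ctx, U)
    if (occupancy) {
      a1 <- S$alive & S$line == 1L
      a2 <- S$alive & S$line == 2L
      occ <- rbind(occ, c(tabulate(S$state[a1], 8L),
                          tabulate(S$state[a2], 8L), sum(!S$alive)))
    }
    if (trace) {
      ev <- attr(S, "last")
      keep <- which(ev$state > 0 & (S$alive | S$death_cycle == cyc))
      traces[[cyc]] <- data.frame(
        cycle = cyc, id = keep, state = ev$state[keep],
        line = S$line[keep], alive = S$alive[keep],
        aids = ev$aids[keep], chd = ev$chd[keep], oi = ev$oi[keep],
        ckd = ev$ckd[keep], ae = ev$ae[keep],
        switched = ev$switched[keep],
        cost = ev$cost[keep], qaly = ev$qaly[keep]
      )
    }
  }
  patients <- data.frame(
    surv_years = S$surv_years, qaly = S$qaly, qaly_raw = S$qaly_raw,
    cost = S$cost, first_years = S$first_years, end_line = S$end_line,
    n_aids = S$n_aids, n_chd = S$n_chd, n_oi = S$n_oi, n_ckd = S$n_ckd,
    n_ae = S$n_ae, n_detect2 = S$n_detect2, death_cycle = S$death_cycle
  )
  out <- list(arm = arm, patients = patients, cycles = cyc)
  if (trace) out$trace <- do.call(rbind, traces[seq_len(cyc)])
  if (occupancy) out$occupancy <- occ
  out
}

.summarize_arm <- function(arm_key, patients, params, seed = NA) {
  py <- sum(patients$surv_years)
  per1000 <- function(x) 1000 * sum(x) / py
  structure(list(
    arm = params$arms[[arm_key]]$name, arm_key = arm_key,
    population = nrow(patients), seed = seed,
    mean_survival = mean(patients$surv_years),
    mean_qaly = mean(patients$qaly),
    mean_qaly_undiscounted = mean(patients$qaly_raw),
    mean_lifetime_cost = mean(patients$cost),
    per_capita_annual_cost = mean(patients$cost) / mean(patients$surv_years),
    cost_per_qaly = mean(patients$cost) / mean(patients$qaly),
    mean_years_first_line = mean(patients$first_years),
    pct_ending_first_line = 100 * mean(patients$end_line == 1L),
    pct_with_chd = 100 * mean(patients$n_chd > 0),
    pct_with_ckd = 100 * mean(patients$n_ckd > 0),
    chd_per_1000py = per1000(patients$n_chd),
    aids_per_1000py = per1000(patients$n_aids),
    ckd_per_1000py = per1000(patients$n_ckd),
    oi_per_1000py = per1000(patients$n_oi),
    ae_per_1000py = per1000(patients$n_ae),
    detect2_per_1000py = per1000(patients$n_detect2),
    total_patient_years = py
  ), class = "cea_arm_summary")
}

#' Simulate one treatment arm to death
#'
#' Seeded front end: generates the baseline cohort, runs every patient to
#' death and returns the lifetime outcome battery for the arm (survival,
#' QALYs, costs, line-switching and event rates per 1000 patient-years).
#'
#' @param arm arm key: `"lpvr"`, `"atvr1"` or `"atvr2"`.
#' @param n cohort size; defaults to the configured
#'   `economics$cohort_size`.
#' @param params a `cea_params` list.
#' @param seed integer seed (all randomness: cohort and event draws).
#' @param matrices,lt optional prebuilt transition matrices / life table.
#' @param cohort optional pre-generated `baseline_cohort` (overrides `n`).
#' @return An object of class `cea_arm_summary`.
#' @export
#' @examples
#' s <- simulate_arm("lpvr", n = 500, seed = 1)
#' s$oi_per_1000py
simulate_arm <- function(arm, n = params$economics$cohort_size,
                         params = default_parameters(), seed = 1L,
                         matrices = NULL, lt = NULL, cohort = NULL) {
  set.seed(seed)
  if (is.null(cohort))
    cohort <- generate_baseline_cohort(n, params$demographics)
  res <- run_microsim(arm, cohort, params, matrices = matrices, lt = lt)
  .summarize_arm(arm, res$patients, params, seed = seed)
}

#' Construct a patient record
#'
#' One simulated individual's evolving state, for use with
#' [step_patient()].
#'
#' @param age,male,prior_dm,prior_chd,start_state baseline fields.
#' @return A list of class `patient_record`.
#' @export
new_patient_record <- function(age = 39.2, male = TRUE, prior_dm = FALSE,
                               prior_chd = FALSE, start_state = 2L) {
  stopifnot(age >= 18, start_state %in% 1:8)
  structure(list(
    state = as.integer(start_state), line = 1L, cycle = 0L, age = age,
    male = male, prior_dm = prior_dm, prior_chd = prior_chd,
    consecutive_detectable = 0L, chd_history = FALSE,
    frozen_ckd_risk = NA_real_, alive = TRUE,
    cost = 0, qaly = 0, surv_years = 0, first_line_years = 0,
    events = c(aids = 0, chd = 0, oi = 0, ckd = 0, ae = 0, detect2 = 0)
  ), class = "patient_record")
}

#' Advance one patient by one cycle
#'
#' Single-patient interface to the same cycle kernel used by
#' [run_microsim()]: executes the documented cycle order (mortality,
#' transition, AIDS, CHD, OI, CKD, AE, switching, accrual) with draws from
#' the current RNG stream.
#'
#' @param patient a `patient_record` (must be alive).
#' @param arm arm key.
#' @param params a `cea_params` list.
#' @param matrices,lt optional prebuilt objects.
#' @return A list with `patient` (the updated record) and `outcome` (events
#'   fired, state after transition, death cause or `NA`, and the cycle's
#'   discounted cost and QALY contributions).
#' @export
step_patient <- function(patient, arm, params = default_parameters(),
                         matrices = NULL, lt = NULL) {
  if (!isTRUE(patient$alive)) stop("cannot step a dead patient")
  if (is.null(matrices)) matrices <- build_arm_matrices(params)
  if (is.null(lt)) lt <- life_table_from_params(params)
  ctx <- .arm_context(arm, params, matrices, lt)
  S <- .init_sim_state(data.frame(
    age = patient$age, male = patient$male, prior_dm = patient$prior_dm,
    prior_chd = patient$prior_chd, start_state = patient$state
  ))
  S$line <- patient$line
  S$consec <- patient$consecutive_detectable
  S$chd_history <- patient$chd_history
  S$frozen_ckd <- patient$frozen_ckd_risk
  cyc <- patient$cycle + 1L
  S <- .advance_cycle(S, cyc, ctx, matrix(runif(9L), 1L, 9L))
  ev <- attr(S, "last")
  patient$state <- S$state
  patient$line <- S$line
  patient$cycle <- cyc
  patient$age <- S$age
  patient$consecutive_detectable <- S$consec
  patient$chd_history <- S$chd_history
  patient$frozen_ckd_risk <- S$frozen_ckd
  patient$alive <- S$alive
  patient$cost <- patient$cost + S$cost
  patient$qaly <- patient$qaly + S$qaly
  patient$surv_years <- patient$surv_years + S$surv_years
  patient$first_line_years <- patient$first_line_years + S$first_years
  patient$events <- patient$events +
    c(aids = ev$aids, chd = ev$chd, oi = ev$oi, ckd = ev$ckd, ae = ev$ae,
      detect2 = ev$two_detectable)
  death_cause <- if (S$alive) NA_character_
    else if (ev$dies_bg) "background"
    else if (ev$chd_death) "chd"
    else "aids"
  outcome <- structure(list(
    cycle = cyc, state = ev$state,
    events = c(aids = ev$aids, chd = ev$chd, chd_fatal = ev$chd_death,
               oi = ev$oi, ckd = ev$ckd, ae = ev$ae,
               two_detectable = ev$two_detectable),
    switched = ev$switched, death_cause = death_cause,
    cost = ev$cost, qaly = ev$qaly
  ), class = "cycle_outcome")
  list(patient = patient, outcome = outcome)
}

#' Cycle QALY contribution
#'
#' Utility weight for a cycle — the minimum (or, if configured,
#' multiplicative combination) over the applicable columns: the state's
#' baseline weight (replaced by the flat second-line weight on second
#' line), the CHD column for patients with a CHD history, and the event
#' columns for events fired this cycle — times the half-year cycle length,
#' times the midpoint discount factor.
#'
#' @param state health state after transition (1..8).
#' @param cycle cycle index (discounting at its midpoint).
#' @param params a `cea_params` list.
#' @param line 1 or 2.
#' @param chd_history logical.
#' @param events character vector among `"aids"`, `"oi"`, `"ckd"`, `"ae"`.
#' @param arm arm key (selects the adverse-event utility column).
#' @return Discounted QALY contribution in years.
#' @export
#' @examples
#' cycle_utility(1, cycle = 1)  # 0.9440 * 0.5 * discount
cycle_utility <- function(state, cycle, params = default_parameters(),
                          line = 1L, chd_history = FALSE,
                          events = character(), arm = "lpvr") {
  u <- params$utilities
  ctx <- list(u_hs = u$hs, u_hs_ref = u$hs, u_chd = u$hs_chd,
              u_second = u$second_line, u_aids = u$event$aids,
              u_oi = u$event$oi, u_ckd = u$event$ckd,
              u_ae = u$event[[params$arms[[arm]]$primary_ae]],
              combine = u$combine)
  w <- .combine_utility(state, line, chd_history,
                        "aids" %in% events, "oi" %in% events,
                        "ckd" %in% events, "ae" %in% events, ctx)
  w * 0.5 * discount_factor((cycle - 0.5) * 0.5,
                            params$economics$annual_discount_rate)
}

#' Cycle cost contribution
#'
#' Half the annual health-state cost of the arm plus the costs of events
#' fired this cycle, discounted at the cycle midpoint.
#'
#' @inheritParams cycle_utility
#' @param alive logical; a dead patient accrues nothing.
#' @return Discounted cost in euro.
#' @export
#' @examples
#' cycle_cost(1, cycle = 1, params = default_parameters())
cycle_cost <- function(state, cycle, params = default_parameters(),
                       events = character(), arm = "lpvr", alive = TRUE) {
  if (!alive) return(0)
  col <- if (arm == "lpvr") "lpvr" else "atvr"
  ev <- params$costs$event
  ae_cost <- ev[[params$arms[[arm]]$primary_ae]]
  total <- 0.5 * unname(params$costs$hs_annual[state, col]) +
    ("aids" %in% events) * ev[["aids"]] + ("chd" %in% events) * ev[["chd"]] +
    ("oi" %in% events) * ev[["oi"]] + ("ckd" %in% events) * ev[["ckd"]] +
    ("ae" %in% events) * ae_cost
  total * discount_factor((cycle - 0.5) * 0.5,
                          params$economics$annual_discount_rate)
}

#' @export
print.cea_arm_summary <- function(x, ...) {
  cat(sprintf("<cea_arm_summary> %s  (n = %s%s)\n", x$arm,
              format(x$population, big.mark = ","),
              if (!is.na(x$seed)) paste0(", seed ", x$seed) else ""))
  f <- function(lab, val, fmt = "%.3f") cat(sprintf("  %-38s %s\n", lab,
                                                    sprintf(fmt, val)))
  f("Survival years (mean)", x$mean_survival)
  f("QALYs (mean, discounted)", x$mean_qaly)
  f("Per capita mean annual cost (EUR)", x$per_capita_annual_cost, "%.2f")
  f("Lifetime cost per patient (EUR)", x$mean_lifetime_cost, "%.2f")
  f("Total cost per QALY (EUR)", x$cost_per_qaly, "%.2f")
  f("Years on first-line therapy (mean)", x$mean_years_first_line)
  f("Ending in first-line therapy (%)", x$pct_ending_first_line, "%.2f")
  f("Patients with >= 1 CHD event (%)", x$pct_with_chd, "%.2f")
  f("Patients with >= 1 CKD event (%)", x$pct_with_ckd, "%.2f")
  f("CHD events /1000 py", x$chd_per_1000py, "%.1f")
  f("AIDS events /1000 py", x$aids_per_1000py, "%.1f")
  f("CKD events /1000 py", x$ckd_per_1000py, "%.1f")
  f("OI events /1000 py", x$oi_per_1000py, "%.1f")
  f("Treatment-emergent AE /1000 py", x$ae_per_1000py, "%.1f")
  f("Two consecutive detectable VL /1000 py", x$detect2_per_1000py, "%.1f")
  f("Total patient-years", x$total_patient_years, "%.0f")
  invisible(x)
}
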