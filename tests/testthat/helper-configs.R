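# Shared test configurations, all built in code.

# Printed self-transition diagonals, repeated here as the test's own copy
# so matrix construction is checked against an independent transcription.
TAB_DIAG <- list(
  lpvr = c(0.70721, 0.86111, 0.38737, 0.45253,
           0.05202, 0.13132, 0.01623, 0.02844),
  atvr1 = c(0.77487, 0.71106, 0.29664, 0.36481,
            0.08941, 0.09041, 0.00485, 0.02175),
  atvr2 = c(0.72320, 0.86980, 0.40847, 0.47386,
            0.05719, 0.14281, 0.01791, 0.03135),
  second = c(0.49504, 0.60277, 0.27118, 0.31675,
             0.03640, 0.09191, 0.01134, 0.01988)
)

# All disease/event processes switched off; only transitions, mortality and
# the detectable-VL switching rule remain.
params_events_off <- function(p = default_parameters()) {
  p$risks$chd_base[] <- 0
  p$risks$oi <- 0
  p$risks$aids[] <- 0
  p$risks$ckd_ramp$lpvr[c("start", "end")] <- 0
  p$risks$ckd_ramp$atvr[c("start", "end")] <- 0
  for (k in names(p$arms)) p$arms[[k]]$ae_risk <- 0
  p
}

# Degenerate demographics: one age, one sex, no comorbidity, so the
# deterministic oracle applies exactly.
params_fixed_demog <- function(p = default_parameters()) {
  p$demographics$age_sd <- 0
  p$demographics$male_fraction <- 1
  p$demographics$prior_dm <- 0
  p$demographics$prior_chd <- 0
  p
}

# Unit utilities and zero discounting: QALY must equal survival.
params_unit_utility <- function(p = default_parameters()) {
  p$utilities$hs[] <- 1
  p$utilities$hs_chd[] <- 1
  for (k in names(p$utilities$event)) p$utilities$event[[k]][] <- 1
  p$utilities$second_line <- 1
  p$economics$annual_discount_rate <- 0
  p
}

# A life table with zero hazard below the closing age.
zero_life_table <- function(max_age = 110) {
  make_life_table(list(male = c(a = 0, b = 0, g = 0.1),
                       female = c(a = 0, b = 0, g = 0.1)),
                  mrr = 1, max_age = max_age)
}

# Identity transition matrices (patients never change state).
identity_matrices <- function() {
  m <- diag(8)
  dimnames(m) <- list(paste0("HS", 1:8), paste0("HS", 1:8))
  structure(list(matrices = list(lpvr = m, atvr1 = m, atvr2 = m,
                                 second = m),
                 upward_mass = rep(0, 8), scheme = "identity"),
            class = "cea_matrices")
}
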