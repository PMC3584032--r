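# Transition-matrix construction and calibration.
#
# The source tables print only the diagonal (self-transition) probability of
# each 8x8 semestral matrix. The full rows are reconstructed here: the
# trial-adjusted ATV+r 2 arm is defined by a 19% reduction of every LPV/r
# transition into a detectable-viral-load state, so the pair of printed
# diagonals (LPV/r, ATV+r 2) pins down, state by state, the LPV/r
# off-diagonal mass flowing into detectable states. The remaining mass is
# spread by a pluggable completion scheme.

#' Convert a semestral probability to an annual rate
#'
#' Standard constant-hazard conversion for a 6-month cycle:
#' rate = -2 ln(1 - p). Inverse of [rate_to_prob()].
#'
#' @param p semestral probability, `0 <= p < 1` (vectorised).
#' @return Annual rate (per person-year).
#' @export
#' @examples
#' prob_to_rate(0.0176)
prob_to_rate <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("semestral probability must lie in [0, 1)")
  -2 * log(1 - p)
}

#' Convert an annual rate to a semestral probability
#'
#' @param r annual rate, `r >= 0` (vectorised).
#' @return Semestral probability `1 - exp(-r/2)`.
#' @export
#' @examples
#' rate_to_prob(prob_to_rate(0.3))  # 0.3
rate_to_prob <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stop("annual rate must be >= 0")
  1 - exp(-r / 2)
}

#' Infer the detectable-VL off-diagonal mass of a reference row
#'
#' If the adjusted arm is obtained from the reference arm by multiplying
#' every off-diagonal transition into a detectable-VL state by
#' `(1 - reduction)` and crediting the removed mass to the diagonal, then
#' `diag_adjusted = diag_ref + reduction * upward_mass`. Solving for the
#' reference arm's total off-diagonal mass into detectable states:
#' `(diag_adjusted - diag_ref) / reduction`.
#'
#' @param diag_ref printed self-transition probability of the reference arm.
#' @param diag_adjusted printed self-transition probability of the adjusted
#'   arm (must be >= `diag_ref`).
#' @param reduction the fractional reduction (> 0), e.g. 0.19.
#' @return The reference arm's off-diagonal probability mass into
#'   detectable-VL states (vectorised).
#' @export
#' @examples
#' infer_upward_mass(0.70721, 0.7232, 0.19)   # state 1: 0.08416
infer_upward_mass <- function(diag_ref, diag_adjusted, reduction) {
  if (any(reduction <= 0)) stop("reduction must be > 0")
  if (any(diag_adjusted < diag_ref))
    stop("calibration error: adjusted diagonal below reference diagonal; ",
         "the detectable-VL reduction rule cannot decrease a diagonal")
  (diag_adjusted - diag_ref) / reduction
}

# Completion schemes: given the current state and a pool of destination
# states, return unnormalised weights for spreading probability mass.
.completion_schemes <- new.env(parent = emptyenv())

#' Register or fetch an off-diagonal completion scheme
#'
#' A scheme is a function `f(state, pool)` returning positive unnormalised
#' weights over `pool` (destination state indices). The default
#' `"rank_proportional"` scheme weights destinations by
#' `1 / (1 + |CD4-stratum distance|)`; `"uniform"` spreads mass equally.
#'
#' @param name scheme identifier.
#' @param fn weight function, or `NULL` to fetch an existing scheme.
#' @return The scheme function, invisibly when registering.
#' @export
completion_scheme <- function(name, fn = NULL) {
  if (is.null(fn)) {
    f <- .completion_schemes[[name]]
    if (is.null(f)) stop("unknown completion scheme: ", name)
    return(f)
  }
  assign(name, fn, envir = .completion_schemes)
  invisible(fn)
}

local({
  strat <- function(s) ceiling(s / 2)  # CD4 stratum 1..4
  completion_scheme("rank_proportional", function(state, pool) {
    1 / (1 + abs(strat(state) - strat(pool)))
  })
  completion_scheme("uniform", function(state, pool) {
    rep(1, length(pool))
  })
})

#' Complete one transition row from its diagonal
#'
#' Builds a full row of 8 semestral transition probabilities from the
#' printed diagonal: `upward_mass` is placed on detectable-VL states other
#' than the current one, the remainder on the suppressed states, each pool
#' spread according to `scheme`.
#'
#' @param state current state index (1..8).
#' @param diagonal printed self-transition probability.
#' @param upward_mass total probability of moving to a detectable-VL state
#'   other than `state`.
#' @param scheme completion scheme id (see [completion_scheme()]).
#' @return Numeric vector of length 8 summing to 1, with
#'   `row[state] == diagonal` exactly.
#' @export
#' @examples
#' complete_row(1, 0.70721, 0.08416)
complete_row <- function(state, diagonal, upward_mass,
                         scheme = "rank_proportional") {
  stopifnot(state %in% 1:8, diagonal >= 0, diagonal < 1, upward_mass >= 0)
  rest <- 1 - diagonal - upward_mass
  if (rest < -1e-12)
    stop(sprintf(
      "calibration error: state %d infeasible (diagonal %.5f + detectable mass %.5f > 1)",
      state, diagonal, upward_mass))
  rest <- max(rest, 0)
  w <- completion_scheme(scheme)
  row <- numeric(8)
  row[state] <- diagonal
  det_pool <- setdiff(which(state_is_detectable(1:8)), state)
  oth_pool <- setdiff(which(!state_is_detectable(1:8)), state)
  spread <- function(pool, mass) {
    if (mass <= 0 || !length(pool)) return()
    ww <- w(state, pool)
    stopifnot(all(ww > 0))
    row[pool] <<- row[pool] + mass * ww / sum(ww)
  }
  spread(det_pool, upward_mass)
  spread(oth_pool, rest)
  row
}

#' Reduce transitions into detectable-VL states
#'
#' Multiplies every off-diagonal entry into a detectable-VL state by
#' `(1 - reduction)` and credits the removed mass to the diagonal, row by
#' row. Rows remain stochastic.
#'
#' @param m an 8x8 row-stochastic matrix.
#' @param reduction fraction in `[0, 1)`.
#' @return The adjusted 8x8 matrix.
#' @export
apply_vl_reduction <- function(m, reduction) {
  stopifnot(is.matrix(m), all(dim(m) == c(8, 8)))
  if (reduction < 0 || reduction >= 1) stop("reduction must lie in [0, 1)")
  det <- state_is_detectable(1:8)
  for (s in 1:8) {
    cols <- which(det & seq_len(8) != s)
    removed <- sum(m[s, cols]) * reduction
    m[s, cols] <- m[s, cols] * (1 - reduction)
    m[s, s] <- m[s, s] + removed
  }
  m
}

#' Build all transition matrices of the model
#'
#' Constructs the first-line matrices for LPV/r, ATV+r 1 and ATV+r 2 plus
#' the shared second-line matrix. The LPV/r detectable-VL off-diagonal mass
#' is calibrated per state from the printed LPV/r and ATV+r 2 diagonals via
#' [infer_upward_mass()]; the ATV+r 2 matrix is then exactly
#' `apply_vl_reduction(LPV/r, reduction)`. For ATV+r 1 and the second line
#' (no calibration constraint) each row assigns the same *proportion* of its
#' off-diagonal mass to detectable states as the corresponding calibrated
#' LPV/r row.
#'
#' @param p a `cea_params` list.
#' @param scheme completion scheme id; defaults to the configured one.
#' @return A list of class `cea_matrices` with components `matrices` (named
#'   list `lpvr`, `atvr1`, `atvr2`, `second` of 8x8 row-stochastic matrices)
#'   and `upward_mass` (the calibrated LPV/r detectable-VL mass per state).
#' @export
#' @examples
#' tm <- build_arm_matrices(default_parameters())
#' diag(tm$matrices$atvr2)
build_arm_matrices <- function(p, scheme = p$transitions$completion_scheme) {
  d <- p$transitions$diagonals
  reduction <- p$arms$atvr2$vl_reduction
  u_lpvr <- tryCatch(
    infer_upward_mass(d[, "lpvr"], d[, "atvr2"], reduction),
    error = function(e) {
      bad <- which(d[, "atvr2"] < d[, "lpvr"])
      stop("calibration failed for state(s) ",
           paste(bad, collapse = ", "), ": ", conditionMessage(e),
           call. = FALSE)
    })
  build <- function(diags, umass) {
    m <- t(vapply(1:8, function(s)
      complete_row(s, diags[s], umass[s], scheme), numeric(8)))
    dimnames(m) <- list(paste0("HS", 1:8), paste0("HS", 1:8))
    m
  }
  frac <- u_lpvr / (1 - d[, "lpvr"])
  mats <- list(
    lpvr = build(d[, "lpvr"], u_lpvr),
    atvr1 = build(d[, "atvr1"], frac * (1 - d[, "atvr1"])),
    second = build(d[, "second"], frac * (1 - d[, "second"]))
  )
  mats$atvr2 <- apply_vl_reduction(mats$lpvr, reduction)
  mats <- mats[c("lpvr", "atvr1", "atvr2", "second")]
  for (k in names(mats)) {
    rs <- rowSums(mats[[k]])
    if (any(abs(rs - 1) > 1e-12) || any(mats[[k]] < 0))
      stop("internal error: matrix ", k, " is not row-stochastic")
  }
  structure(list(matrices = mats, upward_mass = u_lpvr, scheme = scheme),
            class = "cea_matrices")
}

#' Export transition matrices to CSV
#'
#' Writes one CSV per matrix (`transitions_<key>.csv`), with health-state
#' labels as header row and row names.
#'
#' @param tm a `cea_matrices` object.
#' @param dir output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
export_matrices <- function(tm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tm$matrices), function(k) {
    f <- file.path(dir, paste0("transitions_", k, ".csv"))
    write.csv(tm$matrices[[k]], f)
    f
  }, character(1))
  invisible(paths)
}

#' @export
print.cea_matrices <- function(x, ...) {
  cat("<cea_matrices> semestral transition matrices (scheme:",
      x$scheme, ")\n")
  for (k in names(x$matrices))
    cat(sprintf("  %-6s diag: %s\n", k,
                paste(sprintf("%.5f", diag(x$matrices[[k]])),
                      collapse = " ")))
  invisible(x)
}
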