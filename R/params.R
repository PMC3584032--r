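#' hivcea: lifetime cost-utility microsimulation of first-line HIV therapy
#'
#' Patient-level semiannual Markov microsimulation comparing first-line
#' lopinavir/ritonavir (LPV/r) with atazanavir + ritonavir (ATV+r, two
#' variants) in treatment-naive HIV-infected adults. Eight health states
#' defined by CD4 cell count and viral-load (VL) detectability, recurrent
#' clinical events (AIDS, coronary heart disease, opportunistic infections,
#' chronic kidney disease, treatment adverse events), switching to an
#' aggregate second line, life-table mortality scaled by an HIV
#' mortality-rate-ratio, discounted cost and QALY accrual, and a
#' probabilistic sensitivity analysis.
#'
#' @keywords internal
#' @importFrom stats rnorm runif rbinom qnorm pnorm dnorm rbeta setNames
#' @importFrom utils write.csv read.csv modifyList
"_PACKAGE"

# Internal constants: state labelling per the CD4 x VL grid. Even-indexed
# states are detectable (HIV RNA >= 50 copies/mL), odd are suppressed.
.CD4_LABELS <- c("> 350", "> 350", "201-350", "201-350",
                 "50-200", "50-200", "< 50", "< 50")
.ARM_KEYS <- c("lpvr", "atvr1", "atvr2")
.SEVERITY_ORDER <- c(1L, 3L, 2L, 5L, 4L, 6L, 7L, 8L)

#' Health-state definitions
#'
#' The eight CD4 x viral-load strata used throughout the model. States with
#' even index have detectable viral load (HIV RNA >= 50 copies/mL).
#'
#' @return A data frame with columns `index`, `cd4_range` and
#'   `vl_detectable`.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  data.frame(
    index = 1:8,
    cd4_range = .CD4_LABELS,
    vl_detectable = (1:8) %% 2L == 0L,
    stringsAsFactors = FALSE
  )
}

#' Is a health state viral-load detectable?
#' @param state integer state index (1..8), vectorised.
#' @return logical vector.
#' @export
state_is_detectable <- function(state) state %% 2L == 0L

#' Base-case model parameters
#'
#' The complete base-case parameter set: arm specifications, event risks,
#' costs, utilities, economic settings, transition-matrix diagonals,
#' cohort demographics and the parametric life-table coefficients. All
#' probabilities are stored on the \[0, 1\] scale (percent values in the
#' packaged configuration file are divided by 100 once, at load time).
#'
#' @return A list of class `cea_params`. Components:
#' \describe{
#'   \item{arms}{per-arm specification: display name, effect of treatment on
#'     the TC:HDL cholesterol ratio, primary adverse event and its semestral
#'     risk, and the detectable-VL transition reduction (0.19 for the
#'     trial-adjusted ATV+r 2 arm, 0 otherwise).}
#'   \item{risks}{CHD base risks by prior diabetes/CHD stratum, CHD case
#'     fatality, CHD relative-risk per unit of TC:HDL, OI risk, per-state
#'     AIDS probabilities, AIDS case fatality (0 unless configured), and the
#'     per-arm CKD risk ramp (semestral probability at cycles 1 and 40).}
#'   \item{costs}{annual health-state costs per arm (euro) and per-event
#'     costs.}
#'   \item{utilities}{annual utility weights per state without/with CHD
#'     history, per-event state-specific columns, the flat second-line
#'     weight, and the combination rule for co-occurring conditions.}
#'   \item{economics}{annual discount rate, willingness-to-pay threshold,
#'     cycle length (0.5 years) and default cohort size.}
#'   \item{transitions}{the printed per-state self-transition probabilities
#'     (8 states x 4 columns: LPV/r, ATV+r 1, ATV+r 2, second line) and the
#'     off-diagonal completion scheme.}
#'   \item{demographics}{baseline cohort moments and the start-state
#'     distribution (all mass on detectable states, matching the enrolment
#'     criterion of viral load >= 5000 copies/mL).}
#'   \item{life_table}{Gompertz-Makeham coefficients per sex, the HIV
#'     mortality-rate-ratio and the closing age.}
#' }
#' @export
#' @examples
#' p <- default_parameters()
#' p$risks$chd_fatal
default_parameters <- function() {
  p <- list(
    arms = list(
      lpvr = list(name = "LPV/r", tc_hdl_effect = -0.17,
                  primary_ae = "diarrhoea", ae_risk = 0.0176,
                  vl_reduction = 0),
      atvr1 = list(name = "ATV+r 1", tc_hdl_effect = -0.40,
                   primary_ae = "hyperbilirubinemia", ae_risk = 0.0147,
                   vl_reduction = 0),
      atvr2 = list(name = "ATV+r 2", tc_hdl_effect = -0.40,
                   primary_ae = "hyperbilirubinemia", ae_risk = 0.0147,
                   vl_reduction = 0.19)
    ),
    risks = list(
      chd_base = c(none = 0.0017, dm = 0.0082, chd = 0.0375,
                   dm_chd = 0.0494),
      chd_fatal = 0.354,
      chd_rr_per_unit_tc_hdl = 0.14,
      oi = 0.0176,
      aids = c(0.0009, 0.0162, 0.0104, 0.0585,
               0.0212, 0.2276, 0.6934, 0.9435),
      aids_case_fatality = 0,
      ckd_ramp = list(
        lpvr = c(start = 0.0012, end = 0.029),
        atvr = c(start = 0.0012, end = 0.233),
        n_cycles = 40
      )
    ),
    costs = list(
      hs_annual = cbind(
        lpvr = c(11423.24, 11563.34, 11621.42, 11575.64,
                 11837.66, 11753.78, 11895.84, 11409.78),
        atvr = c(11439.40, 11579.48, 11637.56, 11591.78,
                 11853.80, 11769.94, 11912.00, 11425.94)
      ),
      event = c(aids = 4684.00, chd = 1354.07, oi = 2110.69,
                hyperbilirubinemia = 27.61, diarrhoea = 50.82,
                ckd = 1185.36)
    ),
    utilities = list(
      hs = c(0.9440, 0.9350, 0.9290, 0.9320,
             0.8630, 0.8490, 0.7810, 0.7810),
      hs_chd = c(0.6006, 0.6000, 0.5996, 0.5998,
                 0.6002, 0.6007, 0.6005, 0.6005),
      event = list(
        aids = rep(0.5600, 8),
        oi = rep(0.6200, 8),
        hyperbilirubinemia = c(0.8835, 0.8824, 0.8816, 0.8820,
                               0.8725, 0.8704, 0.8592, 0.8592),
        diarrhoea = c(0.8273, 0.8257, 0.8245, 0.8251,
                      0.8111, 0.8080, 0.7913, 0.7913),
        ckd = c(0.8835, 0.8824, 0.8816, 0.8820,
                0.8725, 0.8704, 0.8592, 0.8592)
      ),
      second_line = 0.7810,
      combine = "minimum"
    ),
    economics = list(
      annual_discount_rate = 0.03,
      wtp_threshold = 25000,
      cycle_length = 0.5,
      cohort_size = 500000
    ),
    transitions = list(
      diagonals = cbind(
        lpvr = c(0.70721, 0.86111, 0.38737, 0.45253,
                 0.05202, 0.13132, 0.01623, 0.02844),
        atvr1 = c(0.77487, 0.71106, 0.29664, 0.36481,
                  0.08941, 0.09041, 0.00485, 0.02175),
        atvr2 = c(0.72320, 0.86980, 0.40847, 0.47386,
                  0.05719, 0.14281, 0.01791, 0.03135),
        second = c(0.49504, 0.60277, 0.27118, 0.31675,
                   0.03640, 0.09191, 0.01134, 0.01988)
      ),
      completion_scheme = "rank_proportional"
    ),
    demographics = list(
      age_mean = 39.2, age_sd = 9.5, min_age = 18,
      male_fraction = 0.759, prior_dm = 0.038, prior_chd = 0.012,
      start_state_probs = c(0, 0.45, 0, 0.35, 0, 0.15, 0, 0.05)
    ),
    life_table = list(
      makeham = list(
        male = c(a = 2.0e-4, b = 2.7e-5, g = 0.093),
        female = c(a = 1.0e-4, b = 1.3e-5, g = 0.099)
      ),
      mrr = 3.0,
      max_age = 110
    )
  )
  class(p) <- "cea_params"
  p
}

#' Validate a parameter set
#'
#' Checks every structural and numerical invariant of the model parameters.
#' Never raises: all violations are collected and returned, so callers can
#' report them together.
#'
#' @param p a `cea_params` list (see [default_parameters()]).
#' @return Character vector of violation messages; `character(0)` if the set
#'   is valid.
#' @export
#' @examples
#' validate_parameters(default_parameters())
validate_parameters <- function(p) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  need <- function(name) {
    if (is.null(p[[name]])) { add(sprintf("%s: missing block", name)); FALSE }
    else TRUE
  }
  prob_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)

  if (need("arms")) {
    for (k in .ARM_KEYS) {
      a <- p$arms[[k]]
      if (is.null(a)) { add(sprintf("arms.%s: missing", k)); next }
      if (!prob_ok(a$ae_risk))
        add(sprintf("arms.%s.ae_risk: must be a probability in [0,1]", k))
      if (!is.finite(a$vl_reduction) || a$vl_reduction < 0 ||
          a$vl_reduction >= 1)
        add(sprintf("arms.%s.vl_reduction: must lie in [0,1)", k))
      expected_ae <- if (k == "lpvr") "diarrhoea" else "hyperbilirubinemia"
      if (!identical(a$primary_ae, expected_ae))
        add(sprintf("arms.%s.primary_ae: must be '%s'", k, expected_ae))
    }
    if (!is.null(p$arms$lpvr) && isTRUE(p$arms$lpvr$vl_reduction != 0))
      add("arms.lpvr.vl_reduction: reference arm must have reduction 0")
  }

  if (need("risks")) {
    r <- p$risks
    for (f in c("chd_base", "chd_fatal", "oi", "aids", "aids_case_fatality"))
      if (!prob_ok(r[[f]]))
        add(sprintf("risks.%s: probabilities must lie in [0,1]", f))
    if (length(r$aids) == 8) {
      sev <- r$aids[.SEVERITY_ORDER]
      if (any(diff(sev) <= 0))
        add("risks.aids: must be strictly increasing in disease severity")
    } else add("risks.aids: must have one probability per state (8)")
    for (k in c("lpvr", "atvr")) {
      ramp <- r$ckd_ramp[[k]]
      if (!prob_ok(ramp) || ramp[["start"]] <= 0)
        add(sprintf("risks.ckd_ramp.%s: endpoints must be probabilities > 0", k))
    }
    if (!is.numeric(r$ckd_ramp$n_cycles) || r$ckd_ramp$n_cycles < 2)
      add("risks.ckd_ramp.n_cycles: must be >= 2")
  }

  if (need("costs")) {
    if (!all(dim(p$costs$hs_annual) == c(8, 2)))
      add("costs.hs_annual: must be an 8 x 2 (lpvr, atvr) matrix")
    if (any(p$costs$hs_annual < 0) || any(p$costs$event < 0))
      add("costs: all costs must be >= 0")
    if (all(dim(p$costs$hs_annual) == c(8, 2))) {
      off <- p$costs$hs_annual[, "atvr"] - p$costs$hs_annual[, "lpvr"]
      # printed values round to the cent, so the offset is constant only
      # within a few cents
      if (diff(range(off)) > 0.05 + 1e-9)
        add("costs.hs_annual: ATV+r minus LPV/r state-cost offset must be constant (within rounding)")
    }
    missing_ev <- setdiff(c("aids", "chd", "oi", "hyperbilirubinemia",
                            "diarrhoea", "ckd"), names(p$costs$event))
    if (length(missing_ev))
      add(sprintf("costs.event: missing %s", paste(missing_ev, collapse = ", ")))
  }

  if (need("utilities")) {
    u <- p$utilities
    allw <- c(u$hs, u$hs_chd, unlist(u$event), u$second_line)
    if (!prob_ok(allw)) add("utilities: all weights must lie in [0,1]")
    if (length(u$hs) == 8) {
      if (any(diff(u$hs[c(1, 3, 5, 7)]) > 1e-12) ||
          any(diff(u$hs[c(2, 4, 6, 8)]) > 1e-12))
        add("utilities.hs: must be non-increasing with falling CD4 within each viral-load class")
      if (abs(u$second_line - u$hs[7]) > 1e-9 ||
          abs(u$hs[7] - u$hs[8]) > 1e-9)
        add("utilities.second_line: must equal the state-7/8 weight")
    } else add("utilities.hs: must have one weight per state (8)")
    if (!u$combine %in% c("minimum", "multiplicative"))
      add("utilities.combine: must be 'minimum' or 'multiplicative'")
  }

  if (need("economics")) {
    e <- p$economics
    if (!is.finite(e$annual_discount_rate) || e$annual_discount_rate < 0)
      add("economics.annual_discount_rate: must be >= 0")
    if (!isTRUE(all.equal(e$cycle_length, 0.5)))
      add("economics.cycle_length: the model is semestral, cycle_length must be 0.5")
    if (!is.finite(e$wtp_threshold) || e$wtp_threshold <= 0)
      add("economics.wtp_threshold: must be > 0")
    if (!is.finite(e$cohort_size) || e$cohort_size < 1)
      add("economics.cohort_size: must be >= 1")
  }

  if (need("transitions")) {
    d <- p$transitions$diagonals
    if (!all(dim(d) == c(8, 4)) ||
        !all(c("lpvr", "atvr1", "atvr2", "second") %in% colnames(d)))
      add("transitions.diagonals: must be 8 x {lpvr, atvr1, atvr2, second}")
    else if (any(d < 0) || any(d >= 1))
      add("transitions.diagonals: self-transition probabilities must lie in [0,1)")
  }

  if (need("demographics")) {
    dg <- p$demographics
    if (!is.finite(dg$age_mean) || dg$age_mean < dg$min_age)
      add("demographics.age_mean: must be >= min_age")
    if (!is.finite(dg$age_sd) || dg$age_sd < 0)
      add("demographics.age_sd: must be >= 0")
    if (dg$min_age < 18)
      add("demographics.min_age: adults only (>= 18)")
    for (f in c("male_fraction", "prior_dm", "prior_chd"))
      if (!prob_ok(dg[[f]]))
        add(sprintf("demographics.%s: must be a probability", f))
    ssp <- dg$start_state_probs
    if (length(ssp) != 8 || any(ssp < 0) ||
        abs(sum(ssp) - 1) > 1e-9)
      add("demographics.start_state_probs: must be 8 non-negative probabilities summing to 1")
  }

  if (need("life_table")) {
    for (s in c("male", "female")) {
      co <- p$life_table$makeham[[s]]
      if (is.null(co) || length(co) != 3 || any(!is.finite(co)) ||
          co[["a"]] < 0 || co[["b"]] < 0)
        add(sprintf("life_table.makeham.%s: coefficients (a, b, g) with a, b >= 0", s))
    }
    if (!is.finite(p$life_table$mrr) || p$life_table$mrr <= 0)
      add("life_table.mrr: mortality-rate-ratio must be > 0")
    if (!is.finite(p$life_table$max_age) || p$life_table$max_age < 60)
      add("life_table.max_age: implausibly low closing age")
  }

  v
}

# Fields stored as percentages in the configuration file (as printed in the
# source tables); divided by 100 on load, multiplied by 100 on dump.
.PCT_PATHS <- list(
  c("arms", "lpvr", "ae_risk"), c("arms", "atvr1", "ae_risk"),
  c("arms", "atvr2", "ae_risk"),
  c("risks", "chd_base"), c("risks", "chd_fatal"), c("risks", "oi"),
  c("risks", "aids"), c("risks", "aids_case_fatality"),
  c("risks", "ckd_ramp", "lpvr"), c("risks", "ckd_ramp", "atvr"),
  c("demographics", "male_fraction"), c("demographics", "prior_dm"),
  c("demographics", "prior_chd")
)

.get_path <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

.set_path <- function(x, path, value) {
  if (length(path) == 1L) {
    if (is.list(x)) x[[path]] <- value
    else x[path] <- value  # named atomic vector element
    return(x)
  }
  x[[path[1L]]] <- .set_path(x[[path[1L]]], path[-1L], value)
  x
}

.scale_paths <- function(x, factor) {
  for (pt in .PCT_PATHS) {
    cur <- tryCatch(.get_path(x, pt), error = function(e) NULL)
    if (!is.null(cur) && is.numeric(cur))
      x <- .set_path(x, pt, cur * factor)
  }
  x
}

#' Convert a parameter set to its configuration representation
#'
#' Inverse of [load_model_config()]: returns a plain list in the on-disk
#' schema, with risk and demographic fields expressed as percentages (the
#' form in which the source tables print them).
#'
#' @param p a `cea_params` list.
#' @return A plain nested list suitable for [yaml::write_yaml()] or
#'   [jsonlite::write_json()].
#' @export
as_config_list <- function(p) {
  x <- unclass(p)
  x <- .scale_paths(x, 100)
  # matrices serialise as named column lists
  x$costs$hs_annual <- list(lpvr = unname(p$costs$hs_annual[, "lpvr"]),
                            atvr = unname(p$costs$hs_annual[, "atvr"]))
  x$transitions$diagonals <- lapply(
    setNames(colnames(p$transitions$diagonals),
             colnames(p$transitions$diagonals)),
    function(k) unname(p$transitions$diagonals[, k]))
  x$risks$chd_base <- as.list(x$risks$chd_base)
  x$risks$ckd_ramp$lpvr <- as.list(x$risks$ckd_ramp$lpvr)
  x$risks$ckd_ramp$atvr <- as.list(x$risks$ckd_ramp$atvr)
  x$costs$event <- as.list(x$costs$event)
  x$life_table$makeham <- lapply(x$life_table$makeham, as.list)
  x
}

.config_to_params <- function(x) {
  x$costs$hs_annual <- cbind(lpvr = as.numeric(x$costs$hs_annual$lpvr),
                             atvr = as.numeric(x$costs$hs_annual$atvr))
  x$transitions$diagonals <- do.call(
    cbind, lapply(x$transitions$diagonals, as.numeric))
  x$risks$chd_base <- unlist(x$risks$chd_base)
  x$risks$ckd_ramp$lpvr <- unlist(x$risks$ckd_ramp$lpvr)
  x$risks$ckd_ramp$atvr <- unlist(x$risks$ckd_ramp$atvr)
  x$costs$event <- unlist(x$costs$event)
  x$life_table$makeham <- lapply(x$life_table$makeham, unlist)
  x <- .scale_paths(x, 1 / 100)
  class(x) <- "cea_params"
  x
}

.deep_merge <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base)) return(override)
  for (k in names(override)) base[[k]] <- .deep_merge(base[[k]], override[[k]])
  base
}

#' Load a model configuration
#'
#' Reads a YAML or JSON configuration, fills every omitted field with the
#' packaged base case, converts percentage fields to probabilities, and
#' validates the result. The packaged default lives at
#' `system.file("extdata", "base_case.yaml", package = "hivcea")`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   `NULL` for the packaged base case.
#' @return A validated `cea_params` list.
#' @export
#' @examples
#' p <- load_model_config()      # packaged base case
#' p$risks$chd_fatal             # 0.354
load_model_config <- function(path = NULL) {
  base <- as_config_list(default_parameters())
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- tryCatch(
      if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
      else yaml::read_yaml(path),
      error = function(e) stop("cannot parse configuration '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(user)) user <- list()  # empty file -> all defaults
    if (!is.list(user))
      stop("configuration '", path, "' is not a mapping/object")
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop("configuration '", path, "': unknown top-level key(s): ",
           paste(unknown, collapse = ", "))
  }
  merged <- .deep_merge(base, user)
  p <- .config_to_params(merged)
  viol <- validate_parameters(p)
  if (length(viol))
    stop("invalid model configuration:\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  p
}

#' Write a model configuration
#'
#' @param p a `cea_params` list.
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(p, path) {
  x <- as_config_list(p)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("<cea_params> semiannual HIV cost-utility model parameters\n")
  cat("  arms:", paste(vapply(x$arms, `[[`, "", "name"), collapse = ", "),
      "\n")
  cat(sprintf("  discount %.1f%%/yr, WTP %s euro/QALY, cohort %s\n",
              100 * x$economics$annual_discount_rate,
              format(x$economics$wtp_threshold, big.mark = ","),
              format(x$economics$cohort_size, big.mark = ",")))
  viol <- validate_parameters(x)
  cat("  validation:", if (length(viol)) paste(length(viol), "violation(s)")
      else "ok", "\n")
  invisible(x)
}
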