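# Synthetic-data module: parametric life tables with an HIV
# mortality-rate-ratio and baseline cohort generation, so the full pipeline
# runs without external downloads. The national life table and the
# HIV-cohort mortality-rate-ratios used in the original analysis are not
# published; a Gompertz-Makeham stand-in approximating a modern Western
# European population is used, and any real table can be supplied via CSV.

#' Build a parametric life table
#'
#' Annual death probabilities from a Gompertz-Makeham hazard
#' `h(age) = a + b * exp(g * age)` per sex, multiplied by an HIV
#' mortality-rate-ratio (MRR) on the hazard scale:
#' `q(age, sex) = 1 - exp(-mrr * h(age))`, capped at 1, with
#' `q(max_age, .) = 1` closing the table.
#'
#' @param makeham list with numeric vectors `male` and `female`, each with
#'   named elements `a`, `b`, `g` (hazards must be non-negative).
#' @param mrr mortality-rate-ratio multiplier (> 0); 1 for the general
#'   population.
#' @param max_age closing age (death certain at this age).
#' @param source tag describing the table's origin.
#' @return A list of class `life_table` with components `q` (matrix ages
#'   `0..max_age` x sexes `male`, `female`), `mrr`, `max_age`, `source`.
#' @export
#' @examples
#' lt <- make_life_table(mrr = 3)
#' lt$q["40", "male"]
make_life_table <- function(makeham = default_parameters()$life_table$makeham,
                            mrr = 1, max_age = 110,
                            source = "gompertz-makeham synthetic") {
  stopifnot(mrr > 0, max_age > 0)
  ages <- 0:max_age
  q <- sapply(c("male", "female"), function(s) {
    co <- makeham[[s]]
    if (is.null(co) || any(!is.finite(co)) || co[["a"]] < 0 || co[["b"]] < 0)
      stop("invalid Gompertz-Makeham coefficients for ", s)
    h <- co[["a"]] + co[["b"]] * exp(co[["g"]] * ages)
    pmin(1 - exp(-mrr * h), 1)
  })
  q[nrow(q), ] <- 1
  rownames(q) <- ages
  structure(list(q = q, mrr = mrr, max_age = max_age, source = source),
            class = "life_table")
}

#' Life table from a parameter set
#'
#' Convenience wrapper applying the configured MRR and coefficients.
#' @param p a `cea_params` list.
#' @return A `life_table`.
#' @export
life_table_from_params <- function(p) {
  make_life_table(p$life_table$makeham, mrr = p$life_table$mrr,
                  max_age = p$life_table$max_age)
}

# Vectorised annual-q lookup by (age, sex). Ages below 0 clamp to 0, above
# the closing age to the closing row (q = 1).
.lt_q <- function(lt, age, male) {
  i <- pmin(pmax(floor(age), 0), lt$max_age) + 1L
  j <- ifelse(male, 1L, 2L)
  lt$q[cbind(i, j)]
}

#' Write / read a life table as CSV
#'
#' Plain-text interchange: columns `age`, `sex`, `qx`.
#' @param lt a `life_table`.
#' @param path CSV path.
#' @return `path` (write) or a `life_table` (read).
#' @export
write_life_table <- function(lt, path) {
  df <- data.frame(
    age = rep(0:lt$max_age, 2),
    sex = rep(c("male", "female"), each = lt$max_age + 1),
    qx = c(lt$q[, "male"], lt$q[, "female"])
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("age", "sex", "qx") %in% names(df)))
  max_age <- max(df$age)
  q <- sapply(c("male", "female"), function(s) {
    sub <- df[df$sex == s, ]
    sub$qx[order(sub$age)]
  })
  rownames(q) <- 0:max_age
  if (any(q < 0) || any(q > 1)) stop("qx values must lie in [0,1]")
  q[nrow(q), ] <- 1
  structure(list(q = q, mrr = 1, max_age = max_age, source = path),
            class = "life_table")
}

#' Remaining life expectancy from a life table
#'
#' Deterministic life-table recursion on semestral steps under a uniform
#' hazard within each year of age (semestral survival `(1 - q)^(1/2)`).
#' Matches the microsimulation's survival convention exactly: survival is
#' accumulated in half-year steps, each conditional on surviving that
#' semester's death draw.
#'
#' @param lt a `life_table`.
#' @param age starting age in years.
#' @param sex `"male"` or `"female"`.
#' @return Expected remaining lifetime in years.
#' @export
#' @examples
#' life_expectancy(make_life_table(mrr = 3), 39.2, "male")
life_expectancy <- function(lt, age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  male <- sex == "male"
  surv <- 1
  total <- 0
  a <- age
  # beyond the closing age q = 1, so the loop terminates
  while (surv > 1e-14 && a <= lt$max_age + 1) {
    p_sem <- 1 - sqrt(1 - .lt_q(lt, a, male))
    surv <- surv * (1 - p_sem)
    total <- total + 0.5 * surv
    a <- a + 0.5
  }
  total
}

#' Generate a synthetic baseline cohort
#'
#' Draws baseline patients matching the study demographics: age from a
#' normal distribution truncated below at `min_age` (inverse-CDF sampling),
#' sex, prior diabetes and prior CHD as independent Bernoulli draws, and
#' the starting health state from `start_state_probs` (default: all mass on
#' detectable-VL states, reflecting the enrolment criterion of viral load
#' >= 5000 copies/mL).
#'
#' @param n number of patients (>= 1).
#' @param demographics list as in `default_parameters()$demographics`.
#' @param start_state_probs length-8 probability vector; defaults to
#'   `demographics$start_state_probs`.
#' @param seed optional integer seed for reproducibility; `NULL` uses the
#'   current RNG stream.
#' @return A data frame of class `baseline_cohort` with columns `age`,
#'   `male`, `prior_dm`, `prior_chd`, `start_state`.
#' @export
#' @examples
#' cohort <- generate_baseline_cohort(1000, seed = 42)
#' mean(cohort$age)
generate_baseline_cohort <- function(n,
                                     demographics = default_parameters()$demographics,
                                     start_state_probs = demographics$start_state_probs,
                                     seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  dg <- demographics
  # truncated normal via inverse CDF: exact, no rejection loop
  lo <- pnorm((dg$min_age - dg$age_mean) / max(dg$age_sd, 1e-12))
  u <- runif(n, lo, 1)
  age <- if (dg$age_sd > 0) dg$age_mean + dg$age_sd * qnorm(u)
         else rep(dg$age_mean, n)
  age <- pmax(age, dg$min_age)
  out <- data.frame(
    age = age,
    male = runif(n) < dg$male_fraction,
    prior_dm = runif(n) < dg$prior_dm,
    prior_chd = runif(n) < dg$prior_chd,
    start_state = sample.int(8L, n, replace = TRUE,
                             prob = start_state_probs)
  )
  class(out) <- c("baseline_cohort", "data.frame")
  out
}

#' Export a cohort to CSV
#' @param cohort a `baseline_cohort` data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table>", x$source, sprintf("(MRR %.2f, ages 0-%d)\n",
                                        x$mrr, x$max_age))
  cat(sprintf("  q(40): male %.5f, female %.5f\n",
              x$q["40", "male"], x$q["40", "female"]))
  invisible(x)
}
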