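# Arm comparison and result serialisation.

#' Compare two simulated arms
#'
#' Incremental cost, incremental QALYs and ICER-plane classification of an
#' intervention arm against a comparator, at a willingness-to-pay
#' threshold. "Per capita mean annual cost" follows the lifetime-table
#' convention: mean discounted lifetime cost divided by mean undiscounted
#' survival.
#'
#' @param a intervention `cea_arm_summary`.
#' @param b comparator `cea_arm_summary`.
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @return A list of class `cea_comparison` with the deltas, ICER and
#'   classification.
#' @export
#' @examples
#' sa <- simulate_arm("lpvr", n = 300, seed = 1)
#' sb <- simulate_arm("atvr1", n = 300, seed = 1)
#' compare_arms(sa, sb)
compare_arms <- function(a, b, wtp = 25000) {
  stopifnot(inherits(a, "cea_arm_summary"), inherits(b, "cea_arm_summary"))
  if (a$population != b$population)
    warning("arms simulated with different population sizes")
  cls <- classify_icer_point(a$mean_lifetime_cost - b$mean_lifetime_cost,
                             a$mean_qaly - b$mean_qaly, wtp)
  structure(list(
    intervention = a$arm, comparator = b$arm,
    delta_cost = cls$delta_cost, delta_qaly = cls$delta_qaly,
    icer = cls$icer, category = cls$category,
    cost_effective = cls$cost_effective, wtp = wtp,
    a = a, b = b
  ), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s (WTP %s EUR/QALY)\n",
              x$intervention, x$comparator,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  delta cost: %10.2f EUR\n", x$delta_cost))
  cat(sprintf("  delta QALY: %10.4f\n", x$delta_qaly))
  if (!is.na(x$icer)) cat(sprintf("  ICER:       %10.2f EUR/QALY\n", x$icer))
  cat(sprintf("  category:   %s%s\n", x$category,
              if (x$cost_effective) " (cost-effective)" else ""))
  invisible(x)
}

# Stable short hash of an R object (for run metadata).
.object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.summary_df <- function(s) {
  flat <- s[!vapply(s, is.list, logical(1))]
  data.frame(field = names(flat),
             value = vapply(flat, function(v) as.character(v)[1],
                            character(1)),
             stringsAsFactors = FALSE)
}

#' Write analysis results to disk
#'
#' Emits an arm summary, a comparison or a PSA result as CSV and/or JSON,
#' with run metadata (seed where available, configuration hash, package
#' version) embedded. Output is bit-stable for fixed inputs.
#'
#' @param x a `cea_arm_summary`, `cea_comparison` or `cea_psa`.
#' @param path output path without extension (or with, it is stripped).
#' @param format any of `"csv"`, `"json"`.
#' @param params optional `cea_params` used for the run, hashed into the
#'   metadata.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json"),
                          params = NULL) {
  format <- match.arg(format, several.ok = TRUE)
  stem <- sub("\\.(csv|json)$", "", path)
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    package_version = as.character(utils::packageVersion("hivcea")),
    config_hash = if (!is.null(params)) .object_hash(unclass(params))
                  else NA_character_
  )
  files <- character(0)
  if (inherits(x, "cea_psa")) {
    meta$seed <- x$seed
    if ("csv" %in% format) {
      f <- paste0(stem, "_points.csv")
      write.csv(x$points, f, row.names = FALSE)
      files <- c(files, f)
    }
    if ("json" %in% format) {
      f <- paste0(stem, ".json")
      jsonlite::write_json(
        list(meta = meta, summary = x$summary,
             settings = x[c("intervention", "comparator", "n_outer",
                            "n_inner", "wtp", "crn")]),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, f)
    }
  } else {
    payload <- if (inherits(x, "cea_comparison"))
      c(x[c("intervention", "comparator", "delta_cost", "delta_qaly",
            "icer", "category", "cost_effective", "wtp")])
    else { meta$seed <- x$seed; x[!vapply(x, is.list, logical(1))] }
    if ("csv" %in% format) {
      f <- paste0(stem, ".csv")
      df <- data.frame(field = names(payload),
                       value = vapply(payload, function(v)
                         as.character(v)[1], character(1)))
      write.csv(df, f, row.names = FALSE)
      files <- c(files, f)
    }
    if ("json" %in% format) {
      f <- paste0(stem, ".json")
      jsonlite::write_json(list(meta = meta, results = payload), f,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read back a written arm summary (JSON)
#'
#' Round-trip counterpart of [write_results()] for arm summaries.
#' @param path the `.json` file written by [write_results()].
#' @return A list with `meta` and `results`.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
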