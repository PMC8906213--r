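#' Coefficient of variation (population form), in percent
#'
#' `100 * population SD / mean` (divisor n, not n - 1), the statistic used
#' to summarise the temporal stability of gamma pass-rate columns across
#' postirradiation time. For display the tables round to one decimal;
#' this function returns the unrounded value.
#'
#' @param values Non-empty numeric vector with non-zero mean.
#' @return COV in %.
#' @export
cov_percent <- function(values) {
  if (!length(values)) stop("cov_percent needs a non-empty vector")
  m <- mean(values)
  if (m == 0) stop("cov_percent undefined for zero mean")
  100 * sqrt(mean((values - m)^2)) / m
}

#' Range statistic (maximum minus minimum)
#'
#' @param values Non-empty numeric vector.
#' @return `max(values) - min(values)`.
#' @export
range_stat <- function(values) {
  if (!length(values)) stop("range_stat needs a non-empty vector")
  max(values) - min(values)
}

#' Clinical difference summary between two pass-rate sets
#'
#' Compares pass rates from a tested workflow against the "true" result of
#' each facility's established methodology: per-case absolute difference
#' plus the mean, maximum and range of those absolute differences.
#'
#' @param true_results Pass rates from the reference methodology (%).
#' @param tested_results Pass rates from the workflow under test (%),
#'   same length and order.
#' @return Object of class `clinical_diff`: data frame (`true`, `tested`,
#'   `abs_diff`) with attributes `mean_abs_diff`, `max_abs_diff`,
#'   `range_abs_diff` (all unrounded; print rounds to one decimal).
#' @export
clinical_diff_table <- function(true_results, tested_results) {
  if (length(true_results) != length(tested_results)) {
    stop("true and tested result vectors must have equal length")
  }
  if (!length(true_results)) stop("need at least one case")
  d <- abs(true_results - tested_results)
  out <- data.frame(true = true_results, tested = tested_results,
                    abs_diff = d)
  class(out) <- c("clinical_diff", "data.frame")
  attr(out, "mean_abs_diff") <- mean(d)
  attr(out, "max_abs_diff") <- max(d)
  attr(out, "range_abs_diff") <- max(d) - min(d)
  out
}

#' @export
print.clinical_diff <- function(x, ...) {
  df <- data.frame(true = x$true, tested = x$tested,
                   abs_diff = round(x$abs_diff, 1))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("mean |diff| %.1f%%, max |diff| %.1f%%, range %.1f%%\n",
              attr(x, "mean_abs_diff"), attr(x, "max_abs_diff"),
              attr(x, "range_abs_diff")))
  invisible(x)
}

#' Reference pass-rate tables from the clinical validation study
#'
#' Gamma pass-rate tables (1%/1 mm) measured in the clinical validation of
#' the temporal-calibration method: five EBT3 and five EBT-XD
#' patient-specific QA cases scanned repeatedly over 20 h postirradiation
#' and converted to dose either with the time-matched calibration curve
#' (`*_tcm`) or with a single fixed 20-h curve (`*_single`);
#' plus the two-facility implementation trial (`clinical_trial`:
#' per-case pass rates at 2%/1 mm for the TCM, a single fixed calibration,
#' and each facility's own "true" methodology). Shipped as plain-text CSV
#' under `extdata/qa-tables/`.
#'
#' @param name One of `"ebt3_tcm"`, `"ebt3_single"`, `"ebtxd_tcm"`,
#'   `"ebtxd_single"`, `"clinical_trial"`.
#' @return A data frame.
#' @export
qa_validation_table <- function(name = c("ebt3_tcm", "ebt3_single",
                                         "ebtxd_tcm", "ebtxd_single",
                                         "clinical_trial")) {
  name <- match.arg(name)
  path <- system.file("extdata", "qa-tables", paste0(name, ".csv"),
                      package = "filmtcm", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
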