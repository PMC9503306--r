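#' Reference cohort summary statistics
#'
#' Published per-arm summary statistics (mean and SD) of the four
#' flow-deficit biomarkers at window radii 4 and 8 px for a
#' hydroxychloroquine cohort imaged on a 6 x 6 mm macular field: arm `1a`
#' (treated, no retinopathy), `1b` (toxic retinopathy) and `2` (healthy
#' controls). Shipped as plain CSV and used by the test suite to check
#' the arithmetic link between deficit percentage and total deficit area
#' on a 36 mm^2 field (`fd_total_area_mm2 = fd_percent/100 * 36`). The
#' `1a` rows are known to violate that identity as printed and are not
#' used as consistency anchors.
#'
#' @return Data frame with columns `group, radius_px, metric, mean, sd`.
#' @export
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_summary.csv",
                      package = "ccfd", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(group = "character"))
}

#' @useDynLib ccfd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
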