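comparison_result <- function(metric, test, statistic, p_value, groups) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p-value outside [0, 1]")
  data.frame(metric = metric, test = test, statistic = statistic,
             p_value = p_value, groups = groups, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis omnibus comparison across groups
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on `k - 1` degrees of freedom, as the omnibus test for a
#' difference in a flow-deficit metric across the study arms. When every
#' observation is identical the ranks carry no information; the tie
#' correction degenerates and H is defined as 0 with p = 1.
#'
#' @param values Named list of numeric vectors, one per group (>= 2
#'   observations each).
#' @param metric Metric label carried into the result row.
#' @return A one-row data frame: `metric, test, statistic, p_value,
#'   groups`.
#' @export
kruskal_wallis <- function(values, metric = NA_character_) {
  if (!is.list(values) || length(values) < 2)
    stop("`values` must be a list of at least two groups")
  if (any(vapply(values, length, 1L) < 2))
    stop("every group needs at least 2 observations")
  groups <- paste(names2(values), collapse = " vs ")
  all_v <- unlist(values, use.names = FALSE)
  if (length(unique(all_v)) == 1L)
    return(comparison_result(metric, "kruskal_wallis", 0, 1, groups))
  kt <- stats::kruskal.test(values)
  comparison_result(metric, "kruskal_wallis",
                    unname(kt$statistic), unname(kt$p.value), groups)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("group", seq_along(x))
  nm[nm == ""] <- paste0("group", seq_along(x))[nm == ""]
  nm
}

#' Mann-Whitney (Wilcoxon rank-sum) pairwise comparison
#'
#' Two-sided test on the U statistic. With `mode = "auto"` an exact p is
#' used when the combined sample size is at most 12 and the pooled data
#' contain no ties (enumeration is cheap and exact there); otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @param metric Metric label carried into the result row.
#' @param groups Group label carried into the result row.
#' @return A one-row data frame (see [kruskal_wallis()]); `statistic` is
#'   the U statistic of the first sample.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                         metric = NA_character_, groups = NA_character_) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be nonempty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
                  auto = length(a) + length(b) <= 12 && !has_ties,
                  exact = TRUE,
                  normal_approx = FALSE)
  if (identical(a, b) || (length(a) == length(b) &&
                          all(sort(a) == sort(b)))) {
    # same multiset: no evidence of a shift in either direction
    u <- length(a) * length(b) / 2
    return(comparison_result(metric, "mann_whitney", u, 1, groups))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  comparison_result(metric, "mann_whitney",
                    unname(wt$statistic), min(unname(wt$p.value), 1), groups)
}

#' Welch two-sample t comparison
#'
#' Two-sided t statistic with Welch-Satterthwaite degrees of freedom. If
#' both groups have zero variance, equal means give `t = 0, p = 1` by
#' convention and unequal means are an error (the statistic is undefined).
#'
#' @inheritParams mann_whitney
#' @return A one-row data frame (see [kruskal_wallis()]).
#' @export
welch_t <- function(a, b, metric = NA_character_, groups = NA_character_) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(comparison_result(metric, "welch_t", 0, 1, groups))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  comparison_result(metric, "welch_t",
                    unname(tt$statistic), unname(tt$p.value), groups)
}

fd_covariates <- c("age", "treatment_duration", "daily_dose_mg_per_kg",
                   "cumulative_dose_g")

#' Multiple linear regression of a flow-deficit metric on dose covariates
#'
#' Ordinary least squares of a per-eye metric on age, treatment duration,
#' daily dose (mg/kg) and cumulative dose (g), with intercept — the
#' standard screen for a dose- or age-driven gradient in choriocapillaris
#' deficits among treated eyes. Rank-deficient designs raise an explicit
#' singularity error naming the collinear columns.
#'
#' @param records Data frame with columns `radius_px`, the metric, and
#'   the four covariates (`age`, `treatment_duration`,
#'   `daily_dose_mg_per_kg`, `cumulative_dose_g`), one row per eye per
#'   radius. Both eyes of a subject are treated as independent
#'   observations (a deliberate simplification; see the vignette).
#' @param metric Name of the metric column to regress.
#' @param radius Window radius (4 or 8) selecting the rows to use.
#' @return Data frame with one row per term: `term, estimate, std_error,
#'   t_value, p_value`.
#' @export
fd_regression <- function(records, metric, radius) {
  stopifnot(is.data.frame(records))
  need <- c("radius_px", metric, fd_covariates)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "))
  d <- records[records$radius_px == radius, c(metric, fd_covariates)]
  if (anyNA(d)) stop("missing covariate or metric values among included records")
  if (nrow(d) < length(fd_covariates) + 2)
    stop("need at least 2 more records than covariates")
  x <- cbind(`(Intercept)` = 1, as.matrix(d[fd_covariates]))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(fd_covariates, response = metric),
                   data = d)
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
             t_value = cf[, 3], p_value = cf[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

fd_metrics <- c("fd_percent", "fd_count", "fd_mean_size_um2",
                "fd_total_area_mm2")

#' Group comparisons for every flow-deficit metric and radius
#'
#' Builds the full comparison table over a per-eye report data frame:
#' for each metric and radius, a Kruskal-Wallis omnibus row when three or
#' more groups are present, plus Mann-Whitney and Welch rows for every
#' group pair. Raw p-values are reported without multiplicity correction,
#' one test family per metric, matching common reporting practice for
#' these biomarkers.
#'
#' @param per_eye Data frame in the report schema of [write_fd_report()].
#' @param radii Radii to analyze (default both 4 and 8).
#' @return Data frame with columns `metric, radius_px, test, statistic,
#'   p_value, groups`.
#' @export
compare_groups <- function(per_eye, radii = c(4L, 8L)) {
  stopifnot(is.data.frame(per_eye))
  groups <- sort(unique(per_eye$group))
  if (length(groups) < 2)
    stop("cohort comparison needs at least two groups")
  rows <- list()
  for (r in radii) {
    dr <- per_eye[per_eye$radius_px == r, ]
    for (m in fd_metrics) {
      vals <- lapply(groups, function(g) dr[dr$group == g, m])
      names(vals) <- groups
      if (length(groups) >= 3) {
        row <- tryCatch(
          kruskal_wallis(vals, metric = m),
          error = function(e)
            comparison_result(m, "kruskal_wallis", NA_real_, NA_real_,
                              paste(groups, collapse = " vs ")))
        row$radius_px <- r
        rows[[length(rows) + 1L]] <- row
      }
      for (i in seq_len(length(groups) - 1)) {
        for (j in seq(i + 1, length(groups))) {
          lab <- paste(groups[i], "vs", groups[j])
          # a degenerate pair (e.g. zero variance with unequal means) gets
          # an NA row rather than aborting the whole comparison table
          na_row <- function(test)
            comparison_result(m, test, NA_real_, NA_real_, lab)
          mw <- tryCatch(
            mann_whitney(vals[[i]], vals[[j]], metric = m, groups = lab),
            error = function(e) na_row("mann_whitney"))
          wt <- tryCatch(
            welch_t(vals[[i]], vals[[j]], metric = m, groups = lab),
            error = function(e) na_row("welch_t"))
          mw$radius_px <- r
          wt$radius_px <- r
          rows[[length(rows) + 1L]] <- mw
          rows[[length(rows) + 1L]] <- wt
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[c("metric", "radius_px", "test", "statistic", "p_value", "groups")]
}
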