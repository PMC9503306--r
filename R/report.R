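#' Per-eye flow-deficit report
#'
#' The four flow-deficit biomarkers for one eye and one threshold radius:
#' deficit percentage of the imaged field, number of connected deficit
#' components, mean component area in square microns, and total deficit
#' area in square millimetres. Produced by [quantify_fd()].
#'
#' @param fd_percent Percentage of the field classified as deficit, in
#'   `[0, 100]`.
#' @param fd_count Number of connected deficit components.
#' @param fd_mean_size_um2 Mean component area (um^2); 0 when
#'   `fd_count == 0`.
#' @param fd_total_area_mm2 Summed deficit area (mm^2).
#' @param radius_px Window radius (pixels) of the mask this report came
#'   from, or `NA`.
#' @param geometry The [scan_geometry()] of the source mask.
#' @param eye_id,group Optional identifiers carried through to cohort
#'   reports.
#'
#' @return An object of class `fd_report`.
#' @export
fd_report <- function(fd_percent, fd_count, fd_mean_size_um2,
                      fd_total_area_mm2, radius_px = NA_integer_,
                      geometry = NULL, eye_id = NA_character_,
                      group = NA_character_) {
  if (fd_percent < 0 || fd_percent > 100)
    stop("`fd_percent` must lie in [0, 100]")
  fd_count <- as.integer(fd_count)
  if (fd_count < 0) stop("`fd_count` must be nonnegative")
  if ((fd_count == 0) != (fd_total_area_mm2 == 0))
    stop("`fd_count` is zero if and only if `fd_total_area_mm2` is zero")
  structure(
    list(fd_percent = fd_percent, fd_count = fd_count,
         fd_mean_size_um2 = fd_mean_size_um2,
         fd_total_area_mm2 = fd_total_area_mm2,
         radius_px = as.integer(radius_px), geometry = geometry,
         eye_id = eye_id, group = group),
    class = "fd_report"
  )
}

#' @export
print.fd_report <- function(x, ...) {
  cat(sprintf(
    "fd_report (radius %s px): FD%% = %.2f, count = %d, mean size = %.2f um^2, total area = %.4f mm^2\n",
    ifelse(is.na(x$radius_px), "NA", x$radius_px),
    x$fd_percent, x$fd_count, x$fd_mean_size_um2, x$fd_total_area_mm2))
  invisible(x)
}

report_schema <- c("eye_id", "group", "radius_px", "fd_percent", "fd_count",
                   "fd_mean_size_um2", "fd_total_area_mm2")

#' @export
as.data.frame.fd_report <- function(x, ...) {
  data.frame(eye_id = x$eye_id, group = x$group, radius_px = x$radius_px,
             fd_percent = x$fd_percent, fd_count = x$fd_count,
             fd_mean_size_um2 = x$fd_mean_size_um2,
             fd_total_area_mm2 = x$fd_total_area_mm2,
             stringsAsFactors = FALSE)
}

reports_to_df <- function(reports) {
  if (is.data.frame(reports)) {
    missing <- setdiff(report_schema, names(reports))
    if (length(missing))
      stop("report data frame lacks columns: ", paste(missing, collapse = ", "))
    return(reports[report_schema])
  }
  if (length(reports) == 0)
    return(stats::setNames(
      data.frame(character(), character(), integer(), numeric(), integer(),
                 numeric(), numeric(), stringsAsFactors = FALSE),
      report_schema))
  do.call(rbind, lapply(reports, as.data.frame))
}

#' Write per-eye flow-deficit reports as CSV
#'
#' One row per eye per radius with columns `eye_id, group, radius_px,
#' fd_percent, fd_count, fd_mean_size_um2, fd_total_area_mm2` (RFC 4180,
#' header row, dot decimal separator). When `params` is given, the exact
#' processing parameter set is recorded as `#`-prefixed comment lines
#' before the header, since flow-deficit numbers are only comparable
#' between runs that share every parameter.
#'
#' @param reports A list of [fd_report()] objects or a data frame already
#'   in the report schema.
#' @param path Output CSV path.
#' @param params Optional named list of processing parameters to log.
#' @return Invisibly, `path`.
#' @export
write_fd_report <- function(reports, path, params = NULL) {
  df <- reports_to_df(reports)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    for (nm in names(params))
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(params[[nm]]), collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_report
#' @export
read_fd_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
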