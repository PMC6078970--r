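# Curve and series I/O: the de-facto small-angle scattering ASCII
# dialect (three whitespace-separated columns q, I, sigma; '#' comments)
# plus a manifest CSV (filename, time_s) for time series.

#' Write a scattering curve as a 3-column ASCII .dat file
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @param comments character vector of header comment lines (written
#'   with a leading `#`).
#' @return invisibly, the path.
#' @export
write_curve_dat <- function(curve, path, comments = character()) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines("# q_invA I_abs sigma", con)
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma), con)
  invisible(path)
}

#' Read a 3-column ASCII scattering curve
#'
#' Accepts the common small-angle scattering .dat dialect: whitespace
#' separated columns q, I, sigma; lines starting with `#` (and blank
#' lines) are ignored.
#'
#' @param path input path.
#' @return a [scattering_curve()].
#' @export
read_curve_dat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data lines in ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(x) {
    if (length(x) < 3L) stop("expected 3 columns (q, I, sigma) in ", path)
    as.numeric(x[1:3])
  }))
  if (anyNA(m)) stop("non-numeric data in ", path)
  scattering_curve(m[, 1L], m[, 2L], m[, 3L])
}

#' Write a frame series as a directory of .dat files plus manifest
#'
#' One `frame_NNNN.dat` per frame plus `manifest.csv` with columns
#' `filename, time_s`.  When the series carries ground truth, a JSON
#' sidecar `truth.json` (noiseless I0, mean occupancies, structural
#' coordinate) is written as well.
#'
#' @param series a `frame_series` (or list with `times` and `curves`).
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_frame_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- sprintf("frame_%04d.dat", seq_along(series$times))
  for (i in seq_along(series$times))
    write_curve_dat(series$curves[[i]], file.path(dir, fn[i]),
                    comments = sprintf("t = %.6g s", series$times[i]))
  manifest <- file.path(dir, "manifest.csv")
  write.csv(data.frame(filename = fn, time_s = series$times),
            manifest, row.names = FALSE, quote = FALSE)
  if (!is.null(series$truth)) {
    truth <- list(time_s = series$times, I0 = series$truth$I0,
                  mean_N = series$truth$mean_N,
                  alpha = series$truth$alpha)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(manifest)
}

#' Read a frame series from a manifest
#'
#' @param manifest path to a `manifest.csv` with columns
#'   `filename, time_s`; filenames are resolved relative to the manifest
#'   directory.
#' @return list with `times` and `curves`, ordered by time.
#' @export
read_frame_series <- function(manifest) {
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("filename", "time_s") %in% names(mf)))
    stop("manifest must have columns filename, time_s: ", manifest)
  mf <- mf[order(mf$time_s), , drop = FALSE]
  dir <- dirname(manifest)
  curves <- lapply(file.path(dir, mf$filename), read_curve_dat)
  list(times = mf$time_s, curves = curves)
}

#' Write an observable trace as CSV (t, value, sigma)
#'
#' @param trace an [observable_trace()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
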