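# File readers and writers. Canonical internal units are metres, degrees and
# seconds; all conversions happen at this boundary. Two plain-text dialects
# are supported: TRC (the tab-separated optical-capture standard) for marker
# trials, and a wide CSV with a mandatory per-frame timestamp column for the
# depth-sensor stream (and as an alternative marker container).

#' Write a landmark series as a TRC file
#'
#' @param series a `landmark_series`.
#' @param path output path.
#' @param units `"m"` or `"mm"` for the stored coordinates.
#' @export
write_trc <- function(series, path, units = "m") {
  stopifnot(inherits(series, "landmark_series"))
  scale <- switch(units, m = 1, mm = 1000,
                  stop("units must be 'm' or 'mm'", call. = FALSE))
  nms <- names(series$landmarks)
  n <- length(series$time)
  rate <- series$nominal_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d", rate, rate, n,
                     length(nms), units, rate, n), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(nms, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(nms)),
                                    rep(seq_along(nms), each = 3L))),
                   collapse = "\t"), con)
  dat <- do.call(cbind, lapply(series$landmarks, function(m) m * scale))
  rows <- cbind(seq_len(n), series$time, dat)
  utils::write.table(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a TRC marker file
#'
#' @param path TRC file path.
#' @param mapping optional named character vector mapping file marker names to
#'   the canonical vocabulary (`c(file_name = "canonical_name")`); unmapped
#'   names pass through unchanged.
#' @return a `landmark_series` (marker dialect, metres).
#' @export
read_trc <- function(path, mapping = NULL) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("not a TRC file: too short", call. = FALSE)
  hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  rate <- as.numeric(hdr[1L])
  units <- hdr[5L]
  scale <- switch(units, m = 1, mm = 1e-3,
                  stop(sprintf("unknown TRC units '%s'", units),
                       call. = FALSE))
  names_row <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]]
  nms <- names_row[-(1:2)]
  nms <- nms[nzchar(nms)]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t",
                           colClasses = "numeric")
  if (ncol(dat) != 2L + 3L * length(nms)) {
    stop("TRC data width does not match the marker count", call. = FALSE)
  }
  time <- dat[[2L]]
  lms <- list()
  for (k in seq_along(nms)) {
    cols <- 2L + (3L * (k - 1L) + 1L):(3L * k)
    canonical <- if (!is.null(mapping) && nms[k] %in% names(mapping))
      mapping[[nms[k]]] else nms[k]
    lms[[canonical]] <- as.matrix(dat[, cols]) * scale
  }
  landmark_series(time, lms, MARKER_DIALECT, rate)
}

#' Write a landmark series as a wide CSV
#'
#' Columns: `time`, then `<name>_x`, `<name>_y`, `<name>_z` per landmark,
#' coordinates in metres.
#'
#' @param series a `landmark_series`.
#' @param path output path.
#' @export
write_landmark_csv <- function(series, path) {
  stopifnot(inherits(series, "landmark_series"))
  cols <- list(time = series$time)
  for (nm in names(series$landmarks)) {
    m <- series$landmarks[[nm]]
    cols[[paste0(nm, "_x")]] <- m[, 1L]
    cols[[paste0(nm, "_y")]] <- m[, 2L]
    cols[[paste0(nm, "_z")]] <- m[, 3L]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide landmark CSV (depth-sensor dialect)
#'
#' Requires a `time` column with strictly increasing, duplicate-free
#' timestamps (a fluctuating frame rate is expected and allowed).
#'
#' @param path CSV path.
#' @param mapping optional named character vector mapping file landmark names
#'   to the canonical vocabulary.
#' @param dialect `"kinect"` (default) or `"marker"`.
#' @param nominal_rate nominal rate stored on the series (default 30).
#' @return a `landmark_series`.
#' @export
read_landmark_csv <- function(path, mapping = NULL, dialect = KINECT_DIALECT,
                              nominal_rate = 30) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing required 'time' column",
                                   call. = FALSE)
  time <- as.numeric(df$time)
  if (anyDuplicated(time)) stop("duplicate timestamps in landmark file",
                                call. = FALSE)
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing",
                                 call. = FALSE)
  coord_cols <- grep("_[xyz]$", names(df), value = TRUE)
  nms <- unique(sub("_[xyz]$", "", coord_cols))
  lms <- list()
  for (nm in nms) {
    need <- paste0(nm, c("_x", "_y", "_z"))
    if (!all(need %in% names(df))) {
      stop(sprintf("landmark '%s' lacks a full x/y/z triple", nm),
           call. = FALSE)
    }
    canonical <- if (!is.null(mapping) && nm %in% names(mapping))
      mapping[[nm]] else nm
    lms[[canonical]] <- as.matrix(df[, need])
  }
  landmark_series(time, lms, dialect, nominal_rate)
}

#' Read a marker trial (TRC or wide CSV, by extension)
#'
#' @param path file path (`.trc` or `.csv`).
#' @param mapping optional file-to-canonical name mapping.
#' @return a `landmark_series` (marker dialect).
#' @export
read_marker_file <- function(path, mapping = NULL) {
  if (grepl("\\.trc$", path, ignore.case = TRUE)) {
    read_trc(path, mapping)
  } else {
    read_landmark_csv(path, mapping, dialect = MARKER_DIALECT,
                      nominal_rate = 100)
  }
}

#' Write an agreement report to JSON and CSV tables
#'
#' @param report an `agreement_report`.
#' @param prefix output path prefix; writes `<prefix>.json`,
#'   `<prefix>_waveform.csv`, `<prefix>_discrete.csv`.
#' @export
write_agreement_report <- function(report, prefix) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(list(kind = report$kind, waveform = report$waveform,
                            discrete = report$discrete),
                       paste0(prefix, ".json"), digits = 10, na = "null")
  utils::write.csv(report$waveform, paste0(prefix, "_waveform.csv"),
                   row.names = FALSE)
  utils::write.csv(report$discrete, paste0(prefix, "_discrete.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
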