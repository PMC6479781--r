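# Shared time-series containers and preprocessing: resampling to a uniform
# grid, zero-phase low-pass filtering, gait-cycle time normalization, and
# cycle averaging. Both kinematics backends run on top of these.

MARKER_DIALECT <- "marker"
KINECT_DIALECT <- "kinect"

#' Timestamped named landmark trajectories
#'
#' The common container for both measurement streams: a shared (strictly
#' increasing, possibly nonuniform) time base and one n x 3 coordinate matrix
#' per named landmark, metres, lab frame.
#'
#' @param time numeric vector of timestamps, seconds, strictly increasing.
#' @param landmarks named list of n x 3 numeric matrices.
#' @param dialect `"marker"` (optical, ~100 Hz) or `"kinect"` (depth sensor,
#'   fluctuating ~30 Hz).
#' @param nominal_rate nominal sampling rate in Hz.
#' @return object of class `landmark_series`.
#' @export
landmark_series <- function(time, landmarks, dialect, nominal_rate) {
  if (length(time) < 1L || any(diff(time) <= 0)) {
    stop("time must be non-empty and strictly increasing", call. = FALSE)
  }
  if (!dialect %in% c(MARKER_DIALECT, KINECT_DIALECT)) {
    stop("dialect must be 'marker' or 'kinect'", call. = FALSE)
  }
  if (is.null(names(landmarks)) || any(!nzchar(names(landmarks)))) {
    stop("landmarks must be a fully named list", call. = FALSE)
  }
  landmarks <- lapply(landmarks, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(time) || ncol(m) != 3L) {
      stop("each landmark needs one 3D position per timestamp", call. = FALSE)
    }
    if (any(!is.finite(m))) stop("landmark positions must be finite",
                                 call. = FALSE)
    m
  })
  structure(list(time = as.numeric(time), landmarks = landmarks,
                 dialect = dialect, nominal_rate = nominal_rate),
            class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series dialect=%s  %d frames  %.2f s  %d landmarks>\n",
              x$dialect, length(x$time), diff(range(x$time)),
              length(x$landmarks)))
  cat("  ", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

# Fetch a landmark by canonical name, with an informative error.
get_landmark <- function(series, name) {
  m <- series$landmarks[[name]]
  if (is.null(m)) {
    stop(sprintf("required landmark '%s' is missing from the %s series",
                 name, series$dialect), call. = FALSE)
  }
  m
}

#' Uniformly sampled joint-angle trajectories
#'
#' @param time numeric, uniform grid, seconds.
#' @param angles n x d numeric matrix, degrees.
#' @param dof_names character vector naming the d angle channels.
#' @return object of class `angle_series`.
#' @export
angle_series <- function(time, angles, dof_names = colnames(angles)) {
  angles <- as.matrix(angles)
  if (nrow(angles) != length(time)) {
    stop("angles must have one row per timestamp", call. = FALSE)
  }
  if (length(time) >= 3L) {
    dt <- diff(time)
    if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
      stop("angle_series requires a uniform time grid", call. = FALSE)
    }
  }
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  colnames(angles) <- dof_names
  structure(list(time = as.numeric(time), angles = angles,
                 dof_names = dof_names), class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series  %d frames  %.1f Hz  [%s]>\n", length(x$time),
              1 / mean(diff(x$time)), paste(x$dof_names, collapse = ", ")))
  invisible(x)
}

#' One gait cycle of joint angles on the 0-100% grid
#'
#' @param values 101 x d numeric matrix, degrees; row k is cycle fraction
#'   `(k-1)` percent.
#' @param dof_names channel names.
#' @param trial,day optional provenance labels.
#' @return object of class `angle_cycle`.
#' @export
angle_cycle <- function(values, dof_names = colnames(values),
                        trial = NA_character_, day = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) != 101L) stop("a gait cycle has exactly 101 rows",
                                 call. = FALSE)
  if (any(!is.finite(values))) stop("cycle values must be finite",
                                    call. = FALSE)
  colnames(values) <- dof_names
  structure(list(values = values, dof_names = dof_names,
                 trial = trial, day = day), class = "angle_cycle")
}

# Cubic interpolation of each column of `y` from `t` onto `tout`.
interp_columns <- function(t, y, tout) {
  y <- as.matrix(y)
  out <- matrix(NA_real_, length(tout), ncol(y))
  for (j in seq_len(ncol(y))) {
    out[, j] <- stats::spline(t, y[, j], xout = tout, method = "fmm")$y
  }
  colnames(out) <- colnames(y)
  out
}

#' Resample a landmark series onto a uniform grid
#'
#' Cubic-spline interpolation per coordinate onto a uniform grid spanning the
#' original time range. Gaps longer than `max_gap` (landmark dropouts the
#' interpolant should not be trusted to bridge) raise an error.
#'
#' @param series a `landmark_series`.
#' @param rate target rate, Hz.
#' @param max_gap largest tolerated inter-frame gap, seconds (default 0.2).
#' @return a `landmark_series` on the uniform grid, dialect preserved.
#' @export
resample_uniform <- function(series, rate, max_gap = 0.2) {
  stopifnot(inherits(series, "landmark_series"))
  if (length(series$time) < 2L) {
    stop("resampling needs at least 2 frames", call. = FALSE)
  }
  if (max(diff(series$time)) > max_gap) {
    stop(sprintf("landmark gap exceeds %.3f s; trial segment invalid", max_gap),
         call. = FALSE)
  }
  t0 <- series$time[1L]
  tn <- series$time[length(series$time)]
  tout <- seq(t0, t0 + floor((tn - t0) * rate) / rate, by = 1 / rate)
  lm <- lapply(series$landmarks, function(m) interp_columns(series$time, m, tout))
  landmark_series(tout, lm, series$dialect, rate)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies [filtfilt_lowpass()] to every channel. Requires uniform sampling;
#' nonuniform input must be resampled first (see [resample_uniform()]).
#'
#' @param x an `angle_series` or `landmark_series`.
#' @param cutoff cutoff frequency, Hz (default 6).
#' @param order per-pass order (default 4; dual-pass doubles it).
#' @return same type as the input.
#' @export
butterworth_lowpass <- function(x, cutoff = 6, order = 4L) {
  UseMethod("butterworth_lowpass")
}

check_uniform <- function(time) {
  dt <- diff(time)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("nonuniform sampling: resample to a uniform grid before filtering",
         call. = FALSE)
  }
  1 / mean(dt)
}

#' @export
butterworth_lowpass.angle_series <- function(x, cutoff = 6, order = 4L) {
  rate <- check_uniform(x$time)
  filt <- apply(x$angles, 2L, filtfilt_lowpass, rate = rate, cutoff = cutoff,
                order = order)
  angle_series(x$time, filt, x$dof_names)
}

#' @export
butterworth_lowpass.landmark_series <- function(x, cutoff = 6, order = 4L) {
  rate <- check_uniform(x$time)
  lm <- lapply(x$landmarks, function(m) {
    apply(m, 2L, filtfilt_lowpass, rate = rate, cutoff = cutoff, order = order)
  })
  landmark_series(x$time, lm, x$dialect, x$nominal_rate)
}

#' Time-normalize one gait cycle to 101 points
#'
#' Resamples an angle-series segment onto the closed cycle-fraction grid
#' 0%, 1%, ..., 100% by cubic interpolation; the endpoints reproduce the
#' segment's endpoint values exactly.
#'
#' @param segment an `angle_series` covering exactly one gait cycle.
#' @param trial,day provenance labels stored on the cycle.
#' @return an `angle_cycle`.
#' @export
normalize_cycle <- function(segment, trial = NA_character_, day = NA_integer_) {
  stopifnot(inherits(segment, "angle_series"))
  n <- length(segment$time)
  if (n < 4L) stop("cycle segment too short (need >= 4 samples)", call. = FALSE)
  tout <- seq(segment$time[1L], segment$time[n], length.out = 101L)
  vals <- interp_columns(segment$time, segment$angles, tout)
  vals[1L, ] <- segment$angles[1L, ]
  vals[101L, ] <- segment$angles[n, ]
  angle_cycle(vals, segment$dof_names, trial = trial, day = day)
}

#' Pointwise mean (and SD) of a set of gait cycles
#'
#' @param cycles list of `angle_cycle` objects sharing one DOF set.
#' @return list with `mean` (an `angle_cycle`) and `sd` (101 x d matrix).
#' @export
average_cycles <- function(cycles) {
  if (length(cycles) < 1L) stop("need at least one cycle", call. = FALSE)
  dofs <- cycles[[1L]]$dof_names
  for (cy in cycles) {
    stopifnot(inherits(cy, "angle_cycle"))
    if (!identical(cy$dof_names, dofs)) {
      stop("cycles have mismatched DOF sets", call. = FALSE)
    }
  }
  arr <- vapply(cycles, function(cy) cy$values,
                matrix(0, 101L, length(dofs)))
  dim(arr) <- c(101L, length(dofs), length(cycles))
  m <- apply(arr, c(1L, 2L), mean)
  s <- if (length(cycles) == 1L) matrix(0, 101L, length(dofs)) else
    apply(arr, c(1L, 2L), stats::sd)
  colnames(m) <- colnames(s) <- dofs
  list(mean = angle_cycle(m, dofs, trial = "mean",
                          day = cycles[[1L]]$day),
       sd = s)
}
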