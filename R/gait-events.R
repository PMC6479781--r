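# Right-limb gait events and per-cycle discrete parameters.
#
# Initial contacts are detected coordinate-style (Zeni): local maxima of the
# foot landmark's anterior displacement relative to the pelvis center. The
# study design has no force plates on the markerless walkway, and the
# threshold-free extremum rule needs no tuning.

#' Detect right-limb initial contacts
#'
#' @param series a `landmark_series` (either dialect). The marker dialect uses
#'   the calcaneus vs the mid-ASIS/sacrum pelvis center; the depth dialect the
#'   right ankle vs the spine base.
#' @param min_spacing_frac minimum inter-event spacing as a fraction of the
#'   median stride estimate (default 0.5).
#' @return numeric vector of event times, seconds.
#' @export
detect_initial_contacts <- function(series, min_spacing_frac = 0.5) {
  stopifnot(inherits(series, "landmark_series"))
  if (series$dialect == MARKER_DIALECT) {
    foot <- get_landmark(series, "heel")
    pel <- (get_landmark(series, "asis_l") + get_landmark(series, "asis_r") +
              2 * get_landmark(series, "sacrum")) / 4
  } else {
    foot <- get_landmark(series, "ankle_r")
    pel <- get_landmark(series, "spine_base")
  }
  d <- foot[, 1L] - pel[, 1L]        # anterior (+X) displacement
  n <- length(d)
  if (n < 5L) stop("too few frames for event detection", call. = FALSE)
  # suppress measurement noise before the extremum scan (uniform grids only;
  # the depth stream reaches here already resampled and filtered)
  dt <- diff(series$time)
  uniform <- max(abs(dt - mean(dt))) <= 1e-6 * mean(dt)
  rate <- 1 / mean(dt)
  ds <- if (uniform && rate > 13) filtfilt_lowpass(d, rate, cutoff = 6) else d
  if (diff(range(ds)) < 0.01) {
    stop("fewer than one full gait cycle detected (no anterior foot excursion)",
         call. = FALSE)
  }
  is_max <- c(ds[1L] > ds[2L],
              ds[2:(n - 1)] > ds[1:(n - 2)] & ds[2:(n - 1)] >= ds[3:n],
              ds[n] > ds[n - 1L])
  cand <- which(is_max)
  if (length(cand) < 2L) {
    stop("fewer than one full gait cycle detected", call. = FALSE)
  }
  # enforce minimum spacing: keep the larger peak of any too-close pair
  stride <- stats::median(diff(series$time[cand]))
  min_gap <- min_spacing_frac * stride
  keep <- cand[1L]
  for (k in cand[-1L]) {
    if (series$time[k] - series$time[keep[length(keep)]] < min_gap) {
      if (ds[k] > ds[keep[length(keep)]]) keep[length(keep)] <- k
    } else {
      keep <- c(keep, k)
    }
  }
  if (length(keep) < 2L) {
    stop("fewer than one full gait cycle detected", call. = FALSE)
  }
  series$time[keep]
}

#' Cut an angle series at events and time-normalize each cycle
#'
#' @param angles an `angle_series`.
#' @param events event times (seconds), >= 2, within the series' time range.
#' @param trial,day provenance labels for the cycles.
#' @return list of `angle_cycle` objects, one per consecutive event pair.
#' @export
segment_and_normalize <- function(angles, events, trial = NA_character_,
                                  day = NA_integer_) {
  stopifnot(inherits(angles, "angle_series"))
  events <- sort(events)
  if (length(events) < 2L) stop("need at least 2 events", call. = FALSE)
  out <- vector("list", length(events) - 1L)
  for (k in seq_len(length(events) - 1L)) {
    idx <- which(angles$time >= events[k] - 1e-9 &
                   angles$time <= events[k + 1L] + 1e-9)
    if (length(idx) < 4L) stop("cycle segment too short", call. = FALSE)
    seg <- angle_series(angles$time[idx], angles$angles[idx, , drop = FALSE],
                        angles$dof_names)
    out[[k]] <- normalize_cycle(seg, trial = trial, day = day)
  }
  out
}

#' Discrete gait parameters of one cycle
#'
#' Per DOF: maximum, minimum, range of motion (max - min) and the angle at
#' initial contact (cycle fraction 0).
#'
#' @param cycle an `angle_cycle`.
#' @return data.frame with columns `dof`, `maximum`, `minimum`, `rom`,
#'   `initial_contact` (degrees).
#' @export
extract_discrete_params <- function(cycle) {
  stopifnot(inherits(cycle, "angle_cycle"))
  mx <- apply(cycle$values, 2L, max)
  mn <- apply(cycle$values, 2L, min)
  data.frame(dof = cycle$dof_names, maximum = mx, minimum = mn,
             rom = mx - mn, initial_contact = cycle$values[1L, ],
             row.names = NULL)
}
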