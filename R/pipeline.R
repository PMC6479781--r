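# End-to-end orchestration: from a trial manifest (or an in-memory synthetic
# cohort) through both kinematics backends, cycle segmentation, calibration
# and the validity/reliability reports.

#' Trial manifest
#'
#' @param subject character subject ids.
#' @param day integer day labels (1 or 2).
#' @param trial integer trial ids.
#' @param marker_file,static_file,kinect_file file paths per trial.
#' @return data.frame of class `trial_manifest`.
#' @export
trial_manifest <- function(subject, day, trial, marker_file, static_file,
                           kinect_file) {
  if (!all(day %in% c(1L, 2L))) stop("day must be 1 or 2", call. = FALSE)
  for (f in c(marker_file, static_file, kinect_file)) {
    if (!file.exists(f)) stop(sprintf("manifest file not found: %s", f),
                              call. = FALSE)
  }
  df <- data.frame(subject = subject, day = as.integer(day),
                   trial = as.integer(trial), marker_file = marker_file,
                   static_file = static_file, kinect_file = kinect_file,
                   stringsAsFactors = FALSE)
  class(df) <- c("trial_manifest", "data.frame")
  df
}

#' Read a trial manifest from CSV
#' @param path CSV with columns subject, day, trial, marker_file,
#'   static_file, kinect_file (paths relative to the CSV's directory).
#' @return a `trial_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  root <- dirname(path)
  abs <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  trial_manifest(df$subject, df$day, df$trial, abs(df$marker_file),
                 abs(df$static_file), abs(df$kinect_file))
}

#' Default pipeline configuration
#'
#' @param filter_cutoff low-pass cutoff, Hz.
#' @param kinect_rate uniform resampling rate for the depth stream, Hz.
#' @param hip_model a [hip_center_model()].
#' @param calibration_subject subject id whose trials fit the calibrations.
#' @param lstm_epochs,lstm_hidden,lstm_seed LSTM training controls.
#' @return named list.
#' @export
pipeline_config <- function(filter_cutoff = 6, kinect_rate = 30,
                            hip_model = hip_center_model(),
                            calibration_subject = "CAL",
                            lstm_epochs = 300, lstm_hidden = 100L,
                            lstm_seed = 1L) {
  list(filter_cutoff = filter_cutoff, kinect_rate = kinect_rate,
       hip_model = hip_model, calibration_subject = calibration_subject,
       lstm_epochs = lstm_epochs, lstm_hidden = lstm_hidden,
       lstm_seed = lstm_seed)
}

# Paired per-trial cycles from both streams. Events are detected
# independently per system; cycles are paired by temporal overlap (robust to
# a missed event on either side).
trial_cycles <- function(markers, static, kinect, config,
                         trial = NA_character_, day = NA_integer_) {
  mang <- compute_marker_angles(markers, static, model = config$hip_model,
                                filter_cutoff = config$filter_cutoff)
  mev <- detect_initial_contacts(markers)
  mcyc <- segment_and_normalize(mang, mev, trial = trial, day = day)
  kin <- resample_uniform(kinect, config$kinect_rate)
  kin <- butterworth_lowpass(kin, cutoff = config$filter_cutoff)
  kang <- compute_kinect_angles(kin)
  kev <- detect_initial_contacts(kin)
  kcyc <- segment_and_normalize(kang, kev, trial = trial, day = day)
  # overlap pairing
  mspan <- cbind(mev[-length(mev)], mev[-1L])
  kspan <- cbind(kev[-length(kev)], kev[-1L])
  pairs <- list()
  for (i in seq_len(nrow(kspan))) {
    ov <- pmin(kspan[i, 2L], mspan[, 2L]) - pmax(kspan[i, 1L], mspan[, 1L])
    j <- which.max(ov)
    if (length(j) && ov[j] > 0.5 * diff(kspan[i, ])) {
      pairs[[length(pairs) + 1L]] <- list(marker = mcyc[[j]],
                                          kinect = kcyc[[i]])
    }
  }
  if (!length(pairs)) stop("no overlapping gait cycles between the systems",
                           call. = FALSE)
  list(marker = lapply(pairs, `[[`, "marker"),
       kinect = lapply(pairs, `[[`, "kinect"))
}

# Subject-mean cycles per system for a set of trial records.
subject_mean_cycles <- function(records, config) {
  subjects <- unique(vapply(records, `[[`, character(1L), "subject"))
  mk <- kk <- list()
  for (s in subjects) {
    recs <- Filter(function(r) r$subject == s, records)
    mcs <- unlist(lapply(recs, function(r) r$cycles$marker),
                  recursive = FALSE)
    kcs <- unlist(lapply(recs, function(r) r$cycles$kinect),
                  recursive = FALSE)
    mk[[s]] <- average_cycles(mcs)$mean
    kk[[s]] <- average_cycles(kcs)$mean
    mk[[s]]$trial <- kk[[s]]$trial <- s
  }
  list(marker = mk, kinect = kk, subjects = subjects)
}

#' Run the full validation pipeline
#'
#' Computes per-trial angle cycles for both systems, fits the linear and LSTM
#' calibrations on the designated calibration subject, evaluates concurrent
#' validity on the remaining day-1 subjects (subject-mean cycles) and, when
#' two days are present, inter-day reliability of the markerless system.
#'
#' @param trials either a `trial_manifest` (files are read) or a list of
#'   in-memory records with fields `subject`, `day`, `trial`, `markers`,
#'   `static`, `kinect` (e.g. `synthetic_cohort()$trials` combined with
#'   `$calibration`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; reports are written there as JSON/CSV.
#' @return list with `validity`, `reliability` (or `NULL`), `calibration`
#'   (fitted models), and the per-system subject-mean `tensors`.
#' @export
run_pipeline <- function(trials, config = pipeline_config(), out_dir = NULL) {
  if (inherits(trials, "trial_manifest")) {
    records <- lapply(seq_len(nrow(trials)), function(i) {
      row <- trials[i, ]
      list(subject = row$subject, day = row$day, trial = row$trial,
           markers = read_marker_file(row$marker_file),
           static = read_marker_file(row$static_file),
           kinect = read_landmark_csv(row$kinect_file))
    })
  } else {
    records <- trials
  }
  records <- lapply(records, function(r) {
    r$cycles <- tryCatch(
      trial_cycles(r$markers, r$static, r$kinect, config,
                   trial = sprintf("%s_d%d_t%d", r$subject, r$day, r$trial),
                   day = r$day),
      error = function(e) stop(sprintf("subject %s day %d trial %d: %s",
                                       r$subject, r$day, r$trial,
                                       conditionMessage(e)), call. = FALSE))
    r
  })

  is_cal <- vapply(records, function(r)
    r$subject == config$calibration_subject, logical(1L))
  eval_d1 <- Filter(function(r) r$day == 1L, records[!is_cal])
  eval_d2 <- Filter(function(r) r$day == 2L, records[!is_cal])

  calibration <- list()
  g1_lr <- g1_lstm <- NULL
  sm <- subject_mean_cycles(eval_d1, config)
  g1 <- build_gait_tensor(sm$kinect, system = "G1")
  g2 <- build_gait_tensor(sm$marker, system = "G2")
  # linear regression is fitted on the designated calibration subject's
  # trials; the LSTM trains on the evaluation tensors themselves (the study
  # protocol: its reported LSTM performance is training-set performance)
  if (any(is_cal)) {
    cal <- Filter(function(r) r$day == 1L, records[is_cal])
    cg1 <- build_gait_tensor(unlist(lapply(cal, function(r) r$cycles$kinect),
                                    recursive = FALSE), system = "G1")
    cg2 <- build_gait_tensor(unlist(lapply(cal, function(r) r$cycles$marker),
                                    recursive = FALSE), system = "G2")
    lin <- fit_linear_calibration(cg1, cg2)
    calibration$linear <- lin
    g1_lr <- apply_linear_calibration(lin, g1)
  }
  if (config$lstm_epochs > 0L) {
    lstm <- train_lstm_calibrator(g1, g2, epochs = config$lstm_epochs,
                                  hidden = config$lstm_hidden,
                                  seed = config$lstm_seed)
    calibration$lstm <- lstm
    g1_lstm <- apply_lstm_calibrator(lstm, g1)
  }
  if (!length(calibration)) calibration <- NULL
  validity <- validity_report(g1, g1_lr, g1_lstm, g2)

  reliability <- NULL
  if (length(eval_d2)) {
    sm2 <- subject_mean_cycles(eval_d2, config)
    common <- intersect(sm$subjects, sm2$subjects)
    gk1 <- build_gait_tensor(sm$kinect[common], system = "day1")
    gk2 <- build_gait_tensor(sm2$kinect[common], system = "day2")
    reliability <- reliability_report(gk1, gk2)
  } else {
    message("single-day manifest: reliability section omitted")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_agreement_report(validity, file.path(out_dir, "validity"))
    if (!is.null(reliability)) {
      write_agreement_report(reliability, file.path(out_dir, "reliability"))
    }
  }
  list(validity = validity, reliability = reliability,
       calibration = calibration,
       tensors = list(g1 = g1, g2 = g2, g1_lr = g1_lr, g1_lstm = g1_lstm))
}
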