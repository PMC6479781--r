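# Measurement-agreement statistics: waveform RMSE and the Kadaba coefficient
# of multiple correlation, normality-gated correlation of discrete gait
# parameters, Bland-Altman limits of agreement, ICC(2,k) with its
# F-distribution confidence interval, the standard error of measurement, and
# the interpretation bands used in the clinical gait literature.

CMC_SENTINEL <- "<0.001"

#' Root-mean-square error between two waveforms
#'
#' @param a,b numeric vectors of equal length (typically 101-point cycles),
#'   degrees.
#' @return RMSE in degrees.
#' @export
rmse_waveform <- function(a, b) {
  if (length(a) != length(b)) stop("waveforms differ in length", call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Coefficient of multiple correlation (Kadaba) over a waveform set
#'
#' For M waveforms of T points,
#' `CMC = sqrt(1 - [sum (Y_mt - Ybar_t)^2 / (T (M-1))] /
#'              [sum (Y_mt - Ybar)^2 / (M T - 1)])`
#' with `Ybar_t` the across-waveform mean at each time point and `Ybar` the
#' grand mean. When between-waveform variance dominates, the radicand is
#' negative and the conventional printed sentinel `"<0.001"` is returned
#' (with the raw radicand kept for diagnostics). All-identical input has zero
#' total variance; CMC is then defined as 1 with a degeneracy flag.
#'
#' @param w numeric M x T matrix, M >= 2.
#' @return list with `value` (numeric, `NA` when sentinel), `label`
#'   (formatted value or `"<0.001"`), `radicand`, `degenerate`.
#' @export
cmc <- function(w) {
  w <- as.matrix(w)
  M <- nrow(w); Tn <- ncol(w)
  if (M < 2L || Tn < 2L) stop("need at least 2 waveforms of length >= 2",
                              call. = FALSE)
  if (any(!is.finite(w))) stop("waveforms must be finite", call. = FALSE)
  grand <- mean(w)
  tmeans <- colMeans(w)
  within <- sum(sweep(w, 2L, tmeans)^2) / (Tn * (M - 1))
  total <- sum((w - grand)^2) / (M * Tn - 1)
  if (total == 0) {
    return(list(value = 1, label = "1.000", radicand = 1, degenerate = TRUE))
  }
  radicand <- 1 - within / total
  if (radicand < 0) {
    list(value = NA_real_, label = CMC_SENTINEL, radicand = radicand,
         degenerate = FALSE)
  } else {
    v <- sqrt(radicand)
    list(value = v, label = sprintf("%.3f", v), radicand = radicand,
         degenerate = FALSE)
  }
}

#' Interpretation band for a CMC value
#'
#' Excellent 0.95-1, very good 0.85-0.94, good 0.75-0.84, moderate 0.6-0.74,
#' poor 0-0.59; the `"<0.001"` sentinel maps to poor.
#'
#' @param value numeric CMC, a `cmc()` result, or the sentinel string.
#' @return band label.
#' @export
classify_cmc <- function(value) {
  if (is.list(value)) value <- if (is.na(value$value)) CMC_SENTINEL else
    value$value
  if (identical(value, CMC_SENTINEL)) return("poor")
  v <- as.numeric(value)
  if (is.na(v)) return("poor")
  if (v >= 0.95) "excellent"
  else if (v >= 0.85) "very good"
  else if (v >= 0.75) "good"
  else if (v >= 0.6) "moderate"
  else "poor"
}

#' Normality-gated correlation between paired parameters
#'
#' Both samples are screened with the Shapiro-Wilk test; if both are
#' compatible with normality (p > alpha) the Pearson coefficient is used,
#' otherwise Spearman's rho.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param alpha Shapiro-Wilk gate level (default 0.05).
#' @return list with `coefficient`, `method` ("pearson"/"spearman"),
#'   `p_value` (of the correlation test), `shapiro_p` (length 2).
#' @export
gated_correlation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 4L) {
    stop("need paired samples with n >= 4", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  swx <- stats::shapiro.test(x)$p.value
  swy <- stats::shapiro.test(y)$p.value
  method <- if (swx > alpha && swy > alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(coefficient = unname(ct$estimate), method = method,
       p_value = ct$p.value, shapiro_p = c(x = swx, y = swy))
}

#' Bland-Altman mean difference and 95% limits of agreement
#'
#' @param x,y paired measurements (difference taken as `x - y`), n >= 2.
#' @return list with `mean_diff`, `loa_lower`, `loa_upper` (mean +- 1.96 SD
#'   of the differences, sample SD).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need paired samples with n >= 2", call. = FALSE)
  }
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}

#' ICC(2,k): two-way random effects, absolute agreement, mean of k ratings
#'
#' Computed from the two-way ANOVA mean squares,
#' `ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`,
#' with the 95% confidence interval by the F-distribution method of McGraw &
#' Wong (the single-rating bounds Spearman-Brown-stepped up to k).
#'
#' @param data n x k numeric matrix: subjects in rows, repeated
#'   measurements (days/raters) in columns; no missing cells; n >= 3, k >= 2.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci_lower`, `ci_upper`, the mean squares, and a
#'   `degenerate` flag (zero between-subject variance).
#' @export
icc_2k <- function(data, conf = 0.95) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 3L || k < 2L) stop("need n >= 3 subjects and k >= 2 ratings",
                             call. = FALSE)
  if (any(!is.finite(data))) stop("missing or non-finite cells", call. = FALSE)
  grand <- mean(data)
  rm_ <- rowMeans(data); cm_ <- colMeans(data)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((data - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 || stats::sd(rm_) == 0) {
    return(list(icc = 0, ci_lower = NA_real_, ci_upper = NA_real_,
                ms = c(rows = msr, cols = msc, error = mse),
                degenerate = TRUE))
  }
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  # single-rating point estimate for the CI machinery
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  a <- (k * icc_1) / (n * (1 - icc_1))
  b <- 1 + (k * icc_1 * (n - 1)) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  low1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown step-up
  list(icc = icc_k, ci_lower = sb(low1), ci_upper = sb(up1),
       ms = c(rows = msr, cols = msc, error = mse), degenerate = FALSE)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`. Negative ICC is permitted (reliability can be
#' estimated below zero), giving SEM above the SD.
#'
#' @param sd standard deviation of the measurements, degrees (>= 0).
#' @param icc reliability coefficient (<= 1).
#' @return SEM in degrees.
#' @export
sem <- function(sd, icc) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (icc > 1) stop("icc must be <= 1", call. = FALSE)
  sd * sqrt(1 - icc)
}

#' Interpretation band for an ICC (or r) value
#'
#' Excellent 0.75-1, modest 0.4-0.74, poor below 0.4 (including negative
#' estimates, which floor at poor).
#'
#' @param value numeric.
#' @return band label.
#' @export
classify_icc <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value >= 0.75) "excellent"
  else if (value >= 0.4) "modest"
  else "poor"
}

# --- report assembly ---------------------------------------------------------

# Discrete parameters per tensor row: list of n x 1 value matrices by
# (dof, parameter).
tensor_discrete_params <- function(g) {
  vals <- g$values
  n <- dim(vals)[1L]; d <- dim(vals)[3L]
  out <- list()
  for (j in seq_len(d)) {
    m <- vals[, , j, drop = FALSE]
    mx <- apply(vals[, , j, drop = FALSE], 1L, max)
    mn <- apply(vals[, , j, drop = FALSE], 1L, min)
    out[[g$dof_names[j]]] <- cbind(maximum = mx, minimum = mn,
                                   rom = mx - mn,
                                   initial_contact = vals[, 1L, j])
  }
  out
}

# Mean +- SD of per-row RMSE and per-row pairwise CMC between two tensors.
waveform_agreement <- function(ga, gb) {
  n <- dim(ga$values)[1L]; d <- dim(ga$values)[3L]
  res <- vector("list", d)
  for (j in seq_len(d)) {
    rm_ <- numeric(n); cv <- numeric(n)
    for (i in seq_len(n)) {
      a <- ga$values[i, , j]; b <- gb$values[i, , j]
      rm_[i] <- rmse_waveform(a, b)
      ci <- cmc(rbind(a, b))
      cv[i] <- if (is.na(ci$value)) 0 else ci$value
    }
    cmc_mean <- mean(cv)
    res[[j]] <- data.frame(
      dof = ga$dof_names[j],
      rmse_mean = mean(rm_), rmse_sd = stats::sd(rm_),
      cmc_mean = cmc_mean, cmc_sd = stats::sd(cv),
      cmc_label = if (cmc_mean < 0.001) CMC_SENTINEL else
        sprintf("%.2f", cmc_mean),
      band = classify_cmc(if (cmc_mean < 0.001) CMC_SENTINEL else cmc_mean))
  }
  do.call(rbind, res)
}

#' Concurrent-validity report
#'
#' Mirrors the validity-table structure of the study design: per DOF and
#' per system (uncalibrated, linearly calibrated, LSTM calibrated), the
#' across-subject mean +- SD of the per-subject waveform RMSE and
#' system-pair CMC against the reference; and per discrete parameter the
#' normality-gated correlation and Bland-Altman limits of agreement.
#' Sentinel (negative-radicand) per-subject CMCs enter the mean as 0 and a
#' cell mean below 0.001 is printed as the sentinel.
#'
#' @param g_kinect uncalibrated markerless `gait_tensor` (one row per
#'   subject-mean cycle).
#' @param g_calibrated_lr,g_calibrated_lstm calibrated tensors (or `NULL`).
#' @param g_reference paired reference `gait_tensor`.
#' @return object of class `agreement_report` (kind "validity") with
#'   `waveform` and `discrete` data frames.
#' @export
validity_report <- function(g_kinect, g_calibrated_lr = NULL,
                            g_calibrated_lstm = NULL, g_reference) {
  systems <- list(kinect = g_kinect)
  if (!is.null(g_calibrated_lr)) systems$linear <- g_calibrated_lr
  if (!is.null(g_calibrated_lstm)) systems$lstm <- g_calibrated_lstm
  ref_par <- tensor_discrete_params(g_reference)
  wf <- list(); disc <- list()
  for (nm in names(systems)) {
    check_paired(systems[[nm]], g_reference)
    w <- waveform_agreement(systems[[nm]], g_reference)
    w$system <- nm
    wf[[nm]] <- w
    par <- tensor_discrete_params(systems[[nm]])
    for (dof in names(par)) {
      for (pn in colnames(par[[dof]])) {
        x <- par[[dof]][, pn]; y <- ref_par[[dof]][, pn]
        gc <- tryCatch(gated_correlation(x, y),
                       error = function(e) list(coefficient = NA_real_,
                                                method = NA_character_,
                                                p_value = NA_real_))
        ba <- tryCatch(bland_altman(x, y),
                       error = function(e) list(mean_diff = NA_real_,
                                                loa_lower = NA_real_,
                                                loa_upper = NA_real_))
        disc[[length(disc) + 1L]] <- data.frame(
          system = nm, dof = dof, parameter = pn,
          mean_sys = mean(x), sd_sys = stats::sd(x),
          mean_ref = mean(y), sd_ref = stats::sd(y),
          coefficient = gc$coefficient, method = gc$method,
          p_value = gc$p_value,
          mean_diff = ba$mean_diff, loa_lower = ba$loa_lower,
          loa_upper = ba$loa_upper)
      }
    }
  }
  structure(list(kind = "validity",
                 waveform = do.call(rbind, c(wf, make.row.names = FALSE)),
                 discrete = do.call(rbind, c(disc, make.row.names = FALSE))),
            class = "agreement_report")
}

#' Inter-day reliability report
#'
#' Between-day CMC and RMSE on subject-mean waveforms, and per discrete
#' parameter the ICC(2,k) (subjects as rows, days as the repeated factor)
#' with its 95% CI, the SEM (pooled-measurement SD times sqrt(1 - ICC)) and
#' the interpretation band.
#'
#' @param g_day1,g_day2 `gait_tensor`s with one row per subject (same
#'   subject order).
#' @return object of class `agreement_report` (kind "reliability").
#' @export
reliability_report <- function(g_day1, g_day2) {
  check_paired(g_day1, g_day2)
  wf <- waveform_agreement(g_day1, g_day2)
  p1 <- tensor_discrete_params(g_day1)
  p2 <- tensor_discrete_params(g_day2)
  disc <- list()
  for (dof in names(p1)) {
    for (pn in colnames(p1[[dof]])) {
      m <- cbind(p1[[dof]][, pn], p2[[dof]][, pn])
      ic <- icc_2k(m)
      # the ANOVA estimator can slightly exceed 1 when MS_C < MS_E;
      # truncate for the SEM (a negative residual variance is not meaningful)
      s <- sem(stats::sd(as.vector(m)), min(ic$icc, 1))
      disc[[length(disc) + 1L]] <- data.frame(
        dof = dof, parameter = pn,
        mean_day1 = mean(m[, 1L]), sd_day1 = stats::sd(m[, 1L]),
        mean_day2 = mean(m[, 2L]), sd_day2 = stats::sd(m[, 2L]),
        icc = ic$icc, ci_lower = ic$ci_lower, ci_upper = ic$ci_upper,
        sem = s, band = classify_icc(ic$icc))
    }
  }
  structure(list(kind = "reliability", waveform = wf,
                 discrete = do.call(rbind, c(disc, make.row.names = FALSE))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report kind=%s>\n", x$kind))
  cat("\nWaveform agreement (per DOF):\n")
  print(x$waveform, digits = 3)
  cat("\nDiscrete parameters:\n")
  print(utils::head(x$discrete, 10L), digits = 3)
  if (nrow(x$discrete) > 10L) cat(sprintf("... %d more rows\n",
                                          nrow(x$discrete) - 10L))
  invisible(x)
}
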