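# Zero-phase Butterworth low-pass filtering.
#
# The pre-installed R stack has no IIR filter design, so the classical
# bilinear-transform Butterworth design and forward-backward application are
# implemented here: analog prototype poles -> prewarp -> bilinear map, then
# direct-form-II-transposed filtering with odd-reflection padding and
# steady-state initial conditions (the same scheme scipy.signal.filtfilt
# uses). Effective attenuation is the squared single-pass magnitude response.

# Polynomial with given roots, leading coefficient 1 (complex-safe).
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth low-pass coefficients
#'
#' @param order filter order (per pass).
#' @param cutoff cutoff frequency, Hz.
#' @param rate sampling rate, Hz; must exceed `2 * cutoff`.
#' @return list with numerator `b` and denominator `a` (a[1] = 1).
#' @export
butter_lowpass <- function(order = 4L, cutoff = 6, rate = 100) {
  stopifnot(order >= 1L, cutoff > 0)
  if (rate <= 2 * cutoff) {
    stop("sampling rate must exceed twice the cutoff frequency", call. = FALSE)
  }
  wn <- cutoff / (rate / 2)            # normalized cutoff in (0, 1)
  warped <- tan(pi * wn / 2)           # prewarped analog frequency
  k <- seq_len(order)
  # analog prototype poles on the left half unit circle
  pa <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p <- warped * pa
  pd <- (1 + p) / (1 - p)              # bilinear transform, zeros at z = -1
  a <- Re(poly_from_roots(pd))
  gain <- Re(prod(1 - pd)) / 2^order   # unit DC gain
  b <- gain * choose(order, 0:order)
  list(b = b, a = a)
}

# Direct-form-II-transposed IIR filter with initial state zi (length n-1).
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (n > 2L) {
      for (j in seq_len(n - 2L)) {
        z[j] <- b[j + 1L] * xi - a[j + 1L] * yi + z[j + 1L]
      }
    }
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-amplitude constant input.
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- rbind(-a[-1L], cbind(diag(1, n - 2L), rep(0, n - 2L)))
  IminusA <- diag(1, n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

#' Zero-phase Butterworth low-pass filter of a numeric vector
#'
#' Forward-backward (dual-pass) application, so phase distortion cancels and
#' the effective order doubles. Edges are handled by odd-reflection padding.
#'
#' @param x numeric vector, uniformly sampled.
#' @param rate sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 6, the gait-analysis staple).
#' @param order per-pass filter order (default 4).
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_lowpass <- function(x, rate, cutoff = 6, order = 4L) {
  coefs <- butter_lowpass(order, cutoff, rate)
  b <- coefs$b; a <- coefs$a
  npad <- 3L * max(length(a), length(b))
  if (length(x) <= npad) {
    stop(sprintf("signal too short to filter (need > %d samples)", npad),
         call. = FALSE)
  }
  nx <- length(x)
  ext <- c(2 * x[1L] - x[(npad + 1L):2L],
           x,
           2 * x[nx] - x[(nx - 1L):(nx - npad)])
  zi <- iir_steady_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1L])
  y <- rev(y)
  y[(npad + 1L):(npad + nx)]
}
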