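# Calibration of markerless kinematics onto the reference system:
# (a) per-DOF linear regression (pooled over all cycle time points), after
#     the approach of prior depth-sensor work, and
# (b) a two-layer LSTM sequence model (100 memory cells per layer, linear
#     read-out, full-batch gradient descent at learning rate 0.006),
# both operating on the n x 101 x 5 gait tensor.

#' Stack angle cycles into a gait tensor
#'
#' @param cycles list of `angle_cycle` objects with identical DOF sets.
#' @param system label, e.g. `"G1"` (depth sensor) or `"G2"` (reference).
#' @return object of class `gait_tensor`: `values` (n x 101 x 5 array),
#'   `trials` (labels), `system`.
#' @export
build_gait_tensor <- function(cycles, system = "G1") {
  if (length(cycles) < 1L) stop("need at least one cycle", call. = FALSE)
  dofs <- cycles[[1L]]$dof_names
  for (cy in cycles) {
    stopifnot(inherits(cy, "angle_cycle"))
    if (!identical(cy$dof_names, dofs)) {
      stop("cycles have mismatched DOF sets", call. = FALSE)
    }
  }
  n <- length(cycles)
  values <- array(NA_real_, c(n, 101L, length(dofs)),
                  dimnames = list(NULL, NULL, dofs))
  for (i in seq_len(n)) values[i, , ] <- cycles[[i]]$values
  structure(list(values = values,
                 trials = vapply(cycles, function(cy) as.character(cy$trial),
                                 character(1L)),
                 dof_names = dofs, system = system),
            class = "gait_tensor")
}

#' @export
print.gait_tensor <- function(x, ...) {
  cat(sprintf("<gait_tensor %s  %d x 101 x %d>\n", x$system,
              dim(x$values)[1L], dim(x$values)[3L]))
  invisible(x)
}

check_paired <- function(g1, g2) {
  stopifnot(inherits(g1, "gait_tensor"), inherits(g2, "gait_tensor"))
  if (!identical(dim(g1$values), dim(g2$values))) {
    stop("gait tensors must be paired (identical dimensions)", call. = FALSE)
  }
}

#' Fit the per-DOF linear calibration
#'
#' Ordinary least squares of the reference angle on the markerless angle,
#' pooled over all trials and cycle time points, independently per DOF:
#' `theta_ref ~ a * theta_markerless + b`.
#'
#' @param g1 markerless `gait_tensor`.
#' @param g2 paired reference `gait_tensor`.
#' @return object of class `linear_calibration`: per-DOF `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_linear_calibration <- function(g1, g2) {
  check_paired(g1, g2)
  d <- dim(g1$values)[3L]
  slope <- intercept <- r2 <- numeric(d)
  for (j in seq_len(d)) {
    x <- as.vector(g1$values[, , j])
    y <- as.vector(g2$values[, , j])
    if (stats::sd(x) < 1e-12) {
      stop(sprintf("degenerate (constant) predictor for DOF '%s'",
                   g1$dof_names[j]), call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, x), y)
    slope[j] <- fit$coefficients[2L]
    intercept[j] <- fit$coefficients[1L]
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    r2[j] <- if (sst > 0) 1 - ssr / sst else NA_real_
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = length(as.vector(g1$values[, , 1L])),
                 dof_names = g1$dof_names),
            class = "linear_calibration")
}

#' Apply a linear calibration to a gait tensor
#'
#' @param model a `linear_calibration`.
#' @param g1 markerless `gait_tensor`.
#' @return calibrated `gait_tensor`.
#' @export
apply_linear_calibration <- function(model, g1) {
  stopifnot(inherits(model, "linear_calibration"),
            inherits(g1, "gait_tensor"))
  out <- g1
  for (j in seq_along(model$slope)) {
    out$values[, , j] <- model$slope[j] * g1$values[, , j] +
      model$intercept[j]
  }
  out$system <- paste0(g1$system, "_lr")
  out
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat("<linear_calibration>\n")
  print(data.frame(dof = x$dof_names, slope = round(x$slope, 4),
                   intercept = round(x$intercept, 3),
                   r_squared = round(x$r_squared, 4)), row.names = FALSE)
  invisible(x)
}

# --- LSTM --------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(input_dim, hidden, output_dim) {
  r1 <- 1 / sqrt(hidden)
  rand_mat <- function(nr, nc) matrix(stats::runif(nr * nc, -r1, r1), nr, nc)
  W1 <- rand_mat(4L * hidden, input_dim + hidden)
  W2 <- rand_mat(4L * hidden, hidden + hidden)
  b1 <- rep(0, 4L * hidden); b2 <- rep(0, 4L * hidden)
  # forget-gate bias 1: standard stabilisation for gradient-descent training
  b1[(hidden + 1L):(2L * hidden)] <- 1
  b2[(hidden + 1L):(2L * hidden)] <- 1
  Wo <- rand_mat(output_dim, hidden)
  bo <- rep(0, output_dim)
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, Wo = Wo, bo = bo)
}

# The LSTM internals work on "flat" (n*T) x D matrices with time-major row
# blocks (rows (t-1)*n + 1:n hold time step t), so the non-recurrent matmuls
# (input projections, weight-gradient accumulation, read-out) each run as one
# large BLAS call instead of T small ones.

flatten_tensor <- function(A) {
  n <- dim(A)[1L]; Tn <- dim(A)[2L]; D <- dim(A)[3L]
  out <- matrix(0, n * Tn, D)
  for (t in seq_len(Tn)) out[(t - 1L) * n + seq_len(n), ] <- A[, t, ]
  out
}

unflatten_tensor <- function(M, n, Tn) {
  D <- ncol(M)
  A <- array(0, c(n, Tn, D))
  for (t in seq_len(Tn)) A[, t, ] <- M[(t - 1L) * n + seq_len(n), ]
  A
}

# Forward pass of one LSTM layer. Xf: (n*T) x D flat input. Returns flat
# hidden states and, when cache = TRUE, the gate activations backprop needs.
lstm_layer_forward <- function(Xf, n, Tn, W, b, hidden, cache = FALSE) {
  H <- hidden
  D <- ncol(Xf)
  pre_x <- Xf %*% t(W[, seq_len(D), drop = FALSE])
  pre_x <- pre_x + matrix(b, n * Tn, 4L * H, byrow = TRUE)
  Wh_t <- t(W[, D + seq_len(H), drop = FALSE])
  idx_i <- 1:H; idx_f <- (H + 1L):(2L * H)
  idx_g <- (2L * H + 1L):(3L * H); idx_o <- (3L * H + 1L):(4L * H)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  Hs <- matrix(0, n * Tn, H)
  if (cache) {
    GI <- GF <- GG <- GO <- CP <- TC <- HP <- matrix(0, n * Tn, H)
  }
  for (t in seq_len(Tn)) {
    rows <- (t - 1L) * n + seq_len(n)
    z <- pre_x[rows, , drop = FALSE] + h %*% Wh_t
    gi <- sigmoid(z[, idx_i, drop = FALSE])
    gf <- sigmoid(z[, idx_f, drop = FALSE])
    gg <- tanh(z[, idx_g, drop = FALSE])
    go <- sigmoid(z[, idx_o, drop = FALSE])
    if (cache) { CP[rows, ] <- cc; HP[rows, ] <- h }
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    Hs[rows, ] <- h
    if (cache) {
      GI[rows, ] <- gi; GF[rows, ] <- gf; GG[rows, ] <- gg; GO[rows, ] <- go
      TC[rows, ] <- tc
    }
  }
  if (cache) {
    list(H = Hs, cache = list(GI = GI, GF = GF, GG = GG, GO = GO, CP = CP,
                              TC = TC, HP = HP, Xf = Xf))
  } else {
    list(H = Hs, cache = NULL)
  }
}

# Backward pass of one layer; dH is the flat gradient w.r.t. the layer's
# hidden-state outputs. Returns parameter grads and the flat input gradient.
lstm_layer_backward <- function(dH, fw, W, input_dim, hidden, n, Tn) {
  H <- hidden
  ca <- fw$cache
  idx_i <- 1:H; idx_f <- (H + 1L):(2L * H)
  idx_g <- (2L * H + 1L):(3L * H); idx_o <- (3L * H + 1L):(4L * H)
  Wh <- W[, input_dim + seq_len(H), drop = FALSE]
  DZ <- matrix(0, n * Tn, 4L * H)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    rows <- (t - 1L) * n + seq_len(n)
    gi <- ca$GI[rows, , drop = FALSE]; gf <- ca$GF[rows, , drop = FALSE]
    gg <- ca$GG[rows, , drop = FALSE]; go <- ca$GO[rows, , drop = FALSE]
    tc <- ca$TC[rows, , drop = FALSE]; cp <- ca$CP[rows, , drop = FALSE]
    dh <- dH[rows, , drop = FALSE] + dh_next
    dc <- dh * go * (1 - tc^2) + dc_next
    dz <- cbind(dc * gg * gi * (1 - gi),
                dc * cp * gf * (1 - gf),
                dc * gi * (1 - gg^2),
                dh * tc * go * (1 - go))
    DZ[rows, ] <- dz
    dh_next <- dz %*% Wh
    dc_next <- dc * gf
  }
  dW <- crossprod(DZ, cbind(ca$Xf, ca$HP))
  list(dW = dW, db = colSums(DZ),
       dX = DZ %*% W[, seq_len(input_dim), drop = FALSE])
}

lstm_forward <- function(params, Xf, n, Tn, hidden, cache = FALSE) {
  l1 <- lstm_layer_forward(Xf, n, Tn, params$W1, params$b1, hidden, cache)
  l2 <- lstm_layer_forward(l1$H, n, Tn, params$W2, params$b2, hidden, cache)
  pred <- l2$H %*% t(params$Wo)
  pred <- pred + matrix(params$bo, nrow(pred), ncol(pred), byrow = TRUE)
  list(pred = pred, l1 = l1, l2 = l2)
}

tensor_standardizer <- function(values) {
  d <- dim(values)[3L]
  mu <- sd <- numeric(d)
  for (j in seq_len(d)) {
    v <- as.vector(values[, , j])
    mu[j] <- mean(v)
    sd[j] <- max(stats::sd(v), 1e-8)
  }
  list(mu = mu, sd = sd)
}

standardize_tensor <- function(values, std) {
  for (j in seq_len(dim(values)[3L])) {
    values[, , j] <- (values[, , j] - std$mu[j]) / std$sd[j]
  }
  values
}

destandardize_tensor <- function(values, std) {
  for (j in seq_len(dim(values)[3L])) {
    values[, , j] <- values[, , j] * std$sd[j] + std$mu[j]
  }
  values
}

#' Train the LSTM sequence calibrator
#'
#' Two stacked LSTM layers (`hidden` memory cells each, default 100) with a
#' linear per-time-step read-out, trained by full-batch gradient descent at
#' the stated learning rate on the mean squared error between predicted and
#' reference sequences. Inputs and targets are z-scored per DOF with training
#' statistics (the stated learning rate is only usable on scaled data) and
#' de-standardized on application. Gradients are clipped to a global norm
#' (default 5) to prevent divergence; training stops early when the relative
#' loss change stays below `tol` for 20 consecutive epochs.
#'
#' @param g1 markerless `gait_tensor` (input).
#' @param g2 paired reference `gait_tensor` (target).
#' @param epochs maximum full-batch epochs (default 500).
#' @param learning_rate gradient-descent step (default 0.006).
#' @param hidden memory cells per layer (default 100).
#' @param seed integer seed for the parameter initialisation.
#' @param clip_norm global gradient-norm clip (default 5; `Inf` disables).
#' @param tol relative-loss-change early-stop tolerance (default 1e-6).
#' @return object of class `lstm_calibrator` with the trained parameters,
#'   standardizers and per-epoch `loss_history` (standardized-scale MSE).
#' @export
train_lstm_calibrator <- function(g1, g2, epochs = 500, learning_rate = 0.006,
                                  hidden = 100L, seed = 1L, clip_norm = 5,
                                  tol = 1e-6) {
  check_paired(g1, g2)
  d <- dim(g1$values)[3L]
  std_in <- tensor_standardizer(g1$values)
  std_out <- tensor_standardizer(g2$values)
  n <- dim(g1$values)[1L]; Tn <- dim(g1$values)[2L]
  X <- flatten_tensor(standardize_tensor(g1$values, std_in))
  Y <- flatten_tensor(standardize_tensor(g2$values, std_out))
  params <- with_seed(seed, init_lstm_params(d, hidden, d))
  loss_history <- numeric(epochs)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    fw <- lstm_forward(params, X, n, Tn, hidden, cache = TRUE)
    resid <- fw$pred - Y
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop("LSTM training diverged (non-finite loss); lower the learning rate",
           call. = FALSE)
    }
    loss_history[ep] <- loss
    # output-layer gradients
    dpred <- 2 * resid / length(resid)
    dWo <- crossprod(dpred, fw$l2$H)
    dbo <- colSums(dpred)
    dH2 <- dpred %*% params$Wo
    g2b <- lstm_layer_backward(dH2, fw$l2, params$W2, hidden, hidden, n, Tn)
    g1b <- lstm_layer_backward(g2b$dX, fw$l1, params$W1, d, hidden, n, Tn)
    grads <- list(W1 = g1b$dW, b1 = g1b$db, W2 = g2b$dW, b2 = g2b$db,
                  Wo = dWo, bo = dbo)
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
    scale <- if (is.finite(clip_norm) && gnorm > clip_norm)
      clip_norm / gnorm else 1
    for (nm in names(grads)) {
      params[[nm]] <- params[[nm]] - learning_rate * scale * grads[[nm]]
    }
    if (ep > 1L) {
      rel <- abs(loss_history[ep - 1L] - loss) /
        max(loss_history[ep - 1L], 1e-12)
      stall <- if (rel < tol) stall + 1L else 0L
      if (stall >= 20L) break
    }
  }
  loss_history <- loss_history[seq_len(ep)]
  structure(list(params = params, hidden = as.integer(hidden),
                 std_in = std_in, std_out = std_out,
                 dof_names = g1$dof_names,
                 loss_history = loss_history,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "lstm_calibrator")
}

#' @export
print.lstm_calibrator <- function(x, ...) {
  cat(sprintf(
    "<lstm_calibrator  2 x %d cells  lr %g  %d epochs  final loss %.4g>\n",
    x$hidden, x$learning_rate, length(x$loss_history),
    x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Apply the LSTM calibrator to a gait tensor
#'
#' @param model a trained `lstm_calibrator`.
#' @param g1 markerless `gait_tensor` (any number of trials).
#' @return calibrated `gait_tensor`, same shape as the input.
#' @export
apply_lstm_calibrator <- function(model, g1) {
  stopifnot(inherits(model, "lstm_calibrator"), inherits(g1, "gait_tensor"))
  if (dim(g1$values)[3L] != length(model$std_in$mu)) {
    stop("gait tensor DOF count does not match the trained model",
         call. = FALSE)
  }
  n <- dim(g1$values)[1L]; Tn <- dim(g1$values)[2L]
  X <- flatten_tensor(standardize_tensor(g1$values, model$std_in))
  fw <- lstm_forward(model$params, X, n, Tn, model$hidden, cache = FALSE)
  out <- g1
  out$values <- destandardize_tensor(unflatten_tensor(fw$pred, n, Tn),
                                     model$std_out)
  dimnames(out$values) <- dimnames(g1$values)
  out$system <- paste0(g1$system, "_lstm")
  out
}
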