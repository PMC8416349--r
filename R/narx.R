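# Feedforward (open-loop) multiple-input multiple-output NARX network.
#
# The network maps windows of the two EMG envelopes x_i(t-q), q = 0..d, and
# of the two *measured* targets y_j(t-q), q = 1..d (open loop: measured, not
# predicted, values are fed back) through N tanh hidden units and a linear
# output layer to predictions y_hat_j(t+m) of ankle angle (degrees) and
# ankle moment (N*m/kg) m steps ahead:
#
#   v_n(t+m)     = tanh( sum_{q=0..d} sum_i a_ni(q) x_i(t-q)
#                        - sum_{q=1..d} sum_j c_nj(q) y_j(t-q) + b1_n )
#   y_hat_j(t+m) = sum_n w_jn v_n(t+m) + b2_j
#
# The exogenous delay line includes the current sample (q = 0) while the
# feedback line starts at q = 1, and the feedback term enters with a minus
# sign; both asymmetries are deliberate and regression-tested.

#' NARX structural configuration
#'
#' @param m Prediction interval in time steps (tau = m * dt).
#' @param d Sampling-window length in time steps (D = d * dt).
#' @param N Number of tanh hidden units.
#' @param dt Sample period in seconds (default 1/120).
#' @return A `narx_config` with derived `tau_ms` and `D_ms`.
#' @export
narx_config <- function(m, d, N, dt = 1 / FS) {
  stopifnot(m >= 1, d >= 1, N >= 1, dt > 0)
  structure(
    list(m = as.integer(m), d = as.integer(d), N = as.integer(N), dt = dt,
         tau_ms = m * dt * 1000, D_ms = d * dt * 1000),
    class = "narx_config"
  )
}

#' Convert a time interval in milliseconds to time steps
#'
#' Nearest-integer rounding with a floor of one step; at 120 Hz this maps
#' 58 ms to 7 steps and the 8 ms sampling window to 1 step.
#'
#' @param interval_ms Positive interval in milliseconds.
#' @param dt Sample period in seconds.
#' @export
steps_from_ms <- function(interval_ms, dt = 1 / FS) {
  if (any(interval_ms <= 0)) stop("interval must be positive")
  pmax(1L, as.integer(round(interval_ms / 1000 / dt)))
}

#' Initialize NARX weights
#'
#' Seeded layer-wise uniform initialization in +/- sqrt(3 / fan_in), a
#' standard scale that keeps initial hidden pre-activations on normalized
#' data inside tanh's active region.
#'
#' @param config A [narx_config()].
#' @param seed Integer seed; different seeds give different restarts.
#' @return A `narx_weights` object: `a` (N x 2 x (d+1), exogenous, q = 0..d),
#'   `c` (N x 2 x d, feedback, q = 1..d), `w` (2 x N output weights), `b1`
#'   (N hidden biases), `b2` (2 output biases).
#' @export
init_weights <- function(config, seed = 0) {
  d <- config$d; N <- config$N
  with_seed(derive_seed(seed, 7919), {
    s_h <- sqrt(3 / (4 * d + 2))
    s_o <- sqrt(3 / N)
    structure(
      list(
        a = array(stats::runif(N * 2 * (d + 1), -s_h, s_h), dim = c(N, 2, d + 1)),
        c = array(stats::runif(N * 2 * d, -s_h, s_h), dim = c(N, 2, d)),
        w = matrix(stats::runif(2 * N, -s_o, s_o), 2, N),
        b1 = stats::runif(N, -s_h, s_h),
        b2 = stats::runif(2, -s_o, s_o)
      ),
      class = "narx_weights"
    )
  })
}

#' Zero-valued NARX weights
#' @param config A [narx_config()].
#' @export
zero_weights <- function(config) {
  d <- config$d; N <- config$N
  structure(
    list(a = array(0, c(N, 2, d + 1)), c = array(0, c(N, 2, d)),
         w = matrix(0, 2, N), b1 = numeric(N), b2 = numeric(2)),
    class = "narx_weights"
  )
}

check_weights <- function(weights, config) {
  if (!inherits(weights, "narx_weights")) stop("weights must be narx_weights")
  d <- config$d; N <- config$N
  ok <- identical(dim(weights$a), as.integer(c(N, 2, d + 1))) &&
    identical(dim(weights$c), as.integer(c(N, 2, d))) &&
    identical(dim(weights$w), as.integer(c(2, N))) &&
    length(weights$b1) == N && length(weights$b2) == 2
  if (!ok) stop("weight shapes inconsistent with config (N = ", N, ", d = ", d, ")")
  for (nm in c("a", "c", "w", "b1", "b2")) assert_finite(weights[[nm]], nm)
  invisible(weights)
}

# --- parameter vector packing -------------------------------------------
# Hidden-layer parameters for unit n are packed as
#   [a_n1(0..d), a_n2(0..d), c_n1(1..d), c_n2(1..d), b1_n]
# matching the design-matrix columns [x1 lags, x2 lags, -y1 lags, -y2 lags, 1].

n_hidden_params <- function(d) 2L * (d + 1L) + 2L * d + 1L

theta_matrix <- function(weights, d) {
  N <- length(weights$b1)
  th <- matrix(0, n_hidden_params(d), N)
  for (n in seq_len(N)) {
    th[, n] <- c(weights$a[n, 1, ], weights$a[n, 2, ],
                 weights$c[n, 1, ], weights$c[n, 2, ], weights$b1[n])
  }
  th
}

weights_from_vec <- function(vec, config) {
  d <- config$d; N <- config$N
  ph <- n_hidden_params(d)
  w <- zero_weights(config)
  pos <- 0
  for (n in seq_len(N)) {
    th <- vec[pos + seq_len(ph)]; pos <- pos + ph
    w$a[n, 1, ] <- th[1:(d + 1)]
    w$a[n, 2, ] <- th[(d + 2):(2 * d + 2)]
    w$c[n, 1, ] <- th[(2 * d + 3):(3 * d + 2)]
    w$c[n, 2, ] <- th[(3 * d + 3):(4 * d + 2)]
    w$b1[n] <- th[4 * d + 3]
  }
  w$w[1, ] <- vec[pos + seq_len(N)]; pos <- pos + N
  w$w[2, ] <- vec[pos + seq_len(N)]; pos <- pos + N
  w$b2 <- vec[pos + 1:2]
  w
}

weights_to_vec <- function(weights, config) {
  th <- theta_matrix(weights, config$d)
  c(as.numeric(th), weights$w[1, ], weights$w[2, ], weights$b2)
}

# Build the lagged design matrix for one trial in normalized space.
# Rows correspond to input times t = (d+1)..(T-m); prediction rows are
# aligned to target index t + m.
narx_design <- function(xn, yn, config) {
  d <- config$d; m <- config$m
  T_len <- nrow(xn)
  if (T_len <= d + m) stop("trial too short: length ", T_len, " <= d + m = ", d + m)
  t_in <- (d + 1):(T_len - m)
  lagmat <- function(v, lags) {
    matrix(vapply(lags, function(q) v[t_in - q], numeric(length(t_in))),
           nrow = length(t_in))
  }
  Z <- cbind(lagmat(xn[, 1], 0:d), lagmat(xn[, 2], 0:d),
             -lagmat(yn[, 1], 1:d), -lagmat(yn[, 2], 1:d), 1)
  list(Z = Z, t_in = t_in, t_pred = t_in + m,
       target = yn[t_in + m, , drop = FALSE])
}

forward_full <- function(weights, config, Z) {
  V <- tanh(Z %*% theta_matrix(weights, config$d))
  Yhat <- V %*% t(weights$w)
  Yhat[, 1] <- Yhat[, 1] + weights$b2[1]
  Yhat[, 2] <- Yhat[, 2] + weights$b2[2]
  list(V = V, Yhat = Yhat)
}

#' Single NARX forward step
#'
#' Evaluates the forward equations for one time point, in normalized space.
#'
#' @param weights A `narx_weights` object.
#' @param config A [narx_config()].
#' @param x_window (d+1) x 2 matrix of exogenous inputs, row q+1 holding
#'   x(t-q) for q = 0..d.
#' @param y_window d x 2 matrix of past targets, row q holding y(t-q) for
#'   q = 1..d.
#' @return List with `v` (N hidden outputs) and `y_hat` (2 outputs).
#' @export
forward_step <- function(weights, config, x_window, y_window) {
  check_weights(weights, config)
  xw <- as.matrix(x_window); yw <- as.matrix(y_window)
  if (!all(dim(xw) == c(config$d + 1, 2)) || !all(dim(yw) == c(config$d, 2))) {
    stop("window shapes must be (d+1) x 2 and d x 2")
  }
  assert_finite(xw, "x_window"); assert_finite(yw, "y_window")
  z <- c(xw[, 1], xw[, 2], -yw[, 1], -yw[, 2], 1)
  v <- tanh(as.numeric(z %*% theta_matrix(weights, config$d)))
  y_hat <- as.numeric(weights$w %*% v) + weights$b2
  list(v = v, y_hat = y_hat)
}

# --- min-max normalization ----------------------------------------------

#' Fit the min-max normalization map
#'
#' Per-channel minimum and maximum over the pooled training trials (both EMG
#' envelopes and both targets), mapping each channel onto \[-1, 1\].
#' Validation and test trials are mapped with this same map and may exceed
#' \[-1, 1\]; out-of-range values are passed through (tanh saturates
#' gracefully).
#'
#' @param training_trials List of `processed_trial`.
#' @return A `normalization_map` with `lo` and `hi` per channel
#'   (`emg_ta`, `emg_gm`, `angle`, `moment`).
#' @export
fit_normalizer <- function(training_trials) {
  if (length(training_trials) < 1) stop("need at least one training trial")
  X <- do.call(rbind, lapply(training_trials, function(tr) cbind(tr$x, tr$y)))
  colnames(X) <- c("emg_ta", "emg_gm", "angle", "moment")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  if (any(hi - lo <= 0)) {
    stop("degenerate (constant) channel(s): ",
         paste(colnames(X)[hi - lo <= 0], collapse = ", "))
  }
  structure(list(lo = lo, hi = hi), class = "normalization_map")
}

norm_apply <- function(map, values, channels) {
  v <- as.matrix(values)
  for (j in seq_along(channels)) {
    ch <- channels[j]
    v[, j] <- 2 * (v[, j] - map$lo[[ch]]) / (map$hi[[ch]] - map$lo[[ch]]) - 1
  }
  v
}

norm_invert <- function(map, values, channels) {
  v <- as.matrix(values)
  for (j in seq_along(channels)) {
    ch <- channels[j]
    v[, j] <- (v[, j] + 1) / 2 * (map$hi[[ch]] - map$lo[[ch]]) + map$lo[[ch]]
  }
  v
}

#' Normalize a processed trial
#' @param map A `normalization_map`.
#' @param trial A `processed_trial`.
#' @return List with normalized `x` and `y` matrices.
#' @export
normalize_trial <- function(map, trial) {
  list(x = norm_apply(map, trial$x, c("emg_ta", "emg_gm")),
       y = norm_apply(map, trial$y, c("angle", "moment")))
}

#' Open-loop prediction over a trial
#'
#' Runs the network over every time point with a full input history, feeding
#' back the *measured* targets (open-loop contract). Predictions are
#' de-normalized to physical units and aligned to the target time base:
#' row k of `y_hat` predicts the sample at index `t_pred[k] = t_in[k] + m`,
#' so scoring is a same-index comparison against `trial$y[t_pred, ]`.
#'
#' @param weights,config,normalizer Model components.
#' @param trial A `processed_trial` of length > d + m.
#' @param keep_hidden If `TRUE`, retain the hidden-unit outputs.
#' @return A `prediction_trace`: `y_hat` (physical units), `target`
#'   (measured values at the same indices), `t_pred`, optional `V`.
#' @export
predict_trial <- function(weights, config, normalizer, trial,
                          keep_hidden = FALSE) {
  check_weights(weights, config)
  nt <- normalize_trial(normalizer, trial)
  des <- narx_design(nt$x, nt$y, config)
  fw <- forward_full(weights, config, des$Z)
  y_hat <- norm_invert(normalizer, fw$Yhat, c("angle", "moment"))
  colnames(y_hat) <- c("angle", "moment")
  structure(
    list(y_hat = y_hat,
         target = trial$y[des$t_pred, , drop = FALSE],
         t_pred = des$t_pred,
         V = if (keep_hidden) fw$V else NULL,
         condition = trial$condition,
         trial_id = trial$trial_id),
    class = "prediction_trace"
  )
}

# --- serialization -------------------------------------------------------

#' Serialize / deserialize a NARX model
#'
#' A model (weights + config + normalizer) is written as one versioned JSON
#' document with explicit index order (`a[n][i][q]`, `c[n][j][q]`,
#' `w[j][n]`); the round trip is bit-exact.
#'
#' @param weights,config,normalizer Model components.
#' @param path File path.
#' @rdname model-io
#' @export
write_model <- function(weights, config, normalizer, path) {
  doc <- list(
    schema = "narxgait-model-1",
    config = list(m = config$m, d = config$d, N = config$N, dt = config$dt),
    normalizer = list(lo = as.list(normalizer$lo), hi = as.list(normalizer$hi)),
    weights = list(
      a = lapply(seq_len(config$N), function(n)
        lapply(1:2, function(i) weights$a[n, i, ])),
      c = lapply(seq_len(config$N), function(n)
        lapply(1:2, function(j) weights$c[n, j, ])),
      w = lapply(1:2, function(j) weights$w[j, ]),
      b1 = weights$b1, b2 = weights$b2
    )
  )
  # digits = I(17): 17 significant digits, enough to round-trip any double
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model-io
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "narxgait-model-1")) {
    stop("unrecognized model schema: ", doc$schema %||% "<missing>")
  }
  config <- narx_config(doc$config$m, doc$config$d, doc$config$N, doc$config$dt)
  N <- config$N
  num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  w <- zero_weights(config)
  for (n in seq_len(N)) {
    for (i in 1:2) {
      w$a[n, i, ] <- num(doc$weights$a[[n]][[i]])
      w$c[n, i, ] <- num(doc$weights$c[[n]][[i]])
    }
  }
  w$w <- rbind(num(doc$weights$w[[1]]), num(doc$weights$w[[2]]))
  w$b1 <- num(doc$weights$b1)
  w$b2 <- num(doc$weights$b2)
  chans <- c("emg_ta", "emg_gm", "angle", "moment")
  normalizer <- structure(
    list(lo = structure(num(doc$normalizer$lo[chans]), names = chans),
         hi = structure(num(doc$normalizer$hi[chans]), names = chans)),
    class = "normalization_map"
  )
  list(weights = w, config = config, normalizer = normalizer)
}

#' @export
print.narx_config <- function(x, ...) {
  cat(sprintf("narx_config: m=%d (tau %.0f ms), d=%d (D %.0f ms), N=%d, dt=1/%g s\n",
              x$m, x$tau_ms, x$d, x$D_ms, x$N, 1 / x$dt))
  invisible(x)
}
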