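# Signal conditioning: EMG linear envelope, kinetic/kinematic filtering,
# trial truncation and common-length resampling.
#
# All zero-phase filters are 4th-order Butterworth designs applied
# forward-backward (effective order 8), the convention in gait biomechanics.

#' @rdname sigproc-constants
#' @export
FS_RAW <- 1200

#' Package sampling-rate constants
#'
#' `FS_RAW` (1,200 Hz) is the raw EMG / force-plate rate; `FS` (120 Hz) is the
#' common analysis rate; `PREROLL_SAMPLES` (27) is 225 ms at 120 Hz, the
#' pre-roll kept before the first heel strike when truncating a trial.
#' @name sigproc-constants
#' @export
FS <- 120

#' @rdname sigproc-constants
#' @export
PREROLL_SAMPLES <- 27L

check_rate <- function(fs, expected, what) {
  if (!isTRUE(all.equal(fs, expected))) {
    stop(what, ": expected sampling rate ", expected, " Hz, got ", fs)
  }
}

#' EMG linear envelope
#'
#' Converts raw surface EMG at 1,200 Hz into a linear envelope at 120 Hz:
#' zero-phase 20-499.5 Hz band-pass (4th-order Butterworth), full-wave
#' rectification, zero-phase 5.5 Hz low-pass (4th-order Butterworth), then
#' decimation by 10. The low-pass can slightly undershoot zero; the envelope
#' is clipped at 0 because a physical envelope is non-negative.
#'
#' @param raw Numeric vector, raw EMG samples.
#' @param fs Sampling rate of `raw`; must be 1,200 Hz.
#' @return Numeric envelope at 120 Hz (length `length(raw) / 10`, rounded up).
#' @export
emg_linear_envelope <- function(raw, fs = FS_RAW) {
  check_rate(fs, FS_RAW, "emg_linear_envelope")
  if (anyNA(raw)) stop("raw EMG contains missing values")
  if (length(raw) < 300) {
    stop("raw EMG too short (", length(raw), " samples); need >= 300 at 1,200 Hz")
  }
  bp <- butter_design(4, c(20, 499.5), fs, "bandpass")
  lp <- butter_design(4, 5.5, fs, "lowpass")
  env <- filtfilt_sos(lp, abs(filtfilt_sos(bp, raw)))
  env <- env[seq(1, length(env), by = 10)]
  pmax(env, 0)
}

#' Kinetic-channel filtering
#'
#' Zero-phase 15 Hz low-pass plus 59-61 Hz band-stop (both 4th-order
#' Butterworth) applied to a 1,200 Hz kinetic series, then decimated to
#' 120 Hz. The 15 Hz cutoff is far below the post-decimation Nyquist (60 Hz),
#' so no extra anti-alias stage is needed.
#'
#' @param raw Numeric vector at 1,200 Hz.
#' @param fs Sampling rate; must be 1,200 Hz.
#' @return Filtered series at 120 Hz.
#' @export
filter_kinetics <- function(raw, fs = FS_RAW) {
  check_rate(fs, FS_RAW, "filter_kinetics")
  if (anyNA(raw)) stop("kinetic series contains missing values")
  if (length(raw) < 300) stop("kinetic series too short (", length(raw), " samples)")
  lp <- butter_design(4, 15, fs, "lowpass")
  bs <- butter_design(4, c(59, 61), fs, "bandstop")
  y <- filtfilt_sos(lp, filtfilt_sos(bs, raw))
  y[seq(1, length(y), by = 10)]
}

#' Kinematic-channel filtering
#'
#' Zero-phase 15 Hz low-pass (4th-order Butterworth) at the 120 Hz analysis
#' rate; output length equals input length.
#'
#' @param x Numeric vector at 120 Hz.
#' @param fs Sampling rate; must be 120 Hz.
#' @export
filter_kinematics <- function(x, fs = FS) {
  check_rate(fs, FS, "filter_kinematics")
  if (anyNA(x)) stop("kinematic series contains missing values")
  if (length(x) < 50) stop("kinematic series too short (", length(x), " samples)")
  lp <- butter_design(4, 15, fs, "lowpass")
  filtfilt_sos(lp, x, padlen = min(length(x) - 1L, 200L))
}

#' Truncate a trial to the analysis window
#'
#' Cuts the 120 Hz channels to the analysis window running from 225 ms (27
#' samples) before the first heel strike to the terminal heel strike, the
#' window on which all modelling and reporting is done. Events are re-indexed
#' to the window and a 0-100 percent-trial axis is attached. Applying the
#' operation to an already-truncated trial is the identity.
#'
#' @param trial A `raw_trial` (see [generate_trial()]) or `processed_trial`.
#' @return A `processed_trial`: list with `x` (T x 2 EMG envelopes,
#'   dorsiflexor then plantarflexor), `y` (T x 2: angle in degrees, moment in
#'   N*m/kg), `dt` (1/120 s), `events` (sample indices into the window),
#'   `condition`, `trial_id`, `percent_trial`.
#' @export
truncate_trial <- function(trial) {
  if (inherits(trial, "processed_trial")) {
    env <- trial$x
    ang <- trial$y[, 1]
    mom <- trial$y[, 2]
    ev_idx <- trial$events
  } else if (inherits(trial, "raw_trial")) {
    env <- trial$emg_envelope
    ang <- trial$angle
    mom <- trial$moment
    ev_idx <- lapply(trial$events, function(t) round(t * FS) + 1L)
  } else {
    stop("truncate_trial expects a raw_trial or processed_trial")
  }
  hs <- ev_idx[["HS"]]
  if (is.null(hs) || length(hs) < 1) stop("events must contain at least one HS (heel strike)")
  hs1 <- as.integer(hs[1])
  hs_end <- as.integer(hs[length(hs)])
  if (hs1 - PREROLL_SAMPLES < 1) {
    stop("insufficient pre-roll: need ", PREROLL_SAMPLES,
         " samples (225 ms) before the first heel strike, have ", hs1 - 1)
  }
  if (hs_end > nrow(as.matrix(env))) stop("terminal heel strike beyond end of record")
  win <- (hs1 - PREROLL_SAMPLES):hs_end
  reindex <- function(i) {
    i <- as.integer(i) - (hs1 - PREROLL_SAMPLES) + 1L
    i[i >= 1L & i <= length(win)]
  }
  ev_new <- lapply(ev_idx, reindex)
  ev_new <- ev_new[vapply(ev_new, length, 0L) > 0]
  structure(
    list(
      x = as.matrix(env)[win, , drop = FALSE],
      y = cbind(angle = ang[win], moment = mom[win]),
      dt = 1 / FS,
      events = ev_new,
      condition = trial$condition,
      trial_id = trial$trial_id %||% NA_character_,
      percent_trial = 100 * (seq_along(win) - 1) / (length(win) - 1)
    ),
    class = "processed_trial"
  )
}

#' Resample a series to a fixed length
#'
#' Endpoint-preserving linear interpolation of a series onto `L` uniformly
#' spaced points over its original span; used to put trials of one ambulation
#' condition on a common time base for instantaneous-error analysis.
#'
#' @param series Numeric vector (length >= 2).
#' @param L Target length (>= 2).
#' @export
resample_to_length <- function(series, L) {
  if (length(series) < 2 || L < 2) stop("resample_to_length needs input length >= 2 and L >= 2")
  if (length(series) == L) return(as.numeric(series))
  stats::approx(x = seq(0, 1, length.out = length(series)), y = series,
                xout = seq(0, 1, length.out = L))$y
}

#' Common reporting length for an ambulation condition
#'
#' Trials are interpolated to a common per-condition length before
#' instantaneous-RMSE aggregation: 145 samples for level walking, 430 for
#' stair ascent, 400 for stair descent.
#'
#' @param condition `"LW"`, `"AS"` or `"DS"`.
#' @export
common_trial_length <- function(condition) {
  check_condition(condition)
  c(LW = 145L, AS = 430L, DS = 400L)[[condition]]
}

#' @export
print.processed_trial <- function(x, ...) {
  cat(sprintf("processed_trial %s [%s]: %d samples @ %g Hz, events: %s\n",
              x$trial_id, x$condition, nrow(x$x), 1 / x$dt,
              paste(names(x$events), collapse = " ")))
  invisible(x)
}
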