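# Synthetic multi-condition gait generator.
#
# Produces seeded sessions of level-walking (LW), stair-ascent (AS) and
# stair-descent (DS) trials with the morphology of normative gait curves:
# dorsiflexor EMG bursts around heel strike and swing, a plantarflexor burst
# around push-off, ankle angle with its widest range in stair descent, and a
# single dominant plantarflexion moment peak per stance. Stair conditions
# span three continuous gait cycles (level -> stairs -> level) so terrain
# transitions are present. Trial-to-trial variability comes from per-trial
# amplitude jitter, a smooth monotone time warp, within-trial EMG activation
# fluctuation, and additive measurement noise. A fraction `emg_coupling` of
# the mechanical deviation from the template is driven by the trial's own
# EMG activation fluctuations passed through a causal lag-and-smooth
# operator (EMG leads mechanics), which is what makes EMG informativeness
# testable: with constant-EMG inputs that information is destroyed.

# per-cycle bump tables: center/width in cycle fraction, amplitude in
# channel units (envelopes mV-scale, angle degrees, moment N*m/kg)
bumps_df <- function(center, width, amp) {
  data.frame(center = center, width = width, amp = amp)
}

template_library <- function() {
  lw <- list(
    emg_ta = bumps_df(c(0.02, 0.70, 0.92), c(0.05, 0.05, 0.08), c(0.22, 0.12, 0.18)),
    emg_gm = bumps_df(c(0.35, 0.48), c(0.10, 0.06), c(0.30, 0.18)),
    angle  = bumps_df(c(0.07, 0.40, 0.64, 0.85), c(0.045, 0.13, 0.055, 0.07),
                      c(-6, 11, -19, 4)),
    moment = bumps_df(c(0.10, 0.45), c(0.05, 0.11), c(-0.15, 1.40))
  )
  scale_amp <- function(df, s) { df$amp <- df$amp * s; df }
  as <- list(
    emg_ta = lw$emg_ta,
    emg_gm = scale_amp(lw$emg_gm, 1.2),
    angle  = rbind(scale_amp(lw$angle, 1.05), bumps_df(0.25, 0.12, 4)),
    moment = bumps_df(c(0.10, 0.42), c(0.05, 0.11), c(-0.10, 1.30))
  )
  ds <- list(
    emg_ta = scale_amp(lw$emg_ta, 1.15),
    emg_gm = lw$emg_gm,
    angle  = scale_amp(lw$angle, 1.30),
    moment = rbind(bumps_df(c(0.15, 0.40), c(0.06, 0.12), c(0.35, 1.35)))
  )
  list(LW = lw, AS = as, DS = ds)
}

#' Build a gait template for one ambulation condition
#'
#' Templates are hand-built Gaussian-bump approximations of normative gait
#' curves for four channels: dorsiflexor envelope, plantarflexor envelope,
#' ankle angle (degrees, dorsiflexion positive) and ankle moment (N*m/kg,
#' plantarflexion positive). Level walking spans one gait cycle; stair
#' ascent/descent span three continuous cycles whose per-cycle gains emulate
#' the transition steps onto and off the staircase. The stair-descent angle
#' amplitudes are 1.3x level walking, giving stair descent the widest range
#' of motion.
#'
#' @param condition `"LW"`, `"AS"` or `"DS"`.
#' @return A `gait_template`: bump tables per channel, per-channel baselines,
#'   cycle layout in samples at 120 Hz, per-cycle gains, and event phases
#'   (cycle fractions) for ON, cTO, cHS, cON, OFF, TO (HS at 0).
#' @export
gait_template <- function(condition) {
  check_condition(condition)
  lib <- template_library()
  cyc_samp <- c(LW = 120L, AS = 143L, DS = 132L)[[condition]]
  n_cycles <- if (condition == "LW") 1L else 3L
  cycle_gains <- switch(condition,
    LW = 1.0,
    AS = c(0.90, 1.05, 0.95),
    DS = c(0.95, 1.05, 0.90)
  )
  structure(
    list(
      condition = condition,
      bumps = lib[[condition]],
      baseline = c(emg_ta = 0.010, emg_gm = 0.008, angle = 0, moment = 0),
      cycle_samples = cyc_samp,
      n_cycles = n_cycles,
      cycle_gains = cycle_gains,
      lead_samples = 42L,   # 0.35 s before the first heel strike
      tail_samples = 30L,   # 0.25 s after the terminal heel strike
      event_phases = c(ON = 0.02, cTO = 0.12, cHS = 0.50, cON = 0.52,
                       OFF = 0.58, TO = 0.62)
    ),
    class = "gait_template"
  )
}

# evaluate one channel's bump sum at (possibly warped) cycle-phase values;
# cycles -1 and n_cycles reuse the edge cycle's gain so the pre-roll looks
# like the tail of a preceding gait cycle
eval_channel <- function(template, channel, phase, bump_gain = NULL) {
  df <- template$bumps[[channel]]
  g <- template$cycle_gains
  out <- rep(template$baseline[[channel]], length(phase))
  for (k in -1:template$n_cycles) {
    gk <- g[min(max(k + 1, 1), length(g))]
    for (b in seq_len(nrow(df))) {
      gb <- if (is.null(bump_gain)) 1 else bump_gain[[channel]][b]
      c0 <- k + df$center[b]
      out <- out + gk * gb * df$amp[b] * exp(-0.5 * ((phase - c0) / df$width[b])^2)
    }
  }
  out
}

#' Noise-free template channels at 120 Hz
#'
#' Evaluates a template on its nominal time grid with no variability; the
#' reference against which generated trials are compared.
#'
#' @param template A `gait_template`.
#' @param phase Optional phase values (cycle fractions) at which to evaluate
#'   the template; defaults to the nominal unwarped grid.
#' @return List with `time_s`, matrices-free channel vectors `emg_ta`,
#'   `emg_gm`, `angle`, `moment`, and `events` (named times in seconds; `HS`
#'   has one entry per cycle boundary including the terminal heel strike).
#' @export
evaluate_template <- function(template, phase = NULL) {
  n_tot <- with(template, lead_samples + n_cycles * cycle_samples + tail_samples + 1L)
  t_idx <- seq_len(n_tot)
  if (is.null(phase)) {
    phase <- (t_idx - 1 - template$lead_samples) / template$cycle_samples
  }
  ch <- lapply(c("emg_ta", "emg_gm", "angle", "moment"),
               function(nm) eval_channel(template, nm, phase))
  names(ch) <- c("emg_ta", "emg_gm", "angle", "moment")
  ch$emg_ta <- pmax(ch$emg_ta, 0)
  ch$emg_gm <- pmax(ch$emg_gm, 0)
  hs_phase <- 0:template$n_cycles
  within_phase <- unlist(lapply(0:(template$n_cycles - 1),
                                function(k) k + template$event_phases))
  names(within_phase) <- rep(names(template$event_phases), template$n_cycles)
  ev_phase <- c(structure(hs_phase, names = rep("HS", length(hs_phase))), within_phase)
  # invert phase -> time on this grid
  t_s <- (t_idx - 1) / FS
  ev_time <- stats::approx(phase, t_s, xout = ev_phase)$y
  events <- split(ev_time, names(ev_phase))
  events <- lapply(events, sort)
  c(list(time_s = t_s), ch, list(events = events))
}

#' Trial-to-trial variability model
#'
#' @param amplitude_jitter_sd SD of the log of per-trial multiplicative
#'   gains (lognormal). Applied per EMG bump and per EMG channel; mechanical
#'   channels get a per-trial gain with half this SD (their trial-specific
#'   deviations are mostly driven through the EMG coupling instead).
#' @param time_warp_sd SD of the log-rate fluctuation of the smooth monotone
#'   phase warp (endpoints pinned, so trial span is preserved).
#' @param activation_jitter_sd SD of the smooth (<= 3.5 Hz) within-trial
#'   multiplicative EMG activation fluctuation; this is the component that
#'   propagates into angle and moment when `emg_coupling > 0`.
#' @param additive_noise_sd Named vector, additive smooth measurement noise
#'   SD per channel: `emg` (mV), `angle` (degrees), `moment` (N*m/kg).
#' @param emg_coupling Fraction in \[0, 1\]: how strongly the mechanical
#'   channels follow the trial's own (lagged, smoothed) EMG activation
#'   deviations rather than the fixed template.
#' @param seed Integer; together with condition and trial index it fully
#'   determines every generated sample.
#' @return A `variability_model` list.
#' @export
variability_model <- function(amplitude_jitter_sd = 0.10,
                              time_warp_sd = 0.015,
                              activation_jitter_sd = 0.18,
                              additive_noise_sd = c(emg = 0.004, angle = 0.08,
                                                    moment = 0.0035),
                              emg_coupling = 0.6,
                              seed = 42) {
  stopifnot(amplitude_jitter_sd >= 0, time_warp_sd >= 0,
            activation_jitter_sd >= 0, all(additive_noise_sd >= 0))
  if (emg_coupling < 0 || emg_coupling > 1) stop("emg_coupling must be in [0, 1]")
  need <- c("emg", "angle", "moment")
  if (!all(need %in% names(additive_noise_sd))) {
    stop("additive_noise_sd needs named entries: ", paste(need, collapse = ", "))
  }
  structure(
    list(amplitude_jitter_sd = amplitude_jitter_sd,
         time_warp_sd = time_warp_sd,
         activation_jitter_sd = activation_jitter_sd,
         additive_noise_sd = additive_noise_sd,
         emg_coupling = emg_coupling,
         seed = as.integer(seed)),
    class = "variability_model"
  )
}

# causal lag-and-smooth operator linking EMG activation deviations to
# mechanics: pure delay of `lag_s` then a one-pole low-pass at `cutoff_hz`.
# EMG leads mechanics by ~100 ms, comfortably more than the 58 ms
# prediction interval, so the coupled component is predictable from EMG but
# not from the mechanical history alone.
lag_smooth <- function(x, lag_s = 0.10, cutoff_hz = 6, fs = FS) {
  k <- round(lag_s * fs)
  lagged <- c(rep(x[1], k), x[seq_len(length(x) - k)])
  alpha <- exp(-2 * pi * cutoff_hz / fs)
  y <- stats::filter(lagged * (1 - alpha), alpha, method = "recursive",
                     init = lagged[1])
  as.numeric(y)
}

# coupling gains: degrees / moment units per unit of envelope deviation
COUPLING_GAIN <- c(angle_ta = 18, angle_gm = -13.5, moment_gm = 1.2, moment_ta = -0.25)

#' Generate one synthetic gait trial
#'
#' Draws a seeded trial from a template under a variability model. The
#' per-trial RNG stream is derived from (seed, condition, trial index), so
#' trials are independent and reorderable. With all variability SDs at zero
#' the trial reproduces the template exactly, regardless of `emg_coupling`.
#'
#' @param template A [gait_template()].
#' @param variability A [variability_model()].
#' @param trial_index Non-negative integer identifying the trial.
#' @param include_raw If `TRUE`, also simulate raw 1,200 Hz EMG: a 20-450 Hz
#'   band-limited noise carrier (unit mean absolute amplitude) modulated by
#'   the trial envelope, for end-to-end testing of the envelope chain.
#' @return A `raw_trial`: `emg_envelope` (n x 2, columns `emg_ta`,
#'   `emg_gm`), `angle`, `moment` (120 Hz), optional `emg_raw` (n*10 x 2 at
#'   1,200 Hz), `events` (named list of times in seconds), `condition`,
#'   `trial_id`.
#' @export
generate_trial <- function(template, variability, trial_index,
                           include_raw = TRUE) {
  if (!inherits(template, "gait_template")) stop("template must be a gait_template")
  if (!inherits(variability, "variability_model")) stop("variability must be a variability_model")
  stopifnot(trial_index >= 0)
  cond_idx <- match(template$condition, CONDITIONS)
  seed_t <- derive_seed(variability$seed, cond_idx, trial_index)

  n_tot <- with(template, lead_samples + n_cycles * cycle_samples + tail_samples + 1L)
  nominal_phase <- (seq_len(n_tot) - 1 - template$lead_samples) / template$cycle_samples

  with_seed(seed_t, {
    v <- variability
    # --- monotone phase warp: endpoints of the gait span pinned ---
    gait <- which(nominal_phase >= 0 & nominal_phase <= template$n_cycles)
    phase <- nominal_phase
    if (v$time_warp_sd > 0) {
      rate <- exp(smooth_noise(length(gait), v$time_warp_sd, FS, 0.8))
      du <- diff(nominal_phase[gait])
      w <- c(0, cumsum(rate[-length(rate)] * du))
      w <- w * (template$n_cycles / w[length(w)])
      phase[gait] <- w
      # continue the warp linearly outside the gait span
      phase[nominal_phase < 0] <- nominal_phase[nominal_phase < 0]
      after <- nominal_phase > template$n_cycles
      phase[after] <- template$n_cycles + (nominal_phase[after] - template$n_cycles)
    }

    # --- per-trial amplitude jitter ---
    emg_chans <- c("emg_ta", "emg_gm")
    mech_chans <- c("angle", "moment")
    bump_gain <- lapply(template$bumps, function(df) rep(1, nrow(df)))
    ch_gain <- c(emg_ta = 1, emg_gm = 1, angle = 1, moment = 1)
    if (v$amplitude_jitter_sd > 0) {
      for (nm in emg_chans) {
        bump_gain[[nm]] <- exp(stats::rnorm(nrow(template$bumps[[nm]]),
                                            0, v$amplitude_jitter_sd))
        ch_gain[nm] <- exp(stats::rnorm(1, 0, v$amplitude_jitter_sd))
      }
      for (nm in mech_chans) {
        ch_gain[nm] <- exp(stats::rnorm(1, 0, v$amplitude_jitter_sd / 2))
      }
    }

    base <- lapply(c(emg_chans, mech_chans), function(nm) {
      ch_gain[[nm]] * eval_channel(template, nm, phase, bump_gain)
    })
    names(base) <- c(emg_chans, mech_chans)
    base$emg_ta <- pmax(base$emg_ta, 0)
    base$emg_gm <- pmax(base$emg_gm, 0)

    # --- within-trial activation fluctuation (the EMG-borne information) ---
    act <- base[emg_chans]
    if (v$activation_jitter_sd > 0) {
      for (nm in emg_chans) {
        s <- smooth_noise(n_tot, v$activation_jitter_sd, FS, 3.5)
        act[[nm]] <- pmax(base[[nm]] * (1 + s), 0)
      }
    }

    # --- EMG-coupled mechanical deviations ---
    # Deviations are taken against the warped *condition template* (no trial
    # gains), so every trial-specific feature of the observed envelope --
    # amplitude jitter as well as activation fluctuation -- carries through
    # to the mechanics. With all variability SDs at zero both terms coincide
    # with the template and the deviation vanishes.
    angle <- base$angle
    moment <- base$moment
    if (v$emg_coupling > 0) {
      ref_ta <- pmax(eval_channel(template, "emg_ta", phase), 0)
      ref_gm <- pmax(eval_channel(template, "emg_gm", phase), 0)
      dev_ta <- lag_smooth(act$emg_ta - ref_ta)
      dev_gm <- lag_smooth(act$emg_gm - ref_gm)
      angle <- angle + v$emg_coupling *
        (COUPLING_GAIN["angle_ta"] * dev_ta + COUPLING_GAIN["angle_gm"] * dev_gm)
      moment <- moment + v$emg_coupling *
        (COUPLING_GAIN["moment_gm"] * dev_gm + COUPLING_GAIN["moment_ta"] * dev_ta)
    }

    # --- additive measurement noise ---
    nz <- v$additive_noise_sd
    env <- cbind(
      emg_ta = pmax(act$emg_ta + smooth_noise(n_tot, nz[["emg"]], FS, 5), 0),
      emg_gm = pmax(act$emg_gm + smooth_noise(n_tot, nz[["emg"]], FS, 5), 0)
    )
    angle <- angle + smooth_noise(n_tot, nz[["angle"]], FS, 6)
    moment <- moment + smooth_noise(n_tot, nz[["moment"]], FS, 6)

    # --- events at warped phases ---
    hs_phase <- 0:template$n_cycles
    within <- unlist(lapply(0:(template$n_cycles - 1),
                            function(k) k + template$event_phases))
    names(within) <- rep(names(template$event_phases), template$n_cycles)
    ev_phase <- c(structure(hs_phase, names = rep("HS", length(hs_phase))), within)
    t_s <- (seq_len(n_tot) - 1) / FS
    ev_time <- stats::approx(phase, t_s, xout = ev_phase, ties = "ordered")$y
    events <- lapply(split(ev_time, names(ev_phase)), sort)

    emg_raw <- NULL
    if (include_raw) {
      emg_raw <- vapply(seq_len(2), function(j) {
        carrier <- stats::rnorm(n_tot * 10L)
        bp <- butter_design(4, c(20, 450), FS_RAW, "bandpass")
        carrier <- filtfilt_sos(bp, carrier)
        carrier <- carrier / mean(abs(carrier))
        env_up <- stats::approx(seq_len(n_tot), env[, j],
                                xout = seq(1, n_tot, length.out = n_tot * 10L))$y
        carrier * env_up
      }, numeric(n_tot * 10L))
      colnames(emg_raw) <- c("emg_ta", "emg_gm")
    }

    structure(
      list(
        emg_raw = emg_raw,
        emg_envelope = env,
        angle = angle,
        moment = moment,
        fs_raw = FS_RAW,
        fs = FS,
        events = events,
        condition = template$condition,
        trial_id = sprintf("%s_%03d", template$condition, trial_index)
      ),
      class = "raw_trial"
    )
  })
}

#' Generate a full multi-condition session
#'
#' @param templates Named list of templates (defaults to the built-in LW, AS,
#'   DS templates).
#' @param variability A [variability_model()].
#' @param n_trials_per_condition At least 11: the trial-blocked protocol
#'   needs 8 training + 2 validation + 1 novel test trial per condition per
#'   fold.
#' @param include_raw Forwarded to [generate_trial()].
#' @return A `gait_session`: list with `trials` (list of `raw_trial`),
#'   `variability`, and `n_per_condition`.
#' @export
generate_session <- function(templates = NULL,
                             variability = variability_model(),
                             n_trials_per_condition = 11,
                             include_raw = FALSE) {
  if (n_trials_per_condition < 11) {
    stop("need >= 11 trials per condition: the trial-blocked protocol uses ",
         "8 training + 2 validation + 1 novel test trial per fold")
  }
  if (is.null(templates)) {
    templates <- lapply(CONDITIONS, gait_template)
    names(templates) <- CONDITIONS
  }
  trials <- list()
  for (tpl in templates) {
    for (i in seq_len(n_trials_per_condition)) {
      trials[[length(trials) + 1L]] <-
        generate_trial(tpl, variability, i - 1L, include_raw = include_raw)
    }
  }
  structure(
    list(trials = trials, variability = variability,
         n_per_condition = as.integer(n_trials_per_condition)),
    class = "gait_session"
  )
}

#' @export
print.gait_session <- function(x, ...) {
  conds <- vapply(x$trials, function(tr) tr$condition, "")
  cat("gait_session:", length(x$trials), "trials (",
      paste(sprintf("%s: %d", names(table(conds)), table(conds)), collapse = ", "),
      "), seed", x$variability$seed, "\n")
  invisible(x)
}

#' Generate target series from a known NARX network (teacher)
#'
#' Runs the forward equations closed-loop on a given exogenous series to
#' manufacture data whose generative parameters are known exactly; used for
#' parameter-recovery (teacher-student) testing of the trainer. The first
#' `d + m` rows of the output are the supplied initial values; every later
#' row `y[s, ]` is the network output for prediction time `s` computed from
#' the exogenous window ending at `s - m` and the previously generated
#' targets. All values live in the network's own (normalized) space.
#'
#' @param weights A [narx_weights] object.
#' @param config A [narx_config()].
#' @param exogenous T x 2 matrix of exogenous inputs.
#' @param y_init (d + m) x 2 matrix of initial target samples.
#' @return T x 2 matrix of generated targets.
#' @export
teacher_generate <- function(weights, config, exogenous, y_init) {
  check_weights(weights, config)
  x <- as.matrix(exogenous)
  y0 <- as.matrix(y_init)
  d <- config$d; m <- config$m
  n_init <- d + m
  if (nrow(y0) < n_init) {
    stop("y_init must supply at least d + m = ", n_init, " rows")
  }
  if (nrow(x) <= n_init + 1) stop("exogenous series too short (need > d + m + 1 rows)")
  T_len <- nrow(x)
  y <- matrix(0, T_len, 2)
  y[seq_len(n_init), ] <- y0[seq_len(n_init), ]
  for (s in (n_init + 1):T_len) {
    t <- s - m
    xw <- x[t - (0:d), , drop = FALSE]   # rows q = 0..d
    yw <- y[t - (1:d), , drop = FALSE]   # rows q = 1..d
    y[s, ] <- forward_step(weights, config, xw, yw)$y_hat
  }
  colnames(y) <- c("angle", "moment")
  y
}
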