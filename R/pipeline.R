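# End-to-end pipeline: simulate/ingest -> preprocess -> (D, N) sweep at a
# fixed prediction interval -> zero-error-goal finalization -> evaluation.

#' Preprocess a session to the analysis window
#'
#' Truncates every trial to the 225 ms-pre-heel-strike window. When
#' `from_raw = TRUE` the EMG envelopes are recomputed from the 1,200 Hz raw
#' EMG through the full linear-envelope chain and the kinematic channel is
#' re-filtered at 15 Hz; by default the 120 Hz channels carried by the trial
#' are used as-is.
#'
#' @param session A `gait_session` (or plain list of `raw_trial`).
#' @param from_raw Recompute envelopes from raw EMG (requires `emg_raw`).
#' @return List of `processed_trial`.
#' @export
preprocess_session <- function(session, from_raw = FALSE) {
  trials <- if (inherits(session, "gait_session")) session$trials else session
  lapply(trials, function(tr) {
    if (from_raw) {
      if (is.null(tr$emg_raw)) stop("trial ", tr$trial_id, " carries no raw EMG")
      tr$emg_envelope <- cbind(
        emg_ta = emg_linear_envelope(tr$emg_raw[, 1]),
        emg_gm = emg_linear_envelope(tr$emg_raw[, 2])
      )[seq_along(tr$angle), , drop = FALSE]
      tr$angle <- filter_kinematics(tr$angle)
    }
    truncate_trial(tr)
  })
}

#' Default critical-point specifications for the synthetic benchmark
#'
#' Per condition: toe-off, maximum dorsiflexion, maximum plantarflexion
#' (angle) and maximum plantarflexion moment as stance critical points on the
#' first (level-walking) and, for stair conditions, second (stair) cycle,
#' plus one clearance interval centered on the swing-phase angle minimum of
#' the template (+/- 3 percent of trial), the synthetic stand-in for the
#' minimum toe-clearance timing band.
#'
#' @return Named list (LW, AS, DS) of lists of [critical_point_spec()].
#' @export
default_critical_specs <- function() {
  out <- list()
  for (cond in CONDITIONS) {
    tpl <- gait_template(cond)
    trial <- truncate_trial(generate_trial(tpl, variability_model(
      amplitude_jitter_sd = 0, time_warp_sd = 0, activation_jitter_sd = 0,
      additive_noise_sd = c(emg = 0, angle = 0, moment = 0),
      emg_coupling = 0, seed = 1), 0, include_raw = FALSE))
    n <- nrow(trial$y)
    cycles <- if (cond == "LW") 1L else c(1L, 2L)
    specs <- list()
    for (cy in cycles) {
      specs <- c(specs, list(
        critical_point_spec("stance_event", "TO", "angle", cycle = cy),
        critical_point_spec("stance_event", "max_dorsiflexion", "angle", cycle = cy),
        critical_point_spec("stance_event", "max_plantarflexion", "angle", cycle = cy),
        critical_point_spec("stance_event", "max_pf_moment", "moment", cycle = cy)
      ))
    }
    # clearance interval at the swing-phase angle minimum of the mid cycle
    cy <- if (cond == "LW") 1L else 2L
    to <- trial$events$TO[cy]
    hs_next <- trial$events$HS[cy + 1L]
    swing <- to:hs_next
    ctr <- swing[which.min(trial$y[swing, 1])]
    frac <- (ctr - 1) / (n - 1)
    specs <- c(specs, list(critical_point_spec(
      "clearance_interval", c(max(0, frac - 0.03), min(1, frac + 0.03)),
      "angle")))
    out[[cond]] <- specs
  }
  out
}

#' Run the full benchmark pipeline
#'
#' Generates (or accepts) a session, preprocesses it, characterizes the
#' (D, N) plane of the hyperparameter grid at a fixed prediction interval
#' with the 1 percent moment-variance error goal, selects the optimal
#' (D, N), re-trains at zero error goal, and evaluates the per-fold
#' optimized models on their novel test trials.
#'
#' Desk-scale defaults (reduced D/N grid, 3 folds, 2 sweep restarts, 3
#' finalization restarts, capped epochs) keep a full run in minutes on one
#' CPU; the protocol-scale settings (full grid, 10 folds, 10 restarts) are
#' available through the arguments.
#'
#' @param seed Master seed for generation, folds and training.
#' @param session Optional pre-built `gait_session`; generated when NULL.
#' @param n_trials_per_condition Trials per condition when generating.
#' @param emg_coupling EMG-coupling fraction for the generated session.
#' @param tau_ms Fixed prediction interval (default 58 ms).
#' @param D_ms_grid,N_grid Sweep axes for the (D, N) characterization.
#' @param n_folds Number of cross-validation folds.
#' @param sweep_restarts,final_restarts Restarts in the sweep and the
#'   finalization phases.
#' @param sweep_max_epochs,final_max_epochs Epoch caps for the two phases.
#' @param specs Critical-point specs (default [default_critical_specs()]).
#' @param skip_sweep Optional list `list(D_ms =, N =)` to bypass the sweep.
#' @return List: `processed`, `folds`, `sweep`, `optimal`, `models`,
#'   `report`, `settings`.
#' @export
run_pipeline <- function(seed = 42,
                         session = NULL,
                         n_trials_per_condition = 11,
                         emg_coupling = 0.6,
                         tau_ms = 58,
                         D_ms_grid = c(8, 33, 83),
                         N_grid = c(2, 6, 12),
                         n_folds = 3,
                         sweep_restarts = 2,
                         final_restarts = 3,
                         sweep_max_epochs = 40,
                         final_max_epochs = 120,
                         specs = default_critical_specs(),
                         skip_sweep = NULL) {
  if (is.null(session)) {
    session <- generate_session(
      variability = variability_model(seed = seed, emg_coupling = emg_coupling),
      n_trials_per_condition = n_trials_per_condition,
      include_raw = FALSE
    )
  }
  processed <- preprocess_session(session)
  folds <- make_folds(processed, n_folds = n_folds, seed = seed)

  sweep <- NULL
  if (is.null(skip_sweep)) {
    grid <- sweep_grid(tau_ms = tau_ms, D_ms = D_ms_grid, N = N_grid)
    tc_sweep <- training_config(error_goal = "moment1pct",
                                max_epochs = sweep_max_epochs,
                                restarts = sweep_restarts)
    sweep <- run_sweep(folds, grid, tc_sweep, seed = derive_seed(seed, 11))
    optimal <- select_optimal(sweep, fixed_tau_ms = tau_ms)
  } else {
    optimal <- list(D_ms = skip_sweep$D_ms, N = skip_sweep$N, test_mse = NA_real_)
  }

  tc_final <- training_config(error_goal = 0, max_epochs = final_max_epochs,
                              restarts = final_restarts)
  models <- finalize_model(folds, tau_ms = tau_ms, D_ms = optimal$D_ms,
                           N = optimal$N, tconfig = tc_final,
                           seed = derive_seed(seed, 13))
  report <- build_report(folds, models, specs = specs)

  list(processed = processed, folds = folds, sweep = sweep, optimal = optimal,
       models = models, report = report,
       settings = list(seed = seed, tau_ms = tau_ms, n_folds = n_folds,
                       emg_coupling = emg_coupling,
                       D_ms = optimal$D_ms, N = optimal$N))
}
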