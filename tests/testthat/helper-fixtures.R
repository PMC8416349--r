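# Shared fixtures: tiny teacher-network datasets, hand-built processed
# trials, and an identity normalizer (channels already in [-1, 1]).

identity_normalizer <- function() {
  structure(
    list(lo = c(emg_ta = -1, emg_gm = -1, angle = -1, moment = -1),
         hi = c(emg_ta = 1, emg_gm = 1, angle = 1, moment = 1)),
    class = "normalization_map"
  )
}

make_processed_trial <- function(x, y, condition = "LW", trial_id = "fix",
                                 events = NULL) {
  n <- nrow(x)
  structure(
    list(x = as.matrix(x), y = as.matrix(y), dt = 1 / 120,
         events = events %||% list(HS = c(28L, n)),
         condition = condition, trial_id = trial_id,
         percent_trial = seq(0, 100, length.out = n)),
    class = "processed_trial"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smooth seeded exogenous input in [-1, 1]
smooth_exo <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 2, -1, 1), n, 2)
  xs <- apply(x, 2, function(col) stats::filter(col, rep(1 / 5, 5), sides = 1))
  xs[is.na(xs)] <- 0
  xs
}

# trials generated by a known teacher network (normalized space), with a
# little additive observation noise
teacher_trials <- function(teacher_w, teacher_cfg, n_trials, n_len = 250,
                           noise_sd = 0.001, seed = 100,
                           conditions = c("LW", "AS", "DS")) {
  lapply(seq_len(n_trials), function(i) {
    xs <- smooth_exo(n_len, seed + i)
    y <- teacher_generate(teacher_w, teacher_cfg, xs,
                          matrix(0, teacher_cfg$d + teacher_cfg$m, 2))
    set.seed(seed + 1000 + i)
    y <- y + noise_sd * matrix(rnorm(2 * n_len), n_len, 2)
    make_processed_trial(xs, y,
                         condition = conditions[(i - 1) %% length(conditions) + 1],
                         trial_id = paste0("T", i))
  })
}

teacher_fold <- function(n_train = 8, n_val = 2, n_test = 2, ...) {
  trs <- teacher_trials(..., n_trials = n_train + n_val + n_test)
  structure(
    list(fold_index = 1L,
         train = trs[seq_len(n_train)],
         val = trs[n_train + seq_len(n_val)],
         test = trs[n_train + n_val + seq_len(n_test)]),
    class = "fold_partition"
  )
}

quiet_variability <- function(seed = 1, emg_coupling = 0) {
  variability_model(amplitude_jitter_sd = 0, time_warp_sd = 0,
                    activation_jitter_sd = 0,
                    additive_noise_sd = c(emg = 0, angle = 0, moment = 0),
                    emg_coupling = emg_coupling, seed = seed)
}
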