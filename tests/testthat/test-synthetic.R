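# Synthetic gait generator: determinism, template fidelity, variability,
# event ordering, EMG informativeness, teacher generation.

test_that("noise-free generation reproduces the template exactly", {
  for (cond in c("LW", "AS", "DS")) {
    tpl <- gait_template(cond)
    tr <- generate_trial(tpl, quiet_variability(emg_coupling = 0.8), 3,
                         include_raw = FALSE)
    ref <- evaluate_template(tpl)
    expect_identical(max(abs(tr$angle - ref$angle)), 0, info = cond)
    expect_identical(max(abs(tr$moment - ref$moment)), 0, info = cond)
    expect_identical(max(abs(tr$emg_envelope[, 1] - ref$emg_ta)), 0, info = cond)
    expect_identical(max(abs(tr$emg_envelope[, 2] - ref$emg_gm)), 0, info = cond)
  }
})

test_that("template invariants: non-negative envelopes, DS widest angle range", {
  ranges <- sapply(c("LW", "AS", "DS"), function(cond) {
    ref <- evaluate_template(gait_template(cond))
    expect_true(all(ref$emg_ta >= 0) && all(ref$emg_gm >= 0), info = cond)
    diff(range(ref$angle))
  })
  expect_gt(ranges["DS"], ranges["LW"])
  expect_gt(ranges["DS"], ranges["AS"])
})

test_that("same seed and index give bitwise-identical trials; streams differ", {
  tpl <- gait_template("AS")
  v <- variability_model(seed = 9)
  a <- generate_trial(tpl, v, 4)
  b <- generate_trial(tpl, v, 4)
  expect_identical(a, b)
  c1 <- generate_trial(tpl, v, 5, include_raw = FALSE)
  expect_false(identical(a$angle, c1$angle))
  d1 <- generate_trial(tpl, variability_model(seed = 10), 4, include_raw = FALSE)
  expect_false(identical(a$angle, d1$angle))
})

test_that("events are strictly increasing and HS < TO within every cycle", {
  v <- variability_model(seed = 3)
  for (cond in c("LW", "AS", "DS")) {
    for (i in 0:4) {
      tr <- generate_trial(gait_template(cond), v, i, include_raw = FALSE)
      all_ev <- sort(unlist(tr$events))
      expect_true(all(diff(all_ev) > 0), info = paste(cond, i))
      n_cyc <- length(tr$events$HS) - 1
      expect_true(all(tr$events$HS[seq_len(n_cyc)] < tr$events$TO),
                  info = paste(cond, i))
      expect_lte(max(all_ev), (length(tr$angle) - 1) / 120)
    }
  }
})

test_that("Monte-Carlo: trial spread positive, mean near template", {
  tpl <- gait_template("AS")
  v <- variability_model(seed = 21)
  trials <- lapply(0:9, function(i) generate_trial(tpl, v, i, include_raw = FALSE))
  A <- sapply(trials, function(tr) tr$angle)
  per_sample_sd <- apply(A, 1, sd)
  expect_true(all(per_sample_sd[30:400] > 0))
  ref <- evaluate_template(tpl)$angle
  dev <- abs(rowMeans(A) - ref)
  expect_true(mean(dev <= 2 * per_sample_sd + 0.5) > 0.95)
})

test_that("session counting and the 8/2/1 precondition", {
  s <- generate_session(variability = variability_model(seed = 5),
                        n_trials_per_condition = 11)
  expect_length(s$trials, 33)
  conds <- table(vapply(s$trials, function(tr) tr$condition, ""))
  expect_true(all(conds == 11))
  expect_error(generate_session(n_trials_per_condition = 10), "8 train")
  s15 <- generate_session(variability = variability_model(seed = 5),
                          n_trials_per_condition = 15)
  expect_length(s15$trials, 45)
  expect_true(all(table(vapply(s15$trials, function(tr) tr$condition, "")) == 15))
})

test_that("EMG coupling makes lagged envelopes informative about mechanics", {
  # isolate the coupling mechanism: only activation jitter varies across
  # trials, so across-trial residuals of the moment are purely EMG-driven
  corr_at <- function(coupling) {
    # tiny additive moment noise keeps the zero-coupling correlation defined
    v <- variability_model(amplitude_jitter_sd = 0, time_warp_sd = 0,
                           additive_noise_sd = c(emg = 0, angle = 0,
                                                 moment = 0.003),
                           emg_coupling = coupling, seed = 77)
    trials <- lapply(0:9, function(i)
      truncate_trial(generate_trial(gait_template("LW"), v, i, include_raw = FALSE)))
    GM <- sapply(trials, function(tr) tr$x[, 2])
    MO <- sapply(trials, function(tr) tr$y[, 2])
    lag <- 12 # the generator's EMG-to-mechanics lead (~100 ms)
    GMr <- GM - rowMeans(GM); MOr <- MO - rowMeans(MO)
    n <- nrow(GM)
    cor(as.numeric(GMr[1:(n - lag), ]), as.numeric(MOr[(lag + 1):n, ]))
  }
  expect_gt(corr_at(0.6), 0.3)
  expect_gt(corr_at(0.6), abs(corr_at(0)) + 0.2)
  # and on a full-variability 10-trial session: lagged plantarflexor
  # envelope vs moment, pooled over trials
  v <- variability_model(seed = 78, emg_coupling = 0.6)
  trials <- lapply(0:9, function(i)
    truncate_trial(generate_trial(gait_template("LW"), v, i, include_raw = FALSE)))
  gm <- unlist(lapply(trials, function(tr) tr$x[1:(nrow(tr$x) - 12), 2]))
  mo <- unlist(lapply(trials, function(tr) tr$y[13:nrow(tr$y), 2]))
  expect_gt(cor(gm, mo), 0.3)
})

test_that("raw EMG carrier supports the envelope chain end to end", {
  tr <- generate_trial(gait_template("LW"), variability_model(seed = 2), 0,
                       include_raw = TRUE)
  env <- emg_linear_envelope(tr$emg_raw[, 1])
  n <- min(length(env), length(tr$emg_envelope[, 1]))
  expect_gt(cor(env[1:n], tr$emg_envelope[1:n, 1]), 0.9)
})

test_that("teacher_generate: constant network, oracle equivalence, errors", {
  cfg <- narx_config(m = 1, d = 1, N = 2)
  w0 <- zero_weights(cfg)
  w0$b2 <- c(0.3, -0.1)
  x <- smooth_exo(50, 1)
  y <- teacher_generate(w0, cfg, x, matrix(0, 2, 2))
  expect_true(all(y[3:50, 1] == 0.3) && all(y[3:50, 2] == -0.1))

  # brute-force nested-loop oracle
  cfg2 <- narx_config(m = 1, d = 1, N = 2)
  w <- init_weights(cfg2, 5)
  y2 <- teacher_generate(w, cfg2, x, matrix(0.05, 2, 2))
  yo <- matrix(0.05, 50, 2)
  for (s in 3:50) {
    t <- s - 1
    v <- numeric(2)
    for (n in 1:2) {
      acc <- w$b1[n]
      for (q in 0:1) for (i in 1:2) acc <- acc + w$a[n, i, q + 1] * x[t - q, i]
      for (q in 1:1) for (j in 1:2) acc <- acc - w$c[n, j, q] * yo[t - q, j]
      v[n] <- tanh(acc)
    }
    yo[s, ] <- as.numeric(w$w %*% v) + w$b2
  }
  expect_lt(max(abs(y2 - yo)), 1e-12)

  expect_error(teacher_generate(w, cfg2, x, matrix(0, 1, 2)), "d \\+ m")
  wbad <- init_weights(narx_config(m = 1, d = 3, N = 2), 1)
  expect_error(teacher_generate(wbad, cfg2, x, matrix(0, 2, 2)), "shape|consistent")
})
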