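# Metrics and statistics: oracles and closed forms.

test_that("rmse closed forms and random oracle", {
  x <- rnorm(50)
  expect_identical(rmse(x, x), 0)
  expect_equal(rmse(x + 2.5, x), 2.5)
  set.seed(3)
  for (k in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_lt(abs(rmse(a, b) - sqrt(sum((a - b)^2) / 30)), 1e-12)
  }
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("xcorr_r2: identity, shifts, affine invariance, errors", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(300), rep(1 / 10, 10), sides = 1))
  x[is.na(x)] <- 0
  id <- xcorr_r2(x, x)
  expect_equal(id$r2, 1)
  expect_equal(id$lag, 0L)
  for (k in c(-7L, 3L, 12L)) {
    shifted <- if (k > 0) c(rep(0, k), x[1:(300 - k)]) else
      c(x[(1 - k):300], rep(0, -k))
    expect_equal(xcorr_r2(shifted, x, max_lag = 20)$lag, k)
  }
  aff <- xcorr_r2(3 * x + 2, x)
  expect_equal(aff$r2, 1)
  expect_equal(aff$lag, 0L)
  expect_error(xcorr_r2(rep(1, 100), x[1:100]), "constant")
  expect_error(xcorr_r2(x, x, max_lag = 200), "length/2")
})

test_that("instantaneous_rmse matches a brute-force loop", {
  perfect <- lapply(1:3, function(i) rep(0.0, 40))
  targ <- lapply(1:3, function(i) rnorm(40))
  pred <- lapply(1:3, function(i) targ[[i]])
  out <- instantaneous_rmse(pred, targ)
  expect_true(all(out$mean == 0))
  # constant per-trial error e gives a flat |e| curve
  prede <- lapply(1:3, function(i) targ[[i]] + 0.7)
  oute <- instantaneous_rmse(prede, targ)
  expect_equal(oute$mean, rep(0.7, 40))
  # random oracle
  set.seed(12)
  p <- lapply(1:5, function(i) rnorm(25)); t <- lapply(1:5, function(i) rnorm(25))
  got <- instantaneous_rmse(p, t)
  for (idx in 1:25) {
    es <- vapply(1:5, function(i) p[[i]][idx] - t[[i]][idx], 0)
    expect_lt(abs(got$mean[idx] - sqrt(mean(es^2))), 1e-12)
    expect_lt(abs(got$sd[idx] - sd(es^2) / (2 * sqrt(mean(es^2)))), 1e-12)
  }
  expect_error(instantaneous_rmse(p[1], t[1]), ">= 2")
  expect_error(instantaneous_rmse(p, lapply(t, function(v) v[1:10])), "common length")
})

test_that("constant_emg_inputs: mean preserved, variance removed, idempotent", {
  tr <- truncate_trial(generate_trial(gait_template("AS"),
                                      variability_model(seed = 4), 1,
                                      include_raw = FALSE))
  ce <- constant_emg_inputs(tr)
  expect_lt(abs(mean(ce$x[, 1]) - mean(tr$x[, 1])), 1e-12)
  expect_identical(sd(ce$x[, 1]), 0)
  expect_identical(sd(ce$x[, 2]), 0)
  expect_identical(ce$y, tr$y)
  expect_identical(constant_emg_inputs(ce)$x, ce$x)
})

test_that("critical-point extraction finds injected extrema", {
  n <- 200
  set.seed(55)
  x <- cbind(runif(n, 0, 0.3), runif(n, 0, 0.3))
  angle <- sin(seq(0, 2 * pi, length.out = n)) * 10
  angle[120] <- -25       # injected plantarflexion extremum
  angle[60] <- 18         # injected dorsiflexion extremum
  moment <- cos(seq(0, 2 * pi, length.out = n))
  moment[90] <- 2.2       # injected plantarflexion moment peak
  tr <- make_processed_trial(x, cbind(angle, moment),
                             events = list(HS = c(28L, n), TO = 150L))
  cfg <- narx_config(m = 1, d = 1, N = 2)
  w <- zero_weights(cfg)
  nm <- fit_normalizer(list(tr))
  trace <- predict_trial(w, cfg, nm, tr)
  specs <- list(
    critical_point_spec("stance_event", "max_dorsiflexion", "angle"),
    critical_point_spec("stance_event", "max_plantarflexion", "angle"),
    critical_point_spec("stance_event", "max_pf_moment", "moment"),
    critical_point_spec("stance_event", "TO", "angle"),
    critical_point_spec("clearance_interval", c(0.4, 0.5), "angle")
  )
  got <- extract_critical_points(trace, tr, specs)
  expect_equal(got[[1]]$index, 60L)
  expect_equal(got[[2]]$index, 120L)
  expect_equal(got[[3]]$index, 90L)
  expect_equal(got[[4]]$index, 150L)
  expect_equal(got[[5]]$index, (1 + floor(0.4 * (n - 1))):(1 + ceiling(0.5 * (n - 1))))
  expect_equal(got[[2]]$target, -25)
  # perfect predictions pair to zero differences
  tr_perf <- tr
  trace_perf <- trace
  trace_perf$y_hat <- trace$target
  g2 <- extract_critical_points(trace_perf, tr_perf, specs[1:3])
  expect_true(all(vapply(g2, function(df) all(df$pred == df$target), TRUE)))
})

test_that("critical_point_test gates on Shapiro-Wilk and handles degeneracy", {
  set.seed(101)
  d <- rnorm(30)
  # pred - target = d, a normal draw; gate decision recorded for this seed
  res <- critical_point_test(d, rep(0, 30))
  expect_identical(res$test, "paired_t")
  expect_gt(res$shapiro_p, 0.05)
  ref <- t.test(d)
  expect_equal(res$p, ref$p.value)
  # all +1 differences: zero variance, sign test, p = 2 * 0.5^n
  res2 <- critical_point_test(rep(1, 10), rep(0, 10))
  expect_identical(res2$test, "sign")
  expect_equal(res2$p, 2 * 0.5^10)
  # identical samples
  res3 <- critical_point_test(d, d)
  expect_identical(res3$test, "identical")
  expect_equal(res3$p, 1)
  # clearly non-normal differences select the sign test
  set.seed(102)
  skew <- rexp(40)^3
  res4 <- critical_point_test(skew, rep(0, 40))
  expect_identical(res4$test, "sign")
  bt <- binom.test(sum(skew > 0), 40, 0.5)
  expect_equal(res4$p, bt$p.value)
  expect_error(critical_point_test(1:2, 2:3), ">= 3")
})

test_that("benjamini_hochberg: worked examples, p.adjust oracle, dominance", {
  one <- benjamini_hochberg(0.01, q = 0.05)
  expect_equal(one$adjusted, 0.01)
  expect_true(one$reject)
  four <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(four$reject))
  none <- benjamini_hochberg(rep(1, 5))
  expect_true(all(none$adjusted == 1) && !any(none$reject))
  set.seed(20)
  for (k in 1:25) {
    p <- runif(sample(1:40, 1))
    got <- benjamini_hochberg(p)
    expect_lt(max(abs(got$adjusted - p.adjust(p, "BH"))), 1e-12)
    expect_true(all(got$adjusted >= p - 1e-15))
  }
  # step-up direct evaluation oracle
  p <- c(0.003, 0.04, 0.02, 0.9)
  got <- benjamini_hochberg(p, q = 0.05)
  ord <- order(p); m <- 4
  reject_direct <- logical(4)
  kmax <- max(c(0, which(p[ord] <= seq_len(m) / m * 0.05)))
  if (kmax > 0) reject_direct[ord[seq_len(kmax)]] <- TRUE
  expect_identical(got$reject, reject_direct)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("build_report aggregates trial metrics correctly", {
  # two-trial closed form: RMSE 1 and 3 give mean 2, sample SD sqrt(2)
  cfgT <- narx_config(m = 1, d = 2, N = 3)
  wT <- init_weights(cfgT, 30)
  trials <- teacher_trials(wT, cfgT, n_trials = 12, seed = 700, noise_sd = 0.02,
                           conditions = "LW")
  fold <- structure(list(fold_index = 1L, train = trials[1:8],
                         val = trials[9:10], test = trials[11:12]),
                    class = "fold_partition")
  tc <- training_config(error_goal = 0, max_epochs = 10, restarts = 1)
  model <- train_network(fold, cfgT, tc, restart_seed = 1)
  rep1 <- build_report(list(fold), list(model))
  expect_equal(nrow(rep1$metrics), 4) # 2 trials x 2 outputs
  s <- rep1$summary
  g <- rep1$metrics[rep1$metrics$output == "angle", ]
  expect_equal(s$rmse_mean[s$output == "angle"], mean(g$rmse))
  expect_equal(s$rmse_sd[s$output == "angle"], sd(g$rmse))
  expect_true(all(rep1$metrics$r2 >= 0 & rep1$metrics$r2 <= 1))
  expect_error(build_report(list(fold), list()), "one model per fold")
})
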