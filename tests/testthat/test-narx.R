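# NARX core: forward-pass oracle, open-loop contract, normalization,
# initialization, step conversion, serialization.

brute_forward <- function(w, cfg, xw, yw) {
  N <- cfg$N; d <- cfg$d
  v <- numeric(N)
  for (n in seq_len(N)) {
    acc <- w$b1[n]
    for (q in 0:d) for (i in 1:2) acc <- acc + w$a[n, i, q + 1] * xw[q + 1, i]
    for (q in 1:d) for (j in 1:2) acc <- acc - w$c[n, j, q] * yw[q, j]
    v[n] <- tanh(acc)
  }
  list(v = v, y_hat = as.numeric(w$w %*% v) + w$b2)
}

test_that("vectorized forward pass matches the nested-loop oracle (100 cases)", {
  set.seed(42)
  worst <- 0
  for (k in 1:100) {
    cfg <- narx_config(m = sample(1:5, 1), d = sample(1:6, 1), N = sample(1:8, 1))
    w <- init_weights(cfg, k)
    xw <- matrix(rnorm((cfg$d + 1) * 2), cfg$d + 1, 2)
    yw <- matrix(rnorm(cfg$d * 2), cfg$d, 2)
    got <- forward_step(w, cfg, xw, yw)
    ref <- brute_forward(w, cfg, xw, yw)
    worst <- max(worst, abs(got$v - ref$v), abs(got$y_hat - ref$y_hat))
  }
  expect_lt(worst, 1e-12)
})

test_that("zero weights and bias passthrough", {
  cfg <- narx_config(m = 2, d = 3, N = 4)
  w <- zero_weights(cfg)
  out <- forward_step(w, cfg, matrix(1, 4, 2), matrix(1, 3, 2))
  expect_identical(out$v, numeric(4))
  expect_identical(out$y_hat, c(0, 0))
  w$b2 <- c(0.5, -0.5)
  expect_identical(forward_step(w, cfg, matrix(9, 4, 2), matrix(-3, 3, 2))$y_hat,
                   c(0.5, -0.5))
  expect_error(forward_step(w, cfg, matrix(1, 3, 2), matrix(1, 3, 2)), "shape")
})

test_that("the printed minus sign on the feedback term is real", {
  # negating the c weights must change outputs (sign not silently absorbed),
  # and manually flipping the c-term sign in the oracle must recover them
  cfg <- narx_config(m = 1, d = 2, N = 3)
  w <- init_weights(cfg, 8)
  xw <- matrix(rnorm(6), 3, 2); yw <- matrix(rnorm(4), 2, 2)
  ref <- forward_step(w, cfg, xw, yw)
  wneg <- w; wneg$c <- -w$c
  got <- forward_step(wneg, cfg, xw, yw)
  expect_false(isTRUE(all.equal(ref$y_hat, got$y_hat)))
  # oracle with +c term on negated weights == original
  plus_c <- function(w, xw, yw) {
    v <- sapply(1:3, function(n) tanh(w$b1[n] +
      sum(w$a[n, , ] * t(xw)) + sum(w$c[n, , ] * t(yw))))
    as.numeric(w$w %*% v) + w$b2
  }
  expect_equal(plus_c(wneg, xw, yw), ref$y_hat, tolerance = 1e-12)
})

test_that("open-loop predictions use measured targets and leak no future", {
  cfg <- narx_config(m = 3, d = 4, N = 5)
  w <- init_weights(cfg, 2)
  set.seed(31)
  x <- smooth_exo(120, 3)
  y <- matrix(rnorm(240, sd = 0.3), 120, 2)
  trial <- make_processed_trial(x, y)
  nm <- identity_normalizer()
  pr <- predict_trial(w, cfg, nm, trial)
  # prediction count: t in (d+1)..(T-m)
  expect_equal(nrow(pr$y_hat), 120 - cfg$d - cfg$m)
  expect_equal(pr$t_pred, (cfg$d + 1 + cfg$m):120)
  # row k depends only on y up to t_pred[k] - m - 1; perturbing later targets
  # leaves earlier predictions unchanged
  k <- 40
  y2 <- y
  cut <- pr$t_pred[k] - cfg$m  # inputs used are y[t-1 .. t-d], t = cut
  y2[cut:120, ] <- 9
  pr2 <- predict_trial(w, cfg, nm, make_processed_trial(x, y2))
  expect_identical(pr2$y_hat[seq_len(k), ], pr$y_hat[seq_len(k), ])
  expect_false(isTRUE(all.equal(pr2$y_hat[k + cfg$m + 1, ], pr$y_hat[k + cfg$m + 1, ])))
  # minimal-length trial gives exactly one prediction
  n_min <- cfg$d + cfg$m + 1
  pr3 <- predict_trial(w, cfg, nm, make_processed_trial(x[1:n_min, ], y[1:n_min, ]))
  expect_equal(nrow(pr3$y_hat), 1)
  expect_error(predict_trial(w, cfg, nm,
                             make_processed_trial(x[1:(n_min - 1), ], y[1:(n_min - 1), ])),
               "short")
})

test_that("steps_from_ms reproduces the printed 58 ms = 7 steps pair", {
  expect_identical(steps_from_ms(58), 7L)
  expect_identical(steps_from_ms(8), 1L)
  expect_identical(steps_from_ms(142), 17L)
  expect_identical(steps_from_ms(c(33, 83)), c(4L, 10L))
  expect_error(steps_from_ms(0), "positive")
})

test_that("normalizer: endpoints, pooling, round trip", {
  x <- cbind(runif(100, 0, 0.4), runif(100, 0, 0.5))
  tr1 <- make_processed_trial(x, cbind(runif(100, -10, 20), runif(100, 0, 1)))
  nm <- fit_normalizer(list(tr1))
  expect_equal(unname(nm$lo["angle"]), min(tr1$y[, 1]))
  z <- narxgait:::norm_apply(nm, matrix(c(min(tr1$y[, 1]), max(tr1$y[, 1]), 0, 0),
                                        2, 2), c("angle", "moment"))
  expect_equal(z[, 1], c(-1, 1))
  # union over trials
  tr2 <- make_processed_trial(x, cbind(runif(100, 30, 40), runif(100, 2, 3)))
  nm2 <- fit_normalizer(list(tr1, tr2))
  expect_equal(unname(nm2$hi["angle"]), max(tr2$y[, 1]))
  expect_equal(unname(nm2$lo["angle"]), min(tr1$y[, 1]))
  # round trip
  set.seed(4)
  vals <- matrix(rnorm(2000, 5, 30), ncol = 2)
  rt <- narxgait:::norm_invert(nm2, narxgait:::norm_apply(nm2, vals, c("angle", "moment")),
                               c("angle", "moment"))
  expect_lt(max(abs(rt - vals)), 1e-12)
  # degenerate channel
  tr3 <- make_processed_trial(x, cbind(rep(1, 100), runif(100)))
  expect_error(fit_normalizer(list(tr3)), "constant|degenerate")
})

test_that("initialization is seeded, distinct, and keeps tanh active", {
  cfg <- narx_config(m = 7, d = 10, N = 6)
  expect_identical(init_weights(cfg, 3), init_weights(cfg, 3))
  ws <- lapply(0:9, function(s) init_weights(cfg, s))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_false(identical(ws[[i]], ws[[j]]))
  }
  # pre-activations on a realistic normalized trial stay mostly in |z| < 3
  tr <- truncate_trial(generate_trial(gait_template("LW"),
                                      variability_model(seed = 6), 0,
                                      include_raw = FALSE))
  nm <- fit_normalizer(list(tr))
  nt <- normalize_trial(nm, tr)
  des <- narxgait:::narx_design(nt$x, nt$y, cfg)
  pre <- des$Z %*% narxgait:::theta_matrix(ws[[1]], cfg$d)
  expect_gt(mean(abs(pre) < 3), 0.95)
})

test_that("model JSON round trip is bit-exact", {
  cfg <- narx_config(m = 7, d = 10, N = 6)
  w <- init_weights(cfg, 12)
  tr <- truncate_trial(generate_trial(gait_template("AS"),
                                      variability_model(seed = 6), 0,
                                      include_raw = FALSE))
  nm <- fit_normalizer(list(tr))
  path <- tempfile(fileext = ".json")
  write_model(w, cfg, nm, path)
  back <- read_model(path)
  expect_identical(back$weights$a, w$a)
  expect_identical(back$weights$c, w$c)
  expect_identical(unname(back$weights$w), unname(w$w))
  expect_identical(back$weights$b1, w$b1)
  expect_identical(back$weights$b2, w$b2)
  expect_identical(back$normalizer$lo, nm$lo)
  expect_identical(back$config$m, cfg$m)
  pr1 <- predict_trial(w, cfg, nm, tr)
  pr2 <- predict_trial(back$weights, back$config, back$normalizer, tr)
  expect_identical(pr1$y_hat, pr2$y_hat)
})

test_that("normalization equivariance: constant midpoint predictor MSE equals
           normalized variance", {
  tr <- truncate_trial(generate_trial(gait_template("LW"),
                                      variability_model(seed = 14), 1,
                                      include_raw = FALSE))
  nm <- fit_normalizer(list(tr))
  mid <- cbind(rep(mean(c(nm$lo["angle"], nm$hi["angle"])), nrow(tr$y)),
               rep(mean(c(nm$lo["moment"], nm$hi["moment"])), nrow(tr$y)))
  got <- normalized_mse(mid, tr$y, nm)
  yn <- narxgait:::norm_apply(nm, tr$y, c("angle", "moment"))
  expect_equal(got, mean(c(mean(yn[, 1]^2), mean(yn[, 2]^2))), tolerance = 1e-12)
})
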