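# Levenberg-Marquardt training with validation-based early stopping,
# error-goal stopping, multi-restart selection, and the trial-blocked
# leave-one-out k-fold protocol.
#
# Trials are "a concurrent set of sequences": delay-line windows never cross
# trial boundaries, so per-trial design matrices are built independently and
# stacked. The loss is the MSE of the [-1, 1]-normalized residuals over both
# output channels jointly (errors effectively range over [-2, 2]), which
# weights ankle angle and ankle moment equally.

#' Training configuration
#'
#' @param error_goal Normalized-MSE stopping threshold: a number, or the
#'   string `"moment1pct"` for 1 percent of the pooled normalized moment
#'   variance of the fold's recorded (train + validation) trials.
#' @param max_epochs Maximum LM epochs.
#' @param restarts Number of random restarts for [train_with_restarts()].
#' @param val_patience Epochs of non-improving validation MSE tolerated
#'   before stopping.
#' @param lm_lambda_init,lm_lambda_up,lm_lambda_down Marquardt damping
#'   schedule: initial lambda, multiplier on a rejected step, divisor on an
#'   accepted step.
#' @param seed Base seed for restart initialization.
#' @export
training_config <- function(error_goal = 0, max_epochs = 1000, restarts = 10,
                            val_patience = 6, lm_lambda_init = 1e-3,
                            lm_lambda_up = 10, lm_lambda_down = 10, seed = 0) {
  stopifnot(max_epochs >= 1, restarts >= 1, val_patience >= 1,
            lm_lambda_init > 0, lm_lambda_up > 1, lm_lambda_down > 1)
  if (is.character(error_goal) && !identical(error_goal, "moment1pct")) {
    stop("error_goal must be numeric or \"moment1pct\"")
  }
  structure(
    list(error_goal = error_goal, max_epochs = as.integer(max_epochs),
         restarts = as.integer(restarts), val_patience = as.integer(val_patience),
         lm_lambda_init = lm_lambda_init, lm_lambda_up = lm_lambda_up,
         lm_lambda_down = lm_lambda_down, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Trial-blocked leave-one-out k-fold partitions
#'
#' Splits whole trials (never samples) per condition: each fold holds out one
#' designated novel test trial per condition; the remaining trials are
#' shuffled once per fold (seeded) and divided into contiguous blocks of 8
#' training and 2 validation trials.
#'
#' @param trials List of `processed_trial` (all conditions pooled).
#' @param n_folds Number of folds (default 10); needs at least `n_folds + 1`
#'   and at least 11 trials per condition.
#' @param seed Integer seed.
#' @return List of `fold_partition`: each has `fold_index` and lists
#'   `train`, `val`, `test` of processed trials.
#' @export
make_folds <- function(trials, n_folds = 10, seed = 0) {
  conds <- vapply(trials, function(tr) tr$condition, "")
  by_cond <- split(seq_along(trials), conds)
  n_per <- vapply(by_cond, length, 0L)
  if (any(n_per < 11) || any(n_per < n_folds + 1)) {
    stop("need >= max(11, n_folds + 1) trials per condition for the ",
         "8 train / 2 validation / 1 test trial-blocked split; have: ",
         paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  }
  designated <- lapply(names(by_cond), function(cn) {
    with_seed(derive_seed(seed, 101, match(cn, CONDITIONS)),
              sample(by_cond[[cn]], n_folds))
  })
  names(designated) <- names(by_cond)
  lapply(seq_len(n_folds), function(f) {
    tr_idx <- c(); va_idx <- c(); te_idx <- c()
    for (cn in names(by_cond)) {
      test_i <- designated[[cn]][f]
      rest <- setdiff(by_cond[[cn]], test_i)
      rest <- with_seed(derive_seed(seed, 202, match(cn, CONDITIONS), f),
                        sample(rest, 10))
      tr_idx <- c(tr_idx, rest[1:8])
      va_idx <- c(va_idx, rest[9:10])
      te_idx <- c(te_idx, test_i)
    }
    structure(
      list(fold_index = f,
           train = trials[tr_idx], val = trials[va_idx], test = trials[te_idx],
           train_ids = tr_idx, val_ids = va_idx, test_ids = te_idx),
      class = "fold_partition"
    )
  })
}

#' Normalized mean squared error
#'
#' MSE of predictions against targets after mapping both onto \[-1, 1\] with
#' the given normalization map, averaged over both output channels and all
#' time steps; the training criterion.
#'
#' @param predictions,targets Aligned n x 2 matrices (angle, moment) in
#'   physical units.
#' @param normalizer A `normalization_map`.
#' @export
normalized_mse <- function(predictions, targets, normalizer) {
  p <- as.matrix(predictions); t <- as.matrix(targets)
  if (!all(dim(p) == dim(t)) || nrow(p) < 1) {
    stop("predictions and targets must be non-empty and aligned")
  }
  pn <- norm_apply(normalizer, p, c("angle", "moment"))
  tn <- norm_apply(normalizer, t, c("angle", "moment"))
  mean((pn - tn)^2)
}

#' One-percent-of-moment-variance error goal
#'
#' 0.01 times the pooled variance of the normalized moment channel over all
#' supplied trials (two-pass sample variance).
#'
#' @param trials List of `processed_trial`.
#' @param normalizer A `normalization_map`.
#' @export
moment_variance_error_goal <- function(trials, normalizer) {
  if (length(trials) < 1) stop("need at least one trial")
  mom <- unlist(lapply(trials, function(tr)
    norm_apply(normalizer, tr$y, c("angle", "moment"))[, 2]))
  0.01 * stats::var(mom)
}

# stack per-trial designs (windows never cross trial boundaries)
stack_designs <- function(trials, normalizer, config) {
  parts <- lapply(trials, function(tr) {
    nt <- normalize_trial(normalizer, tr)
    narx_design(nt$x, nt$y, config)
  })
  list(Z = do.call(rbind, lapply(parts, `[[`, "Z")),
       target = do.call(rbind, lapply(parts, `[[`, "target")))
}

# residuals stacked [output1; output2], plus hidden activations
lm_residual <- function(vec, config, Z, target) {
  w <- weights_from_vec(vec, config)
  fw <- forward_full(w, config, Z)
  list(r = c(fw$Yhat[, 1] - target[, 1], fw$Yhat[, 2] - target[, 2]),
       V = fw$V, w = w)
}

# analytic Jacobian of the stacked residuals wrt the packed parameter vector
lm_jacobian <- function(vec, config, Z, V) {
  w <- weights_from_vec(vec, config)
  R <- nrow(Z); N <- config$N; ph <- n_hidden_params(config$d)
  P <- ph * N + 2 * N + 2
  J <- matrix(0, 2 * R, P)
  G <- 1 - V^2
  for (n in seq_len(N)) {
    cols <- (n - 1) * ph + seq_len(ph)
    block <- Z * G[, n]
    J[1:R, cols] <- w$w[1, n] * block
    J[R + (1:R), cols] <- w$w[2, n] * block
  }
  J[1:R, ph * N + seq_len(N)] <- V
  J[R + (1:R), ph * N + N + seq_len(N)] <- V
  J[1:R, P - 1] <- 1
  J[R + (1:R), P] <- 1
  J
}

#' Train one NARX network with Levenberg-Marquardt
#'
#' Full-batch LM on the normalized MSE over the fold's training trials.
#' The normalizer is fitted on the fold's training trials only; the error
#' goal (when `"moment1pct"`) is computed from the fold's train + validation
#' trials, so the novel test trial never influences training. Stops on the
#' error goal, on `val_patience` epochs without validation improvement, or at
#' `max_epochs`; a stall (no damping value yields a descent step) is reported
#' as `patience`. Returns the weights from the epoch with the best validation
#' MSE.
#'
#' @param fold A `fold_partition`.
#' @param config A [narx_config()].
#' @param tconfig A [training_config()].
#' @param restart_seed Seed for the weight initialization.
#' @return List with `weights`, `normalizer`, `config`, and `history`
#'   (data frame: epoch, train_mse, val_mse, lambda; attribute `stop_reason`).
#' @export
train_network <- function(fold, config, tconfig, restart_seed = 0) {
  normalizer <- fit_normalizer(fold$train)
  goal <- tconfig$error_goal
  if (identical(goal, "moment1pct")) {
    goal <- moment_variance_error_goal(c(fold$train, fold$val), normalizer)
  }
  train <- stack_designs(fold$train, normalizer, config)
  val <- stack_designs(fold$val, normalizer, config)

  vec <- weights_to_vec(init_weights(config, restart_seed), config)
  lambda <- tconfig$lm_lambda_init
  P <- length(vec)

  hist_epoch <- integer(0); hist_train <- numeric(0)
  hist_val <- numeric(0); hist_lambda <- numeric(0)
  best_val <- Inf; best_vec <- vec; stall <- 0L
  stop_reason <- "max_epochs"

  res <- lm_residual(vec, config, train$Z, train$target)
  loss <- mean(res$r^2)

  for (epoch in seq_len(tconfig$max_epochs)) {
    val_fw <- lm_residual(vec, config, val$Z, val$target)
    val_loss <- mean(val_fw$r^2)
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, loss)
    hist_val <- c(hist_val, val_loss)
    hist_lambda <- c(hist_lambda, lambda)
    if (!is.finite(loss)) {
      stop("non-finite training loss at epoch ", epoch)
    }
    if (val_loss < best_val - 1e-15) {
      best_val <- val_loss; best_vec <- vec; stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (loss <= goal) { stop_reason <- "error_goal"; break }
    if (stall >= tconfig$val_patience) { stop_reason <- "patience"; break }
    if (epoch == tconfig$max_epochs) { stop_reason <- "max_epochs"; break }

    J <- lm_jacobian(vec, config, train$Z, res$V)
    g <- crossprod(J, res$r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (try in 1:30) {
      step <- tryCatch(
        solve(JtJ + diag(lambda, P), g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- vec - as.numeric(step)
        cres <- lm_residual(cand, config, train$Z, train$target)
        closs <- mean(cres$r^2)
        if (is.finite(closs) && closs < loss) {
          vec <- cand; res <- cres; loss <- closs
          lambda <- max(lambda / tconfig$lm_lambda_down, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * tconfig$lm_lambda_up
      if (lambda > 1e12) break
    }
    if (!accepted) { stop_reason <- "patience"; break }
  }

  # validation discipline: return weights from the best validation epoch
  history <- data.frame(epoch = hist_epoch, train_mse = hist_train,
                        val_mse = hist_val, lambda = hist_lambda)
  attr(history, "stop_reason") <- stop_reason
  attr(history, "error_goal") <- goal
  list(weights = weights_from_vec(best_vec, config),
       normalizer = normalizer, config = config, history = history)
}

# per-condition normalized MSE of a trained net on a set of trials
condition_mse <- function(model, trials) {
  conds <- vapply(trials, function(tr) tr$condition, "")
  vapply(split(trials, conds), function(trs) {
    se <- 0; n <- 0
    for (tr in trs) {
      pr <- predict_trial(model$weights, model$config, model$normalizer, tr)
      pn <- norm_apply(model$normalizer, pr$y_hat, c("angle", "moment"))
      tn <- norm_apply(model$normalizer, pr$target, c("angle", "moment"))
      se <- se + sum((pn - tn)^2); n <- n + length(pn)
    }
    se / n
  }, 0)
}

#' Multi-restart training with generalized-network selection
#'
#' Trains `tconfig$restarts` networks from different seeded initializations
#' and returns the one with the lowest normalized MSE averaged across
#' ambulation conditions on the fold's train + validation trials (the novel
#' test trial stays untouched until evaluation).
#'
#' @inheritParams train_network
#' @return The selected model (as from [train_network()]) with an extra
#'   element `restart_scores` (selection score per restart).
#' @export
train_with_restarts <- function(fold, config, tconfig) {
  models <- vector("list", tconfig$restarts)
  scores <- rep(NA_real_, tconfig$restarts)
  for (r in seq_len(tconfig$restarts)) {
    m <- tryCatch(
      train_network(fold, config, tconfig,
                    restart_seed = derive_seed(tconfig$seed, r - 1L)),
      error = function(e) e
    )
    if (inherits(m, "error")) next
    models[[r]] <- m
    scores[r] <- mean(condition_mse(m, c(fold$train, fold$val)))
  }
  if (all(is.na(scores))) {
    stop("all ", tconfig$restarts, " restarts failed to train")
  }
  best <- which.min(scores)
  out <- models[[best]]
  out$restart_scores <- scores
  out$selected_restart <- best
  out
}
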