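# Hyperparameter characterization over prediction interval (tau), sampling
# window (D) and hidden-unit count (N); fixed-tau optimal (D, N) selection;
# and zero-error-goal re-training of the optimized network.

#' Hyperparameter grid
#'
#' The full grid is tau {33, 42, 50, 58, 67, 75, 83, 108, 142} ms, D {8, 17,
#' 33, 50, 67, 83} ms, N 2..16 in steps of 2 (432 cells). The reduced grid
#' (tau {33, 58, 142}, D {8, 33, 83}, N {2, 6, 12}; 27 cells) keeps the span
#' of each axis at desk scale.
#'
#' @param preset `"full"` or `"reduced"`, or pass explicit vectors.
#' @param tau_ms,D_ms,N Strictly increasing vectors overriding the preset.
#' @export
sweep_grid <- function(preset = c("full", "reduced"),
                       tau_ms = NULL, D_ms = NULL, N = NULL) {
  preset <- match.arg(preset)
  if (is.null(tau_ms)) tau_ms <- if (preset == "full")
    c(33, 42, 50, 58, 67, 75, 83, 108, 142) else c(33, 58, 142)
  if (is.null(D_ms)) D_ms <- if (preset == "full")
    c(8, 17, 33, 50, 67, 83) else c(8, 33, 83)
  if (is.null(N)) N <- if (preset == "full") seq(2, 16, 2) else c(2, 6, 12)
  for (v in list(tau_ms, D_ms, N)) {
    if (length(v) < 1 || any(diff(v) <= 0)) {
      stop("grid axes must be non-empty and strictly increasing")
    }
  }
  structure(list(tau_ms = tau_ms, D_ms = D_ms, N = as.integer(N)),
            class = "sweep_grid")
}

#' Run the hyperparameter sweep
#'
#' For every grid cell, trains (with restarts) on each fold and evaluates the
#' novel test trials, producing an RMSE tensor indexed
#' \[tau\]\[D\]\[N\]\[condition\]\[output\] (physical units, averaged over
#' folds and test trials) and a test normalized-MSE tensor \[tau\]\[D\]\[N\]
#' (averaged over conditions, outputs and folds) used for optimal-parameter
#' selection. Per-cell training seeds are derived from `seed` and the cell
#' index, so the sweep is deterministic and resumable; a failed cell is
#' recorded as NA, not fatal.
#'
#' @param folds List of `fold_partition` from [make_folds()].
#' @param grid A [sweep_grid()].
#' @param tconfig A [training_config()]; the protocol's characterization
#'   phase uses `error_goal = "moment1pct"`.
#' @param seed Integer seed for per-cell training streams.
#' @return A `sweep_result`: `rmse` (5-d array), `test_mse` (3-d array),
#'   `grid`, `n_folds`, `cell_seeds`.
#' @export
run_sweep <- function(folds, grid, tconfig = training_config(error_goal = "moment1pct"),
                      seed = 0) {
  nt <- length(grid$tau_ms); nd <- length(grid$D_ms); nn <- length(grid$N)
  dn <- list(tau = paste(grid$tau_ms), D = paste(grid$D_ms), N = paste(grid$N),
             condition = CONDITIONS, output = c("angle", "moment"))
  rmse_arr <- array(NA_real_, c(nt, nd, nn, 3, 2), dimnames = dn)
  mse_arr <- array(NA_real_, c(nt, nd, nn), dimnames = dn[1:3])
  cell_seeds <- array(NA_integer_, c(nt, nd, nn), dimnames = dn[1:3])

  for (it in seq_len(nt)) for (id in seq_len(nd)) for (iN in seq_len(nn)) {
    config <- narx_config(m = steps_from_ms(grid$tau_ms[it]),
                          d = steps_from_ms(grid$D_ms[id]),
                          N = grid$N[iN])
    cell_seed <- derive_seed(seed, it, id, iN)
    cell_seeds[it, id, iN] <- cell_seed
    tc <- tconfig
    tc$seed <- cell_seed
    res <- tryCatch(
      sweep_cell(folds, config, tc),
      error = function(e) {
        warning("sweep cell (tau=", grid$tau_ms[it], ", D=", grid$D_ms[id],
                ", N=", grid$N[iN], ") failed: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(res)) {
      rmse_arr[it, id, iN, , ] <- res$rmse
      mse_arr[it, id, iN] <- res$test_mse
    }
  }
  structure(
    list(rmse = rmse_arr, test_mse = mse_arr, grid = grid,
         n_folds = length(folds), cell_seeds = cell_seeds),
    class = "sweep_result"
  )
}

# train + evaluate one grid cell over all folds
sweep_cell <- function(folds, config, tconfig) {
  rmse_acc <- array(0, c(3, 2)); cnt <- array(0, c(3, 2))
  mse_acc <- 0; mse_n <- 0
  for (fold in folds) {
    model <- train_with_restarts(fold, config, tconfig)
    for (tr in fold$test) {
      pr <- predict_trial(model$weights, model$config, model$normalizer, tr)
      ci <- match(tr$condition, CONDITIONS)
      for (ch in 1:2) {
        rmse_acc[ci, ch] <- rmse_acc[ci, ch] + rmse(pr$y_hat[, ch], pr$target[, ch])
        cnt[ci, ch] <- cnt[ci, ch] + 1
      }
      mse_acc <- mse_acc + normalized_mse(pr$y_hat, pr$target, model$normalizer)
      mse_n <- mse_n + 1
    }
  }
  list(rmse = rmse_acc / pmax(cnt, 1), test_mse = mse_acc / mse_n)
}

#' Collapse the RMSE tensor along one parameter axis
#'
#' Arithmetic mean of the RMSE tensor across the two non-selected parameter
#' axes, giving the marginal RMSE curve per condition and output.
#'
#' @param result A `sweep_result`.
#' @param axis `"tau"`, `"D"` or `"N"`.
#' @return 3-d array \[axis value\]\[condition\]\[output\].
#' @export
collapse_rmse <- function(result, axis = c("tau", "D", "N")) {
  axis <- match.arg(axis)
  if (anyNA(result$rmse)) {
    bad <- which(is.na(result$test_mse), arr.ind = TRUE)
    stop("cannot collapse: missing cells at (tau, D, N) index rows:\n",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  }
  keep <- match(axis, c("tau", "D", "N"))
  apply(result$rmse, c(keep, 4, 5), mean)
}

#' OLS fit of a marginal RMSE curve
#'
#' Ordinary least squares of mean RMSE on the parameter value, with the R^2
#' of the fit and the ANOVA F-test p-value for a zero slope.
#'
#' @param x Parameter values (>= 3).
#' @param y Mean RMSE at each value.
#' @return List: `slope`, `intercept`, `r2`, `slope_p`.
#' @export
regress_marginal <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need >= 3 aligned (x, y) points")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  fit <- intercept + slope * x
  sse <- sum((y - fit)^2)
  sst <- sum((y - my)^2)
  if (sst <= 0) {
    return(list(slope = 0, intercept = my, r2 = 0, slope_p = 1))
  }
  r2 <- 1 - sse / sst
  if (sse <= 1e-300) {
    slope_p <- 0
  } else {
    f <- (sst - sse) / (sse / (n - 2))
    slope_p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(slope = slope, intercept = intercept, r2 = r2, slope_p = slope_p)
}

#' Optimal sampling window and hidden-unit count at a fixed prediction interval
#'
#' Argmin over (D, N) of the test normalized MSE at the fixed tau, ties
#' broken toward smaller N and then smaller D (cheaper networks preferred at
#' equal error).
#'
#' @param result A `sweep_result`.
#' @param fixed_tau_ms Prediction interval to condition on (default 58 ms).
#' @return List: `D_ms`, `N`, `test_mse`.
#' @export
select_optimal <- function(result, fixed_tau_ms = 58) {
  it <- match(paste(fixed_tau_ms), dimnames(result$test_mse)$tau)
  if (is.na(it)) {
    stop("tau = ", fixed_tau_ms, " ms is not in the sweep grid (",
         paste(result$grid$tau_ms, collapse = ", "), ")")
  }
  slice <- result$test_mse[it, , , drop = TRUE]
  if (anyNA(slice)) stop("missing cells in the tau = ", fixed_tau_ms, " ms slice")
  best <- Inf; bD <- NA; bN <- NA
  for (iN in seq_along(result$grid$N)) {      # smaller N wins ties
    for (id in seq_along(result$grid$D_ms)) { # then smaller D
      v <- slice[id, iN]
      if (v < best - 1e-15) {
        best <- v; bD <- result$grid$D_ms[id]; bN <- result$grid$N[iN]
      }
    }
  }
  list(D_ms = bD, N = bN, test_mse = best)
}

#' Re-train the optimized network at zero error goal
#'
#' Repeats training per fold with the fixed prediction interval and the
#' selected (D, N), with `error_goal = 0` so training runs to validation
#' patience or the epoch cap, maximizing network performance.
#'
#' @param folds List of `fold_partition`.
#' @param tau_ms Fixed prediction interval (default 58 ms).
#' @param D_ms,N Optimal sampling window and hidden-unit count from
#'   [select_optimal()].
#' @param tconfig A [training_config()]; its `error_goal` is forced to 0.
#' @param seed Seed for per-fold restart streams.
#' @return List of trained models, one per fold.
#' @export
finalize_model <- function(folds, tau_ms = 58, D_ms, N,
                           tconfig = training_config(), seed = 0) {
  config <- narx_config(m = steps_from_ms(tau_ms), d = steps_from_ms(D_ms), N = N)
  tconfig$error_goal <- 0
  lapply(folds, function(fold) {
    tc <- tconfig
    tc$seed <- derive_seed(seed, 303, fold$fold_index)
    train_with_restarts(fold, config, tc)
  })
}
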