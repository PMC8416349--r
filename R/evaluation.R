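# Performance measurement and statistics: RMSE, cross-correlation-peak R^2,
# instantaneous RMSE on common-length trials, constant-EMG ablation, gait
# critical-point extraction and hypothesis testing with Benjamini-Hochberg
# correction.
#
# Sign conventions (recorded in every report): ankle angle dorsiflexion
# positive / plantarflexion negative, so "maximum plantarflexion" is the
# angle minimum; ankle moment plantarflexion positive, so "maximum
# plantarflexion moment" is the moment maximum.

#' Root mean square error
#' @param pred,target Equal-length numeric vectors (physical units).
#' @export
rmse <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 1) {
    stop("pred and target must be non-empty and of equal length")
  }
  sqrt(mean((pred - target)^2))
}

#' Cross-correlation-peak R^2
#'
#' Normalized cross-correlation between prediction and target, evaluated as
#' the Pearson correlation of the overlapping segments at every lag in
#' `-max_lag..max_lag` (per-lag re-centering, so offset and shape are not
#' conflated). R^2 is the square of the peak-magnitude correlation; the lag
#' of that peak is reported, ties broken toward the smallest |lag|.
#'
#' @param pred,target Equal-length numeric vectors.
#' @param max_lag Maximum |lag| searched; defaults to 25 percent of the
#'   series length.
#' @return List with `r2` and `lag` (samples; positive lag means `pred`
#'   trails `target`).
#' @export
xcorr_r2 <- function(pred, target, max_lag = NULL) {
  n <- length(pred)
  if (n != length(target) || n < 4) stop("need equal-length series (>= 4 samples)")
  if (stats::sd(pred) == 0 || stats::sd(target) == 0) {
    stop("correlation undefined for a constant series")
  }
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  if (max_lag >= n / 2) stop("max_lag must be < length/2")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- pred[(1 + k):n]; b <- target[1:(n - k)]
    } else {
      a <- pred[1:(n + k)]; b <- target[(1 - k):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, 0)
  # peak of |correlation|; ties toward the smallest |lag|
  ord <- order(-abs(cc), abs(lags))
  peak <- ord[1]
  list(r2 = cc[peak]^2, lag = lags[peak], correlation = cc[peak])
}

#' Instantaneous RMSE across trials on a common time base
#'
#' All trials must already share a common length (see
#' [resample_to_length()]). At each time index the RMSE across trials of
#' (pred - target) is computed; the +/- 1 SD band is the SD across trials of
#' the squared errors propagated to the RMSE scale (delta method,
#' `sd(e^2) / (2 * rmse)`).
#'
#' @param pred_trials,target_trials Lists (>= 2) of equal-length numeric
#'   vectors.
#' @return List with `mean` and `sd` curves.
#' @export
instantaneous_rmse <- function(pred_trials, target_trials) {
  if (length(pred_trials) < 2 || length(pred_trials) != length(target_trials)) {
    stop("need >= 2 aligned prediction/target trials")
  }
  L <- unique(c(vapply(pred_trials, length, 0L), vapply(target_trials, length, 0L)))
  if (length(L) != 1) stop("all trials must share a common length; resample first")
  E <- mapply(function(p, t) p - t, pred_trials, target_trials)  # L x n_trials
  sq <- E^2
  m <- sqrt(rowMeans(sq))
  s <- apply(sq, 1, stats::sd) / pmax(2 * m, .Machine$double.eps)
  list(mean = m, sd = s)
}

#' Replace EMG inputs by their temporal means
#'
#' Builds the constant-EMG ablation input: each EMG channel is replaced by
#' its own mean over the trial (same average signal power, no time-varying
#' information); targets are untouched. Idempotent.
#'
#' @param trial A `processed_trial`.
#' @export
constant_emg_inputs <- function(trial) {
  out <- trial
  out$x[, 1] <- mean(trial$x[, 1])
  out$x[, 2] <- mean(trial$x[, 2])
  out
}

#' Critical-point specification
#'
#' @param kind `"stance_event"` (a single sample at a gait-defined extremum
#'   or event) or `"clearance_interval"` (all samples in a timing band).
#' @param definition For stance events one of `"TO"`, `"max_dorsiflexion"`,
#'   `"max_plantarflexion"`, `"max_pf_moment"`; for clearance intervals a
#'   numeric `c(lo, hi)` of trial fractions (timing mean -/+ SD of the
#'   minimum-clearance angle).
#' @param channel `"angle"` or `"moment"`.
#' @param cycle Which gait cycle's stance to search (default 1).
#' @export
critical_point_spec <- function(kind = c("stance_event", "clearance_interval"),
                                definition, channel = c("angle", "moment"),
                                cycle = 1L) {
  kind <- match.arg(kind)
  channel <- match.arg(channel)
  if (kind == "stance_event") {
    stopifnot(definition %in% c("TO", "max_dorsiflexion", "max_plantarflexion",
                                "max_pf_moment"))
  } else {
    if (!is.numeric(definition) || length(definition) != 2 ||
        definition[1] >= definition[2] || any(definition < 0 | definition > 1)) {
      stop("clearance interval needs numeric c(lo, hi) trial fractions in [0, 1]")
    }
  }
  structure(list(kind = kind, definition = definition, channel = channel,
                 cycle = as.integer(cycle)),
            class = "critical_point_spec")
}

# stance window (HS..TO) of the requested cycle, as sample indices
stance_window <- function(trial, cycle) {
  hs <- trial$events$HS; to <- trial$events$TO
  if (is.null(hs) || is.null(to)) stop("trial events must contain HS and TO")
  if (cycle > length(hs) || cycle > length(to)) {
    stop("trial has no cycle ", cycle, " (trial ", trial$trial_id, ")")
  }
  if (to[cycle] <= hs[cycle]) stop("TO precedes HS in cycle ", cycle)
  hs[cycle]:to[cycle]
}

#' Extract paired prediction/target samples at critical points
#'
#' Stance events are located on the *target* series (toe-off from the event
#' table; extrema within the stance window); both prediction and target are
#' then sampled at that index. Clearance intervals return every sample whose
#' trial fraction lies in the band.
#'
#' @param trace A `prediction_trace` from [predict_trial()].
#' @param trial The `processed_trial` the trace was computed on.
#' @param specs List of [critical_point_spec()].
#' @return List (one element per spec) of data frames with `index`, `pred`,
#'   `target`.
#' @export
extract_critical_points <- function(trace, trial, specs) {
  n_trial <- nrow(trial$y)
  lapply(specs, function(sp) {
    ch <- if (sp$channel == "angle") 1L else 2L
    if (sp$kind == "stance_event") {
      if (sp$definition == "TO") {
        idx <- trial$events$TO[sp$cycle]
        if (is.na(idx)) stop("no TO event for cycle ", sp$cycle,
                             " in trial ", trial$trial_id)
      } else {
        win <- stance_window(trial, sp$cycle)
        series <- trial$y[win, ch]
        idx <- win[switch(sp$definition,
          max_dorsiflexion = which.max(series),
          max_plantarflexion = which.min(series),
          max_pf_moment = which.max(series)
        )]
      }
      idx <- as.integer(idx)
    } else {
      lo <- 1L + floor(sp$definition[1] * (n_trial - 1))
      hi <- 1L + ceiling(sp$definition[2] * (n_trial - 1))
      idx <- lo:hi
    }
    # map trial indices onto trace rows (predictions exist for t_pred only)
    pos <- match(idx, trace$t_pred)
    keep <- !is.na(pos)
    if (!any(keep)) {
      stop("no predictions available at the requested critical point (trial ",
           trial$trial_id, ")")
    }
    data.frame(index = idx[keep],
               pred = trace$y_hat[pos[keep], ch],
               target = trace$target[pos[keep], ch])
  })
}

#' Normality-gated paired test at a critical point
#'
#' Shapiro-Wilk on the paired differences at alpha = 0.05 selects a paired
#' t-test (normal) or an exact binomial sign test (non-normal). All-zero
#' differences are reported as `"identical"` with p = 1; zero-variance
#' non-zero differences go to the sign test.
#'
#' @param pred,target Paired samples (n >= 3).
#' @return List: `test` (`"paired_t"`, `"sign"` or `"identical"`),
#'   `statistic`, `p`, `shapiro_p`, `n`.
#' @export
critical_point_test <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 3) {
    stop("need >= 3 paired samples")
  }
  d <- pred - target
  if (all(d == 0)) {
    return(list(test = "identical", statistic = 0, p = 1, shapiro_p = NA_real_,
                n = length(d)))
  }
  sw_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
  if (sw_p > 0.05) {
    tt <- stats::t.test(d)
    list(test = "paired_t", statistic = unname(tt$statistic), p = tt$p.value,
         shapiro_p = sw_p, n = length(d))
  } else {
    nz <- d[d != 0]
    bt <- stats::binom.test(sum(nz > 0), length(nz), 0.5)
    list(test = "sign", statistic = sum(nz > 0), p = bt$p.value,
         shapiro_p = sw_p, n = length(d))
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @return List with `adjusted` (monotone step-up adjusted p-values, in input
#'   order) and `reject` (adjusted p <= q).
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  adj <- pvals[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))   # enforce monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  list(adjusted = out, reject = out <= q)
}

# mean/sd helpers tolerant of single values
msd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)

#' Evaluate trained per-fold models on their novel test trials
#'
#' For every fold and every test trial, runs the open-loop prediction with
#' time-varying EMG and with the constant-EMG ablation, and accumulates
#' per-condition, per-output RMSE, cross-correlation-peak R^2, peak lags and
#' common-length instantaneous error curves.
#'
#' @param folds List of `fold_partition`.
#' @param models List of trained models (same order as `folds`), each as
#'   returned by [train_network()] / [train_with_restarts()].
#' @param specs Optional critical-point specification: either a flat list of
#'   [critical_point_spec()] applied to every condition, or a named list
#'   (`LW`, `AS`, `DS`) of per-condition spec lists. When supplied, the
#'   critical-point table with Shapiro-Wilk-gated tests and B-H adjusted
#'   p-values is included.
#' @param fdr False discovery rate for the B-H correction.
#' @return An `evaluation_report`: `metrics` data frame (condition, output,
#'   fold, trial, rmse, r2, lag, ablation rmse), `summary` (per condition x
#'   output means and SDs), `instantaneous` (per condition x output mean/SD
#'   curves for both input types), optional `critical_points`, and the sign
#'   conventions.
#' @export
build_report <- function(folds, models, specs = NULL, fdr = 0.05) {
  if (length(folds) != length(models)) stop("one model per fold required")
  missing <- which(vapply(models, is.null, TRUE))
  if (length(missing)) stop("missing models for folds: ", paste(missing, collapse = ", "))

  per_cond_specs <- !is.null(specs) && !is.null(names(specs)) &&
    all(names(specs) %in% CONDITIONS)

  rows <- list()
  inst_err <- list()   # condition -> output -> type -> list of error curves
  cp_samples <- list() # spec x condition -> accumulated paired samples
  cp_specs <- list()   # spec object per accumulated key

  for (f in seq_along(folds)) {
    model <- models[[f]]
    for (tr in folds[[f]]$test) {
      trace_tv <- predict_trial(model$weights, model$config, model$normalizer, tr)
      trace_ce <- predict_trial(model$weights, model$config, model$normalizer,
                                constant_emg_inputs(tr))
      L <- common_trial_length(tr$condition)
      for (ch in 1:2) {
        out_name <- c("angle", "moment")[ch]
        xc <- xcorr_r2(trace_tv$y_hat[, ch], trace_tv$target[, ch])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = tr$condition, output = out_name, fold = f,
          trial_id = tr$trial_id,
          rmse = rmse(trace_tv$y_hat[, ch], trace_tv$target[, ch]),
          r2 = xc$r2, lag = xc$lag,
          rmse_constant_emg = rmse(trace_ce$y_hat[, ch], trace_ce$target[, ch])
        )
        key <- paste(tr$condition, out_name, sep = ".")
        e_tv <- resample_to_length(trace_tv$y_hat[, ch] - trace_tv$target[, ch], L)
        e_ce <- resample_to_length(trace_ce$y_hat[, ch] - trace_ce$target[, ch], L)
        inst_err[[key]]$tv <- c(inst_err[[key]]$tv %||% list(), list(e_tv))
        inst_err[[key]]$ce <- c(inst_err[[key]]$ce %||% list(), list(e_ce))
      }
      if (!is.null(specs)) {
        sp <- if (per_cond_specs) specs[[tr$condition]] else specs
        cps <- extract_critical_points(trace_tv, tr, sp)
        for (s in seq_along(sp)) {
          key <- paste(tr$condition, s, sep = ".")
          cp_samples[[key]] <- rbind(cp_samples[[key]], cps[[s]])
          cp_specs[[key]] <- sp[[s]]
        }
      }
    }
  }
  metrics <- do.call(rbind, rows)

  summary <- do.call(rbind, lapply(
    split(metrics, list(metrics$condition, metrics$output)), function(g) {
      data.frame(condition = g$condition[1], output = g$output[1],
                 rmse_mean = mean(g$rmse), rmse_sd = msd(g$rmse)[["sd"]],
                 r2_mean = mean(g$r2), r2_sd = msd(g$r2)[["sd"]],
                 lag_mode = as.integer(names(which.max(table(g$lag)))),
                 rmse_ce_mean = mean(g$rmse_constant_emg),
                 rmse_ce_sd = msd(g$rmse_constant_emg)[["sd"]])
    }))
  rownames(summary) <- NULL

  instantaneous <- lapply(inst_err, function(by_type) {
    lapply(by_type, function(curves) {
      zeros <- lapply(curves, function(e) numeric(length(e)))
      instantaneous_rmse(curves, zeros)
    })
  })

  critical_points <- NULL
  if (!is.null(specs)) {
    cp_rows <- list()
    for (key in names(cp_samples)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      s <- as.integer(parts[2])
      sp_s <- cp_specs[[key]]
      df <- cp_samples[[key]]
      tst <- critical_point_test(df$pred, df$target)
      cp_rows[[length(cp_rows) + 1L]] <- data.frame(
        condition = parts[1], spec = s, kind = sp_s$kind,
        channel = sp_s$channel,
        definition = paste(format(sp_s$definition), collapse = "-"),
        n = tst$n,
        target_mean = mean(df$target), target_sd = msd(df$target)[["sd"]],
        pred_mean = mean(df$pred), pred_sd = msd(df$pred)[["sd"]],
        test = tst$test, statistic = tst$statistic, p = tst$p
      )
    }
    critical_points <- do.call(rbind, cp_rows)
    bh <- benjamini_hochberg(critical_points$p, q = fdr)
    critical_points$p_adjusted <- bh$adjusted
    critical_points$reject <- bh$reject
  }

  structure(
    list(metrics = metrics, summary = summary, instantaneous = instantaneous,
         critical_points = critical_points,
         conventions = c(angle = "dorsiflexion positive",
                         moment = "plantarflexion positive"),
         fdr = fdr),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", nrow(x$metrics), "trial x output rows )\n")
  print(x$summary, digits = 3)
  if (!is.null(x$critical_points)) {
    n_rej <- sum(x$critical_points$reject)
    cat(sprintf("critical points: %d tested, %d rejected at FDR %.2f\n",
                nrow(x$critical_points), n_rej, x$fdr))
  }
  invisible(x)
}
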