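#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation so that trials / restarts / folds get
# independent, reorderable RNG streams. Kept strictly below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  # multipliers kept small enough that every intermediate stays below 2^53,
  # so no low-order bits (the varying trial/fold/restart indices) are lost
  h <- 5381
  for (p in parts) {
    p <- as.numeric(p) %% 2147483647
    h <- (h * 69069 + p * 40503 + 12345) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

# smooth band-limited Gaussian noise: white noise low-passed with a simple
# recursive smoother, rescaled to unit variance before scaling by sd
smooth_noise <- function(n, sd, fs, cutoff_hz) {
  if (sd <= 0) return(numeric(n))
  alpha <- exp(-2 * pi * cutoff_hz / fs)
  w <- stats::rnorm(n + 200)
  y <- stats::filter(w, alpha, method = "recursive")
  y <- as.numeric(y)[201:(n + 200)]
  sd * (y - mean(y)) / stats::sd(y)
}

CONDITIONS <- c("LW", "AS", "DS")

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% CONDITIONS) {
    stop("condition must be one of ", paste(CONDITIONS, collapse = ", "))
  }
  condition
}
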