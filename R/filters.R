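# Butterworth filter design and zero-phase filtering.
#
# Implemented from the standard analog-prototype + frequency-transform +
# bilinear-transform construction, kept in zero-pole-gain form and realized
# as cascaded biquads (second-order sections) for numerical stability at the
# low relative cutoffs used here (e.g. 15 Hz at a 1,200 Hz rate).

#' Design a digital Butterworth filter
#'
#' Designs a digital Butterworth filter of the given analog design order and
#' returns it as second-order sections. "Order" is the analog prototype
#' order; band-pass and band-stop designs have twice that many poles, and
#' zero-phase (forward-backward) application doubles the effective order
#' again.
#'
#' @param order Analog prototype order (>= 1).
#' @param cutoff_hz Cutoff frequency in Hz; length 1 for `lowpass`/`highpass`,
#'   length 2 (low, high) for `bandpass`/`bandstop`.
#' @param fs Sampling rate in Hz.
#' @param type One of `"lowpass"`, `"highpass"`, `"bandpass"`, `"bandstop"`.
#' @return An object of class `butter_sos`: a list with the section matrix
#'   `sos` (columns b0, b1, b2, a0, a1, a2), and the design parameters.
#' @examples
#' f <- butter_design(4, 15, fs = 1200, type = "lowpass")
#' y <- filtfilt_sos(f, sin(2 * pi * 5 * (0:2399) / 1200))
#' @export
butter_design <- function(order, cutoff_hz, fs,
                          type = c("lowpass", "highpass", "bandpass", "bandstop")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0)
  n_cut <- if (type %in% c("lowpass", "highpass")) 1L else 2L
  if (length(cutoff_hz) != n_cut) {
    stop("'", type, "' design needs ", n_cut, " cutoff frequency(ies)")
  }
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2)) {
    stop("cutoff frequencies must lie strictly between 0 and Nyquist (",
         fs / 2, " Hz)")
  }
  if (n_cut == 2L && diff(cutoff_hz) <= 0) {
    stop("band edges must be strictly increasing")
  }

  # analog Butterworth prototype: poles on the unit circle, no zeros
  k_idx <- seq_len(order)
  theta <- pi * (2 * k_idx - 1) / (2 * order) + pi / 2
  p <- complex(modulus = 1, argument = theta)
  z <- complex(0)
  k <- 1

  # prewarped analog frequencies
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)

  if (type == "lowpass") {
    w0 <- warped
    p <- p * w0
    k <- k * w0^order
  } else if (type == "highpass") {
    w0 <- warped
    k <- k * Re(1 / prod(-p))
    p <- w0 / p
    z <- rep(0 + 0i, order)
  } else {
    w0 <- sqrt(prod(warped))
    bw <- diff(warped)
    if (type == "bandpass") {
      k <- k * bw^order
      pl <- p * bw / 2
      p <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
      z <- rep(0 + 0i, order)
    } else { # bandstop
      k <- k * Re(1 / prod(-p))
      pl <- (bw / 2) / p
      p <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
      z <- rep(c(1i * w0, -1i * w0), order)
    }
  }

  # bilinear transform
  fs2 <- 2 * fs
  k <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  structure(
    list(sos = zpk_to_sos(zd, pd, k), order = order, cutoff_hz = cutoff_hz,
         fs = fs, type = type),
    class = "butter_sos"
  )
}

# Pair conjugate roots into real quadratic factors. Roots are assumed to be
# closed under conjugation (true for real-coefficient designs).
conjugate_pairs <- function(r, tol = 1e-8) {
  cplx <- r[Im(r) > tol]
  real <- sort(Re(r[abs(Im(r)) <= tol]))
  pairs <- lapply(cplx, function(x) c(x, Conj(x)))
  while (length(real) >= 2) {
    pairs <- c(pairs, list(complex(real = real[1:2], imaginary = 0)))
    real <- real[-(1:2)]
  }
  if (length(real) == 1) {
    pairs <- c(pairs, list(complex(real = real, imaginary = 0)))
  }
  pairs
}

# zero-pole-gain to second-order sections; pole pairs closest to the unit
# circle are matched with their nearest zero pair.
zpk_to_sos <- function(z, p, k) {
  stopifnot(length(z) <= length(p))
  ppairs <- conjugate_pairs(p)
  zpairs <- conjugate_pairs(z)
  ppairs <- ppairs[order(vapply(ppairs, function(q) min(abs(1 - abs(q))), 0))]
  n_sec <- length(ppairs)
  sos <- matrix(0, n_sec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (s in seq_len(n_sec)) {
    pp <- ppairs[[s]]
    a <- if (length(pp) == 2) {
      c(1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))
    } else {
      c(1, -Re(pp), 0)
    }
    b <- c(1, 0, 0)
    if (length(zpairs) > 0) {
      d <- vapply(zpairs, function(q) min(abs(q[1] - pp)), 0)
      zz <- zpairs[[which.min(d)]]
      zpairs <- zpairs[-which.min(d)]
      b <- if (length(zz) == 2) {
        c(1, -Re(zz[1] + zz[2]), Re(zz[1] * zz[2]))
      } else {
        c(1, -Re(zz), 0)
      }
    }
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# single-pass cascade filter, direct form II transposed
sosfilt <- function(sos, x) {
  y <- as.numeric(x)
  for (s in seq_len(nrow(sos))) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    w1 <- 0; w2 <- 0
    for (i in seq_along(y)) {
      xi <- y[i]
      yi <- b0 * xi + w1
      w1 <- b1 * xi - a1 * yi + w2
      w2 <- b2 * xi - a2 * yi
      y[i] <- yi
    }
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies a designed filter forward and backward so that the net result has
#' zero phase lag and a squared magnitude response. Edges are handled by odd
#' (point-reflected) extension before filtering; the pad is discarded.
#'
#' @param filt A `butter_sos` object from [butter_design()].
#' @param x Numeric signal.
#' @param padlen Number of reflected samples prepended/appended; defaults to
#'   enough to let the slowest design used here settle, capped at
#'   `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_sos <- function(filt, x, padlen = NULL) {
  stopifnot(inherits(filt, "butter_sos"))
  if (anyNA(x)) stop("input contains missing values; gap-free input required")
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 1000L)
  if (n <= 3) stop("input too short to filter (length ", n, ")")
  head_pad <- 2 * x[1] - x[(padlen + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(head_pad, x, tail_pad)
  ext <- sosfilt(filt$sos, ext)
  ext <- rev(sosfilt(filt$sos, rev(ext)))
  ext[(padlen + 1):(padlen + n)]
}

#' @export
print.butter_sos <- function(x, ...) {
  cat(sprintf("Butterworth %s, order %d (x2 zero-phase), cutoff %s Hz @ %g Hz\n",
              x$type, x$order, paste(x$cutoff_hz, collapse = "-"), x$fs))
  invisible(x)
}
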