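# Digital filter primitives: Butterworth low/high-pass design via the bilinear
# transform, an RBJ second-order notch, single-pass IIR filtering on
# stats::filter (zero initial state), and zero-phase forward-backward
# application with odd-reflection edge padding.  Implemented in-package because
# the runtime has no filter-design library; designs were cross-checked against
# an independent reference implementation during development and are covered by
# spectral tests.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth (maximally flat) low-pass or high-pass filter
#' by the bilinear transform of the analog prototype.
#'
#' @param order filter order (number of poles).
#' @param cutoff_hz -3 dB cutoff in Hz.
#' @param sampling_rate sampling frequency in Hz; `cutoff_hz` must lie in
#'   (0, sampling_rate/2).
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` and denominator `a` coefficient vectors.
#' @export
butter_coeffs <- function(order, cutoff_hz, sampling_rate, type = c("low", "high")) {
  type <- match.arg(type)
  wn <- 2 * cutoff_hz / sampling_rate
  if (wn <= 0 || wn >= 1) stop("cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  n <- as.integer(order)
  # analog prototype: poles on the unit circle in the left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs <- 2
  warped <- 2 * fs * tan(pi * wn / fs)
  if (type == "low") {
    pa <- p * warped
    za <- complex(0)
    gain <- warped^n
  } else {
    pa <- warped / p
    za <- rep(0 + 0i, n)
    gain <- 1 # prod(-p) = 1 for the Butterworth prototype
  }
  fs2 <- 2 * fs
  pd <- (fs2 + pa) / (fs2 - pa)
  zd <- if (length(za)) (fs2 + za) / (fs2 - za) else complex(0)
  zd <- c(zd, rep(-1 + 0i, length(pa) - length(za)))
  gd <- gain * Re(prod(fs2 - za) / prod(fs2 - pa))
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Second-order IIR notch coefficients
#'
#' Narrow band-stop biquad centred at `freq_hz` with quality factor `q`
#' (bandwidth = freq/q).
#'
#' @inheritParams butter_coeffs
#' @param freq_hz notch centre frequency in Hz, below Nyquist.
#' @param q quality factor; higher is narrower.
#' @return list with `b` and `a`.
#' @export
notch_coeffs <- function(freq_hz, sampling_rate, q = 30) {
  if (freq_hz <= 0 || freq_hz >= sampling_rate / 2) {
    stop("notch frequency must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  w0 <- 2 * pi * freq_hz / sampling_rate
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(b = c(1, -2 * cos(w0), 1) / a0,
       a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0))
}

# single-pass IIR filter, zero initial state (direct form)
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  y <- as.numeric(y[nb:length(xp)])
  if (length(a) > 1) y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
  y
}

# zero-phase forward-backward filtering with odd-reflection padding at both
# ends; pad is clamped to length(x) - 1
filtfilt_zero_phase <- function(b, a, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# centred moving average with edge replication; window in samples (odd-ified)
moving_average <- function(x, window) {
  w <- max(1L, as.integer(window))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  xe <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xe, rep(1 / w, w), method = "convolution", sides = 2))[(half + 1):(half + n)]
}
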