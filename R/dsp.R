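# Signal-processing layer: Butterworth band-pass design (bilinear transform of
# the analog prototype), zero-phase filtering, and polyphase rational
# resampling with a Kaiser-windowed sinc anti-alias filter.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Continued-fraction rational approximation p/q of x with q <= max_den.
rational_approx <- function(x, max_den = 1000L, tol = 1e-9) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * max(1, abs(x))) break
    fr <- r - a
    if (fr < 1e-15) break
    r <- 1 / fr
  }
  if (abs(x - p1 / q1) > 1e-6) {
    stop("sampling-rate ratio is not a simple rational number")
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog Butterworth low-pass prototype, low-pass-to-band-pass transform,
#' then bilinear transform with frequency pre-warping. Returns transfer
#' function coefficients `b` (numerator) and `a` (denominator); a band-pass
#' of order `n` yields polynomials of degree `2n`.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz < rate/2`.
#' @param order Prototype filter order (default 4).
#' @param rate Sampling rate in Hz.
#' @return List with numeric vectors `b` and `a`.
#' @export
butter_bandpass <- function(low_hz, high_hz, order = 4L, rate) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2)) {
    stop("need 0 < low_hz < high_hz < rate/2 (band edges must be below Nyquist)")
  }
  if (order < 1L) stop("`order` must be >= 1")
  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped analog band edges (bilinear with fs = 2)
  fs <- 2
  w1 <- 2 * fs * tan(pi * (low_hz / rate))
  w2 <- 2 * fs * tan(pi * (high_hz / rate))
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # low-pass -> band-pass: each pole splits into two
  pb <- p * bw / 2
  p_bp <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  z_bp <- rep(complex(real = 0), n)          # n zeros at s = 0
  k_bp <- bw^n
  # bilinear transform z = (2fs + s) / (2fs - s)
  fs2 <- 2 * fs
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_z <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_z)) * k_z
  a <- Re(poly_from_roots(p_z))
  list(b = b, a = a)
}

# Steady-state delay-line initialization for a step input of unit height
# (suppresses filter start-up transients in the zero-phase wrapper).
iir_initial_state <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1]
  b <- c(b, rep(0, n - length(b))) / 1
  b <- b / a[1]
  if (n == 1L) return(numeric(0))
  # companion matrix of a, transposed
  C <- matrix(0, n - 1, n - 1)
  C[1, ] <- -a[-1]
  if (n > 2L) C[cbind(2:(n - 1), 1:(n - 2))] <- 1
  A <- t(C)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward (squaring the magnitude response,
#' cancelling phase), with odd-reflection end padding and steady-state
#' initialization to suppress edge transients.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric signal vector.
#' @return Filtered vector of the same length.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  pad <- 3L * (nfilt - 1L)
  if (n <= pad) stop("signal too short for the requested filter order")
  zi <- iir_initial_state(b, a)
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass applied channel-wise. By default the filter is run
#' zero-phase (forward-backward), doubling the effective roll-off; set
#' `zero_phase = FALSE` for a single causal pass.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band edges in Hz (default 1-45).
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase Run forward-backward (default `TRUE`).
#' @return A filtered [recording()] with the same shape and rate.
#' @export
bandpass <- function(rec, low_hz = 1, high_hz = 45, order = 4L,
                     zero_phase = TRUE) {
  stopifnot(inherits(rec, "Recording"))
  coefs <- butter_bandpass(low_hz, high_hz, order, rec$rate)
  out <- rec$data
  nz <- max(length(coefs$a), length(coefs$b)) - 1L
  for (ch in seq_len(nrow(out))) {
    if (zero_phase) {
      out[ch, ] <- filtfilt(coefs$b, coefs$a, rec$data[ch, ])
    } else {
      out[ch, ] <- iir_filter_cpp(coefs$b, coefs$a, rec$data[ch, ],
                                  numeric(nz))
    }
  }
  recording(out, rec$rate, rec$channel_names, rec$label, rec$subject_id)
}

# Kaiser window of length n (besselI is the modified Bessel function I0).
kaiser_window <- function(n, beta) {
  m <- n - 1
  k <- 0:m
  besselI(beta * sqrt(pmax(0, 1 - ((2 * k - m) / m)^2)), 0) / besselI(beta, 0)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Low-pass FIR for p/q polyphase resampling: Kaiser-windowed sinc, cutoff at
# the tighter of the two Nyquist limits, unit DC gain before the gain-of-p
# compensation applied by the caller.
resample_fir <- function(p, q, beta = 5) {
  half <- 10L * max(p, q)
  fc <- 1 / max(p, q)
  k <- (-half):half
  h <- fc * sinc(fc * k) * kaiser_window(2L * half + 1L, beta)
  h / sum(h)
}

#' Resample a recording to a lower rate
#'
#' Rational-factor (p/q) resampling: zero-stuff by p, apply a Kaiser-windowed
#' sinc anti-alias low-pass (linear phase, delay-compensated), keep every
#' q-th sample. Upsampling requests are rejected; duration is preserved to
#' within one output sample.
#'
#' @param rec A [recording()].
#' @param target_rate New rate in Hz; must satisfy `0 < target_rate <= rate`.
#' @return A [recording()] at `target_rate`.
#' @export
resample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "Recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("`target_rate` must be a single positive number")
  }
  if (target_rate > rec$rate) {
    stop("upsampling is not supported (target_rate > rate)")
  }
  if (isTRUE(all.equal(target_rate, rec$rate))) return(rec)
  pq <- rational_approx(target_rate / rec$rate)
  p <- pq[["p"]]; q <- pq[["q"]]
  h <- resample_fir(p, q) * p
  half <- (length(h) - 1L) %/% 2L
  n_in <- ncol(rec$data)
  n_up <- n_in * p
  n_out <- ceiling(n_in * p / q)
  idx <- half + 1L + (seq_len(n_out) - 1L) * q   # delay-compensated picks
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    up <- numeric(n_up)
    up[seq(1L, n_up, by = p)] <- rec$data[ch, ]
    full <- fft_convolve(up, h)
    out[ch, ] <- full[idx]
  }
  recording(out, target_rate, rec$channel_names, rec$label, rec$subject_id)
}

# Full ("open") linear convolution via FFT.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Preprocess a recording into epochs
#'
#' The default stage order follows the study protocol: downsample to
#' `target_rate`, band-pass `band[1]`-`band[2]` Hz with a Butterworth filter
#' of the given order, then cut into non-overlapping windows. Set
#' `filter_first = TRUE` to band-pass at the original rate before
#' downsampling (numerically the safer order).
#'
#' @param rec A [recording()].
#' @param target_rate Rate after downsampling (default 200 Hz).
#' @param band Band-pass edges in Hz (default `c(1, 45)`).
#' @param order Butterworth order (default 4).
#' @param window_seconds Epoch length in seconds (default 10).
#' @param filter_first Band-pass before downsampling (default `FALSE`).
#' @param zero_phase Zero-phase filtering (default `TRUE`).
#' @return An [epoch_set()].
#' @export
preprocess <- function(rec, target_rate = 200, band = c(1, 45), order = 4L,
                       window_seconds = 10, filter_first = FALSE,
                       zero_phase = TRUE) {
  stopifnot(inherits(rec, "Recording"), length(band) == 2L)
  if (filter_first) {
    rec <- bandpass(rec, band[1], band[2], order, zero_phase)
    rec <- resample(rec, target_rate)
  } else {
    rec <- resample(rec, target_rate)
    rec <- bandpass(rec, band[1], band[2], order, zero_phase)
  }
  segment(rec, window_seconds)
}
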