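# Butterworth band-pass design and zero-phase filtering.
#
# No DSP package is assumed: the design follows the textbook route
# (analog low-pass prototype -> low-pass-to-band-pass transform -> bilinear
# transform with frequency pre-warping) and the result is kept as a cascade
# of second-order sections for numerical stability near the Nyquist edge.

#' Design a digital Butterworth band-pass filter
#'
#' Designs a band-pass Butterworth filter as second-order sections via the
#' bilinear transform with frequency pre-warping. `order` is the order of
#' the analog low-pass prototype; the resulting band-pass filter has
#' `2 * order` poles, matching the convention of the common
#' `butter(order, c(low, high))` DSP interfaces.
#'
#' @param order low-pass prototype order (default 4).
#' @param low_hz,high_hz band edges in Hz.
#' @param fs sampling rate in Hz; `high_hz` must be below `fs / 2`.
#' @return an object of class `butter_sos` with elements `sos` (matrix with
#'   columns b0, b1, b2, a0, a1, a2, one row per biquad), `gain`, and the
#'   design parameters.
#' @seealso [filtfilt_sos()], [freq_response()]
#' @export
butter_bandpass <- function(order = 4, low_hz = 35, high_hz = 450, fs = 1000) {
  abort_if(low_hz <= 0 || high_hz <= low_hz, "band edges must satisfy 0 < low < high")
  abort_if(high_hz >= fs / 2,
           "high cutoff (%g Hz) must be below the Nyquist frequency fs/2 = %g Hz",
           high_hz, fs / 2)
  n <- as.integer(order)
  abort_if(n < 1, "order must be >= 1")

  # Pre-warped analog edge frequencies (rad/s) for the bilinear transform.
  wl <- 2 * fs * tan(pi * low_hz / fs)
  wh <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(wl * wh)          # analog center frequency
  bw <- wh - wl                # analog bandwidth

  # Analog Butterworth low-pass prototype poles (unit cutoff, left half plane).
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  # Low-pass -> band-pass: each prototype pole p yields the two roots of
  # s^2 - (p * bw) s + w0^2 = 0.
  disc <- sqrt(as.complex((p_lp * bw)^2 - 4 * w0^2))
  p_bp <- c((p_lp * bw + disc) / 2, (p_lp * bw - disc) / 2)

  # Bilinear transform: z = (2 fs + s) / (2 fs - s).
  p_z <- (2 * fs + p_bp) / (2 * fs - p_bp)
  # Band-pass zeros: n at s = 0 -> z = +1 and n at s = Inf -> z = -1.

  # Pair poles into conjugate biquads: sort by imaginary part magnitude and
  # match each pole with positive imaginary part to its conjugate.
  pos <- p_z[Im(p_z) >= 0]
  pos <- pos[order(Re(pos), Im(pos))]
  abort_if(length(pos) != n, "internal error: expected %d conjugate pole pairs", n)
  sos <- matrix(0, nrow = n, ncol = 6,
                dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (i in seq_len(n)) {
    p <- pos[i]
    # numerator (z - 1)(z + 1) = z^2 - 1 -> coefficients in z^-1: (1, 0, -1)
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }

  flt <- structure(list(sos = sos, gain = 1, order = n,
                        low_hz = low_hz, high_hz = high_hz, fs = fs),
                   class = "butter_sos")
  # Normalize so the response at the (warped) center frequency is exactly 1.
  f_center <- fs / pi * atan(w0 / (2 * fs))
  flt$gain <- 1 / Mod(freq_response(flt, f_center))
  flt
}

#' Complex frequency response of a second-order-section filter
#'
#' @param flt a `butter_sos` filter.
#' @param f frequencies in Hz.
#' @return complex response values; use `Mod()` for the magnitude.
#' @export
freq_response <- function(flt, f) {
  z1 <- exp(-1i * 2 * pi * f / flt$fs)  # z^-1
  h <- rep(flt$gain + 0i, length(f))
  for (i in seq_len(nrow(flt$sos))) {
    s <- unname(flt$sos[i, ])
    h <- h * (s[1] + s[2] * z1 + s[3] * z1^2) / (s[4] + s[5] * z1 + s[6] * z1^2)
  }
  h
}

# Single forward pass of one biquad using stats::filter (C implementation):
# FIR part by convolution, then the recursive part.
biquad_forward <- function(x, s) {
  nx <- length(x)
  v <- s[1] * x
  if (nx >= 2) v[2:nx] <- v[2:nx] + s[2] * x[1:(nx - 1)]
  if (nx >= 3) v[3:nx] <- v[3:nx] + s[3] * x[1:(nx - 2)]
  as.numeric(stats::filter(v, filter = -s[5:6], method = "recursive"))
}

sos_forward <- function(x, flt) {
  y <- x * flt$gain
  for (i in seq_len(nrow(flt$sos))) y <- biquad_forward(y, flt$sos[i, ])
  y
}

#' Zero-phase filtering with a second-order-section filter
#'
#' Applies the filter forward and backward (squaring the magnitude response
#' and cancelling the phase). The signal is extended at both ends by an odd
#' reflection of length `padlen` so start-up transients decay inside the
#' padding.
#'
#' @param x numeric vector.
#' @param flt a `butter_sos` filter.
#' @param padlen reflection padding length in samples (default 500, clipped
#'   to `length(x) - 1`).
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_sos <- function(x, flt, padlen = 500) {
  nx <- length(x)
  abort_if(nx < 4, "signal too short to filter")
  p <- min(padlen, nx - 1)
  # odd extension: 2*x[1] - x[p+1 .. 2], 2*x[n] - x[n-1 .. n-p]
  head_ext <- 2 * x[1] - x[(p + 1):2]
  tail_ext <- 2 * x[nx] - x[(nx - 1):(nx - p)]
  ext <- c(head_ext, x, tail_ext)
  y <- sos_forward(ext, flt)
  y <- rev(sos_forward(rev(y), flt))
  y[(p + 1):(p + nx)]
}
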