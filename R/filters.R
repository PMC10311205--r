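#' Design a Butterworth filter as second-order sections
#'
#' Analytic biquad-cascade design of an even-order Butterworth low- or
#' high-pass filter. Prototype poles are placed on the unit circle and mapped
#' to the digital domain with a pre-warped bilinear transform, one conjugate
#' pole pair per section. The cascade form stays numerically stable at the
#' very low normalized cutoffs needed for slow FHR modulation bands, where a
#' single transfer-function realisation of the same filter is unusable.
#'
#' @param n filter order (even).
#' @param fc cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return an object of class `ctg_sos`: a list of biquads, each with
#'   numerator `b` and denominator `a` (length-3 vectors), plus design
#'   metadata.
#' @keywords internal
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (n %% 2 != 0 || n < 2) stop("filter order must be a positive even integer")
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie strictly inside (0, fs/2)")
  wc <- 2 * fs * tan(pi * fc / fs)  # pre-warped analog cutoff, rad/s
  k <- seq_len(n %/% 2)
  theta <- pi * (2 * k + n - 1) / (2 * n)
  proto <- complex(modulus = 1, argument = theta)  # upper-half-plane poles
  K <- 2 * fs
  sections <- lapply(proto, function(pk) {
    pj <- if (type == "low") wc * pk else wc / pk
    a1 <- -2 * Re(pj)
    a0 <- Mod(pj)^2              # analog denominator s^2 + a1 s + a0
    d0 <- K^2 + a1 * K + a0
    A <- c(1, 2 * (a0 - K^2) / d0, (K^2 - a1 * K + a0) / d0)
    if (type == "low") {
      B <- (a0 / d0) * c(1, 2, 1)
    } else {
      B <- (K^2 / d0) * c(1, -2, 1)
    }
    list(b = B, a = A)
  })
  structure(list(sections = sections, n = n, fc = fc, fs = fs, type = type),
            class = "ctg_sos")
}

# Zero-phase filtering of one biquad with odd-reflection padding.  The pad
# length must cover the filter's settling time; for the slow bands this can
# exceed the segment, in which case the whole signal is mirrored.  Each pass
# subtracts the leading sample and adds back its steady-state response
# (DC gain x offset), so constant signals are reproduced exactly and edge
# transients reduce to curvature effects.
filtfilt_biquad <- function(b, a, x, padlen) {
  nx <- length(x)
  padlen <- min(padlen, nx - 1L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[nx] - x[seq(nx - 1, nx - padlen)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  K <- sum(b) / sum(a)                        # DC gain
  run <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(signal::Arma(b = b, a = a), z - z0)) + K * z0
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[seq(padlen + 1, padlen + nx)]
}

#' Apply a biquad cascade forwards and backwards (zero phase)
#' @param sos a `ctg_sos` object (or plain list of `b`/`a` pairs).
#' @param x numeric signal.
#' @keywords internal
sos_filtfilt <- function(sos, x) {
  sections <- if (inherits(sos, "ctg_sos")) sos$sections else sos
  fc <- if (inherits(sos, "ctg_sos")) sos$fc else NA_real_
  fs <- if (inherits(sos, "ctg_sos")) sos$fs else 1
  padlen <- if (is.finite(fc)) ceiling(3 * fs / fc) else 3L * 10L
  for (s in sections) x <- filtfilt_biquad(s$b, s$a, x, padlen)
  x
}

#' Band-pass filter an FHR signal
#'
#' Zero-phase 6th-order Butterworth filtering with cutoffs given in cycles
#' per minute of signal modulation (the natural unit for accel/decel time
#' scales: 0.1--7 cycles/min spans event durations of roughly 9 s to 10 min).
#' Cutoffs are converted as f_Hz = f_cpm / 60. A lower edge of 0 gives a pure
#' low-pass; otherwise the band-pass is realised as the cascade of a
#' high-pass at the lower edge and a low-pass at the upper edge, each 6th
#' order and applied forward-backward so events are not phase-shifted.
#'
#' @param x numeric FHR series (bpm), gap-free.
#' @param low_bpm lower band edge in cycles/min (0 for low-pass).
#' @param high_bpm upper band edge in cycles/min; must be below the Nyquist
#'   rate `sample_rate * 30` cycles/min.
#' @param sample_rate sampling rate in Hz (default 4).
#' @param order filter order (default 6).
#' @return filtered numeric series, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1800, by = 0.25)
#' x <- sin(2 * pi * (0.5 / 60) * t)       # 0.5 cycles/min oscillation
#' y <- bandpass(x, 0.1, 1)                # passed nearly unchanged
bandpass <- function(x, low_bpm, high_bpm, sample_rate = 4, order = 6) {
  if (!is.numeric(x)) stop("x must be numeric")
  nyq_bpm <- sample_rate / 2 * 60
  if (low_bpm < 0 || low_bpm >= high_bpm || high_bpm >= nyq_bpm)
    stop("band edges must satisfy 0 <= low < high < Nyquist (", nyq_bpm,
         " cycles/min)")
  if (length(x) <= 3 * order)
    stop("series too short for filtering: need more than ", 3 * order,
         " samples, got ", length(x))
  y <- x
  if (low_bpm > 0)
    y <- sos_filtfilt(butter_sos(order, low_bpm / 60, sample_rate, "high"), y)
  y <- sos_filtfilt(butter_sos(order, high_bpm / 60, sample_rate, "low"), y)
  y
}

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal x + i H(x), with the Hilbert transform H
#' computed by the standard FFT construction (positive frequencies doubled,
#' negative frequencies zeroed). The envelope tracks the slowly varying
#' amplitude of an oscillatory signal and always dominates its absolute
#' value.
#'
#' @param x numeric series.
#' @return nonnegative numeric series of the same length.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}
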