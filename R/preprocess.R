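#' Filter band specifications
#'
#' The four signal variants used throughout the pipeline, as 4th-order
#' Butterworth band-pass bands plus a powerline notch cascade:
#' \describe{
#'   \item{eng}{250-7500 Hz, the intraneural multiunit band.}
#'   \item{imemg}{50-350 Hz, inter-muscular EMG picked up by the
#'     intraneural contacts.}
#'   \item{eng_only}{350-7500 Hz, neural band with all residual muscular
#'     content excluded.}
#'   \item{hybrid}{50-7500 Hz, neural plus inter-muscular content.}
#' }
#'
#' @param band Band name.
#' @param order Butterworth design order (pole pairs per band edge).
#' @param low,high Cutoff overrides in Hz (defaults come from the named
#'   band).
#' @param notch_base_hz,notch_q,notch_max_hz Powerline notch cascade:
#'   harmonics of `notch_base_hz` up to `notch_max_hz` (and below the
#'   Nyquist frequency), each an IIR biquad with quality factor
#'   `notch_q` = center frequency / bandwidth.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(band = c("eng", "imemg", "eng_only", "hybrid"),
                        order = 4, low = NULL, high = NULL,
                        notch_base_hz = 50, notch_q = 100,
                        notch_max_hz = 10000) {
  band <- match.arg(band)
  cut <- switch(band,
    eng = c(250, 7500),
    imemg = c(50, 350),
    eng_only = c(350, 7500),
    hybrid = c(50, 7500))
  if (!is.null(low)) cut[1] <- low
  if (!is.null(high)) cut[2] <- high
  stopifnot(order >= 1, cut[1] < cut[2])
  structure(list(band_name = band, low = cut[1], high = cut[2],
                 order = order, notch_base_hz = notch_base_hz,
                 notch_q = notch_q, notch_max_hz = notch_max_hz),
            class = "filter_spec")
}

#' Butterworth band-pass as second-order sections
#'
#' Designs a digital Butterworth band-pass of design order `order`
#' (2*`order` poles) directly in second-order-section form: analog
#' prototype poles, band transformation and bilinear mapping are applied
#' pole by pole, so no high-order polynomial is ever formed. This keeps
#' the design numerically sound for narrow bands at high sampling rates,
#' where transfer-function coefficients are ill-conditioned.
#'
#' @param order Design order (scipy convention: a band-pass of design
#'   order N has 2N poles).
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return An n x 6 matrix of sections `(b0 b1 b2 a0 a1 a2)`, `a0 = 1`.
#' @export
butter_bandpass_sos <- function(order, low, high, fs) {
  if (high >= fs / 2) stop("high cutoff ", high, " >= Nyquist ", fs / 2)
  if (low <= 0 || low >= high) stop("invalid band edges")
  n <- order
  # analog low-pass prototype poles on the unit Butterworth circle
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped band edges and low-pass -> band-pass transform constants
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # each prototype pole yields two analog band-pass poles
  poles <- c(vapply(proto, function(p) {
    disc <- sqrt(as.complex((p * bw)^2 - 4 * w0^2))
    (p * bw + disc) / 2
  }, complex(1)), vapply(proto, function(p) {
    disc <- sqrt(as.complex((p * bw)^2 - 4 * w0^2))
    (p * bw - disc) / 2
  }, complex(1)))
  K <- 2 * fs
  zpoles <- (K + poles) / (K - poles)
  # pair conjugates into biquads; each gets one zero at +1, one at -1
  pos <- zpoles[Im(zpoles) > 1e-12]
  real <- sort(Re(zpoles[abs(Im(zpoles)) <= 1e-12]))
  sos <- matrix(0, nrow = 0, ncol = 6)
  for (p in pos) {
    sos <- rbind(sos, c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2))
  }
  while (length(real) >= 2) {
    p1 <- real[1]; p2 <- real[length(real)]
    real <- real[-c(1, length(real))]
    sos <- rbind(sos, c(1, 0, -1, 1, -(p1 + p2), p1 * p2))
  }
  if (nrow(sos) != n) stop("internal error: expected ", n, " sections")
  # normalize gain to 1 at the (warped) analog center frequency
  fc <- fs / pi * atan(w0 / (2 * fs))
  g <- Mod(sos_response(sos, fc, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

#' Notch biquad cascade at powerline harmonics
#'
#' Standard constrained-zero IIR notch biquads at 50, 100, ... Hz up to
#' `notch_max_hz` (harmonics at or above Nyquist are skipped).
#'
#' @inheritParams butter_bandpass_sos
#' @param spec A [filter_spec()].
#' @return n x 6 SOS matrix, or `NULL` if no harmonic is applicable.
#' @export
notch_sos <- function(fs, spec = filter_spec("eng")) {
  n_h <- floor(min(spec$notch_max_hz, fs / 2 - 1e-6) /
                 spec$notch_base_hz)
  if (n_h < 1) return(NULL)
  f0s <- spec$notch_base_hz * seq_len(n_h)
  t(vapply(f0s, function(f0) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * spec$notch_q)
    a0 <- 1 + alpha
    c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
      1, -2 * cos(w0) / a0, (1 - alpha) / a0)
  }, numeric(6)))
}

#' Complex frequency response of an SOS cascade
#'
#' @param sos n x 6 SOS matrix.
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Complex vector of the cascade response at `f`.
#' @export
sos_response <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  h
}

# zero-phase (forward-backward) SOS filtering with odd-reflection padding
filtfilt_sos <- function(sos, x) {
  n <- length(x)
  padlen <- min(3L * (2L * nrow(sos) + 1L), n - 1L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- sosfilt_cpp(sos, ext)
  y <- rev(sosfilt_cpp(sos, rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

apply_sos <- function(x, sos) {
  if (is.matrix(x)) {
    sos_filtfilt_mat_cpp(sos, x)
  } else {
    filtfilt_sos(sos, x)
  }
}

#' Remove powerline interference
#'
#' Zero-phase cascade of IIR notch biquads at multiples of the powerline
#' frequency. If no harmonic lies below Nyquist the signal is returned
#' unchanged with a warning.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same shape as `x`.
#' @export
notch_powerline <- function(x, fs, spec = filter_spec("eng")) {
  if (fs <= 2 * spec$notch_base_hz) {
    warning("no powerline harmonic below Nyquist at fs = ", fs,
            " Hz; returning signal unchanged")
    return(x)
  }
  sos <- notch_sos(fs, spec)
  apply_sos(x, sos)
}

#' Band-pass filter a signal
#'
#' 4th-order Butterworth band-pass, applied zero-phase
#' (forward-backward), so the effective magnitude response is the squared
#' design response and the phase is zero. DC and drift are rejected.
#'
#' @inheritParams notch_powerline
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec("eng")) {
  sos <- butter_bandpass_sos(spec$order, spec$low, spec$high, fs)
  apply_sos(x, sos)
}

#' Preprocess a recording into one of the band variants
#'
#' Powerline notch first, then the Butterworth band-pass of the requested
#' variant; both zero-phase. The notch-first order matters for the imEMG
#' band, whose passband contains powerline harmonics.
#'
#' @param recording An `eng_recording`.
#' @param band Band name, see [filter_spec()].
#' @param notch Apply the powerline notch cascade first.
#' @return A new `eng_recording` with filtered samples.
#' @export
preprocess_recording <- function(recording, band = "eng", notch = TRUE) {
  spec <- filter_spec(band)
  x <- recording$data
  if (notch) x <- notch_powerline(x, recording$fs, spec)
  x <- bandpass_filter(x, recording$fs, spec)
  eng_recording(x, fs = recording$fs, channels = recording$channels,
                subject_id = recording$subject_id)
}
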