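## Photometry preprocessing: lock-in demodulation of frequency-multiplexed
## LED channels, FFT-domain isosbestic subtraction, and delta-F/F
## normalisation against a session-scale total-fluorescence trend.

#' Demodulation configuration
#'
#' Carrier frequencies of the frequency-multiplexed LEDs and the baseband
#' output rate. Defaults follow the standard acquisition setup: 470 nm LED
#' modulated at 211 Hz, 405 nm isosbestic LED at 539 Hz, raw photoreceiver
#' signal sampled at 6.1 kHz, baseband output at 1017 Hz.
#'
#' @param carrier_470 carrier of the calcium-dependent channel (Hz).
#' @param carrier_405 carrier of the isosbestic channel (Hz).
#' @param lowpass_cutoff low-pass cutoff of the lock-in filter (Hz). The
#'   filter is a 4th-order zero-phase Butterworth; the first and last 0.5 s
#'   are filter-settling regions.
#' @param output_rate baseband sampling rate (Hz).
#' @return a list with class \code{"DemodConfig"}.
#' @export
demodConfig <- function(carrier_470 = 211, carrier_405 = 539,
                        lowpass_cutoff = 20, output_rate = 1017) {
  if (carrier_470 == carrier_405) stop("carriers must be distinct")
  if (min(carrier_470, carrier_405) <= 2 * lowpass_cutoff)
    stop("carriers must exceed twice the low-pass cutoff")
  if (output_rate < 2 * lowpass_cutoff)
    stop("output_rate must be at least twice the low-pass cutoff")
  structure(list(carrier_470 = carrier_470, carrier_405 = carrier_405,
                 lowpass_cutoff = lowpass_cutoff, output_rate = output_rate),
            class = "DemodConfig")
}

## zero-phase 4th-order Butterworth low-pass
.butter_lowpass <- function(x, cutoff, fs) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

#' Lock-in demodulation of a carrier-modulated photometry signal
#'
#' Recovers the baseband fluorescence of each LED from the raw modulated
#' photoreceiver signal by quadrature (sine + cosine reference) demodulation
#' at each carrier, low-pass filtering, and resampling to the baseband rate.
#' Amplitude-calibrated: a pure tone \eqn{A \sin(2\pi f_c t)} demodulates to
#' the constant \eqn{A}.
#'
#' @param raw a \linkS4class{PhotometrySignal} sampled above twice the
#'   highest carrier (either a single modulated channel or the summed
#'   photoreceiver signal carrying both carriers).
#' @param config a \code{\link{demodConfig}}.
#' @return list with elements \code{sig470} and \code{sig405}, baseband
#'   \linkS4class{PhotometrySignal}s at \code{config$output_rate}; each
#'   carries an attribute \code{settling_s = 0.5} marking the filter-settling
#'   margin at both ends.
#' @export
demodulate <- function(raw, config = demodConfig()) {
  stopifnot(is(raw, "PhotometrySignal"))
  fs <- raw@sample_rate
  fmax <- max(config$carrier_470, config$carrier_405)
  if (fs <= 2 * fmax)
    stop("carrier at or above Nyquist: sample rate ", fs,
         " Hz cannot carry ", fmax, " Hz")
  t <- raw@timestamps
  x <- raw@values
  demod_one <- function(fc) {
    i_comp <- .butter_lowpass(x * sin(2 * pi * fc * t), config$lowpass_cutoff, fs)
    q_comp <- .butter_lowpass(x * cos(2 * pi * fc * t), config$lowpass_cutoff, fs)
    2 * sqrt(i_comp^2 + q_comp^2)
  }
  a470 <- demod_one(config$carrier_470)
  a405 <- demod_one(config$carrier_405)
  t_out <- seq(t[1], t[length(t)], by = 1 / config$output_rate)
  mk <- function(a, label) {
    out <- PhotometrySignal(stats::approx(t, a, xout = t_out)$y,
                            sample_rate = config$output_rate,
                            channel_label = label, timestamps = t_out)
    attr(out, "settling_s") <- 0.5
    out
  }
  list(sig470 = mk(a470, "470_demod"), sig405 = mk(a405, "405_demod"))
}

## forward FFT low-pass: keeps bins with |f| <= cutoff. Reflection padding to
## a 2-3-5-smooth length keeps the transform O(n log n) for any n and avoids
## wrap-around edge artifacts.
.fft_lowpass <- function(x, cutoff, fs) {
  n <- length(x)
  m <- stats::nextn(2L * n, c(2L, 3L, 5L))
  pad <- c(x, rev(x), rep(x[1], m - 2L * n))
  freq <- (seq_len(m) - 1L) / m * fs
  freq <- pmin(freq, fs - freq)            # two-sided
  xf <- stats::fft(pad)
  xf[freq > cutoff] <- 0
  Re(stats::fft(xf, inverse = TRUE) / m)[seq_len(n)]
}

#' FFT-domain isosbestic correction
#'
#' Transforms both channels to the frequency domain, subtracts the 405 nm
#' (calcium-independent) spectrum from the 470 nm spectrum bin-wise, and
#' inverse-transforms. Shared artifacts (motion, autofluorescence drift)
#' present with equal gain in both channels cancel; the operation is linear
#' and mathematically identical to time-domain subtraction.
#'
#' @param sig470,sig405 \linkS4class{PhotometrySignal}s on the same grid.
#' @param scale_405 if TRUE, least-squares fit the 405 channel onto the 470
#'   channel before subtracting (for recordings where channel gains differ);
#'   default FALSE, i.e. literal unit-gain subtraction.
#' @return a \linkS4class{PhotometrySignal} with label \code{"corrected"};
#'   attribute \code{provenance} records method and parameters.
#' @export
fftSubtractCorrect <- function(sig470, sig405, scale_405 = FALSE) {
  stopifnot(is(sig470, "PhotometrySignal"), is(sig405, "PhotometrySignal"))
  if (length(sig470@values) != length(sig405@values))
    stop("channel length mismatch")
  if (max(abs(sig470@timestamps - sig405@timestamps)) > 1e-9)
    stop("channels must share one time grid")
  v405 <- sig405@values
  beta <- 1
  if (scale_405) {
    beta <- stats::coef(stats::lm(sig470@values ~ v405))[["v405"]]
    v405 <- beta * v405
  }
  n <- length(v405)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  padded <- function(v) c(v, rep(0, m - n))
  diff_f <- stats::fft(padded(sig470@values)) - stats::fft(padded(v405))
  out_c <- stats::fft(diff_f, inverse = TRUE)[seq_len(n)] / m
  if (max(Mod(Im(out_c))) > 1e-9 * max(sqrt(mean(Mod(out_c)^2)), 1e-300))
    warning("unexpected imaginary residue after inverse FFT")
  out <- PhotometrySignal(Re(out_c), sample_rate = sig470@sample_rate,
                          channel_label = "corrected",
                          timestamps = sig470@timestamps)
  attr(out, "provenance") <- list(method = "fft_subtract",
                                  scale_405 = scale_405, beta_405 = beta)
  out
}

#' Delta-F-over-F normalisation
#'
#' Expresses the corrected signal as a change in fluorescence relative to
#' total fluorescence: \eqn{dF/F(t) = corrected(t) / F_0(t)}, where
#' \eqn{F_0} is the session-scale (very-low-frequency) trend of the 470 nm
#' channel, capturing total fluorescence including photobleaching.
#' Invariant under common rescaling of both inputs.
#'
#' @param corrected the \code{"corrected"} \linkS4class{PhotometrySignal}.
#' @param sig470 the 470 nm baseband channel on the same grid.
#' @param f0_cutoff low-pass cutoff defining the trend (Hz); default 0.001.
#' @param f0_method \code{"lowpass"} (default) or \code{"mean"} (session-mean
#'   F0).
#' @return a \linkS4class{PhotometrySignal} with label \code{"dff"}.
#' @export
deltaFOverF <- function(corrected, sig470, f0_cutoff = 0.001,
                        f0_method = c("lowpass", "mean")) {
  stopifnot(is(corrected, "PhotometrySignal"), is(sig470, "PhotometrySignal"))
  f0_method <- match.arg(f0_method)
  if (length(corrected@values) != length(sig470@values) ||
      max(abs(corrected@timestamps - sig470@timestamps)) > 1e-9)
    stop("corrected and 470 channels must share one grid")
  f0 <- switch(f0_method,
               lowpass = .fft_lowpass(sig470@values, f0_cutoff,
                                      sig470@sample_rate),
               mean = rep(mean(sig470@values), length(sig470@values)))
  if (any(f0 <= 0)) stop("non-physical total fluorescence: F0 <= 0")
  PhotometrySignal(corrected@values / f0, sample_rate = corrected@sample_rate,
                   channel_label = "dff", timestamps = corrected@timestamps)
}

#' Run the full preprocessing chain on a session
#'
#' Dispatches on the channels present: raw carrier-modulated channels are
#' demodulated first (the two stored modulated channels are summed back into
#' the composite photoreceiver signal); sessions that already hold baseband
#' channels go straight to FFT-domain correction and dF/F.
#'
#' @param session a \linkS4class{PhotometrySession}.
#' @param config a \code{\link{demodConfig}} (used only for raw-stage input).
#' @param f0_cutoff,f0_method passed to \code{\link{deltaFOverF}}.
#' @param scale_405 passed to \code{\link{fftSubtractCorrect}}.
#' @return the session with \code{"corrected"} and \code{"dff"} channels
#'   added (and demodulated channels, when starting from raw).
#' @export
preprocessSession <- function(session, config = demodConfig(),
                              f0_cutoff = 0.001, f0_method = "lowpass",
                              scale_405 = FALSE) {
  stopifnot(is(session, "PhotometrySession"))
  labs <- names(session@signals)
  if (all(c("470_demod", "405_demod") %in% labs)) {
    s470 <- session@signals[["470_demod"]]
    s405 <- session@signals[["405_demod"]]
  } else {
    raw470 <- session@signals[["470_raw"]]
    raw405 <- session@signals[["405_raw"]]
    composite <- PhotometrySignal(raw470@values + raw405@values,
                                  sample_rate = raw470@sample_rate,
                                  channel_label = "470_raw",
                                  timestamps = raw470@timestamps)
    dem <- demodulate(composite, config)
    s470 <- dem$sig470
    s405 <- dem$sig405
    session@signals[["470_demod"]] <- s470
    session@signals[["405_demod"]] <- s405
  }
  corrected <- fftSubtractCorrect(s470, s405, scale_405 = scale_405)
  session@signals[["corrected"]] <- corrected
  session@signals[["dff"]] <- deltaFOverF(corrected, s470,
                                          f0_cutoff = f0_cutoff,
                                          f0_method = f0_method)
  session
}
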