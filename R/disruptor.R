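#' Synthesize a pure tone (PT)
#'
#' One of the three artificial disruptive-signal types: an unmodulated
#' sinusoid, \code{samples[k] = amplitude * sin(2 pi f k / sample_rate)}.
#' The screening study used 150, 225 and 300 Hz, spanning the female
#' courtship band; 225 Hz proved the most disruptive.
#'
#' @param frequency Tone frequency, Hz; must be below Nyquist.
#' @param duration Duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param amplitude Peak amplitude.
#' @param label Optional class tag (defaults to \code{"PT<frequency>"}).
#' @return A [wave_signal()].
#' @export
gen_pure_tone <- function(frequency, duration, sample_rate = 8000,
                          amplitude = 1, label = NULL) {
  if (frequency <= 0 || frequency >= sample_rate / 2)
    stop(sprintf(
      "gen_pure_tone: Nyquist violation: frequency = %g Hz, sample_rate = %g Hz",
      frequency, sample_rate))
  if (duration <= 0) stop("gen_pure_tone: duration must be > 0")
  n <- round(duration * sample_rate)
  t <- (0:(n - 1)) / sample_rate
  if (is.null(label)) label <- sprintf("PT%g", frequency)
  wave_signal(amplitude * sin(2 * pi * frequency * t), sample_rate, label = label)
}

#' Synthesize a continuous pulse signal (CPS)
#'
#' The second disruptive-signal type, built the same way as the female
#' courtship signal: a standard sine wave "filled" with a triangular pulse
#' envelope, at a constant pulse rate of 22 Hz in the screening study.
#'
#' @param frequency Carrier (MVF) frequency, Hz.
#' @param pulse_rate Triangular-envelope repetition rate, Hz (default 22).
#' @param duration Duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param amplitude Peak amplitude.
#' @param duty Envelope duty cycle in (0, 1].
#' @param label Optional class tag (defaults to \code{"CPS<frequency>"}).
#' @return A [wave_signal()].
#' @export
gen_cps <- function(frequency, pulse_rate = 22, duration = 2,
                    sample_rate = 8000, amplitude = 1, duty = 0.8,
                    label = NULL) {
  if (frequency <= 2 * pulse_rate)
    stop(sprintf("gen_cps: carrier %g Hz must exceed 2 x pulse rate (%g Hz)",
                 frequency, pulse_rate))
  if (is.null(label)) label <- sprintf("CPS%g", frequency)
  gen_pulse_train(frequency, pulse_rate, duration, sample_rate,
                  amplitude = amplitude, duty = duty, label = label)
}

#' Synthesize white Gaussian noise (WGN)
#'
#' The third disruptive-signal type: i.i.d. Gaussian samples with variance
#' \code{10^(power_dbw / 10)}. The 0 dBW convention maps to unit variance in
#' dimensionless amplitude units (1 W into unit impedance).
#'
#' @param power_dbw Noise power in dBW (default 0).
#' @param duration Duration, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional integer seed.
#' @return A [wave_signal()] labelled \code{"WGN"}.
#' @export
gen_wgn <- function(power_dbw = 0, duration = 2, sample_rate = 8000,
                    seed = NULL) {
  if (duration <= 0) stop("gen_wgn: duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sample_rate)
  sd <- sqrt(10^(power_dbw / 10))
  wave_signal(stats::rnorm(n, sd = sd), sample_rate, label = "WGN")
}

#' The seven artificial disruptive signals
#'
#' Generates the full screening set: pure tones at 150/225/300 Hz, continuous
#' pulse signals at a 22 Hz pulse rate with carriers 150/225/300 Hz, and
#' 0 dBW white Gaussian noise. Labels are the condition codes used throughout
#' the behavioral module (\code{PT150} ... \code{WGN}).
#'
#' @param duration Duration of each signal (one played syllable), seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Seed for the WGN component.
#' @param rms_normalize If \code{TRUE}, rescale every signal to RMS 1 so all
#'   seven are played at equal intensity.
#' @return A named list of 7 [wave_signal()] objects.
#' @export
make_all_seven <- function(duration = 2, sample_rate = 8000, seed = NULL,
                           rms_normalize = FALSE) {
  sigs <- list(
    PT150 = gen_pure_tone(150, duration, sample_rate, label = "PT150"),
    PT225 = gen_pure_tone(225, duration, sample_rate, label = "PT225"),
    PT300 = gen_pure_tone(300, duration, sample_rate, label = "PT300"),
    CPS150 = gen_cps(150, 22, duration, sample_rate, label = "CPS150"),
    CPS225 = gen_cps(225, 22, duration, sample_rate, label = "CPS225"),
    CPS300 = gen_cps(300, 22, duration, sample_rate, label = "CPS300"),
    WGN = gen_wgn(0, duration, sample_rate, seed = seed)
  )
  if (rms_normalize)
    sigs <- lapply(sigs, function(w) {
      w$samples <- w$samples / wave_rms(w)
      w
    })
  sigs
}

#' Mix a courtship signal with a disruptive signal at uniform intensity
#'
#' Playback trials present the pre-recorded courtship signal and the
#' disruptive signal mixed "according to a uniform intensity", interpreted
#' here as equal RMS: both components are rescaled to RMS 1 before summation
#' (component RMS ratio exactly 1), and the mixture is peak-normalized to
#' \code{peak} to avoid clipping. A peak-equal matching is available for
#' comparison.
#'
#' @param courtship A [wave_signal()].
#' @param disruptive A [wave_signal()] at the same sample rate; tiled or
#'   truncated to the courtship duration.
#' @param match \code{"rms"} (default) or \code{"peak"} intensity matching.
#' @param peak Peak amplitude of the normalized mixture.
#' @return A [wave_signal()] labelled from both components.
#' @export
mix_uniform_intensity <- function(courtship, disruptive, match = c("rms", "peak"),
                                  peak = 0.9) {
  stopifnot(inherits(courtship, "wave_signal"), inherits(disruptive, "wave_signal"))
  match <- match.arg(match)
  if (courtship$sample_rate != disruptive$sample_rate)
    stop(sprintf(
      "mix_uniform_intensity: sample-rate mismatch (%g vs %g Hz); no implicit resampling",
      courtship$sample_rate, disruptive$sample_rate))
  n <- length(courtship$samples)
  d <- rep_len(disruptive$samples, n)
  scale_of <- function(x) {
    s <- if (match == "rms") sqrt(mean(x^2)) else max(abs(x))
    if (s == 0) 1 else s
  }
  mixed <- courtship$samples / scale_of(courtship$samples) + d / scale_of(d)
  pk <- max(abs(mixed))
  if (pk > 0) mixed <- mixed * (peak / pk)
  lab <- paste(c(courtship$label, disruptive$label), collapse = "+")
  wave_signal(mixed, courtship$sample_rate,
              label = if (nzchar(lab)) lab else NULL)
}
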