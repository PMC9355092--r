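#' Design the Chebyshev band-pass front end
#'
#' Digital emulation of the recording chain's Chebyshev type-I sixth-order
#' active band-pass filter. The total band-pass order is \code{order} (three
#' biquads for the default 6), designed with \code{signal::cheby1}.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param low,high Band edges, Hz; \code{0 < low < high < sample_rate/2}.
#' @param order Total band-pass filter order (even; default 6).
#' @param ripple_db Passband ripple, dB (default 0.5).
#' @return A \code{signal::Arma} filter object (coefficients \code{b}, \code{a}).
#' @export
design_bandpass <- function(sample_rate, low = 100, high = 500, order = 6,
                            ripple_db = 0.5) {
  if (!(low > 0 && low < high && high < sample_rate / 2))
    stop(sprintf(
      "design_bandpass: need 0 < low < high < sample_rate/2, got (%g, %g) at %g Hz",
      low, high, sample_rate))
  if (order %% 2 != 0 || order < 2)
    stop("design_bandpass: band-pass order must be a positive even number")
  signal::cheby1(order / 2, ripple_db, c(low, high) / (sample_rate / 2),
                 type = "pass")
}

#' Complex frequency response of a digital filter
#'
#' Evaluates \code{H(f) = B(e^{-i 2 pi f / fs}) / A(e^{-i 2 pi f / fs})} by
#' direct polynomial evaluation at the requested frequencies.
#'
#' @param filt A \code{signal::Arma} object (fields \code{b}, \code{a}).
#' @param freqs Frequencies, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @return Complex vector of responses (single-pass; zero-phase application
#'   has magnitude \code{Mod(H)^2}).
#' @export
filter_response <- function(filt, freqs, sample_rate) {
  z <- exp(-2i * pi * freqs / sample_rate)
  # B and A are polynomials in z^-1 with increasing powers; Horner scheme.
  horner <- function(coefs) {
    acc <- rep(0 + 0i, length(z))
    for (c_k in rev(coefs)) acc <- acc * z + c_k
    acc
  }
  horner(as.numeric(filt$b)) / horner(as.numeric(filt$a))
}

#' Zero-phase Chebyshev band-pass filtering
#'
#' Applies the [design_bandpass()] filter forward-backward
#' (\code{signal::filtfilt}), giving zero phase so downstream segmentation
#' boundaries are not delayed; the magnitude response is the square of the
#' single-pass response. The analog original is causal, so this is a
#' deliberate deviation in favour of boundary accuracy.
#'
#' @param w A [wave_signal()].
#' @inheritParams design_bandpass
#' @return The filtered [wave_signal()].
#' @export
bandpass_filter <- function(w, low = 100, high = 500, order = 6,
                            ripple_db = 0.5) {
  stopifnot(inherits(w, "wave_signal"))
  filt <- design_bandpass(w$sample_rate, low, high, order, ripple_db)
  y <- signal::filtfilt(filt, w$samples)
  wave_signal(y, w$sample_rate, label = w$label)
}

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(max(2, n)))

#' One-sided magnitude spectrum
#'
#' FFT magnitude spectrum with optional zero-padding and windowing. With the
#' default rectangular window and \code{n_fft} a power of two at least
#' \code{pad_factor} times the signal length, spectral peaks can be localized
#' to a small fraction of the native resolution via [estimate_mvf()]'s
#' quadratic interpolation.
#'
#' @param w A [wave_signal()].
#' @param n_fft FFT length; default next power of two \code{>= pad_factor *
#'   length(samples)}.
#' @param window \code{"rect"} (default) or \code{"hann"}.
#' @param pad_factor Zero-padding factor used when \code{n_fft} is NULL.
#' @return A data frame with columns \code{freq} (Hz, 0..Nyquist) and
#'   \code{mag} (linear magnitude \code{|X(f)|}).
#' @export
power_spectrum <- function(w, n_fft = NULL, window = c("rect", "hann"),
                           pad_factor = 8) {
  stopifnot(inherits(w, "wave_signal"))
  window <- match.arg(window)
  x <- w$samples
  n <- length(x)
  if (n == 0L) stop("power_spectrum: empty signal")
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  if (is.null(n_fft)) n_fft <- next_pow2(pad_factor * n)
  if (n_fft < n) stop("power_spectrum: n_fft must be >= signal length")
  X <- stats::fft(c(x, numeric(n_fft - n)))
  half <- 1:(n_fft / 2 + 1)
  data.frame(freq = (half - 1) * w$sample_rate / n_fft, mag = Mod(X)[half])
}

# Parabolic refinement of a spectral peak: offset of the apex of the parabola
# through (m_l, m_c, m_r), in bins, clamped to half a bin.
parabolic_offset <- function(m_l, m_c, m_r) {
  denom <- m_l - 2 * m_c + m_r
  if (denom == 0) return(0)
  max(-0.5, min(0.5, 0.5 * (m_l - m_r) / denom))
}

# argmax of mag within [band[1], band[2]] with quadratic interpolation; ties
# broken toward the lowest frequency. spec = output of power_spectrum.
peak_frequency <- function(spec, band) {
  in_band <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(in_band)) stop("peak_frequency: empty analysis band")
  mag <- spec$mag
  idx_band <- which(in_band)
  mb <- mag[idx_band]
  if (max(mb) <= 1e-12 * max(1, max(mag)))
    stop("no spectral peak detectable in band (no energy)")
  i <- idx_band[which.max(mb)]          # which.max: first (lowest-f) max on ties
  df <- spec$freq[2] - spec$freq[1]
  delta <- if (i > 1 && i < length(mag))
    parabolic_offset(mag[i - 1], mag[i], mag[i + 1]) else 0
  spec$freq[i] + delta * df
}

#' Estimate the main vibration frequency (MVF)
#'
#' The MVF is the dominant spectral peak within the analysis band: the
#' maximum-magnitude FFT bin in \code{band}, refined by quadratic
#' interpolation over the three bins around the peak. Ties break toward the
#' lowest frequency.
#'
#' @param w A [wave_signal()].
#' @param band Analysis band (low, high) in Hz; the default (100, 500)
#'   covers all reported BPH carrier frequencies with margin.
#' @param pad_factor Zero-padding factor for the underlying FFT.
#' @return Estimated MVF, Hz. Errors if the band holds no energy.
#' @examples
#' estimate_mvf(gen_pure_tone(225, 1))
#' @export
estimate_mvf <- function(w, band = c(100, 500), pad_factor = 8) {
  spec <- power_spectrum(w, pad_factor = pad_factor)
  tryCatch(peak_frequency(spec, band),
           error = function(e) stop("estimate_mvf: no MVF detectable in band [",
                                    band[1], ", ", band[2], "] Hz", call. = FALSE))
}

# Amplitude envelope via the analytic-signal magnitude (FFT Hilbert
# transform), optionally smoothed by a centered moving average.
hilbert_envelope <- function(x, smooth_n = 0L) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smooth_n > 1L) {
    k <- rep(1 / smooth_n, smooth_n)
    sm <- stats::filter(env, k, sides = 2)
    env <- ifelse(is.na(sm), env, as.numeric(sm))
  }
  env
}

#' Estimate the pulse rate (PR)
#'
#' The pulse rate is the repetition frequency of the amplitude pulses
#' modulating the carrier: the amplitude envelope is computed (analytic-signal
#' magnitude by default, or rectify + low-pass), its mean removed, and the
#' dominant envelope-spectrum frequency within \code{pr_band} returned with
#' quadratic peak interpolation. Unmodulated inputs (envelope modulation
#' depth, sd/mean, below \code{min_depth}) return \code{NA}.
#'
#' @param w A [wave_signal()].
#' @param pr_band Envelope-spectrum search band (low, high), Hz.
#' @param method \code{"hilbert"} (default) or \code{"rectify"}.
#' @param min_depth Minimum envelope modulation depth; below it the signal is
#'   treated as unmodulated.
#' @param pad_factor Zero-padding factor for the envelope FFT.
#' @return Estimated pulse rate in Hz, or \code{NA_real_} when no amplitude
#'   modulation is detectable.
#' @examples
#' estimate_pulse_rate(gen_cps(150, 22, duration = 2))
#' @export
estimate_pulse_rate <- function(w, pr_band = c(5, 60),
                                method = c("hilbert", "rectify"),
                                min_depth = 0.05, pad_factor = 8) {
  stopifnot(inherits(w, "wave_signal"))
  method <- match.arg(method)
  if (wave_duration(w) < 10 / pr_band[1])
    stop(sprintf(
      "estimate_pulse_rate: need >= 10 pulse periods at %g Hz (>= %.1f s), got %.2f s",
      pr_band[1], 10 / pr_band[1], wave_duration(w)))
  env <- if (method == "hilbert") {
    hilbert_envelope(w$samples)
  } else {
    # full-wave rectify then moving-average low-pass at ~2x the band top
    k <- max(3L, round(w$sample_rate / (2 * pr_band[2])))
    hilbert_envelope(abs(w$samples), smooth_n = k)
  }
  m <- mean(env)
  if (m <= 0 || stats::sd(env) / m < min_depth) return(NA_real_)
  ew <- wave_signal(env - m, w$sample_rate)
  spec <- power_spectrum(ew, pad_factor = pad_factor)
  tryCatch(peak_frequency(spec, pr_band), error = function(e) NA_real_)
}

# Envelope-threshold pulse detection. Returns a data.frame of half-open
# [start, end) sample intervals (0-based). Pulses separated by gaps shorter
# than `hysteresis` seconds are merged; detections narrower than `min_width`
# seconds are dropped.
detect_pulses <- function(w, threshold_frac = 0.2, hysteresis = 0.010,
                          min_width = 0.001, smooth_s = 0.002) {
  sr <- w$sample_rate
  env <- hilbert_envelope(w$samples, smooth_n = max(1L, round(smooth_s * sr)))
  thr <- threshold_frac * stats::quantile(env, 0.95, names = FALSE)
  above <- env > thr
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  # merge across sub-hysteresis gaps
  if (nrow(runs) > 1) {
    gap <- runs$start[-1] - runs$end[-nrow(runs)]
    keep_break <- gap >= round(hysteresis * sr)
    grp <- cumsum(c(TRUE, keep_break))
    runs <- data.frame(
      start = tapply(runs$start, grp, min),
      end = tapply(runs$end, grp, max)
    )
    rownames(runs) <- NULL
  }
  runs <- runs[runs$end - runs$start >= round(min_width * sr), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Segment a multi-part male signal
#'
#' Envelope-threshold pulse detection followed by part grouping. At the
#' package's duty cycle the continuous pulse train's inter-pulse gaps fall
#' below the merge hysteresis, so the train appears as the single longest
#' envelope block; discrete pulses before it form part a (irregular pulses)
#' and, for male courtship, pulses after it form part c (wide pulses). For
#' competition signals the train is part a and trailing short pulses are
#' part b. The continuous train's pulse count is reported as \code{NA} (its
#' pulses are not individually resolved; use [estimate_pulse_rate()]).
#'
#' @param w A [wave_signal()].
#' @param class_hint \code{"male_courtship"} or \code{"male_competition"}.
#' @param threshold_frac Envelope threshold as a fraction of the envelope's
#'   95th percentile.
#' @param hysteresis Merge gap, seconds.
#' @param min_width Minimum detected pulse width, seconds.
#' @return A data frame with columns \code{part}, \code{start}, \code{end}
#'   (0-based half-open sample intervals) and \code{n_pulses}; zero rows when
#'   no pulses are detected.
#' @export
segment_signal <- function(w, class_hint = c("male_courtship", "male_competition"),
                           threshold_frac = 0.2, hysteresis = 0.010,
                           min_width = 0.001) {
  stopifnot(inherits(w, "wave_signal"))
  class_hint <- match.arg(class_hint)
  pulses <- detect_pulses(w, threshold_frac, hysteresis, min_width)
  empty <- data.frame(part = character(0), start = integer(0),
                      end = integer(0), n_pulses = integer(0))
  if (nrow(pulses) == 0) return(empty)
  i_train <- which.max(pulses$end - pulses$start)
  before <- pulses[seq_len(nrow(pulses)) < i_train, , drop = FALSE]
  after <- pulses[seq_len(nrow(pulses)) > i_train, , drop = FALSE]
  train <- pulses[i_train, ]
  interval_of <- function(p) if (nrow(p) == 0) c(NA_integer_, NA_integer_) else
    c(min(p$start), max(p$end))

  if (class_hint == "male_courtship") {
    a <- interval_of(before); cc <- interval_of(after)
    out <- data.frame(
      part = c("a", "b", "c"),
      start = c(a[1], train$start, cc[1]),
      end = c(a[2], train$end, cc[2]),
      n_pulses = c(nrow(before), NA_integer_, nrow(after))
    )
    out[!(is.na(out$start) & out$part != "b"), , drop = FALSE]
  } else {
    b <- interval_of(after)
    out <- data.frame(
      part = c("a", "b"),
      start = c(train$start, b[1]),
      end = c(train$end, b[2]),
      n_pulses = c(NA_integer_, nrow(after))
    )
    out[!is.na(out$start), , drop = FALSE]
  }
}

#' Summarize a synthetic corpus: per-class MVF and PR
#'
#' Runs the estimators over every signal of a corpus (as produced by
#' [gen_corpus()]) and aggregates per class as mean +/- SD, reproducing the
#' descriptive style of the recorded-signal analysis (e.g. "236 +/- 43 Hz").
#' Female signals are analyzed whole; male courtship signals are segmented
#' and the part-b train analyzed; competition signals likewise for part a.
#'
#' @param corpus Either the list returned by [gen_corpus()] or a corpus
#'   directory containing WAVs plus \code{ground_truth.csv}.
#' @param band MVF analysis band, Hz.
#' @param out_csv Optional path; when given, the summary is also written as
#'   CSV.
#' @return A list with \code{per_signal} (file, class, estimated
#'   \code{mvf_hz}, \code{pulse_rate_hz}) and \code{summary} (per-class n,
#'   mean and sd of both descriptors).
#' @export
summarize_corpus <- function(corpus, band = c(100, 500), out_csv = NULL) {
  if (is.character(corpus)) {
    truth <- utils::read.csv(file.path(corpus, "ground_truth.csv"),
                             stringsAsFactors = FALSE)
    signals <- lapply(truth$file, function(f) read_wav(file.path(corpus, f)))
    names(signals) <- truth$file
  } else {
    truth <- corpus$truth
    signals <- corpus$signals
  }
  if (nrow(truth) < 2) stop("summarize_corpus: need at least 2 signals")
  srs <- vapply(signals, function(w) w$sample_rate, numeric(1))
  if (length(unique(srs)) != 1)
    stop("summarize_corpus: mixed sample rates in corpus")

  est <- lapply(seq_len(nrow(truth)), function(i) {
    w <- signals[[i]]
    cls <- truth$class[i]
    if (cls == "female_courtship") {
      mvf <- estimate_mvf(w, band)
      pr <- estimate_pulse_rate(w)
    } else {
      hint <- if (cls == "male_courtship") "male_courtship" else "male_competition"
      seg <- segment_signal(w, hint)
      tr <- seg[seg$part == ifelse(hint == "male_courtship", "b", "a"), ]
      if (nrow(tr) == 1 && !is.na(tr$start)) {
        ws <- wave_slice(w, tr$start, tr$end)
        mvf <- estimate_mvf(ws, band)
        pr <- tryCatch(estimate_pulse_rate(ws), error = function(e) NA_real_)
      } else {
        mvf <- NA_real_; pr <- NA_real_
      }
    }
    data.frame(file = truth$file[i], class = cls, mvf_hz = mvf,
               pulse_rate_hz = pr, stringsAsFactors = FALSE)
  })
  per_signal <- do.call(rbind, est)

  agg <- lapply(split(per_signal, per_signal$class), function(d) {
    data.frame(
      class = d$class[1], n = nrow(d),
      mvf_mean_hz = mean(d$mvf_hz, na.rm = TRUE),
      mvf_sd_hz = stats::sd(d$mvf_hz, na.rm = TRUE),
      pr_mean_hz = mean(d$pulse_rate_hz, na.rm = TRUE),
      pr_sd_hz = stats::sd(d$pulse_rate_hz, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  if (!is.null(out_csv)) utils::write.csv(summary, out_csv, row.names = FALSE)
  list(per_signal = per_signal, summary = summary)
}
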