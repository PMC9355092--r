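#' Population parameters of the three BPH signal classes
#'
#' Per-individual carrier frequencies (main vibration frequency, MVF) and
#' pulse rates (PR) are modelled as normal across individuals, with the
#' moments reported for the three natural signal classes of *Nilaparvata
#' lugens*: female courtship MVF 236 +/- 43 Hz and PR 23 +/- 2 Hz; male
#' courtship continuous-train (part b) MVF 255 +/- 24 Hz; male competition
#' continuous-train (part a) main frequency 281 +/- 46 Hz. The male pulse
#' rate (82 Hz) is reported only as a mean, so its sd defaults to 0.
#'
#' Draws are truncated at +/- 3 sd (physically implausible tails removed) and
#' re-drawn until the carrier exceeds twice the pulse rate, so every sampled
#' individual has a carrier that oscillates several times within each pulse.
#'
#' @param female_mvf_mean,female_mvf_sd Female courtship MVF moments (Hz).
#' @param female_pr_mean,female_pr_sd Female courtship pulse-rate moments (Hz).
#' @param male_mvf_mean,male_mvf_sd Male courtship part-b MVF moments (Hz).
#' @param male_pr_mean,male_pr_sd Male pulse-rate moments (Hz).
#' @param comp_mvf_mean,comp_mvf_sd Male competition part-a MVF moments (Hz).
#' @param comp_pr_mean,comp_pr_sd Male competition pulse-rate moments (Hz).
#' @param noise_snr_db Signal-to-noise ratio of additive white Gaussian
#'   background noise, in dB (recording-floor emulation).
#' @return A validated list of class \code{population_params}.
#' @export
population_params <- function(female_mvf_mean = 236, female_mvf_sd = 43,
                              female_pr_mean = 23, female_pr_sd = 2,
                              male_mvf_mean = 255, male_mvf_sd = 24,
                              male_pr_mean = 82, male_pr_sd = 0,
                              comp_mvf_mean = 281, comp_mvf_sd = 46,
                              comp_pr_mean = 82, comp_pr_sd = 0,
                              noise_snr_db = 20) {
  p <- list(
    female_mvf_mean = female_mvf_mean, female_mvf_sd = female_mvf_sd,
    female_pr_mean = female_pr_mean, female_pr_sd = female_pr_sd,
    male_mvf_mean = male_mvf_mean, male_mvf_sd = male_mvf_sd,
    male_pr_mean = male_pr_mean, male_pr_sd = male_pr_sd,
    comp_mvf_mean = comp_mvf_mean, comp_mvf_sd = comp_mvf_sd,
    comp_pr_mean = comp_pr_mean, comp_pr_sd = comp_pr_sd,
    noise_snr_db = noise_snr_db
  )
  num <- unlist(p)
  if (!all(is.finite(num))) stop("population_params: all parameters must be finite")
  sds <- num[grepl("_sd$", names(num))]
  if (any(sds < 0)) stop("population_params: standard deviations must be >= 0")
  means <- num[grepl("_mean$", names(num))]
  if (any(means <= 0)) stop("population_params: means must be > 0")
  structure(p, class = "population_params")
}

# Normal draw truncated at +/- 3 sd; re-drawn (then floored) so that the
# result stays strictly above `lower`. Used for per-individual MVF/PR.
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) {
    if (mean <= lower) stop("rnorm_trunc: degenerate draw below lower bound")
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- abs(x - mean) > 3 * sd | x <= lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  if (any(abs(x - mean) > 3 * sd | x <= lower))
    stop("rnorm_trunc: cannot draw above lower bound ", lower,
         " from Normal(", mean, ", ", sd, ")")
  x
}

# Periodic triangular pulse envelope in [0, 1]: within each pulse period
# (1/pulse_rate) a symmetric triangle occupies the leading `duty` fraction
# and the floor is 0 for the remainder.
triangle_envelope <- function(t, pulse_rate, duty = 0.8) {
  u <- (t * pulse_rate) %% 1
  ifelse(u < duty, 1 - abs(2 * u / duty - 1), 0)
}

#' Synthesize a continuous pulse train
#'
#' The deterministic core shared by the natural-signal generators and the
#' artificial CPS disruptive signal: a sine carrier at the main vibration
#' frequency, amplitude-modulated by a periodic triangular envelope repeating
#' at the pulse rate ("filling a standard sine wave with a triangular
#' pulse"). Samples are the exact pointwise product
#' \code{amplitude * env(t) * sin(2 pi mvf t)}, so the peak amplitude equals
#' \code{amplitude} up to the sine phase at the envelope apex.
#'
#' @param mvf Carrier (main vibration) frequency, Hz.
#' @param pulse_rate Envelope repetition rate, Hz; must satisfy
#'   \code{0 < pulse_rate < mvf}.
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate, Hz; must exceed \code{2 * mvf}.
#' @param amplitude Peak amplitude of the envelope.
#' @param duty Fraction of each pulse period occupied by the triangle, in
#'   (0, 1\].
#' @param envelope_shape \code{"triangle"} (default) or \code{"flat"}; a flat
#'   envelope with \code{duty = 1} degenerates to a pure sine.
#' @param label Optional class tag for the result.
#' @return A [wave_signal()].
#' @examples
#' w <- gen_pulse_train(236, 23, duration = 1)
#' estimate_mvf(w)
#' @export
gen_pulse_train <- function(mvf, pulse_rate, duration, sample_rate = 8000,
                            amplitude = 1, duty = 0.8,
                            envelope_shape = c("triangle", "flat"),
                            label = NULL) {
  envelope_shape <- match.arg(envelope_shape)
  if (duration <= 0) stop("gen_pulse_train: duration must be > 0")
  if (amplitude <= 0) stop("gen_pulse_train: amplitude must be > 0")
  if (duty <= 0 || duty > 1) stop("gen_pulse_train: duty must be in (0, 1]")
  if (pulse_rate <= 0 || pulse_rate >= mvf)
    stop(sprintf(
      "gen_pulse_train: need 0 < pulse_rate < mvf, got pulse_rate = %g, mvf = %g",
      pulse_rate, mvf))
  if (sample_rate <= 2 * mvf)
    stop(sprintf(
      "gen_pulse_train: Nyquist violation: mvf = %g Hz needs sample_rate > %g Hz (got %g)",
      mvf, 2 * mvf, sample_rate))
  n <- round(duration * sample_rate)
  t <- (0:(n - 1)) / sample_rate
  env <- if (envelope_shape == "flat") rep(1, n)
         else triangle_envelope(t, pulse_rate, duty)
  wave_signal(amplitude * env * sin(2 * pi * mvf * t), sample_rate, label = label)
}

# Additive white Gaussian noise at a given SNR (dB) relative to the mean
# power of `x` over its full extent (silences included).
add_noise_snr <- function(x, snr_db) {
  p_sig <- mean(x^2)
  if (p_sig == 0 || is.infinite(snr_db)) return(x)
  x + stats::rnorm(length(x), sd = sqrt(p_sig / 10^(snr_db / 10)))
}

#' Generate a synthetic female courtship signal
#'
#' Draws one individual's MVF and pulse rate from the population distribution
#' (truncated normal), builds the continuous pulse train and adds background
#' noise at the configured SNR. The drawn parameters are attached as ground
#' truth (see [signal_truth()]).
#'
#' @param pop A [population_params()].
#' @param duration Signal duration in seconds (one played syllable).
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional integer seed for exact reproducibility.
#' @return A [wave_signal()] labelled \code{"female_courtship"}.
#' @export
gen_female_courtship <- function(pop = population_params(), duration = 2,
                                 sample_rate = 8000, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  pr <- rnorm_trunc(1, pop$female_pr_mean, pop$female_pr_sd, lower = 0)
  mvf <- rnorm_trunc(1, pop$female_mvf_mean, pop$female_mvf_sd, lower = 2 * pr)
  w <- gen_pulse_train(mvf, pr, duration, sample_rate,
                       label = "female_courtship")
  w$samples <- add_noise_snr(w$samples, pop$noise_snr_db)
  set_truth(w, list(class = "female_courtship", mvf = mvf, pulse_rate = pr))
}

# A single pulse: sine carrier under one symmetric triangular envelope of the
# given width (seconds).
single_pulse <- function(mvf, width, amplitude, sample_rate) {
  n <- max(2L, round(width * sample_rate))
  t <- (0:(n - 1)) / sample_rate
  env <- 1 - abs(2 * t / width - 1)
  env[env < 0] <- 0
  amplitude * env * sin(2 * pi * mvf * t)
}

# Assemble [pulse, gap, pulse, ...] sample blocks; returns samples plus the
# half-open [start, end) interval covered by the pulses (0-based).
pulse_group <- function(n_pulses, mvf, width, amp_range, gap_range, sample_rate) {
  if (n_pulses == 0L)
    return(list(samples = numeric(0), n = 0L))
  blocks <- vector("list", 2L * n_pulses - 1L)
  for (i in seq_len(n_pulses)) {
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    blocks[[2L * i - 1L]] <- single_pulse(mvf, width, amp, sample_rate)
    if (i < n_pulses) {
      gap <- stats::runif(1, gap_range[1], gap_range[2])
      blocks[[2L * i]] <- numeric(round(gap * sample_rate))
    }
  }
  list(samples = unlist(blocks), n = n_pulses)
}

#' Generate a synthetic male courtship signal
#'
#' Male courtship signals have three parts: (a) three to ten irregular pulses
#' with randomized amplitudes and spacing, (b) a continuous pulse train whose
#' MVF is drawn from Normal(255, 24) Hz, and (c) zero to five wide pulses.
#' Pulse-count draws are uniform over the observed ranges. True part
#' boundaries (0-based, half-open sample intervals) and drawn parameters are
#' attached as ground truth for segmentation tests.
#'
#' @param pop A [population_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param seed Optional integer seed.
#' @param part_b_duration Duration of the continuous train, seconds.
#' @param gap_dur Silent gap between parts, seconds.
#' @param lead_dur Leading/trailing silence, seconds.
#' @param duty Envelope duty cycle of the continuous train.
#' @return A [wave_signal()] labelled \code{"male_courtship"}; ground truth
#'   (including a \code{boundaries} data frame with parts a/b/c) via
#'   [signal_truth()].
#' @export
gen_male_courtship <- function(pop = population_params(), sample_rate = 8000,
                               seed = NULL, part_b_duration = 1,
                               gap_dur = 0.05, lead_dur = 0.1, duty = 0.8) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  pr <- rnorm_trunc(1, pop$male_pr_mean, pop$male_pr_sd, lower = 0)
  mvf <- rnorm_trunc(1, pop$male_mvf_mean, pop$male_mvf_sd, lower = 2 * pr)
  n_irregular <- sample(3:10, 1)
  n_wide <- sample(0:5, 1)

  pw <- duty / pr                       # width of one train pulse, seconds
  part_a <- pulse_group(n_irregular, mvf, pw, c(0.3, 1.0), c(0.02, 0.08),
                        sample_rate)
  part_b <- gen_pulse_train(mvf, pr, part_b_duration, sample_rate, duty = duty)
  part_c <- pulse_group(n_wide, mvf, 3 * pw, c(0.5, 1.0), c(0.02, 0.08),
                        sample_rate)

  lead <- numeric(round(lead_dur * sample_rate))
  gap <- numeric(round(gap_dur * sample_rate))
  a0 <- length(lead)
  a1 <- a0 + length(part_a$samples)
  b0 <- a1 + length(gap)
  b1 <- b0 + length(part_b$samples)
  if (n_wide > 0L) {
    c0 <- b1 + length(gap)
    c1 <- c0 + length(part_c$samples)
    samples <- c(lead, part_a$samples, gap, part_b$samples, gap,
                 part_c$samples, lead)
  } else {
    c0 <- c1 <- b1
    samples <- c(lead, part_a$samples, gap, part_b$samples, lead)
  }
  boundaries <- data.frame(
    part = c("a", "b", "c"),
    start = c(a0, b0, c0),
    end = c(a1, b1, c1),
    n_pulses = c(n_irregular, NA_integer_, n_wide),
    stringsAsFactors = FALSE
  )
  w <- wave_signal(add_noise_snr(samples, pop$noise_snr_db), sample_rate,
                   label = "male_courtship")
  set_truth(w, list(class = "male_courtship", mvf = mvf, pulse_rate = pr,
                    n_irregular = n_irregular, n_wide = n_wide,
                    boundaries = boundaries))
}

#' Generate a synthetic male competition signal
#'
#' Competition signals have two parts: (a) a continuous pulse train whose
#' main frequency is drawn from Normal(281, 46) Hz, and (b) two to four short
#' pulses. Structure and ground-truth conventions match
#' [gen_male_courtship()].
#'
#' @inheritParams gen_male_courtship
#' @param part_a_duration Duration of the continuous train, seconds.
#' @return A [wave_signal()] labelled \code{"male_competition"}.
#' @export
gen_male_competition <- function(pop = population_params(), sample_rate = 8000,
                                 seed = NULL, part_a_duration = 1,
                                 gap_dur = 0.05, lead_dur = 0.1, duty = 0.8) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  pr <- rnorm_trunc(1, pop$comp_pr_mean, pop$comp_pr_sd, lower = 0)
  mvf <- rnorm_trunc(1, pop$comp_mvf_mean, pop$comp_mvf_sd, lower = 2 * pr)
  n_short <- sample(2:4, 1)

  pw <- duty / pr
  part_a <- gen_pulse_train(mvf, pr, part_a_duration, sample_rate, duty = duty)
  part_b <- pulse_group(n_short, mvf, 0.5 * pw, c(0.5, 1.0), c(0.02, 0.08),
                        sample_rate)

  lead <- numeric(round(lead_dur * sample_rate))
  gap <- numeric(round(gap_dur * sample_rate))
  a0 <- length(lead)
  a1 <- a0 + length(part_a$samples)
  b0 <- a1 + length(gap)
  b1 <- b0 + length(part_b$samples)
  samples <- c(lead, part_a$samples, gap, part_b$samples, lead)
  boundaries <- data.frame(
    part = c("a", "b"),
    start = c(a0, b0),
    end = c(a1, b1),
    n_pulses = c(NA_integer_, n_short),
    stringsAsFactors = FALSE
  )
  w <- wave_signal(add_noise_snr(samples, pop$noise_snr_db), sample_rate,
                   label = "male_competition")
  set_truth(w, list(class = "male_competition", mvf = mvf, pulse_rate = pr,
                    n_short = n_short, boundaries = boundaries))
}

# Serialize a boundaries data frame as "start:end;start:end" (0-based,
# half-open), the ground-truth CSV convention.
format_boundaries <- function(boundaries) {
  if (is.null(boundaries)) return("")
  paste(sprintf("%d:%d", boundaries$start, boundaries$end), collapse = ";")
}

#' Generate a labelled corpus of synthetic BPH signals
#'
#' Writes WAV files for each class plus a ground-truth CSV of the drawn
#' per-signal parameters, standing in for a recorded signal library (the
#' study's library held 60 female courtship, 66 male courtship and 39 male
#' competition recordings). Byte-identical output under a fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_female,n_male_court,n_male_comp Signals per class.
#' @param pop A [population_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed; per-signal sub-seeds are derived from it.
#' @param female_duration Female signal duration, seconds.
#' @param write_wavs Set \code{FALSE} to skip WAV output (ground truth and
#'   in-memory signals only).
#' @return Invisibly, a list with \code{truth} (the ground-truth data frame,
#'   also written to \code{ground_truth.csv}) and \code{signals} (the
#'   generated \code{wave_signal} objects, named by file).
#' @export
gen_corpus <- function(out_dir, n_female = 60, n_male_court = 66,
                       n_male_comp = 39, pop = population_params(),
                       sample_rate = 8000, seed = 1, female_duration = 2,
                       write_wavs = TRUE) {
  if (any(c(n_female, n_male_court, n_male_comp) < 0))
    stop("gen_corpus: counts must be >= 0")
  if (write_wavs && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("gen_corpus: cannot create output directory ", out_dir)

  set.seed(seed)
  n_total <- n_female + n_male_court + n_male_comp
  sub_seeds <- if (n_total > 0) sample.int(.Machine$integer.max, n_total) else integer(0)

  plan <- data.frame(
    class = rep(c("female_courtship", "male_courtship", "male_competition"),
                c(n_female, n_male_court, n_male_comp)),
    idx = c(seq_len(n_female), seq_len(n_male_court), seq_len(n_male_comp)),
    stringsAsFactors = FALSE
  )
  prefix <- c(female_courtship = "female", male_courtship = "male_court",
              male_competition = "male_comp")

  signals <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cls <- plan$class[i]
    s <- sub_seeds[i]
    w <- switch(cls,
      female_courtship = gen_female_courtship(pop, duration = female_duration,
                                              sample_rate = sample_rate, seed = s),
      male_courtship = gen_male_courtship(pop, sample_rate = sample_rate, seed = s),
      male_competition = gen_male_competition(pop, sample_rate = sample_rate, seed = s)
    )
    truth <- signal_truth(w)
    fname <- sprintf("%s_%04d.wav", prefix[[cls]], plan$idx[i])
    if (write_wavs) write_wav(w, file.path(out_dir, fname))
    signals[[i]] <- w
    rows[[i]] <- data.frame(
      file = fname, class = cls,
      mvf_hz = truth$mvf, pulse_rate_hz = truth$pulse_rate,
      part_boundaries = format_boundaries(truth$boundaries),
      seed = s, stringsAsFactors = FALSE
    )
  }
  truth_df <- if (n_total > 0) do.call(rbind, rows) else
    data.frame(file = character(0), class = character(0),
               mvf_hz = numeric(0), pulse_rate_hz = numeric(0),
               part_boundaries = character(0), seed = integer(0))
  names(signals) <- truth_df$file
  if (write_wavs)
    utils::write.csv(truth_df, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  invisible(list(truth = truth_df, signals = signals))
}
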