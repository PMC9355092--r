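test_that("band-pass magnitude response matches the closed-form Chebyshev formula", {
  fs <- 8000; low <- 100; high <- 500; rp <- 0.5
  filt <- design_bandpass(fs, low, high, 6, rp)
  f <- seq(10, 3900, by = 7.3)
  H <- Mod(filter_response(filt, f, fs))
  # analytic oracle: bilinear prewarp + lowpass-to-bandpass transform of the
  # order-3 Chebyshev type-I prototype, |H| = 1/sqrt(1 + eps^2 T3(L)^2)
  eps <- sqrt(10^(rp / 10) - 1)
  W1 <- tan(pi * low / fs); W2 <- tan(pi * high / fs)
  Om <- tan(pi * f / fs)
  L <- (Om^2 - W1 * W2) / (Om * (W2 - W1))
  Href <- 1 / sqrt(1 + eps^2 * (4 * L^3 - 3 * L)^2)
  expect_lt(max(abs(H - Href)), 1e-6)
})

test_that("in-band tones pass, DC is rejected, and MVF is not shifted", {
  tone <- gen_pure_tone(225, 1)
  out <- bandpass_filter(tone)
  expect_gt(wave_rms(out), 0.97 * wave_rms(tone))   # within double-pass ripple
  dc <- wave_signal(rep(0.5, 8000), 8000)
  expect_lt(abs(mean(bandpass_filter(dc)$samples)), 1e-2)
  for (f in c(150, 236, 300)) {
    w <- gen_cps(f, 22, 2)
    expect_lt(abs(estimate_mvf(bandpass_filter(w)) - estimate_mvf(w)), 1)
  }
  expect_error(design_bandpass(8000, 500, 100), "low < high")
  expect_error(design_bandpass(8000, 100, 5000), "low < high")
})

test_that("power spectrum localizes tones, is linear, and satisfies Parseval", {
  w <- gen_pure_tone(225, 1)
  sp <- power_spectrum(w)
  expect_lt(abs(sp$freq[which.max(sp$mag)] - 225), w$sample_rate / 65536 + 1e-9)

  sp2 <- power_spectrum(wave_signal(2 * w$samples, w$sample_rate))
  expect_equal(sp2$mag, 2 * sp$mag, tolerance = 1e-9)

  zero <- wave_signal(rep(0, 100), 8000)
  expect_true(all(power_spectrum(zero)$mag == 0))
  expect_error(power_spectrum(wave_signal(1, 8000), n_fft = 0), "n_fft")

  # Parseval with an un-padded power-of-two length
  set.seed(5)
  x <- rnorm(4096)
  spx <- power_spectrum(wave_signal(x, 8000), n_fft = 4096)
  n_fft <- 4096
  two_sided <- c(spx$mag[1]^2, 2 * spx$mag[2:(n_fft / 2)]^2, spx$mag[n_fft / 2 + 1]^2)
  expect_equal(sum(two_sided) / n_fft, sum(x^2), tolerance = 1e-6)
})

test_that("MVF estimation recovers tones to a fraction of a bin", {
  for (f in c(150, 225, 300))
    expect_lt(abs(estimate_mvf(gen_pure_tone(f, 1)) - f), 0.05)
  # tone on an exact DFT bin of an un-padded transform: recovery is exact
  f0 <- 230 * 8000 / 8192
  w0 <- gen_pure_tone(f0, 8192 / 8000)
  expect_lt(abs(estimate_mvf(w0, pad_factor = 1) - f0), 1e-6)
})

test_that("MVF picks the dominant of two tones and errors on an empty band", {
  fs <- 8000; t <- (0:15999) / fs
  two <- wave_signal(sin(2 * pi * 200 * t) + 0.5 * sin(2 * pi * 400 * t), fs)
  expect_lt(abs(estimate_mvf(two, band = c(100, 500)) - 200), 0.05)
  expect_error(estimate_mvf(wave_signal(rep(0, 8000), fs)), "no MVF detectable")
})

test_that("pulse-rate estimation recovers modulation rates and rejects pure tones", {
  expect_lt(abs(estimate_pulse_rate(gen_cps(150, 22, 2)) - 22), 0.5)
  expect_lt(abs(estimate_pulse_rate(gen_pulse_train(236, 23, 2)) - 23), 0.5)
  expect_lt(abs(estimate_pulse_rate(gen_cps(150, 22, 2), method = "rectify") - 22),
            0.5)
  expect_true(is.na(estimate_pulse_rate(gen_pure_tone(225, 2))))
  expect_error(estimate_pulse_rate(gen_cps(150, 22, 1)), "10 pulse periods")
})

test_that("segmentation recovers generated part boundaries and counts", {
  set.seed(606)
  n_ok <- 0; n <- 40
  for (i in 1:n) {
    s <- sample.int(1e6, 1)
    w <- gen_male_courtship(seed = s)
    truth <- signal_truth(w)
    seg <- segment_signal(w, "male_courtship")
    expect_equal(seg$n_pulses[seg$part == "a"], truth$n_irregular)
    if (truth$n_wide > 0)
      expect_equal(seg$n_pulses[seg$part == "c"], truth$n_wide)
    tol <- 0.05 * w$sample_rate
    tb <- truth$boundaries[truth$boundaries$end > truth$boundaries$start, ]
    sb <- seg[match(tb$part, seg$part), ]
    if (all(!is.na(sb$start)) &&
        all(abs(sb$start - tb$start) <= tol) &&
        all(abs(sb$end - tb$end) <= tol))
      n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n, 0.9)
})

test_that("competition segmentation counts the short pulses", {
  set.seed(707)
  for (i in 1:15) {
    w <- gen_male_competition(seed = sample.int(1e6, 1))
    truth <- signal_truth(w)
    seg <- segment_signal(w, "male_competition")
    expect_equal(seg$n_pulses[seg$part == "b"], truth$n_short)
    expect_true(seg$n_pulses[seg$part == "b"] %in% 2:4)
  }
})

test_that("a bare continuous train segments to part b only; silence to nothing", {
  w <- gen_pulse_train(255, 82, 1)
  seg <- segment_signal(w, "male_courtship")
  expect_identical(seg$part, "b")
  silence <- wave_signal(rep(0, 8000), 8000)
  expect_equal(nrow(segment_signal(silence, "male_courtship")), 0)
})

test_that("corpus summary recovers per-signal truth and per-class moments", {
  corp <- gen_corpus(file.path(tempdir(), "corpus_feat"), 6, 4, 3,
                     seed = 21, write_wavs = FALSE)
  out <- summarize_corpus(corp)
  expect_setequal(out$summary$class,
                  c("female_courtship", "male_courtship", "male_competition"))
  joined <- merge(out$per_signal, corp$truth, by = "file")
  expect_true(all(abs(joined$mvf_hz.x - joined$mvf_hz.y) < 2))
  fem <- joined[joined$class.x == "female_courtship", ]
  expect_true(all(abs(fem$pulse_rate_hz.x - fem$pulse_rate_hz.y) < 0.5))
})

test_that("corpus summary validates its inputs", {
  corp <- gen_corpus(file.path(tempdir(), "corpus_bad"), 2, 0, 0,
                     seed = 3, write_wavs = FALSE)
  corp$signals[[2]]$sample_rate <- 4000
  expect_error(summarize_corpus(corp), "mixed sample rates")
  one <- gen_corpus(file.path(tempdir(), "corpus_one"), 1, 0, 0,
                    seed = 3, write_wavs = FALSE)
  expect_error(summarize_corpus(one), "at least 2")
})

test_that("zero-variance corpus summarizes with near-zero spread", {
  pop <- population_params(female_mvf_sd = 0, female_pr_sd = 0,
                           noise_snr_db = 100)
  corp <- gen_corpus(file.path(tempdir(), "corpus_zv"), 4, 0, 0, pop = pop,
                     seed = 8, write_wavs = FALSE)
  s <- summarize_corpus(corp)$summary
  expect_lt(s$mvf_sd_hz, 0.05)
  expect_equal(s$mvf_mean_hz, 236, tolerance = 0.05)
})
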