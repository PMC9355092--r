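test_that("gen_pulse_train matches the pointwise sine x triangle oracle", {
  w <- gen_pulse_train(200, 20, 0.5, 8000)
  expect_equal(w$samples, oracle_sine_triangle(200, 20, 0.5, 8000),
               tolerance = 1e-9)
  w2 <- gen_pulse_train(236, 23, 0.3, 8000, amplitude = 0.5, duty = 0.6)
  expect_equal(w2$samples,
               oracle_sine_triangle(236, 23, 0.3, 8000, 0.5, 0.6),
               tolerance = 1e-9)
})

test_that("a flat envelope at duty 1 degenerates to a pure sine", {
  flat <- gen_pulse_train(236, 23, 0.5, 8000, envelope_shape = "flat", duty = 1)
  tone <- gen_pure_tone(236, 0.5, 8000)
  expect_equal(flat$samples, tone$samples, tolerance = 1e-12)
})

test_that("pulse-train preconditions are enforced with informative errors", {
  expect_error(gen_pulse_train(236, 23, 0), "duration")
  expect_error(gen_pulse_train(236, 300, 1), "pulse_rate < mvf")
  expect_error(gen_pulse_train(5000, 23, 1, 8000), "Nyquist")
  expect_error(gen_pulse_train(236, 23, 1, duty = 0), "duty")
  expect_error(gen_pulse_train(236, 23, 1, amplitude = 0), "amplitude")
})

test_that("pulse train carries its spectral signature: carrier and envelope peaks", {
  w <- gen_pulse_train(236, 23, 2, 8000)
  expect_equal(estimate_mvf(w), 236, tolerance = 0.01)
  expect_equal(estimate_pulse_rate(w), 23, tolerance = 0.05)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_female_courtship(seed = 11)
  b <- gen_female_courtship(seed = 11)
  expect_identical(a$samples, b$samples)
  m1 <- gen_male_courtship(seed = 12)
  m2 <- gen_male_courtship(seed = 12)
  expect_identical(m1$samples, m2$samples)
  expect_identical(signal_truth(m1)$boundaries, signal_truth(m2)$boundaries)
  c1 <- gen_male_competition(seed = 13)
  c2 <- gen_male_competition(seed = 13)
  expect_identical(c1$samples, c2$samples)
})

test_that("zero population variance gives identical signals up to noise", {
  pop <- population_params(female_mvf_sd = 0, female_pr_sd = 0,
                           noise_snr_db = 200)
  a <- gen_female_courtship(pop, seed = 1)
  b <- gen_female_courtship(pop, seed = 2)
  expect_equal(a$samples, b$samples, tolerance = 1e-6)
  expect_equal(signal_truth(a)$mvf, 236)
  expect_equal(signal_truth(a)$pulse_rate, 23)
})

test_that("per-individual draws recover the population moments at n = 10000", {
  set.seed(101)
  mvf <- bphdisrupt:::rnorm_trunc(10000, 236, 43, lower = 46)
  expect_lt(abs(mean(mvf) - 236), 3 * 43 / sqrt(10000))
  expect_true(all(abs(mvf - 236) <= 3 * 43))
  pr <- bphdisrupt:::rnorm_trunc(10000, 23, 2, lower = 0)
  expect_lt(abs(mean(pr) - 23), 3 * 2 / sqrt(10000))
})

test_that("male courtship structure respects the observed part ranges", {
  set.seed(202)
  seeds <- sample.int(1e6, 120)
  n_irr <- n_wide <- integer(length(seeds))
  for (i in seq_along(seeds)) {
    tr <- signal_truth(gen_male_courtship(seed = seeds[i]))
    n_irr[i] <- tr$n_irregular
    n_wide[i] <- tr$n_wide
    expect_identical(tr$boundaries$part, c("a", "b", "c"))
    # part b always non-empty, parts ordered and non-overlapping
    b <- tr$boundaries
    expect_true(b$end[2] > b$start[2])
    expect_true(all(diff(as.vector(rbind(b$start, b$end))) >= 0))
  }
  expect_true(all(n_irr >= 3 & n_irr <= 10))
  expect_true(all(n_wide >= 0 & n_wide <= 5))
  expect_true(any(n_wide == 0))  # the empty part-c case occurs
  tr0 <- signal_truth(gen_male_courtship(seed = seeds[which(n_wide == 0)[1]]))
  expect_equal(tr0$boundaries$start[3], tr0$boundaries$end[3])
})

test_that("male competition structure respects the observed part ranges", {
  set.seed(303)
  seeds <- sample.int(1e6, 60)
  for (s in seeds) {
    tr <- signal_truth(gen_male_competition(seed = s))
    expect_true(tr$n_short >= 2 && tr$n_short <= 4)
    expect_identical(tr$boundaries$part, c("a", "b"))
  }
})

test_that("population sampling means match the reported class moments", {
  set.seed(404)
  pop <- population_params()
  mvf_b <- replicate(400, signal_truth(gen_male_courtship(pop))$mvf)
  expect_lt(abs(mean(mvf_b) - 255), 3 * 24 / sqrt(400))
  mvf_a <- replicate(400, signal_truth(gen_male_competition(pop))$mvf)
  # part-a draws are floored at twice the 82 Hz pulse rate, a slight upward pull
  expect_lt(abs(mean(mvf_a) - 281), 3 * 46 / sqrt(400) + 1)
})

test_that("gen_corpus writes one WAV and one truth row per signal, deterministically", {
  d1 <- file.path(tempdir(), "corpus_a")
  d2 <- file.path(tempdir(), "corpus_b")
  unlink(c(d1, d2), recursive = TRUE)
  c1 <- gen_corpus(d1, 3, 3, 2, seed = 5)
  expect_equal(nrow(c1$truth), 8)
  expect_length(list.files(d1, pattern = "\\.wav$"), 8)
  expect_identical(sort(unique(c1$truth$class)),
                   c("female_courtship", "male_competition", "male_courtship"))
  expect_true(all(c("file", "class", "mvf_hz", "pulse_rate_hz",
                    "part_boundaries", "seed") %in% names(c1$truth)))
  gen_corpus(d2, 3, 3, 2, seed = 5)
  expect_identical(readLines(file.path(d1, "ground_truth.csv")),
                   readLines(file.path(d2, "ground_truth.csv")))
  # WAV on disk round-trips to the in-memory signal at float32 precision
  w <- read_wav(file.path(d1, c1$truth$file[1]))
  expect_lt(max(abs(w$samples - c1$signals[[1]]$samples)), 1e-6)
})

test_that("an empty corpus is valid", {
  d <- file.path(tempdir(), "corpus_empty")
  unlink(d, recursive = TRUE)
  c0 <- gen_corpus(d, 0, 0, 0, seed = 1)
  expect_equal(nrow(c0$truth), 0)
  expect_error(gen_corpus(d, -1, 0, 0), ">= 0")
})
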