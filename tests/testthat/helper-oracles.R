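# Independent oracles used across test files. These are deliberately written
# as naive scalar evaluations, separate from the package's vectorized code
# paths.

# Pointwise sine x triangular-envelope product, evaluated sample by sample.
oracle_sine_triangle <- function(mvf, pulse_rate, duration, sample_rate,
                                 amplitude = 1, duty = 0.8) {
  n <- round(duration * sample_rate)
  vapply(0:(n - 1), function(k) {
    t <- k / sample_rate
    ph <- t * pulse_rate
    u <- ph - floor(ph)
    env <- if (u < duty) {
      half <- duty / 2
      if (u <= half) u / half else (duty - u) / half
    } else 0
    amplitude * env * sin(2 * pi * mvf * t)
  }, numeric(1))
}

# Brute-force active-reply-period scan: enumerate every window of the
# required length.
oracle_arp <- function(latencies, window, need) {
  n <- length(latencies)
  if (n < need) return(FALSE)
  for (s in 1:(n - need + 1)) {
    win <- latencies[s:(s + need - 1)]
    if (all(!is.na(win) & win <= window)) return(TRUE)
  }
  FALSE
}

# Scalar transcription of Dunn's pairwise z on pooled midranks with tie
# correction (two-sided normal p).
oracle_dunn <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  tie_sum <- 0
  for (v in unique(x)) {
    tt <- sum(x == v)
    tie_sum <- tie_sum + (tt^3 - tt)
  }
  s2 <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  k <- length(groups)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ri <- mean(r[g == i]); rj <- mean(r[g == j])
    ni <- sum(g == i); nj <- sum(g == j)
    z <- (ri - rj) / sqrt(s2 * (1 / ni + 1 / nj))
    out <- rbind(out, data.frame(i = i, j = j, z = z,
                                 p = 2 * pnorm(-abs(z))))
  }
  out
}

# Mean of a normal truncated to (lo, hi], closed form.
truncnorm_mean <- function(mu, sigma, lo = 0, hi = 45) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
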