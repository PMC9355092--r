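test_that("active-reply-period screening follows the two-in-a-row rule", {
  expect_true(check_arp(c(8, 9)))
  expect_false(check_arp(c(12, 3)))
  expect_false(check_arp(numeric(0)))
  expect_false(check_arp(c(NA, 4)))
  expect_true(check_arp(c(NA, 4, 3)))
  expect_false(check_arp(c(4, NA, 3)))
  cfg3 <- protocol_config(arp_required_consecutive = 3)
  expect_false(check_arp(c(1, 2), cfg3))
  expect_true(check_arp(c(11, 1, 2, 3), cfg3))
})

test_that("check_arp equals the brute-force run scan on exhaustive inputs", {
  vals <- c(3, 12, NA)
  grid <- expand.grid(a = vals, b = vals, c = vals, d = vals)
  for (need in 2:3) {
    cfg <- protocol_config(arp_required_consecutive = need)
    for (r in seq_len(nrow(grid))) {
      lat <- as.numeric(grid[r, ])
      expect_identical(check_arp(lat, cfg), oracle_arp(lat, 10, need))
    }
  }
})

test_that("reply rates reproduce the printed screening percentages from counts", {
  expect_equal(reply_rate(45, 43), 95.6)
  expect_equal(reply_rate(42, 18), 42.9)
  expect_equal(reply_rate(39, 22), 56.4)
  expect_equal(reply_rate(100, 0), 0)
  expect_error(reply_rate(0, 0), "> 0")
  expect_error(reply_rate(10, 11), "<=")
})

test_that("the screening table recomputes consistently except the flagged row", {
  t1 <- table1_screening()
  expect_equal(nrow(t1), 8)
  expect_identical(t1$condition, condition_levels())
  consistent <- t1$condition != "PT225"
  expect_equal(t1$rate_from_counts_pct[consistent],
               t1$printed_rate_pct[consistent])
  expect_identical(t1$inconsistent, t1$condition == "PT225")
  expect_equal(t1$rate_from_counts_pct[t1$condition == "PT225"], 40.5)
})

test_that("condition summaries aggregate counts, rates and replier-only delays", {
  trials <- rbind(
    data.frame(subject_id = sprintf("c%02d", 1:45), condition = "Control",
               replied = rep(c(TRUE, FALSE), c(43, 2)),
               delay_s = c(rep(5, 43), NA, NA)),
    data.frame(subject_id = sprintf("p%02d", 1:10), condition = "PT225",
               replied = FALSE, delay_s = NA_real_)
  )
  s <- summarize_conditions(trials)
  ctrl <- s[s$condition == "Control", ]
  expect_equal(ctrl$n_tests, 45)
  expect_equal(ctrl$n_replies, 43)
  expect_equal(ctrl$reply_rate_pct, 95.6)
  expect_equal(ctrl$delay_mean_s, 5)
  pt <- s[s$condition == "PT225", ]
  expect_equal(pt$n_replies, 0)
  expect_true(is.na(pt$delay_mean_s))

  bad <- trials; bad$condition[1] <- "PT999"
  expect_error(summarize_conditions(bad), "unknown condition")
  bad2 <- trials; bad2$delay_s[44] <- 3
  expect_error(summarize_conditions(bad2), "delay present")
})

test_that("the simulator respects probabilities, windows and seeds", {
  params <- table1_sim_params()
  tr <- simulate_experiment(params, 200, seed = 42)
  expect_equal(nrow(tr), 1600)
  expect_true(all(is.na(tr$delay_s[!tr$replied])))
  d <- tr$delay_s[tr$replied]
  expect_true(all(d > 0 & d <= 45))
  expect_identical(tr, simulate_experiment(params, 200, seed = 42))

  p1 <- data.frame(condition = "Control", reply_prob = 1,
                   delay_mean = 5.3, delay_sd = 3.3)
  expect_true(all(simulate_experiment(p1, 50, seed = 1)$replied))
  p0 <- data.frame(condition = "Control", reply_prob = 0,
                   delay_mean = 5.3, delay_sd = 3.3)
  expect_false(any(simulate_experiment(p0, 50, seed = 1)$replied))

  ln <- simulate_experiment(params, 100, seed = 7, delay_family = "lognormal")
  dl <- ln$delay_s[ln$replied]
  expect_true(all(dl > 0 & dl <= 45))
})

test_that("simulated summaries recover the model parameters at large n", {
  params <- table1_sim_params()
  n <- 4000
  tr <- simulate_experiment(params, n, seed = 99)
  s <- summarize_conditions(tr)
  s <- s[match(params$condition, s$condition), ]
  se_rate <- sqrt(params$reply_prob * (1 - params$reply_prob) / n)
  expect_true(all(abs(s$n_replies / s$n_tests - params$reply_prob) <=
                    3 * se_rate))
  # replier delays follow the truncated normal; compare to its implied mean
  mu_trunc <- mapply(truncnorm_mean, params$delay_mean, params$delay_sd)
  se_delay <- params$delay_sd / sqrt(s$n_replies)
  expect_true(all(abs(s$delay_mean_s - mu_trunc) <= 3.5 * se_delay))
})

test_that("the disruption report quantifies the drop against control", {
  t1 <- table1_screening()
  summary <- data.frame(condition = t1$condition,
                        n_tests = t1$n_tests, n_replies = t1$n_replies,
                        reply_rate_pct = t1$printed_rate_pct)
  rep <- disruption_report(summary)
  expect_equal(rep$control_rate_pct, 95.6)
  pt225 <- rep$table[rep$table$condition == "PT225", ]
  expect_equal(pt225$drop_points, 95.6 - 33.3)
  expect_equal(pt225$relative_reduction_pct, round(100 * (95.6 - 33.3) / 95.6, 1))
  expect_true(pt225$disruptive)
  wgn <- rep$table[rep$table$condition == "WGN", ]
  expect_false(wgn$disruptive)

  same <- data.frame(condition = c("Control", "X"),
                     reply_rate_pct = c(80, 80))
  r2 <- disruption_report(same, control = "Control")
  expect_equal(r2$table$drop_points, 0)
  expect_false(r2$table$disruptive)
  expect_error(disruption_report(summary[-1, ]), "missing")
  expect_output(print(rep), "PT225")
})

test_that("trial CSVs round-trip through read/write", {
  tr <- simulate_experiment(table1_sim_params(), 20, seed = 3)
  path <- file.path(tempdir(), "trials_rt.csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_identical(back$replied, tr$replied)
  expect_equal(back$delay_s, tr$delay_s, tolerance = 1e-9)
  expect_identical(back$condition, tr$condition)
})
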