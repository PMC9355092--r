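# Playback-experiment data model, simulator and analysis: active-reply-period
# screening, trial records, per-condition reply-rate / reply-delay summaries,
# and the disruption report built on the rank statistics in stats-rank.R.

#' Condition labels of the screening experiment
#'
#' The closed set of playback conditions: the disruption-free control plus
#' the seven artificial disruptive signals.
#'
#' @return Character vector of the 8 condition codes.
#' @export
condition_levels <- function() {
  c("Control", "PT150", "PT225", "PT300", "CPS150", "CPS225", "CPS300", "WGN")
}

#' Playback protocol configuration
#'
#' Protocol constants of the screening experiment: a male is in the active
#' reply period (ARP) if it replied to the played female signal within 10 s
#' twice in a row; responses are observed within 45 s after playback; waits
#' between trials and before retests are 60 s.
#'
#' @param arp_window ARP reply window, seconds.
#' @param arp_required_consecutive Consecutive in-window replies required.
#' @param observation_window Post-playback observation window, seconds.
#' @param inter_trial_wait,retest_wait Waits between trials / retests, seconds.
#' @return A validated list of class \code{protocol_config}.
#' @export
protocol_config <- function(arp_window = 10, arp_required_consecutive = 2,
                            observation_window = 45, inter_trial_wait = 60,
                            retest_wait = 60) {
  cfg <- list(arp_window = arp_window,
              arp_required_consecutive = as.integer(arp_required_consecutive),
              observation_window = observation_window,
              inter_trial_wait = inter_trial_wait, retest_wait = retest_wait)
  if (any(unlist(cfg[c(1, 3, 4, 5)]) <= 0))
    stop("protocol_config: all durations must be > 0")
  if (cfg$arp_required_consecutive < 1L)
    stop("protocol_config: arp_required_consecutive must be >= 1")
  structure(cfg, class = "protocol_config")
}

#' Active-reply-period (ARP) check
#'
#' A subject qualifies as being in the ARP iff some run of
#' \code{cfg$arp_required_consecutive} consecutive reply latencies are all
#' within \code{cfg$arp_window} seconds. Missing replies are encoded as
#' \code{NA}.
#'
#' @param reply_latencies Numeric vector of reply latencies in trial order,
#'   \code{NA} for no reply.
#' @param cfg A [protocol_config()].
#' @return \code{TRUE} or \code{FALSE} (\code{FALSE} for an empty sequence).
#' @examples
#' check_arp(c(8, 9))    # TRUE
#' check_arp(c(12, 3))   # FALSE
#' @export
check_arp <- function(reply_latencies, cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (length(reply_latencies) == 0) return(FALSE)
  ok <- !is.na(reply_latencies) & reply_latencies <= cfg$arp_window
  need <- cfg$arp_required_consecutive
  if (length(ok) < need) return(FALSE)
  run <- 0L
  for (v in ok) {
    run <- if (v) run + 1L else 0L
    if (run >= need) return(TRUE)
  }
  FALSE
}

#' Reply rate as a percentage
#'
#' \code{100 * n_replies / n_tests}, reported to 1 decimal as in the
#' screening table (43/45 -> 95.6).
#'
#' @param n_tests Number of tests (> 0).
#' @param n_replies Number of replies, \code{0 <= n_replies <= n_tests}.
#' @return Percentage rounded to 1 decimal. Vectorized.
#' @export
reply_rate <- function(n_tests, n_replies) {
  if (any(n_tests <= 0)) stop("reply_rate: n_tests must be > 0")
  if (any(n_replies < 0 | n_replies > n_tests))
    stop("reply_rate: need 0 <= n_replies <= n_tests")
  round(100 * n_replies / n_tests, 1)
}

#' Printed screening results of the playback experiment
#'
#' The published per-condition counts and reply-delay moments: number of
#' tests, number of replies, printed reply rate (%), and mean +/- SD reply
#' delay (s) for the control and the seven disruptive signals. The
#' \code{rate_from_counts_pct} column recomputes the rate from the counts;
#' for PT225 the printed 33.3% is inconsistent with its own counts
#' (17/42 = 40.5%), which the \code{inconsistent} flag marks.
#'
#' @return A data frame with one row per condition.
#' @export
table1_screening <- function() {
  d <- data.frame(
    condition = condition_levels(),
    signal_label = c("Control", "PT (150 Hz)", "PT (225 Hz)", "PT (300 Hz)",
                     "CPS (22-150 Hz)", "CPS (22-225 Hz)", "CPS (22-300 Hz)",
                     "WGN"),
    n_tests = c(45L, 39L, 42L, 42L, 42L, 40L, 40L, 43L),
    n_replies = c(43L, 22L, 17L, 18L, 28L, 21L, 22L, 36L),
    printed_rate_pct = c(95.6, 56.4, 33.3, 42.9, 66.7, 52.5, 55.0, 83.7),
    delay_mean_s = c(5.3, 8.0, 9.1, 9.3, 5.8, 7.2, 7.4, 5.0),
    delay_sd_s = c(3.3, 5.2, 5.6, 5.9, 3.2, 5.0, 6.0, 3.1),
    stringsAsFactors = FALSE
  )
  d$rate_from_counts_pct <- reply_rate(d$n_tests, d$n_replies)
  d$inconsistent <- d$rate_from_counts_pct != d$printed_rate_pct
  d
}

#' Behavioral simulator parameters from the screening table
#'
#' Reply probabilities (from the published counts) and truncated-normal
#' delay moments per condition, ready for [simulate_experiment()].
#'
#' @return Data frame with columns \code{condition}, \code{reply_prob},
#'   \code{delay_mean}, \code{delay_sd}.
#' @export
table1_sim_params <- function() {
  t1 <- table1_screening()
  data.frame(
    condition = t1$condition,
    reply_prob = t1$n_replies / t1$n_tests,
    delay_mean = t1$delay_mean_s,
    delay_sd = t1$delay_sd_s,
    stringsAsFactors = FALSE
  )
}

# Truncated normal on (lo, hi] by rejection; sd = 0 collapses to the
# clamped mean.
rtrunc_delay <- function(n, mean, sd, lo = 0, hi = 45) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lo + 1e-9), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate playback trials
#'
#' Seeded stand-in for the live playback experiment: for each trial the
#' subject replies with its condition's probability (independent Bernoulli;
#' subjects were discarded after testing, so there is no repeated-measures
#' structure), and repliers draw a delay from a normal distribution truncated
#' to \code{(0, observation_window]} seconds. A lognormal delay family is
#' available as an alternative.
#'
#' @param params Data frame with columns \code{condition},
#'   \code{reply_prob}, \code{delay_mean}, \code{delay_sd} (e.g.
#'   [table1_sim_params()]).
#' @param n_per_condition Trials per condition (single value or vector
#'   matching \code{params} rows).
#' @param cfg A [protocol_config()].
#' @param seed Optional integer seed.
#' @param delay_family \code{"truncnorm"} (default) or \code{"lognormal"}
#'   (moment-matched, truncated to the observation window).
#' @return Trial-record data frame: \code{subject_id}, \code{condition},
#'   \code{replied} (logical), \code{delay_s} (\code{NA} unless replied).
#' @export
simulate_experiment <- function(params, n_per_condition, cfg = protocol_config(),
                                seed = NULL,
                                delay_family = c("truncnorm", "lognormal")) {
  delay_family <- match.arg(delay_family)
  stopifnot(inherits(cfg, "protocol_config"))
  req <- c("condition", "reply_prob", "delay_mean", "delay_sd")
  if (!all(req %in% names(params)))
    stop("simulate_experiment: params needs columns ", paste(req, collapse = ", "))
  if (any(params$reply_prob < 0 | params$reply_prob > 1))
    stop("simulate_experiment: reply_prob must be in [0, 1]")
  if (any(params$delay_sd < 0))
    stop("simulate_experiment: delay_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_per_condition <- rep_len(n_per_condition, nrow(params))
  hi <- cfg$observation_window

  rows <- lapply(seq_len(nrow(params)), function(i) {
    n <- n_per_condition[i]
    replied <- stats::runif(n) < params$reply_prob[i]
    delay <- rep(NA_real_, n)
    nr <- sum(replied)
    if (nr > 0) {
      delay[replied] <- if (delay_family == "truncnorm") {
        rtrunc_delay(nr, params$delay_mean[i], params$delay_sd[i], 0, hi)
      } else {
        m <- params$delay_mean[i]; s <- params$delay_sd[i]
        if (s == 0) rep(min(m, hi), nr) else {
          sigma2 <- log(1 + (s / m)^2)
          d <- stats::rlnorm(nr, log(m) - sigma2 / 2, sqrt(sigma2))
          while (any(d > hi)) d[d > hi] <-
            stats::rlnorm(sum(d > hi), log(m) - sigma2 / 2, sqrt(sigma2))
          d
        }
      }
    }
    data.frame(
      subject_id = sprintf("%s_%04d", params$condition[i], seq_len(n)),
      condition = params$condition[i], replied = replied, delay_s = delay,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Aggregate trial records per condition
#'
#' Builds the screening-table aggregation from raw trial records: tests,
#' replies, reply rate (1-decimal %), and reply-delay mean/SD over repliers
#' only (reported as \code{NA} for conditions with no repliers).
#'
#' @param trials Trial-record data frame (see [simulate_experiment()] for the
#'   schema).
#' @param levels Allowed condition labels; records outside this set are an
#'   error.
#' @return Data frame with one row per condition present, in \code{levels}
#'   order.
#' @export
summarize_conditions <- function(trials, levels = condition_levels()) {
  req <- c("condition", "replied", "delay_s")
  if (!all(req %in% names(trials)))
    stop("summarize_conditions: trials needs columns ", paste(req, collapse = ", "))
  bad <- setdiff(unique(trials$condition), levels)
  if (length(bad) > 0)
    stop("summarize_conditions: unknown condition label(s): ",
         paste(bad, collapse = ", "))
  if (any(!trials$replied & !is.na(trials$delay_s)))
    stop("summarize_conditions: delay present on non-replied trial")
  present <- levels[levels %in% trials$condition]
  rows <- lapply(present, function(cond) {
    d <- trials[trials$condition == cond, ]
    delays <- d$delay_s[d$replied]
    data.frame(
      condition = cond, n_tests = nrow(d), n_replies = sum(d$replied),
      reply_rate_pct = reply_rate(nrow(d), sum(d$replied)),
      delay_mean_s = if (length(delays)) mean(delays) else NA_real_,
      delay_sd_s = if (length(delays) > 1) stats::sd(delays) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Disruption report
#'
#' Quantifies each disruptive signal's effect against the control: drop in
#' reply rate (percentage points), relative reduction (%), and a flag for
#' conditions exceeding the disruption threshold (default: relative reduction
#' above 50%, the study's headline criterion). Optionally bundles the
#' Kruskal-Wallis and Dunn results for rendering.
#'
#' @param summary Condition summary from [summarize_conditions()] (or the
#'   printed-table equivalent).
#' @param kw Optional \code{kw_test} result on reply delays.
#' @param dunn Optional [dunn_pairwise()] result.
#' @param control Label of the control condition.
#' @param threshold Disruption threshold, percent.
#' @param relative If \code{TRUE} (default) the threshold applies to the
#'   relative reduction, otherwise to the percentage-point drop.
#' @return A list of class \code{disruption_report} with elements
#'   \code{table}, \code{kw}, \code{dunn}, \code{control_rate_pct}.
#' @export
disruption_report <- function(summary, kw = NULL, dunn = NULL,
                              control = "Control", threshold = 50,
                              relative = TRUE) {
  if (!control %in% summary$condition)
    stop("disruption_report: control condition '", control, "' missing")
  ctrl <- summary$reply_rate_pct[summary$condition == control]
  tab <- summary[summary$condition != control, , drop = FALSE]
  tab$drop_points <- round(ctrl - tab$reply_rate_pct, 1)
  tab$relative_reduction_pct <- round(100 * (ctrl - tab$reply_rate_pct) / ctrl, 1)
  tab$disruptive <- (if (relative) tab$relative_reduction_pct else
    tab$drop_points) > threshold
  rownames(tab) <- NULL
  structure(list(table = tab, kw = kw, dunn = dunn,
                 control_rate_pct = ctrl),
            class = "disruption_report")
}

#' @export
print.disruption_report <- function(x, ...) {
  cat(sprintf("Control reply rate: %.1f%%\n", x$control_rate_pct))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-7s %5.1f%%  (%.1f -> %.1f, -%.1f pts, rel. -%.1f%%)%s\n",
                t$condition[i], t$reply_rate_pct[i], x$control_rate_pct,
                t$reply_rate_pct[i], t$drop_points[i],
                t$relative_reduction_pct[i],
                if (t$disruptive[i]) "  *disruptive*" else ""))
  }
  if (!is.null(x$kw)) print(x$kw)
  invisible(x)
}

#' Read / write trial-record CSVs
#'
#' Trial CSVs use the columns \code{subject_id}, \code{condition},
#' \code{replied} (0/1) and \code{delay_s} (empty when not replied).
#'
#' @param trials Trial-record data frame.
#' @param path CSV path.
#' @return \code{write_trials}: \code{path} invisibly; \code{read_trials}:
#'   the trial-record data frame.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  out$replied <- as.integer(out$replied)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(out, tmp, row.names = FALSE, na = "")
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("write_trials: cannot write ", path)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$replied <- as.logical(d$replied)
  if (!"delay_s" %in% names(d)) d$delay_s <- NA_real_
  d$delay_s <- as.numeric(d$delay_s)
  d
}
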