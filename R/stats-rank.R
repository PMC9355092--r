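# Rank statistics for reply-delay comparisons, implemented directly from the
# rank-sum formulas (with midranks and tie correction) rather than delegated,
# so the computation is fully transparent and testable against independent
# oracles.

# Pooled midranks plus the tie-correction sum T = sum(t^3 - t) over tie groups.
pooled_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)  # midranks
  tie_sizes <- table(x)
  list(rank = r, group = g, n = length(x),
       tie_sum = sum(tie_sizes^3 - tie_sizes))
}

#' Kruskal-Wallis rank test
#'
#' The k-sample rank test used to compare reply delays across playback
#' conditions: \code{H = 12 / (N (N + 1)) * sum n_i (Rbar_i - (N + 1) / 2)^2},
#' computed on pooled midranks and divided by the tie-correction factor
#' \code{1 - sum(t^3 - t) / (N^3 - N)}. The p-value uses the chi-square
#' approximation with \code{k - 1} degrees of freedom. When every observation
#' is identical the statistic is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors, one per condition (>= 2 non-empty
#'   groups).
#' @return A list of class \code{kw_test}: \code{H}, \code{df}, \code{p},
#'   \code{tie_corrected}.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis: need a list of >= 2 groups")
  if (any(lengths(groups) == 0)) stop("kruskal_wallis: empty group")
  pr <- pooled_ranks(groups)
  N <- pr$n
  k <- length(groups)
  rbar <- tapply(pr$rank, pr$group, mean)
  ni <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  correction <- 1 - pr$tie_sum / (N^3 - N)
  tie_corrected <- pr$tie_sum > 0
  if (correction <= 0) {
    H <- 0  # all observations tied
  } else {
    H <- H / correction
  }
  p <- if (H == 0) 1 else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  structure(list(H = H, df = k - 1L, p = p, tie_corrected = tie_corrected),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank test: H = %.3f, df = %d, p = %.4g%s\n",
              x$H, x$df, x$p,
              if (x$tie_corrected) " (tie-corrected)" else ""))
  invisible(x)
}

#' Dunn's pairwise comparison test
#'
#' Post-hoc pairwise comparisons on the pooled midranks of all groups:
#' \code{z_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (1/n_i + 1/n_j))} with
#' \code{S2 = N (N + 1) / 12 - sum(t^3 - t) / (12 (N - 1))}, two-sided normal
#' p-values. No multiplicity adjustment is applied by default (the study's
#' reported pairwise p-values state none); Bonferroni or Holm are available
#' via \code{adjust}. Fully tied data yield z = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per condition.
#' @param comparisons Optional 2-column matrix (or list of length-2 vectors)
#'   of group indices to compare; default all pairs.
#' @param adjust \code{"none"} (default), \code{"bonferroni"} or
#'   \code{"holm"}.
#' @return A data frame with columns \code{group1}, \code{group2}, \code{z},
#'   \code{p}, \code{p_adj}.
#' @export
dunn_pairwise <- function(groups, comparisons = NULL,
                          adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2)
    stop("dunn_pairwise: need a list of >= 2 groups")
  if (any(lengths(groups) == 0)) stop("dunn_pairwise: empty group")
  k <- length(groups)
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(k, 2))
  } else if (is.list(comparisons)) {
    comparisons <- do.call(rbind, comparisons)
  }
  if (any(comparisons < 1 | comparisons > k))
    stop("dunn_pairwise: comparison indices out of range")

  pr <- pooled_ranks(groups)
  N <- pr$n
  rbar <- tapply(pr$rank, pr$group, mean)
  ni <- lengths(groups)
  S2 <- N * (N + 1) / 12 - pr$tie_sum / (12 * (N - 1))

  z <- p <- numeric(nrow(comparisons))
  for (r in seq_len(nrow(comparisons))) {
    i <- comparisons[r, 1]; j <- comparisons[r, 2]
    se <- sqrt(S2 * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) {         # all observations tied across the whole data set
      z[r] <- 0; p[r] <- 1
    } else {
      z[r] <- (rbar[i] - rbar[j]) / se
      p[r] <- 2 * stats::pnorm(-abs(z[r]))
    }
  }
  nm <- names(groups)
  lab <- function(idx) if (is.null(nm)) as.character(idx) else nm[idx]
  data.frame(
    group1 = lab(comparisons[, 1]), group2 = lab(comparisons[, 2]),
    z = z, p = p, p_adj = stats::p.adjust(p, method = adjust),
    stringsAsFactors = FALSE
  )
}
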