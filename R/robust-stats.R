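#' Robust descriptive statistics for absolute pose errors
#'
#' The error distributions are summarised with the median, limits of
#' agreement (LOA), the unscaled median absolute deviation (MAD), the
#' cumulative error, and Hampel outlier counts; group differences are
#' tested nonparametrically (Kruskal-Wallis, then Dunn's post-hoc test
#' with Bonferroni correction when significant).
#'
#' @name robust_stats
NULL

#' Limits of agreement: median +/- 1.45 x IQR
#'
#' The interquartile range uses linear-interpolation quantiles
#' (`stats::quantile` type 7, the common default of major numeric
#' environments; the LOA values depend on this convention, so it is
#' pinned). Because the data are absolute errors, a negative lower
#' bound is truncated to 0.
#'
#' @param x numeric vector of non-negative values, length >= 2.
#' @return `c(low, high)`.
#' @export
loa <- function(x) {
  if (length(x) < 2L) stop("loa requires at least 2 observations")
  m <- stats::median(x)
  iqr <- diff(stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
  c(low = max(0, m - 1.45 * iqr), high = m + 1.45 * iqr)
}

#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` with no consistency factor: used as a raw
#' spread descriptor, not a robust sigma estimate.
#'
#' @param x numeric vector.
#' @return a number.
#' @export
mad_unscaled <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

#' Cumulative error
#'
#' Sum of absolute differences from the gold standard: `sum(|x|)`.
#'
#' @param x numeric vector of errors.
#' @return a number.
#' @export
cumulative_error <- function(x) sum(abs(x))

#' Hampel outlier identifier
#'
#' Flags observations whose modified z-score
#' `0.6745 * |x - median(x)| / mad(x)` exceeds `threshold` (default
#' 3.5, the standard pairing for the modified z-score form). The
#' unscaled variant (`|x - median| / mad > threshold`) is available
#' with `scaled = FALSE`. When the MAD is zero the rule degenerates;
#' exactly the values differing from the median are flagged.
#'
#' @param x numeric vector, length >= 3.
#' @param threshold cut-off on the (modified) z-score.
#' @param scaled use the 0.6745 modified z-score scaling.
#' @return logical mask of outliers.
#' @export
hampel_outliers <- function(x, threshold = 3.5, scaled = TRUE) {
  if (length(x) < 3L) stop("hampel_outliers requires at least 3 observations")
  m <- stats::median(x)
  s <- mad_unscaled(x)
  if (s == 0) return(x != m)
  k <- if (scaled) 0.6745 else 1
  k * abs(x - m) / s > threshold
}

#' Kruskal-Wallis rank test across condition groups
#'
#' Wraps `stats::kruskal.test` (rank-based H with tie correction,
#' chi-square reference with k - 1 degrees of freedom). The degenerate
#' case of all observations identical is defined as H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, total N >= 3).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  stopifnot(all(n >= 1L), sum(n) >= 3L)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), n))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' For each pair of groups the standardised mean-rank difference is
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 -
#'   \sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)}}
#' with ranks over the pooled sample and the usual tie correction;
#' two-sided p-values come from the standard normal and are Bonferroni
#' adjusted within the family of `choose(k, 2)` pairs, capped at 1.
#'
#' @param groups list of numeric vectors; names label the groups.
#' @return data frame with `group_a`, `group_b`, `z`, `p`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  g <- rep(seq_len(k), n)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  out <- data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
                    z = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (q in seq_len(m)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    out$z[q] <- z
    out$p[q] <- p
    out$p_adjusted[q] <- min(1, m * p)
  }
  out
}

#' Summarise one error distribution (one table cell group)
#'
#' @param x numeric vector of absolute errors (length >= 2).
#' @param hampel_threshold Hampel cut-off.
#' @return list with `median`, `loa_low`, `loa_high`,
#'   `cumulative_error`, `mad`, `n_outliers`, `n`.
#' @export
summarize_errors <- function(x, hampel_threshold = 3.5) {
  lo <- loa(x)
  list(median = stats::median(x), loa_low = unname(lo[1]),
       loa_high = unname(lo[2]), cumulative_error = cumulative_error(x),
       mad = mad_unscaled(x),
       n_outliers = if (length(x) >= 3L)
         sum(hampel_outliers(x, hampel_threshold)) else 0L,
       n = length(x))
}

#' Kruskal-Wallis with gated Dunn post-hoc across conditions
#'
#' Dunn's pairwise comparisons are computed only when the
#' Kruskal-Wallis test is significant at `alpha` (default 0.05); the
#' returned list always carries the omnibus result.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param alpha gate level for the post-hoc test.
#' @return list with `kw` (see [kruskal_wallis()]) and `dunn` (a data
#'   frame, or `NULL` when the gate is not passed).
#' @export
condition_tests <- function(groups, alpha = 0.05) {
  kw <- kruskal_wallis(groups)
  dunn <- if (is.finite(kw$p) && kw$p < alpha) dunn_posthoc(groups) else NULL
  list(kw = kw, dunn = dunn)
}
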