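# Agreement and comparison statistics for paired length / PWV measurements.

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias is their mean and the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample SD). Median/IQR summaries of the
#' differences and absolute differences are included, matching how
#' non-normally distributed length and PWV differences are reported.
#'
#' @param a,b Equal-length numeric vectors (n >= 3), e.g. 2D and 3D lengths.
#' @return An object of class `bland_altman`: `bias`, `loa_lower`,
#'   `loa_upper`, `sd`, `n`, plus median/IQR of differences and absolute
#'   differences.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("measurements must be finite")
  d <- a - b
  s <- stats::sd(d)
  qd <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qa <- stats::quantile(abs(d), c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(bias = mean(d), sd = s,
                 loa_lower = mean(d) - 1.96 * s,
                 loa_upper = mean(d) + 1.96 * s,
                 n = length(d),
                 median_diff = qd[2], iqr_diff = qd[c(1, 3)],
                 median_absdiff = qa[2], iqr_absdiff = qa[c(1, 3)]),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, limits of agreement [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  cat(sprintf("  median difference %.4g [%.4g - %.4g]\n", x$median_diff,
              x$iqr_diff[1], x$iqr_diff[2]))
  invisible(x)
}

# Exact null distribution of the Wilcoxon signed-rank statistic W+ over the
# 2^n equiprobable sign assignments, via the generating-polynomial DP.
# Ranks are midranks; doubling makes them integers so ties are handled.
.signed_rank_dist <- function(ranks2) {
  # ranks2: integer 2*midranks
  tot <- sum(ranks2)
  coef <- numeric(tot + 1)
  coef[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), coef[seq_len(tot + 1 - r)])
    coef <- coef + shifted
  }
  coef / 2^length(ranks2)   # P(2*W+ = 0..tot)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped; ties
#' among the remaining absolute differences receive midranks. For `n <= 25`
#' non-zero differences the p-value is exact, computed from the full
#' distribution of the statistic over all `2^n` sign assignments (a
#' dynamic-programming enumeration that handles midranks); above that a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a Numeric vector of first measurements, or (if `b` is `NULL`)
#'   the paired differences themselves.
#' @param b Optional numeric vector of second measurements.
#' @return `list(statistic, p_value, n, method)` with `statistic` the rank
#'   sum of positive differences (W+).
#' @export
wilcoxon_signed_rank <- function(a, b = NULL) {
  d <- if (is.null(b)) as.numeric(a) else {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    as.numeric(a) - as.numeric(b)
  }
  if (any(!is.finite(d))) stop("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate: all paired differences are zero")
  r <- rank(abs(d))                       # midranks
  W <- sum(r[d > 0])
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * r))
    dist <- .signed_rank_dist(ranks2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (sign-assignment enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' KS test of the sample against a normal distribution with the sample's
#' own mean and SD, with p-values from the asymptotic KS distribution.
#' Because the reference parameters are estimated from the same sample, the
#' test is conservative (true rejection rates below nominal); it is used
#' here, as in common practice, as a screen for switching to
#' non-parametric summaries.
#'
#' @param values Numeric vector, n >= 5, non-zero variance.
#' @return `list(statistic, p_value, n, conservative = TRUE)`.
#' @export
ks_normality <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 5) stop("need at least 5 values")
  if (any(!is.finite(x))) stop("values must be finite")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: normality test undefined")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(x), conservative = TRUE)
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), pinned so summaries are bit-reproducible.
#'
#' @param values Numeric vector (n >= 1).
#' @return `list(median, iqr_lower, iqr_upper)`.
#' @export
median_iqr <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 1 || any(!is.finite(x)))
    stop("need at least one finite value")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], iqr_lower = q[1], iqr_upper = q[3])
}
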