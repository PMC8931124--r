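#' Pearson chi-square test for a 2x2 table, with Cohen's w
#'
#' The uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on a 2x2 contingency table
#' (rows = condition, columns = later/earlier choice), its df = 1 p-value
#' and the effect size `w = sqrt(chi2 / N)`. No continuity correction is
#' applied: the uncorrected statistic is the one conventionally reported
#' alongside `w` in this literature.
#'
#' @param tab A 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts with positive margins.
#' @return A tibble with `statistic`, `df`, `p_value`, `cohen_w`, `n`.
#' @examples
#' pearson_chi2(matrix(c(56, 16, 39, 36), 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(tab) {
  tab <- as_2x2(tab)
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("All margins must be positive.", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  stat <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  tibble::tibble(
    statistic = stat,
    df = 1,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    cohen_w = sqrt(stat / n),
    n = n
  )
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Conditional on the margins, the count in the first cell is
#' hypergeometric; the two-sided p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (up to a small relative slack guarding
#' against floating-point ties).
#'
#' @inheritParams pearson_chi2
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(56, 16, 39, 36), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("All margins must be positive.", call. = FALSE)
  }
  m <- sum(tab[, 1])          # first-column total
  nn <- sum(tab[, 2])         # second-column total
  r1 <- sum(tab[1, ])         # first-row total
  lo <- max(0, r1 - nn)
  hi <- min(r1, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, nn, r1)
  p_obs <- stats::dhyper(tab[1, 1], m, nn, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. `U` is computed from mid-ranks
#' (ties shared); the default inference is the large-sample normal
#' approximation with tie-corrected variance and no continuity
#' correction, reported as a z statistic and two-sided p. For small
#' untied samples `exact = TRUE` computes the exact two-sided p by full
#' enumeration of the `choose(n1 + n2, n1)` group assignments of the
#' ranks (doubling the smaller tail, capped at 1).
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact Use exact enumeration (small samples, no ties) instead of
#'   the normal approximation?
#' @return A tibble with `u`, `z`, `p_value`, `n1`, `n2`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$u  # complete separation: 0
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  if (!length(x) || !length(y)) {
    stop("Both samples must be non-empty.", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (exact) {
    if (any(duplicated(c(x, y)))) {
      stop("Exact enumeration requires untied samples.", call. = FALSE)
    }
    if (n1 + n2 > 12) {
      stop("Exact enumeration supported only for n1 + n2 <= 12.",
           call. = FALSE)
    }
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    z <- NA_real_
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(c(x, y))
    tie_adj <- sum(ties^3 - ties) / (nn * (nn - 1))
    v <- n1 * n2 / 12 * (nn + 1 - tie_adj)
    if (v == 0) {
      z <- 0
      p <- 1
    } else {
      z <- (u - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  tibble::tibble(u = u, z = z, p_value = p, n1 = n1, n2 = n2,
                 method = method)
}

#' Cohen's d with pooled standard deviation
#'
#' Standardised mean difference `(mean1 - mean2) / s_p` with the
#' `(n-1)`-weighted pooled variance
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (non-negative).
#' @param n1,n2 Group sizes (at least 2).
#' @return Cohen's d.
#' @examples
#' cohen_d_pooled(67.02, 2.57, 97, 66.05, 2.67, 97)
#' @export
cohen_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0)) stop("SDs must be non-negative.", call. = FALSE)
  if (any(c(n1, n2) < 2)) stop("Group sizes must be at least 2.",
                               call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (any(sp2 == 0)) stop("Pooled SD is zero.", call. = FALSE)
  (mean1 - mean2) / sqrt(sp2)
}

#' Percentage-weighted mean start age
#'
#' `sum(age * pct) / sum(pct)` over a distribution of chosen start ages,
#' as used to summarise retirement-menu responses.
#'
#' @param start_age Vector of ages (years).
#' @param pct Percentage choosing each age (should sum to roughly 100).
#' @return The weighted mean age in years.
#' @examples
#' f <- fixtures_experiment4()
#' weighted_mean_age(f$start_age, f$pct_cancellation)  # 67.02
#' @export
weighted_mean_age <- function(start_age, pct) {
  if (!length(start_age) || length(start_age) != length(pct)) {
    stop("`start_age` and `pct` must be non-empty and equal length.",
         call. = FALSE)
  }
  if (sum(pct) <= 0) stop("Percentages must have positive mass.",
                          call. = FALSE)
  sum(start_age * pct) / sum(pct)
}

#' Reconstruct 2x2 counts from rounded condition percentages
#'
#' Published binary-choice results often report only the per-condition
#' percentage choosing the later option (to one decimal place) and the
#' total N. This enumerates every split of N into two group sizes and
#' every integer count whose rounded percentage matches, recovering the
#' contingency table(s) consistent with the printed summary.
#'
#' Rounded percentages can be ambiguous (several splits of N may round to
#' the same pair); when the published report also prints 95% confidence
#' intervals for the percentages, passing them as `ci1` / `ci2` filters
#' the candidates to those whose Wilson score interval rounds to the
#' printed limits, which typically restores uniqueness.
#'
#' @param pct1,pct2 Later-choice percentages in condition 1 / condition 2,
#'   rounded to `decimal_places`.
#' @param n_total Total sample size across both conditions.
#' @param decimal_places Precision of the printed percentages (default 1).
#' @param ci1,ci2 Optional length-2 vectors: the printed 95% CI limits
#'   (in percent, same precision) for each condition's percentage.
#' @return A tibble of candidate tables (`n1`, `later1`, `n2`, `later2`)
#'   with a `unique` column flagging whether a single candidate exists;
#'   errors when none is consistent.
#' @examples
#' reconstruct_counts(77.8, 52.0, 147)  # two candidates
#' reconstruct_counts(77.8, 52.0, 147,
#'                    ci1 = c(66.9, 85.8), ci2 = c(40.9, 62.9))
#' @export
reconstruct_counts <- function(pct1, pct2, n_total, decimal_places = 1,
                               ci1 = NULL, ci2 = NULL) {
  hits <- list()
  for (n1 in seq_len(n_total - 1)) {
    n2 <- n_total - n1
    a <- which(round(100 * (0:n1) / n1, decimal_places) == pct1) - 1
    if (!length(a)) next
    b <- which(round(100 * (0:n2) / n2, decimal_places) == pct2) - 1
    if (!length(b)) next
    hits[[length(hits) + 1]] <-
      tidyr::expand_grid(n1 = n1, later1 = a, n2 = n2, later2 = b)
  }
  if (!length(hits)) {
    stop("No integer table is consistent with the printed percentages.",
         call. = FALSE)
  }
  out <- dplyr::bind_rows(hits)
  ci_ok <- function(k, n, ci) {
    if (is.null(ci)) return(rep(TRUE, length(k)))
    w <- wilson_ci(k, n)
    round(100 * w$lower, decimal_places) == ci[1] &
      round(100 * w$upper, decimal_places) == ci[2]
  }
  out <- out[ci_ok(out$later1, out$n1, ci1) &
               ci_ok(out$later2, out$n2, ci2), , drop = FALSE]
  if (!nrow(out)) {
    stop("No candidate table matches the supplied confidence intervals.",
         call. = FALSE)
  }
  out$unique <- nrow(out) == 1
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return A list with vectors `lower` and `upper` (proportions).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = centre - half, upper = centre + half)
}

#' Contingency table from a reconstructed-count row
#'
#' Helper turning one [reconstruct_counts()] row into the 2x2 matrix
#' consumed by [pearson_chi2()] and [fisher_exact_2x2()] (rows =
#' conditions, columns = later/earlier).
#'
#' @param counts A one-row tibble with `n1`, `later1`, `n2`, `later2`.
#' @return A 2x2 integer matrix.
#' @export
counts_to_table <- function(counts) {
  stopifnot(nrow(counts) == 1)
  matrix(c(counts$later1, counts$n1 - counts$later1,
           counts$later2, counts$n2 - counts$later2),
         nrow = 2, byrow = TRUE,
         dimnames = list(condition = c("1", "2"),
                         choice = c("later", "earlier")))
}

as_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("Expected a 2x2 table.", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  if (sum(tab) == 0) stop("Table is empty.", call. = FALSE)
  tab
}
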