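#' Sample size for a df = 1 chi-square test of two proportions
#'
#' A priori total sample size to detect effect size `w` in a 2x2 design.
#' Two conventions are supported. One-tailed: the df = 1 chi-square test
#' of two proportions is equivalent to a one-sided two-proportion z-test,
#' giving the closed form `N = ceiling(((z_(1-alpha) + z_power) / w)^2)`.
#' Two-tailed: the smallest N whose noncentral chi-square power (df = 1,
#' noncentrality `N w^2`) reaches the target at the central critical
#' value.
#'
#' @param w Cohen's w effect size, positive.
#' @param alpha_level Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param tails 1 or 2.
#' @return Total N across both groups.
#' @examples
#' required_n_chi2_df1(w = 0.27, tails = 1)  # 85
#' @export
required_n_chi2_df1 <- function(w, alpha_level = 0.05, power = 0.80,
                                tails = 2) {
  check_power_spec(w, alpha_level, power)
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2.", call. = FALSE)
  if (tails == 1) {
    return(ceiling(((stats::qnorm(1 - alpha_level) + stats::qnorm(power)) /
                      w)^2))
  }
  crit <- stats::qchisq(1 - alpha_level, df = 1)
  n <- 4
  repeat {
    if (stats::pchisq(crit, df = 1, ncp = n * w^2,
                      lower.tail = FALSE) >= power) {
      return(n)
    }
    n <- n + 1
    if (n > 1e7) stop("Sample-size search did not converge.", call. = FALSE)
  }
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest per-group n such that a two-sided two-sample t-test at level
#' `alpha_level` has power at least `power` against a standardised mean
#' difference of `d`, using the exact noncentral-t power with
#' noncentrality `|d| sqrt(n/2)` and `2n - 2` degrees of freedom.
#'
#' @param d Cohen's d (its sign is ignored), non-zero.
#' @param alpha_level Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @return Participants per group.
#' @examples
#' required_n_two_sample_t(d = 0.60)  # 45 per group
#' @export
required_n_two_sample_t <- function(d, alpha_level = 0.05, power = 0.80) {
  d <- abs(d)
  check_power_spec(d, alpha_level, power)
  n <- 2
  repeat {
    df <- 2 * n - 2
    crit <- stats::qt(1 - alpha_level / 2, df)
    ncp <- d * sqrt(n / 2)
    pw <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
    if (pw >= power) return(n)
    n <- n + 1
    if (n > 1e6) stop("Sample-size search did not converge.", call. = FALSE)
  }
}

check_power_spec <- function(effect, alpha_level, power) {
  if (effect <= 0) stop("Effect size must be positive.", call. = FALSE)
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("`alpha_level` must lie in (0, 1).", call. = FALSE)
  }
  if (power <= 0 || power >= 1) {
    stop("`power` must lie in (0, 1).", call. = FALSE)
  }
  invisible(TRUE)
}
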