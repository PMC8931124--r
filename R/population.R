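#' Draw a synthetic agent population
#'
#' Samples agents with CRRA curvature `alpha`, present bias `beta` and
#' per-day discount factor `delta` from independent truncated normal
#' distributions. The default location/scale parameters are the empirical
#' descriptive moments of structurally estimated time preferences
#' (alpha 0.8861 / 0.1255, beta 0.9977 / 0.1645, delta 0.9988 / 0.0068),
#' truncated to the model's admissible ranges: `alpha` in (0, 1], `beta`
#' positive, `delta` in (0, 1]. Because the admissible upper bound 1 sits
#' inside the mass of the alpha and delta normals, the realised truncated
#' means fall below the location parameters (about 0.846 and 0.994
#' respectively); [truncnorm_moments()] gives the analytic values.
#'
#' Draws use inverse-CDF truncation, so they are exact (no rejection) and
#' reproducible under the seed.
#'
#' @param n_agents Number of agents, at least 1.
#' @param alpha_mean,alpha_sd,beta_mean,beta_sd,delta_mean,delta_sd
#'   Location and scale of the underlying normals (`sd = 0` collapses a
#'   parameter to its location, clipped to the truncation window).
#' @param alpha_bounds,beta_bounds,delta_bounds Length-2 truncation
#'   windows (lower, upper).
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `alpha`, `beta`, `delta`.
#' @examples
#' pop <- sample_population(5, seed = 1)
#' @export
sample_population <- function(n_agents,
                              alpha_mean = 0.8861, alpha_sd = 0.1255,
                              beta_mean = 0.9977, beta_sd = 0.1645,
                              delta_mean = 0.9988, delta_sd = 0.0068,
                              alpha_bounds = c(1e-6, 1),
                              beta_bounds = c(1e-6, Inf),
                              delta_bounds = c(1e-6, 1),
                              seed = NULL) {
  if (n_agents < 1) stop("`n_agents` must be at least 1.", call. = FALSE)
  if (any(c(alpha_sd, beta_sd, delta_sd) < 0)) {
    stop("Standard deviations must be non-negative.", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  tibble::tibble(
    subject_id = seq_len(n_agents),
    alpha = rtruncnorm(n_agents, alpha_mean, alpha_sd, alpha_bounds),
    beta = rtruncnorm(n_agents, beta_mean, beta_sd, beta_bounds),
    delta = rtruncnorm(n_agents, delta_mean, delta_sd, delta_bounds)
  )
}

# Exact inverse-CDF truncated-normal sampler.
rtruncnorm <- function(n, mean, sd, bounds) {
  lo <- bounds[1]
  hi <- bounds[2]
  if (!(lo < hi)) stop("Degenerate truncation window.", call. = FALSE)
  if (sd == 0) {
    return(rep(min(max(mean, lo), hi), n))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo <= 0) {
    stop("Truncation window carries no probability mass.", call. = FALSE)
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Analytic moments of a truncated normal
#'
#' Mean and standard deviation of a normal with the given location and
#' scale truncated to `bounds`. Used to document (and test) what the
#' population sampler actually draws once the admissible-range truncation
#' is applied.
#'
#' @inheritParams sample_population
#' @param mean,sd Location and scale of the underlying normal.
#' @param bounds Length-2 truncation window.
#' @return A named list with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mean, sd, bounds) {
  a <- (bounds[1] - mean) / sd
  b <- (bounds[2] - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (aa - bb) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}
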