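#' Utility-maximising token allocation for a convex-time-budget task
#'
#' Solves, for one agent and one task, the allocation of the token budget
#' between the earlier and the later date that maximises beta-delta
#' discounted CRRA utility
#' `(1/alpha) delta^t (n a_t)^alpha + (1/alpha) beta^I delta^(t+k) ((B-n) a_tk)^alpha`
#' over `n` in `[0, B]`, with `I = 1` iff `t = 0`. For `alpha < 1` the
#' first-order condition `(c_t / c_(t+k))^(alpha-1) = beta^I delta^k (a_tk / a_t)`
#' has the closed-form interior solution
#' `n = B s a_tk / (a_t + s a_tk)` with `s = R^(1/(alpha-1))` and
#' `R = beta^I delta^k a_tk / a_t`, which always lies inside the budget.
#' For linear utility (`alpha = 1`) the optimum is a corner: all tokens go
#' later when `beta^I delta^k a_tk >= a_t` (ties to later) and all early
#' otherwise.
#'
#' @param alpha,beta,delta Agent preferences (vectorised).
#' @param a_t,a_tk Per-token values at the earlier/later date,
#'   `a_tk > a_t > 0`.
#' @param t_days Delay of the earlier date (0 or more days).
#' @param k_days Delay between the two dates, at least 1 day.
#' @param budget_tokens Token budget (default 50).
#' @return Tokens allocated to the earlier date, in `[0, budget_tokens]`.
#' @examples
#' foc_allocation(alpha = 0.5, beta = 1, delta = 0.999,
#'                a_t = 0.16, a_tk = 0.20, t_days = 7, k_days = 35)
#' @export
foc_allocation <- function(alpha, beta, delta, a_t, a_tk,
                           t_days, k_days, budget_tokens = 50) {
  check_prefs(alpha, beta, delta)
  if (any(a_t <= 0) || any(a_tk <= a_t)) {
    stop("Token values must satisfy a_tk > a_t > 0.", call. = FALSE)
  }
  if (any(alpha > 1)) {
    stop("`alpha` above 1 (convex utility) is outside the model.",
         call. = FALSE)
  }
  len <- length(alpha + beta + delta + a_t + a_tk + t_days + k_days +
                  budget_tokens)
  alpha <- rep_len(alpha, len); beta <- rep_len(beta, len)
  delta <- rep_len(delta, len); a_t <- rep_len(a_t, len)
  a_tk <- rep_len(a_tk, len); t_days <- rep_len(t_days, len)
  k_days <- rep_len(k_days, len); budget <- rep_len(budget_tokens, len)

  bias <- ifelse(t_days == 0, beta, 1)
  r <- bias * delta^k_days * a_tk / a_t
  out <- numeric(len)
  lin <- alpha == 1
  # linear: corner, ties to the later date
  out[lin] <- ifelse(r[lin] >= 1, 0, budget[lin])
  if (any(!lin)) {
    i <- !lin
    s <- r[i]^(1 / (alpha[i] - 1))
    n <- budget[i] * s * a_tk[i] / (a_t[i] + s * a_tk[i])
    out[i] <- pmin(pmax(n, 0), budget[i])
  }
  out
}

#' Estimate time preferences from one subject's allocations
#'
#' Recovers `(alpha, beta, delta)` from convex-time-budget allocations by
#' least squares on the log-linearised first-order condition
#' `ln(c_t / c_(t+k)) = b0 I + b1 k + b2 ln(a_tk / a_t)` (no intercept),
#' inverted as `alpha = 1 + 1/b2`, `delta = exp(b1 / b2)`,
#' `beta = exp(b0 / b2)`. Corner allocations (either date empty) have no
#' interior first-order condition; they are dropped from the fit and
#' counted. Inconsistent choice patterns can produce a negative estimated
#' curvature; such estimates are reported as-is and flagged, never
#' clipped, so that downstream analyses can apply the standard drop rule
#' via [exclusion_filter()].
#'
#' @param allocations A tibble of one subject's allocations with columns
#'   `a_t`, `a_tk`, `t_days`, `k_days`, `budget_tokens`, `tokens_early`
#'   (as produced by [simulate_cbs()]).
#' @param corner_tol Allocations within this many tokens of 0 or the
#'   budget are treated as corners.
#' @return A one-row tibble: `alpha_hat`, `beta_hat`, `delta_hat`,
#'   `n_interior`, `n_corner`, `negative_alpha_flag`, `residual_sse`.
#' @examples
#' pop <- sample_population(1, seed = 2)
#' alloc <- simulate_cbs(pop, cbs_tasks())
#' estimate_preferences(alloc)
#' @export
estimate_preferences <- function(allocations, corner_tol = 1e-9) {
  validate_cbs_tasks(allocations)
  if (any(allocations$tokens_early < -corner_tol) ||
      any(allocations$tokens_early > allocations$budget_tokens + corner_tol)) {
    stop("`tokens_early` must lie within the token budget.", call. = FALSE)
  }
  corner <- allocations$tokens_early <= corner_tol |
    allocations$tokens_early >= allocations$budget_tokens - corner_tol
  interior <- allocations[!corner, , drop = FALSE]

  identified <- nrow(interior) >= 3 &&
    length(unique(interior$k_days)) >= 2 &&
    length(unique(interior$t_days == 0)) >= 2
  if (!identified) {
    stop("Under-identified: need at least 3 interior allocations spanning ",
         "two k values and both immediate and delayed earlier dates.",
         call. = FALSE)
  }

  c_t <- interior$tokens_early * interior$a_t
  c_tk <- (interior$budget_tokens - interior$tokens_early) * interior$a_tk
  dat <- data.frame(
    lr = log(c_t / c_tk),
    i0 = as.numeric(interior$t_days == 0),
    k = interior$k_days,
    lp = log(interior$a_tk / interior$a_t)
  )
  fit <- stats::lm(lr ~ 0 + i0 + k + lp, data = dat)
  b <- stats::coef(fit)
  alpha_hat <- 1 + 1 / b[["lp"]]
  tibble::tibble(
    alpha_hat = alpha_hat,
    beta_hat = exp(b[["i0"]] / b[["lp"]]),
    delta_hat = exp(b[["k"]] / b[["lp"]]),
    n_interior = nrow(interior),
    n_corner = sum(corner),
    negative_alpha_flag = alpha_hat < 0,
    residual_sse = sum(stats::resid(fit)^2)
  )
}

#' Estimate time preferences for every subject in an allocation table
#'
#' Applies [estimate_preferences()] subject by subject.
#'
#' Subjects whose allocations are under-identified (e.g. near-linear
#' utility puts every task at a corner) are omitted with a warning giving
#' their count; they are thereby excluded from downstream analyses just
#' like negative-curvature subjects.
#'
#' @param allocations A multi-subject allocation tibble with a
#'   `subject_id` column.
#' @param corner_tol Passed to [estimate_preferences()].
#' @return A tibble with one row per estimable subject: `subject_id` plus
#'   the [estimate_preferences()] columns.
#' @export
estimate_population <- function(allocations, corner_tol = 1e-9) {
  split_ids <- unique(allocations$subject_id)
  rows <- purrr::map(split_ids, function(sid) {
    one <- allocations[allocations$subject_id == sid, , drop = FALSE]
    tryCatch(
      dplyr::bind_cols(tibble::tibble(subject_id = sid),
                       estimate_preferences(one, corner_tol = corner_tol)),
      error = function(e) NULL
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " subject(s) under-identified and omitted from the ",
            "estimate table.", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Drop subjects with negative estimated curvature
#'
#' The standard pre-regression exclusion: subjects whose estimated
#' `alpha` is negative (inconsistent allocation behaviour) are removed
#' before any downstream analysis, and the counts are reported.
#'
#' @param estimates An estimate tibble from [estimate_population()] (or a
#'   one-row result), containing `negative_alpha_flag`.
#' @return A list with elements `retained` (tibble), `n_excluded` and
#'   `n_retained`. Warns when every subject is excluded.
#' @examples
#' est <- tibble::tibble(subject_id = 1:3, alpha_hat = c(0.9, -0.2, 0.8),
#'                       negative_alpha_flag = c(FALSE, TRUE, FALSE))
#' exclusion_filter(est)$n_excluded
#' @export
exclusion_filter <- function(estimates) {
  flagged <- estimates$negative_alpha_flag
  retained <- estimates[!flagged, , drop = FALSE]
  if (nrow(retained) == 0 && nrow(estimates) > 0) {
    warning("All subjects excluded by the negative-curvature rule.",
            call. = FALSE)
  }
  list(
    retained = retained,
    n_excluded = sum(flagged),
    n_retained = nrow(retained)
  )
}

validate_cbs_tasks <- function(tasks) {
  needed <- c("a_t", "a_tk", "t_days", "k_days", "budget_tokens")
  missing <- setdiff(needed, names(tasks))
  if (length(missing)) {
    stop("Task table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tasks$a_t <= 0) || any(tasks$a_tk <= tasks$a_t)) {
    stop("Task token values must satisfy a_tk > a_t > 0.", call. = FALSE)
  }
  if (any(tasks$k_days < 1)) stop("`k_days` must be at least 1.", call. = FALSE)
  invisible(TRUE)
}
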