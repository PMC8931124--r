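#' Random-intercept panel logit for trial-level choices
#'
#' Fits a subject-random-intercept logistic regression of the later-choice
#' indicator on framing condition and time-preference covariates by
#' maximum likelihood with adaptive Gauss-Hermite quadrature
#' (via [lme4::glmer()]). Three nested specifications mirror the standard
#' reporting ladder:
#' \describe{
#'   \item{1}{`cancellation` only;}
#'   \item{2}{adds `t0` and the subject's estimated `alpha`, `delta`,
#'     `beta`;}
#'   \item{3}{adds the `cancellation x t0` and `cancellation x alpha`
#'     interactions — the curvature-moderation specification.}
#' }
#' Subjects flagged by the negative-curvature exclusion rule should be
#' removed upstream (see [exclusion_filter()]). The random intercept is
#' the within-subject clustering correction; reported standard errors are
#' the model-based (Wald) ML errors.
#'
#' @param trials Trial-level tibble (from [simulate_binary_experiment()]
#'   or [read_trials()]) with `subject_id`, `condition`, `t0`,
#'   `choice_later`.
#' @param estimates Per-subject estimates with `subject_id`, `alpha_hat`,
#'   `beta_hat`, `delta_hat`; required for specifications 2 and 3.
#' @param specification 1, 2 or 3.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points.
#' @return An object of class `cancel_panel_logit`: a list with the
#'   fitted `lme4` model (`fit`), `specification`, `lnsig2u` (log
#'   random-intercept variance), `n_obs`, `n_clusters`, and the
#'   model frame used. Methods: [tidy()], [glance()], `print()`.
#' @export
panel_logit <- function(trials, estimates = NULL, specification = 3,
                        nAGQ = 25) {
  if (!specification %in% 1:3) {
    stop("`specification` must be 1, 2 or 3.", call. = FALSE)
  }
  dat <- tibble::as_tibble(trials)
  dat$cancellation <- as.numeric(dat$condition == "cancellation")
  if (specification >= 2) {
    if (is.null(estimates)) {
      stop("Specifications 2 and 3 need per-subject `estimates`.",
           call. = FALSE)
    }
    dat <- dplyr::inner_join(
      dat,
      dplyr::select(estimates, "subject_id", alpha = "alpha_hat",
                    beta = "beta_hat", delta = "delta_hat"),
      by = "subject_id"
    )
  }
  form <- switch(specification,
    `1` = choice_later ~ cancellation + (1 | subject_id),
    `2` = choice_later ~ cancellation + t0 + alpha + delta + beta +
      (1 | subject_id),
    `3` = choice_later ~ cancellation + t0 + alpha + delta + beta +
      cancellation:t0 + cancellation:alpha + (1 | subject_id)
  )
  fit <- lme4::glmer(form, data = dat, family = stats::binomial(),
                     nAGQ = nAGQ)
  sig2u <- unname(lme4::VarCorr(fit)$subject_id[1, 1])
  structure(
    list(
      fit = fit,
      specification = specification,
      lnsig2u = log(sig2u),
      sigma2_u = sig2u,
      n_obs = nrow(dat),
      n_clusters = length(unique(dat$subject_id)),
      data = dat
    ),
    class = "cancel_panel_logit"
  )
}

#' Average marginal effects of a panel logit
#'
#' For each fixed-effect regressor, the sample-average derivative of the
#' predicted later-choice probability with respect to that regressor,
#' holding the others fixed. By default probabilities are evaluated at a
#' zero random intercept (the modal subject); `integrate = TRUE` instead
#' averages the derivative over the estimated random-intercept
#' distribution by Gauss-Hermite quadrature (the population-averaged
#' variant).
#'
#' @param object A `cancel_panel_logit`.
#' @param integrate Average over the random-intercept distribution?
#' @param gh_points Quadrature points used when `integrate = TRUE`.
#' @return A tibble with `term` and `ame`.
#' @export
panel_logit_ame <- function(object, integrate = FALSE, gh_points = 21) {
  x <- stats::model.matrix(object$fit)
  b <- lme4::fixef(object$fit)
  eta <- drop(x %*% b)
  if (!integrate) {
    w <- mean(stats::dlogis(eta))
  } else {
    # Gauss-Hermite nodes for N(0, sigma_u^2), via eigen decomposition of
    # the Jacobi matrix (Golub-Welsch).
    gh <- gauss_hermite(gh_points)
    sd_u <- sqrt(object$sigma2_u)
    w <- mean(vapply(
      eta,
      function(e) sum(gh$weights * stats::dlogis(e + sqrt(2) * sd_u *
                                                   gh$nodes)) / sqrt(pi),
      numeric(1)
    ))
  }
  terms <- setdiff(names(b), "(Intercept)")
  tibble::tibble(term = terms, ame = unname(b[terms]) * w)
}

# Golub-Welsch Gauss-Hermite rule (physicists' weight exp(-x^2)).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  jac <- matrix(0, n, n)
  off <- sqrt(i / 2)
  jac[cbind(i, i + 1)] <- off
  jac[cbind(i + 1, i)] <- off
  eig <- eigen(jac, symmetric = TRUE)
  list(nodes = eig$values,
       weights = sqrt(pi) * eig$vectors[1, ]^2)
}

#' @export
print.cancel_panel_logit <- function(x, ...) {
  cat("Random-intercept panel logit (specification ", x$specification,
      ")\n", sep = "")
  cat("  observations: ", x$n_obs, "; clusters (subjects): ",
      x$n_clusters, "\n", sep = "")
  cat("  lnsig2u: ", format(x$lnsig2u, digits = 4), "\n\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a panel logit fit
#'
#' Coefficients, model-based standard errors, z statistics, p-values and
#' average marginal effects, one row per fixed-effect term.
#'
#' @param x A `cancel_panel_logit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `ame`.
#' @export
tidy.cancel_panel_logit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "z value"]),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
  dplyr::left_join(out, panel_logit_ame(x), by = "term")
}

#' Glance at a panel logit fit
#'
#' @param x A `cancel_panel_logit`.
#' @param ... Unused.
#' @return A one-row tibble with `lnsig2u`, `sigma2_u`, `n_obs`,
#'   `n_clusters`, `log_lik`, `aic`, `specification`.
#' @export
glance.cancel_panel_logit <- function(x, ...) {
  ll <- stats::logLik(x$fit)
  tibble::tibble(
    lnsig2u = x$lnsig2u,
    sigma2_u = x$sigma2_u,
    n_obs = x$n_obs,
    n_clusters = x$n_clusters,
    log_lik = as.numeric(ll),
    aic = stats::AIC(x$fit),
    specification = x$specification
  )
}

#' OLS moderation analysis for retirement-age choices
#'
#' Ordinary least squares of the chosen start age on the cancellation
#' dummy, respondent age and income, and the age-by-condition and
#' income-by-condition interactions, testing whether demographics
#' moderate the framing effect.
#'
#' @param choices A tibble with columns `start_age`, `condition`
#'   (`"baseline"` / `"cancellation"`), `age`, `income` (complete cases).
#' @return A list with `fit` (the `lm` object) and `coefficients`
#'   (a broom-style tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`). Collinear terms are reported with `NA` estimates via a
#'   warning.
#' @export
ols_moderation <- function(choices) {
  needed <- c("start_age", "condition", "age", "income")
  missing <- setdiff(needed, names(choices))
  if (length(missing)) {
    stop("`choices` lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(choices[needed])) {
    stop("Covariates must be complete.", call. = FALSE)
  }
  dat <- tibble::as_tibble(choices)
  dat$cancellation <- as.numeric(dat$condition == "cancellation")
  fit <- stats::lm(
    start_age ~ cancellation + age + income +
      cancellation:age + cancellation:income,
    data = dat
  )
  if (anyNA(stats::coef(fit))) {
    warning("Collinear predictors: some coefficients are not estimable.",
            call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  list(
    fit = fit,
    coefficients = tibble::tibble(
      term = rownames(sm),
      estimate = unname(sm[, 1]),
      std_error = unname(sm[, 2]),
      statistic = unname(sm[, 3]),
      p_value = unname(sm[, 4])
    )
  )
}
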