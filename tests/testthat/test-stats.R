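test_that("Pearson chi-square matches the closed form, base R, and known tables", {
  tab <- matrix(c(56, 16, 39, 36), 2, byrow = TRUE)
  res <- pearson_chi2(tab)
  expect_equal(round(res$statistic, 2), 10.68)
  expect_equal(round(res$cohen_w, 2), 0.27)
  expect_equal(res$statistic,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  # independence and perfect-association references
  expect_equal(pearson_chi2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(pearson_chi2(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  # random tables agree with base R's uncorrected statistic
  set.seed(8)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(pearson_chi2(t2)$statistic,
                 unname(stats::chisq.test(t2, correct = FALSE)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
})

test_that("Fisher exact p agrees with enumeration and base R everywhere tested", {
  tab <- matrix(c(56, 16, 39, 36), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(tab), 3), 0.002)
  expect_equal(fisher_exact_2x2(tab),
               stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  # every 2x2 table with N <= 10 and positive margins, vs the factorial
  # enumeration oracle and base R
  grids <- expand.grid(a = 0:6, b = 0:6, c = 0:6, d = 0:6)
  grids <- grids[rowSums(grids) <= 10 & rowSums(grids) > 0, ]
  keep <- with(grids, (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0)
  grids <- grids[keep, ]
  set.seed(3)
  grids <- grids[sample(nrow(grids), 150), ]
  for (i in seq_len(nrow(grids))) {
    t2 <- matrix(unlist(grids[i, ]), 2, byrow = TRUE)
    p <- fisher_exact_2x2(t2)
    expect_equal(p, oracle_fisher_enum(t2), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(t2)$p.value, tolerance = 1e-7)
  }
})

test_that("Mann-Whitney U, tie-corrected z and p behave as specified", {
  # complete separation and identical samples
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$u, 0)
  same <- mann_whitney(rep(1:3, 2), rep(1:3, 2))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # tie-corrected normal approximation matches base R (no continuity corr.)
  set.seed(12)
  for (i in 1:15) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(2:8, 11, replace = TRUE)
    mine <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  # exact enumeration matches base R's exact test for small untied samples
  set.seed(13)
  for (i in 1:10) {
    z <- sample(1:40, 9)
    x <- z[1:4]; y <- z[5:9]
    mine <- mann_whitney(x, y, exact = TRUE)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney(c(1, 1, 2), c(2, 3), exact = TRUE), "untied")
})

test_that("pooled Cohen's d reproduces the published effect sizes", {
  # equal-n case from the retirement study's under-62 analysis
  expect_equal(round(cohen_d_pooled(67.02, 2.57, 97, 66.05, 2.67, 97), 2),
               0.37)
  # unequal-n arithmetic on the gain-trial summary (40/35 split)
  expect_equal(round(cohen_d_pooled(56, 41.92, 40, 84.57, 29.34, 35), 2),
               -0.78)
  expect_equal(cohen_d_pooled(5, 1, 10, 5, 2, 10), 0)
  expect_error(cohen_d_pooled(1, 0, 5, 2, 0, 5), "zero")
})

test_that("sample-size routines hit the published values and are monotone", {
  expect_equal(required_n_chi2_df1(0.27, tails = 1), 85)
  expect_equal(required_n_two_sample_t(0.60), 45)
  expect_equal(required_n_two_sample_t(0.48), 70)  # 140 in total
  expect_equal(required_n_chi2_df1(0.23, tails = 2), 149)
  # monotone in effect size and in target power
  ws <- c(0.1, 0.2, 0.3, 0.5)
  expect_true(all(diff(sapply(ws, required_n_chi2_df1)) < 0))
  ds <- c(0.2, 0.4, 0.6, 0.8)
  expect_true(all(diff(sapply(ds, required_n_two_sample_t)) < 0))
  expect_lt(required_n_two_sample_t(0.6, power = 0.5),
            required_n_two_sample_t(0.6, power = 0.95))
  # achieved power at the returned n really clears the target
  n <- required_n_two_sample_t(0.6)
  crit <- qt(0.975, 2 * n - 2)
  pw <- pt(crit, 2 * n - 2, ncp = 0.6 * sqrt(n / 2), lower.tail = FALSE) +
    pt(-crit, 2 * n - 2, ncp = 0.6 * sqrt(n / 2))
  expect_gte(pw, 0.80)
  expect_error(required_n_chi2_df1(-0.2), "positive")
})

test_that("count reconstruction finds all candidates and flags ambiguity", {
  plain <- reconstruct_counts(77.8, 52.0, 147)
  expect_equal(nrow(plain), 2)
  expect_false(any(plain$unique))
  # the printed confidence intervals single out the published table
  rc <- reconstruct_counts(77.8, 52.0, 147,
                           ci1 = c(66.9, 85.8), ci2 = c(40.9, 62.9))
  expect_true(rc$unique)
  expect_equal(rc$n1, 72)
  expect_equal(rc$later1, 56)
  expect_equal(rc$n2, 75)
  expect_equal(rc$later2, 39)
  # verify every candidate really rounds to the printed percentages
  for (i in seq_len(nrow(plain))) {
    expect_equal(round(100 * plain$later1[i] / plain$n1[i], 1), 77.8)
    expect_equal(round(100 * plain$later2[i] / plain$n2[i], 1), 52.0)
  }
  # genuinely ambiguous summaries: several splits of 8 give 50.0%/50.0%,
  # and a 100%/0% split of 10 is consistent with every group division
  amb <- reconstruct_counts(50.0, 50.0, 8)
  expect_gt(nrow(amb), 1)
  expect_false(any(amb$unique))
  all_or_none <- reconstruct_counts(100.0, 0.0, 10)
  expect_equal(nrow(all_or_none), 9)
  expect_false(any(all_or_none$unique))
  expect_error(reconstruct_counts(33.9, 71.2, 5), "consistent")
})

test_that("weighted mean age reproduces both menu columns", {
  f4 <- fixtures_experiment4()
  expect_equal(weighted_mean_age(f4$start_age, f4$pct_cancellation), 67.02)
  # recomputed baseline mean is 66.06 (the printed 66.05 reflects
  # unrounded percentages)
  expect_equal(weighted_mean_age(f4$start_age, f4$pct_baseline), 66.06)
  expect_equal(weighted_mean_age(65, 100), 65)
  expect_error(weighted_mean_age(numeric(0), numeric(0)), "non-empty")
})

test_that("OLS moderation matches the normal equations and detects null moderation", {
  # five-respondent worked example against solve(t(X) X) t(X) y
  ch <- tibble::tibble(
    start_age = c(64, 66, 70, 62, 67),
    condition = c("baseline", "cancellation", "cancellation", "baseline",
                  "baseline"),
    age = c(30, 45, 52, 28, 39),
    income = c(3, 6, 8, 2, 5)
  )
  expect_warning(fit <- ols_moderation(ch), "Collinear")
  cz <- as.numeric(ch$condition == "cancellation")
  x <- cbind(1, cz, ch$age, ch$income, cz * ch$age, cz * ch$income)
  # two interaction columns are collinear with so few points; drop one
  x <- x[, 1:5]
  beta_hand <- unname(drop(solve(t(x) %*% x, t(x) %*% ch$start_age)))
  expect_equal(fit$coefficients$estimate[1:5], beta_hand,
               tolerance = 1e-8)

  # generator truth: demographics that never influenced choices give
  # interactions indistinguishable from zero
  pop <- default_population(300, seed = 61)
  rep4 <- run_experiment(4, population = pop, seed = 61)
  co <- rep4$ols$coefficients
  inter <- co[grepl(":", co$term), ]
  expect_true(all(inter$p_value > 0.01))

  # constant outcome: all slopes vanish
  flat <- ch
  flat$start_age <- 65
  co2 <- suppressWarnings(ols_moderation(flat)$coefficients)
  expect_true(all(abs(co2$estimate[-1]) < 1e-10, na.rm = TRUE))
})

test_that("panel logit collapses to plain logit without subject variance and integrates exactly", {
  # data truly generated without a random intercept
  set.seed(91)
  n_sub <- 60
  dat <- tidyr::expand_grid(subject_id = 1:n_sub, trial = 1:8)
  dat$condition <- ifelse(dat$subject_id <= n_sub / 2, "baseline",
                          "cancellation")
  dat$t0 <- as.integer(dat$trial %% 2 == 0)
  eta <- -0.3 + 1 * (dat$condition == "cancellation") + 0.5 * dat$t0
  dat$choice_later <- rbinom(nrow(dat), 1, plogis(eta))
  fit <- suppressMessages(panel_logit(dat, specification = 1, nAGQ = 15))
  glm_ref <- stats::glm(choice_later ~ I(condition == "cancellation"),
                        data = dat, family = binomial())
  expect_lt(fit$sigma2_u, 0.05)
  expect_equal(unname(lme4::fixef(fit$fit)),
               unname(coef(glm_ref)), tolerance = 1e-2)

  # small heterogeneous dataset (so the intercept variance is interior):
  # quadrature log-likelihood equals brute-force adaptive integration
  tiny <- tibble::tibble(
    subject_id = rep(1:6, each = 6),
    condition = rep(c("baseline", "cancellation"), each = 18),
    t0 = rep(c(0L, 1L), 18),
    choice_later = c(1, 1, 1, 1, 0, 1,  0, 0, 1, 0, 0, 0,
                     1, 1, 1, 0, 1, 1,  0, 1, 0, 0, 0, 0,
                     1, 0, 1, 1, 1, 1,  0, 0, 0, 1, 0, 0)
  )
  tf <- suppressMessages(panel_logit(tiny, specification = 1, nAGQ = 25))
  expect_gt(tf$sigma2_u, 0)
  x <- stats::model.matrix(tf$fit)
  ll_oracle <- oracle_ri_loglik(tf$data, lme4::fixef(tf$fit), x,
                                sqrt(tf$sigma2_u))
  expect_equal(as.numeric(stats::logLik(tf$fit)), ll_oracle,
               tolerance = 1e-6)
})

test_that("panel logit recovers known coefficients from a seeded simulation", {
  set.seed(101)
  n_sub <- 200
  dat <- tidyr::expand_grid(subject_id = 1:n_sub, trial = 1:10)
  cond <- sample(rep(c("baseline", "cancellation"), n_sub / 2))
  dat$condition <- cond[dat$subject_id]
  dat$t0 <- as.integer(dat$trial <= 5)
  u <- rnorm(n_sub, 0, 1)
  truth <- c(intercept = -0.5, cancellation = 1.2, t0 = 0.6)
  eta <- truth["intercept"] + truth["cancellation"] *
    (dat$condition == "cancellation") + truth["t0"] * dat$t0 +
    u[dat$subject_id]
  dat$choice_later <- rbinom(nrow(dat), 1, plogis(eta))
  fit <- panel_logit(dat, specification = 1, nAGQ = 15)
  td <- tidy(fit)
  est <- td$estimate[td$term == "cancellation"]
  se <- td$std_error[td$term == "cancellation"]
  expect_lt(abs(est - truth["cancellation"]), 2 * se + 0.1)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 2000)
  expect_equal(gl$n_clusters, 200)
  expect_true(is.finite(gl$lnsig2u))
  # AME equals coefficient times mean logistic density at the linear pred.
  x <- stats::model.matrix(fit$fit)
  w <- mean(stats::dlogis(drop(x %*% lme4::fixef(fit$fit))))
  expect_equal(td$ame[td$term == "cancellation"], est * w,
               tolerance = 1e-10)
  # integrating over the random intercept attenuates the AME scale factor
  ame_int <- panel_logit_ame(fit, integrate = TRUE)
  expect_true(all(is.finite(ame_int$ame)))
})
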