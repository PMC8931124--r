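test_that("instant utility matches the CRRA kernel and rejects bad input", {
  expect_equal(instant_utility(5, alpha = 1), 5)
  expect_equal(instant_utility(4, alpha = 0.5), 4)
  expect_equal(instant_utility(0, alpha = 0.5), 0)
  # strictly increasing and concave on a grid for alpha < 1
  x <- seq(0.1, 10, by = 0.1)
  u <- instant_utility(x, alpha = 0.6)
  expect_true(all(diff(u) > 0))
  expect_true(all(diff(diff(u)) < 0))
  expect_error(instant_utility(3, alpha = 0), "non-zero")
  expect_error(instant_utility(-1, alpha = 0.5), "non-negative")
})

test_that("discounted utility applies present bias only to immediate-earlier prospects", {
  expect_equal(discounted_utility(3, 0, 0, 7, alpha = 1), 3)
  # independent arithmetic: u(4; 0.5) = 4, biased and discounted
  expect_equal(
    discounted_utility(0, 0, 4, 7, alpha = 0.5, beta = 0.8, delta = 0.99),
    0.8 * 0.99^7 * 4,
    tolerance = 1e-12
  )
  # earlier date in the future: beta inactive
  expect_equal(
    discounted_utility(2, 7, 3, 14, alpha = 1, beta = 0.5, delta = 1), 5)
})

test_that("threshold formulas agree with numeric indifference roots", {
  cases <- expand.grid(x0 = c(2, 7), xk = c(3, 8, 12), k = c(7, 14),
                       alpha = c(0.5, 0.8861, 1), beta = c(0.8, 1))
  cases <- cases[cases$xk > cases$x0, ]
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(
      delta_star(cs$x0, cs$xk, cs$k, cs$alpha, cs$beta),
      oracle_delta_root(cs$x0, cs$xk, cs$k, cs$alpha, cs$beta),
      tolerance = 1e-8
    )
  }
  expect_equal(delta_star(2, 3, 7), 0.9437221, tolerance = 1e-6)
  expect_equal(delta_star(7, 8, 7), 0.9811049, tolerance = 1e-6)
  # equal-amount limit: threshold tends to 1
  expect_equal(delta_star(0.999999, 1, 7), 1, tolerance = 1e-5)
  expect_error(delta_star(3, 3, 7), "exceed")
  expect_error(delta_star(0, 3, 7), "positive")
})

test_that("cancelled threshold works on residuals, zero residual and the c -> 0 limit", {
  expect_equal(delta_star_cancelled(2, 3, common = 1, k = 7),
               0.9057237, tolerance = 1e-6)
  expect_equal(delta_star_cancelled(2, 3, common = 1, k = 7),
               oracle_delta_root(1, 2, 7), tolerance = 1e-8)
  # zero earlier residual: later always preferred
  expect_equal(delta_star_cancelled(3, 4, common = 3, k = 7, alpha = 0.7), 0)
  # continuity at c -> 0+
  expect_equal(delta_star_cancelled(2, 3, common = 1e-10, k = 7),
               delta_star(2, 3, 7), tolerance = 1e-8)
  expect_error(delta_star_cancelled(2, 3, common = 0, k = 7), "positive")
  expect_error(delta_star_cancelled(2, 3, common = 2.5, k = 7), "exceed")
})

test_that("threshold sensitivity matches finite differences of delta_star", {
  expect_equal(threshold_sensitivity(0.9437, 7, 2 / 3), -0.0546625,
               tolerance = 1e-5)
  h <- 1e-6
  for (a in c(0.4, 0.8, 1)) {
    fd <- (delta_star(2, 3, 7, a + h) - delta_star(2, 3, 7, a - h)) / (2 * h)
    expect_equal(threshold_sensitivity(delta_star(2, 3, 7, a), 7, 2 / 3),
                 fd, tolerance = 1e-4)
  }
  # vanishing sensitivity at equal amounts
  expect_lt(abs(threshold_sensitivity(1, 7, 1 - 1e-9)), 1e-8)
  expect_error(threshold_sensitivity(0.9, 7, 1.2), "between 0 and 1")
})

test_that("cancellation steepens the curvature sensitivity of the threshold", {
  rep_ <- threshold_report(2, 3, common = 1, k = 7)
  expect_lt(rep_$sensitivity_integrated, 0)
  expect_lt(rep_$sensitivity_cancelled, rep_$sensitivity_integrated)
  expect_gt(abs(rep_$sensitivity_cancelled), abs(rep_$sensitivity_integrated))
  # finite-difference confirmation on the cancelled threshold
  h <- 1e-6
  fd <- (delta_star_cancelled(2, 3, 1, 7, 1 + h) -
           delta_star_cancelled(2, 3, 1, 7, 1 - h)) / (2 * h)
  expect_equal(rep_$sensitivity_cancelled, fd, tolerance = 1e-4)
})

test_that("cancelled threshold sits strictly below the integrated one (random sweep)", {
  set.seed(42)
  n <- 2000
  x0 <- runif(n, 0.5, 20)
  xk <- x0 + runif(n, 0.1, 10)
  cc <- runif(n, 1e-3, 1 - 1e-3) * x0
  k <- sample(1:70, n, replace = TRUE)
  alpha <- runif(n, 0.05, 1)
  beta <- runif(n, 0.05, 1)
  ds <- delta_star(x0, xk, k, alpha, beta)
  dsc <- delta_star_cancelled(x0, xk, cc, k, alpha, beta)
  expect_true(all(dsc < ds))
  expect_true(all(dsc >= 0))
})

test_that("deterministic decide follows the threshold rule with ties to later", {
  p1 <- tibble::tibble(earlier_amount = 3, later_amount = 4,
                       earlier_delay_days = 0L, later_delay_days = 7L,
                       common_amount = 3)
  expect_equal(decide(p1, alpha = 1, delta = 0.99)$choice_later, 1)
  p2 <- tibble::tibble(earlier_amount = 7, later_amount = 8,
                       earlier_delay_days = 0L, later_delay_days = 7L,
                       common_amount = 7)
  expect_equal(decide(p2, alpha = 1, delta = 0.97,
                      frame = "integrated")$choice_later, 0)
  expect_equal(decide(p2, alpha = 1, delta = 0.97,
                      frame = "partitioned")$choice_later, 1)
  # exact indifference: tie goes to later
  dstar <- delta_star(3, 4, 7)
  tie <- decide(p1, alpha = 1, delta = dstar, frame = "integrated")
  expect_equal(tie$choice_later, 1)
})

test_that("noisy decide is logistic in the utility gap and converges to the rule", {
  pair <- tibble::tibble(earlier_amount = 3, later_amount = 4,
                         earlier_delay_days = 0L, later_delay_days = 7L,
                         common_amount = 0)
  # probability is exactly 1/2 at the indifference threshold
  dstar <- delta_star(3, 4, 7)
  p <- decide(pair, alpha = 1, delta = dstar, noise_temperature = 0.3,
              seed = 1)$p_later
  expect_equal(p, 0.5, tolerance = 1e-12)
  # temperature -> 0 recovers the deterministic probabilities
  for (d in c(0.93, 0.99)) {
    p_small <- decide(pair, alpha = 1, delta = d,
                      noise_temperature = 1e-9, seed = 1)$p_later
    p_det <- decide(pair, alpha = 1, delta = d)$p_later
    expect_equal(p_small, p_det, tolerance = 1e-6)
  }
  # seeded draws are reproducible
  a <- decide(pair, alpha = 1, delta = 0.96, noise_temperature = 0.5,
              seed = 9)$choice_later
  b <- decide(pair, alpha = 1, delta = 0.96, noise_temperature = 0.5,
              seed = 9)$choice_later
  expect_identical(a, b)
})

test_that("loss pairs map to kept wealth and partitioning suppresses later losses", {
  kept <- loss_to_gain_frame(3, 4, endowment = 10)
  expect_equal(kept$earlier_kept, 7)
  expect_equal(kept$later_kept, 6)
  kept0 <- loss_to_gain_frame(0, 1, endowment = 10)
  expect_equal(kept0$earlier_kept, 10)
  expect_equal(kept0$later_kept, 9)
  expect_error(loss_to_gain_frame(3, 3, 10), "exceed")
  expect_error(loss_to_gain_frame(3, 11, 10), "endowment")

  loss_pair <- tibble::tibble(earlier_amount = 3, later_amount = 4,
                              earlier_delay_days = 0L, later_delay_days = 7L,
                              common_amount = 3, domain = "loss",
                              endowment = 10)
  # an extremely present-biased-against agent (beta > 1) postpones the loss
  # under integrated framing but never under partitioning
  d_int <- decide(loss_pair, alpha = 0.9, beta = 1.3, delta = 0.999,
                  frame = "integrated")
  d_par <- decide(loss_pair, alpha = 0.9, beta = 1.3, delta = 0.999,
                  frame = "partitioned")
  expect_equal(d_int$choice_later, 1)
  expect_equal(d_par$choice_later, 0)
  # patient-but-ordinary agents avoid the later loss in both frames
  d2 <- decide(loss_pair, alpha = 0.9, beta = 1, delta = 0.999,
               frame = "integrated")
  expect_equal(d2$choice_later, 0)
})

test_that("deterministic populations shift weakly toward later gains and away from later losses", {
  set.seed(7)
  agents <- data.frame(alpha = runif(40, 0.3, 1), beta = runif(40, 0.6, 1.4),
                       delta = runif(40, 0.9, 1))
  gains <- fixtures_experiment2()
  losses <- fixtures_experiment3()
  for (i in seq_len(nrow(agents))) {
    gi <- decide(gains, agents$alpha[i], agents$beta[i], agents$delta[i],
                 frame = "integrated")$choice_later
    gp <- decide(gains, agents$alpha[i], agents$beta[i], agents$delta[i],
                 frame = "partitioned")$choice_later
    expect_true(all(gp >= gi))
    li <- decide(losses, agents$alpha[i], agents$beta[i], agents$delta[i],
                 frame = "integrated")$choice_later
    lp <- decide(losses, agents$alpha[i], agents$beta[i], agents$delta[i],
                 frame = "partitioned")$choice_later
    expect_true(all(lp <= li))
  }
})

test_that("pair validation catches malformed tables", {
  base <- fixtures_experiment2()[1, ]
  bad <- base; bad$later_amount <- 2
  expect_error(decide(bad, alpha = 1), "exceed")
  bad <- base; bad$common_amount <- 10
  expect_error(decide(bad, alpha = 1), "common_amount")
  bad <- base; bad$later_delay_days <- 0L
  expect_error(decide(bad, alpha = 1), "delay")
  bad <- fixtures_experiment3()[1, ]; bad$endowment <- NA_real_
  expect_error(decide(bad, alpha = 1), "endowment")
})
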