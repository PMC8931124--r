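#' Instantaneous CRRA utility
#'
#' Power utility kernel `u(x) = x^alpha / alpha` with constant relative risk
#' aversion `1 - alpha`. For `alpha` in (0, 1) the function is strictly
#' increasing and strictly concave in `x`; `alpha = 1` is the linear
#' (risk-neutral) case. The log-utility limit `alpha -> 0` is not supported.
#'
#' @param amount Non-negative monetary amount (vectorised).
#' @param alpha Utility curvature, non-zero. Model-generated agents use
#'   `alpha` in (0, 1]; estimated curvature may fall outside that range and
#'   is deliberately not clipped here.
#' @return Utility in utils, same length as the longer of the inputs.
#' @examples
#' instant_utility(5, alpha = 1)    # 5
#' instant_utility(4, alpha = 0.5)  # 2 * sqrt(4) = 4
#' @export
instant_utility <- function(amount, alpha) {
  if (any(alpha == 0)) {
    stop("`alpha` must be non-zero (the log-utility limit is not supported).",
         call. = FALSE)
  }
  if (any(amount < 0)) {
    stop("`amount` must be non-negative.", call. = FALSE)
  }
  amount^alpha / alpha
}

#' Quasi-hyperbolic discounted utility of a two-dated prospect
#'
#' Evaluates the beta-delta discounted utility of receiving `amount_early`
#' at `delay_early` days and `amount_late` at `delay_late` days:
#' `delta^t u(x_t) + beta^I delta^(t+k) u(x_(t+k))`, where the present-bias
#' multiplier `beta` is applied to the later payment only when the earlier
#' one is immediate (`I = 1` iff `delay_early == 0`). When the earlier date
#' is itself in the future the extra bias is inactive.
#'
#' @param amount_early,amount_late Non-negative amounts.
#' @param delay_early,delay_late Non-negative integer delays in days, with
#'   `delay_late > delay_early`.
#' @param alpha Utility curvature in (0, 1].
#' @param beta Present-bias multiplier, positive; `beta < 1` means delayed
#'   payoffs are additionally devalued when an immediate payoff is on offer.
#' @param delta Per-day discount factor in (0, 1].
#' @return Discounted utility in utils (vectorised).
#' @export
discounted_utility <- function(amount_early, delay_early,
                               amount_late, delay_late,
                               alpha, beta = 1, delta = 1) {
  check_prefs(alpha, beta, delta)
  if (any(delay_early < 0) || any(delay_late < 0)) {
    stop("Delays must be non-negative.", call. = FALSE)
  }
  bias <- ifelse(delay_early == 0, beta, 1)
  delta^delay_early * instant_utility(amount_early, alpha) +
    bias * delta^delay_late * instant_utility(amount_late, alpha)
}

#' Indifference threshold for the per-day discount factor
#'
#' The discount factor at which an agent with curvature `alpha` and
#' present bias `beta` is exactly indifferent between the smaller earlier
#' amount `x0` (immediate) and the larger later amount `xk` delivered `k`
#' days later: `delta* = ((1/beta) (x0/xk)^alpha)^(1/k)`. Agents with
#' `delta >= delta*` choose the later amount (ties go to later).
#'
#' @param x0 Smaller earlier amount, positive.
#' @param xk Larger later amount, `xk > x0`.
#' @param k Delay between the two amounts in days, at least 1.
#' @param alpha Utility curvature in (0, 1].
#' @param beta Present-bias multiplier, positive (set 1 when the earlier
#'   date is not immediate).
#' @return The threshold discount factor (vectorised).
#' @seealso [delta_star_cancelled()] for the threshold after cancelling a
#'   common component, [threshold_sensitivity()] for its derivative in
#'   `alpha`.
#' @examples
#' delta_star(2, 3, k = 7)            # (2/3)^(1/7)
#' delta_star(7, 8, k = 7)            # (7/8)^(1/7)
#' @export
delta_star <- function(x0, xk, k, alpha = 1, beta = 1) {
  check_prefs(alpha, beta, delta = 1)
  if (any(x0 <= 0)) stop("`x0` must be positive.", call. = FALSE)
  if (any(xk <= x0)) {
    stop("`xk` must exceed `x0`: no interior threshold otherwise.",
         call. = FALSE)
  }
  if (any(k < 1)) stop("`k` must be at least 1 day.", call. = FALSE)
  ((1 / beta) * (x0 / xk)^alpha)^(1 / k)
}

#' Indifference threshold after cancelling a common component
#'
#' When both amounts are partitioned as `x0 = y0 + c` and `xk = yk + c` and
#' the decision maker cancels the seemingly identical component `c`, the
#' choice reduces to the residuals and the threshold becomes
#' `delta*_c = ((1/beta) (y0/yk)^alpha)^(1/k)`, which is strictly below the
#' integrated threshold whenever `0 < c < x0`. When the earlier residual is
#' zero the later residual wins at any discount factor and the threshold
#' is 0.
#'
#' The present-bias factor is carried through the cancelled threshold
#' exactly as in the integrated one (it multiplies both sides of the
#' indifference condition identically, so the ordering
#' `delta*_c < delta*` is unaffected by it).
#'
#' @inheritParams delta_star
#' @param common Common (cancellable) component `c`, with
#'   `0 < common <= x0`.
#' @return The cancelled-frame threshold discount factor (vectorised).
#' @examples
#' delta_star_cancelled(2, 3, common = 1, k = 7)  # (1/2)^(1/7)
#' delta_star_cancelled(3, 4, common = 3, k = 7)  # 0: zero earlier residual
#' @export
delta_star_cancelled <- function(x0, xk, common, k, alpha = 1, beta = 1) {
  if (any(common <= 0)) {
    stop("`common` must be positive; use delta_star() for integrated pairs.",
         call. = FALSE)
  }
  if (any(common > x0)) {
    stop("`common` cannot exceed the earlier amount `x0`.", call. = FALSE)
  }
  y0 <- x0 - common
  yk <- xk - common
  if (any(yk <= y0)) stop("Residuals must satisfy yk > y0 >= 0.", call. = FALSE)
  out <- rep_len(0, length(y0 + yk + k + alpha + beta))
  pos <- rep_len(y0, length(out)) > 0
  if (any(pos)) {
    out[pos] <- delta_star(rep_len(y0, length(out))[pos],
                           rep_len(yk, length(out))[pos],
                           rep_len(k, length(out))[pos],
                           rep_len(alpha, length(out))[pos],
                           rep_len(beta, length(out))[pos])
  }
  out
}

#' Sensitivity of the indifference threshold to utility curvature
#'
#' Derivative of the threshold discount factor with respect to `alpha`:
#' `d delta*/d alpha = (delta*/k) ln(z)` with amount ratio
#' `z = x_t / x_(t+k) < 1`, hence always negative: more curvature (lower
#' `alpha`) raises the threshold. Because cancelling a common component
#' lowers the ratio `z`, the cancelled threshold moves faster in `alpha`
#' than the integrated one, which is the comparative static behind the
#' curvature-by-framing interaction.
#'
#' @param delta_star_value The threshold at which the derivative is
#'   evaluated.
#' @param k Delay between the amounts in days.
#' @param z Amount ratio `x_t / x_(t+k)` in (0, 1).
#' @return The derivative (negative, vectorised).
#' @export
threshold_sensitivity <- function(delta_star_value, k, z) {
  if (any(z >= 1) || any(z <= 0)) {
    stop("`z` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (any(k < 1)) stop("`k` must be at least 1 day.", call. = FALSE)
  delta_star_value / k * log(z)
}

#' Threshold report for a partitioned choice pair
#'
#' Convenience summary of one choice pair: the integrated and cancelled
#' indifference thresholds and their sensitivities to curvature.
#'
#' @inheritParams delta_star_cancelled
#' @return A tibble with columns `delta_star`, `delta_star_cancelled`,
#'   `sensitivity_integrated`, `sensitivity_cancelled`.
#' @export
threshold_report <- function(x0, xk, common, k, alpha = 1, beta = 1) {
  ds <- delta_star(x0, xk, k, alpha, beta)
  dsc <- delta_star_cancelled(x0, xk, common, k, alpha, beta)
  y0 <- x0 - common
  yk <- xk - common
  sens_c <- ifelse(y0 > 0,
                   threshold_sensitivity(dsc, k, pmax(y0, 1e-300) / yk), 0)
  tibble::tibble(
    delta_star = ds,
    delta_star_cancelled = dsc,
    sensitivity_integrated = threshold_sensitivity(ds, k, x0 / xk),
    sensitivity_cancelled = sens_c
  )
}

#' Map a loss pair to its kept-wealth gain representation
#'
#' A choice between surrendering `earlier_loss` now-ish and surrendering
#' the larger `later_loss` later, out of a cash `endowment`, is materially
#' the choice between keeping `endowment - earlier_loss` at the earlier
#' date and keeping `endowment - later_loss` at the later date. Note the
#' reversal: in kept-wealth terms the *earlier* option carries the larger
#' payoff, so "choose the later loss" means choosing the smaller later
#' kept amount.
#'
#' @param earlier_loss,later_loss Amounts surrendered, with
#'   `later_loss > earlier_loss >= 0`.
#' @param endowment Cash endowment out of which losses are paid,
#'   `endowment >= later_loss`.
#' @return A tibble with columns `earlier_kept`, `later_kept` (vectorised).
#' @examples
#' loss_to_gain_frame(3, 4, endowment = 10)  # keep 7 earlier vs keep 6 later
#' @export
loss_to_gain_frame <- function(earlier_loss, later_loss, endowment) {
  if (any(earlier_loss < 0)) stop("Losses must be non-negative.", call. = FALSE)
  if (any(later_loss <= earlier_loss)) {
    stop("`later_loss` must exceed `earlier_loss`.", call. = FALSE)
  }
  if (any(later_loss > endowment)) {
    stop("Losses cannot exceed the endowment.", call. = FALSE)
  }
  tibble::tibble(
    earlier_kept = endowment - earlier_loss,
    later_kept = endowment - later_loss
  )
}

# Validate scalar/vector preference parameters shared by several operations.
check_prefs <- function(alpha, beta, delta, noise_temperature = 0) {
  if (any(!is.finite(alpha)) || any(alpha == 0)) {
    stop("`alpha` must be finite and non-zero.", call. = FALSE)
  }
  if (any(beta <= 0)) stop("`beta` must be positive.", call. = FALSE)
  if (any(delta <= 0) || any(delta > 1)) {
    stop("`delta` must lie in (0, 1].", call. = FALSE)
  }
  if (any(noise_temperature < 0)) {
    stop("`noise_temperature` must be non-negative.", call. = FALSE)
  }
  invisible(TRUE)
}

# Utility gap (later minus earlier) for a table of choice pairs under one
# agent's preferences. `pairs` must carry earlier_amount, later_amount,
# earlier_delay_days, later_delay_days, common_amount, frame, domain and
# (for losses) endowment. The gap is the latent variable of the logistic
# choice rule; ties (gap == 0) go to later.
utility_gap <- function(pairs, alpha, beta, delta) {
  t0 <- pairs$earlier_delay_days
  tk <- pairs$later_delay_days
  bias <- ifelse(t0 == 0, beta, 1)
  part <- pairs$frame == "partitioned"
  gain <- pairs$domain == "gain"

  u_early <- u_late <- numeric(nrow(pairs))

  if (any(gain)) {
    xe <- pairs$earlier_amount[gain]
    xl <- pairs$later_amount[gain]
    cc <- ifelse(part[gain], pairs$common_amount[gain], 0)
    u_early[gain] <- delta^t0[gain] * instant_utility(xe - cc, alpha)
    u_late[gain] <- bias[gain] * delta^tk[gain] * instant_utility(xl - cc, alpha)
  }
  if (any(!gain)) {
    loss <- !gain
    kept <- loss_to_gain_frame(pairs$earlier_amount[loss],
                               pairs$later_amount[loss],
                               pairs$endowment[loss])
    # Integrated: compare kept wealth at the two dates. Partitioned: the
    # common kept component (endowment - later_loss) is cancelled, leaving
    # "keep the saved difference at t" versus "keep nothing at t+k".
    resid <- kept$earlier_kept - kept$later_kept
    u_early[loss] <- delta^t0[loss] *
      instant_utility(ifelse(part[loss], resid, kept$earlier_kept), alpha)
    u_late[loss] <- bias[loss] * delta^tk[loss] *
      instant_utility(ifelse(part[loss], 0, kept$later_kept), alpha)
  }
  u_late - u_early
}

#' Simulate choices for a table of intertemporal choice pairs
#'
#' Applies the beta-delta CRRA decision rule of one agent to every row of a
#' choice-pair table. In the `integrated` frame the discounted utilities of
#' the full amounts are compared; in the `partitioned` frame the common
#' component is cancelled first and the residuals are compared. Loss-domain
#' rows are mapped to kept wealth via [loss_to_gain_frame()]. Ties go to
#' the later option. With `noise_temperature = 0` the rule is
#' deterministic; otherwise the later-choice probability is logistic in the
#' utility gap divided by the temperature (a Fechner noise extension of the
#' deterministic model) and a seeded draw realises the choice.
#'
#' @param pairs A data frame of choice pairs with columns `earlier_amount`,
#'   `later_amount`, `earlier_delay_days`, `later_delay_days`,
#'   `common_amount`, `domain` (`"gain"` or `"loss"`), `endowment`
#'   (loss rows only) — e.g. from [fixtures_experiment2()].
#' @param alpha,beta,delta Agent preferences (scalars).
#' @param frame `"integrated"` or `"partitioned"`; overrides any `frame`
#'   column in `pairs`.
#' @param noise_temperature Non-negative logistic noise scale in utils;
#'   0 (default) reproduces the deterministic rule.
#' @param seed Optional integer seed for the noise draws.
#' @return The input pairs with added columns `frame`, `p_later` (choice
#'   probability of the later option) and `choice_later` (0/1 realised
#'   choice; for losses, 1 means choosing the later, larger loss).
#' @examples
#' decide(fixtures_experiment1(), alpha = 1, beta = 1, delta = 0.92,
#'        frame = "partitioned")
#' @export
decide <- function(pairs, alpha, beta = 1, delta = 1,
                   frame = NULL, noise_temperature = 0, seed = NULL) {
  check_prefs(alpha, beta, delta, noise_temperature)
  pairs <- validate_choice_pairs(pairs)
  if (!is.null(frame)) {
    frame <- match.arg(frame, c("integrated", "partitioned"))
    pairs$frame <- frame
  } else if (!"frame" %in% names(pairs)) {
    pairs$frame <- "integrated"
  }
  gap <- utility_gap(pairs, alpha, beta, delta)
  if (noise_temperature == 0) {
    p <- as.numeric(gap >= 0)
    choice <- p
  } else {
    p <- stats::plogis(gap / noise_temperature)
    if (!is.null(seed)) {
      old <- local_seed(seed)
      on.exit(restore_seed(old), add = TRUE)
    }
    choice <- as.numeric(stats::runif(length(p)) < p)
  }
  pairs$p_later <- p
  pairs$choice_later <- choice
  tibble::as_tibble(pairs)
}

# Validate a pairs table: amount/delay ordering, residual feasibility,
# loss-domain endowments. Fills missing common_amount (0) / domain ("gain").
validate_choice_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  needed <- c("earlier_amount", "later_amount",
              "earlier_delay_days", "later_delay_days")
  missing <- setdiff(needed, names(pairs))
  if (length(missing)) {
    stop("`pairs` lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"common_amount" %in% names(pairs)) pairs$common_amount <- 0
  if (!"domain" %in% names(pairs)) pairs$domain <- "gain"
  if (!all(pairs$domain %in% c("gain", "loss"))) {
    stop("`domain` must be \"gain\" or \"loss\".", call. = FALSE)
  }
  if (any(pairs$later_delay_days <= pairs$earlier_delay_days)) {
    stop("`later_delay_days` must exceed `earlier_delay_days`.", call. = FALSE)
  }
  if (any(pairs$later_amount <= pairs$earlier_amount)) {
    stop("`later_amount` must exceed `earlier_amount` (losses are amounts ",
         "surrendered).", call. = FALSE)
  }
  if (any(pairs$common_amount < 0) ||
      any(pairs$common_amount > pairs$earlier_amount)) {
    stop("`common_amount` must lie in [0, earlier_amount].", call. = FALSE)
  }
  is_loss <- pairs$domain == "loss"
  if (any(is_loss)) {
    if (!"endowment" %in% names(pairs) || anyNA(pairs$endowment[is_loss])) {
      stop("Loss-domain rows require an `endowment` column.", call. = FALSE)
    }
    if (any(pairs$later_amount[is_loss] > pairs$endowment[is_loss])) {
      stop("Losses cannot exceed the endowment.", call. = FALSE)
    }
  }
  pairs
}

# Seed management that leaves the caller's RNG state untouched.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
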