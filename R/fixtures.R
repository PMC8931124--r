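#' Stimulus fixtures: cafeteria-voucher field experiment
#'
#' The single binary choice of the field experiment: a $2 voucher valid
#' from today versus a $3 voucher valid from one week later. In the
#' cancellation condition the same options are presented as $1 + $1 today
#' versus $2 + $1 in a week, i.e. a common $1 component is separated out.
#' Published condition-level summaries (percent choosing the later
#' voucher, total N) are carried as reference columns.
#'
#' @return A one-row tibble of choice-pair columns plus `baseline_pct`,
#'   `cancellation_pct`, `n_total`.
#' @export
fixtures_experiment1 <- function() {
  tibble::tibble(
    trial_id = 1L,
    earlier_amount = 2, later_amount = 3,
    earlier_delay_days = 0L, later_delay_days = 7L,
    common_amount = 1, domain = "gain", endowment = NA_real_,
    baseline_pct = 52.0, cancellation_pct = 77.8, n_total = 147L
  )
}

#' Stimulus fixtures: 20 binary gain choices
#'
#' The gain-domain stimulus list: earlier amounts $3, $4, $5, $7, $8 with
#' the later amount $1 or $2 higher, delivered 7 days after the earlier
#' date, which is either today or a week away. In the cancellation
#' condition the full earlier amount is the separated common component
#' (e.g. $3 + $0 today versus $3 + $1 in a week). Published per-row
#' later-choice percentages and Fisher p-values are carried as reference
#' columns.
#'
#' @return A 20-row tibble of choice-pair columns plus `baseline_pct`,
#'   `cancellation_pct`, `fisher_p`.
#' @export
fixtures_experiment2 <- function() {
  earlier <- c(3, 4, 5, 7, 8)
  rows <- tidyr::expand_grid(
    earlier_delay_days = c(0L, 7L),
    increment = c(1, 2),
    earlier_amount = earlier
  )
  base_pct <- c(65, 67.5, 67.5, 67.5, 65,
                85, 85, 87.5, 85, 85,
                42.5, 45, 45, 45, 50,
                80, 82.5, 80, 77.5, 80)
  canc_pct <- c(94.29, 91.43, 94.29, 94.29, 88.57,
                94.29, 97.14, 97.14, 94.29, 94.29,
                77.14, 74.29, 77.14, 77.14, 77.14,
                88.57, 91.43, 85.71, 91.43, 82.86)
  fisher_p <- c(0.002, 0.02, 0.004, 0.004, 0.036,
                0.277, 0.118, 0.219, 0.27, 0.27,
                0.004, 0.02, 0.005, 0.005, 0.02,
                0.36, 0.32, 0.56, 0.12, 0.77)
  tibble::tibble(
    trial_id = seq_len(20L),
    earlier_amount = rows$earlier_amount,
    later_amount = rows$earlier_amount + rows$increment,
    earlier_delay_days = rows$earlier_delay_days,
    later_delay_days = rows$earlier_delay_days + 7L,
    common_amount = rows$earlier_amount,
    domain = "gain",
    endowment = NA_real_,
    baseline_pct = base_pct,
    cancellation_pct = canc_pct,
    fisher_p = fisher_p
  )
}

#' Stimulus fixtures: 20 binary loss choices
#'
#' The loss-domain stimulus list, symmetric to the gain list: later losses
#' $7, $6, $5, $3, $2 with the earlier loss $1 or $2 smaller, paid out of a
#' $10 cash endowment, at the same two timing blocks. In the cancellation
#' condition the full earlier loss is the separated common component
#' (e.g. give up $3 + $0 today versus give up $3 + $1 in a week).
#' Published per-row later-loss percentages and Fisher p-values are
#' carried as reference columns (one p-value is unprinted and stored as
#' `NA`).
#'
#' @return A 20-row tibble of choice-pair columns plus `baseline_pct`,
#'   `cancellation_pct`, `fisher_p`.
#' @export
fixtures_experiment3 <- function() {
  later <- c(7, 6, 5, 3, 2)
  rows <- tidyr::expand_grid(
    earlier_delay_days = c(0L, 7L),
    decrement = c(1, 2),
    later_amount = later
  )
  base_pct <- c(20.37, 12.96, 11.11, 5.56, 9.26,
                7.41, 5.56, 3.70, 0, 1.85,
                16.67, 9.26, 22.22, 7.41, 5.56,
                5.56, 3.70, 1.85, 1.85, 0)
  canc_pct <- c(11.54, 5.77, 5.77, 1.92, 3.85,
                1.92, 0, 0, 0, 1.92,
                3.85, 1.92, 0, 0, 1.92,
                1.92, 0, 0, 0, 5.77)
  fisher_p <- c(0.29, 0.32, 0.48, 0.61, 0.43,
                0.36, 0.24, 0.49, NA, 1,
                0.05, 0.20, 0.001, 0.11, 0.61,
                0.61, 0.49, 1, 1, 0.11)
  tibble::tibble(
    trial_id = seq_len(20L),
    earlier_amount = rows$later_amount - rows$decrement,
    later_amount = rows$later_amount,
    earlier_delay_days = rows$earlier_delay_days,
    later_delay_days = rows$earlier_delay_days + 7L,
    common_amount = rows$later_amount - rows$decrement,
    domain = "loss",
    endowment = 10,
    baseline_pct = base_pct,
    cancellation_pct = canc_pct,
    fisher_p = fisher_p
  )
}

#' Stimulus fixtures: nine-option retirement benefit menu
#'
#' The retirement claiming menu: an annual Social Security benefit that can
#' start at any age from 62 to 70, growing from $9,400 to $16,600 per year
#' of delay. In the baseline frame each option is a single benefit figure;
#' in the cancellation frame every option is split into a constant $9,400
#' base plus an age-varying supplement ($0 to $7,100), separating the
#' common component. The published percentage of (under-62) respondents
#' choosing each start age in each condition is carried in
#' `pct_baseline` / `pct_cancellation`.
#'
#' The published age-70 row is internally inconsistent by $100 (baseline
#' benefit $16,600 versus base $9,400 + supplement $7,100); the fixture
#' preserves the printed figures rather than reconciling them.
#'
#' @return A 9-row tibble with columns `start_age`, `benefit_baseline`,
#'   `base_benefit`, `supplement`, `pct_baseline`, `pct_cancellation`.
#' @export
fixtures_experiment4 <- function() {
  tibble::tibble(
    start_age = 62:70,
    benefit_baseline = c(9400, 10000, 10700, 11600, 12500,
                         13400, 14400, 15500, 16600),
    base_benefit = 9400,
    supplement = c(0, 600, 1300, 2200, 3100, 4000, 5000, 6100, 7100),
    pct_baseline = c(16, 5, 4, 16, 19, 12, 7, 1, 20),
    pct_cancellation = c(6, 6, 4, 14, 11, 18, 7, 2, 32)
  )
}

#' Convex-time-budget task fixtures
#'
#' The 20 token-allocation tasks: 50 tokens to split between an earlier
#' date (`t` = 0 or 7 days) and a later date `k` = 35 or 70 days after it,
#' with per-token values drawn from the five price pairs
#' (0.19, 0.20), (0.18, 0.20), (0.16, 0.20), (0.14, 0.20), (0.20, 0.25) —
#' the later token is always worth more.
#'
#' @return A 20-row tibble with columns `task_id`, `budget_tokens`, `a_t`,
#'   `a_tk`, `t_days`, `k_days`.
#' @export
cbs_tasks <- function() {
  prices <- tibble::tibble(
    a_t = c(0.19, 0.18, 0.16, 0.14, 0.20),
    a_tk = c(0.20, 0.20, 0.20, 0.20, 0.25)
  )
  grid <- tidyr::expand_grid(
    t_days = c(0L, 7L),
    k_days = c(35L, 70L),
    prices
  )
  tibble::tibble(
    task_id = seq_len(nrow(grid)),
    budget_tokens = 50,
    a_t = grid$a_t,
    a_tk = grid$a_tk,
    t_days = grid$t_days,
    k_days = grid$k_days
  )
}
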