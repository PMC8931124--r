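#' Simulate a between-subjects binary-choice experiment
#'
#' Runs every agent of a population through every row of a binary
#' choice-pair stimulus set. Mirroring the experimental designs, condition
#' assignment is between subjects: each agent is randomly assigned (seeded,
#' balanced) to either the `baseline` (integrated) or the `cancellation`
#' (partitioned) condition and answers all trials under that framing.
#'
#' @param population A tibble of agents from [sample_population()]
#'   (columns `subject_id`, `alpha`, `beta`, `delta`).
#' @param stimuli A choice-pair tibble, e.g. [fixtures_experiment2()].
#' @param noise_temperature Logistic choice-noise scale in utils; 0
#'   (default) gives the deterministic rule.
#' @param seed Integer seed governing condition assignment and noise.
#' @return A trial-level tibble with one row per agent x pair: columns
#'   `subject_id`, `condition`, `trial_id`, the stimulus fields,
#'   `t0` (1 if the earlier date is immediate), `p_later`, `choice_later`.
#' @examples
#' pop <- sample_population(10, seed = 1)
#' trials <- simulate_binary_experiment(pop, fixtures_experiment2(), seed = 1)
#' @export
simulate_binary_experiment <- function(population, stimuli,
                                       noise_temperature = 0, seed = 1) {
  stimuli <- validate_choice_pairs(stimuli)
  if (nrow(population) == 0) {
    return(empty_trials())
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- nrow(population)
  condition <- sample(rep_len(c("baseline", "cancellation"), n))
  frames <- c(baseline = "integrated", cancellation = "partitioned")

  trials <- purrr::pmap_dfr(
    list(population$subject_id, population$alpha, population$beta,
         population$delta, condition),
    function(sid, alpha, beta, delta, cond) {
      out <- decide(stimuli, alpha = alpha, beta = beta, delta = delta,
                    frame = frames[[cond]],
                    noise_temperature = noise_temperature)
      out$subject_id <- sid
      out$condition <- cond
      out
    }
  )
  trials$t0 <- as.integer(trials$earlier_delay_days == 0)
  dplyr::select(
    trials, "subject_id", "condition", "trial_id",
    "earlier_amount", "later_amount", "earlier_delay_days",
    "later_delay_days", "common_amount", "domain", "endowment",
    "t0", "p_later", "choice_later"
  )
}

empty_trials <- function() {
  tibble::tibble(
    subject_id = integer(), condition = character(), trial_id = integer(),
    earlier_amount = numeric(), later_amount = numeric(),
    earlier_delay_days = integer(), later_delay_days = integer(),
    common_amount = numeric(), domain = character(), endowment = numeric(),
    t0 = integer(), p_later = numeric(), choice_later = numeric()
  )
}

#' Simulate convex-time-budget token allocations
#'
#' Gives every agent the full task list and records the
#' utility-maximising number of tokens placed on the earlier date,
#' computed analytically by [foc_allocation()]. Allocations are continuous
#' by default; `integer_rounding = TRUE` rounds to the nearest whole token
#' to mimic real responses.
#'
#' @inheritParams simulate_binary_experiment
#' @param tasks A task tibble, e.g. [cbs_tasks()].
#' @param integer_rounding Round allocations to whole tokens?
#' @return An allocation tibble: `subject_id`, `task_id`, `a_t`, `a_tk`,
#'   `t_days`, `k_days`, `budget_tokens`, `tokens_early`.
#' @examples
#' pop <- sample_population(3, seed = 1)
#' alloc <- simulate_cbs(pop, cbs_tasks())
#' @export
simulate_cbs <- function(population, tasks = cbs_tasks(),
                         integer_rounding = FALSE, seed = 1) {
  validate_cbs_tasks(tasks)
  grid <- tidyr::expand_grid(
    population[, c("subject_id", "alpha", "beta", "delta")],
    tasks
  )
  grid$tokens_early <- foc_allocation(
    alpha = grid$alpha, beta = grid$beta, delta = grid$delta,
    a_t = grid$a_t, a_tk = grid$a_tk, t_days = grid$t_days,
    k_days = grid$k_days, budget_tokens = grid$budget_tokens
  )
  if (integer_rounding) grid$tokens_early <- round(grid$tokens_early)
  dplyr::select(
    grid, "subject_id", "task_id", "a_t", "a_tk", "t_days", "k_days",
    "budget_tokens", "tokens_early"
  )
}

#' Simulate retirement-age choices from a benefit menu
#'
#' Each agent values every menu option as the beta-delta discounted CRRA
#' utility of the annual payment stream from the start age to a horizon
#' age, and picks the maximising start age (ties go to the later age). In
#' the `baseline` frame the stream pays the full benefit; in the
#' `cancellation` frame the constant base benefit is cancelled across all
#' options first, so only the age-varying supplement is valued — the
#' predicted mental representation of the partitioned menu. The decision
#' is taken at age 62, so payments after age 62 attract the present-bias
#' multiplier; `delta` compounds daily (365 days per year of delay).
#'
#' The valuation model is a modelling extension: the menu task itself
#' specifies no valuation rule, and the horizon materially affects the
#' simulated ages, so it is exposed as a parameter.
#'
#' @inheritParams simulate_binary_experiment
#' @param menu A menu tibble, e.g. [fixtures_experiment4()].
#' @param frame `"baseline"`, `"cancellation"`, or `"both"` (default:
#'   between-subjects random assignment as in the survey).
#' @param horizon_age Final age (exclusive) through which payments are
#'   valued; must exceed 70.
#' @return A tibble with `subject_id`, `condition`, `start_age`.
#' @export
simulate_retirement <- function(population, menu = fixtures_experiment4(),
                                frame = c("both", "baseline", "cancellation"),
                                horizon_age = 85, seed = 1) {
  frame <- match.arg(frame)
  if (horizon_age <= 70) stop("`horizon_age` must exceed 70.", call. = FALSE)
  if (nrow(menu) < 1) stop("`menu` must have at least one option.",
                           call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(population)
  condition <- switch(frame,
    both = sample(rep_len(c("baseline", "cancellation"), n)),
    rep(frame, n)
  )
  ages <- purrr::pmap_dbl(
    list(population$alpha, population$beta, population$delta, condition),
    function(alpha, beta, delta, cond) {
      annual <- if (cond == "cancellation") menu$supplement else
        if ("benefit_baseline" %in% names(menu)) menu$benefit_baseline else
          menu$base_benefit + menu$supplement
      v <- purrr::map2_dbl(menu$start_age, annual, function(s, a) {
        yrs <- seq(s, horizon_age - 1)
        sum(ifelse(yrs > 62, beta, 1) * delta^((yrs - 62) * 365) *
              instant_utility(a, alpha))
      })
      # ties broken toward the later start age
      menu$start_age[max(which(v == max(v)))]
    }
  )
  tibble::tibble(
    subject_id = population$subject_id,
    condition = condition,
    start_age = ages
  )
}

#' Per-row later-choice proportions by condition
#'
#' Summarises a trial table into the share choosing the later option in
#' each condition for every stimulus row, plus the cancellation minus
#' baseline gap — the simulated analogue of the published stimulus
#' tables.
#'
#' @param trials A trial tibble from [simulate_binary_experiment()].
#' @return A tibble with one row per `trial_id`: `earlier_amount`,
#'   `later_amount`, `t0`, `pct_baseline`, `pct_cancellation`, `gap`.
#' @export
summarise_frame_effect <- function(trials) {
  trials |>
    dplyr::group_by(.data$trial_id, .data$earlier_amount,
                    .data$later_amount, .data$t0) |>
    dplyr::summarise(
      pct_baseline =
        100 * mean(.data$choice_later[.data$condition == "baseline"]),
      pct_cancellation =
        100 * mean(.data$choice_later[.data$condition == "cancellation"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(gap = .data$pct_cancellation - .data$pct_baseline)
}
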