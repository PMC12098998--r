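#' Cost regimes for the avoidance tasks
#'
#' Each task charges the active choice a cost built from a fixed component
#' plus a percentage of the trial's offer. The robber task pairs set costs of
#' 10, 40 and 75 points with 15, 5 and 0 percent of the offer; the factory
#' task pairs 0, 50 and 100 points with 10, 5 and 0 percent.
#'
#' @param task `"robber"` or `"factory"`.
#' @return A tibble with columns `regime`, `set_cost`, `pct_of_offer`.
#' @export
#' @examples
#' cost_regimes("robber")
cost_regimes <- function(task = c("robber", "factory")) {
  task <- match.arg(task)
  if (task == "robber") {
    tibble::tibble(regime = 1:3, set_cost = c(10, 40, 75),
                   pct_of_offer = c(0.15, 0.05, 0))
  } else {
    tibble::tibble(regime = 1:3, set_cost = c(0, 50, 100),
                   pct_of_offer = c(0.10, 0.05, 0))
  }
}

#' Offer magnitudes used in both tasks
#'
#' Offers are 50 divided elementwise by the grid (0.10, 0.15, ..., 0.95, 1, 2)
#' and rounded half-up to whole points, giving 20 magnitudes from 25 to 500.
#' The same magnitudes serve both tasks; the factory task reads them as
#' losses at stake rather than tips to keep.
#'
#' @param task `"robber"` or `"factory"` (magnitudes are identical).
#' @return Numeric vector of 20 offer magnitudes, in grid order (descending
#'   except for the final 50/1 = 50 and 50/2 = 25 entries).
#' @export
#' @examples
#' generate_offers("robber")
generate_offers <- function(task = c("robber", "factory")) {
  task <- match.arg(task)
  divisors <- c(seq(0.10, 0.95, by = 0.05), 1, 2)
  round_half_up(50 / divisors)
}

#' Action cost for an offer under a cost regime
#'
#' The cost of the active choice is `set_cost + pct_of_offer * offer`,
#' rounded half-up to whole points.
#'
#' @param offer Positive offer magnitude(s) in points.
#' @param set_cost Fixed cost component (points).
#' @param pct_of_offer Proportional component, a fraction in `[0, 1]`.
#' @return Integer-valued cost(s) in points.
#' @export
#' @examples
#' compute_cost(500, set_cost = 10, pct_of_offer = 0.15)  # 85
compute_cost <- function(offer, set_cost, pct_of_offer) {
  if (any(offer <= 0)) {
    stop("`offer` must be positive; sign conventions are applied by the utility functions.")
  }
  round_half_up(set_cost + pct_of_offer * offer)
}

#' Stimulus success probabilities
#'
#' Twelve equidistant success probabilities, k/13 for k = 1..12. The grid is
#' symmetric about 0.5 and its endpoints are 7.69% and 92.31% to printed
#' precision. Each stimulus in a block carries exactly one of these values.
#'
#' @return Sorted numeric vector of length 12.
#' @export
generate_success_probabilities <- function() {
  (1:12) / 13
}

# Run-length lists for consecutive stimulus encounters. The multiset
# {4,4,4,4,4,4,5,5,5,6,7,8} is split into two lists balanced by total
# (30 trials each); runs are shuffled within each list so both halves of a
# block mix short and long runs.
encounter_lists <- function() {
  list(A = c(4, 4, 4, 5, 5, 8), B = c(4, 4, 4, 5, 6, 7))
}

#' Build one 60-trial block schedule
#'
#' Generates the full trial schedule for one block of either task: 20 offers
#' x 3 cost regimes = 60 unique offer-cost pairs in shuffled order, and 12
#' stimuli encountered in consecutive runs whose lengths form the multiset
#' {4 x 6, 5 x 3, 6, 7, 8}, each stimulus carrying one of the 12 success
#' probabilities by seeded random assignment.
#'
#' The seeded draw order is fixed (probability assignment, run shuffles,
#' offer-cost order) so a design is bit-reproducible from `(task, seed)`.
#' Offer-cost ordering is randomised independently of the stimulus sequence,
#' and independently per task.
#'
#' @param task `"robber"` or `"factory"`.
#' @param seed Integer seed for the block's randomisation.
#' @param block Block index stored in the output (default 1).
#' @param subject Subject id stored in the output (default 1).
#' @return A tibble of class `avoid_design` with one row per trial and
#'   columns `subject`, `task`, `block`, `trial`, `stimulus`, `offer`,
#'   `cost`, `success_prob`.
#' @export
#' @examples
#' d <- build_block_design("robber", seed = 1)
#' table(d$offer)  # every offer appears 3 times
build_block_design <- function(task = c("robber", "factory"), seed,
                               block = 1L, subject = 1L) {
  task <- match.arg(task)
  probs <- generate_success_probabilities()
  offers <- generate_offers(task)
  regimes <- cost_regimes(task)
  lists <- encounter_lists()

  drawn <- with_local_seed(seed, {
    list(
      prob_perm = sample.int(12L),
      runs_a = sample(lists$A),
      runs_b = sample(lists$B),
      pair_order = sample.int(60L)
    )
  })

  run_lengths <- c(drawn$runs_a, drawn$runs_b)
  stimulus <- rep(1:12, times = run_lengths)
  stim_prob <- probs[drawn$prob_perm]

  pairs <- tidyr::expand_grid(offer = offers, regimes)
  pairs <- dplyr::mutate(pairs,
                         cost = compute_cost(.data$offer, .data$set_cost,
                                             .data$pct_of_offer))
  pairs <- pairs[drawn$pair_order, ]

  out <- tibble::tibble(
    subject = as.integer(subject),
    task = task,
    block = as.integer(block),
    trial = 1:60,
    stimulus = stimulus,
    offer = pairs$offer,
    cost = pairs$cost,
    success_prob = stim_prob[stimulus]
  )
  new_avoid_design(out, seed = seed)
}

#' Build an 18-trial practice schedule
#'
#' Practice blocks use four dedicated stimuli (ids 101-104, never reused in
#' main blocks) with per-stimulus trial counts {4, 4, 4, 6} and success
#' probabilities {0.8, 0.2, 0.5, 0.5} respectively, runs in seeded random
#' order. Offer-cost pairs are drawn without replacement from the task's
#' 60-pair grid.
#'
#' @inheritParams build_block_design
#' @return An `avoid_design` tibble with 18 rows.
#' @export
build_practice_design <- function(task = c("robber", "factory"), seed,
                                  block = 0L, subject = 1L) {
  task <- match.arg(task)
  offers <- generate_offers(task)
  regimes <- cost_regimes(task)
  runs <- tibble::tibble(
    stimulus = 101:104,
    n_trials = c(4L, 4L, 4L, 6L),
    success_prob = c(0.8, 0.2, 0.5, 0.5)
  )

  drawn <- with_local_seed(seed, {
    list(run_order = sample.int(4L), pair_idx = sample.int(60L, 18L))
  })
  runs <- runs[drawn$run_order, ]

  pairs <- tidyr::expand_grid(offer = offers, regimes)
  pairs <- dplyr::mutate(pairs,
                         cost = compute_cost(.data$offer, .data$set_cost,
                                             .data$pct_of_offer))
  pairs <- pairs[drawn$pair_idx, ]

  out <- tibble::tibble(
    subject = as.integer(subject),
    task = task,
    block = as.integer(block),
    trial = 1:18,
    stimulus = rep(runs$stimulus, times = runs$n_trials),
    offer = pairs$offer,
    cost = pairs$cost,
    success_prob = rep(runs$success_prob, times = runs$n_trials)
  )
  new_avoid_design(out, seed = seed, practice = TRUE)
}

new_avoid_design <- function(x, seed = NULL, practice = FALSE) {
  structure(x, class = unique(c("avoid_design", class(x))),
            design_seed = seed, practice = practice)
}
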