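#' Model recovery by confusion matrix
#'
#' For each generating model and repeat: simulate a cohort of agents from
#' that model, fit every candidate model to every subject, run
#' random-effects model selection, and record which model wins by protected
#' exceedance probability and by model frequency. The defaults (50
#' subjects, 240 trials, 20 repeats) are a desk-scale analogue of a full
#' power simulation.
#'
#' @param models Candidate models fitted to every cohort.
#' @param generating_models Models to simulate from (default: `models`).
#' @param n_subjects Subjects per simulated cohort.
#' @param n_blocks 60-trial blocks per subject.
#' @param n_repeats Cohorts per generating model.
#' @param seed Master seed.
#' @param group_mean,group_sd Unconstrained group mean and SD of the
#'   generating parameters.
#' @param task Task for single-task models.
#' @param ... Passed to [fit_cohort()] (e.g. `n_restarts`).
#' @return List of class `model_recovery`: `results` (one row per
#'   generating model x repeat with winners and the generating model's
#'   PXP), `confusion_pxp` and `confusion_freq` count tibbles.
#' @export
model_recovery <- function(models, generating_models = models,
                           n_subjects = 50, n_blocks = 4, n_repeats = 20,
                           seed = 1, group_mean = 0, group_sd = 1,
                           task = "robber", ...) {
  if (length(models) < 2) stop("At least two candidate models are required.")
  seeds <- spawn_seeds(seed, length(generating_models) * n_repeats * 2L)
  i <- 0L
  results <- purrr::map_dfr(generating_models, function(gen) {
    purrr::map_dfr(seq_len(n_repeats), function(rep) {
      i <<- i + 1L
      cfg <- cohort_config(n_subjects, stats::setNames(1, gen),
                           group_means = stats::setNames(list(group_mean), gen),
                           group_sds = stats::setNames(list(group_sd), gen))
      cohort <- simulate_cohort(cfg, seed = seeds[2 * i - 1], task = task,
                                n_blocks = n_blocks)
      fits <- fit_cohort(cohort$data, models, ...)
      bms <- rfx_bms(log_evidence_matrix(fits), seed = seeds[2 * i])
      tibble::tibble(
        generating = gen, repeat_id = rep,
        winner_pxp = bms$models[which.max(bms$pxp)],
        winner_freq = bms$models[which.max(bms$model_frequency)],
        pxp_generating = unname(bms$pxp[gen]),
        m_freq_generating = unname(bms$model_frequency[gen]))
    })
  })
  confusion <- function(col) {
    dplyr::count(results, .data$generating, selected = .data[[col]])
  }
  structure(list(results = results,
                 confusion_pxp = confusion("winner_pxp"),
                 confusion_freq = confusion("winner_freq"),
                 mean_pxp = mean(results$pxp_generating)),
            class = "model_recovery")
}

#' Parameter recovery for one model
#'
#' Simulates agents with known parameters drawn from a group Gaussian in
#' unconstrained space, refits the same model, and reports per-parameter
#' Pearson and Spearman correlations, bias and RMSE of true versus
#' recovered values on the constrained scale.
#'
#' @param spec Model or model name.
#' @param n_subjects Number of simulated agents.
#' @param n_blocks 60-trial blocks per agent.
#' @param seed Master seed.
#' @param group_mean,group_sd Generating group moments (unconstrained).
#' @param task Task for single-task models.
#' @param ... Passed to [fit_cohort()].
#' @return List of class `parameter_recovery`: `report` (parameter,
#'   pearson, spearman, bias, rmse) and `values` (long tibble of true and
#'   recovered values per subject and parameter).
#' @export
parameter_recovery <- function(spec, n_subjects = 100, n_blocks = 4,
                               seed = 1, group_mean = 0, group_sd = 1,
                               task = "robber", ...) {
  spec <- as_model_spec(spec)
  cfg <- cohort_config(n_subjects, stats::setNames(1, spec$name),
                       group_means = stats::setNames(list(group_mean),
                                                     spec$name),
                       group_sds = stats::setNames(list(group_sd),
                                                   spec$name))
  cohort <- simulate_cohort(cfg, seed = seed, task = task,
                            n_blocks = n_blocks)
  fits <- fit_cohort(cohort$data, spec$name, ...)
  recovered <- purrr::map_dfr(seq_len(nrow(fits)), function(r) {
    f <- fits$fit[[r]]
    tibble::tibble(subject = fits$subject[r], parameter = names(f$theta),
                   recovered = unlist(f$constrained, use.names = FALSE),
                   recovered_unconstrained = unname(f$theta))
  })
  values <- dplyr::inner_join(
    dplyr::rename(cohort$truth, true = "constrained",
                  true_unconstrained = "unconstrained"),
    recovered, by = c("subject", "parameter"))
  report <- dplyr::summarise(
    dplyr::group_by(values, .data$parameter),
    pearson = stats::cor(.data$true, .data$recovered),
    spearman = stats::cor(.data$true, .data$recovered, method = "spearman"),
    bias = mean(.data$recovered - .data$true),
    rmse = sqrt(mean((.data$recovered - .data$true)^2)),
    .groups = "drop")
  structure(list(report = report, values = values, model = spec$name),
            class = "parameter_recovery")
}

#' Power simulation for random-effects model selection
#'
#' Replicates the design of an a priori power analysis at configurable
#' scale: for each sample size, cohorts are simulated from a model mixture,
#' all mixture models are fitted, and the proportion of repeats in which
#' the most frequent generating model attains a protected exceedance
#' probability above `threshold` is reported.
#'
#' @param mixture Named model mixture (frequencies summing to 1).
#' @param n_grid Sample sizes to evaluate.
#' @param n_repeats Simulated comparisons per sample size.
#' @param seed Master seed.
#' @param group_means,group_sds Per-model generating moments (see
#'   [cohort_config()]).
#' @param n_blocks Blocks per subject.
#' @param threshold PXP criterion (default 0.95).
#' @param task Task for single-task models.
#' @param ... Passed to [fit_cohort()].
#' @return Tibble with columns `n`, `power` (fraction of repeats with
#'   PXP > threshold for the target model) and `mean_pxp`.
#' @export
power_simulation <- function(mixture, n_grid, n_repeats = 20, seed = 1,
                             group_means = NULL, group_sds = NULL,
                             n_blocks = 4, threshold = 0.95,
                             task = "robber", ...) {
  target <- names(mixture)[which.max(mixture)]
  models <- names(mixture)
  if (length(models) < 2) stop("The mixture must involve >= 2 models.")
  seeds <- spawn_seeds(seed, length(n_grid) * n_repeats * 2L)
  i <- 0L
  purrr::map_dfr(n_grid, function(n) {
    pxps <- purrr::map_dbl(seq_len(n_repeats), function(rep) {
      i <<- i + 1L
      cfg <- cohort_config(n, mixture, group_means, group_sds)
      cohort <- simulate_cohort(cfg, seed = seeds[2 * i - 1], task = task,
                                n_blocks = n_blocks)
      fits <- fit_cohort(cohort$data, models, ...)
      bms <- rfx_bms(log_evidence_matrix(fits), seed = seeds[2 * i])
      unname(bms$pxp[target])
    })
    tibble::tibble(n = n, power = mean(pxps > threshold),
                   mean_pxp = mean(pxps))
  })
}
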