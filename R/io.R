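choice_data_columns <- c("subject", "task", "block", "trial", "stimulus",
                         "offer", "cost", "success_prob", "choice",
                         "outcome")

#' Write choice data or a design to CSV
#'
#' Flat comma-separated files (UTF-8, `NA` for missing) with a provenance
#' header comment carrying the package version and, when known, the seed.
#' Designs are written with the same column layout minus the choice and
#' outcome columns.
#'
#' @param data Choice data or `avoid_design` tibble.
#' @param path Output file path.
#' @param seed Optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_choice_data <- function(data, path, seed = NULL) {
  seed <- seed %||% attr(data, "sim_seed") %||% attr(data, "design_seed")
  cols <- intersect(choice_data_columns, names(data))
  header <- sprintf("# avoidprior %s%s",
                    as.character(utils::packageVersion("avoidprior")),
                    if (is.null(seed)) "" else paste0(" seed=", seed))
  writeLines(header, path)
  readr::write_csv(data[, cols], path, append = TRUE, col_names = TRUE,
                   na = "NA")
  invisible(path)
}

#' @rdname write_choice_data
#' @export
write_design <- write_choice_data

#' Read choice data from CSV
#'
#' Reads a flat trial-by-trial file (header
#' `subject,task,block,trial,stimulus,offer,cost,success_prob,choice,outcome`;
#' leading `#` comment lines are ignored) and validates the coding
#' conventions: choice 0 = passive / 1 = active, outcome 1 = success /
#' 0 = loss and present if and only if the choice was active, success
#' probabilities strictly inside (0, 1). Violations are reported with row
#' numbers.
#'
#' @param path CSV file path.
#' @return A validated choice-data tibble sorted by subject, task, block
#'   and trial.
#' @export
read_choice_data <- function(path) {
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(data) == 0) {
    warning("Empty choice-data file: ", path)
    return(tibble::as_tibble(
      stats::setNames(rep(list(numeric(0)), length(choice_data_columns)),
                      choice_data_columns)))
  }
  missing_cols <- setdiff(setdiff(choice_data_columns, "outcome"),
                          names(data))
  if (length(missing_cols)) {
    stop("Missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"outcome" %in% names(data)) data$outcome <- NA_real_

  bad_choice <- which(!data$choice %in% c(0, 1))
  if (length(bad_choice)) {
    stop("Invalid `choice` (must be 0/1) at row(s): ",
         paste(utils::head(bad_choice, 5), collapse = ", "))
  }
  bad_passive <- which(data$choice == 0 & !is.na(data$outcome))
  if (length(bad_passive)) {
    stop("Outcome present on passive trial(s) at row(s): ",
         paste(utils::head(bad_passive, 5), collapse = ", "))
  }
  bad_active <- which(data$choice == 1 & is.na(data$outcome))
  if (length(bad_active)) {
    stop("Missing outcome on active trial(s) at row(s): ",
         paste(utils::head(bad_active, 5), collapse = ", "))
  }
  bad_prob <- which(data$success_prob <= 0 | data$success_prob >= 1)
  if (length(bad_prob)) {
    stop("`success_prob` outside (0, 1) at row(s): ",
         paste(utils::head(bad_prob, 5), collapse = ", "))
  }
  dplyr::arrange(data, .data$subject, .data$task, .data$block, .data$trial)
}

#' Run the full analysis pipeline
#'
#' Executes design generation, cohort simulation, subject fitting,
#' random-effects model selection and (optionally) parameter recovery in
#' order, writing every intermediate artifact to `out_dir` and returning a
#' summary: the winning model, the model-frequency/PXP table, and the 25th,
#' 50th and 75th percentiles of pseudo-r-squared for the winning model.
#'
#' @param config List with elements `seed`, `models` (fitted candidates),
#'   `cohort` (a [cohort_config()]), and optionally `task`, `n_blocks`,
#'   `recover_model` (model name for a parameter-recovery pass),
#'   `n_restarts`.
#' @param out_dir Output directory (created if needed).
#' @return List of class `avoid_pipeline`: `bms`, `fits`, `summary`
#'   (winner, model table, pseudo-r2 percentiles), and file paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("avoidprior")) {
  stopifnot(is.list(config), inherits(config$cohort, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  task <- config$task %||% "robber"
  n_blocks <- config$n_blocks %||% 4L
  n_restarts <- config$n_restarts %||% 10L
  seeds <- spawn_seeds(seed, 4L)

  cohort <- simulate_cohort(config$cohort, seed = seeds[1], task = task,
                            n_blocks = n_blocks)
  data_path <- file.path(out_dir, "cohort.csv")
  write_choice_data(cohort$data, data_path, seed = seeds[1])
  readr::write_csv(cohort$truth, file.path(out_dir, "cohort.truth.csv"))

  fits <- fit_cohort(cohort$data, config$models, n_restarts = n_restarts,
                     seed = seeds[2])
  fits_path <- file.path(out_dir, "fits.json")
  fit_table <- dplyr::select(fits, -"fit")
  jsonlite::write_json(fit_table, fits_path, digits = NA)

  bms <- rfx_bms(log_evidence_matrix(fits), seed = seeds[3])
  bms_path <- file.path(out_dir, "bms.json")
  jsonlite::write_json(
    list(model = bms$models, m_freq = unname(bms$model_frequency),
         xp = unname(bms$xp), pxp = unname(bms$pxp), bor = bms$bor),
    bms_path, digits = NA, auto_unbox = TRUE)

  winner <- bms$models[which.max(bms$pxp)]
  pr2 <- stats::quantile(fits$pseudo_r2[fits$model == winner],
                         c(0.25, 0.5, 0.75))

  recovery <- NULL
  if (!is.null(config$recover_model)) {
    recovery <- parameter_recovery(config$recover_model,
                                   n_subjects = config$cohort$n_subjects,
                                   n_blocks = n_blocks, seed = seeds[4],
                                   task = task, n_restarts = n_restarts)
    readr::write_csv(recovery$report,
                     file.path(out_dir, "parameter_recovery.csv"))
  }

  structure(list(
    bms = bms, fits = fits, recovery = recovery,
    summary = list(winner = winner,
                   model_table = tibble::tibble(
                     model = bms$models,
                     m_freq = unname(bms$model_frequency),
                     pxp = unname(bms$pxp)),
                   pseudo_r2_percentiles = pr2),
    paths = list(data = data_path, fits = fits_path, bms = bms_path,
                 out_dir = out_dir)
  ), class = "avoid_pipeline")
}
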