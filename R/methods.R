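#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a subject fit
#'
#' @param x A `subject_fit`.
#' @param ... Unused.
#' @return One row per parameter: unconstrained MAP estimate and its
#'   constrained value.
#' @method tidy subject_fit
#' @export
tidy.subject_fit <- function(x, ...) {
  tibble::tibble(model = x$model, parameter = names(x$theta),
                 estimate = unname(x$theta),
                 constrained = unlist(x$constrained, use.names = FALSE))
}

#' @rdname tidy.subject_fit
#' @method glance subject_fit
#' @export
glance.subject_fit <- function(x, ...) {
  tibble::tibble(model = x$model, log_evidence = x$log_evidence,
                 log_lik = x$log_lik, pseudo_r2 = x$pseudo_r2,
                 n_trials = x$n_trials, converged = x$converged,
                 grad_norm = x$grad_norm)
}

#' Tidy a model-selection result
#'
#' @param x A `bms_result`.
#' @param ... Unused.
#' @return One row per model with `m_freq`, `xp` and `pxp`.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(model = x$models, m_freq = unname(x$model_frequency),
                 xp = unname(x$xp), pxp = unname(x$pxp))
}

#' @rdname tidy.bms_result
#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = length(x$models),
                 bor = x$bor, winner = x$models[which.max(x$pxp)])
}

#' Tidy a parameter-recovery report
#'
#' @param x A `parameter_recovery`.
#' @param ... Unused.
#' @return The per-parameter recovery report.
#' @method tidy parameter_recovery
#' @export
tidy.parameter_recovery <- function(x, ...) {
  dplyr::mutate(x$report, model = x$model, .before = 1)
}

#' Tidy a model-recovery result
#'
#' @param x A `model_recovery`.
#' @param ... Unused.
#' @return Confusion counts of generating versus selected model (by PXP).
#' @method tidy model_recovery
#' @export
tidy.model_recovery <- function(x, ...) {
  x$confusion_pxp
}
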