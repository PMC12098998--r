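#' Pseudo-r-squared of a fit
#'
#' `1 - LL / (n * ln 0.5)`: 0 for a model at chance, 1 for perfect
#' prediction, negative when the model fits worse than a coin flip.
#'
#' @param log_lik Total log-likelihood (a non-positive number).
#' @param n_trials Number of binary choices.
#' @return Scalar pseudo-r-squared (at most 1).
#' @export
#' @examples
#' pseudo_r2(60 * log(0.5), 60)  # chance: 0
pseudo_r2 <- function(log_lik, n_trials) {
  if (n_trials <= 0) stop("`n_trials` must be positive.")
  1 - log_lik / (n_trials * log(0.5))
}

# Project a symmetric matrix to positive-definite by flooring eigenvalues.
pd_project <- function(h, floor = 1e-8) {
  h <- (h + t(h)) / 2
  e <- eigen(h, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  list(mat = e$vectors %*% (vals * t(e$vectors)), logdet = sum(log(vals)))
}

# Central finite-difference Hessian, step 1e-4.
fd_hessian <- function(fn, x, step = 1e-4) {
  d <- length(x)
  h <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (k in i:d) {
      ei <- ek <- numeric(d)
      ei[i] <- step
      ek[k] <- step
      h[i, k] <- h[k, i] <-
        (fn(x + ei + ek) - fn(x + ei - ek) -
           fn(x - ei + ek) + fn(x - ei - ek)) / (4 * step^2)
    }
  }
  h
}

#' MAP fit of one subject under one model
#'
#' Minimises the penalised negative log-likelihood
#' `NLL(theta) + 0.5 * sum((theta - m)^2 / v)` in the unconstrained space,
#' where the default prior is the zero-centred normal with variance 6.25
#' used for all parameters. Optimisation restarts from seeded N(0, 1) draws
#' (plus the prior mean) to cope with multimodal lapse models; the Laplace
#' log model evidence is
#' `-NLL(theta*) + log N(theta*|m, v) + (d/2) log 2*pi - 0.5 log det H`,
#' with `H` the Hessian of the negative log-posterior at the optimum
#' (central finite differences, projected to positive-definite).
#'
#' @param data Choice data for one subject.
#' @param spec Model or model name.
#' @param prior_mean,prior_var Gaussian prior moments in unconstrained
#'   space; scalars recycle across parameters.
#' @param n_restarts Number of optimisation starts (>= 1; default 10).
#' @param seed Seed for the restart draws.
#' @param smoothing Choice-function smoothing for bias models.
#' @param start Optional warm-start vector prepended to the restart list.
#' @return Object of class `subject_fit`: MAP estimate (unconstrained and
#'   constrained), Hessian, Laplace log-evidence, log-likelihood,
#'   pseudo-r-squared, and convergence diagnostics.
#' @export
fit_subject_map <- function(data, spec, prior_mean = 0, prior_var = 6.25,
                            n_restarts = 10, seed = 1,
                            smoothing = c("softplus", "rectifier"),
                            start = NULL) {
  spec <- as_model_spec(spec)
  smoothing <- match.arg(smoothing)
  if (nrow(data) == 0) stop("Choice data has zero trials.")
  data <- prepare_choice_data(data)
  d <- spec$n_par
  m <- rep(prior_mean, length.out = d)
  v <- rep(prior_var, length.out = d)

  nll <- function(theta) negative_log_likelihood(data, spec, theta, smoothing)
  obj <- function(theta) {
    val <- nll(theta) + 0.5 * sum((theta - m)^2 / v)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- with_local_seed(seed, {
    s <- matrix(stats::rnorm(n_restarts * d), nrow = n_restarts)
    s[1, ] <- m
    # the temperature spans orders of magnitude (tau = 0.01 * exp(theta));
    # spread its starts over the decades so near-deterministic and noisy
    # regimes are both reached
    tau_cols <- which(spec$transforms == "tau")
    for (j in tau_cols) {
      s[, j] <- s[, j] + rep(c(0, 2, 4, 6), length.out = n_restarts)
    }
    s
  })
  if (!is.null(start)) starts <- rbind(matrix(start, nrow = 1), starts)

  best <- NULL
  n_converged <- 0L
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[r, ], obj, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        if (d == 1) {
          stats::optim(starts[r, ], obj, method = "Brent",
                       lower = -25, upper = 25)
        } else {
          stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 2000))
        },
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    if (fit$convergence == 0) n_converged <- n_converged + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("All optimisation restarts failed.")

  theta <- as.numeric(best$par)
  names(theta) <- spec$par_names
  grad <- tryCatch(
    numeric_gradient(obj, theta),
    error = function(e) rep(NA_real_, d))
  h <- fd_hessian(obj, theta)
  proj <- pd_project(h)
  ll <- -nll(theta)
  log_prior <- sum(stats::dnorm(theta, m, sqrt(v), log = TRUE))
  log_evidence <- ll + log_prior + (d / 2) * log(2 * pi) - 0.5 * proj$logdet

  structure(list(
    model = spec$name,
    theta = theta,
    constrained = transform_parameters(spec, theta),
    hessian = proj$mat,
    log_evidence = log_evidence,
    log_lik = ll,
    pseudo_r2 = pseudo_r2(ll, nrow(data)),
    n_trials = nrow(data),
    prior_mean = m,
    prior_var = v,
    restarts_used = nrow(starts),
    n_converged = n_converged,
    grad_norm = sqrt(sum(grad^2)),
    converged = n_converged > 0
  ), class = "subject_fit")
}

numeric_gradient <- function(fn, x, step = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- step
    (fn(x + e) - fn(x - e)) / (2 * step)
  }, numeric(1))
}

#' @export
print.subject_fit <- function(x, ...) {
  cat("<subject_fit> model:", x$model, "\n")
  cat("  log-evidence:", format(x$log_evidence, digits = 5),
      " log-lik:", format(x$log_lik, digits = 5),
      " pseudo-r2:", format(x$pseudo_r2, digits = 3), "\n")
  cat("  ", paste(names(x$theta),
                  format(unlist(x$constrained), digits = 3),
                  sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Fit every subject under every model
#'
#' @param data Cohort choice data (multiple subjects).
#' @param models Character vector of model names.
#' @param ... Passed to [fit_subject_map()].
#' @return A tibble with one row per subject x model: `subject`, `model`,
#'   `log_evidence`, `log_lik`, `pseudo_r2` and a `fit` list-column of
#'   `subject_fit` objects.
#' @export
fit_cohort <- function(data, models, ...) {
  data <- prepare_choice_data(data)
  subjects <- unique(data$subject)
  grid <- tidyr::expand_grid(subject = subjects, model = models)
  fits <- purrr::pmap(grid, function(subject, model) {
    fit_subject_map(data[data$subject == subject, ], model, ...)
  })
  dplyr::mutate(grid,
    log_evidence = purrr::map_dbl(fits, "log_evidence"),
    log_lik = purrr::map_dbl(fits, "log_lik"),
    pseudo_r2 = purrr::map_dbl(fits, "pseudo_r2"),
    fit = fits)
}

#' Subjects-by-models log-evidence matrix
#'
#' @param fits Output of [fit_cohort()].
#' @return Numeric matrix (rows: subjects, columns: models) of Laplace log
#'   evidences, ready for [rfx_bms()].
#' @export
log_evidence_matrix <- function(fits) {
  wide <- tidyr::pivot_wider(
    fits[, c("subject", "model", "log_evidence")],
    names_from = "model", values_from = "log_evidence")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject
  m
}

#' Empirical-Bayes group refinement of subject fits
#'
#' A simplified hierarchical scheme in the spirit of hierarchical Bayesian
#' inference over models and parameters: subjects are first fitted under
#' the non-informative N(0, 6.25) prior; then, iteratively, (1) per-subject
#' model responsibilities are computed from the Laplace evidences, (2) each
#' model's group mean and variance are set to the responsibility-weighted
#' moments of the subject MAP estimates (variance floored at 1e-4), and
#' (3) subjects are refitted under the updated Gaussian prior (warm-started
#' at their previous optimum). Iteration stops when the largest change in
#' any group mean falls below `tol` or after `max_iter` rounds.
#'
#' @param data Cohort choice data.
#' @param models Character vector of model names.
#' @param fits Optional initial [fit_cohort()] result (computed if omitted).
#' @param max_iter,tol Convergence controls (defaults 50 and 1e-4).
#' @param refit_restarts Restarts used in refits beyond the warm start.
#' @param ... Passed to the initial [fit_cohort()] call.
#' @return List of class `hier_fit`: `fits` (updated tibble),
#'   `responsibilities` (subject x model tibble), `group` (model,
#'   parameter, mean, var), `iterations`, `total_evidence` trace.
#' @export
hierarchical_refit <- function(data, models, fits = NULL, max_iter = 50,
                               tol = 1e-4, refit_restarts = 2, ...) {
  data <- prepare_choice_data(data)
  if (is.null(fits)) fits <- fit_cohort(data, models, ...)
  subjects <- unique(fits$subject)

  responsibilities <- function(fits) {
    dplyr::mutate(
      dplyr::group_by(fits[, c("subject", "model", "log_evidence")],
                      .data$subject),
      resp = exp(.data$log_evidence - logsumexp(.data$log_evidence))) |>
      dplyr::ungroup()
  }

  group_moments <- function(fits, resp) {
    purrr::map_dfr(models, function(mod) {
      rows <- fits$model == mod
      r <- resp$resp[match(paste(fits$subject[rows], mod),
                           paste(resp$subject, resp$model))]
      thetas <- do.call(rbind, purrr::map(fits$fit[rows], "theta"))
      # subject-level posterior variances (inverse Hessian diagonals) enter
      # the group variance alongside the spread of the MAPs, so a tight
      # cluster of uncertain estimates does not collapse the prior
      within_var <- do.call(rbind, purrr::map(fits$fit[rows], function(f) {
        diag(solve(f$hessian))
      }))
      w <- r / sum(r)
      mu <- colSums(w * thetas)
      vv <- pmax(colSums(w * (sweep(thetas, 2, mu)^2 + within_var)), 1e-4)
      tibble::tibble(model = mod, parameter = colnames(thetas),
                     mean = unname(mu), var = unname(vv))
    })
  }

  # cohort-level objective: each subject's evidence marginalised over models
  # (uniform model prior); this is the quantity the EB iterations improve
  mixture_evidence <- function(fits) {
    per_subject <- tapply(fits$log_evidence, fits$subject,
                          function(x) logsumexp(x) - log(length(x)))
    sum(per_subject)
  }

  trace <- numeric(0)
  group <- NULL
  for (it in seq_len(max_iter)) {
    resp <- responsibilities(fits)
    new_group <- group_moments(fits, resp)
    trace <- c(trace, mixture_evidence(fits))
    if (!is.null(group)) {
      delta <- max(abs(new_group$mean - group$mean))
      if (delta < tol) {
        group <- new_group
        break
      }
    }
    group <- new_group
    fits$fit <- purrr::pmap(fits[, c("subject", "model", "fit")],
      function(subject, model, fit) {
        g <- group[group$model == model, ]
        fit_subject_map(data[data$subject == subject, ], model,
                        prior_mean = g$mean, prior_var = g$var,
                        n_restarts = refit_restarts, seed = it,
                        start = fit$theta)
      })
    fits$log_evidence <- purrr::map_dbl(fits$fit, "log_evidence")
    fits$log_lik <- purrr::map_dbl(fits$fit, "log_lik")
    fits$pseudo_r2 <- purrr::map_dbl(fits$fit, "pseudo_r2")
  }
  resp <- responsibilities(fits)
  structure(list(fits = fits,
                 responsibilities = resp[, c("subject", "model", "resp")],
                 group = group, iterations = it,
                 total_evidence = trace),
            class = "hier_fit")
}
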