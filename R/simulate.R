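#' Simulate one agent on a task schedule
#'
#' Plays a model forward through a design: on each trial the model's
#' utilities and choice function give P(go), the action is sampled, and an
#' outcome is drawn Bernoulli(success probability of the stimulus) only if
#' the active choice was taken. Belief and outcome history reset at block
#' boundaries. Joint models expect a design spanning both tasks.
#'
#' @param spec Model or model name.
#' @param params Named list (or named vector) of constrained parameter
#'   values, e.g. `list(tau = 0.3, mu0 = 0.5, sigma0sq = 0.2)`.
#' @param design An `avoid_design` (or row-bound designs for several blocks
#'   and, for joint models, both tasks).
#' @param seed Integer seed; the simulation is fully reproducible.
#' @param smoothing Choice-function mode for bias models; simulation
#'   defaults to the exact `"rectifier"`.
#' @return A choice-data tibble (design columns plus `choice`, `outcome`,
#'   and the generating `p_go`) with attributes `model` and `params`.
#' @export
#' @examples
#' d <- build_block_design("robber", seed = 1)
#' sim <- simulate_subject("bayes", list(tau = 0.3, mu0 = 0.4, sigma0sq = 0.2),
#'                         d, seed = 2)
#' mean(sim$choice)
simulate_subject <- function(spec, params, design, seed,
                             smoothing = c("rectifier", "softplus")) {
  spec <- as_model_spec(spec)
  smoothing <- match.arg(smoothing)
  params <- as.list(params)
  design <- dplyr::arrange(tibble::as_tibble(design), .data$subject,
                           .data$task, .data$block, .data$trial)
  if (spec$joint && length(unique(design$task)) != 2) {
    stop("Joint models need a design covering both tasks.")
  }

  name <- spec$name
  bayes_like <- name %in% c("bayes", "bayes_bias", "bayes_between_stim") ||
    spec$joint
  if (bayes_like && !spec$joint) {
    pr <- beta_prior_from_moments(params$mu0, params$sigma0sq)
  }

  n <- nrow(design)
  choice <- integer(n)
  outcome <- rep(NA_real_, n)
  p_go_trace <- numeric(n)

  groups <- paste(design$subject, design$task, design$block)
  with_local_seed(seed, {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      task <- design$task[idx[1]]
      robber <- task == "robber"
      # per-block state
      prev_success <- 0
      prev_loss <- 0
      s_cnt <- numeric(0)   # per-stimulus successes
      f_cnt <- numeric(0)
      s_all <- 0            # stimulus-blind counts
      f_all <- 0
      if (spec$joint) {
        if (name == "joint_1prior") {
          pr <- beta_prior_from_moments(params$mu0, params$sigma0sq)
        } else if (robber) {
          pr <- beta_prior_from_moments(params$mu0_R, params$sigma0sq_R)
        } else {
          pr <- beta_prior_from_moments(params$mu0_F, params$sigma0sq_F)
        }
      }
      for (i in idx) {
        o <- design$offer[i]
        cst <- design$cost[i]
        j <- as.character(design$stimulus[i])
        if (bayes_like && is.na(s_cnt[j])) {
          s_cnt[j] <- 0
          f_cnt[j] <- 0
        }
        p_hat <- switch(name,
          static_prob = ,
          static_prob_bias = params$p,
          bayes = ,
          bayes_bias = ,
          joint_1prior = ,
          joint_2prior =
            (pr$alpha0 + s_cnt[j]) /
              (pr$alpha0 + pr$beta0 + s_cnt[j] + f_cnt[j]),
          bayes_between_stim =
            (pr$alpha0 + s_all) / (pr$alpha0 + pr$beta0 + s_all + f_all),
          NULL)
        q_ng <- if (robber) 0 else -o
        q_go <- if (name == "softmax_only") {
          if (robber) o - cst else -cst
        } else if (name == "wsls") {
          (if (robber) o - cst else -cst) +
            prev_success * params$gamma_pos - prev_loss * params$gamma_neg
        } else {
          if (robber) -cst + p_hat * o else -cst - (1 - p_hat) * o
        }
        tau <- if (spec$joint) {
          if (robber) params$tau_R else params$tau_F
        } else {
          params$tau
        }
        p_sm <- stats::plogis((q_go - q_ng) / tau)
        phi <- if (spec$joint) {
          if (robber) NULL else params$phi_F
        } else if (grepl("_bias$", name)) {
          params$phi
        } else {
          NULL
        }
        p_go <- if (is.null(phi)) p_sm else {
          biased_choice_prob(phi, p_sm, smoothing)
        }
        # same clipping convention as the likelihood evaluator
        p_go <- min(max(p_go, 1e-12), 1 - 1e-12)
        act <- stats::rbinom(1, 1, p_go)
        choice[i] <- act
        p_go_trace[i] <- p_go
        if (act == 1) {
          out <- stats::rbinom(1, 1, design$success_prob[i])
          outcome[i] <- out
          prev_success <- as.integer(out == 1)
          prev_loss <- as.integer(out == 0)
          if (bayes_like) {
            if (out == 1) {
              s_cnt[j] <- s_cnt[j] + 1
              s_all <- s_all + 1
            } else {
              f_cnt[j] <- f_cnt[j] + 1
              f_all <- f_all + 1
            }
          }
        } else {
          prev_success <- 0
          prev_loss <- 0
        }
      }
    }
  })

  out <- dplyr::mutate(design, choice = choice, outcome = outcome,
                       p_go = p_go_trace)
  out <- tibble::as_tibble(out)
  attr(out, "model") <- name
  attr(out, "params") <- params
  attr(out, "sim_seed") <- seed
  out
}

#' Cohort simulation settings
#'
#' Describes a population of agents: how many subjects, the mixture over
#' generating models, and per-model group means and standard deviations of
#' the unconstrained parameters. Defaults (mean 0, SD 1) sit well inside
#' the N(0, 6.25) fitting prior and produce identifiable, moderate
#' behaviour.
#'
#' @param n_subjects Number of agents.
#' @param mixture Named numeric vector of model frequencies summing to 1,
#'   e.g. `c(bayes = 0.6, static_prob = 0.4)`.
#' @param group_means,group_sds Optional named lists mapping model name to
#'   a numeric vector (length = that model's parameter count, or length 1
#'   to recycle) of unconstrained group means / SDs.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, mixture, group_means = NULL,
                          group_sds = NULL) {
  if (is.null(names(mixture)) || any(!names(mixture) %in% avoid_models())) {
    stop("`mixture` must be named by model.")
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop("`mixture` must sum to 1.")
  if (any(mixture < 0)) stop("Mixture frequencies must be non-negative.")
  structure(list(n_subjects = as.integer(n_subjects), mixture = mixture,
                 group_means = group_means, group_sds = group_sds),
            class = "cohort_config")
}

cohort_draw <- function(config, model) {
  spec <- model_spec(model)
  m <- config$group_means[[model]] %||% 0
  s <- config$group_sds[[model]] %||% 1
  stats::setNames(stats::rnorm(spec$n_par, mean = m, sd = s), spec$par_names)
}

#' Simulate a cohort of agents
#'
#' Each subject's generating model is drawn from the mixture, unconstrained
#' parameters from that model's group Gaussian, and a fresh seeded design is
#' built per subject before simulating choices. Subject-level random streams
#' are spawned from the master seed, so results do not depend on iteration
#' order.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @param task Task for single-task models (`"robber"` or `"factory"`);
#'   joint models always play alternating blocks of both tasks.
#' @param n_blocks Blocks of 60 trials per subject (default 4, i.e. 240
#'   trials, the study's first-day volume).
#' @return List with `data` (row-bound choice data for all subjects) and
#'   `truth` (long tibble: subject, model, parameter, unconstrained and
#'   constrained generating values).
#' @export
simulate_cohort <- function(config, seed, task = "robber", n_blocks = 4) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  models <- names(config$mixture)
  subject_seeds <- spawn_seeds(seed, 3L * n)

  res <- purrr::map(seq_len(n), function(i) {
    pick_seed <- subject_seeds[3 * i - 2]
    design_seed <- subject_seeds[3 * i - 1]
    sim_seed <- subject_seeds[3 * i]
    drawn <- with_local_seed(pick_seed, {
      model <- if (length(models) == 1) models else {
        sample(models, 1, prob = config$mixture)
      }
      list(model = model, theta = cohort_draw(config, model))
    })
    spec <- model_spec(drawn$model)
    params <- transform_parameters(spec, drawn$theta)
    block_seeds <- spawn_seeds(design_seed, n_blocks)
    design <- if (spec$joint) {
      purrr::map_dfr(seq_len(n_blocks), function(b) {
        tk <- if (b %% 2 == 1) "robber" else "factory"
        build_block_design(tk, seed = block_seeds[b], block = b, subject = i)
      })
    } else {
      purrr::map_dfr(seq_len(n_blocks), function(b) {
        build_block_design(task, seed = block_seeds[b], block = b,
                           subject = i)
      })
    }
    data <- simulate_subject(spec, params, design, seed = sim_seed)
    truth <- tibble::tibble(
      subject = i, model = drawn$model, parameter = spec$par_names,
      unconstrained = unname(drawn$theta),
      constrained = unlist(params, use.names = FALSE)
    )
    list(data = data, truth = truth)
  })

  list(data = purrr::map_dfr(res, "data"),
       truth = purrr::map_dfr(res, "truth"))
}
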