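#' Available choice models
#'
#' Single-task models: `softmax_only` (temperature only, assumes certain
#' success), `wsls` (win-stay lose-shift bonuses on the previous trial's
#' outcome), `static_prob` (a fixed subjective success probability),
#' `bayes` (beta-Bernoulli learner that reverts to its prior with each new
#' stimulus), `bayes_between_stim` (carries the posterior across stimuli),
#' and the action-bias augmentations `static_prob_bias` and `bayes_bias`.
#' Joint cross-task models: `joint_1prior` (one shared prior for both tasks)
#' and `joint_2prior` (task-specific priors); both use task-specific
#' temperatures and an action bias in the factory task only.
#'
#' @return Character vector of model names.
#' @export
avoid_models <- function() {
  c("softmax_only", "wsls", "static_prob", "bayes", "bayes_between_stim",
    "static_prob_bias", "bayes_bias", "joint_1prior", "joint_2prior")
}

# Parameter metadata: name order defines the unconstrained vector layout.
# Transform codes: tau = 0.01 * exp(theta); exp = exp(theta);
# logit = logistic(theta); signed = 2 * logistic(theta) - 1.
model_parameter_table <- function(name) {
  switch(name,
    softmax_only = c(tau = "tau"),
    wsls = c(tau = "tau", gamma_pos = "exp", gamma_neg = "exp"),
    static_prob = c(tau = "tau", p = "logit"),
    bayes = c(tau = "tau", mu0 = "logit", sigma0sq = "logit"),
    bayes_between_stim = c(tau = "tau", mu0 = "logit", sigma0sq = "logit"),
    static_prob_bias = c(tau = "tau", p = "logit", phi = "signed"),
    bayes_bias = c(tau = "tau", mu0 = "logit", sigma0sq = "logit",
                   phi = "signed"),
    joint_1prior = c(tau_R = "tau", tau_F = "tau", phi_F = "signed",
                     mu0 = "logit", sigma0sq = "logit"),
    joint_2prior = c(tau_R = "tau", tau_F = "tau", phi_F = "signed",
                     mu0_R = "logit", sigma0sq_R = "logit",
                     mu0_F = "logit", sigma0sq_F = "logit"),
    stop("Unknown model: ", name)
  )
}

#' Model specification
#'
#' @param name One of [avoid_models()].
#' @return A list of class `avoid_model` with elements `name`, `par_names`,
#'   `n_par`, `transforms` and `joint` (whether the model spans both tasks).
#' @export
#' @examples
#' model_spec("bayes")$par_names
model_spec <- function(name) {
  name <- match.arg(name, avoid_models())
  tab <- model_parameter_table(name)
  structure(
    list(name = name, par_names = names(tab), n_par = length(tab),
         transforms = unname(tab), joint = name %in% c("joint_1prior",
                                                       "joint_2prior")),
    class = "avoid_model"
  )
}

as_model_spec <- function(model) {
  if (inherits(model, "avoid_model")) model else model_spec(model)
}

#' Map unconstrained parameters to their model scale
#'
#' Fitting and group priors live in an unconstrained space carrying a
#' zero-centred normal prior with variance 6.25. Positive parameters are
#' exponentiated (the temperature additionally scaled by 0.01 to improve
#' coverage of small values), unit-interval parameters pass through the
#' logistic, and the action bias phi in (-1, 1) uses 2 * logistic - 1.
#'
#' @param spec An `avoid_model` or model name.
#' @param unconstrained Numeric vector matching the model's parameter count.
#' @return Named list of constrained parameter values.
#' @seealso [untransform_parameters()] for the exact inverse.
#' @export
#' @examples
#' transform_parameters("bayes", c(0, 0, 0))  # tau 0.01, mu0 0.5, sigma0sq 0.5
transform_parameters <- function(spec, unconstrained) {
  spec <- as_model_spec(spec)
  if (length(unconstrained) != spec$n_par) {
    stop("Model '", spec$name, "' expects ", spec$n_par,
         " parameters, got ", length(unconstrained), ".")
  }
  out <- purrr::map2(spec$transforms, as.numeric(unconstrained),
                     function(tr, th) {
                       switch(tr,
                              tau = 0.01 * exp(th),
                              exp = exp(th),
                              logit = stats::plogis(th),
                              signed = 2 * stats::plogis(th) - 1)
                     })
  names(out) <- spec$par_names
  out
}

#' Inverse parameter transform
#'
#' @inheritParams transform_parameters
#' @param constrained Named list or vector of constrained values.
#' @return Unconstrained numeric vector in the model's parameter order.
#' @export
untransform_parameters <- function(spec, constrained) {
  spec <- as_model_spec(spec)
  constrained <- as.list(constrained)
  th <- purrr::map2_dbl(spec$transforms, spec$par_names, function(tr, nm) {
    x <- constrained[[nm]]
    if (is.null(x)) stop("Missing parameter '", nm, "'.")
    switch(tr,
           tau = log(x / 0.01),
           exp = log(x),
           logit = stats::qlogis(x),
           signed = stats::qlogis((x + 1) / 2))
  })
  stats::setNames(th, spec$par_names)
}

#' Softmax probability of the active choice
#'
#' `P(go) = 1 / (1 + exp(-(q_go - q_ng) / tau))`: the probability of acting
#' rises smoothly with the utility advantage of acting, with temperature
#' `tau` setting the decision noise.
#'
#' @param q_go,q_ng Utilities of the active and passive options (points).
#' @param tau Positive temperature.
#' @return Probability in (0, 1); vectorised.
#' @export
softmax_p_go <- function(q_go, q_ng, tau) {
  if (any(tau <= 0)) stop("`tau` must be positive.")
  stats::plogis((q_go - q_ng) / tau)
}

#' Beta prior from mean and relative variance
#'
#' Converts the prior mean `mu0` and relative variance `sigma0sq` (the beta
#' variance divided by its upper bound `mu0 * (1 - mu0)`) into the shape
#' parameters `alpha0 = mu0 * (1 / sigma0sq - 1)` and
#' `beta0 = (1 - mu0) * (1 / sigma0sq - 1)`.
#'
#' @param mu0 Prior mean in (0, 1).
#' @param sigma0sq Relative variance in (0, 1).
#' @return List with `alpha0` and `beta0`.
#' @export
#' @examples
#' beta_prior_from_moments(0.5, 1/3)  # uniform prior: alpha0 = beta0 = 1
beta_prior_from_moments <- function(mu0, sigma0sq) {
  if (any(mu0 <= 0 | mu0 >= 1) || any(sigma0sq <= 0 | sigma0sq >= 1)) {
    stop("`mu0` and `sigma0sq` must lie strictly in (0, 1).")
  }
  nu <- 1 / sigma0sq - 1
  list(alpha0 = mu0 * nu, beta0 = (1 - mu0) * nu)
}

#' Create a belief state for the Bayesian learner
#'
#' @param stimuli Vector of stimulus ids.
#' @param alpha0,beta0 Initial beta shape parameters shared by all stimuli.
#' @return A list of class `belief_state` with named `alpha` and `beta`
#'   vectors.
#' @export
belief_state <- function(stimuli, alpha0, beta0) {
  stimuli <- as.character(unique(stimuli))
  structure(
    list(alpha = stats::setNames(rep(alpha0, length(stimuli)), stimuli),
         beta = stats::setNames(rep(beta0, length(stimuli)), stimuli)),
    class = "belief_state"
  )
}

#' Conjugate belief update after one trial
#'
#' An active choice increments `alpha` on success or `beta` on loss for the
#' encountered stimulus only; a passive choice leaves the state untouched
#' (passivity yields no observation of the success probability).
#'
#' @param state A `belief_state`.
#' @param stimulus Stimulus id encountered.
#' @param action `"go"` or `"ng"`.
#' @param outcome `"success"`, `"loss"`, or `"none"` (required iff passive).
#' @return Updated `belief_state`.
#' @export
update_belief <- function(state, stimulus, action = c("go", "ng"),
                          outcome = c("success", "loss", "none")) {
  action <- match.arg(action)
  outcome <- match.arg(outcome)
  if (action == "ng" && outcome != "none") {
    stop("A passive choice has no outcome; use outcome = 'none'.")
  }
  if (action == "go" && outcome == "none") {
    stop("An active choice must carry a 'success' or 'loss' outcome.")
  }
  if (action == "ng") return(state)
  j <- as.character(stimulus)
  if (outcome == "success") {
    state$alpha[[j]] <- state$alpha[[j]] + 1
  } else {
    state$beta[[j]] <- state$beta[[j]] + 1
  }
  state
}

#' Posterior mean success probability
#'
#' @param state A `belief_state`.
#' @param stimulus Stimulus id.
#' @return `alpha / (alpha + beta)` for that stimulus.
#' @export
posterior_mean <- function(state, stimulus) {
  j <- as.character(stimulus)
  state$alpha[[j]] / (state$alpha[[j]] + state$beta[[j]])
}

# Numerically stable softplus surrogate log(1 + exp(a * x)) / a for the
# rectifier [x]_+; a = 100 reproduces the rectifier to within 0.007.
softplus <- function(x, alpha = 100) {
  z <- alpha * x
  ifelse(z > 30, x + log1p(exp(-z)) / alpha, log1p(exp(z)) / alpha)
}

#' Action-biased choice probability
#'
#' Mixes a fixed action (phi > 0) or passivity (phi < 0) tendency into the
#' softmax choice probability: `P(go) = [phi]_+ + (1 - |phi|) * p_softmax`.
#' The `"softplus"` mode replaces the rectifier by `log(1 + exp(100 phi))/100`
#' and `|phi|` by `softplus(phi) + softplus(-phi)` so the likelihood stays
#' differentiable at phi = 0 for gradient-based fitting; it deviates from
#' the exact rectifier by at most 0.007 anywhere in (-1, 1).
#'
#' @param phi Action bias in `[-1, 1]`.
#' @param p_softmax Softmax choice probability in (0, 1).
#' @param smoothing `"rectifier"` (exact) or `"softplus"` (surrogate).
#' @param alpha Softplus sharpness (default 100).
#' @return Probability, clipped to (0, 1); vectorised.
#' @export
#' @examples
#' biased_choice_prob(-0.5, 0.6, "rectifier")  # 0.3
biased_choice_prob <- function(phi, p_softmax,
                               smoothing = c("softplus", "rectifier"),
                               alpha = 100) {
  smoothing <- match.arg(smoothing)
  if (any(phi < -1 | phi > 1)) stop("`phi` must lie in [-1, 1].")
  if (smoothing == "rectifier") {
    p <- pmax(phi, 0) + (1 - abs(phi)) * p_softmax
  } else {
    p <- softplus(phi, alpha) +
      (1 - (softplus(phi, alpha) + softplus(-phi, alpha))) * p_softmax
  }
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Trial utilities for the active and passive options
#'
#' Implements the task-specific utility functions. In the robber task the
#' passive option forfeits the offer (utility 0 relative to walking away
#' empty-handed) while acting risks the cost for a chance at the offer; in
#' the factory task the passive option is a sure loss of the offer and
#' acting risks cost plus offer. Probability-sensitive models weight the
#' offer by the subjective success probability `p`.
#'
#' @param spec Model or model name.
#' @param task `"robber"` or `"factory"`.
#' @param offer,cost Trial offer and cost magnitudes (points).
#' @param params Named list of constrained parameters (as from
#'   [transform_parameters()]).
#' @param p Subjective success probability (static value or posterior mean),
#'   required for `static_prob*` and `bayes*` models.
#' @param prev_success,prev_loss Flags for the previous trial's outcome
#'   (win-stay lose-shift models only).
#' @return List with numeric `q_go` and `q_ng`.
#' @export
trial_utilities <- function(spec, task, offer, cost, params = list(),
                            p = NULL, prev_success = 0, prev_loss = 0) {
  spec <- as_model_spec(spec)
  base <- sub("_bias$", "", spec$name)
  if (spec$joint) base <- "bayes"
  robber <- task == "robber"
  q_ng <- ifelse(robber, 0, -offer)
  q_go <- switch(base,
    softmax_only = ifelse(robber, offer - cost, -cost),
    wsls = ifelse(robber, offer - cost, -cost) +
      prev_success * params$gamma_pos - prev_loss * params$gamma_neg,
    static_prob = ,
    bayes = ,
    bayes_between_stim = {
      pp <- if (is.null(p)) params$p else p
      if (is.null(pp)) stop("A success probability `p` is required.")
      ifelse(robber, -cost + pp * offer, -cost - (1 - pp) * offer)
    },
    stop("Unknown model: ", spec$name)
  )
  list(q_go = q_go, q_ng = q_ng)
}

# --- vectorised likelihood machinery ---------------------------------------

# Augment choice data with the per-trial sufficient statistics every model
# needs: previous-trial outcome flags (within subject x task x block, any
# stimulus) and cumulative success/loss counts before each trial, both
# stimulus-specific and stimulus-blind. These depend only on the data, so
# the likelihood of any parameter vector is a vectorised expression.
prepare_choice_data <- function(data) {
  if (isTRUE(attr(data, "avoid_prepared"))) return(data)
  need <- c("subject", "task", "block", "trial", "stimulus", "offer",
            "cost", "choice", "outcome")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("Choice data is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  data <- dplyr::arrange(data, .data$subject, .data$task, .data$block,
                         .data$trial)
  succ <- as.integer(data$choice == 1 & !is.na(data$outcome) &
                       data$outcome == 1)
  loss <- as.integer(data$choice == 1 & !is.na(data$outcome) &
                       data$outcome == 0)
  data$.succ <- succ
  data$.loss <- loss
  data <- dplyr::group_by(data, .data$subject, .data$task, .data$block)
  data <- dplyr::mutate(data,
    prev_success = dplyr::lag(.data$.succ, default = 0L),
    prev_loss = dplyr::lag(.data$.loss, default = 0L),
    s_before_any = cumsum(.data$.succ) - .data$.succ,
    f_before_any = cumsum(.data$.loss) - .data$.loss)
  data <- dplyr::group_by(data, .data$subject, .data$task, .data$block,
                          .data$stimulus)
  data <- dplyr::mutate(data,
    s_before = cumsum(.data$.succ) - .data$.succ,
    f_before = cumsum(.data$.loss) - .data$.loss)
  data <- dplyr::ungroup(data)
  data$.succ <- NULL
  data$.loss <- NULL
  attr(data, "avoid_prepared") <- TRUE
  data
}

# P(go) for every trial of prepared single-subject data under constrained
# parameters. `params` is a named list on the model scale.
go_probability <- function(spec, data, params,
                           smoothing = c("softplus", "rectifier")) {
  spec <- as_model_spec(spec)
  smoothing <- match.arg(smoothing)
  data <- prepare_choice_data(data)
  robber <- data$task == "robber"

  if (spec$joint) {
    if (spec$name == "joint_1prior") {
      pr <- beta_prior_from_moments(params$mu0, params$sigma0sq)
      a0 <- rep(pr$alpha0, nrow(data))
      b0 <- rep(pr$beta0, nrow(data))
    } else {
      prR <- beta_prior_from_moments(params$mu0_R, params$sigma0sq_R)
      prF <- beta_prior_from_moments(params$mu0_F, params$sigma0sq_F)
      a0 <- ifelse(robber, prR$alpha0, prF$alpha0)
      b0 <- ifelse(robber, prR$beta0, prF$beta0)
    }
    p_hat <- (a0 + data$s_before) / (a0 + b0 + data$s_before + data$f_before)
    q_go <- ifelse(robber, -data$cost + p_hat * data$offer,
                   -data$cost - (1 - p_hat) * data$offer)
    q_ng <- ifelse(robber, 0, -data$offer)
    tau <- ifelse(robber, params$tau_R, params$tau_F)
    p_sm <- stats::plogis((q_go - q_ng) / tau)
    p_go <- ifelse(robber, p_sm,
                   biased_choice_prob(params$phi_F, p_sm, smoothing))
    return(pmin(pmax(p_go, 1e-12), 1 - 1e-12))
  }

  p_hat <- switch(spec$name,
    static_prob = ,
    static_prob_bias = rep(params$p, nrow(data)),
    bayes = ,
    bayes_bias = {
      pr <- beta_prior_from_moments(params$mu0, params$sigma0sq)
      (pr$alpha0 + data$s_before) /
        (pr$alpha0 + pr$beta0 + data$s_before + data$f_before)
    },
    bayes_between_stim = {
      pr <- beta_prior_from_moments(params$mu0, params$sigma0sq)
      (pr$alpha0 + data$s_before_any) /
        (pr$alpha0 + pr$beta0 + data$s_before_any + data$f_before_any)
    },
    NULL)

  ut <- trial_utilities(spec, data$task, data$offer, data$cost,
                        params = params, p = p_hat,
                        prev_success = data$prev_success,
                        prev_loss = data$prev_loss)
  p_sm <- softmax_p_go(ut$q_go, ut$q_ng, params$tau)
  p_go <- if (grepl("_bias$", spec$name)) {
    biased_choice_prob(params$phi, p_sm, smoothing)
  } else {
    p_sm
  }
  pmin(pmax(p_go, 1e-12), 1 - 1e-12)
}

#' Negative log-likelihood of choice data under a model
#'
#' Composes the model's utilities, belief updating and choice function over
#' all trials of one subject and returns `-sum(log P(chosen action))`.
#' Choice probabilities are clipped at 1e-12 so the result stays finite
#' under extreme parameters. Belief states reset at block boundaries and
#' (except for the between-stimulus variant) with each new stimulus; joint
#' models evaluate both tasks with task-specific temperatures, an action
#' bias in the factory task only, and shared or separate priors.
#'
#' @param data Choice data for one subject (columns `subject`, `task`,
#'   `block`, `trial`, `stimulus`, `offer`, `cost`, `choice`, `outcome`).
#' @param spec Model or model name.
#' @param unconstrained Unconstrained parameter vector.
#' @param smoothing Choice-function smoothing for bias models; `"softplus"`
#'   (default, differentiable) or `"rectifier"` (exact).
#' @return Finite negative log-likelihood.
#' @export
negative_log_likelihood <- function(data, spec, unconstrained,
                                    smoothing = c("softplus", "rectifier")) {
  spec <- as_model_spec(spec)
  smoothing <- match.arg(smoothing)
  if (any(!is.finite(unconstrained))) stop("Non-finite parameters.")
  if (!all(data$choice %in% c(0, 1))) {
    stop("`choice` must be coded 0 (passive) / 1 (active).")
  }
  params <- transform_parameters(spec, unconstrained)
  data <- prepare_choice_data(data)
  p_go <- go_probability(spec, data, params, smoothing)
  -sum(log(ifelse(data$choice == 1, p_go, 1 - p_go)))
}
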