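# Independent oracles and fixtures used across tests. The likelihood oracle
# walks the belief trajectory trial by trial with explicit bookkeeping and
# scalar arithmetic, sharing no code with the package's vectorised path.

softplus_ref <- function(x, a = 100) {
  z <- a * x
  ifelse(z > 30, x + log1p(exp(-z)) / a, log1p(exp(z)) / a)
}

# Brute-force negative log-likelihood: explicit per-trial loop.
# `params` on the constrained scale.
oracle_nll <- function(data, model, params, smoothing = "softplus") {
  data <- data[order(data$subject, data$task, data$block, data$trial), ]
  nll <- 0
  joint <- model %in% c("joint_1prior", "joint_2prior")
  key_prev <- NULL
  alpha <- beta <- list()
  a_all <- b_all <- 0
  prev_succ <- prev_loss <- 0
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    key <- paste(row$subject, row$task, row$block)
    if (!identical(key, key_prev)) {
      alpha <- beta <- list()
      a_all <- b_all <- 0
      prev_succ <- prev_loss <- 0
      key_prev <- key
    }
    robber <- row$task == "robber"
    if (joint) {
      if (model == "joint_1prior") {
        mu <- params$mu0; s2 <- params$sigma0sq
      } else if (robber) {
        mu <- params$mu0_R; s2 <- params$sigma0sq_R
      } else {
        mu <- params$mu0_F; s2 <- params$sigma0sq_F
      }
      a0 <- mu * (1 / s2 - 1); b0 <- (1 - mu) * (1 / s2 - 1)
    } else if (model %in% c("bayes", "bayes_bias", "bayes_between_stim")) {
      a0 <- params$mu0 * (1 / params$sigma0sq - 1)
      b0 <- (1 - params$mu0) * (1 / params$sigma0sq - 1)
    }
    j <- as.character(row$stimulus)
    if (model %in% c("bayes", "bayes_bias") || joint) {
      if (is.null(alpha[[j]])) { alpha[[j]] <- a0; beta[[j]] <- b0 }
      p_hat <- alpha[[j]] / (alpha[[j]] + beta[[j]])
    } else if (model == "bayes_between_stim") {
      p_hat <- (a0 + a_all) / (a0 + b0 + a_all + b_all)
    } else if (model %in% c("static_prob", "static_prob_bias")) {
      p_hat <- params[["p"]]
    } else {
      p_hat <- NULL
    }
    q_ng <- if (robber) 0 else -row$offer
    q_go <- if (model %in% c("softmax_only", "wsls")) {
      base <- if (robber) row$offer - row$cost else -row$cost
      if (model == "wsls") {
        base + prev_succ * params$gamma_pos - prev_loss * params$gamma_neg
      } else {
        base
      }
    } else {
      if (robber) -row$cost + p_hat * row$offer
      else -row$cost - (1 - p_hat) * row$offer
    }
    tau <- if (joint) (if (robber) params$tau_R else params$tau_F) else params$tau
    p_sm <- 1 / (1 + exp(-(q_go - q_ng) / tau))
    phi <- if (joint) (if (robber) NULL else params$phi_F)
           else if (model %in% c("static_prob_bias", "bayes_bias")) params$phi
           else NULL
    p_go <- if (is.null(phi)) {
      p_sm
    } else if (smoothing == "rectifier") {
      max(phi, 0) + (1 - abs(phi)) * p_sm
    } else {
      softplus_ref(phi) +
        (1 - (softplus_ref(phi) + softplus_ref(-phi))) * p_sm
    }
    p_go <- min(max(p_go, 1e-12), 1 - 1e-12)
    nll <- nll - log(if (row$choice == 1) p_go else 1 - p_go)
    # state updates
    if (row$choice == 1) {
      if (row$outcome == 1) {
        prev_succ <- 1; prev_loss <- 0
        if (!is.null(p_hat) && is.null(params[["p"]])) {
          if (model == "bayes_between_stim") a_all <- a_all + 1
          else alpha[[j]] <- alpha[[j]] + 1
        }
      } else {
        prev_succ <- 0; prev_loss <- 1
        if (!is.null(p_hat) && is.null(params[["p"]])) {
          if (model == "bayes_between_stim") b_all <- b_all + 1
          else beta[[j]] <- beta[[j]] + 1
        }
      }
    } else {
      prev_succ <- 0; prev_loss <- 0
    }
  }
  nll
}

# Hand-built 10-trial single-task fixture with a mix of go/ng choices,
# successes and losses, and repeated stimuli.
fixture_trials <- function(task = "robber") {
  tibble::tibble(
    subject = 1L, task = task, block = 1L, trial = 1:10,
    stimulus = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 1L, 2L),
    offer = c(100, 50, 200, 80, 80, 125, 60, 300, 100, 90),
    cost = c(30, 20, 60, 10, 15, 40, 25, 75, 30, 20),
    success_prob = c(rep(0.3, 3), rep(0.7, 2), rep(0.5, 3), 0.3, 0.7),
    choice = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1),
    outcome = c(1, 0, NA, 1, 1, NA, 0, 1, NA, 0)
  )
}

# Two-task 20-trial fixture for joint models.
fixture_joint_trials <- function() {
  r <- fixture_trials("robber")
  f <- fixture_trials("factory")
  f$block <- 2L
  f$choice <- c(0, 1, 1, 1, 0, 1, 0, 1, 1, 0)
  f$outcome <- c(NA, 1, 0, 1, NA, 0, NA, 1, 1, NA)
  rbind(r, f)
}

# A design where the active choice strictly dominates (offer > cost, robber).
fixture_dominant_design <- function(n = 30) {
  tibble::tibble(
    subject = 1L, task = "robber", block = 1L, trial = seq_len(n),
    stimulus = rep(1:3, length.out = n),
    offer = 100, cost = 10, success_prob = 0.5
  )
}

# Exhaustive permutations of 1..n (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}
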