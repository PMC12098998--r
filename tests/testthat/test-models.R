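test_that("parameter transforms map the unconstrained space correctly", {
  p <- transform_parameters("bayes", c(0, 0, 0))
  expect_equal(p$tau, 0.01)          # 0.01 * exp(0)
  expect_equal(p$mu0, 0.5)
  expect_equal(p$sigma0sq, 0.5)
  pb <- transform_parameters("bayes_bias", c(0, 0, 0, 0))
  expect_equal(pb$phi, 0)
  expect_error(transform_parameters("bayes", c(0, 0)), "expects 3")
})

test_that("transforms round-trip to machine precision for every model", {
  for (m in avoid_models()) {
    spec <- model_spec(m)
    theta <- seq(-2, 2, length.out = spec$n_par)
    back <- untransform_parameters(spec, transform_parameters(spec, theta))
    expect_equal(unname(back), theta, tolerance = 1e-12)
  }
})

test_that("softmax choice probability has the right closed form and limits", {
  expect_equal(softmax_p_go(10, 10, 3), 0.5)
  expect_equal(softmax_p_go(5, 0, 5), 1 / (1 + exp(-1)))
  expect_equal(softmax_p_go(5, 0, 5), 0.73106, tolerance = 1e-5)
  expect_equal(softmax_p_go(100, 0, 1e9), 0.5, tolerance = 1e-6)
  expect_true(softmax_p_go(10, 0, 2) > softmax_p_go(5, 0, 2))
  expect_error(softmax_p_go(1, 0, 0), "positive")
})

test_that("trial utilities implement the task-specific value functions", {
  u <- trial_utilities("softmax_only", "robber", offer = 100, cost = 30,
                       params = list(tau = 1))
  expect_equal(c(u$q_go, u$q_ng), c(70, 0))
  u <- trial_utilities("softmax_only", "factory", offer = 100, cost = 30,
                       params = list(tau = 1))
  expect_equal(c(u$q_go, u$q_ng), c(-30, -100))
  u <- trial_utilities("static_prob", "factory", offer = 100, cost = 20,
                       params = list(tau = 1, p = 0.5))
  expect_equal(c(u$q_go, u$q_ng), c(-70, -100))
  u <- trial_utilities("static_prob", "robber", offer = 100, cost = 20,
                       params = list(tau = 1, p = 0.5))
  expect_equal(c(u$q_go, u$q_ng), c(30, 0))
  u <- trial_utilities("wsls", "robber", offer = 100, cost = 30,
                       params = list(tau = 1, gamma_pos = 5, gamma_neg = 2),
                       prev_success = 1, prev_loss = 0)
  expect_equal(c(u$q_go, u$q_ng), c(75, 0))
  u <- trial_utilities("wsls", "robber", offer = 100, cost = 30,
                       params = list(tau = 1, gamma_pos = 5, gamma_neg = 2),
                       prev_success = 0, prev_loss = 1)
  expect_equal(c(u$q_go, u$q_ng), c(68, 0))
})

test_that("beta prior from moments recovers shape parameters and inverts", {
  pr <- beta_prior_from_moments(0.5, 1 / 3)
  expect_equal(pr$alpha0, 1)
  expect_equal(pr$beta0, 1)
  pr <- beta_prior_from_moments(0.8, 0.2)
  expect_equal(pr$alpha0, 3.2)
  expect_equal(pr$beta0, 0.8)
  # round-trip: beta moments give back (mu0, relative variance)
  for (mu in c(0.2, 0.5, 0.9)) {
    for (s2 in c(0.1, 0.4, 0.8)) {
      pr <- beta_prior_from_moments(mu, s2)
      mean_b <- pr$alpha0 / (pr$alpha0 + pr$beta0)
      var_b <- pr$alpha0 * pr$beta0 /
        ((pr$alpha0 + pr$beta0)^2 * (pr$alpha0 + pr$beta0 + 1))
      expect_equal(mean_b, mu, tolerance = 1e-12)
      expect_equal(var_b / (mu * (1 - mu)), s2, tolerance = 1e-12)
    }
  }
  expect_error(beta_prior_from_moments(0, 0.5), "strictly")
  expect_error(beta_prior_from_moments(0.5, 1), "strictly")
})

test_that("belief updates are conjugate and passive choices leave no trace", {
  st <- belief_state(1:3, alpha0 = 1, beta0 = 1)
  st2 <- update_belief(st, 1, "go", "success")
  expect_equal(unname(st2$alpha["1"]), 2)
  expect_equal(unname(st2$beta["1"]), 1)
  expect_equal(posterior_mean(st2, 1), 2 / 3)
  expect_equal(st2$alpha["2"], st$alpha["2"])
  st3 <- update_belief(st2, 1, "go", "loss")
  expect_equal(unname(st3$beta["1"]), 2)
  st4 <- belief_state(1, alpha0 = 3, beta0 = 1)
  expect_equal(posterior_mean(st4, 1), 0.75)
  expect_identical(update_belief(st, 2, "ng", "none"), st)
  expect_error(update_belief(st, 1, "ng", "success"), "passive")
  expect_error(update_belief(st, 1, "go", "none"), "active")
})

test_that("action bias mixes a lapse into the choice probability", {
  expect_equal(biased_choice_prob(0, 0.6, "rectifier"), 0.6)
  expect_equal(biased_choice_prob(-0.5, 0.6, "rectifier"), 0.3)
  expect_equal(biased_choice_prob(0.5, 0.6, "rectifier"), 0.8)
  expect_error(biased_choice_prob(1.5, 0.5), "\\[-1, 1\\]")
})

test_that("softplus smoothing tracks the rectifier within 0.007 and converges", {
  phis <- seq(-0.99, 0.99, by = 0.01)
  ps <- seq(0.05, 0.95, by = 0.1)
  grid <- expand.grid(phi = phis, p = ps)
  gap <- abs(biased_choice_prob(grid$phi, grid$p, "softplus") -
               biased_choice_prob(grid$phi, grid$p, "rectifier"))
  expect_lt(max(gap), 0.007)
  # gap shrinks monotonically as the sharpness alpha grows
  gaps <- sapply(c(100, 300, 1000, 3000), function(a) {
    max(abs(biased_choice_prob(grid$phi, grid$p, "softplus", alpha = a) -
              biased_choice_prob(grid$phi, grid$p, "rectifier")))
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("likelihood equals chance when the options are indistinguishable", {
  d <- tibble::tibble(subject = 1L, task = "robber", block = 1L,
                      trial = 1:60, stimulus = rep(1:12, each = 5),
                      offer = 50, cost = 50, success_prob = 0.5,
                      choice = rep(c(0, 1), 30),
                      outcome = ifelse(rep(c(0, 1), 30) == 1, 1, NA))
  # softmax-only utilities are offer - cost = 0 on every trial
  expect_equal(negative_log_likelihood(d, "softmax_only", 0.7), 60 * log(2))
})

test_that("vectorised likelihood matches the trial-by-trial oracle", {
  data <- fixture_trials("robber")
  data_f <- fixture_trials("factory")
  cases <- list(
    list(model = "softmax_only", theta = c(1.2)),
    list(model = "wsls", theta = c(1.0, 2.5, 2.0)),
    list(model = "static_prob", theta = c(1.5, -0.4)),
    list(model = "bayes", theta = c(1.1, 0.3, -0.5)),
    list(model = "bayes_between_stim", theta = c(1.1, 0.3, -0.5)),
    list(model = "static_prob_bias", theta = c(1.5, -0.4, 0.6)),
    list(model = "bayes_bias", theta = c(1.1, 0.3, -0.5, -0.7))
  )
  for (cs in cases) {
    params <- transform_parameters(cs$model, cs$theta)
    for (dat in list(data, data_f)) {
      for (sm in c("softplus", "rectifier")) {
        expect_equal(
          negative_log_likelihood(dat, cs$model, cs$theta, smoothing = sm),
          oracle_nll(dat, cs$model, params, smoothing = sm),
          tolerance = 1e-10)
      }
    }
  }
  # joint models on the two-task fixture
  for (m in c("joint_1prior", "joint_2prior")) {
    spec <- model_spec(m)
    theta <- seq(0.8, -0.8, length.out = spec$n_par)
    params <- transform_parameters(spec, theta)
    dj <- fixture_joint_trials()
    for (sm in c("softplus", "rectifier")) {
      expect_equal(negative_log_likelihood(dj, m, theta, smoothing = sm),
                   oracle_nll(dj, m, params, smoothing = sm),
                   tolerance = 1e-10)
    }
  }
})

test_that("static probability is the no-learning limit of the Bayesian model", {
  data <- fixture_trials("robber")
  for (p in c(0.3, 0.5, 0.8)) {
    th_static <- untransform_parameters("static_prob", list(tau = 0.5, p = p))
    th_bayes <- c(th_static[1], stats::qlogis(p), stats::qlogis(1e-9))
    expect_equal(negative_log_likelihood(data, "static_prob", th_static),
                 negative_log_likelihood(data, "bayes", th_bayes),
                 tolerance = 1e-6)
  }
})

test_that("prior variance limits bracket the learning regimes", {
  # sigma0sq -> 1: the first observed outcome dominates the posterior mean
  pr <- beta_prior_from_moments(0.5, 1 - 1e-10)
  expect_equal((pr$alpha0 + 1) / (pr$alpha0 + pr$beta0 + 1), 1,
               tolerance = 1e-9)
  expect_equal(pr$alpha0 / (pr$alpha0 + pr$beta0 + 1), 0, tolerance = 1e-9)
  # sigma0sq -> 0: the posterior mean never moves off mu0
  pr0 <- beta_prior_from_moments(0.37, 1e-12)
  expect_equal((pr0$alpha0 + 10) / (pr0$alpha0 + pr0$beta0 + 20), 0.37,
               tolerance = 1e-9)
})

test_that("choice probabilities stay inside (0, 1) across random parameters", {
  data <- fixture_joint_trials()
  set.seed(42)
  for (m in avoid_models()) {
    spec <- model_spec(m)
    dat <- if (spec$joint) data else fixture_trials("robber")
    for (r in 1:5) {
      theta <- rnorm(spec$n_par, sd = 2.5)
      params <- transform_parameters(spec, theta)
      p <- avoidprior:::go_probability(spec, dat, params)
      expect_true(all(p > 0 & p < 1))
      nll <- negative_log_likelihood(dat, m, theta)
      expect_true(is.finite(nll))
    }
  }
})
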