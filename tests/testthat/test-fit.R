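test_that("pseudo-r-squared anchors at chance, perfection and double chance", {
  expect_equal(pseudo_r2(60 * log(0.5), 60), 0)
  expect_equal(pseudo_r2(0, 60), 1)
  expect_equal(pseudo_r2(2 * 60 * log(0.5), 60), -1)
  expect_error(pseudo_r2(-10, 0), "positive")
})

# Data on which softmax-only has a constant likelihood (offer == cost, so
# delta-Q = 0 and P(go) = 0.5 whatever tau): the posterior equals the prior.
flat_likelihood_data <- function(n = 40) {
  tibble::tibble(subject = 1L, task = "robber", block = 1L, trial = seq_len(n),
                 stimulus = rep(1:4, length.out = n), offer = 80, cost = 80,
                 success_prob = 0.5, choice = rep(c(0, 1), n / 2),
                 outcome = ifelse(rep(c(0, 1), n / 2) == 1, 1, NA))
}

test_that("with a flat likelihood the MAP sits at the prior mean and the
          Laplace evidence is exact", {
  d <- flat_likelihood_data(40)
  f <- fit_subject_map(d, "softmax_only", n_restarts = 4, seed = 1)
  expect_equal(unname(f$theta), 0, tolerance = 1e-3)
  # the posterior is exactly Gaussian here, so Laplace is exact:
  # evidence = P(data) = 0.5^n
  expect_equal(f$log_evidence, 40 * log(0.5), tolerance = 1e-4)
  expect_equal(f$pseudo_r2, 0, tolerance = 1e-10)
  expect_error(fit_subject_map(d[0, ], "softmax_only"), "zero trials")
})

test_that("the MAP estimate shrinks toward the prior mean as the prior
          tightens", {
  d <- build_block_design("robber", seed = 4)
  s <- simulate_subject("static_prob", list(tau = 30, p = 0.7), d, seed = 2)
  norms <- vapply(c(25, 6.25, 1, 0.1, 0.01), function(v) {
    f <- fit_subject_map(s, "static_prob", prior_var = v, n_restarts = 4,
                         seed = 1)
    sqrt(sum(f$theta^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-6))
})

test_that("unconstrained optimisation agrees with constrained grid search", {
  d <- build_block_design("robber", seed = 8)
  s <- simulate_subject("static_prob", list(tau = 40, p = 0.6), d, seed = 3)
  f <- fit_subject_map(s, "static_prob", n_restarts = 6, seed = 1)
  obj <- function(th) {
    negative_log_likelihood(s, "static_prob", th) + 0.5 * sum(th^2) / 6.25
  }
  # grid over the constrained space mapped back to unconstrained coordinates
  taus <- exp(seq(log(1), log(200), length.out = 80))
  ps <- seq(0.02, 0.98, length.out = 80)
  grid_vals <- outer(taus, ps, Vectorize(function(tau, p) {
    obj(c(log(tau / 0.01), stats::qlogis(p)))
  }))
  best <- arrayInd(which.min(grid_vals), dim(grid_vals))
  expect_lte(obj(f$theta), min(grid_vals) + 1e-6)
  cons <- f$constrained
  expect_equal(cons$tau, taus[best[1]], tolerance = 0.05)
  expect_equal(cons$p, ps[best[2]], tolerance = 0.05)
})

test_that("the generating model's evidence beats the softmax baseline on
          Bayesian agents", {
  wins <- 0L
  n_rep <- 50
  seeds <- avoidprior:::spawn_seeds(101, 3 * n_rep)
  for (r in seq_len(n_rep)) {
    design <- dplyr::bind_rows(purrr::map(1:4, function(b) {
      build_block_design("robber", seed = seeds[3 * r - 2] + b, block = b)
    }))
    theta <- avoidprior:::with_local_seed(seeds[3 * r - 1], rnorm(3))
    s <- simulate_subject("bayes", transform_parameters("bayes", theta),
                          design, seed = seeds[3 * r])
    fb <- fit_subject_map(s, "bayes", n_restarts = 5, seed = r)
    fs <- fit_subject_map(s, "softmax_only", n_restarts = 5, seed = r)
    if (fb$log_evidence > fs$log_evidence) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("fit_cohort returns a tidy fit table and an evidence matrix", {
  cfg <- cohort_config(3, c(bayes = 1))
  cohort <- simulate_cohort(cfg, seed = 31, n_blocks = 1)
  fits <- fit_cohort(cohort$data, c("bayes", "softmax_only"),
                     n_restarts = 3, seed = 1)
  expect_equal(nrow(fits), 6)
  expect_s3_class(fits$fit[[1]], "subject_fit")
  lev <- log_evidence_matrix(fits)
  expect_equal(dim(lev), c(3, 2))
  expect_equal(colnames(lev), c("bayes", "softmax_only"))
  td <- tidy(fits$fit[[1]])
  expect_equal(td$parameter, c("tau", "mu0", "sigma0sq"))
  gl <- glance(fits$fit[[1]])
  expect_equal(gl$n_trials, 60)
})

test_that("duplicated candidate models split responsibilities evenly", {
  cfg <- cohort_config(3, c(static_prob = 1))
  cohort <- simulate_cohort(cfg, seed = 41, n_blocks = 1)
  fits <- fit_cohort(cohort$data, c("static_prob", "static_prob"),
                     n_restarts = 3, seed = 1)
  hf <- hierarchical_refit(cohort$data, c("static_prob", "static_prob"),
                           fits = fits, max_iter = 1)
  expect_equal(hf$responsibilities$resp, rep(0.5, 6), tolerance = 1e-6)
})

test_that("the group refinement concentrates responsibility on the true
          model in a mixed cohort", {
  cfg <- cohort_config(
    20, c(bayes = 0.5, static_prob = 0.5),
    group_sds = list(bayes = 1, static_prob = 1))
  cohort <- simulate_cohort(cfg, seed = 77, n_blocks = 2)
  hf <- hierarchical_refit(cohort$data, c("bayes", "static_prob"),
                           max_iter = 2, n_restarts = 4, seed = 1)
  resp <- dplyr::inner_join(
    hf$responsibilities,
    dplyr::distinct(cohort$truth[, c("subject", "model")]),
    by = "subject")
  # keep only each subject's responsibility for its generating model
  own <- resp[resp$model.x == resp$model.y, ]
  expect_gte(mean(own$resp > 0.5), 0.7)
  # group means exist for both models and every parameter
  expect_equal(nrow(hf$group), 3 + 2)
  # cohort mixture evidence is stable across iterations: the Laplace
  # approximation on plateaued likelihoods keeps the trace only
  # approximately monotone, so bound the average per-subject drift
  if (length(hf$total_evidence) > 1) {
    expect_true(all(diff(hf$total_evidence) > -0.5 * 20))
  }
})
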