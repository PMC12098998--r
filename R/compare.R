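#' Random-effects Bayesian model selection
#'
#' Treats the model identity of each subject as a random effect with
#' population frequencies `r ~ Dirichlet(alpha)`. A variational update
#' (uniform Dirichlet(1) start) yields the posterior over frequencies and
#' per-subject model assignments; exceedance probabilities (XP, the
#' probability that a model's frequency is the largest) are computed by
#' seeded Monte-Carlo sampling of the Dirichlet posterior. The Bayes
#' omnibus risk (BOR) is the posterior probability of the null hypothesis
#' that all models are equally frequent, and the protected exceedance
#' probability is `PXP = (1 - BOR) * XP + BOR / K`, which shrinks XP toward
#' chance when the model frequencies are indistinguishable.
#'
#' @param log_evidence Subjects x models matrix of log model evidences
#'   (column names label the models).
#' @param seed Seed for the Monte-Carlo exceedance draws.
#' @param n_samples Dirichlet draws for XP (default 1e5).
#' @return Object of class `bms_result` with `model_frequency`, `xp`,
#'   `pxp`, `bor`, Dirichlet `alpha`, and per-subject `responsibilities`.
#' @export
#' @examples
#' lev <- cbind(a = c(0, 0, 0), b = c(-3, -2, -4))
#' rfx_bms(lev, seed = 1)
rfx_bms <- function(log_evidence, seed = 1, n_samples = 1e5) {
  log_evidence <- as.matrix(log_evidence)
  if (ncol(log_evidence) < 2) stop("At least two models are required.")
  if (any(!is.finite(log_evidence))) stop("Log evidences must be finite.")
  k <- ncol(log_evidence)
  n <- nrow(log_evidence)
  models <- colnames(log_evidence) %||% paste0("model", seq_len(k))
  colnames(log_evidence) <- models

  alpha0 <- rep(1, k)
  alpha <- alpha0
  g <- matrix(1 / k, n, k)
  for (iter in 1:500) {
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    u <- sweep(log_evidence, 2, elog_r, "+")
    g <- exp(u - apply(u, 1, logsumexp))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  m_freq <- alpha / sum(alpha)

  xp <- with_local_seed(seed, {
    draws <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha,
                                                             each = n_samples)),
                    nrow = n_samples)
    winners <- max.col(draws, ties.method = "random")
    tabulate(winners, nbins = k) / n_samples
  })

  # Free energy of the RFX model vs the equal-frequency null.
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
    sum((alpha - alpha0) * elog_r)
  ent_z <- -sum(g[g > 0] * log(g[g > 0]))
  f1 <- sum(g * log_evidence) + sum(sweep(g, 2, elog_r, "*")) +
    ent_z - kl_dir
  f0 <- sum(apply(log_evidence, 1, logsumexp) - log(k))
  bor <- 1 / (1 + exp(f1 - f0))

  pxp <- (1 - bor) * xp + bor / k

  structure(list(
    models = models,
    alpha = stats::setNames(alpha, models),
    model_frequency = stats::setNames(m_freq, models),
    xp = stats::setNames(xp, models),
    pxp = stats::setNames(pxp, models),
    bor = bor,
    responsibilities = g,
    n_subjects = n,
    n_samples = n_samples,
    seed = seed
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", x$n_subjects, "subjects,", length(x$models),
      "models; BOR =", format(x$bor, digits = 3), "\n")
  print(tibble::tibble(model = x$models,
                       m_freq = unname(x$model_frequency),
                       xp = unname(x$xp),
                       pxp = unname(x$pxp)))
  invisible(x)
}
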