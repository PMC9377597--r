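# Random-effects model comparison and model-validation diagnostics.
#
# Model frequencies in the population are given a Dirichlet prior and
# inferred by the standard variational scheme: responsibilities
# u_nk propto exp(log_evidence_nk + digamma(alpha_k) - digamma(sum alpha)),
# pseudo-counts alpha_k = alpha0 + sum_n u_nk, iterated to convergence.
# The exceedance probability of model k is the posterior probability that
# its population frequency is the largest, estimated by Monte-Carlo argmax
# frequency over Dirichlet draws.

#' Build a log-evidence matrix from per-run BICs
#'
#' Uses `-BIC/2` as the log model evidence surrogate.
#'
#' @param fits Data frame as produced by [fit_cohort()] (needs
#'   `participant_id`, `model_id`, `bic`).
#' @param referent Optional filter if the data frame holds both referents.
#' @return Matrix participants x models of log evidences, with dimnames.
#' @export
evidence_matrix <- function(fits, referent = NULL) {
  if (!is.null(referent)) fits <- fits[fits$referent == referent, ]
  .check(nrow(fits) > 0, "no rows after filtering")
  tab <- stats::xtabs(bic ~ participant_id + model_id, data = fits)
  m <- -as.matrix(tab) / 2
  .check(all(is.finite(m)), "non-finite log evidence (missing participant x model fits?)")
  m
}

#' Random-effects model comparison by exceedance probabilities
#'
#' @param log_evidence Participants x models matrix of log model evidences
#'   (e.g. from [evidence_matrix()]).
#' @param alpha0 Dirichlet prior pseudo-count per model.
#' @param tol Convergence tolerance on the pseudo-counts.
#' @param max_iter Iteration cap for the variational loop.
#' @param n_mc Monte-Carlo sample size for the exceedance estimate.
#' @param seed Optional seed for the Monte-Carlo stage.
#' @return A `comparison_result` list: `dirichlet_alpha`, `expected_freq`
#'   (`alpha / sum(alpha)`), `exceedance_prob`, `n_mc_samples`, `seed`,
#'   `n_iter`.
#' @export
exceedance_probabilities <- function(log_evidence, alpha0 = 1, tol = 1e-6,
                                     max_iter = 10000L, n_mc = 1e5, seed = NULL) {
  .check(is.matrix(log_evidence) && all(is.finite(log_evidence)),
         "log_evidence must be a finite numeric matrix")
  n <- nrow(log_evidence); k <- ncol(log_evidence)
  .check(n >= 1 && k >= 1, "need at least one participant and one model")
  model_ids <- colnames(log_evidence)
  if (is.null(model_ids)) model_ids <- as.character(seq_len(k))

  alpha <- rep(alpha0, k)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol || iter >= max_iter) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  if (k == 1L) {
    xp <- 1
  } else {
    xp <- with_seed(seed, {
      g <- matrix(stats::rgamma(n_mc * k, shape = rep(alpha, each = n_mc)), ncol = k)
      tabulate(max.col(g, ties.method = "first"), nbins = k) / n_mc
    })
  }
  structure(list(
    dirichlet_alpha = stats::setNames(alpha, model_ids),
    expected_freq = stats::setNames(alpha / sum(alpha), model_ids),
    exceedance_prob = stats::setNames(xp, model_ids),
    n_mc_samples = as.integer(n_mc),
    seed = seed,
    n_iter = iter
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  print(round(rbind(expected_freq = x$expected_freq,
                    exceedance_prob = x$exceedance_prob), 4))
  invisible(x)
}

#' Write a comparison result to JSON
#'
#' @param x A `comparison_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  jsonlite::write_json(list(
    dirichlet_alpha = as.list(x$dirichlet_alpha),
    expected_freq = as.list(x$expected_freq),
    exceedance_prob = as.list(x$exceedance_prob),
    settings = list(n_mc_samples = x$n_mc_samples, seed = x$seed, n_iter = x$n_iter)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Default parameter sampler for recovery studies: draws from the MAP priors
# truncated to each model's bounds.
.prior_param_sampler <- function(model_id) {
  tab <- get_model(model_id)$params
  stats::setNames(as.list(.sample_start(tab)), tab$name)
}

#' Model-recovery confusion matrix
#'
#' For each generating model: simulate `n_sim` runs with parameters from
#' `param_sampler`, fit every candidate model, and tally which model wins
#' on BIC. Rows are generating models, columns recovering models, entries
#' percentages summing to 100 per row.
#'
#' @param model_ids Candidate (and generating) model ids.
#' @param param_sampler Function `(model_id) -> named parameter list` within
#'   that model's bounds; defaults to sampling from the MAP priors truncated
#'   to the bounds.
#' @param n_sim Simulated runs per generating model.
#' @param feedback_seq Feedback sequence used for every simulated run
#'   (default: the canonical positive-first sequence).
#' @param seed Optional seed.
#' @param n_restarts Restarts per fit (recovery studies trade a little
#'   optimiser robustness for speed).
#' @return A `confusion_matrix`: percentage matrix with attribute `n_sim`.
#' @export
model_recovery <- function(model_ids = registered_models(),
                           param_sampler = .prior_param_sampler,
                           n_sim = 100L,
                           feedback_seq = canonical_feedback_sequences()$positive_first,
                           seed = NULL, n_restarts = 3L) {
  .check(n_sim >= 1, "n_sim must be >= 1")
  k <- length(model_ids)
  counts <- matrix(0L, k, k, dimnames = list(
    generating = as.character(model_ids), recovering = as.character(model_ids)))
  with_seed(seed, {
    for (gi in seq_len(k)) {
      g <- model_ids[gi]
      for (s in seq_len(n_sim)) {
        pars <- param_sampler(g)
        .check_params(g, pars)  # sampler must respect bounds
        tr <- simulate_trajectory(g, pars, feedback_seq)
        bics <- vapply(model_ids, function(m) fit_map(m, tr, n_restarts = n_restarts)$bic,
                       numeric(1))
        counts[gi, which.min(bics)] <- counts[gi, which.min(bics)] + 1L
      }
    }
  })
  structure(100 * counts / n_sim, n_sim = n_sim, class = c("confusion_matrix", "matrix"))
}

#' Posterior-predictive check of belief updates
#'
#' Simulates `n_rep` trajectories at a run's MAP parameters, computes the
#' mean signed report change following positive and following negative
#' feedback in each replicate, and compares the pooled simulated update
#' distribution with the observed one by a two-sample Kolmogorov-Smirnov
#' test.
#'
#' @param fit A `fit_result` from [fit_map()].
#' @param trajectory The observed [belief_trajectory()] the fit refers to.
#' @param n_rep Number of simulated replicates.
#' @param seed Optional seed.
#' @return List with `mean_update_pos`, `mean_update_neg` (length `n_rep`),
#'   `observed_update_pos`, `observed_update_neg`, `ks_stat`, `ks_p`.
#' @export
posterior_predictive_updates <- function(fit, trajectory, n_rep = 20L, seed = NULL) {
  .check(isTRUE(fit$converged), "fit must have converged")
  .check(n_rep >= 1, "n_rep must be >= 1")
  fb <- trajectory$feedback
  upd <- function(reports) diff(reports)
  obs <- upd(trajectory$reports)
  sims <- with_seed(seed, {
    replicate(n_rep,
      upd(simulate_trajectory(fit$model_id, fit$map_params, fb)$reports),
      simplify = FALSE)
  })
  ks <- suppressWarnings(stats::ks.test(unlist(sims), obs))
  list(
    mean_update_pos = vapply(sims, function(u) mean(u[fb == 1]), numeric(1)),
    mean_update_neg = vapply(sims, function(u) mean(u[fb == 0]), numeric(1)),
    observed_update_pos = mean(obs[fb == 1]),
    observed_update_neg = mean(obs[fb == 0]),
    ks_stat = unname(ks$statistic),
    ks_p = ks$p.value
  )
}
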