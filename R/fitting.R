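# MAP estimation of belief-model parameters, one participant x referent run
# at a time, and the BIC used as the log-model-evidence surrogate.
#
# Priors are the stated untruncated Normal / half-normal densities; the
# parameter ranges are enforced as hard box constraints in the optimiser
# (truncation renormalisation would only add a constant inside the box and
# cannot move the mode).

#' Log prior density of a parameter vector
#'
#' Sum of the per-parameter log prior densities from the model's parameter
#' table. Half-normal priors with scale s have density
#' `2 / (s * sqrt(2*pi)) * exp(-x^2 / (2 s^2))` on `x >= 0`.
#'
#' @param model_id Registered model id.
#' @param params Named parameter vector within bounds.
#' @return Scalar log prior density.
#' @keywords internal
log_prior <- function(model_id, params) {
  tab <- get_model(model_id)$params
  params <- .check_params(model_id, params)
  lp <- 0
  for (i in seq_len(nrow(tab))) {
    x <- params[[tab$name[i]]]
    lp <- lp + switch(tab$prior_family[i],
      normal = stats::dnorm(x, tab$prior_location[i], tab$prior_scale[i], log = TRUE),
      half_normal = log(2) + stats::dnorm(x, tab$prior_location[i],
                                          tab$prior_scale[i], log = TRUE),
      stop("unknown prior family: ", tab$prior_family[i])
    )
  }
  lp
}

#' Log-likelihood of a run under a model
#'
#' Sum over all 21 reports (the pre-feedback report included) of the Beta
#' log-density of the report under the belief state current at that time.
#'
#' @inheritParams log_prior
#' @param trajectory A [belief_trajectory()].
#' @param clip_eps Report clipping threshold, see [report_logdensity()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model_id, params, trajectory,
                           clip_eps = DEFAULT_CLIP_EPS) {
  shp <- trajectory_shapes(model_id, params, trajectory$feedback)
  sum(report_logdensity(shp[, "alpha"], shp[, "beta"], trajectory$reports, clip_eps))
}

#' Log posterior density (likelihood plus priors) of a run under a model
#'
#' @inheritParams log_likelihood
#' @return Scalar log posterior density (up to the normalising constant).
#' @export
log_posterior <- function(model_id, params, trajectory,
                          clip_eps = DEFAULT_CLIP_EPS) {
  log_likelihood(model_id, params, trajectory, clip_eps) + log_prior(model_id, params)
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 * log_likelihood + k * log(n)`. Following the reporting
#' convention for this task, `n` defaults to the 20 post-feedback reports
#' even though all 21 reports enter the likelihood; pass `n = 21` to count
#' the pre-feedback report as well.
#'
#' @param log_likelihood Maximised (or MAP) log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations entering the penalty.
#' @return Scalar BIC.
#' @export
bic <- function(log_likelihood, k, n = 20L) {
  .check(is.numeric(k) && all(k >= 0), "k must be >= 0")
  .check(is.numeric(n) && all(n >= 1), "n must be >= 1")
  -2 * log_likelihood + k * log(n)
}

# Draw one start point from the (bound-truncated) priors, by inverse-CDF
# sampling of the underlying normal restricted to [lower, upper].
.sample_start <- function(tab) {
  x <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lo <- tab$lower[i]; hi <- tab$upper[i]
    m <- tab$prior_location[i]; s <- tab$prior_scale[i]
    if (tab$prior_family[i] == "half_normal") lo <- max(lo, 0)
    plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
    x[i] <- stats::qnorm(stats::runif(1, plo, phi), m, s)
    x[i] <- min(max(x[i], tab$lower[i]), tab$upper[i])
  }
  stats::setNames(x, tab$name)
}

#' Fit a model to one run by MAP estimation
#'
#' Bounded local optimisation (L-BFGS-B) of the log posterior from
#' `n_restarts` start points drawn from the priors plus one fixed
#' bounds-midpoint start. The best mode found is returned; restarts whose
#' objective lies within `tol` of the best are counted as agreeing.
#'
#' @param model_id Registered model id.
#' @param trajectory A [belief_trajectory()].
#' @param n_restarts Number of random restarts (>= 1).
#' @param tol Objective tolerance for convergence/agreement.
#' @param seed Optional integer seed making the restarts reproducible.
#' @param bic_n Observation count used in the BIC penalty (default 20).
#' @param clip_eps Report clipping threshold.
#' @return A `fit_result` list: `model_id`, `map_params`, `log_likelihood`,
#'   `log_posterior`, `bic`, `n_obs`, `converged`, `n_restarts_agreeing`,
#'   `at_bound` (logical per parameter).
#' @export
fit_map <- function(model_id, trajectory, n_restarts = 10L, tol = 1e-6,
                    seed = NULL, bic_n = 20L, clip_eps = DEFAULT_CLIP_EPS) {
  .check(n_restarts >= 1, "n_restarts must be >= 1")
  def <- get_model(model_id)
  tab <- def$params
  negobj <- function(x) {
    -log_posterior(model_id, stats::setNames(x, tab$name), trajectory, clip_eps)
  }
  midpoint <- (tab$lower + tab$upper) / 2
  starts <- with_seed(seed, {
    c(list(stats::setNames(midpoint, tab$name)),
      replicate(n_restarts, .sample_start(tab), simplify = FALSE))
  })
  runs <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, negobj, method = "L-BFGS-B",
                   lower = tab$lower, upper = tab$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) {
    return(structure(list(
      model_id = def$id, map_params = stats::setNames(rep(NA_real_, nrow(tab)), tab$name),
      log_likelihood = NA_real_, log_posterior = NA_real_, bic = NA_real_,
      n_obs = length(trajectory$reports), converged = FALSE,
      n_restarts_agreeing = 0L, at_bound = stats::setNames(rep(NA, nrow(tab)), tab$name)
    ), class = "fit_result"))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  # best objective; ties broken by lexicographically smallest parameter vector
  best_val <- min(vals)
  cand <- runs[vals <= best_val + tol]
  ord <- order(vapply(cand, function(r) paste(sprintf("%.12e", r$par), collapse = ","),
                      character(1)))
  best <- cand[[ord[1]]]
  map <- stats::setNames(pmin(pmax(best$par, tab$lower), tab$upper), tab$name)
  ll <- log_likelihood(model_id, map, trajectory, clip_eps)
  structure(list(
    model_id = def$id,
    map_params = map,
    log_likelihood = ll,
    log_posterior = -best$value,
    bic = bic(ll, nrow(tab), bic_n),
    n_obs = length(trajectory$reports),
    converged = best$convergence == 0,
    n_restarts_agreeing = sum(vals <= best_val + max(tol, 1e-4)),
    at_bound = stats::setNames(map <= tab$lower + 1e-8 | map >= tab$upper - 1e-8,
                               tab$name)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %d (%s)\n", x$model_id, get_model(x$model_id)$name))
  cat("  MAP:", paste(sprintf("%s = %.4g", names(x$map_params), x$map_params),
                      collapse = ", "), "\n")
  cat(sprintf("  logLik = %.3f, logPost = %.3f, BIC = %.3f, converged = %s\n",
              x$log_likelihood, x$log_posterior, x$bic, x$converged))
  invisible(x)
}

#' Fit several models to several runs
#'
#' Convenience wrapper producing one row per run x model, in the layout of
#' the `fits.csv` interchange format.
#'
#' @param trajectories List of [belief_trajectory()] objects.
#' @param model_ids Models to fit (default: all registered).
#' @param ... Passed to [fit_map()] (`n_restarts`, `tol`, `bic_n`, ...).
#' @param seed Optional seed; each run x model gets a distinct derived seed.
#' @return Data frame with participant_id, referent, model_id, one column
#'   per parameter (NA where a model lacks it), log_likelihood,
#'   log_posterior, bic, converged.
#' @export
fit_cohort <- function(trajectories, model_ids = registered_models(),
                       seed = NULL, ...) {
  all_par <- unique(unlist(lapply(model_ids, function(m) get_model(m)$params$name)))
  rows <- list()
  idx <- 0L
  for (tr in trajectories) {
    for (m in model_ids) {
      idx <- idx + 1L
      sub_seed <- if (is.null(seed)) NULL else (seed + idx) %% .Machine$integer.max
      f <- fit_map(m, tr, seed = sub_seed, ...)
      par_cols <- stats::setNames(as.list(rep(NA_real_, length(all_par))), all_par)
      par_cols[names(f$map_params)] <- as.list(unname(f$map_params))
      rows[[idx]] <- data.frame(
        participant_id = tr$participant_id, referent = tr$referent,
        model_id = f$model_id, as.data.frame(par_cols),
        log_likelihood = f$log_likelihood, log_posterior = f$log_posterior,
        bic = f$bic, converged = f$converged, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
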