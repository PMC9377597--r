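# Downstream individual-differences statistics: data-quality filters,
# model-agnostic belief indices, permutation correlation tests with FDR
# control, joint regressions with coefficient-difference permutation tests,
# and bootstrap linear mediation.

#' Directional-error exclusion filter
#'
#' Counts trials on which the report moved strictly opposite to the
#' feedback just received (a decrease after positive feedback or an
#' increase after negative feedback). Leaving the report unchanged is not
#' an error. Participants with `threshold` or more errors are flagged for
#' exclusion.
#'
#' @param trajectory A [belief_trajectory()].
#' @param threshold Exclusion threshold on the error count.
#' @return List with `error_count` and `excluded`.
#' @export
directional_error_filter <- function(trajectory, threshold = 9L) {
  ch <- diff(trajectory$reports)
  fb <- trajectory$feedback
  errors <- sum((fb == 1 & ch < 0) | (fb == 0 & ch > 0))
  list(error_count = errors, excluded = errors >= threshold)
}

#' Model-agnostic belief indices for one run
#'
#' @param trajectory A [belief_trajectory()].
#' @return List with `starting_belief` (pre-feedback report),
#'   `ending_belief` (final report) and `belief_change` (their difference).
#' @export
model_agnostic_indices <- function(trajectory) {
  q <- trajectory$reports
  list(starting_belief = q[1],
       ending_belief = q[length(q)],
       belief_change = q[length(q)] - q[1])
}

#' Permutation test for a Pearson correlation
#'
#' Two-tailed: one variable is randomly permuted, the correlation
#' recomputed, and the p-value is the add-one-corrected share of permuted
#' `|r|` values at least as large as the observed one,
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)`. For `n <= 7` with
#' `enumerate_small = TRUE` all `n!` permutations are enumerated and the
#' p-value is the exact proportion.
#'
#' @param x,y Numeric vectors of equal length >= 3; `y` must not be
#'   constant.
#' @param n_perm Number of random permutations.
#' @param seed Optional seed.
#' @param enumerate_small Enumerate all permutations when `n <= 7`?
#' @return A `correlation_result` list: `r`, `p_uncorrected`, `n_perm`,
#'   `seed`, `method`.
#' @export
permutation_corr <- function(x, y, n_perm = 10000L, seed = NULL,
                             enumerate_small = FALSE) {
  .check(length(x) == length(y) && length(x) >= 3,
         "x and y must have equal length >= 3")
  .check(stats::sd(x) > 0 && stats::sd(y) > 0,
         "correlation undefined for constant input")
  r_obs <- stats::cor(x, y)
  n <- length(x)
  # centred/scaled once: r under a permutation is a plain cross-product
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  perm_r <- function(idx) sum(xs * ys[idx]) / (n - 1)
  if (enumerate_small && n <= 7) {
    perms <- .all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- mean(abs(rs) >= abs(r_obs) - 1e-12)
    method <- "exact_enumeration"
    n_perm <- length(perms)
  } else {
    rs <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) perm_r(sample.int(n)), numeric(1)))
    p <- (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
    method <- "monte_carlo"
  }
  structure(list(r = r_obs, p_uncorrected = p, n_perm = as.integer(n_perm),
                 seed = seed, method = method),
            class = "correlation_result")
}

.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR-adjusted p-values (`adj_i = min_{j >= rank(i)} m * p_(j) / j`,
#' capped at 1), delegating to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  .check(.is_prob(p_values), "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Joint regressions of factor scores on prior mean and bias, with
#' coefficient-difference permutation tests
#'
#' For each latent factor an OLS regression `factor ~ mu0 + b` is fitted.
#' Differences of a predictor's coefficient between two factors' models
#' (e.g. the prior-mean coefficient in the depression model minus in the
#' anxiety model) are referred to a permutation null built by jointly
#' shuffling participants' factor-score rows against their parameter rows,
#' which preserves the mu0-b dependence. Optionally the `mu0 x b`
#' interaction is assessed per factor by a likelihood-ratio test of nested
#' linear models.
#'
#' @param factor_scores Participants x factors matrix (colnames = factor
#'   labels).
#' @param mu0,b Aligned numeric vectors of parameter estimates.
#' @param n_perm Number of permutations for the difference tests.
#' @param seed Optional seed.
#' @param contrasts List of character pairs `c(factor_a, factor_b)`; the
#'   difference statistics are `coef(factor_a) - coef(factor_b)` for each
#'   predictor. Default: depression vs anxiety models if those labels are
#'   present, else the first two factors.
#' @param interaction Also fit `factor ~ mu0 * b` and report the LRT
#'   p-value for the interaction?
#' @return List with `regressions` (per factor: coefficients, and LRT
#'   p-value if requested) and `coef_diff` (per contrast x predictor:
#'   observed difference and two-tailed permutation p).
#' @export
joint_regression_coef_diff <- function(factor_scores, mu0, b, n_perm = 10000L,
                                       seed = NULL, contrasts = NULL,
                                       interaction = FALSE) {
  fs <- as.matrix(factor_scores)
  .check(nrow(fs) == length(mu0) && length(mu0) == length(b),
         "factor_scores, mu0 and b must be row-aligned")
  .check(nrow(fs) >= 10, "need at least 10 participants")
  factors <- colnames(fs)
  if (is.null(factors)) factors <- paste0("f", seq_len(ncol(fs)))
  colnames(fs) <- factors
  if (is.null(contrasts)) {
    contrasts <- if (all(c("depression_specific", "anxiety_specific") %in% factors)) {
      list(c("depression_specific", "anxiety_specific"))
    } else {
      list(factors[1:2])
    }
  }

  design <- cbind(1, mu0 = mu0, b = b)
  qrd <- qr(design)
  .check(qrd$rank == ncol(design), "rank-deficient design (mu0/b collinear?)")
  # coefficients for every factor at once
  coefs_for <- function(fsm) qr.coef(qrd, fsm)  # 3 x n_factors
  obs_coefs <- coefs_for(fs)

  regressions <- list()
  for (f in factors) {
    reg <- list(coefficients = c(intercept = obs_coefs[1, f],
                                 mu0 = obs_coefs["mu0", f], b = obs_coefs["b", f]))
    if (interaction) {
      m0 <- stats::lm(fs[, f] ~ mu0 + b)
      m1 <- stats::lm(fs[, f] ~ mu0 * b)
      lr <- 2 * (stats::logLik(m1) - stats::logLik(m0))
      reg$interaction_lrt_p <- stats::pchisq(as.numeric(lr), df = 1, lower.tail = FALSE)
      reg$interaction_coef <- unname(stats::coef(m1)["mu0:b"])
    }
    regressions[[f]] <- reg
  }

  diff_stats <- function(cm, contrast) {
    c(mu0 = cm["mu0", contrast[1]] - cm["mu0", contrast[2]],
      b = cm["b", contrast[1]] - cm["b", contrast[2]])
  }
  obs_diff <- lapply(contrasts, function(ct) diff_stats(obs_coefs, ct))
  n <- nrow(fs)
  perm_diffs <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) {
      cm <- coefs_for(fs[sample.int(n), , drop = FALSE])
      lapply(contrasts, function(ct) diff_stats(cm, ct))
    })
  })
  coef_diff <- list()
  for (ci in seq_along(contrasts)) {
    perm_mat <- do.call(rbind, lapply(perm_diffs, `[[`, ci))
    ps <- vapply(c("mu0", "b"), function(pred) {
      (1 + sum(abs(perm_mat[, pred]) >= abs(obs_diff[[ci]][pred]) - 1e-12)) / (n_perm + 1)
    }, numeric(1))
    coef_diff[[paste(contrasts[[ci]], collapse = "_vs_")]] <-
      list(difference = obs_diff[[ci]], p = ps)
  }
  list(regressions = regressions, coef_diff = coef_diff,
       n_perm = as.integer(n_perm), seed = seed)
}

#' Bootstrap linear mediation (product of coefficients)
#'
#' Fits `mediator ~ x` (path a) and `y ~ x + mediator` (path b); the
#' average causal mediation effect is `a * b`, the direct effect the `x`
#' coefficient of the outcome model, and the total effect the `x`
#' coefficient of `y ~ x` (equal to ACME + direct in the linear case).
#' Uncertainty comes from a nonparametric percentile bootstrap over rows.
#'
#' @param x Exposure vector.
#' @param mediator Candidate mediator vector.
#' @param y Outcome vector.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional seed.
#' @return A `mediation_result` list: `acme`, `acme_p` (two-tailed
#'   percentile bootstrap), `acme_ci` (95%), `direct_effect`,
#'   `total_effect`, `n_boot`, `seed`.
#' @export
bootstrap_mediation <- function(x, mediator, y, n_boot = 5000L, seed = NULL) {
  .check(length(x) == length(mediator) && length(x) == length(y),
         "x, mediator and y must be aligned")
  .check(length(x) >= 10, "need at least 10 observations")
  acme_of <- function(xi, mi, yi) {
    a <- stats::cov(xi, mi) / stats::var(xi)
    fit <- stats::lm(yi ~ xi + mi)
    c(acme = a * unname(stats::coef(fit)["mi"]),
      direct = unname(stats::coef(fit)["xi"]))
  }
  obs <- acme_of(x, mediator, y)
  total <- stats::cov(x, y) / stats::var(x)
  n <- length(x)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      acme_of(x[idx], mediator[idx], y[idx])["acme"]
    }, numeric(1))
  })
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  p <- min(max(p, 1 / n_boot), 1)
  structure(list(
    acme = unname(obs["acme"]), acme_p = p,
    acme_ci = unname(stats::quantile(boots, c(0.025, 0.975))),
    direct_effect = unname(obs["direct"]), total_effect = total,
    n_boot = as.integer(n_boot), seed = seed
  ), class = "mediation_result")
}

#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` after regressing out `z` from both.
#'
#' @param x,y,z Aligned numeric vectors.
#' @return Scalar partial correlation.
#' @export
partial_corr <- function(x, y, z) {
  stats::cor(stats::resid(stats::lm(x ~ z)), stats::resid(stats::lm(y ~ z)))
}

#' Run the full individual-differences analysis on a fitted cohort
#'
#' Convenience pipeline: applies the directional-error filter, computes
#' factor scores, correlates every biased-RW parameter with every factor
#' (permutation tests, Benjamini-Hochberg correction across the 12-test
#' family of 3 factors x 4 parameters), runs the joint regressions with
#' coefficient-difference tests, and the popularity mediation analysis.
#'
#' @param cohort A `cohort` from [sample_cohort()].
#' @param fits Data frame from [fit_cohort()] (model 3 rows are used).
#' @param referent Which runs to analyse (`"self"` default).
#' @param n_perm Permutations for correlation and difference tests.
#' @param n_boot Bootstrap resamples for the mediation analysis.
#' @param seed Optional seed.
#' @return An `analysis_report` list: `exclusions`, `factor_scores`,
#'   `correlations` (one row per factor x parameter with r, p, p_fdr),
#'   `regressions`, `mediation`.
#' @export
analyze_cohort <- function(cohort, fits, referent = "self", n_perm = 10000L,
                           n_boot = 5000L, seed = NULL) {
  part <- cohort$participants
  f3 <- fits[fits$model_id == 3 & fits$referent == referent, ]
  .check(nrow(f3) > 0, "fits must contain model 3 rows for the requested referent")

  excl <- vapply(part$participant_id, function(pid) {
    tr <- cohort$trajectories[[paste(pid, referent, sep = "_")]]
    directional_error_filter(tr)$error_count
  }, numeric(1))
  keep_ids <- part$participant_id[excl < 9]

  scores <- anderson_rubin_scores(cohort$items, cohort$loadings)
  rownames(scores) <- part$participant_id

  f3 <- f3[match(keep_ids, f3$participant_id), ]
  .check(!anyNA(f3$participant_id), "fits are missing included participants")
  sc <- scores[keep_ids, , drop = FALSE]
  pop <- part$popularity[match(keep_ids, part$participant_id)]

  params <- c("mu0", "nu", "eta", "b")
  rows <- list()
  i <- 0L
  for (f in colnames(sc)) {
    for (p in params) {
      i <- i + 1L
      res <- permutation_corr(sc[, f], f3[[p]], n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else seed + i)
      rows[[i]] <- data.frame(factor = f, parameter = p, r = res$r,
                              p_uncorrected = res$p_uncorrected,
                              stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows)
  correlations$p_fdr <- bh_adjust(correlations$p_uncorrected)

  regressions <- joint_regression_coef_diff(
    sc, f3$mu0, f3$b, n_perm = n_perm,
    seed = if (is.null(seed)) NULL else seed + 100L, interaction = TRUE)

  mediation <- bootstrap_mediation(
    sc[, "depression_specific"], pop, f3$mu0, n_boot = n_boot,
    seed = if (is.null(seed)) NULL else seed + 200L)

  structure(list(
    exclusions = data.frame(participant_id = part$participant_id,
                            directional_errors = unname(excl),
                            excluded = unname(excl >= 9)),
    factor_scores = scores,
    correlations = correlations,
    regressions = regressions,
    mediation = mediation,
    referent = referent,
    n_included = length(keep_ids)
  ), class = "analysis_report")
}

#' Write an analysis report to JSON
#'
#' @param report An `analysis_report` from [analyze_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(report, path) {
  jsonlite::write_json(list(
    referent = report$referent,
    n_included = report$n_included,
    exclusions = report$exclusions,
    correlations = report$correlations,
    regressions = report$regressions,
    mediation = unclass(report$mediation)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
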