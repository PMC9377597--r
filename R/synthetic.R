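# Synthetic cohort generator.
#
# Generates cohorts with the individual-difference structure the analysis
# pipeline assumes: three orthogonal latent internalizing factors (general
# negative affect, anxiety-specific, depression-specific), per-participant
# biased-RW (model 3) belief parameters whose unconstrained scales carry
# planted correlations with the factors and with each other (the
# "confirmation bias" coupling between prior mean and updating bias), a
# profile-popularity percentage only weakly tied to depression, Likert
# item responses generated from a fixed bifactor loadings matrix, and
# belief trajectories simulated from the biased-RW model under two
# counterbalanced feedback orders.

#' The two canonical counterbalanced feedback sequences
#'
#' Each sequence delivers exactly ten positive and ten negative feedback
#' events over 20 trials. The positive-first sequence begins with two
#' positive events and contains six positives in the first ten trials; the
#' negative-first sequence is its elementwise complement.
#'
#' @return List with binary vectors `positive_first` and `negative_first`.
#' @export
canonical_feedback_sequences <- function() {
  positive_first <- c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L,
                      0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L)
  list(positive_first = positive_first,
       negative_first = 1L - positive_first)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the cohort the pipeline is designed for: 66 analysed
#' participants, a depression-specific association with the prior belief
#' mean of r = -0.33 and an anxiety-specific association with the updating
#' bias of r = -0.32 (both on the unconstrained parameter scales), a
#' confirmation-bias coupling of 0.5 between prior mean and bias, a weak
#' (-0.17) depression-popularity association, counterbalanced top/bottom
#' framing, and a small fraction of careless responders whose reports
#' ignore the feedback.
#'
#' @param n_participants Cohort size.
#' @param factor_effects Named list: planted latent-scale correlations
#'   `depression_mu0` and `anxiety_b`.
#' @param confirm_corr Planted correlation between logit prior mean and log
#'   updating bias (self-referent runs).
#' @param confirm_corr_other Same coupling for the other-referent runs.
#' @param popularity_corr Planted depression-popularity correlation.
#' @param fraction_bottom_framing Fraction of participants answering under
#'   the bottom-half framing.
#' @param careless_fraction Fraction of participants whose reports are a
#'   feedback-blind random walk.
#' @param param_scales Named list of location/scale for the parameter
#'   transforms: `mu0_logit_mean/sd`, `b_log_mean/sd`, `eta_logit_mean/sd`,
#'   `nu_log_mean/sd`, and other-referent shifts `mu0_logit_mean_other`,
#'   `b_log_mean_other`. Population means follow the typical task values
#'   (prior mean near 0.5, bias near 1, learning rate near 0.1, precision
#'   near 320; other-referent priors and bias mildly optimistic).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 66L,
                          factor_effects = list(depression_mu0 = -0.33,
                                                anxiety_b = -0.32),
                          confirm_corr = 0.5,
                          confirm_corr_other = 0.41,
                          popularity_corr = -0.17,
                          fraction_bottom_framing = 0.5,
                          careless_fraction = 0.04,
                          param_scales = list(),
                          seed = 1L) {
  defaults <- list(
    mu0_logit_mean = 0, mu0_logit_sd = 0.9,
    b_log_mean = 0, b_log_sd = 0.4,
    eta_logit_mean = stats::qlogis(0.098), eta_logit_sd = 0.6,
    nu_log_mean = log(320), nu_log_sd = 0.5,
    mu0_logit_mean_other = stats::qlogis(0.55),
    b_log_mean_other = log(1.16)
  )
  defaults[names(param_scales)] <- param_scales
  cfg <- list(
    n_participants = as.integer(n_participants),
    factor_effects = factor_effects,
    confirm_corr = confirm_corr,
    confirm_corr_other = confirm_corr_other,
    popularity_corr = popularity_corr,
    fraction_bottom_framing = fraction_bottom_framing,
    careless_fraction = careless_fraction,
    param_scales = defaults,
    seed = as.integer(seed)
  )
  planted <- c(unlist(factor_effects), confirm_corr, confirm_corr_other, popularity_corr)
  .check(all(planted > -1 & planted < 1), "planted correlations must lie in (-1, 1)")
  .check(fraction_bottom_framing >= 0 && fraction_bottom_framing <= 1 &&
           careless_fraction >= 0 && careless_fraction <= 1,
         "fractions must lie in [0, 1]")
  structure(cfg, class = "cohort_config")
}

# Draw n rows from N(0, Sigma) given a correlation matrix, via Cholesky.
.rmvn <- function(n, sigma) {
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("planted correlation matrix is not positive-definite",
                                          call. = FALSE))
  matrix(stats::rnorm(n * ncol(sigma)), n) %*% ch
}

#' Generate a synthetic cohort
#'
#' Latent factor scores and unconstrained parameter scores are drawn
#' jointly from a Gaussian copula whose correlation matrix plants the
#' configured effect structure; parameters are then pushed through logistic
#' / exponential transforms into their bounds and each participant's self-
#' and other-referent trajectories are simulated from the biased-RW model.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` list: `participants` data frame (factor scores, true
#'   parameters for both referents, popularity, framing, feedback order,
#'   careless flag), `trajectories` (list of [belief_trajectory()], self
#'   and other per participant), `items` (Likert response matrix),
#'   `loadings` (the bifactor loadings used), `config`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  n <- config$n_participants
  fe <- config$factor_effects
  sc <- config$param_scales

  # latent order: general, anxiety, depression, z_mu0, z_b, z_pop
  sigma <- diag(6)
  dimnames(sigma) <- rep(list(c("g", "anx", "dep", "z_mu0", "z_b", "z_pop")), 2)
  sigma["dep", "z_mu0"] <- sigma["z_mu0", "dep"] <- fe$depression_mu0
  sigma["anx", "z_b"] <- sigma["z_b", "anx"] <- fe$anxiety_b
  sigma["z_mu0", "z_b"] <- sigma["z_b", "z_mu0"] <- config$confirm_corr
  sigma["dep", "z_pop"] <- sigma["z_pop", "dep"] <- config$popularity_corr

  sigma_other <- matrix(c(1, config$confirm_corr_other,
                          config$confirm_corr_other, 1), 2)

  with_seed(config$seed, {
    z <- .rmvn(n, sigma)
    z_other <- .rmvn(n, sigma_other)
    seqs <- canonical_feedback_sequences()

    participants <- data.frame(
      participant_id = sprintf("p%03d", seq_len(n)),
      general = z[, 1], anxiety = z[, 2], depression = z[, 3],
      mu0_self = stats::plogis(sc$mu0_logit_mean + sc$mu0_logit_sd * z[, 4]),
      b_self = exp(sc$b_log_mean + sc$b_log_sd * z[, 5]),
      eta_self = stats::plogis(sc$eta_logit_mean + sc$eta_logit_sd * stats::rnorm(n)),
      nu_self = pmin(pmax(exp(sc$nu_log_mean + sc$nu_log_sd * stats::rnorm(n)), 2), 1000),
      mu0_other = stats::plogis(sc$mu0_logit_mean_other + sc$mu0_logit_sd * z_other[, 1]),
      b_other = exp(sc$b_log_mean_other + sc$b_log_sd * z_other[, 2]),
      eta_other = stats::plogis(sc$eta_logit_mean + sc$eta_logit_sd * stats::rnorm(n)),
      nu_other = pmin(pmax(exp(sc$nu_log_mean + sc$nu_log_sd * stats::rnorm(n)), 2), 1000),
      popularity = pmin(pmax(50 + 15 * z[, 6], 1), 99),
      framing = ifelse(stats::runif(n) < config$fraction_bottom_framing,
                       "bottom_half", "top_half"),
      feedback_order = rep_len(c("positive_first", "negative_first"), n)[sample(n)],
      careless = stats::runif(n) < config$careless_fraction,
      stringsAsFactors = FALSE
    )
    participants$b_self <- pmin(participants$b_self, 5)
    participants$b_other <- pmin(participants$b_other, 5)

    trajectories <- list()
    for (i in seq_len(n)) {
      fb <- seqs[[participants$feedback_order[i]]]
      for (ref in c("self", "other")) {
        pars <- c(mu0 = participants[[paste0("mu0_", ref)]][i],
                  nu = participants[[paste0("nu_", ref)]][i],
                  eta = participants[[paste0("eta_", ref)]][i],
                  b = participants[[paste0("b_", ref)]][i])
        tr <- simulate_trajectory(3, pars, fb,
                                  participant_id = participants$participant_id[i],
                                  referent = ref,
                                  framing = participants$framing[i],
                                  feedback_order = participants$feedback_order[i])
        if (participants$careless[i]) {
          # feedback-blind responder: reports follow a clipped random walk
          q <- numeric(N_TRIALS + 1L)
          q[1] <- stats::runif(1, 0.2, 0.8)
          for (t in 2:(N_TRIALS + 1L)) {
            q[t] <- min(max(q[t - 1] + stats::rnorm(1, 0, 0.15), 0.01), 0.99)
          }
          tr$reports <- q
        }
        trajectories[[paste(participants$participant_id[i], ref, sep = "_")]] <- tr
      }
    }

    loadings <- synthetic_loadings()
    scores <- as.matrix(participants[, c("general", "anxiety", "depression")])
    colnames(scores) <- colnames(loadings)
    items <- sample_item_responses(scores, loadings)

    structure(list(participants = participants, trajectories = trajectories,
                   items = items, loadings = loadings, config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d trajectories, %d questionnaire items\n",
              nrow(x$participants), length(x$trajectories), ncol(x$items)))
  invisible(x)
}

#' Synthetic bifactor loadings matrix (95 items x 3 factors)
#'
#' A stand-in for a bifactor loadings matrix estimated on questionnaire
#' item responses: every item loads moderately (0.3-0.6) on the general
#' negative-affect factor; worry items additionally load 0.4-0.7 on the
#' anxiety-specific factor and anhedonia items on the depression-specific
#' factor. All communalities are below 1. Deterministic: the matrix is a
#' fixed fixture generated from an internal seed.
#'
#' @param n_worry,n_anhedonia,n_general Item counts per block (default
#'   33 + 30 + 32 = 95 items).
#' @return Numeric matrix with rownames (item ids) and colnames
#'   `general`, `anxiety_specific`, `depression_specific`.
#' @export
synthetic_loadings <- function(n_worry = 33L, n_anhedonia = 30L, n_general = 32L) {
  n_items <- n_worry + n_anhedonia + n_general
  with_seed(20220815L %% .Machine$integer.max, {
    l <- matrix(0, n_items, 3,
                dimnames = list(
                  c(sprintf("worry_%02d", seq_len(n_worry)),
                    sprintf("anhedonia_%02d", seq_len(n_anhedonia)),
                    sprintf("general_%02d", seq_len(n_general))),
                  c("general", "anxiety_specific", "depression_specific")))
    l[, "general"] <- stats::runif(n_items, 0.3, 0.6)
    l[seq_len(n_worry), "anxiety_specific"] <- stats::runif(n_worry, 0.4, 0.7)
    l[n_worry + seq_len(n_anhedonia), "depression_specific"] <-
      stats::runif(n_anhedonia, 0.4, 0.7)
    l
  })
}

#' Simulate questionnaire item responses from factor scores
#'
#' Responses follow the linear factor model `scores %*% t(loadings) +
#' noise`. By default the noise standard deviation per item is
#' `sqrt(1 - communality)`, so the population item correlation matrix is
#' `loadings %*% t(loadings)` off the diagonal. Continuous responses are
#' then discretised to a Likert range.
#'
#' @param factor_scores Participants x 3 matrix of factor scores.
#' @param loadings Items x 3 loadings matrix ([synthetic_loadings()] form).
#' @param noise_sd Scalar noise SD, or `NULL` for per-item
#'   `sqrt(1 - communality)`.
#' @param seed Optional seed.
#' @param discretize Cut continuous responses into `likert_levels` ordered
#'   categories (1-based)?
#' @param likert_levels Number of response options.
#' @return Participants x items matrix (item ids as colnames).
#' @export
sample_item_responses <- function(factor_scores, loadings, noise_sd = NULL,
                                  seed = NULL, discretize = TRUE,
                                  likert_levels = 4L) {
  factor_scores <- as.matrix(factor_scores)
  loadings <- as.matrix(loadings)
  .check(ncol(factor_scores) == ncol(loadings),
         "factor_scores and loadings must agree on the number of factors")
  n <- nrow(factor_scores)
  m <- nrow(loadings)
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(pmax(1 - rowSums(loadings^2), 0))
  } else {
    noise_sd <- rep_len(noise_sd, m)
  }
  with_seed(seed, {
    resp <- tcrossprod(factor_scores, loadings) +
      matrix(stats::rnorm(n * m), n, m) %*% diag(noise_sd, m)
    colnames(resp) <- rownames(loadings)
    if (discretize) {
      breaks <- c(-Inf, stats::qnorm(seq_len(likert_levels - 1) / likert_levels), Inf)
      resp[] <- findInterval(resp, breaks)
    }
    resp
  })
}

#' Write a cohort to a directory of CSV files
#'
#' Emits `trajectories.csv`, `cohort.csv`, `items.csv` and `loadings.csv`.
#'
#' @param cohort A `cohort` from [sample_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trajectories(cohort$trajectories, file.path(dir, "trajectories.csv"))
  utils::write.csv(cohort$participants, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(data.frame(participant_id = cohort$participants$participant_id,
                              cohort$items, check.names = FALSE),
                   file.path(dir, "items.csv"), row.names = FALSE)
  utils::write.csv(data.frame(item = rownames(cohort$loadings), cohort$loadings,
                              check.names = FALSE),
                   file.path(dir, "loadings.csv"), row.names = FALSE)
  invisible(dir)
}
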