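# The four main belief-updating models.
#
# All models share one observation architecture: on trial t the participant
# holds a Beta(alpha_t, beta_t) belief about the probability of being in the
# top half, and each probability report is a single sample from that
# distribution. The models differ in how feedback moves (alpha_t, beta_t):
#
#   1 biased_bayes   alpha_{t} = alpha_{t-1} + omega * X_t
#                    beta_{t}  = beta_{t-1} + (1/omega) * (1 - X_t)
#   2 bayes          model 1 with omega fixed at 1 (exact Bayesian counting)
#   3 biased_rw      mean/precision parameterisation, Rescorla-Wagner mean
#                    update mu_t = min(mu_{t-1} + eta * (b * X_t - mu_{t-1}), 1)
#                    with constant precision nu; alpha_t = nu * mu_t
#   4 rw             model 3 with b fixed at 1
#
# The registry is open: additional models can be registered with
# register_model() as long as they provide the same hooks.

DEFAULT_CLIP_EPS <- 1e-4

#' Convert a mean/precision Beta parameterisation to shape parameters
#'
#' The belief distribution of the Rescorla-Wagner models is parameterised by
#' its mean `mu` and a total pseudo-count ("precision") `nu`; the standard
#' shapes are `alpha = nu * mu`, `beta = nu * (1 - mu)`, so `alpha + beta =
#' nu` is conserved across trials.
#'
#' @param mu Belief mean in (0, 1).
#' @param nu Precision (total pseudo-count), > 0.
#' @return Named list with elements `alpha` and `beta`.
#' @examples
#' mean_precision_to_shape(0.5, 320)  # alpha = beta = 160
#' @export
mean_precision_to_shape <- function(mu, nu) {
  .check(is.numeric(mu) && all(mu > 0 & mu < 1), "mu must lie strictly in (0, 1)")
  .check(is.numeric(nu) && all(nu > 0), "nu must be positive")
  list(alpha = nu * mu, beta = nu * (1 - mu))
}

#' One Rescorla-Wagner belief-mean update
#'
#' Moves the belief mean toward the (bias-scaled) feedback at rate `eta`:
#' `min(mu + eta * (bias * x - mu), 1)`. A bias above 1 weighs positive
#' feedback more heavily; below 1, less. The clamp at 1 is needed because
#' `bias * x` can exceed 1.
#'
#' @param mu_prev Previous belief mean in `[0, 1]`.
#' @param feedback Binary feedback event (0 or 1).
#' @param eta Learning rate in `[0, 1]`.
#' @param bias Valence bias in `[0, 5]`.
#' @return Updated belief mean in `[0, 1]`.
#' @export
rw_update <- function(mu_prev, feedback, eta, bias) {
  .check(.is_prob(mu_prev), "mu_prev must lie in [0, 1]")
  .check(.is_binary(feedback), "feedback must be 0 or 1")
  .check(is.numeric(eta) && all(eta >= 0 & eta <= 1), "eta must lie in [0, 1]")
  .check(is.numeric(bias) && all(bias >= 0 & bias <= 5), "bias must lie in [0, 5]")
  pmin(mu_prev + eta * (bias * feedback - mu_prev), 1)
}

#' One (possibly biased) Bayesian evidence update
#'
#' Positive feedback adds `omega` pseudo-counts to `alpha`; negative
#' feedback adds `1/omega` to `beta`. With `omega = 1` this is exact
#' Bayesian counting of Bernoulli evidence.
#'
#' @param alpha_prev,beta_prev Previous Beta shape parameters, > 0.
#' @param feedback Binary feedback event (0 or 1).
#' @param omega Valence bias, > 0 (`omega = 0` would divide by zero on
#'   negative feedback).
#' @return Named list with updated `alpha` and `beta`.
#' @export
bayes_update <- function(alpha_prev, beta_prev, feedback, omega) {
  .check(is.numeric(alpha_prev) && all(alpha_prev > 0), "alpha_prev must be positive")
  .check(is.numeric(beta_prev) && all(beta_prev > 0), "beta_prev must be positive")
  .check(.is_binary(feedback), "feedback must be 0 or 1")
  .check(is.numeric(omega) && all(omega > 0), "omega must be strictly positive")
  list(
    alpha = alpha_prev + omega * feedback,
    beta = beta_prev + (1 / omega) * (1 - feedback)
  )
}

#' Log-density of a probability report under the current belief
#'
#' Reports are modelled as single samples from the Beta belief
#' distribution. Slider reports of exactly 0 or 1 have zero or infinite
#' Beta density, so reports are clipped into `[clip_eps, 1 - clip_eps]`
#' before evaluation; the result is always finite.
#'
#' @param alpha,beta Beta shape parameters, > 0.
#' @param report Probability report in `[0, 1]`.
#' @param clip_eps Clipping threshold in (0, 0.1).
#' @return Log-density (finite scalar, vectorised over inputs).
#' @export
report_logdensity <- function(alpha, beta, report, clip_eps = DEFAULT_CLIP_EPS) {
  .check(is.numeric(alpha) && all(alpha > 0), "alpha must be positive")
  .check(is.numeric(beta) && all(beta > 0), "beta must be positive")
  .check(.is_prob(report), "report must lie in [0, 1]")
  .check(is.numeric(clip_eps) && length(clip_eps) == 1 && clip_eps > 0 && clip_eps < 0.1,
         "clip_eps must lie in (0, 0.1)")
  stats::dbeta(pmin(pmax(report, clip_eps), 1 - clip_eps), alpha, beta, log = TRUE)
}

# ---- model registry ---------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Register a belief-updating model
#'
#' A model provides its parameter table (names, box bounds, MAP priors) and
#' a `shapes` hook that propagates the belief state over a feedback sequence
#' and returns the Beta shapes governing each of the 21 reports (row 1 is
#' the pre-feedback prior state).
#'
#' @param id Integer model id.
#' @param name Human-readable model name.
#' @param params Data frame with columns `name`, `lower`, `upper`, and prior
#'   columns `prior_family` (`"half_normal"` or `"normal"`), `prior_location`,
#'   `prior_scale`.
#' @param shapes Function `(params, feedback)` returning a `(length(feedback)
#'   + 1) x 2` matrix of Beta shapes.
#' @return The model definition, invisibly.
#' @export
register_model <- function(id, name, params, shapes) {
  .check(is.numeric(id) && length(id) == 1, "id must be a single number")
  need <- c("name", "lower", "upper", "prior_family", "prior_location", "prior_scale")
  .check(is.data.frame(params) && all(need %in% names(params)),
         "params must be a data frame with name/lower/upper/prior_* columns")
  def <- list(id = as.integer(id), name = name, params = params, shapes = shapes)
  assign(as.character(as.integer(id)), def, envir = .model_registry)
  invisible(def)
}

#' Look up a registered model
#'
#' @param model_id Integer id of a registered model (1-4 are built in).
#' @return The model definition list (`id`, `name`, `params`, `shapes`).
#' @export
get_model <- function(model_id) {
  key <- as.character(as.integer(model_id))
  if (!exists(key, envir = .model_registry, inherits = FALSE)) {
    stop(sprintf("unknown model id %s; registered: %s", model_id,
                 paste(sort(as.integer(ls(.model_registry))), collapse = ", ")),
         call. = FALSE)
  }
  get(key, envir = .model_registry)
}

#' List registered model ids
#' @return Sorted integer vector of model ids.
#' @export
registered_models <- function() sort(as.integer(ls(.model_registry)))

#' Number of free parameters of a model
#' @param model_id Registered model id.
#' @return Integer parameter count (the `k` of the BIC penalty).
#' @export
n_params <- function(model_id) nrow(get_model(model_id)$params)

# Parameter bounds as named vectors, convenience for optimisers/samplers
.param_bounds <- function(model_id) {
  p <- get_model(model_id)$params
  list(lower = stats::setNames(p$lower, p$name),
       upper = stats::setNames(p$upper, p$name))
}

.check_params <- function(model_id, params) {
  p <- get_model(model_id)$params
  .check(all(p$name %in% names(params)),
         paste("params must be named and include:", paste(p$name, collapse = ", ")))
  v <- unlist(params[p$name])
  .check(all(is.finite(v)), "parameters must be finite")
  .check(all(v >= p$lower - 1e-12 & v <= p$upper + 1e-12),
         sprintf("parameters outside bounds for model %d", get_model(model_id)$id))
  stats::setNames(as.numeric(v), p$name)
}

# Shape propagation hooks. Both return a (T+1) x 2 matrix; row t+1 holds the
# state from which the report after feedback event t is drawn.
.shapes_bayes <- function(params, feedback) {
  a <- params[["alpha0"]] + params[["omega"]] * cumsum(feedback)
  b <- params[["beta0"]] + (1 / params[["omega"]]) * cumsum(1 - feedback)
  cbind(alpha = c(params[["alpha0"]], a), beta = c(params[["beta0"]], b))
}

.shapes_rw <- function(params, feedback) {
  mu <- numeric(length(feedback) + 1L)
  mu[1] <- params[["mu0"]]
  eta <- params[["eta"]]
  b <- params[["b"]]
  for (t in seq_along(feedback)) {
    mu[t + 1L] <- min(mu[t] + eta * (b * feedback[t] - mu[t]), 1)
  }
  # the mean dynamics may hit 0 or 1 exactly; clip so the Beta stays proper
  mu_c <- pmin(pmax(mu, DEFAULT_CLIP_EPS), 1 - DEFAULT_CLIP_EPS)
  nu <- params[["nu"]]
  cbind(alpha = nu * mu_c, beta = nu * (1 - mu_c))
}

.prior_table <- function(name, lower, upper, family, location, scale) {
  data.frame(name = name, lower = lower, upper = upper,
             prior_family = family, prior_location = location,
             prior_scale = scale, stringsAsFactors = FALSE)
}

# Built-in registry. omega's lower bound is lifted off zero: omega = 0 makes
# the negative-feedback increment 1/omega undefined, so the box constraint
# for estimation starts at a small positive value.
.register_builtin_models <- function() {
  register_model(1, "biased_bayes", rbind(
    .prior_table("alpha0", 2, 100, "half_normal", 0, 50),
    .prior_table("beta0", 2, 100, "half_normal", 0, 50),
    .prior_table("omega", 1e-3, 5, "normal", 1, 0.5)
  ), .shapes_bayes)
  register_model(2, "bayes", rbind(
    .prior_table("alpha0", 2, 100, "half_normal", 0, 50),
    .prior_table("beta0", 2, 100, "half_normal", 0, 50)
  ), function(params, feedback) {
    .shapes_bayes(c(params, omega = 1), feedback)
  })
  register_model(3, "biased_rw", rbind(
    .prior_table("mu0", 0, 1, "normal", 0.5, 0.5),
    .prior_table("nu", 2, 1000, "half_normal", 0, 500),
    .prior_table("eta", 0, 1, "half_normal", 0, 0.5),
    .prior_table("b", 0, 5, "half_normal", 0, 2)
  ), .shapes_rw)
  register_model(4, "rw", rbind(
    .prior_table("mu0", 0, 1, "normal", 0.5, 0.5),
    .prior_table("nu", 2, 1000, "half_normal", 0, 500),
    .prior_table("eta", 0, 1, "half_normal", 0, 0.5)
  ), function(params, feedback) {
    .shapes_rw(c(params, b = 1), feedback)
  })
}

#' Beta shapes governing each report of a run
#'
#' Propagates a model's belief state across a feedback sequence. Row `t + 1`
#' of the result holds the Beta shapes from which the report after feedback
#' event `t` is drawn; row 1 is the pre-feedback prior state.
#'
#' @param model_id Registered model id.
#' @param params Named parameter vector or list for the model.
#' @param feedback Binary feedback vector.
#' @return `(length(feedback) + 1) x 2` matrix with columns `alpha`, `beta`.
#' @export
trajectory_shapes <- function(model_id, params, feedback) {
  def <- get_model(model_id)
  params <- .check_params(model_id, params)
  .check(.is_binary(feedback), "feedback must be a binary vector")
  def$shapes(params, feedback)
}

#' Simulate a belief trajectory from a model
#'
#' Propagates the belief state through `feedback_seq` under the model's
#' update rule and draws one report per time point (t = 0 .. 20) from the
#' current Beta distribution.
#'
#' @param model_id Registered model id.
#' @param params Named parameter vector/list, within the model's bounds.
#' @param feedback_seq Binary feedback vector (length 20 for the standard
#'   task).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   trajectory without disturbing the caller's RNG.
#' @param participant_id,referent,framing,feedback_order Metadata stored on
#'   the returned trajectory.
#' @return A [belief_trajectory()].
#' @export
simulate_trajectory <- function(model_id, params, feedback_seq, seed = NULL,
                                participant_id = "sim", referent = "self",
                                framing = "top_half",
                                feedback_order = NA_character_) {
  shp <- trajectory_shapes(model_id, params, feedback_seq)
  reports <- with_seed(seed, stats::rbeta(nrow(shp), shp[, "alpha"], shp[, "beta"]))
  # rbeta can return exact 0/1 only for degenerate shapes; keep reports in (0,1)
  reports <- pmin(pmax(reports, DEFAULT_CLIP_EPS), 1 - DEFAULT_CLIP_EPS)
  belief_trajectory(participant_id, referent, framing,
                    feedback = feedback_seq, reports = reports,
                    feedback_order = feedback_order)
}
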