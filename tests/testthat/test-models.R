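test_that("mean/precision to shape mapping matches its definition", {
  s <- mean_precision_to_shape(0.5, 320)
  expect_equal(s$alpha, 160)
  expect_equal(s$beta, 160)
  expect_equal(mean_precision_to_shape(0.25, 4), list(alpha = 1, beta = 3))
  # conservation: alpha + beta = nu for arbitrary inputs
  set.seed(1)
  for (i in 1:20) {
    mu <- runif(1, 0.01, 0.99); nu <- runif(1, 2, 1000)
    s <- mean_precision_to_shape(mu, nu)
    expect_equal(s$alpha + s$beta, nu)
  }
  expect_error(mean_precision_to_shape(0, 10), "mu")
  expect_error(mean_precision_to_shape(0.5, 0), "nu")
})

test_that("RW update follows the clamped delta rule", {
  expect_equal(rw_update(0.5, 1, 0.0, 2.0), 0.5)     # zero learning rate
  expect_equal(rw_update(0.9, 1, 1.0, 5.0), 1.0)     # clamp at 1
  expect_equal(rw_update(0.5, 1, 0.098, 1.0), 0.549) # hand evaluation
  expect_equal(rw_update(0.5, 0, 0.5, 0.8), 0.25)    # decay toward 0
  expect_error(rw_update(0.5, 1, 1.5, 1), "eta")
  expect_error(rw_update(0.5, 1, 0.5, 6), "bias")
})

test_that("Bayesian update adds valence-scaled pseudo-counts", {
  expect_equal(bayes_update(2, 2, 1, 1.0), list(alpha = 3, beta = 2))
  expect_equal(bayes_update(2, 2, 0, 2.0), list(alpha = 2, beta = 2.5))
  # positive feedback never touches beta
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 2, 100); b <- runif(1, 2, 100); w <- runif(1, 0.1, 5)
    expect_equal(bayes_update(a, b, 1, w)$beta, b)
  }
  expect_error(bayes_update(2, 2, 0, 0), "omega")
})

test_that("report log-density is the clipped Beta log-density and finite", {
  expect_equal(report_logdensity(1, 1, 0.7), 0)
  expect_equal(report_logdensity(2, 2, 0.5), log(1.5))
  expect_true(is.finite(report_logdensity(2, 2, 1.0)))
  expect_true(is.finite(report_logdensity(2, 2, 0.0)))
  # boundary reports evaluate at the clip point
  expect_equal(report_logdensity(2, 2, 1.0, 1e-3),
               dbeta(1 - 1e-3, 2, 2, log = TRUE))
})

test_that("simulate_trajectory honours the length and seed contracts", {
  pars <- c(mu0 = 0.5, nu = 100, eta = 0.1, b = 1)
  tr1 <- simulate_trajectory(3, pars, FB$positive_first, seed = 7)
  tr2 <- simulate_trajectory(3, pars, FB$positive_first, seed = 7)
  expect_length(tr1$feedback, 20)
  expect_length(tr1$reports, 21)
  expect_identical(tr1$reports, tr2$reports)
  expect_true(all(tr1$reports > 0 & tr1$reports < 1))
  expect_error(simulate_trajectory(99, pars, FB$positive_first), "unknown model")
})

test_that("high precision concentrates reports near the belief mean", {
  pars <- c(mu0 = 0.5, nu = 1000, eta = 0.1, b = 1)
  shp <- trajectory_shapes(3, pars, FB$positive_first)
  mu <- shp[, "alpha"] / (shp[, "alpha"] + shp[, "beta"])
  devs <- replicate(50, {
    tr <- simulate_trajectory(3, pars, FB$positive_first)
    mean(abs(tr$reports - mu))
  })
  expect_lt(mean(devs), 0.05)
})

test_that("RW dynamics conserve precision and respect monotonicity", {
  pars <- c(mu0 = 0.3, nu = 250, eta = 0.2, b = 0.8)
  shp <- trajectory_shapes(3, pars, FB$negative_first)
  expect_equal(unname(rowSums(shp)), rep(250, 21))
  # with b = 1: mean non-decreasing after X = 1, non-increasing after X = 0
  pars1 <- c(mu0 = 0.5, nu = 100, eta = 0.15, b = 1)
  shp1 <- trajectory_shapes(3, pars1, FB$positive_first)
  mu1 <- shp1[, "alpha"] / rowSums(shp1)
  d <- diff(mu1)
  expect_true(all(d[FB$positive_first == 1] >= -1e-12))
  expect_true(all(d[FB$positive_first == 0] <= 1e-12))
})

test_that("RW mean converges geometrically to b under constant feedback", {
  eta <- 0.3; b <- 0.7
  mu <- 0.2
  for (t in 1:60) mu <- rw_update(mu, 1, eta, b)
  expect_equal(mu, b, tolerance = 1e-6)
  mu <- 0.9
  for (t in 1:60) mu <- rw_update(mu, 0, eta, b)
  expect_equal(mu, 0, tolerance = 1e-6)
})

test_that("unbiased Bayesian model grows evidence by one per trial and matches the closed form", {
  pars <- c(alpha0 = 5, beta0 = 8)
  shp <- trajectory_shapes(2, pars, FB$positive_first)
  expect_equal(unname(rowSums(shp)), 13 + 0:20)
  # sequential updating equals closed-form counting
  t_idx <- 0:20
  cum_x <- c(0, cumsum(FB$positive_first))
  expect_equal(unname(shp[, "alpha"] / rowSums(shp)),
               (5 + cum_x) / (13 + t_idx))
})

test_that("model registry reports the documented parameter counts and is extensible", {
  expect_equal(n_params(1), 3L)
  expect_equal(n_params(2), 2L)
  expect_equal(n_params(3), 4L)
  expect_equal(n_params(4), 3L)
  register_model(99, "toy_uniform",
                 data.frame(name = "mu0", lower = 0, upper = 1,
                            prior_family = "normal", prior_location = 0.5,
                            prior_scale = 0.5),
                 function(params, feedback) {
                   n <- length(feedback) + 1L
                   cbind(alpha = rep(1, n), beta = rep(1, n))
                 })
  expect_true(99L %in% registered_models())
  expect_equal(log_likelihood(99, c(mu0 = 0.5), ref_trajectory()), 0)
})
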