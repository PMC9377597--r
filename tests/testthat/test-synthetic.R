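test_that("canonical feedback sequences satisfy every stated constraint", {
  s <- canonical_feedback_sequences()
  expect_length(s$positive_first, 20)
  expect_equal(sum(s$positive_first), 10)
  expect_equal(sum(s$negative_first), 10)
  expect_equal(s$positive_first[1:2], c(1L, 1L))
  expect_equal(sum(s$positive_first[1:10]), 6)
  expect_true(all(xor(s$positive_first, s$negative_first)))
})

test_that("cohort size and trajectory invariants hold", {
  co <- sample_cohort(cohort_config(n_participants = 66, seed = 1))
  expect_equal(nrow(co$participants), 66)
  expect_length(co$trajectories, 132)
  refs <- vapply(co$trajectories, `[[`, character(1), "referent")
  expect_equal(sum(refs == "self"), 66)
  expect_equal(sum(refs == "other"), 66)
  for (tr in co$trajectories[1:10]) {
    expect_s3_class(tr, "belief_trajectory")
    expect_true(all(tr$reports >= 0 & tr$reports <= 1))
    expect_true(tr$feedback_order %in% c("positive_first", "negative_first"))
    expect_equal(sum(tr$feedback), 10)
  }
  # same seed reproduces the cohort exactly
  co2 <- sample_cohort(cohort_config(n_participants = 66, seed = 1))
  expect_identical(co$participants, co2$participants)
})

test_that("null config plants no structure", {
  cfg <- cohort_config(n_participants = 500, seed = 2,
                       factor_effects = list(depression_mu0 = 0, anxiety_b = 0),
                       confirm_corr = 0, popularity_corr = 0,
                       careless_fraction = 0)
  co <- sample_cohort(cfg)
  p <- co$participants
  lat <- cbind(z_mu0 = qlogis(p$mu0_self), z_b = log(p$b_self))
  for (f in c("general", "anxiety", "depression")) {
    expect_lt(abs(cor(p[[f]], lat[, "z_mu0"])), 0.15)
    expect_lt(abs(cor(p[[f]], lat[, "z_b"])), 0.15)
  }
  expect_lt(abs(cor(lat[, "z_mu0"], lat[, "z_b"])), 0.15)
})

test_that("planted correlations are recovered at n = 500", {
  co <- sample_cohort(cohort_config(n_participants = 500, seed = 3,
                                    careless_fraction = 0))
  p <- co$participants
  z_mu0 <- qlogis(p$mu0_self); z_b <- log(p$b_self)
  expect_lt(abs(cor(p$depression, z_mu0) - (-0.33)), 0.1)
  expect_lt(abs(cor(p$anxiety, z_b) - (-0.32)), 0.1)
  expect_lt(abs(cor(z_mu0, z_b) - 0.5), 0.1)
  expect_lt(abs(cor(p$depression, p$popularity) - (-0.17)), 0.1)
  # popularity nearly uncorrelated with the prior mean ("poor insight")
  expect_lt(abs(cor(p$popularity, p$mu0_self)), 0.15)
  # factor scores are orthogonal in the population model
  expect_lt(max(abs(cor(p[, c("general", "anxiety", "depression")])
                    [upper.tri(diag(3))])), 0.15)
})

test_that("infeasible correlation structure raises a config error", {
  cfg <- cohort_config(n_participants = 10, seed = 1,
                       factor_effects = list(depression_mu0 = -0.9,
                                             anxiety_b = -0.9),
                       confirm_corr = 0.9)
  expect_error(sample_cohort(cfg), "positive-definite")
})

test_that("careless responders are planted and caught by the filter", {
  co <- sample_cohort(cohort_config(n_participants = 80, seed = 4,
                                    careless_fraction = 0.3))
  p <- co$participants
  expect_gt(sum(p$careless), 0)
  errs <- vapply(p$participant_id, function(pid) {
    directional_error_filter(co$trajectories[[paste0(pid, "_self")]])$error_count
  }, numeric(1))
  # careless responders make many more directional errors than modelled ones
  expect_gt(mean(errs[p$careless]), mean(errs[!p$careless]))
  # with no careless responders and high precision, errors are rare
  co0 <- sample_cohort(cohort_config(n_participants = 60, seed = 5,
                                     careless_fraction = 0,
                                     param_scales = list(nu_log_mean = log(600),
                                                         nu_log_sd = 0.2)))
  errs0 <- vapply(co0$participants$participant_id, function(pid) {
    directional_error_filter(co0$trajectories[[paste0(pid, "_self")]])$error_count
  }, numeric(1))
  expect_gt(mean(errs0 <= 2), 0.6)
})

test_that("item responses follow the linear factor model", {
  l <- synthetic_loadings()
  expect_equal(dim(l), c(95L, 3L))
  expect_true(all(rowSums(l^2) < 1))
  set.seed(6)
  scores <- matrix(rnorm(300 * 3), 300)
  # noise-free continuous responses have rank <= 3
  resp0 <- sample_item_responses(scores, l, noise_sd = 0, seed = 1,
                                 discretize = FALSE)
  expect_lte(qr(resp0)$rank, 3)
  # determinism
  r1 <- sample_item_responses(scores, l, seed = 2)
  r2 <- sample_item_responses(scores, l, seed = 2)
  expect_identical(r1, r2)
  expect_true(all(r1 %in% 1:4))
})

test_that("item correlations approach the loadings cross-product at large n", {
  l <- synthetic_loadings()
  set.seed(7)
  scores <- matrix(rnorm(2000 * 3), 2000)
  resp <- sample_item_responses(scores, l, seed = 3, discretize = FALSE)
  emp <- cor(resp)
  pop <- tcrossprod(l)
  off <- upper.tri(emp)
  expect_lt(mean(abs(emp[off] - pop[off])), 0.03)
})

test_that("cohort files round-trip through the CSV interfaces", {
  co <- sample_cohort(cohort_config(n_participants = 6, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("trajectories.csv", "cohort.csv",
                                               "items.csv", "loadings.csv")))))
  back <- read_trajectories(file.path(dir, "trajectories.csv"))
  expect_length(back, 12)
  expect_equal(back[["p001_self"]]$reports, co$trajectories[["p001_self"]]$reports)
})
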