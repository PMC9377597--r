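test_that("directional error filter counts strictly anti-feedback moves", {
  # monotone-correct run: reports move with the feedback
  fb <- FB$positive_first
  q <- numeric(21); q[1] <- 0.5
  for (t in 1:20) q[t + 1] <- q[t] + ifelse(fb[t] == 1, 0.01, -0.01)
  tr <- belief_trajectory("p", "self", "top_half", fb, q)
  expect_equal(directional_error_filter(tr),
               list(error_count = 0L, excluded = FALSE))

  # exactly 9 anti-feedback moves -> excluded
  q2 <- numeric(21); q2[1] <- 0.5
  for (t in 1:20) {
    dir <- if (t <= 9) -1 else 1          # first 9 moves oppose the feedback
    q2[t + 1] <- q2[t] + dir * ifelse(fb[t] == 1, 0.01, -0.01)
  }
  tr2 <- belief_trajectory("p", "self", "top_half", fb, q2)
  res2 <- directional_error_filter(tr2)
  expect_equal(res2$error_count, 9)
  expect_true(res2$excluded)

  # unchanged reports are not errors
  tr3 <- belief_trajectory("p", "self", "top_half", fb, rep(0.5, 21))
  expect_equal(directional_error_filter(tr3)$error_count, 0)
})

test_that("model-agnostic indices are the start/end reports and their difference", {
  q <- c(0.4, runif(19), 0.7)
  tr <- belief_trajectory("p", "self", "top_half", FB$positive_first, q)
  idx <- model_agnostic_indices(tr)
  expect_equal(idx$starting_belief, 0.4)
  expect_equal(idx$ending_belief, 0.7)
  expect_equal(idx$belief_change, 0.3)
})

test_that("feedback order splits the belief-change distribution", {
  # Under delta-rule recency weighting the late trials dominate the final
  # belief, so the positive-first order (6 positives in the first 10 trials,
  # hence only 4 in the last 10) ends *below* the negative-first order: the
  # two counterbalanced sequences produce clearly separated belief-change
  # distributions.
  co <- sample_cohort(cohort_config(n_participants = 120, seed = 10,
                                    careless_fraction = 0))
  ch <- vapply(co$participants$participant_id, function(pid) {
    model_agnostic_indices(co$trajectories[[paste0(pid, "_self")]])$belief_change
  }, numeric(1))
  ord <- co$participants$feedback_order
  expect_lt(mean(ch[ord == "positive_first"]), mean(ch[ord == "negative_first"]))
  expect_lt(t.test(ch[ord == "positive_first"], ch[ord == "negative_first"])$p.value,
            0.01)
})

test_that("permutation correlation matches full enumeration on tiny inputs", {
  x <- c(1, 2, 3, 4, 5)
  res <- permutation_corr(x, x, enumerate_small = TRUE)
  expect_equal(res$r, 1)
  expect_equal(res$p_uncorrected, 2 / 120)  # only identity and reversal reach |r| = 1
  expect_equal(res$method, "exact_enumeration")
})

test_that("permutation correlation respects the add-one bound and determinism", {
  set.seed(11)
  x <- rnorm(30); y <- 0.9 * x + rnorm(30, 0, 0.1)
  res <- permutation_corr(x, y, n_perm = 500, seed = 1)
  expect_gte(res$p_uncorrected, 1 / 501)
  res2 <- permutation_corr(x, y, n_perm = 500, seed = 1)
  expect_identical(res$p_uncorrected, res2$p_uncorrected)
  expect_error(permutation_corr(x, rep(1, 30)), "constant")
  # p agrees with cor.test on strongly correlated normal data (both tiny)
  expect_lt(res$p_uncorrected, 0.01)
})

test_that("Benjamini-Hochberg adjustment reproduces hand-computed cases", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p12 <- c(0.007, 0.008, seq(0.28, 0.97, length.out = 10))
  adj <- bh_adjust(p12)
  expect_equal(adj[1], 0.048)
  expect_equal(adj[2], 0.048)
  # never decreases, never exceeds 1, order preserving
  set.seed(12)
  p <- runif(50)
  a <- bh_adjust(p)
  expect_true(all(a >= p - 1e-12))
  expect_true(all(a <= 1))
  expect_equal(order(a[order(p)]), seq_along(p))  # monotone in order statistics
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("joint regressions recover planted linear truth", {
  set.seed(13)
  n <- 80
  mu0 <- runif(n, 0.2, 0.8)
  b <- runif(n, 0.5, 1.5)
  fs <- cbind(dep = 2 * mu0, anx = -1.5 * b)
  res <- joint_regression_coef_diff(fs, mu0, b, n_perm = 200, seed = 1,
                                    contrasts = list(c("dep", "anx")))
  expect_equal(unname(res$regressions$dep$coefficients["mu0"]), 2, tolerance = 1e-8)
  expect_equal(unname(res$regressions$dep$coefficients["b"]), 0, tolerance = 1e-8)
  expect_equal(unname(res$regressions$anx$coefficients["b"]), -1.5, tolerance = 1e-8)
  # planted difference in the mu0 coefficient is detected
  expect_lt(res$coef_diff$dep_vs_anx$p[["mu0"]], 0.05)
  expect_error(joint_regression_coef_diff(fs, mu0, mu0 * 2, n_perm = 10),
               "rank-deficient")
})

test_that("coefficient-difference p-values are roughly uniform under the null", {
  set.seed(14)
  ps <- vapply(1:40, function(i) {
    n <- 40
    fs <- cbind(f1 = rnorm(n), f2 = rnorm(n))
    mu0 <- rnorm(n); b <- 0.5 * mu0 + rnorm(n)
    joint_regression_coef_diff(fs, mu0, b, n_perm = 120, seed = i,
                               contrasts = list(c("f1", "f2")))$coef_diff[[1]]$p[["mu0"]]
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)   # ~95% expected; binomial slack
  expect_gt(min(ps), 0)
})

test_that("bootstrap mediation handles null and full mediation", {
  set.seed(15)
  n <- 60
  x <- rnorm(n)
  m_null <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, 0.2)
  res0 <- bootstrap_mediation(x, m_null, y, n_boot = 400, seed = 1)
  expect_lt(abs(res0$acme), 0.1)
  expect_gt(res0$acme_p, 0.1)
  expect_equal(res0$total_effect, res0$acme + res0$direct_effect, tolerance = 1e-9)

  m_full <- 0.7 * x + rnorm(n, 0, 0.3)   # mediator has its own variation
  y_full <- 1.2 * m_full                 # y depends on x only through it
  res1 <- bootstrap_mediation(x, m_full, y_full, n_boot = 400, seed = 2)
  expect_equal(res1$acme, res1$total_effect, tolerance = 1e-9)
  expect_equal(res1$direct_effect, 0, tolerance = 1e-9)
})

test_that("partialing out an irrelevant mediator leaves the correlation intact", {
  set.seed(16)
  n <- 100
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.5); z <- rnorm(n)
  expect_equal(partial_corr(x, y, z), cor(x, y), tolerance = 0.05)
})

test_that("the full pipeline runs end-to-end on a small cohort", {
  co <- sample_cohort(cohort_config(n_participants = 14, seed = 17))
  self_runs <- Filter(function(tr) tr$referent == "self", co$trajectories)
  fits <- fit_cohort(self_runs, model_ids = 3, seed = 1, n_restarts = 2)
  rep <- analyze_cohort(co, fits, n_perm = 200, n_boot = 200, seed = 1)
  expect_equal(nrow(rep$correlations), 12)
  expect_true(all(rep$correlations$p_fdr >= rep$correlations$p_uncorrected - 1e-12))
  expect_true(all(c("regressions", "coef_diff") %in% names(rep$regressions)))
  path <- withr::local_tempfile(fileext = ".json")
  write_analysis_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_included, rep$n_included)
})
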