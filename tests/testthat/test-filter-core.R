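particles_of <- function(states, weights) {
  tibble::tibble(state = states, weight = weights)
}

test_that("effective sample size follows its closed form", {
  expect_equal(effective_sample_size(particles_of(runif(10), rep(0.1, 10))), 10)
  expect_equal(effective_sample_size(particles_of(runif(4), c(1, 0, 0, 0))), 1)
  expect_equal(effective_sample_size(particles_of(runif(3), c(0.5, 0.25, 0.25))),
               1 / (0.25 + 0.0625 + 0.0625))
})

test_that("posterior mean is the weighted state mean", {
  expect_equal(posterior_mean(particles_of(c(0, 1), c(0.5, 0.5))), 0.5)
  expect_equal(posterior_mean(particles_of(c(0.2, 0.8), c(0.75, 0.25))), 0.35)
  expect_equal(posterior_mean(particles_of(c(0.63, 0.2), c(1, 0))), 0.63)
})

test_that("systematic resampling has deterministic counts for a two-point set", {
  # with weights (0.75, 0.25) and Ns = 4 every offset yields counts (3, 1)
  for (s in 1:25) {
    set.seed(s)
    out <- systematic_resample(particles_of(c(0.1, 0.9), c(0.75, 0.25)), n = 4)
    expect_equal(sum(out$state == 0.1), 3)
    expect_equal(sum(out$state == 0.9), 1)
    expect_equal(out$weight, rep(0.25, 4))
  }
})

test_that("systematic resampling keeps ancestor counts within one of expectation", {
  set.seed(5)
  w <- runif(100); w <- w / sum(w)
  states <- seq_len(100) / 100
  out <- systematic_resample(particles_of(states, w))
  counts <- table(factor(out$state, levels = states))
  expect_true(all(abs(as.integer(counts) - 100 * w) < 1))
})

test_that("systematic resampling preserves the posterior mean closely", {
  set.seed(6)
  ns <- 4000
  states <- runif(ns)
  w <- exp(-(states - 0.6)^2 / 0.02); w <- w / sum(w)
  p <- particles_of(states, w)
  pme <- posterior_mean(p)
  out <- systematic_resample(p)
  expect_lt(abs(posterior_mean(out) - pme), 2 / ns)
})

test_that("convergence criterion is mean squared change with inclusive boundary", {
  expect_true(check_convergence(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), xi = 1e-9))
  prev <- rep(0.4, 5)
  expect_false(check_convergence(prev, prev + 0.1, xi = 0.005))  # MSE 0.01
  expect_true(check_convergence(prev, prev + 0.1, xi = 0.01))    # boundary
  expect_error(check_convergence(1:4 / 10, 1:5 / 10, xi = 0.1), "length")
})

test_that("weight updates reward likelihood agreement and normalize", {
  model <- cached_model()
  lik <- likelihood_config()
  # observation taken exactly on the generator curve at u = 0.6
  observed <- features_for_state(0.6, noisefree_config())
  p <- particles_of(c(0.1, 0.35, 0.6, 0.85), rep(0.25, 4))
  out <- compute_weights(p, observed, model, lik, sigma_w = 0.05)
  expect_equal(sum(out$weight), 1, tolerance = 1e-9)
  expect_equal(which.max(out$weight), 3)

  # equal discrepancy, equal prior weight -> exactly equal posterior weight
  # (identity model: predicted likelihood equals the particle state)
  obs_mid <- features_for_state(0.5, noisefree_config())
  p2 <- particles_of(c(0.45, 0.55), c(0.5, 0.5))
  out2 <- compute_weights(p2, obs_mid, identity_model(), lik, sigma_w = 0.05)
  expect_equal(out2$weight[1], out2$weight[2], tolerance = 1e-12)
})

test_that("fully degenerate weights reset to uniform with a warning", {
  model <- cached_model()
  lik <- likelihood_config()
  observed <- features_for_state(0.95, noisefree_config())
  p <- particles_of(c(0.01, 0.02, 0.03), rep(1 / 3, 3))
  expect_warning(
    out <- compute_weights(p, observed, model, lik, sigma_w = 1e-8),
    "degenerate"
  )
  expect_equal(out$weight, rep(1 / 3, 3))
})

test_that("the filter recovers a constant benign state and labels it benign", {
  traj <- make_trajectory(rep(0.30, 5))
  fit <- run_filter(traj, cached_model(), cfg = filter_config(seed = 301))
  expect_s3_class(fit, "nodule_diagnosis")
  expect_equal(as.character(fit$label), "benign")
  expect_lt(abs(fit$final_score - 0.30), 0.05)
  expect_true(all(fit$pme >= 0 & fit$pme <= 1))
  expect_true(fit$converged)
  expect_gte(fit$outer_iterations, 2)
})

test_that("a ramped malignant trajectory ends advanced-stage", {
  traj <- make_trajectory(seq(0.55, 0.85, length.out = 5))
  fit <- run_filter(traj, cached_model(), cfg = filter_config(seed = 302))
  expect_equal(as.character(fit$label), "advanced_stage")
})

test_that("identical configuration and seed give bitwise-identical diagnoses", {
  traj <- make_trajectory(c(0.2, 0.25, 0.4, 0.55, 0.62))
  cfg <- quick_filter_config(seed = 77)
  f1 <- run_filter(traj, cached_model(), cfg = cfg)
  f2 <- run_filter(traj, cached_model(), cfg = cfg)
  expect_identical(f1$pme, f2$pme)
  expect_identical(f1$ess, f2$ess)
  expect_identical(glance(f1), glance(f2))
})

test_that("filter input validation catches mismatches", {
  traj <- make_trajectory(rep(0.3, 4))
  expect_error(run_filter(traj, cached_model(), cfg = filter_config()),
               "K = 5")
  traj5 <- make_trajectory(rep(0.3, 5))
  expect_error(run_filter(traj5, cached_model(),
                          cfg = filter_config(order = 2)), "order")
})

test_that("grid posterior is self-consistent under refinement and matches the filter", {
  traj <- make_trajectory(c(0.2, 0.3, 0.45, 0.6, 0.7))
  model <- cached_model()
  g501 <- grid_posterior(traj, model, n_grid = 501)
  g2001 <- grid_posterior(traj, model, n_grid = 2001)
  expect_lt(max(abs(g501 - g2001)), 1e-3)

  fit <- run_filter(traj, model, cfg = filter_config(seed = 44))
  expect_lt(max(abs(fit$pme - g2001)), 0.02)
  expect_error(grid_posterior(traj, model, n_grid = 50), "101")
})

test_that("an uninformative update leaves the grid posterior at the prior mean", {
  traj <- make_trajectory(c(0.2, 0.3, 0.45, 0.6, 0.7))
  cfg <- filter_config(sigma_w = 1e6)
  pme <- grid_posterior(traj, cached_model(), cfg = cfg, n_grid = 501)
  expect_equal(pme, rep(0.5, 5), tolerance = 1e-6)
})

test_that("run_cohort isolates failing nodules and keeps the rest", {
  cfg0 <- noisefree_config()
  good <- make_trajectory(rep(0.3, 5), id = "good")
  bad <- make_trajectory(rep(0.3, 4), id = "bad")  # unusable length
  cohort <- dplyr::bind_rows(good, bad)
  res <- run_cohort(cohort, cached_model(), cfg = quick_filter_config(seed = 5))
  expect_equal(res$nodule_id, "good")
  fails <- attr(res, "failures")
  expect_equal(fails$nodule_id, "bad")
  expect_match(fails$error, "3 annual readings|K = 5")
})

test_that("filter configuration validates its fields", {
  expect_error(filter_config(n_particles = 1), "n_particles")
  expect_error(filter_config(sigma_w = 0), "sigma_w")
  expect_error(filter_config(ess_fraction = 0), "ess_fraction")
  expect_error(filter_config(xi = -1), "xi")
})
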