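test_that("destroyed droplets below the robust cut are removed", {
  set.seed(42)
  amps <- c(rnorm(1000, 2000, 100), rep(0, 5))
  res <- filter_low_droplets(amps, calling_config())
  # oracle: direct median/MAD computation on the same sample
  lower <- amps[amps <= median(amps)]
  cut <- median(lower) - 5 * mad(lower)
  expect_identical(res$removed_idx, which(amps < cut))
  expect_identical(sort(c(res$retained_idx, res$removed_idx)), seq_along(amps))
  expect_true(all(res$removed_idx > 1000))
  expect_length(res$removed_idx, 5L)
})

test_that("filtering is the identity when nothing is below the cut", {
  set.seed(7)
  amps <- rnorm(500, 2000, 100)
  res <- filter_low_droplets(amps, calling_config())
  expect_length(res$removed_idx, 0L)
  expect_identical(res$retained_idx, seq_along(amps))
})

test_that("constant amplitudes are flagged zero_spread, nothing removed", {
  res <- filter_low_droplets(rep(2000, 100), calling_config())
  expect_true("zero_spread" %in% res$qc_flags)
  expect_length(res$removed_idx, 0L)
  expect_error(filter_low_droplets(numeric(0), calling_config()))
})

test_that("BIC selects one component for a single Gaussian cloud", {
  set.seed(3)
  a <- rnorm(5000, 2000, 120)
  fit <- fit_amplitude_mixture(a, fast_config())
  expect_equal(fit$n_components, 1L)
  # MLE oracle for the single component
  expect_equal(fit$means, mean(a), tolerance = 1e-6)
  expect_equal(fit$sds, sd(a), tolerance = 1e-2)
})

test_that("two well-separated clouds recover component parameters", {
  tc <- two_cloud(4000, 1000, seed = 5)  # separation 50 negative sds
  fit <- fit_amplitude_mixture(tc$amps, fast_config())
  expect_equal(fit$n_components, 2L)
  expect_lt(abs(fit$means[1] - 2000) / 2000, 0.02)
  expect_lt(abs(fit$means[2] - 8000) / 8000, 0.02)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$means) > 0))
  expect_true(all(fit$sds > 0))
})

test_that("mixture fit refuses fewer droplets than min_droplets", {
  expect_error(fit_amplitude_mixture(rnorm(100, 2000, 100), calling_config()),
               "min_droplets")
})

test_that("single-component threshold is mean + k_sd * sd", {
  fit <- structure(list(n_components = 1L, weights = 1, means = 2000,
                        sds = 100, bic = 0, model_name = "X", converged = TRUE),
                   class = "mixture_fit")
  thr <- select_threshold(fit, rnorm(1000, 2000, 100), calling_config(k_sd = 5))
  expect_equal(thr, 2500)
})

test_that("two-component thresholds separate well-separated clouds perfectly", {
  tc <- two_cloud(9000, 1000, seed = 9)
  cfg <- fast_config()
  fit <- fit_amplitude_mixture(tc$amps, cfg)
  thr <- select_threshold(fit, tc$amps, cfg)
  expect_gt(thr, fit$means[1])
  expect_lt(thr, fit$means[2])
  # brute-force check against the generating membership
  expect_identical(classify_droplets(tc$amps, thr), tc$truth)
})

test_that("mean_plus_k_sd threshold is shift-equivariant", {
  tc <- two_cloud(4500, 500, seed = 13)
  cfg <- fast_config()
  t0 <- select_threshold(fit_amplitude_mixture(tc$amps, cfg), tc$amps, cfg)
  t1 <- select_threshold(fit_amplitude_mixture(tc$amps + 500, cfg),
                         tc$amps + 500, cfg)
  expect_equal(t1, t0 + 500, tolerance = 1e-6)
  expect_identical(classify_droplets(tc$amps, t0),
                   classify_droplets(tc$amps + 500, t1))
})

test_that("classification is strict: ties at the threshold go negative", {
  expect_identical(classify_droplets(c(1, 2, 3), 2),
                   c("negative", "negative", "positive"))
  expect_true(all(classify_droplets(c(1, 2, 3), 10) == "negative"))
  expect_true(all(classify_droplets(c(1, 2, 3), 0) == "positive"))
  expect_error(classify_droplets(1:3, NA_real_))
})

test_that("positive counts are monotone non-increasing in the threshold", {
  set.seed(21)
  a <- c(rnorm(300, 2000, 120), rnorm(60, 8000, 180))
  n_pos <- vapply(seq(1000, 9000, by = 250),
                  function(t) sum(classify_droplets(a, t) == "positive"), 0L)
  expect_true(all(diff(n_pos) <= 0))
})

test_that("call_well recovers simulation truth within binomial error", {
  sim <- simulate_well(sim_well_config(n_droplets = 15000, lambda_ch1 = 0.1,
                                       lambda_ch2 = NULL, seed = 31))
  call <- call_well(sim$well, calling_config())
  p <- 1 - exp(-0.1)
  expect_lt(abs(call$channels$ch1$n_positive - sim$truth$true_positive_ch1), 1)
  expect_lt(abs(call$channels$ch1$n_positive - 15000 * p),
            3 * sqrt(15000 * p * (1 - p)))
  expect_equal(call$channels$ch1$n_positive,
               sum(call$channels$ch1$labels == "positive", na.rm = TRUE))
})

test_that("an NTC well yields zero positives", {
  sim <- simulate_well(sim_well_config(n_droplets = 10000, lambda_ch1 = 0,
                                       lambda_ch2 = NULL, seed = 33))
  call <- call_well(sim$well, calling_config())
  expect_equal(call$channels$ch1$n_positive, 0L)
  expect_equal(call$channels$ch1$fit$n_components, 1L)
})

test_that("wells below the droplet floor are flagged, never dropped", {
  w <- droplet_well("A05", rnorm(50, 2000, 100))
  call <- call_well(w, calling_config(min_droplets = 1000))
  expect_true("low_droplet_count" %in% call$qc_flags)
  expect_true(is.na(call$channels$ch1$threshold))
  expect_true(is.na(call$channels$ch1$n_positive))
  expect_equal(call$channels$ch1$n_total_retained, 50L)
})

test_that("calling is deterministic and permutation-invariant", {
  sim <- simulate_well(sim_well_config(n_droplets = 6000, lambda_ch2 = NULL,
                                       seed = 37))
  cfg <- fast_config()
  c1 <- call_well(sim$well, cfg)
  c2 <- call_well(sim$well, cfg)
  expect_identical(c1, c2)
  set.seed(99)
  perm <- sample(sim$well$n_droplets)
  wp <- droplet_well(sim$well$well_id, sim$well$ch1_amplitude[perm])
  cp <- call_well(wp, cfg)
  expect_equal(cp$channels$ch1$threshold, c1$channels$ch1$threshold,
               tolerance = 1e-8)
  expect_identical(cp$channels$ch1$labels, c1$channels$ch1$labels[perm])
})

test_that("manual override relabels retained droplets and marks the source", {
  sim <- simulate_well(sim_well_config(n_droplets = 6000, lambda_ch1 = 0.1,
                                       lambda_ch2 = NULL,
                                       destroyed_fraction = 0.001, seed = 41))
  cfg <- fast_config()
  call <- call_well(sim$well, cfg)
  auto_thr <- call$channels$ch1$threshold
  n_removed <- sum(call$channels$ch1$labels == "removed_low", na.rm = TRUE)

  low <- override_threshold(call, "ch1", min(sim$well$ch1_amplitude) - 1)
  expect_identical(low$channels$ch1$threshold_source, "manual")
  expect_equal(low$channels$ch1$n_positive,
               sim$well$n_droplets - n_removed)
  expect_equal(sum(low$channels$ch1$labels == "removed_low", na.rm = TRUE),
               n_removed)

  same <- override_threshold(call, 1, auto_thr)
  expect_identical(same$channels$ch1$labels, call$channels$ch1$labels)
  expect_identical(same$channels$ch1$threshold_source, "manual")

  expect_error(override_threshold(call, "ch2", 5000), "not present")
})
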