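test_that("an NTC config yields only negative-cloud droplets", {
  sim <- simulate_well(sim_well_config(n_droplets = 2000, lambda_ch1 = 0,
                                       lambda_ch2 = 0, seed = 1))
  expect_equal(sim$truth$true_positive_ch1, 0L)
  expect_equal(sim$truth$true_positive_ch2, 0L)
  expect_true(all(abs(sim$well$ch1_amplitude - 2000) < 120 * 6))
})

test_that("true positive counts follow the binomial occupancy oracle", {
  p <- 1 - exp(-0.1)
  for (seed in 1:5) {
    sim <- simulate_well(sim_well_config(n_droplets = 20000, lambda_ch1 = 0.1,
                                         lambda_ch2 = NULL, seed = seed))
    expect_lt(abs(sim$truth$true_positive_ch1 - 20000 * p),
              3 * sqrt(20000 * p * (1 - p)))
    expect_equal(sim$truth$true_positive_ch1, sum(sim$truth$occupied_ch1))
  }
})

test_that("the same seed reproduces the well bit for bit", {
  cfg <- sim_well_config(n_droplets = 3000, rain_fraction = 0.05,
                         destroyed_fraction = 0.01, baseline_shift = 120,
                         seed = 77)
  s1 <- simulate_well(cfg)
  s2 <- simulate_well(cfg)
  expect_identical(s1$well$ch1_amplitude, s2$well$ch1_amplitude)
  expect_identical(s1$well$ch2_amplitude, s2$well$ch2_amplitude)
  expect_identical(s1$truth$occupied_ch1, s2$truth$occupied_ch1)
})

test_that("failure modes land where configured", {
  cfg <- sim_well_config(n_droplets = 5000, lambda_ch1 = 0.5,
                         destroyed_fraction = 0.01, baseline_shift = 300,
                         seed = 5)
  sim <- simulate_well(cfg)
  destroyed <- sim$truth$destroyed_idx
  expect_gt(length(destroyed), 0)
  # destroyed droplets sit near zero (plus the baseline shift), both channels
  expect_true(all(sim$well$ch1_amplitude[destroyed] <= 100 + 300))
  expect_true(all(sim$well$ch2_amplitude[destroyed] <= 100 + 300))
  # baseline shift moves the negative cloud
  neg <- !sim$truth$occupied_ch1 & !(seq_len(5000) %in% destroyed)
  expect_equal(mean(sim$well$ch1_amplitude[neg]), 2300, tolerance = 0.01)
})

test_that("rain amplitudes fall between the cloud means", {
  cfg <- sim_well_config(n_droplets = 10000, lambda_ch1 = 0.5,
                         lambda_ch2 = NULL, rain_fraction = 0.2, seed = 9)
  sim <- simulate_well(cfg)
  occ <- sim$well$ch1_amplitude[sim$truth$occupied_ch1]
  in_gap <- occ > 2600 & occ < 7000
  expect_gt(sum(in_gap), 0.1 * length(occ) * 0.5)  # rain is present
  expect_true(all(occ[in_gap] >= 2000 & occ[in_gap] <= 8000))
})

test_that("simulated plates round-trip through the readers", {
  d <- tempfile("plate"); dir.create(d)
  cfgs <- list(A01 = sim_well_config(n_droplets = 500, seed = 1),
               B01 = sim_well_config(n_droplets = 500, lambda_ch1 = 0.3, seed = 2),
               H05 = sim_well_config(n_droplets = 500, lambda_ch1 = 0,
                                     lambda_ch2 = 0, seed = 3))
  sp <- simulate_plate(cfgs, d)
  expect_length(sp$amplitude_files, 3L)
  expect_equal(nrow(read_sample_sheet(sp$sample_sheet)), 3L)
  expect_equal(nrow(sp$truth), 6L)  # 3 wells x 2 channels
  expect_equal(sp$truth$true_positive_count[sp$truth$well_id == "H05"], c(0L, 0L))
  for (id in names(cfgs)) {
    f <- sp$amplitude_files[grepl(paste0("_", id, "_"), sp$amplitude_files)]
    w <- expect_silent(read_amplitude_file(f))
    sim <- simulate_well(cfgs[[id]], well_id = id)
    expect_identical(w$well_id, id)
    expect_equal(w$ch1_amplitude, sim$well$ch1_amplitude, tolerance = 1e-10)
    expect_equal(w$ch2_amplitude, sim$well$ch2_amplitude, tolerance = 1e-10)
  }
})

test_that("plate simulation validates well ids", {
  expect_error(simulate_plate(list(sim_well_config()), tempfile()), "named")
  expect_error(simulate_plate(list(Z99 = sim_well_config()), tempfile()),
               "invalid plate well")
})

test_that("caller plus quantifier recover true lambda across seeded wells", {
  # separation >= 10 sd, no rain: lambda within 3 binomial SEs in >= 95%
  n <- 10000
  hits <- 0L
  n_wells <- 30L
  for (seed in seq_len(n_wells)) {
    sim <- simulate_well(sim_well_config(n_droplets = n, lambda_ch1 = 0.1,
                                         lambda_ch2 = NULL, seed = 1000 + seed))
    call <- call_well(sim$well, calling_config())
    lam <- estimate_lambda(call$channels$ch1$n_positive,
                           call$channels$ch1$n_total_retained)
    p <- 1 - exp(-0.1)
    se_lam <- sqrt(p / ((1 - p) * n))
    hits <- hits + (abs(lam - 0.1) <= 3 * se_lam)
  }
  expect_gte(hits / n_wells, 0.95)
})
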