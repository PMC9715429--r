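test_that("forcing curve has a glacial plateau, warming sign and zero 0-2 ka mean", {
  f <- make_forcing()
  plateau <- f$anomaly[f$ages >= 17 & f$ages <= 23]
  expect_lt(diff(range(plateau)), 1e-12)
  expect_lt(forcing_at(f, 20), forcing_at(f, 5))
  expect_lt(abs(mean(f$anomaly[f$ages <= 2])), 1e-9)
  # monotone warming across the deglaciation
  ramp <- forcing_at(f, seq(11, 17, 0.5))
  expect_true(all(diff(ramp) <= 0))
  expect_error(make_forcing(deglaciation = c(17, 11)), "interval")
})

test_that("local SST is additive in scale and event offset", {
  f <- make_forcing()
  site <- synthetic_sites(n_sites = 2)[[1]]
  site$glacial_cooling_scale <- 0
  site$heinrich_event <- NULL
  expect_equal(local_sst(site, f, c(0, 12, 20)), rep(site$modern_sst, 3))
  site$heinrich_event <- list(t_start = 15, t_end = 17, delta_T = -4)
  expect_equal(local_sst(site, f, 16), site$modern_sst - 4)
  # doubling the scale doubles the glacial-Holocene contrast
  s1 <- site; s1$heinrich_event <- NULL; s1$glacial_cooling_scale <- 1
  s2 <- s1; s2$glacial_cooling_scale <- 2
  c1 <- local_sst(s1, f, 1) - local_sst(s1, f, 20)
  c2 <- local_sst(s2, f, 1) - local_sst(s2, f, 20)
  expect_equal(c2, 2 * c1)
  expect_error(local_sst(site, f, 30), "outside")
})

test_that("expected proportions follow the Gaussian niche model", {
  n1 <- data.frame(name = "a", optimum = 20, tolerance = 2, amplitude = 1,
                   secondary_sensitivity = 0)
  expect_equal(unname(expected_proportions(n1, 15)), 1)
  n2 <- rbind(n1, n1); n2$name <- c("a", "b")
  expect_equal(unname(expected_proportions(n2, 10)), c(0.5, 0.5))
  # a species at its optimum dominates a distant one by exp(0)/exp(-50)
  n3 <- data.frame(name = c("warm", "cold"), optimum = c(25, 5),
                   tolerance = 2, amplitude = 1, secondary_sensitivity = 0)
  p <- expected_proportions(n3, 25)
  expect_equal(unname(p["warm"] / p["cold"]), exp(0) / exp(-50), tolerance = 1e-9)
  expect_error(expected_proportions(n1, 1e6), "degenerate environment")
  # proportions sum to one for the default niches across the SST range
  niches <- synthetic_niches()
  for (sst in c(-5, 0, 10, 25, 30)) {
    expect_equal(sum(expected_proportions(niches, sst)), 1)
  }
})

test_that("simulated censuses are deterministic multinomials around the niche expectation", {
  f <- make_forcing()
  niches <- synthetic_niches()
  site <- synthetic_sites()[[10]]
  a <- simulate_series(site, niches, f, seed = 11)
  b <- simulate_series(site, niches, f, seed = 11)
  expect_identical(a, b)
  expect_true(all(rowSums(abundance_matrix(a)) == site$count_depth))
  # law of large numbers: at depth 1e7 empirical proportions match expectation
  site$sampling_ages <- 5
  site$count_depth <- 1e7
  big <- simulate_series(site, niches, f, seed = 3)
  p_hat <- to_relative_abundance(abundance_matrix(big))[1, ]
  p_exp <- expected_proportions(niches, local_sst(site, f, 5))
  expect_lt(max(abs(p_hat - p_exp)), 1e-2)
})

test_that("constant forcing yields near-zero compositional turnover", {
  # sampling noise only: first-to-last M-H below 0.05 at depth 10,000
  f <- make_forcing(glacial = 0, holocene = 0)
  niches <- synthetic_niches()
  site <- synthetic_sites()[[12]]
  site$heinrich_event <- NULL
  site$count_depth <- 10000
  x <- simulate_series(site, niches, f, seed = 5)
  ab <- abundance_matrix(x)
  expect_lt(morisita_horn(ab[1, ], ab[nrow(ab), ]), 0.05)
})

test_that("simulate_dataset returns the full study layout plus truth", {
  ds <- simulate_dataset(synthetic_config(), seed = 2)
  expect_equal(length(unique(ds$samples$site_id)), 25)
  expect_equal(nrow(ds$samples), 25 * 41)
  expect_s3_class(ds$reference, "reference_set")
  expect_true(all(ds$reference$samples$age_ka >= 19 &
                  ds$reference$samples$age_ka <= 23))
  expect_true(all(is.na(ds$truth$no_analogue_onset)))
  # expected proportions in the truth record sum to 1 everywhere
  sums <- unlist(lapply(ds$truth$expected_proportions, rowSums))
  expect_equal(unname(sums), rep(1, length(sums)))
  expect_error(simulate_dataset(synthetic_config(n_sites = 1)), "2 sites")
})

test_that("the secondary driver is recorded as truth onsets at mid-latitude sites", {
  cfg <- synthetic_config(secondary_driver = TRUE)
  ds <- simulate_dataset(cfg, seed = 2)
  onset <- ds$truth$no_analogue_onset
  lats <- vapply(ds$truth$sites, `[[`, numeric(1), "latitude")
  affected <- lats >= 30 & lats <= 50
  expect_true(all(onset[affected] == 11))
  expect_true(all(is.na(onset[!affected])))
})

test_that("richness-ramp series impose the requested linear trend", {
  rr <- simulate_richness_ramp(0.4, seed = 9)
  gl <- gains_losses_series(rr)
  fit <- lm(richness ~ I(-age_ka), data = gl)
  expect_lt(abs(coef(fit)[2] - 0.4), 3 * summary(fit)$coef[2, 2] + 1e-9)
})
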