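test_that("simulated counts follow the configured Poisson means", {
  # single focal species at the calibrated rates, many visits for tight MC error
  pool <- data.frame(species = "WEBL", guild = "I", lambda = 0.18,
                     multiplier = 10)
  cfg <- sim_config(n_sites = 1, points_per_area = 20, visits_per_period = 6,
                    species = pool, seed = 101)
  pc <- simulate_pointcounts(cfg)
  n_int <- 20 * 18 * 6  # points x visits x intervals per area
  mean_box <- sum(pc$count[pc$area == "nestbox"]) / n_int
  mean_ctl <- sum(pc$count[pc$area == "control"]) / n_int
  # Poisson mean lambda * multiplier = 1.8 (box) and 0.18 (control);
  # 3 MC sigma = 3 * sqrt(mu / n_int)
  expect_lt(abs(mean_box - 1.8), 3 * sqrt(1.8 / n_int))
  expect_lt(abs(mean_ctl - 0.18), 3 * sqrt(0.18 / n_int))
  # variance matches the Poisson law (nest-box interval cells, incl. zeros)
  xb <- pc$count[pc$area == "nestbox"]
  ivar <- (sum(xb^2) - sum(xb)^2 / n_int) / (n_int - 1)
  expect_lt(abs(ivar / 1.8 - 1), 0.2)
})

test_that("unit multipliers imply no expected treatment difference", {
  pool <- default_species_pool()
  pool$multiplier <- 1
  cfg <- sim_config(species = pool, seed = 55)
  pc <- simulate_pointcounts(cfg)
  tot <- tapply(pc$count, pc$area, sum)
  expect_lt(abs(tot["nestbox"] - tot["control"]) /
              sqrt(tot["nestbox"] + tot["control"]), 4)
})

test_that("simulation is deterministic: same seed, byte-identical CSV", {
  cfg <- sim_config(seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pointcounts(simulate_pointcounts(cfg), f1)
  write_pointcounts(simulate_pointcounts(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  write_sentinel(simulate_sentinel(cfg), f1)
  write_sentinel(simulate_sentinel(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the draw
  expect_false(identical(
    simulate_pointcounts(cfg),
    simulate_pointcounts(sim_config(seed = 78))))
})

test_that("sentinel outcomes follow the binomial law of the configured logits", {
  # boundary: removal probability ~ 1 -> every station removed
  cfg1 <- sim_config(seed = 5, sentinel = list(
    beta = c(control = 20, nestbox_random = 0, active_nest = 0), sigma_b = 0))
  expect_true(all(simulate_sentinel(cfg1)$removed == 5))

  # p = 0.5, sigma_b = 0, many transects: mean removed -> 2.5
  cfg2 <- sim_config(seed = 6, sentinel = list(
    beta = c(control = 0, nestbox_random = 0, active_nest = 0),
    sigma_b = 0, transects_per_group = 400, active_per_site = c(400, 400)))
  tr <- simulate_sentinel(cfg2)
  n_tr <- nrow(tr)
  expect_lt(abs(mean(tr$removed) - 2.5), 3 * sqrt(5 * 0.25 / n_tr))
  # binomial variance of removed counts
  expect_lt(abs(var(tr$removed) / (5 * 0.25) - 1), 0.15)
})

test_that("default sentinel rates reproduce the calibrated group means", {
  # inverse-logit of the default coefficients at sigma_b = 0
  cfg <- sim_config(seed = 8, sentinel = list(
    sigma_b = 0, transects_per_group = 500, active_per_site = c(500, 500)))
  b <- cfg$sentinel$beta
  expect_equal(5 * plogis(b[["control"]]), 1.2, tolerance = 1e-12)
  expect_equal(5 * plogis(b[["control"]] + b[["nestbox_random"]]), 2.9,
               tolerance = 1e-12)
  expect_equal(5 * plogis(b[["control"]] + b[["active_nest"]]), 4.14,
               tolerance = 1e-12)
  tr <- simulate_sentinel(cfg)
  mns <- tapply(tr$removed, tr$group, mean)
  ns <- table(tr$group)
  for (g in names(mns)) {
    p <- plogis(b[["control"]] + if (g == "control") 0 else b[[g]])
    expect_lt(abs(mns[[g]] - 5 * p), 3 * sqrt(5 * p * (1 - p) / ns[[g]]))
  }
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(), "seed")
  pool <- default_species_pool(); pool$lambda[1] <- -1
  expect_error(sim_config(species = pool, seed = 1), ">= 0")
  expect_error(sim_config(seed = 1, sentinel = list(sigma_b = -0.1)),
               "sigma_b")
})

test_that("YAML configs round-trip into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_sites: 1", "points_per_area: 3", "seed: 9",
               "sentinel:", "  sigma_b: 0.5"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_sites, 1)
  expect_equal(cfg$points_per_area, 3)
  expect_equal(cfg$sentinel$sigma_b, 0.5)
  expect_equal(cfg$seed, 9L)
  cfg2 <- read_sim_config(path, seed = 12)
  expect_equal(cfg2$seed, 12L)
})
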