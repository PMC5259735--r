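# Synthetic-data generator: determinism, noise structure, defaults.

test_that("the parameter library carries the reference estimates", {
  lib <- default_parameter_library()
  expect_equal(lib$growth$TRL$params$large[["Cm"]], 149.52)
  expect_equal(lib$growth$TRL$se$large[["Cm"]], 6.89)
  expect_equal(lib$growth$CDW$params$small[["Max"]], 0.121)
  expect_equal(lib$growth$SDLDW$params$small[["Wf"]], 0.19)
  w <- lib$seed_traits[lib$seed_traits$trait == "weight", ]
  expect_equal(w$mean[w$line == "G19833"], 0.55)
  expect_equal(w$mean[w$line == "G23419"], 0.10)
  # standard deviation implied by an SE of 0.01 at n = 30
  expect_equal(0.01 * sqrt(30), 0.0548, tolerance = 1e-3)
})

test_that("simulation is reproducible and honors the noise-free limit", {
  cfg <- sim_config("TRL", plants_per_line = 3, seed = 99)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
  d2 <- simulate_trajectories(sim_config("TRL", plants_per_line = 3,
                                         seed = 100))
  expect_false(identical(simulate_trajectories(cfg)$value, d2$value))

  quiet <- simulate_trajectories(sim_config("TRL", plants_per_line = 2,
                                            sigma = 1e-9, seed = 1))
  truth <- default_parameter_library()$growth$TRL$params
  lv <- grouping_scheme("MAPHE")$level_of[quiet$line_id]
  mu <- ifelse(lv == "large",
               expolinear(quiet$day, 149.52, 0.92, 6.22),
               expolinear(quiet$day, 84.86, 0.65, 6.14))
  expect_equal(quiet$value, unname(mu), tolerance = 1e-6)
})

test_that("simulated residuals carry the configured AR1 correlation", {
  cfg <- sim_config("TRL", plants_per_line = 500, rho = 0.5, seed = 12)
  d <- simulate_trajectories(cfg)       # 2000 plants
  truth <- default_parameter_library()$growth$TRL$params
  lv <- grouping_scheme("MAPHE")$level_of[d$line_id]
  mu <- ifelse(lv == "large",
               expolinear(d$day, 149.52, 0.92, 6.22),
               expolinear(d$day, 84.86, 0.65, 6.14))
  sd_day <- growsel:::config_noise_sd(cfg)[as.character(d$day)]
  z <- (d$value - mu) / sd_day
  Z <- matrix(z[order(d$plant_id, d$day)], nrow = length(cfg$days))
  lag1 <- cor(as.vector(Z[-nrow(Z), ]), as.vector(Z[-1, ]))
  expect_lt(abs(lag1 - 0.5), 0.03)
  # marginal standardized variance is ~1 by construction
  expect_equal(sd(as.vector(Z)), 1, tolerance = 0.05)
})

test_that("destructive harvests honor the per-stratum variance ratios", {
  ratios <- c(`0` = 1, `2` = 1.5, `4` = 2, `6` = 1.2, `8` = 0.8,
              `10` = 1, `12` = 0.6)
  cfg <- sim_config("CDW", plants_per_line = 250, ratios = ratios,
                    seed = 13)
  d <- simulate_destructive(cfg)        # 1000 plants per harvest day
  truth <- default_parameter_library()$growth$CDW$params
  lv <- grouping_scheme("MAPHE")$level_of[d$line_id]
  mu <- ifelse(lv == "large",
               decay_curve(d$day, 0.436, 0.058, 6.012),
               decay_curve(d$day, 0.121, 0.011, 2.727))
  res <- d$value - mu
  sds <- tapply(res, d$day, sd)
  rel <- sds / sds[["0"]]
  expect_equal(as.numeric(rel), as.numeric(ratios), tolerance = 0.1,
               ignore_attr = TRUE)
  # each plant appears exactly once
  expect_equal(anyDuplicated(d$plant_id), 0L)
})

test_that("destructive defaults match the decay design", {
  cfg1 <- sim_config("CDW", plants_per_line = 1, seed = 14)
  expect_equal(cfg1$days, seq(0, 12, 2))   # day-0 first harvest
  d <- simulate_destructive(cfg1)
  # one plant per harvest day and line
  expect_equal(nrow(d), 7 * 4)
  # large-seed day-12 mean is near the decayed plateau
  cfg <- sim_config("CDW", plants_per_line = 300, seed = 15)
  d <- simulate_destructive(cfg)
  m12 <- mean(d$value[d$day == 12 &
                        d$line_id %in% c("G19833", "G19833xG23419")])
  expect_equal(m12, 0.0589, tolerance = 0.01)
})

test_that("negative-value truncation is opt-in and counted", {
  cfg <- sim_config("TRL", plants_per_line = 50, cv = 0.4,
                    truncate_negative = TRUE, seed = 16)
  expect_message(d <- simulate_trajectories(cfg), "truncated")
  expect_gte(attr(d, "n_truncated"), 1)
  expect_true(all(d$value >= 0))
})

test_that("seed-descriptor simulation draws from the library", {
  s <- simulate_seed_traits(n = 30, seed = 17)
  expect_setequal(unique(s$line), bean_lines()$line_id)
  m <- mean(s$value[s$line == "G19833"])
  expect_lt(abs(m - 0.55), 3 * 0.01)   # sample mean within 3 SE of 0.55
  expect_identical(s, simulate_seed_traits(n = 30, seed = 17))
  expect_error(simulate_seed_traits("nope", n = 5), "unknown line")
  expect_error(simulate_seed_traits(n = 1), "n >= 2")
})

test_that("config validation catches bad designs", {
  expect_error(sim_config("TRL", rho = 1.5), "rho")
  expect_error(sim_config("XYZ"), "family")
  expect_error(sim_config("TRL", truth_scheme = "GEN4"), "truth_params")
})
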