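# Maximum-likelihood GNLS fitting.

make_sim <- function(trait = "TRL", n = 8, seed = 1, ...) {
  simulate_trajectories(sim_config(trait, plants_per_line = n, seed = seed,
                                   ...))
}

test_that("noise-free data recover the generating parameters", {
  d <- simulate_trajectories(sim_config("TRL", plants_per_line = 4,
                                        rho = 0, sigma = 1e-6, seed = 2))
  f <- fit_growth(d, "expolinear", grouping_scheme("MAPHE"),
                  correlation = "independent", variance = "constant")
  truth <- default_parameter_library()$growth$TRL$params
  for (lv in c("large", "small")) for (pn in c("Cm", "Rm", "tb")) {
    est <- f$coefficients[[paste(pn, lv, sep = ".")]]
    expect_equal(est, truth[[lv]][[pn]], tolerance = 1e-3)
  }
  expect_true(f$converged)
})

test_that("self-starting values are sensible for all three families", {
  # expolinear: noiseless curve -> Cm start within 25% of truth
  d <- simulate_trajectories(sim_config("TRL", plants_per_line = 3, rho = 0,
                                        sigma = 1e-9, seed = 3))
  sv <- initial_values("expolinear", d, grouping_scheme("MAPHE"))
  expect_lt(abs(sv$large[["Cm"]] - 149.52) / 149.52, 0.25)
  expect_lt(abs(sv$small[["Cm"]] - 84.86) / 84.86, 0.25)

  # gompertz on constant response -> Wf near that constant
  dc <- data.frame(plant_id = rep(paste0("p", 1:2), each = 4),
                   line_id = "G19833", day = rep(c(2, 4, 6, 8), 2),
                   value = 7)
  sv <- initial_values("gompertz", dc, grouping_scheme("UNI"))
  expect_equal(sv$all[["Wf"]], 7 * 1.05, tolerance = 1e-8)

  # decay with flat tail -> Min near the tail mean
  dd <- simulate_destructive(sim_config("CDW", plants_per_line = 5,
                                        sigma = 1e-9, seed = 4))
  sv <- initial_values("decay", dd, grouping_scheme("MAPHE"))
  expect_equal(sv$large[["Min"]], 0.058, tolerance = 0.02)

  # too few observations in a level is an input error
  expect_error(initial_values("expolinear", dc[1, ], grouping_scheme("UNI")),
               "fewer than 3")
})

test_that("degenerate designs are rejected", {
  d <- make_sim(n = 3, seed = 5)
  one_day <- d[d$day == 4, ]
  expect_error(fit_growth(one_day, "expolinear", "MAPHE",
                          correlation = "independent"),
               "single measurement day")
  # AR1 demands repeated measurements on some plant
  dd <- simulate_destructive(sim_config("CDW", plants_per_line = 4, seed = 6))
  expect_error(fit_growth(dd, "decay", "MAPHE", correlation = "AR1",
                          variance = "varIdent"),
               "repeated")
})

test_that("profiled sigma agrees with joint optimization", {
  d <- make_sim(n = 6, seed = 7)
  f1 <- fit_growth(d, "expolinear", "MAPHE",
                   control = growth_control(profile_sigma = TRUE))
  f2 <- fit_growth(d, "expolinear", "MAPHE",
                   control = growth_control(profile_sigma = FALSE))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-5)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-3)
})

test_that("fit agrees with the reference GNLS implementation in nlme", {
  d <- make_sim(n = 10, seed = 8)
  f <- fit_growth(d, "expolinear", "MAPHE")
  d$lev <- factor(grouping_scheme("MAPHE")$level_of[d$line_id],
                  levels = c("large", "small"))
  g <- nlme::gnls(
    value ~ (Cm / Rm) * log(1 + exp(Rm * (day - tb))), data = d,
    params = list(Cm ~ lev - 1, Rm ~ lev - 1, tb ~ lev - 1),
    start = list(Cm = c(150, 85), Rm = c(0.9, 0.65), tb = c(6.2, 6.1)),
    correlation = nlme::corAR1(form = ~ 1 | plant_id),
    weights = nlme::varExp(form = ~ day))
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
  expect_equal(unname(f$coefficients[c("Cm.large", "Cm.small")]),
               unname(coef(g)[c("Cm.levlarge", "Cm.levsmall")]),
               tolerance = 1e-4)
  # asymptotic SEs agree with the reference to a few percent
  se_g <- summary(g)$tTable[, "Std.Error"]
  expect_equal(unname(f$se["Cm.large"]), unname(se_g["Cm.levlarge"]),
               tolerance = 0.05)
})

test_that("warm starts enforce likelihood nesting across schemes", {
  d <- make_sim(n = 6, seed = 9)
  uni <- fit_growth(d, "expolinear", "UNI")
  fits <- list(UNI = uni)
  for (nm in c("MAPHE", "MAHY", "GEN3")) {
    sch <- grouping_scheme(nm)
    fits[[nm]] <- fit_growth(d, "expolinear", sch,
                             start = expand_start(uni, sch))
    expect_gte(fits[[nm]]$logLik, uni$logLik - 1e-6)
  }
  best_coarse <- fits[[which.max(vapply(fits, `[[`, 0, "logLik"))]]
  gen4 <- fit_growth(d, "expolinear", grouping_scheme("GEN4"),
                     start = expand_start(best_coarse,
                                          grouping_scheme("GEN4")))
  for (f in fits) expect_gte(gen4$logLik, f$logLik - 1e-6)
})

test_that("fit results satisfy their structural invariants", {
  d <- make_sim(n = 6, seed = 10)
  f <- fit_growth(d, "expolinear", "MAPHE")
  expect_equal(f$df, param_count(grouping_scheme("MAPHE"), "expolinear", 3))
  expect_true(all(f$se >= 0))
  expect_true(all(f$ci[, "ll95"] <= f$coefficients))
  expect_true(all(f$ci[, "ul95"] >= f$coefficients))
  expect_equal(f$n_obs, nrow(d))
  # reported logLik is reproducible through the exported likelihood
  spec <- cov_spec("AR1", rho = f$rho, variance = "varExp", delta = f$delta,
                   sigma = f$sigma)
  expect_equal(gnls_loglik(d, "expolinear", grouping_scheme("MAPHE"),
                           f$mean_params, spec),
               f$logLik, tolerance = 1e-8)
  # confint at other levels brackets more tightly
  ci90 <- confint(f, level = 0.90)
  expect_true(all(ci90[, 1] >= f$ci[, "ll95"]))
})

test_that("a decay fit with per-harvest variance honors the df bookkeeping", {
  d <- simulate_destructive(sim_config("CDW", plants_per_line = 6, seed = 11))
  f <- fit_growth(d, "decay", "MAPHE", correlation = "independent",
                  variance = "varIdent")
  expect_equal(f$df, 13)  # 2 levels x 3 + sigma + 6 harvest ratios
  expect_true(f$converged)
  expect_equal(f$coefficients[["Max.large"]], 0.436, tolerance = 0.05)
})
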