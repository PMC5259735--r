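# AICc, Akaike weights, evidence ratios and the selection table.

test_that("aicc formula and limits", {
  expect_equal(aicc(-469.8, 9, 110), 959.4, tolerance = 1e-10)
  # large-n limit approaches plain AIC
  expect_equal(aicc(-10, 3, 1e9), 26.0, tolerance = 1e-6)
  # correction undefined at n <= k + 1
  expect_error(aicc(0, 1, 2), "undefined")
  # AICc always exceeds AIC by a positive correction
  expect_gt(aicc(-50, 4, 30), -2 * (-50) + 2 * 4)
  # monotone decreasing in n at fixed logL, k
  ns <- c(20, 50, 200, 1e5)
  expect_true(all(diff(vapply(ns, function(n) aicc(-50, 4, n), 0)) < 0))
})

test_that("akaike weights reproduce the published two-decimal values", {
  w_trl <- akaike_weights(c(0, 1.8, 38.8, 42.6, 53.5))
  expect_equal(round(w_trl[1:2], 2), c(0.71, 0.29), ignore_attr = TRUE)
  w_fork <- akaike_weights(c(0, 5.6, 30.5, 35.3, 42.3))
  expect_equal(round(w_fork[1], 2), 0.94, ignore_attr = TRUE)
  expect_equal(sum(w_trl), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(0), 1)
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  expect_error(akaike_weights(numeric(0)), "empty")
  expect_error(akaike_weights(c(1, 2)), "zero")
})

test_that("evidence ratios and their relation to weights", {
  expect_equal(round(evidence_ratio(1.8), 1), 2.5)
  expect_equal(evidence_ratio(0), 1)
  # a ratio printed from unrounded deltas differs slightly from exp(13.3/2)
  expect_equal(evidence_ratio(13.3), 772.78, tolerance = 1e-4)
  expect_error(evidence_ratio(-0.1), "non-negative")
  # identity ER = w_best / w_other
  d <- c(0, 1.8, 38.8, 42.6, 53.5)
  w <- akaike_weights(d)
  expect_equal(evidence_ratio(d), w[1] / w, tolerance = 1e-12)
})

test_that("support categories follow the banding", {
  expect_equal(support_category(0), "strong")
  expect_equal(support_category(1.99), "strong")
  expect_equal(support_category(2), "moderate")
  expect_equal(support_category(5.6), "substantial-to-weak")
  expect_equal(support_category(10), "substantial-to-weak")
  expect_equal(support_category(42.3), "discard")
  expect_error(support_category(-1), "non-negative")
})

test_that("selection_table ranks the published root-length fits correctly", {
  fits <- list(
    list(scheme = "MAPHE", logLik = -469.8, df = 9, n_obs = 110),
    list(scheme = "GEN4", logLik = -463.0, df = 15, n_obs = 110),
    list(scheme = "MAHY", logLik = -485.5, df = 12, n_obs = 110),
    list(scheme = "GEN3", logLik = -487.3, df = 12, n_obs = 110),
    list(scheme = "UNI", logLik = -500.0, df = 6, n_obs = 110))
  tab <- selection_table(fits)
  expect_equal(tab$scheme, c("MAPHE", "GEN4", "MAHY", "GEN3", "UNI"))
  expect_equal(tab$dAICc[1], 0)
  expect_equal(tab$ER[1], 1)
  expect_equal(sum(tab$wAICc), 1, tolerance = 1e-9)
  expect_equal(round(tab$AICc[1], 1), 959.4)
  # recomputing AICc from logL/df/n reproduces the printed delta to ~0.1
  # (the published table's own rounding)
  expect_equal(tab$dAICc[2], 1.8, tolerance = 0.1)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_equal(tab$support[1], "strong")

  # single fit: one row, full weight
  tab1 <- selection_table(fits[1])
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$wAICc, 1)

  # mixed sample sizes are an input error
  fits_bad <- fits
  fits_bad[[2]]$n_obs <- 120
  expect_error(selection_table(fits_bad), "different sample sizes")
})

test_that("adding a strictly worse model keeps the best row", {
  fits <- list(
    list(scheme = "A", logLik = -100, df = 4, n_obs = 60),
    list(scheme = "B", logLik = -108, df = 4, n_obs = 60))
  t1 <- selection_table(fits)
  t2 <- selection_table(c(fits, list(
    list(scheme = "C", logLik = -150, df = 4, n_obs = 60))))
  expect_equal(t1$scheme[1], t2$scheme[1])
  expect_equal(t2$wAICc[1] / t2$wAICc[2], t1$wAICc[1] / t1$wAICc[2],
               tolerance = 1e-12)
})
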