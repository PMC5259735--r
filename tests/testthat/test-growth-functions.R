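# Mean-function values, gradients and shape properties.

test_that("expolinear hits its closed-form identities and reference values", {
  # at t = tb the curve equals (Cm/Rm) * ln 2
  expect_equal(expolinear(6.22, Cm = 149.52, Rm = 0.92, tb = 6.22),
               (149.52 / 0.92) * log(2))
  # deep exponential tail is numerically zero
  expect_lt(expolinear(-30, Cm = 1, Rm = 1, tb = 0), 1e-12)
  # frozen high-precision evaluation at the large-seed TRL estimates, day 12
  expect_equal(expolinear(12, Cm = 149.52, Rm = 0.92, tb = 6.22),
               865.020741266, tolerance = 1e-9)
})

test_that("gompertz hits inflection, asymptote and reference value", {
  expect_equal(gompertz(5.51, Wf = 26.99, k = 0.26, TT = 5.51),
               26.99 / exp(1))
  expect_equal(gompertz(1e4, Wf = 26.99, k = 0.26, TT = 5.51), 26.99)
  expect_equal(gompertz(12, Wf = 26.99, k = 0.26, TT = 5.51),
               22.4315068874, tolerance = 1e-9)
})

test_that("decay curve hits mid-point, plateaus and reference value", {
  expect_equal(decay_curve(6.012, Max = 0.436, Min = 0.058, TT = 6.012),
               (0.436 + 0.058) / 2)
  expect_equal(decay_curve(-1e4, Max = 0.436, Min = 0.058, TT = 6.012),
               0.436)
  expect_equal(decay_curve(12, Max = 0.436, Min = 0.058, TT = 6.012),
               0.0589459067, tolerance = 1e-8)
})

test_that("non-finite times are rejected", {
  expect_error(expolinear(NA, 1, 1, 0), "finite")
  expect_error(gompertz(Inf, 1, 1, 0), "finite")
  expect_error(decay_curve(NaN, 2, 1, 0), "finite")
})

test_that("analytic gradients match the trivial identities", {
  # expolinear dY/dtb at t = tb is -Cm/2
  g <- growth_gradient("expolinear", c(Cm = 3, Rm = 0.7, tb = 5), t = 5)
  expect_equal(g[1, "tb"], -3 / 2, ignore_attr = TRUE)
  # gompertz dY/dWf = Y/Wf
  p <- c(Wf = 20, k = 0.3, TT = 6)
  g <- growth_gradient("gompertz", p, t = c(2, 6, 10))
  expect_equal(g[, "Wf"], gompertz(c(2, 6, 10), 20, 0.3, 6) / 20,
               ignore_attr = TRUE)
})

test_that("gradients match central finite differences on random draws", {
  set.seed(11)
  for (rep in 1:20) {
    t <- runif(1, 0, 14)
    p_exp <- c(Cm = runif(1, 10, 300), Rm = runif(1, 0.2, 2),
               tb = runif(1, 2, 9))
    p_gom <- c(Wf = runif(1, 5, 50), k = runif(1, 0.1, 1),
               TT = runif(1, 2, 9))
    p_dec <- c(Max = runif(1, 0.3, 0.6), Min = runif(1, 0.01, 0.1),
               TT = runif(1, 2, 8), rate = runif(1, 0.5, 2))
    for (fam in list(list("expolinear", p_exp, FALSE),
                     list("gompertz", p_gom, FALSE),
                     list("decay", p_dec, TRUE))) {
      f <- function(x) growth_value(fam[[1]],
                                    setNames(x, names(fam[[2]])), t)
      ana <- growth_gradient(fam[[1]], fam[[2]], t, free_rate = fam[[3]])
      num <- fd_gradient(f, fam[[2]])
      expect_equal(as.numeric(ana), num, tolerance = 1e-6)
    }
  }
})

test_that("growth curves are monotone and stable at extreme exponents", {
  set.seed(21)
  tt <- seq(0, 14, by = 0.25)
  for (rep in 1:10) {
    ye <- expolinear(tt, runif(1, 10, 300), runif(1, 0.2, 2), runif(1, 2, 9))
    yg <- gompertz(tt, runif(1, 5, 50), runif(1, 0.1, 1), runif(1, 2, 9))
    yd <- decay_curve(tt, runif(1, 0.3, 0.6), runif(1, 0, 0.1),
                      runif(1, 2, 8), runif(1, 0.5, 2))
    expect_true(all(diff(ye) > 0))
    ## strict increase wherever the value is representable above underflow
    expect_true(all(diff(yg) >= 0))
    expect_true(all(diff(yg)[yg[-1] > 1e-12 * max(yg)] > 0))
    expect_true(all(diff(yd) < 0))
  }
  # |exponent| up to ~700 stays finite
  expect_true(is.finite(expolinear(800, Cm = 10, Rm = 1, tb = 0)))
  expect_true(is.finite(expolinear(-700, Cm = 10, Rm = 1, tb = 0)))
  expect_true(is.finite(gompertz(-700, Wf = 10, k = 1, TT = 0)))
  expect_true(is.finite(decay_curve(700, Max = 2, Min = 0, TT = 0)))
  expect_true(is.finite(decay_curve(-700, Max = 2, Min = 0, TT = 0)))
})

test_that("expolinear approaches its linear asymptote and gompertz its limit", {
  Cm <- 120; Rm <- 0.8; tb <- 6
  t <- 60
  y <- expolinear(t, Cm, Rm, tb)
  expect_lt(abs(y - Cm * (t - tb)) / y, 1e-10)
  # gompertz within 1e-9 * Wf once k (t - TT) > 25
  Wf <- 30; k <- 0.5; TT <- 5
  expect_lt(abs(gompertz(TT + 26 / k, Wf, k, TT) - Wf), 1e-9 * Wf)
})

test_that("unknown family is rejected", {
  expect_error(growth_value("logistic", c(a = 1), 1))
  expect_error(growth_gradient("richards", c(a = 1), 1))
})
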