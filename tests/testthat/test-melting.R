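test_that("duplex fraction is one half at the melting temperature", {
  for (self in c(TRUE, FALSE)) {
    tm <- melting_tm(-85, -240, 3.2e-4, self_complementary = self)
    expect_equal(duplex_fraction(tm, -85, -240, 3.2e-4, self), 0.5,
                 tolerance = 1e-12)
  }
})

test_that("duplex fraction attains its physical limits", {
  # far below Tm with a strong duplex: fully associated
  expect_equal(duplex_fraction(10, -120, -320, 1e-4, TRUE), 1,
               tolerance = 1e-4)
  # far above Tm: fully melted
  expect_equal(duplex_fraction(95, -85, -240, 1e-6, TRUE), 0,
               tolerance = 1e-3)
  # bounded in [0, 1] and monotonically non-increasing in temperature
  tt <- seq(10, 95, by = 0.5)
  f <- duplex_fraction(tt, -85, -240, 3.2e-4, TRUE)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) <= 1e-12))
})

test_that("closed-form root agrees with a bisection oracle to 1e-10", {
  R <- 1.98720425864083
  grid <- expand.grid(dH = c(-60, -85, -110), dS = c(-170, -240, -300),
                      ct = c(1e-6, 3.2e-4), self = c(TRUE, FALSE),
                      temp = c(15, 37, 55, 75, 90))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tK <- g$temp + 273.15
    K <- exp(-(g$dH * 1000 - tK * g$dS) / (R * tK))
    a <- if (g$self) 2 * K * g$ct else K * g$ct / 2
    oracle <- if (a < 1e-14) a else {
      stats::uniroot(function(f) a * (1 - f)^2 - f, c(0, 1),
                     tol = 1e-14)$root
    }
    expect_lt(abs(duplex_fraction(g$temp, g$dH, g$dS, g$ct, g$self) - oracle),
              1e-10)
  }
})

test_that("duplex and single-stranded fractions are conserved", {
  cv <- simulate_melting_curve(-85, -240, 3.2e-4, TRUE)
  fit <- fit_two_state(cv, 3.2e-4, TRUE)
  for (temp in c(23, 40, coef(fit)["Tm"], 80)) {
    fd <- predict(fit, temp, type = "duplex_fraction")
    expect_equal(single_stranded_percent(fit, temp) + 100 * fd, 100,
                 tolerance = 1e-10)
  }
  expect_equal(single_stranded_percent(fit, coef(fit)["Tm"]), 50,
               tolerance = 1e-6)
})

test_that("noiseless curves are refit to within one percent", {
  cases <- list(list(dH = -85, dS = -240, ct = 3.2e-4, self = TRUE),
                list(dH = -120, dS = -330, ct = 2.0e-4, self = FALSE))
  for (cs in cases) {
    cv <- simulate_melting_curve(cs$dH, cs$dS, cs$ct, cs$self)
    fit <- fit_two_state(cv, cs$ct, cs$self)
    cf <- coef(fit)
    expect_lt(abs(cf["dH"] - cs$dH) / abs(cs$dH), 0.01)
    expect_lt(abs(cf["dS"] - cs$dS) / abs(cs$dS), 0.01)
    expect_equal(unname(cf["Tm"]),
                 melting_tm(cs$dH, cs$dS, cs$ct, cs$self), tolerance = 0.05)
  }
})

test_that("curves without a transition raise a non-convergence error", {
  flat <- data.frame(temperature_C = seq(10, 95, 0.5), absorbance = 0.6)
  expect_error(fit_two_state(flat, 3.2e-4, TRUE), "non-convergence")
  line <- data.frame(temperature_C = seq(10, 95, 0.5),
                     absorbance = 0.5 + 0.001 * seq(10, 95, 0.5))
  expect_error(fit_two_state(line, 3.2e-4, TRUE), "non-convergence")
})

test_that("melting temperature rises with strand concentration", {
  tms <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(ct) {
    melting_tm(-85, -240, ct, TRUE)
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("a methylation-scale Tm offset is recovered within 0.2 C", {
  ct <- 3.2e-4
  dH <- -85
  tm1 <- melting_tm(dH, -240, ct, TRUE)
  for (dtm in c(1, 2, 3)) {
    dS2 <- dH * 1000 / (tm1 + dtm + 273.15) -
      1.98720425864083 * log(ct)
    cv1 <- simulate_melting_curve(dH, -240, ct, TRUE)
    cv2 <- simulate_melting_curve(dH, dS2, ct, TRUE)
    f1 <- fit_two_state(cv1, ct, TRUE)
    f2 <- fit_two_state(cv2, ct, TRUE)
    expect_equal(unname(coef(f2)["Tm"] - coef(f1)["Tm"]), dtm,
                 tolerance = 0.2)
  }
})

test_that("the simulator rejects nonphysical parameters and is seed-stable", {
  expect_error(simulate_melting_curve(10, -240, 1e-4, TRUE), "negative")
  expect_error(simulate_melting_curve(-85, -240, 1e-4, TRUE,
                                      temps = seq(0, 50, 1)),
               "scan window")
  a <- simulate_melting_curve(-85, -240, 1e-4, TRUE, noise_sd = 0.003,
                              seed = 5)
  b <- simulate_melting_curve(-85, -240, 1e-4, TRUE, noise_sd = 0.003,
                              seed = 5)
  c <- simulate_melting_curve(-85, -240, 1e-4, TRUE, noise_sd = 0.003,
                              seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})
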