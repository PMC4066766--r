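test_that("exact linear series are recovered perfectly", {
  d <- c(0, 50, 100, 200)
  f <- fit_rate(d, 0.05 * d)
  expect_equal(f$slope, 0.05, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_false(f$flagged)
  # flat series: zero slope, r2 undefined
  flat <- fit_rate(d, rep(3, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(flat$r2))
})

test_that("fit matches the closed-form normal equations on noisy data", {
  set.seed(99)
  for (i in 1:10) {
    d <- sample(0:200, 8)
    y <- 0.03 * d + rnorm(8, 0, 0.5)
    f <- fit_rate(d, y)
    sxx <- sum((d - mean(d))^2)
    sxy <- sum((d - mean(d)) * (y - mean(y)))
    expect_equal(f$slope, sxy / sxx, tolerance = 1e-10)
    expect_equal(f$intercept, mean(y) - f$slope * mean(d), tolerance = 1e-10)
    expect_equal(f$r2, stats::cor(d, y)^2, tolerance = 1e-10)
  }
})

test_that("degenerate dose designs are rejected", {
  expect_error(fit_rate(c(10, 10, 10), c(1, 2, 3)), "identical")
  expect_error(fit_rate(c(0, 100, 0, 100), c(1, 2, 1, 2)), "3 distinct")
  expect_error(fit_rate(c(0, 100), c(0, 5)), "3 observations")
})

test_that("replicate aggregation uses mean and sample SD", {
  same <- data.frame(slope = rep(0.05, 3), intercept = 0, r2 = 1)
  a <- aggregate_replicates(same)
  expect_equal(a$slope, 0.05)
  expect_equal(a$slope_sd, 0)
  spread <- data.frame(slope = c(1, 2, 3), intercept = c(0, 0, 0), r2 = 1)
  b <- aggregate_replicates(spread)
  expect_equal(b$slope, 2)
  expect_equal(b$slope_sd, 1)
  single <- data.frame(slope = 2, intercept = 0, r2 = 1)
  expect_true(is.na(aggregate_replicates(single)$slope_sd))
})

test_that("total damage reproduces the reference sums with summed SDs", {
  reg <- analyte_registry()
  td_c <- total_damage(ref_sub("ODN1:1"), reg, "C")
  expect_equal(td_c$total, 12.47, tolerance = 1e-9)
  expect_equal(td_c$total_sd, 0.87, tolerance = 1e-9)
  td_m <- total_damage(ref_sub("ODN2:2"), reg, "5mC")
  expect_equal(td_m$total, 12.65, tolerance = 1e-9)
  # quadrature option is the independent-error alternative
  td_q <- total_damage(ref_sub("ODN1:1"), reg, "C", sd_mode = "quadrature")
  r <- ref_sub("ODN1:1")
  sds <- r$slope_sd[match(td_q$members, r$analyte_id)]
  expect_equal(td_q$total_sd, sqrt(sum(sds^2)), tolerance = 1e-12)
})

test_that("total damage is permutation-invariant, additive, and guards membership", {
  reg <- analyte_registry()
  r <- ref_sub("ODN2:2")
  shuffled <- r[sample(nrow(r)), ]
  expect_equal(total_damage(shuffled, reg, "5mC")$total,
               total_damage(r, reg, "5mC")$total)
  one <- r[r$analyte_id == "5fC", ]
  expect_warning(td1 <- total_damage(one, reg, "5mC"), "excluded")
  expect_equal(td1$total, 5.45)
  expect_error(total_damage(one, reg, "G"), "no measured members")
  expect_error(total_damage(r, reg, "Z"), "unknown parent_base")
})

test_that("noiseless synthetic data yield exact rate recovery with r2 = 1", {
  cfg <- isolated_config(cv_area = 0, digestion_leak = TRUE)
  ds <- simulate_mrm_dataset(cfg)
  yt <- correct_deamination(build_yield_table(ds$peaks, ds$readings),
                            deamination_edges())
  fit <- fit_dose_response(yt, ds$samples)
  expect_s3_class(fit, "lesion_rates")
  truth <- cfg$true_rates[fit$rates$analyte_id]
  expect_equal(fit$rates$slope, unname(truth), tolerance = 1e-8)
  expect_equal(fit$rates$intercept, rep(0, nrow(fit$rates)), tolerance = 1e-8)
  expect_true(all(abs(fit$rates$r2 - 1) < 1e-12))
  expect_equal(fit$rates$slope_sd, rep(0, nrow(fit$rates)), tolerance = 1e-8)
})

test_that("lesion_rates methods expose the fitted model", {
  cfg <- isolated_config(cv_area = 0, digestion_leak = FALSE,
                         doses = c(0, 50, 100, 200), n_replicates = 2)
  ds <- simulate_mrm_dataset(cfg)
  fit <- fit_dose_response(build_yield_table(ds$peaks, ds$readings),
                           ds$samples)
  cm <- coef(fit)
  expect_true(all(c("slope", "intercept") %in% colnames(cm)))
  p <- predict(fit, doses = c(0, 100), analyte_id = "5fC")
  expect_equal(p$yield[p$dose == 100],
               unname(cfg$true_rates["5fC"]) * 100, tolerance = 1e-8)
  s <- summary(fit)
  expect_true("totals" %in% names(s))
  tot <- s$totals[s$totals$parent_base == "5mC", ]
  expect_equal(tot$total, sum(cfg$true_rates[c("5mC-Gly", "5mC-Hyd",
                                               "5mC-Imid", "5hmC", "5fC")]),
               tolerance = 1e-8)
  expect_output(print(fit), "Dose-response")
})
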