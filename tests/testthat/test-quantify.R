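test_that("isotope dilution follows the ratio equation", {
  expect_equal(isotope_dilution_amount(1000, 1000, 3.0), 3.0)
  expect_equal(isotope_dilution_amount(500, 1000, 8.3), 4.15)
  # linearity and scale invariance over a random grid, against the formula
  set.seed(42)
  an <- runif(50, 0, 5e4); al <- runif(50, 1e3, 1e5); sp <- runif(50, 1, 10)
  expect_equal(isotope_dilution_amount(an, al, sp), an / al * sp)
  expect_equal(isotope_dilution_amount(2 * an, al, sp),
               2 * isotope_dilution_amount(an, al, sp))
  k <- runif(50, 0.1, 10)
  expect_equal(isotope_dilution_amount(k * an, k * al, sp),
               isotope_dilution_amount(an, al, sp))
})

test_that("a lost internal standard is a quantification failure", {
  expect_error(isotope_dilution_amount(100, 0, 3), "quantification failure")
  expect_error(isotope_dilution_amount(-1, 100, 3), "area_natural")
  expect_error(isotope_dilution_amount(100, 100, 0), "standard_spike")
})

test_that("normalization to lesions per million bases is exact algebra", {
  expect_equal(lesions_per_million(0.01, 250, 0.25), 10)
  expect_equal(lesions_per_million(0, 250, 0.25), 0)
  set.seed(7)
  am <- runif(40, 0, 1); dc <- runif(40, 10, 1000); fr <- runif(40, 0.05, 0.9)
  expect_equal(lesions_per_million(am, dc, fr), am * fr * 1e6 / dc)
  expect_error(lesions_per_million(1, 0, 0.2), "dC_pmol")
  expect_error(lesions_per_million(1, 100, 0), "dC_fraction")
  expect_error(lesions_per_million(1, 100, 1), "dC_fraction")
})

test_that("yield table covers every sample x registry analyte", {
  reg <- analyte_registry()
  cfg <- isolated_config(cv_area = 0, digestion_leak = FALSE,
                         doses = c(0, 100), n_replicates = 1)
  ds <- simulate_mrm_dataset(cfg)
  yt <- build_yield_table(ds$peaks, ds$readings, reg)
  expect_equal(nrow(yt), nrow(ds$samples) * nrow(reg))
  expect_false(isTRUE(attr(yt, "corrected")))
  # ODN5:6 has no cytosine products: those registry analytes are
  # not-detected (NA), which is distinct from a measured zero
  nd <- yt[yt$analyte_id == "U-Gly", ]
  expect_true(all(nd$status == "nd"))
  expect_true(all(is.na(nd$yield)))
  zero <- yt[yt$analyte_id == "5fC" & grepl("_d0_", yt$sample_id), ]
  expect_true(all(zero$status == "ok"))
  expect_equal(zero$yield, rep(0, nrow(zero)))
})

test_that("yield table enforces its contracts", {
  reg <- analyte_registry()
  cfg <- isolated_config(cv_area = 0, doses = c(0, 50), n_replicates = 1)
  ds <- simulate_mrm_dataset(cfg)
  expect_error(build_yield_table(ds$peaks[0, ], ds$readings, reg),
               "empty peaks")
  expect_error(build_yield_table(ds$peaks, ds$readings[0, ], reg),
               "without a dC normalization reading.*d0")
  dup <- rbind(ds$peaks, ds$peaks[1, ])
  expect_error(build_yield_table(dup, ds$readings, reg), "duplicate")
  alien <- ds$peaks
  alien$analyte_id[1] <- "mystery"
  expect_error(build_yield_table(alien, ds$readings, reg), "unregistered")
})

test_that("noiseless generate-quantify round trip is exact", {
  cfg <- isolated_config(cv_area = 0, digestion_leak = FALSE)
  ds <- simulate_mrm_dataset(cfg)
  yt <- build_yield_table(ds$peaks, ds$readings)
  m <- merge(as.data.frame(yt), ds$truth, by = c("sample_id", "analyte_id"))
  m <- m[m$status == "ok", ]
  expect_equal(m$yield, m$true_yield, tolerance = 1e-10)
})

test_that("yields are invariant to common scaling of both channels", {
  cfg <- isolated_config(cv_area = 0, digestion_leak = FALSE,
                         doses = c(0, 50, 100), n_replicates = 1)
  ds <- simulate_mrm_dataset(cfg)
  yt1 <- build_yield_table(ds$peaks, ds$readings)
  scaled <- ds$peaks
  scaled$area_natural <- scaled$area_natural * 17.3
  scaled$area_labeled <- scaled$area_labeled * 17.3
  yt2 <- build_yield_table(scaled, ds$readings)
  expect_equal(yt2$yield, yt1$yield, tolerance = 1e-12)
})
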