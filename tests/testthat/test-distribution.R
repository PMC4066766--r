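test_that("product distributions reproduce the display percentages", {
  reg <- analyte_registry()
  d56 <- product_distribution(ref_sub("ODN5:6"), reg, "5mC")
  expect_equal(d56$percent_rounded[d56$analyte_id == "5fC"], 63)
  dct <- product_distribution(ref_sub("CT-DNA"), reg, "5mC")
  expect_equal(dct$percent_rounded[dct$analyte_id == "5mC-Hyd"], 26)
  # percentages sum to 100 (integer rounding tolerance)
  expect_equal(sum(d56$percent), 100, tolerance = 1e-9)
  expect_lte(abs(sum(d56$percent_rounded) - 100), 1)
  # single measured product carries the whole distribution
  one <- data.frame(analyte_id = "5fC", slope = 2.2)
  expect_equal(product_distribution(one, reg, "5mC")$percent, 100)
  zero <- data.frame(analyte_id = "5fC", slope = 0)
  expect_error(product_distribution(zero, reg, "5mC"), "zero")
})

test_that("distributions are invariant to rescaling the rates", {
  reg <- analyte_registry()
  r <- ref_sub("ODN2:2")
  d1 <- product_distribution(r, reg, "5mC")
  r$slope <- r$slope * 37.5
  d2 <- product_distribution(r, reg, "5mC")
  expect_equal(d2$percent, d1$percent, tolerance = 1e-12)
})

test_that("pathway grouping partitions the total damage", {
  reg <- analyte_registry()
  for (pb in c("5mC", "C", "T")) {
    r <- ref_sub("CT-DNA")
    s <- pathway_sums(r, reg, pb)
    expect_equal(sum(s), total_damage(r, reg, pb)$total, tolerance = 1e-12)
  }
})

test_that("glycol-to-hydantoin ratios discriminate 5mC from C and T", {
  reg <- analyte_registry()
  ct <- ref_sub("CT-DNA")
  expect_equal(pathway_ratio(ct, reg, "5mC"), 1.0, tolerance = 1e-12)
  # cytosine pathway I includes the 5-hydroxy dehydration descendants
  expect_equal(pathway_ratio(ct, reg, "C"),
               (0.83 + 1.47 + 1.27) / 1.08, tolerance = 1e-9)
  expect_equal(round(pathway_ratio(ct, reg, "C"), 1), 3.3)
  expect_gt(pathway_ratio(ct, reg, "T"), 3)
  nohyd <- data.frame(analyte_id = c("5mC-Gly", "5mC-Hyd"), slope = c(1, 0))
  expect_error(pathway_ratio(nohyd, reg, "5mC"), "hydantoin")
})

test_that("methyl oxidation fractions match direct arithmetic", {
  reg <- analyte_registry()
  expect_equal(methyl_oxidation_fraction(ref_sub("ODN5:6"), reg, "5mC"),
               (4.67 + 0.24) / 7.42, tolerance = 1e-9)
  expect_equal(methyl_oxidation_fraction(ref_sub("ODN3:4"), reg, "T"),
               (4.65 + 0.42) / 8.23, tolerance = 1e-9)
  only_methyl <- data.frame(analyte_id = c("5hmC", "5fC"), slope = c(1, 2))
  expect_equal(methyl_oxidation_fraction(only_methyl, reg, "5mC"), 1)
  expect_error(methyl_oxidation_fraction(ref_sub("CT-DNA"), reg, "C"),
               "only for parent bases T and 5mC")
})

test_that("hydroxymethyl-to-formyl ratios match the cellular reference", {
  reg <- analyte_registry()
  cell <- reference_rates("cellular")
  expect_equal(round(hydroxymethyl_to_formyl_ratio(cell, reg, "5mC"), 1), 2.6)
  expect_equal(round(hydroxymethyl_to_formyl_ratio(cell, reg, "T"), 2), 0.68)
  eq <- data.frame(analyte_id = c("5hmC", "5fC"), slope = c(1.7, 1.7))
  expect_equal(hydroxymethyl_to_formyl_ratio(eq, reg, "5mC"), 1)
  zf <- data.frame(analyte_id = c("5hmC", "5fC"), slope = c(1, 0))
  expect_error(hydroxymethyl_to_formyl_ratio(zf, reg, "5mC"), "formyl")
})

test_that("multi-duplex averages follow the display-percentage convention", {
  reg <- analyte_registry()
  dists <- lapply(c("ODN2:2", "ODN3:6", "ODN5:6"), function(s) {
    product_distribution(ref_sub(s), reg, "5mC")
  })
  avg <- average_distribution(dists)
  expect_equal(avg$percent[avg$analyte_id == "5mC-Gly"], 9)
  expect_equal(avg$percent[avg$analyte_id == "5mC-Hyd"], 25)
  expect_equal(avg$percent[avg$analyte_id == "5mC-Imid"], 9)
  # averaging identical inputs is the identity
  same <- average_distribution(list(dists[[1]], dists[[1]]))
  expect_equal(same$percent,
               dists[[1]]$percent_rounded[match(same$analyte_id,
                                                dists[[1]]$analyte_id)])
  # mixing parent bases is refused
  dt <- product_distribution(ref_sub("ODN5:6"), reg, "T")
  expect_error(average_distribution(list(dists[[1]], dt)), "mismatched")
  expect_error(average_distribution(dists[1]), "at least 2")
})
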