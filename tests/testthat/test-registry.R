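test_that("default registry contains the measured species with correct grouping", {
  reg <- analyte_registry()
  expect_s3_class(reg, "analyte_registry")
  expect_equal(nrow(reg), 15)
  counts <- table(reg$parent_base)
  expect_equal(counts[["5mC"]], 5)
  expect_equal(counts[["C"]], 5)
  expect_equal(counts[["T"]], 4)
  expect_equal(counts[["G"]], 1)
  expect_true(all(reg$pathway %in% pathway_classes()))
  # digestion-time deamination defaults
  expect_equal(reg$deaminates_to[reg$analyte_id == "5mC-Gly"], "T-Gly")
  expect_equal(reg$deamination_fraction[reg$analyte_id == "5mC-Gly"], 0.20)
  expect_equal(reg$deamination_fraction[reg$analyte_id == "5mC-Hyd"], 0.05)
  # the 5-hydroxy descendants belong to the cytosine glycol pathway
  expect_equal(reg$pathway[reg$analyte_id %in% c("5ohC", "5ohU")],
               rep("I-glycol", 2))
})

test_that("registry round-trips exactly through CSV", {
  reg <- analyte_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_analyte_registry(reg, path)
  back <- read_analyte_registry(path)
  expect_equal(as.data.frame(back), as.data.frame(reg))
})

test_that("registry validation rejects malformed tables by row", {
  reg <- as.data.frame(analyte_registry())

  dangling <- reg
  dangling$deaminates_to[dangling$analyte_id == "5mC-Gly"] <- "Y"
  expect_error(validate_registry(dangling), "5mC-Gly.*not a registered")

  bad_frac <- reg
  bad_frac$deamination_fraction[1] <- 1.2
  expect_error(validate_registry(bad_frac), "outside \\[0, 1\\]")

  orphan_frac <- reg
  orphan_frac$deamination_fraction[orphan_frac$analyte_id == "5hmC"] <- 0.1
  expect_error(validate_registry(orphan_frac), "must be 0 when deaminates_to is absent")

  bad_parent <- reg
  bad_parent$parent_base[1] <- "X"
  expect_error(validate_registry(bad_parent), "unknown parent_base")

  same_parent <- reg
  same_parent$deaminates_to[same_parent$analyte_id == "5mC-Gly"] <- "5hmC"
  expect_error(validate_registry(same_parent), "must change the parent base")
})

test_that("deamination edge set has measurable and virtual components", {
  edges <- deamination_edges()
  live <- edges[!edges$virtual, ]
  expect_setequal(live$parent, c("5mC-Gly", "5mC-Hyd"))
  expect_true(all(live$fraction < 1))
  virt <- edges[edges$virtual, ]
  expect_setequal(virt$parent, c("C-Gly", "C-Hyd"))
  expect_true(all(virt$fraction == 1))
  # edge children cross parent bases: 5mC products deaminate to T products
  reg <- analyte_registry()
  expect_equal(reg$parent_base[match(live$child, reg$analyte_id)],
               rep("T", 2))
})

test_that("base fractions follow duplex counting and normalize to one", {
  subs <- default_substrates()
  # Dickerson-Drew dodecamer CGCGAATTCGCG: 4 C per strand of 12
  expect_equal(base_fraction(substrate_row(subs, "ODN1:1"), "C"), 1 / 3)
  for (id in subs$substrate_id) {
    comp <- substrate_row(subs, id)
    fr <- vapply(base_symbols(), function(b) base_fraction(comp, b),
                 numeric(1))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
  # calf thymus: 5mC is 6.4% of unmodified cytosine
  ct <- substrate_row(subs, "CT-DNA")
  expect_equal(base_fraction(ct, "5mC") / base_fraction(ct, "C"), 0.064,
               tolerance = 1e-12)
})

test_that("base_fraction rejects bad inputs", {
  subs <- default_substrates()
  comp <- substrate_row(subs, "ODN1:1")
  expect_error(base_fraction(comp, "B"), "unknown base")
  empty <- comp
  empty[, c("A", "C", "G", "T", "mC")] <- 0
  expect_error(base_fraction(empty, "C"), "empty composition")
  expect_error(substrate_row(subs, "nope"), "unknown substrate_id")
})
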