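# Shared fixture builders for the suite. Everything is generated in code;
# the only stored inputs are the package's own reference rate tables.

ref_sub <- function(substrate_id) {
  ref <- reference_rates("isolated")
  ref[ref$substrate_id == substrate_id, , drop = FALSE]
}

# minimal uncorrected yield table (bypasses quantification) for algebra tests
toy_yields <- function(analytes, yields, sample_id = "s1") {
  yt <- data.frame(sample_id = sample_id, analyte_id = analytes,
                   yield = yields, status = "ok", stringsAsFactors = FALSE)
  attr(yt, "corrected") <- FALSE
  class(yt) <- c("yield_table", "data.frame")
  yt
}
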