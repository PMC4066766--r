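#' Bundled reference lesion formation rates
#'
#' Reference dose-response rates for the assay, shipped as plain-text tables:
#'
#' * `"isolated"` -- rates (lesions per 1e6 DNA bases, on a common per-dose
#'   scale) with replicate SDs for the five oligonucleotide duplexes and
#'   calf-thymus DNA, together with the integer display percentages. The
#'   calf-thymus 5mC-Imid entry is a quantification-limit upper bound and is
#'   marked `censored = TRUE` (its SD is carried as 0).
#' * `"cellular"` -- rates per kGy for irradiated cells, with the lesion
#'   levels measured in non-irradiated cells as `baseline` (lesions per 1e6
#'   bases; analytes not detected in non-irradiated cells carry baseline 0).
#'
#' These tables serve three purposes: default truths for the synthetic
#' generator, worked-example inputs for the scale-invariant distribution and
#' sensitivity analyses, and fixtures for the package's verification suite.
#'
#' @param context `"isolated"` or `"cellular"`.
#' @return data.frame. For `"isolated"`: `substrate_id, analyte_id, slope,
#'   slope_sd, percent_printed, censored`. For `"cellular"`: `analyte_id,
#'   slope, slope_sd, baseline`.
#' @export
reference_rates <- function(context = c("isolated", "cellular")) {
  context <- match.arg(context)
  file <- switch(context,
                 isolated = "reference_rates_isolated.csv",
                 cellular = "reference_rates_cellular.csv")
  path <- system.file("extdata", file, package = "pyrimox", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
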