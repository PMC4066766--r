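#' Isotope-dilution amount from an MRM peak-area pair
#'
#' The amount of a natural analyte is the ratio of its MRM signal to that of
#' the co-injected stable-isotope-labeled internal standard, times the known
#' spiked amount of the standard:
#' `amount = area_natural / area_labeled * standard_spike`.
#' Linear in `area_natural`; invariant to any common scaling of both channels.
#'
#' @param area_natural MRM peak area of the natural analyte (arbitrary units).
#' @param area_labeled MRM peak area of the labeled standard (same units,
#'   must be positive -- a zero labeled area signals a lost standard).
#' @param standard_spike Amount of labeled standard added, pmol.
#' @return Amount of analyte in pmol (vectorized).
#' @examples
#' isotope_dilution_amount(500, 1000, 8.3) # 4.15 pmol
#' @export
isotope_dilution_amount <- function(area_natural, area_labeled, standard_spike) {
  if (any(!is.finite(area_natural)) || any(area_natural < 0)) {
    stop("area_natural must be finite and >= 0")
  }
  if (any(!is.finite(area_labeled)) || any(area_labeled <= 0)) {
    stop("quantification failure: area_labeled must be > 0 (lost internal standard)")
  }
  if (any(!is.finite(standard_spike)) || any(standard_spike <= 0)) {
    stop("standard_spike must be > 0")
  }
  area_natural / area_labeled * standard_spike
}

#' Normalize an analyte amount to lesions per million DNA bases
#'
#' Total DNA in the digest is calibrated from the UV-determined amount of
#' 2'-deoxycytidine and the substrate's cytosine fraction:
#' `total_bases_pmol = dC_pmol / dC_fraction`, and
#' `yield = amount / total_bases_pmol * 1e6`.
#'
#' @param amount Analyte amount, pmol.
#' @param dC_pmol 2'-deoxycytidine in the digest, pmol (UV at 260 nm).
#' @param dC_fraction Fraction of DNA bases that are unmodified C, in (0, 1).
#' @return Lesions per 1e6 DNA bases (vectorized).
#' @examples
#' lesions_per_million(0.01, 250, 0.25) # 10 lesions / 1e6 bases
#' @export
lesions_per_million <- function(amount, dC_pmol, dC_fraction) {
  if (any(!is.finite(dC_pmol)) || any(dC_pmol <= 0)) {
    stop("dC_pmol must be > 0")
  }
  if (any(!is.finite(dC_fraction)) || any(dC_fraction <= 0) ||
      any(dC_fraction >= 1)) {
    stop("dC_fraction must lie in (0, 1)")
  }
  amount / (dC_pmol / dC_fraction) * 1e6
}

#' Build a yield table from peak areas and normalization readings
#'
#' One row per sample x registry analyte. Analytes without a peak record in a
#' sample are flagged `status = "nd"` (not detected), with `yield = NA`:
#' not-detected is propagated distinctly from zero through all downstream
#' analysis.
#'
#' @param peaks data.frame with columns `sample_id`, `analyte_id`,
#'   `area_natural`, `area_labeled` and optionally `standard_spike_pmol`
#'   (defaults to the registry spike).
#' @param readings data.frame with columns `sample_id`, `dC_pmol`,
#'   `dC_fraction` (one row per sample).
#' @param registry An [analyte_registry()].
#' @return A `yield_table` data.frame with columns `sample_id`, `analyte_id`,
#'   `yield` (lesions per 1e6 bases) and `status` (`"ok"` or `"nd"`), carrying
#'   attribute `corrected = FALSE`.
#' @export
build_yield_table <- function(peaks, readings, registry = analyte_registry()) {
  if (nrow(peaks) == 0) {
    stop("empty peaks table: no MRM records to quantify")
  }
  required <- c("sample_id", "analyte_id", "area_natural", "area_labeled")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peaks table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(c("sample_id", "dC_pmol", "dC_fraction") %in% names(readings))) {
    stop("readings table requires columns sample_id, dC_pmol, dC_fraction")
  }
  unknown <- setdiff(unique(peaks$analyte_id), registry$analyte_id)
  if (length(unknown) > 0) {
    stop("peaks table contains unregistered analytes: ",
         paste(unknown, collapse = ", "))
  }
  key <- paste(peaks$sample_id, peaks$analyte_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sample, analyte) record: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  samples <- unique(peaks$sample_id)
  no_reading <- setdiff(samples, readings$sample_id)
  if (length(no_reading) > 0) {
    stop("samples without a dC normalization reading: ",
         paste(no_reading, collapse = ", "))
  }
  if (anyDuplicated(readings$sample_id)) {
    stop("readings table has duplicated sample_id rows")
  }

  if (!"standard_spike_pmol" %in% names(peaks)) {
    peaks$standard_spike_pmol <-
      registry$standard_spike_pmol[match(peaks$analyte_id, registry$analyte_id)]
  }

  grid <- expand.grid(sample_id = samples,
                      analyte_id = registry$analyte_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$sample_id, samples),
                     match(grid$analyte_id, registry$analyte_id)), ,
               drop = FALSE]
  i <- match(paste(grid$sample_id, grid$analyte_id, sep = "\r"), key)
  grid$status <- ifelse(is.na(i), "nd", "ok")
  grid$yield <- NA_real_

  ok <- !is.na(i)
  p <- peaks[i[ok], , drop = FALSE]
  amount <- isotope_dilution_amount(p$area_natural, p$area_labeled,
                                    p$standard_spike_pmol)
  r <- readings[match(p$sample_id, readings$sample_id), , drop = FALSE]
  grid$yield[ok] <- lesions_per_million(amount, r$dC_pmol, r$dC_fraction)
  rownames(grid) <- NULL
  structure(grid, corrected = FALSE,
            class = c("yield_table", "data.frame"))
}

#' Write a yield table to CSV
#'
#' Emits columns `sample_id,analyte_id,yield_per_1e6_bases,status,corrected`.
#' @param yields A `yield_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(yields, path) {
  out <- data.frame(sample_id = yields$sample_id,
                    analyte_id = yields$analyte_id,
                    yield_per_1e6_bases = yields$yield,
                    status = yields$status,
                    corrected = isTRUE(attr(yields, "corrected")))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
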