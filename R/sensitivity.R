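# Methylation-sensitivity statistics: how much more damage accrues at a
# cytosine site once it is methylated.

#' Fold change for a matched methylated/control duplex pair
#'
#' For duplexes identical except that cytosines are replaced by 5mC at fixed
#' positions: the total cytosine-family damage of the methylated duplex
#' (total 5mC products plus total remaining C products) divided by the total
#' C damage of the nonmethylated control.
#'
#' @param methylated_total Combined 5mC + C total damage of the methylated
#'   duplex (lesions / 1e6 bases per dose unit).
#' @param control_total Total C damage of the matched control duplex.
#' @return Fold change (> 0).
#' @export
matched_pair_fold <- function(methylated_total, control_total) {
  if (!is.finite(control_total) || control_total <= 0) {
    stop("control total must be > 0")
  }
  if (!is.finite(methylated_total) || methylated_total <= 0) {
    stop("methylated total must be > 0")
  }
  methylated_total / control_total
}

#' Mean methylation sensitivity over matched pairs
#'
#' @param folds Numeric vector of matched-pair fold changes (length >= 1).
#' @return Unweighted mean fold.
#' @export
mean_methylation_sensitivity <- function(folds) {
  if (length(folds) < 1) stop("need at least one pair fold")
  if (any(!is.finite(folds)) || any(folds <= 0)) {
    stop("folds must be finite and > 0")
  }
  mean(folds)
}

#' Expected versus observed C/5mC damage partition in genomic DNA
#'
#' If hydroxyl radical attacked C and 5mC equally, damage would split in
#' proportion to base abundance: `expected = 1 / mC_fraction_of_C` (e.g. 15.6
#' when 5mC is 6.4\% of cytosine). The observed fold is the measured
#' `total_C / total_5mC`. The discrepancy `expected / observed` exceeding 1
#' quantifies the excess sensitivity of the methylated base.
#'
#' `discrepancy` is the exact unrounded ratio. `discrepancy_printed` applies
#' the display convention of quoting each fold at one decimal place before
#' dividing (the form in which such numbers are conventionally reported).
#'
#' @param total_C Total cytosine damage (lesions / 1e6 bases per dose unit).
#' @param total_5mC Total 5mC damage, same units.
#' @param mC_fraction_of_C 5mC as a fraction of total cytosine, in (0, 1).
#' @return List with `expected_fold`, `observed_fold`, `discrepancy`,
#'   `discrepancy_printed`.
#' @examples
#' expected_observed_composition(5.88, 1.04, 0.064)
#' @export
expected_observed_composition <- function(total_C, total_5mC,
                                          mC_fraction_of_C) {
  vals <- c(total_C, total_5mC, mC_fraction_of_C)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be finite and > 0")
  }
  if (mC_fraction_of_C >= 1) stop("mC_fraction_of_C must be < 1")
  expected <- 1 / mC_fraction_of_C
  observed <- total_C / total_5mC
  list(expected_fold = expected,
       observed_fold = observed,
       discrepancy = expected / observed,
       discrepancy_printed = round(expected, 1) / round(observed, 1))
}

#' Methylation sensitivity from a rate table
#'
#' Convenience wrapper combining [total_damage()] and [matched_pair_fold()]
#' over a pairing table of methylated and control substrates. For a fully
#' methylated duplex with no remaining measurable C products the C total
#' contributes zero.
#'
#' @param rates A `lesion_rates` object or data.frame with `substrate_id`,
#'   `analyte_id`, `slope`.
#' @param registry An [analyte_registry()].
#' @param pairs data.frame with columns `methylated`, `control` naming
#'   substrate ids.
#' @return List with `pair_folds` (data.frame) and `mean_fold`.
#' @export
methylation_sensitivity <- function(rates, registry = analyte_registry(),
                                    pairs) {
  if (inherits(rates, "lesion_rates")) rates <- rates$rates
  if (!all(c("methylated", "control") %in% names(pairs))) {
    stop("pairs require columns methylated and control")
  }
  total_for <- function(sub, pb) {
    rsub <- rates[rates$substrate_id == sub, , drop = FALSE]
    tryCatch(suppressWarnings(total_damage(rsub, registry, pb)$total),
             error = function(e) 0)
  }
  folds <- vapply(seq_len(nrow(pairs)), function(i) {
    meth <- pairs$methylated[i]; ctrl <- pairs$control[i]
    meth_total <- total_for(meth, "5mC") + total_for(meth, "C")
    ctrl_total <- total_for(ctrl, "C")
    matched_pair_fold(meth_total, ctrl_total)
  }, numeric(1))
  pair_folds <- data.frame(methylated = pairs$methylated,
                           control = pairs$control, fold = folds,
                           stringsAsFactors = FALSE)
  list(pair_folds = pair_folds,
       mean_fold = mean_methylation_sensitivity(folds))
}
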