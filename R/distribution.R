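# Product-distribution percentages, pathway grouping and characteristic
# ratios. All of these are scale-invariant in the rates, so they can be
# computed equally from fitted slopes or from a published rate table.

as_rates_df <- function(rates, substrate_id = NULL) {
  if (inherits(rates, "lesion_rates")) rates <- rates$rates
  if (!is.null(substrate_id) && "substrate_id" %in% names(rates)) {
    rates <- rates[rates$substrate_id == substrate_id, , drop = FALSE]
  }
  if (!all(c("analyte_id", "slope") %in% names(rates))) {
    stop("rates require columns analyte_id and slope")
  }
  rates
}

#' Product distribution for one parent base
#'
#' Percentage of the total damage at a parent base contributed by each member
#' analyte: `100 * slope_i / total`. Both the unrounded percentage and the
#' integer-rounded display value are reported; percentages are invariant to
#' any common rescaling of the rates.
#'
#' @param rates A `lesion_rates` object or data.frame with `analyte_id`,
#'   `slope` (optionally `substrate_id`).
#' @param registry An [analyte_registry()].
#' @param parent_base Parent base to profile.
#' @param substrate_id Optional filter when `rates` spans several substrates.
#' @return data.frame `analyte_id, slope, percent, percent_rounded`, with
#'   attribute `parent_base`.
#' @export
product_distribution <- function(rates, registry = analyte_registry(),
                                 parent_base, substrate_id = NULL) {
  r <- as_rates_df(rates, substrate_id)
  members <- registry$analyte_id[registry$parent_base == parent_base]
  rows <- r[r$analyte_id %in% members & !is.na(r$slope), , drop = FALSE]
  if (nrow(rows) == 0) stop("no measured members for parent base ", parent_base)
  total <- sum(rows$slope)
  if (total <= 0) stop("total damage is zero; distribution undefined")
  out <- data.frame(analyte_id = rows$analyte_id, slope = rows$slope,
                    percent = 100 * rows$slope / total,
                    stringsAsFactors = FALSE)
  out$percent_rounded <- round(out$percent)
  attr(out, "parent_base") <- parent_base
  out
}

#' Yields grouped by mechanistic pathway
#'
#' Partitions the member analytes of a parent base into the pathway classes
#' and sums their rates. Every member contributes to exactly one class, so
#' the class sums add back up to the total damage.
#'
#' @inheritParams product_distribution
#' @return Named numeric vector of pathway sums.
#' @export
pathway_sums <- function(rates, registry = analyte_registry(), parent_base,
                         substrate_id = NULL) {
  r <- as_rates_df(rates, substrate_id)
  members <- registry[registry$parent_base == parent_base, , drop = FALSE]
  rows <- r[r$analyte_id %in% members$analyte_id & !is.na(r$slope), ,
            drop = FALSE]
  if (nrow(rows) == 0) stop("no measured members for parent base ", parent_base)
  pw <- members$pathway[match(rows$analyte_id, members$analyte_id)]
  tapply(rows$slope, factor(pw, levels = unique(pw)), sum)
}

#' Glycol-to-hydantoin pathway ratio
#'
#' Ratio of the 5,6-addition branch points: the glycol-family sum (pathway I,
#' which for cytosine includes the dehydration descendants 5ohC and 5ohU)
#' over the hydantoin sum (pathway II). A drop in this ratio -- near 1:1 for
#' 5mC versus ~4:1 for thymine -- is the signature of the methylated base's
#' shifted peroxyl-radical chemistry.
#'
#' @inheritParams product_distribution
#' @return Numeric ratio.
#' @export
pathway_ratio <- function(rates, registry = analyte_registry(), parent_base,
                          substrate_id = NULL) {
  s <- pathway_sums(rates, registry, parent_base, substrate_id)
  gly <- sum(s[names(s) == "I-glycol"])
  hyd <- sum(s[names(s) == "II-hydantoin"])
  if (!is.finite(hyd) || hyd <= 0) {
    stop("hydantoin-pathway sum is zero; ratio undefined")
  }
  gly / hyd
}

#' Fraction of damage via exocyclic methyl oxidation
#'
#' For thymine and 5-methylcytosine: the share of total damage carried by the
#' 5-hydroxymethyl and 5-formyl products (H-abstraction at the methyl group,
#' pathway IV) rather than by 5,6-double-bond addition.
#'
#' @inheritParams product_distribution
#' @return Fraction in `[0, 1]`.
#' @export
methyl_oxidation_fraction <- function(rates, registry = analyte_registry(),
                                      parent_base, substrate_id = NULL) {
  if (!parent_base %in% c("T", "5mC")) {
    stop("methyl oxidation is defined only for parent bases T and 5mC")
  }
  s <- pathway_sums(rates, registry, parent_base, substrate_id)
  total <- sum(s)
  if (total <= 0) stop("total damage is zero")
  methyl <- sum(s[names(s) %in% c("IV-methyl-hydroxy", "IV-methyl-formyl")])
  methyl / total
}

#' Hydroxymethyl-to-formyl product ratio
#'
#' `5hmC/5fC` (parent 5mC) or `5hmU/5fU` (parent T): the branch ratio between
#' the alcohol and aldehyde end points of methyl oxidation, diagnostic of the
#' oxygen/redox environment in which the intermediate methyl radical decays.
#'
#' @inheritParams product_distribution
#' @return Numeric ratio.
#' @export
hydroxymethyl_to_formyl_ratio <- function(rates,
                                          registry = analyte_registry(),
                                          parent_base, substrate_id = NULL) {
  if (!parent_base %in% c("T", "5mC")) {
    stop("hydroxymethyl/formyl ratio is defined only for parent bases T and 5mC")
  }
  r <- as_rates_df(rates, substrate_id)
  members <- registry[registry$parent_base == parent_base, , drop = FALSE]
  hm_id <- members$analyte_id[members$pathway == "IV-methyl-hydroxy"]
  f_id <- members$analyte_id[members$pathway == "IV-methyl-formyl"]
  hm <- r$slope[match(hm_id, r$analyte_id)]
  fo <- r$slope[match(f_id, r$analyte_id)]
  if (length(fo) != 1 || !is.finite(fo) || fo <= 0) {
    stop("formyl yield is zero or missing; ratio undefined")
  }
  if (length(hm) != 1 || !is.finite(hm)) stop("hydroxymethyl yield missing")
  hm / fo
}

#' Average product distributions across substrates
#'
#' Unweighted mean of the per-substrate *rounded-as-displayed* percentages,
#' rounded again to integers. Averaging display percentages (rather than
#' pooling yields) reproduces how multi-duplex averages are conventionally
#' quoted for this assay.
#'
#' @param dists List of [product_distribution()] results for the same parent
#'   base (at least 2).
#' @return data.frame `analyte_id, percent_mean, percent` (integer), with
#'   attribute `parent_base`.
#' @export
average_distribution <- function(dists) {
  if (length(dists) < 2) stop("need at least 2 distributions to average")
  pb <- unique(vapply(dists, function(d) attr(d, "parent_base"), character(1)))
  if (length(pb) != 1) {
    stop("distributions have mismatched parent_base: ",
         paste(pb, collapse = ", "))
  }
  ids <- sort(unique(unlist(lapply(dists, function(d) d$analyte_id))))
  m <- vapply(dists, function(d) {
    d$percent_rounded[match(ids, d$analyte_id)]
  }, numeric(length(ids)))
  m <- matrix(m, nrow = length(ids))
  pm <- rowMeans(m, na.rm = TRUE)
  out <- data.frame(analyte_id = ids, percent_mean = pm,
                    percent = round(pm), stringsAsFactors = FALSE)
  attr(out, "parent_base") <- pb
  out
}
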