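#' Mechanistic pathway classes
#'
#' Stable end products of hydroxyl-radical attack on pyrimidines fall into a
#' small set of mechanistic families: addition to the 5,6-double bond yields
#' glycols (pathway I, including the ring-saturation descendants 5ohC and 5ohU
#' of the cytosine glycol), hydantoins by C5-C6 ring contraction (pathway II)
#' and imidazolidines by C4-C5 cleavage (pathway III); H-atom abstraction from
#' the exocyclic methyl group of thymine and 5-methylcytosine yields the
#' 5-hydroxymethyl (pathway IV, alcohol branch) and 5-formyl (pathway IV,
#' aldehyde branch) derivatives. 8-oxo-7,8-dihydroguanine is carried as the
#' purine oxidation marker.
#'
#' @return Character vector of the six pathway class labels.
#' @export
pathway_classes <- function() {
  c("I-glycol", "II-hydantoin", "III-imidazolidine",
    "IV-methyl-hydroxy", "IV-methyl-formyl", "purine")
}

#' DNA base symbols recognised in substrate compositions
#' @return Character vector `A, C, G, T, 5mC`.
#' @export
base_symbols <- function() c("A", "C", "G", "T", "5mC")

parent_base_symbols <- function() c("5mC", "C", "T", "G")

#' Default analyte registry
#'
#' The 15 lesion species measured by the assay: five oxidation products of
#' 5-methylcytosine (5mC-Gly, 5mC-Hyd, 5mC-Imid, 5hmC, 5fC), five of cytosine
#' (U-Gly, U-Hyd, C-Imid, 5ohC, 5ohU -- the cytosine glycol and hydantoin
#' deaminate quantitatively during digestion, so the uracil derivatives are the
#' reported species), four of thymine (T-Gly, T-Hyd, 5hmU, 5fU) and 8oxoG.
#'
#' Deamination during enzymatic digestion links 5mC-Gly to T-Gly (an estimated
#' 20\% of the formed 5mC-Gly converts, from internal-standard loss) and
#' 5mC-Hyd to T-Hyd (a smaller leak, below 5\%; the default uses the
#' conservative 0.05 upper bound). Both fractions are configurable through the
#' registry table.
#'
#' Standard spikes default to the amounts of isotope-labeled internal standard
#' co-injected per digest: 3.0 pmol for the ring-saturated products analysed on
#' the porous-graphitic-carbon column and 8.3 pmol for the 5,6-unsaturated
#' products analysed on the reversed-phase column.
#'
#' @return A `data.frame` of class `analyte_registry` with columns
#'   `analyte_id`, `parent_base`, `pathway`, `deaminates_to`,
#'   `deamination_fraction`, `standard_spike_pmol`.
#' @examples
#' reg <- analyte_registry()
#' table(reg$parent_base)
#' @export
analyte_registry <- function() {
  reg <- data.frame(
    analyte_id = c("5mC-Gly", "5mC-Hyd", "5mC-Imid", "5hmC", "5fC",
                   "U-Gly", "U-Hyd", "C-Imid", "5ohC", "5ohU",
                   "T-Gly", "T-Hyd", "5hmU", "5fU",
                   "8oxoG"),
    parent_base = c(rep("5mC", 5), rep("C", 5), rep("T", 4), "G"),
    pathway = c("I-glycol", "II-hydantoin", "III-imidazolidine",
                "IV-methyl-hydroxy", "IV-methyl-formyl",
                "I-glycol", "II-hydantoin", "III-imidazolidine",
                "I-glycol", "I-glycol",
                "I-glycol", "II-hydantoin",
                "IV-methyl-hydroxy", "IV-methyl-formyl",
                "purine"),
    deaminates_to = c("T-Gly", "T-Hyd", NA, NA, NA, rep(NA, 10)),
    deamination_fraction = c(0.20, 0.05, 0, 0, 0, rep(0, 10)),
    standard_spike_pmol = c(3.0, 3.0, 3.0, 8.3, 8.3,
                            3.0, 3.0, 3.0, 8.3, 8.3,
                            3.0, 3.0, 8.3, 8.3,
                            8.3),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

#' Validate an analyte registry table
#'
#' Checks the registry schema and cross-references: known parent bases and
#' pathway classes, deamination fractions in `[0, 1]` (zero when no deamination
#' child is declared), and that every `deaminates_to` entry names a registered
#' analyte with a different parent base. Errors name the offending row.
#'
#' @param reg A data.frame with the registry columns.
#' @return The validated registry, classed `analyte_registry`.
#' @export
validate_registry <- function(reg) {
  required <- c("analyte_id", "parent_base", "pathway", "deaminates_to",
                "deamination_fraction", "standard_spike_pmol")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reg$analyte_id)) {
    stop("duplicate analyte_id in registry: ",
         paste(unique(reg$analyte_id[duplicated(reg$analyte_id)]), collapse = ", "))
  }
  for (i in seq_len(nrow(reg))) {
    row <- reg[i, ]
    if (!row$parent_base %in% parent_base_symbols()) {
      stop(sprintf("registry row '%s': unknown parent_base '%s'",
                   row$analyte_id, row$parent_base))
    }
    if (!row$pathway %in% pathway_classes()) {
      stop(sprintf("registry row '%s': unknown pathway '%s'",
                   row$analyte_id, row$pathway))
    }
    f <- row$deamination_fraction
    if (!is.finite(f) || f < 0 || f > 1) {
      stop(sprintf("registry row '%s': deamination_fraction %s outside [0, 1]",
                   row$analyte_id, format(f)))
    }
    if (is.na(row$deaminates_to)) {
      if (f != 0) {
        stop(sprintf(
          "registry row '%s': deamination_fraction must be 0 when deaminates_to is absent",
          row$analyte_id))
      }
    } else {
      j <- match(row$deaminates_to, reg$analyte_id)
      if (is.na(j)) {
        stop(sprintf("registry row '%s': deaminates_to '%s' is not a registered analyte",
                     row$analyte_id, row$deaminates_to))
      }
      if (reg$parent_base[j] == row$parent_base) {
        stop(sprintf(
          "registry row '%s': deamination must change the parent base ('%s' -> '%s')",
          row$analyte_id, row$parent_base, reg$parent_base[j]))
      }
    }
    if (!is.finite(row$standard_spike_pmol) || row$standard_spike_pmol <= 0) {
      stop(sprintf("registry row '%s': standard_spike_pmol must be > 0",
                   row$analyte_id))
    }
  }
  class(reg) <- c("analyte_registry", "data.frame")
  reg
}

#' Read an analyte registry from CSV
#'
#' Expects columns `analyte_id, parent_base, pathway, deaminates_to,
#' deamination_fraction, standard_spike_pmol`; empty `deaminates_to` cells are
#' treated as absent. Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @return A validated `analyte_registry`.
#' @export
read_analyte_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if ("deaminates_to" %in% names(reg)) {
    reg$deaminates_to[!is.na(reg$deaminates_to) &
                        !nzchar(trimws(reg$deaminates_to))] <- NA
  }
  validate_registry(reg)
}

#' Write an analyte registry to CSV
#'
#' Round-trips exactly through [read_analyte_registry()].
#'
#' @param reg An `analyte_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analyte_registry <- function(reg, path) {
  utils::write.csv(as.data.frame(reg), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Deamination edge set
#'
#' Builds the digestion-time deamination network: one edge per registry analyte
#' that declares a deamination child, plus (optionally) the virtual edges for
#' the unmeasurable cytosine glycol and hydantoin, which convert quantitatively
#' (fraction 1) to U-Gly and U-Hyd during digestion. Virtual edges carry
#' `virtual = TRUE` and are skipped by [correct_deamination()]: for those the
#' child analyte is itself the reported species.
#'
#' @param registry An `analyte_registry`.
#' @param include_virtual Include the quantitative C-Gly/C-Hyd edges.
#' @return data.frame with columns `parent`, `child`, `fraction`, `virtual`.
#' @export
deamination_edges <- function(registry = analyte_registry(),
                              include_virtual = TRUE) {
  has_edge <- !is.na(registry$deaminates_to) & registry$deamination_fraction > 0
  edges <- data.frame(
    parent = registry$analyte_id[has_edge],
    child = registry$deaminates_to[has_edge],
    fraction = registry$deamination_fraction[has_edge],
    virtual = FALSE,
    stringsAsFactors = FALSE
  )
  if (include_virtual) {
    edges <- rbind(edges, data.frame(
      parent = c("C-Gly", "C-Hyd"),
      child = c("U-Gly", "U-Hyd"),
      fraction = c(1, 1),
      virtual = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  if (any(edges$fraction >= 1 & !edges$virtual)) {
    stop("measurable deamination parents require fraction < 1")
  }
  edges
}
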