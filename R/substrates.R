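#' Default substrate composition table
#'
#' Base counts per duplex (both strands) for the irradiated substrates, plus
#' strand molarity used in melting analysis.
#'
#' The 12-mer entries derive from the Dickerson-Drew dodecamer
#' `CGCGAATTCGCG` (self-complementary): `ODN1:1` is the unmethylated duplex;
#' in `ODN2:2` two internal cytosines per strand are replaced by 5mC.
#'
#' The 19-mer compositions (`ODN3:4`, `ODN3:6`, `ODN5:6`) are *synthetic
#' reconstructions*: the original sequences are not published. They are modeled
#' as 19-mers with four CpG sites per strand (methylated on neither, one, or
#' both strands) plus two non-CpG cytosines per strand so that
#' 2'-deoxycytidine UV normalization remains defined, with Watson-Crick
#' consistent counts. All cross-substrate statistics in this package are
#' scale-invariant ratios, so these reconstructions only affect the synthetic
#' generator's normalization channel, not any reported comparison.
#'
#' `CT-DNA` (calf thymus, ~42\% GC) and `F98-cells` (rat glioma genomic DNA)
#' are given as base fractions; their 5mC content is expressed relative to
#' total cytosine (6.4\% of C for CT-DNA, ~4.5\% for mammalian cells).
#' Strand molarities for the oligonucleotide duplexes are estimates from the
#' 1.2 mg/ml irradiation concentration.
#'
#' @return data.frame with columns `substrate_id`, `A`, `C`, `G`, `T`, `mC`,
#'   `strand_molarity` (mol strands / L; `NA` for genomic DNA) and
#'   `self_complementary`.
#' @examples
#' subs <- default_substrates()
#' base_fraction(substrate_row(subs, "ODN1:1"), "C")
#' @export
default_substrates <- function() {
  ct_c <- 0.21 / 1.064          # unmodified C fraction, calf thymus
  ct_mc <- 0.21 * 0.064 / 1.064 # 5mC = 6.4% of total cytosine
  f98_c <- 0.21 / 1.045
  f98_mc <- 0.21 * 0.045 / 1.045
  data.frame(
    substrate_id = c("ODN1:1", "ODN2:2", "ODN3:4", "ODN3:6", "ODN5:6",
                     "CT-DNA", "F98-cells"),
    A = c(4, 4, 7, 7, 7, 0.29, 0.29),
    C = c(8, 4, 12, 8, 4, ct_c, f98_c),
    G = c(8, 8, 12, 12, 12, 0.21, 0.21),
    T = c(4, 4, 7, 7, 7, 0.29, 0.29),
    mC = c(0, 4, 0, 4, 8, ct_mc, f98_mc),
    strand_molarity = c(3.2e-4, 3.2e-4, 2.0e-4, 2.0e-4, 2.0e-4, NA, NA),
    self_complementary = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Select one substrate row
#'
#' @param substrates A substrate composition table.
#' @param substrate_id Identifier to select.
#' @return The single matching row.
#' @export
substrate_row <- function(substrates, substrate_id) {
  i <- match(substrate_id, substrates$substrate_id)
  if (is.na(i)) {
    stop(sprintf("unknown substrate_id '%s'", substrate_id))
  }
  substrates[i, , drop = FALSE]
}

#' Fraction of a base in a substrate
#'
#' Count (or fraction) of the base divided by the total over all five base
#' symbols, per duplex (both strands) -- damage yields are normalized to total
#' DNA bases, so counting is duplex-wide.
#'
#' @param comp A single substrate composition row (see [substrate_row()]).
#' @param base One of `A`, `C`, `G`, `T`, `5mC`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' base_fraction(substrate_row(default_substrates(), "ODN1:1"), "C") # 1/3
#' @export
base_fraction <- function(comp, base) {
  if (!base %in% base_symbols()) {
    stop(sprintf("unknown base '%s' (expected one of %s)",
                 base, paste(base_symbols(), collapse = ", ")))
  }
  if (nrow(comp) != 1) {
    stop("comp must be a single composition row; see substrate_row()")
  }
  col <- if (base == "5mC") "mC" else base
  counts <- as.numeric(comp[1, c("A", "C", "G", "T", "mC")])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("composition counts must be finite and nonnegative")
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("empty composition: base counts sum to zero")
  }
  as.numeric(comp[[col]][1]) / total
}

#' Read a substrate composition table from CSV
#'
#' Columns: `substrate_id,A,C,G,T,mC,strand_molarity,self_complementary`.
#' @param path Path to the CSV file.
#' @return data.frame of compositions.
#' @export
read_substrates <- function(path) {
  subs <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  required <- c("substrate_id", "A", "C", "G", "T", "mC")
  missing_cols <- setdiff(required, names(subs))
  if (length(missing_cols) > 0) {
    stop("substrate table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  subs
}

#' Read a sample manifest from CSV
#'
#' Columns: `sample_id,substrate_id,dose,replicate,context`. Doses must be
#' nonnegative and replicates positive integers.
#' @param path Path to the CSV file.
#' @return data.frame of sample records.
#' @export
read_samples <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "substrate_id", "dose", "replicate")
  missing_cols <- setdiff(required, names(s))
  if (length(missing_cols) > 0) {
    stop("sample manifest missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(s$dose < 0)) stop("sample manifest: dose must be >= 0")
  if (any(s$replicate < 1)) stop("sample manifest: replicate must be >= 1")
  s
}
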