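#' Fraction converted by first-order decay
#'
#' First-order kinetics helper for configuring deamination scenarios from a
#' half-life: the fraction of a species converted after time `t` is
#' `1 - 2^(-t / half_life)`.
#'
#' @param t Elapsed time (hours, or any unit matching `half_life`), `>= 0`.
#' @param half_life Half-life in the same unit, `> 0`.
#' @return Fraction converted, in `[0, 1)` for finite `t` (vectorized).
#' @examples
#' fraction_converted(20, 20) # 0.5 after one half-life
#' fraction_converted(2, 20)  # ~0.067 over a 2 h digestion
#' @export
fraction_converted <- function(t, half_life) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  if (any(!is.finite(half_life)) || any(half_life <= 0)) {
    stop("half_life must be > 0")
  }
  1 - 2^(-t / half_life)
}

#' Undo digestion-time deamination in a yield table
#'
#' During enzymatic digestion a fraction `f` of each formed deamination-prone
#' lesion converts to its deaminated counterpart (e.g. 5mC-Gly to T-Gly), so
#' the measured parent is depleted and the measured child inflated. For each
#' edge with a measurable parent:
#' \deqn{formed = measured_{parent} / (1 - f)}
#' the corrected parent is `formed` and the corrected child is
#' `measured_child - formed * f` (floored at zero with a warning, since noise
#' can drive small negatives). Virtual edges (`fraction = 1`, the quantitative
#' C-Gly/C-Hyd conversions) are skipped: there the child analyte is itself the
#' reported species.
#'
#' The correction must be applied exactly once; the output carries attribute
#' `corrected = TRUE` and the function refuses already-corrected input.
#' When no flooring occurs the correction conserves moles per edge:
#' corrected parent + corrected child = measured parent + measured child.
#'
#' @param yields A `yield_table` from [build_yield_table()].
#' @param edges Edge set from [deamination_edges()] (columns `parent`,
#'   `child`, `fraction`, optional `virtual`).
#' @return The corrected `yield_table` (attribute `corrected = TRUE`).
#' @examples
#' yt <- data.frame(sample_id = "s1",
#'                  analyte_id = c("5mC-Gly", "T-Gly"),
#'                  yield = c(0.80, 2.00), status = "ok")
#' attr(yt, "corrected") <- FALSE
#' ed <- data.frame(parent = "5mC-Gly", child = "T-Gly",
#'                  fraction = 0.2, virtual = FALSE)
#' correct_deamination(yt, ed)$yield # 1.00, 1.80
#' @export
correct_deamination <- function(yields, edges) {
  if (isTRUE(attr(yields, "corrected"))) {
    stop("yield table is already deamination-corrected; the correction must be applied exactly once")
  }
  if (!all(c("parent", "child", "fraction") %in% names(edges))) {
    stop("edges require columns parent, child, fraction")
  }
  if (!"virtual" %in% names(edges)) edges$virtual <- edges$fraction >= 1
  live <- edges[!edges$virtual, , drop = FALSE]
  if (any(live$fraction >= 1)) {
    stop("deamination fraction must be < 1 for a measurable parent")
  }
  if (any(live$fraction < 0)) stop("deamination fraction must be >= 0")
  # acyclicity: a parent may not also appear as a child of another live edge
  if (length(intersect(live$parent, live$child)) > 0) {
    stop("deamination edge set must be acyclic")
  }

  out <- yields
  for (k in seq_len(nrow(live))) {
    p <- live$parent[k]; ch <- live$child[k]; f <- live$fraction[k]
    if (f == 0) next
    for (s in unique(out$sample_id)) {
      ip <- which(out$sample_id == s & out$analyte_id == p)
      ic <- which(out$sample_id == s & out$analyte_id == ch)
      if (length(ip) == 0) next
      if (out$status[ip] != "ok" || is.na(out$yield[ip])) next
      formed <- out$yield[ip] / (1 - f)
      transfer <- formed * f
      out$yield[ip] <- formed
      if (length(ic) == 1 && out$status[ic] == "ok" && !is.na(out$yield[ic])) {
        corrected_child <- out$yield[ic] - transfer
        if (corrected_child < 0) {
          warning(sprintf(
            "sample %s: corrected %s would be %.4g; floored at 0",
            s, ch, corrected_child))
          corrected_child <- 0
        }
        out$yield[ic] <- corrected_child
      } else if (transfer > 0) {
        warning(sprintf(
          "sample %s: deamination child %s not measured; transfer from %s not subtracted",
          s, ch, p))
      }
    }
  }
  attr(out, "corrected") <- TRUE
  out
}

#' Read a deamination edge set from CSV
#'
#' Columns `parent,child,fraction` (optional `virtual`).
#' @param path Path to the CSV file.
#' @return data.frame of edges.
#' @export
read_deamination_edges <- function(path) {
  ed <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("parent", "child", "fraction") %in% names(ed))) {
    stop("edges file requires columns parent, child, fraction")
  }
  if (!"virtual" %in% names(ed)) ed$virtual <- ed$fraction >= 1
  ed
}
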