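#' Ordinary least-squares dose-response rate for one series
#'
#' Fits `yield ~ dose` by OLS and reports the slope (lesions per 1e6 bases per
#' dose unit), intercept (baseline level at dose zero) and coefficient of
#' determination. A fit with `r2 <= r2_flag` is flagged, not rejected: the
#' linearity threshold is a quality indicator of the assay, not a filter.
#'
#' @param dose Numeric doses (at least 3 distinct values).
#' @param yield Lesion yields, same length.
#' @param r2_flag Flagging threshold for `r2` (default 0.95).
#' @return List with `slope`, `intercept`, `r2` (`NA` for an exactly flat
#'   series), `n` and `flagged`.
#' @export
fit_rate <- function(dose, yield, r2_flag = 0.95) {
  keep <- is.finite(dose) & is.finite(yield)
  dose <- dose[keep]; yield <- yield[keep]
  if (length(dose) < 3) stop("need at least 3 observations to fit a rate")
  n_distinct <- length(unique(dose))
  if (n_distinct == 1) stop("all doses are identical; cannot estimate a rate")
  if (n_distinct < 3) stop("need at least 3 distinct doses to fit a rate")
  fit <- stats::lm(yield ~ dose)
  cf <- stats::coef(fit)
  sst <- sum((yield - mean(yield))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  flagged <- !is.na(r2) && r2 <= r2_flag
  list(slope = unname(cf["dose"]), intercept = unname(cf["(Intercept)"]),
       r2 = r2, n = length(dose), flagged = flagged)
}

#' Aggregate per-replicate rate fits
#'
#' Replicates are independent experiments; the reported rate is the mean of
#' the replicate slopes and its SD the sample standard deviation across
#' replicates. With a single replicate the SD is unavailable (`NA`).
#'
#' @param fits data.frame with one row per replicate and columns `slope`,
#'   `intercept`, `r2`.
#' @return List with `slope`, `slope_sd`, `intercept`, `r2` (mean of replicate
#'   values) and `n_replicates`.
#' @export
aggregate_replicates <- function(fits) {
  if (nrow(fits) < 1) stop("no replicate fits to aggregate")
  n <- nrow(fits)
  list(slope = mean(fits$slope),
       slope_sd = if (n >= 2) stats::sd(fits$slope) else NA_real_,
       intercept = mean(fits$intercept),
       r2 = mean(fits$r2, na.rm = TRUE),
       n_replicates = n)
}

#' Fit dose-response rates for every substrate and analyte
#'
#' The central model of the workflow: for each substrate x analyte, the yield
#' (lesions per 1e6 DNA bases) grows linearly with absorbed dose. Each
#' replicate experiment (a full dose series) is fitted by OLS; replicate
#' slopes are averaged and their SD reported. The pooled-fit `r2` over all
#' points is reported as the linearity diagnostic.
#'
#' @param yields A `yield_table` (ideally deamination-corrected).
#' @param samples Sample manifest with columns `sample_id`, `substrate_id`,
#'   `dose`, `replicate`.
#' @param registry An [analyte_registry()].
#' @param r2_flag Linearity flag threshold passed to [fit_rate()].
#' @return An object of class `lesion_rates`: a list with `rates` (data.frame
#'   `substrate_id, analyte_id, slope, slope_sd, intercept, r2, n_replicates,
#'   flagged`), `replicate_fits`, `data`, `registry`, `not_detected`, `call`.
#' @seealso [total_damage()], [product_distribution()], [predict.lesion_rates()]
#' @export
fit_dose_response <- function(yields, samples, registry = analyte_registry(),
                              r2_flag = 0.95) {
  required <- c("sample_id", "substrate_id", "dose", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample manifest missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  d <- merge(as.data.frame(yields), samples, by = "sample_id")
  if (nrow(d) == 0) stop("no yields match the sample manifest")

  rate_rows <- list()
  rep_fits <- list()
  not_detected <- character(0)
  for (sub in unique(d$substrate_id)) {
    ds <- d[d$substrate_id == sub, , drop = FALSE]
    for (an in intersect(registry$analyte_id, unique(ds$analyte_id))) {
      da <- ds[ds$analyte_id == an & ds$status == "ok" &
                 is.finite(ds$yield), , drop = FALSE]
      if (nrow(da) == 0) {
        not_detected <- c(not_detected, paste(sub, an, sep = " / "))
        next
      }
      per_rep <- lapply(split(da, da$replicate), function(dr) {
        f <- fit_rate(dr$dose, dr$yield, r2_flag = r2_flag)
        data.frame(replicate = dr$replicate[1], slope = f$slope,
                   intercept = f$intercept, r2 = f$r2)
      })
      per_rep <- do.call(rbind, per_rep)
      agg <- aggregate_replicates(per_rep)
      pooled <- fit_rate(da$dose, da$yield, r2_flag = r2_flag)
      key <- paste(sub, an, sep = " / ")
      rep_fits[[key]] <- per_rep
      rate_rows[[key]] <- data.frame(
        substrate_id = sub, analyte_id = an,
        slope = agg$slope, slope_sd = agg$slope_sd,
        intercept = agg$intercept, r2 = pooled$r2,
        n_replicates = agg$n_replicates,
        flagged = !is.na(pooled$r2) && pooled$r2 <= r2_flag,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rate_rows) == 0) stop("no analyte had quantifiable yields")
  rates <- do.call(rbind, rate_rows)
  rownames(rates) <- NULL
  structure(list(rates = rates, replicate_fits = rep_fits, data = d,
                 registry = registry, not_detected = not_detected,
                 r2_flag = r2_flag, call = match.call()),
            class = "lesion_rates")
}

#' @export
print.lesion_rates <- function(x, ...) {
  cat("Dose-response lesion formation rates\n")
  cat(sprintf("  %d substrate/analyte series, %d replicate fits\n",
              nrow(x$rates), sum(x$rates$n_replicates)))
  if (any(x$rates$flagged)) {
    cat(sprintf("  %d series flagged with r2 <= %.2f\n",
                sum(x$rates$flagged), x$r2_flag))
  }
  print(format(x$rates, digits = 4), ...)
  invisible(x)
}

#' @export
coef.lesion_rates <- function(object, ...) {
  m <- as.matrix(object$rates[, c("slope", "intercept")])
  rownames(m) <- paste(object$rates$substrate_id, object$rates$analyte_id,
                       sep = ":")
  m
}

#' Expected yields at new doses
#'
#' @param object A `lesion_rates` fit.
#' @param doses Numeric doses at which to predict.
#' @param substrate_id,analyte_id Optional filters.
#' @param ... Unused.
#' @return data.frame `substrate_id, analyte_id, dose, yield`.
#' @export
predict.lesion_rates <- function(object, doses, substrate_id = NULL,
                                 analyte_id = NULL, ...) {
  r <- object$rates
  if (!is.null(substrate_id)) r <- r[r$substrate_id %in% substrate_id, ]
  if (!is.null(analyte_id)) r <- r[r$analyte_id %in% analyte_id, ]
  if (nrow(r) == 0) stop("no fitted series match the requested filter")
  out <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    data.frame(substrate_id = r$substrate_id[i], analyte_id = r$analyte_id[i],
               dose = doses, yield = r$intercept[i] + r$slope[i] * doses)
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.lesion_rates <- function(object, ...) {
  totals <- list()
  for (sub in unique(object$rates$substrate_id)) {
    rsub <- object$rates[object$rates$substrate_id == sub, ]
    for (pb in intersect(parent_base_symbols(),
                         object$registry$parent_base[
                           object$registry$analyte_id %in% rsub$analyte_id])) {
      td <- suppressWarnings(total_damage(rsub, object$registry, pb))
      totals[[paste(sub, pb)]] <- data.frame(
        substrate_id = sub, parent_base = pb,
        total = td$total, total_sd = td$total_sd, n_members = td$n,
        stringsAsFactors = FALSE)
    }
  }
  totals <- do.call(rbind, totals)
  rownames(totals) <- NULL
  structure(list(rates = object$rates, totals = totals,
                 not_detected = object$not_detected),
            class = "summary.lesion_rates")
}

#' @export
print.summary.lesion_rates <- function(x, ...) {
  cat("Rates (lesions / 1e6 bases per dose unit):\n")
  print(format(x$rates, digits = 4))
  cat("\nTotal damage by parent base:\n")
  print(format(x$totals, digits = 4))
  if (length(x$not_detected) > 0) {
    cat("\nNot detected:", paste(x$not_detected, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Plot one fitted dose-response series
#'
#' @param x A `lesion_rates` fit.
#' @param substrate_id,analyte_id Series to plot.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lesion_rates <- function(x, substrate_id, analyte_id, ...) {
  d <- x$data[x$data$substrate_id == substrate_id &
                x$data$analyte_id == analyte_id & x$data$status == "ok", ]
  if (nrow(d) == 0) stop("no data for that substrate/analyte")
  r <- x$rates[x$rates$substrate_id == substrate_id &
                 x$rates$analyte_id == analyte_id, ]
  graphics::plot(d$dose, d$yield, pch = 19,
                 col = as.integer(factor(d$replicate)),
                 xlab = "dose", ylab = "lesions / 1e6 bases",
                 main = paste(substrate_id, analyte_id, sep = " : "), ...)
  graphics::abline(r$intercept, r$slope)
  invisible(x)
}

#' Total damage at a parent base
#'
#' Sums the member analyte rates of one parent base. Following the
#' convention of the underlying assay, the SD of the total is the *plain sum*
#' of the member SDs (a conservative, fully-correlated propagation);
#' `sd_mode = "quadrature"` gives the independent-error alternative.
#' Members absent from the table (not detected) are excluded with a warning.
#'
#' @param rates A `lesion_rates` object or a data.frame with columns
#'   `analyte_id`, `slope` and (optionally) `slope_sd`.
#' @param registry An [analyte_registry()].
#' @param parent_base One of `5mC`, `C`, `T`, `G`.
#' @param sd_mode `"sum"` (default) or `"quadrature"`.
#' @return List with `parent_base`, `total`, `total_sd`, `members`
#'   (contributing analytes) and `n`.
#' @export
total_damage <- function(rates, registry = analyte_registry(), parent_base,
                         sd_mode = c("sum", "quadrature")) {
  sd_mode <- match.arg(sd_mode)
  if (inherits(rates, "lesion_rates")) rates <- rates$rates
  if (!parent_base %in% parent_base_symbols()) {
    stop(sprintf("unknown parent_base '%s'", parent_base))
  }
  members <- registry$analyte_id[registry$parent_base == parent_base]
  rows <- rates[rates$analyte_id %in% members & !is.na(rates$slope), ,
                drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no measured members for parent base %s", parent_base))
  }
  absent <- setdiff(members, rows$analyte_id)
  if (length(absent) > 0) {
    warning("members excluded (not detected): ",
            paste(absent, collapse = ", "))
  }
  sds <- if ("slope_sd" %in% names(rows)) rows$slope_sd else rep(NA_real_, nrow(rows))
  total_sd <- if (all(is.finite(sds))) {
    if (sd_mode == "sum") sum(sds) else sqrt(sum(sds^2))
  } else NA_real_
  list(parent_base = parent_base, total = sum(rows$slope),
       total_sd = total_sd, members = rows$analyte_id, n = nrow(rows))
}
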