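# Seeded generator of pipeline inputs with the statistical structure the
# analysis assumes: linear dose-response yields with replicate noise,
# non-zero cellular baselines, digestion-time deamination leakage, and
# isotope-dilution peak-area pairs.

#' Configuration for the synthetic MRM dataset generator
#'
#' @param true_rates Named numeric: lesion formation slope per analyte
#'   (lesions / 1e6 bases per dose unit). Every name must be registered.
#' @param baselines Named numeric: lesions / 1e6 bases at dose zero
#'   (defaults to 0 for every analyte in `true_rates`).
#' @param doses Dose grid (in `dose_unit`).
#' @param n_replicates Independent experiments per dose.
#' @param cv_area Coefficient of variation of the measured area ratio,
#'   in `[0, 0.5]`.
#' @param digestion_leak Apply the forward deamination transfer before
#'   "measurement".
#' @param seed Integer seed; the same seed reproduces the tables bit for bit.
#' @param substrate_id Substrate the samples come from.
#' @param context `"isolated"` or `"cellular"`.
#' @param dose_unit `"Gy"` or `"kGy"`; slopes and doses share this unit.
#' @param total_bases_pmol DNA amount per digest, pmol of bases.
#' @param labeled_area Nominal labeled-standard peak area (arbitrary units).
#' @return A `synth_config` list.
#' @export
synth_config <- function(true_rates, baselines = NULL,
                         doses = c(0, 25, 50, 100, 150, 200),
                         n_replicates = 3, cv_area = 0.05,
                         digestion_leak = TRUE, seed = 1L,
                         substrate_id = "ODN5:6",
                         context = c("isolated", "cellular"),
                         dose_unit = c("Gy", "kGy"),
                         total_bases_pmol = 1e5, labeled_area = 1e5) {
  context <- match.arg(context)
  dose_unit <- match.arg(dose_unit)
  if (is.null(names(true_rates)) || any(!nzchar(names(true_rates)))) {
    stop("true_rates must be a named numeric vector")
  }
  if (any(!is.finite(true_rates)) || any(true_rates < 0)) {
    stop("true_rates must be finite and >= 0")
  }
  if (is.null(baselines)) {
    baselines <- stats::setNames(rep(0, length(true_rates)), names(true_rates))
  }
  if (any(!is.finite(baselines)) || any(baselines < 0)) {
    stop("baselines must be finite and >= 0")
  }
  if (!is.finite(cv_area) || cv_area < 0 || cv_area > 0.5) {
    stop("cv_area must lie in [0, 0.5]")
  }
  if (any(doses < 0)) stop("doses must be >= 0")
  structure(list(true_rates = true_rates, baselines = baselines,
                 doses = doses, n_replicates = n_replicates,
                 cv_area = cv_area, digestion_leak = digestion_leak,
                 seed = as.integer(seed), substrate_id = substrate_id,
                 context = context, dose_unit = dose_unit,
                 total_bases_pmol = total_bases_pmol,
                 labeled_area = labeled_area),
            class = "synth_config")
}

#' Default generator configuration for isolated DNA
#'
#' True rates are the bundled reference rates for the chosen substrate (see
#' [reference_rates()]), doses span the 0-200 Gy exposure range, with three
#' independent replicate experiments -- the conditions of the isolated-DNA
#' irradiations this generator emulates.
#'
#' @param substrate_id Substrate whose reference rates to use.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
isolated_config <- function(substrate_id = "ODN5:6", ...) {
  ref <- reference_rates("isolated")
  ref <- ref[ref$substrate_id == substrate_id, , drop = FALSE]
  if (nrow(ref) == 0) stop("no reference rates for ", substrate_id)
  rates <- stats::setNames(ref$slope, ref$analyte_id)
  defaults <- list(true_rates = rates, doses = c(0, 25, 50, 100, 150, 200),
                   n_replicates = 3, substrate_id = substrate_id,
                   context = "isolated", dose_unit = "Gy")
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

#' Default generator configuration for cellular DNA
#'
#' True rates (per kGy) and non-irradiated baselines are the bundled cellular
#' reference values; doses span 0-4 kGy with five independent experiments.
#'
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
cellular_config <- function(...) {
  ref <- reference_rates("cellular")
  rates <- stats::setNames(ref$slope, ref$analyte_id)
  baselines <- stats::setNames(ref$baseline, ref$analyte_id)
  defaults <- list(true_rates = rates, baselines = baselines,
                   doses = 0:4, n_replicates = 5,
                   substrate_id = "F98-cells", context = "cellular",
                   dose_unit = "kGy")
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

#' Generate a synthetic MRM dataset
#'
#' For each dose and replicate the true yield of each analyte is
#' `baseline + slope * dose`. With `digestion_leak` on, the forward
#' deamination transfer moves fraction `f` of each deamination-prone parent's
#' formed amount to its child analyte before "measurement" (the inverse of
#' [correct_deamination()]). Yields are converted to pmol against the
#' configured DNA amount and emitted as natural/labeled peak-area pairs
#' consistent with the isotope-dilution equation.
#'
#' Noise model: a shared per-injection multiplicative factor scales both
#' channels of a record (it cancels in the area ratio, which is the point of
#' internal standardization), and mean-one Gaussian noise with CV `cv_area`
#' multiplies the natural/labeled ratio. With `cv_area = 0` the dataset is an
#' exact noiseless image of the configured truth.
#'
#' @param cfg A [synth_config()].
#' @param registry An [analyte_registry()].
#' @param substrates Substrate composition table containing
#'   `cfg$substrate_id`.
#' @return List of class `mrm_dataset` with `samples`, `peaks`, `readings`,
#'   `truth` (pre-leak true yields) and `config`.
#' @export
simulate_mrm_dataset <- function(cfg, registry = analyte_registry(),
                                 substrates = default_substrates()) {
  stopifnot(inherits(cfg, "synth_config"))
  unknown <- setdiff(names(cfg$true_rates), registry$analyte_id)
  if (length(unknown) > 0) {
    stop("true_rates name unregistered analytes: ",
         paste(unknown, collapse = ", "))
  }
  comp <- substrate_row(substrates, cfg$substrate_id)
  dC_fraction <- base_fraction(comp, "C")
  if (dC_fraction <= 0) {
    stop("substrate has no unmodified cytosine; dC normalization undefined")
  }
  set.seed(cfg$seed)

  grid <- expand.grid(dose = cfg$doses, replicate = seq_len(cfg$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  grid$sample_id <- sprintf("%s_d%g_r%d", gsub("[^A-Za-z0-9]", "", cfg$substrate_id),
                            grid$dose, grid$replicate)
  samples <- data.frame(sample_id = grid$sample_id,
                        substrate_id = cfg$substrate_id,
                        dose = grid$dose, replicate = grid$replicate,
                        context = cfg$context,
                        stringsAsFactors = FALSE)

  analytes <- names(cfg$true_rates)
  n_s <- nrow(samples)
  truth <- expand.grid(sample_id = samples$sample_id, analyte_id = analytes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$dose <- samples$dose[match(truth$sample_id, samples$sample_id)]
  base <- ifelse(is.na(cfg$baselines[truth$analyte_id]), 0,
                 cfg$baselines[truth$analyte_id])
  truth$true_yield <- as.numeric(base +
                                   cfg$true_rates[truth$analyte_id] * truth$dose)

  measured <- truth$true_yield
  if (cfg$digestion_leak) {
    edges <- deamination_edges(registry, include_virtual = FALSE)
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]; ch <- edges$child[k]; f <- edges$fraction[k]
      ip <- truth$analyte_id == p
      ic <- truth$analyte_id == ch
      if (!any(ip)) next
      transfer <- truth$true_yield[ip] * f
      measured[ip] <- truth$true_yield[ip] - transfer
      if (any(ic)) {
        # rows are ordered identically by sample within each analyte block
        measured[ic] <- measured[ic] + transfer
      }
    }
  }
  if (any(measured < 0)) {
    stop("inconsistent configuration: negative measured amounts")
  }

  amount_pmol <- measured * 1e-6 * cfg$total_bases_pmol
  spike <- registry$standard_spike_pmol[match(truth$analyte_id,
                                              registry$analyte_id)]
  n_rec <- nrow(truth)
  if (cfg$cv_area > 0) {
    injection <- exp(stats::rnorm(n_rec, 0, 0.1))
    ratio_noise <- pmax(1 + cfg$cv_area * stats::rnorm(n_rec), 0.01)
  } else {
    injection <- rep(1, n_rec)
    ratio_noise <- rep(1, n_rec)
  }
  area_labeled <- cfg$labeled_area * injection
  area_natural <- (amount_pmol / spike) * area_labeled * ratio_noise

  peaks <- data.frame(sample_id = truth$sample_id,
                      analyte_id = truth$analyte_id,
                      area_natural = area_natural,
                      area_labeled = area_labeled,
                      standard_spike_pmol = spike,
                      stringsAsFactors = FALSE)
  readings <- data.frame(sample_id = samples$sample_id,
                         dC_pmol = cfg$total_bases_pmol * dC_fraction,
                         dC_fraction = dC_fraction,
                         stringsAsFactors = FALSE)
  structure(list(samples = samples, peaks = peaks, readings = readings,
                 truth = truth[, c("sample_id", "analyte_id", "true_yield")],
                 config = cfg),
            class = "mrm_dataset")
}

#' @export
print.mrm_dataset <- function(x, ...) {
  cat(sprintf("Synthetic MRM dataset: %d samples x %d analytes (%s, seed %d)\n",
              nrow(x$samples), length(unique(x$peaks$analyte_id)),
              x$config$substrate_id, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Emits `samples.csv`, `peaks.csv`, `dc_readings.csv` (and `truth.csv`) into
#' a directory, each with a header comment recording the generator seed.
#'
#' @param ds An `mrm_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mrm_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# generator seed: %d", ds$config$seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  emit(ds$samples, "samples.csv")
  emit(ds$peaks, "peaks.csv")
  emit(ds$readings, "dc_readings.csv")
  emit(ds$truth, "truth.csv")
  invisible(dir)
}

#' Slope and baseline recovery study
#'
#' Calibration check of the whole chain generate -> quantify -> correct ->
#' fit: over `n_seeds` independently seeded synthetic datasets, compares the
#' mean fitted slope (and intercept) per analyte with the configured truth,
#' reporting the Monte Carlo standard error and the z-score of the
#' discrepancy. Under an unbiased pipeline the z-scores are standard normal.
#'
#' @param n_seeds Number of seeded repetitions.
#' @param base_seed Seeds used are `base_seed + 1, ..., base_seed + n_seeds`.
#' @param cfg A [synth_config()] whose `seed` field is overridden per run.
#' @param registry,substrates Passed through to the generator and fits.
#' @return data.frame per analyte: true slope/baseline, mean and SE of the
#'   fitted values, and z-scores `z_slope`, `z_intercept`.
#' @export
recovery_study <- function(n_seeds = 200, base_seed = 0,
                           cfg = cellular_config(n_replicates = 3,
                                                 cv_area = 0.1),
                           registry = analyte_registry(),
                           substrates = default_substrates()) {
  analytes <- names(cfg$true_rates)
  slopes <- matrix(NA_real_, n_seeds, length(analytes),
                   dimnames = list(NULL, analytes))
  intercepts <- slopes
  edges <- deamination_edges(registry)
  for (i in seq_len(n_seeds)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + i)
    ds <- simulate_mrm_dataset(cfg_i, registry, substrates)
    yt <- build_yield_table(ds$peaks, ds$readings, registry)
    yt <- correct_deamination(yt, edges)
    fit <- fit_dose_response(yt, ds$samples, registry)
    idx <- match(analytes, fit$rates$analyte_id)
    slopes[i, ] <- fit$rates$slope[idx]
    intercepts[i, ] <- fit$rates$intercept[idx]
  }
  se <- function(m) apply(m, 2, stats::sd) / sqrt(n_seeds)
  truth_b <- ifelse(is.na(cfg$baselines[analytes]), 0, cfg$baselines[analytes])
  out <- data.frame(
    analyte_id = analytes,
    true_slope = as.numeric(cfg$true_rates[analytes]),
    mean_slope = colMeans(slopes),
    se_slope = se(slopes),
    true_baseline = as.numeric(truth_b),
    mean_intercept = colMeans(intercepts),
    se_intercept = se(intercepts),
    stringsAsFactors = FALSE)
  out$z_slope <- (out$mean_slope - out$true_slope) / out$se_slope
  out$z_intercept <- (out$mean_intercept - out$true_baseline) / out$se_intercept
  rownames(out) <- NULL
  out
}
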