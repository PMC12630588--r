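## Orchestration: the two analysis workflows and the synthetic harness.
## Every run writes its outputs plus a manifest that makes it reproducible.

.pkgVersion <- function() {
  as.character(utils::packageVersion("cppaint"))
}

.writeManifest <- function(dir, command, params, inputs = character(),
                           counts = integer()) {
  lines <- c(
    paste0("command = ", command),
    paste0("package = cppaint ", .pkgVersion()),
    vapply(names(params), function(k)
      paste0(k, " = ", paste(params[[k]], collapse = ",")), character(1))
  )
  if (length(inputs)) {
    md5 <- tools::md5sum(inputs)
    lines <- c(lines, vapply(seq_along(inputs), function(i)
      paste0("input.", basename(inputs[i]), ".md5 = ", md5[i]),
      character(1)))
  }
  lines <- c(lines, vapply(names(counts), function(k)
    paste0("count.", k, " = ", counts[[k]]), character(1)))
  ## the manifest records a digest of its own configuration block
  tmp <- tempfile(); writeLines(lines, tmp)
  lines <- c(lines, paste0("config.md5 = ", unname(tools::md5sum(tmp))))
  unlink(tmp)
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(file.path(dir, "manifest.txt"))
}

#' Quantification workflow: measurements to site and comparison tables
#'
#' Runs QC filtering, site aggregation and -- when at least two conditions
#' are present -- per-site ANOVA with FDR correction and significance tiers,
#' writing `site_accessibility.tsv`, `rejections.tsv`, `comparisons.tsv`,
#' `condition_matrix.tsv`, a `swap_consistency.tsv` when a swap run is
#' supplied, and a `manifest.txt` with stage counts. Configuration or schema
#' errors abort before any output is written.
#'
#' @param forward path to a forward-orientation measurement TSV, or a
#'   [CPPMeasurements-class] object.
#' @param swap optional path or object for the label-swap run.
#' @param outDir output directory (created if absent).
#' @param filter a [FilterConfig-class].
#' @param fdrMethod `"BH"` or `"BKY"`.
#' @param swapTolerance label-swap concordance tolerance (percentage
#'   points).
#' @param mode aggregation mode, see [aggregateSites()].
#' @return Invisibly, a list with `sites`, `rejected`, `comparisons`,
#'   `matrix`, `swap` (or `NULL`).
#' @export
runQuantifyWorkflow <- function(forward, swap = NULL, outDir,
                                filter = FilterConfig(),
                                fdrMethod = c("BH", "BKY"),
                                swapTolerance = 10,
                                mode = c("measurement", "replicate")) {
  fdrMethod <- match.arg(fdrMethod)
  mode <- match.arg(mode)
  inputs <- character()
  if (is.character(forward)) {
    inputs <- c(inputs, forward)
    forward <- readMeasurementTable(forward, "forward")
  }
  if (is.character(swap)) {
    inputs <- c(inputs, swap)
    swap <- readMeasurementTable(swap, "swap")
  }
  stopifnot(is(forward, "CPPMeasurements"))

  filtered <- applyQCFilters(forward, filter)
  sites <- aggregateSites(filtered$retained, mode)
  n_cond <- length(unique(sites$condition))
  comparisons <- NULL
  if (n_cond >= 2) {
    comparisons <- compareConditions(filtered$retained, fdrMethod)
  } else {
    message("single condition: comparison stage skipped")
  }
  cmatrix <- conditionMatrix(sites)

  swap_out <- NULL
  if (!is.null(swap)) {
    sw_filtered <- applyQCFilters(swap, filter)
    sw_sites <- aggregateSites(sw_filtered$retained, mode)
    swap_out <- mergeLabelSwap(sites, sw_sites, swapTolerance)
  }

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeSiteTable(sites, file.path(outDir, "site_accessibility.tsv"))
  utils::write.table(filtered$rejected, file.path(outDir, "rejections.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(comparisons))
    writeSiteTable(comparisons, file.path(outDir, "comparisons.tsv"))
  writeSiteTable(cmatrix, file.path(outDir, "condition_matrix.tsv"))
  if (!is.null(swap_out))
    writeSiteTable(swap_out$consistency,
                   file.path(outDir, "swap_consistency.tsv"))

  .writeManifest(outDir, "quantify",
                 params = list(fdr_method = fdrMethod, mode = mode,
                               min_determinant_factor =
                                 filter@minDeterminantFactor,
                               min_profile_score = filter@minProfileScore,
                               allow_rt_shift = filter@allowRtShift,
                               swap_tolerance = swapTolerance),
                 inputs = inputs,
                 counts = c(measurements_in = nrow(measurements(forward)),
                            rejected = nrow(filtered$rejected),
                            sites = nrow(sites),
                            comparisons =
                              if (is.null(comparisons)) 0L
                              else nrow(comparisons)))
  invisible(list(sites = sites, rejected = filtered$rejected,
                 comparisons = comparisons, matrix = cmatrix,
                 swap = swap_out))
}

#' Structure-concordance workflow
#'
#' Computes rolling-probe epsilon-amine SASA and accessibility classes for
#' every site of a per-site accessibility table in each supplied structure,
#' scores agreement with the CPP classes, and writes `concordance.tsv` plus
#' a manifest. Unreadable structures abort with the file name.
#'
#' @param siteTable data.frame from [aggregateSites()] (or a path to one
#'   written by [writeSiteTable()]), restricted to one condition.
#' @param pdbPaths named character vector of PDB file paths; names become
#'   structure identifiers.
#' @param outDir output directory.
#' @param chain optional chain identifier.
#' @param config a [SASAConfig-class].
#' @param thresholds a [ClassThresholds-class].
#' @param accessibleMin,partialMin CPP bin boundaries (percent).
#' @return Invisibly, the concordance data.frame.
#' @export
runStructureWorkflow <- function(siteTable, pdbPaths, outDir, chain = NULL,
                                 config = SASAConfig(),
                                 thresholds = ClassThresholds(),
                                 accessibleMin = 90, partialMin = 50) {
  inputs <- character()
  if (is.character(siteTable)) {
    inputs <- c(inputs, siteTable)
    siteTable <- readSiteTable(siteTable)
  }
  if (is.null(names(pdbPaths)))
    names(pdbPaths) <- tools::file_path_sans_ext(basename(pdbPaths))
  struct <- do.call(rbind, lapply(names(pdbPaths), function(id) {
    pdb <- tryCatch(bio3d::read.pdb(pdbPaths[[id]]),
                    error = function(e)
                      stop("cannot read structure file ", pdbPaths[[id]],
                           ": ", conditionMessage(e), call. = FALSE))
    structureSiteSasa(pdb, unique(siteTable$residue), id, chain,
                      config, thresholds)
  }))
  conc <- concordance(siteTable, struct, accessibleMin, partialMin)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeSiteTable(conc, file.path(outDir, "concordance.tsv"))
  .writeManifest(outDir, "structure",
                 params = list(probe_radius = config@probeRadius,
                               n_sphere_points = config@nSpherePoints,
                               inaccessible_max = thresholds@inaccessibleMax,
                               partial_max = thresholds@partialMax,
                               accessible_min_pct = accessibleMin,
                               partial_min_pct = partialMin),
                 inputs = c(inputs, unname(pdbPaths)),
                 counts = c(sites = length(unique(siteTable$residue)),
                            structures = length(pdbPaths),
                            unmapped = sum(conc$structure_class == "unmapped")))
  invisible(conc)
}

#' Synthetic-experiment workflow
#'
#' Generates a seeded synthetic CPP experiment, runs the quantification
#' pipeline on it, and writes truth, measurement tables, pipeline outputs
#' and a recovery report. The design's seed is mandatory, so there is no
#' silent randomness.
#'
#' @param design a [SyntheticDesign-class].
#' @param outDir output directory.
#' @param filter a [FilterConfig-class].
#' @param fdrMethod `"BH"` or `"BKY"`.
#' @return Invisibly, a list with `experiment`, `pipeline` and `recovery`.
#' @export
runSimulateWorkflow <- function(design, outDir, filter = FilterConfig(),
                                fdrMethod = c("BKY", "BH")) {
  fdrMethod <- match.arg(fdrMethod)
  stopifnot(is(design, "SyntheticDesign"))
  exp <- generateExperiment(design)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(exp$truth, file.path(outDir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(measurements(exp$forward),
                     file.path(outDir, "measurements_forward.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(measurements(exp$swap),
                     file.path(outDir, "measurements_swap.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  pipeline <- runQuantifyWorkflow(exp$forward, exp$swap, outDir,
                                  filter = filter, fdrMethod = fdrMethod)
  recovery <- recoveryReport(exp$truth, pipeline$sites,
                             pipeline$swap$consistency)
  writeSiteTable(recovery, file.path(outDir, "recovery.tsv"))
  .writeManifest(outDir, "simulate",
                 params = list(seed = design@seed,
                               kappa = design@concentration,
                               qc_fail_fraction = design@qcFailFraction,
                               fdr_method = fdrMethod),
                 counts = c(truth_rows = nrow(exp$truth),
                            forward_rows = nrow(measurements(exp$forward)),
                            swap_rows = nrow(measurements(exp$swap))))
  invisible(list(experiment = exp, pipeline = pipeline,
                 recovery = recovery))
}
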