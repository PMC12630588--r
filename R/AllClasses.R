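## S4 classes for the CPP pipeline. Tables live as plain data.frames inside
## container objects; configuration objects carry validity-checked scalars.

#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Quality-control filter configuration
#'
#' Thresholds used to accept a quantified light/heavy pair: the peak-quality
#' determinant factor and profile score must both be at least their minima
#' (inclusive), and retention-time-shifted pairs are rejected unless
#' explicitly allowed. Rows whose QC columns are missing pass by default
#' (`treatMissingQC = TRUE`) so minimal tables remain usable; set it to
#' `FALSE` for strict mode.
#'
#' @slot minDeterminantFactor numeric in \[0,1\], default 0.5.
#' @slot minProfileScore numeric in \[0,1\], default 0.5.
#' @slot allowRtShift logical, default `FALSE`.
#' @slot treatMissingQC logical, default `TRUE`.
#' @export
setClass("FilterConfig",
  representation(
    minDeterminantFactor = "numeric",
    minProfileScore      = "numeric",
    allowRtShift         = "logical",
    treatMissingQC       = "logical"
  ),
  prototype(
    minDeterminantFactor = 0.5,
    minProfileScore      = 0.5,
    allowRtShift         = FALSE,
    treatMissingQC       = TRUE
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  for (s in c("minDeterminantFactor", "minProfileScore")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0,1]", s))
  }
  for (s in c("allowRtShift", "treatMissingQC")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v))
      msg <- c(msg, sprintf("%s must be a single logical", s))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
#' @param minDeterminantFactor,minProfileScore inclusive lower thresholds.
#' @param allowRtShift keep retention-time-shifted pairs?
#' @param treatMissingQC treat missing QC columns as passing?
#' @return A `FilterConfig` object.
#' @export
#' @examples
#' FilterConfig()
FilterConfig <- function(minDeterminantFactor = 0.5, minProfileScore = 0.5,
                         allowRtShift = FALSE, treatMissingQC = TRUE) {
  new("FilterConfig",
      minDeterminantFactor = minDeterminantFactor,
      minProfileScore = minProfileScore,
      allowRtShift = allowRtShift,
      treatMissingQC = treatMissingQC)
}

#' Isotopic dimethyl labeling scheme
#'
#' Mass bookkeeping for the light (CH3) and heavy (13CD3) dimethyl labels.
#' The per-lysine pair spacing is the heavy minus light difference and the
#' validity method enforces that identity to four decimals.
#'
#' @slot lightDelta Da added per light-dimethylated amine.
#' @slot heavyDelta Da added per heavy-dimethylated amine.
#' @slot pairDeltaPerLysine Da spacing between pair members per labeled lysine.
#' @slot carbamidomethylCys Da, static cysteine modification.
#' @export
setClass("LabelScheme",
  representation(
    lightDelta         = "numeric",
    heavyDelta         = "numeric",
    pairDeltaPerLysine = "numeric",
    carbamidomethylCys = "numeric"
  )
)

setValidity("LabelScheme", function(object) {
  d <- object@heavyDelta - object@lightDelta
  if (abs(object@pairDeltaPerLysine - d) > 5e-5)
    return("pairDeltaPerLysine must equal heavyDelta - lightDelta to 4 decimals")
  TRUE
})

#' @rdname LabelScheme-class
#' @param lightDelta,heavyDelta,carbamidomethylCys label mass shifts (Da);
#'   defaults are computed from monoisotopic atomic masses.
#' @return A `LabelScheme` object.
#' @export
#' @examples
#' scheme <- LabelScheme()
#' round(scheme@pairDeltaPerLysine, 4)
LabelScheme <- function(lightDelta = lightLabelDelta(),
                        heavyDelta = heavyLabelDelta(),
                        carbamidomethylCys = carbamidomethylDelta()) {
  new("LabelScheme",
      lightDelta = lightDelta,
      heavyDelta = heavyDelta,
      pairDeltaPerLysine = heavyDelta - lightDelta,
      carbamidomethylCys = carbamidomethylCys)
}

.MEASUREMENT_COLUMNS <- c(
  "protein", "residue", "peptide", "charge", "replicate", "condition",
  "light_area", "heavy_area", "determinant_factor", "profile_score",
  "rt_shift"
)

#' Container for measurement-level CPP quantifications
#'
#' Holds one admitted row per peptide x charge x replicate x condition with
#' light and heavy integrated MS1 areas and QC columns, together with the
#' dataset-level label orientation (a whole run is either `forward` -- light
#' label in vivo -- or `swap`) and the rows excluded on read because both
#' areas were zero.
#'
#' @slot measurements data.frame with the canonical measurement columns.
#' @slot orientation `"forward"` or `"swap"`.
#' @slot excluded data.frame of rows excluded at read time.
#' @export
setClass("CPPMeasurements",
  representation(
    measurements = "data.frame",
    orientation  = "character",
    excluded     = "data.frame"
  )
)

setValidity("CPPMeasurements", function(object) {
  msg <- character()
  if (!object@orientation %in% c("forward", "swap"))
    msg <- c(msg, "orientation must be 'forward' or 'swap'")
  missing_cols <- setdiff(.MEASUREMENT_COLUMNS, names(object@measurements))
  if (length(missing_cols))
    msg <- c(msg, paste0("missing measurement columns: ",
                         paste(missing_cols, collapse = ", ")))
  m <- object@measurements
  if (nrow(m)) {
    if (any(m$light_area < 0, na.rm = TRUE) ||
        any(m$heavy_area < 0, na.rm = TRUE))
      msg <- c(msg, "areas must be non-negative")
    if (any(m$light_area + m$heavy_area <= 0, na.rm = TRUE))
      msg <- c(msg, "admitted measurements need light_area + heavy_area > 0")
    if (any(m$charge < 1, na.rm = TRUE))
      msg <- c(msg, "charge must be >= 1")
    if (any(m$residue < 1, na.rm = TRUE))
      msg <- c(msg, "residue numbers are 1-based and must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CPPMeasurements-class
#' @param measurements data.frame with the canonical columns.
#' @param orientation dataset-level label orientation.
#' @param excluded data.frame of excluded rows (default empty).
#' @return A `CPPMeasurements` object.
#' @export
CPPMeasurements <- function(measurements, orientation = c("forward", "swap"),
                            excluded = measurements[0, , drop = FALSE]) {
  orientation <- match.arg(orientation)
  new("CPPMeasurements",
      measurements = as.data.frame(measurements),
      orientation = orientation,
      excluded = as.data.frame(excluded))
}

#' Rolling-probe SASA configuration
#'
#' Parameters for Shrake-Rupley style solvent-accessible surface computation
#' of lysine epsilon-amine groups: probe radius (1.2 angstrom by default),
#' number of deterministic sphere sample points, the van der Waals radii
#' table, and whether amine hydrogens are included when the structure
#' resolves them (cryo-EM depositions usually do not, in which case the NZ
#' heavy atom represents the epsilon-amine).
#'
#' @slot probeRadius numeric, angstrom, > 0.
#' @slot nSpherePoints integer >= 96.
#' @slot radii named numeric vector of van der Waals radii by element symbol.
#' @slot includeHydrogens logical.
#' @export
setClass("SASAConfig",
  representation(
    probeRadius      = "numeric",
    nSpherePoints    = "numeric",
    radii            = "numeric",
    includeHydrogens = "logical"
  )
)

setValidity("SASAConfig", function(object) {
  msg <- character()
  if (length(object@probeRadius) != 1 || object@probeRadius <= 0)
    msg <- c(msg, "probeRadius must be a single positive value")
  if (length(object@nSpherePoints) != 1 || object@nSpherePoints < 96)
    msg <- c(msg, "nSpherePoints must be >= 96")
  if (is.null(names(object@radii)) || any(object@radii <= 0))
    msg <- c(msg, "radii must be a named vector of positive radii")
  if (length(msg)) msg else TRUE
})

#' Default van der Waals radii by element
#'
#' @return Named numeric vector (angstrom).
#' @export
defaultVdwRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

#' @rdname SASAConfig-class
#' @param probeRadius probe sphere radius in angstrom.
#' @param nSpherePoints number of surface sample points per atom.
#' @param radii named van der Waals radii table.
#' @param includeHydrogens include resolved amine hydrogens?
#' @return A `SASAConfig` object.
#' @export
#' @examples
#' SASAConfig()
SASAConfig <- function(probeRadius = 1.2, nSpherePoints = 960,
                       radii = defaultVdwRadii(), includeHydrogens = TRUE) {
  new("SASAConfig", probeRadius = probeRadius,
      nSpherePoints = nSpherePoints, radii = radii,
      includeHydrogens = includeHydrogens)
}

#' Accessibility class thresholds on epsilon-amine SASA
#'
#' Areas at or below `inaccessibleMax` classify as `inaccessible`, areas in
#' (`inaccessibleMax`, `partialMax`\] as `partially_accessible`, larger areas
#' as `accessible`.
#'
#' @slot inaccessibleMax numeric, angstrom^2, default 1.0.
#' @slot partialMax numeric, angstrom^2, default 7.5.
#' @export
setClass("ClassThresholds",
  representation(inaccessibleMax = "numeric", partialMax = "numeric"),
  prototype(inaccessibleMax = 1.0, partialMax = 7.5)
)

setValidity("ClassThresholds", function(object) {
  if (object@inaccessibleMax <= 0 ||
      object@partialMax <= object@inaccessibleMax)
    return("need 0 < inaccessibleMax < partialMax")
  TRUE
})

#' @rdname ClassThresholds-class
#' @param inaccessibleMax,partialMax class boundaries in angstrom^2.
#' @return A `ClassThresholds` object.
#' @export
ClassThresholds <- function(inaccessibleMax = 1.0, partialMax = 7.5) {
  new("ClassThresholds", inaccessibleMax = inaccessibleMax,
      partialMax = partialMax)
}

#' Design of a synthetic CPP experiment
#'
#' Describes ground truth and sampling design for the seeded generator: per
#' site x condition true accessibilities, biological replicate counts per
#' condition, peptide and charge multiplicity, a log-normal model for total
#' precursor intensity, a Beta model (precision `concentration`) for the
#' labeled fraction, and the fraction of rows given an injected QC failure.
#'
#' @slot truth data.frame with columns `protein`, `residue`, `condition`,
#'   `true_accessibility` (percent), optionally `peptide` and `region`.
#' @slot replicates named integer vector: biological replicates per condition.
#' @slot swapReplicates replicates used for the label-swap run (defaults to
#'   the forward counts when `NULL`).
#' @slot peptidesPerSite integer.
#' @slot charges integer vector of charge states observed per peptide.
#' @slot intensityLocation,intensityScale log-normal meanlog/sdlog of total
#'   intensity.
#' @slot concentration Beta precision kappa (> 0).
#' @slot qcFailFraction fraction of rows with an injected QC violation.
#' @slot paired logical; label-swap rows reuse the forward draws.
#' @slot seed integer seed (mandatory).
#' @export
setClass("SyntheticDesign",
  representation(
    truth             = "data.frame",
    replicates        = "integer",
    swapReplicates    = "numericOrNULL",
    peptidesPerSite   = "numeric",
    charges           = "numeric",
    intensityLocation = "numeric",
    intensityScale    = "numeric",
    concentration     = "numeric",
    qcFailFraction    = "numeric",
    paired            = "logical",
    seed              = "numeric"
  )
)

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  t <- object@truth
  need <- c("protein", "residue", "condition", "true_accessibility")
  missing_cols <- setdiff(need, names(t))
  if (length(missing_cols))
    msg <- c(msg, paste0("truth is missing columns: ",
                         paste(missing_cols, collapse = ", ")))
  else {
    if (any(t$true_accessibility < 0 | t$true_accessibility > 100))
      msg <- c(msg, "true accessibilities must lie in [0,100]")
    if (!all(t$condition %in% names(object@replicates)))
      msg <- c(msg, "every truth condition needs a replicate count")
  }
  if (any(object@replicates < 1))
    msg <- c(msg, "replicate counts must be >= 1")
  if (object@concentration <= 0)
    msg <- c(msg, "concentration (kappa) must be > 0")
  if (object@qcFailFraction < 0 || object@qcFailFraction > 1)
    msg <- c(msg, "qcFailFraction must lie in [0,1]")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "a single integer seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticDesign-class
#' @param truth data.frame of per site x condition ground truth (percent).
#' @param replicates named integer vector of replicates per condition.
#' @param swapReplicates optional named vector for the swap run.
#' @param peptidesPerSite,charges peptide/charge multiplicity.
#' @param intensityLocation,intensityScale log-normal intensity parameters.
#' @param concentration Beta precision kappa.
#' @param qcFailFraction fraction of rows with injected QC failures.
#' @param paired reuse forward draws for the swap run?
#' @param seed integer seed.
#' @return A `SyntheticDesign` object.
#' @export
SyntheticDesign <- function(truth,
                            replicates,
                            swapReplicates = NULL,
                            peptidesPerSite = 2,
                            charges = c(2, 3),
                            intensityLocation = log(1e6),
                            intensityScale = 0.8,
                            concentration = 200,
                            qcFailFraction = 0.05,
                            paired = TRUE,
                            seed) {
  new("SyntheticDesign",
      truth = as.data.frame(truth),
      replicates = structure(as.integer(replicates), names = names(replicates)),
      swapReplicates = swapReplicates,
      peptidesPerSite = peptidesPerSite,
      charges = charges,
      intensityLocation = intensityLocation,
      intensityScale = intensityScale,
      concentration = concentration,
      qcFailFraction = qcFailFraction,
      paired = paired,
      seed = seed)
}
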