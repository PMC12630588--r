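#' Accessors for CPP containers
#'
#' `measurements()` returns the admitted measurement table, `orientation()`
#' the dataset-level label orientation, and `excludedRows()` the rows dropped
#' at read time because both areas were zero.
#'
#' @param x a [CPPMeasurements-class] object.
#' @return `measurements()` and `excludedRows()` return data.frames;
#'   `orientation()` returns a character scalar.
#' @name cpp-accessors
NULL

#' @rdname cpp-accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname cpp-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname cpp-accessors
#' @export
setGeneric("excludedRows", function(x) standardGeneric("excludedRows"))

#' @rdname cpp-accessors
setMethod("measurements", "CPPMeasurements", function(x) x@measurements)

#' @rdname cpp-accessors
setMethod("orientation", "CPPMeasurements", function(x) x@orientation)

#' @rdname cpp-accessors
setMethod("excludedRows", "CPPMeasurements", function(x) x@excluded)

setMethod("show", "CPPMeasurements", function(object) {
  m <- object@measurements
  cat(sprintf("CPPMeasurements (%s orientation)\n", object@orientation))
  cat(sprintf("  %d measurements over %d sites, %d conditions, %d replicates\n",
              nrow(m),
              length(unique(paste(m$protein, m$residue))),
              length(unique(m$condition)),
              length(unique(m$replicate))))
  if (nrow(object@excluded))
    cat(sprintf("  %d rows excluded on read (zero total area)\n",
                nrow(object@excluded)))
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: determinant_factor >=", object@minDeterminantFactor,
      "| profile_score >=", object@minProfileScore,
      "| rt shift", if (object@allowRtShift) "allowed" else "rejected",
      "| missing QC",
      if (object@treatMissingQC) "passes" else "rejected", "\n")
})

setMethod("show", "LabelScheme", function(object) {
  cat(sprintf(
    "LabelScheme: light +%.4f Da, heavy +%.4f Da, pair spacing %.4f Da/K\n",
    object@lightDelta, object@heavyDelta, object@pairDeltaPerLysine))
})

setMethod("show", "SASAConfig", function(object) {
  cat(sprintf(
    "SASAConfig: probe %.2f A, %d sphere points, %d element radii\n",
    object@probeRadius, as.integer(object@nSpherePoints),
    length(object@radii)))
})

setMethod("show", "ClassThresholds", function(object) {
  cat(sprintf(
    "ClassThresholds: inaccessible <= %.2f A^2 < partially accessible <= %.2f A^2 < accessible\n",
    object@inaccessibleMax, object@partialMax))
})

setMethod("show", "SyntheticDesign", function(object) {
  t <- object@truth
  cat(sprintf(
    "SyntheticDesign: %d sites x %d conditions, kappa = %g, seed = %d\n",
    length(unique(paste(t$protein, t$residue))),
    length(unique(t$condition)), object@concentration,
    as.integer(object@seed)))
  reps <- object@replicates
  cat("  replicates:",
      paste(sprintf("%s=%d", names(reps), reps), collapse = ", "), "\n")
})
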