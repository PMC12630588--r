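## Ratio-to-accessibility conversion, QC filtering, site aggregation, and
## forward/label-swap reconciliation.

#' Per-measurement solvent accessibility from light/heavy areas
#'
#' In forward orientation the in-vivo label is light, so the light share of
#' the pair is the fraction of molecules in which the lysine was exposed:
#' `100 * light / (light + heavy)`. In a label-swap run the in-vivo label is
#' heavy and the numerator inverts. Results are clipped to \[0, 100\].
#'
#' @param light,heavy non-negative integrated MS1 areas (vectorized).
#' @param orientation `"forward"` or `"swap"`.
#' @return Accessibility percent in \[0, 100\].
#' @export
#' @examples
#' measurementAccessibility(618, 382, "forward")  # 61.8
#' measurementAccessibility(382, 618, "swap")     # 61.8
measurementAccessibility <- function(light, heavy,
                                     orientation = c("forward", "swap")) {
  orientation <- match.arg(orientation)
  if (any(light < 0, na.rm = TRUE) || any(heavy < 0, na.rm = TRUE))
    stop("areas must be non-negative")
  total <- light + heavy
  if (any(total <= 0, na.rm = TRUE))
    stop("light + heavy must be > 0; zero-total rows are excluded upstream")
  num <- if (orientation == "forward") light else heavy
  pmin(100, pmax(0, 100 * num / total))
}

#' Apply peak-quality filters to admitted measurements
#'
#' Retains measurements whose determinant factor and profile score meet the
#' configured minima (inclusive) and which show no retention-time shift
#' (unless allowed). Each rejected row is annotated with the first failing
#' rule, in the order determinant_factor, profile_score, rt_shift. Missing
#' QC values pass (with a one-off warning) when `treatMissingQC` is `TRUE`,
#' otherwise they reject with reason `missing_qc`.
#'
#' @param x a [CPPMeasurements-class] object.
#' @param config a [FilterConfig-class].
#' @return List with elements `retained` (a `CPPMeasurements`) and
#'   `rejected` (data.frame with a `reason` column).
#' @export
applyQCFilters <- function(x, config = FilterConfig()) {
  stopifnot(is(x, "CPPMeasurements"), is(config, "FilterConfig"))
  m <- measurements(x)
  reason <- rep(NA_character_, nrow(m))

  qc_missing <- is.na(m$determinant_factor) | is.na(m$profile_score) |
    is.na(m$rt_shift)
  if (any(qc_missing)) {
    if (config@treatMissingQC)
      warning(sprintf("%d measurement(s) with missing QC values pass filters",
                      sum(qc_missing)))
    else
      reason[qc_missing] <- "missing_qc"
  }

  fail_df <- !is.na(m$determinant_factor) &
    m$determinant_factor < config@minDeterminantFactor
  fail_ps <- !is.na(m$profile_score) &
    m$profile_score < config@minProfileScore
  fail_rt <- !config@allowRtShift & !is.na(m$rt_shift) & m$rt_shift

  reason[is.na(reason) & fail_df] <- "determinant_factor"
  reason[is.na(reason) & fail_ps] <- "profile_score"
  reason[is.na(reason) & fail_rt] <- "rt_shift"

  keep <- is.na(reason)
  rejected <- m[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  list(
    retained = CPPMeasurements(m[keep, , drop = FALSE], orientation(x),
                               excluded = excludedRows(x)),
    rejected = rejected
  )
}

#' Aggregate measurements to site x condition accessibility summaries
#'
#' Every peptide x charge x replicate row is an independent, equally
#' weighted measurement (the default, mirroring per-point scatter plots);
#' `mode = "replicate"` first averages within biological replicates and then
#' summarizes the replicate means. The standard error is the sample standard
#' deviation of the pooled values divided by sqrt(n); single-measurement
#' sites report `sem = 0` and are flagged.
#'
#' @param x a [CPPMeasurements-class] (typically the retained set from
#'   [applyQCFilters()]).
#' @param mode `"measurement"` (default) or `"replicate"`.
#' @return data.frame with columns `protein`, `residue`, `label`,
#'   `condition`, `mean_accessibility`, `sem`, `n_measurements`,
#'   `n_replicates`, `single_measurement`.
#' @export
aggregateSites <- function(x, mode = c("measurement", "replicate")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "CPPMeasurements"))
  m <- measurements(x)
  if (!nrow(m)) {
    message("aggregateSites: no measurements to aggregate")
    return(data.frame(protein = character(), residue = integer(),
                      label = character(), condition = character(),
                      mean_accessibility = numeric(), sem = numeric(),
                      n_measurements = integer(), n_replicates = integer(),
                      single_measurement = logical()))
  }
  m$accessibility <- measurementAccessibility(m$light_area, m$heavy_area,
                                              orientation(x))
  key <- interaction(m$protein, m$residue, m$condition, drop = TRUE)
  groups <- split(m, key)
  rows <- lapply(groups, function(g) {
    vals <- if (mode == "measurement") g$accessibility
            else vapply(split(g$accessibility, g$replicate), mean, numeric(1))
    n <- length(vals)
    data.frame(
      protein = g$protein[1],
      residue = g$residue[1],
      label = paste0("K", g$residue[1]),
      condition = g$condition[1],
      mean_accessibility = mean(vals),
      sem = if (n > 1) stats::sd(vals) / sqrt(n) else 0,
      n_measurements = nrow(g),
      n_replicates = length(unique(g$replicate)),
      single_measurement = n == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protein, out$residue, out$condition), , drop = FALSE]
}

#' Reconcile forward and label-swap site tables
#'
#' Sites quantified in both orientations are compared per condition; a site
#' is concordant when the absolute difference of the two mean accessibilities
#' is at most `tolerance` percentage points (default 10, reflecting the
#' expected run-to-run variation of swap experiments). Sites present in only
#' one orientation are listed separately.
#'
#' @param forward,swap site tables from [aggregateSites()] on forward and
#'   swap runs.
#' @param tolerance concordance tolerance in percentage points.
#' @return List with `consistency` (data.frame: site, condition, forward and
#'   swap means, `absolute_difference`, `concordant`), `forwardOnly` and
#'   `swapOnly` data.frames.
#' @export
mergeLabelSwap <- function(forward, swap, tolerance = 10) {
  key <- function(d) paste(d$protein, d$residue, d$condition, sep = "\r")
  kf <- key(forward); ks <- key(swap)
  shared <- intersect(kf, ks)
  fi <- match(shared, kf); si <- match(shared, ks)
  consistency <- data.frame(
    protein = forward$protein[fi],
    residue = forward$residue[fi],
    label = forward$label[fi],
    condition = forward$condition[fi],
    forward_mean = forward$mean_accessibility[fi],
    swap_mean = swap$mean_accessibility[si],
    stringsAsFactors = FALSE
  )
  consistency$absolute_difference <-
    abs(consistency$forward_mean - consistency$swap_mean)
  consistency$concordant <- consistency$absolute_difference <= tolerance
  list(
    consistency = consistency,
    forwardOnly = forward[!kf %in% shared, , drop = FALSE],
    swapOnly = swap[!ks %in% shared, , drop = FALSE]
  )
}
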