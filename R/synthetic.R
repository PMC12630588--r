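## Seeded generator of complete CPP experiments with known ground truth.

## run code under a local RNG state so generation never disturbs (and is
## never disturbed by) the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Beta draw on the labeled fraction with precision kappa; truths of exactly
## 0 or 100 are point masses, not NaN
.drawLabeledFraction <- function(n, accessibility, kappa) {
  a <- accessibility / 100
  out <- numeric(n)
  degenerate <- a <= 0 | a >= 1
  out[degenerate] <- a[degenerate]
  idx <- !degenerate
  if (any(idx))
    out[idx] <- stats::rbeta(sum(idx), a[idx] * kappa, (1 - a[idx]) * kappa)
  out
}

## random chymotryptic-looking peptide containing one K (for sites whose
## real peptide is not specified)
.randomPeptide <- function(len = 12) {
  pool <- c("A", "S", "T", "V", "I", "N", "Q", "D", "E", "G", "P", "R", "H")
  kpos <- sample(2:(len - 1), 1)
  chars <- sample(pool, len, replace = TRUE)
  chars[kpos] <- "K"
  chars[len] <- sample(c("F", "Y", "W", "L", "M"), 1)
  paste(chars, collapse = "")
}

#' Generate a complete synthetic CPP experiment
#'
#' For every site x condition x replicate x peptide x charge cell the
#' generator draws a total precursor intensity from a log-normal and a
#' labeled fraction from a Beta distribution centred on the true
#' accessibility with precision `concentration`, then splits the intensity
#' into light and heavy areas (forward orientation: light = in-vivo-labeled
#' share). The label-swap table reuses the same draws with the areas
#' exchanged (`paired = TRUE`, so forward and swap accessibilities are
#' exactly complementary on the raw light share) or redraws them. A
#' configured fraction of rows receives one injected QC violation (low
#' determinant factor, low profile score, or a retention-time shift),
#' independent of accessibility. Identical seeds give identical tables.
#'
#' @param design a [SyntheticDesign-class].
#' @return List with `truth` (the design's truth table), `forward` and
#'   `swap` ([CPPMeasurements-class] objects), and `design`.
#' @export
#' @examples
#' d <- SyntheticDesign(
#'   truth = data.frame(protein = "P1", residue = 10, condition = "a",
#'                      true_accessibility = 60),
#'   replicates = c(a = 3), peptidesPerSite = 1, charges = 2, seed = 1)
#' generateExperiment(d)$forward
generateExperiment <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  .withSeed(design@seed, {
    truth <- design@truth
    sites <- unique(truth[, c("protein", "residue"), drop = FALSE])
    has_pep <- "peptide" %in% names(truth)
    peptides <- lapply(seq_len(nrow(sites)), function(i) {
      base <- if (has_pep)
        truth$peptide[truth$protein == sites$protein[i] &
                        truth$residue == sites$residue[i]][1]
      else NA_character_
      if (is.na(base)) base <- .randomPeptide()
      n <- as.integer(design@peptidesPerSite)
      if (n == 1) base
      else c(base, vapply(seq_len(n - 1), function(j) .randomPeptide(),
                          character(1)))
    })

    grid <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      reps <- design@replicates[[truth$condition[i]]]
      si <- which(sites$protein == truth$protein[i] &
                    sites$residue == truth$residue[i])
      expand.grid(row = i,
                  replicate = paste0("rep", seq_len(reps)),
                  peptide = peptides[[si]],
                  charge = design@charges,
                  stringsAsFactors = FALSE)
    }))

    n <- nrow(grid)
    a <- truth$true_accessibility[grid$row]
    total <- stats::rlnorm(n, design@intensityLocation,
                           design@intensityScale)
    f <- .drawLabeledFraction(n, a, design@concentration)

    qc_ok_df <- stats::runif(n, 0.55, 1)
    qc_ok_ps <- stats::runif(n, 0.55, 1)
    fail <- stats::runif(n) < design@qcFailFraction
    fail_kind <- sample(c("determinant_factor", "profile_score", "rt_shift"),
                        n, replace = TRUE)
    det <- ifelse(fail & fail_kind == "determinant_factor",
                  stats::runif(n, 0, 0.45), qc_ok_df)
    ps <- ifelse(fail & fail_kind == "profile_score",
                 stats::runif(n, 0, 0.45), qc_ok_ps)
    rt <- fail & fail_kind == "rt_shift"

    base <- data.frame(
      protein = truth$protein[grid$row],
      residue = truth$residue[grid$row],
      peptide = grid$peptide,
      charge = grid$charge,
      replicate = grid$replicate,
      condition = truth$condition[grid$row],
      determinant_factor = round(det, 4),
      profile_score = round(ps, 4),
      rt_shift = rt,
      stringsAsFactors = FALSE
    )

    forward <- base
    forward$light_area <- total * f
    forward$heavy_area <- total * (1 - f)
    forward <- forward[, .MEASUREMENT_COLUMNS]

    swap_reps <- design@swapReplicates
    if (is.null(swap_reps)) swap_reps <- design@replicates
    if (design@paired) {
      swap <- base
      swap$light_area <- total * (1 - f)
      swap$heavy_area <- total * f
    } else {
      total2 <- stats::rlnorm(n, design@intensityLocation,
                              design@intensityScale)
      f2 <- .drawLabeledFraction(n, a, design@concentration)
      swap <- base
      swap$light_area <- total2 * (1 - f2)
      swap$heavy_area <- total2 * f2
    }
    swap <- swap[, .MEASUREMENT_COLUMNS]
    keep <- rep(TRUE, n)
    for (cond in unique(swap$condition)) {
      allowed <- paste0("rep", seq_len(
        if (cond %in% names(swap_reps)) swap_reps[[cond]] else 0))
      keep[swap$condition == cond & !base$replicate %in% allowed] <- FALSE
    }
    swap <- swap[keep, , drop = FALSE]
    rownames(forward) <- rownames(swap) <- NULL

    list(truth = truth,
         forward = CPPMeasurements(forward, "forward"),
         swap = CPPMeasurements(swap, "swap"),
         design = design)
  })
}

#' Recovery report: pipeline estimates vs ground truth
#'
#' Joins a site table produced by the pipeline with the generator's truth
#' table and reports per site x condition bias (estimate minus truth).
#' Orphaned keys on either side are an explicit error. When a swap
#' consistency table from [mergeLabelSwap()] is supplied its absolute
#' forward/swap differences are merged in.
#'
#' @param truth truth table from [generateExperiment()].
#' @param siteTable data.frame from [aggregateSites()].
#' @param swapConsistency optional `consistency` data.frame.
#' @return data.frame with `protein`, `residue`, `condition`,
#'   `true_accessibility`, `estimate`, `bias` and (optionally)
#'   `swap_difference`.
#' @export
recoveryReport <- function(truth, siteTable, swapConsistency = NULL) {
  key <- function(d) paste(d$protein, d$residue, d$condition, sep = "\r")
  kt <- key(truth); ks <- key(siteTable)
  orphans <- c(setdiff(ks, kt))
  if (length(orphans))
    stop("site table keys absent from truth: ",
         paste(gsub("\r", "/", orphans), collapse = ", "), call. = FALSE)
  merged <- merge(truth[, c("protein", "residue", "condition",
                            "true_accessibility")],
                  siteTable[, c("protein", "residue", "condition",
                                "mean_accessibility", "sem",
                                "n_measurements")],
                  by = c("protein", "residue", "condition"), all.x = TRUE)
  names(merged)[names(merged) == "mean_accessibility"] <- "estimate"
  merged$bias <- merged$estimate - merged$true_accessibility
  if (!is.null(swapConsistency))
    merged <- merge(merged,
                    data.frame(protein = swapConsistency$protein,
                               residue = swapConsistency$residue,
                               condition = swapConsistency$condition,
                               swap_difference =
                                 swapConsistency$absolute_difference),
                    by = c("protein", "residue", "condition"), all.x = TRUE)
  merged[order(merged$protein, merged$residue, merged$condition), ,
         drop = FALSE]
}
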