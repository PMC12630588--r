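## Published CFTR lysine accessibility reference and the study-scale
## synthetic design built from it.

#' Published CFTR lysine accessibility reference
#'
#' The published mapping of CPP-quantified CFTR lysines to cryo-EM
#' structures: per site (or site pair sharing one peptide) the chymotryptic
#' peptide, mean CPP accessibility (%) in wt and deltaF508 CFTR, and the
#' rolling-probe epsilon-amine isosurface area with its accessibility class
#' in the dephosphorylated wt structure (PDB 5UAK) and the phosphorylated,
#' ATP-bound structure (PDB 6MSM). Two sites (K411, K420) fall in regions
#' not resolved in the cryo-EM models and carry `mapped = FALSE`. `NA`
#' means not determined in that condition. Rows keyed by two residues
#' (K370/K377) carry two semicolon-separated areas per structure.
#'
#' @return data.frame, one row per reference table entry.
#' @export
#' @examples
#' ref <- cftrReferenceTable()
#' subset(ref, row == "K273")$class_5uak
cftrReferenceTable <- function() {
  path <- system.file("extdata", "cftr_lysine_reference.tsv",
                      package = "cppaint", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(row = "character", residues = "character",
                                   peptide = "character"))
}

#' Reference areas in long format
#'
#' Unnests the semicolon-separated areas of [cftrReferenceTable()] into one
#' row per residue x structure with the printed area and class label; only
#' mapped rows are returned.
#'
#' @return data.frame with `residue`, `structure_id`, `area`, `class`.
#' @export
cftrReferenceAreas <- function() {
  ref <- cftrReferenceTable()
  ref <- ref[ref$mapped, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    res <- as.integer(strsplit(ref$residues[i], ";")[[1]])
    do.call(rbind, lapply(c("5uak", "6msm"), function(s) {
      areas <- as.numeric(strsplit(ref[[paste0("area_", s)]][i], ";")[[1]])
      data.frame(residue = res,
                 structure_id = toupper(s),
                 area = areas,
                 class = ref[[paste0("class_", s)]][i],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Study-scale synthetic CPP design for CFTR
#'
#' A [SyntheticDesign-class] emulating the published CFTR study: 26 lysine
#' sites quantified in wt CFTR across eight conditions with the published
#' biological replicate counts (wt 4, wt_VX770 3, dF508 4, dF508_DMSO 3,
#' dF508_VX809 3, dF508_28C 3, dF508_Trikafta 3, dF508_VX661_VX445 3).
#' Ground-truth accessibilities are the published per-site means; the K273
#' condition series encodes the reported values (wt 61.8, dF508 95.0,
#' VX-770-activated wt 0.66, Trikafta 81.5, permissive temperature 89), and
#' K1218 drops 35 percentage points under VX-809, representing the reported
#' greater-than-30-point reduction. Sites not determined in one condition
#' reuse the other condition's value; the two unnamed R-region sites of the
#' published count are included as synthetic stand-ins (K698, K710, flagged
#' in the `region` column).
#'
#' @param seed integer seed for the generator.
#' @param ... further arguments passed to [SyntheticDesign()].
#' @return A [SyntheticDesign-class] object.
#' @export
cftrStudyDesign <- function(seed, ...) {
  ref <- cftrReferenceTable()
  long <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    data.frame(residue = as.integer(strsplit(ref$residues[i], ";")[[1]]),
               peptide = ref$peptide[i],
               wt = ref$wt_mean_pct[i],
               df508 = ref$df508_mean_pct[i],
               stringsAsFactors = FALSE)
  }))
  base <- long[!duplicated(long$residue), , drop = FALSE]
  ## fill not-determined cells from the paired condition
  base$wt[is.na(base$wt)] <- base$df508[is.na(base$wt)]
  base$df508[is.na(base$df508)] <- base$wt[is.na(base$df508)]
  ## unmapped RI-element sites were quantified (disordered, highly exposed)
  base$wt[is.na(base$wt)] <- 98.5
  base$df508[is.na(base$df508)] <- 98.5
  base$peptide[is.na(base$peptide)] <-
    paste0("SYNTH", base$residue[is.na(base$peptide)])
  extra <- data.frame(
    residue = c(643, 716, 698, 710),
    peptide = NA_character_,
    wt = c(98.5, 98.5, 99.0, 99.0),
    df508 = c(98.5, 98.5, 99.0, 99.0),
    stringsAsFactors = FALSE
  )
  extra$peptide <- paste0("SYNTH", extra$residue)
  base <- rbind(base, extra)
  base$region <- ifelse(base$residue %in% c(698, 710),
                        "R-region (synthetic stand-in)", "")

  conditions <- c(wt = 4L, wt_VX770 = 3L, dF508 = 4L, dF508_DMSO = 3L,
                  dF508_VX809 = 3L, dF508_28C = 3L, dF508_Trikafta = 3L,
                  dF508_VX661_VX445 = 3L)
  truth <- do.call(rbind, lapply(names(conditions), function(cond) {
    a <- if (startsWith(cond, "wt")) base$wt else base$df508
    data.frame(protein = "P13569", residue = base$residue,
               peptide = base$peptide, region = base$region,
               condition = cond, true_accessibility = a,
               stringsAsFactors = FALSE)
  }))
  override <- function(res, cond, value) {
    i <- truth$residue == res & truth$condition == cond
    truth$true_accessibility[i] <<- value
  }
  override(273, "wt_VX770", 0.66)
  override(273, "dF508_Trikafta", 81.5)
  override(273, "dF508_28C", 89.0)
  override(1218, "dF508_VX809", 89.3 - 35)

  SyntheticDesign(truth = truth, replicates = conditions,
                  swapReplicates = c(wt = 2L, dF508 = 2L), seed = seed, ...)
}
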