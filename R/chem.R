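## Dimethyl label arithmetic, peptide masses, chymotryptic digestion and
## site-to-peptide mapping.

#' Pair mass spacing for a peptide with k labeled lysines
#'
#' The light and heavy members of a quantified precursor pair differ by the
#' heavy-minus-light label difference once per labeled lysine.
#'
#' @param scheme a [LabelScheme-class] object.
#' @param k number of labeled lysines (non-negative integer).
#' @return Mass difference in Da.
#' @export
#' @examples
#' round(pairMassDelta(LabelScheme(), 1), 4)  # 8.0444
pairMassDelta <- function(scheme = LabelScheme(), k) {
  if (any(k < 0) || any(k != round(k)))
    stop("k must be a non-negative integer count of labeled lysines")
  k * (scheme@heavyDelta - scheme@lightDelta)
}

#' Monoisotopic mass of an unlabeled peptide
#'
#' Sum of standard residue monoisotopic masses plus one water.
#'
#' @param sequence uppercase amino-acid string (standard 20 letters).
#' @return Neutral monoisotopic mass, Da.
#' @export
peptideMass <- function(sequence) {
  rm <- residueMasses()
  vapply(strsplit(toupper(sequence), ""), function(chars) {
    bad <- setdiff(chars, names(rm))
    if (length(bad))
      stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    sum(rm[chars]) + .waterMass()
  }, numeric(1))
}

#' m/z of one labeled peptide form
#'
#' Computes the precursor m/z of a dimethyl-labeled peptide form: all lysines
#' carry `lysineLabel` and the peptide N-terminus carries `ntermLabel`
#' (`"none"` for an unlabeled terminus).
#'
#' @param sequence amino-acid string.
#' @param charge positive integer charge state.
#' @param lysineLabel `"light"` or `"heavy"` label on every lysine.
#' @param ntermLabel `"light"`, `"heavy"` or `"none"` on the N-terminus.
#' @param scheme a [LabelScheme-class].
#' @return m/z of the protonated form.
#' @export
#' @examples
#' precursorMz("VITSEMIENIQSVKAY", charge = 2)
precursorMz <- function(sequence, charge,
                        lysineLabel = c("light", "heavy"),
                        ntermLabel = c("light", "heavy", "none"),
                        scheme = LabelScheme()) {
  lysineLabel <- match.arg(lysineLabel)
  ntermLabel <- match.arg(ntermLabel)
  if (charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  nK <- lengths(regmatches(sequence, gregexpr("K", sequence)))
  delta <- c(light = scheme@lightDelta, heavy = scheme@heavyDelta, none = 0)
  mass <- peptideMass(sequence) +
    nK * delta[[lysineLabel]] + delta[[ntermLabel]]
  (mass + charge * atomicMasses()[["proton"]]) / charge
}

#' m/z of the light/heavy quantified precursor pair
#'
#' The quantified pair differs only in the lysine labels: the light member
#' carries light lysines, the heavy member heavy lysines, and both share the
#' same N-terminal label state. The pair spacing is therefore
#' `n_lysines * pairDeltaPerLysine / charge`.
#'
#' @inheritParams precursorMz
#' @return Named numeric vector `c(light = , heavy = )`.
#' @export
#' @examples
#' mz <- precursorPairMz("VITSEMIENIQSVKAY", charge = 2)
#' round(mz[["heavy"]] - mz[["light"]], 4)  # 8.0444 / 2
precursorPairMz <- function(sequence, charge,
                            ntermLabel = c("light", "heavy", "none"),
                            scheme = LabelScheme()) {
  ntermLabel <- match.arg(ntermLabel)
  c(light = precursorMz(sequence, charge, "light", ntermLabel, scheme),
    heavy = precursorMz(sequence, charge, "heavy", ntermLabel, scheme))
}

#' In-silico chymotryptic digestion
#'
#' Cleaves C-terminal to F, Y, W, L and M, suppressed when the next residue
#' is proline (broad-specificity convention; lysine-insensitive, so labeled
#' lysines never block a cut). At zero missed cleavages the fragments tile
#' the input without gaps; up to `missedCleavages` adjacent fragments are
#' additionally joined.
#'
#' @param sequence protein sequence (uppercase amino acids).
#' @param missedCleavages integer in \[0, 5\].
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `sequence`, `missed`, `n_lysines` and `lysine_residues` (semicolon
#'   separated residue numbers, empty for lysine-free peptides).
#' @export
#' @examples
#' chymotrypticDigest("MKWVTF")$sequence  # "M" "KW" "VTF"
chymotrypticDigest <- function(sequence, missedCleavages = 0) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (missedCleavages < 0 || missedCleavages > 5)
    stop("missedCleavages must be in [0, 5]")
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  ## cut after position i when chars[i] is a cleavage residue and the
  ## following residue is not proline
  cut_after <- which(chars %in% c("F", "Y", "W", "L", "M"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1, n)] != "P"]
  bounds <- unique(c(0, cut_after, n))
  starts0 <- bounds[-length(bounds)] + 1
  ends0 <- bounds[-1]
  nb <- length(starts0)
  rows <- list()
  for (mc in 0:min(missedCleavages, nb - 1)) {
    i <- seq_len(nb - mc)
    rows[[mc + 1]] <- data.frame(start = starts0[i], end = ends0[i + mc],
                                 missed = mc)
  }
  out <- do.call(rbind, rows)
  out$sequence <- vapply(seq_len(nrow(out)), function(i)
    paste(chars[out$start[i]:out$end[i]], collapse = ""), character(1))
  kinfo <- lapply(seq_len(nrow(out)), function(i) {
    off <- which(chars[out$start[i]:out$end[i]] == "K")
    out$start[i] + off - 1
  })
  out$n_lysines <- lengths(kinfo)
  out$lysine_residues <- vapply(kinfo, paste, character(1), collapse = ";")
  out[, c("start", "end", "sequence", "missed", "n_lysines",
          "lysine_residues")]
}

#' Map a positioned peptide to its lysine sites
#'
#' Given a peptide's 1-based start coordinate in the full-length protein,
#' returns one site per lysine with its residue number in protein
#' coordinates and display label `K<residue>`.
#'
#' @param start 1-based start position of the peptide in the protein.
#' @param sequence peptide sequence.
#' @param protein protein accession for the site key.
#' @param proteinLength optional full protein length used to validate the
#'   peptide coordinates.
#' @return data.frame with columns `protein`, `residue`, `label`; zero rows
#'   for a lysine-free peptide.
#' @export
#' @examples
#' mapPeptideToSites(260, "VITSEMIENIQSVKAY", "P13569")$label  # "K273"
mapPeptideToSites <- function(start, sequence, protein,
                              proteinLength = NULL) {
  if (start < 1) stop("peptide start must be >= 1")
  end <- start + nchar(sequence) - 1
  if (!is.null(proteinLength) && end > proteinLength)
    stop(sprintf("peptide coordinates %d-%d exceed protein length %d",
                 start, end, proteinLength))
  off <- which(strsplit(toupper(sequence), "")[[1]] == "K")
  residue <- start + off - 1
  data.frame(protein = rep(protein, length(residue)),
             residue = residue,
             label = if (length(residue)) paste0("K", residue)
                     else character(0),
             stringsAsFactors = FALSE)
}
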