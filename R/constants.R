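## Monoisotopic constants used throughout. All masses in Da.

#' Monoisotopic atomic masses
#'
#' Named vector of monoisotopic atomic masses (Da) for the elements and
#' isotopes needed by dimethyl-label arithmetic: `H`, `D` (2H), `C`,
#' `C13` (13C), `N`, `O`, `S`, plus the proton mass under `proton`.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' atomicMasses()[["proton"]]
atomicMasses <- function() {
  c(
    H      = 1.0078250319,
    D      = 2.0141017780,
    C      = 12.0000000000,
    C13    = 13.0033548378,
    N      = 14.0030740052,
    O      = 15.9949146221,
    S      = 31.9720706900,
    proton = 1.0072764669
  )
}

#' Monoisotopic amino-acid residue masses
#'
#' Residue (i.e. water-subtracted) monoisotopic masses for the 20 standard
#' amino acids, one-letter codes.
#'
#' @return Named numeric vector, Da.
#' @export
residueMasses <- function() {
  c(
    G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
    V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
    I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
    K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
    F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

## water = 2H + O; used when assembling peptide masses from residues
.waterMass <- function() {
  am <- atomicMasses()
  2 * am[["H"]] + am[["O"]]
}

#' Light dimethyl label mass shift
#'
#' Mass added by reductive dimethylation of a primary amine with CH2O /
#' NaBH3CN: a net C2H4 addition, computed from monoisotopic atomic masses.
#'
#' @return Mass shift in Da (28.0313 to four decimals).
#' @export
#' @examples
#' round(lightLabelDelta(), 4)
lightLabelDelta <- function() {
  am <- atomicMasses()
  2 * am[["C"]] + 4 * am[["H"]]
}

#' Heavy dimethyl label mass shift
#'
#' Mass added by reductive dimethylation with 13CD2O / NaBD3CN: two 13CD3
#' groups replace two amine hydrogens, a net 2x13C + 6xD - 2xH addition.
#'
#' @return Mass shift in Da (36.0757 to four decimals).
#' @export
heavyLabelDelta <- function() {
  am <- atomicMasses()
  2 * am[["C13"]] + 6 * am[["D"]] - 2 * am[["H"]]
}

#' Carbamidomethylation mass shift for cysteine
#'
#' @return Mass shift in Da (57.02146 to five decimals).
#' @export
carbamidomethylDelta <- function() {
  am <- atomicMasses()
  2 * am[["C"]] + 3 * am[["H"]] + am[["N"]] + am[["O"]]
}
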