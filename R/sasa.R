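## Rolling-probe solvent-accessible surface area of lysine epsilon-amines,
## accessibility classification, and concordance with CPP accessibilities.

#' Deterministic unit-sphere sample points
#'
#' Fibonacci (golden-spiral) lattice on the unit sphere: near-uniform and
#' fully deterministic, so SASA values are reproducible for a fixed
#' configuration.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## Shrake-Rupley area for selected atoms against all atoms.
## xyz: n x 3 coordinates, radii: length-n vdW radii, targets: indices.
.shrakeRupley <- function(xyz, radii, targets, probe, nPoints) {
  pts <- fibonacciSphere(nPoints)
  vapply(targets, function(t) {
    R <- radii[t] + probe
    centered <- sweep(pts * R, 2, xyz[t, ], `+`)
    ## only atoms whose expanded sphere can reach the test sphere occlude
    d2 <- colSums((t(xyz) - xyz[t, ])^2)
    reach <- radii + probe + R
    nb <- which(d2 < reach^2 & d2 > 0)
    if (!length(nb)) return(4 * pi * R^2)
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      rj2 <- (radii[j] + probe)^2
      dx <- centered[, 1] - xyz[j, 1]
      dy <- centered[, 2] - xyz[j, 2]
      dz <- centered[, 3] - xyz[j, 3]
      free <- free & (dx * dx + dy * dy + dz * dz >= rj2)
      if (!any(free)) break
    }
    4 * pi * R^2 * mean(free)
  }, numeric(1))
}

#' SASA of selected atoms in an atom table
#'
#' Low-level Shrake-Rupley computation over a plain atom table; used both
#' for PDB structures (via [lysineAmineSasa()]) and directly in tests on
#' toy systems.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` and `element`.
#' @param targets integer indices of the atoms whose area is wanted.
#' @param config a [SASAConfig-class].
#' @return Numeric vector of areas (angstrom^2), one per target.
#' @export
#' @examples
#' one <- data.frame(x = 0, y = 0, z = 0, element = "N")
#' atomSasa(one, 1)  # ~ 4*pi*(1.55+1.2)^2
atomSasa <- function(atoms, targets, config = SASAConfig()) {
  stopifnot(is(config, "SASAConfig"))
  radii <- config@radii[atoms$element]
  unknown <- is.na(radii)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(atoms$element[unknown]),
                                         collapse = ", "),
            "; using carbon radius")
    radii[unknown] <- config@radii[["C"]]
  }
  .shrakeRupley(as.matrix(atoms[, c("x", "y", "z")]), radii, targets,
                config@probeRadius, as.integer(config@nSpherePoints))
}

## normalize a bio3d pdb (or path) into an atom table with element symbols,
## altloc resolved to highest occupancy
.pdbAtomTable <- function(pdb) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- toupper(substr(gsub("[0-9]", "", at$elety), 1, 1))
  }
  at$element <- trimws(toupper(elem))
  ## resolve alternate locations: keep highest occupancy, ties by label order
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_along(key), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at
}

#' Rolling-probe SASA of one lysine epsilon-amine
#'
#' Selects the NZ heavy atom of the requested lysine (plus the HZ hydrogens
#' when the structure resolves them and `includeHydrogens` is set) and
#' computes its solvent-accessible surface against all atoms of the
#' structure with a rolling probe (default 1.2 angstrom). Cryo-EM
#' depositions typically lack amine hydrogens, in which case the NZ atom
#' represents the epsilon-amino group.
#'
#' @param pdb a `bio3d` pdb object or a path to a PDB file.
#' @param residue lysine residue number (author numbering).
#' @param chain chain identifier; default: first chain containing the
#'   residue.
#' @param config a [SASAConfig-class].
#' @return Area in angstrom^2, or `NA` when the residue is present but its
#'   epsilon-amine atoms are unresolved. Raises an error when the residue is
#'   absent or not a lysine.
#' @export
lysineAmineSasa <- function(pdb, residue, chain = NULL,
                            config = SASAConfig()) {
  at <- .pdbAtomTable(pdb)
  res <- at[at$resno == residue, , drop = FALSE]
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  if (!nrow(res))
    stop(sprintf("residue %d%s not found in structure", residue,
                 if (is.null(chain)) "" else paste0(" chain ", chain)),
         call. = FALSE)
  use_chain <- if (is.null(chain)) res$chain[1] else chain
  res <- res[res$chain == use_chain, , drop = FALSE]
  if (!all(res$resid == "LYS"))
    stop(sprintf("residue %d chain %s is %s, not LYS", residue, use_chain,
                 res$resid[1]), call. = FALSE)
  sel <- at$resno == residue & at$chain == use_chain & at$elety == "NZ"
  if (config@includeHydrogens)
    sel <- sel | (at$resno == residue & at$chain == use_chain &
                    at$elety %in% c("HZ1", "HZ2", "HZ3"))
  if (!any(sel)) return(NA_real_)  # residue modeled without its amine
  sum(atomSasa(at, which(sel), config))
}

#' Classify an epsilon-amine SASA
#'
#' @param area numeric areas (angstrom^2); `NA` propagates as
#'   `"unresolved"`.
#' @param thresholds a [ClassThresholds-class].
#' @return Character vector: `"inaccessible"`, `"partially_accessible"`,
#'   `"accessible"` or `"unresolved"`.
#' @export
#' @examples
#' classifySasa(c(0.48, 3.51, 53.98))
classifySasa <- function(area, thresholds = ClassThresholds()) {
  stopifnot(is(thresholds, "ClassThresholds"))
  if (any(area < 0, na.rm = TRUE)) stop("areas must be non-negative")
  out <- ifelse(area <= thresholds@inaccessibleMax, "inaccessible",
         ifelse(area <= thresholds@partialMax, "partially_accessible",
                "accessible"))
  out[is.na(area)] <- "unresolved"
  out
}

#' Per-site SASA and class for a set of lysines in one structure
#'
#' Applies [lysineAmineSasa()] to each requested residue; residues absent
#' from the structure become `unmapped` rows rather than errors, matching
#' how truncated constructs omit disordered regions.
#'
#' @param pdb a `bio3d` pdb object or PDB path.
#' @param residues integer vector of lysine residue numbers.
#' @param structureId identifier recorded in the output (e.g. `"5UAK"`).
#' @param chain optional chain.
#' @param config a [SASAConfig-class].
#' @param thresholds a [ClassThresholds-class].
#' @return data.frame with `residue`, `structure_id`, `area`,
#'   `accessibility_class`.
#' @export
structureSiteSasa <- function(pdb, residues, structureId = "structure",
                              chain = NULL, config = SASAConfig(),
                              thresholds = ClassThresholds()) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  area <- vapply(residues, function(r) {
    tryCatch(lysineAmineSasa(pdb, r, chain, config),
             error = function(e) NaN)  # NaN marks unmapped, NA unresolved
  }, numeric(1))
  cls <- classifySasa(ifelse(is.nan(area), NA, area), thresholds)
  cls[is.nan(area)] <- "unmapped"
  data.frame(residue = residues, structure_id = structureId,
             area = ifelse(is.nan(area), NA, area),
             accessibility_class = cls, stringsAsFactors = FALSE)
}

#' Bin a CPP accessibility percentage into the structural vocabulary
#'
#' `accessible` at or above the accessible bound (default 90%),
#' `inaccessible` below the partial bound (default 50%),
#' `partially_accessible` in between.
#'
#' @param percent CPP mean accessibility in \[0, 100\].
#' @param accessibleMin,partialMin bin boundaries in percent.
#' @return Character vector of classes.
#' @export
binCppAccessibility <- function(percent, accessibleMin = 90,
                                partialMin = 50) {
  ifelse(percent >= accessibleMin, "accessible",
         ifelse(percent >= partialMin, "partially_accessible",
                "inaccessible"))
}

#' Concordance between CPP accessibility and structure classes
#'
#' Joins a per-site CPP accessibility table with one or more structure class
#' tables and flags per site and structure whether the chemistry and the
#' model agree. A site whose CPP value is intermediate while the structure
#' sits at an extreme (fully accessible or inaccessible) is flagged as
#' conformational heterogeneity: the chemistry averages over the molecule
#' population, the model shows a single conformer. Sites without a mapped
#' residue in the structure are reported `unmapped`.
#'
#' @param siteTable data.frame with `residue` and `mean_accessibility`
#'   (one condition).
#' @param structTable data.frame from [structureSiteSasa()] (several
#'   structures may be row-bound).
#' @param accessibleMin,partialMin CPP bin boundaries, see
#'   [binCppAccessibility()].
#' @return data.frame with one row per site x structure: `residue`,
#'   `structure_id`, `cpp_accessibility`, `cpp_class`, `structure_class`,
#'   `area`, `agree`, `heterogeneity`.
#' @export
concordance <- function(siteTable, structTable, accessibleMin = 90,
                        partialMin = 50) {
  merged <- merge(siteTable[, c("residue", "mean_accessibility")],
                  structTable, by = "residue")
  merged$cpp_class <- binCppAccessibility(merged$mean_accessibility,
                                          accessibleMin, partialMin)
  sc <- merged$accessibility_class
  merged$agree <- !sc %in% c("unmapped", "unresolved") &
    merged$cpp_class == sc
  merged$heterogeneity <- merged$cpp_class == "partially_accessible" &
    sc %in% c("accessible", "inaccessible")
  data.frame(residue = merged$residue,
             structure_id = merged$structure_id,
             cpp_accessibility = merged$mean_accessibility,
             cpp_class = merged$cpp_class,
             structure_class = sc,
             area = merged$area,
             agree = merged$agree,
             heterogeneity = merged$heterogeneity,
             stringsAsFactors = FALSE)
}
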