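## Shared fixtures, all generated in code.

## minimal well-formed measurement data.frame
makeMeasurementDf <- function(n = 3, condition = "wt", replicate = "rep1",
                              light = 618, heavy = 382) {
  data.frame(
    protein = "P13569",
    residue = 273,
    peptide = "VITSEMIENIQSVKAY",
    charge = seq_len(n) + 1,
    replicate = replicate,
    condition = condition,
    light_area = rep_len(light, n),
    heavy_area = rep_len(heavy, n),
    determinant_factor = 0.9,
    profile_score = 0.9,
    rt_shift = FALSE,
    stringsAsFactors = FALSE
  )
}

writeMeasurementTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

## independent elemental-composition oracle for peptide masses
elementalPeptideMass <- function(sequence) {
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  am <- cppaint::atomicMasses()
  chars <- strsplit(sequence, "")[[1]]
  total <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from one water
  for (ch in chars) {
    cc <- comp[[ch]]
    total[names(cc)] <- total[names(cc)] + cc
  }
  sum(total * am[c("C", "H", "N", "O", "S")])
}

## toy atom systems for SASA tests -------------------------------------------

## a single nitrogen atom at the origin
isolatedNitrogen <- function() {
  data.frame(x = 0, y = 0, z = 0, element = "N", stringsAsFactors = FALSE)
}

## nitrogen enclosed by a dense carbon shell at the given radius
buriedNitrogen <- function(shellRadius = 3.0, nShell = 120) {
  shell <- cppaint::fibonacciSphere(nShell) * shellRadius
  rbind(isolatedNitrogen(),
        data.frame(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                   element = "C", stringsAsFactors = FALSE))
}

## write a small PDB file: one exposed lysine NZ, one NZ buried under a
## carbon shell, plus an arginine for not-a-lysine lookups
writeToyPdb <- function(path = tempfile(fileext = ".pdb")) {
  fmt <- function(serial, name, resn, chain, resno, x, y, z, occ = 1,
                  elem) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resn, chain, resno, x, y, z, occ, 0, elem)
  }
  lines <- c(
    fmt(1, "NZ", "LYS", "A", 10, 0, 0, 0, elem = "N"),
    fmt(2, "NZ", "LYS", "A", 20, 50, 0, 0, elem = "N"),
    fmt(3, "CZ", "ARG", "A", 30, -50, 0, 0, elem = "C")
  )
  shell <- cppaint::fibonacciSphere(120) * 3.0
  for (i in seq_len(nrow(shell)))
    lines <- c(lines, fmt(100 + i, "C", "ALA", "A", 40 + i,
                          shell[i, 1], shell[i, 2], shell[i, 3], elem = "C"))
  writeLines(c(lines, "END"), path)
  path
}

## two-condition design at the published K273 effect size
k273Design <- function(seed, ...) {
  cppaint::SyntheticDesign(
    truth = data.frame(protein = "P13569", residue = 273,
                       condition = c("wt", "dF508"),
                       true_accessibility = c(61.8, 95.0),
                       stringsAsFactors = FALSE),
    replicates = c(wt = 4L, dF508 = 4L),
    seed = seed, ...)
}
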