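## Readers/writers for the measurement-table dialect and derived tables.

#' Read a measurement-level CPP quantification table
#'
#' Reads a TSV with one row per peptide x charge x replicate x condition,
#' carrying integrated light/heavy MS1 areas and peak-QC columns. Mandatory
#' columns: `protein`, `residue`, `peptide`, `charge`, `replicate`,
#' `condition`, `light_area`, `heavy_area`, `determinant_factor`,
#' `profile_score`, `rt_shift`; extra columns are ignored. Rows in which both
#' areas are zero carry no ratio information and are excluded (kept in
#' [excludedRows()]); a negative area is a validation error reported with its
#' line number.
#'
#' @param path path to a TSV file.
#' @param orientation label orientation of the whole run: `"forward"` (light
#'   label in vivo) or `"swap"`.
#' @return A [CPPMeasurements-class] object.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(protein = "P13569", residue = 273,
#'   peptide = "VITSEMIENIQSVKAY", charge = 2, replicate = "r1",
#'   condition = "wt", light_area = 618, heavy_area = 382,
#'   determinant_factor = 0.9, profile_score = 0.9, rt_shift = FALSE)
#' write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readMeasurementTable(tf, "forward")
readMeasurementTable <- function(path, orientation = c("forward", "swap")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(.MEASUREMENT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("measurement table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, .MEASUREMENT_COLUMNS, drop = FALSE]
  raw$rt_shift <- .asLogicalFlag(raw$rt_shift)

  neg <- which(raw$light_area < 0 | raw$heavy_area < 0)
  if (length(neg))
    stop(sprintf("negative area in row %d (file line %d) of %s",
                 neg[1], neg[1] + 1L, path), call. = FALSE)

  total <- raw$light_area + raw$heavy_area
  zero <- !is.na(total) & total <= 0
  admitted <- raw[!zero, , drop = FALSE]
  excluded <- raw[zero, , drop = FALSE]
  if (nrow(excluded))
    message(sprintf("readMeasurementTable: excluded %d row(s) with zero total area",
                    nrow(excluded)))
  CPPMeasurements(admitted, orientation, excluded = excluded)
}

.asLogicalFlag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

#' Write / read a per-site accessibility table
#'
#' `writeSiteTable()` writes a site x condition accessibility summary as TSV
#' with numeric columns formatted to four decimals so that a write/read
#' round trip is lossless at that precision. An empty record set produces a
#' header-only file with a warning.
#'
#' @param records data.frame as produced by [aggregateSites()].
#' @param path output TSV path.
#' @return `writeSiteTable()` returns `path` invisibly; `readSiteTable()`
#'   returns a data.frame.
#' @export
writeSiteTable <- function(records, path) {
  records <- as.data.frame(records)
  if (!nrow(records))
    warning("writing header-only site table: no records")
  out <- records
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.4f", out[[col]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers become numeric, `true`/`false` become
#' logical, comma-separated values become vectors.
#'
#' @param path path to the configuration file.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line: ", ln, call. = FALSE)
    key <- trimws(m[2])
    val <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(val))
    if (!anyNA(parsed)) val <- parsed
    else if (all(tolower(val) %in% c("true", "false")))
      val <- tolower(val) == "true"
    out[[key]] <- val
  }
  out
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a plain named
#' character vector keyed by the first token of each FASTA header.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  seqs
}
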