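## Readers and writers for the plain-text interchange formats: contact lists,
## dense delimited matrices (optionally gzip-compressed), 3-column coordinate
## files, PDB-like bead files for molecular viewers, and JSON reports.

#' Read a tab-delimited single-cell Hi-C contact list
#'
#' Supports the common 3-column layout (chromosome, position_i, position_j;
#' both ends on the same chromosome) and 4-column layouts (chrom_a, pos_a,
#' chrom_b, pos_b) via the column-mapping arguments. Reports the number of
#' records parsed.
#'
#' @param path File path (plain or gzipped text).
#' @param col_chrom_a,col_pos_a,col_chrom_b,col_pos_b 1-based column indices;
#'   set `col_chrom_b = NULL` for 3-column files (both ends share the
#'   chromosome in `col_chrom_a`).
#' @param header Does the file have a header line? (default `FALSE`)
#' @param sep Field separator (default tab).
#' @return Data frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#' @export
read_contact_list <- function(path, col_chrom_a = 1, col_pos_a = 2,
                              col_chrom_b = NULL, col_pos_b = 3,
                              header = FALSE, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("contact list not found: %s", path))
  raw <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE)
  out <- data.frame(
    chrom_a = as.character(raw[[col_chrom_a]]),
    pos_a = as.numeric(raw[[col_pos_a]]),
    chrom_b = as.character(raw[[col_chrom_b %||% col_chrom_a]]),
    pos_b = as.numeric(raw[[col_pos_b]]),
    stringsAsFactors = FALSE)
  message(sprintf("read_contact_list: parsed %d records from %s",
                  nrow(out), path))
  out
}

#' Write / read a dense matrix as delimited text
#'
#' Paths ending in `.gz` are transparently gzip-compressed.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `read_matrix` returns the matrix; `write_matrix` its path,
#'   invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(m, con, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path))
  as.matrix(utils::read.table(path, sep = sep, header = FALSE))
}

#' Write / read bead coordinates as 3-column text (x y z in nm)
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param path Output path.
#' @return `read_coords` returns the matrix; `write_coords` its path,
#'   invisibly.
#' @export
write_coords <- function(coords, path) {
  coords <- as_coords(coords)
  utils::write.table(format(coords, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop(sprintf("coordinate file not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a minimal PDB-like bead file for molecular viewers
#'
#' One CA-style ATOM record per bin, consecutive bins joined by the residue
#' sequence. Coordinates are written in the structure's nm units (viewers
#' treat them as generic lengths).
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param path Output path.
#' @param chrom Chain/segment label (single character used as chain ID).
#' @return The path, invisibly.
#' @export
write_bead_pdb <- function(coords, path, chrom = "A") {
  coords <- as_coords(coords)
  n <- nrow(coords)
  ch <- substr(as.character(chrom), 1, 1)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  BIN %s%4d    %8.2f%8.2f%8.2f  1.00  0.00",
            i %% 100000, ch, i %% 10000,
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a reconstruction report (plus run parameters) as JSON
#'
#' @param report A `reconstruction_report`.
#' @param path Output path.
#' @param extra Named list of extra fields (parameters, seeds, ...).
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path, extra = list()) {
  payload <- c(unclass(report), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
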