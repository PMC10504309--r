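.matrix_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 scoring matrix (including the ambiguity
#' codes B, Z, X and the stop symbol), the default matrix for all pairwise
#' and progressive alignments in this package.
#'
#' @return Integer matrix with identical row and column names giving the
#'   scoring alphabet.
#' @export
blosum62 <- function() {
  if (is.null(.matrix_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .matrix_cache$BLOSUM62 <- e$BLOSUM62
  }
  .matrix_cache$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text scoring matrix format used by NCBI BLAST and EMBOSS
#' (comment lines starting with `#`, a header row of single-letter codes,
#' then one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with row and column names.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop_io(path, "?", "not a substitution matrix: need header plus rows")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  ok <- vapply(rows, function(r) length(r) == length(header) + 1L, logical(1))
  if (!all(ok))
    stop_io(path, which(!ok)[1] + 1L, "row length does not match header")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(m) <- vapply(rows, `[`, character(1), 1L)
  colnames(m) <- header
  if (anyNA(m)) stop_io(path, "?", "non-numeric score entry")
  m
}

# Validate and normalize a substitution matrix argument.
check_submat <- function(submat) {
  if (is.null(submat)) submat <- blosum62()
  if (!is.matrix(submat) || is.null(rownames(submat)) ||
      !identical(rownames(submat), colnames(submat)))
    stop("substitution matrix must be square with matching dimnames")
  storage.mode(submat) <- "double"
  submat
}
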