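#' Read protein sequences from a FASTA file
#'
#' Strict FASTA reader for protein sequences.  Records are uppercased and
#' checked against the amino-acid alphabet; ambiguity codes other than `X`
#' (`B`, `Z`, `J`, `U`, `O`, `*`) are mapped to `X` with a warning.  Header
#' descriptions of the form `key=value` are parsed into columns, which is how
#' the bundled simulator transports genome, genus, and family labels.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A data frame with columns `protein_id`, `residues`, plus one
#'   column per `key=value` token found in the headers.
#' @export
read_fasta <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop_io(path, 1, "empty FASTA file")
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop_io(path, nonempty[1], "expected FASTA header line starting with '>'")

  hdr_idx <- which(startsWith(lines, ">"))
  ids <- character(length(hdr_idx))
  desc <- character(length(hdr_idx))
  seqs <- character(length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (k in seq_along(hdr_idx)) {
    h <- sub("^>", "", trimws(lines[hdr_idx[k]]))
    if (!nzchar(h)) stop_io(path, hdr_idx[k], "empty FASTA header")
    ids[k] <- sub("\\s.*$", "", h)
    desc[k] <- ifelse(grepl("\\s", h), sub("^\\S+\\s+", "", h), "")
    body <- lines[seq.int(hdr_idx[k] + 1L, bounds[k + 1L] - 1L,
                          length.out = max(0L, bounds[k + 1L] - hdr_idx[k] - 1L))]
    s <- toupper(gsub("\\s", "", paste(body, collapse = "")))
    if (!nzchar(s)) stop_io(path, hdr_idx[k], paste0("empty sequence for '", ids[k], "'"))
    seqs[k] <- s
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop_io(path, hdr_idx[which(ids == dup)[2]],
            paste0("duplicate sequence id '", dup, "'"))
  }
  # alphabet check; ambiguity codes other than X collapse to X
  ambig <- c("B", "Z", "J", "U", "O", "*")
  for (k in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[k], "")[[1]])
    bad <- setdiff(chars, c(AA20, "X", ambig))
    if (length(bad))
      stop_io(path, hdr_idx[k],
              paste0("invalid residue(s) ", paste(bad, collapse = ","),
                     " in '", ids[k], "'"))
    if (any(chars %in% ambig)) {
      warning("ambiguous residues mapped to X in '", ids[k], "'", call. = FALSE)
      seqs[k] <- chartr(paste(ambig, collapse = ""),
                        strrep("X", length(ambig)), seqs[k])
    }
  }
  out <- data.frame(protein_id = ids, residues = seqs,
                    stringsAsFactors = FALSE)
  # expand key=value descriptions
  kv <- regmatches(desc, gregexpr("\\S+=\\S+", desc))
  keys <- unique(unlist(lapply(kv, function(x) sub("=.*$", "", x))))
  for (key in keys) {
    out[[key]] <- vapply(kv, function(x) {
      hit <- x[startsWith(x, paste0(key, "="))]
      if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
    }, character(1))
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences, or a data frame with
#'   `protein_id` and `residues` columns; any further columns are written to
#'   the header as `key=value` tokens.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.data.frame(seqs)) {
    extra <- setdiff(names(seqs), c("protein_id", "residues"))
    hdr <- seqs$protein_id
    if (length(extra)) {
      kv <- vapply(seq_len(nrow(seqs)), function(i) {
        paste(sprintf("%s=%s", extra, vapply(extra, function(e)
          as.character(seqs[[e]][i]), character(1))), collapse = " ")
      }, character(1))
      hdr <- paste(hdr, kv)
    }
    sq <- seqs$residues
  } else {
    sq <- as_seqvec(seqs)
    hdr <- names(sq)
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(sq)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- sq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene locations
#'
#' Reads the table mapping proteins to their position along a contig.  Gene
#' positions are 0-based ranks in gene order (the unit in which synteny
#' distances are measured), not nucleotide coordinates.
#'
#' The TSV dialect requires columns `genome`, `contig`, `index`, `strand`,
#' `gene_id`, `protein_id` and takes ranks verbatim, validating that each
#' contig's ranks are consecutive from 0.  The GFF3 dialect consumes only
#' `CDS` features and re-derives ranks from the coordinate sort of each
#' contig (requires the rtracklayer package).
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param genome_id Genome label for GFF3 input (defaults to the file name
#'   without extension); ignored for TSV.
#' @return Data frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `index`, `strand`, `protein_id`.
#' @export
read_gene_locations <- function(path, dialect = c("tsv", "gff3"),
                                genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome", "contig", "index", "strand", "gene_id", "protein_id")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop_io(path, 1, paste0("missing column(s): ", paste(missing, collapse = ", ")))
    bad_strand <- which(!df$strand %in% c("+", "-"))
    if (length(bad_strand))
      stop_io(path, bad_strand[1] + 1L,
              paste0("unknown strand symbol '", df$strand[bad_strand[1]], "'"))
    out <- data.frame(gene_id = as.character(df$gene_id),
                      genome_id = as.character(df$genome),
                      contig_id = as.character(df$contig),
                      index = as.integer(df$index),
                      strand = df$strand,
                      protein_id = as.character(df$protein_id),
                      stringsAsFactors = FALSE)
    for (key in split(seq_len(nrow(out)),
                      paste(out$genome_id, out$contig_id, sep = "\r"))) {
      idx <- sort(out$index[key])
      if (!identical(idx, seq(0L, length(idx) - 1L)))
        stop_io(path, "?", paste0(
          "indices on contig '", out$contig_id[key[1]], "' of genome '",
          out$genome_id[key[1]], "' are not consecutive from 0"))
    }
    return(out[order(out$genome_id, out$contig_id, out$index), , drop = FALSE])
  }
  # GFF3: only seqid, start, strand and a protein_id/ID attribute are used
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the 'rtracklayer' package")
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)[as.character(gff$type) == "CDS", , drop = FALSE]
  if (nrow(gff) == 0L) stop_io(path, "?", "no CDS features found")
  pid <- if ("protein_id" %in% names(gff)) as.character(gff$protein_id)
         else as.character(gff$ID)
  if (anyNA(pid)) stop_io(path, "?", "CDS feature lacking protein_id/ID attribute")
  strand <- as.character(gff$strand)
  if (any(!strand %in% c("+", "-")))
    stop_io(path, "?", "unknown strand symbol in CDS feature")
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  out <- data.frame(gene_id = pid,
                    genome_id = genome_id,
                    contig_id = as.character(gff$seqid),
                    start = as.integer(gff$start),
                    strand = strand,
                    protein_id = pid,
                    stringsAsFactors = FALSE)
  pieces <- lapply(split(out, out$contig_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    d$index <- seq_len(nrow(d)) - 1L
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("gene_id", "genome_id", "contig_id", "index", "strand", "protein_id")]
}

#' Write gene locations as TSV
#'
#' @param genes Data frame as returned by [read_gene_locations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_locations <- function(genes, path) {
  df <- data.frame(genome = genes$genome_id, contig = genes$contig_id,
                   index = genes$index, strand = genes$strand,
                   gene_id = genes$gene_id, protein_id = genes$protein_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity-search hit table
#'
#' Ingests externally produced HMM- or BLAST-style hits as a TSV with columns
#' `query_family`, `target`, `pident`, `evalue`, `bitscore`.  Rows whose
#' numeric fields fail coercion are dropped with a warning (row numbers kept
#' in the `"rejected"` attribute); out-of-bounds values (identity outside
#' 0-100, negative E-value) are an error.
#'
#' @param path Input TSV.
#' @return Data frame of typed hit records.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("query_family", "target", "pident", "evalue", "bitscore")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_io(path, 1, paste0("missing column(s): ", paste(missing, collapse = ", ")))
  pident <- suppressWarnings(as.numeric(df$pident))
  evalue <- suppressWarnings(as.numeric(df$evalue))
  bitscore <- suppressWarnings(as.numeric(df$bitscore))
  bad <- which(is.na(pident) | is.na(evalue) | is.na(bitscore))
  if (length(bad)) {
    warning("rejected ", length(bad), " malformed row(s): ",
            paste(bad + 1L, collapse = ", "), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    pident <- pident[-bad]; evalue <- evalue[-bad]; bitscore <- bitscore[-bad]
  }
  oob <- which(pident < 0 | pident > 100 | evalue < 0)
  if (length(oob))
    stop_io(path, oob[1] + 1L, "percent identity outside [0,100] or negative E-value")
  out <- data.frame(query_family = df$query_family, target = df$target,
                    pident = pident, evalue = evalue, bitscore = bitscore,
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- if (length(bad)) bad else integer(0)
  out
}

#' Read and write trees in newick format
#'
#' Thin validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()].  Round-trips preserve topology, labels, branch
#' lengths (to the 10 significant digits written), and the root.
#'
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    stop_io(path, 1, sprintf("unbalanced parentheses (%d '(' vs %d ')')",
                             n_open, n_close))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop_io(path, 1, "newick parse error")
  if (anyDuplicated(tree$tip.label))
    stop_io(path, 1, "duplicate leaf labels")
  tree
}

#' @param tree An [ape::phylo] tree with uniquely labelled leaves.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("tree leaves must be uniquely labelled")
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
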