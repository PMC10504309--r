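aln_stats <- function(a, b) {
  if (!nzchar(a)) return(c(matches = 0, length = 0, identity = 0))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  c(matches = matches, length = length(ca),
    identity = 100 * matches / length(ca))
}

make_alignment_result <- function(raw, qid, tid, mode) {
  st <- aln_stats(raw$aligned_a, raw$aligned_b)
  structure(list(query_id = qid, target_id = tid,
                 aligned_query = raw$aligned_a, aligned_target = raw$aligned_b,
                 score = raw$score, mode = mode,
                 percent_identity = unname(st["identity"]),
                 n_matches = unname(st["matches"]),
                 alignment_length = unname(st["length"])),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s: score %.1f, identity %.1f%% over %d columns\n",
              x$mode, x$query_id, x$target_id, x$score, x$percent_identity,
              x$alignment_length))
  invisible(x)
}

check_pair_input <- function(a, b) {
  a <- as_seqvec(a); b <- as_seqvec(b)
  if (length(a) != 1L || length(b) != 1L) stop("expected single sequences")
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  list(a = a, b = b)
}

#' Pairwise affine-gap alignment
#'
#' Optimal global (Needleman-Wunsch) or local (Smith-Waterman) alignment
#' with affine gap costs (a gap run of length L costs
#' `gap_open + L * gap_extend`, terminal gaps included in global mode).
#' Percent identity counts identical columns over the full alignment length,
#' gap columns in the denominator.  Traceback ties resolve deterministically
#' (diagonal, then up, then left).  A local alignment whose optimum is
#' non-positive is reported as empty with score 0.
#'
#' @param a,b Named single sequences (character vectors of length 1).
#' @param submat Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return An `alignment_result` with aligned strings, score, mode, and
#'   percent identity.
#' @export
align_global <- function(a, b, submat = NULL, gap_open = 10, gap_extend = 0.5) {
  p <- check_pair_input(a, b)
  submat <- check_submat(submat)
  raw <- .cpp_align_pair(unname(p$a), unname(p$b), submat,
                         paste(rownames(submat), collapse = ""),
                         gap_open, gap_extend, FALSE)
  make_alignment_result(raw, names(p$a), names(p$b), "global")
}

#' @rdname align_global
#' @export
align_local <- function(a, b, submat = NULL, gap_open = 10, gap_extend = 0.5) {
  p <- check_pair_input(a, b)
  submat <- check_submat(submat)
  raw <- .cpp_align_pair(unname(p$a), unname(p$b), submat,
                         paste(rownames(submat), collapse = ""),
                         gap_open, gap_extend, TRUE)
  make_alignment_result(raw, names(p$a), names(p$b), "local")
}

# Karlin-Altschul constants used by the offline E-value surrogate
# (gapped BLOSUM62 statistics).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' E-value surrogate from a local alignment score
#'
#' Karlin-Altschul form `E = K * m * n * exp(-lambda * S)` with constants
#' for gapped BLOSUM62 alignments, so the E-value filter of family
#' assignment can be exercised without an embedded database search engine.
#' Externally supplied E-values from hit tables take precedence over this
#' surrogate.
#'
#' @param score Raw local alignment score(s).
#' @param m,n Query and target sequence lengths.
#' @param K,lambda Karlin-Altschul parameters.
#' @return Numeric E-value(s).
#' @export
evalue_surrogate <- function(score, m, n, K = KA_K, lambda = KA_LAMBDA) {
  K * m * n * exp(-lambda * score)
}

bitscore_from_raw <- function(score, K = KA_K, lambda = KA_LAMBDA) {
  (lambda * score - log(K)) / log(2)
}

#' Decoy-aware protein family assignment
#'
#' Assigns each protein to the family of its best-scoring reference under
#' local alignment (best raw score; ties broken by lower E-value, then
#' lexicographic family name).  A protein whose best hit is a decoy family
#' is rejected (`decoy_rejected`); a best hit below `min_identity` percent
#' local identity or above `max_evalue` is filtered.  In all three negative
#' cases `family` is `NA`.
#'
#' @param proteins Sequences (named character vector or data frame).
#' @param references Data frame with `protein_id`, `residues`, `family`
#'   columns (one or more references per family).
#' @param decoy_families Character vector of family names acting as decoys.
#' @param min_identity Minimum percent local identity (default 25).
#' @param max_evalue Maximum E-value (default 1e-10).
#' @param submat,gap_open,gap_extend Alignment parameters.
#' @param hits Optional externally produced hit table (see
#'   [read_hit_table()]); when given, its per-target best rows replace the
#'   internal alignment sweep and its E-values are used as-is.
#' @return Data frame with one row per protein: `protein_id`, `family`,
#'   `best_family`, `best_identity`, `best_evalue`, `best_bitscore`,
#'   `decoy_rejected`, `filtered`.
#' @export
assign_families <- function(proteins, references, decoy_families = character(0),
                            min_identity = 25, max_evalue = 1e-10,
                            submat = NULL, gap_open = 10, gap_extend = 0.5,
                            hits = NULL) {
  seqs <- as_seqvec(proteins)
  if (!is.null(decoy_families)) {
    known <- if (is.null(hits)) unique(references$family)
             else unique(c(references$family, hits$query_family))
    bad <- setdiff(decoy_families, known)
    if (length(bad))
      stop("decoy family not among reference families: ",
           paste(bad, collapse = ", "))
  }
  if (is.null(hits)) {
    stopifnot(is.data.frame(references),
              all(c("protein_id", "residues", "family") %in% names(references)))
    submat <- check_submat(submat)
    alpha <- paste(rownames(submat), collapse = "")
    best <- data.frame(protein_id = names(seqs), family = NA_character_,
                       identity = NA_real_, evalue = NA_real_,
                       bitscore = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(seqs)) {
      q <- seqs[[i]]
      sc <- .cpp_align_scores(q, references$residues, submat, alpha,
                              gap_open, gap_extend, TRUE)
      ev <- evalue_surrogate(sc, nchar(q), nchar(references$residues))
      ord <- order(-sc, ev, references$family)
      top <- ord[1]
      # identity needs the traceback; compute it only for the winner
      aln <- .cpp_align_pair(q, references$residues[top], submat, alpha,
                             gap_open, gap_extend, TRUE)
      st <- aln_stats(aln$aligned_a, aln$aligned_b)
      best$family[i] <- references$family[top]
      best$identity[i] <- st["identity"]
      best$evalue[i] <- ev[top]
      best$bitscore[i] <- bitscore_from_raw(sc[top])
    }
  } else {
    best <- data.frame(protein_id = names(seqs), family = NA_character_,
                       identity = NA_real_, evalue = NA_real_,
                       bitscore = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(seqs)) {
      h <- hits[hits$target == names(seqs)[i], , drop = FALSE]
      if (nrow(h) == 0L) next
      h <- h[order(-h$bitscore, h$evalue, h$query_family), , drop = FALSE]
      best$family[i] <- h$query_family[1]
      best$identity[i] <- h$pident[1]
      best$evalue[i] <- h$evalue[1]
      best$bitscore[i] <- h$bitscore[1]
    }
  }
  decoy_rejected <- !is.na(best$family) & best$family %in% decoy_families
  filtered <- is.na(best$family) |
    (!decoy_rejected & (best$identity < min_identity | best$evalue > max_evalue))
  family <- best$family
  family[decoy_rejected | filtered] <- NA_character_
  data.frame(protein_id = best$protein_id, family = family,
             best_family = best$family, best_identity = best$identity,
             best_evalue = best$evalue, best_bitscore = best$bitscore,
             decoy_rejected = decoy_rejected, filtered = filtered & !decoy_rejected,
             stringsAsFactors = FALSE)
}

#' All-vs-all global percent identity
#'
#' Computes the symmetric matrix of pairwise global percent identities
#' within a sequence set (each unordered pair aligned once; diagonal 100).
#'
#' @param sequences Named character vector or sequence data frame (>= 2
#'   sequences).
#' @param submat,gap_open,gap_extend Alignment parameters.
#' @return Symmetric numeric matrix with sequence names as dimnames.
#' @export
all_vs_all_identity <- function(sequences, submat = NULL, gap_open = 10,
                                gap_extend = 0.5) {
  seqs <- as_seqvec(sequences)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  submat <- check_submat(submat)
  alpha <- paste(rownames(submat), collapse = "")
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      raw <- .cpp_align_pair(seqs[[i]], seqs[[j]], submat, alpha,
                             gap_open, gap_extend, FALSE)
      st <- aln_stats(raw$aligned_a, raw$aligned_b)
      m[i, j] <- m[j, i] <- st["identity"]
    }
  }
  m
}
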