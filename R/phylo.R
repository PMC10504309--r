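aln_matrix <- function(aln) {
  aln <- as_seqvec(aln)
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment rows differ in length")
  m <- t(vapply(aln, function(s) strsplit(s, "")[[1]], character(L)))
  rownames(m) <- names(aln)
  m
}

kmer_cosine_dist <- function(seqs, k) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(s))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  kmers <- unique(unlist(lapply(counts, names)))
  V <- vapply(counts, function(ct) {
    v <- numeric(length(kmers))
    v[match(names(ct), kmers)] <- as.numeric(ct)
    v
  }, numeric(length(kmers)))
  V <- t(V)  # one row per sequence
  norms <- sqrt(rowSums(V^2))
  sim <- (V %*% t(V)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0
  rownames(d) <- colnames(d) <- names(seqs)
  d
}

#' Progressive multiple sequence alignment
#'
#' Self-contained progressive aligner: k-mer count cosine distances feed a
#' UPGMA guide tree, and profiles are merged up the guide tree by
#' profile-profile global alignment (average-of-pairs column scores under
#' the substitution matrix, affine gaps).  Fully deterministic; row order of
#' the result is input order.  An external aligner can be substituted
#' upstream wherever an alignment is consumed.
#'
#' The default gap penalties (open 15, extend 2) are stiffer than the
#' pairwise-scan defaults: at the divergence levels typical of deep protein
#' families, cheap gap extension lets score fluctuations open spurious gaps
#' between sequences that differ by substitutions only, and the multiple
#' aligner is expected to keep indel-free homologs gap-free.
#'
#' @param sequences Named character vector or sequence data frame (>= 2).
#' @param k k-mer length for guide-tree distances (default 3).
#' @param submat,gap_open,gap_extend Alignment parameters.
#' @return Named character vector of gapped rows (equal lengths), in input
#'   order.
#' @export
progressive_align <- function(sequences, k = 3L, submat = NULL,
                              gap_open = 15, gap_extend = 2) {
  seqs <- as_seqvec(sequences)
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  submat <- check_submat(submat)
  alpha <- paste(rownames(submat), collapse = "")
  if (length(seqs) == 2L) {
    raw <- .cpp_align_pair(seqs[[1]], seqs[[2]], submat, alpha,
                           gap_open, gap_extend, FALSE)
    out <- c(raw$aligned_a, raw$aligned_b)
    names(out) <- names(seqs)
    return(out)
  }
  D <- kmer_cosine_dist(seqs, k)
  guide <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA
  profiles <- lapply(seq_along(seqs), function(i) {
    p <- seqs[i]
    p
  })
  merged <- vector("list", nrow(guide$merge))
  for (s in seq_len(nrow(guide$merge))) {
    pick <- function(v) if (v < 0) profiles[[-v]] else merged[[v]]
    A <- pick(guide$merge[s, 1]); B <- pick(guide$merge[s, 2])
    res <- .cpp_align_profiles(unname(A), unname(B), submat, alpha,
                               gap_open, gap_extend)
    rows <- res$rows
    names(rows) <- c(names(A), names(B))
    merged[[s]] <- rows
  }
  final <- merged[[nrow(guide$merge)]]
  final[names(seqs)]
}

#' Trim alignment columns by gap fraction
#'
#' Keeps exactly the columns whose fraction of non-gap residues is at least
#' `gap_threshold` (the trimming convention of a 95 percent gap-threshold
#' filter).
#'
#' @param aln Named character vector of aligned rows.
#' @param gap_threshold Minimum retained non-gap fraction per column.
#' @return Trimmed alignment (named character vector) with the surviving
#'   column indices in the `"kept_columns"` attribute.
#' @export
trim_alignment <- function(aln, gap_threshold = 0.95) {
  m <- aln_matrix(aln)
  frac <- colMeans(m != "-")
  keep <- which(frac >= gap_threshold)
  if (length(keep) == 0L)
    stop("all columns removed at gap threshold ", gap_threshold,
         "; lower the threshold")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- rownames(m)
  attr(out, "kept_columns") <- keep
  out
}

#' Corrected pairwise distances from an alignment
#'
#' Observed p-distances over columns where both rows are non-gap, corrected
#' under the uniform 20-state substitution model:
#' `d = -(19/20) * log(1 - (20/19) * p)`.  The correction matches the
#' simulator's model exactly, so parameter-recovery tests have a closed-form
#' oracle.  Saturated pairs (`p >= 0.95`) are capped at `d = 10` with a
#' warning.
#'
#' @param aln Named character vector of aligned rows.
#' @return List of class `aa_distance` with `labels`, `p` (observed
#'   proportions), and `d` (corrected distances).
#' @export
distance_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  labels <- rownames(m)
  p <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(shared))
        stop("no shared non-gap columns between '", labels[i], "' and '",
             labels[j], "'")
      p[i, j] <- p[j, i] <- mean(m[i, shared] != m[j, shared])
    }
  }
  d <- p
  sat <- p >= 0.95
  d[!sat] <- -(19 / 20) * log(1 - (20 / 19) * p[!sat])
  if (any(sat[upper.tri(sat)])) {
    warning("saturated pairs (p >= 0.95) capped at distance 10", call. = FALSE)
    d[sat] <- 10
  }
  diag(d) <- 0
  structure(list(labels = labels, p = p, d = d), class = "aa_distance")
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a corrected distance matrix (the
#' self-contained stand-in for external maximum-likelihood inference; see
#' [external_tree_adapter()]).  Negative branch lengths are clamped to zero
#' with a warning.
#'
#' @param dm An `aa_distance` object from [distance_matrix()], or a square
#'   symmetric numeric matrix.
#' @return Unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "aa_distance")) dm$d else dm
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("need a square distance matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Nonparametric bootstrap supports on the NJ tree
#'
#' Felsenstein column bootstrap over the distance/NJ path: alignment columns
#' are resampled with replacement per replicate, a replicate tree is built,
#' and the support of each internal edge of the point-estimate tree is the
#' percentage of replicate trees containing the same bipartition.
#'
#' @param aln Named character vector of aligned rows (>= 4).
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return The point-estimate NJ tree with supports (0-100) as
#'   `node.label`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed) {
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  m <- aln_matrix(aln)
  if (nrow(m) < 4L) stop("need at least 4 rows for bootstrap supports")
  point <- neighbor_joining(distance_matrix(aln))
  L <- ncol(m)
  reps <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- m[, cols, drop = FALSE]
    rows <- apply(sub, 1, paste, collapse = "")
    names(rows) <- rownames(m)
    tr <- tryCatch(suppressWarnings(neighbor_joining(distance_matrix(rows))),
                   error = function(e) NULL)
    tr
  }))
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps), 1)
  point$node.label <- as.character(support)
  attr(point, "n_bootstrap") <- length(reps)
  point
}

#' Run an external tree-inference engine
#'
#' Adapter contract for plugging a maximum-likelihood engine into the
#' pipeline: the alignment is written as FASTA, a user-supplied command
#' template with `{in}` and `{out}` placeholders is executed, and the
#' engine's newick output is parsed and validated against the alignment's
#' leaf set.
#'
#' @param aln Named character vector of aligned rows.
#' @param command_template Shell command with `{in}` and `{out}`
#'   placeholders.
#' @return [ape::phylo] tree.
#' @export
external_tree_adapter <- function(aln, command_template) {
  aln <- as_seqvec(aln)
  fin <- tempfile(fileext = ".faa")
  fout <- tempfile(fileext = ".nwk")
  on.exit(unlink(c(fin, fout)))
  write_fasta(aln, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, command_template, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)  # the template controls its own redirections
  if (status != 0L)
    stop("external tree engine failed (exit ", status, "): ", cmd)
  if (!file.exists(fout)) stop("external engine produced no output file")
  tree <- read_newick(fout)
  if (!setequal(tree$tip.label, names(aln)))
    stop("external engine leaf set does not match the alignment")
  tree
}
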