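#' Markov clustering of an identity graph
#'
#' Dense implementation of the Markov cluster (MCL) algorithm on a weighted
#' undirected similarity graph.  Edges at or below `threshold` are removed
#' (the redundancy-reduction convention is strictly-above-90 percent
#' identity), self-loops weighted by each node's maximum incident edge (the
#' MCL tool's loop convention, which damps the period-2 oscillation of small
#' cliques; isolated nodes get a unit loop) are added, the transition matrix
#' is made column-stochastic, and expansion (matrix squaring) alternates with
#' inflation (elementwise power, column renormalisation) and pruning of
#' entries below `prune_below` until the maximum elementwise change drops
#' below `tol`.  Clusters are the weakly connected components of the
#' attractor structure of the converged matrix; a node attracted to several
#' attractor systems goes to the one holding the largest attraction value
#' (ties to the lowest cluster id).
#'
#' @param identities Symmetric numeric matrix of pairwise similarities
#'   (e.g. percent global identity) with dimnames, or a 3-column data frame
#'   `from, to, weight`.
#' @param threshold Edges with weight strictly greater than this survive;
#'   use `-Inf` to keep all.
#' @param inflation Inflation exponent (default 2.0).
#' @param prune_below Entries below this are zeroed each iteration.
#' @param max_iter,tol Convergence controls; hitting `max_iter` emits a
#'   warning and returns the current partition.
#' @return Data frame with columns `protein_id`, `cluster_id` (a partition
#'   of the node set, cluster ids ordered by first member appearance).
#' @export
mcl_cluster <- function(identities, threshold = 90, inflation = 2,
                        prune_below = 1e-5, max_iter = 100L, tol = 1e-6) {
  if (is.data.frame(identities)) {
    nodes <- sort(unique(c(identities[[1]], identities[[2]])))
    m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(identities))) {
      m[identities[[1]][r], identities[[2]][r]] <- identities[[3]][r]
      m[identities[[2]][r], identities[[1]][r]] <- identities[[3]][r]
    }
    identities <- m
  }
  if (!is.matrix(identities) || nrow(identities) == 0L)
    stop("identity graph is empty")
  if (is.null(rownames(identities)))
    stop("identity matrix needs dimnames")
  if (any(identities < 0)) stop("negative edge weight")
  nodes <- rownames(identities)
  n <- length(nodes)
  if (n == 1L)
    return(data.frame(protein_id = nodes, cluster_id = 1L,
                      stringsAsFactors = FALSE))

  A <- identities
  A[A <= threshold] <- 0
  diag(A) <- 0
  loops <- apply(A, 1, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- M
    M <- M %*% M                      # expansion
    M <- M^inflation                  # inflation
    M[M < prune_below] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current partition", call. = FALSE)

  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # degenerate
  # attractor systems: components of the attractor-attractor support graph
  sub <- (M[attractors, attractors, drop = FALSE] > 0) |
         t(M[attractors, attractors, drop = FALSE] > 0)
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  cluster_of <- integer(n)
  for (i in seq_len(n)) {
    w <- M[attractors, i]
    if (i %in% attractors && all(w == 0)) {
      cluster_of[i] <- comp[match(i, attractors)]
      next
    }
    if (all(w == 0)) {
      # no attraction at all (isolated after pruning): own component support
      w <- (M[attractors, , drop = FALSE] %*% M[, i])[, 1]
    }
    if (all(w == 0)) {
      cluster_of[i] <- NA_integer_
      next
    }
    best <- max(w)
    cand <- sort(unique(comp[w == best]))
    cluster_of[i] <- cand[1]  # ties: lowest cluster id
  }
  # leftover unattracted nodes become singletons
  if (anyNA(cluster_of)) {
    extra <- max(comp) + seq_len(sum(is.na(cluster_of)))
    cluster_of[is.na(cluster_of)] <- extra
  }
  # renumber by first appearance for determinism
  ids <- match(cluster_of, unique(cluster_of))
  data.frame(protein_id = nodes, cluster_id = ids, stringsAsFactors = FALSE)
}

#' Redundancy reduction: longest sequence per genus per cluster
#'
#' Within each cluster, members are grouped by genus and only the longest
#' sequence is kept (ties to the lexicographically smallest protein id).
#' With `complete_only = TRUE`, representatives from incomplete assemblies
#' are dropped afterwards.
#'
#' @param clusters Data frame from [mcl_cluster()].
#' @param proteins Data frame with `protein_id`, `residues` (or `length`),
#'   `genus`, and (if `complete_only`) `complete` columns.
#' @param complete_only Drop representatives from incomplete assemblies.
#' @return Character vector of retained protein ids.
#' @export
reduce_redundancy <- function(clusters, proteins, complete_only = FALSE) {
  meta <- proteins
  if (!"length" %in% names(meta)) {
    if (!"residues" %in% names(meta))
      stop("proteins need a 'residues' or 'length' column")
    meta$length <- nchar(meta$residues)
  }
  if (!"genus" %in% names(meta) || anyNA(meta$genus))
    stop("every protein needs a genus label")
  idx <- match(clusters$protein_id, meta$protein_id)
  if (anyNA(idx)) stop("cluster member missing from protein table")
  d <- data.frame(protein_id = clusters$protein_id,
                  cluster_id = clusters$cluster_id,
                  genus = meta$genus[idx], length = meta$length[idx],
                  stringsAsFactors = FALSE)
  keep <- unlist(lapply(split(d, paste(d$cluster_id, d$genus, sep = "\r")),
                        function(grp) {
                          grp <- grp[order(-grp$length, grp$protein_id), ,
                                     drop = FALSE]
                          grp$protein_id[1]
                        }), use.names = FALSE)
  keep <- sort(keep)
  if (complete_only) {
    if (!"complete" %in% names(meta))
      stop("complete_only requires a 'complete' column")
    ok <- meta$complete[match(keep, meta$protein_id)]
    keep <- keep[as.logical(ok)]
  }
  keep
}

#' Complete-linkage hierarchical clustering of an identity matrix
#'
#' Agglomerative clustering of the rows of a square identity matrix using
#' euclidean row distances and complete linkage -- the layout step behind
#' similarity heatmaps.  Rows are sorted lexicographically first so that
#' distance ties resolve deterministically.
#'
#' @param identities Square symmetric numeric matrix with dimnames.
#' @return List with `hclust` (the [stats::hclust] object), `order`
#'   (leaf labels in dendrogram order), and `newick` (the dendrogram as a
#'   newick string).
#' @export
hierarchical_cluster <- function(identities) {
  if (!is.matrix(identities) || nrow(identities) != ncol(identities))
    stop("need a square identity matrix")
  if (is.null(rownames(identities))) stop("identity matrix needs dimnames")
  m <- identities[order(rownames(identities)), order(rownames(identities)),
                  drop = FALSE]
  h <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  tree <- ape::as.phylo(h)
  list(hclust = h, order = h$labels[h$order],
       newick = ape::write.tree(tree))
}
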