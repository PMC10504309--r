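# Tip sets on the child side of every edge (storage orientation).
edge_sides <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2]]])
}

# Root an unrooted tree at a point `dist_from_child` along edge `e`
# (measured from the child node of the edge in storage orientation).
root_on_edge <- function(tree, e, dist_from_child) {
  t_len <- tree$edge.length[e]
  eps <- min(1e-8, t_len / 2)
  pos <- min(max(dist_from_child, eps), t_len - eps)
  v <- tree$edge[e, 2]
  tmp <- phytools::bind.tip(tree, "..root..", edge.length = 1,
                            where = v, position = pos)
  rt <- ape::root(tmp, outgroup = "..root..", resolve.root = TRUE)
  rt <- ape::drop.tip(rt, "..root..", collapse.singles = FALSE)
  ape::collapse.singles(rt)
}

# Canonical root bipartition of a rooted tree: the lexicographically
# smaller of the two root-child tip sets, as a collapsed string.
root_split <- function(tree) {
  stopifnot(ape::is.rooted(tree))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k)
    sort(tree$tip.label[phangorn::Descendants(tree, k, "tips")[[1]]]))
  keys <- vapply(sides, paste, character(1), collapse = "|")
  keys[order(keys)][1]
}

#' Root a tree by minimal ancestor deviation (MAD)
#'
#' Evaluates every branch as a root candidate.  For each branch and each
#' leaf pair, the pair's inferred ancestor is the candidate root point (for
#' pairs straddling the branch) or their fixed induced ancestor node
#' (otherwise), and the pair's relative deviation from a strict clock is
#' the absolute value of `2 * d(ancestor, b) / d(b, c) - 1`.  The branch score is the
#' root-mean-square of `r` over all pairs, minimised over the relative root
#' position `rho` in closed form (the objective is quadratic in `rho`;
#' the minimiser is clamped to the branch).  The branch with the smallest
#' score wins; ties go to the branch whose smaller tip set is
#' lexicographically smallest.  Zero-length branches are replaced by 1e-9
#' internally so the ratio statistic stays defined.
#'
#' @param tree Unrooted (or rooted; it is unrooted first) [ape::phylo] tree
#'   with branch lengths and >= 3 leaves.
#' @return List with `tree` (rooted at the MAD point), `candidates`
#'   (data frame of all branches sorted by deviation: `edge`, `parent`,
#'   `child`, `rho`, `deviation`, `side`), `root_deviation`, and
#'   `ambiguity_ratio` (second-best / best deviation).
#' @export
mad_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need at least 3 leaves")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length <= 0))
    stop("degenerate tree: all pairwise distances are zero")
  tree$edge.length[tree$edge.length <= 0] <- 1e-9
  D <- ape::dist.nodes(tree)
  sides <- edge_sides(tree)
  tips <- seq_len(ntip)
  n_edge <- nrow(tree$edge)
  rho <- numeric(n_edge)
  dev <- numeric(n_edge)
  side_key <- character(n_edge)
  for (e in seq_len(n_edge)) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; t_len <- tree$edge.length[e]
    sv <- sides[[e]]
    su <- setdiff(tips, sv)
    # straddling pairs: ancestor is the candidate root point
    dvb <- D[v, sv]
    duc <- D[u, su]
    dbc <- outer(dvb, rep(1, length(su))) + t_len +
           outer(rep(1, length(dvb)), duc)
    num <- sum((dbc - 2 * outer(dvb, rep(1, length(su)))) / dbc^2)
    den <- 2 * t_len * sum(1 / dbc^2)
    r0 <- min(max(num / den, 0), 1)
    r_cross <- abs(2 * (outer(dvb, rep(1, length(su))) + r0 * t_len) / dbc - 1)
    # same-side pairs: ancestor is their induced ancestor, rho-independent
    same_side_sq <- function(node, set) {
      if (length(set) < 2L) return(numeric(0))
      dn <- D[node, set]
      pairs <- utils::combn(seq_along(set), 2)
      b <- pairs[1, ]; c <- pairs[2, ]
      (abs(dn[b] - dn[c]) / D[cbind(set[b], set[c])])^2
    }
    rsq <- c(r_cross^2, same_side_sq(v, sv), same_side_sq(u, su))
    rho[e] <- r0
    dev[e] <- sqrt(mean(rsq))
    smaller <- if (length(sv) <= length(su)) sv else su
    side_key[e] <- paste(sort(tree$tip.label[smaller]), collapse = "|")
  }
  ord <- order(dev, side_key)
  candidates <- data.frame(edge = ord,
                           parent = tree$edge[ord, 1],
                           child = tree$edge[ord, 2],
                           rho = rho[ord], deviation = dev[ord],
                           side = side_key[ord], stringsAsFactors = FALSE)
  best <- ord[1]
  rooted <- root_on_edge(tree, best, rho[best] * tree$edge.length[best])
  amb <- if (n_edge > 1L) {
    if (candidates$deviation[1] == 0) {
      if (candidates$deviation[2] == 0) 1 else Inf
    } else candidates$deviation[2] / candidates$deviation[1]
  } else 1
  list(tree = rooted, candidates = candidates,
       root_deviation = candidates$deviation[1], ambiguity_ratio = amb)
}

#' Root a tree with a designated outgroup
#'
#' If the outgroup is monophyletic in the unrooted tree, the root is placed
#' at the midpoint of the branch separating it from the ingroup (the
#' paralogous-rooting design: a pre-duplication paralog such as AsrC serves
#' as the outgroup for a tree of duplicated families).  A scattered
#' outgroup is flagged: the root goes on the branch minimising the number
#' of misplaced leaves relative to a clean outgroup/ingroup bipartition,
#' with MAD deviation breaking ties.
#'
#' @param tree Unrooted (or rooted) [ape::phylo] tree with branch lengths.
#' @param outgroup_leaves Non-empty proper subset of leaf labels.
#' @return Rooted tree; attribute `"monophyletic"` reports whether the
#'   outgroup was clean.
#' @export
outgroup_root <- function(tree, outgroup_leaves) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  og <- unique(outgroup_leaves)
  if (length(og) == 0L) stop("outgroup is empty")
  if (!all(og %in% tree$tip.label)) stop("outgroup leaf not in tree")
  if (setequal(og, tree$tip.label)) stop("outgroup cannot be all leaves")
  tree$edge.length[tree$edge.length <= 0] <- 1e-9
  ntip <- length(tree$tip.label)
  og_idx <- match(og, tree$tip.label)
  sides <- edge_sides(tree)
  mismatch <- vapply(seq_along(sides), function(e) {
    sv <- sides[[e]]
    m1 <- length(setdiff(og_idx, sv)) + length(setdiff(sv, og_idx))
    su <- setdiff(seq_len(ntip), sv)
    m2 <- length(setdiff(og_idx, su)) + length(setdiff(su, og_idx))
    min(m1, m2)
  }, numeric(1))
  best_m <- min(mismatch)
  cand <- which(mismatch == best_m)
  mono <- best_m == 0L
  if (!mono) {
    warning("outgroup is not monophyletic; rooting at the best-agreement branch",
            call. = FALSE)
    if (length(cand) > 1L) {
      devs <- mad_root(tree)$candidates
      cand <- cand[order(devs$deviation[match(cand, devs$edge)])]
    }
  }
  e <- cand[1]
  rooted <- root_on_edge(tree, e, tree$edge.length[e] / 2)
  attr(rooted, "monophyletic") <- mono
  rooted
}

#' Compare MAD and outgroup root placements
#'
#' @param mad_result Result of [mad_root()].
#' @param outgroup_result Result of [outgroup_root()].
#' @return List reporting whether both methods place the root on the same
#'   branch (identical root bipartition), the MAD ambiguity ratio, and the
#'   outgroup monophyly flag.
#' @export
compare_roots <- function(mad_result, outgroup_result) {
  same <- identical(root_split(mad_result$tree), root_split(outgroup_result))
  list(same_branch = same,
       mad_deviation = mad_result$root_deviation,
       mad_ambiguity_ratio = mad_result$ambiguity_ratio,
       outgroup_monophyletic = isTRUE(attr(outgroup_result, "monophyletic")))
}
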