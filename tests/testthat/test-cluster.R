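clique_matrix <- function(groups, within = 95, between = 0) {
  n <- sum(lengths(groups))
  ids <- unlist(groups)
  m <- matrix(between, n, n, dimnames = list(ids, ids))
  for (g in groups) m[g, g] <- within
  diag(m) <- 100
  m
}

test_that("MCL separates disconnected cliques and handles singletons", {
  m <- clique_matrix(list(paste0("a", 1:5), paste0("b", 1:5)))
  cl <- mcl_cluster(m, threshold = 90)
  expect_equal(sort(unique(cl$cluster_id)), 1:2)
  expect_equal(unname(table(cl$cluster_id)[as.character(1:2)]),
               array(c(5L, 5L)))
  split_by <- split(cl$protein_id, cl$cluster_id)
  expect_true(all(vapply(split_by, function(s)
    all(startsWith(s, "a")) || all(startsWith(s, "b")), logical(1))))

  single <- matrix(100, 1, 1, dimnames = list("x", "x"))
  expect_equal(mcl_cluster(single)$cluster_id, 1L)
  expect_error(mcl_cluster(matrix(-1, 2, 2, dimnames = list(1:2, 1:2)),
                           threshold = -Inf), "negative")
})

test_that("MCL output partitions the node set; strict threshold drops
           at-threshold edges", {
  set.seed(8)
  n <- 12
  m <- matrix(stats::runif(n * n, 0, 100), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 100
  dimnames(m) <- list(paste0("p", 1:n), paste0("p", 1:n))
  cl <- mcl_cluster(m, threshold = 90)
  expect_setequal(cl$protein_id, rownames(m))
  expect_equal(anyDuplicated(cl$protein_id), 0L)
  # an edge exactly at 90 does not connect (strictly-above rule)
  m2 <- clique_matrix(list(c("x1", "x2")), within = 90)
  cl2 <- mcl_cluster(m2, threshold = 90)
  expect_equal(length(unique(cl2$cluster_id)), 2)
  m3 <- clique_matrix(list(c("x1", "x2")), within = 90.01)
  expect_equal(length(unique(mcl_cluster(m3, threshold = 90)$cluster_id)), 1)
})

test_that("MCL on a disjoint union equals the union of MCL on the parts", {
  set.seed(9)
  blocks <- lapply(1:3, function(k) {
    ids <- paste0("g", k, "_", 1:6)
    m <- matrix(stats::runif(36, 91, 99), 6, 6, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 100
    m
  })
  big <- matrix(0, 18, 18)
  ids <- unlist(lapply(blocks, rownames))
  dimnames(big) <- list(ids, ids)
  for (b in blocks) big[rownames(b), colnames(b)] <- b
  whole <- mcl_cluster(big, threshold = 90)
  parts <- lapply(blocks, mcl_cluster, threshold = 90)
  for (k in 1:3) {
    sub <- whole[whole$protein_id %in% rownames(blocks[[k]]), ]
    expect_equal(length(unique(sub$cluster_id)),
                 length(unique(parts[[k]]$cluster_id)))
  }
})

test_that("MCL recovers planted partitions", {
  planted_graph <- function(seed, groups = 3, size = 8, p_in = 0.9,
                            p_out = 0.05) {
    set.seed(seed)
    n <- groups * size
    lab <- rep(seq_len(groups), each = size)
    ids <- paste0("n", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      w <- if (lab[i] == lab[j]) {
        if (stats::runif(1) < p_in) 95 else 0
      } else {
        if (stats::runif(1) < p_out) 91 else 0
      }
      m[i, j] <- m[j, i] <- w
    }
    diag(m) <- 100
    list(m = m, lab = lab)
  }
  ok <- 0
  for (s in 1:20) {
    g <- planted_graph(s)
    cl <- mcl_cluster(g$m, threshold = 90)
    if (mclust::adjustedRandIndex(cl$cluster_id, g$lab) == 1) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("redundancy reduction keeps the longest per genus per cluster", {
  clusters <- data.frame(protein_id = c("p1", "p2", "p3"),
                         cluster_id = c(1L, 1L, 1L))
  prot <- data.frame(protein_id = c("p1", "p2", "p3"),
                     length = c(300L, 310L, 290L),
                     genus = c("A", "A", "B"),
                     complete = c(TRUE, FALSE, TRUE))
  expect_setequal(reduce_redundancy(clusters, prot), c("p2", "p3"))
  # complete_only drops incomplete representatives afterwards
  expect_setequal(reduce_redundancy(clusters, prot, complete_only = TRUE), "p3")
  # length ties break to the lexicographically smaller id
  prot$length <- c(300L, 300L, 290L)
  expect_setequal(reduce_redundancy(clusters, prot), c("p1", "p3"))
  # singleton clusters map to themselves
  singles <- data.frame(protein_id = paste0("p", 1:3), cluster_id = 1:3)
  expect_setequal(reduce_redundancy(singles, prot), prot$protein_id)
  prot$genus[1] <- NA
  expect_error(reduce_redundancy(clusters, prot), "genus")
})

test_that("every dropped representative shares cluster and genus with its keeper", {
  cfg <- small_sim(seed = 77, subst_rate = 0.02)  # shallow: >90% identities
  ds <- simulate_dataset(cfg)
  ids <- ds$truth$layout$gene_id[ds$truth$layout$family == "DsrA"]
  seqs <- stats::setNames(ds$proteins$residues, ds$proteins$protein_id)[ids]
  idm <- all_vs_all_identity(seqs)
  cl <- mcl_cluster(idm, threshold = 90)
  meta <- ds$proteins
  kept <- reduce_redundancy(cl, meta)
  expect_true(length(kept) < length(ids))  # shallow divergence collapses genera
  dropped <- setdiff(ids, kept)
  for (d in dropped) {
    cid <- cl$cluster_id[cl$protein_id == d]
    gen <- meta$genus[meta$protein_id == d]
    mates <- cl$protein_id[cl$cluster_id == cid]
    keeper <- intersect(mates, kept)
    expect_true(any(meta$genus[match(keeper, meta$protein_id)] == gen))
  }
})

test_that("complete-linkage euclidean clustering is deterministic and monotone", {
  m <- rbind(a = c(100, 95, 10, 12), b = c(95, 100, 11, 9),
             c = c(10, 11, 100, 96), d = c(12, 9, 96, 100))
  colnames(m) <- rownames(m)
  res <- hierarchical_cluster(m)
  h <- res$hclust
  # two identical rows merge at height 0
  m2 <- m; m2["b", ] <- m2["a", ]
  expect_equal(hierarchical_cluster(m2)$hclust$height[1], 0)
  # well-separated pairs merge first
  first_two <- lapply(1:2, function(i) sort(h$labels[-h$merge[i, ]]))
  expect_setequal(first_two, list(c("a", "b"), c("c", "d")))
  expect_true(all(diff(h$height) >= 0))
  expect_error(hierarchical_cluster(m[, 1:3]), "square")
  # dendrogram exports as parseable newick
  expect_s3_class(ape::read.tree(text = res$newick), "phylo")
})
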