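test_that("species trees are ultrametric, binary, and seed-deterministic", {
  cfg <- sim_config(n_genomes = 3, seed = 1)
  tr <- simulate_species_tree(cfg)
  expect_true(ape::is.ultrametric(tr))
  expect_true(ape::is.rooted(tr))
  expect_equal(length(tr$tip.label), 3)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(depths)), 1e-8)
  tr2 <- simulate_species_tree(cfg)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("pure-birth tree height matches the Yule expectation", {
  # E[height] of a Yule tree with n extant tips at rate b is sum_{k=2}^n 1/(b k)
  n <- 16; b <- 1
  expected <- sum(1 / (b * 2:n))
  heights <- vapply(1:200, function(i) {
    cfg <- sim_config(n_genomes = n, birth = b, death = 0, seed = 5000 + i)
    max(ape::node.depth.edgelength(simulate_species_tree(cfg, rescale = FALSE)))
  }, numeric(1))
  se <- stats::sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - expected), 3 * se + 1e-9)
})

test_that("evolution over zero-length branches is the identity", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  cfg <- sim_config(n_genomes = 3, seq_length = 50, seed = 2)
  ev <- evolve_family(tr, cfg, seed = 9)
  expect_equal(unname(ev$sequences["a"]), ev$root_seq)
  expect_true(all(ev$sequences == ev$root_seq))
})

test_that("observed p-distance follows the uniform 20-state closed form", {
  # two leaves at divergence t each: E[p] = (19/20)(1 - exp(-2 r t * 20/19))
  t_br <- 0.4; r <- 0.5; L <- 500
  cfg <- sim_config(n_genomes = 3, seq_length = L, subst_rate = r, seed = 3)
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t_br, t_br))
  ps <- vapply(1:20, function(i) {
    ev <- evolve_family(tr, cfg, seed = 100 + i)
    mean(strsplit(ev$sequences[["a"]], "")[[1]] !=
         strsplit(ev$sequences[["b"]], "")[[1]])
  }, numeric(1))
  p_exp <- (19 / 20) * (1 - exp(-2 * r * t_br * 20 / 19))
  se <- sqrt(p_exp * (1 - p_exp) / (L * length(ps)))
  expect_lt(abs(mean(ps) - p_exp), 3 * se)
})

test_that("gamma site rates increase the variance of per-site change counts", {
  tr <- ape::read.tree(text = "(a:2,b:2);")
  base <- sim_config(n_genomes = 3, seq_length = 2000, subst_rate = 0.5, seed = 4)
  hetero <- sim_config(n_genomes = 3, seq_length = 2000, subst_rate = 0.5,
                       gamma_shape = 0.3, seed = 4)
  diff_sites <- function(cfg, seed) {
    ev <- evolve_family(tr, cfg, seed)
    s <- strsplit(ev$sequences, "")
    s$a != s$b
  }
  # chunked variance of the per-site mismatch indicator: rate heterogeneity
  # clusters changes, inflating between-chunk variance
  chunk_var <- function(x) stats::var(colMeans(matrix(x, nrow = 50)))
  v_base <- mean(vapply(1:5, function(i) chunk_var(diff_sites(base, i)), numeric(1)))
  v_het <- mean(vapply(1:5, function(i) chunk_var(diff_sites(hetero, i)), numeric(1)))
  expect_gt(v_het, v_base)
})

test_that("complete genomes carry the full class repertoire, blocks contiguous", {
  cfg <- small_sim(seed = 21, incompleteness_prob = 0)
  ds <- simulate_dataset(cfg)
  fams <- cfg$families
  classes <- ds$truth$classes
  layout <- ds$truth$layout
  bact <- names(classes)[classes == "bacterial_reductive"][1]
  carried <- layout$family[layout$genome_id == bact & layout$family != "cargo"]
  expected <- fams$name[vapply(strsplit(fams$classes, ","),
                               function(cc) "bacterial_reductive" %in% cc,
                               logical(1))]
  expect_setequal(carried, expected)
  # the dsr block is one contiguous run in planted order
  blk <- fams[fams$block == "dsr", ]
  blk <- blk$name[order(blk$block_pos)]
  present <- blk[blk %in% carried]
  rows <- layout[layout$genome_id == bact & layout$family %in% present, ]
  rows <- rows[order(rows$index), ]
  expect_equal(rows$family, present)
  expect_equal(rows$index, seq(min(rows$index), length.out = nrow(rows)))
})

test_that("incompleteness deletes genes at the configured rate", {
  cfg <- sim_config(n_genomes = 20, seq_length = 50, incompleteness_prob = 0.1,
                    seed = 33)
  ds <- simulate_dataset(cfg)
  n_del <- nrow(ds$truth$deleted)
  n_tot <- n_del + nrow(ds$proteins)
  p_hat <- n_del / n_tot
  se <- sqrt(0.1 * 0.9 / n_tot)
  expect_lt(abs(p_hat - 0.1), 3 * se)
  # deleted genes re-rank: indices stay consecutive from 0 per contig
  for (g in unique(ds$genes$genome_id)) {
    idx <- sort(ds$genes$index[ds$genes$genome_id == g])
    expect_equal(idx, seq(0L, length(idx) - 1L))
  }
  expect_true(any(!ds$genomes$complete))
})

test_that("export round-trips gene orders, counts, and the LGT ledger", {
  cls <- preview_classes(small_sim(seed = 7))
  donor <- cls$genome_id[cls$class == "bacterial_reductive"][1]
  recip <- cls$genome_id[cls$class == "archaeal_minimal"][1]
  cfg <- small_sim(seed = 7, lgt_events = list(
    list(family = "DsrA", donor = donor, recipient = recip)))
  ds <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  export_dataset(ds, out)
  prot <- read_fasta(file.path(out, "proteins.faa"))
  expect_equal(nrow(prot), nrow(ds$proteins))
  genes <- read_gene_locations(file.path(out, "genes.tsv"), "tsv")
  expect_equal(genes$gene_id, ds$genes$gene_id)
  expect_equal(genes$index, ds$genes$index)
  gt <- jsonlite::read_json(file.path(out, "ground_truth.json"))
  expect_equal(length(gt$lgt_events), 1)
  expect_equal(gt$lgt_events[[1]]$family, "DsrA")
  expect_equal(gt$lgt_events[[1]]$recipient, recip)
})

test_that("gene trees are congruent with the species tree; LGT regrafts", {
  cls <- preview_classes(small_sim(seed = 13))
  donor <- cls$genome_id[cls$class == "bacterial_reductive"][1]
  recip <- cls$genome_id[cls$class == "archaeal_minimal"][1]
  cfg <- small_sim(seed = 13, lgt_events = list(
    list(family = "DsrB", donor = donor, recipient = recip)))
  ds <- simulate_dataset(cfg)
  sp <- ds$truth$species_tree
  # vertical family: restricted species tree identical
  gtC <- ds$truth$gene_trees[["DsrC"]]
  ref <- ape::keep.tip(sp, gtC$tip.label)
  expect_equal(phangorn::RF.dist(ape::unroot(gtC), ape::unroot(ref)), 0)
  # LGT family: recipient is sister to the donor in the true gene tree
  gtB <- ds$truth$gene_trees[["DsrB"]]
  pd <- ape::cophenetic.phylo(gtB)
  others <- setdiff(gtB$tip.label, recip)
  expect_equal(others[which.min(pd[recip, others])], donor)
  # an LGT event naming a non-carrier leaf errors
  bad <- sim_config(n_genomes = 10, seq_length = 200, seed = 13,
                    lgt_events = list(list(family = "DsrT", donor = donor,
                                           recipient = recip)))
  expect_error(simulate_dataset(bad), "lacking the family")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- small_sim(seed = 99, n_genomes = 6, seq_length = 80)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$genes, d2$genes)
  expect_identical(ape::write.tree(d1$truth$species_tree),
                   ape::write.tree(d2$truth$species_tree))
})
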