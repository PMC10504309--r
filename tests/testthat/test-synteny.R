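# build a one-contig gene table with family hits at the given ranks
toy_contig <- function(hit_at, n = 25, genome = "g1", contig = "c1",
                       offset = 0L) {
  idx <- seq_len(n) - 1L + offset
  data.frame(gene_id = sprintf("%s_g%02d", genome, idx),
             genome_id = genome, contig_id = contig, index = idx,
             strand = rep(c("+", "-"), length.out = n),
             protein_id = sprintf("%s_g%02d", genome, idx),
             stringsAsFactors = FALSE)
}

toy_assign <- function(genes, hit_at, family = "DsrA") {
  data.frame(protein_id = genes$protein_id,
             family = ifelse(genes$index %in% hit_at, family, NA_character_),
             stringsAsFactors = FALSE)
}

test_that("the four-gene distance rule splits hit runs as specified", {
  hits <- c(2, 4, 9, 15, 21)
  genes <- toy_contig(hits)
  cl <- extract_synteny_clusters(genes, toy_assign(genes, hits), max_gap = 4)
  members <- lapply(split(cl[cl$family != "cargo", ],
                          cl$cluster_id[cl$family != "cargo"]),
                    function(d) sort(d$index))
  expect_equal(unname(members), list(c(2, 4, 9), 15, 21))
  # intervening genes appear as cargo inside the first cluster
  first <- cl[cl$cluster_id == 1, ]
  expect_equal(sort(first$index), 2:9)
  expect_equal(sum(first$family == "cargo"), 5)
  expect_equal(first$span_start[1], 2)
  expect_equal(first$span_end[1], 10)
  # the alternative offset convention reads the limit as index difference
  cl2 <- extract_synteny_clusters(genes, toy_assign(genes, hits),
                                  max_gap = 4, gap = "offset")
  mem2 <- lapply(split(cl2[cl2$family != "cargo", ],
                       cl2$cluster_id[cl2$family != "cargo"]),
                 function(d) sort(d$index))
  expect_equal(unname(mem2), list(c(2, 4), 9, 15, 21))
})

test_that("clusters never span contigs and the rule is translation invariant", {
  g1 <- toy_contig(c(2, 4), n = 10, contig = "c1")
  g2 <- toy_contig(c(0, 2), n = 10, contig = "c2")
  genes <- rbind(g1, g2)
  genes$gene_id <- make.unique(genes$gene_id)
  genes$protein_id <- genes$gene_id
  asn <- data.frame(protein_id = genes$protein_id,
                    family = ifelse((genes$contig_id == "c1" &
                                       genes$index %in% c(2, 4)) |
                                    (genes$contig_id == "c2" &
                                       genes$index %in% c(0, 2)),
                                    "DsrB", NA_character_))
  cl <- extract_synteny_clusters(genes, asn, max_gap = 4)
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(length(unique(paste(cl$cluster_id, cl$contig_id))), 2)
  # translation invariance: shifting all ranks leaves the split pattern intact
  hits <- c(2, 4, 9, 15, 21)
  shifted <- toy_contig(hits + 100L, offset = 100L, n = 25)
  cls <- extract_synteny_clusters(shifted, toy_assign(shifted, hits + 100L),
                                  max_gap = 4)
  sizes <- table(cls$cluster_id[cls$family != "cargo"])
  expect_equal(unname(sort(as.integer(sizes))), c(1L, 1L, 3L))
  # every hit belongs to exactly one cluster
  hit_rows <- cls[cls$family != "cargo", ]
  expect_equal(sort(hit_rows$index), sort(hits + 100L))
  expect_equal(anyDuplicated(hit_rows$gene_id), 0L)
  # unknown protein in assignments errors
  bad <- rbind(asn, data.frame(protein_id = "ghost", family = "DsrA"))
  expect_error(extract_synteny_clusters(genes, bad), "unknown gene")
})

test_that("the planted dsr cluster is recovered as one block in order", {
  cfg <- small_sim(seed = 91)
  ds <- simulate_dataset(cfg)
  asn <- assign_families(ds$proteins, ds$references,
                         decoy_families = ds$references$family[ds$references$decoy])
  cl <- extract_synteny_clusters(ds$genes, asn, max_gap = 4)
  arr <- arrangement_strings(cl)
  bact <- names(ds$truth$classes)[ds$truth$classes == "bacterial_reductive"]
  # the planted block survives as a consecutive run (other nearby hits may
  # extend the cluster at either end, so match as a substring)
  expect_true(any(grepl("A-B-D-N-C-T-M-K-J-O-P",
                        arr$arrangement[arr$genome_id %in% bact],
                        fixed = TRUE)))
})

test_that("presence/absence counts assignments with all-zero rows kept", {
  genes <- rbind(toy_contig(c(0, 1, 2), n = 5, genome = "g1"),
                 toy_contig(integer(0), n = 3, genome = "g2"))
  asn <- data.frame(protein_id = genes$protein_id, family = NA_character_)
  asn$family[1] <- "DsrA"
  asn$family[2:3] <- "DsrC"
  pa <- presence_absence(genes, asn, families = c("DsrA", "DsrB", "DsrC"))
  expect_equal(unname(pa["g1", ]), c(1L, 0L, 2L))
  expect_equal(unname(pa["g2", ]), c(0L, 0L, 0L))
  # column sums equal total assignments per family
  expect_equal(unname(colSums(pa)),
               unname(vapply(c("DsrA", "DsrB", "DsrC"), function(f)
                 sum(asn$family == f, na.rm = TRUE), integer(1)) * 1L))
})

test_that("genotype calls follow the minimal-set rules and precedence", {
  fams <- c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK", "DsrN", "DsrD", "DsrT",
            "DsrE", "DsrF", "DsrH", "DsrL", "Sat", "AprA", "AprB", "QmoA",
            "QmoB")
  row_for <- function(present) as.integer(fams %in% present)
  pa <- rbind(
    minimal = row_for(c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK", "DsrN")),
    sulfate = row_for(c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK", "DsrD", "DsrT",
                        "Sat", "AprA", "AprB", "QmoA")),
    oxidative = row_for(c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK", "DsrE",
                          "DsrF", "DsrH", "DsrL")),
    chimeric = row_for(c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK", "DsrD",
                         "DsrE", "DsrF", "DsrH")),
    partial = row_for(c("DsrA", "DsrB")),
    none = row_for(character(0)),
    # sulfate-capable repertoire plus oxidative markers: chimeric wins
    both = row_for(c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK", "DsrD", "Sat",
                     "AprA", "AprB", "QmoA", "DsrL")))
  colnames(pa) <- fams
  calls <- call_genotypes(pa)
  expect_equal(calls$class,
               c("sulfite_minimal", "sulfate_capable", "oxidative", "chimeric",
                 "partial", "none", "chimeric"))
  expect_equal(calls$has_minimal_set, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                        TRUE))
  expect_error(call_genotypes(pa, type_labels = c(DsrD = "weird")), "reductive")
})

test_that("Apr/Qmo-without-Dsr screening matches the stated rule", {
  fams <- c("DsrA", "DsrC", "AprA", "AprB", "QmoA")
  pa <- rbind(apr_only = c(0L, 0L, 1L, 1L, 0L),
              apr_plus_dsr = c(0L, 1L, 1L, 0L, 0L),
              qmo_only = c(0L, 0L, 0L, 0L, 2L),
              nothing = c(0L, 0L, 0L, 0L, 0L))
  colnames(pa) <- fams
  expect_setequal(screen_apr_qmo_without_dsr(pa), c("apr_only", "qmo_only"))
})

test_that("simulator genotype classes are recovered exactly when complete", {
  cfg <- small_sim(seed = 95, incompleteness_prob = 0)
  ds <- simulate_dataset(cfg)
  asn <- assign_families(ds$proteins, ds$references,
                         decoy_families = ds$references$family[ds$references$decoy])
  pa <- presence_absence(ds$genes, asn)
  calls <- call_genotypes(pa)
  expected <- c(archaeal_minimal = "sulfite_minimal",
                bacterial_reductive = "sulfate_capable",
                oxidative = "oxidative", chimeric = "chimeric")
  truth_cls <- unname(expected[ds$truth$classes[calls$genome_id]])
  expect_equal(calls$class, truth_cls)
  # the count matrix equals the planted layout
  layout <- ds$truth$layout
  for (g in rownames(pa)) for (f in colnames(pa)) {
    expect_equal(unname(pa[g, f]),
                 sum(layout$genome_id == g & layout$family == f))
  }
})
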