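#' Family specification for the genome simulator
#'
#' Describes one protein family to plant into simulated genomes: which
#' genotype classes carry it, whether it sits inside an ordered gene-cluster
#' block or is scattered, its reductive/oxidative type label, and (for decoy
#' families) which target family it shares a sequence motif with.
#'
#' @param name Family name (e.g. `"DsrA"`).
#' @param classes Character vector of genome classes carrying the family.
#' @param block Block name for clustered families, or `"scattered"`.
#' @param block_pos Ordered position within the block (ignored if scattered).
#' @param type `"reductive"`, `"oxidative"`, or `"none"`.
#' @param decoy Logical; decoy families resemble a target family locally but
#'   must be rejected by family assignment.
#' @param motif_from For decoys, name of the target family whose root
#'   sequence donates a shared 30-residue motif.
#' @return A one-row data frame.
#' @export
family_spec <- function(name, classes, block = "scattered", block_pos = NA_integer_,
                        type = "none", decoy = FALSE, motif_from = NA_character_) {
  data.frame(name = name, classes = paste(classes, collapse = ","),
             block = block, block_pos = as.integer(block_pos), type = type,
             decoy = decoy, motif_from = motif_from, stringsAsFactors = FALSE)
}

#' Default family layout for the Dsr pathway simulator
#'
#' Emulates the canonical genomic repertoires of sulfur-dissimilating
#' prokaryotes: a consecutive *dsrABDNCTMKJOP* cluster (with per-class
#' subsets), a *sat-aprBA-qmoABC* sulfate-activation block in sulfate
#' reducers, the *dsrEFH*/*dsrL* oxidative accessories, the AsrC paralog, and
#' two decoy homolog families (NarG-like and HdrA-like).
#'
#' @return Data frame of family specifications.
#' @export
default_family_specs <- function() {
  all4 <- c("archaeal_minimal", "bacterial_reductive", "oxidative", "chimeric")
  rbind(
    family_spec("DsrA", all4, "dsr", 1),
    family_spec("DsrB", all4, "dsr", 2),
    family_spec("DsrD", c("bacterial_reductive", "chimeric"), "dsr", 3,
                type = "reductive"),
    family_spec("DsrN", c("archaeal_minimal", "bacterial_reductive", "chimeric"),
                "dsr", 4),
    family_spec("DsrC", all4, "dsr", 5),
    family_spec("DsrT", "bacterial_reductive", "dsr", 6, type = "reductive"),
    family_spec("DsrM", all4, "dsr", 7),
    family_spec("DsrK", all4, "dsr", 8),
    family_spec("DsrJ", c("bacterial_reductive", "oxidative", "chimeric"), "dsr", 9),
    family_spec("DsrO", c("bacterial_reductive", "oxidative", "chimeric"), "dsr", 10),
    family_spec("DsrP", c("bacterial_reductive", "oxidative", "chimeric"), "dsr", 11),
    family_spec("DsrE", c("oxidative", "chimeric"), "efh", 1, type = "oxidative"),
    family_spec("DsrF", c("oxidative", "chimeric"), "efh", 2, type = "oxidative"),
    family_spec("DsrH", c("oxidative", "chimeric"), "efh", 3, type = "oxidative"),
    family_spec("DsrL", c("oxidative", "chimeric"), type = "oxidative"),
    family_spec("Sat", "bacterial_reductive", "sat_apr_qmo", 1),
    family_spec("AprB", "bacterial_reductive", "sat_apr_qmo", 2),
    family_spec("AprA", "bacterial_reductive", "sat_apr_qmo", 3),
    family_spec("QmoA", "bacterial_reductive", "sat_apr_qmo", 4),
    family_spec("QmoB", "bacterial_reductive", "sat_apr_qmo", 5),
    family_spec("QmoC", "bacterial_reductive", "sat_apr_qmo", 6),
    family_spec("AsrC", all4),
    family_spec("NarG_decoy", all4, decoy = TRUE, motif_from = "DsrB"),
    family_spec("HdrA_decoy", c("bacterial_reductive", "oxidative", "chimeric"),
                decoy = TRUE, motif_from = "QmoA")
  )
}

#' Simulation configuration
#'
#' Collects every simulator parameter.  The defaults describe the study
#' conditions the package is tested under: 20 genomes on a clock-like
#' birth-death species tree rescaled to unit height, 300-residue proteins
#' evolving under a uniform 20-state substitution model at 0.5 expected
#' substitutions per site from root to tip, no site-rate heterogeneity, and
#' no genome incompleteness.
#'
#' @param n_genomes Number of genomes (tree leaves), at least 3.
#' @param birth,death Birth-death rates of the species-tree simulation.
#' @param seq_length Protein length in residues (>= 10).
#' @param subst_rate Expected substitutions per site per unit branch length.
#' @param gamma_shape Shape of the gamma distribution of per-site rate
#'   multipliers (mean 1), or `NULL` for homogeneous rates.
#' @param families Family specification table (see [default_family_specs()]).
#' @param lgt_events List of lateral-transfer events, each a list with
#'   elements `family`, `donor`, `recipient` (leaf labels).
#' @param incompleteness_prob Independent deletion probability per gene,
#'   emulating incomplete assemblies.
#' @param n_cargo Number of unrelated cargo genes interleaved per genome.
#' @param class_proportions Named numeric vector of genome-class proportions;
#'   classes are assigned to contiguous clades in ladderized tip order.
#' @param genus_size Number of consecutive tips sharing a genus label.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genomes = 20L, birth = 1, death = 0,
                       seq_length = 300L, subst_rate = 0.5,
                       gamma_shape = NULL, families = default_family_specs(),
                       lgt_events = list(), incompleteness_prob = 0,
                       n_cargo = 8L,
                       class_proportions = c(archaeal_minimal = 0.25,
                                             bacterial_reductive = 0.35,
                                             oxidative = 0.25,
                                             chimeric = 0.15),
                       genus_size = 2L, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_genomes >= 3, birth > 0, death >= 0, seq_length >= 10,
            subst_rate > 0, incompleteness_prob >= 0, incompleteness_prob <= 1,
            is.null(gamma_shape) || gamma_shape > 0)
  if (anyDuplicated(families$name)) stop("family names must be unique")
  for (b in setdiff(unique(families$block), "scattered")) {
    pos <- families$block_pos[families$block == b]
    if (anyDuplicated(pos)) stop("duplicate block positions in block '", b, "'")
  }
  structure(list(n_genomes = as.integer(n_genomes), birth = birth,
                 death = death, seq_length = as.integer(seq_length),
                 subst_rate = subst_rate, gamma_shape = gamma_shape,
                 families = families, lgt_events = lgt_events,
                 incompleteness_prob = incompleteness_prob,
                 n_cargo = as.integer(n_cargo),
                 class_proportions = class_proportions,
                 genus_size = as.integer(genus_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a clock-like species tree
#'
#' Draws a rooted ultrametric birth-death tree with `n_genomes` extant
#' leaves via [ape::rphylo()], relabels leaves `g01`, `g02`, ..., and (by
#' default) rescales the root-to-tip height to 1 so that `subst_rate` reads
#' as expected substitutions per site from root to tip.
#'
#' @param config A [sim_config()].
#' @param rescale Rescale tree height to 1 (default `TRUE`).
#' @return Rooted ultrametric [ape::phylo] tree.
#' @export
simulate_species_tree <- function(config, rescale = TRUE) {
  tree <- NULL
  for (attempt in seq_len(100L)) {
    tree <- with_seed(derive_seed(config$seed, paste0("species_tree_", attempt)),
                      tryCatch(ape::rphylo(config$n_genomes, config$birth,
                                           config$death),
                               error = function(e) NULL))
    if (!is.null(tree)) break
  }
  if (is.null(tree))
    stop("birth-death simulation failed in 100 attempts; check rates")
  tree$tip.label <- sprintf("g%02d", seq_len(config$n_genomes))
  if (rescale) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / h
  }
  ape::ladderize(tree)
}

# Pre-generated alternatives for each residue (used by the event sampler).
.aa_alternatives <- local({
  out <- lapply(AA20, function(a) setdiff(AA20, a))
  names(out) <- AA20
  out
})

# Apply Poisson substitution events to a residue vector along one branch.
mutate_branch <- function(res, rate, bl, site_rates) {
  nev <- stats::rpois(length(res), rate * bl * site_rates)
  for (s in which(nev > 0L)) {
    for (k in seq_len(nev[s])) {
      alt <- .aa_alternatives[[res[s]]]
      res[s] <- alt[sample.int(19L, 1L)]
    }
  }
  res
}

#' Evolve a protein family along a tree
#'
#' Simulates sequence evolution under a uniform 20-state model: per site,
#' substitution events arrive as a Poisson process with rate
#' `subst_rate * branch_length * site_rate`, and each event replaces the
#' residue with one of the 19 alternatives uniformly.  Site rates are 1
#' everywhere, or gamma-distributed with mean 1 when `gamma_shape` is set.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param config A [sim_config()] (supplies `seq_length`, `subst_rate`,
#'   `gamma_shape`).
#' @param seed Integer seed for this family's stream.
#' @param root_seq Optional root sequence (character scalar); drawn uniformly
#'   if omitted.
#' @return List with `sequences` (named character vector, one per leaf),
#'   `root_seq`, and `site_rates`.
#' @export
evolve_family <- function(tree, config, seed, root_seq = NULL) {
  L <- config$seq_length
  if (L < 10L) stop("seq_length must be at least 10")
  with_seed(seed, {
    if (is.null(root_seq)) {
      root <- AA20[sample.int(20L, L, replace = TRUE)]
    } else {
      root <- strsplit(root_seq, "")[[1]]
      if (length(root) != L) stop("root_seq length does not match seq_length")
    }
    site_rates <- if (is.null(config$gamma_shape)) rep(1, L)
                  else stats::rgamma(L, shape = config$gamma_shape,
                                     rate = config$gamma_shape)
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- length(tr$tip.label)
    node_seq <- vector("list", ntip + tr$Nnode)
    node_seq[[ntip + 1L]] <- root
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]
      child <- tr$edge[e, 2L]
      node_seq[[child]] <- mutate_branch(node_seq[[parent]], config$subst_rate,
                                         tr$edge.length[e], site_rates)
    }
    seqs <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""),
                   character(1))
    names(seqs) <- tr$tip.label
    list(sequences = seqs, root_seq = paste(root, collapse = ""),
         site_rates = site_rates)
  })
}

# Assign genome classes to contiguous blocks of ladderized tips and genus
# labels to runs of `genus_size` consecutive tips.
assign_classes <- function(tree, config) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  tips <- tr$tip.label[tr$edge[tr$edge[, 2] <= length(tr$tip.label), 2]]
  props <- config$class_proportions / sum(config$class_proportions)
  n <- length(tips)
  counts <- floor(props * n)
  while (sum(counts) < n) {
    i <- which.max(props * n - counts)
    counts[i] <- counts[i] + 1L
  }
  classes <- rep(names(counts), counts)
  names(classes) <- tips
  genera <- sprintf("genus%02d", (seq_len(n) - 1L) %/% config$genus_size + 1L)
  names(genera) <- tips
  list(classes = classes, genera = genera)
}

# Build the true gene tree of one family: species tree restricted to the
# carriers, with each lateral-transfer event applied as a xenologous
# replacement (recipient re-attached inside the donor's terminal branch).
build_gene_tree <- function(species_tree, carriers, events) {
  if (length(carriers) < 2L) return(NULL)
  gt <- ape::keep.tip(species_tree, carriers)
  for (ev in events) {
    if (!(ev$donor %in% gt$tip.label) || !(ev$recipient %in% gt$tip.label))
      stop("LGT event names a leaf lacking the family: ",
           ev$family, " ", ev$donor, " -> ", ev$recipient)
    gt <- ape::drop.tip(gt, ev$recipient)
    donor_tip <- which(gt$tip.label == ev$donor)
    donor_bl <- gt$edge.length[gt$edge[, 2] == donor_tip]
    h <- donor_bl * 0.5  # transfer halfway along the donor's terminal branch
    gt <- phytools::bind.tip(gt, ev$recipient, edge.length = h,
                             where = donor_tip, position = h)
  }
  gt
}

#' Preview genome classes and genera for a configuration
#'
#' Returns the genome-class and genus assignment a configuration will
#' produce, without simulating sequences -- useful for choosing donor and
#' recipient leaves when planting lateral-transfer events.
#'
#' @param config A [sim_config()].
#' @return Data frame with `genome_id`, `class`, `genus`.
#' @export
preview_classes <- function(config) {
  tree <- simulate_species_tree(config)
  lab <- assign_classes(tree, config)
  data.frame(genome_id = names(lab$classes), class = unname(lab$classes),
             genus = unname(lab$genera[names(lab$classes)]),
             stringsAsFactors = FALSE)
}

#' Simulate a complete annotated-genome dataset with ground truth
#'
#' Runs the full generative model: species tree, per-family gene trees
#' (vertical descent restricted to carrier classes, plus planted xenologous
#' replacements), sequence evolution, genome assembly with contiguous
#' cluster blocks interleaved with unrelated cargo genes, decoy families
#' sharing a 30-residue motif with their target family, and i.i.d. gene
#' deletion emulating incomplete assemblies.
#'
#' @param config A [sim_config()].
#' @return List with elements `proteins` (data frame: `protein_id`,
#'   `residues`, `genome_id`, `genus`), `genes` (gene-location table),
#'   `genomes` (per-genome metadata incl. completeness), `references`
#'   (one reference sequence per family, decoys flagged), and `truth`
#'   (species tree, gene trees, class/genus maps, planted layout, LGT and
#'   deletion ledgers).
#' @export
simulate_dataset <- function(config) {
  species_tree <- simulate_species_tree(config)
  lab <- assign_classes(species_tree, config)
  fams <- config$families
  classes_of <- strsplit(fams$classes, ",")
  names(classes_of) <- fams$name

  # group LGT events per family
  ev_by_fam <- list()
  for (ev in config$lgt_events) {
    if (!ev$family %in% fams$name) stop("unknown LGT family: ", ev$family)
    ev_by_fam[[ev$family]] <- c(ev_by_fam[[ev$family]], list(ev))
  }

  # root sequences (decoys borrow a motif from their target family's root)
  root_seqs <- list()
  for (i in seq_len(nrow(fams))) {
    fam <- fams$name[i]
    root_seqs[[fam]] <- with_seed(derive_seed(config$seed, paste0("root_", fam)),
                                  paste(AA20[sample.int(20L, config$seq_length,
                                                        replace = TRUE)],
                                        collapse = ""))
  }
  motif_len <- 30L
  for (i in which(fams$decoy)) {
    src <- fams$motif_from[i]
    if (is.na(src) || !src %in% fams$name) next
    start <- with_seed(derive_seed(config$seed, paste0("motif_", fams$name[i])),
                       sample.int(config$seq_length - motif_len + 1L, 1L))
    s <- strsplit(root_seqs[[fams$name[i]]], "")[[1]]
    m <- strsplit(root_seqs[[src]], "")[[1]]
    s[start:(start + motif_len - 1L)] <- m[start:(start + motif_len - 1L)]
    root_seqs[[fams$name[i]]] <- paste(s, collapse = "")
  }

  # gene trees and leaf sequences per family
  gene_trees <- list()
  fam_seqs <- list()
  for (fam in fams$name) {
    carriers <- names(lab$classes)[lab$classes %in% classes_of[[fam]]]
    gt <- build_gene_tree(species_tree, carriers, ev_by_fam[[fam]] %||% list())
    gene_trees[[fam]] <- gt
    if (is.null(gt)) {
      fam_seqs[[fam]] <- character(0)
      next
    }
    fam_seqs[[fam]] <- evolve_family(gt, config,
                                     derive_seed(config$seed, paste0("evolve_", fam)),
                                     root_seq = root_seqs[[fam]])$sequences
  }

  asm <- assemble_genomes(species_tree, fam_seqs, config,
                          classes = lab$classes, genera = lab$genera)

  references <- data.frame(protein_id = paste0("ref_", fams$name),
                           residues = unlist(root_seqs[fams$name], use.names = FALSE),
                           family = fams$name, decoy = fams$decoy,
                           stringsAsFactors = FALSE)

  truth <- list(species_tree = species_tree, gene_trees = gene_trees,
                classes = lab$classes, genera = lab$genera,
                layout = asm$layout,
                lgt_events = config$lgt_events,
                deleted = asm$deleted,
                families = fams)
  list(proteins = asm$proteins, genes = asm$genes, genomes = asm$genomes,
       references = references, truth = truth, config = config)
}

#' Assemble annotated genomes from evolved family sequences
#'
#' Lays out each genome as a single contig: cluster blocks are placed as
#' contiguous units in their specified internal order, scattered families
#' and unrelated random cargo genes are interleaved around them, and genes
#' are then deleted independently with `incompleteness_prob`.
#'
#' @param species_tree The species tree (leaves = genomes).
#' @param fam_seqs Named list: family -> named character vector of leaf
#'   sequences.
#' @param config A [sim_config()].
#' @param classes,genera Named character vectors keyed by genome; defaults
#'   re-derive them from the tree.
#' @return List with `proteins`, `genes`, `genomes`, `layout`, `deleted`.
#' @export
assemble_genomes <- function(species_tree, fam_seqs, config,
                             classes = NULL, genera = NULL) {
  if (is.null(classes) || is.null(genera)) {
    lab <- assign_classes(species_tree, config)
    classes <- classes %||% lab$classes
    genera <- genera %||% lab$genera
  }
  fams <- config$families
  cargo_len <- max(60L, config$seq_length %/% 2L)
  genes_list <- list()
  prot_list <- list()
  layout_list <- list()
  deleted_list <- list()
  genome_rows <- list()

  for (g in species_tree$tip.label) {
    cls <- classes[[g]]
    carried <- fams$name[vapply(strsplit(fams$classes, ","),
                                function(cc) cls %in% cc, logical(1))]
    carried <- carried[vapply(carried, function(f) g %in% names(fam_seqs[[f]]),
                              logical(1))]
    # assemble layout items: blocks as units, scattered families, cargo
    items <- list()
    for (b in setdiff(unique(fams$block[fams$name %in% carried]), "scattered")) {
      members <- fams[fams$name %in% carried & fams$block == b, , drop = FALSE]
      members <- members[order(members$block_pos), , drop = FALSE]
      items <- c(items, list(members$name))
    }
    for (f in carried[fams$block[match(carried, fams$name)] == "scattered"])
      items <- c(items, list(f))
    n_cargo <- config$n_cargo
    items <- c(items, as.list(rep("__cargo__", n_cargo)))
    ord <- with_seed(derive_seed(config$seed, paste0("layout_", g)),
                     sample.int(length(items)))
    flat <- unlist(items[ord], use.names = FALSE)
    strands <- with_seed(derive_seed(config$seed, paste0("strand_", g)),
                         sample(c("+", "-"), length(items), replace = TRUE))
    strand_flat <- rep(strands[seq_along(ord)], lengths(items[ord]))

    cargo_count <- 0L
    rows <- vector("list", length(flat))
    for (i in seq_along(flat)) {
      fam <- flat[i]
      if (fam == "__cargo__") {
        cargo_count <- cargo_count + 1L
        gid <- sprintf("%s_cargo%02d", g, cargo_count)
        res <- with_seed(derive_seed(config$seed, gid),
                         paste(AA20[sample.int(20L, cargo_len, replace = TRUE)],
                               collapse = ""))
        rows[[i]] <- list(gene_id = gid, family = "cargo", residues = res)
      } else {
        gid <- sprintf("%s_%s", g, fam)
        rows[[i]] <- list(gene_id = gid, family = fam,
                          residues = unname(fam_seqs[[fam]][g]))
      }
    }
    keep <- rep(TRUE, length(rows))
    if (config$incompleteness_prob > 0) {
      keep <- with_seed(derive_seed(config$seed, paste0("incomplete_", g)),
                        stats::runif(length(rows)) >= config$incompleteness_prob)
    }
    full_idx <- seq_along(rows) - 1L
    gl <- data.frame(gene_id = vapply(rows, `[[`, character(1), "gene_id"),
                     genome_id = g, contig_id = paste0(g, "_c1"),
                     index = full_idx, strand = strand_flat,
                     protein_id = vapply(rows, `[[`, character(1), "gene_id"),
                     family = vapply(rows, `[[`, character(1), "family"),
                     stringsAsFactors = FALSE)
    layout_list[[g]] <- gl
    deleted_list[[g]] <- gl[!keep, c("genome_id", "gene_id", "family")]
    kept <- gl[keep, , drop = FALSE]
    kept$index <- seq_len(nrow(kept)) - 1L  # re-rank after deletion
    genes_list[[g]] <- kept[, c("gene_id", "genome_id", "contig_id", "index",
                                "strand", "protein_id")]
    prot_list[[g]] <- data.frame(
      protein_id = kept$gene_id,
      residues = vapply(rows, `[[`, character(1), "residues")[keep],
      genome_id = g, genus = unname(genera[[g]]), stringsAsFactors = FALSE)
    genome_rows[[g]] <- data.frame(genome_id = g, genus = unname(genera[[g]]),
                                   complete = all(keep), stringsAsFactors = FALSE)
  }
  list(proteins = do.call(rbind, c(prot_list, list(make.row.names = FALSE))),
       genes = do.call(rbind, c(genes_list, list(make.row.names = FALSE))),
       genomes = do.call(rbind, c(genome_rows, list(make.row.names = FALSE))),
       layout = do.call(rbind, c(layout_list, list(make.row.names = FALSE))),
       deleted = do.call(rbind, c(deleted_list, list(make.row.names = FALSE))))
}

#' Export a simulated dataset to disk
#'
#' Writes the artifacts the pipeline consumes -- `proteins.faa`,
#' `references.faa`, `genes.tsv`, `genomes.tsv` -- plus
#' `ground_truth.json` (trees as newick strings, ledgers as arrays).
#'
#' @param dataset Result of [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
export_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  write_fasta(dataset$proteins, file.path(outdir, "proteins.faa"))
  refs <- dataset$references
  write_fasta(refs, file.path(outdir, "references.faa"))
  write_gene_locations(dataset$genes, file.path(outdir, "genes.tsv"))
  utils::write.table(dataset$genomes, file.path(outdir, "genomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  gt_json <- list(
    species_tree = ape::write.tree(tr$species_tree),
    gene_trees = lapply(tr$gene_trees, function(t)
      if (is.null(t)) NULL else ape::write.tree(t)),
    classes = as.list(tr$classes),
    genera = as.list(tr$genera),
    layout = tr$layout,
    lgt_events = tr$lgt_events,
    deleted = tr$deleted,
    families = tr$families)
  jsonlite::write_json(gt_json, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Simulate a duplicated-family fixture for paralogous rooting
#'
#' Builds the classic pre-duplication outgroup design used to root a tree of
#' two paralogous families: one species tree evolved as three homologous
#' copies -- an outgroup paralog (the AsrC role) splitting at the root, and
#' two in-paralogs (the DsrA/DsrB roles) splitting afterwards.  The true
#' root lies on the outgroup stem.
#'
#' @param config A [sim_config()]; `n_genomes` species per copy.
#' @param paralogs Names of the two in-paralog copies.
#' @param outgroup Name of the outgroup paralog.
#' @return List with `tree` (true rooted tree, leaves `Family_genome`),
#'   `sequences`, and `outgroup_leaves`.
#' @export
simulate_paralog_fixture <- function(config, paralogs = c("DsrA", "DsrB"),
                                     outgroup = "AsrC") {
  sp <- simulate_species_tree(config)
  sub_nwk <- function(label) {
    t2 <- sp
    t2$tip.label <- paste(label, t2$tip.label, sep = "_")
    sub(";$", "", ape::write.tree(t2))
  }
  nwk <- sprintf("(%s:1.0,(%s:0.5,%s:0.5):0.5);",
                 sub_nwk(outgroup), sub_nwk(paralogs[1]), sub_nwk(paralogs[2]))
  tree <- ape::read.tree(text = nwk)
  ev <- evolve_family(tree, config, derive_seed(config$seed, "paralog_fixture"))
  list(tree = tree, sequences = ev$sequences,
       outgroup_leaves = grep(paste0("^", outgroup, "_"),
                              names(ev$sequences), value = TRUE))
}
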