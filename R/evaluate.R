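#' Simulate a dataset, run the pipeline, and score it against ground truth
#'
#' The end-to-end testing harness: generates a dataset with
#' [simulate_dataset()], exports it, runs [run_pipeline()] on the export,
#' and scores the outputs against the simulator's ledgers.
#'
#' @param sim A [sim_config()].
#' @param workdir Working directory (defaults to a temporary directory).
#' @param ... Overrides passed to [pipeline_config()] (e.g. `n_bootstrap`).
#' @param verbose Progress messages.
#' @return List with `report` (the pipeline run report), `evaluation`
#'   (see [evaluate_run()]), `dataset`, and `out_dir`.
#' @export
simulate_and_run <- function(sim, workdir = tempfile("dsrevo_"), ...,
                             verbose = FALSE) {
  dataset <- simulate_dataset(sim)
  ind <- file.path(workdir, "input")
  outd <- file.path(workdir, "output")
  export_dataset(dataset, ind)
  overrides <- list(...)
  args <- c(list(input_dir = ind, out_dir = outd), overrides)
  if (is.null(args$seed)) args$seed <- sim$seed
  config <- do.call(pipeline_config, args)
  report <- run_pipeline(config, verbose = verbose)
  evaluation <- evaluate_run(dataset, outd)
  list(report = report, evaluation = evaluation, dataset = dataset,
       out_dir = outd)
}

# expected genotype class per simulated genome class
EXPECTED_CLASS <- c(archaeal_minimal = "sulfite_minimal",
                    bacterial_reductive = "sulfate_capable",
                    oxidative = "oxidative",
                    chimeric = "chimeric")

#' Score pipeline outputs against simulator ground truth
#'
#' Computes, from a [simulate_dataset()] object and a pipeline output
#' directory: per-protein family-assignment accuracy (cargo and decoy
#' proteins count as correct when unassigned), the adjusted Rand index
#' between the assignment-induced partition and the true family partition,
#' per-family Robinson-Foulds distances between each inferred tree and the
#' true gene tree restricted to the retained leaves, a root-recovery flag
#' per family (MAD root bipartition vs the true rooted split), per-family
#' genotype-call accuracy, and -- for every planted lateral transfer -- a
#' discordance flag per family tree (is the recipient's nearest leaf, by
#' patristic distance, a genome of the donor's class rather than its own?).
#'
#' @param dataset Result of [simulate_dataset()].
#' @param out_dir Pipeline output directory.
#' @return List of scores; see details above.
#' @export
evaluate_run <- function(dataset, out_dir) {
  truth <- dataset$truth
  layout <- truth$layout
  assignments <- utils::read.delim(file.path(out_dir, "assignments.tsv"),
                                   stringsAsFactors = FALSE)
  genotypes <- utils::read.delim(file.path(out_dir, "genotypes.tsv"),
                                 stringsAsFactors = FALSE)

  # --- assignment accuracy ------------------------------------------------
  truth_fam <- layout$family[match(assignments$protein_id, layout$gene_id)]
  decoy_names <- truth$families$name[truth$families$decoy]
  expected <- ifelse(truth_fam %in% c("cargo", decoy_names), NA_character_,
                     truth_fam)
  called <- assignments$family
  correct <- (is.na(expected) & is.na(called)) |
             (!is.na(expected) & !is.na(called) & expected == called)
  assignment_accuracy <- mean(correct)

  planted <- !is.na(expected)
  ari <- if (any(planted)) {
    mclust::adjustedRandIndex(expected[planted],
                              ifelse(is.na(called[planted]), "unassigned",
                                     called[planted]))
  } else NA_real_

  # --- genotype accuracy --------------------------------------------------
  exp_class <- unname(EXPECTED_CLASS[truth$classes[genotypes$genome_id]])
  genotype_accuracy <- mean(genotypes$class == exp_class)

  # --- per-family tree scores ---------------------------------------------
  tree_files <- list.files(file.path(out_dir, "trees"),
                           pattern = "\\.nwk$", full.names = TRUE)
  tree_files <- tree_files[!grepl("\\.rooted\\.nwk$", tree_files)]
  fam_scores <- list()
  lgt_flags <- list()
  for (tf in tree_files) {
    fam <- sub("\\.nwk$", "", basename(tf))
    true_gt <- truth$gene_trees[[fam]]
    if (is.null(true_gt)) next
    tree <- read_newick(tf)
    # protein ids -> genome ids
    genome_of <- layout$genome_id[match(tree$tip.label, layout$gene_id)]
    if (anyNA(genome_of) || anyDuplicated(genome_of)) next
    tree$tip.label <- genome_of
    shared <- intersect(genome_of, true_gt$tip.label)
    if (length(shared) < 4L) next
    ref <- ape::keep.tip(true_gt, shared)
    est <- ape::keep.tip(tree, shared)
    rf <- phangorn::RF.dist(ape::unroot(est), ape::unroot(ref))
    mad <- mad_root(est)
    root_ok <- identical(root_split(mad$tree), root_split(ref))
    fam_scores[[fam]] <- list(family = fam, n_leaves = length(shared),
                              rf = rf, root_recovered = root_ok)
    # LGT discordance: nearest leaf of each recipient, by patristic distance
    for (ev in truth$lgt_events) {
      if (!(ev$donor %in% est$tip.label) || !(ev$recipient %in% est$tip.label))
        next
      pd <- ape::cophenetic.phylo(est)
      others <- setdiff(est$tip.label, ev$recipient)
      nearest <- others[which.min(pd[ev$recipient, others])]
      flagged <- truth$classes[[nearest]] == truth$classes[[ev$donor]] &&
                 truth$classes[[ev$donor]] != truth$classes[[ev$recipient]]
      lgt_flags[[paste(fam, ev$family, ev$recipient, sep = ":")]] <-
        list(tree_family = fam, lgt_family = ev$family, donor = ev$donor,
             recipient = ev$recipient, nearest_leaf = nearest,
             discordant = flagged)
    }
  }
  rf_values <- vapply(fam_scores, `[[`, numeric(1), "rf")
  list(assignment_accuracy = assignment_accuracy,
       family_ari = ari,
       genotype_accuracy = genotype_accuracy,
       family_scores = fam_scores,
       rf_zero_fraction = if (length(rf_values)) mean(rf_values == 0)
                          else NA_real_,
       root_recovered_fraction = if (length(fam_scores))
         mean(vapply(fam_scores, `[[`, logical(1), "root_recovered"))
         else NA_real_,
       lgt_flags = lgt_flags)
}
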