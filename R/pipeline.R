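#' Pipeline configuration
#'
#' Central numeric settings of the analysis: a 25 percent minimum local
#' identity and 1e-10 E-value ceiling for family assignment, a strict
#' above-90-percent global-identity graph with inflation 2.0 for MCL
#' redundancy clustering, a 95 percent gap-threshold for alignment
#' trimming, a four-gene maximum distance for synteny clusters, and 1000
#' bootstrap replicates for branch supports.
#'
#' @param input_dir Directory holding `proteins.faa`, `references.faa`,
#'   `genes.tsv`, `genomes.tsv` (the [export_dataset()] layout).
#' @param out_dir Output directory for all artifacts.
#' @param min_local_identity,max_evalue Family-assignment filters.
#' @param cluster_identity_threshold Strict lower bound (percent global
#'   identity) for redundancy-graph edges.
#' @param mcl_inflation MCL inflation.
#' @param trim_gap_threshold Minimum non-gap column fraction kept.
#' @param synteny_max_gap Maximum genes between consecutive synteny hits.
#' @param n_bootstrap Bootstrap replicates (0 disables supports).
#' @param complete_only Restrict tree sequences to complete assemblies.
#' @param min_family_size Minimum retained sequences for tree building.
#' @param tree_engine Optional external engine command template (see
#'   [external_tree_adapter()]); `NULL` uses the internal distance/NJ path.
#' @param seed Mandatory integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            min_local_identity = 25, max_evalue = 1e-10,
                            cluster_identity_threshold = 90,
                            mcl_inflation = 2, trim_gap_threshold = 0.95,
                            synteny_max_gap = 4L, n_bootstrap = 1000L,
                            complete_only = FALSE, min_family_size = 3L,
                            tree_engine = NULL, seed) {
  if (missing(seed)) stop("pipeline_config requires an explicit seed")
  stopifnot(min_local_identity >= 0, min_local_identity <= 100,
            max_evalue >= 0, cluster_identity_threshold >= 0,
            cluster_identity_threshold <= 100, mcl_inflation > 1,
            trim_gap_threshold > 0, trim_gap_threshold <= 1,
            synteny_max_gap >= 0, n_bootstrap >= 0)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 min_local_identity = min_local_identity,
                 max_evalue = max_evalue,
                 cluster_identity_threshold = cluster_identity_threshold,
                 mcl_inflation = mcl_inflation,
                 trim_gap_threshold = trim_gap_threshold,
                 synteny_max_gap = as.integer(synteny_max_gap),
                 n_bootstrap = as.integer(n_bootstrap),
                 complete_only = complete_only,
                 min_family_size = as.integer(min_family_size),
                 tree_engine = tree_engine, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

log_stage <- function(stage, msg, verbose) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes assignment, genotyping, synteny extraction, and the per-family
#' phylogenetics chain (identity graph, MCL redundancy reduction,
#' progressive alignment, gap trimming, distance/NJ tree, bootstrap
#' supports, MAD rooting), writing every intermediate artifact under
#' `config$out_dir` plus a machine-readable `report.json`.  Fully
#' deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit progress messages.
#' @return The run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  ind <- config$input_dir
  outd <- config$out_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)

  log_stage("load", paste("reading", ind), verbose)
  proteins <- read_fasta(file.path(ind, "proteins.faa"))
  references <- read_fasta(file.path(ind, "references.faa"))
  references$decoy <- tolower(references$decoy %||% "false") == "true"
  genes <- read_gene_locations(file.path(ind, "genes.tsv"), "tsv")
  genomes <- utils::read.delim(file.path(ind, "genomes.tsv"),
                               stringsAsFactors = FALSE)

  log_stage("assign", paste(nrow(proteins), "proteins vs",
                            nrow(references), "references"), verbose)
  assignments <- assign_families(
    proteins, references,
    decoy_families = references$family[references$decoy],
    min_identity = config$min_local_identity,
    max_evalue = config$max_evalue)
  utils::write.table(assignments, file.path(outd, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("genotype", "presence/absence and genotype calls", verbose)
  fam_order <- sort(references$family[!references$decoy])
  pa <- presence_absence(genes, assignments, families = fam_order)
  utils::write.table(data.frame(genome_id = rownames(pa), pa,
                                check.names = FALSE),
                     file.path(outd, "presence_absence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  genotypes <- call_genotypes(pa)
  utils::write.table(genotypes, file.path(outd, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  apr_only <- screen_apr_qmo_without_dsr(pa)

  log_stage("synteny", "extracting gene-neighborhood clusters", verbose)
  syn <- extract_synteny_clusters(genes, assignments,
                                  max_gap = config$synteny_max_gap)
  utils::write.table(syn, file.path(outd, "synteny_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  arr <- arrangement_strings(syn)
  utils::write.table(arr, file.path(outd, "arrangements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # per-family phylogenetics
  prot_meta <- proteins
  prot_meta$complete <- genomes$complete[match(prot_meta$genome_id,
                                               genomes$genome_id)]
  families <- sort(unique(assignments$family[!is.na(assignments$family)]))
  tree_dir <- file.path(outd, "trees")
  aln_dir <- file.path(outd, "alignments")
  dir.create(tree_dir, showWarnings = FALSE)
  dir.create(aln_dir, showWarnings = FALSE)
  fam_summaries <- list()
  roots <- list()
  counts <- list(screened = nrow(proteins),
                 assigned = sum(!is.na(assignments$family)),
                 decoy_rejected = sum(assignments$decoy_rejected),
                 clustered = 0L, retained = 0L, trees_built = 0L)
  cluster_rows <- list()
  for (fam in families) {
    ids <- assignments$protein_id[!is.na(assignments$family) &
                                  assignments$family == fam]
    fam_seqs <- as_seqvec(proteins)[ids]
    entry <- list(family = fam, n_assigned = length(ids), n_retained = NA,
                  tree = NA, skipped = NA)
    if (length(ids) < 2L) {
      entry$skipped <- "fewer than 2 assigned sequences"
      fam_summaries[[fam]] <- entry
      next
    }
    log_stage("cluster", paste(fam, ":", length(ids), "sequences"), verbose)
    idm <- all_vs_all_identity(fam_seqs)
    clusters <- mcl_cluster(idm, threshold = config$cluster_identity_threshold,
                            inflation = config$mcl_inflation)
    counts$clustered <- counts$clustered + nrow(clusters)
    kept <- reduce_redundancy(clusters, prot_meta,
                              complete_only = config$complete_only)
    clusters$kept <- clusters$protein_id %in% kept
    clusters$family <- fam
    cluster_rows[[fam]] <- clusters
    counts$retained <- counts$retained + length(kept)
    entry$n_retained <- length(kept)
    if (length(kept) < config$min_family_size) {
      entry$skipped <- paste0("fewer than ", config$min_family_size,
                              " retained sequences")
      fam_summaries[[fam]] <- entry
      next
    }
    log_stage("tree", paste(fam, ":", length(kept), "retained"), verbose)
    aln <- progressive_align(fam_seqs[kept])
    trimmed <- trim_alignment(aln, config$trim_gap_threshold)
    write_fasta(trimmed, file.path(aln_dir, paste0(fam, ".faa")))
    tree <- if (!is.null(config$tree_engine)) {
      external_tree_adapter(trimmed, config$tree_engine)
    } else if (config$n_bootstrap > 0 && length(kept) >= 4L) {
      bootstrap_support(trimmed, config$n_bootstrap,
                        derive_seed(config$seed, paste0("bootstrap_", fam)))
    } else {
      suppressWarnings(neighbor_joining(distance_matrix(trimmed)))
    }
    write_newick(tree, file.path(tree_dir, paste0(fam, ".nwk")))
    mad <- mad_root(tree)
    write_newick(mad$tree, file.path(tree_dir, paste0(fam, ".rooted.nwk")))
    roots[[fam]] <- list(family = fam, root_split = root_split(mad$tree),
                         deviation = mad$root_deviation,
                         ambiguity_ratio = mad$ambiguity_ratio)
    counts$trees_built <- counts$trees_built + 1L
    entry$tree <- file.path("trees", paste0(fam, ".nwk"))
    fam_summaries[[fam]] <- entry
  }
  if (length(cluster_rows)) {
    allc <- do.call(rbind, cluster_rows)
    rownames(allc) <- NULL
    utils::write.table(allc, file.path(outd, "mcl_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # config echo without filesystem paths: reports from identical seeds and
  # inputs are byte-identical regardless of where they are written
  config_echo <- unclass(config)
  config_echo$input_dir <- NULL
  config_echo$out_dir <- NULL
  report <- list(
    tool = "dsrevo",
    version = as.character(utils::packageVersion("dsrevo")),
    seed = config$seed,
    config = config_echo,
    counts = counts,
    genotypes = genotypes,
    apr_qmo_without_dsr = apr_only,
    families = unname(fam_summaries),
    roots = unname(roots))
  jsonlite::write_json(report, file.path(outd, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  txt <- c(sprintf("dsrevo run (seed %d)", config$seed),
           sprintf("proteins screened : %d", counts$screened),
           sprintf("family assigned   : %d", counts$assigned),
           sprintf("decoy rejected    : %d", counts$decoy_rejected),
           sprintf("retained for trees: %d", counts$retained),
           sprintf("trees built       : %d", counts$trees_built),
           "", "genotype classes:",
           utils::capture.output(print(table(genotypes$class))))
  writeLines(txt, file.path(outd, "report.txt"))
  invisible(report)
}
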