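#' Extract gene-neighborhood synteny clusters
#'
#' Scans each contig's family hits in gene order and joins consecutive hits
#' separated by at most `max_gap` genes into one cluster; intervening
#' non-hit genes are included in the output with the label `"cargo"`.
#' Clusters never span contigs and singleton clusters are allowed.  By
#' default the distance between two hits counts the genes between them
#' (`gap = "intervening"`, i.e. index difference `max_gap + 1`); set
#' `gap = "offset"` to read the limit as a raw index difference instead.
#'
#' @param genes Gene-location table (see [read_gene_locations()]).
#' @param assignments Family-assignment table (see [assign_families()]);
#'   rows with `family = NA` are non-hits.
#' @param max_gap Maximum distance, in genes, between consecutive hits.
#' @param gap Gap-counting convention (see above).
#' @return Data frame with one gene per row: `cluster_id`, `genome_id`,
#'   `contig_id`, `index`, `gene_id`, `strand`, `family` (`"cargo"` for
#'   intervening genes), plus per-cluster `span_start`/`span_end`
#'   (half-open).
#' @export
extract_synteny_clusters <- function(genes, assignments, max_gap = 4L,
                                     gap = c("intervening", "offset")) {
  gap <- match.arg(gap)
  fam <- assignments$family[match(genes$protein_id, assignments$protein_id)]
  unknown <- setdiff(assignments$protein_id, genes$protein_id)
  if (length(unknown))
    stop("assignment references unknown gene(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  genes$family <- fam
  max_diff <- if (gap == "intervening") max_gap + 1L else max_gap
  out <- list()
  cid <- 0L
  for (key in split(seq_len(nrow(genes)),
                    paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    d <- genes[key, , drop = FALSE]
    d <- d[order(d$index), , drop = FALSE]
    hits <- which(!is.na(d$family))
    if (length(hits) == 0L) next
    breaks <- c(0L, which(diff(d$index[hits]) > max_diff), length(hits))
    for (b in seq_len(length(breaks) - 1L)) {
      cid <- cid + 1L
      members <- hits[(breaks[b] + 1L):breaks[b + 1L]]
      rows <- d[min(members):max(members), , drop = FALSE]
      rows$family[is.na(rows$family)] <- "cargo"
      rows$cluster_id <- cid
      rows$span_start <- d$index[min(members)]
      rows$span_end <- d$index[max(members)] + 1L
      out[[cid]] <- rows[, c("cluster_id", "genome_id", "contig_id", "index",
                             "gene_id", "strand", "family",
                             "span_start", "span_end")]
    }
  }
  if (length(out) == 0L)
    return(data.frame(cluster_id = integer(0), genome_id = character(0),
                      contig_id = character(0), index = integer(0),
                      gene_id = character(0), strand = character(0),
                      family = character(0), span_start = integer(0),
                      span_end = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compact arrangement strings per synteny cluster
#'
#' Collapses each cluster to the familiar dash-joined gene-order notation
#' (e.g. `"A-B-D-N-C-T-M-K-J-O-P"`), stripping a common family prefix.
#'
#' @param clusters Result of [extract_synteny_clusters()].
#' @param strip_prefix Prefix removed from family names (default `"Dsr"`).
#' @return Data frame `cluster_id`, `genome_id`, `arrangement`.
#' @export
arrangement_strings <- function(clusters, strip_prefix = "Dsr") {
  if (nrow(clusters) == 0L)
    return(data.frame(cluster_id = integer(0), genome_id = character(0),
                      arrangement = character(0)))
  parts <- lapply(split(clusters, clusters$cluster_id), function(d) {
    d <- d[order(d$index), , drop = FALSE]
    lab <- ifelse(d$family == "cargo", "x",
                  sub(paste0("^", strip_prefix), "", d$family))
    data.frame(cluster_id = d$cluster_id[1], genome_id = d$genome_id[1],
               arrangement = paste(lab, collapse = "-"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Genome-by-family presence/absence matrix
#'
#' Counts assigned proteins per genome per family; genomes with no
#' assignments appear as all-zero rows.
#'
#' @param genes Gene-location table (supplies the full genome list).
#' @param assignments Family-assignment table.
#' @param families Column order; defaults to the sorted set of assigned
#'   families.
#' @return Integer matrix, genomes as rows, families as columns.
#' @export
presence_absence <- function(genes, assignments, families = NULL) {
  genomes <- sort(unique(genes$genome_id))
  asn <- assignments[!is.na(assignments$family), , drop = FALSE]
  asn$genome_id <- genes$genome_id[match(asn$protein_id, genes$protein_id)]
  families <- families %||% sort(unique(asn$family))
  m <- matrix(0L, length(genomes), length(families),
              dimnames = list(genomes, families))
  if (nrow(asn)) {
    tab <- table(factor(asn$genome_id, levels = genomes),
                 factor(asn$family, levels = families))
    m[] <- as.integer(tab)
  }
  m
}

MINIMAL_SET <- c("DsrA", "DsrB", "DsrC", "DsrM", "DsrK")

#' Classify pathway genotypes from presence/absence
#'
#' Calls a sulfur-metabolism genotype per genome from its family
#' repertoire.  The minimal set is `DsrABCMK` -- the five proteins required
#' for dissimilatory sulfite processing in any direction.  Classes, in
#' precedence order: `chimeric` (reductive- and oxidative-type marker
#' families co-occur), `oxidative` (minimal set plus DsrEFH or DsrL,
#' without DsrD), `sulfate_capable` (minimal set plus Sat, AprA, AprB and
#' QmoA or QmoB), `sulfite_minimal` (minimal set only), `partial` (some but
#' not all of the minimal set), `none`.
#'
#' @param pa Presence/absence matrix from [presence_absence()].
#' @param type_labels Named character vector mapping marker families to
#'   `"reductive"` or `"oxidative"`; defaults to DsrD/DsrT reductive and
#'   DsrE/DsrF/DsrH/DsrL oxidative.
#' @return Data frame `genome_id`, `has_minimal_set`, `class`.
#' @export
call_genotypes <- function(pa, type_labels = NULL) {
  if (is.null(type_labels))
    type_labels <- c(DsrD = "reductive", DsrT = "reductive",
                     DsrE = "oxidative", DsrF = "oxidative",
                     DsrH = "oxidative", DsrL = "oxidative")
  if (!all(type_labels %in% c("reductive", "oxidative")))
    stop("type labels must be 'reductive' or 'oxidative'")
  has <- function(fams) {
    present <- intersect(fams, colnames(pa))
    if (length(present) < length(fams))
      return(rep(FALSE, nrow(pa)))
    if (length(present) == 1L) pa[, present] > 0
    else rowSums(pa[, present, drop = FALSE] > 0) == length(present)
  }
  any_of <- function(fams) {
    present <- intersect(fams, colnames(pa))
    if (length(present) == 0L) return(rep(FALSE, nrow(pa)))
    rowSums(pa[, present, drop = FALSE] > 0) > 0
  }
  minimal <- has(MINIMAL_SET)
  n_min <- rowSums(pa[, intersect(MINIMAL_SET, colnames(pa)), drop = FALSE] > 0)
  red_markers <- names(type_labels)[type_labels == "reductive"]
  ox_markers <- names(type_labels)[type_labels == "oxidative"]
  chimeric <- any_of(red_markers) & any_of(ox_markers)
  oxidative <- minimal & (has(c("DsrE", "DsrF", "DsrH")) | any_of("DsrL")) &
               !any_of("DsrD")
  sulfate <- minimal & has(c("Sat", "AprA", "AprB")) & any_of(c("QmoA", "QmoB"))
  cls <- rep("none", nrow(pa))
  cls[n_min >= 1] <- "partial"
  cls[minimal] <- "sulfite_minimal"
  cls[sulfate] <- "sulfate_capable"
  cls[oxidative] <- "oxidative"
  cls[chimeric & minimal] <- "chimeric"
  data.frame(genome_id = rownames(pa), has_minimal_set = unname(minimal),
             class = cls, stringsAsFactors = FALSE)
}

DSR_FAMILIES <- c("DsrA", "DsrB", "DsrC", "DsrD", "DsrE", "DsrF", "DsrH",
                  "DsrJ", "DsrK", "DsrL", "DsrM", "DsrN", "DsrO", "DsrP",
                  "DsrT")
APR_QMO_FAMILIES <- c("AprA", "AprB", "QmoA", "QmoB", "QmoC")

#' Genomes carrying Apr/Qmo but lacking the Dsr pathway
#'
#' Returns genomes with at least one AprA/AprB/QmoA/QmoB/QmoC assignment
#' and no assignment to any Dsr family -- the screen for the
#' sulfate-activation arm occurring outside Dsr-pathway genomes.
#'
#' @param pa Presence/absence matrix from [presence_absence()].
#' @return Character vector of genome ids.
#' @export
screen_apr_qmo_without_dsr <- function(pa) {
  apr <- intersect(APR_QMO_FAMILIES, colnames(pa))
  dsr <- intersect(DSR_FAMILIES, colnames(pa))
  has_apr <- if (length(apr)) rowSums(pa[, apr, drop = FALSE]) > 0
             else rep(FALSE, nrow(pa))
  has_dsr <- if (length(dsr)) rowSums(pa[, dsr, drop = FALSE]) > 0
             else rep(FALSE, nrow(pa))
  rownames(pa)[has_apr & !has_dsr]
}
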