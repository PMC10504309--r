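# Independent oracles used across the suite.  These deliberately re-derive
# results with naive methods and never call the code paths they check.

# Plain-R Gotoh DP (three state matrices, no traceback): returns the optimal
# affine-gap score, gap run of length L costing gap_open + L * gap_extend.
oracle_align_score <- function(a, b, sm, gap_open, gap_extend, local = FALSE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NI <- -Inf
  M <- matrix(NI, m + 1, n + 1)
  U <- matrix(NI, m + 1, n + 1)
  L <- matrix(NI, m + 1, n + 1)
  M[1, 1] <- 0
  if (!local) {
    for (i in seq_len(m)) U[i + 1, 1] <- -(gap_open + i * gap_extend)
    for (j in seq_len(n)) L[1, j + 1] <- -(gap_open + j * gap_extend)
  }
  op <- gap_open + gap_extend
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    s <- sm[A[i], B[j]]
    prev <- max(M[i, j], U[i, j], L[i, j])
    M[i + 1, j + 1] <- if (local) {
      if (prev <= 0 || prev == NI) s else prev + s
    } else {
      if (prev == NI) NI else prev + s
    }
    U[i + 1, j + 1] <- max(M[i, j + 1] - op, U[i, j + 1] - gap_extend,
                           L[i, j + 1] - op)
    L[i + 1, j + 1] <- max(M[i + 1, j] - op, U[i + 1, j] - op,
                           L[i + 1, j] - gap_extend)
    if (local) best <- max(best, M[i + 1, j + 1])
  }
  if (local) best else max(M[m + 1, n + 1], U[m + 1, n + 1], L[m + 1, n + 1])
}

random_protein <- function(len, alphabet = dsrevo:::AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive MAD oracle: grid search of rho over every branch.
oracle_mad_grid <- function(tree, step = 1e-4) {
  tree$edge.length[tree$edge.length <= 0] <- 1e-9
  D <- ape::dist.nodes(tree)
  nt <- length(tree$tip.label)
  sides <- dsrevo:::edge_sides(tree)
  best <- Inf; best_rho <- NA; best_edge <- NA
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; t_len <- tree$edge.length[e]
    sv <- sides[[e]]; su <- setdiff(seq_len(nt), sv)
    dvb <- D[v, sv]; duc <- D[u, su]
    dbc <- outer(dvb, rep(1, length(su))) + t_len +
           outer(rep(1, length(dvb)), duc)
    fixed <- c()
    for (set_node in list(list(v, sv), list(u, su))) {
      node <- set_node[[1]]; set <- set_node[[2]]
      if (length(set) > 1) {
        cb <- utils::combn(set, 2)
        fixed <- c(fixed, ((D[node, cb[1, ]] - D[node, cb[2, ]]) /
                             D[cbind(cb[1, ], cb[2, ])])^2)
      }
    }
    for (rho in seq(0, 1, by = step)) {
      rr <- (2 * (outer(dvb, rep(1, length(su))) + rho * t_len) / dbc - 1)^2
      sc <- sqrt(mean(c(rr, fixed)))
      if (sc < best) { best <- sc; best_rho <- rho; best_edge <- e }
    }
  }
  list(deviation = best, rho = best_rho, edge = best_edge)
}

# Tiny dataset used by several pipeline-level tests.
small_sim <- function(seed, n_genomes = 10, seq_length = 200, ...) {
  sim_config(n_genomes = n_genomes, seq_length = seq_length, seed = seed, ...)
}

root_split <- dsrevo:::root_split
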