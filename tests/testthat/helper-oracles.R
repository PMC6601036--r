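# Independent oracles for the graph-descriptor tests: brute-force
# enumeration over edge subsets, Floyd-Warshall distances, and the
# Mann-Whitney AUC. Deliberately naive and separate from the package's
# implementation paths.

# Floyd-Warshall all-pairs shortest paths from an edge matrix
oracle_distances <- function(n, edges) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    D[edges[k, 1], edges[k, 2]] <- 1; D[edges[k, 2], edges[k, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_wiener <- function(g) sum(oracle_distances(g$n, g$edges)) / 2

# pruning-based centric index, re-derived independently: delete all
# degree-1 vertices per step (sum of squared deletion counts); a remaining
# leaf-free core of c vertices adds c^2
oracle_centric <- function(g) {
  edges <- g$edges
  alive <- seq_len(g$n)
  total <- 0
  repeat {
    deg <- sapply(alive, function(v) sum(edges == v))
    leaves <- alive[deg == 1]
    if (!length(leaves)) break
    total <- total + length(leaves)^2
    alive <- setdiff(alive, leaves)
    keep <- edges[, 1] %in% alive & edges[, 2] %in% alive
    edges <- edges[keep, , drop = FALSE]
  }
  total + length(alive)^2
}

# classify the subgraph induced by an edge subset: "path", "cluster"
# (star), "chain" (contains its single cycle), or NA (disconnected /
# path-cluster / multi-cycle)
oracle_subgraph_type <- function(edge_rows) {
  verts <- sort(unique(as.vector(edge_rows)))
  nv <- length(verts); ne <- nrow(edge_rows)
  # connectivity by repeated expansion
  reach <- verts[1]
  repeat {
    nxt <- unique(c(reach, as.vector(
      edge_rows[edge_rows[, 1] %in% reach | edge_rows[, 2] %in% reach, ])))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (length(reach) < nv) return(NA_character_)
  deg <- sapply(verts, function(v) sum(edge_rows == v))
  if (ne == nv - 1) {           # tree
    if (max(deg) <= 2) return("path")
    if (sort(deg, decreasing = TRUE)[2] == 1) return("cluster")  # star
    return(NA_character_)       # path/cluster hybrid, not scored here
  }
  if (ne == nv && max(deg) == 2) return("chain")  # single simple cycle
  NA_character_
}

# brute-force chi of a given type and order by enumerating all m-edge subsets
oracle_chi <- function(g, m, type, valence = FALSE) {
  d <- if (valence) g$deltav else g$degree
  if (m == 0) return(sum(ifelse(d == 0, 1, 1 / sqrt(d))))
  ne <- nrow(g$edges)
  if (ne < m) return(0)
  total <- 0
  for (cols in utils::combn(ne, m, simplify = FALSE)) {
    sub <- g$edges[cols, , drop = FALSE]
    if (identical(oracle_subgraph_type(sub), type)) {
      verts <- unique(as.vector(sub))
      total <- total + 1 / sqrt(prod(d[verts]))
    }
  }
  total
}

# brute-force m-edge path count via the same enumeration
oracle_path_count <- function(g, m) {
  if (m == 0) return(g$n)
  ne <- nrow(g$edges)
  if (ne < m) return(0)
  sum(vapply(utils::combn(ne, m, simplify = FALSE), function(cols)
    identical(oracle_subgraph_type(g$edges[cols, , drop = FALSE]), "path"),
    logical(1)))
}

oracle_kappa <- function(g) {
  A <- g$n
  P1 <- oracle_path_count(g, 1); P2 <- oracle_path_count(g, 2)
  P3 <- oracle_path_count(g, 3)
  c(kappa1 = if (P1 > 0) A * (A - 1)^2 / P1^2 else NA_real_,
    kappa2 = if (P2 > 0) (A - 1) * (A - 2)^2 / P2^2 else NA_real_,
    kappa3 = if (P3 > 0) {
      if (A %% 2 == 1) (A - 1) * (A - 3)^2 / P3^2 else (A - 3) * (A - 2)^2 / P3^2
    } else NA_real_)
}

# Mann-Whitney AUC with half-credit for ties
oracle_auc <- function(scores, truth) {
  sa <- scores[truth == 1]; si <- scores[truth == -1]
  mean(outer(sa, si, function(a, b) (a > b) + 0.5 * (a == b)))
}

# molecules used across descriptor tests (standardized on construction)
test_molecules <- function() {
  smi <- c(propane = "CCC", butane = "CCCC", isobutane = "CC(C)C",
           neopentane = "CC(C)(C)C", hexane = "CCCCCC",
           cyclobutane = "C1CCC1", cyclopentane = "C1CCCC1",
           cyclohexane = "C1CCCCC1", benzene = "c1ccccc1",
           methylcyclopentane = "CC1CCCC1", bicyclobutane = "C1CC2CC12",
           ethanol = "CCO", pyridine = "c1ccncc1", isopentane = "CCC(C)C",
           toluene = "Cc1ccccc1", mea = "NCCO")
  ms <- standardize(read_smiles(unname(smi), names(smi)))
  names(ms) <- vapply(ms, function(m) m$id, character(1))
  ms
}
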