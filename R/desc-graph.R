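# Topological, connectivity (chi) and shape (kappa) descriptors.
#
# All operate on the hydrogen-suppressed graph from heavy_graph(). Subgraph
# conventions follow Kier & Hall: 'path' subgraphs are simple paths with m
# edges, 'cluster' subgraphs are m-edge stars centred on one vertex, and
# 'chain' subgraphs are simple cycles with m vertices (each simple cycle of
# a fused system counts once). A vertex with degree 0 (single-atom molecule)
# contributes weight 1 to the order-0 term by convention.

# enumerate simple paths with exactly m >= 1 edges; returns list of vertex vectors
.simple_paths <- function(g, m) {
  out <- list()
  extend <- function(path, inpath) {
    v <- path[length(path)]
    for (w in g$adj[[v]]) {
      if (inpath[w]) next
      np <- c(path, w)
      if (length(np) == m + 1L) {
        if (np[1] < np[m + 1L]) out[[length(out) + 1L]] <<- np
      } else {
        inpath[w] <- TRUE
        extend(np, inpath)
        inpath[w] <- FALSE
      }
    }
  }
  for (s in seq_len(g$n)) {
    inpath <- rep.int(FALSE, g$n); inpath[s] <- TRUE
    extend(s, inpath)
  }
  out
}

# number of paths with m edges (kappa uses m = 1..3)
.path_count <- function(g, m) {
  if (m == 0L) return(g$n)
  if (m == 1L) return(nrow(g$edges))
  if (m == 2L) return(sum(choose(g$degree, 2)))
  length(.simple_paths(g, m))
}

#' Wiener index
#'
#' Sum of topological shortest-path distances over all unordered pairs of
#' heavy atoms.
#'
#' @param g a graph from [heavy_graph()].
#' @return non-negative integer.
#' @examples
#' g <- heavy_graph(read_smiles("CCC")[[1]])
#' wiener_index(g)  # 4
#' @export
wiener_index <- function(g) {
  D <- .graph_distances(g)
  if (any(!is.finite(D))) stop("Wiener index requires a connected graph; standardize() first")
  sum(D) / 2
}

#' Balaban pruning centric index (Tcent)
#'
#' Repeatedly deletes all degree-1 vertices; the index is the sum of squared
#' deletion counts per pruning step. A terminal core with no degree-1
#' vertices (a lone vertex, a single surviving edge, or a cyclic core of c
#' vertices) contributes c squared, so a lone vertex adds 1 and a lone edge
#' adds 4.
#'
#' @param g a graph from [heavy_graph()].
#' @return non-negative integer.
#' @export
centric_index <- function(g) {
  deg <- g$degree
  alive <- rep.int(TRUE, g$n)
  total <- 0
  repeat {
    leaves <- which(alive & deg == 1L)
    if (!length(leaves)) break
    total <- total + length(leaves)^2
    for (v in leaves) {
      alive[v] <- FALSE; deg[v] <- 0L
      for (w in g$adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
    }
  }
  total + sum(alive)^2 * (sum(alive) > 0)
}

# chi weight of a vertex set: product of degrees to the power -1/2
.chi_term <- function(deg) {
  if (any(deg == 0)) return(1)  # lone-vertex convention (order 0 only)
  1 / sqrt(prod(deg))
}

#' Molecular connectivity chi indices
#'
#' Simple and valence-corrected Kier-Hall connectivity indices: path orders
#' 0-6 (`Xp.0`..`Xp.6`, `Xvp.*`), cluster (star) orders 3-6 (`Xc.*`,
#' `Xvc.*`), and chain (simple-cycle) orders 3-6 (`Xch.*`, `Xvch.*`). Each
#' qualifying subgraph contributes the reciprocal square root of the product
#' of its vertices' (valence) degrees.
#'
#' @param g a graph from [heavy_graph()].
#' @return named numeric vector of the 30 chi descriptors.
#' @export
chi_indices <- function(g) {
  d <- g$degree; dv <- g$deltav
  out <- numeric(0)
  # paths 0..6
  for (m in 0:6) {
    if (m == 0L) {
      sets <- as.list(seq_len(g$n))
    } else sets <- .simple_paths(g, m)
    out[paste0("Xp.", m)]  <- sum(vapply(sets, function(s) .chi_term(d[s]),  numeric(1)))
    out[paste0("Xvp.", m)] <- sum(vapply(sets, function(s) .chi_term(dv[s]), numeric(1)))
  }
  # clusters (stars) 3..6: centre vertex plus m chosen neighbours
  for (m in 3:6) {
    simple <- 0; valence <- 0
    for (v in which(d >= m)) {
      nb <- g$adj[[v]]
      combos <- utils::combn(nb, m)
      for (j in seq_len(ncol(combos))) {
        s <- c(v, combos[, j])
        simple <- simple + .chi_term(d[s]); valence <- valence + .chi_term(dv[s])
      }
    }
    out[paste0("Xc.", m)] <- simple; out[paste0("Xvc.", m)] <- valence
  }
  # chains: simple cycles with m vertices
  cycles <- .simple_cycles(g$adj, g$n, maxlen = 6L)
  for (m in 3:6) {
    cyc_m <- Filter(function(cc) length(cc) == m, cycles)
    out[paste0("Xch.", m)]  <- sum(vapply(cyc_m, function(s) .chi_term(d[s]),  numeric(1)))
    out[paste0("Xvch.", m)] <- sum(vapply(cyc_m, function(s) .chi_term(dv[s]), numeric(1)))
  }
  out
}

# Kier covalent radii (Angstrom) by element and hybridisation; sp3 carbon is
# the alpha reference. Hybridisation: triple bond -> sp, double/aromatic ->
# sp2, else sp3.
.kier_radius <- function(element, hyb) {
  tab <- list(
    C  = c(sp3 = 0.77, sp2 = 0.67, sp = 0.60),
    N  = c(sp3 = 0.74, sp2 = 0.62, sp = 0.55),
    O  = c(sp3 = 0.74, sp2 = 0.62, sp = 0.62),
    F  = c(sp3 = 0.72, sp2 = 0.72, sp = 0.72),
    P  = c(sp3 = 1.10, sp2 = 1.00, sp = 1.00),
    S  = c(sp3 = 1.04, sp2 = 0.94, sp = 0.94),
    Cl = c(sp3 = 0.99, sp2 = 0.99, sp = 0.99),
    Br = c(sp3 = 1.14, sp2 = 1.14, sp = 1.14),
    I  = c(sp3 = 1.33, sp2 = 1.33, sp = 1.33))
  vapply(seq_along(element), function(i) tab[[element[i]]][[hyb[i]]], numeric(1))
}

.hybridisation <- function(g) {
  hyb <- rep("sp3", g$n)
  if (length(g$bond_order)) for (k in seq_along(g$bond_order)) {
    a <- g$edges[k, 1]; b <- g$edges[k, 2]
    if (g$bond_order[k] == 3L) { hyb[a] <- "sp"; hyb[b] <- "sp" }
    else if (g$bond_order[k] == 2L || g$bond_aromatic[k]) {
      if (hyb[a] == "sp3") hyb[a] <- "sp2"
      if (hyb[b] == "sp3") hyb[b] <- "sp2"
    }
  }
  hyb[g$aromatic & hyb == "sp3"] <- "sp2"
  hyb
}

#' Kier kappa shape indices
#'
#' First- to third-order kappa indices and their alpha-modified variants.
#' `kappa1 = A(A-1)^2/P1^2`, `kappa2 = (A-1)(A-2)^2/P2^2`, and `kappa3`
#' uses the parity-dependent form `(A-1)(A-3)^2/P3^2` (odd A) or
#' `(A-3)(A-2)^2/P3^2` (even A), where A is the heavy-atom count and Pm the
#' number of m-edge paths. Alpha variants replace A by A + alpha with
#' alpha = sum(r_i/r_Csp3 - 1) over covalent radii. Degenerate denominators
#' (molecules too small to have m-edge paths) yield NA, not an error.
#'
#' @param g a graph from [heavy_graph()].
#' @return named numeric vector `kappa1..kappa3`, `kappaA1..kappaA3`.
#' @export
kappa_indices <- function(g) {
  A <- g$n
  P <- vapply(1:3, function(m) .path_count(g, m), numeric(1))
  alpha <- sum(.kier_radius(g$element, .hybridisation(g)) / 0.77 - 1)
  kap <- function(Aeff, m) {
    if (P[m] == 0) return(NA_real_)
    switch(m,
      Aeff * (Aeff - 1)^2 / P[1]^2,
      (Aeff - 1) * (Aeff - 2)^2 / P[2]^2,
      if (A %% 2L == 1L) (Aeff - 1) * (Aeff - 3)^2 / P[3]^2
      else               (Aeff - 3) * (Aeff - 2)^2 / P[3]^2)
  }
  c(kappa1 = kap(A, 1), kappa2 = kap(A, 2), kappa3 = kap(A, 3),
    kappaA1 = kap(A + alpha, 1), kappaA2 = kap(A + alpha, 2),
    kappaA3 = kap(A + alpha, 3))
}
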