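# Structural diversity: D(A) = sum over ordered pairs i != j of diss(i, j),
# divided by N(N - 1) -- the mean pairwise dissimilarity of a compound set.
# The default dissimilarity is 1 - Tanimoto over hashed linear-path
# fingerprints; any user-supplied dissimilarity matrix is accepted.

# deterministic 32-bit-ish polynomial string hash into [0, nbits)
.hash_string <- function(s, nbits) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  (h %% nbits) + 1L
}

#' Hashed linear-path fingerprint
#'
#' Enumerates all simple linear paths of 1 to `max_len` bonds in the
#' hydrogen-suppressed graph; each path is encoded as the
#' direction-canonical string of its atom labels (element plus aromatic
#' flag) and bond symbols, hashed into a fixed bit space. Deterministic.
#'
#' @param mol a standardized `Molecule`.
#' @param nbits fingerprint length in bits.
#' @param max_len maximum path length in bonds.
#' @return sorted integer vector of set bit positions, class
#'   `path_fingerprint`.
#' @export
fingerprint <- function(mol, nbits = 2048L, max_len = 7L) {
  g <- heavy_graph(mol)
  atom_lab <- paste0(g$element, ifelse(g$aromatic, "a", ""))
  bmat <- matrix("", g$n, g$n)
  if (nrow(g$edges)) for (k in seq_len(nrow(g$edges))) {
    s <- if (g$bond_aromatic[k]) ":" else c("-", "=", "#")[g$bond_order[k]]
    bmat[g$edges[k, 1], g$edges[k, 2]] <- s
    bmat[g$edges[k, 2], g$edges[k, 1]] <- s
  }
  bits <- integer(0)
  emit <- function(path) {
    lab <- character(2L * length(path) - 1L)
    lab[seq(1, length(lab), 2)] <- atom_lab[path]
    if (length(path) > 1L)
      lab[seq(2, length(lab) - 1L, 2)] <-
        bmat[cbind(path[-length(path)], path[-1])]
    fwd <- paste(lab, collapse = "")
    rev_ <- paste(rev(lab), collapse = "")
    bits[length(bits) + 1L] <<- .hash_string(min(fwd, rev_), nbits)
  }
  walk <- function(path, inpath) {
    v <- path[length(path)]
    for (w in g$adj[[v]]) {
      if (inpath[w]) next
      np <- c(path, w)
      if (np[1] <= np[length(np)]) emit(np)
      if (length(np) <= max_len) {
        inpath[w] <- TRUE
        walk(np, inpath)
        inpath[w] <- FALSE
      }
    }
  }
  for (s in seq_len(g$n)) {
    inpath <- rep.int(FALSE, g$n); inpath[s] <- TRUE
    walk(s, inpath)
  }
  structure(sort(unique(bits)), class = "path_fingerprint", nbits = nbits)
}

#' Tanimoto dissimilarity between two fingerprints
#'
#' `1 - |a intersect b| / |a union b|`; two empty fingerprints give 0 by
#' convention.
#'
#' @param a,b fingerprints from [fingerprint()] (any integer sets work).
#' @return numeric in `[0, 1]`.
#' @export
dissimilarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

#' Pairwise dissimilarity matrix for a set of molecules
#'
#' @param mols list of standardized `Molecule` objects.
#' @param ... passed to [fingerprint()].
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = molecule ids.
#' @export
dissimilarity_matrix <- function(mols, ...) {
  fps <- lapply(mols, fingerprint, ...)
  n <- length(mols)
  M <- matrix(0, n, n,
              dimnames = rep(list(vapply(mols, function(m) m$id, character(1))), 2))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    M[i, j] <- M[j, i] <- dissimilarity(fps[[i]], fps[[j]])
  M
}

#' Structural diversity D(A) of a compound set
#'
#' Mean dissimilarity over all ordered pairs:
#' `D(A) = sum_{i != j} diss(i, j) / (N (N - 1))`. Higher values indicate a
#' structurally more diverse set (and hence a wider applicability domain for
#' models trained on it).
#'
#' @param x list of standardized `Molecule` objects, or a precomputed
#'   square dissimilarity matrix (entries in `[0, 1]`, zero diagonal).
#' @param ... passed to [dissimilarity_matrix()] when `x` is a molecule
#'   list.
#' @return numeric scalar in `[0, 1]`.
#' @export
diversity_score <- function(x, ...) {
  M <- if (is.matrix(x)) x else dissimilarity_matrix(x, ...)
  n <- nrow(M)
  if (n < 2L) stop("D(A) needs at least 2 compounds")
  if (!isSymmetric(unname(M)) || any(diag(M) != 0) || any(M < 0 | M > 1))
    stop("dissimilarity matrix must be symmetric with zero diagonal and entries in [0,1]")
  sum(M) / (n * (n - 1))
}
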