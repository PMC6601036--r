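#' @importFrom stats cmdscale median qbeta rnorm runif sd
#' @importFrom utils head read.csv write.csv
NULL

# Element tables for the supported organic subset.
# Zv: valence electrons; pqn: principal quantum number (E-state);
# mass: monoisotopic mass of the most abundant isotope; vdw: Bondi radius (A);
# rcov: single-bond covalent radius (A) used for kappa-alpha.
.ELEMENTS <- data.frame(
  symbol = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "H"),
  Zv     = c(4, 5, 6, 7, 5, 6, 7, 7, 7, 1),
  pqn    = c(2, 2, 2, 2, 3, 3, 3, 4, 5, 1),
  mass   = c(12.0, 14.003074, 15.994915, 18.998403, 30.973762,
             31.972071, 34.968853, 78.918338, 126.904473, 1.0078250319),
  vdw    = c(1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98, 1.20),
  rcov   = c(0.77, 0.74, 0.74, 0.72, 1.10, 1.04, 0.99, 1.14, 1.33, 0.37),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# default (lowest) standard valence used to infer implicit hydrogens
.STD_VALENCE <- c(C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1, Br = 1, I = 1)

.supported_element <- function(sym) sym %in% rownames(.ELEMENTS)

#' Construct a molecule
#'
#' A `Molecule` stores the hydrogen-suppressed connection table of a small
#' organic compound: heavy atoms (element, formal charge, attached-hydrogen
#' count, aromatic flag, optional 3D coordinates in Angstrom) and bonds
#' (atom-index pair, integer order 1-3, aromatic flag). Explicit hydrogens
#' supplied by input files are folded into their heavy neighbour's
#' `nH` count, so descriptor code always sees the heavy-atom graph.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `element`, `charge`, `nH`,
#'   `aromatic`, and optionally `x`, `y`, `z`.
#' @param bonds data.frame with columns `a1`, `a2`, `order`, `aromatic`.
#'   May have zero rows for single-atom molecules.
#' @param source provenance tag, e.g. `"smiles"` or `"sdf"`.
#' @return object of class `Molecule`.
#' @export
molecule <- function(id, atoms, bonds, source = "constructed") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) == 0L)
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = integer(), aromatic = logical())
  stopifnot(all(c("element", "charge", "nH", "aromatic") %in% names(atoms)))
  n <- nrow(atoms)
  if (nrow(bonds)) {
    lo <- pmin(bonds$a1, bonds$a2); hi <- pmax(bonds$a1, bonds$a2)
    if (any(lo < 1L | hi > n)) stop("bond endpoint out of range for molecule '", id, "'")
    if (any(lo == hi)) stop("self-bond in molecule '", id, "'")
    if (anyDuplicated(paste(lo, hi))) stop("duplicate bond in molecule '", id, "'")
    bonds$a1 <- lo; bonds$a2 <- hi
  }
  has_xyz <- all(c("x", "y", "z") %in% names(atoms)) && !anyNA(atoms[, c("x", "y", "z")])
  if (!has_xyz) atoms$x <- atoms$y <- atoms$z <- NA_real_
  m <- structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                      source = source), class = "Molecule")
  m
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule %s: %d heavy atoms, %d bonds, %s, %s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (has_coordinates(x)) "3D" else "2D/graph", x$source))
  invisible(x)
}

#' Does the molecule carry 3D coordinates?
#' @param mol a `Molecule`.
#' @return logical scalar.
#' @export
has_coordinates <- function(mol) !anyNA(mol$atoms[, c("x", "y", "z")])

#' Hydrogen-suppressed molecular graph
#'
#' Builds the simple graph view used by every topological descriptor:
#' vertices are heavy atoms; per-vertex simple degree `delta` (count of heavy
#' neighbours) and valence degree `deltav` computed with the Kier-Hall
#' convention `deltav = Zv - nH` (valence electrons minus attached
#' hydrogens).
#'
#' @param mol a standardized `Molecule`.
#' @return list with `n`, `edges` (2-column matrix), `adj` (adjacency list),
#'   `degree`, `deltav`, `element`, `aromatic` (atom flags), `nH`,
#'   `bond_order`, `bond_aromatic`.
#' @export
heavy_graph <- function(mol) {
  el <- mol$atoms$element
  bad <- el[!.supported_element(el) | el == "H"]
  if (length(bad))
    stop("unsupported element(s) in molecule '", mol$id, "': ",
         paste(unique(bad), collapse = ", "))
  n <- nrow(mol$atoms)
  edges <- as.matrix(mol$bonds[, c("a1", "a2"), drop = FALSE])
  storage.mode(edges) <- "integer"
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
      adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
    }
  }
  degree <- vapply(adj, length, integer(1))
  deltav <- .ELEMENTS[el, "Zv"] - mol$atoms$nH
  list(n = n, edges = edges, adj = adj, degree = degree, deltav = deltav,
       element = el, aromatic = mol$atoms$aromatic, nH = mol$atoms$nH,
       bond_order = mol$bonds$order, bond_aromatic = mol$bonds$aromatic)
}

# connected components of the heavy graph; returns integer membership vector
.components <- function(n, edges) {
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (length(edges) && nrow(edges))
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) comp[a] <- b
    }
  vapply(seq_len(n), find, integer(1))
}

# all-pairs shortest path matrix (BFS per vertex; graphs here are small)
.graph_distances <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n); dist[s] <- 0L; queue <- s; qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      for (w in g$adj[[v]]) if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
    }
    D[s, ] <- dist
  }
  D[D < 0] <- Inf
  D
}
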