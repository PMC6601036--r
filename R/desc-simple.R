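# Simple molecular properties (counts and sums readable off the connection
# table). Ring count is the cyclomatic number E - V + components; rotatable
# bonds are non-ring single bonds between two heavy atoms of degree >= 2;
# donors are N/O bearing at least one hydrogen, acceptors any N/O.

# is bond k a bridge (not part of any cycle)?
.bridges <- function(g) {
  ne <- nrow(g$edges)
  if (!ne) return(logical(0))
  base_comp <- length(unique(.components(g$n, g$edges)))
  vapply(seq_len(ne), function(k) {
    length(unique(.components(g$n, g$edges[-k, , drop = FALSE]))) > base_comp
  }, logical(1))
}

#' Simple molecular properties
#'
#' Monoisotopic molecular weight (hydrogens included), atom-class counts,
#' cyclomatic ring count, rotatable-bond count, and hydrogen-bond
#' donor/acceptor counts.
#'
#' @param mol a standardized `Molecule`.
#' @return named numeric vector of 14 properties.
#' @export
simple_properties <- function(mol) {
  g <- heavy_graph(mol)
  el <- g$element
  mw <- sum(.ELEMENTS[el, "mass"]) + sum(g$nH) * .ELEMENTS["H", "mass"]
  ncomp <- length(unique(.components(g$n, g$edges)))
  nrings <- nrow(g$edges) - g$n + ncomp
  bridge <- .bridges(g)
  rot <- 0L
  if (nrow(g$edges))
    rot <- sum(bridge & g$bond_order == 1L & !g$bond_aromatic &
               g$degree[g$edges[, 1]] >= 2L & g$degree[g$edges[, 2]] >= 2L)
  c(MW = mw,
    nHeavy = g$n,
    nHtot = sum(g$nH),
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nS = sum(el == "S"), nP = sum(el == "P"),
    nHal = sum(el %in% c("F", "Cl", "Br", "I")),
    nRings = nrings,
    nRotB = rot,
    nHBD = sum(el %in% c("N", "O") & g$nH >= 1L),
    nHBA = sum(el %in% c("N", "O")),
    nAromAtoms = sum(g$aromatic))
}
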