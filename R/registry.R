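# The descriptor registry: the fixed, versioned feature space. Column order
# of every downstream feature matrix is the registry order, so the order is
# part of the interface and must not change within a version.

.registry_v1 <- function() {
  simple <- c("MW", "nHeavy", "nHtot", "nC", "nN", "nO", "nS", "nP", "nHal",
              "nRings", "nRotB", "nHBD", "nHBA", "nAromAtoms")
  topo <- c("W", "Tcent", "Zagreb1", "Zagreb2")
  conn <- c(paste0("Xp.", 0:6), paste0("Xvp.", 0:6),
            paste0("Xc.", 3:6), paste0("Xvc.", 3:6),
            paste0("Xch.", 3:6), paste0("Xvch.", 3:6))
  shape <- c("kappa1", "kappa2", "kappa3", "kappaA1", "kappaA2", "kappaA3")
  estate <- c("SsumS", paste0("S", .ESTATE_TYPES))
  geom <- c("Rugty", "SASA", "Vmol", "RadG")
  reg <- data.frame(
    name = c(simple, topo, conn, shape, estate, geom),
    family = rep(c("simple", "topological", "connectivity", "shape",
                   "estate", "geometric"),
                 times = c(length(simple), length(topo), length(conn),
                           length(shape), length(estate), length(geom))),
    requires_3d = FALSE, stringsAsFactors = FALSE)
  reg$requires_3d[reg$family == "geometric"] <- TRUE
  note <- stats::setNames(rep("", nrow(reg)), reg$name)
  note["Rugty"]  <- "molecular folding (surface / equal-volume sphere surface)"
  note["Tcent"]  <- "Balaban pruning centric index"
  note["SaaCH"]  <- "aromatic :CH: E-state atom-type sum, a.k.a. S(27)"
  note["Xch.5"]  <- "simple connectivity chi for 5-atom chains (5chi_CH)"
  note["W"]      <- "Wiener index"
  reg$description <- unname(note)
  attr(reg, "version") <- 1L
  reg
}

#' Descriptor registry
#'
#' Returns the ordered, versioned table of descriptors computed by
#' [compute_all()]: name, family (`simple`, `topological`, `connectivity`,
#' `shape`, `estate`, `geometric`) and whether 3D coordinates are required.
#' The row order defines the feature-column order used everywhere
#' downstream. Version 1 carries 85 descriptors across the six families,
#' including the named descriptors `Rugty`, `Tcent`, `SaaCH` (the S(27)
#' aromatic-CH E-state sum) and `Xch.5` (the 5-ring chain connectivity
#' index).
#'
#' @param version registry version (only 1 is defined).
#' @return data.frame with columns `name`, `family`, `requires_3d`,
#'   `description` and attribute `version`.
#' @export
descriptor_registry <- function(version = 1L) {
  if (version != 1L) stop("unknown registry version: ", version)
  .registry_v1()
}

#' Compute the full descriptor vector for one molecule
#'
#' Fills every registry entry in registry order, masking (with `NA`) the
#' 3D-dependent entries when the molecule has no coordinates, and the shape
#' indices whose denominators vanish on too-small molecules. Deterministic
#' for a fixed input.
#'
#' @param mol a standardized `Molecule`.
#' @param registry a registry from [descriptor_registry()].
#' @return named numeric vector, one value per registry row (`NA` = masked).
#' @export
compute_all <- function(mol, registry = descriptor_registry()) {
  g <- tryCatch(heavy_graph(mol), error = function(e)
    stop("descriptor computation failed for molecule '", mol$id, "': ",
         conditionMessage(e)))
  vals <- c(simple_properties(mol),
            W = wiener_index(g), Tcent = centric_index(g),
            Zagreb1 = sum(g$degree^2),
            Zagreb2 = if (nrow(g$edges))
              sum(g$degree[g$edges[, 1]] * g$degree[g$edges[, 2]]) else 0,
            chi_indices(g), kappa_indices(g), estate_indices(g),
            .geometric_descriptors(mol))
  out <- vals[registry$name]
  names(out) <- registry$name
  if (any(!is.finite(out) & !is.na(out)))
    stop("non-finite descriptor value for molecule '", mol$id, "'")
  out
}

#' Compute a descriptor table for a set of molecules
#'
#' Applies [compute_all()] to each molecule; molecules whose descriptors
#' cannot be computed (e.g. unsupported elements) are dropped with a
#' diagnostic and reported in the `failures` attribute.
#'
#' @param mols list of standardized `Molecule` objects.
#' @param registry a registry from [descriptor_registry()].
#' @return data.frame: column `id` then one column per registry entry;
#'   attribute `failures` lists dropped molecules.
#' @export
compute_descriptors <- function(mols, registry = descriptor_registry()) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  rows <- list(); ids <- character(); fid <- character(); fwhy <- character()
  for (m in mols) {
    v <- tryCatch(compute_all(m, registry), error = function(e) e)
    if (inherits(v, "error")) {
      fid <- c(fid, m$id); fwhy <- c(fwhy, conditionMessage(v))
    } else { rows[[length(rows) + 1L]] <- v; ids <- c(ids, m$id) }
  }
  X <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0, nrow(registry))
  out <- data.frame(id = ids, X, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- c("id", registry$name)
  attr(out, "failures") <- data.frame(id = fid, reason = fwhy,
                                      stringsAsFactors = FALSE)
  if (length(fid))
    warning(length(fid), " molecule(s) dropped during descriptor computation: ",
            paste(fid, collapse = ", "))
  out
}

#' Write / read a descriptor table as CSV
#'
#' Header is `id` followed by registry names; masked values are empty cells.
#'
#' @param tab data.frame from [compute_descriptors()].
#' @param path CSV path.
#' @return `write_descriptor_table` returns the path invisibly;
#'   `read_descriptor_table` returns the data.frame.
#' @export
write_descriptor_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
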