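# Geometric descriptors (require 3D coordinates).
#
# Surface area is estimated Shrake-Rupley style on a deterministic Fibonacci
# point set over each solvent-expanded atom sphere; molecular volume by
# counting occupied cells of a regular grid. Rugosity ("Rugty", molecular
# folding) is the surface area divided by the area of the sphere whose
# volume equals the molecular volume -- exactly 1 for a single sphere, and
# growing as the shape departs from a ball.

# deterministic quasi-uniform points on the unit sphere (golden-angle spiral)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.solvent_surface_area <- function(xyz, radii, probe = 1.4, n_points = 256L) {
  r <- radii + probe
  pts <- .fibonacci_sphere(n_points)
  total <- 0
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep.int(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
      if (!any(exposed)) break
    }
    total <- total + 4 * pi * r[i]^2 * mean(exposed)
  }
  total
}

.grid_volume <- function(xyz, radii, probe = 1.4, spacing = 0.4) {
  r <- radii + probe
  lo <- apply(xyz, 2, min) - max(r); hi <- apply(xyz, 2, max) + max(r)
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  occ_xy <- matrix(FALSE, length(gx), length(gy))
  count <- 0
  # loop over z-slabs to bound memory on larger molecules
  for (z in gz) {
    occ <- occ_xy
    for (i in seq_len(nrow(xyz))) {
      dz2 <- (z - xyz[i, 3])^2
      if (dz2 > r[i]^2) next
      dx2 <- (gx - xyz[i, 1])^2
      dy2 <- (gy - xyz[i, 2])^2
      occ <- occ | (outer(dx2, dy2, "+") <= r[i]^2 - dz2)
    }
    count <- count + sum(occ)
  }
  count * spacing^3
}

#' Rugosity (molecular folding, Rugty)
#'
#' Dimensionless ratio of the numerically estimated solvent-expanded
#' molecular surface area to the surface area of the sphere of equal
#' molecular volume. 1 for a single sphere (up to discretisation); larger
#' for folded or elongated shapes.
#'
#' @param mol a `Molecule` with 3D coordinates, or a coordinate matrix.
#' @param radii atomic radii (Angstrom); defaults to Bondi van der Waals
#'   radii looked up per element when `mol` is a `Molecule`.
#' @param probe probe radius in Angstrom.
#' @param spacing volume-grid spacing in Angstrom.
#' @param n_points surface sample points per atom.
#' @return numeric scalar >= ~1, or `NA` if coordinates are missing.
#' @export
rugosity <- function(mol, radii = NULL, probe = 1.4, spacing = 0.4,
                     n_points = 256L) {
  if (inherits(mol, "Molecule")) {
    if (!has_coordinates(mol)) return(NA_real_)
    xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
    if (is.null(radii)) radii <- .ELEMENTS[mol$atoms$element, "vdw"]
  } else xyz <- as.matrix(mol)
  stopifnot(!is.null(radii), length(radii) == nrow(xyz))
  area <- .solvent_surface_area(xyz, radii, probe, n_points)
  vol <- .grid_volume(xyz, radii, probe, spacing)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  area / (4 * pi * r_eq^2)
}

# the four geometric registry entries
.geometric_descriptors <- function(mol, probe = 1.4, spacing = 0.4,
                                   n_points = 256L) {
  if (!has_coordinates(mol))
    return(c(Rugty = NA_real_, SASA = NA_real_, Vmol = NA_real_,
             RadG = NA_real_))
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  radii <- .ELEMENTS[mol$atoms$element, "vdw"]
  area <- .solvent_surface_area(xyz, radii, probe, n_points)
  vol <- .grid_volume(xyz, radii, probe, spacing)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  cen <- colMeans(xyz)
  radg <- sqrt(mean(rowSums(sweep(xyz, 2, cen)^2)))
  c(Rugty = area / (4 * pi * r_eq^2), SASA = area, Vmol = vol, RadG = radg)
}
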