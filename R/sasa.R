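# Shrake-Rupley solvent-accessible surface area.
#
# Each atom is inflated by the probe radius and covered with a deterministic
# quasi-uniform point set (golden-angle spiral); the accessible area is the
# fraction of points not buried inside any neighbouring inflated sphere,
# times the sphere area.

# van der Waals radii (Angstrom) by element symbol; unknown elements fall
# back to carbon.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

# Golden-angle spiral on the unit sphere: n quasi-uniform directions,
# deterministic in n.
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = rho * cos(theta), y = rho * sin(theta), z = z)
}

#' Shrake-Rupley accessible surface area per atom
#'
#' Computes the solvent-accessible surface area of every atom in a coordinate
#' set by the Shrake-Rupley rolling-probe point-sampling method.
#'
#' @param xyz numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param element character vector of element symbols, length n_atoms.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points number of test points per atomic sphere; more points give
#'   smaller sampling error at linear cost.
#' @return numeric vector of per-atom accessible areas in square Angstrom.
#' @export
shrake_rupley <- function(xyz, element, probe_radius = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(element), nrow(xyz) >= 1)
  radii <- vdw_radius(element) + probe_radius
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbour cutoff per pair: r_i + r_j
  for (i in seq_len(n)) {
    ri <- radii[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj <- rowSums(sweep(sp[accessible, , drop = FALSE], 2, xyz[j, ], "-")^2)
      accessible[accessible] <- dj >= radii[j]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(accessible) / n_points
  }
  area
}
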