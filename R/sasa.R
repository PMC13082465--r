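# Shrake-Rupley solvent-accessible surface area. Each atom is covered with a
# deterministic golden-spiral point set on its solvent-expanded sphere
# (radius r_vdw + probe); the accessible area is the exposed-point fraction
# times the sphere area. Neighbor pruning keeps the test set per atom small.

#' Deterministic golden-spiral points on the unit sphere
#'
#' @param n Number of points (>= 1).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param atoms Data frame with `x`, `y`, `z` and either a `radius` column
#'   (used verbatim, e.g. pocket pseudo-atoms) or `vdw_radius`/`element`
#'   columns. Rows with `is_heavy == FALSE` are dropped unless
#'   `include_hydrogens` is `TRUE`.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere test points per atom (>= 92; default 960).
#' @param include_hydrogens Keep hydrogen atoms.
#' @return A tibble with one row per atom: `atom` (row index into the kept
#'   set), `radius`, `sasa` (square Angstrom). Total SASA is `sum(sasa)`.
#' @export
#' @examples
#' a <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
#' sum(shrake_rupley(a)$sasa) # ~ 4*pi*(1.7+1.4)^2
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960,
                          include_hydrogens = FALSE) {
  stopifnot(n_points >= 92, probe >= 0)
  atoms <- as_tibble(atoms)
  if ("model" %in% names(atoms)) atoms <- atoms[atoms$model == atoms$model[1], ]
  if (!include_hydrogens && "is_heavy" %in% names(atoms)) {
    atoms <- atoms[atoms$is_heavy, ]
  }
  if (nrow(atoms) == 0) abort("no atoms for SASA computation")
  radii <- atom_radii(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  rs <- radii + probe

  # neighbor candidates: centers closer than the sum of expanded radii
  d2 <- cross_dist2(xyz, xyz)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * rs[i], 2, xyz[i, ], "+")
    nb <- which(d2[i, ] < (rs[i] + rs)^2)
    nb <- nb[nb != i]
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      pd2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      exposed <- exposed & (pd2 > rs[j]^2)
      if (!any(exposed)) break
    }
    sasa[i] <- mean(exposed) * 4 * pi * rs[i]^2
  }
  tibble(atom = seq_len(n), radius = radii, sasa = sasa)
}

# per-atom radius: explicit `radius` column wins (pocket pseudo-atoms carry
# their alpha-sphere radius), then tabulated vdw radius, then 1.7 A default
atom_radii <- function(atoms) {
  if ("radius" %in% names(atoms) && !all(is.na(atoms$radius))) {
    r <- atoms$radius
    if ("vdw_radius" %in% names(atoms)) r[is.na(r)] <- atoms$vdw_radius[is.na(r)]
    r[is.na(r)] <- 1.7
    return(r)
  }
  if ("vdw_radius" %in% names(atoms)) return(atoms$vdw_radius)
  if ("element" %in% names(atoms)) return(element_vdw_radius(atoms$element))
  rep(1.7, nrow(atoms))
}
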