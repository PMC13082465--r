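# Complex-level screening: interface definition, spatial extent and the
# structural retention criteria applied to candidate protein-RNA complexes.

#' Identify protein-RNA interface atoms
#'
#' Interface atoms are heavy atoms of one macromolecule within `cutoff`
#' Angstrom of any heavy atom of the other. Hydrogens are ignored by default
#' (crystal structures mostly lack them).
#'
#' @param model An `rpi_complex` with at least one protein and one RNA chain.
#' @param cutoff Heavy-atom contact distance in Angstrom.
#' @param include_hydrogens Include hydrogens in the contact search.
#' @return A list of class `rpi_interface` with elements `protein` and `rna`
#'   (atom tibbles) and `fractions`, a tibble with per-side interface atom
#'   counts, heavy-atom totals and interface fractions.
#' @export
interface_atoms <- function(model, cutoff = 5, include_hydrogens = FALSE) {
  m <- model[model$model == model$model[1], ]
  if (!include_hydrogens) m <- m[m$is_heavy, ]
  prot <- m[m$kind == "protein", ]
  rna <- m[m$kind == "rna", ]
  if (nrow(prot) == 0) abort("no protein chain in complex")
  if (nrow(rna) == 0) abort("no RNA chain in complex")

  d2 <- cross_dist2(as.matrix(prot[, c("x", "y", "z")]),
    as.matrix(rna[, c("x", "y", "z")]))
  in_p <- apply(d2, 1, min) <= cutoff^2
  in_r <- apply(d2, 2, min) <= cutoff^2

  fractions <- tibble(
    side = c("protein", "rna"),
    n_interface = c(sum(in_p), sum(in_r)),
    n_heavy = c(nrow(prot), nrow(rna)),
    fraction = c(sum(in_p) / nrow(prot), sum(in_r) / nrow(rna))
  )
  structure(
    list(protein = prot[in_p, ], rna = rna[in_r, ], fractions = fractions),
    class = "rpi_interface"
  )
}

#' @export
print.rpi_interface <- function(x, ...) {
  cat("<rpi_interface>\n")
  print(x$fractions)
  invisible(x)
}

# squared cross-distance matrix between two n x 3 coordinate matrices
cross_dist2 <- function(a, b) {
  sa <- rowSums(a^2)
  sb <- rowSums(b^2)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Maximum spatial extent of a complex
#'
#' Largest pairwise distance between heavy atoms, computed exactly over the
#' vertices of the 3-D convex hull (which must contain both endpoints of the
#' diameter); degenerate point sets fall back to the brute-force maximum.
#'
#' @param model An `rpi_complex` or data frame with `x`, `y`, `z` columns.
#' @param include_hydrogens Include hydrogens.
#' @return Maximum pairwise distance in Angstrom.
#' @export
max_extent <- function(model, include_hydrogens = FALSE) {
  m <- as_tibble(model)
  if ("model" %in% names(m)) m <- m[m$model == m$model[1], ]
  if (!include_hydrogens && "is_heavy" %in% names(m)) m <- m[m$is_heavy, ]
  pts <- as.matrix(m[, c("x", "y", "z")])
  if (nrow(pts) < 2) abort("max_extent needs at least 2 atoms")
  v <- tryCatch(pts[convex_hull_3d(pts)$vertices, , drop = FALSE],
    error = function(e) pts)
  sqrt(max(cross_dist2(v, v)))
}

#' Screening criteria for protein-RNA complexes
#'
#' Bundles the structural retention criteria: the RNA:protein heavy-atom
#' ratio window (0.1 to 20), the minimum interface atom count per side (25),
#' the minimum per-side interface fraction (reported range 2% to 5%; default
#' threshold 0.02, the permissive end, with the measured fractions reported
#' so stricter bounds can be applied), and the maximum spatial extent
#' (70 Angstrom). The interface contact cutoff defaults to the common 5
#' Angstrom heavy-atom convention.
#'
#' @param atom_ratio_range Length-2 numeric, inclusive RNA/protein atom ratio
#'   window.
#' @param min_interface_atoms Minimum interface atoms per side.
#' @param min_interface_fraction Minimum interface fraction per side.
#' @param max_extent Maximum pairwise heavy-atom distance, Angstrom.
#' @param contact_cutoff Interface contact distance, Angstrom.
#' @return A list of class `rpi_criteria`.
#' @export
screening_criteria <- function(atom_ratio_range = c(0.1, 20),
                               min_interface_atoms = 25,
                               min_interface_fraction = 0.02,
                               max_extent = 70,
                               contact_cutoff = 5) {
  stopifnot(length(atom_ratio_range) == 2,
    atom_ratio_range[1] < atom_ratio_range[2],
    all(c(atom_ratio_range, min_interface_atoms, min_interface_fraction,
      max_extent, contact_cutoff) > 0))
  structure(list(
    atom_ratio_range = atom_ratio_range,
    min_interface_atoms = min_interface_atoms,
    min_interface_fraction = min_interface_fraction,
    max_extent = max_extent,
    contact_cutoff = contact_cutoff
  ), class = "rpi_criteria")
}

#' Apply the complex-screening criteria
#'
#' Evaluates the four retention criteria (atom ratio, interface atoms per
#' side, interface fraction per side, spatial extent) on a complex and
#' reports each measured value against its bound.
#'
#' @param model An `rpi_complex`.
#' @param criteria An [screening_criteria()] object.
#' @return A tibble of class `rpi_verdict` with columns `criterion`, `value`,
#'   `bound` (printable bound description) and `pass`; the overall verdict is
#'   stored in attribute `passed` and available via `passed()`.
#' @export
screen_complex <- function(model, criteria = screening_criteria()) {
  m <- model[model$model == model$model[1] & model$is_heavy, ]
  n_prot <- sum(m$kind == "protein")
  n_rna <- sum(m$kind == "rna")
  ratio <- n_rna / n_prot
  iface <- interface_atoms(model, cutoff = criteria$contact_cutoff)
  fr <- iface$fractions
  extent <- max_extent(model)

  rng <- criteria$atom_ratio_range
  verdict <- tibble(
    criterion = c("atom_ratio", "interface_atoms_protein",
      "interface_atoms_rna", "interface_fraction_protein",
      "interface_fraction_rna", "max_extent"),
    value = c(ratio, fr$n_interface[1], fr$n_interface[2],
      fr$fraction[1], fr$fraction[2], extent),
    bound = c(sprintf("[%g, %g]", rng[1], rng[2]),
      sprintf(">= %g", criteria$min_interface_atoms),
      sprintf(">= %g", criteria$min_interface_atoms),
      sprintf(">= %g", criteria$min_interface_fraction),
      sprintf(">= %g", criteria$min_interface_fraction),
      sprintf("< %g", criteria$max_extent)),
    pass = c(ratio >= rng[1] & ratio <= rng[2],
      fr$n_interface[1] >= criteria$min_interface_atoms,
      fr$n_interface[2] >= criteria$min_interface_atoms,
      fr$fraction[1] >= criteria$min_interface_fraction,
      fr$fraction[2] >= criteria$min_interface_fraction,
      extent < criteria$max_extent)
  )
  structure(verdict, class = c("rpi_verdict", class(tibble())),
    passed = all(verdict$pass))
}

#' Overall pass/fail of a screening verdict
#' @param verdict An `rpi_verdict` from [screen_complex()].
#' @return Logical scalar; `TRUE` iff every criterion passed.
#' @export
passed <- function(verdict) isTRUE(attr(verdict, "passed"))
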