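# Buried-surface-area scoring: BSA of a pocket or ligand against each
# macromolecule, the second-rank BSA used for pocket and compound selection,
# pocket ranking/deduplication and docking-box construction.

#' Construct a pocket point-cloud model
#'
#' A pocket is a cloud of alpha-sphere centers or grid points, each carrying
#' a radius used when the pocket is treated as a set of pseudo-atoms for
#' SASA/BSA computation.
#'
#' @param points Data frame or matrix with `x`, `y`, `z` (and optionally
#'   `radius`) columns.
#' @param radius Default point radius when no per-point radius is given
#'   (1.7 Angstrom).
#' @param pocket_id,complex_id Identifiers.
#' @param algorithm Detection algorithm tag: `"fpocket"`, `"mdpocket"`,
#'   `"deeppocket"` or `"other"`.
#' @param drug_score,apolar_ratio Optional detector scores in `[0, 1]`.
#' @return A tibble of class `rpi_pocket` with columns `x`, `y`, `z`,
#'   `radius` and the metadata stored as attributes.
#' @export
pocket_model <- function(points, radius = 1.7, pocket_id = "pocket",
                         complex_id = "complex",
                         algorithm = c("other", "fpocket", "mdpocket", "deeppocket"),
                         drug_score = NA_real_, apolar_ratio = NA_real_) {
  algorithm <- match.arg(algorithm)
  pts <- as_tibble(as.data.frame(points))
  if (!all(c("x", "y", "z") %in% names(pts))) {
    names(pts)[1:3] <- c("x", "y", "z")
  }
  if (!"radius" %in% names(pts)) pts$radius <- radius
  stopifnot(all(pts$radius > 0))
  structure(pts[, c("x", "y", "z", "radius")],
    class = c("rpi_pocket", class(tibble())),
    pocket_id = pocket_id, complex_id = complex_id, algorithm = algorithm,
    drug_score = drug_score, apolar_ratio = apolar_ratio)
}

#' Read a pocket point cloud from a PQR or PDB-like file
#'
#' One pseudo-atom per point. For whitespace-separated PQR records the last
#' field is the point radius (per the PQR convention); for fixed-width PDB
#' records the occupancy column is used as the radius when positive.
#'
#' @param path File path.
#' @param ... Passed to [pocket_model()] (ids, algorithm, scores).
#' @return An `rpi_pocket`.
#' @export
read_pocket <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines)) abort("empty pocket file")
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (all(nf >= 10)) { # PQR: ... x y z charge radius
    pts <- tibble(
      x = map_dbl(fields, ~ as.numeric(.x[length(.x) - 4])),
      y = map_dbl(fields, ~ as.numeric(.x[length(.x) - 3])),
      z = map_dbl(fields, ~ as.numeric(.x[length(.x) - 2])),
      radius = map_dbl(fields, ~ as.numeric(.x[length(.x)]))
    )
    if (anyNA(pts) || any(pts$radius <= 0)) {
      pts <- NULL
    }
  } else {
    pts <- NULL
  }
  if (is.null(pts)) { # fixed-width PDB-like, radius from occupancy
    x <- as.numeric(substr(lines, 31, 38))
    y <- as.numeric(substr(lines, 39, 46))
    z <- as.numeric(substr(lines, 47, 54))
    occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
    pts <- tibble(x = x, y = y, z = z,
      radius = ifelse(is.na(occ) | occ <= 0, 1.7, occ))
  }
  pocket_model(pts, ...)
}

#' Buried surface area between two entities
#'
#' BSA(A, B) = SASA(A) + SASA(B) - SASA(A u B), with all three SASA values
#' computed by the same Shrake-Rupley settings. Pocket points act as
#' pseudo-atoms with their stored radii. Small negative values from
#' numerical noise (within `1e-6`) are clamped to zero.
#'
#' @param entity_a,entity_b Atom tables or `rpi_pocket`s.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom.
#' @param include_hydrogens Keep hydrogens.
#' @return One-row tibble: `sasa_entity_a`, `sasa_entity_b`, `sasa_joint`,
#'   `bsa` (square Angstrom).
#' @export
bsa <- function(entity_a, entity_b, probe = 1.4, n_points = 960,
                include_hydrogens = FALSE) {
  a <- sasa_ready(entity_a, include_hydrogens)
  b <- sasa_ready(entity_b, include_hydrogens)
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty entity in bsa()")
  sa <- sum(shrake_rupley(a, probe, n_points, TRUE)$sasa)
  sb <- sum(shrake_rupley(b, probe, n_points, TRUE)$sasa)
  sj <- sum(shrake_rupley(bind_rows(a, b), probe, n_points, TRUE)$sasa)
  v <- sa + sb - sj
  if (v < 0 && v > -1e-6) v <- 0
  tibble(sasa_entity_a = sa, sasa_entity_b = sb, sasa_joint = sj, bsa = v)
}

# reduce any entity to x/y/z/radius pseudo-atoms for joint SASA evaluation
sasa_ready <- function(entity, include_hydrogens = FALSE) {
  e <- as_tibble(entity)
  if ("model" %in% names(e)) e <- e[e$model == e$model[1], ]
  if (!include_hydrogens && "is_heavy" %in% names(e)) e <- e[e$is_heavy, ]
  tibble(x = e$x, y = e$y, z = e$z, radius = atom_radii(e))
}

#' Second-rank BSA of a pocket or ligand
#'
#' The smaller of the entity's BSA with the protein and with the RNA. High
#' values indicate balanced two-sided interface contact, the signature
#' sought in molecular-glue pockets.
#'
#' @param entity Pocket (`rpi_pocket`) or ligand atom table.
#' @param protein,rna Macromolecule atom tables.
#' @param ... Passed to [bsa()].
#' @return One-row tibble: `bsa_protein`, `bsa_rna`, `second_rank_bsa`,
#'   `side` (the minimizing macromolecule).
#' @export
second_rank_bsa <- function(entity, protein, rna, ...) {
  bp <- bsa(entity, protein, ...)$bsa
  br <- bsa(entity, rna, ...)$bsa
  tibble(bsa_protein = bp, bsa_rna = br,
    second_rank_bsa = min(bp, br),
    side = if (bp <= br) "protein" else "rna")
}

#' Rank pockets by second-rank BSA
#'
#' Drops pockets whose second-rank BSA falls below `min_bsa` and sorts the
#' remainder by second-rank BSA (descending), breaking ties by drug score
#' (descending) and then input order.
#'
#' @param pockets List of `rpi_pocket`s (optionally named).
#' @param protein,rna Macromolecule atom tables.
#' @param min_bsa Exclusion floor in square Angstrom (default 50, the
#'   histogram floor; 20 is the counting floor).
#' @param ... Passed to [bsa()].
#' @return A tibble of class `rpi_pocket_ranking`: `pocket_id`, `algorithm`,
#'   `drug_score`, `bsa_protein`, `bsa_rna`, `second_rank_bsa`, `rank`.
#' @export
rank_pockets <- function(pockets, protein, rna, min_bsa = 50, ...) {
  stopifnot(length(pockets) >= 1)
  rows <- imap(pockets, function(p, i) {
    id <- attr(p, "pocket_id")
    if (is.null(id) || identical(id, "pocket")) {
      id <- if (is.character(i)) i else paste0("pocket_", i)
    }
    sr <- second_rank_bsa(p, protein, rna, ...)
    mutate(sr, pocket_id = id,
      algorithm = attr(p, "algorithm") %||% "other",
      drug_score = attr(p, "drug_score") %||% NA_real_,
      .before = 1)
  })
  out <- bind_rows(rows) |>
    mutate(.order = dplyr::row_number()) |>
    filter(.data$second_rank_bsa >= min_bsa)
  if (nrow(out) == 0) {
    warn("all pockets excluded by the second-rank BSA floor")
  }
  out <- out |>
    arrange(desc(.data$second_rank_bsa),
      desc(ifelse(is.na(.data$drug_score), -Inf, .data$drug_score)),
      .data$.order) |>
    mutate(rank = dplyr::row_number()) |>
    select(-".order", -"side")
  structure(out, class = c("rpi_pocket_ranking", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is a candidate pocket novel relative to already-selected pockets?
#'
#' A candidate counts as already identified when at least `overlap_threshold`
#' of its points lie within `contact_dist` of any selected pocket's points.
#'
#' @param candidate An `rpi_pocket`.
#' @param selected List of `rpi_pocket`s already kept.
#' @param overlap_threshold Point-fraction threshold in `(0, 1]`.
#' @param contact_dist Point-to-point contact distance, Angstrom.
#' @return `TRUE` when the candidate is novel.
#' @export
dedup_pocket <- function(candidate, selected, overlap_threshold = 0.5,
                         contact_dist = 3) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  if (!length(selected)) return(TRUE)
  cpts <- as.matrix(as_tibble(candidate)[, c("x", "y", "z")])
  spts <- do.call(rbind, lapply(selected, function(s) {
    as.matrix(as_tibble(s)[, c("x", "y", "z")])
  }))
  d2 <- cross_dist2(cpts, spts)
  overlap <- mean(apply(d2, 1, min) <= contact_dist^2)
  overlap < overlap_threshold
}

#' Axis-aligned docking box around a pocket
#'
#' Bounding box of the pocket points expanded by `margin` on every face.
#'
#' @param pocket An `rpi_pocket` (or any x/y/z table).
#' @param margin Margin added on every face, Angstrom (default 5).
#' @return One-row tibble: `xmin`..`zmax`, `half_diagonal` (Angstrom).
#' @export
docking_box <- function(pocket, margin = 5) {
  p <- as_tibble(pocket)
  stopifnot(nrow(p) >= 1)
  lo <- c(min(p$x), min(p$y), min(p$z)) - margin
  hi <- c(max(p$x), max(p$y), max(p$z)) + margin
  tibble(xmin = lo[1], ymin = lo[2], zmin = lo[3],
    xmax = hi[1], ymax = hi[2], zmax = hi[3],
    half_diagonal = sqrt(sum((hi - lo)^2)) / 2)
}
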