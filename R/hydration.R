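# Pocket hydration descriptors: representative-frame selection from a
# trajectory, convex-hull water counting, density normalization against bulk
# water, and the translational order parameter of pocket waters.

#' Representative frame of a trajectory
#'
#' Aligns every frame to the first on a backbone selection, computes the
#' time-averaged structure of the aligned selection, and returns the index
#' of the frame with the minimum RMSD to that mean structure. Ties go to the
#' earliest frame.
#'
#' @param traj Multi-model `rpi_complex` (frames in the `model` column).
#' @param selection Logical or integer index into the atoms of one frame;
#'   default: macromolecule backbone atoms (protein N, CA, C, O; RNA P,
#'   O5', C5', C4', C3', O3').
#' @return Integer frame index (1-based into the sorted model numbers), with
#'   the per-frame RMSD-to-mean in attribute `rmsd_to_mean`.
#' @export
representative_frame <- function(traj, selection = NULL) {
  frames <- traj_frames(traj)
  nf <- length(frames)
  if (nf < 2) abort("representative_frame needs >= 2 frames")
  first <- frames[[1]]
  if (is.null(selection)) selection <- which(first$is_backbone & first$is_heavy)
  if (is.logical(selection)) selection <- which(selection)
  if (!length(selection)) abort("empty alignment selection")

  ref <- coords_matrix(first[selection, ])
  aligned <- lapply(frames, function(fr) {
    p <- coords_matrix(fr[selection, ])
    apply_alignment(p, kabsch(p, ref))
  })
  mean_structure <- Reduce(`+`, aligned) / nf
  rmsds <- map_dbl(aligned, function(a) {
    sqrt(mean(rowSums((a - mean_structure)^2)))
  })
  structure(which.min(rmsds), rmsd_to_mean = rmsds)
}

# split a multi-model complex into per-frame tibbles with a consistent
# atom order
traj_frames <- function(traj) {
  t <- as_tibble(traj)
  models <- sort(unique(t$model))
  lapply(models, function(m) {
    fr <- t[t$model == m, ]
    fr[order(fr$serial), ]
  })
}

#' Count waters enclosed by a pocket's convex hull
#'
#' @param waters Coordinates of water oxygen atoms (matrix or x/y/z table).
#' @param pocket An `rpi_pocket` (>= 4 non-coplanar points).
#' @return One-row tibble: `count`, `hull_volume` (cubic Angstrom). Points on
#'   hull facets count as inside.
#' @export
waters_in_hull <- function(waters, pocket) {
  hull <- tryCatch(
    convex_hull_3d(as_tibble(pocket)[, c("x", "y", "z")]),
    error = function(e) abort("coplanar pocket: cannot form a 3-D hull")
  )
  w <- coords_matrix(waters)
  count <- if (nrow(w)) sum(in_hull(hull, w)) else 0L
  tibble(count = as.integer(count), hull_volume = hull$volume)
}

#' Absolute and relative pocket water density
#'
#' Relative density normalizes by the density of bulk water at standard
#' conditions (0.0334 oxygens per cubic Angstrom).
#'
#' @param count Number of enclosed waters.
#' @param volume Hull volume in cubic Angstrom (> 0).
#' @return One-row tibble: `absolute` (per cubic Angstrom), `relative`
#'   (unitless).
#' @export
water_density <- function(count, volume) {
  if (any(volume <= 0)) abort("water_density: volume must be positive")
  tibble(absolute = count / volume,
    relative = count / volume / BULK_WATER_DENSITY)
}

#' Translational order parameter of a water site
#'
#' `Sk = 1 - (1 / (12 * rbar^2)) * sum_i (r_i - rbar)^2` over the distances
#' `r_1..r_4` from a central water oxygen to its four neighboring water
#' oxygens, with `rbar` their mean. `Sk = 1` for a perfectly uniform shell
#' and decreases with the spread of the neighbor distances.
#'
#' @param neighbor_distances Numeric vector of exactly 4 positive distances.
#' @return `Sk` (unitless, `<= 1`).
#' @export
#' @examples
#' translational_order(c(3, 3, 3, 3)) # 1
#' translational_order(c(2, 2, 4, 4)) # 0.962963
translational_order <- function(neighbor_distances) {
  r <- as.numeric(neighbor_distances)
  if (length(r) != 4 || any(!is.finite(r)) || any(r <= 0)) {
    abort("translational_order needs exactly 4 positive distances")
  }
  rbar <- mean(r)
  1 - sum((r - rbar)^2) / (12 * rbar^2)
}

#' Hydration profile of a pocket over a trajectory
#'
#' Selects `n_frames` equidistant frames (first and last included), and per
#' frame counts the waters inside the pocket's convex hull, converts the
#' count to absolute/relative densities, and evaluates the translational
#' order parameter for every enclosed water with at least four enclosed
#' neighbors. Per-frame values and pooled summary statistics are returned;
#' the summaries feed the druggability feature vector.
#'
#' @param traj Multi-model `rpi_complex` containing water molecules.
#' @param pocket An `rpi_pocket`.
#' @param n_frames Number of equidistant frames to evaluate (default 10).
#' @param water_resnames Residue names treated as water.
#' @return A list of class `rpi_hydration`: `per_frame` tibble (`frame`,
#'   `count`, `hull_volume`, `abs_density`, `rel_density`, `mean_sk`,
#'   `n_sk`), `sk` tibble of pooled per-water values (`frame`, `sk`), and
#'   `summary` tibble (`metric`, `mean`, `min`, `max`, `sd`).
#' @export
hydration_profile <- function(traj, pocket, n_frames = 10,
                              water_resnames = .water_residues) {
  frames <- traj_frames(traj)
  nf <- length(frames)
  if (n_frames > nf) abort("n_frames exceeds trajectory length")
  idx <- equidistant_frames(nf, n_frames)

  hull <- tryCatch(
    convex_hull_3d(as_tibble(pocket)[, c("x", "y", "z")]),
    error = function(e) abort("coplanar pocket: cannot form a 3-D hull")
  )

  per_frame <- list()
  sk_rows <- list()
  for (k in seq_along(idx)) {
    fr <- frames[[idx[k]]]
    wox <- fr[fr$resname %in% water_resnames &
      toupper(fr$element) == "O", ]
    w <- coords_matrix(wox)
    keep <- if (nrow(w)) in_hull(hull, w) else logical(0)
    inw <- w[keep, , drop = FALSE]
    count <- nrow(inw)
    dens <- water_density(count, hull$volume)
    sk <- frame_sk(inw)
    per_frame[[k]] <- tibble(frame = idx[k], count = count,
      hull_volume = hull$volume, abs_density = dens$absolute,
      rel_density = dens$relative,
      mean_sk = if (length(sk)) mean(sk) else NA_real_,
      n_sk = length(sk))
    if (length(sk)) sk_rows[[k]] <- tibble(frame = idx[k], sk = sk)
  }
  per_frame <- bind_rows(per_frame)
  sk_tbl <- if (length(sk_rows)) bind_rows(sk_rows) else tibble(frame = integer(), sk = numeric())

  summarise_metric <- function(v, name) {
    v <- v[is.finite(v)]
    if (!length(v)) return(tibble(metric = name, mean = NA_real_,
      min = NA_real_, max = NA_real_, sd = NA_real_))
    tibble(metric = name, mean = mean(v), min = min(v), max = max(v),
      sd = if (length(v) > 1) sd(v) else 0)
  }
  summary <- bind_rows(
    summarise_metric(per_frame$count, "count"),
    summarise_metric(per_frame$abs_density, "abs_density"),
    summarise_metric(per_frame$rel_density, "rel_density"),
    summarise_metric(per_frame$mean_sk, "frame_mean_sk"),
    summarise_metric(sk_tbl$sk, "sk")
  )
  structure(list(per_frame = per_frame, sk = sk_tbl, summary = summary),
    class = "rpi_hydration")
}

#' @export
print.rpi_hydration <- function(x, ...) {
  cat("<rpi_hydration> ", nrow(x$per_frame), " frames\n", sep = "")
  print(x$summary)
  invisible(x)
}

# Sk for every enclosed water with >= 4 enclosed neighbors; waters with
# fewer neighbors are skipped (flagged by their absence)
frame_sk <- function(inw) {
  n <- nrow(inw)
  if (n < 5) return(numeric(0))
  d2 <- cross_dist2(inw, inw)
  diag(d2) <- Inf
  apply(d2, 1, function(row) {
    r <- sqrt(sort(row)[1:4])
    translational_order(r)
  })
}

# 1-based equidistant indices, first and last included
equidistant_frames <- function(n_total, n_sel) {
  if (n_sel == 1) return(1L)
  unique(as.integer(round((seq_len(n_sel) - 1) * (n_total - 1) / (n_sel - 1))) + 1L)
}
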