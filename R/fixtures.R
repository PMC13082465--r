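# Seeded synthetic fixtures: toy protein-RNA complexes with a plantable
# contact patch, jittered trajectories with pocket waters, docking/BSA/
# energy tables with planted stabilizer fractions, pocket manifests, and
# ligand placement pairs with known ground truth. Geometry uses idealized
# templates (helix rise/twist, strand spacing) chosen for plausibility, not
# physical accuracy: fixtures exercise code paths, not chemistry. All
# randomness flows from one seed via independent per-table streams.

# derive an independent, reproducible sub-seed per named stream
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483587)
}

rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s <- sin(angle); t <- 1 - c1
  matrix(c(
    t * a[1]^2 + c1, t * a[1] * a[2] - s * a[3], t * a[1] * a[3] + s * a[2],
    t * a[1] * a[2] + s * a[3], t * a[2]^2 + c1, t * a[2] * a[3] - s * a[1],
    t * a[1] * a[3] - s * a[2], t * a[2] * a[3] + s * a[1], t * a[3]^2 + c1
  ), 3, 3, byrow = TRUE)
}

#' Generate a synthetic protein-RNA complex
#'
#' Builds an idealized protein alpha-helix (chain A) and a parallel RNA
#' strand (chain B), then slides the RNA toward the protein until the
#' 5-Angstrom interface holds at least `interface_patch_size` heavy atoms on
#' each side (`interface_patch_size = 0` keeps the chains far apart so
#' screening fails on the interface criterion). Optionally plants a small
#' organic ligand (chain L) at the interface midpoint. Deterministic per
#' seed; repeated calls give byte-identical PDB output.
#'
#' @param seed Integer seed.
#' @param n_protein_residues,n_rna_residues Chain lengths.
#' @param interface_patch_size Minimum interface atoms per side at 5 A.
#' @param ligand Add an 8-atom interface ligand.
#' @param jitter_sigma Seeded coordinate jitter applied to the idealized
#'   template (Angstrom); distinguishes seeds and avoids exact geometric
#'   degeneracies.
#' @param source_id Identifier for the complex.
#' @return An `rpi_complex`.
#' @export
make_complex <- function(seed = 1, n_protein_residues = 30,
                         n_rna_residues = 10, interface_patch_size = 30,
                         ligand = FALSE, jitter_sigma = 0.02,
                         source_id = "fixture") {
  withr::with_seed(stream_seed(seed, "complex"), {
    prot <- helix_chain(n_protein_residues)
    rna <- strand_chain(n_rna_residues)
    if (interface_patch_size > min(nrow(prot), nrow(rna))) {
      abort("infeasible interface patch size for these chain lengths")
    }
    # slide the RNA along -y toward the helix until the patch holds
    gap <- if (interface_patch_size == 0) 30 else 8
    repeat {
      rna_shift <- rna
      rna_shift$y <- rna$y + gap
      atoms <- bind_rows(prot, rna_shift)
      cx <- as_complex(atoms, source_id = source_id)
      if (interface_patch_size == 0) break
      fr <- interface_atoms(cx, cutoff = 5)$fractions
      if (all(fr$n_interface >= interface_patch_size)) break
      gap <- gap - 0.25
      if (gap < 2) abort("infeasible interface patch size")
    }
    if (ligand) {
      center <- c(mean(range(prot$x)), gap / 2 + 1.5, mean(prot$z) + 0.5)
      lig <- ligand_blob(center)
      cx <- as_complex(bind_rows(as_tibble(cx)[, names(lig)], lig),
        source_id = source_id)
    }
    if (jitter_sigma > 0) {
      cx$x <- round(cx$x + rnorm(nrow(cx), 0, jitter_sigma), 3)
      cx$y <- round(cx$y + rnorm(nrow(cx), 0, jitter_sigma), 3)
      cx$z <- round(cx$z + rnorm(nrow(cx), 0, jitter_sigma), 3)
    }
    cx$serial <- seq_len(nrow(cx))
    cx
  })
}

helix_chain <- function(n_res) {
  # idealized alpha helix: 1.5 A rise, 100 deg twist, 2.3 A CA radius
  res <- seq_len(n_res)
  ang <- (res - 1) * 100 * pi / 180
  ca <- cbind(1.5 * (res - 1), 2.3 * cos(ang), 2.3 * sin(ang))
  per_res <- tibble(
    name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    dx = c(-0.8, 0, 0.9, 1.1, -0.3),
    dr = c(-0.4, 0, -0.3, 0.5, 1.3)
  )
  bind_rows(lapply(res, function(i) {
    u <- c(cos(ang[i]), sin(ang[i]))
    tibble(
      name = per_res$name, element = per_res$element,
      resname = "ALA", chain = "A", resno = i,
      x = ca[i, 1] + per_res$dx,
      y = ca[i, 2] + per_res$dr * u[1],
      z = ca[i, 3] + per_res$dr * u[2],
      record = "ATOM"
    )
  }))
}

strand_chain <- function(n_res) {
  # extended RNA strand: 4.5 A rise per nucleotide along x, bases toward -y
  res <- seq_len(n_res)
  per_res <- tibble(
    name = c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'", "N1", "C2"),
    element = c("P", "O", "C", "C", "C", "O", "C", "N", "C"),
    dx = c(0, 0.7, 1.5, 2.3, 3.0, 3.7, 2.6, 2.4, 2.0),
    dy = c(1.8, 1.2, 1.4, 0.8, 1.5, 1.0, -0.4, -1.7, -2.6),
    dz = c(0.3, -0.4, 0.5, -0.2, 0.6, -0.5, 0.1, 0.3, -0.2)
  )
  bind_rows(lapply(res, function(i) {
    tibble(
      name = per_res$name, element = per_res$element,
      resname = c("A", "U", "G", "C")[(i - 1) %% 4 + 1],
      chain = "B", resno = i,
      x = 4.5 * (i - 1) + per_res$dx,
      y = per_res$dy, z = per_res$dz,
      record = "ATOM"
    )
  }))
}

ligand_blob <- function(center) {
  offs <- matrix(c(
    0, 0, 0, 1.4, 0, 0, 2.1, 1.2, 0, 1.4, 2.4, 0,
    0, 2.4, 0, -0.7, 1.2, 0, 2.8, -1.0, 0.4, -2.1, 1.2, -0.4
  ), ncol = 3, byrow = TRUE)
  tibble(
    name = paste0(c("C1", "C2", "C3", "C4", "C5", "C6", "O1", "N1")),
    element = c("C", "C", "C", "C", "C", "C", "O", "N"),
    resname = "LIG", chain = "L", resno = 1L,
    x = center[1] + offs[, 1], y = center[2] + offs[, 2],
    z = center[3] + offs[, 3],
    record = "HETATM"
  )
}

#' Generate a jittered trajectory with pocket waters
#'
#' Frames are the input complex plus per-frame Gaussian coordinate jitter;
#' when a pocket is supplied, waters (oxygens only) are placed uniformly
#' inside its convex hull, resampled each frame. The water count is fixed
#' across frames either explicitly (`n_waters`) or from a target density
#' (`water_density`, oxygens per cubic Angstrom, e.g. 0.0334 for bulk).
#'
#' @param model An `rpi_complex` (single model).
#' @param n_frames Number of frames.
#' @param jitter_sigma Coordinate jitter standard deviation, Angstrom.
#' @param pocket Optional `rpi_pocket` hosting the waters.
#' @param n_waters Waters per frame (ignored when `water_density` given).
#' @param water_density Optional target density inside the pocket hull.
#' @param seed Integer seed.
#' @return A multi-model `rpi_complex`.
#' @export
make_trajectory <- function(model, n_frames = 10, jitter_sigma = 0.1,
                            pocket = NULL, n_waters = 30,
                            water_density = NULL, seed = 1) {
  base <- as_tibble(model)
  base <- base[base$model == base$model[1], ]
  hull <- NULL
  if (!is.null(pocket)) {
    hull <- convex_hull_3d(as_tibble(pocket)[, c("x", "y", "z")])
    if (!is.null(water_density)) {
      n_waters <- max(1L, as.integer(round(water_density * hull$volume)))
    }
  }
  withr::with_seed(stream_seed(seed, "trajectory"), {
    frames <- lapply(seq_len(n_frames), function(f) {
      fr <- base
      if (jitter_sigma > 0) {
        fr$x <- fr$x + rnorm(nrow(fr), 0, jitter_sigma)
        fr$y <- fr$y + rnorm(nrow(fr), 0, jitter_sigma)
        fr$z <- fr$z + rnorm(nrow(fr), 0, jitter_sigma)
      }
      if (!is.null(hull) && n_waters > 0) {
        w <- sample_in_hull(hull, n_waters)
        wat <- tibble(
          serial = max(fr$serial) + seq_len(n_waters),
          name = "O", element = "O", resname = "HOH", chain = "W",
          resno = seq_len(n_waters), x = w[, 1], y = w[, 2], z = w[, 3],
          record = "HETATM"
        )
        fr <- bind_rows(fr[, names(wat)], wat)
      }
      fr$model <- f
      fr
    })
  })
  as_complex(bind_rows(frames), source_id = attr(model, "source_id") %||% "traj")
}

# uniform points inside a convex hull by rejection from the bounding box
sample_in_hull <- function(hull, n) {
  lo <- apply(hull$points, 2, min)
  hi <- apply(hull$points, 2, max)
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    cand <- cbind(runif(4 * n, lo[1], hi[1]), runif(4 * n, lo[2], hi[2]),
      runif(4 * n, lo[3], hi[3]))
    out <- rbind(out, cand[in_hull(hull, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a pocket-detection manifest
#'
#' One pocket per complex per detector, minus `n_failures` planted detector
#' failures (87 complexes x 3 detectors with one failure gives the
#' 260-pocket manifest).
#'
#' @param n_complexes Number of complexes.
#' @param detectors Detector names.
#' @param n_failures Planted detection failures.
#' @param seed Integer seed choosing which detections fail.
#' @return Tibble: `complex_id`, `detector`, `pocket_id`.
#' @export
make_pocket_manifest <- function(n_complexes = 87,
                                 detectors = c("fpocket", "mdpocket", "deeppocket"),
                                 n_failures = 1, seed = 1) {
  m <- tidyr::expand_grid(
    complex_id = sprintf("cx%03d", seq_len(n_complexes)),
    detector = detectors
  )
  withr::with_seed(stream_seed(seed, "manifest"), {
    drop <- sample(nrow(m), n_failures)
  })
  m <- m[setdiff(seq_len(nrow(m)), drop), ]
  mutate(m, pocket_id = paste(.data$complex_id, .data$detector, sep = "_"))
}

#' Generate docking, BSA and energy tables with planted stabilizers
#'
#' Per pocket, `n_compounds` Gaussian docking scores and right-skewed
#' (log-normal) ligand BSA pairs are drawn. The two-stage funnel is then
#' applied, and MMGB/SA energies are planted for the stage-2 survivors so
#' that exactly `round(f * n)` of them satisfy the basic / elevated
#' stabilizer definitions (exclusive classes); ground-truth labels are
#' emitted alongside.
#'
#' @param manifest Pocket manifest (tibble with `pocket_id`) or `NULL` to
#'   build one from `n_pockets`.
#' @param n_pockets Used when `manifest` is `NULL`.
#' @param n_compounds Docking records per pocket.
#' @param score_mean,score_sd Docking-score distribution (kcal/mol).
#' @param planted_fractions Named fractions `c(basic =, elevated =)` among
#'   the stage-2 survivors.
#' @param top1,top2 Funnel sizes.
#' @param seed Integer seed.
#' @return A list of tibbles: `docking` (`pocket_id`, `compound_id`,
#'   `docking_score`), `bsa` (adds `bsa_protein`, `bsa_rna`,
#'   `second_rank_bsa`), `energies` (stage-2 survivors with `ddg_protein`,
#'   `ddg_rna`, `true_class`), plus `stage1` and `stage2` record sets.
#' @export
make_screen_tables <- function(manifest = NULL, n_pockets = 260,
                               n_compounds = 200, score_mean = -7,
                               score_sd = 1.5,
                               planted_fractions = c(basic = 0.17, elevated = 0.07),
                               top1 = 100, top2 = 5, seed = 1) {
  if (is.null(manifest)) {
    manifest <- tibble(pocket_id = sprintf("pocket_%04d", seq_len(n_pockets)))
  }
  pockets <- unique(manifest$pocket_id)
  withr::with_seed(stream_seed(seed, "docking"), {
    docking <- tidyr::expand_grid(
      pocket_id = pockets,
      compound_id = sprintf("cmpd_%05d", seq_len(n_compounds))
    )
    docking$docking_score <- rnorm(nrow(docking), score_mean, score_sd)
  })
  withr::with_seed(stream_seed(seed, "bsa"), {
    bsa_tbl <- docking
    bsa_tbl$bsa_protein <- stats::rlnorm(nrow(bsa_tbl), log(80), 0.6)
    bsa_tbl$bsa_rna <- stats::rlnorm(nrow(bsa_tbl), log(80), 0.6)
    bsa_tbl$second_rank_bsa <- pmin(bsa_tbl$bsa_protein, bsa_tbl$bsa_rna)
    bsa_tbl$docking_score <- NULL
  })
  stage1 <- suppressWarnings(funnel_stage1(docking, top_n = top1))
  stage2 <- funnel_stage2(
    inner_join(stage1, bsa_tbl, by = c("pocket_id", "compound_id")),
    top_n = top2)

  n <- nrow(stage2)
  n_basic <- round(planted_fractions[["basic"]] * n)
  n_elev <- round(planted_fractions[["elevated"]] * n)
  withr::with_seed(stream_seed(seed, "energies"), {
    cls <- sample(c(rep("basic", n_basic), rep("elevated", n_elev),
      rep("regular", n - n_basic - n_elev)))
    ddg_p <- ddg_r <- numeric(n)
    b <- cls == "basic"; e <- cls == "elevated"; r <- cls == "regular"
    # basic: both in (-9.9, -7.1) -> below -7 on both sides, not both < -10
    ddg_p[b] <- runif(sum(b), -9.9, -7.1)
    ddg_r[b] <- runif(sum(b), -9.9, -7.1)
    # elevated: both clearly below -10
    ddg_p[e] <- runif(sum(e), -16, -10.2)
    ddg_r[e] <- runif(sum(e), -16, -10.2)
    # regular: protein side above -7 keeps both-below conditions false
    ddg_p[r] <- runif(sum(r), -6.8, -2)
    ddg_r[r] <- runif(sum(r), -12, -2)
  })
  energies <- stage2 |>
    select("pocket_id", "compound_id") |>
    mutate(ddg_protein = ddg_p, ddg_rna = ddg_r, true_class = cls)

  list(docking = docking, bsa = bsa_tbl, stage1 = stage1, stage2 = stage2,
    energies = energies)
}

#' Generate a reference/mobile placement pair with known ground truth
#'
#' The mobile complex is the reference with its ligand displaced (and
#' optionally rotated about its center of mass), then optionally subjected
#' to a global rigid motion of the whole complex and Gaussian coordinate
#' noise. With zero noise the ground-truth center-of-mass displacement
#' equals `|displacement|` regardless of the global motion.
#'
#' @param model An `rpi_complex` containing a ligand (see
#'   [make_complex()]'s `ligand` argument).
#' @param displacement Length-3 ligand displacement, Angstrom.
#' @param rotation_angle,rotation_axis Ligand rotation about its COM.
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @param global_motion Apply a seeded random rigid motion to the whole
#'   mobile complex.
#' @param seed Integer seed.
#' @return A list with `reference` and `mobile` (`rpi_complex`es).
#' @export
make_placement_pair <- function(model, displacement = c(0, 0, 0),
                                rotation_angle = 0, rotation_axis = c(0, 0, 1),
                                noise_sigma = 0, global_motion = FALSE,
                                seed = 1) {
  ref <- as_tibble(model)
  ref <- ref[ref$model == ref$model[1], ]
  if (!any(ref$kind == "ligand")) abort("model contains no ligand")
  mob <- ref
  is_lig <- mob$kind == "ligand"
  lig_xyz <- as.matrix(mob[is_lig, c("x", "y", "z")])
  if (rotation_angle != 0) {
    com <- colMeans(lig_xyz)
    lig_xyz <- sweep(sweep(lig_xyz, 2, com) %*%
      t(rot_axis_angle(rotation_axis, rotation_angle)), 2, com, "+")
  }
  lig_xyz <- sweep(lig_xyz, 2, displacement, "+")
  mob$x[is_lig] <- lig_xyz[, 1]
  mob$y[is_lig] <- lig_xyz[, 2]
  mob$z[is_lig] <- lig_xyz[, 3]
  withr::with_seed(stream_seed(seed, "placement"), {
    if (isTRUE(global_motion)) {
      rot <- rot_axis_angle(runif(3, -1, 1), runif(1, 0, 2 * pi))
      trans <- runif(3, -10, 10)
      xyz <- sweep(as.matrix(mob[, c("x", "y", "z")]) %*% t(rot), 2, trans, "+")
      mob$x <- xyz[, 1]; mob$y <- xyz[, 2]; mob$z <- xyz[, 3]
    }
    if (noise_sigma > 0) {
      mob$x <- mob$x + rnorm(nrow(mob), 0, noise_sigma)
      mob$y <- mob$y + rnorm(nrow(mob), 0, noise_sigma)
      mob$z <- mob$z + rnorm(nrow(mob), 0, noise_sigma)
    }
  })
  list(
    reference = as_complex(ref, source_id = "reference"),
    mobile = as_complex(mob, source_id = "mobile")
  )
}
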