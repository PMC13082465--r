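# Geometric congruence between ligand placements from different prediction
# sources: the center-of-mass displacement after macromolecule-backbone
# alignment, ligand RMSD after pocket / interface alignment, the per-frame
# trajectory minimum, and acceptance gating on alignment quality.

complex_ligand <- function(cx) {
  l <- cx[cx$kind == "ligand" & cx$is_heavy & cx$model == cx$model[1], ]
  if (nrow(l) == 0) abort("complex contains no ligand")
  l
}

complex_backbone <- function(cx) {
  cx[cx$kind %in% c("protein", "rna") & cx$is_backbone & cx$is_heavy &
    cx$model == cx$model[1], ]
}

# one-to-one correspondence of backbone atoms by (kind, chain, resno, name);
# when chain labels differ between sources the chain is dropped from the key
match_atoms <- function(mobile, reference, use_chain = TRUE) {
  key <- if (use_chain) c("kind", "chain", "resno", "name") else
    c("kind", "resno", "name")
  m <- mobile |> mutate(.mi = dplyr::row_number())
  r <- reference |> mutate(.ri = dplyr::row_number())
  j <- inner_join(m[, c(key, ".mi")], r[, c(key, ".ri")], by = key,
    relationship = "one-to-one")
  if (nrow(j) < 3 && use_chain) {
    return(match_atoms(mobile, reference, use_chain = FALSE))
  }
  if (nrow(j) < 3) {
    un <- reference |>
      anti_join(m[, key], by = key) |>
      distinct(.data$chain, .data$resno)
    abort(paste0("backbone correspondence failure; unmatched residues: ",
      paste(paste0(un$chain, un$resno), collapse = " ")))
  }
  list(mobile = mobile[j$.mi, ], reference = reference[j$.ri, ])
}

ligand_com <- function(atoms) {
  w <- atoms$mass / sum(atoms$mass)
  c(sum(atoms$x * w), sum(atoms$y * w), sum(atoms$z * w))
}

#' Center-of-mass ligand displacement after backbone alignment
#'
#' Aligns the mobile complex onto the reference by least-squares
#' superposition of the matched macromolecule backbone atoms, transforms
#' the mobile ligand accordingly, and reports the Euclidean distance
#' between the two ligands' mass-weighted centers of mass. A COM measure is
#' used because the ligand atom sets may differ between sources.
#'
#' @param mobile,reference `rpi_complex`es, each with macromolecule chains
#'   and one ligand.
#' @return One-row tibble: `delta_l_macro` (Angstrom), `alignment_rmsd`
#'   (backbone RMSD of the superposition, used for gating).
#' @export
delta_l_macro <- function(mobile, reference) {
  mb <- complex_backbone(mobile)
  rb <- complex_backbone(reference)
  mm <- match_atoms(mb, rb)
  al <- kabsch(coords_matrix(mm$mobile), coords_matrix(mm$reference))
  lig_m <- complex_ligand(mobile)
  lig_r <- complex_ligand(reference)
  com_m <- apply_alignment(matrix(ligand_com(lig_m), 1), al)[1, ]
  com_r <- ligand_com(lig_r)
  tibble(delta_l_macro = sqrt(sum((com_m - com_r)^2)),
    alignment_rmsd = al$rmsd)
}

#' Pocket backbone selection around a reference ligand
#'
#' The pocket is the set of macromolecular backbone atoms within `cutoff`
#' (default 6 Angstrom) of any heavy ligand atom; the interface adds the
#' heavy ligand atoms themselves.
#'
#' @param reference An `rpi_complex` containing the reference ligand.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Tibble of selected backbone atoms.
#' @export
define_pocket_atoms <- function(reference, cutoff = 6) {
  lig <- complex_ligand(reference)
  bb <- complex_backbone(reference)
  d2 <- cross_dist2(coords_matrix(bb), coords_matrix(lig))
  sel <- apply(d2, 1, min) <= cutoff^2
  if (!any(sel)) abort("ligand outside macromolecule context: empty pocket")
  bb[sel, ]
}

# one-to-one ligand atom correspondence (atom sets must match)
match_ligand <- function(mobile, reference) {
  lm <- complex_ligand(mobile)
  lr <- complex_ligand(reference)
  if (nrow(lm) != nrow(lr)) abort("ligand atom sets do not match")
  j <- tryCatch(
    inner_join(mutate(lm, .mi = dplyr::row_number())[, c("name", "resno", ".mi")],
      mutate(lr, .ri = dplyr::row_number())[, c("name", "resno", ".ri")],
      by = c("name", "resno"), relationship = "one-to-one"),
    error = function(e) abort("ligand atom sets do not match (duplicate names)"))
  if (nrow(j) != nrow(lm)) abort("ligand atom sets do not match")
  list(mobile = lm[j$.mi, ], reference = lr[j$.ri, ])
}

rmsd_after <- function(al, mobile_atoms, reference_atoms) {
  fitted <- apply_alignment(coords_matrix(mobile_atoms), al)
  sqrt(mean(rowSums((fitted - coords_matrix(reference_atoms))^2)))
}

#' Ligand RMSD after pocket alignment
#'
#' Superposes the two complexes on the pocket backbone atoms (defined on the
#' reference, see [define_pocket_atoms()]) and reports the ligand RMSD
#' under that transform.
#'
#' @param mobile,reference `rpi_complex`es with matching ligand atom sets.
#' @param cutoff Pocket cutoff, Angstrom.
#' @return One-row tibble: `value` (ligand RMSD, Angstrom),
#'   `alignment_rmsd`.
#' @export
rmsd_pocket <- function(mobile, reference, cutoff = 6) {
  pocket <- define_pocket_atoms(reference, cutoff)
  mm <- match_atoms(complex_backbone(mobile), pocket)
  al <- kabsch(coords_matrix(mm$mobile), coords_matrix(mm$reference))
  lig <- match_ligand(mobile, reference)
  tibble(value = rmsd_after(al, lig$mobile, lig$reference),
    alignment_rmsd = al$rmsd)
}

#' Ligand RMSD after interface alignment
#'
#' As [rmsd_pocket()], but the alignment set is the interface: the pocket
#' backbone atoms plus the heavy ligand atoms.
#'
#' @inheritParams rmsd_pocket
#' @return One-row tibble: `value`, `alignment_rmsd`.
#' @export
rmsd_interface <- function(mobile, reference, cutoff = 6) {
  pocket <- define_pocket_atoms(reference, cutoff)
  mm <- match_atoms(complex_backbone(mobile), pocket)
  lig <- match_ligand(mobile, reference)
  p_m <- rbind(coords_matrix(mm$mobile), coords_matrix(lig$mobile))
  p_r <- rbind(coords_matrix(mm$reference), coords_matrix(lig$reference))
  al <- kabsch(p_m, p_r)
  tibble(value = rmsd_after(al, lig$mobile, lig$reference),
    alignment_rmsd = al$rmsd)
}

#' Minimum interface RMSD over a reference trajectory
#'
#' Evaluates [rmsd_interface()] against every frame of a multi-model
#' reference (re-aligning per frame) and returns the minimum.
#'
#' @param mobile An `rpi_complex`.
#' @param reference_traj Multi-model `rpi_complex` whose every frame carries
#'   the reference ligand.
#' @param cutoff Pocket cutoff, Angstrom.
#' @return One-row tibble: `value`, `frame` (minimizing frame),
#'   `alignment_rmsd` (of that frame).
#' @export
rmsd_interface_traj <- function(mobile, reference_traj, cutoff = 6) {
  frames <- traj_frames(reference_traj)
  if (!length(frames)) abort("empty trajectory")
  per <- map(frames, function(fr) {
    rmsd_interface(mobile, new_complex(fr), cutoff)
  })
  vals <- map_dbl(per, "value")
  i <- which.min(vals)
  tibble(value = vals[i], frame = i, alignment_rmsd = per[[i]]$alignment_rmsd)
}

#' Full congruence report between two ligand placements
#'
#' Computes the center-of-mass displacement and, when the ligand atom sets
#' match, the three RMSD variants, then applies the acceptance gates.
#'
#' @param mobile,reference `rpi_complex`es.
#' @param reference_traj Optional multi-model reference for the trajectory
#'   minimum.
#' @param cutoff Pocket cutoff, Angstrom.
#' @param ... Gate thresholds passed to [gate()].
#' @return A gated tibble of class `rpi_congruence` (see [gate()]).
#' @export
congruence_report <- function(mobile, reference, reference_traj = NULL,
                              cutoff = 6, ...) {
  dl <- delta_l_macro(mobile, reference)
  rows <- list(tibble(metric = "delta_l_macro", value = dl$delta_l_macro,
    alignment_rmsd = dl$alignment_rmsd))
  lig_ok <- tryCatch({match_ligand(mobile, reference); TRUE},
    error = function(e) FALSE)
  if (lig_ok) {
    rp <- rmsd_pocket(mobile, reference, cutoff)
    ri <- rmsd_interface(mobile, reference, cutoff)
    rows <- c(rows, list(
      tibble(metric = "rmsd_pocket", value = rp$value,
        alignment_rmsd = rp$alignment_rmsd),
      tibble(metric = "rmsd_interface", value = ri$value,
        alignment_rmsd = ri$alignment_rmsd)))
    if (!is.null(reference_traj)) {
      rt <- rmsd_interface_traj(mobile, reference_traj, cutoff)
      rows <- c(rows, list(tibble(metric = "rmsd_interface_traj",
        value = rt$value, alignment_rmsd = rt$alignment_rmsd)))
    }
  }
  gate(bind_rows(rows), ...)
}

#' Gate congruence metrics on alignment quality and agreement thresholds
#'
#' A metric whose alignment RMSD reaches `align_cutoff` is
#' `rejected_alignment`; otherwise the metric value classifies the placement
#' as `agreeing` (below `agree_cutoff`), `disagreeing` (above
#' `disagree_cutoff`) or `accepted` (between). When
#' `reference_half_diagonal` is given, the center-of-mass metric is also
#' compared against it (`above_half_diagonal` column), the safe-disagreement
#' yardstick.
#'
#' @param report Tibble with `metric`, `value`, `alignment_rmsd`.
#' @param align_cutoff Alignment-quality gate, Angstrom (default 3; the
#'   stricter 2 is also in common use for the COM metric, 5 for the RMSD
#'   metrics).
#' @param agree_cutoff,disagree_cutoff Agreement thresholds, Angstrom.
#' @param reference_half_diagonal Optional mean docking-box half-diagonal.
#' @return The report with `status` (and possibly `above_half_diagonal`)
#'   columns, classed `rpi_congruence`.
#' @export
gate <- function(report, align_cutoff = 3, agree_cutoff = 5,
                 disagree_cutoff = 10, reference_half_diagonal = NULL) {
  r <- as_tibble(report)
  r$status <- dplyr::case_when(
    r$alignment_rmsd >= align_cutoff ~ "rejected_alignment",
    r$value < agree_cutoff ~ "agreeing",
    r$value > disagree_cutoff ~ "disagreeing",
    TRUE ~ "accepted"
  )
  if (!is.null(reference_half_diagonal)) {
    r$above_half_diagonal <- ifelse(r$metric == "delta_l_macro",
      r$value > reference_half_diagonal, NA)
  }
  structure(r, class = c("rpi_congruence", class(tibble())))
}
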