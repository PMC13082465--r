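# The 77-entry pocket feature vector feeding the druggability classifier.
# Families: docking-score statistics (all docked records, the top-100 and
# the top-5 subsets), ligand-BSA statistics over the retained sets, static
# pocket geometry, pocket-volume fluctuation over trajectory frames, and
# hydration statistics (water counts, densities, translational order). The
# exact registry is versioned here and pluggable: downstream code only
# relies on `feature_registry()` and `assemble_features()` agreeing.

stats7 <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(rep(NA_real_, 7))
  c(min(v), max(v), mean(v), if (length(v) > 1) sd(v) else 0,
    unname(quantile(v, c(0.25, 0.5, 0.75))))
}
stats4 <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(rep(NA_real_, 4))
  c(min(v), max(v), mean(v), if (length(v) > 1) sd(v) else 0)
}
.s7 <- c("min", "max", "mean", "sd", "q25", "median", "q75")
.s4 <- c("min", "max", "mean", "sd")

#' The druggability feature registry
#'
#' @return A 77-row tibble with columns `name` and `family`, in the exact
#'   order produced by [assemble_features()].
#' @export
feature_registry <- function() {
  reg <- bind_rows(
    tibble(name = paste0("dock_all_", .s7), family = "docking_score"),
    tibble(name = paste0("dock_top100_", .s7), family = "docking_score"),
    tibble(name = paste0("dock_top5_", .s7), family = "docking_score"),
    tibble(name = c("n_docked", "n_top100"), family = "docking_score"),
    tibble(name = paste0("lig5_srbsa_", .s4), family = "ligand_bsa"),
    tibble(name = paste0("lig5_bsaprot_", .s4), family = "ligand_bsa"),
    tibble(name = paste0("lig5_bsarna_", .s4), family = "ligand_bsa"),
    tibble(name = paste0("lig100_srbsa_", .s4), family = "ligand_bsa"),
    tibble(name = c("pocket_n_points", "pocket_hull_volume",
      "pocket_hull_area", "pocket_radius_mean", "pocket_radius_sd",
      "box_half_diagonal", "box_volume", "pocket_drug_score",
      "pocket_apolar_ratio"), family = "pocket_geometry"),
    tibble(name = paste0("pocket_volume_", .s4), family = "pocket_geometry"),
    tibble(name = paste0("hyd_count_", .s4), family = "hydration"),
    tibble(name = paste0("hyd_absdens_", .s4), family = "hydration"),
    tibble(name = paste0("hyd_reldens_", .s4), family = "hydration"),
    tibble(name = paste0("hyd_framesk_", .s4), family = "hydration"),
    tibble(name = paste0("sk_", .s7), family = "hydration"),
    tibble(name = c("sk_n_total", "hyd_count_total"), family = "hydration")
  )
  stopifnot(nrow(reg) == 77, !anyDuplicated(reg$name))
  reg
}

#' Assemble the 77-feature vector for one pocket
#'
#' Deterministically maps a pocket's docked records, geometry and hydration
#' profile onto the [feature_registry()] order. Missing components yield
#' `NA` features, which [train_druggability()] imputes by training-set
#' medians.
#'
#' @param docked All docked records for the pocket (`compound_id`,
#'   `docking_score`, optionally `bsa_protein`, `bsa_rna`,
#'   `second_rank_bsa`, `pocket_id`).
#' @param pocket Optional `rpi_pocket` for geometry features.
#' @param hydration Optional `rpi_hydration` from [hydration_profile()].
#' @param pocket_volumes Optional numeric vector of per-frame pocket volumes
#'   (fluctuation features).
#' @param top1,top2 Funnel sizes defining the top-100 / top-5 subsets.
#' @return A one-row tibble with 77 numeric columns named per the registry.
#' @export
assemble_features <- function(docked, pocket = NULL, hydration = NULL,
                              pocket_volumes = NULL, top1 = 100, top2 = 5) {
  d <- as_tibble(docked)
  if (!"pocket_id" %in% names(d)) d$pocket_id <- "pocket"
  if (nrow(distinct(d, .data$pocket_id)) > 1) {
    abort("assemble_features expects records of a single pocket")
  }
  has_bsa <- "second_rank_bsa" %in% names(d)
  t100 <- suppressWarnings(funnel_stage1(d, top_n = top1))
  t5 <- if (has_bsa) funnel_stage2(t100, top_n = top2) else t100[0, ]

  col <- function(tab, nm) if (nm %in% names(tab)) tab[[nm]] else numeric(0)

  pocket_geom <- if (!is.null(pocket)) {
    p <- as_tibble(pocket)
    hull <- tryCatch(convex_hull_3d(p[, c("x", "y", "z")]),
      error = function(e) NULL)
    box <- docking_box(pocket)
    c(nrow(p), if (is.null(hull)) NA_real_ else hull$volume,
      if (is.null(hull)) NA_real_ else hull$area,
      mean(p$radius), if (nrow(p) > 1) sd(p$radius) else 0,
      box$half_diagonal,
      (box$xmax - box$xmin) * (box$ymax - box$ymin) * (box$zmax - box$zmin),
      attr(pocket, "drug_score") %||% NA_real_,
      attr(pocket, "apolar_ratio") %||% NA_real_)
  } else rep(NA_real_, 9)

  hyd <- if (!is.null(hydration)) {
    pf <- hydration$per_frame
    c(stats4(pf$count), stats4(pf$abs_density), stats4(pf$rel_density),
      stats4(pf$mean_sk), stats7(hydration$sk$sk),
      sum(pf$n_sk), sum(pf$count))
  } else rep(NA_real_, 25)

  vals <- c(
    stats7(d$docking_score), stats7(t100$docking_score),
    stats7(col(t5, "docking_score")),
    nrow(d), nrow(t100),
    stats4(col(t5, "second_rank_bsa")), stats4(col(t5, "bsa_protein")),
    stats4(col(t5, "bsa_rna")), stats4(col(t100, "second_rank_bsa")),
    pocket_geom, stats4(pocket_volumes %||% numeric(0)), hyd
  )
  reg <- feature_registry()
  stopifnot(length(vals) == nrow(reg))
  as_tibble(as.list(setNames(vals, reg$name)))
}
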