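# The virtual-screening filter funnel: physicochemical compound filtering,
# per-pocket top-N selection by docking score, top-N selection by
# second-rank BSA, stabilizer classification from MMGB/SA energies, and
# docking-task scheduling.

# Inclusive physicochemical ranges for drug-like compound filtering
# (averages of orally admissible drugs +/- one standard deviation).
#' Physicochemical filter ranges
#'
#' The inclusive property ranges used to filter a compound database down to
#' drug-like candidates: LogP 1-3, mass 250-450 Da, NOCount 2-9, NHOHCount
#' 0-3, TPSA 19-70 square Angstrom, rotatable bonds 1-8, aromatic
#' carbocycles 0-2, aromatic heterocycles 0-1, aromatic rings 1-3,
#' FractionCSP3 0.2-0.6.
#'
#' @return A tibble with columns `property`, `lower`, `upper`.
#' @export
physchem_ranges <- function() {
  tibble::tribble(
    ~property, ~lower, ~upper,
    "logp", 1, 3,
    "mass", 250, 450,
    "no_count", 2, 9,
    "nhoh_count", 0, 3,
    "tpsa", 19, 70,
    "rotatable_bonds", 1, 8,
    "aromatic_carbocycles", 0, 2,
    "aromatic_heterocycles", 0, 1,
    "aromatic_rings", 1, 3,
    "fraction_csp3", 0.2, 0.6
  )
}

#' Filter compounds by physicochemical properties
#'
#' Every property must fall inside its inclusive range (see
#' [physchem_ranges()]). Descriptors can be supplied directly or computed
#' from SMILES with [compound_descriptors()].
#'
#' @param descriptors Tibble with one row per compound and the columns named
#'   in [physchem_ranges()] (plus optionally `compound_id`).
#' @param ranges Range table; override individual bounds here.
#' @return The input with columns `pass` (logical) and `failing_properties`
#'   (list of character vectors) appended.
#' @export
physchem_filter <- function(descriptors, ranges = physchem_ranges()) {
  d <- as_tibble(descriptors)
  missing <- setdiff(ranges$property, names(d))
  if (length(missing)) {
    abort(paste0("missing descriptor(s): ", paste(missing, collapse = ", ")))
  }
  fails <- lapply(seq_len(nrow(d)), function(i) {
    v <- unlist(d[i, ranges$property])
    if (anyNA(v)) abort(paste0("missing descriptor value(s): ",
      paste(ranges$property[is.na(v)], collapse = ", ")))
    ranges$property[v < ranges$lower | v > ranges$upper]
  })
  d$pass <- lengths(fails) == 0
  d$failing_properties <- fails
  d
}

#' Funnel stage 1: best docking scores per pocket
#'
#' Retains, for each pocket, the `top_n` records with the lowest (best)
#' docking score. Ties are broken by `compound_id` lexical order so runs
#' are reproducible. Pockets with fewer than `top_n` records keep all of
#' them, with a warning.
#'
#' @param records Tibble with `pocket_id`, `compound_id`, `docking_score`.
#' @param top_n Records retained per pocket (default 100).
#' @return Retained records, ordered by pocket then score.
#' @export
funnel_stage1 <- function(records, top_n = 100) {
  r <- as_tibble(records)
  stopifnot(all(c("pocket_id", "compound_id", "docking_score") %in% names(r)),
    all(is.finite(r$docking_score)))
  short <- r |> count(.data$pocket_id) |> filter(.data$n < top_n)
  if (nrow(short)) {
    warn(paste0(nrow(short), " pocket(s) have fewer than ", top_n,
      " records; all their records are retained"))
  }
  r |>
    group_by(.data$pocket_id) |>
    arrange(.data$docking_score, .data$compound_id, .by_group = TRUE) |>
    slice_head(n = top_n) |>
    ungroup()
}

#' Funnel stage 2: best second-rank BSA per pocket
#'
#' From stage-1 survivors, retains per pocket the `top_n` records with the
#' largest second-rank BSA (ligand-vs-macromolecule burial). Ties are broken
#' by docking score, then `compound_id`.
#'
#' @param records Stage-1 output joined with `second_rank_bsa` (and
#'   optionally `bsa_protein`, `bsa_rna`).
#' @param top_n Records retained per pocket (default 5).
#' @return Retained records.
#' @export
funnel_stage2 <- function(records, top_n = 5) {
  r <- as_tibble(records)
  stopifnot(all(c("pocket_id", "compound_id", "second_rank_bsa") %in% names(r)))
  has_score <- "docking_score" %in% names(r)
  r |>
    group_by(.data$pocket_id) |>
    arrange(desc(.data$second_rank_bsa),
      if (has_score) .data$docking_score else .data$compound_id,
      .data$compound_id, .by_group = TRUE) |>
    slice_head(n = top_n) |>
    ungroup()
}

#' Classify a compound's stabilizing potential from MMGB/SA energies
#'
#' A compound whose interaction free energies with both the protein and the
#' RNA are strictly below -10 kcal/mol is an `elevated` stabilizer
#' candidate; strictly below -7 kcal/mol on both sides, a `basic`
#' candidate; anything else is a `regular` organic ligand. "Lower than" is
#' read strictly, so boundary values demote. When replicate energy vectors
#' are supplied their means are classified.
#'
#' @param ddg_protein,ddg_rna Interaction free energies (kcal/mol),
#'   vectorized.
#' @param basic_threshold,elevated_threshold Class thresholds (kcal/mol).
#' @return Character vector: `"elevated"`, `"basic"` or `"regular"`.
#' @export
#' @examples
#' classify_stabilizer(c(-10.5, -8, -7), c(-12, -7.5, -20))
classify_stabilizer <- function(ddg_protein, ddg_rna,
                                basic_threshold = -7,
                                elevated_threshold = -10) {
  if (any(!is.finite(ddg_protein)) || any(!is.finite(ddg_rna))) {
    abort("classify_stabilizer: energies must be finite")
  }
  dplyr::case_when(
    ddg_protein < elevated_threshold & ddg_rna < elevated_threshold ~ "elevated",
    ddg_protein < basic_threshold & ddg_rna < basic_threshold ~ "basic",
    TRUE ~ "regular"
  )
}

#' Classify an energy table
#'
#' Convenience wrapper over [classify_stabilizer()] for a tibble of MMGB/SA
#' results; replicate columns (`replicate_values` list-column or multiple
#' `ddg_*_rep*` columns) are averaged first.
#'
#' @param energies Tibble with `compound_id`, `ddg_protein`, `ddg_rna`.
#' @param ... Thresholds passed on.
#' @return Input with a `stabilizer_class` column appended.
#' @export
classify_energy_table <- function(energies, ...) {
  e <- as_tibble(energies)
  e$stabilizer_class <- classify_stabilizer(e$ddg_protein, e$ddg_rna, ...)
  e
}

#' Schedule docking tasks over a pocket manifest
#'
#' Counts the docking tasks implied by docking `n_compounds` compounds into
#' every pocket of a manifest; tasks are counted, not materialized.
#'
#' @param manifest Tibble with a `pocket_id` column (one row per pocket).
#' @param n_compounds Compounds docked per pocket.
#' @return A list with `per_pocket` (tibble `pocket_id`, `n_tasks`) and
#'   `total` (numeric scalar).
#' @export
docking_manifest <- function(manifest, n_compounds) {
  m <- distinct(as_tibble(manifest), .data$pocket_id)
  per <- mutate(m, n_tasks = as.numeric(n_compounds))
  list(per_pocket = per, total = sum(per$n_tasks))
}
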