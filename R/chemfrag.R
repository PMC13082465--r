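# Fragment-based chemical analysis: circular-fingerprint (ECFP-style)
# environment enumeration, discrimination scoring of fragments between
# stabilizer candidates and regular ligands, greedy covering-set statistics,
# and BRICS decomposition/recombination for de novo library construction.

#' Enumerate circular-fingerprint fragments of a molecule
#'
#' Extracts the circular atom environment of every heavy atom at radii
#' 1..`max_radius` bonds, renders each as a canonical substructure SMILES,
#' drops fragments with fewer than `min_atoms` atoms and deduplicates.
#'
#' @param smiles Character vector of SMILES (one or more molecules).
#' @param max_radius Maximum environment radius in bonds (default 5).
#' @param min_atoms Minimum fragment size in atoms (default 3).
#' @return For a single molecule, a character vector of fragment SMILES; for
#'   several, a tibble with `compound_id`, `smiles`, `fragments`
#'   (list-column).
#' @export
enumerate_fragments <- function(smiles, max_radius = 5, min_atoms = 3) {
  res <- rdkit_call("morgan_fragments", list(smiles = as.list(smiles),
    max_radius = max_radius, min_atoms = min_atoms))$fragments
  if (length(smiles) == 1) res <- list(res)
  bad <- vapply(res, function(x) {
    is.null(x) || (length(x) == 1 && is.logical(x) && is.na(x))
  }, logical(1))
  if (any(bad)) {
    abort(paste0("unparseable SMILES: ", paste(smiles[bad], collapse = ", ")))
  }
  res <- lapply(res, function(x) as.character(unlist(x)))
  if (length(smiles) == 1) return(res[[1]])
  tibble(compound_id = paste0("cmpd_", seq_along(smiles)),
    smiles = smiles, fragments = res)
}

#' Fragment frequencies in glue and non-glue compound sets
#'
#' For every fragment, the fraction of compounds in the stabilizer-candidate
#' ("glue") set and in the regular-ligand set that contain it as a
#' substructure (compound-level counting), together with the discrimination
#' score from [score_fragment()].
#'
#' @param fragments Character vector of fragment SMILES.
#' @param glue_smiles,nonglue_smiles Character vectors of compound SMILES.
#' @return A tibble: `fragment`, `freq_glue`, `freq_nonglue`, `score`,
#'   ordered by descending score (ties by fragment string); the raw
#'   fragment-by-compound match matrices are kept in attributes
#'   `match_glue` / `match_nonglue` for coverage analysis.
#' @export
fragment_frequencies <- function(fragments, glue_smiles, nonglue_smiles) {
  if (!length(glue_smiles) || !length(nonglue_smiles)) {
    abort("both compound sets must be non-empty")
  }
  fragments <- unique(as.character(fragments))
  mg <- substruct_matrix(fragments, glue_smiles)
  mn <- substruct_matrix(fragments, nonglue_smiles)
  out <- tibble(
    fragment = fragments,
    freq_glue = rowMeans(mg),
    freq_nonglue = rowMeans(mn)
  ) |>
    mutate(score = score_fragment(.data$freq_glue, .data$freq_nonglue)) |>
    arrange(desc(.data$score), .data$fragment)
  ord <- match(out$fragment, fragments)
  structure(out, match_glue = mg[ord, , drop = FALSE],
    match_nonglue = mn[ord, , drop = FALSE])
}

# fragment x compound logical matrix of substructure containment
substruct_matrix <- function(fragments, smiles) {
  m <- rdkit_call("substruct_matrix",
    list(fragments = as.list(fragments), smiles = as.list(smiles)))$matrix
  m <- matrix(as.logical(m), nrow = length(fragments), byrow = FALSE)
  if (is.list(m)) m <- do.call(rbind, m)
  matrix(m, nrow = length(fragments))
}

#' Fragment discrimination score
#'
#' `score = (f_g - f_gbar) * exp(f_gbar)` where `f_g` is the fragment's
#' frequency among stabilizer candidates and `f_gbar` among regular
#' ligands. Positive scores mark glue-enriched fragments; the exponential
#' term penalizes fragments that are also common in the background set.
#'
#' @param f_g,f_gbar Frequencies in `[0, 1]` (vectorized).
#' @return Numeric score.
#' @export
#' @examples
#' score_fragment(0.5, 0.1) # 0.442068
score_fragment <- function(f_g, f_gbar) {
  if (any(f_g < 0 | f_g > 1 | f_gbar < 0 | f_gbar > 1, na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]")
  }
  (f_g - f_gbar) * exp(f_gbar)
}

#' Greedy covering set of scored fragments
#'
#' Takes fragments in descending score order until at least `coverage_goal`
#' of the target compounds contain at least one chosen fragment, and
#' reports the off-target coverage of the same set.
#'
#' @param records Scored fragment table from [fragment_frequencies()] (its
#'   match-matrix attributes are used; otherwise supply `target_smiles` /
#'   `offtarget_smiles` to recompute matches).
#' @param coverage_goal Fraction of target compounds to cover (default 0.8).
#' @param target_smiles,offtarget_smiles Optional compound sets overriding
#'   the stored match matrices (target defaults to the glue set).
#' @return A list of class `rpi_coverage`: `fragments` (tibble with
#'   cumulative target/off-target coverage per added fragment), `n_selected`,
#'   `covered_fraction_target`, `covered_fraction_offtarget`,
#'   `goal_reached`.
#' @export
minimal_covering_set <- function(records, coverage_goal = 0.8,
                                 target_smiles = NULL, offtarget_smiles = NULL) {
  r <- arrange(as_tibble(records), desc(.data$score), .data$fragment)
  if (!is.null(target_smiles)) {
    mt <- substruct_matrix(r$fragment, target_smiles)
  } else {
    mt <- attr(records, "match_glue")
  }
  if (!is.null(offtarget_smiles)) {
    mo <- substruct_matrix(r$fragment, offtarget_smiles)
  } else {
    mo <- attr(records, "match_nonglue")
  }
  if (is.null(mt)) abort("no target match information available")
  ord <- match(r$fragment, records$fragment)
  mt <- mt[ord, , drop = FALSE]
  if (!is.null(mo)) mo <- mo[ord, , drop = FALSE]

  covered_t <- rep(FALSE, ncol(mt))
  covered_o <- if (!is.null(mo)) rep(FALSE, ncol(mo)) else logical(0)
  rows <- list()
  n_sel <- 0L
  for (i in seq_len(nrow(r))) {
    marginal <- sum(mt[i, ] & !covered_t)
    covered_t <- covered_t | mt[i, ]
    if (length(covered_o)) covered_o <- covered_o | mo[i, ]
    n_sel <- i
    rows[[i]] <- tibble(fragment = r$fragment[i], score = r$score[i],
      marginal_coverage = marginal,
      covered_fraction_target = mean(covered_t),
      covered_fraction_offtarget = if (length(covered_o)) mean(covered_o) else NA_real_)
    if (mean(covered_t) >= coverage_goal) break
  }
  fragments <- bind_rows(rows)
  goal_reached <- mean(covered_t) >= coverage_goal
  if (!goal_reached) {
    warn(sprintf("coverage goal %.2f unreachable; achieved %.3f",
      coverage_goal, mean(covered_t)))
  }
  structure(list(fragments = fragments, n_selected = n_sel,
    covered_fraction_target = mean(covered_t),
    covered_fraction_offtarget = if (length(covered_o)) mean(covered_o) else NA_real_,
    goal_reached = goal_reached), class = "rpi_coverage")
}

#' @export
print.rpi_coverage <- function(x, ...) {
  cat(sprintf("<rpi_coverage> %d fragments cover %.1f%% of targets (%.1f%% off-target)\n",
    x$n_selected, 100 * x$covered_fraction_target,
    100 * (x$covered_fraction_offtarget %||% NA_real_)))
  invisible(x)
}

#' BRICS decomposition of molecules
#'
#' Standard BRICS retrosynthetic bond cleavage (delegated to RDKit);
#' attachment points are retained as numbered dummy atoms. A molecule with
#' no cleavable bond returns itself.
#'
#' @param smiles Character vector of SMILES.
#' @return For one molecule a character vector of fragment SMILES; for
#'   several, a tibble with a `fragments` list-column.
#' @export
brics_decompose <- function(smiles) {
  res <- rdkit_call("brics_decompose", list(smiles = as.list(smiles)))$fragments
  if (length(smiles) == 1) res <- list(res)
  bad <- vapply(res, function(x) {
    is.null(x) || (length(x) == 1 && is.logical(x) && is.na(x))
  }, logical(1))
  if (any(bad)) {
    abort(paste0("unparseable SMILES: ", paste(smiles[bad], collapse = ", ")))
  }
  res <- lapply(res, function(x) as.character(unlist(x)))
  if (length(smiles) == 1) return(res[[1]])
  tibble(smiles = smiles, fragments = res)
}

#' Recombine BRICS fragments into novel molecules
#'
#' Enumerates attachment-compatible joins of `k` BRICS substructures
#' (level-wise application of the inverted cleavage rules), hydrogen-caps
#' any remaining attachment points, sanitizes and deduplicates by canonical
#' SMILES. When the product space exceeds `limit`, a seeded uniform sample
#' without replacement is returned.
#'
#' @param fragments Character vector of attachment-labeled BRICS fragment
#'   SMILES (dummy atoms `[n*]`).
#' @param k Number of fragments joined per product (default 3).
#' @param limit Maximum number of products (default 1e5).
#' @param seed Integer seed for any sampling.
#' @return Character vector of canonical product SMILES (possibly empty,
#'   with a warning, when no compatible joins exist).
#' @export
brics_recombine <- function(fragments, k = 3, limit = 1e5, seed = 1L) {
  stopifnot(k >= 2, length(fragments) >= 1)
  res <- rdkit_call("brics_recombine", list(
    fragments = as.list(as.character(fragments)),
    k = k, limit = limit, seed = as.integer(seed)))
  out <- as.character(unlist(res$products))
  if (!length(out)) warn("no attachment-compatible BRICS joins found")
  out
}
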