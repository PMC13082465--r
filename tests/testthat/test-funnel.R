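mid_compound <- function(...) {
  base <- tibble::tibble(
    compound_id = "c1", logp = 2, mass = 350, no_count = 5, nhoh_count = 1,
    tpsa = 45, rotatable_bonds = 4, aromatic_carbocycles = 1,
    aromatic_heterocycles = 0, aromatic_rings = 2, fraction_csp3 = 0.4)
  dplyr::mutate(base, ...)
}

test_that("physicochemical ranges are inclusive at the boundaries", {
  expect_true(physchem_filter(mid_compound(mass = 250))$pass)
  expect_true(physchem_filter(mid_compound(mass = 450))$pass)
  expect_true(physchem_filter(mid_compound(fraction_csp3 = 0.2))$pass)
  low_all <- mid_compound(logp = 1, mass = 250, no_count = 2, nhoh_count = 0,
    tpsa = 19, rotatable_bonds = 1, aromatic_carbocycles = 0,
    aromatic_heterocycles = 0, aromatic_rings = 1, fraction_csp3 = 0.2)
  expect_true(physchem_filter(low_all)$pass)
})

test_that("out-of-range properties are reported by name", {
  r <- physchem_filter(mid_compound(tpsa = 75))
  expect_false(r$pass)
  expect_equal(r$failing_properties[[1]], "tpsa")
  r2 <- physchem_filter(mid_compound(aromatic_rings = 4))
  expect_false(r2$pass)
  expect_true("aromatic_rings" %in% r2$failing_properties[[1]])
  expect_error(physchem_filter(dplyr::select(mid_compound(), -tpsa)), "tpsa")
})

test_that("stage 1 keeps the best-scored records per pocket", {
  withr::with_seed(1, {
    rec <- tibble::tibble(
      pocket_id = "p1", compound_id = sprintf("c%03d", 1:200),
      docking_score = rnorm(200, -7, 1.5))
  })
  kept <- funnel_stage1(rec, top_n = 100)
  expect_equal(nrow(kept), 100)
  dropped <- dplyr::anti_join(rec, kept, by = "compound_id")
  expect_lte(max(kept$docking_score), min(dropped$docking_score))

  expect_warning(funnel_stage1(rec[1:50, ], top_n = 100), "fewer than")
  expect_equal(nrow(suppressWarnings(funnel_stage1(rec[1:50, ], top_n = 100))), 50)
})

test_that("stage 2 selects by BSA, not score, with deterministic ties", {
  rec <- tibble::tibble(
    pocket_id = "p1", compound_id = sprintf("c%d", 1:6),
    docking_score = c(-12, -8, -8, -7, -6, -5),
    second_rank_bsa = c(0, 80, 80, 60, 90, 70))
  kept <- funnel_stage2(rec, top_n = 5)
  expect_false("c1" %in% kept$compound_id) # best score, zero BSA -> dropped
  expect_equal(kept$compound_id[1], "c5")
  expect_equal(kept$compound_id[2:3], c("c2", "c3")) # tie at 80 -> id order

  withr::with_seed(2, {
    big <- tibble::tibble(
      pocket_id = rep(c("a", "b"), each = 50),
      compound_id = rep(sprintf("c%02d", 1:50), 2),
      docking_score = rnorm(100), second_rank_bsa = runif(100, 0, 200))
  })
  kept2 <- funnel_stage2(big, top_n = 5)
  brute <- big |>
    dplyr::group_by(pocket_id) |>
    dplyr::arrange(dplyr::desc(second_rank_bsa), docking_score, compound_id,
      .by_group = TRUE) |>
    dplyr::slice_head(n = 5) |>
    dplyr::ungroup()
  expect_equal(as.data.frame(kept2), as.data.frame(brute))
})

test_that("the funnel conserves the 260 x 100 / 260 x 5 count chain", {
  manifest <- make_pocket_manifest(seed = 1)
  expect_equal(nrow(manifest), 260)
  tabs <- make_screen_tables(manifest = manifest, n_compounds = 200, seed = 1)
  expect_equal(nrow(tabs$stage1), 26000)
  expect_equal(nrow(tabs$stage2), 1300)
  expect_equal(docking_manifest(manifest, 200000)$total, 52e6)
})

test_that("a pocket without records shrinks the chain by exactly 100 and 5", {
  tabs <- make_screen_tables(n_pockets = 10, n_compounds = 200, seed = 3)
  docking <- dplyr::filter(tabs$docking, pocket_id != "pocket_0001")
  bsa_tbl <- dplyr::filter(tabs$bsa, pocket_id != "pocket_0001")
  s1 <- funnel_stage1(docking, top_n = 100)
  s2 <- funnel_stage2(dplyr::inner_join(s1, bsa_tbl,
    by = c("pocket_id", "compound_id")), top_n = 5)
  expect_equal(nrow(s1), 9 * 100)
  expect_equal(nrow(s2), 9 * 5)
})

test_that("stabilizer classes follow the strict -7/-10 thresholds", {
  expect_equal(classify_stabilizer(-10.5, -12), "elevated")
  expect_equal(classify_stabilizer(-8, -7.5), "basic")
  expect_equal(classify_stabilizer(-7, -20), "regular") # boundary demotes
  expect_equal(classify_stabilizer(-10, -11), "basic")  # boundary demotes
  expect_equal(classify_stabilizer(-6, -6), "regular")
  expect_error(classify_stabilizer(NA_real_, -8), "finite")

  # monotone: lowering either energy never demotes
  rank_of <- c(regular = 1, basic = 2, elevated = 3)
  withr::with_seed(4, {
    for (i in 1:100) {
      e <- runif(2, -15, -2)
      before <- rank_of[classify_stabilizer(e[1], e[2])]
      after <- rank_of[classify_stabilizer(e[1] - runif(1, 0, 5), e[2])]
      expect_gte(after, before)
    }
  })
})

test_that("planted energy tables are recovered with zero misclassifications", {
  tabs <- make_screen_tables(seed = 5)
  got <- classify_energy_table(tabs$energies)
  expect_equal(got$stabilizer_class, got$true_class)
  n <- nrow(got)
  expect_equal(sum(got$stabilizer_class == "basic"), round(0.17 * n))
  expect_equal(sum(got$stabilizer_class == "elevated"), round(0.07 * n))
})
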