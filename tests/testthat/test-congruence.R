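lig_complex <- function(seed = 1) make_complex(seed = seed, ligand = TRUE)

test_that("identical complexes give zero displacement and RMSDs", {
  cx <- lig_complex(1)
  pair <- make_placement_pair(cx)
  expect_equal(delta_l_macro(pair$mobile, pair$reference)$delta_l_macro, 0,
    tolerance = 1e-9)
  expect_equal(rmsd_pocket(pair$mobile, pair$reference)$value, 0,
    tolerance = 1e-9)
  expect_equal(rmsd_interface(pair$mobile, pair$reference)$value, 0,
    tolerance = 1e-9)
})

test_that("all metrics are invariant under rigid motion of the mobile complex", {
  cx <- lig_complex(2)
  pair <- make_placement_pair(cx, global_motion = TRUE, seed = 3)
  expect_equal(delta_l_macro(pair$mobile, pair$reference)$delta_l_macro, 0,
    tolerance = 1e-6)
  expect_equal(rmsd_pocket(pair$mobile, pair$reference)$value, 0,
    tolerance = 1e-6)
  expect_equal(rmsd_interface(pair$mobile, pair$reference)$value, 0,
    tolerance = 1e-6)

  # and under a common rigid transform of both inputs
  rot <- rpiglue:::rot_axis_angle(c(0, 1, 1), 0.9)
  move <- function(cx) {
    d <- as.data.frame(cx)
    xyz <- sweep(as.matrix(d[, c("x", "y", "z")]) %*% t(rot), 2, c(3, -2, 8), "+")
    d$x <- xyz[, 1]; d$y <- xyz[, 2]; d$z <- xyz[, 3]
    as_complex(d)
  }
  pair2 <- make_placement_pair(cx, displacement = c(4, 0, 0))
  before <- delta_l_macro(pair2$mobile, pair2$reference)$delta_l_macro
  after <- delta_l_macro(move(pair2$mobile), move(pair2$reference))$delta_l_macro
  expect_equal(after, before, tolerance = 1e-9)
})

test_that("a planted ligand displacement is recovered exactly", {
  cx <- lig_complex(4)
  pair <- make_placement_pair(cx, displacement = c(7, 0, 0), seed = 5)
  r <- delta_l_macro(pair$mobile, pair$reference)
  expect_equal(r$delta_l_macro, 7, tolerance = 1e-9)
  expect_lt(r$alignment_rmsd, 1e-9)
  # with a global motion stacked on top the answer is unchanged
  pair2 <- make_placement_pair(cx, displacement = c(7, 0, 0),
    global_motion = TRUE, seed = 6)
  expect_equal(delta_l_macro(pair2$mobile, pair2$reference)$delta_l_macro, 7,
    tolerance = 1e-6)
  # oracle: direct COM arithmetic without any alignment machinery
  lig <- as.data.frame(pair$reference)
  lig <- lig[lig$kind == "ligand" & lig$is_heavy, ]
  w <- lig$mass / sum(lig$mass)
  com_ref <- c(sum(lig$x * w), sum(lig$y * w), sum(lig$z * w))
  expect_equal(r$delta_l_macro, sqrt(sum((com_ref + c(7, 0, 0) - com_ref)^2)))
})

test_that("COM displacement is bounded by ligand RMSD under the same alignment", {
  cx <- lig_complex(5)
  pair <- make_placement_pair(cx, displacement = c(2, 1, 0),
    rotation_angle = 0.8, seed = 7)
  dl <- delta_l_macro(pair$mobile, pair$reference)$delta_l_macro
  # same macromolecule alignment (identity here), ligand RMSD directly
  ref <- as.data.frame(pair$reference); mob <- as.data.frame(pair$mobile)
  rl <- ref[ref$kind == "ligand" & ref$is_heavy, ]
  ml <- mob[mob$kind == "ligand" & mob$is_heavy, ]
  lig_rmsd <- sqrt(mean((ml$x - rl$x)^2 + (ml$y - rl$y)^2 + (ml$z - rl$z)^2))
  expect_lte(dl, lig_rmsd + 1e-9)
})

test_that("pocket definition honors the 6 A cutoff boundary", {
  atoms <- tibble::tibble(
    name = c("CA", "CA", "C1"),
    element = c("C", "C", "C"),
    resname = c("ALA", "ALA", "LIG"),
    chain = c("A", "A", "L"), resno = c(1L, 2L, 1L),
    x = c(5.9, 6.1, 0), y = 0, z = 0)
  cx <- as_complex(atoms)
  sel <- define_pocket_atoms(cx, cutoff = 6)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$x, 5.9)

  far <- dplyr::mutate(atoms, x = c(50, 55, 0))
  expect_error(define_pocket_atoms(as_complex(far), cutoff = 6),
    "outside macromolecule context")

  # brute-force agreement on a full fixture
  cx2 <- lig_complex(6)
  sel2 <- define_pocket_atoms(cx2, cutoff = 6)
  d <- as.data.frame(cx2)
  bb <- d[d$kind %in% c("protein", "rna") & d$is_backbone & d$is_heavy, ]
  lig <- d[d$kind == "ligand" & d$is_heavy, ]
  keep <- apply(as.matrix(bb[, c("x", "y", "z")]), 1, function(a) {
    any(colSums((t(as.matrix(lig[, c("x", "y", "z")])) - a)^2) <= 36)
  })
  expect_equal(nrow(sel2), sum(keep))
})

test_that("interface alignment absorbs part of a ligand displacement", {
  cx <- lig_complex(7)
  pair <- make_placement_pair(cx, displacement = c(5, 0, 0), seed = 8)
  rp <- rmsd_pocket(pair$mobile, pair$reference)
  ri <- rmsd_interface(pair$mobile, pair$reference)
  expect_equal(rp$value, 5, tolerance = 1e-9) # pocket alignment unaffected
  expect_lt(ri$value, 5)                      # ligand in the fit contracts it
  expect_gt(ri$value, 0)
})

test_that("trajectory minimum bounds the static interface RMSD", {
  cx <- lig_complex(8)
  pair <- make_placement_pair(cx, displacement = c(3, 1, 0), seed = 9)
  # trajectory: the reference frame plus jittered copies
  ref_df <- as.data.frame(pair$reference)
  frames <- dplyr::bind_rows(lapply(1:5, function(m) {
    fr <- ref_df
    if (m > 1) {
      withr::with_seed(100 + m, {
        fr$x <- fr$x + rnorm(nrow(fr), 0, 0.3)
        fr$y <- fr$y + rnorm(nrow(fr), 0, 0.3)
        fr$z <- fr$z + rnorm(nrow(fr), 0, 0.3)
      })
    }
    fr$model <- m
    fr
  }))
  traj <- as_complex(frames)
  rt <- rmsd_interface_traj(pair$mobile, traj)
  ri <- rmsd_interface(pair$mobile, pair$reference)
  expect_lte(rt$value, ri$value + 1e-9)
  # brute force over frames
  per_frame <- vapply(1:5, function(m) {
    rmsd_interface(pair$mobile, get_model(traj, m))$value
  }, numeric(1))
  expect_equal(rt$value, min(per_frame))
  expect_equal(rt$frame, which.min(per_frame))

  # a trajectory containing the exact mobile configuration reaches zero
  mob_df <- dplyr::mutate(as.data.frame(pair$mobile), model = 6L)
  traj2 <- as_complex(dplyr::bind_rows(frames, mob_df))
  expect_equal(rmsd_interface_traj(pair$mobile, traj2)$value, 0,
    tolerance = 1e-9)
})

test_that("gating classifies by alignment quality then agreement thresholds", {
  rep <- tibble::tibble(
    metric = c("delta_l_macro", "rmsd_interface", "rmsd_pocket", "rmsd_interface_traj"),
    value = c(4.2, 11, 7, 2),
    alignment_rmsd = c(0.5, 0.8, 3.5, 1))
  g <- gate(rep, align_cutoff = 3, reference_half_diagonal = 13.55)
  expect_equal(g$status, c("agreeing", "disagreeing", "rejected_alignment",
    "agreeing"))
  expect_false(g$above_half_diagonal[1])
  g2 <- gate(tibble::tibble(metric = "delta_l_macro", value = 15,
    alignment_rmsd = 1), reference_half_diagonal = 13.55)
  expect_true(g2$above_half_diagonal)
  expect_equal(g2$status, "disagreeing")
})

test_that("the full congruence report assembles and gates all metrics", {
  cx <- lig_complex(9)
  pair <- make_placement_pair(cx, displacement = c(2, 0, 0), seed = 10)
  rep <- congruence_report(pair$mobile, pair$reference,
    reference_half_diagonal = 13.55)
  expect_setequal(rep$metric, c("delta_l_macro", "rmsd_pocket", "rmsd_interface"))
  expect_true(all(rep$status == "agreeing"))
})
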