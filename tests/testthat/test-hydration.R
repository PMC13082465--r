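test_that("representative frame handles ties and constructed geometries", {
  cx <- toy_complex(seed = 1)
  static <- make_trajectory(cx, n_frames = 5, jitter_sigma = 0, seed = 2)
  expect_equal(as.integer(representative_frame(static)), 1L)

  # frame 2 is the exact midpoint of frames 1 and 3 along a line
  base <- as.data.frame(cx)
  shift <- function(d) {
    fr <- base
    fr$x <- fr$x + d
    fr
  }
  frames <- dplyr::bind_rows(
    dplyr::mutate(shift(0), model = 1L),
    dplyr::mutate(shift(1), model = 2L),
    dplyr::mutate(shift(2), model = 3L))
  # translation is removed by alignment; add a small structured distortion
  frames$y <- frames$y + 0.3 * c(0, 1, 2)[frames$model] * sin(frames$z)
  traj <- as_complex(frames)
  expect_equal(as.integer(representative_frame(traj)), 2L)
})

test_that("representative frame equals brute-force evaluation and is rigid-invariant", {
  cx <- toy_complex(seed = 3)
  traj <- make_trajectory(cx, n_frames = 20, jitter_sigma = 0.3, seed = 4)
  t_min <- representative_frame(traj)

  # brute force: align all frames to frame 1 on the same selection, average,
  # pick the closest frame
  frames <- rpiglue:::traj_frames(traj)
  sel <- which(frames[[1]]$is_backbone & frames[[1]]$is_heavy)
  ref <- as.matrix(frames[[1]][sel, c("x", "y", "z")])
  aligned <- lapply(frames, function(fr) {
    p <- as.matrix(fr[sel, c("x", "y", "z")])
    apply_alignment(p, kabsch(p, ref))
  })
  mean_s <- Reduce(`+`, aligned) / length(aligned)
  rmsds <- vapply(aligned, function(a) sqrt(mean(rowSums((a - mean_s)^2))),
    numeric(1))
  expect_equal(as.integer(t_min), which.min(rmsds))

  # invariance to a global rigid transform of every frame
  rot <- rpiglue:::rot_axis_angle(c(1, 2, 3), 0.8)
  moved <- as.data.frame(traj)
  xyz <- sweep(as.matrix(moved[, c("x", "y", "z")]) %*% t(rot), 2, c(5, -3, 7), "+")
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  expect_equal(as.integer(representative_frame(as_complex(moved))),
    as.integer(t_min))
})

test_that("hull water counting handles containment, boundaries and permutation", {
  pocket <- pocket_model(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  inside <- matrix(c(0.5, 0.5, 0.5), 1)
  expect_equal(waters_in_hull(inside, pocket)$count, 1L)
  expect_equal(waters_in_hull(inside, pocket)$hull_volume, 1)
  expect_equal(waters_in_hull(matrix(c(2, 2, 2), 1), pocket)$count, 0L)
  on_face <- matrix(c(0.5, 0.5, 1), 1) # boundary counts as inside
  expect_equal(waters_in_hull(on_face, pocket)$count, 1L)

  withr::with_seed(5, w <- matrix(runif(300, -0.5, 1.5), ncol = 3))
  n1 <- waters_in_hull(w, pocket)$count
  n2 <- waters_in_hull(w[sample(nrow(w)), ], pocket)$count
  expect_equal(n1, n2)
  oracle <- sum(apply(w, 1, function(q) {
    in_hull_lp(as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)), q)
  }))
  expect_equal(n1, oracle)
  flat <- pocket_model(data.frame(x = runif(5), y = runif(5), z = 0))
  expect_error(waters_in_hull(inside, flat), "coplanar pocket")
})

test_that("water density normalizes against bulk", {
  d <- water_density(334, 10000)
  expect_equal(d$absolute, 0.0334)
  expect_equal(d$relative, 1)
  expect_equal(unlist(water_density(0, 50)), c(absolute = 0, relative = 0))
  d2 <- water_density(50, 1234)
  expect_equal(d2$absolute, 50 / 1234)
  expect_equal(d2$relative, 50 / 1234 / 0.0334)
  expect_error(water_density(5, 0), "positive")
})

test_that("translational order parameter matches hand-evaluated cases", {
  expect_equal(translational_order(c(3, 3, 3, 3)), 1)
  expect_equal(translational_order(c(2, 2, 4, 4)), 1 - 4 / 108)
  expect_equal(translational_order(c(2, 2, 4, 4)), 0.962963, tolerance = 1e-6)
  expect_equal(translational_order(c(1, 1, 1, 9)), 1 - 48 / 108)
  expect_equal(translational_order(c(1, 1, 1, 9)), 0.555556, tolerance = 1e-6)
  expect_error(translational_order(c(1, 2, 3)), "exactly 4")
  # Sk <= 1 with equality iff all distances equal
  withr::with_seed(6, {
    for (i in 1:50) {
      r <- runif(4, 0.5, 6)
      s <- translational_order(r)
      expect_lte(s, 1)
      if (diff(range(r)) > 1e-12) expect_lt(s, 1)
    }
  })
})

test_that("hydration profile selects equidistant frames and aggregates correctly", {
  cx <- toy_complex(seed = 7)
  pocket <- pocket_model(expand.grid(x = c(10, 22), y = c(2, 14), z = c(-6, 6)))
  traj <- make_trajectory(cx, n_frames = 10, jitter_sigma = 0, pocket = pocket,
    n_waters = 20, seed = 8)
  hp <- hydration_profile(traj, pocket, n_frames = 10)
  expect_equal(hp$per_frame$frame, 1:10)
  expect_true(all(hp$per_frame$count == 20))
  expect_equal(hp$summary$sd[hp$summary$metric == "count"], 0)
  expect_equal(hp$summary$mean[hp$summary$metric == "count"], 20)

  # subsampling keeps first and last frames
  hp4 <- hydration_profile(traj, pocket, n_frames = 4)
  expect_equal(hp4$per_frame$frame, c(1, 4, 7, 10))
  expect_error(hydration_profile(traj, pocket, n_frames = 11), "exceeds")
})

test_that("profile values equal frame-by-frame recomputation", {
  cx <- toy_complex(seed = 9)
  pocket <- pocket_model(expand.grid(x = c(12, 20), y = c(4, 12), z = c(-4, 4)))
  traj <- make_trajectory(cx, n_frames = 6, jitter_sigma = 0.2, pocket = pocket,
    n_waters = 25, seed = 10)
  hp <- hydration_profile(traj, pocket, n_frames = 6)
  frames <- rpiglue:::traj_frames(traj)
  for (k in c(1, 3, 6)) {
    fr <- frames[[k]]
    w <- as.matrix(fr[fr$resname == "HOH", c("x", "y", "z")])
    ora <- waters_in_hull(w, pocket)
    expect_equal(hp$per_frame$count[k], ora$count)
    expect_equal(hp$per_frame$abs_density[k],
      water_density(ora$count, ora$hull_volume)$absolute)
  }
})

test_that("bulk-density planting recovers relative density 1 within 2%", {
  cx <- toy_complex(seed = 11)
  pocket <- pocket_model(expand.grid(x = c(8, 20), y = c(0, 12), z = c(-6, 6)))
  traj <- make_trajectory(cx, n_frames = 5, jitter_sigma = 0, pocket = pocket,
    water_density = 0.0334, seed = 12)
  hp <- hydration_profile(traj, pocket, n_frames = 5)
  expect_equal(mean(hp$per_frame$rel_density), 1, tolerance = 0.02)
})
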