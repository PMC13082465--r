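# Independent oracles used by the tests; none of them share code with the
# implementation paths they check.

# Monte-Carlo SASA oracle for a two-sphere system: per-atom accessible area
# from uniformly random points on each expanded sphere, rejected when buried
# in the other expanded sphere.
mc_sasa_pair <- function(c1, c2, r1, r2, probe = 1.4, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    one <- function(center, r_self, other, r_other) {
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * (r_self + probe), 2, center, "+")
      d2 <- rowSums(sweep(pts, 2, other)^2)
      mean(d2 > (r_other + probe)^2) * 4 * pi * (r_self + probe)^2
    }
    c(one(c1, r1, c2, r2), one(c2, r2, c1, r1))
  })
}

# Monte-Carlo SASA oracle for an arbitrary atom set (x, y, z, radius).
mc_sasa_set <- function(atoms, probe = 1.4, n = 2e5, seed = 1) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atoms$radius + probe
  withr::with_seed(seed, {
    vapply(seq_len(nrow(xyz)), function(i) {
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * r[i], 2, xyz[i, ], "+")
      exposed <- rep(TRUE, n)
      for (j in seq_len(nrow(xyz))[-i]) {
        exposed <- exposed & rowSums(sweep(pts, 2, xyz[j, ])^2) > r[j]^2
      }
      mean(exposed) * 4 * pi * r[i]^2
    }, numeric(1))
  })
}

# Linear-feasibility convex-hull membership oracle: q is in conv(P) iff
# weights w >= 0, sum(w) = 1 reproduce q; solved as a non-negative
# least-squares problem on the homogenized system.
in_hull_lp <- function(points, q, tol = 1e-6) {
  a <- rbind(t(points), rep(1, nrow(points)))
  b <- c(q, 1)
  fit <- pracma::lsqnonneg(a, b)
  sqrt(sum((a %*% fit$x - b)^2)) < tol
}

# brute-force interface: heavy atoms of one side within cutoff of the other
brute_interface_count <- function(cx, cutoff = 5) {
  m <- as.data.frame(cx)
  m <- m[m$model == m$model[1] & m$is_heavy, ]
  p <- as.matrix(m[m$kind == "protein", c("x", "y", "z")])
  r <- as.matrix(m[m$kind == "rna", c("x", "y", "z")])
  np <- sum(apply(p, 1, function(a) any(colSums((t(r) - a)^2) <= cutoff^2)))
  nr <- sum(apply(r, 1, function(a) any(colSums((t(p) - a)^2) <= cutoff^2)))
  c(protein = np, rna = nr)
}

# small helper: toy complex reused across test files
toy_complex <- function(seed = 1, ...) make_complex(seed = seed, ...)

expect_tibble_near <- function(a, b, tol = 1e-8) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
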