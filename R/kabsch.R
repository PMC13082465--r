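# Least-squares rigid superposition (Kabsch), the primitive behind
# representative-frame selection and all congruence metrics.

#' Optimal rigid superposition of two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (optionally weighted) RMSD between `R %*% x + t` over the mobile points
#' `x` and the reference points. The reflection branch of the SVD solution
#' is corrected so `det(R) = +1`.
#'
#' @param mobile,reference Numeric matrices (n x 3) with matched rows, or
#'   data frames with `x`, `y`, `z` columns.
#' @param weights Optional non-negative weights (e.g. masses); uniform by
#'   default.
#' @return A list of class `rpi_alignment`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, weighted).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  p <- coords_matrix(mobile)
  q <- coords_matrix(reference)
  if (nrow(p) != nrow(q)) abort("kabsch: point counts differ")
  n <- nrow(p)
  if (n < 3) abort("kabsch needs >= 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)

  pc <- colSums(p * w)
  qc <- colSums(q * w)
  pp <- sweep(p, 2, pc)
  qq <- sweep(q, 2, qc)
  h <- crossprod(pp * w, qq)
  sv <- svd(h)
  # degenerate spread: all points (weighted) collinear
  spread <- svd(pp * sqrt(w))$d
  if (spread[2] <= 1e-8 * max(spread[1], 1)) {
    abort("kabsch: degenerate (collinear) point set")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- qc - as.vector(rot %*% pc)
  fitted <- tcrossprod(pp, rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - qq)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
    class = "rpi_alignment")
}

#' @export
print.rpi_alignment <- function(x, ...) {
  cat("<rpi_alignment> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords Matrix or data frame of points.
#' @param alignment An `rpi_alignment` from [kabsch()].
#' @return Transformed coordinate matrix.
#' @export
apply_alignment <- function(coords, alignment) {
  p <- coords_matrix(coords)
  sweep(tcrossprod(p, alignment$rotation), 2, alignment$translation, "+")
}

coords_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x[, 1:3, drop = FALSE]
  } else {
    m <- as.matrix(as_tibble(x)[, c("x", "y", "z")])
  }
  storage.mode(m) <- "double"
  m
}
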