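# Incremental 3-D convex hull. Pocket point clouds are small (tens to a few
# hundred points), so an O(n * f) incremental construction with tolerance-
# based visibility tests is ample. Faces are kept consistently wound with
# outward normals, giving the enclosed volume by the divergence theorem and
# point containment by facet half-space tests.

#' Convex hull of a 3-D point set
#'
#' @param pts Numeric matrix or data frame with 3 columns (x, y, z).
#' @param tol Degeneracy/containment tolerance, relative to the point-cloud
#'   diameter.
#' @return A list of class `rpi_hull` with `vertices` (row indices of `pts`
#'   on the hull), `faces` (m x 3 index matrix, outward wound), `volume`
#'   (cubic Angstrom), `area`, and the inputs needed for containment tests.
#' @export
convex_hull_3d <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) abort("convex_hull_3d expects 3 columns")
  orig_idx <- seq_len(nrow(pts))
  dup <- duplicated(round(pts, 12))
  upts <- pts[!dup, , drop = FALSE]
  uidx <- orig_idx[!dup]
  n <- nrow(upts)
  if (n < 4) abort("coplanar or degenerate point set: need >= 4 distinct points")
  scale <- max(apply(upts, 2, function(v) diff(range(v))), 1)
  eps <- tol * scale

  # initial simplex: farthest pair among axis extremes, then farthest from
  # the line, then farthest from the plane
  ext <- unique(c(apply(upts, 2, which.min), apply(upts, 2, which.max)))
  d2 <- cross_dist2(upts[ext, , drop = FALSE], upts[ext, , drop = FALSE])
  ij <- arrayInd(which.max(d2), dim(d2))
  i1 <- ext[ij[1]]; i2 <- ext[ij[2]]
  if (sqrt(max(d2)) <= eps) abort("coplanar or degenerate point set")
  ab <- upts[i2, ] - upts[i1, ]
  rel <- sweep(upts, 2, upts[i1, ])
  cr <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
    rel[, 3] * ab[1] - rel[, 1] * ab[3],
    rel[, 1] * ab[2] - rel[, 2] * ab[1])
  line_d <- sqrt(rowSums(cr^2)) / sqrt(sum(ab^2))
  i3 <- which.max(line_d)
  if (line_d[i3] <= eps) abort("coplanar or degenerate point set: collinear")
  nrm <- cross3(upts[i2, ] - upts[i1, ], upts[i3, ] - upts[i1, ])
  plane_d <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(plane_d)
  if (plane_d[i4] <= eps) abort("coplanar or degenerate point set: coplanar")

  interior <- colMeans(upts[c(i1, i2, i3, i4), , drop = FALSE])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, pts = upts, interior = interior))

  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    q <- upts[p, ]
    vis <- face_visible(faces, upts, q, eps)
    if (!any(vis)) next
    horizon <- horizon_edges(faces[vis, , drop = FALSE])
    faces <- faces[!vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient_face, pts = upts, interior = interior))
    faces <- rbind(faces, newf)
  }

  verts <- sort(unique(as.vector(faces)))
  vol <- hull_volume_faces(faces, upts, interior)
  area <- sum(apply(faces, 1, function(f) {
    0.5 * sqrt(sum(cross3(upts[f[2], ] - upts[f[1], ],
      upts[f[3], ] - upts[f[1], ])^2))
  }))
  structure(list(
    vertices = uidx[verts], faces = faces, points = upts,
    volume = vol, area = area, interior = interior, eps = eps
  ), class = "rpi_hull")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orient_face <- function(f, pts, interior) {
  nrm <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(nrm * (interior - pts[f[1], ])) > 0) f <- f[c(1, 3, 2)]
  f
}

face_visible <- function(faces, pts, q, eps) {
  apply(faces, 1, function(f) {
    nrm <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nn <- sqrt(sum(nrm^2))
    if (nn == 0) return(FALSE)
    sum(nrm / nn * (q - pts[f[1], ])) > eps
  })
}

# boundary of the visible region: edges used exactly once among visible faces
horizon_edges <- function(vis_faces) {
  e <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)], vis_faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

hull_volume_faces <- function(faces, pts, interior) {
  s <- apply(faces, 1, function(f) {
    a <- pts[f[1], ] - interior
    b <- pts[f[2], ] - interior
    cc <- pts[f[3], ] - interior
    sum(a * cross3(b, cc)) / 6
  })
  abs(sum(s))
}

#' Test points for convex-hull membership
#'
#' Points on a facet count as inside (within the hull's construction
#' tolerance).
#'
#' @param hull An `rpi_hull` from [convex_hull_3d()].
#' @param query Numeric matrix/data frame of points (3 columns).
#' @return Logical vector, one element per query point.
#' @export
in_hull <- function(hull, query) {
  query <- as.matrix(query)
  storage.mode(query) <- "double"
  pts <- hull$points
  inside <- rep(TRUE, nrow(query))
  for (r in seq_len(nrow(hull$faces))) {
    f <- hull$faces[r, ]
    nrm <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nrm <- nrm / sqrt(sum(nrm^2))
    d <- sweep(query, 2, pts[f[1], ]) %*% nrm
    inside <- inside & (d <= hull$eps)
    if (!any(inside)) break
  }
  as.vector(inside)
}
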