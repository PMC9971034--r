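# 2-D polygon / rigid-transform primitives shared by the voxeliser, the
# contour builder and the implant CAD operations.  Polygons are n x 2
# matrices of (x, y) in mm, open storage (last vertex != first), implicitly
# closed.

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a right-handed (x, y)
#' frame.
#'
#' @param xy n x 2 matrix of vertices, implicitly closed.
#' @return Signed area in squared input units.
#' @keywords internal
polygon_signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_signed_area
#' @return Non-negative area.
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' Length of a polyline
#' @param xy n x d matrix of points.
#' @param closed Treat the last-to-first segment as part of the line?
#' @return Summed Euclidean segment length.
#' @export
polyline_length <- function(xy, closed = TRUE) {
  n <- nrow(xy)
  if (n < 2) return(0)
  idx <- if (closed) c(2:n, 1) else 2:n
  base <- if (closed) 1:n else 1:(n - 1)
  sum(sqrt(rowSums((xy[idx, , drop = FALSE] - xy[base, , drop = FALSE])^2)))
}

#' Ensure counter-clockwise vertex order
#' @keywords internal
polygon_ccw <- function(xy) {
  if (polygon_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Clip a polygon against a half-plane (Sutherland-Hodgman)
#'
#' Keeps the region where `(p - point) . normal <= 0`.
#'
#' @param xy n x 2 polygon.
#' @param point,normal Point on the line and outward normal of the removed
#'   side (length-2).
#' @return Clipped polygon (possibly 0 rows).
#' @keywords internal
clip_polygon_halfplane <- function(xy, point, normal) {
  n <- nrow(xy)
  if (n == 0) return(xy)
  d <- as.numeric((xy[, 1] - point[1]) * normal[1] +
                  (xy[, 2] - point[2]) * normal[2])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, xy[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, xy[i, ] + t * (xy[j, ] - xy[i, ]))
    }
  }
  out
}

#' Rasterise closed loops into a binary pixel mask (even-odd rule)
#'
#' Pixel (r, c), 1-based, has world centre
#' `(x = x0 + (c-1) * sp[2], y = y0 + (r-1) * sp[1])` following the
#' package-wide convention that pixel index 0 sits at the frame origin.
#'
#' @param loops List of n x 2 (x, y) polygons in mm.
#' @param nrow,ncol Mask dimensions.
#' @param origin `(x0, y0)` of pixel (1, 1).
#' @param spacing `(row, col)` pixel spacing in mm.
#' @return Integer matrix in \{0, 1\}.
#' @keywords internal
rasterize_loops <- function(loops, nrow, ncol, origin, spacing) {
  mask <- matrix(0L, nrow, ncol)
  loops <- Filter(function(l) !is.null(l) && nrow(l) >= 3, loops)
  if (!length(loops)) return(mask)
  for (r in seq_len(nrow)) {
    y <- origin[2] + (r - 1) * spacing[1]
    cross <- numeric(0)
    for (l in loops) {
      n <- nrow(l)
      j <- c(2:n, 1)
      y1 <- l[, 2]; y2 <- l[j, 2]
      hit <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
      if (any(hit)) {
        t <- (y - y1[hit]) / (y2[hit] - y1[hit])
        cross <- c(cross, l[hit, 1] + t * (l[j, 1][hit] - l[hit, 1]))
      }
    }
    if (length(cross) >= 2) {
      cross <- sort(cross)
      for (k in seq(1, length(cross) - 1, by = 2)) {
        c1 <- ceiling((cross[k] - origin[1]) / spacing[2] - 1e-9) + 1L
        c2 <- floor((cross[k + 1] - origin[1]) / spacing[2] + 1e-9) + 1L
        if (c2 >= c1) {
          c1 <- max(1L, c1); c2 <- min(ncol, c2)
          if (c2 >= c1) mask[r, c1:c2] <- 1L
        }
      }
    }
  }
  mask
}

point_in_triangle <- function(p, a, b, c) {
  s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
  s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
  (s1 >= -1e-12 && s2 >= -1e-12 && s3 >= -1e-12)
}

#' Triangulate a simple polygon by ear clipping
#'
#' @param xy n x 2 simple polygon (any orientation).
#' @return m x 3 integer matrix of vertex indices into `xy` (CCW triangles).
#' @keywords internal
ear_clip <- function(xy) {
  n0 <- nrow(xy)
  if (n0 < 3) stop("polygon needs >= 3 vertices")
  rev_order <- polygon_signed_area(xy) < 0
  idx <- if (rev_order) rev(seq_len(n0)) else seq_len(n0)
  tris <- matrix(integer(0), 0, 3)
  guard <- 0L
  while (length(idx) > 3 && guard < 4L * n0 * n0) {
    n <- length(idx)
    clipped <- FALSE
    for (i in seq_len(n)) {
      ip <- idx[if (i == 1) n else i - 1]
      ic <- idx[i]
      iq <- idx[if (i == n) 1 else i + 1]
      a <- xy[ip, ]; b <- xy[ic, ]; c <- xy[iq, ]
      cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (cr <= 1e-12) next  # reflex or degenerate
      others <- setdiff(idx, c(ip, ic, iq))
      inside <- FALSE
      for (o in others) {
        if (point_in_triangle(xy[o, ], a, b, c)) { inside <- TRUE; break }
      }
      if (!inside) {
        tris <- rbind(tris, c(ip, ic, iq))
        idx <- idx[-i]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) {  # numerically stuck: clip the most convex corner anyway
      best <- 1L; bestcr <- -Inf
      n <- length(idx)
      for (i in seq_len(n)) {
        ip <- idx[if (i == 1) n else i - 1]; ic <- idx[i]
        iq <- idx[if (i == n) 1 else i + 1]
        a <- xy[ip, ]; b <- xy[ic, ]; c <- xy[iq, ]
        cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
        if (cr > bestcr) { bestcr <- cr; best <- i }
      }
      i <- best; n <- length(idx)
      ip <- idx[if (i == 1) n else i - 1]; ic <- idx[i]
      iq <- idx[if (i == n) 1 else i + 1]
      tris <- rbind(tris, c(ip, ic, iq))
      idx <- idx[-i]
    }
    guard <- guard + 1L
  }
  if (length(idx) == 3) tris <- rbind(tris, idx)
  tris
}

#' Triangulate an annular region (outer polygon minus one hole)
#'
#' Bridges the hole to the outer boundary at the nearest vertex pair and
#' ear-clips the resulting simple polygon.  Suitable for the convex-ish
#' profiles arising here; not a general CDT.
#'
#' @param outer,hole n x 2 polygons; hole strictly inside outer.
#' @return List with `vertices` (stacked outer then hole) and `faces`.
#' @keywords internal
triangulate_with_hole <- function(outer, hole) {
  outer <- polygon_ccw(outer)
  hole <- polygon_ccw(hole)
  hole <- hole[rev(seq_len(nrow(hole))), , drop = FALSE]  # CW hole
  no <- nrow(outer); nh <- nrow(hole)
  # nearest bridge pair
  d2 <- outer[rep(seq_len(no), each = nh), , drop = FALSE] -
    hole[rep(seq_len(nh), no), , drop = FALSE]
  dd <- rowSums(d2^2)
  k <- which.min(dd)
  oi <- ((k - 1) %/% nh) + 1
  hi <- ((k - 1) %% nh) + 1
  verts <- rbind(outer, hole)
  ring <- c(seq(oi, no), seq_len(oi),            # outer, back to bridge vertex
            no + c(seq(hi, nh), seq_len(hi)))    # hole loop and back
  poly <- verts[ring, , drop = FALSE]
  tris_local <- ear_clip(poly)
  faces <- matrix(ring[tris_local], ncol = 3)
  list(vertices = verts, faces = faces)
}

#' Least-squares rigid transform between paired point sets (Kabsch)
#'
#' Finds proper rotation `R` and translation `t` minimising
#' `sum ||R a_i + t - b_i||^2`.
#'
#' @param A,B n x d matrices of paired points (d = 2 or 3).
#' @return List with `rotation` (d x d, det +1) and `translation` (length d).
#' @export
kabsch <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  d <- ncol(A)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  D <- diag(d)
  D[d, d] <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, translation = as.numeric(cb - R %*% ca))
}

#' Construct a rigid transform object
#'
#' @param rotation d x d proper orthogonal matrix.
#' @param translation Length-d numeric.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper orthogonal (det = 1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf `rigid_transform`.
#' @param x n x d matrix.
#' @return Transformed n x d matrix.
#' @export
apply_rigid <- function(tf, x) {
  sweep(x %*% t(tf$rotation), 2, -tf$translation)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Compose rigid transforms (`a` after `b`)
#' @keywords internal
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrices about coordinate axes
#' @param theta Angle in radians.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
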