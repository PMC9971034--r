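# Triangle-mesh container and geometry kernels.  Meshes are stored as
# `vertices` (n x 3 mm, canonical frame: x = medial-lateral,
# y = anterior-posterior, z = scan axis increasing tibia -> femur) and
# `faces` (m x 3, 1-based, outward CCW orientation).  `parts` optionally
# tags faces belonging to separate watertight solids of one component
# (e.g. fixation pins).

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param parts Optional integer vector (length m) tagging faces by
#'   connected solid; defaults to 1.
#' @return Object of class `ak_mesh`.
#' @export
mesh <- function(vertices, faces, parts = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (is.null(parts)) parts <- rep(1L, nrow(faces))
  structure(list(vertices = vertices, faces = faces,
                 parts = as.integer(parts)), class = "ak_mesh")
}

#' @export
print.ak_mesh <- function(x, ...) {
  cat(sprintf("ak_mesh: %d vertices, %d faces, %d part(s)\n",
              nrow(x$vertices), nrow(x$faces), length(unique(x$parts))))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented faces.
#'
#' @param m `ak_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(m) {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  sum(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz) / 6
}

#' Per-face areas
#' @keywords internal
mesh_face_areas <- function(m) {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  e1 <- m$vertices[m$faces[, 2], , drop = FALSE] - v1
  e2 <- m$vertices[m$faces[, 3], , drop = FALSE] - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Apply a rigid transform to a mesh
#' @param m `ak_mesh`.
#' @param tf `rigid_transform`.
#' @return Transformed mesh (same topology).
#' @export
transform_mesh <- function(m, tf) {
  m$vertices <- apply_rigid(tf, m$vertices)
  m
}

#' Uniformly scale a mesh about a centre
#' @param m `ak_mesh`.
#' @param s Scale factor.
#' @param centre Length-3 centre of scaling (default origin).
#' @return Scaled mesh.
#' @export
scale_mesh <- function(m, s, centre = c(0, 0, 0)) {
  m$vertices <- sweep(sweep(m$vertices, 2, centre) * s, 2, -centre)
  m
}

#' Build a capped tube mesh from ordered vertex rings
#'
#' Rings are stacked along the scan axis; each ring is an `n_a x 3` matrix
#' ordered counter-clockwise viewed from +z.  Flat caps (fans around the
#' ring centroid) close both ends; faces are oriented outward.
#'
#' @param rings List of n_a x 3 matrices, in increasing z order.
#' @return Watertight `ak_mesh`.  Cap-centre vertices are the last two.
#' @export
tube_mesh <- function(rings) {
  n_r <- length(rings)
  n_a <- nrow(rings[[1]])
  stopifnot(n_r >= 2, n_a >= 3)
  V <- do.call(rbind, rings)
  bottom_c <- colMeans(rings[[1]])
  top_c <- colMeans(rings[[n_r]])
  V <- rbind(V, bottom_c, top_c)
  ib <- nrow(V) - 1L; it <- nrow(V)
  idx <- function(k, i) (k - 1L) * n_a + ((i - 1L) %% n_a) + 1L
  faces <- vector("list", 2L * (n_r - 1L) * n_a + 2L * n_a)
  f <- 0L
  for (k in seq_len(n_r - 1L)) {
    for (i in seq_len(n_a)) {
      a <- idx(k, i); b <- idx(k, i + 1L)
      c_ <- idx(k + 1L, i + 1L); d <- idx(k + 1L, i)
      f <- f + 1L; faces[[f]] <- c(a, b, c_)
      f <- f + 1L; faces[[f]] <- c(a, c_, d)
    }
  }
  for (i in seq_len(n_a)) {  # bottom cap, normal -z
    f <- f + 1L; faces[[f]] <- c(ib, idx(1L, i + 1L), idx(1L, i))
    f <- f + 1L; faces[[f]] <- c(it, idx(n_r, i), idx(n_r, i + 1L))
  }
  m <- mesh(V, do.call(rbind, faces))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Latitude-longitude sphere mesh
#'
#' Shares the tube topology (rings plus two cap centres at the poles), so
#' all spheres of equal resolution are in vertex correspondence.
#'
#' @param radius Sphere radius (mm).
#' @param n_lat,n_lon Number of latitude rings / vertices per ring.
#' @param centre Length-3 centre.
#' @return Watertight `ak_mesh`.
#' @export
uv_sphere <- function(radius = 1, n_lat = 16, n_lon = 24,
                      centre = c(0, 0, 0)) {
  phis <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  theta <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  rings <- lapply(phis, function(phi) {
    cbind(centre[1] + radius * cos(phi) * cos(theta),
          centre[2] + radius * cos(phi) * sin(theta),
          centre[3] + radius * sin(phi))
  })
  m <- tube_mesh(rings)
  # move cap centres to the true poles
  nv <- nrow(m$vertices)
  m$vertices[nv - 1L, ] <- centre + c(0, 0, -radius)
  m$vertices[nv, ] <- centre + c(0, 0, radius)
  m
}

#' Laplacian-smooth mesh vertices
#'
#' Uniform-weight umbrella operator applied `iters` times; damping
#' `lambda` in (0, 1].
#'
#' @param m `ak_mesh`.
#' @param iters Number of smoothing passes (0 = no-op).
#' @param lambda Step size toward the neighbourhood mean.
#' @return Smoothed mesh (same topology).
#' @export
laplacian_smooth <- function(m, iters = 0, lambda = 0.5) {
  if (iters <= 0) return(m)
  edges <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  V <- m$vertices
  deg <- tabulate(edges[, 1], nbins = nrow(V))
  for (it in seq_len(iters)) {
    nb <- rowsum(V[edges[, 2], , drop = FALSE], edges[, 1])
    mean_nb <- nb / deg
    V <- V + lambda * (mean_nb - V)
  }
  m$vertices <- V
  m
}

# ---- plane slicing -------------------------------------------------------

# Chain unordered segments (p1, p2 rows) into closed loops by endpoint
# matching.  Returns a list of k x d matrices.
chain_segments <- function(seg_a, seg_b, digits = 6) {
  n <- nrow(seg_a)
  if (!n) return(list())
  key <- function(p) paste(round(p, digits), collapse = "|")
  ka <- apply(seg_a, 1, key); kb <- apply(seg_b, 1, key)
  # adjacency: endpoint key -> segment indices
  adj <- new.env(hash = TRUE, parent = emptyenv())
  addk <- function(k, i) assign(k, c(adj[[k]], i), envir = adj)
  for (i in seq_len(n)) { addk(ka[i], i); addk(kb[i], i) }
  used <- logical(n)
  loops <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(seg_a[start, ], seg_b[start, ])
    cur_key <- kb[start]
    first_key <- ka[start]
    repeat {
      cand <- adj[[cur_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      i <- cand[1]
      used[i] <- TRUE
      if (ka[i] == cur_key) { pts[[length(pts) + 1]] <- seg_b[i, ]; cur_key <- kb[i] }
      else { pts[[length(pts) + 1]] <- seg_a[i, ]; cur_key <- ka[i] }
      if (cur_key == first_key) break
    }
    loop <- do.call(rbind, pts)
    # drop duplicated closing point
    if (nrow(loop) > 1 &&
        isTRUE(all.equal(loop[1, ], loop[nrow(loop), ],
                         tolerance = 1e-9, check.attributes = FALSE)))
      loop <- loop[-nrow(loop), , drop = FALSE]
    if (nrow(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Intersect a mesh with a constant-z plane
#'
#' @param m `ak_mesh`.
#' @param z Plane height (mm).
#' @return List of closed loops, each an k x 2 matrix of (x, y) mm.
#' @export
slice_mesh_z <- function(m, z) {
  s <- m$vertices[, 3] - z
  if (any(abs(s) < 1e-9)) {       # nudge the plane off exact vertices
    z <- z + 1e-6
    s <- m$vertices[, 3] - z
  }
  f <- m$faces
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  crossing <- (pmax(s1, s2, s3) > 0) & (pmin(s1, s2, s3) < 0)
  if (!any(crossing)) return(list())
  f <- f[crossing, , drop = FALSE]
  seg_a <- matrix(0, nrow(f), 2); seg_b <- matrix(0, nrow(f), 2)
  edge_point <- function(i, j) {
    # canonical order so shared edges yield bit-identical points
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    pi_ <- m$vertices[i, ]; pj <- m$vertices[j, ]
    t <- (z - pi_[3]) / (pj[3] - pi_[3])
    pi_[1:2] + t * (pj[1:2] - pi_[1:2])
  }
  for (r in seq_len(nrow(f))) {
    vv <- f[r, ]
    sv <- s[vv]
    pos <- vv[sv > 0]; neg <- vv[sv < 0]
    if (length(pos) == 1) { lone <- pos; pair <- neg } else { lone <- neg; pair <- pos }
    seg_a[r, ] <- edge_point(lone, pair[1])
    seg_b[r, ] <- edge_point(lone, pair[2])
  }
  chain_segments(seg_a, seg_b)
}

#' Orthonormal basis completing a unit normal
#' @keywords internal
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v, n = n)
}

#' Intersect a mesh with an arbitrary plane
#'
#' @param m `ak_mesh`.
#' @param point,normal Plane origin and normal (mm).
#' @return List with `loops2d` (in-plane (u, v) coords), `loops3d`, and the
#'   `basis` used for projection.
#' @export
slice_mesh_plane <- function(m, point, normal) {
  b <- plane_basis(normal)
  Vl <- sweep(m$vertices, 2, point) %*% cbind(b$u, b$v, b$n)
  ml <- m; ml$vertices <- Vl
  loops <- slice_mesh_z(ml, 0)
  loops3d <- lapply(loops, function(l) {
    sweep(l[, 1, drop = FALSE] %*% t(b$u) + l[, 2, drop = FALSE] %*% t(b$v),
          2, -point)
  })
  list(loops2d = loops, loops3d = loops3d, basis = b)
}

#' Clip a watertight mesh by a plane, capping the cut
#'
#' Keeps the half-space `(p - point) . normal <= 0`; crossing triangles are
#' split and the cut rim is capped by triangle fans so the result is again
#' watertight.  Vertices exactly on the plane count as kept.
#'
#' @param m `ak_mesh`.
#' @param point,normal Plane origin and (removed-side) normal.
#' @param cap Close the cut with planar facets?
#' @return List with `mesh` (possibly 0 faces) and `rims`, the cut-rim
#'   loops as k x 3 matrices in mm.
#' @export
clip_mesh_plane <- function(m, point, normal, cap = TRUE) {
  n_hat <- normal / sqrt(sum(normal^2))
  d <- as.numeric(sweep(m$vertices, 2, point) %*% n_hat)
  d[abs(d) < 1e-9] <- -1e-9          # on-plane vertices count as kept
  keep <- d <= 0
  V <- m$vertices
  newV <- list()
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  cut_point <- function(i, j) {
    k <- if (i < j) paste(i, j) else paste(j, i)
    hit <- edge_cache[[k]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    newV[[length(newV) + 1]] <<- p
    id <- nrow(V) + length(newV)
    assign(k, id, envir = edge_cache)
    id
  }
  out_faces <- list(); out_parts <- integer(0)
  rim_a <- list(); rim_b <- list()
  for (r in seq_len(nrow(m$faces))) {
    f <- m$faces[r, ]; pt <- m$parts[r]
    k <- keep[f]
    nk <- sum(k)
    if (nk == 3L) {
      out_faces[[length(out_faces) + 1]] <- f; out_parts <- c(out_parts, pt)
    } else if (nk == 1L) {
      a <- f[k]
      # rotate so orientation a -> b -> c preserved
      ia <- which(k)
      b_ <- f[(ia %% 3) + 1]; c_ <- f[((ia + 1) %% 3) + 1]
      iab <- cut_point(a, b_); iac <- cut_point(a, c_)
      out_faces[[length(out_faces) + 1]] <- c(a, iab, iac)
      out_parts <- c(out_parts, pt)
      rim_a[[length(rim_a) + 1]] <- iab; rim_b[[length(rim_b) + 1]] <- iac
    } else if (nk == 2L) {
      ia <- which(!k)
      c_ <- f[ia]                       # dropped vertex
      a <- f[(ia %% 3) + 1]; b_ <- f[((ia + 1) %% 3) + 1]
      ibc <- cut_point(b_, c_); ica <- cut_point(c_, a)
      out_faces[[length(out_faces) + 1]] <- c(a, b_, ibc)
      out_faces[[length(out_faces) + 1]] <- c(a, ibc, ica)
      out_parts <- c(out_parts, pt, pt)
      rim_a[[length(rim_a) + 1]] <- ibc; rim_b[[length(rim_b) + 1]] <- ica
    }
  }
  if (!length(out_faces))
    return(list(mesh = mesh(matrix(numeric(0), 0, 3),
                            matrix(integer(0), 0, 3)), rims = list()))
  Vall <- rbind(V, do.call(rbind, newV))
  faces <- do.call(rbind, out_faces)
  rims <- list()
  if (length(rim_a)) {
    sa <- Vall[unlist(rim_a), , drop = FALSE]
    sb <- Vall[unlist(rim_b), , drop = FALSE]
    rims <- chain_segments(sa, sb)
    if (cap && length(rims)) {
      bas <- plane_basis(n_hat)
      for (loop in rims) {
        lu <- sweep(loop, 2, point) %*% cbind(bas$u, bas$v)
        # orient CCW seen from +n so cap normals point along +n (outward)
        if (polygon_signed_area(lu) < 0) loop <- loop[rev(seq_len(nrow(loop))), ]
        ctr <- colMeans(loop)
        base_id <- nrow(Vall)
        Vall <- rbind(Vall, ctr, loop)
        nl <- nrow(loop)
        ctr_id <- base_id + 1L
        ring_ids <- base_id + 1L + seq_len(nl)
        cap_faces <- cbind(ctr_id, ring_ids, ring_ids[c(2:nl, 1)])
        faces <- rbind(faces, cap_faces)
        out_parts <- c(out_parts, rep(1L, nl))
      }
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(Vall)); remap[used] <- seq_along(used)
  res <- mesh(Vall[used, , drop = FALSE],
              matrix(remap[as.integer(faces)], ncol = 3), out_parts)
  rims <- lapply(rims, function(l) l)
  list(mesh = res, rims = rims)
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted triangle choice with uniform barycentric coordinates.
#'
#' @param m `ak_mesh`.
#' @param n Number of samples.
#' @param faces_subset Optional face indices restricting the sampled region.
#' @return n x 3 matrix of surface points.
#' @export
sample_mesh_points <- function(m, n, faces_subset = NULL) {
  f <- if (is.null(faces_subset)) seq_len(nrow(m$faces)) else faces_subset
  areas <- mesh_face_areas(m)[f]
  pick <- sample(f, n, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  a <- m$vertices[m$faces[pick, 1], , drop = FALSE]
  b <- m$vertices[m$faces[pick, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[pick, 3], , drop = FALSE]
  (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
}

#' Faces whose centroid lies within a z band
#' @param m `ak_mesh`.
#' @param zmin,zmax Band limits in mm.
#' @return Integer face indices.
#' @export
faces_in_z_band <- function(m, zmin, zmax) {
  cz <- (m$vertices[m$faces[, 1], 3] + m$vertices[m$faces[, 2], 3] +
           m$vertices[m$faces[, 3], 3]) / 3
  which(cz >= zmin & cz <= zmax)
}

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle queries over all faces (compiled).
#'
#' @param points n x 3 query points.
#' @param m `ak_mesh`.
#' @param faces_subset Optional face indices restricting the target surface.
#' @return List with `distance`, `point` (n x 3 foot points), `face`
#'   (index into the *subset*-restricted face list mapped back to `m`),
#'   and `bary` (barycentric coordinates).
#' @export
closest_point_mesh <- function(points, m, faces_subset = NULL) {
  faces <- m$faces
  map <- seq_len(nrow(faces))
  if (!is.null(faces_subset)) {
    faces <- faces[faces_subset, , drop = FALSE]
    map <- faces_subset
  }
  res <- cpp_closest_point_mesh(as.matrix(points), m$vertices, faces)
  res$face <- map[res$face]
  res
}

# ---- text-based mesh I/O -------------------------------------------------

#' Write a mesh as ASCII PLY
#' @param m `ak_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(m$vertices, 1, function(v) paste(v, collapse = " ")), con)
  writeLines(apply(m$faces - 1L, 1,
                   function(f) paste(c(3L, f), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file written by [write_ply()] (or any ascii PLY with
#'   x/y/z vertex properties and triangular faces).
#' @return `ak_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(end + 1):(end + nv)]
  fl <- lines[(end + nv + 1):(end + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(vl, " +"),
                             function(x) as.numeric(x[1:3])))
  F_ <- do.call(rbind, lapply(strsplit(fl, " +"),
                              function(x) as.integer(x[2:4]) + 1L))
  mesh(V, F_)
}

#' Write a mesh as ASCII STL
#' @param m `ak_mesh`.
#' @param path Output file.
#' @param name Solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(m, path, name = "autoknee") {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(m$faces))) {
    writeLines(c(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", v1[i, 1], v1[i, 2], v1[i, 3]),
                 sprintf("    vertex %g %g %g", v2[i, 1], v2[i, 2], v2[i, 3]),
                 sprintf("    vertex %g %g %g", v3[i, 1], v3[i, 2], v3[i, 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
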