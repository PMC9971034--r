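# Statistical shape models over corresponded bone meshes, rigid ICP, and
# limited-mode morphing of the base shape onto a contour stack.
#
# Vertex layout convention: a mesh with V vertices flattens to a length-3V
# vector column-major (all x, then all y, then all z); the component
# matrix rows live in that space.

flatten_vertices <- function(V) as.numeric(V)
unflatten_vertices <- function(v) matrix(v, ncol = 3)

#' Fit a statistical shape model to a corresponded mesh population
#'
#' Generalised Procrustes alignment (rigid — rotations and translations
#' only, no scaling, so absolute size is carried by the modes) followed by
#' principal-component analysis of the aligned vertex coordinates.  The
#' mean mesh may be Laplacian-smoothed to give an idealised base shape for
#' implant design; the component basis is always computed from the
#' unsmoothed coordinates.
#'
#' @param meshes List of >= 2 `ak_mesh` objects with identical topology.
#' @param smooth_iters Laplacian smoothing passes applied to the base
#'   shape (0 = none).
#' @param gpa_iters Procrustes alignment sweeps.
#' @return Object of class `shape_model`: `mean_vertices`, `faces`,
#'   `components` (modes x 3V, orthonormal rows), `variances`
#'   (non-increasing), `n_modes`, `weights` (training-mesh scores).
#' @export
shape_model <- function(meshes, smooth_iters = 0, gpa_iters = 5) {
  if (length(meshes) < 2) stop("need >= 2 meshes")
  faces <- meshes[[1]]$faces
  for (m in meshes) {
    if (!identical(dim(m$vertices), dim(meshes[[1]]$vertices)) ||
        !identical(m$faces, faces))
      stop("topology mismatch: meshes are not in correspondence")
  }
  Vs <- lapply(meshes, function(m) {
    sweep(m$vertices, 2, colMeans(m$vertices))
  })
  ref <- Vs[[1]]
  for (it in seq_len(gpa_iters)) {
    Vs <- lapply(Vs, function(V) {
      k <- kabsch(V, ref)
      apply_rigid(rigid_transform(k$rotation, k$translation), V)
    })
    ref <- Reduce(`+`, Vs) / length(Vs)
  }
  X <- do.call(rbind, lapply(Vs, flatten_vertices))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  n_modes <- max(1L, length(meshes) - 1L)
  comps <- t(sv$v[, seq_len(n_modes), drop = FALSE])
  vars <- sv$d[seq_len(n_modes)]^2 / (length(meshes) - 1)
  mean_mesh <- mesh(unflatten_vertices(mu), faces)
  base <- laplacian_smooth(mean_mesh, smooth_iters)
  structure(list(mean_vertices = mean_mesh$vertices,
                 base_vertices = base$vertices,
                 faces = faces,
                 components = comps,
                 variances = vars,
                 n_modes = n_modes,
                 smooth_iters = smooth_iters,
                 weights = Xc %*% t(comps),
                 n_training = length(meshes)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d training meshes, %d vertices, %d modes\n",
              x$n_training, nrow(x$mean_vertices), x$n_modes))
  pv <- x$variances / sum(x$variances)
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * pv[seq_len(min(5, length(pv)))]),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  pv <- object$variances / sum(object$variances)
  out <- data.frame(mode = seq_len(object$n_modes),
                    sd = sqrt(object$variances),
                    var_fraction = pv,
                    cum_var = cumsum(pv))
  class(out) <- c("summary.shape_model", "data.frame")
  out
}

#' Synthesize a mesh from shape-model mode weights
#'
#' Mean (idealised base) shape plus the weighted sum of the principal
#' modes.
#'
#' @param model `shape_model`.
#' @param weights Numeric, length <= `n_modes` (missing modes are 0).
#' @param use_base Use the smoothed base shape (default) rather than the
#'   raw mean.
#' @return `ak_mesh`.
#' @export
synthesize <- function(model, weights = numeric(0), use_base = TRUE) {
  if (length(weights) > model$n_modes)
    stop("more weights than available modes")
  V0 <- if (use_base) model$base_vertices else model$mean_vertices
  v <- flatten_vertices(V0)
  if (length(weights))
    v <- v + as.numeric(t(model$components[seq_along(weights), ,
                                           drop = FALSE]) %*% weights)
  mesh(unflatten_vertices(v), model$faces)
}

#' @export
predict.shape_model <- function(object, weights = numeric(0), ...) {
  synthesize(object, weights)
}

#' Rigid iterative-closest-point registration of points onto a mesh
#'
#' Alternates closest-point correspondence on the target surface with a
#' least-squares rigid (Kabsch) solve until the RMS closest-point distance
#' stops improving.  The recorded RMS history is non-increasing and the
#' best transform found is returned.
#'
#' @param source_points n x 3 matrix (n >= 3, non-collinear).
#' @param target `ak_mesh` target surface.
#' @param max_iters Iteration cap.
#' @param tol_mm Stop when RMS improvement falls below this.
#' @param init Optional initial `rigid_transform`.
#' @return `rigid_transform` with attributes `rms` (final RMS distance,
#'   mm) and `history` (per-iteration RMS).
#' @export
rigid_icp <- function(source_points, target, max_iters = 60,
                      tol_mm = 1e-8, init = NULL) {
  P0 <- as.matrix(source_points)
  if (nrow(P0) < 3) stop("degenerate source: need >= 3 points")
  sv <- svd(sweep(P0, 2, colMeans(P0)))$d
  if (sv[2] < 1e-9) stop("degenerate source: points are collinear")
  # target face normals for the point-to-plane step
  v1 <- target$vertices[target$faces[, 1], , drop = FALSE]
  e1 <- target$vertices[target$faces[, 2], , drop = FALSE] - v1
  e2 <- target$vertices[target$faces[, 3], , drop = FALSE] - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-300)
  rodrigues <- function(w) {
    a <- sqrt(sum(w^2))
    if (a < 1e-14) return(diag(3))
    u <- w / a
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  }
  tf <- init %||% rigid_transform()
  P <- apply_rigid(tf, P0)
  cp <- closest_point_mesh(P, target)
  best <- tf
  best_rms <- sqrt(mean(cp$distance^2))
  history <- best_rms
  for (it in seq_len(max_iters)) {
    # point-to-plane step (linearised rotation), falling back to a
    # point-to-point Kabsch step when it does not reduce the RMS
    n <- fn[cp$face, , drop = FALSE]
    cxn <- cbind(P[, 2] * n[, 3] - P[, 3] * n[, 2],
                 P[, 3] * n[, 1] - P[, 1] * n[, 3],
                 P[, 1] * n[, 2] - P[, 2] * n[, 1])
    A <- cbind(cxn, n)
    b <- rowSums(n * (cp$point - P))
    sol <- tryCatch(qr.solve(A, b), error = function(e) rep(0, 6))
    step_pl <- rigid_transform(rodrigues(sol[1:3]), sol[4:6])
    cand <- compose_rigid(step_pl, tf)
    P_c <- apply_rigid(cand, P0)
    cp_c <- closest_point_mesh(P_c, target)
    rms_c <- sqrt(mean(cp_c$distance^2))
    if (!is.finite(rms_c) || rms_c >= best_rms) {
      k <- kabsch(P, cp$point)
      cand <- compose_rigid(rigid_transform(k$rotation, k$translation), tf)
      P_c <- apply_rigid(cand, P0)
      cp_c <- closest_point_mesh(P_c, target)
      rms_c <- sqrt(mean(cp_c$distance^2))
    }
    if (!is.finite(rms_c) || rms_c >= best_rms - tol_mm) {
      if (is.finite(rms_c) && rms_c < best_rms) {
        best <- cand; best_rms <- rms_c
        history <- c(history, rms_c)
      }
      break
    }
    tf <- cand; P <- P_c; cp <- cp_c
    best <- cand; best_rms <- rms_c
    history <- c(history, rms_c)
  }
  attr(best, "rms") <- best_rms
  attr(best, "history") <- history
  best
}

#' Align a contour stack to a shape-model base shape
#'
#' Coarse initialisation matches the stack to the base shape by centroid
#' translation in-plane and by the anatomically informative end along the
#' scan axis (the femoral stack starts at the condyle end, the tibial
#' stack ends at the plateau), keeping z as the slice normal; rigid ICP
#' refines.
#'
#' @param stack `contour_stack`.
#' @param model `shape_model` for the same bone.
#' @param max_points Deterministic subsample size used for the ICP solve
#'   (the returned points are the full transformed stack).
#' @return List with `points` (transformed n x 3), `transform`
#'   (`rigid_transform`) and `rms` (mm).
#' @export
align_stack_to_base <- function(stack, model, max_points = 600) {
  pts <- stack_points(stack)
  if (is.null(pts) || !nrow(pts)) stop("empty stack")
  base <- mesh(model$base_vertices, model$faces)
  bz <- range(base$vertices[, 3])
  t_xy <- colMeans(base$vertices[, 1:2]) - colMeans(pts[, 1:2, drop = FALSE])
  t_z <- if (identical(stack$bone, "tibia"))
    bz[2] - max(pts[, 3]) - stack$slice_spacing
  else
    bz[1] - min(pts[, 3]) + stack$slice_spacing
  init <- rigid_transform(diag(3), c(t_xy, t_z))
  sub <- pts[unique(round(seq(1, nrow(pts),
                              length.out = min(max_points, nrow(pts))))), ,
             drop = FALSE]
  tf <- rigid_icp(sub, base, init = init)
  list(points = apply_rigid(tf, pts), transform = tf,
       rms = attr(tf, "rms"))
}

#' Morph a shape model to fit an aligned contour stack
#'
#' Minimises the mean squared closest-point distance from the stack
#' points to the synthesized surface over the first `n_pc` mode weights,
#' alternating an exact linear weight solve (through the closest-point
#' barycentric correspondences) with correspondence updates; weights are
#' bounded within +/- 3 sd per mode to prevent extrapolation blow-up.
#'
#' @param model `shape_model`.
#' @param stack_pts n x 3 matrix of aligned stack points (or a
#'   `contour_stack`, taken as already aligned).
#' @param n_pc Number of principal components morphed (default 2).
#' @param max_outer Outer iteration cap.
#' @param tol Relative objective-improvement stopping tolerance.
#' @param max_points Deterministic subsample size for the optimisation.
#' @return `ak_mesh` prediction with attributes `weights`, `objective`
#'   (per-iteration mean squared distance, non-increasing), `rms`, and
#'   `converged`.
#' @export
morph_to_stack <- function(model, stack_pts, n_pc = 2, max_outer = 25,
                           tol = 1e-4, max_points = 900) {
  if (inherits(stack_pts, "contour_stack"))
    stack_pts <- stack_points(stack_pts)
  stack_pts <- as.matrix(stack_pts)
  if (nrow(stack_pts) > max_points)
    stack_pts <- stack_pts[unique(round(seq(1, nrow(stack_pts),
                                            length.out = max_points))), ,
                           drop = FALSE]
  if (n_pc > model$n_modes) stop("n_pc exceeds available modes")
  if (n_pc == 0) {
    out <- synthesize(model)
    attr(out, "weights") <- numeric(0)
    cp <- closest_point_mesh(stack_pts, out)
    attr(out, "objective") <- mean(cp$distance^2)
    attr(out, "rms") <- sqrt(mean(cp$distance^2))
    attr(out, "converged") <- TRUE
    return(out)
  }
  Vn <- nrow(model$mean_vertices)
  sds <- sqrt(model$variances[seq_len(n_pc)])
  bounds <- 3 * sds
  # per-mode vertex displacement fields, V x 3 each
  fields <- lapply(seq_len(n_pc), function(k) {
    unflatten_vertices(model$components[k, ])
  })
  w <- numeric(n_pc)
  base_flat <- synthesize(model, use_base = TRUE)
  obj <- Inf
  history <- numeric(0)
  best_w <- w; best_obj <- Inf
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    cur <- synthesize(model, w)
    cp <- closest_point_mesh(stack_pts, cur)
    o <- mean(cp$distance^2)
    if (is.finite(obj) && o > obj) { converged <- TRUE; break }
    if (o < best_obj) { best_obj <- o; best_w <- w }
    history <- c(history, o)
    if (is.finite(obj) &&
        ((obj - o) < tol * max(obj, 1e-12) || o < 1e-10)) {
      converged <- TRUE
      break
    }
    obj <- o
    # linear solve for w through fixed barycentric correspondences;
    # correspondences far beyond the typical distance (residual
    # segmentation noise) are trimmed from the solve
    keep_i <- which(cp$distance <= 2.5 * stats::median(cp$distance) + 0.5)
    if (length(keep_i) < max(10, nrow(stack_pts) %/% 2))
      keep_i <- seq_len(nrow(stack_pts))
    fv <- model$faces[cp$face[keep_i], , drop = FALSE]
    bary <- cp$bary[keep_i, , drop = FALSE]
    interp <- function(M) {
      bary[, 1] * M[fv[, 1], , drop = FALSE] +
        bary[, 2] * M[fv[, 2], , drop = FALSE] +
        bary[, 3] * M[fv[, 3], , drop = FALSE]
    }
    b0 <- interp(base_flat$vertices)
    A <- vapply(fields, function(Fk) as.numeric(interp(Fk)),
                numeric(3 * length(keep_i)))
    rhs <- as.numeric(stack_pts[keep_i, , drop = FALSE] - b0)
    w_new <- tryCatch(qr.solve(A, rhs), error = function(e) w)
    w <- pmin(pmax(w_new, -bounds), bounds)
  }
  if (!converged)
    warning("morph_to_stack: iteration cap reached; returning best iterate")
  out <- synthesize(model, best_w)
  cp <- closest_point_mesh(stack_pts, out)
  attr(out, "weights") <- best_w
  attr(out, "objective") <- history
  attr(out, "rms") <- sqrt(mean(cp$distance^2))
  attr(out, "converged") <- converged
  out
}
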