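# Implant and prediction fit metrics: surface-to-surface RMSE over the
# fitted (condylar) region, maximum over/underhang as the directed
# Hausdorff distance between component edges and resected-bone edges, the
# 3 mm clinical flag, distance heatmaps and cohort statistics.

#' Root-mean-squared error of paired distances
#' @param distances Numeric vector of point distances (mm).
#' @return `sqrt(mean(d^2))`.
#' @export
rmse_mm <- function(distances) sqrt(mean(distances^2))

#' Surface-to-surface RMSE between two meshes
#'
#' Samples `n_samples` points on the prediction surface (optionally
#' restricted to a z band — the region covered by the contour stack,
#' i.e. the condylar region), optionally rigid-ICP aligns them to the
#' reference, and returns the RMSE of the closest-point distances.
#'
#' @param pred_surface,gt_surface `ak_mesh` surfaces.
#' @param region Optional `(zmin, zmax)` band on the prediction.
#' @param n_samples Surface sample count.
#' @param seed RNG seed for sampling (reported determinism).
#' @param align Rigid-ICP align before measuring (default TRUE).
#' @return RMSE in mm, with attribute `alignment` (`rigid_transform` or
#'   NULL).
#' @export
surface_rmse <- function(pred_surface, gt_surface, region = NULL,
                         n_samples = 2000, seed = NULL, align = TRUE) {
  if (!nrow(pred_surface$faces) || !nrow(gt_surface$faces))
    stop("empty surface")
  fs <- NULL
  if (!is.null(region)) {
    fs <- faces_in_z_band(pred_surface, region[1], region[2])
    if (!length(fs)) stop("empty region: no faces in the z band")
  }
  if (!is.null(seed)) set.seed(seed)
  pts <- sample_mesh_points(pred_surface, n_samples, faces_subset = fs)
  tf <- NULL
  if (align) {
    init <- rigid_transform(diag(3),
                            colMeans(gt_surface$vertices) - colMeans(pts))
    tf <- rigid_icp(pts, gt_surface, init = init)
    pts <- apply_rigid(tf, pts)
  }
  d <- closest_point_mesh(pts, gt_surface)$distance
  out <- rmse_mm(d)
  attr(out, "alignment") <- tf
  out
}

#' Maximum over/underhang (directed Hausdorff distance)
#'
#' `h(C, B) = max over c in C of min over b in B of |c - b|`, exact over
#' the given point sets: the farthest any component-edge point sits from
#' the resected-bone edge.
#'
#' @param C Component edge points (n x d matrix, d = 2 or 3).
#' @param B Resected-bone edge points (m x d).
#' @return Maximum OUH in mm.
#' @export
max_ouh <- function(C, B) {
  C <- as.matrix(C); B <- as.matrix(B)
  if (!nrow(C) || !nrow(B)) stop("empty edge set")
  if (!all(is.finite(C)) || !all(is.finite(B)))
    stop("edge sets must be finite")
  cpp_hausdorff_directed(C, B)
}

#' Clinical over/underhang flag
#'
#' Inclusive threshold: `h >= threshold` (default 3 mm) is flagged as
#' clinically significant.
#'
#' @param h_mm Maximum OUH (mm, >= 0).
#' @param threshold Flag threshold (default 3 mm).
#' @return Logical.
#' @export
ouh_flag <- function(h_mm, threshold = 3.0) {
  stopifnot(h_mm >= 0)
  h_mm >= threshold
}

resample_polygon <- function(poly, n = 400) {
  k <- nrow(poly)
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[k + 1]
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  idx <- findInterval(at, cum, rightmost.closed = TRUE)
  idx[idx > k] <- k
  t <- (at - cum[idx]) / pmax(seg[idx], 1e-12)
  closed[idx, , drop = FALSE] +
    t * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
}

align_profiles_2d <- function(C, B, iters = 30) {
  tf <- list(R = diag(2), t = colMeans(B) - colMeans(C))
  Ct <- sweep(C %*% t(tf$R), 2, -tf$t)
  for (i in seq_len(iters)) {
    nn <- apply(Ct, 1, function(p) which.min(colSums((t(B) - p)^2)))
    k <- kabsch(Ct, B[nn, , drop = FALSE])
    Ct <- sweep(Ct %*% t(k$rotation), 2, -k$translation)
    tf <- list(R = k$rotation %*% tf$R,
               t = as.numeric(k$rotation %*% tf$t) + k$translation)
    if (sum(abs(k$translation)) + sum(abs(k$rotation - diag(2))) < 1e-10)
      break
  }
  list(points = Ct, transform = tf)
}

#' Fit report for one component against ground truth
#'
#' Femur: the component surface (fixation pins excluded) is rigid-ICP
#' aligned to the ground-truth bone; RMSE is measured over the component
#' surface and maximum OUH between the component's cut-facet edges and
#' the equivalently resected ground-truth edges.  Tibia: the plate's 2-D
#' base profile is compared to the equivalent ground-truth profile taken
#' at the same section plane after rigid 2-D alignment.
#'
#' @param component `implant_component`.
#' @param gt_mesh Ground-truth bone `ak_mesh`.
#' @param threshold OUH flag threshold (mm, inclusive; default 3).
#' @param n_samples Surface samples (femur branch).
#' @param seed RNG seed for sampling.
#' @return `fit_report`: `rmse_mm`, `max_ouh_mm`, `ouh_flag`, `alignment`,
#'   `region`.
#' @export
component_fit <- function(component, gt_mesh, threshold = 3.0,
                          n_samples = 1500, seed = NULL) {
  stopifnot(inherits(component, "implant_component"))
  if (!is.null(seed)) set.seed(seed)
  # Bring the ground truth into the component's design frame first (whole
  # bone rigid ICP onto the source prediction): the resection geometry is
  # defined at fixed positions in that frame, which makes the whole
  # report invariant to rigid motion of the ground truth.
  pred_ref <- component$provenance$prediction
  if (!is.null(pred_ref)) {
    gpts <- sample_mesh_points(gt_mesh, 500)
    ginit <- rigid_transform(diag(3),
                             colMeans(pred_ref$vertices) -
                               colMeans(gt_mesh$vertices))
    gtf <- rigid_icp(gpts, pred_ref, init = ginit)
    gt_mesh <- transform_mesh(gt_mesh, gtf)
  }
  if (component$kind == "femur_component") {
    plan <- component$provenance$plan
    res <- resect_bone(gt_mesh, plan)
    body_faces <- which(component$mesh$parts == 1L)
    pts <- sample_mesh_points(component$mesh, n_samples,
                              faces_subset = body_faces)
    # align to the equivalently resected ground-truth piece: the matching
    # surface region, so the registration is well posed
    init <- rigid_transform(diag(3),
                            colMeans(res$mesh$vertices) - colMeans(pts))
    sub <- pts[unique(round(seq(1, nrow(pts), length.out = 500))), ,
               drop = FALSE]
    tf <- rigid_icp(sub, res$mesh, init = init)
    d <- closest_point_mesh(apply_rigid(tf, pts), res$mesh)$distance
    C <- apply_rigid(tf, do.call(rbind, component$provenance$edges))
    B <- do.call(rbind, res$edges)
    h <- max_ouh(C, B)
    report <- list(rmse_mm = rmse_mm(d), max_ouh_mm = h,
                   ouh_flag = ouh_flag(h, threshold), alignment = tf,
                   region = "femur_component", threshold = threshold)
  } else {
    prof_c <- component$provenance$cut_profile %||%
      component$provenance$profile
    res <- resect_bone(gt_mesh, component$provenance)
    # compare full base profile (before plate feature cuts) to gt section
    C <- resample_polygon(component$provenance$profile)
    B <- resample_polygon(res$polygon)
    al <- align_profiles_2d(C, B)
    d <- cpp_dist_to_polyline(al$points, res$polygon, TRUE)
    h <- max_ouh(al$points, B)
    report <- list(rmse_mm = rmse_mm(d), max_ouh_mm = h,
                   ouh_flag = ouh_flag(h, threshold), alignment = al$transform,
                   region = "tibia_profile", threshold = threshold)
  }
  structure(report, class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report (%s): RMSE %.3f mm, max OUH %.3f mm (%s %g mm)\n",
              x$region, x$rmse_mm, x$max_ouh_mm,
              if (x$ouh_flag) "FLAGGED at >=" else "below", x$threshold))
  invisible(x)
}

#' Distance heatmap figure between two surfaces
#'
#' Computes per-vertex closest-point distances from `surface` to
#' `reference` (inputs assumed aligned), renders a colour-coded scatter
#' (colour scale spanning 0 to the maximum distance) and writes the
#' per-vertex distance table alongside.
#'
#' @param surface,reference `ak_mesh` surfaces.
#' @param out_image PNG path.
#' @param out_table Optional CSV path for the per-vertex distances.
#' @return Numeric vector of per-vertex distances, invisibly.
#' @export
distance_heatmap <- function(surface, reference, out_image,
                             out_table = NULL) {
  d <- closest_point_mesh(surface$vertices, reference)$distance
  pal <- grDevices::colorRampPalette(c("navy", "cyan", "yellow", "red"))(64)
  dmax <- max(d, 1e-12)
  cols <- pal[pmin(64L, 1L + floor(d / dmax * 63.999))]
  grDevices::png(out_image, width = 800, height = 700)
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(surface$vertices[, 1], surface$vertices[, 3], col = cols,
                 pch = 16, cex = 0.6, asp = 1,
                 xlab = "medial-lateral x (mm)", ylab = "scan axis z (mm)",
                 main = sprintf("surface distance (max %.2f mm)", max(d)))
  graphics::legend("topright",
                   legend = sprintf("%.2f mm", seq(0, dmax, length.out = 5)),
                   fill = pal[c(1, 16, 32, 48, 64)], bty = "n")
  grDevices::dev.off()
  if (!is.null(out_table))
    utils::write.csv(data.frame(vertex = seq_along(d), distance_mm = d),
                     out_table, row.names = FALSE)
  invisible(d)
}

remove_outliers_iqr <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  x[x >= q[1] - k * iqr & x <= q[2] + k * iqr]
}

#' Cohort statistics over fit metrics
#'
#' For each metric column: Welch two-sample t-tests between the levels of
#' each binary grouping attribute (after 1.5 x IQR outlier removal per
#' group) and Spearman rank correlations against each continuous
#' covariate.  Significance at p <= 0.05 for t-tests and |r| >= 0.5 for
#' correlations.
#'
#' @param data Data frame of per-subject metrics and attributes.
#' @param metrics Metric column names.
#' @param groups Binary attribute column names (exactly 2 levels each).
#' @param covariates Continuous covariate column names.
#' @param p_threshold,r_threshold Significance thresholds.
#' @return Data frame: metric, comparison, type, estimate, p_value,
#'   significant (NA rows marked `"n/a"` in `note` when n is
#'   insufficient).
#' @export
cohort_stats <- function(data, metrics, groups = character(0),
                         covariates = character(0),
                         p_threshold = 0.05, r_threshold = 0.5) {
  rows <- list()
  push <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (m in metrics) {
    for (g in groups) {
      lv <- unique(stats::na.omit(data[[g]]))
      if (length(lv) != 2) {
        push(metric = m, comparison = g, type = "welch_t",
             estimate = NA_real_, p_value = NA_real_, significant = NA,
             note = "n/a")
        next
      }
      x <- remove_outliers_iqr(data[[m]][data[[g]] == lv[1]])
      y <- remove_outliers_iqr(data[[m]][data[[g]] == lv[2]])
      if (length(x) < 2 || length(y) < 2 ||
          (stats::sd(x) == 0 && stats::sd(y) == 0)) {
        p <- if (length(x) >= 1 && length(y) >= 1 &&
                 isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
        push(metric = m, comparison = g, type = "welch_t",
             estimate = mean(x) - mean(y), p_value = p,
             significant = if (is.na(p)) NA else p <= p_threshold,
             note = if (is.na(p)) "n/a" else "degenerate")
      } else {
        tt <- stats::t.test(x, y)
        push(metric = m, comparison = g, type = "welch_t",
             estimate = unname(diff(rev(tt$estimate))),
             p_value = tt$p.value,
             significant = tt$p.value <= p_threshold, note = "")
      }
    }
    for (cv in covariates) {
      ok <- stats::complete.cases(data[[m]], data[[cv]])
      if (sum(ok) < 3) {
        push(metric = m, comparison = cv, type = "spearman",
             estimate = NA_real_, p_value = NA_real_, significant = NA,
             note = "n/a")
      } else {
        r <- suppressWarnings(
          stats::cor.test(data[[m]][ok], data[[cv]][ok],
                          method = "spearman"))
        push(metric = m, comparison = cv, type = "spearman",
             estimate = unname(r$estimate), p_value = r$p.value,
             significant = abs(r$estimate) >= r_threshold, note = "")
      }
    }
  }
  do.call(rbind, rows)
}
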