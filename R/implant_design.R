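# Generic implant geometry from predicted bone surfaces.
#
# Femoral component: the solidified prediction is clipped by a five-plane
# cut family (anterior, anterior chamfer, distal, posterior chamfer,
# posterior) whose offsets scale with the subject's condylar AP/ML
# measurements; two cylindrical fixation pins are added on the bone-facing
# side.  Tibial plate: a 2-D cross-section taken 2 mm below the widest
# medial-condyle point on a plane parallel to the tibial plateau is
# extruded to 5 mm, with a bearing recess, a posterior cut and a central
# fixation pin.  All operations are deterministic; fillets/chamfer
# rounding is intentionally omitted (it does not move the evaluated
# surfaces or edges).

#' Condylar anterior-posterior and medial-lateral measurements
#'
#' Bounding-box extents of the condylar region (lowest `condylar_frac` of
#' the z extent) in the canonical frame (x medial-lateral, y
#' anterior-posterior).
#'
#' @param pred_mesh Femur prediction (`ak_mesh`, canonical frame).
#' @param condylar_frac Fraction of the z extent treated as condylar.
#' @return List: `AP`, `ML` (mm), `bbox` (2 x 3 range matrix of the
#'   condylar region) and `z_range` of the full mesh.
#' @export
measure_ap_ml <- function(pred_mesh, condylar_frac = 0.45) {
  V <- pred_mesh$vertices
  if (!nrow(V)) stop("empty mesh")
  zr <- range(V[, 3])
  cond <- V[V[, 3] <= zr[1] + condylar_frac * diff(zr), , drop = FALSE]
  bb <- apply(cond, 2, range)
  list(AP = bb[2, 2] - bb[1, 2], ML = bb[2, 1] - bb[1, 1],
       bbox = bb, z_range = zr)
}

#' Default femoral cut-plane template
#'
#' Plane offsets as fractions of the AP measurement (the five-plane
#' box-cut family); editable and shipped as plain data.  These fractions
#' are package defaults, not published values.
#'
#' @return Data frame with `name`, `frac` and plane orientation codes.
#' @export
femur_cut_template <- function() {
  data.frame(
    name = c("anterior", "anterior_chamfer", "distal",
             "posterior_chamfer", "posterior"),
    frac = c(0.10, 0.16, 0.30, 0.16, 0.10),
    stringsAsFactors = FALSE)
}

#' Plan the femoral cuts from AP/ML measurements
#'
#' Converts the relative template into absolute oriented planes
#' (point + unit normal, mm).  Every offset is a fraction of AP, so the
#' plan scales linearly with the subject.
#'
#' @param measures Output of [measure_ap_ml()].
#' @param template [femur_cut_template()]-style data frame.
#' @return `cut_plan`: ordered list of planes with `name`, `point`,
#'   `normal`.
#' @export
plan_femur_cuts <- function(measures, template = femur_cut_template()) {
  if (measures$AP <= 0 || measures$ML <= 0)
    stop("measures must be positive")
  bb <- measures$bbox
  AP <- measures$AP
  fr <- stats::setNames(template$frac, template$name)
  y_a <- bb[2, 2] - fr[["anterior"]] * AP      # keep y <= y_a
  y_p <- bb[1, 2] + fr[["posterior"]] * AP     # keep y >= y_p
  z_d <- bb[1, 3] + fr[["distal"]] * AP        # keep z <= z_d
  ch <- fr[["anterior_chamfer"]] * AP
  planes <- list(
    list(name = "anterior", point = c(0, y_a, 0), normal = c(0, 1, 0)),
    list(name = "anterior_chamfer",
         point = c(0, y_a - ch / 2, z_d - ch / 2),
         normal = c(0, 1, 1) / sqrt(2)),
    list(name = "distal", point = c(0, 0, z_d), normal = c(0, 0, 1)),
    list(name = "posterior_chamfer",
         point = c(0, y_p + ch / 2, z_d - ch / 2),
         normal = c(0, -1, 1) / sqrt(2)),
    list(name = "posterior", point = c(0, y_p, 0), normal = c(0, -1, 0)))
  structure(list(planes = planes, measures = list(AP = measures$AP,
                                                  ML = measures$ML)),
            class = "cut_plan")
}

#' @export
print.cut_plan <- function(x, ...) {
  cat(sprintf("cut_plan: %d planes (AP %.1f mm, ML %.1f mm)\n",
              length(x$planes), x$measures$AP, x$measures$ML))
  invisible(x)
}

clip_with_plan <- function(m, plan) {
  for (p in plan$planes) {
    res <- clip_mesh_plane(m, p$point, p$normal, cap = TRUE)
    m <- res$mesh
    if (!nrow(m$faces)) stop("degenerate cut plan: clipping emptied the mesh")
  }
  m
}

# outline loops of the cut facets: slice the clipped solid just inside
# each plane
component_edges <- function(clipped, plan, eps = 1e-3) {
  loops <- list()
  for (p in plan$planes) {
    sl <- slice_mesh_plane(clipped, p$point - eps * p$normal, p$normal)
    loops <- c(loops, sl$loops3d)
  }
  loops
}

cylinder_mesh <- function(centre_xy, z0, z1, radius, n_seg = 20) {
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring <- function(z) cbind(centre_xy[1] + radius * cos(theta),
                            centre_xy[2] + radius * sin(theta),
                            rep(z, n_seg))
  tube_mesh(list(ring(z0), ring(z1)))
}

merge_meshes <- function(a, b) {
  nv <- nrow(a$vertices)
  mesh(rbind(a$vertices, b$vertices),
       rbind(a$faces, b$faces + nv),
       c(a$parts, b$parts + max(a$parts)))
}

#' Design the generic femoral component
#'
#' Clips the solid prediction by the plan's five planes (capping each cut,
#' so the component stays watertight), then adds two cylindrical fixation
#' pins on the bone-facing (cut) side.  The component edges used by the
#' over/underhang metric are the outlines of the cut facets.
#'
#' @param pred_mesh Femur prediction (`ak_mesh`).
#' @param plan `cut_plan` from [plan_femur_cuts()].
#' @param shell_mm Bone-facing surface tolerance recorded with the
#'   component (mm).
#' @param pin_params List: `radius`, `length` (mm), `ml_frac` (pin offset
#'   as a fraction of ML).
#' @return `implant_component` (kind `"femur_component"`); pins are mesh
#'   parts 2 and 3 so metrics can exclude them.
#' @export
design_femur_component <- function(pred_mesh, plan, shell_mm = 1,
                                   pin_params = list(radius = 3, length = 10,
                                                     ml_frac = 0.22)) {
  body <- clip_with_plan(pred_mesh, plan)
  edges <- component_edges(body, plan)
  distal <- plan$planes[[which(vapply(plan$planes, `[[`, "", "name") ==
                                 "distal")]]
  z_d <- distal$point[3]
  ml <- plan$measures$ML
  ctr_x <- mean(range(body$vertices[, 1]))
  ctr_y <- mean(range(body$vertices[, 2]))
  out <- body
  for (sgn in c(-1, 1)) {
    pin <- cylinder_mesh(c(ctr_x + sgn * pin_params$ml_frac * ml, ctr_y),
                         z_d, z_d + pin_params$length, pin_params$radius)
    out <- merge_meshes(out, pin)
  }
  structure(list(mesh = out, kind = "femur_component",
                 provenance = list(plan = plan, shell_mm = shell_mm,
                                   pin_params = pin_params,
                                   edges = edges,
                                   prediction = pred_mesh)),
            class = "implant_component")
}

#' @export
print.implant_component <- function(x, ...) {
  cat(sprintf("implant_component (%s): %d faces, volume %.0f mm^3\n",
              x$kind, nrow(x$mesh$faces), mesh_volume(x$mesh)))
  invisible(x)
}

#' Fit the tibial plateau plane
#'
#' Least-squares plane through the proximal plateau facets (faces whose
#' outward normal points within 35 degrees of +z, restricted to the top
#' fifth of the z extent), oriented distally (normal z < 0, away from the
#' femur).
#'
#' @param pred_mesh Tibia prediction (`ak_mesh`).
#' @param top_frac Fraction of the z extent searched for plateau facets.
#' @return List: `point`, `normal` (unit, distal), `slope_rad` (tilt from
#'   the axial plane).
#' @export
tibia_plateau_plane <- function(pred_mesh, top_frac = 0.2) {
  V <- pred_mesh$vertices; F_ <- pred_mesh$faces
  e1 <- V[F_[, 2], ] - V[F_[, 1], ]
  e2 <- V[F_[, 3], ] - V[F_[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cz <- (V[F_[, 1], 3] + V[F_[, 2], 3] + V[F_[, 3], 3]) / 3
  zr <- range(V[, 3])
  sel <- which(nrm[, 3] > cos(35 * pi / 180) &
                 cz > zr[2] - top_frac * diff(zr))
  if (length(sel) < 4) stop("too few plateau facets for a plane fit")
  pts <- V[unique(as.integer(F_[sel, ])), , drop = FALSE]
  fit <- stats::lm.fit(cbind(1, pts[, 1], pts[, 2]), pts[, 3])
  b <- fit$coefficients[2]; c_ <- fit$coefficients[3]
  n <- c(-b, -c_, 1); n <- n / sqrt(sum(n^2))
  n <- -n  # orient distally, away from the femur
  list(point = colMeans(pts), normal = n,
       slope_rad = acos(min(1, abs(n[3]))))
}

#' Extract the tibial base-profile cross-section
#'
#' Finds the widest medial-condyle point (maximum medial x after
#' levelling the mesh so the plateau plane is horizontal), shifts the
#' plateau-parallel plane `offset_mm` distally through it, intersects the
#' mesh, and keeps the largest closed loop projected to plane
#' coordinates.
#'
#' @param pred_mesh Tibia prediction (`ak_mesh`).
#' @param plane Plateau plane from [tibia_plateau_plane()]; fitted when
#'   `NULL`.
#' @param offset_mm Distal offset from the widest point (default 2 mm).
#' @param medial_sign +1 if medial is +x (left-knee canonical frame).
#' @param condyle_frac Proximal fraction of the z extent searched for the
#'   widest medial-condyle point.
#' @return List: `polygon` (k x 2 in-plane mm, largest loop),
#'   `section_plane` (point + normal in mesh frame), `basis`, `widest`
#'   point.
#' @export
extract_tibia_profile <- function(pred_mesh, plane = NULL, offset_mm = 2,
                                  medial_sign = 1, condyle_frac = 0.4) {
  if (is.null(plane)) plane <- tibia_plateau_plane(pred_mesh)
  V <- pred_mesh$vertices
  zr <- range(V[, 3])
  cond <- V[V[, 3] >= zr[2] - condyle_frac * diff(zr), , drop = FALSE]
  widest <- cond[which.max(medial_sign * cond[, 1]), ]
  pt <- widest + offset_mm * plane$normal   # normal is distal
  sl <- slice_mesh_plane(pred_mesh, pt, plane$normal)
  if (!length(sl$loops2d)) stop("section plane does not intersect the mesh")
  areas <- vapply(sl$loops2d, polygon_area, 0)
  poly <- sl$loops2d[[which.max(areas)]]
  list(polygon = polygon_ccw(poly),
       section_plane = list(point = pt, normal = plane$normal),
       basis = sl$basis, widest = widest, prediction = pred_mesh)
}

#' Tibial plate build specification
#'
#' Defaults follow the design rules the pipeline uses: section 2 mm below
#' the widest medial-condyle point and a 5 mm extruded plate.
#'
#' @param thickness_mm Plate thickness (default 5).
#' @param section_offset_mm Profile offset below the widest point
#'   (default 2).
#' @param pin List: central fixation pin `radius`, `length` (mm).
#' @param bearing List: central recess `frac` of profile extents and
#'   `depth` (mm).
#' @param posterior_cut_frac Posterior chord trim as a fraction of the
#'   profile's AP extent.
#' @return `plate_spec`.
#' @export
plate_spec <- function(thickness_mm = 5, section_offset_mm = 2,
                       pin = list(radius = 3, length = 8),
                       bearing = list(frac = 0.45, depth = 2),
                       posterior_cut_frac = 0.08) {
  stopifnot(thickness_mm > 0, section_offset_mm >= 0)
  structure(list(thickness_mm = thickness_mm,
                 section_offset_mm = section_offset_mm,
                 pin = pin, bearing = bearing,
                 posterior_cut_frac = posterior_cut_frac),
            class = "plate_spec")
}

#' Design the generic tibial plate
#'
#' Extrudes the base profile to the plate thickness, cuts the posterior
#' chord and the central bearing recess, and extrudes a central fixation
#' pin on the distal face.  The plate is built in the section-plane frame:
#' the proximal (bone-facing) face sits at z = 0, the distal face at
#' -thickness.
#'
#' @param profile Output of [extract_tibia_profile()] (or a bare k x 2
#'   polygon).
#' @param spec `plate_spec`.
#' @return `implant_component` (kind `"tibia_plate"`); the pin is mesh
#'   part 2.  Provenance records the cut profile, face groups and the
#'   section plane.
#' @export
design_tibia_plate <- function(profile, spec = plate_spec()) {
  poly <- if (is.list(profile) && !is.null(profile$polygon))
    profile$polygon else as.matrix(profile)
  poly <- polygon_ccw(poly)
  if (nrow(poly) < 3) stop("degenerate profile")
  if (anyDuplicated(round(poly, 9))) poly <- poly[!duplicated(round(poly, 9)), ]
  # posterior cut: straight chord trimming the posterior margin
  yr <- range(poly[, 2])
  y_cut <- yr[1] + spec$posterior_cut_frac * diff(yr)
  poly2 <- clip_polygon_halfplane(poly, c(0, y_cut), c(0, -1))
  if (nrow(poly2) < 3) stop("posterior cut removed the whole profile")
  poly2 <- polygon_ccw(poly2)
  # bearing recess rectangle, centred
  ctr <- colMeans(poly2)
  hx <- spec$bearing$frac * diff(range(poly2[, 1])) / 2
  hy <- spec$bearing$frac * diff(range(poly2[, 2])) / 2
  rect <- cbind(ctr[1] + c(-hx, hx, hx, -hx), ctr[2] + c(-hy, -hy, hy, hy))
  th <- spec$thickness_mm
  dpt <- spec$bearing$depth
  n_out <- nrow(poly2)
  # vertex blocks: outer top (z=0), outer bottom (-th), rect top (0),
  # rect bottom (-dpt)
  Vtop <- cbind(poly2, 0)
  Vbot <- cbind(poly2, -th)
  Rtop <- cbind(rect, 0)
  Rbot <- cbind(rect, -dpt)
  V <- rbind(Vtop, Vbot, Rtop, Rbot)
  i_top <- seq_len(n_out)
  i_bot <- n_out + seq_len(n_out)
  i_rt <- 2 * n_out + 1:4
  i_rb <- 2 * n_out + 4 + 1:4
  faces <- list(); groups <- character(0)
  add <- function(f, g) {
    faces[[length(faces) + 1]] <<- f
    groups[length(groups) + 1] <<- g
  }
  nxt <- function(i, n) (i %% n) + 1
  # outer wall (outward normals)
  for (i in seq_len(n_out)) {
    j <- nxt(i, n_out)
    add(c(i_top[i], i_bot[i], i_bot[j]), "wall")
    add(c(i_top[i], i_bot[j], i_top[j]), "wall")
  }
  # bottom face at -th (normal -z): triangulate poly2, reversed order
  tb <- ear_clip(poly2)
  for (r in seq_len(nrow(tb))) add(i_bot[tb[r, c(1, 3, 2)]], "bottom")
  # top annulus (poly2 minus rect), normal +z
  annul <- triangulate_with_hole(poly2, rect)
  # annul vertices: outer (1..n_out) then hole (rect, CW); map indices
  map_top <- c(i_top, i_rt[c(4, 3, 2, 1)])  # hole stored reversed (CW)
  for (r in seq_len(nrow(annul$faces)))
    add(map_top[annul$faces[r, ]], "top")
  # recess walls (inward-facing)
  for (i in 1:4) {
    j <- nxt(i, 4)
    add(c(i_rt[i], i_rt[j], i_rb[j]), "recess_wall")
    add(c(i_rt[i], i_rb[j], i_rb[i]), "recess_wall")
  }
  # recess floor at -dpt, normal +z
  add(c(i_rb[1], i_rb[2], i_rb[3]), "recess_floor")
  add(c(i_rb[1], i_rb[3], i_rb[4]), "recess_floor")
  plate <- mesh(V, do.call(rbind, faces))
  if (mesh_volume(plate) < 0) plate$faces <- plate$faces[, c(1, 3, 2)]
  pin <- cylinder_mesh(ctr, -th - spec$pin$length, -th, spec$pin$radius)
  out <- merge_meshes(plate, pin)
  groups <- c(groups, rep("pin", nrow(pin$faces)))
  structure(list(mesh = out, kind = "tibia_plate",
                 provenance = list(spec = spec, profile = poly,
                                   cut_profile = poly2,
                                   bearing_rect = rect,
                                   face_groups = groups,
                                   section_plane =
                                     if (is.list(profile)) profile$section_plane
                                     else NULL,
                                   prediction =
                                     if (is.list(profile)) profile$prediction
                                     else NULL)),
            class = "implant_component")
}

#' Resect ground-truth bone with the component's own cut geometry
#'
#' Femur: clips the ground-truth mesh with the *same* cut plan used for
#' the component and returns the resected piece plus its cut-facet edge
#' loops.  Tibia: sections the ground truth at the *same* plane used for
#' the profile and returns the equivalent profile polygon.
#'
#' @param gt_mesh Ground-truth bone mesh (`ak_mesh`).
#' @param plan_or_spec A `cut_plan` (femur) or the profile/provenance list
#'   holding `section_plane` (tibia).
#' @return Femur: list(`mesh`, `edges`); tibia: list(`polygon`,
#'   `section_plane`).
#' @export
resect_bone <- function(gt_mesh, plan_or_spec) {
  if (inherits(plan_or_spec, "cut_plan")) {
    clipped <- clip_with_plan(gt_mesh, plan_or_spec)
    list(mesh = clipped,
         edges = component_edges(clipped, plan_or_spec))
  } else {
    sp <- plan_or_spec$section_plane %||% plan_or_spec
    sl <- slice_mesh_plane(gt_mesh, sp$point, sp$normal)
    if (!length(sl$loops2d)) stop("section plane misses the ground truth")
    areas <- vapply(sl$loops2d, polygon_area, 0)
    list(polygon = polygon_ccw(sl$loops2d[[which.max(areas)]]),
         section_plane = sp)
  }
}
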