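# Implant CAD: measurements, cut planning, component and plate builds,
# plateau plane, profile extraction and resection.

test_that("AP/ML measurements follow the condylar bounding box", {
  box <- local({
    v <- as.matrix(expand.grid(c(0, 60), c(0, 70), c(0, 40)))
    f <- rbind(c(1, 2, 4), c(1, 4, 3), c(5, 8, 6), c(5, 7, 8),
               c(1, 6, 2), c(1, 5, 6), c(3, 4, 8), c(3, 8, 7),
               c(1, 3, 7), c(1, 7, 5), c(2, 8, 4), c(2, 6, 8))
    mesh(v, f)
  })
  meas <- measure_ap_ml(box)
  expect_equal(meas$ML, 60)
  expect_equal(meas$AP, 70)
  fem <- ak_test_case()$subject$femur
  m1 <- measure_ap_ml(fem)
  m2 <- measure_ap_ml(scale_mesh(fem, 1.1))
  expect_equal(m2$AP / m1$AP, 1.1, tolerance = 1e-6)
  expect_equal(m2$ML / m1$ML, 1.1, tolerance = 1e-6)
  # phantom condylar extents are known from the template parameters
  tmpl <- autoknee:::ak_template()
  g <- 1 + ak_test_case()$subject$mode_weights[["scale"]]
  amp <- tmpl$condyle_amp + ak_test_case()$subject$mode_weights[["condyle"]]
  expect_lt(abs(m1$ML - 2 * tmpl$femur_r * g *
                  max(vapply(seq(0, 1, 0.01), function(t) {
                    (0.45 + 0.55 * exp(-((t - 0.15) / 0.2)^2)) *
                      (1 + amp * exp(-3 * t))
                  }, 0))), 2)
  expect_error(measure_ap_ml(mesh(matrix(numeric(0), 0, 3),
                                  matrix(integer(0), 0, 3))), "empty")
})

test_that("cut plans scale linearly with the measurements", {
  fem <- ak_test_case()$subject$femur
  meas <- measure_ap_ml(fem)
  plan <- plan_femur_cuts(meas)
  expect_length(plan$planes, 5)
  for (p in plan$planes) expect_equal(sum(p$normal^2), 1, tolerance = 1e-12)
  meas2 <- measure_ap_ml(scale_mesh(fem, 2))
  plan2 <- plan_femur_cuts(meas2)
  # AP-referenced offsets double when AP doubles
  off1 <- plan$planes[[3]]$point[3] - meas$bbox[1, 3]
  off2 <- plan2$planes[[3]]$point[3] - meas2$bbox[1, 3]
  expect_equal(off2 / off1, 2, tolerance = 1e-6)
  expect_identical(plan_femur_cuts(meas)$planes, plan$planes)  # pure
  bad <- meas; bad$AP <- -1
  expect_error(plan_femur_cuts(bad), "positive")
})

test_that("femoral components are deterministic clipped solids with pins", {
  fem <- ak_test_case()$subject$femur
  plan <- plan_femur_cuts(measure_ap_ml(fem))
  comp <- design_femur_component(fem, plan)
  comp2 <- design_femur_component(fem, plan)
  expect_identical(comp$mesh$vertices, comp2$mesh$vertices)
  expect_lt(mesh_volume(comp$mesh), mesh_volume(fem))
  expect_equal(sort(unique(comp$mesh$parts)), 1:3)  # body + 2 pins
  # two cylindrical pin cross-sections at pin mid-height
  z_d <- plan$planes[[3]]$point[3]
  pin_faces <- which(comp$mesh$parts > 1)
  pin_mesh <- mesh(comp$mesh$vertices, comp$mesh$faces[pin_faces, ])
  loops <- slice_mesh_z(pin_mesh, z_d + 5)
  expect_length(loops, 2)
  for (l in loops)
    expect_lt(abs(polygon_area(l) - pi * 9) / (pi * 9), 0.1)
  # component body surface coincides with the equivalently resected
  # prediction piece, to within the recorded bone-facing tolerance
  res_self <- resect_bone(fem, plan)
  set.seed(9)
  d <- closest_point_mesh(sample_mesh_points(comp$mesh, 500,
                                             faces_subset = which(comp$mesh$parts == 1)),
                          res_self$mesh)$distance
  expect_lte(max(d), comp$provenance$shell_mm + 1e-6)
  # a plan that removes everything errors
  silly <- plan
  silly$planes[[3]]$point[3] <- min(fem$vertices[, 3]) - 10
  expect_error(design_femur_component(fem, silly), "degenerate cut plan")
})

test_that("plateau plane recovery matches the generator slope", {
  tc <- ak_test_case()
  pl <- tibia_plateau_plane(tc$subject$tibia)
  true_slope <- abs(autoknee:::ak_template()$plateau_slope_deg * pi / 180 +
                      tc$subject$mode_weights[["slope_rad"]])
  expect_lt(abs(pl$slope_rad - true_slope) * 180 / pi, 1)
  expect_lt(pl$normal[3], 0)  # distal orientation, away from the femur
  # flat-topped cylinder: normal within 1e-3 rad of the axis
  cyl <- autoknee:::cylinder_mesh(c(0, 0), 0, 30, 15, n_seg = 48)
  pc <- tibia_plateau_plane(cyl)
  expect_lt(acos(min(1, abs(pc$normal[3]))), 1e-3)
})

test_that("profile extraction matches analytic cross-sections", {
  cyl <- autoknee:::cylinder_mesh(c(0, 0), 0, 40, 20, n_seg = 64)
  plane <- list(point = c(0, 0, 40), normal = c(0, 0, -1))
  prof <- extract_tibia_profile(cyl, plane, offset_mm = 2)
  expect_lt(abs(polygon_area(prof$polygon) - pi * 400) / (pi * 400), 0.02)
  # frustum: the distal section (per the plane orientation) is smaller
  frustum <- local({
    theta <- seq(0, 2 * pi, length.out = 33)[-33]
    rings <- lapply(seq(0, 1, length.out = 5), function(t) {
      r <- 20 - 8 * t  # narrows upward
      cbind(r * cos(theta), r * sin(theta), 40 * t)
    })
    tube_mesh(rings)
  })
  ptop <- list(point = c(0, 0, 40), normal = c(0, 0, -1))
  p0 <- extract_tibia_profile(frustum, ptop, offset_mm = 0)
  p2 <- extract_tibia_profile(frustum, ptop, offset_mm = 2)
  expect_gt(polygon_area(p2$polygon), polygon_area(p0$polygon))
  expect_error(extract_tibia_profile(cyl, plane, offset_mm = 1000),
               "does not intersect")
})

test_that("tibial plates honour thickness, cuts and volume bookkeeping", {
  tc <- ak_test_case()
  prof <- extract_tibia_profile(tc$subject$tibia)
  spec <- plate_spec()
  plate <- design_tibia_plate(prof, spec)
  zr <- range(plate$mesh$vertices[, 3])
  expect_equal(diff(zr), spec$thickness_mm + spec$pin$length,
               tolerance = 1e-9)
  prov <- plate$provenance
  a_cut <- polygon_area(prov$cut_profile)
  a_rect <- polygon_area(prov$bearing_rect)
  expect_lt(a_cut, polygon_area(prov$profile))  # posterior cut removed area
  # proximal face area equals the cut profile minus the bearing recess
  top_faces <- which(prov$face_groups == "top")
  a_top <- sum(autoknee:::mesh_face_areas(plate$mesh)[top_faces])
  expect_equal(a_top, a_cut - a_rect, tolerance = 0.01 * a_cut)
  # volume: full extrusion minus recess, minus the pin part
  body_faces <- which(prov$face_groups != "pin")
  body <- mesh(plate$mesh$vertices, plate$mesh$faces[body_faces, ])
  expect_equal(mesh_volume(body),
               a_cut * spec$thickness_mm - a_rect * spec$bearing$depth,
               tolerance = 0.01 * a_cut * spec$thickness_mm)
  expect_lt(mesh_volume(body), a_cut * spec$thickness_mm)
  expect_error(design_tibia_plate(matrix(c(0, 0), 1, 2)), "degenerate")
})

test_that("resection mirrors the component geometry (self-consistency)", {
  tc <- ak_test_case()
  fem <- tc$subject$femur
  plan <- plan_femur_cuts(measure_ap_ml(fem))
  comp <- design_femur_component(fem, plan)
  res <- resect_bone(fem, plan)
  expect_lt(mesh_volume(res$mesh), mesh_volume(fem))
  C <- do.call(rbind, comp$provenance$edges)
  B <- do.call(rbind, res$edges)
  expect_lt(max_ouh(C, B), 0.01)
  # tibia: identical mesh gives identical profiles and zero OUH
  prof <- extract_tibia_profile(tc$subject$tibia)
  res_t <- resect_bone(tc$subject$tibia, prof)
  expect_lt(max_ouh(prof$polygon, res_t$polygon), 0.01)
})
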