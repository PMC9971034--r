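# Shape-model fitting, synthesis, rigid ICP and stack morphing.

test_that("two-mesh model has a midpoint mean and one non-null mode", {
  pop <- ak_population()
  sm <- shape_model(list(pop[[1]]$femur, pop[[3]]$femur))
  expect_equal(sm$n_modes, 1)
  # mean equals the vertex-wise midpoint of the two aligned shapes:
  # reconstructing with +w and -w averages back to the mean
  w <- sm$weights[1, 1]
  a <- synthesize(sm, w)$vertices
  b <- synthesize(sm, -w)$vertices
  expect_equal((a + b) / 2, sm$mean_vertices, tolerance = 1e-9)
})

test_that("mode rows are orthonormal with non-increasing variances", {
  sm <- ak_ssms()$femur
  G <- sm$components %*% t(sm$components)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-8)
  expect_true(all(diff(sm$variances) <= 1e-9))
})

test_that("training meshes reconstruct exactly with all modes", {
  pop <- ak_population()
  meshes <- lapply(pop, `[[`, "femur")
  sm <- shape_model(meshes, smooth_iters = 0)
  for (i in c(1, 4, 8)) {
    V <- meshes[[i]]$vertices
    V <- sweep(V, 2, colMeans(V))
    k <- kabsch(V, sm$mean_vertices)
    Va <- apply_rigid(rigid_transform(k$rotation, k$translation), V)
    x <- as.numeric(Va) - as.numeric(sm$mean_vertices)
    w <- as.numeric(sm$components %*% x)
    resid <- x - as.numeric(t(sm$components) %*% w)
    expect_lt(sqrt(mean(resid^2)), 1e-6)
  }
})

test_that("three construction modes concentrate >= 95% of the variance", {
  for (bone in c("femur", "tibia")) {
    sm <- ak_ssms()[[bone]]
    pv <- cumsum(sm$variances) / sum(sm$variances)
    expect_gte(pv[3], 0.95)
  }
})

test_that("synthesis is linear in the weights", {
  sm <- ak_ssms()$femur
  base <- synthesize(sm)
  expect_equal(synthesize(sm, c(0, 0))$vertices, base$vertices)
  w <- c(4, -2)
  a <- synthesize(sm, w)$vertices
  b <- synthesize(sm, -w)$vertices
  expect_equal((a + b) / 2, base$vertices, tolerance = 1e-9)
  # brute-force vertex arithmetic oracle
  manual <- as.numeric(base$vertices) +
    as.numeric(t(sm$components[1:2, ]) %*% w)
  expect_equal(as.numeric(a), manual, tolerance = 1e-12)
  expect_error(synthesize(sm, rep(1, sm$n_modes + 1)), "more weights")
})

test_that("rigid ICP recovers known transforms on sampled surfaces", {
  fem <- ak_template_femur()
  set.seed(31)
  pts <- sample_mesh_points(fem, 400)
  for (rep in 1:3) {
    ang <- runif(3, -10, 10) * pi / 180
    R <- autoknee:::rot_z(ang[1]) %*% autoknee:::rot_y(ang[2]) %*%
      autoknee:::rot_x(ang[3])
    t0 <- runif(3, -4, 4)
    moved <- sweep(pts %*% t(R), 2, -t0)
    tf <- rigid_icp(moved, fem)
    recovered <- apply_rigid(tf, moved)
    expect_lt(max(abs(recovered - pts)), 1e-3)
    expect_lt(max(abs(tf$rotation %*% R - diag(3))), 1e-3)
  }
})

test_that("ICP is a no-op on aligned points and monotone in RMS", {
  fem <- ak_template_femur()
  set.seed(32)
  pts <- sample_mesh_points(fem, 300)
  tf <- rigid_icp(pts, fem)
  expect_lt(attr(tf, "rms"), 1e-6)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-6)
  moved <- sweep(pts %*% t(autoknee:::rot_z(0.1)), 2, -c(3, 1, -2))
  tf2 <- rigid_icp(moved, fem)
  expect_true(all(diff(attr(tf2, "history")) <= 1e-12))
  expect_error(rigid_icp(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), fem),
               "collinear")
})

base_cross_section_stack <- function(model, bone, zs) {
  base <- synthesize(model)
  slices <- lapply(zs, function(z) {
    loops <- slice_mesh_z(base, z)
    list(z = z, points = do.call(rbind, loops))
  })
  contour_stack(slices, bone, diff(zs[1:2]))
}

test_that("stacks sampled from the base shape self-align", {
  sm <- ak_ssms()$femur
  zr <- range(sm$base_vertices[, 3])
  zs <- seq(zr[1] + 2, zr[1] + 14, by = 1)
  st <- base_cross_section_stack(sm, "femur", zs)
  al <- align_stack_to_base(st, sm)
  expect_lte(al$rms, 0.1)
  # translated copy gives the same residual
  st2 <- st
  st2$slices <- lapply(st2$slices, function(s) {
    s$points <- s$points + matrix(c(12, -7), nrow(s$points), 2,
                                  byrow = TRUE)
    s
  })
  al2 <- align_stack_to_base(st2, sm)
  expect_equal(al2$rms, al$rms, tolerance = 1e-3)
  empty <- st
  empty$slices <- list()
  expect_error(align_stack_to_base(empty, sm), "empty")
})

test_that("morphing recovers generating weights from stack samples", {
  sm <- ak_ssms()$femur
  sds <- sqrt(sm$variances[1:2])
  w_true <- c(1.2 * sds[1], -0.8 * sds[2])
  target <- synthesize(sm, w_true)
  zr <- range(target$vertices[, 3])
  zs <- seq(zr[1] + 1.5, zr[2] - 1.5, by = 1)
  slices <- lapply(zs, function(z) {
    loops <- slice_mesh_z(target, z)
    list(z = z, points = do.call(rbind, loops))
  })
  pts <- do.call(rbind, lapply(slices, function(s) cbind(s$points, s$z)))
  pred <- morph_to_stack(sm, pts, n_pc = 2)
  w_hat <- attr(pred, "weights")
  expect_lt(max(abs(w_hat - w_true) / abs(w_true)), 0.10)
  rmse <- surface_rmse(pred, target, n_samples = 1200, seed = 7,
                       align = FALSE)
  expect_lte(as.numeric(rmse), 0.3)
  expect_true(all(diff(attr(pred, "objective")) <= 1e-9))
})

test_that("morphing with zero components returns the base shape", {
  sm <- ak_ssms()$tibia
  pts <- sample_mesh_points(synthesize(sm), 100)
  out <- morph_to_stack(sm, pts, n_pc = 0)
  expect_equal(out$vertices, synthesize(sm)$vertices)
  expect_error(morph_to_stack(sm, pts, n_pc = sm$n_modes + 1), "exceeds")
})
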