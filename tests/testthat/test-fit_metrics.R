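# Surface RMSE, maximum over/underhang, component fit reports, heatmaps
# and cohort statistics.

plane_mesh <- function(z, half = 10) {
  v <- rbind(c(-half, -half, z), c(half, -half, z),
             c(half, half, z), c(-half, half, z))
  mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
}

test_that("surface RMSE matches closed-form cases", {
  fem <- ak_template_femur()
  expect_lt(as.numeric(surface_rmse(fem, fem, n_samples = 400, seed = 2,
                                    align = FALSE)), 1e-9)
  # two parallel planes 1 mm apart, alignment disabled
  r <- surface_rmse(plane_mesh(0), plane_mesh(1), n_samples = 500,
                    seed = 3, align = FALSE)
  expect_equal(as.numeric(r), 1.0, tolerance = 1e-9)
  # direct arithmetic: paired distances {3, 4}
  expect_equal(rmse_mm(c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_error(surface_rmse(fem, fem, region = c(1e5, 2e5)), "empty region")
})

test_that("surface RMSE is invariant to rigid motion when aligned", {
  fem <- ak_template_femur()
  moved <- transform_mesh(fem, rigid_transform(autoknee:::rot_z(0.05),
                                               c(8, -3, 5)))
  r <- surface_rmse(fem, moved, n_samples = 600, seed = 4, align = TRUE)
  expect_lt(as.numeric(r), 0.05)
})

test_that("maximum OUH equals the directed Hausdorff distance", {
  expect_equal(max_ouh(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  A <- matrix(rnorm(20), 10, 2)
  expect_equal(max_ouh(A, A), 0)
  expect_equal(max_ouh(rbind(c(0, 0), c(10, 0)), rbind(c(0, 0))), 10)
  # brute-force double-loop oracle on random fixtures (2-D and 3-D)
  set.seed(14)
  for (rep in 1:10) {
    d <- sample(2:3, 1)
    C <- matrix(rnorm(d * sample(5:80, 1)), ncol = d)
    B <- matrix(rnorm(d * sample(5:80, 1)), ncol = d)
    brute <- max(apply(C, 1, function(p) {
      min(sqrt(colSums((t(B) - p)^2)))
    }))
    expect_equal(max_ouh(C, B), brute, tolerance = 1e-12)
  }
  expect_error(max_ouh(matrix(numeric(0), 0, 2), rbind(c(0, 0))), "empty")
})

test_that("the clinical flag threshold is inclusive", {
  expect_false(ouh_flag(2.99))
  expect_true(ouh_flag(3.0))
  expect_true(ouh_flag(5.2))
  expect_false(ouh_flag(3.5, threshold = 4))  # config override
})

test_that("component self-fit is clean and rigidly invariant", {
  tc <- ak_test_case()
  fem <- tc$subject$femur
  comp <- design_femur_component(fem, plan_femur_cuts(measure_ap_ml(fem)))
  fit <- component_fit(comp, fem, seed = 6)
  expect_lte(fit$rmse_mm, comp$provenance$shell_mm)
  expect_lt(fit$max_ouh_mm, 0.1)
  expect_false(fit$ouh_flag)
  moved <- transform_mesh(fem, rigid_transform(diag(3), c(10, 0, 0)))
  fit2 <- component_fit(comp, moved, seed = 6)
  expect_equal(fit2$rmse_mm, fit$rmse_mm, tolerance = 1e-3)
  expect_equal(fit2$max_ouh_mm, fit$max_ouh_mm, tolerance = 1e-3)
})

test_that("uniform in-plane inflation appears as the OUH magnitude", {
  tc <- ak_test_case()
  tib <- tc$subject$tibia
  prof <- extract_tibia_profile(tib)
  plate <- design_tibia_plate(prof)
  # inflate the ground truth in-plane by 4 mm: every profile point moves
  # 4 mm outward, so the directed Hausdorff from the (smaller) component
  # profile is ~4 mm
  c0 <- colMeans(tib$vertices[, 1:2])
  inflated <- tib
  xy <- tib$vertices[, 1:2]
  r <- sqrt(rowSums(sweep(xy, 2, c0)^2))
  inflated$vertices[, 1:2] <- sweep(sweep(xy, 2, c0) * (1 + 4 / r), 2, -c0)
  fit <- component_fit(plate, inflated, seed = 6)
  expect_equal(fit$max_ouh_mm, 4, tolerance = 0.35)
  expect_true(fit$ouh_flag)
})

test_that("heatmap renders and dumps distances that match recomputation", {
  fem <- ak_template_femur()
  moved <- transform_mesh(fem, rigid_transform(diag(3), c(0.5, 0, 0)))
  img <- withr::local_tempfile(fileext = ".png")
  tab <- withr::local_tempfile(fileext = ".csv")
  d <- distance_heatmap(fem, moved, img, tab)
  expect_true(file.exists(img))
  dumped <- read.csv(tab)
  expect_equal(dumped$distance_mm, as.numeric(d), tolerance = 1e-9)
  recompute <- closest_point_mesh(fem$vertices, moved)$distance
  expect_equal(as.numeric(d), recompute, tolerance = 1e-12)
  d0 <- distance_heatmap(fem, fem, withr::local_tempfile(fileext = ".png"))
  expect_true(all(d0 < 1e-9))
})

test_that("cohort statistics follow the Welch and Spearman definitions", {
  df <- data.frame(metric = c(1, 2, 3, 1, 2, 3),
                   grp = rep(c("a", "b"), each = 3),
                   cov = c(10, 30, 20, 11, 31, 21))
  out <- cohort_stats(df, "metric", groups = "grp")
  t_row <- out[out$type == "welch_t", ]
  expect_equal(t_row$p_value, 1, tolerance = 1e-9)
  expect_false(t_row$significant)
  # strictly monotone covariate-metric pairs
  dfs <- data.frame(metric = c(1, 3, 2, 5, 4, 6),
                    cov = c(10, 30, 20, 50, 40, 60))
  s_row <- cohort_stats(dfs, "metric", covariates = "cov")
  expect_equal(unname(s_row$estimate), 1)
  expect_true(s_row$significant)
  # hand-computed Welch t-test: x = (1,2,3), y = (2,4,9)
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  sx2 <- var(x) / 3; sy2 <- var(y) / 3
  t_stat <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df_w <- (sx2 + sy2)^2 / (sx2^2 / 2 + sy2^2 / 2)
  p_manual <- 2 * pt(-abs(t_stat), df_w)
  df2 <- data.frame(m = c(x, y), g = rep(c("x", "y"), each = 3))
  out2 <- cohort_stats(df2, "m", groups = "g")
  expect_equal(out2$p_value[1], p_manual, tolerance = 1e-9)
  # insufficient n is marked n/a
  df3 <- data.frame(m = c(1, 2), g = c("a", "b"))
  out3 <- cohort_stats(df3, "m", groups = "g")
  expect_identical(out3$note, "n/a")
})
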