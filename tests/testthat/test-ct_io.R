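# DICOM round trips, windowed PNG export and the horizontal flip.

make_small_volume <- function(n = 6, px = 24, seed = 4) {
  set.seed(seed)
  slices <- lapply(seq_len(n), function(k) {
    matrix(sample.int(400, px * px, replace = TRUE), px, px)
  })
  ct_volume(slices, pixel_spacing = c(0.8, 0.8), slice_spacing = 1.0)
}

test_that("DICOM series round trip preserves geometry and intensities", {
  vol <- make_small_volume()
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_dicom_series(dir)
  expect_equal(n_slices(back), n_slices(vol))
  expect_equal(back$pixel_spacing, vol$pixel_spacing, tolerance = 1e-6)
  expect_equal(back$slice_spacing, vol$slice_spacing, tolerance = 1e-6)
  for (k in seq_len(n_slices(vol)))
    expect_identical(back$slices[[k]], vol$slices[[k]])
})

test_that("slices are ordered by position, not filename", {
  vol <- make_small_volume(n = 8)
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(vol, dir)
  # scramble filenames; position tags still carry the true order
  set.seed(9)
  scrambled <- file.path(dir, sprintf("f_%s.dcm",
                                      sample(letters, length(paths))))
  file.rename(paths, scrambled)
  back <- load_dicom_series(dir)
  for (k in seq_len(n_slices(vol)))
    expect_identical(back$slices[[k]], vol$slices[[k]])
})

test_that("degenerate series directories are rejected", {
  vol <- make_small_volume(n = 2)
  dir <- withr::local_tempdir()
  write_dicom_slice(vol$slices[[1]], file.path(dir, "only.dcm"),
                    c(0.8, 0.8), 1, 1, c(0, 0, 0), 1, "1.2.3.4")
  expect_error(load_dicom_series(dir), "no usable series")
  # two files from different series
  write_dicom_slice(vol$slices[[2]], file.path(dir, "other.dcm"),
                    c(0.8, 0.8), 1, 1, c(0, 0, 1), 2, "9.9.9.9")
  expect_error(load_dicom_series(dir), "no usable series")
})

test_that("metadata written by the DICOM writer is readable by pydicom", {
  vol <- make_small_volume(n = 2)
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(vol, dir)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", paths[1], "'); ",
    "print(float(d.PixelSpacing[0]), float(d.SliceThickness), ",
    "d.pixel_array.shape[0], int(d.pixel_array[0,0]))"))),
    stdout = TRUE, stderr = TRUE)
  vals <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.numeric(vals[1]), 0.8, tolerance = 1e-9)
  expect_equal(as.numeric(vals[2]), 1.0, tolerance = 1e-9)
  expect_equal(as.integer(vals[3]), 24L)
  expect_equal(as.integer(vals[4]), vol$slices[[1]][1, 1])
})

test_that("windowed export clips at the window and is monotone", {
  px <- 16
  lo_img <- matrix(10, px, px)
  hi_img <- matrix(300, px, px)
  ramp <- matrix(seq(0, 400, length.out = px * px), px, px)
  vol <- ct_volume(list(lo_img, hi_img, ramp), c(0.8, 0.8), 1)
  dir <- withr::local_tempdir()
  paths <- export_slice_images(vol, dir, window = c(10, 300))
  g1 <- png::readPNG(paths[1]); g2 <- png::readPNG(paths[2])
  g3 <- png::readPNG(paths[3])
  expect_true(all(g1 == 0))
  expect_true(all(g2 == 1))
  # monotone in input intensity along the ramp
  ord <- order(as.numeric(ramp))
  expect_true(all(diff(as.numeric(g3)[ord]) >= 0))
  # direct linear map agreement
  expected <- pmin(pmax((as.numeric(ramp) - 10) / 290, 0), 1)
  expect_equal(as.numeric(g3), round(expected * 255) / 255,
               tolerance = 1 / 255)
  expect_error(export_slice_images(vol, dir, window = c(5, 5)), "lo < hi")
})

test_that("horizontal flip reverses columns and is an involution", {
  expect_identical(flip_slice_horizontal(matrix(1:4, 2, byrow = TRUE)),
                   matrix(c(2L, 1L, 4L, 3L), 2, byrow = TRUE))
  sym <- matrix(c(1, 2, 1, 3, 4, 3), 2, byrow = TRUE)
  expect_identical(flip_slice_horizontal(sym), sym)
  set.seed(5)
  img <- matrix(rnorm(35), 5, 7)
  expect_identical(flip_slice_horizontal(flip_slice_horizontal(img)), img)
  expect_error(flip_slice_horizontal(matrix(numeric(0), 0, 0)), "empty")
})
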