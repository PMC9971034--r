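# Knee region-of-interest location: a bounding-box-centre regressor over
# knee slices, aggregation to the per-volume median ROI (fixed square,
# default 160 px) and cropping, with the flip-then-detect convention for
# right knees so only a left-knee detector is ever trained.

#' Train the knee bounding-box centre regressor
#'
#' A single-hidden-layer network (linear outputs) mapping per-slice shape
#' descriptors ([slice_descriptors()]) to the (row, col) box centre,
#' normalised by image size.
#'
#' @param dataset List with `train` / optional `validation`, each holding
#'   `images` (list of matrices) and `centres` (n x 2, px).
#' @param hyperparams List: `hidden`, `maxit`, `decay`, `bone_threshold`
#'   for the slice descriptors.
#' @param seed RNG seed.
#' @return `ak_roi_detector` with `validation_error_px` (mean Euclidean
#'   centre error).
#' @export
train_roi_detector <- function(dataset,
                               hyperparams = list(hidden = 6, maxit = 500,
                                                  decay = 1e-5,
                                                  bone_threshold = 140),
                               seed = 1L) {
  tr <- dataset$train %||% dataset
  if (!length(tr$images)) stop("empty detector dataset")
  dims <- t(vapply(tr$images, dim, integer(2)))
  ctr <- as.matrix(tr$centres)
  if (any(ctr[, 1] < 1 | ctr[, 1] > dims[, 1] |
          ctr[, 2] < 1 | ctr[, 2] > dims[, 2]))
    stop("bounding box centre outside image bounds")
  bone_threshold <- hyperparams$bone_threshold %||% 140
  X <- descriptor_matrix(tr$images, bone_threshold)
  Y <- ctr / dims  # normalised targets
  set.seed(seed)
  net <- nnet::nnet(X, Y, size = hyperparams$hidden %||% 6, linout = TRUE,
                    maxit = hyperparams$maxit %||% 500,
                    decay = hyperparams$decay %||% 1e-5,
                    MaxNWts = 50000, trace = FALSE)
  model <- structure(list(net = net, bone_threshold = bone_threshold,
                          geometry = dim(tr$images[[1]]),
                          validation_error_px = NA_real_),
                     class = "ak_roi_detector")
  if (!is.null(dataset$validation) && length(dataset$validation$images)) {
    p <- predict_roi_centres(model, dataset$validation$images)
    err <- sqrt(rowSums((p - as.matrix(dataset$validation$centres))^2))
    model$validation_error_px <- mean(err)
  }
  model
}

#' Predict knee box centres for a set of slices
#' @param model `ak_roi_detector`.
#' @param images List of slice matrices (left-knee convention).
#' @return n x 2 matrix of (row, col) centres in px.
#' @export
predict_roi_centres <- function(model, images) {
  X <- descriptor_matrix(images, model$bone_threshold)
  P <- predict(model$net, X)
  dims <- t(vapply(images, dim, integer(2)))
  P * dims
}

lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(x) / 2)]
}

#' Aggregate per-slice centres into the fixed square ROI
#'
#' Takes the per-axis median of the slice centres (lower median for even
#' counts, for determinism), centres a `size` px square box there, and
#' clamps the window inside the image.
#'
#' @param centres List or n x 2 matrix of (row, col) centres.
#' @param size Square box side in px (default 160).
#' @param image_dim `(rows, cols)` of the slices.
#' @return `roi_spec`: `centre`, `size`, and 1-based inclusive `rows` /
#'   `cols` crop windows.
#' @export
median_roi_box <- function(centres, size = 160, image_dim) {
  if (is.list(centres)) centres <- do.call(rbind, centres)
  centres <- as.matrix(centres)
  if (!nrow(centres)) stop("no centres supplied")
  if (any(size > image_dim)) stop("roi larger than image")
  med <- c(lower_median(centres[, 1]), lower_median(centres[, 2]))
  start <- round(med) - size %/% 2 + 1L
  start <- pmax(1L, pmin(as.integer(start), as.integer(image_dim) - size + 1L))
  structure(list(centre = med, size = as.integer(size),
                 rows = c(start[1], start[1] + size - 1L),
                 cols = c(start[2], start[2] + size - 1L)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("roi_spec: %d px square at centre (%.1f, %.1f); rows %d..%d cols %d..%d\n",
              x$size, x$centre[1], x$centre[2], x$rows[1], x$rows[2],
              x$cols[1], x$cols[2]))
  invisible(x)
}

#' Crop one matrix to an ROI window
#' @param img Matrix.
#' @param roi `roi_spec`.
#' @return `size x size` matrix.
#' @export
crop_matrix <- function(img, roi) {
  img[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE]
}

#' Crop knee slices to the shared ROI
#'
#' For right knees each slice is horizontally flipped *before* cropping,
#' so the crop window (trained and computed on the left-knee convention)
#' applies unchanged.
#'
#' @param slices List of slice matrices.
#' @param roi `roi_spec`.
#' @param side `"left"` or `"right"`.
#' @return List of `size x size` matrices.
#' @export
crop_to_roi <- function(slices, roi, side = c("left", "right")) {
  side <- match.arg(side)
  d <- dim(slices[[1]])
  if (roi$size > min(d)) stop("roi larger than image")
  lapply(slices, function(s) {
    if (side == "right") s <- flip_slice_horizontal(s)
    crop_matrix(s, roi)
  })
}
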