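# Per-bone binary segmentation of cropped knee slices, contour tracing and
# length filtering.
#
# One model per bone (separate femur and tibia models give cleaner
# per-bone geometry than a shared one).  Each model is a compact two-stage
# segmenter standing behind the module's dense-segmentation contract: a
# slice gate (single-hidden-layer network deciding whether the bone is
# present in the crop) and a per-pixel stage (intensity threshold selected
# to maximise training Dice, followed by a largest-connected-component
# rule that suppresses the fibula and patella distractors).

dice_coef <- function(a, b) {
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}

clean_mask <- function(raw, bone, min_area = 40) {
  if (!any(raw > 0)) return(matrix(0L, nrow(raw), ncol(raw)))
  lab <- EBImage::bwlabel(raw)
  sizes <- tabulate(lab[lab > 0])
  # each bone is a single connected cross-section; keeping the largest
  # component rejects the fibula and patella distractors
  keep <- which.max(sizes)
  if (sizes[keep] < min_area)
    return(matrix(0L, nrow(raw), ncol(raw)))
  matrix(as.integer(lab == keep), nrow(raw), ncol(raw))
}

# gate features: geometry of the largest thresholded component (profile
# dips expose the intercondylar notch, so femoral condylar sections are
# separable from tibial plateau sections) plus secondary-component layout
crop_gate_features <- function(imgs, bone_threshold = 140) {
  t(vapply(imgs, function(im) {
    b <- matrix(as.integer(im >= bone_threshold), nrow(im), ncol(im))
    if (!any(b > 0)) return(numeric(12))
    lab <- EBImage::bwlabel(b)
    sizes <- tabulate(lab[lab > 0])
    k <- which.max(sizes)
    main <- lab == k
    rr <- which(main, arr.ind = TRUE)
    cs <- colSums(main); nz <- which(cs > 0)
    prof <- cs[nz[1]:nz[length(nz)]]; n <- length(prof)
    mid <- prof[max(1, floor(n * 0.3)):ceiling(n * 0.7)]
    dipx <- 1 - min(mid) / max(prof)
    rs <- rowSums(main); nzr <- which(rs > 0)
    profr <- rs[nzr[1]:nzr[length(nzr)]]; nr <- length(profr)
    midr <- profr[max(1, floor(nr * 0.3)):ceiling(nr * 0.7)]
    dipy <- 1 - min(midr) / max(profr)
    w <- diff(range(rr[, 2])) + 1; h <- diff(range(rr[, 1])) + 1
    second <- sort(sizes, decreasing = TRUE)
    a2 <- if (length(second) > 1) second[2] else 0
    off <- c(0, 0)
    if (a2 >= 40) {
      k2 <- order(sizes, decreasing = TRUE)[2]
      rr2 <- which(lab == k2, arr.ind = TRUE)
      off <- (colMeans(rr2) - colMeans(rr)) / nrow(im)
    }
    c(sizes[k] / length(im), a2 / length(im), dipx, dipy, w / ncol(im),
      h / nrow(im), w / h, colMeans(rr) / nrow(im), off,
      length(second) / 4)
  }, numeric(12)))
}

#' Train a per-bone segmentation model
#'
#' @param bone `"femur"` or `"tibia"`.
#' @param dataset List with `train` / optional `validation`, each holding
#'   `images` and binary `masks` of identical size.
#' @param hyperparams List: gate `hidden`/`maxit`/`decay`,
#'   `bone_threshold` for the gate features, `min_area` (px) for the
#'   component rule, `n_thresholds` candidate intensity cut points.
#' @param seed RNG seed.
#' @return `ak_bone_segmenter` with `validation_dice`.
#' @export
train_bone_segmenter <- function(bone, dataset,
                                 hyperparams = list(hidden = 8, maxit = 600,
                                                    decay = 1e-4,
                                                    bone_threshold = 140,
                                                    min_area = 40,
                                                    n_thresholds = 24),
                                 seed = 1L) {
  bone <- match.arg(bone, c("femur", "tibia"))
  tr <- dataset$train %||% dataset
  if (!length(tr$images)) stop("empty segmentation dataset")
  for (i in seq_along(tr$images)) {
    if (!identical(dim(tr$images[[i]]), dim(tr$masks[[i]])))
      stop("image/mask shape mismatch at pair ", i)
    v <- unique(as.integer(tr$masks[[i]]))
    if (!all(v %in% c(0L, 1L))) stop("masks must be binary")
  }
  pos <- vapply(tr$masks, function(m) sum(m > 0), 0)
  if (all(pos == 0)) stop("no positive pixels in any training mask")
  gate_threshold <- hyperparams$bone_threshold %||% 140
  set.seed(seed)
  # stage 1: presence gate
  X <- crop_gate_features(tr$images, gate_threshold)
  present <- as.integer(pos > 0)
  gate <- NULL
  if (length(unique(present)) > 1) {
    gate <- nnet::nnet(X, present, size = hyperparams$hidden %||% 8,
                       entropy = TRUE, maxit = hyperparams$maxit %||% 600,
                       decay = hyperparams$decay %||% 1e-4,
                       MaxNWts = 50000, trace = FALSE)
  }
  # stage 2: intensity threshold maximising mean Dice on present slices
  idx <- which(pos > 0)
  idx <- idx[seq_len(min(50, length(idx)))]
  ints <- unlist(lapply(idx, function(i) as.numeric(tr$images[[i]])))
  cand <- unique(stats::quantile(ints, seq(0.5, 0.98,
                                           length.out = hyperparams$n_thresholds %||% 24)))
  min_area <- hyperparams$min_area %||% 40
  scores <- vapply(cand, function(th) {
    mean(vapply(idx, function(i) {
      pred <- clean_mask((tr$images[[i]] >= th) * 1L, bone, min_area)
      dice_coef(pred, tr$masks[[i]])
    }, 0))
  }, 0)
  threshold <- cand[which.max(scores)]
  model <- structure(list(bone = bone, gate = gate, threshold = threshold,
                          gate_threshold = gate_threshold,
                          min_area = min_area,
                          crop_size = dim(tr$images[[1]]),
                          train_dice = max(scores),
                          validation_dice = NA_real_),
                     class = "ak_bone_segmenter")
  if (!is.null(dataset$validation) && length(dataset$validation$images)) {
    preds <- segment_knee_slices(model, dataset$validation$images)
    model$validation_dice <- mean(vapply(seq_along(preds), function(i) {
      dice_coef(preds[[i]], dataset$validation$masks[[i]])
    }, 0))
  }
  model
}

#' Segment cropped knee slices for one bone
#'
#' @param model `ak_bone_segmenter`.
#' @param crops List of ROI-cropped slice matrices (training crop size).
#' @return List of binary integer masks (values 0/1), one per crop.
#' @export
segment_knee_slices <- function(model, crops) {
  if (!identical(dim(crops[[1]]), model$crop_size))
    stop("crop size differs from training size")
  gate_p <- if (is.null(model$gate)) rep(1, length(crops)) else
    as.numeric(predict(model$gate,
                       crop_gate_features(crops, model$gate_threshold)))
  lapply(seq_along(crops), function(i) {
    if (gate_p[i] < 0.5)
      return(matrix(0L, nrow(crops[[i]]), ncol(crops[[i]])))
    clean_mask((crops[[i]] >= model$threshold) * 1L, model$bone,
               model$min_area)
  })
}

#' Ground-truth segmentation oracle
#'
#' Returns the exact phantom mask for one slice and bone, cropped to the
#' ROI (right-knee masks are mirrored to the left-knee convention first).
#' Used to test contour/shape/implant stages independently of learned
#' model quality; available for synthetic runs only.
#'
#' @param truth `knee_ground_truth` from [voxelize_subject()].
#' @param slice 1-based slice index.
#' @param bone `"femur"` or `"tibia"`.
#' @param roi Optional `roi_spec` crop.
#' @return Binary integer mask.
#' @export
oracle_segmenter <- function(truth, slice, bone, roi = NULL) {
  if (!inherits(truth, "knee_ground_truth"))
    stop("ground truth unavailable")
  m <- truth$masks[[bone]][[slice]]
  if (is.null(m)) stop("ground truth unavailable for slice ", slice)
  if (identical(truth$side, "right")) m <- flip_slice_horizontal(m)
  if (!is.null(roi)) m <- crop_matrix(m, roi)
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}

#' Trace bone contours from a binary mask
#'
#' Labels connected components, traces the outer boundary of each (inner
#' hole contours are discarded) and drops contours shorter than
#' `min_length_px` — the noise filter that removes spurious small
#' segmentation fragments.
#'
#' @param mask Binary matrix.
#' @param min_length_px Minimum closed-contour perimeter in px.
#' @return List of contours: each a list with `points` (k x 2 (row, col),
#'   1-based), `closed = TRUE` and `length` (perimeter in px).  Empty mask
#'   gives an empty list.
#' @export
extract_bone_contours <- function(mask, min_length_px = 20) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (!any(mask > 0)) return(list())
  lab <- EBImage::bwlabel(mask)
  chains <- EBImage::ocontour(lab)
  out <- list()
  for (ch in chains) {
    pts <- ch + 1  # 0-based (dim1, dim2) -> 1-based (row, col)
    len <- polyline_length(pts, closed = TRUE)
    if (len >= min_length_px)
      out[[length(out) + 1]] <- list(points = pts, closed = TRUE,
                                     length = len)
  }
  out
}

#' Segmented area of a mask in mm^2
#'
#' @param mask Binary matrix.
#' @param pixel_spacing `(row, col)` spacing in mm.
#' @return Positive-pixel count times pixel area.
#' @export
mask_area_mm2 <- function(mask, pixel_spacing) {
  sum(mask > 0) * pixel_spacing[1] * pixel_spacing[2]
}
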