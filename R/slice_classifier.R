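# Slice classification into the four anatomical classes
# (FIBULA_TIBIA / KNEE / FEMUR / OTHER), label-sequence smoothing, bone
# order and knee-region delimitation.
#
# The classifier is a compact single-hidden-layer network (nnet) over
# block-averaged slice intensities; the contract it fulfils is the
# four-class split at >= 0.95 held-out accuracy on phantom data.

#' Block-average image features
#'
#' Downsamples an intensity matrix to `blocks x blocks` block means and
#' rescales stored intensities to roughly [0, 1].  Resolution independent,
#' so models transfer across slice sizes.
#'
#' @param img Numeric matrix.
#' @param blocks Output grid size.
#' @return Numeric vector of length `blocks^2`.
#' @export
block_features <- function(img, blocks = 16) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- floor((seq_len(nr) - 1) * blocks / nr) + 1
  ci <- floor((seq_len(nc) - 1) * blocks / nc) + 1
  sums <- rowsum(t(rowsum(img, ri)), ci)
  cnt <- tabulate(ri, blocks) %o% tabulate(ci, blocks)
  as.numeric(t(sums) / cnt) / 255
}

feature_matrix <- function(images, blocks) {
  t(vapply(images, block_features, numeric(blocks^2), blocks = blocks))
}

#' Per-slice shape descriptors
#'
#' Compact descriptors of the thresholded bone content of one slice:
#' bone-pixel fraction, connected-component count and the two largest
#' component areas, bounding-box extents, normalised centroid, second
#' moment eccentricity and soft-tissue fraction.  These expose the
#' geometry that separates the four slice classes and carry the knee
#' centre for the box regressor.
#'
#' @param img Intensity matrix (stored values).
#' @param bone_threshold Stored value above which a pixel counts as bone.
#' @return Named numeric vector of length 11.
#' @export
slice_descriptors <- function(img, bone_threshold = 140) {
  npix <- length(img)
  bone <- img >= bone_threshold
  soft_frac <- sum(img >= 30 & img < bone_threshold) / npix
  if (!any(bone)) {
    return(c(frac_bone = 0, n_comp = 0, a1 = 0, a2 = 0, bb_h = 0, bb_w = 0,
             cent_r = 0.5, cent_c = 0.5, ecc = 1, spread = 0,
             soft = soft_frac))
  }
  lab <- EBImage::bwlabel(matrix(as.integer(bone), nrow(img), ncol(img)))
  sizes <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
  sizes <- sizes[sizes >= 8]  # ignore specks
  if (!length(sizes)) sizes <- 0
  rr <- which(bone, arr.ind = TRUE)
  cent <- colMeans(rr)
  if (nrow(rr) >= 3) {
    cv <- stats::cov(rr)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  } else ev <- c(1e-9, 1e-9)
  ecc <- sqrt(max(ev[1], 1e-9) / max(ev[2], 1e-9))
  c(frac_bone = sum(bone) / npix,
    n_comp = min(length(sizes), 4) / 4,
    a1 = sizes[1] / npix,
    a2 = if (length(sizes) > 1) sizes[2] / npix else 0,
    bb_h = diff(range(rr[, 1])) / nrow(img),
    bb_w = diff(range(rr[, 2])) / ncol(img),
    cent_r = cent[1] / nrow(img),
    cent_c = cent[2] / ncol(img),
    ecc = min(ecc, 6) / 6,
    spread = sqrt(sum(ev)) / nrow(img),
    soft = soft_frac)
}

descriptor_matrix <- function(images, bone_threshold = 140) {
  t(vapply(images, slice_descriptors, numeric(11),
           bone_threshold = bone_threshold))
}

#' Train the four-class slice classifier
#'
#' @param dataset List with `train` and optional `validation`, each holding
#'   `images` (list of matrices) and `labels` (character in
#'   FIBULA_TIBIA/KNEE/FEMUR/OTHER).
#' @param hyperparams List: `hidden` units, `maxit`, `decay`,
#'   `bone_threshold` for the slice descriptors.
#' @param seed RNG seed for weight initialisation.
#' @return `ak_slice_classifier` model handle with `validation_accuracy`.
#' @export
train_slice_classifier <- function(dataset,
                                   hyperparams = list(hidden = 12,
                                                      maxit = 500,
                                                      decay = 1e-4,
                                                      bone_threshold = 140),
                                   seed = 1L) {
  tr <- dataset$train %||% dataset
  labs <- factor(tr$labels, levels = AK_CLASSES)
  if (any(is.na(labs))) stop("unknown class label in training data")
  if (any(table(labs) == 0))
    stop("class coverage: every class needs >= 1 training example")
  bone_threshold <- hyperparams$bone_threshold %||% 140
  X <- descriptor_matrix(tr$images, bone_threshold)
  set.seed(seed)
  net <- nnet::nnet(X, nnet::class.ind(labs), size = hyperparams$hidden %||% 12,
                    softmax = TRUE, maxit = hyperparams$maxit %||% 500,
                    decay = hyperparams$decay %||% 1e-4,
                    MaxNWts = 50000, trace = FALSE)
  model <- structure(list(net = net, classes = AK_CLASSES,
                          bone_threshold = bone_threshold,
                          geometry = dim(tr$images[[1]]),
                          validation_accuracy = NA_real_),
                     class = "ak_slice_classifier")
  if (!is.null(dataset$validation) && length(dataset$validation$images)) {
    pred <- classify_images(model, dataset$validation$images)
    model$validation_accuracy <-
      mean(pred$labels == dataset$validation$labels)
  }
  model
}

classify_images <- function(model, images, strict = FALSE) {
  if (strict) {
    dims <- vapply(images, dim, integer(2))
    if (any(dims != model$geometry))
      stop("slice size differs from training geometry (strict mode)")
  }
  X <- descriptor_matrix(images, model$bone_threshold)
  P <- predict(model$net, X, type = "raw")
  P <- P / rowSums(P)
  colnames(P) <- model$classes
  list(labels = model$classes[max.col(P, ties.method = "first")],
       probabilities = P)
}

#' Classify every slice of a CT volume
#'
#' @param model `ak_slice_classifier`.
#' @param vol `ct_volume`.
#' @param strict Error (rather than re-pool features) when slice size
#'   differs from the training geometry.
#' @return `slice_labels` object: per-slice `labels` and a normalised
#'   class-probability matrix.
#' @export
classify_volume <- function(model, vol, strict = FALSE) {
  res <- classify_images(model, vol$slices, strict = strict)
  slice_labels(res$labels, res$probabilities)
}

#' Construct a slice label sequence
#' @param labels Character vector over the four classes.
#' @param probabilities Optional n x 4 matrix, rows summing to 1.
#' @return `slice_labels` object.
#' @export
slice_labels <- function(labels, probabilities = NULL) {
  stopifnot(all(labels %in% AK_CLASSES))
  if (is.null(probabilities)) {
    probabilities <- matrix(0, length(labels), length(AK_CLASSES),
                            dimnames = list(NULL, AK_CLASSES))
    probabilities[cbind(seq_along(labels),
                        match(labels, AK_CLASSES))] <- 1
  }
  stopifnot(nrow(probabilities) == length(labels))
  structure(list(labels = labels, probabilities = probabilities),
            class = "slice_labels")
}

#' @export
print.slice_labels <- function(x, ...) {
  r <- rle(x$labels)
  cat("slice_labels:", length(x$labels), "slices;",
      paste(sprintf("%s x%d", r$values, r$lengths), collapse = " | "), "\n")
  invisible(x)
}

#' Majority-vote smoothing of a slice label sequence
#'
#' Sliding-window majority vote; ties keep the original label.  Never
#' introduces a class absent from the window.
#'
#' @param seq `slice_labels`.
#' @param window Odd window width (1 = identity).
#' @return Smoothed `slice_labels` (probabilities carried through
#'   unchanged).
#' @export
smooth_labels <- function(seq, window = 5) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  labs <- seq$labels
  n <- length(labs)
  half <- (window - 1) %/% 2
  out <- labs
  if (half > 0) {
    for (i in seq_len(n)) {
      w <- labs[max(1, i - half):min(n, i + half)]
      tab <- table(w)
      top <- names(tab)[tab == max(tab)]
      out[i] <- if (length(top) == 1) top
        else if (labs[i] %in% top) labs[i] else top[1]
    }
  }
  slice_labels(out, seq$probabilities)
}

#' Determine the scan's bone order
#'
#' Compares the median slice positions of the FIBULA_TIBIA and FEMUR runs;
#' downstream stages renormalise stacks so z increases tibia to femur.
#'
#' @param seq `slice_labels`.
#' @return `"tibia_to_femur"` or `"femur_to_tibia"`.
#' @export
determine_bone_order <- function(seq) {
  labs <- seq$labels
  it <- which(labs == "FIBULA_TIBIA")
  ifm <- which(labs == "FEMUR")
  if (!length(it) || !length(ifm))
    stop("indeterminate order: need both FIBULA_TIBIA and FEMUR slices")
  if (stats::median(it) < stats::median(ifm)) "tibia_to_femur"
  else "femur_to_tibia"
}

#' Delimit the knee region
#'
#' Returns the longest contiguous run of KNEE labels as 1-based inclusive
#' `(first, last)` slice indices.
#'
#' @param seq `slice_labels`.
#' @return Integer pair `(first, last)`.
#' @export
knee_slice_range <- function(seq) {
  r <- rle(seq$labels == "KNEE")
  if (!any(r$values)) stop("no knee region: no KNEE slice present")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  knee_runs <- which(r$values)
  best <- knee_runs[which.max(r$lengths[knee_runs])]
  c(first = starts[best], last = ends[best])
}
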