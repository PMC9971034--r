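# CT volume ingest and export.
#
# Package-wide coordinate convention: pixel (row r, col c) of slice k
# (all 1-based in R) maps to the mm point
#   x = (c - 1) * pixel_spacing[2],  y = (r - 1) * pixel_spacing[1],
#   z = (k - 1) * slice_spacing
# relative to the volume origin (position of pixel (1,1) of slice 1).

#' Construct a CT volume
#'
#' @param slices List of equally sized integer matrices (stored values),
#'   ordered along the scan axis.
#' @param pixel_spacing `(row, col)` in-plane spacing, mm.
#' @param slice_spacing Inter-slice spacing, mm.
#' @param slice_ids Acquisition indices (default sequential).
#' @param origin `(x, y, z)` mm position of pixel (1,1) of slice 1.
#' @return Object of class `ct_volume`.
#' @export
ct_volume <- function(slices, pixel_spacing, slice_spacing,
                      slice_ids = seq_along(slices), origin = c(0, 0, 0)) {
  stopifnot(length(slices) >= 1, all(pixel_spacing > 0), slice_spacing > 0)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inhomogeneous series: slice dimensions differ")
  if (is.unsorted(slice_ids, strictly = TRUE))
    stop("slice_ids must be strictly increasing")
  structure(list(slices = slices,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_spacing = as.numeric(slice_spacing),
                 slice_ids = as.integer(slice_ids),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("ct_volume: %d slices of %d x %d px, %.3f x %.3f mm in-plane, %.3f mm spacing\n",
              length(x$slices), d[1], d[2],
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_spacing))
  invisible(x)
}

#' Number of slices
#' @param vol `ct_volume`.
#' @return Integer count.
#' @export
n_slices <- function(vol) length(vol$slices)

#' Write a CT volume as a DICOM series
#'
#' One single-frame file per slice, named by zero-padded acquisition index.
#'
#' @param vol `ct_volume`.
#' @param dir Output directory (created if missing).
#' @param series_uid Optional series UID; generated when `NULL`.
#' @return Character vector of written file paths, invisibly.
#' @export
write_dicom_series <- function(vol, dir, series_uid = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(series_uid))
    series_uid <- paste0(dicom_uid_root, ".",
                         format(sample.int(.Machine$integer.max, 1)))
  paths <- character(n_slices(vol))
  for (k in seq_len(n_slices(vol))) {
    pos <- vol$origin + c(0, 0, (k - 1) * vol$slice_spacing)
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", vol$slice_ids[k]))
    write_dicom_slice(vol$slices[[k]], paths[k],
                      pixel_spacing = vol$pixel_spacing,
                      slice_thickness = vol$slice_spacing,
                      spacing_between = vol$slice_spacing,
                      position = pos,
                      instance = vol$slice_ids[k],
                      series_uid = series_uid)
  }
  invisible(paths)
}

#' Load a DICOM series into an ordered CT volume
#'
#' Reads every DICOM file in `directory`, checks that a single series is
#' present, sorts slices by image position along the scan axis (falling
#' back to instance number), and derives the slice spacing from the
#' inter-slice position deltas; the per-file spacing tag is only trusted
#' when it agrees with the deltas.
#'
#' @param directory Directory containing one single-frame CT series.
#' @return `ct_volume`.
#' @export
load_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  recs <- list()
  for (f in files) {
    rec <- tryCatch(read_dicom_slice(f), error = function(e) NULL)
    if (!is.null(rec)) recs[[length(recs) + 1]] <- rec
  }
  if (length(recs) < 2)
    stop("no usable series in ", directory,
         " (need >= 2 readable single-frame DICOM files)")
  uids <- vapply(recs, function(r) r$series_uid %||% "", "")
  if (length(unique(uids)) != 1)
    stop("no usable series: directory mixes multiple series")
  dims <- vapply(recs, function(r) dim(r$img), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inhomogeneous series: slice dimensions differ")
  zs <- vapply(recs, function(r) {
    if (!is.null(r$position)) r$position[3] else NA_real_
  }, 0)
  ord <- if (all(is.finite(zs))) order(zs) else
    order(vapply(recs, function(r) r$instance, 0L))
  recs <- recs[ord]; zs <- zs[ord]
  deltas <- diff(zs)
  slice_spacing <- if (all(is.finite(deltas)) && length(deltas))
    stats::median(deltas) else recs[[1]]$spacing_between
  tag_sp <- recs[[1]]$spacing_between
  if (is.finite(tag_sp) && is.finite(slice_spacing) &&
      abs(tag_sp - slice_spacing) < 1e-6)
    slice_spacing <- tag_sp
  ct_volume(slices = lapply(recs, `[[`, "img"),
            pixel_spacing = recs[[1]]$pixel_spacing,
            slice_spacing = slice_spacing,
            slice_ids = seq_along(recs),
            origin = recs[[1]]$position %||% c(0, 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linearly window an intensity matrix to 8 bits
#' @keywords internal
window_to_8bit <- function(img, window) {
  lo <- window[1]; hi <- window[2]
  if (!(lo < hi)) stop("window must satisfy lo < hi")
  x <- (img - lo) / (hi - lo)
  x[x < 0] <- 0; x[x > 1] <- 1
  x
}

#' Export windowed per-slice PNG images
#'
#' Each slice is linearly mapped from the intensity window to 8-bit grey
#' (clipped outside it) and written as `slice_XXXX.png`.
#'
#' @param vol `ct_volume`.
#' @param out_dir Output directory (created if missing).
#' @param window `(lo, hi)` stored-intensity window; defaults to the
#'   package's bone window [ak_default_window()].
#' @return Character vector of file paths, invisibly.
#' @export
export_slice_images <- function(vol, out_dir, window = ak_default_window()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  paths <- character(n_slices(vol))
  for (k in seq_len(n_slices(vol))) {
    g <- window_to_8bit(vol$slices[[k]], window)
    paths[k] <- file.path(out_dir, sprintf("slice_%04d.png", k))
    png::writePNG(g, paths[k])
  }
  invisible(paths)
}

#' Default display window for stored CT values
#'
#' The phantom's stored-value scale puts air at 0, soft tissue near 60 and
#' bone near 220; the default window spans the full informative range so
#' exports are deterministic.
#' @return `(lo, hi)` numeric pair.
#' @export
ak_default_window <- function() c(0, 255)

#' Flip a slice image horizontally
#'
#' Reverses the column order (mirror about the vertical axis); applying it
#' twice returns the input exactly.  Used to map right knees onto the
#' left-knee convention before detection.
#'
#' @param img 2-D matrix.
#' @return Flipped matrix.
#' @export
flip_slice_horizontal <- function(img) {
  if (!length(img)) stop("empty image")
  img[, rev(seq_len(ncol(img))), drop = FALSE]
}
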