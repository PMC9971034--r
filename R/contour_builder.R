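# Per-slice area profiles, tibia-femur transition detection, and assembly
# of trimmed 3-D contour stacks.
#
# The transition slice is where the femoral condyles end and the tibial
# plateau begins: with slice indices normalised tibia -> femur, it is the
# first index between the two area-curve maxima at which the femur curve
# meets or exceeds the tibia curve.

#' Per-slice segmented-area profiles for both bones
#'
#' @param femur_masks,tibia_masks Aligned lists of binary masks over the
#'   knee range.
#' @param pixel_spacing `(row, col)` mm.
#' @return `area_profile`: list with `femur` and `tibia` mm^2 vectors.
#' @export
area_profiles <- function(femur_masks, tibia_masks, pixel_spacing) {
  if (length(femur_masks) != length(tibia_masks))
    stop("mask lists must be aligned by slice")
  structure(list(
    femur = vapply(femur_masks, mask_area_mm2, 0, pixel_spacing),
    tibia = vapply(tibia_masks, mask_area_mm2, 0, pixel_spacing)),
    class = "area_profile")
}

#' Find the tibia-femur transition slice
#'
#' Locates both curve maxima and scans the closed interval between them
#' (in tibia -> femur orientation) for the first index where
#' `femur >= tibia`; equality resolves to that index.
#'
#' @param profile `area_profile` (or list with `femur`/`tibia` vectors).
#' @param order Slice direction of the input profile.
#' @return 1-based slice index into the profile as given.
#' @export
find_transition_slice <- function(profile,
                                  order = c("tibia_to_femur",
                                            "femur_to_tibia")) {
  order <- match.arg(order)
  fa <- profile$femur; ta <- profile$tibia
  n <- length(fa)
  if (order == "femur_to_tibia") { fa <- rev(fa); ta <- rev(ta) }
  if (max(fa) <= 0 || max(ta) <= 0)
    stop("no transition found: a bone curve has no positive maximum")
  at <- which.max(ta); af <- which.max(fa)
  if (!(at < af))
    stop("inconsistent profile: tibia maximum must precede femur maximum")
  for (k in at:af) {
    if (fa[k] >= ta[k])
      return(if (order == "femur_to_tibia") n - k + 1L else k)
  }
  stop("no transition found: curves do not intersect between the maxima")
}

#' Contour stack container
#'
#' @param slices List of `(z, points)` entries; `points` is a k x 2 (x, y)
#'   mm matrix.
#' @param bone Bone tag.
#' @param slice_spacing Source spacing in mm.
#' @return `contour_stack`.
#' @export
contour_stack <- function(slices, bone, slice_spacing) {
  zs <- vapply(slices, `[[`, 0, "z")
  if (length(zs) > 1 && any(diff(zs) <= 0)) stop("z must be increasing")
  if (any(vapply(slices, function(s) nrow(s$points) == 0, TRUE)))
    stop("empty polyline in contour stack")
  structure(list(slices = slices, bone = bone,
                 slice_spacing = slice_spacing), class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  zs <- vapply(x$slices, `[[`, 0, "z")
  cat(sprintf("contour_stack (%s): %d slices, z %.1f..%.1f mm, %d points\n",
              x$bone, length(x$slices), min(zs), max(zs),
              nrow(stack_points(x))))
  invisible(x)
}

#' All stack points as an n x 3 matrix
#' @param stack `contour_stack`.
#' @return n x 3 (x, y, z) mm matrix.
#' @export
stack_points <- function(stack) {
  do.call(rbind, lapply(stack$slices, function(s) {
    cbind(s$points, s$z)
  }))
}

contours_to_mm <- function(contours, pixel_spacing) {
  pts <- do.call(rbind, lapply(contours, `[[`, "points"))
  if (is.null(pts)) return(matrix(numeric(0), 0, 2))
  # (row, col) 1-based -> (x, y) mm in the ROI frame
  cbind((pts[, 2] - 1) * pixel_spacing[2], (pts[, 1] - 1) * pixel_spacing[1])
}

#' Split contours at the transition and build both stacks
#'
#' In tibia -> femur orientation the tibia stack covers slices
#' `(knee_first + trim) .. (transition - 1)` and the femur stack
#' `transition .. (knee_last - trim)` (1-based inclusive, knee-relative):
#' contours up to the transition belong to the tibia, contours from it on
#' to the femur, and `trim` slices are dropped at the two knee-region
#' boundary ends where end-of-region segmentation noise concentrates.
#'
#' @param femur_contours,tibia_contours Lists (one entry per knee slice,
#'   each a list of contours from [extract_bone_contours()]).
#' @param transition Knee-relative 1-based transition slice index.
#' @param knee_range Volume slice indices `(first, last)` of the knee run.
#' @param trim Slices trimmed at each outer end (default 5).
#' @param pixel_spacing `(row, col)` mm of the crops.
#' @param slice_spacing mm between slices.
#' @return List with `femur` and `tibia` `contour_stack`s.
#' @export
split_and_build_stacks <- function(femur_contours, tibia_contours,
                                   transition, knee_range, trim = 5,
                                   pixel_spacing, slice_spacing) {
  n <- length(femur_contours)
  stopifnot(length(tibia_contours) == n, trim >= 0)
  if (transition < 1 || transition > n)
    stop("transition outside knee range")
  tib_idx <- seq_len(n)[seq_len(n) >= 1 + trim & seq_len(n) < transition]
  fem_idx <- seq_len(n)[seq_len(n) >= transition & seq_len(n) <= n - trim]
  if (!length(tib_idx) || !length(fem_idx))
    stop("stack too short: trim consumes an entire stack")
  build <- function(contour_list, idx, bone) {
    slices <- list()
    for (k in idx) {
      pts <- contours_to_mm(contour_list[[k]], pixel_spacing)
      if (nrow(pts) == 0) next  # slice without surviving contours
      vol_slice <- knee_range[1] + k - 1
      slices[[length(slices) + 1]] <-
        list(z = (vol_slice - 1) * slice_spacing, points = pts)
    }
    if (!length(slices)) stop("stack too short: no contours for ", bone)
    contour_stack(slices, bone, slice_spacing)
  }
  list(femur = build(femur_contours, fem_idx, "femur"),
       tibia = build(tibia_contours, tib_idx, "tibia"))
}
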