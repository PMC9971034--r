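# Parametric knee phantom generator.
#
# Stands in for a restricted clinical training corpus: a population of
# distal-femur / proximal-tibia / fibula-stub triangle meshes in exact
# vertex correspondence (every subject deforms one template analytically),
# voxelised into CT-like volumes with full ground truth (per-bone masks,
# per-slice class labels, knee bounding boxes, source meshes).
#
# Canonical LEFT-knee frame: x medial-lateral (medial = +x), y
# anterior-posterior, z scan axis increasing tibia -> femur; the joint
# space sits near z = -2 mm.

AK_CLASSES <- c("FIBULA_TIBIA", "KNEE", "FEMUR", "OTHER")

# template constants (mm / dimensionless)
ak_template <- function() {
  list(
    femur_z = c(3, 45), femur_r = 26, femur_rings = 26, femur_seg = 56,
    femur_wx = 1.0, femur_wy = 0.78, condyle_amp = 0.35, condyle_decay = 3,
    notch_amp = 0.28, notch_width = 0.55,
    tibia_z = c(-39, -3), tibia_r = 24, tibia_rings = 22, tibia_seg = 48,
    tibia_wx = 1.0, tibia_wy = 0.82, tibia_amp = 0.12,
    plateau_slope_deg = 4,
    fibula_centre = c(-27, 4), fibula_r = 4.5, fibula_z = c(-39, -12),
    fibula_rings = 6, fibula_seg = 16,
    patella_centre = c(0, -34), patella_r = 12, patella_wy = 0.55,
    patella_z = c(-6, 8), patella_rings = 8, patella_seg = 20,
    soft_axes = c(52, 46), soft_centre = c(0, 2), soft_z = c(-44, 43),
    # knee-class band: where the condylar flare / plateau flare is visible
    # (envelope factor >= 0.55); boundaries derived from the envelopes below
    knee_band_z = c(-14.2, 20.3),
    intensity = c(air = 0, soft = 60, bone = 220)
  )
}

#' Population parameters for the phantom generator
#'
#' The defaults define the study conditions used throughout the package:
#' a global-scale mode (sd 0.04, dimensionless), a femoral condyle
#' prominence/spacing mode (sd 0.05, dimensionless lobe amplitude), and a
#' tibial plateau slope mode (sd 3 degrees around a 4 degree template
#' slope), plus 0.1 mm isotropic vertex jitter.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param mode_sds Named numeric: `scale`, `condyle`, `slope_deg`.
#' @param noise_sd_mm Isotropic vertex jitter, mm.
#' @param offset_sd_mm In-plane knee off-centre sd, mm (clamped at 2 sd).
#' @param seed RNG seed.
#' @return Object of class `population_params`.
#' @export
population_params <- function(n_subjects = 20,
                              mode_sds = c(scale = 0.04, condyle = 0.05,
                                           slope_deg = 3),
                              noise_sd_mm = 0.1,
                              offset_sd_mm = 5,
                              seed = 1L) {
  stopifnot(n_subjects >= 2, all(mode_sds >= 0), noise_sd_mm >= 0)
  need <- c("scale", "condyle", "slope_deg")
  if (!all(need %in% names(mode_sds)))
    stop("mode_sds must name: ", paste(need, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 mode_sds = mode_sds[need],
                 noise_sd_mm = noise_sd_mm,
                 offset_sd_mm = offset_sd_mm,
                 seed = as.integer(seed)),
            class = "population_params")
}

# radial tube builder shared by all bones
build_tube <- function(z_range, n_rings, n_seg, radius_fun, centre_fun,
                       wx, wy) {
  ts <- seq(0, 1, length.out = n_rings)
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  rings <- lapply(ts, function(t) {
    r <- radius_fun(theta, t)
    ctr <- centre_fun(t)
    z <- z_range[1] + t * (z_range[2] - z_range[1])
    cbind(ctr[1] + r * cos(theta) * wx,
          ctr[2] + r * sin(theta) * wy,
          rep(z, n_seg))
  })
  rings
}

# deterministic mesh for one subject given mode weights
phantom_meshes <- function(w_scale, w_condyle, w_slope_rad, noise_sd,
                           tmpl = ak_template()) {
  g <- 1 + w_scale
  if (g <= 0.05) stop("degenerate phantom: non-positive scale")
  # condylar bulge near the distal end, narrowing to a shaft proximally
  femur_s <- function(t) tmpl$femur_r *
    (0.45 + 0.55 * exp(-((t - 0.15) / 0.20)^2))
  femur_rad <- function(theta, t) {
    decay <- exp(-tmpl$condyle_decay * t)
    amp <- (tmpl$condyle_amp + w_condyle) * decay
    # intercondylar notch: posterior concavity between the condyles
    dth <- atan2(sin(theta - 3 * pi / 2), cos(theta - 3 * pi / 2))
    notch <- tmpl$notch_amp * decay * exp(-(dth / tmpl$notch_width)^2)
    femur_s(t) * (1 + amp * cos(2 * theta) - notch)
  }
  femur_rings <- build_tube(tmpl$femur_z, tmpl$femur_rings, tmpl$femur_seg,
                            femur_rad, function(t) c(0, 0),
                            tmpl$femur_wx, tmpl$femur_wy)
  femur <- tube_mesh(femur_rings)

  # narrow shaft flaring into the plateau near the proximal end
  tibia_s <- function(t) tmpl$tibia_r * (0.42 + 0.58 * t^4)
  tibia_rad <- function(theta, t) {
    tibia_s(t) * (1 + tmpl$tibia_amp * cos(2 * theta))
  }
  tibia_rings <- build_tube(tmpl$tibia_z, tmpl$tibia_rings, tmpl$tibia_seg,
                            tibia_rad, function(t) c(0, 0),
                            tmpl$tibia_wx, tmpl$tibia_wy)
  # plateau slope: tilt the proximal rings about the y axis
  slope <- tmpl$plateau_slope_deg * pi / 180 + w_slope_rad
  ts <- seq(0, 1, length.out = tmpl$tibia_rings)
  for (k in seq_along(tibia_rings)) {
    wgt <- max(0, (ts[k] - 0.6) / 0.4)^2
    tibia_rings[[k]][, 3] <- tibia_rings[[k]][, 3] +
      wgt * tan(slope) * tibia_rings[[k]][, 1]
  }
  tibia <- tube_mesh(tibia_rings)

  fib_rad <- function(theta, t) rep(tmpl$fibula_r, length(theta))
  fib_rings <- build_tube(tmpl$fibula_z, tmpl$fibula_rings, tmpl$fibula_seg,
                          fib_rad, function(t) tmpl$fibula_centre, 1, 1)
  fibula <- tube_mesh(fib_rings)

  # patella: small flat ellipsoid anterior to the joint space
  pat_rad <- function(theta, t) {
    tmpl$patella_r * (0.15 + 0.85 * sin(pi * t)) * rep(1, length(theta))
  }
  pat_rings <- build_tube(tmpl$patella_z, tmpl$patella_rings,
                          tmpl$patella_seg, pat_rad,
                          function(t) tmpl$patella_centre, 1,
                          tmpl$patella_wy)
  patella <- tube_mesh(pat_rings)

  out <- lapply(list(femur = femur, tibia = tibia, fibula = fibula,
                     patella = patella),
                function(m) scale_mesh(m, g))
  if (noise_sd > 0) {
    for (nm in names(out)) {
      V <- out[[nm]]$vertices
      out[[nm]]$vertices <- V + matrix(rnorm(length(V), 0, noise_sd),
                                       nrow(V), 3)
    }
  }
  out
}

#' Generate a corresponded phantom bone population
#'
#' Every subject is an analytic deformation of one template (scale,
#' condyle prominence, plateau slope) plus small vertex jitter, so all
#' femur (resp. tibia) meshes share identical topology and are in exact
#' vertex correspondence by construction.
#'
#' @param params [population_params()].
#' @return List of `knee_phantom` subjects, each holding `femur`, `tibia`,
#'   `fibula` meshes (left-knee frame), `mode_weights`, `side`, in-plane
#'   `offset_mm` and cohort `metadata` (sex, age, height).
#' @export
generate_bone_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  sds <- params$mode_sds
  w_scale <- rnorm(n, 0, sds["scale"])
  w_condyle <- rnorm(n, 0, sds["condyle"])
  w_slope <- rnorm(n, 0, sds["slope_deg"] * pi / 180)
  off <- matrix(rnorm(2 * n, 0, params$offset_sd_mm), n, 2)
  off <- pmin(pmax(off, -2 * params$offset_sd_mm), 2 * params$offset_sd_mm)
  sides <- rep(c("left", "right"), length.out = n)
  sexes <- rep(c("F", "M"), length.out = n)
  ages <- sample(21:60, n, replace = TRUE)
  heights <- round(161 * (1 + w_scale) + rnorm(n, 0, 2), 1)
  lapply(seq_len(n), function(i) {
    meshes <- phantom_meshes(w_scale[i], w_condyle[i], w_slope[i],
                             params$noise_sd_mm)
    structure(list(id = sprintf("subj%03d", i),
                   femur = meshes$femur, tibia = meshes$tibia,
                   fibula = meshes$fibula, patella = meshes$patella,
                   mode_weights = c(scale = w_scale[i],
                                    condyle = w_condyle[i],
                                    slope_rad = w_slope[i]),
                   side = sides[i],
                   offset_mm = off[i, ],
                   metadata = list(sex = sexes[i], age = ages[i],
                                   height_cm = heights[i])),
              class = "knee_phantom")
  })
}

#' @export
print.knee_phantom <- function(x, ...) {
  cat(sprintf("knee_phantom %s (%s knee, %s, %d y, %.0f cm)\n",
              x$id, x$side, x$metadata$sex, x$metadata$age,
              x$metadata$height_cm))
  cat(sprintf("  mode weights: scale %+.3f condyle %+.3f slope %+.2f deg\n",
              x$mode_weights[1], x$mode_weights[2],
              x$mode_weights[3] * 180 / pi))
  invisible(x)
}

# mm grid description for a phantom volume
phantom_grid <- function(subject, pixel_mm, slice_mm, n_px = 176) {
  tmpl <- ak_template()
  half <- n_px / 2 * pixel_mm
  origin <- c(-half + subject$offset_mm[1],
              -half + subject$offset_mm[2], -52)
  nz <- ceiling(104 / slice_mm)
  list(n_px = n_px, nz = nz, origin = origin,
       pixel_spacing = c(pixel_mm, pixel_mm), slice_spacing = slice_mm,
       zs = origin[3] + (seq_len(nz) - 1) * slice_mm, tmpl = tmpl)
}

slice_mask <- function(m, z, grid) {
  loops <- slice_mesh_z(m, z)
  rasterize_loops(loops, grid$n_px, grid$n_px,
                  grid$origin[1:2], grid$pixel_spacing)
}

#' Voxelise a phantom subject into a CT-like volume with ground truth
#'
#' Bone voxels take the high stored intensity, a soft-tissue ellipse the
#' medium one, air the low one; Gaussian read noise is added on top.
#' Right-knee subjects are mirrored at the image level (the stored
#' ground-truth meshes remain in the canonical left frame, matching the
#' pipeline's flip-to-left convention).
#'
#' @param subject `knee_phantom`.
#' @param pixel_mm In-plane spacing (default 0.8 mm).
#' @param slice_mm Slice spacing (default 1 mm).
#' @param noise_sd Intensity noise sd in stored units (default 8).
#' @param seed RNG seed for the noise.
#' @param masks_only Skip intensity synthesis (ground truth only; the
#'   returned volume slices are then the raw class intensities without
#'   noise).
#' @return List with `volume` (`ct_volume`) and `truth`
#'   (`knee_ground_truth`: per-bone masks, per-slice labels, knee boxes,
#'   source meshes, true transition slice).
#' @export
voxelize_subject <- function(subject, pixel_mm = 0.8, slice_mm = 1,
                             noise_sd = 8, seed = 1L, masks_only = FALSE) {
  stopifnot(pixel_mm > 0, slice_mm > 0)
  grid <- phantom_grid(subject, pixel_mm, slice_mm)
  tmpl <- grid$tmpl
  g <- 1 + subject$mode_weights[["scale"]]
  # field-of-view check on bone meshes
  for (nm in c("femur", "tibia", "fibula", "patella")) {
    bb <- apply(subject[[nm]]$vertices, 2, range)
    if (bb[1, 1] < grid$origin[1] || bb[2, 1] > grid$origin[1] +
        (grid$n_px - 1) * pixel_mm ||
        bb[1, 2] < grid$origin[2] || bb[2, 2] > grid$origin[2] +
        (grid$n_px - 1) * pixel_mm ||
        bb[1, 3] < grid$zs[1] || bb[2, 3] > grid$zs[grid$nz])
      stop("FOV overflow: ", nm, " extends outside the voxel grid")
  }
  set.seed(seed)
  inten <- tmpl$intensity
  n_px <- grid$n_px
  flip_right <- identical(subject$side, "right")
  # soft-tissue ellipse mask (constant across its z range)
  xs <- grid$origin[1] + (seq_len(n_px) - 1) * pixel_mm
  ys <- grid$origin[2] + (seq_len(n_px) - 1) * pixel_mm
  ex <- (outer(rep(1, n_px), xs) - tmpl$soft_centre[1]) / (tmpl$soft_axes[1] * g)
  ey <- (outer(ys, rep(1, n_px)) - tmpl$soft_centre[2]) / (tmpl$soft_axes[2] * g)
  soft_mask <- (ex^2 + ey^2 <= 1) * 1L
  if (flip_right) soft_mask <- flip_slice_horizontal(soft_mask)
  slices <- vector("list", grid$nz)
  masks <- list(femur = vector("list", grid$nz),
                tibia = vector("list", grid$nz),
                fibula = vector("list", grid$nz),
                patella = vector("list", grid$nz))
  labels <- character(grid$nz)
  boxes <- vector("list", grid$nz)
  knee_band <- tmpl$knee_band_z * g
  for (k in seq_len(grid$nz)) {
    z <- grid$zs[k]
    mf <- slice_mask(subject$femur, z, grid)
    mt <- slice_mask(subject$tibia, z, grid)
    mb <- slice_mask(subject$fibula, z, grid)
    mp <- slice_mask(subject$patella, z, grid)
    soft_here <- z >= tmpl$soft_z[1] * g && z <= tmpl$soft_z[2] * g
    if (flip_right) {
      mf <- flip_slice_horizontal(mf); mt <- flip_slice_horizontal(mt)
      mb <- flip_slice_horizontal(mb); mp <- flip_slice_horizontal(mp)
    }
    masks$femur[[k]] <- mf; masks$tibia[[k]] <- mt; masks$fibula[[k]] <- mb
    masks$patella[[k]] <- mp
    bone <- pmax(mf, mt, mb, mp)
    has_bone <- any(bone > 0)
    labels[k] <- if (z >= knee_band[1] && z <= knee_band[2]) "KNEE"
      else if (has_bone && z < knee_band[1]) "FIBULA_TIBIA"
      else if (has_bone && z > knee_band[2]) "FEMUR"
      else "OTHER"
    if (labels[k] == "KNEE" && has_bone) {
      rr <- range(which(rowSums(bone) > 0))
      cc <- range(which(colSums(bone) > 0))
      boxes[[k]] <- list(centre = c(mean(rr), mean(cc)),
                         height = diff(rr) + 1, width = diff(cc) + 1)
    }
    if (masks_only) {
      img <- soft_here * soft_mask * (inten["soft"])
      img <- pmax(img, bone * inten["bone"])
      slices[[k]] <- matrix(as.integer(img), n_px, n_px)
    } else {
      img <- matrix(inten["air"], n_px, n_px)
      if (soft_here) img[soft_mask > 0] <- inten["soft"]
      img[bone > 0] <- inten["bone"]
      if (noise_sd > 0)
        img <- img + matrix(rnorm(n_px * n_px, 0, noise_sd), n_px, n_px)
      img <- round(pmin(pmax(img, 0), 1000))
      slices[[k]] <- matrix(as.integer(img), n_px, n_px)
    }
  }
  vol <- ct_volume(slices, grid$pixel_spacing, grid$slice_spacing,
                   origin = grid$origin)
  # proximal-most tibia point: where the plateau begins
  boundary_z <- max(subject$tibia$vertices[, 3])
  truth <- structure(list(
    masks = masks, labels = labels, boxes = boxes,
    meshes = list(femur = subject$femur, tibia = subject$tibia),
    side = subject$side,
    transition_slice = which.min(abs(grid$zs - boundary_z)),
    plateau_top_z = boundary_z, condyle_tip_z = 3 * g,
    origin = grid$origin, pixel_spacing = grid$pixel_spacing,
    slice_spacing = grid$slice_spacing, zs = grid$zs,
    subject_id = subject$id, metadata = subject$metadata),
    class = "knee_ground_truth")
  list(volume = vol, truth = truth)
}

#' Build labelled training fixtures for the learned pipeline stages
#'
#' Voxelises each subject and assembles three datasets: full-slice images
#' with class labels (classifier), knee-slice images with bounding-box
#' centres (detector) and 160 x 160 knee crops with per-bone masks
#' (segmenters).  Right-knee subjects are mirrored to the left-knee
#' convention before cropping, so both sides contribute crops.  The
#' train/validation split is by subject, never by slice.
#'
#' @param pop List of `knee_phantom` subjects.
#' @param split `(train, validation)` fractions summing to 1.
#' @param seed RNG seed (noise + split).
#' @param roi_size Crop size in px (default 160).
#' @param pixel_mm,slice_mm,noise_sd Voxelisation settings.
#' @return List with `classifier`, `detector`, `segmentation` (per bone),
#'   each split into `train` / `validation`.
#' @export
make_training_fixtures <- function(pop, split = c(0.7, 0.3), seed = 1L,
                                   roi_size = 160, pixel_mm = 0.8,
                                   slice_mm = 1, noise_sd = 8) {
  if (!length(pop)) stop("empty population")
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  set.seed(seed)
  n <- length(pop)
  n_train <- max(1L, round(split[1] * n))
  ord <- sample.int(n)
  train_ids <- sort(ord[seq_len(n_train)])
  is_train <- seq_len(n) %in% train_ids
  cls <- list(train = list(images = list(), labels = character()),
              validation = list(images = list(), labels = character()))
  det <- list(train = list(images = list(), centres = NULL),
              validation = list(images = list(), centres = NULL))
  seg <- list(
    femur = list(train = list(images = list(), masks = list()),
                 validation = list(images = list(), masks = list())),
    tibia = list(train = list(images = list(), masks = list()),
                 validation = list(images = list(), masks = list())))
  for (i in seq_len(n)) {
    vx <- voxelize_subject(pop[[i]], pixel_mm, slice_mm, noise_sd,
                           seed = seed + i)
    part <- if (is_train[i]) "train" else "validation"
    vol <- vx$volume; truth <- vx$truth
    # classifier: raw full slices (classification precedes the left-flip
    # convention, so both orientations appear in training)
    cls[[part]]$images <- c(cls[[part]]$images, vol$slices)
    cls[[part]]$labels <- c(cls[[part]]$labels, truth$labels)
    # detector/segmentation operate in the left-knee convention
    imgs <- vol$slices
    if (identical(truth$side, "right"))
      imgs <- lapply(imgs, flip_slice_horizontal)
    # detector: knee slices with known boxes (boxes stored in original
    # image frame; mirror for right knees to match flipped images)
    kn <- which(!vapply(truth$boxes, is.null, TRUE))
    ctrs <- t(vapply(kn, function(k) {
      ctr <- truth$boxes[[k]]$centre
      if (identical(truth$side, "right"))
        ctr[2] <- ncol(imgs[[k]]) + 1 - ctr[2]
      ctr
    }, numeric(2)))
    det[[part]]$images <- c(det[[part]]$images, imgs[kn])
    det[[part]]$centres <- rbind(det[[part]]$centres, ctrs)
    # segmentation crops at the volume's median ROI
    if (length(kn)) {
      roi <- median_roi_box(lapply(kn, function(k) {
        ctr <- truth$boxes[[k]]$centre
        if (identical(truth$side, "right"))
          ctr[2] <- ncol(imgs[[k]]) + 1 - ctr[2]
        ctr
      }), size = roi_size, image_dim = dim(imgs[[1]]))
      for (k in kn) {
        crop_img <- crop_matrix(imgs[[k]], roi)
        for (bone in c("femur", "tibia")) {
          msk <- truth$masks[[bone]][[k]]
          if (identical(truth$side, "right"))
            msk <- flip_slice_horizontal(msk)
          seg[[bone]][[part]]$images <-
            c(seg[[bone]][[part]]$images, list(crop_img))
          seg[[bone]][[part]]$masks <-
            c(seg[[bone]][[part]]$masks, list(crop_matrix(msk, roi)))
        }
      }
    }
  }
  list(classifier = cls, detector = det, segmentation = seg,
       train_subjects = vapply(pop[is_train], `[[`, "", "id"),
       validation_subjects = vapply(pop[!is_train], `[[`, "", "id"))
}
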