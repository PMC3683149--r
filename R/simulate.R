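#' Configuration for synthetic cohort generation
#'
#' Defaults emulate the simulated study populations at desk scale: a 64^3
#' grid at 2 mm spacing (128 mm field of view), cohorts of 20 images,
#' Rician noise at 3% of the maximum intensity, one spherical
#' hyper-intense lesion per image with intensity 1-2 times the mean brain
#' tissue intensity and radius drawn uniformly from 0 up to the phantom
#' brain radius, and random 9-dof transforms with translations within
#' +/- 7 mm (the +/- 20 mm of the full-size setting scaled with the
#' geometry), rotations within +/- 30 degrees and scales within
#' +/- 0.025.
#'
#' @param cohort_size number of images per cohort.
#' @param shape grid dimensions (3 integers).
#' @param spacing voxel size in mm (scalar or length 3).
#' @param noise_fraction Rician noise sigma as a fraction of the maximum
#'   intensity.
#' @param lesion_radius_range radius range in mm; `NULL` means 0 up to the
#'   phantom brain radius.
#' @param lesion_factor_range lesion intensity as a multiple of the mean
#'   tissue intensity.
#' @param lesions_per_image lesions inserted per image.
#' @param max_translation,max_rotation,max_scale half-widths of the
#'   uniform 9-dof parameter ranges (mm, degrees, scale offset).
#' @param seed master seed; every random draw in [build_cohort()] derives
#'   from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(cohort_size = 20, shape = c(64, 64, 64),
                              spacing = c(2, 2, 2), noise_fraction = 0.03,
                              lesion_radius_range = NULL,
                              lesion_factor_range = c(1, 2),
                              lesions_per_image = 1,
                              max_translation = 7, max_rotation = 30,
                              max_scale = 0.025, seed = 1) {
  stopifnot(cohort_size >= 2, noise_fraction >= 0,
            lesion_factor_range[1] <= lesion_factor_range[2])
  if (!is.null(lesion_radius_range))
    stopifnot(lesion_radius_range[1] >= 0,
              lesion_radius_range[1] <= lesion_radius_range[2])
  structure(list(cohort_size = as.integer(cohort_size), shape = shape,
                 spacing = rep_len(spacing, 3),
                 noise_fraction = noise_fraction,
                 lesion_radius_range = lesion_radius_range,
                 lesion_factor_range = lesion_factor_range,
                 lesions_per_image = as.integer(lesions_per_image),
                 max_translation = max_translation,
                 max_rotation = max_rotation, max_scale = max_scale,
                 seed = seed),
            class = "simulation_config")
}

#' Procedural brain-like phantom
#'
#' A deterministic smooth head phantom: an ellipsoidal scalp shell, a dark
#' skull layer, and a brain with nested tissue compartments (white-matter
#' core, grey-matter shell, ventricles, an off-centre posterior lobe),
#' sinusoidal internal texture, a left-right intensity gradient and a few
#' seeded smooth blobs, lightly Gaussian-smoothed. The asymmetric internal
#' structure gives registration a well-posed optimum. World coordinates
#' are centred on the grid.
#'
#' @param shape grid dimensions.
#' @param spacing voxel size in mm.
#' @param seed seed for the random internal blobs.
#' @return A list with `volume` (`image_volume`), `brain_mask`
#'   (`binary_mask`, strictly inside the grid) and `mean_tissue` (mean
#'   intensity over the brain mask).
#' @export
make_phantom <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                         seed = 1) {
  shape <- as.integer(rep_len(shape, 3))
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(shape < 16)) stop("phantom grid must be at least 16 per axis")
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * spacing # world origin at grid centre
  ax <- lapply(1:3, function(k) ((0:(shape[k] - 1)) - (shape[k] - 1) / 2) *
                 spacing[k])
  X <- array(ax[[1]], shape)
  Y <- array(rep(ax[[2]], each = shape[1]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  F <- min(shape * spacing) / 2 # half field of view, mm

  ell <- function(cx, cy, cz, a, b, c)
    ((X - cx) / a)^2 + ((Y - cy) / b)^2 + ((Z - cz) / c)^2
  head_e <- ell(0, 0, 0, 0.78 * F, 0.88 * F, 0.72 * F)
  brain_ax <- c(0.60, 0.70, 0.55) * F
  brain_e <- ell(0, 1.5, 2, brain_ax[1], brain_ax[2], brain_ax[3])
  skull_e <- ell(0, 1.5, 2, 1.14 * brain_ax[1], 1.12 * brain_ax[2],
                 1.16 * brain_ax[3])
  wm_e <- ell(0, -2, 0, 0.70 * brain_ax[1], 0.72 * brain_ax[2],
              0.68 * brain_ax[3])
  v1 <- ell(-0.18 * F, 0.10 * F, 0.04 * F, 0.10 * F, 0.22 * F, 0.12 * F)
  v2 <- ell(0.18 * F, 0.10 * F, 0.04 * F, 0.10 * F, 0.22 * F, 0.12 * F)
  lobe <- ell(0.15 * F, -0.42 * F, -0.12 * F, 0.22 * F, 0.22 * F, 0.20 * F)

  vol <- array(0, shape)
  vol[head_e <= 1] <- 50
  vol[skull_e <= 1] <- 15
  brain <- brain_e <= 1
  vol[brain] <- 110

  # Gyrified white-matter core: the WM boundary radius is modulated
  # angularly, giving the cortical-like folding structure that makes the
  # NMI landscape realistically non-convex under rotation.
  theta <- atan2(Y - 1.5, X)
  phi <- atan2(Z - 2, sqrt(X^2 + (Y - 1.5)^2) + 1e-9)
  rho <- sqrt(brain_e)
  gyri <- 0.70 + 0.14 * sin(5 * theta + 1) * cos(3 * phi) +
    0.06 * sin(9 * theta - 2 * phi)
  vol[brain & rho < gyri] <- 155
  vol[lobe <= 1 & brain] <- 132
  vol[(v1 <= 1 | v2 <= 1) & brain] <- 35

  # Short-period texture plus a left-right gradient: gives translation
  # capture range a realistic scale and breaks mirror symmetry.
  tex <- 10 * sin(2 * pi * X / 17 + 0.5) * sin(2 * pi * Y / 21) +
    8 * sin(2 * pi * Z / 19 + X / 25) + 0.25 * X
  vol[brain] <- vol[brain] + tex[brain]
  blobs <- with_seed(seed, {
    k <- 6
    data.frame(cx = runif(k, -0.4, 0.4) * brain_ax[1],
               cy = runif(k, -0.4, 0.4) * brain_ax[2] + 1.5,
               cz = runif(k, -0.4, 0.4) * brain_ax[3] + 2,
               amp = runif(k, -15, 15), sig = runif(k, 0.08, 0.16) * F)
  })
  for (b in seq_len(nrow(blobs))) {
    g <- exp(-((X - blobs$cx[b])^2 + (Y - blobs$cy[b])^2 +
                 (Z - blobs$cz[b])^2) / (2 * blobs$sig[b]^2))
    vol[brain] <- vol[brain] + blobs$amp[b] * g[brain]
  }
  vol <- pmax(smooth_gauss3(vol, sigma_vox = 1), 0)
  v <- image_volume(vol, affine = aff, id = "phantom")
  list(volume = v,
       brain_mask = binary_mask(brain, affine = aff, id = "brain"),
       mean_tissue = mean(vol[brain]))
}

# Separable Gaussian smoothing with edge replication.
smooth_gauss3 <- function(a, sigma_vox = 1) {
  half <- max(1L, ceiling(2 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(a)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- base::matrix(aperm(a, perm), d[axis])
    pad <- rbind(m[rep(1, half), , drop = FALSE], m,
                 m[rep(nrow(m), half), , drop = FALSE])
    f <- stats::filter(pad, k, sides = 2)
    m <- f[(half + 1):(half + d[axis]), , drop = FALSE]
    a <- aperm(array(m, d[perm]), order(perm))
  }
  a
}

#' Insert a spherical hyper-intense lesion
#'
#' Voxels inside the sphere and inside the brain mask are set to
#' `factor * mean_tissue` (one intensity value per lesion); nothing
#' outside the brain is changed and no mechanical effect is simulated.
#'
#' @param v `image_volume` to lesion.
#' @param brain `binary_mask` restricting the lesion to brain voxels.
#' @param centre lesion centre in world mm; must fall inside the brain.
#' @param radius_mm sphere radius (0 leaves the image unchanged).
#' @param factor intensity multiple of `mean_tissue`, typically in
#'   \[1, 2\].
#' @param mean_tissue mean brain tissue intensity.
#' @return A list with `volume` and the `lesion_mask` of changed voxels.
#' @export
add_lesion <- function(v, brain, centre, radius_mm, factor, mean_tissue) {
  stopifnot(radius_mm >= 0, factor > 0)
  cv <- round(world_to_voxel(v, base::matrix(centre, 1)))
  d <- dim(v$data)
  if (any(cv < 0) || any(cv > d - 1) ||
      !brain$data[cv[1] + 1, cv[2] + 1, cv[3] + 1])
    stop("lesion centre must lie inside the brain mask")
  mask <- array(FALSE, d)
  if (radius_mm > 0) {
    w <- voxel_world_coords(v)
    r2 <- (w[, 1] - centre[1])^2 + (w[, 2] - centre[2])^2 +
      (w[, 3] - centre[3])^2
    mask <- array(r2 <= radius_mm^2, d) & brain$data
  }
  out <- v$data
  out[mask] <- factor * mean_tissue
  list(volume = image_volume(out, affine = v$affine, id = v$id),
       lesion_mask = binary_mask(mask, affine = v$affine,
                                 id = paste0(v$id, "_lesion")))
}

#' Add Rician (magnitude-MR) noise
#'
#' Each voxel x is replaced by `sqrt((x + n1)^2 + n2^2)` with n1, n2
#' independent zero-mean Gaussians of standard deviation
#' `fraction * max(x)`. Background voxels therefore acquire the Rayleigh
#' noise floor with mean `sigma * sqrt(pi / 2)`.
#'
#' @param v an `image_volume`.
#' @param fraction noise sigma as a fraction of the maximum intensity.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return A noisy `image_volume`.
#' @export
add_rician_noise <- function(v, fraction = 0.03, seed = NULL) {
  if (fraction == 0) return(v)
  sigma <- fraction * max(v$data)
  noisy <- with_seed(seed, {
    n <- length(v$data)
    sqrt((v$data + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  })
  image_volume(array(noisy, dim(v$data)), affine = v$affine, id = v$id)
}

#' Random 9-dof affine transform
#'
#' Translations, Euler rotations and scales are drawn independently and
#' uniformly from symmetric ranges; scale factors are `1 + u` with
#' `u ~ U(-max_scale, max_scale)`. The linear part acts about `center`
#' in the fixed order scale, then rotate, then translate.
#'
#' @param max_translation,max_rotation,max_scale range half-widths in mm,
#'   degrees and scale offset.
#' @param center world point the rotation/scaling acts about.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return A 9-dof `affine_transform`.
#' @export
random_affine_9dof <- function(max_translation = 7, max_rotation = 30,
                               max_scale = 0.025, center = c(0, 0, 0),
                               seed = NULL) {
  par <- with_seed(seed, c(runif(3, -max_translation, max_translation),
                           runif(3, -max_rotation, max_rotation),
                           runif(3, -max_scale, max_scale)))
  params_to_transform(par, center = center)
}

#' Build a synthetic cohort with known ground truth
#'
#' Three populations built on the procedural phantom:
#' * `vA` (variable appearance): lesioned, noisy copies in perfect
#'   alignment; the ground-truth transform is the identity.
#' * `vP` (variable positioning): unlesioned noisy copies under random
#'   9-dof transforms.
#' * `vAP`: the vA images under the vP transforms, with the same
#'   per-index pairing (image i of vAP is image i of vA resampled under
#'   transform i of vP).
#'
#' The stored ground-truth transform maps reference world coordinates to
#' image world coordinates, so a perfect registration of image to
#' reference recovers its inverse. All randomness derives from
#' `config$seed`; identical seeds give identical cohorts.
#'
#' @param kind `"vA"`, `"vP"` or `"vAP"`.
#' @param config a [simulation_config()].
#' @return An object of class `chains_cohort`: named `volumes`, the clean
#'   `reference` volume, `brain_mask`, `gt_transforms`, `lesions`
#'   (metadata data frame), `lesion_masks` (in image space), `kind`,
#'   `mean_tissue` and `config`.
#' @export
build_cohort <- function(kind = c("vA", "vP", "vAP"),
                         config = simulation_config()) {
  kind <- match.arg(kind)
  ph <- make_phantom(config$shape, config$spacing, seed = config$seed)
  n <- config$cohort_size
  ids <- sprintf("img_%02d", seq_len(n))
  brain_w <- voxel_world_coords(ph$volume, ph$brain_mask)
  rmax_brain <- max(apply(brain_w, 2, function(x) diff(range(x)) / 2))
  rr <- config$lesion_radius_range
  if (is.null(rr)) rr <- c(0, rmax_brain)

  sub <- with_seed(config$seed, sample.int(2^30, 3))
  lesions <- with_seed(sub[1], {
    k <- n * config$lesions_per_image
    pick <- sample.int(nrow(brain_w), k, replace = TRUE)
    data.frame(id = rep(ids, each = config$lesions_per_image),
               radius = runif(k, rr[1], rr[2]),
               factor = runif(k, config$lesion_factor_range[1],
                              config$lesion_factor_range[2]),
               cx = brain_w[pick, 1], cy = brain_w[pick, 2],
               cz = brain_w[pick, 3])
  })
  centre <- colMeans(brain_w)
  gt <- with_seed(sub[2], lapply(seq_len(n), function(i)
    random_affine_9dof(config$max_translation, config$max_rotation,
                       config$max_scale, center = centre)))
  names(gt) <- ids

  volumes <- list()
  lesion_masks <- list()
  with_seed(sub[3], {
    for (i in seq_len(n)) {
      v <- ph$volume
      v$id <- ids[i]
      lm <- NULL
      if (kind %in% c("vA", "vAP")) {
        rows <- which(lesions$id == ids[i])
        for (rw in rows) {
          les <- add_lesion(v, ph$brain_mask,
                            c(lesions$cx[rw], lesions$cy[rw],
                              lesions$cz[rw]),
                            lesions$radius[rw], lesions$factor[rw],
                            ph$mean_tissue)
          v <- les$volume
          lm <- if (is.null(lm)) les$lesion_mask else
            mask_like(v, lm$data | les$lesion_mask$data, id = lm$id)
        }
      }
      if (kind == "vP")
        v <- resample(v, gt[[i]], ph$volume)
      v <- add_rician_noise(v, config$noise_fraction)
      if (kind == "vAP") {
        v <- resample(v, gt[[i]], ph$volume)
        if (!is.null(lm)) lm <- resample_mask(lm, gt[[i]], ph$volume)
      }
      v$id <- ids[i]
      volumes[[ids[i]]] <- v
      if (!is.null(lm)) lesion_masks[[ids[i]]] <- lm
    }
  })
  if (kind == "vA") gt <- setNames(replicate(n, identity_transform(),
                                             simplify = FALSE), ids)
  structure(list(volumes = volumes, reference = ph$volume,
                 brain_mask = ph$brain_mask, gt_transforms = gt,
                 lesions = if (kind %in% c("vA", "vAP")) lesions else NULL,
                 lesion_masks = lesion_masks, kind = kind,
                 mean_tissue = ph$mean_tissue, config = config),
            class = "chains_cohort")
}

#' @export
print.chains_cohort <- function(x, ...) {
  cat(sprintf("<chains_cohort '%s': %d volumes of %s voxels>\n", x$kind,
              length(x$volumes),
              paste(dim(x$reference$data), collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes NIfTI volumes, ground-truth transform text files, lesion-mask
#' NIfTIs, a plain-text manifest of volume paths (one per line) and a
#' metadata JSON.
#'
#' @param cohort a `chains_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(cohort$volumes)) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    write_volume(cohort$volumes[[id]], p)
    paths <- c(paths, p)
    write_transform(cohort$gt_transforms[[id]],
                    file.path(dir, paste0(id, "_gt.mat")))
    if (!is.null(cohort$lesion_masks[[id]]))
      write_volume(cohort$lesion_masks[[id]],
                   file.path(dir, paste0(id, "_lesion.nii.gz")))
  }
  write_volume(cohort$reference, file.path(dir, "reference.nii.gz"))
  write_volume(cohort$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  writeLines(paths, file.path(dir, "manifest.txt"))
  meta <- list(kind = cohort$kind, mean_tissue = cohort$mean_tissue,
               config = unclass(cohort$config))
  if (!is.null(cohort$lesions)) meta$lesions <- cohort$lesions
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "cohort.json"))
  invisible(dir)
}
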