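#' 3-D image volumes
#'
#' An `image_volume` couples a 3-D scalar intensity grid with a 4x4
#' voxel-to-world affine (0-based voxel indices, voxel centre at integer
#' index, world units mm) and a cohort-unique identifier. Binary masks
#' (`binary_mask`) share the lattice of their volume.
#'
#' @param data 3-D numeric array of finite intensities.
#' @param affine 4x4 voxel-index-to-world-mm map; if `NULL`, built from
#'   `spacing` with the origin at voxel (0,0,0).
#' @param spacing voxel size per axis in mm (used when `affine` is `NULL`).
#' @param id identifier string.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine = NULL, spacing = c(1, 1, 1),
                         id = "volume") {
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop("data must be a 3-D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume intensities must be finite")
  if (is.null(affine)) {
    spacing <- rep_len(as.numeric(spacing), 3)
    if (any(spacing <= 0)) stop("spacing must be strictly positive")
    affine <- diag(c(spacing, 1))
  }
  affine <- base::matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("voxel-to-world map must be invertible")
  structure(list(data = data, affine = affine, id = as.character(id)),
            class = "image_volume")
}

#' @rdname image_volume
#' @param v an `image_volume`.
#' @export
voxel_spacing <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<image_volume '%s': %dx%dx%d voxels, %.3gx%.3gx%.3g mm>\n",
              x$id, d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  invisible(x)
}

#' @rdname image_volume
#' @param mask 3-D logical array on the same lattice as its volume.
#' @export
binary_mask <- function(mask, affine = NULL, spacing = c(1, 1, 1),
                        id = "mask") {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3) stop("mask must be a 3-D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA")
  v <- image_volume(array(0, dim(mask)), affine = affine, spacing = spacing,
                    id = id)
  structure(list(data = mask, affine = v$affine, id = as.character(id)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s': %s voxels, %d foreground>\n", x$id,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# Mask on the lattice of a volume, carrying its geometry.
mask_like <- function(v, mask, id = paste0(v$id, "_mask")) {
  if (!all(dim(mask) == dim(v$data)))
    stop("mask shape must match its volume")
  binary_mask(mask, affine = v$affine, id = id)
}

#' Voxel/world coordinate mapping
#'
#' `voxel_to_world` maps 0-based voxel indices to world mm through the
#' volume's affine; `world_to_voxel` is the inverse. `voxel_world_coords`
#' returns the world coordinates of every voxel centre selected by a mask.
#'
#' @param v an `image_volume` or `binary_mask`.
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @param pts n x 3 matrix of world coordinates in mm.
#' @return n x 3 coordinate matrix.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- base::matrix(idx, ncol = 3)
  h <- cbind(idx, 1) %*% t(v$affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, pts) {
  pts <- base::matrix(pts, ncol = 3)
  h <- cbind(pts, 1) %*% t(solve(v$affine))
  h[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param mask logical array (or `binary_mask`) selecting voxels; `NULL`
#'   selects all.
#' @export
voxel_world_coords <- function(v, mask = NULL) {
  d <- dim(v$data)
  if (inherits(mask, "binary_mask")) mask <- mask$data
  idx <- if (is.null(mask)) {
    as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                          z = 0:(d[3] - 1)))
  } else {
    which(mask, arr.ind = TRUE) - 1
  }
  voxel_to_world(v, idx)
}

#' NIfTI input and output
#'
#' Volumes and masks are stored as NIfTI-1 with the voxel-to-world map in
#' the sform; identifiers default to the file stem.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param id identifier; defaults to the file stem.
#' @param v an `image_volume` or `binary_mask`.
#' @return `read_volume`/`read_mask` return the object; writers return
#'   `path` invisibly.
#' @export
read_volume <- function(path, id = NULL) {
  n <- RNifti::readNifti(path)
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  aff <- base::matrix(RNifti::xform(n), 4, 4)
  image_volume(drop_to_3d(as.array(n)), affine = aff, id = id)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, id = NULL) {
  v <- read_volume(path, id = id)
  binary_mask(v$data > 0.5, affine = v$affine, id = v$id)
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  dat <- if (inherits(v, "binary_mask")) array(as.numeric(v$data), dim(v$data))
         else v$data
  n <- RNifti::asNifti(dat)
  RNifti::sform(n) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(n, path)
  invisible(path)
}

drop_to_3d <- function(a) {
  d <- dim(a)
  if (length(d) < 3 || (length(d) > 3 && any(d[-(1:3)] != 1)))
    stop("expected a 3-D volume, got dimensions ", paste(d, collapse = "x"))
  array(as.vector(a), d[1:3]) # also drops reader-specific attributes
}
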