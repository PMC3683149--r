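#' Resample a volume into a reference space
#'
#' Pull-resampling: every voxel of the reference lattice is mapped through
#' `invert(t)` into the moving volume's world space and interpolated there.
#' `t` must map moving-image world coordinates to reference (fixed) world
#' coordinates, the package-wide transform direction.
#'
#' @param moving `image_volume` to resample.
#' @param t `affine_transform`, moving world to reference world.
#' @param reference `image_volume` (or `binary_mask`) whose lattice defines
#'   the output grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param pad value for voxels mapped outside the moving field of view.
#' @return An `image_volume` on the reference lattice.
#' @export
resample <- function(moving, t, reference,
                     interpolation = c("trilinear", "nearest"), pad = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(t, "affine_transform"))
  interp <- if (interpolation == "nearest") 0L else 1L
  # output voxel index -> moving voxel index
  M <- solve(moving$affine) %*% solve(t$matrix) %*% reference$affine
  dat <- if (inherits(moving, "binary_mask"))
    array(as.numeric(moving$data), dim(moving$data)) else moving$data
  out <- resample_affine_cpp(as.numeric(dat), dim(dat), M,
                             dim(reference$data), interp, pad)
  image_volume(array(out, dim(reference$data)), affine = reference$affine,
               id = moving$id)
}

#' @rdname resample
#' @param mask `binary_mask` to resample (nearest-neighbour, so the result
#'   stays binary).
#' @export
resample_mask <- function(mask, t, reference) {
  v <- resample(mask, t, reference, interpolation = "nearest", pad = 0)
  binary_mask(v$data > 0.5, affine = reference$affine, id = mask$id)
}
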