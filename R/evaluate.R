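#' Residual transform of a recovered registration
#'
#' Composes the known applied transform (forward, reference world to image
#' world) with the recovered registration (reverse, image world to
#' reference world). The residual is the identity exactly when the
#' recovery is perfect.
#'
#' @param applied_forward the ground-truth applied `affine_transform`.
#' @param recovered the recovered `affine_transform`.
#' @return The residual `affine_transform`.
#' @export
residual_transform <- function(applied_forward, recovered) {
  compose(recovered, applied_forward)
}

#' Residual Displacement Error (RDE)
#'
#' Mean displacement, in mm, that a residual transform induces over the
#' voxel centres of a brain mask defined on the reference:
#' `mean(||residual(x) - x||)` over masked world positions x. Perfect
#' registration gives 0.0 mm.
#'
#' @param residual an `affine_transform` (see [residual_transform()]).
#' @param mask non-empty `binary_mask` on the reference grid.
#' @param grid `image_volume` (or mask) carrying the reference geometry;
#'   defaults to the mask itself.
#' @return RDE in mm.
#' @export
rde <- function(residual, mask, grid = mask) {
  if (!any(mask$data)) stop("RDE mask is empty")
  x <- voxel_world_coords(grid, mask)
  y <- transform_points(residual, x)
  mean(sqrt(rowSums((y - x)^2)))
}

#' Count gross mis-registrations
#'
#' Number of RDE values strictly greater than the threshold (default
#' 1.0 mm, the gross-failure criterion).
#'
#' @param rdes numeric vector of RDE values in mm.
#' @param threshold_mm failure threshold, strict inequality.
#' @return Integer count.
#' @export
count_misregistrations <- function(rdes, threshold_mm = 1.0) {
  stopifnot(threshold_mm > 0)
  sum(rdes > threshold_mm, na.rm = TRUE)
}

#' Lesion-brain overlap after registration
#'
#' Transforms a lesion mask into the reference space (nearest-neighbour)
#' and returns the percentage of transformed lesion voxels that fall
#' inside the reference brain region. 0% indicates complete
#' mis-registration; a transformed lesion that is empty (fully out of
#' field) also scores 0%. High overlap is necessary but not sufficient
#' for good registration.
#'
#' @param lesion `binary_mask` in the image space.
#' @param t `affine_transform` mapping lesion-image world to reference
#'   world.
#' @param ref_brain `binary_mask` of the brain on the reference grid.
#' @param ref_grid reference `image_volume` (defaults to `ref_brain`).
#' @return Overlap percentage in \[0, 100\].
#' @export
lesion_overlap <- function(lesion, t, ref_brain, ref_grid = ref_brain) {
  moved <- resample_mask(lesion, t, ref_grid)
  n <- sum(moved$data)
  if (n == 0) return(0)
  100 * sum(moved$data & ref_brain$data) / n
}

#' Voxelwise mean and standard-deviation images
#'
#' Computed over a list of registered volumes on a shared grid; the
#' standard deviation is the population form (denominator n). A
#' well-registered cohort shows a sharper mean and lower total variance
#' than the same cohort unregistered.
#'
#' @param registered list of `image_volume`s on the same grid.
#' @return A list with `mean` and `sd` `image_volume`s.
#' @export
mean_std_images <- function(registered) {
  stopifnot(length(registered) >= 1)
  d <- dim(registered[[1]]$data)
  for (v in registered)
    if (!all(dim(v$data) == d)) stop("volumes must share a grid")
  n <- length(registered)
  s <- s2 <- array(0, d)
  for (v in registered) {
    s <- s + v$data
    s2 <- s2 + v$data^2
  }
  m <- s / n
  sdv <- sqrt(pmax(s2 / n - m^2, 0))
  aff <- registered[[1]]$affine
  list(mean = image_volume(m, affine = aff, id = "mean"),
       sd = image_volume(sdv, affine = aff, id = "sd"))
}

#' Per-image RDE report with summary statistics
#'
#' @param rdes named numeric vector of per-image RDE values (mm).
#' @param threshold_mm gross-failure threshold (strict).
#' @param method optional method label.
#' @return An object of class `evaluation_report`: `per_image` data frame
#'   (id, rde_mm, misregistered), `summary` (mean/sd/min/max in mm),
#'   `n_misreg` and `threshold_mm`.
#' @export
evaluation_report <- function(rdes, threshold_mm = 1.0, method = "method") {
  per <- data.frame(id = names(rdes), rde_mm = unname(rdes),
                    misregistered = unname(rdes) > threshold_mm)
  structure(list(
    method = method,
    per_image = per,
    summary = c(mean = mean(rdes), sd = stats::sd(rdes),
                min = min(rdes), max = max(rdes)),
    n_misreg = count_misregistrations(rdes, threshold_mm),
    threshold_mm = threshold_mm), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report '%s': %d images>\n", x$method,
              nrow(x$per_image)))
  cat(sprintf("  Mean %.3f  s.d. %.3f  Min %.3f  Max %.3f (mm)\n",
              x$summary["mean"], x$summary["sd"], x$summary["min"],
              x$summary["max"]))
  cat(sprintf("  N(misreg, RDE > %.2f mm) = %d\n", x$threshold_mm,
              x$n_misreg))
  invisible(x)
}

#' Summary table across registration methods
#'
#' One row per method with Mean/s.d./Min/Max RDE (mm) and the
#' mis-registration count, regenerated from the per-image values.
#'
#' @param reports list of [evaluation_report()]s.
#' @return A data frame.
#' @export
method_summary_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(method = r$method, mean_mm = r$summary["mean"],
               sd_mm = r$summary["sd"], min_mm = r$summary["min"],
               max_mm = r$summary["max"], n_misreg = r$n_misreg,
               row.names = NULL)))
}
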