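#' Configuration for the local registration engine
#'
#' The engine performs a purely local, derivative-free (Nelder-Mead)
#' search over affine parameters, maximising NMI between the fixed image
#' and the resampled moving image over a region of interest. There is no
#' global or multi-resolution search: the capture range is deliberately
#' small, and large displacements are expected to be bridged by the chain
#' graph, not by the optimiser.
#'
#' @param dof degrees of freedom: 6 (rigid), 9 (+ scales), 12 (+ shears).
#' @param bins histogram bins for the NMI cost.
#' @param max_iterations Nelder-Mead iteration cap.
#' @param reltol relative convergence tolerance on the cost.
#' @param fn_tol slack allowed in the monotone-acceptance contract (the
#'   returned transform's NMI is never below the initialisation's by more
#'   than this).
#' @param simplex_step initial search steps: translations (mm), rotations
#'   (degrees), scale and shear offsets.
#' @param smooth_sigma Gaussian pre-smoothing of both images inside the
#'   cost, in voxels (0 disables). Mild smoothing suppresses the
#'   interpolation artifact of histogram-based costs, where trilinear
#'   resampling averages the moving image's independent noise and biases
#'   the optimum ~half a voxel off true alignment.
#' @param restarts number of Nelder-Mead restarts from the incumbent
#'   optimum (each restart re-expands the simplex, which reliably escapes
#'   premature simplex collapse).
#' @param max_samples cap on the number of ROI voxels used by the cost
#'   (deterministic stride subsampling; `Inf` uses all).
#' @param two_level if `TRUE`, a first pass runs on a subsampled ROI
#'   before full-resolution refinement (a speed knob; default off).
#' @param min_overlap minimum fraction of ROI voxels that must fall inside
#'   the moving field of view for a cost value to be accepted.
#' @param seed seed for any stochastic component (the default engine is
#'   fully deterministic; kept for pluggable backends).
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(dof = 9, bins = 64, max_iterations = 500,
                                reltol = 1e-8, fn_tol = 1e-9,
                                simplex_step = c(trans = 1, rot = 1,
                                                 scale = 0.01, shear = 0.01),
                                smooth_sigma = 1, restarts = 2,
                                max_samples = Inf,
                                two_level = FALSE, min_overlap = 0.1,
                                seed = NULL) {
  if (!dof %in% c(6, 9, 12)) stop("dof must be 6, 9 or 12")
  stopifnot(bins >= 2, max_iterations >= 1, reltol > 0, fn_tol >= 0,
            restarts >= 0, max_samples >= 100)
  structure(list(dof = as.integer(dof), bins = as.integer(bins),
                 max_iterations = as.integer(max_iterations),
                 reltol = reltol, fn_tol = fn_tol,
                 simplex_step = simplex_step, smooth_sigma = smooth_sigma,
                 restarts = as.integer(restarts),
                 max_samples = max_samples, two_level = isTRUE(two_level),
                 min_overlap = min_overlap, seed = seed),
            class = "registration_config")
}

#' Approximate foreground mask by global (Otsu) thresholding
#'
#' Separates foreground (head) from background with a single global
#' threshold chosen by Otsu's method on the intensity histogram.
#'
#' @param v an `image_volume`.
#' @param levels histogram levels for the threshold search.
#' @return A `binary_mask` on the volume's lattice.
#' @export
foreground_mask <- function(v, levels = 256) {
  lo <- min(v$data); hi <- max(v$data)
  if (hi <= lo) stop("cannot threshold a constant image")
  norm <- (v$data - lo) / (hi - lo)
  d <- dim(norm)
  th <- EBImage::otsu(EBImage::Image(base::matrix(norm, d[1], d[2] * d[3])),
                      range = c(0, 1), levels = levels)
  m <- norm > th
  if (!any(m)) stop("foreground mask is empty")
  mask_like(v, m, id = paste0(v$id, "_fg"))
}

#' Local affine registration by NMI maximisation
#'
#' Registers `moving` to `fixed` with a Nelder-Mead search over `dof`
#' affine parameters, starting at `init`. The cost is the negated NMI
#' between the fixed intensities and the moving image sampled at the
#' mapped ROI voxel centres; rotation/scaling act about the ROI centroid.
#' The best transform encountered is returned, so the result's similarity
#' is never below the initialisation's (monotone acceptance).
#'
#' @param moving,fixed `image_volume`s.
#' @param init `affine_transform` (moving world to fixed world) used as
#'   the starting point; default identity.
#' @param cfg a [registration_config()].
#' @param roi `binary_mask` on the fixed lattice; default
#'   `foreground_mask(fixed)`.
#' @return A list of class `registration_result` with elements
#'   `transform`, `final_similarity` (NMI), `status` (`"converged"`,
#'   `"max-iter"` or `"failed"`) and `n_evaluations`.
#' @export
register_local <- function(moving, fixed, init = identity_transform(),
                           cfg = registration_config(), roi = NULL) {
  stopifnot(inherits(init, "affine_transform"))
  if (is.null(roi)) roi <- foreground_mask(fixed)
  if (!any(roi$data)) stop("ROI is empty")

  failed <- function(nev = 0L) {
    structure(list(transform = init, final_similarity = NA_real_,
                   status = "failed", n_evaluations = nev),
              class = "registration_result")
  }
  if (cfg$smooth_sigma > 0) {
    moving <- image_volume(smooth_gauss3(moving$data, cfg$smooth_sigma),
                           affine = moving$affine, id = moving$id)
    fixed <- image_volume(smooth_gauss3(fixed$data, cfg$smooth_sigma),
                          affine = fixed$affine, id = fixed$id)
  }
  pts_w <- voxel_world_coords(fixed, roi)
  fx <- fixed$data[roi$data]
  fb <- tryCatch(attr(bin_index(fx, cfg$bins), "idx"),
                 error = function(e) NULL)
  mov_rng <- range(moving$data)
  if (is.null(fb) || mov_rng[2] <= mov_rng[1]) return(failed())

  center <- colMeans(pts_w)
  Ainv_mov <- solve(moving$affine)
  n_eval <- 0L

  make_cost <- function(keep) {
    ptsh <- t(cbind(pts_w[keep, , drop = FALSE], 1)) # 4 x N
    fbk <- fb[keep]
    n_roi <- length(fbk)
    function(par) {
      n_eval <<- n_eval + 1L
      tm <- tryCatch(params_to_transform(par, center)$matrix %*% init$matrix,
                     error = function(e) NULL)
      if (is.null(tm)) return(1e6)
      M <- Ainv_mov %*% solve(tm)
      P <- t((M %*% ptsh)[1:3, , drop = FALSE])
      r <- nmi_points_cpp(moving$data, dim(moving$data), P, fbk,
                          cfg$bins, mov_rng[1], mov_rng[2])
      if (is.na(r[1]) || r[2] < cfg$min_overlap * n_roi) return(1e6)
      -r[1]
    }
  }

  np <- cfg$dof
  step <- with(as.list(cfg$simplex_step),
               c(rep(trans, 3), rep(rot, 3), rep(scale, 3),
                 rep(shear, 3))[seq_len(np)])
  # optim's Nelder-Mead builds its initial simplex with steps of
  # 0.1 * parscale, so parscale = 10 * step gives the intended step sizes.
  control <- list(maxit = cfg$max_iterations, reltol = cfg$reltol,
                  parscale = 10 * step)

  run_opt <- function(cost, par0) {
    f0 <- cost(par0)
    if (!is.finite(f0) || f0 >= 1e6) return(NULL)
    o <- optim(par0, cost, method = "Nelder-Mead", control = control)
    # Restart from the incumbent: re-expanding the simplex escapes the
    # premature collapse Nelder-Mead is prone to.
    for (k in seq_len(cfg$restarts)) {
      o2 <- optim(o$par, cost, method = "Nelder-Mead", control = control)
      if (!is.finite(o2$value) || o2$value > o$value - 1e-5) {
        if (is.finite(o2$value) && o2$value < o$value) o <- o2
        break
      }
      o <- o2
    }
    if (!is.finite(o$value) || o$value > f0 + cfg$fn_tol) {
      o$par <- par0; o$value <- f0; o$convergence <- 0L
    }
    o
  }

  n_pts <- nrow(pts_w)
  full <- if (is.finite(cfg$max_samples) && n_pts > cfg$max_samples)
    unique(round(seq(1, n_pts, length.out = cfg$max_samples)))
  else seq_len(n_pts)
  par0 <- rep(0, np)
  if (cfg$two_level) {
    o1 <- run_opt(make_cost(full[seq(1, length(full), by = 4L)]), par0)
    if (!is.null(o1)) par0 <- o1$par
  }
  o <- run_opt(make_cost(full), par0)
  if (is.null(o)) return(failed(n_eval))

  structure(list(
    transform = compose(params_to_transform(o$par, center), init),
    final_similarity = -o$value,
    status = if (o$convergence == 0L) "converged" else "max-iter",
    n_evaluations = n_eval), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: %s, NMI = %s, %d evaluations>\n",
              x$status,
              if (is.na(x$final_similarity)) "NA"
              else sprintf("%.4f", x$final_similarity),
              x$n_evaluations))
  invisible(x)
}

#' Register every ordered pair in a cohort
#'
#' Registers image i (moving) to image j (fixed) from an identity
#' initialisation for every ordered pair, and stores the inverse-NMI
#' distance after alignment (computed over the fixed image's foreground
#' mask), the recovered transform and the status. A pair that fails is
#' assigned the maximal distance 1.0 and the run continues. With a
#' `representative` subset of m ids, only subset members serve as fixed
#' images, so cost scales as m^2 + m(n - m) instead of n^2; remaining
#' images can later join the graph with [add_image()].
#'
#' @param cohort named list of `image_volume`s (names are ids).
#' @param cfg a [registration_config()].
#' @param representative optional character vector of ids forming the
#'   representative subset.
#' @param engine pairwise registration backend,
#'   `function(moving, fixed, init, cfg, roi)` returning a
#'   `registration_result`; defaults to [register_local()]. The chain
#'   machinery is agnostic to the engine.
#' @param verbose print per-pair progress.
#' @return A [distance_matrix()] with per-pair transforms and statuses.
#' @export
pairwise_all <- function(cohort, cfg = registration_config(),
                         representative = NULL, engine = register_local,
                         verbose = FALSE) {
  ids <- cohort_ids(cohort)
  n <- length(ids)
  if (n < 2) stop("need at least 2 images")
  fixed_ids <- if (is.null(representative)) ids else {
    stopifnot(all(representative %in% ids))
    representative
  }
  d <- base::matrix(NA_real_, n, n, dimnames = list(ids, ids))
  status <- base::matrix(NA_character_, n, n, dimnames = list(ids, ids))
  transforms <- setNames(lapply(ids, function(i) list()), ids)
  for (j in fixed_ids) {
    fixed <- cohort[[j]]
    roi <- foreground_mask(fixed)
    for (i in ids) {
      if (i == j) next
      res <- engine(cohort[[i]], fixed, init = identity_transform(),
                    cfg = cfg, roi = roi)
      ok <- res$status != "failed" && is.finite(res$final_similarity)
      d[i, j] <- if (ok) min(max(1 / res$final_similarity, 0.5), 1.0) else 1.0
      status[i, j] <- res$status
      transforms[[i]][[j]] <- res$transform
      if (verbose)
        message(sprintf("%s -> %s: d = %.4f (%s)", i, j, d[i, j], res$status))
    }
  }
  distance_matrix(d, status = status, transforms = transforms)
}

cohort_ids <- function(cohort) {
  ids <- if (!is.null(names(cohort)) && all(nzchar(names(cohort))))
    names(cohort) else vapply(cohort, function(v) v$id, character(1))
  if (anyDuplicated(ids)) stop("cohort ids must be unique")
  ids
}
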