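#' Joint intensity histogram of two volumes on a shared lattice
#'
#' The histogram is accumulated by nearest-bin assignment over the voxels
#' selected by `roi`, with per-image bin edges spanning each image's
#' intensity range within the ROI.
#'
#' @param a,b `image_volume`s on the same lattice (resample first if not).
#' @param roi `binary_mask` (or logical array) selecting voxels; `NULL`
#'   uses every voxel.
#' @param bins number of bins per image (default 64).
#' @return An object of class `joint_histogram` with elements `counts`
#'   (`bins` x `bins`), `edges_a`, `edges_b` and `n_samples`.
#' @export
joint_histogram <- function(a, b, roi = NULL, bins = 64) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("volumes must share a lattice; resample first")
  bins <- as.integer(bins)
  if (bins < 1) stop("bins must be a positive integer")
  sel <- if (is.null(roi)) rep(TRUE, length(a$data))
         else as.logical(if (inherits(roi, "binary_mask")) roi$data else roi)
  if (!any(sel)) stop("ROI is empty")
  xa <- a$data[sel]
  xb <- b$data[sel]
  ia <- bin_index(xa, bins)
  ib <- bin_index(xb, bins)
  counts <- base::matrix(
    tabulate(attr(ia, "idx") + bins * (attr(ib, "idx") - 1L),
             nbins = bins * bins), bins, bins)
  structure(list(counts = counts, edges_a = attr(ia, "edges"),
                 edges_b = attr(ib, "edges"), n_samples = length(xa)),
            class = "joint_histogram")
}

bin_index <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("degenerate histogram: image is constant within the ROI")
  idx <- pmin(as.integer((x - lo) / (hi - lo) * bins) + 1L, bins)
  structure(x, idx = idx, edges = seq(lo, hi, length.out = bins + 1))
}

#' Normalised Mutual Information
#'
#' NMI = (H(A) + H(B)) / H(A, B) with entropies in nats computed from the
#' normalised joint histogram; its range is \[1, 2\], with 2 for identical
#' images and 1 for independent ones in the infinite-sample limit.
#'
#' @param h a `joint_histogram`.
#' @return The NMI value.
#' @export
nmi <- function(h) {
  stopifnot(inherits(h, "joint_histogram"))
  p <- h$counts / h$n_samples
  hab <- entropy_nats(p)
  if (hab <= 0)
    stop("degenerate histogram: joint entropy is zero")
  (entropy_nats(rowSums(p)) + entropy_nats(colSums(p))) / hab
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Inverse-NMI surrogate distance between two volumes
#'
#' Returns `1 / NMI(a, b)`, in \[0.5, 1\]; smaller means more similar.
#' Within batch pairwise computation a degenerate histogram is reported as
#' the maximal distance 1.0 with a warning rather than an error, so one bad
#' pair cannot abort a cohort run.
#'
#' @inheritParams joint_histogram
#' @param on_degenerate `"error"` (default) or `"max"` (return 1.0 with a
#'   warning).
#' @return Distance in \[0.5, 1\].
#' @export
inverse_nmi_distance <- function(a, b, roi = NULL, bins = 64,
                                 on_degenerate = c("error", "max")) {
  on_degenerate <- match.arg(on_degenerate)
  val <- tryCatch(1 / nmi(joint_histogram(a, b, roi = roi, bins = bins)),
                  error = function(e) {
                    if (on_degenerate == "error") stop(e)
                    warning("degenerate pair (", a$id, ", ", b$id,
                            "): distance set to 1.0", call. = FALSE)
                    1.0
                  })
  min(max(val, 0.5), 1.0)
}
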