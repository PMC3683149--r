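#' Affine transforms in world (mm) coordinates
#'
#' An `affine_transform` is a 4x4 homogeneous matrix acting on world-mm
#' column vectors, mapping moving-image world coordinates to fixed-image
#' world coordinates, together with its declared degrees of freedom
#' (6 = rigid, 9 = rigid + anisotropic scales, 12 = full affine).
#'
#' @param matrix 4x4 numeric matrix with bottom row `(0, 0, 0, 1)`.
#' @param dof degrees of freedom, one of 6, 9, 12. For `dof = 6` the
#'   upper-left 3x3 block must be a proper rotation (orthogonal,
#'   determinant +1) to within `tol`.
#' @param tol tolerance for the rigidity check.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, dof = 12, tol = 1e-6) {
  matrix <- base::matrix(as.numeric(matrix), 4, 4)
  if (!all(is.finite(matrix)))
    stop("transform matrix must be finite")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > tol)
    stop("bottom row of an affine transform must be (0, 0, 0, 1)")
  matrix[4, ] <- c(0, 0, 0, 1)
  if (!dof %in% c(6, 9, 12))
    stop("dof must be 6, 9 or 12")
  d <- det(matrix[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("invalid transform: matrix is singular")
  if (dof == 6) {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > tol || abs(d - 1) > tol)
      stop("a 6-dof transform must have an orthogonal, det +1 linear part")
  }
  structure(list(matrix = matrix, dof = as.integer(dof)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform: %d dof, moving -> fixed, world mm>\n", x$dof))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Elementary transforms
#'
#' Constructors for the identity, pure translations, axis-aligned scalings
#' and Euler rotations, all in world-mm coordinates.
#'
#' @param t,s length-3 numeric: translation in mm / scale factors per axis.
#' @param angles length-3 numeric, rotations about x, y, z in degrees,
#'   applied as `Rz %*% Ry %*% Rx`.
#' @param center length-3 world point (mm) the scaling/rotation is about.
#' @return An `affine_transform`.
#' @export
identity_transform <- function() affine_transform(diag(4), dof = 6)

#' @rdname identity_transform
#' @export
translation_transform <- function(t) {
  m <- diag(4)
  m[1:3, 4] <- t
  affine_transform(m, dof = 6)
}

#' @rdname identity_transform
#' @export
scaling_transform <- function(s, center = c(0, 0, 0)) {
  m <- diag(c(s, 1))
  m[1:3, 4] <- center - s * center
  affine_transform(m, dof = 9)
}

#' @rdname identity_transform
#' @export
rotation_transform <- function(angles, center = c(0, 0, 0)) {
  R <- euler_matrix(angles)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center
  affine_transform(m, dof = 6)
}

euler_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Compose two affine transforms
#'
#' If `inner` maps space A to space B and `outer` maps B to C, the result
#' maps A to C; its matrix is `matrix(outer) %*% matrix(inner)` and its
#' declared dof is the loosest of the two.
#'
#' @param outer,inner `affine_transform` objects.
#' @return An `affine_transform` mapping A to C.
#' @export
compose <- function(outer, inner) {
  stopifnot(inherits(outer, "affine_transform"),
            inherits(inner, "affine_transform"))
  affine_transform(outer$matrix %*% inner$matrix,
                   dof = max(outer$dof, inner$dof))
}

#' Invert an affine transform
#'
#' @param t an `affine_transform`.
#' @return The inverse transform, such that `compose(t, invert(t))` is the
#'   identity to numerical precision. A warning is issued for
#'   near-singular matrices (condition number above 1e8).
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "affine_transform"))
  k <- kappa(t$matrix[1:3, 1:3], exact = TRUE)
  if (!is.finite(k))
    stop("invalid transform: matrix is singular")
  if (k > 1e8)
    warning("transform is near-singular (condition number ", signif(k, 3), ")")
  affine_transform(solve(t$matrix), dof = t$dof)
}

#' Apply a transform to world points
#'
#' @param t an `affine_transform`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped world coordinates.
#' @export
transform_points <- function(t, pts) {
  pts <- base::matrix(pts, ncol = 3)
  h <- cbind(pts, 1) %*% t(t$matrix)
  h[, 1:3, drop = FALSE]
}

#' Build an affine transform from optimisation parameters
#'
#' Parameters are ordered translations (mm), rotations (degrees), scales
#' (offsets from 1), shears; the first `dof` are used. The linear part is
#' applied about `center`: `x' = c + R S Sh (x - c) + t`, i.e. scale, then
#' shear, then rotate, then translate.
#'
#' @param par numeric vector of length `dof` (6, 9 or 12).
#' @param center length-3 world point (mm).
#' @return An `affine_transform`.
#' @export
params_to_transform <- function(par, center = c(0, 0, 0)) {
  np <- length(par)
  if (!np %in% c(6, 9, 12))
    stop("parameter vector must have length 6, 9 or 12")
  t3 <- par[1:3]
  R <- euler_matrix(par[4:6])
  S <- if (np >= 9) diag(1 + par[7:9]) else diag(3)
  Sh <- diag(3)
  if (np == 12) {
    Sh[1, 2] <- par[10]
    Sh[1, 3] <- par[11]
    Sh[2, 3] <- par[12]
  }
  L <- R %*% S %*% Sh
  m <- diag(4)
  m[1:3, 1:3] <- L
  m[1:3, 4] <- center - L %*% center + t3
  affine_transform(m, dof = np)
}

#' Read and write transforms as plain 4x4 text files
#'
#' The file layout is four lines of four whitespace-separated numbers, the
#' same textual layout as FLIRT `.mat` files, but the semantics here are
#' always world-mm moving-to-fixed maps.
#'
#' @param path file path.
#' @param t an `affine_transform`.
#' @param dof declared dof to attach on read.
#' @return `read_transform` returns an `affine_transform`;
#'   `write_transform` returns `path` invisibly.
#' @export
read_transform <- function(path, dof = 12) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (!all(dim(m) == c(4, 4)))
    stop("expected a 4x4 matrix in ", path)
  affine_transform(unname(m), dof = dof)
}

#' @rdname read_transform
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "affine_transform"))
  lines <- apply(t$matrix, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}

#' @importFrom utils read.table
NULL
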