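# Traceless magnetic susceptibility anisotropy tensors and the
# point-dipole pseudocontact-shift forward model.
#
# Unit conventions throughout the package: coordinates in Angstrom,
# Delta-chi components in 1e-32 m^3, PCS in ppm.  In these units
#   delta(ppm) = 1e4/(12*pi*r^3) * [dax*(3cos^2(theta)-1)
#                                   + 1.5*drh*sin^2(theta)*cos(2*phi)]
# which in Cartesian form is delta = 1e4/(4*pi) * (d' X d) / r^5 with X the
# traceless symmetric anisotropy tensor and d the metal-to-nucleus vector.

PCS_CONST <- 1e4 / (4 * pi)

#' Construct a susceptibility-anisotropy tensor
#'
#' A `chi_tensor` bundles a paramagnetic-centre position with the five
#' independent Cartesian components of the traceless symmetric anisotropy
#' tensor. The sixth entry is implied by tracelessness
#' (`chi_zz = -chi_xx - chi_yy`). Fitting is linear in this representation;
#' the principal-frame view (axial and rhombic components plus ZYZ Euler
#' angles) is available through [principal_form()].
#'
#' @param position numeric length-3, metal position in Angstrom.
#' @param components numeric length-5, Cartesian components
#'   `(chi_xx, chi_yy, chi_xy, chi_xz, chi_yz)` in units of 1e-32 m^3.
#' @return An object of class `chi_tensor`.
#' @seealso [principal_form()], [chi_from_principal()], [pcs_forward()]
#' @examples
#' t <- chi_from_principal(c(0, 0, 0), dax = 10, drh = 0)
#' pcs_forward(t, c(0, 0, 10))
#' @export
chi_tensor <- function(position, components) {
  position <- as.numeric(position)
  components <- as.numeric(components)
  stopifnot(length(position) == 3, length(components) == 5)
  if (!all(is.finite(position)) || !all(is.finite(components)))
    stop("chi_tensor: position and components must be finite")
  names(components) <- c("xx", "yy", "xy", "xz", "yz")
  structure(list(position = position, components = components),
            class = "chi_tensor")
}

#' @export
print.chi_tensor <- function(x, ...) {
  p <- principal_form(x)
  cat("chi_tensor (units 1e-32 m^3, Angstrom)\n")
  cat(sprintf("  metal position: %8.3f %8.3f %8.3f\n",
              x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  Dchi_ax = %.4f   Dchi_rh = %.4f\n", p$dax, p$drh))
  cat(sprintf("  Euler ZYZ (deg): alpha = %.2f  beta = %.2f  gamma = %.2f\n",
              deg(p$euler[1]), deg(p$euler[2]), deg(p$euler[3])))
  invisible(x)
}

#' Full 3x3 tensor matrix
#'
#' Reconstructs the symmetric traceless 3x3 matrix from the five stored
#' components.
#'
#' @param x a `chi_tensor`.
#' @param ... unused.
#' @return 3x3 numeric matrix.
#' @export
as.matrix.chi_tensor <- function(x, ...) {
  k <- x$components
  matrix(c(k["xx"], k["xy"], k["xz"],
           k["xy"], k["yy"], k["yz"],
           k["xz"], k["yz"], -k["xx"] - k["yy"]), 3, 3,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

chi_from_matrix <- function(position, M) {
  if (abs(sum(diag(M))) > 1e-9 * max(1, max(abs(M))))
    stop("chi_from_matrix: matrix is not traceless")
  chi_tensor(position, c(M[1, 1], M[2, 2], M[1, 2], M[1, 3], M[2, 3]))
}

#' Principal-frame view of a tensor
#'
#' Diagonalises the tensor and reports the axial component
#' `dax = chi_zz - (chi_xx + chi_yy)/2`, the rhombic component
#' `drh = chi_xx - chi_yy`, and ZYZ Euler angles of the principal frame.
#' The unique representation orders the eigenvalues by absolute value,
#' `|chi_zz| >= |chi_yy| >= |chi_xx|`, which guarantees
#' `|drh| <= (2/3)|dax|`.
#'
#' @param tensor a `chi_tensor`.
#' @return list with `dax`, `drh` (1e-32 m^3), `euler` (radians,
#'   `c(alpha, beta, gamma)`), and the principal-axis rotation matrix `R`
#'   (columns are the x, y, z principal axes; `M = R D R'`).
#' @export
principal_form <- function(tensor) {
  M <- as.matrix(tensor)
  if (all(abs(M) < 1e-300))
    return(list(dax = 0, drh = 0, euler = c(alpha = 0, beta = 0, gamma = 0),
                R = diag(3)))
  e <- eigen(M, symmetric = TRUE)
  ord <- order(abs(e$values))            # |xx| <= |yy| <= |zz|
  vals <- e$values[ord]
  R <- e$vectors[, ord, drop = FALSE]
  # canonical axis signs: make each of x and z point towards its largest
  # molecular-frame component, then complete a right-handed frame
  for (j in c(1, 3)) {
    i <- which.max(abs(R[, j]))
    if (R[i, j] < 0) R[, j] <- -R[, j]
  }
  R[, 2] <- cross3(R[, 3], R[, 1])
  euler <- matrix_to_euler(R)
  list(dax = 1.5 * vals[3], drh = vals[1] - vals[2], euler = euler, R = R)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a tensor from principal-frame parameters
#'
#' Inverse of [principal_form()]: assembles the Cartesian tensor from axial
#' and rhombic components and an orientation given either as ZYZ Euler
#' angles (radians) or as a rotation matrix.
#'
#' @param position metal position, Angstrom.
#' @param dax,drh axial and rhombic anisotropy, 1e-32 m^3.
#' @param euler numeric length-3 `c(alpha, beta, gamma)` in radians
#'   (ignored when `R` is given).
#' @param R optional 3x3 rotation matrix whose columns are the principal
#'   axes.
#' @return a `chi_tensor`.
#' @export
chi_from_principal <- function(position, dax, drh = 0, euler = c(0, 0, 0),
                               R = NULL) {
  if (is.null(R)) R <- euler_to_matrix(euler[1], euler[2], euler[3])
  zz <- (2 / 3) * dax
  xx <- (-zz + drh) / 2
  yy <- (-zz - drh) / 2
  M <- R %*% diag(c(xx, yy, zz)) %*% t(R)
  chi_from_matrix(position, M)
}

# Rows of the linear design: pcs = design %*% components for nuclei at
# `positions` (n x 3) given a metal at `metal`.  Shared by the forward
# model and the linear fit.
pcs_design <- function(metal, positions) {
  positions <- as_xyz_matrix(positions)
  dx <- positions[, 1] - metal[1]
  dy <- positions[, 2] - metal[2]
  dz <- positions[, 3] - metal[3]
  r2 <- dx^2 + dy^2 + dz^2
  if (any(r2 == 0))
    stop("singular geometry: nucleus coincides with the metal position")
  s <- PCS_CONST / r2^2.5
  cbind(xx = s * (dx^2 - dz^2),
        yy = s * (dy^2 - dz^2),
        xy = s * 2 * dx * dy,
        xz = s * 2 * dx * dz,
        yz = s * 2 * dy * dz)
}

#' Pseudocontact shift predicted by a tensor
#'
#' Evaluates the point-dipole PCS equation for one or more nuclei.
#'
#' @param tensor a `chi_tensor`.
#' @param nucleus_position length-3 vector or n x 3 matrix of coordinates,
#'   Angstrom.
#' @return PCS in ppm (numeric vector of length n).
#' @examples
#' t <- chi_from_principal(c(0, 0, 0), dax = 10)
#' pcs_forward(t, c(0, 0, 10))   # on the principal axis: ~5.305 ppm
#' @export
pcs_forward <- function(tensor, nucleus_position) {
  A <- pcs_design(tensor$position, nucleus_position)
  unname(drop(A %*% tensor$components))
}

#' Spatial gradient of the pseudocontact shift
#'
#' Analytic gradient of [pcs_forward()] with respect to the nucleus
#' position; the normal of the local PCS isosurface.
#'
#' @inheritParams pcs_forward
#' @return ppm per Angstrom; length-3 vector, or n x 3 matrix for matrix
#'   input.
#' @export
pcs_gradient <- function(tensor, nucleus_position) {
  X <- as_xyz_matrix(nucleus_position)
  M <- as.matrix(tensor)
  D <- sweep(X, 2, tensor$position)
  r2 <- rowSums(D^2)
  if (any(r2 == 0))
    stop("singular geometry: nucleus coincides with the metal position")
  MD <- D %*% M
  quad <- rowSums(D * MD)
  G <- PCS_CONST * (2 * MD / r2^2.5 - 5 * quad * D / r2^3.5)
  dimnames(G) <- NULL
  if (nrow(G) == 1) drop(G) else G
}
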