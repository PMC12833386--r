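#' Smooth deformation specification with closed-form oracles
#'
#' Describes the mapping between a reference ("neutral") and deformed
#' ("extension") configuration as the composition of a rigid motion about a
#' centre, a small affine gradient, and a mild quadratic displacement term:
#' \deqn{\phi(x) = c + R (I + A)(x - c) + t + P(x - c)}
#' where `P` is a per-component quadratic polynomial. Both the displacement
#' `u(x) = phi(x) - x` and the Green-Lagrange strain
#' `E(x) = (F^T F - I)/2` (with `F = R(I + A) + dP/dx`) are evaluable in
#' closed form, so any volume warped with such a spec carries an analytic
#' ground truth.
#'
#' @param translation rigid translation (mm, length 3).
#' @param rotation_axis rotation axis (length 3, need not be unit).
#' @param rotation_angle rotation angle about `rotation_axis` in degrees.
#' @param centre rotation/expansion centre (mm); `NULL` defers to the volume
#'   centre at warp time.
#' @param affine 3 x 3 displacement-gradient matrix (dimensionless, small).
#' @param poly 3 x 6 matrix of quadratic displacement coefficients
#'   (1/mm); columns correspond to the monomials
#'   `dx^2, dy^2, dz^2, dx*dy, dx*dz, dy*dz` of the centred coordinates.
#' @return an object of class `deformation_spec`.
#' @export
deformation_spec <- function(translation = c(0, 0, 0),
                             rotation_axis = c(0, 0, 1),
                             rotation_angle = 0,
                             centre = NULL,
                             affine = matrix(0, 3, 3),
                             poly = matrix(0, 3, 6)) {
  stopifnot(length(translation) == 3L, length(rotation_axis) == 3L,
            length(rotation_angle) == 1L)
  affine <- as.matrix(affine)
  poly <- as.matrix(poly)
  if (!all(dim(affine) == c(3, 3))) stop_input("`affine` must be 3 x 3")
  if (!all(dim(poly) == c(3, 6))) stop_input("`poly` must be 3 x 6")
  if (sum(rotation_axis^2) == 0) stop_input("`rotation_axis` must be non-zero")
  structure(list(translation = as.numeric(translation),
                 rotation_axis = as.numeric(rotation_axis),
                 rotation_angle = as.numeric(rotation_angle),
                 centre = if (!is.null(centre)) as.numeric(centre),
                 affine = affine, poly = poly),
            class = "deformation_spec")
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; the axis is normalised internally.
#'
#' @param axis rotation axis (length 3).
#' @param angle_deg angle in degrees.
#' @return orthonormal 3 x 3 matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

spec_centre <- function(spec, dims = NULL, spacing = NULL) {
  spec$centre %||% {
    if (is.null(dims)) stop_input("deformation centre unset and no volume given")
    dims * spacing / 2
  }
}

# quadratic displacement P(d) and its gradient, d is n x 3 centred coords
poly_disp <- function(poly, d) {
  terms <- cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
                 d[, 1] * d[, 2], d[, 1] * d[, 3], d[, 2] * d[, 3])
  terms %*% t(poly)
}

poly_grad <- function(poly, d) {
  # returns n x 3 x 3 array, [, i, j] = dP_i/dd_j
  n <- nrow(d)
  g <- array(0, c(n, 3, 3))
  for (i in 1:3) {
    q <- poly[i, ]
    g[, i, 1] <- 2 * q[1] * d[, 1] + q[4] * d[, 2] + q[5] * d[, 3]
    g[, i, 2] <- 2 * q[2] * d[, 2] + q[4] * d[, 1] + q[6] * d[, 3]
    g[, i, 3] <- 2 * q[3] * d[, 3] + q[5] * d[, 1] + q[6] * d[, 2]
  }
  g
}

#' Evaluate a deformation and its analytic oracles
#'
#' `deformation_apply()` maps reference points to deformed points;
#' `deformation_displacement()` returns `u(x) = phi(x) - x`;
#' `deformation_gradient()` returns the deformation gradient `F(x)`;
#' `deformation_strain()` returns the Green-Lagrange tensor `E(x)`.
#'
#' @param spec a [deformation_spec()].
#' @param x n x 3 matrix of reference coordinates (mm).
#' @param centre optional explicit centre overriding the spec's.
#' @return `deformation_apply`/`deformation_displacement`: n x 3 matrix;
#'   `deformation_gradient`/`deformation_strain`: n x 3 x 3 array.
#' @export
deformation_apply <- function(spec, x, centre = NULL) {
  x <- rbind(x)
  cen <- centre %||% spec_centre(spec)
  R <- rotation_matrix(spec$rotation_axis, spec$rotation_angle)
  M <- R %*% (diag(3) + spec$affine)
  d <- sweep(x, 2, cen)
  sweep(d %*% t(M) + poly_disp(spec$poly, d), 2,
        cen + spec$translation, `+`)
}

#' @rdname deformation_apply
#' @export
deformation_displacement <- function(spec, x, centre = NULL) {
  deformation_apply(spec, x, centre) - rbind(x)
}

#' @rdname deformation_apply
#' @export
deformation_gradient <- function(spec, x, centre = NULL) {
  x <- rbind(x)
  cen <- centre %||% spec_centre(spec)
  R <- rotation_matrix(spec$rotation_axis, spec$rotation_angle)
  M <- R %*% (diag(3) + spec$affine)
  g <- poly_grad(spec$poly, sweep(x, 2, cen))
  for (i in 1:3) for (j in 1:3) g[, i, j] <- g[, i, j] + M[i, j]
  g
}

#' @rdname deformation_apply
#' @export
deformation_strain <- function(spec, x, centre = NULL) {
  Fg <- deformation_gradient(spec, x, centre)
  n <- dim(Fg)[1]
  E <- array(0, c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:3) s <- s + Fg[, k, i] * Fg[, k, j]
    E[, i, j] <- (s - (i == j)) / 2
  }
  E
}

# Invert phi at deformed points y (n x 3) by fixed-point iteration on the
# quadratic part; exact (one step) when poly is zero.
deformation_invert <- function(spec, y, centre, tol = 1e-12, maxit = 100L) {
  y <- rbind(y)
  # pure-translation (incl. identity) specs invert exactly, keeping warped
  # volumes bit-identical to direct texture sampling at the mapped grid
  if (spec$rotation_angle == 0 && all(spec$affine == 0) &&
      all(spec$poly == 0)) {
    return(sweep(y, 2, spec$translation))
  }
  R <- rotation_matrix(spec$rotation_axis, spec$rotation_angle)
  M <- R %*% (diag(3) + spec$affine)
  if (abs(det(M)) < 1e-8) stop_input("deformation error: linear part singular")
  Minv <- solve(M)
  rhs0 <- sweep(y, 2, centre + spec$translation) # y - c - t
  d <- rhs0 %*% t(Minv)
  has_poly <- any(spec$poly != 0)
  if (has_poly) {
    for (it in seq_len(maxit)) {
      d_new <- (rhs0 - poly_disp(spec$poly, d)) %*% t(Minv)
      delta <- max(abs(d_new - d))
      d <- d_new
      if (delta < tol) break
    }
    if (delta >= tol) {
      stop_input("deformation error: inverse mapping did not converge (not invertible on domain?)")
    }
  }
  sweep(d, 2, centre, `+`)
}

#' Warp a phantom texture under a known deformation
#'
#' Produces the deformed counterpart of a reference volume by sampling the
#' analytic texture at inverse-mapped voxel centres, i.e.
#' `deformed(y) = texture(phi^{-1}(y))`. This is an exact resampling: the
#' only approximation anywhere is the numerical inversion of the quadratic
#' term (converged to 1e-12 mm). The returned truth object carries the
#' displacement and strain oracles evaluated on reference coordinates.
#'
#' @param texture an [analytic_texture()].
#' @param spec a [deformation_spec()]; must be invertible on the volume
#'   domain.
#' @param dims voxel counts per axis.
#' @param spacing isotropic voxel size (mm).
#' @return list with `volume` (deformed [scalar_volume()]) and `truth`, a
#'   list of `u(x)` / `E(x)` oracle functions (n x 3 matrices of mm
#'   coordinates in, matrices/arrays out), the spec, and the centre used.
#' @export
warp_volume <- function(texture, spec, dims, spacing) {
  dims <- as.integer(dims)
  cen <- spec_centre(spec, dims, spacing)
  gc_ <- voxel_centres(dims, spacing)
  n <- prod(dims)
  pts <- cbind(rep(gc_[[1]], times = dims[2] * dims[3]),
               rep(rep(gc_[[2]], each = dims[1]), times = dims[3]),
               rep(gc_[[3]], each = dims[1] * dims[2]))
  xin <- deformation_invert(spec, pts, centre = cen)
  # invertibility check: det F > 0 on a coarse probe of the domain
  probe <- pts[seq(1, n, length.out = min(n, 125L)), , drop = FALSE]
  Fg <- deformation_gradient(spec, probe, centre = cen)
  dets <- apply(Fg, 1, function(m) det(matrix(m, 3, 3)))
  if (any(dets <= 0.05)) {
    stop_input("deformation error: mapping not invertible on the volume domain")
  }
  coords <- list(x = array(xin[, 1], dims), y = array(xin[, 2], dims),
                 z = array(xin[, 3], dims))
  vol <- scalar_volume(sample_texture(texture, dims, spacing, coords = coords),
                       spacing)
  truth <- list(
    u = function(x) deformation_displacement(spec, x, centre = cen),
    E = function(x) deformation_strain(spec, x, centre = cen),
    spec = spec, centre = cen)
  list(volume = vol, truth = truth)
}
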