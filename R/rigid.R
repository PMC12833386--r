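#' Rigid transform
#'
#' A rigid motion `y = R (x - c) + c + t` about a centroid `c`, as estimated
#' from a displacement field.
#'
#' @param translation mm 3-vector.
#' @param rotation orthonormal 3 x 3 matrix with determinant +1.
#' @param centroid mm 3-vector.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation, rotation, centroid) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop_input("`rotation` must be orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop_input("`rotation` must have determinant +1")
  }
  structure(list(translation = as.numeric(translation), rotation = rotation,
                 centroid = as.numeric(centroid)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> t = (%.4g, %.4g, %.4g) mm, rotation %.4g deg\n",
              x$translation[1], x$translation[2], x$translation[3], ang))
  invisible(x)
}

#' Estimate the common rigid-body motion of a displacement field
#'
#' The translation is the mean displacement over valid nodes. The rotation
#' is the orthogonal factor of the polar decomposition of the best-fit
#' linear mapping of node positions (least squares over valid nodes, about
#' their centroid), so pure rigid fields are recovered exactly and
#' rigid-plus-stretch fields yield the rotation factor of the underlying
#' deformation gradient.
#'
#' @param field a [displacement_field()] with at least 4 non-coplanar valid
#'   nodes.
#' @return a [rigid_transform()].
#' @export
estimate_rigid <- function(field) {
  X <- grid_nodes_mm(field$grid)[field$valid, , drop = FALSE]
  U <- field$u[field$valid, , drop = FALSE]
  if (nrow(X) < 4L) {
    stop_input("estimation error: need at least 4 valid nodes")
  }
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  sv0 <- svd(Xc)
  if (sv0$d[3] < 1e-8 * max(sv0$d[1], 1)) {
    stop_input("estimation error: valid nodes are (near-)coplanar")
  }
  Y <- X + U
  Yc <- sweep(Y, 2, colMeans(Y))
  B <- solve(crossprod(Xc), crossprod(Xc, Yc)) # rows: y_c ~ x_c B
  A <- t(B)                                    # columns: y_c ~ A x_c
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    sv$u[, 3] <- -sv$u[, 3]
    R <- sv$u %*% t(sv$v)
  }
  rigid_transform(translation = colMeans(U), rotation = R, centroid = xbar)
}

#' Remove a rigid-body motion from a displacement field
#'
#' Composes the field's mapping with the inverse rigid motion — i.e. the
#' residual displacement is `u'(x) = R^T (x + u(x) - c - t) + c - x` — so
#' rotation removal is exact at finite angles (naive subtraction of the
#' rigid displacement is only first-order correct). Green-Lagrange strain
#' is invariant under this operation.
#'
#' @param field a [displacement_field()].
#' @param transform a [rigid_transform()], typically from
#'   [estimate_rigid()].
#' @return a [displacement_field()] of residual displacements.
#' @export
remove_rigid <- function(field, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  X <- grid_nodes_mm(field$grid)
  Y <- X + field$u
  Yc <- sweep(Y, 2, transform$centroid + transform$translation)
  Xr <- sweep(Yc %*% transform$rotation, 2, transform$centroid, `+`)
  u2 <- Xr - X
  u2[!field$valid, ] <- 0
  displacement_field(field$grid, u2, field$valid, field$peak)
}
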