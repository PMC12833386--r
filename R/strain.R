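# Green-Lagrange strain mapping: displacement gradient on the node lattice,
# tensor assembly, eigen-decomposition, and per-disc summaries.

# finite differences along one axis of a 3D array (central interior,
# one-sided at the boundaries); h in mm
axis_diff <- function(arr, h, axis) {
  n <- dim(arr)[axis]
  if (n < 2L) stop_input("sizing error: need >= 2 nodes on every axis")
  idx <- function(i) {
    ix <- list(quote(expr =), quote(expr =), quote(expr =))
    ix[[axis]] <- i
    do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
  }
  out <- array(NA_real_, dim(arr))
  asg <- function(i, val) {
    ix <- list(quote(expr =), quote(expr =), quote(expr =))
    ix[[axis]] <- i
    do.call(`[<-`, c(list(out), ix, list(value = val)))
  }
  if (n >= 3L) {
    out <- asg(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
  }
  out <- asg(1L, (idx(2L) - idx(1L)) / h)
  out <- asg(n, (idx(n) - idx(n - 1L)) / h)
  out
}

#' Displacement gradient of a field
#'
#' Dimensionless gradient `G[i, j] = du_i / dx_j` on the node lattice:
#' central differences at interior nodes, one-sided at lattice boundaries,
#' with the node spacing (mm) as the step. Displacements at invalid nodes
#' are treated as missing, so any node whose stencil touches an invalid
#' node is itself flagged invalid.
#'
#' @param field a [displacement_field()] with at least 2 nodes per axis.
#' @return an object of class `displacement_gradient`: list with `G`
#'   (n x 3 x 3 array, node-major, `expand.grid` order), `valid`, and the
#'   grid.
#' @export
displacement_gradient <- function(field) {
  grid <- field$grid
  if (any(grid$n_nodes < 2L)) {
    stop_input("sizing error: need >= 2 nodes on every axis")
  }
  h <- grid$step_mm
  n <- prod(grid$n_nodes)
  G <- array(NA_real_, c(n, 3, 3))
  for (comp in 1:3) {
    arr <- field_component(field, comp)
    arr[array(!field$valid, grid$n_nodes)] <- NA_real_
    for (ax in 1:3) {
      G[, comp, ax] <- as.numeric(axis_diff(arr, h, ax))
    }
  }
  valid <- !apply(G, 1, anyNA)
  structure(list(G = G, valid = valid, grid = grid),
            class = "displacement_gradient")
}

# E = (G + G^T + G^T G) / 2 for one 3x3 or a stack n x 3 x 3
gl_tensor <- function(G) {
  if (is.matrix(G)) {
    return((G + t(G) + crossprod(G)) / 2)
  }
  n <- dim(G)[1]
  E <- array(NA_real_, c(n, 3, 3))
  for (i in 1:3) for (j in i:3) {
    s <- G[, i, j] + G[, j, i]
    for (k in 1:3) s <- s + G[, k, i] * G[, k, j]
    E[, i, j] <- s / 2
    E[, j, i] <- s / 2
  }
  E
}

#' Green-Lagrange strain tensor from a displacement gradient
#'
#' `E = (G + G^T + G^T G) / 2`, the finite-deformation strain measure:
#' symmetric by construction and exactly zero for pure rotations
#' (`G = R - I`). Accepts either a single 3 x 3 gradient matrix (returns
#' the 3 x 3 tensor) or the [displacement_gradient()] of a field (returns
#' a `strain_tensor_field` with per-node principal strains and maximum
#' shear).
#'
#' @param gradient 3 x 3 matrix or `displacement_gradient` object.
#' @param shear `"tensorial"` gives the maximum shear as
#'   `(eps1 - eps3) / 2`; `"engineering"` gives `eps1 - eps3`.
#' @return a 3 x 3 matrix, or an object of class `strain_tensor_field`:
#'   list with `E` (n x 3 x 3), `principal` (n x 3, descending
#'   eigenvalues), `gamma_max`, `valid`, and the grid.
#' @export
green_lagrange <- function(gradient, shear = c("tensorial", "engineering")) {
  shear <- match.arg(shear)
  if (is.matrix(gradient)) {
    if (!all(dim(gradient) == c(3, 3)) || any(!is.finite(gradient))) {
      stop_input("`gradient` must be a finite 3 x 3 matrix")
    }
    return(gl_tensor(gradient))
  }
  stopifnot(inherits(gradient, "displacement_gradient"))
  E <- gl_tensor(gradient$G)
  pr <- principal_values(E, gradient$valid, shear)
  structure(list(E = E, principal = pr$principal, gamma_max = pr$gamma_max,
                 valid = gradient$valid, grid = gradient$grid,
                 shear = shear),
            class = "strain_tensor_field")
}

#' @export
print.strain_tensor_field <- function(x, ...) {
  cat(sprintf("<strain_tensor_field> %s nodes (%d valid)\n",
              paste(x$grid$n_nodes, collapse = " x "), sum(x$valid)))
  if (any(x$valid)) {
    cat(sprintf("  eps1 in [%.3g, %.3g], eps3 in [%.3g, %.3g]\n",
                min(x$principal[x$valid, 1]), max(x$principal[x$valid, 1]),
                min(x$principal[x$valid, 3]), max(x$principal[x$valid, 3])))
  }
  invisible(x)
}

# eigen-decomposition per node (descending) + max shear
principal_values <- function(E, valid, shear = "tensorial") {
  n <- dim(E)[1]
  principal <- matrix(NA_real_, n, 3)
  for (i in which(valid)) {
    principal[i, ] <- eigen(matrix(E[i, , ], 3, 3), symmetric = TRUE,
                            only.values = TRUE)$values
  }
  gmax <- (principal[, 1] - principal[, 3]) /
    if (shear == "tensorial") 2 else 1
  list(principal = principal, gamma_max = gmax)
}

#' Principal strains and maximum shear of a strain tensor
#'
#' Eigenvalues in descending order (`eps1 >= eps2 >= eps3`) and the maximum
#' shear `gamma_max = (eps1 - eps3) / 2` (tensorial convention; the
#' engineering convention drops the factor of two). Accepts a single
#' symmetric 3 x 3 tensor or a `strain_tensor_field`.
#'
#' @param E symmetric 3 x 3 matrix or `strain_tensor_field`.
#' @param shear `"tensorial"` or `"engineering"`.
#' @param tol symmetry tolerance relative to the largest entry.
#' @return for a matrix: named list `eps` (length 3) and `gamma_max`; for a
#'   field: list with `principal` (n x 3) and `gamma_max` (n).
#' @export
principal_invariants <- function(E, shear = c("tensorial", "engineering"),
                                 tol = 1e-8) {
  shear <- match.arg(shear)
  if (is.matrix(E)) {
    if (max(abs(E - t(E))) > tol * max(abs(E), 1e-12)) {
      stop_input("input error: strain tensor is not symmetric")
    }
    ev <- eigen((E + t(E)) / 2, symmetric = TRUE, only.values = TRUE)$values
    return(list(eps = ev,
                gamma_max = (ev[1] - ev[3]) /
                  if (shear == "tensorial") 2 else 1))
  }
  stopifnot(inherits(E, "strain_tensor_field"))
  list(principal = E$principal, gamma_max = E$gamma_max)
}

#' Per-disc strain summary
#'
#' Averages and extracts peak strains over the nodes whose subset centre
#' voxel lies inside a disc's mask (mean = unweighted average over valid
#' qualifying nodes; peak = the signed value with the highest magnitude,
#' and the node index attaining it). Strains are reported in percent.
#'
#' @param strain a `strain_tensor_field` from [green_lagrange()].
#' @param mask a [label_mask()] containing the level.
#' @param level disc label, e.g. `"L4-L5"`.
#' @return a list of class `level_strain_summary`: level, `n_nodes`, mean
#'   and peak `eps1` / `eps3` / `gamma_max` in percent with peak node
#'   indices, and `resolved`. When no valid node centre falls inside the
#'   mask, `resolved` is `FALSE` and no summary values are emitted.
#' @export
summarize_level <- function(strain, mask, level) {
  stopifnot(inherits(strain, "strain_tensor_field"))
  code <- mask_code(mask, level)
  nodes <- round(grid_nodes_vox(strain$grid))
  dims <- dim(mask$data)
  inb <- nodes[, 1] >= 1 & nodes[, 1] <= dims[1] &
         nodes[, 2] >= 1 & nodes[, 2] <= dims[2] &
         nodes[, 3] >= 1 & nodes[, 3] <= dims[3]
  inmask <- rep(FALSE, nrow(nodes))
  inmask[inb] <- mask$data[nodes[inb, , drop = FALSE]] == code
  sel <- which(inmask & strain$valid)
  if (length(sel) == 0L) {
    return(structure(list(level = level, resolved = FALSE, n_nodes = 0L),
                     class = "level_strain_summary"))
  }
  pick_peak <- function(v) {
    i <- sel[which.max(abs(v[sel]))]
    list(value = v[i], node = i)
  }
  e1 <- strain$principal[, 1]; e3 <- strain$principal[, 3]
  gm <- strain$gamma_max
  p1 <- pick_peak(e1); p3 <- pick_peak(e3); pg <- pick_peak(gm)
  structure(list(
    level = level, resolved = TRUE, n_nodes = length(sel),
    mean_eps1 = 100 * mean(e1[sel]), mean_eps3 = 100 * mean(e3[sel]),
    mean_gamma = 100 * mean(gm[sel]),
    peak_eps1 = 100 * p1$value, peak_eps1_node = p1$node,
    peak_eps3 = 100 * p3$value, peak_eps3_node = p3$node,
    peak_gamma = 100 * pg$value, peak_gamma_node = pg$node),
    class = "level_strain_summary")
}

#' @export
print.level_strain_summary <- function(x, ...) {
  if (!x$resolved) {
    cat(sprintf("<level_strain_summary> %s: unresolvable (no valid nodes in mask)\n",
                x$level))
    return(invisible(x))
  }
  cat(sprintf("<level_strain_summary> %s (%d nodes)\n", x$level, x$n_nodes))
  cat(sprintf("  mean eps1 %.3g%%, eps3 %.3g%%, gamma %.3g%% | peak eps1 %.3g%%, eps3 %.3g%%, gamma %.3g%%\n",
              x$mean_eps1, x$mean_eps3, x$mean_gamma,
              x$peak_eps1, x$peak_eps3, x$peak_gamma))
  invisible(x)
}

#' Strain summaries for several discs as one table
#'
#' Applies [summarize_level()] to each level and binds the rows
#' (unresolved levels are reported with NA values).
#'
#' @inheritParams summarize_level
#' @param levels character vector of disc labels.
#' @return data.frame with one row per level.
#' @export
summarize_levels <- function(strain, mask, levels) {
  rows <- lapply(levels, function(lv) {
    s <- summarize_level(strain, mask, lv)
    data.frame(level = lv, resolved = s$resolved,
               n_nodes = s$n_nodes,
               mean_eps1 = s$mean_eps1 %||% NA_real_,
               mean_eps3 = s$mean_eps3 %||% NA_real_,
               mean_gamma = s$mean_gamma %||% NA_real_,
               peak_eps1 = s$peak_eps1 %||% NA_real_,
               peak_eps3 = s$peak_eps3 %||% NA_real_,
               peak_gamma = s$peak_gamma %||% NA_real_)
  })
  do.call(rbind, rows)
}
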