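#' Multipass correlation schedule
#'
#' The coarse-to-fine subset schedule of the correlation engine. The default
#' is the 48-32-24-16 voxel pyramid with 1-1-2-2 passes, 50% subset overlap
#' and a 50% minimum valid-voxel fraction.
#'
#' @param sizes strictly decreasing subset edge lengths (voxels).
#' @param passes number of correlation passes per stage.
#' @param overlap subset overlap fraction in (0, 1); node spacing is
#'   `size * (1 - overlap)`.
#' @param min_valid minimum fraction of subset voxels inside the foreground
#'   for a node to be considered valid, in (0, 1].
#' @return an object of class `subset_schedule`.
#' @export
subset_schedule <- function(sizes = c(48L, 32L, 24L, 16L),
                            passes = c(1L, 1L, 2L, 2L),
                            overlap = 0.5, min_valid = 0.5) {
  sizes <- as.integer(sizes)
  passes <- as.integer(passes)
  if (length(sizes) < 1L || any(diff(sizes) >= 0)) {
    stop_input("`sizes` must be strictly decreasing")
  }
  if (length(passes) != length(sizes) || any(passes < 1L)) {
    stop_input("`passes` must give >= 1 pass per stage")
  }
  if (overlap <= 0 || overlap >= 1) stop_input("`overlap` must be in (0, 1)")
  if (min_valid <= 0 || min_valid > 1) stop_input("`min_valid` must be in (0, 1]")
  structure(list(sizes = sizes, passes = passes, overlap = overlap,
                 min_valid = min_valid),
            class = "subset_schedule")
}

#' @export
print.subset_schedule <- function(x, ...) {
  cat(sprintf("<subset_schedule> %s voxels, passes %s, overlap %d%%, min valid %d%%\n",
              paste(x$sizes, collapse = "-"), paste(x$passes, collapse = "-"),
              round(100 * x$overlap), round(100 * x$min_valid)))
  invisible(x)
}

#' Build the node grid for one subset size
#'
#' Lays cubic subsets over the volume at spacing
#' `subset * (1 - overlap)` voxels, symmetrically placed so every subset is
#' fully inside the volume. Node centres are stored in voxel units (centre
#' of voxel `i` at index `i`, i.e. a subset starting at voxel `s` has its
#' centre at `s + (subset - 1) / 2`).
#'
#' @param dims voxel counts per axis.
#' @param subset subset edge length (voxels); must not exceed any dimension,
#'   and `subset * (1 - overlap)` must be a whole number of voxels.
#' @param overlap overlap fraction in (0, 1), or 0 for abutting subsets.
#' @param spacing voxel size in mm.
#' @return an object of class `subset_grid` with per-axis subset start
#'   indices, node centres (voxel units), node counts, the node spacing in
#'   voxels (`step_vox`) and mm (`step_mm`).
#' @examples
#' g <- build_subset_grid(c(64, 64, 64), 16, 0.5, 0.58)
#' g$step_mm # 4.64
#' @export
build_subset_grid <- function(dims, subset, overlap, spacing) {
  dims <- as.integer(dims)
  if (any(subset > dims)) {
    stop_input("sizing error: subset (%d) exceeds a volume dimension (%s)",
               subset, paste(dims, collapse = " x "))
  }
  if (overlap < 0 || overlap >= 1) stop_input("`overlap` must be in [0, 1)")
  step <- subset * (1 - overlap)
  if (abs(step - round(step)) > 1e-9) {
    stop_input("subset %d with overlap %.3g gives a non-integer node spacing",
               subset, overlap)
  }
  step <- as.integer(round(step))
  if (step < 1L) stop_input("node spacing must be at least one voxel")
  starts <- lapply(1:3, function(a) {
    k <- (dims[a] - subset) %/% step + 1L
    off <- (dims[a] - subset - (k - 1L) * step) %/% 2L
    off + 1L + step * (seq_len(k) - 1L)
  })
  centres <- lapply(starts, function(s) s + (subset - 1) / 2)
  structure(list(dims = dims, subset = as.integer(subset),
                 overlap = overlap, spacing = spacing,
                 step_vox = step, step_mm = step * spacing,
                 starts = starts, centres = centres,
                 n_nodes = vapply(starts, length, integer(1))),
            class = "subset_grid")
}

#' @export
print.subset_grid <- function(x, ...) {
  cat(sprintf("<subset_grid> subset %d vox, %s nodes, spacing %d vox = %.3g mm\n",
              x$subset, paste(x$n_nodes, collapse = " x "), x$step_vox,
              x$step_mm))
  invisible(x)
}

# all node centres as an n x 3 matrix (voxel units), x fastest
grid_nodes_vox <- function(grid) {
  as.matrix(expand.grid(grid$centres[[1]], grid$centres[[2]],
                        grid$centres[[3]], KEEP.OUT.ATTRS = FALSE))
}

# node centres in mm (voxel i centre at (i - 0.5) * spacing)
grid_nodes_mm <- function(grid) {
  (grid_nodes_vox(grid) - 0.5) * grid$spacing
}

#' Displacement field on a subset grid
#'
#' Per-node 3-vector displacements in mm with validity flags and the
#' correlation peak quality attained at each node.
#'
#' @param grid a [build_subset_grid()].
#' @param u n x 3 matrix of displacements (mm), ordered like
#'   `expand.grid` over the grid's per-axis node centres (x fastest).
#' @param valid logical vector of length n.
#' @param peak numeric vector of correlation peak values.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(grid, u, valid = NULL, peak = NULL) {
  n <- prod(grid$n_nodes)
  u <- rbind(u)
  if (nrow(u) != n || ncol(u) != 3L) stop_input("`u` must be %d x 3", n)
  valid <- valid %||% rep(TRUE, n)
  peak <- peak %||% rep(NA_real_, n)
  if (any(!is.finite(u[valid, ]))) {
    stop_input("valid nodes must have finite displacements")
  }
  structure(list(grid = grid, u = u, valid = as.logical(valid),
                 peak = as.numeric(peak)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %s nodes (%d valid), |u| up to %.3g mm\n",
              paste(x$grid$n_nodes, collapse = " x "), sum(x$valid),
              if (any(x$valid)) max(abs(x$u[x$valid, ])) else NA))
  invisible(x)
}

# one displacement component as an array over the node lattice
field_component <- function(field, comp) {
  array(field$u[, comp], field$grid$n_nodes)
}

# Trilinear interpolation of a (possibly partially invalid) field at target
# voxel coordinates; invalid nodes are filled with the mean valid
# displacement first, and targets outside the node hull are clamped.
interp_field <- function(field, targets_vox) {
  grid <- field$grid
  if (!any(field$valid)) stop_input("cannot interpolate: no valid nodes")
  fill <- colMeans(field$u[field$valid, , drop = FALSE])
  u <- field$u
  u[!field$valid, ] <- rep(fill, each = sum(!field$valid))
  out <- matrix(0, nrow(targets_vox), 3)
  idx_w <- lapply(1:3, function(a) {
    cs <- grid$centres[[a]]
    t <- pmin(pmax(targets_vox[, a], cs[1]), cs[length(cs)])
    if (length(cs) == 1L) return(list(i0 = rep(1L, length(t)),
                                      i1 = rep(1L, length(t)),
                                      w = rep(0, length(t))))
    i0 <- pmin(findInterval(t, cs), length(cs) - 1L)
    w <- (t - cs[i0]) / (cs[i0 + 1L] - cs[i0])
    list(i0 = i0, i1 = i0 + 1L, w = w)
  })
  nx <- grid$n_nodes[1]; ny <- grid$n_nodes[2]
  lin <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  for (comp in 1:3) {
    v <- u[, comp]
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ii <- if (cx == 0) idx_w[[1]]$i0 else idx_w[[1]]$i1
      jj <- if (cy == 0) idx_w[[2]]$i0 else idx_w[[2]]$i1
      kk <- if (cz == 0) idx_w[[3]]$i0 else idx_w[[3]]$i1
      wx <- if (cx == 0) 1 - idx_w[[1]]$w else idx_w[[1]]$w
      wy <- if (cy == 0) 1 - idx_w[[2]]$w else idx_w[[2]]$w
      wz <- if (cz == 0) 1 - idx_w[[3]]$w else idx_w[[3]]$w
      acc <- acc + v[lin(ii, jj, kk)] * wx * wy * wz
    }
    out[, comp] <- acc
  }
  out
}
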