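#' Analytic speckle texture
#'
#' A band-limited intensity field defined as a sum of isotropic Gaussian
#' blobs over a constant background. Because the field is evaluable at any
#' continuous coordinate, a deformed volume can be produced by *exact
#' resampling* of the texture at inverse-mapped voxel centres: there is no
#' image-interpolation error to confound correlation-accuracy measurements.
#'
#' @param centres n x 3 matrix of blob centres (mm).
#' @param widths vector of n Gaussian standard deviations (mm), all > 0.
#' @param amplitudes vector of n blob amplitudes (arbitrary intensity).
#' @param background constant background intensity.
#' @return an object of class `analytic_texture`.
#' @seealso [make_speckle_phantom()], [warp_volume()]
#' @export
analytic_texture <- function(centres, widths, amplitudes, background = 0) {
  centres <- rbind(centres)
  if (ncol(centres) != 3L) stop_input("`centres` must be an n x 3 matrix")
  n <- nrow(centres)
  if (length(widths) != n || length(amplitudes) != n) {
    stop_input("`widths` and `amplitudes` must match the number of centres")
  }
  if (n > 0 && any(widths <= 0)) stop_input("all blob widths must be > 0")
  structure(list(centres = centres, widths = as.numeric(widths),
                 amplitudes = as.numeric(amplitudes),
                 background = as.numeric(background)),
            class = "analytic_texture")
}

#' @export
print.analytic_texture <- function(x, ...) {
  cat(sprintf("<analytic_texture> %d Gaussian blobs, background %.3g\n",
              nrow(x$centres), x$background))
  invisible(x)
}

# Evaluate the texture on a voxel grid.
#
# coords: optional list(x=, y=, z=) of dims-shaped arrays of mm coordinates
# at which to evaluate (used for warped resampling); NULL means the regular
# voxel-centre grid. Each blob only contributes within `cutoff` standard
# deviations, localised through the regular-grid index bounds (widened by
# the maximum deviation of `coords` from the regular grid), which keeps the
# evaluation linear in blob count rather than blob count x voxel count.
sample_texture <- function(texture, dims, spacing, coords = NULL,
                           cutoff = 5) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  gc_ <- voxel_centres(dims, spacing)
  if (is.null(coords)) {
    X <- array(gc_[[1]], dims)
    Y <- array(rep(gc_[[2]], each = dims[1]), dims)
    Z <- array(rep(gc_[[3]], each = dims[1] * dims[2]), dims)
    marg <- c(0, 0, 0)
  } else {
    X <- coords$x; Y <- coords$y; Z <- coords$z
    stopifnot(identical(dim(X), dims), identical(dim(Y), dims),
              identical(dim(Z), dims))
    marg <- c(max(abs(X - array(gc_[[1]], dims))),
              max(abs(Y - array(rep(gc_[[2]], each = dims[1]), dims))),
              max(abs(Z - array(rep(gc_[[3]], each = dims[1] * dims[2]),
                                dims))))
  }
  vals <- array(texture$background, dims)
  nb <- nrow(texture$centres)
  if (nb == 0L) return(vals)
  for (b in seq_len(nb)) {
    cb <- texture$centres[b, ]
    w <- texture$widths[b]
    a <- texture$amplitudes[b]
    cut <- cutoff * w
    i1 <- pmax(1L, ceiling((cb - cut - marg) / spacing + 0.5))
    i2 <- pmin(dims, floor((cb + cut + marg) / spacing + 0.5))
    if (any(i1 > i2)) next
    ix <- i1[1]:i2[1]; iy <- i1[2]:i2[2]; iz <- i1[3]:i2[3]
    d2 <- ((X[ix, iy, iz, drop = FALSE] - cb[1])^2 +
           (Y[ix, iy, iz, drop = FALSE] - cb[2])^2) +
          (Z[ix, iy, iz, drop = FALSE] - cb[3])^2
    vals[ix, iy, iz] <- vals[ix, iy, iz] + a * exp(-d2 / (2 * w^2))
  }
  vals
}

#' Generate a speckle-textured phantom volume
#'
#' Draws a random analytic blob texture (blob centres uniform over the
#' volume, widths and amplitudes uniform within the given ranges) and samples
#' it at the voxel centres. The returned texture object can be resampled
#' under any smooth deformation by [warp_volume()] to create exactly-known
#' deformed counterparts for correlation testing.
#'
#' @param dims voxel counts per axis (length-3, each at least `min_dim`).
#' @param spacing isotropic voxel size in mm.
#' @param blob_count number of Gaussian blobs (0 gives a uniform volume).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param width_range blob standard-deviation range in voxel units
#'   (converted to mm internally).
#' @param amp_range blob amplitude range.
#' @param amp_scale multiplier applied to all amplitudes.
#' @param background constant background intensity.
#' @param min_dim minimum allowed dimension; defaults to 48 voxels so the
#'   largest correlation subset of the default multipass schedule fits.
#' @return list with elements `volume` (a [scalar_volume()]) and `texture`
#'   (an [analytic_texture()]).
#' @examples
#' ph <- make_speckle_phantom(c(48, 48, 48), 0.58, blob_count = 500, seed = 1)
#' ph$volume
#' @export
make_speckle_phantom <- function(dims, spacing, blob_count = 3000, seed,
                                 width_range = c(0.9, 1.6),
                                 amp_range = c(0.5, 1.5), amp_scale = 1,
                                 background = 0, min_dim = 48L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < min_dim)) {
    stop_input("all `dims` must be at least %d voxels (largest subset must fit)",
               min_dim)
  }
  if (!is.numeric(blob_count) || length(blob_count) != 1L || blob_count < 0) {
    stop_input("`blob_count` must be a non-negative count")
  }
  extent <- dims * spacing
  tex <- with_seed(seed, {
    n <- as.integer(blob_count)
    centres <- cbind(stats::runif(n, 0, extent[1]),
                     stats::runif(n, 0, extent[2]),
                     stats::runif(n, 0, extent[3]))
    widths <- stats::runif(n, width_range[1], width_range[2]) * spacing
    amps <- stats::runif(n, amp_range[1], amp_range[2]) * amp_scale
    analytic_texture(centres, widths, amps, background = background)
  })
  vol <- scalar_volume(sample_texture(tex, dims, spacing), spacing)
  list(volume = vol, texture = tex)
}
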