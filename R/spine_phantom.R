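#' Spine phantom geometry
#'
#' Prescribes the mid-sagittal geometry of a stack of vertebral bodies and
#' intervertebral discs: per-disc anterior/posterior heights (or,
#' equivalently, central height plus wedge angle), a common
#' anterior-posterior depth, per-vertebra body heights, and the sacral
#' endplate tilt. Endplates within a vertebra are parallel, so the disc
#' wedge fully determines the segmental Cobb angle and segmental angles
#' telescope into the lumbar lordosis. The wedge and the heights are linked
#' exactly by `sin(wedge/2) = (anterior - posterior) / (2 * depth)`.
#'
#' @param levels number of disc levels (default 5, L1-L2 to L5-S1).
#' @param disc_anterior,disc_posterior per-disc anterior/posterior heights
#'   (mm), recycled to `levels`. Ignored when `wedge` is given.
#' @param wedge optional per-disc wedge (segmental lordosis) angles in
#'   degrees, positive = lordotic; combined with `disc_central` to derive
#'   the anterior/posterior heights.
#' @param disc_central per-disc central heights (mm), only used with `wedge`.
#' @param depth anterior-posterior body depth (mm).
#' @param vertebra_height per-vertebra body heights (mm), recycled to
#'   `levels + 1`.
#' @param sacral_angle tilt of the most caudal superior endplate relative to
#'   horizontal, degrees (positive = posterior rim more cranial, the usual
#'   sacral slope sense).
#' @param width lateral (z) extent of the bodies (mm).
#' @return an object of class `spine_geometry`.
#' @export
spine_geometry <- function(levels = 5L,
                           disc_anterior = 11, disc_posterior = 8,
                           wedge = NULL, disc_central = 9.5,
                           depth = 35, vertebra_height = 26,
                           sacral_angle = 38, width = 30) {
  if (!is_count(levels)) stop_input("`levels` must be a positive count")
  m <- as.integer(levels)
  if (!is.null(wedge)) {
    wedge <- rep_len(wedge, m)
    if (any(abs(wedge) > 45)) stop_input("wedge angles must be within +/-45 degrees")
    g0 <- rep_len(disc_central, m)
    half <- sin(wedge * pi / 360) * depth
    disc_anterior <- g0 + half
    disc_posterior <- g0 - half
  } else {
    disc_anterior <- rep_len(disc_anterior, m)
    disc_posterior <- rep_len(disc_posterior, m)
    wedge <- 2 * asin((disc_anterior - disc_posterior) / (2 * depth)) * 180 / pi
  }
  if (any(disc_anterior <= 0) || any(disc_posterior <= 0)) {
    stop_input("geometry error: disc heights must be > 0")
  }
  if (abs(sacral_angle) > 45) stop_input("`sacral_angle` must be within +/-45 degrees")
  vh <- rep_len(vertebra_height, m + 1L)
  if (any(vh <= 0)) stop_input("vertebra heights must be > 0")
  structure(list(levels = m, disc_anterior = disc_anterior,
                 disc_posterior = disc_posterior,
                 disc_central = (disc_anterior + disc_posterior) / 2,
                 wedge = wedge, depth = depth, vertebra_height = vh,
                 sacral_angle = sacral_angle, width = width),
            class = "spine_geometry")
}

default_vertebra_names <- function(m) {
  if (m == 5L) c("L1", "L2", "L3", "L4", "L5", "S1")
  else c(paste0("V", seq_len(m)), "S1")
}

# convex polygon overlap via separating-axis test (2D, n x 2 vertex mats)
quads_overlap <- function(a, b) {
  axes <- rbind(a[c(2:4, 1), ] - a, b[c(2:4, 1), ] - b)
  for (i in seq_len(nrow(axes))) {
    n <- c(-axes[i, 2], axes[i, 1])
    if (sum(n^2) == 0) next
    pa <- a %*% n; pb <- b %*% n
    if (max(pa) <= min(pb) || max(pb) <= min(pa)) return(FALSE)
  }
  TRUE
}

# inside test for a convex quad with vertices in order; px/py vectors
in_quad <- function(px, py, v) {
  cr <- vector("list", 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    cr[[i]] <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) -
               (v[j, 2] - v[i, 2]) * (px - v[i, 1])
  }
  all_pos <- cr[[1]] >= 0 & cr[[2]] >= 0 & cr[[3]] >= 0 & cr[[4]] >= 0
  all_neg <- cr[[1]] <= 0 & cr[[2]] <= 0 & cr[[3]] <= 0 & cr[[4]] <= 0
  all_pos | all_neg
}

#' Generate a synthetic lumbar spine phantom
#'
#' Builds a speckle-textured volume containing a stack of `levels + 1`
#' vertebral bodies and `levels` discs in the sagittal plane per a
#' [spine_geometry()], together with the label mask, the mid-sagittal
#' endplate landmark set, and a ground-truth record of every prescribed
#' metric. Vertebral bodies are axis-aligned rounded boxes only in spirit:
#' they are convex quadrilaterals extruded laterally, tilted so that all
#' prescribed heights and angles hold exactly on the emitted landmarks.
#'
#' @param geometry a [spine_geometry()].
#' @param spacing isotropic voxel size (mm).
#' @param seed RNG seed for the speckle texture.
#' @param names vertebra names, cranial to caudal (default `L1..L5, S1` for
#'   five levels).
#' @param blob_density speckle blobs per voxel.
#' @param margin clearance between anatomy and volume border (mm).
#' @param min_dim minimum volume dimension in voxels (default 48 so the
#'   default correlation schedule fits).
#' @param ... further speckle arguments passed to
#'   [make_speckle_phantom()] (e.g. `width_range`, `amp_range`).
#' @return list with `volume` ([scalar_volume()]), `texture`
#'   ([analytic_texture()]), `mask` ([label_mask()] with one label per
#'   vertebra and disc), `landmarks` ([landmark_set()]) and `truth` (list of
#'   prescribed per-disc heights/wedges, sacral angle, lumbar lordosis,
#'   lumbar height and endplate tilts).
#' @examples
#' geo <- spine_geometry(levels = 2, depth = 28, vertebra_height = 18)
#' ph <- make_spine_phantom(geo, spacing = 1.5, seed = 7)
#' ph$mask
#' @export
make_spine_phantom <- function(geometry, spacing = 0.58, seed = 1L,
                               names = NULL, blob_density = 0.05,
                               margin = 5, min_dim = 48L, ...) {
  stopifnot(inherits(geometry, "spine_geometry"))
  m <- geometry$levels
  nv <- m + 1L
  names <- names %||% default_vertebra_names(m)
  if (length(names) != nv) stop_input("`names` must have %d entries", nv)
  disc_names <- paste(names[-nv], names[-1], sep = "-")

  e_dir <- function(t) c(cos(t), sin(t))     # along endplate, +posterior
  n_up <- function(t) c(-sin(t), cos(t))     # endplate normal, +cranial

  # endplate tilts (radians, posterior-up positive), caudal to cranial
  tilt <- numeric(nv)
  tilt[nv] <- geometry$sacral_angle * pi / 180
  for (j in rev(seq_len(m))) tilt[j] <- tilt[j + 1] - geometry$wedge[j] * pi / 180

  Tc <- matrix(0, nv, 2) # superior endplate centres
  Bc <- matrix(0, nv, 2) # inferior endplate centres
  Tc[nv, ] <- c(0, 0)
  Bc[nv, ] <- Tc[nv, ] - geometry$vertebra_height[nv] * n_up(tilt[nv])
  for (j in rev(seq_len(m))) {
    mu <- (tilt[j] + tilt[j + 1]) / 2
    Bc[j, ] <- Tc[j + 1, ] + geometry$disc_central[j] * n_up(mu)
    Tc[j, ] <- Bc[j, ] + geometry$vertebra_height[j] * n_up(tilt[j])
  }

  hD <- geometry$depth / 2
  corner <- function(centre, t, s) centre + s * hD * e_dir(t)
  vert_quads <- lapply(seq_len(nv), function(j) {
    rbind(corner(Tc[j, ], tilt[j], -1), corner(Tc[j, ], tilt[j], 1),
          corner(Bc[j, ], tilt[j], 1), corner(Bc[j, ], tilt[j], -1))
  })
  disc_quads <- lapply(seq_len(m), function(j) {
    rbind(corner(Bc[j, ], tilt[j], -1), corner(Bc[j, ], tilt[j], 1),
          corner(Tc[j + 1, ], tilt[j + 1], 1),
          corner(Tc[j + 1, ], tilt[j + 1], -1))
  })
  for (a in seq_len(nv - 1)) for (b in (a + 1):nv) {
    if (quads_overlap(vert_quads[[a]], vert_quads[[b]])) {
      stop_input("geometry error: vertebra bodies %s and %s overlap",
                 names[a], names[b])
    }
  }

  # shift into positive coordinates and size the volume
  allv <- do.call(rbind, c(vert_quads, disc_quads))
  lo <- apply(allv, 2, min) - margin
  hi <- apply(allv, 2, max) + margin
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)),
               as.integer(min_dim))
  dims <- c(dims, max(as.integer(ceiling((geometry$width + 2 * margin) /
                                           spacing)), as.integer(min_dim)))
  shift <- -lo + (dims[1:2] * spacing - (hi - lo)) / 2
  shifted <- function(q) sweep(q, 2, shift, `+`)
  vert_quads <- lapply(vert_quads, shifted)
  disc_quads <- lapply(disc_quads, shifted)
  Tc <- shifted(Tc); Bc <- shifted(Bc)

  # mask: paint vertebrae first, discs last (shared endplate voxels belong
  # to the disc, endplates included in the disc region of interest)
  gx <- (seq_len(dims[1]) - 0.5) * spacing
  gy <- (seq_len(dims[2]) - 0.5) * spacing
  px <- rep(gx, times = dims[2])
  py <- rep(gy, each = dims[1])
  plane <- matrix(0L, dims[1], dims[2])
  labels <- stats::setNames(seq_len(nv + m),
                            c(names, disc_names))
  for (j in seq_len(nv)) {
    plane[in_quad(px, py, vert_quads[[j]])] <- labels[[names[j]]]
  }
  for (j in seq_len(m)) {
    plane[in_quad(px, py, disc_quads[[j]])] <- labels[[disc_names[j]]]
  }
  zc <- dims[3] * spacing / 2
  gz <- (seq_len(dims[3]) - 0.5) * spacing
  zin <- abs(gz - zc) <= geometry$width / 2
  mask_arr <- array(0L, dims)
  for (k in which(zin)) mask_arr[, , k] <- plane
  mask <- label_mask(mask_arr, labels, spacing)

  # landmarks (2D sagittal, mm, in the shifted frame)
  pts <- do.call(rbind, lapply(seq_len(nv), function(j) {
    rbind(
      data.frame(vertebra = names[j], endplate = "sup", rim = "ant",
                 x = corner(Tc[j, ], tilt[j], -1)[1],
                 y = corner(Tc[j, ], tilt[j], -1)[2]),
      data.frame(vertebra = names[j], endplate = "sup", rim = "post",
                 x = corner(Tc[j, ], tilt[j], 1)[1],
                 y = corner(Tc[j, ], tilt[j], 1)[2]),
      data.frame(vertebra = names[j], endplate = "inf", rim = "ant",
                 x = corner(Bc[j, ], tilt[j], -1)[1],
                 y = corner(Bc[j, ], tilt[j], -1)[2]),
      data.frame(vertebra = names[j], endplate = "inf", rim = "post",
                 x = corner(Bc[j, ], tilt[j], 1)[1],
                 y = corner(Bc[j, ], tilt[j], 1)[2]))
  }))
  lms <- landmark_set(pts, vertebrae = names)

  sp <- make_speckle_phantom(dims, spacing,
                             blob_count = round(blob_density * prod(dims)),
                             seed = seed, min_dim = 0L, ...)

  truth <- list(
    disc = data.frame(level = disc_names,
                      anterior = geometry$disc_anterior,
                      central = geometry$disc_central,
                      posterior = geometry$disc_posterior,
                      wedge = geometry$wedge),
    sacral_angle = geometry$sacral_angle,
    lumbar_lordosis = sum(geometry$wedge),
    lumbar_height = sqrt(sum((corner(Tc[1, ], tilt[1], -1) -
                              corner(Tc[nv, ], tilt[nv], -1))^2)),
    tilts_deg = tilt * 180 / pi)

  list(volume = sp$volume, texture = sp$texture, mask = mask,
       landmarks = lms, truth = truth)
}
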