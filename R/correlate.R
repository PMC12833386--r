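# Subset correlation engine: FFT cross-correlation for the coarse predictor
# stages, zero-normalised direct correlation (ZNCC) over a bounded search
# window for the corrector stages, with separable three-point Gaussian
# sub-voxel peak refinement.

# 3D Hann window, separable
hann3 <- function(n) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  outer(outer(w, w), w)
}

# three-point Gaussian peak offset; falls back to a parabola when the
# correlation triple is not strictly positive, and to 0 when degenerate
subvoxel_offset <- function(cm, c0, cp) {
  if (!is.finite(cm) || !is.finite(cp) || !is.finite(c0)) return(0)
  if (c0 < cm || c0 < cp) return(0)
  if (cm > 0 && cp > 0 && c0 > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den < 0) return(max(-0.5, min(0.5, (log(cm) - log(cp)) / den)))
  }
  den <- cm - 2 * c0 + cp
  if (den < 0) return(max(-0.5, min(0.5, (cm - cp) / (2 * den))))
  0
}

extract_block <- function(vol, start, size) {
  vol[start[1]:(start[1] + size - 1L),
      start[2]:(start[2] + size - 1L),
      start[3]:(start[3] + size - 1L)]
}

# Catmull-Rom cubic convolution weights for fractional offsets g in [0, 1);
# vectorised: returns an n x 4 matrix over support offsets -1..2
cubic_weights <- function(g) {
  cbind(-0.5 * g + g^2 - 0.5 * g^3,
        1 - 2.5 * g^2 + 1.5 * g^3,
        0.5 * g + 2 * g^2 - 1.5 * g^3,
        -0.5 * g^2 + 0.5 * g^3)
}

# Cubic interpolation of a volume array at arbitrary voxel coordinates
# (n x 3). Returns NULL when any support voxel falls outside the volume.
cubic_sample <- function(vol, dims, pts) {
  base <- floor(pts)
  if (any(base < 2) || any(base[, 1] > dims[1] - 2L) ||
      any(base[, 2] > dims[2] - 2L) || any(base[, 3] > dims[3] - 2L)) {
    return(NULL)
  }
  g <- pts - base
  W1 <- cubic_weights(g[, 1])
  W2 <- cubic_weights(g[, 2])
  W3 <- cubic_weights(g[, 3])
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  b1 <- base[, 1]; b2 <- base[, 2]; b3 <- base[, 3]
  out <- numeric(nrow(pts))
  for (dz in 0:3) for (dy in 0:3) {
    wyz <- W2[, dy + 1] * W3[, dz + 1]
    idx0 <- (b2 + dy - 2L) * nx + (b3 + dz - 2L) * nxy
    for (dx in 0:3) {
      out <- out + vol[b1 + dx - 1L + idx0] * (W1[, dx + 1] * wyz)
    }
  }
  out
}

#' Single correlation pass between two volumes
#'
#' For every node of the subset grid, finds the displacement (mm) that best
#' matches the reference subset inside the deformed volume. A seed field
#' (typically the interpolated result of a coarser stage) shifts the search
#' region; the integer-voxel correlation peak is then refined to sub-voxel
#' precision by separable three-point Gaussian fitting. Nodes are flagged
#' invalid when the subset foreground fraction falls below
#' `min_valid`, the subset has no intensity variance, or the
#' (seed-shifted) search region leaves the volume.
#'
#' In `"fft"` mode the match is the peak of the zero-mean, Hann-windowed
#' circular cross-correlation of the two subsets (shifts limited to a
#' quarter subset to avoid wrap-around aliasing). In `"direct"` mode it is
#' the peak of the zero-normalised cross-correlation evaluated over integer
#' shifts within `search` voxels of the seed. When the peak correlation is
#' numerically perfect the sub-voxel step is skipped, so exact integer
#' shifts are recovered exactly. Ties on the correlation peak are broken
#' toward the lowest-magnitude displacement.
#'
#' @param ref,deformed reference and deformed [scalar_volume()]s (same
#'   dimensions and spacing).
#' @param grid a [build_subset_grid()].
#' @param seed_field optional [displacement_field()] on a coarser or equal
#'   grid used as predictor.
#' @param mode `"direct"` or `"fft"`.
#' @param search half-width of the integer search window (direct mode),
#'   voxels.
#' @param min_valid minimum subset foreground fraction.
#' @param foreground optional [label_mask()] or logical/numeric array;
#'   non-zero voxels are foreground. `NULL` treats the whole volume as
#'   foreground.
#' @return a [displacement_field()].
#' @export
correlate_pass <- function(ref, deformed, grid, seed_field = NULL,
                           mode = c("direct", "fft"), search = 2L,
                           min_valid = 0.5, foreground = NULL) {
  mode <- match.arg(mode)
  if (!identical(dim(ref$data), dim(deformed$data)) ||
      abs(ref$spacing - deformed$spacing) > 1e-9) {
    stop_input("input error: volumes must share dimensions and spacing")
  }
  dims <- dim(ref$data)
  ss <- grid$subset
  fg <- NULL
  if (!is.null(foreground)) {
    fg <- if (inherits(foreground, "label_mask")) foreground$data != 0L
          else foreground != 0
  }
  nodes <- grid_nodes_vox(grid)
  n <- nrow(nodes)
  starts <- as.matrix(expand.grid(grid$starts[[1]], grid$starts[[2]],
                                  grid$starts[[3]], KEEP.OUT.ATTRS = FALSE))
  seed_vox <- if (is.null(seed_field)) {
    matrix(0, n, 3)
  } else {
    interp_field(seed_field, nodes) / grid$spacing
  }
  s0 <- round(seed_vox)

  # local seed-field displacement gradient per node (dimensionless, voxel
  # frame), used by the direct-mode affine corrector; clamped to modest
  # strains so a noisy coarse seed cannot destabilise the counter-warp
  Gall <- NULL
  if (mode == "direct" && !is.null(seed_field)) {
    h <- grid$step_vox
    Gall <- array(0, c(n, 3, 3))
    for (j in 1:3) {
      pp <- nodes; pp[, j] <- pp[, j] + h
      pm <- nodes; pm[, j] <- pm[, j] - h
      Gall[, , j] <- (interp_field(seed_field, pp) -
                        interp_field(seed_field, pm)) /
        (2 * h * grid$spacing)
    }
    Gall[Gall > 0.08] <- 0.08
    Gall[Gall < -0.08] <- -0.08
  }

  u <- matrix(NA_real_, n, 3)
  valid <- rep(FALSE, n)
  peak <- rep(NA_real_, n)
  win <- if (mode == "fft") hann3(ss)
  max_shift <- ss %/% 4L

  for (i in seq_len(n)) {
    st <- starts[i, ]
    if (!is.null(fg)) {
      frac <- mean(extract_block(fg, st, ss))
      if (frac < min_valid) next
    }
    a <- extract_block(ref$data, st, ss)
    a0 <- a - mean(a)
    na2 <- sum(a0 * a0)
    if (na2 <= .Machine$double.eps * ss^3) next # flat subset: invalid

    if (mode == "fft") {
      stb <- st + s0[i, ]
      if (any(stb < 1L) || any(stb + ss - 1L > dims)) next
      b <- extract_block(deformed$data, stb, ss)
      b0 <- b - mean(b)
      nb2 <- sum(b0 * b0)
      if (nb2 <= .Machine$double.eps * ss^3) next
      aw <- a0 * win
      bw <- b0 * win
      cc <- Re(stats::fft(Conj(stats::fft(aw)) * stats::fft(bw),
                          inverse = TRUE)) / length(aw)
      qn <- sqrt(sum(aw * aw) * sum(bw * bw))
      # shift for index i along an axis: s = i - 1, wrapped to (-ss/2, ss/2]
      sh <- function(idx) ifelse(idx - 1L > ss %/% 2L, idx - 1L - ss, idx - 1L)
      shifts <- sh(seq_len(ss))
      ok <- abs(shifts) <= max_shift
      cc_ok <- cc[ok, ok, ok]
      pk <- which(cc_ok == max(cc_ok), arr.ind = TRUE)
      sx <- shifts[ok][pk[, 1]]; sy <- shifts[ok][pk[, 2]]
      sz <- shifts[ok][pk[, 3]]
      best <- which.min(sx^2 + sy^2 + sz^2)
      sp <- c(sx[best], sy[best], sz[best])
      q <- max(cc_ok) / qn
      delta <- c(0, 0, 0)
      if (q < 1 - 1e-9) {
        wrap <- function(s) ((s + ss) %% ss) + 1L
        for (ax in 1:3) {
          cm <- cc[wrap(sp[1] - (ax == 1)), wrap(sp[2] - (ax == 2)),
                   wrap(sp[3] - (ax == 3))]
          c0 <- cc[wrap(sp[1]), wrap(sp[2]), wrap(sp[3])]
          cp <- cc[wrap(sp[1] + (ax == 1)), wrap(sp[2] + (ax == 2)),
                   wrap(sp[3] + (ax == 3))]
          delta[ax] <- subvoxel_offset(cm, c0, cp)
        }
      }
      u[i, ] <- (s0[i, ] + sp + delta) * grid$spacing
      valid[i] <- TRUE
      peak[i] <- q
    } else {
      w <- 2L * as.integer(search) + 1L
      na <- sqrt(na2)
      zncc <- function(b) {
        b0 <- b - mean(b)
        nb2 <- sum(b0 * b0)
        if (nb2 <= .Machine$double.eps * ss^3) return(NA_real_)
        sum(a0 * b0) / (na * sqrt(nb2))
      }
      fit_peak <- function(cc, shift0) {
        mx <- max(cc, na.rm = TRUE)
        pk <- which(cc == mx, arr.ind = TRUE)
        off <- pk - (search + 1L)
        tot <- sweep(off, 2, shift0, `+`)
        best <- which.min(rowSums(tot^2))
        sp <- off[best, ]
        delta <- c(0, 0, 0)
        if (mx < 1 - 1e-9) {
          for (ax in 1:3) {
            idm <- sp + (search + 1L) - (1:3 == ax)
            idp <- sp + (search + 1L) + (1:3 == ax)
            cm <- if (all(idm >= 1L & idm <= w)) cc[idm[1], idm[2], idm[3]] else NA
            cp <- if (all(idp >= 1L & idp <= w)) cc[idp[1], idp[2], idp[3]] else NA
            delta[ax] <- subvoxel_offset(cm, mx, cp)
          }
        }
        list(shift = sp + delta, mx = mx)
      }

      # predictor: integer-shift ZNCC search around the rounded seed
      cc <- array(NA_real_, c(w, w, w))
      oob <- FALSE
      for (oz in -search:search) for (oy in -search:search) {
        for (ox in -search:search) {
          stb <- st + s0[i, ] + c(ox, oy, oz)
          if (any(stb < 1L) || any(stb + ss - 1L > dims)) {
            oob <- TRUE
            next
          }
          cc[ox + search + 1L, oy + search + 1L, oz + search + 1L] <-
            zncc(extract_block(deformed$data, stb, ss))
        }
      }
      if (oob || all(is.na(cc))) next # out-of-bounds search: invalid
      res <- fit_peak(cc, s0[i, ])
      disp <- s0[i, ] + res$shift
      if (res$mx < 1 - 1e-9 && !is.null(seed_field)) {
        # corrector: counter-warp the deformed subset by the seed field's
        # local affine motion (fractional shift + gradient), so the
        # residual within-subset motion is near zero where the ZNCC model
        # and the three-point Gaussian fit are unbiased
        fr <- seed_vox[i, ] - s0[i, ]
        Gv <- Gall[i, , ]
        m <- as.integer(search)
        ext <- (1L - m):(ss + m)
        ne <- length(ext)
        ctr <- st + (ss - 1) / 2
        exg <- as.matrix(expand.grid(st[1] - 1L + ext, st[2] - 1L + ext,
                                     st[3] - 1L + ext,
                                     KEEP.OUT.ATTRS = FALSE))
        pts <- exg + rep(s0[i, ] + fr, each = nrow(exg)) +
          sweep(exg, 2, ctr) %*% t(Gv)
        Wv <- cubic_sample(deformed$data, dims, pts)
        if (is.null(Wv)) next # corrector support leaves the volume: invalid
        Wb <- array(Wv, c(ne, ne, ne))
        ccf <- array(NA_real_, c(w, w, w))
        for (oz in -search:search) for (oy in -search:search) {
          for (ox in -search:search) {
            b <- Wb[(m + 1L + ox):(m + ox + ss),
                    (m + 1L + oy):(m + oy + ss),
                    (m + 1L + oz):(m + oz + ss)]
            ccf[ox + search + 1L, oy + search + 1L, oz + search + 1L] <-
              zncc(b)
          }
        }
        if (!all(is.na(ccf))) {
          resf <- fit_peak(ccf, s0[i, ] + fr)
          # keep the counter-warped solution only when it matches better
          if (resf$mx >= res$mx) {
            disp <- s0[i, ] + fr +
              as.numeric((diag(3) + Gv) %*% resf$shift)
            res <- resf
          }
        }
      }
      u[i, ] <- disp * grid$spacing
      valid[i] <- TRUE
      peak[i] <- res$mx
    }
  }
  u[!valid, ] <- 0
  displacement_field(grid, u, valid, peak)
}

#' Coarse-to-fine multipass correlation
#'
#' Runs the predictor-corrector scheme over the subset pyramid: each stage
#' seeds from the (trilinearly interpolated) field of the previous stage,
#' and repeated passes within a stage re-correct using the latest field.
#' All stages except the last use FFT cross-correlation; the final stage
#' uses direct zero-normalised correlation. The returned field is the final
#' finest-stage field.
#'
#' @inheritParams correlate_pass
#' @param schedule a [subset_schedule()].
#' @param keep_stages if `TRUE`, all intermediate stage fields are attached
#'   as the `"stages"` attribute.
#' @return a [displacement_field()] on the finest grid.
#' @export
run_multipass <- function(ref, deformed, schedule = subset_schedule(),
                          foreground = NULL, search = 2L,
                          keep_stages = FALSE) {
  stopifnot(inherits(schedule, "subset_schedule"))
  ns <- length(schedule$sizes)
  field <- NULL
  stages <- list()
  for (s in seq_len(ns)) {
    grid <- build_subset_grid(dim(ref$data), schedule$sizes[s],
                              schedule$overlap, ref$spacing)
    mode <- if (s == ns) "direct" else "fft"
    for (p in seq_len(schedule$passes[s])) {
      field <- correlate_pass(ref, deformed, grid, seed_field = field,
                              mode = mode, search = search,
                              min_valid = schedule$min_valid,
                              foreground = foreground)
    }
    if (keep_stages) stages[[s]] <- field
  }
  if (keep_stages) attr(field, "stages") <- stages
  field
}

#' Serialise a displacement field
#'
#' Writes the three displacement components as a 4D NIfTI volume over the
#' node lattice plus a JSON sidecar describing the grid and validity.
#'
#' @param field a [displacement_field()].
#' @param prefix path prefix; writes `<prefix>.nii.gz` and `<prefix>.json`.
#' @return the two file paths, invisibly.
#' @export
write_displacement_field <- function(field, prefix) {
  arr <- array(field$u, c(field$grid$n_nodes, 3L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(field$grid$step_mm, 3), 1)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    subset = field$grid$subset, overlap = field$grid$overlap,
    spacing_mm = field$grid$spacing, step_vox = field$grid$step_vox,
    step_mm = field$grid$step_mm,
    centres_vox = field$grid$centres, n_nodes = field$grid$n_nodes,
    n_valid = sum(field$valid), valid = field$valid,
    peak = field$peak), side, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, side))
}
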