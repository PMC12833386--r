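test_that("subset grid spacing follows size and overlap", {
  g <- build_subset_grid(c(64, 64, 64), 16, 0.5, 0.58)
  expect_equal(g$step_vox, 8L)
  expect_equal(g$step_mm, 4.64)
  g0 <- build_subset_grid(c(64, 64, 64), 16, 0, 1)
  expect_equal(g0$step_vox, 16L)
  expect_error(build_subset_grid(c(32, 64, 64), 48, 0.5, 1), "sizing error")
})

test_that("node counts match brute-force subset enumeration", {
  count_fits <- function(dim, subset, step) {
    # enumerate all start positions on the step lattice that keep the
    # subset inside the volume
    sum((seq(1, dim, by = step) + subset - 1) <= dim)
  }
  for (dim in c(48, 50, 64, 70)) {
    for (subset in c(16, 24, 32)) {
      for (ov in c(0.5, 0.25)) {
        step <- subset * (1 - ov)
        if (step != round(step)) next
        g <- build_subset_grid(c(dim, 64, 64), subset, ov, 1)
        expect_equal(g$n_nodes[1], count_fits(dim, subset, step),
                     info = sprintf("dim %d subset %d ov %.2f", dim,
                                    subset, ov))
      }
    }
  }
})

# nodes whose search window cannot leave the volume (the border layer is
# flagged invalid by the out-of-bounds rule)
interior_nodes <- function(g) {
  nodes <- as.matrix(expand.grid(g$centres[[1]], g$centres[[2]],
                                 g$centres[[3]]))
  inner <- lapply(g$centres, function(cs) cs[-c(1, length(cs))])
  nodes[, 1] %in% inner[[1]] & nodes[, 2] %in% inner[[2]] &
    nodes[, 3] %in% inner[[3]]
}

test_that("identical volumes correlate to zero displacement", {
  ph <- speckle48()
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f <- correlate_pass(ph$volume, ph$volume, g, mode = "direct")
  expect_true(all(f$valid[interior_nodes(g)]))
  expect_true(all(f$u == 0))
  expect_true(all(f$peak[f$valid] > 1 - 1e-9))
})

test_that("integer-voxel shifts are recovered exactly at valid nodes", {
  ph <- speckle48()
  sp <- deformation_spec(translation = c(3, -2, 1))
  w <- warp_volume(ph$texture, sp, c(48, 48, 48), 1)
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f <- correlate_pass(ph$volume, w$volume, g, mode = "direct", search = 3L)
  expect_gt(sum(f$valid), 0)
  err <- sweep(f$u[f$valid, , drop = FALSE], 2, c(3, -2, 1))
  expect_equal(max(abs(err)), 0)
})

test_that("sub-voxel uniform shifts are recovered within a tenth of a voxel", {
  ph <- speckle48()
  sp <- deformation_spec(translation = c(0.3, 0, 0))
  w <- warp_volume(ph$texture, sp, c(48, 48, 48), 1)
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f <- correlate_pass(ph$volume, w$volume, g, mode = "direct")
  err <- sweep(f$u[f$valid, , drop = FALSE], 2, c(0.3, 0, 0))
  expect_lt(max(abs(err)), 0.1)
})

test_that("flat subsets are flagged invalid rather than erroring", {
  flat <- scalar_volume(array(5, c(48, 48, 48)), 1)
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f <- correlate_pass(flat, flat, g, mode = "direct")
  expect_true(all(!f$valid))
})

test_that("mismatched inputs are rejected", {
  ph <- speckle48()
  other <- scalar_volume(array(0, c(50, 48, 48)), 1)
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  expect_error(correlate_pass(ph$volume, other, g), "input error")
})

test_that("foreground fraction below the minimum invalidates nodes", {
  ph <- speckle48()
  fg <- array(0L, c(48, 48, 48))
  fg[1:24, , ] <- 1L # only the anterior half is foreground
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f <- correlate_pass(ph$volume, ph$volume, g, foreground = fg,
                      min_valid = 0.5)
  nodes <- as.matrix(expand.grid(g$centres[[1]], g$centres[[2]],
                                 g$centres[[3]]))
  expect_true(all(!f$valid[nodes[, 1] > 28]))
  expect_true(all(f$valid[nodes[, 1] < 20 & interior_nodes(g)]))
})

test_that("multipass recovers rigid shifts uniformly", {
  ph <- speckle48()
  sp <- deformation_spec(translation = c(2, 0, 0))
  w <- warp_volume(ph$texture, sp, c(48, 48, 48), 1)
  sched <- subset_schedule(c(32, 16), c(1, 2))
  f <- run_multipass(ph$volume, w$volume, sched)
  err <- sweep(f$u[f$valid, , drop = FALSE], 2, c(2, 0, 0))
  expect_lt(max(abs(err)), 0.05)
})

test_that("multipass tracks smooth affine warps to sub-voxel accuracy", {
  ph <- speckle48()
  sp <- deformation_spec(affine = matrix(c(0.02, 0.005, 0,
                                           0, -0.015, 0,
                                           0, 0, 0.01), 3, 3, byrow = TRUE))
  w <- warp_volume(ph$texture, sp, c(48, 48, 48), 1)
  sched <- subset_schedule(c(32, 16), c(1, 2))
  f <- run_multipass(ph$volume, w$volume, sched)
  ut <- w$truth$u(field_nodes_mm(f))
  err <- (f$u - ut)[f$valid, , drop = FALSE]
  expect_gt(sum(f$valid), 20)
  expect_lt(sqrt(mean(err^2)), 0.15)
})

test_that("a single-stage schedule equals one unseeded direct pass", {
  ph <- speckle48()
  sp <- deformation_spec(translation = c(0.9, -0.4, 0))
  w <- warp_volume(ph$texture, sp, c(48, 48, 48), 1)
  sched <- subset_schedule(sizes = 16L, passes = 1L)
  f1 <- run_multipass(ph$volume, w$volume, sched)
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f2 <- correlate_pass(ph$volume, w$volume, g, mode = "direct")
  expect_equal(f1$u, f2$u)
  expect_equal(f1$valid, f2$valid)
})

test_that("swapping reference and deformed negates the field", {
  ph <- speckle48()
  sp <- deformation_spec(translation = c(0.6, 0.3, -0.2))
  w <- warp_volume(ph$texture, sp, c(48, 48, 48), 1)
  sched <- subset_schedule(c(32, 16), c(1, 2))
  fwd <- run_multipass(ph$volume, w$volume, sched)
  bwd <- run_multipass(w$volume, ph$volume, sched)
  both <- fwd$valid & bwd$valid
  expect_gt(sum(both), 20)
  expect_lt(max(abs(fwd$u[both, ] + bwd$u[both, ])), 0.12)
})

test_that("displacement fields survive a NIfTI + JSON round trip", {
  ph <- speckle48()
  g <- build_subset_grid(c(48, 48, 48), 16, 0.5, 1)
  f <- correlate_pass(ph$volume, ph$volume, g)
  paths <- write_displacement_field(f, file.path(tempdir(), "dfield"))
  expect_true(all(file.exists(paths)))
  arr <- RNifti::readNifti(paths[1])
  expect_equal(dim(arr), c(g$n_nodes, 3L))
  side <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(side$subset, 16L)
  expect_equal(side$n_valid, sum(f$valid))
})
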