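grid8 <- function(spacing = 1) build_subset_grid(c(48, 48, 48), 16, 0.5,
                                                 spacing)

test_that("constant and linear fields differentiate exactly", {
  fc <- analytic_field(grid8(), function(x) cbind(rep(2, nrow(x)), -1, 0))
  gc_ <- displacement_gradient(fc)
  expect_lt(max(abs(gc_$G)), 1e-12)

  A <- diag(c(0.01, 0.02, -0.03))
  fl <- analytic_field(grid8(), function(x) x %*% t(A))
  gl <- displacement_gradient(fl)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(gl$G[, i, j], rep(A[i, j], dim(gl$G)[1]),
                 tolerance = 1e-10)
  }
})

test_that("gradient error of smooth fields shrinks quadratically with node spacing", {
  quadratic_u <- function(x) cbind(1e-3 * x[, 1]^3 / 50, 0, 0)
  err_at <- function(subset) {
    g <- build_subset_grid(c(48, 48, 48), subset, 0.5, 1)
    f <- analytic_field(g, quadratic_u)
    gr <- displacement_gradient(f)
    nodes <- field_nodes_mm(f)
    truth <- 3e-3 * nodes[, 1]^2 / 50
    # interior nodes only (central differences)
    nx <- g$n_nodes
    idx <- array(seq_len(prod(nx)), nx)
    interior <- as.vector(idx[2:(nx[1] - 1), 2:(nx[2] - 1), 2:(nx[3] - 1)])
    max(abs(gr$G[interior, 1, 1] - truth[interior]))
  }
  e16 <- err_at(16) # node spacing 8
  e8 <- err_at(8)   # node spacing 4
  expect_equal(e16 / e8, 4, tolerance = 0.3)
})

test_that("Green-Lagrange tensor matches closed forms", {
  expect_equal(green_lagrange(matrix(0, 3, 3)), matrix(0, 3, 3))
  E <- green_lagrange(diag(c(0.1, 0, 0)))
  expect_equal(E[1, 1], 0.105, tolerance = 1e-12)
  expect_equal(E[2, 2], 0)
  R <- rotation_matrix(c(0, 1, 0), 5)
  expect_lt(max(abs(green_lagrange(R - diag(3)))), 1e-12)
})

test_that("principal strains and maximum shear follow the eigenstructure", {
  pr <- principal_invariants(diag(c(0.02, 0.01, -0.03)))
  expect_equal(pr$eps, c(0.02, 0.01, -0.03))
  expect_equal(pr$gamma_max, 0.025)
  iso <- principal_invariants(0.01 * diag(3))
  expect_equal(iso$eps, rep(0.01, 3))
  expect_equal(iso$gamma_max, 0)
  expect_error(principal_invariants(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0),
                                           3, 3)),
               "input error")
})

test_that("eigenvalues match a characteristic-polynomial root oracle", {
  set.seed(31)
  for (rep in 1:25) {
    S <- matrix(rnorm(9, sd = 0.05), 3, 3)
    E <- (S + t(S)) / 2
    pr <- principal_invariants(E)
    # oracle: roots of det(E - x I) from the cubic's coefficients
    i1 <- sum(diag(E))
    i2 <- (i1^2 - sum(diag(E %*% E))) / 2
    i3 <- det(E)
    roots <- sort(Re(polyroot(c(-i3, i2, -i1, 1))), decreasing = TRUE)
    expect_equal(pr$eps, roots, tolerance = 1e-8)
    expect_gte(pr$gamma_max, 0)
  }
})

test_that("strain invariants are unchanged by a rotated frame", {
  set.seed(7)
  sp <- deformation_spec(affine = matrix(rnorm(9, sd = 0.01), 3, 3),
                         centre = c(24, 24, 24))
  f <- analytic_field(grid8(), function(x) deformation_displacement(sp, x))
  st <- green_lagrange(displacement_gradient(f))
  R <- rotation_matrix(c(1, 0.5, 0.2), 30)
  # left-composing any rotation onto the motion (F -> R F, i.e.
  # G -> R(I + G) - I) must leave E and its eigenvalues unchanged
  for (i in sample(which(st$valid), 10)) {
    G <- matrix(displacement_gradient(f)$G[i, , ], 3, 3)
    Grot <- R %*% (diag(3) + G) - diag(3)
    Erot <- green_lagrange(Grot)
    expect_equal(principal_invariants(Erot)$eps,
                 st$principal[i, ], tolerance = 1e-9)
  }
})

test_that("level summaries report signed peaks and unweighted means", {
  ph <- spine_small()
  # uniform analytic strain: mean equals peak
  sp_u <- deformation_spec(affine = diag(c(0.02, -0.01, 0)),
                           centre = dim(ph$volume) * 1.5 / 2)
  g <- build_subset_grid(dim(ph$volume), 16, 0.5, 1.5)
  f <- analytic_field(g, function(x) deformation_displacement(sp_u, x))
  st <- green_lagrange(displacement_gradient(f))
  s <- summarize_level(st, ph$mask, ph$truth$disc$level[1])
  expect_true(s$resolved)
  expect_equal(s$mean_eps1, s$peak_eps1, tolerance = 1e-6)
  expect_equal(s$mean_eps1, 100 * (1.02^2 - 1) / 2, tolerance = 1e-6)
  expect_gte(abs(s$peak_eps3), abs(s$mean_eps3))
})

test_that("the peak is the signed value of highest magnitude", {
  ph <- spine_small()
  g <- build_subset_grid(dim(ph$volume), 16, 0.5, 1.5)
  f <- analytic_field(g, function(x) matrix(0, nrow(x), 3))
  st <- green_lagrange(displacement_gradient(f))
  # plant eps3 values on the first three qualifying nodes
  lv <- ph$truth$disc$level[1]
  code <- ph$mask$labels[[lv]]
  nodes <- round(as.matrix(expand.grid(g$centres[[1]], g$centres[[2]],
                                       g$centres[[3]])))
  sel <- which(ph$mask$data[nodes] == code)[1:3]
  st$principal[, 3] <- 0
  st$principal[sel, 3] <- c(-0.05, 0.02, -0.01)
  st$principal[, 1] <- abs(st$principal[, 3])
  st$gamma_max <- (st$principal[, 1] - st$principal[, 3]) / 2
  s <- summarize_level(st, ph$mask, lv)
  expect_equal(s$peak_eps3, -5) # percent, signed
})

test_that("nonuniform analytic strain means match a dense integration oracle", {
  ph <- spine_small()
  dims <- dim(ph$volume)
  poly <- matrix(0, 3, 6)
  poly[1, 1] <- 2e-4  # u_x gains a quadratic-in-x term
  poly[2, 2] <- -1e-4
  sp <- deformation_spec(poly = poly, centre = dims * 1.5 / 2)
  g <- build_subset_grid(dims, 16, 0.5, 1.5)
  f <- analytic_field(g, function(x) deformation_displacement(sp, x))
  st <- green_lagrange(displacement_gradient(f))
  lv <- ph$truth$disc$level[2]
  s <- summarize_level(st, ph$mask, lv)
  # oracle: analytic E averaged over every voxel centre in the disc mask
  vox <- which(ph$mask$data == ph$mask$labels[[lv]], arr.ind = TRUE)
  Ev <- deformation_strain(sp, (vox - 0.5) * 1.5)
  oracle_e1 <- 100 * mean(apply(Ev, 1, function(m) {
    max(eigen(matrix(m, 3, 3), symmetric = TRUE, only.values = TRUE)$values)
  }))
  expect_equal(s$mean_eps1, oracle_e1, tolerance = 0.05) # 5% relative
})

test_that("levels without valid nodes are flagged unresolvable", {
  ph <- spine_small()
  g <- build_subset_grid(dim(ph$volume), 16, 0.5, 1.5)
  f <- analytic_field(g, function(x) matrix(0, nrow(x), 3))
  f$valid[] <- FALSE
  f$u[] <- 0
  st_g <- displacement_gradient(f)
  expect_true(all(!st_g$valid))
  st <- green_lagrange(st_g)
  s <- summarize_level(st, ph$mask, ph$truth$disc$level[1])
  expect_false(s$resolved)
})
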