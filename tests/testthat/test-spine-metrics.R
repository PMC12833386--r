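# landmark set for a single disc between two vertebrae with endplate tilts
# given in degrees (posterior-up positive), constructed from first
# principles as an independent geometry oracle
two_vertebra_landmarks <- function(tilt_sup_deg, tilt_inf_deg, gap_centre,
                                   depth = 30) {
  e <- function(t) c(cos(t), sin(t))
  nup <- function(t) c(-sin(t), cos(t))
  tu <- tilt_sup_deg * pi / 180
  tl <- tilt_inf_deg * pi / 180
  mu <- (tu + tl) / 2
  lower_c <- c(50, 50)
  upper_c <- lower_c + gap_centre * nup(mu)
  pts <- rbind(
    data.frame(vertebra = "A", endplate = "sup", rim = "ant",
               x = (upper_c + 12 * nup(tu) - depth / 2 * e(tu))[1],
               y = (upper_c + 12 * nup(tu) - depth / 2 * e(tu))[2]),
    data.frame(vertebra = "A", endplate = "sup", rim = "post",
               x = (upper_c + 12 * nup(tu) + depth / 2 * e(tu))[1],
               y = (upper_c + 12 * nup(tu) + depth / 2 * e(tu))[2]),
    data.frame(vertebra = "A", endplate = "inf", rim = "ant",
               x = (upper_c - depth / 2 * e(tu))[1],
               y = (upper_c - depth / 2 * e(tu))[2]),
    data.frame(vertebra = "A", endplate = "inf", rim = "post",
               x = (upper_c + depth / 2 * e(tu))[1],
               y = (upper_c + depth / 2 * e(tu))[2]),
    data.frame(vertebra = "B", endplate = "sup", rim = "ant",
               x = (lower_c - depth / 2 * e(tl))[1],
               y = (lower_c - depth / 2 * e(tl))[2]),
    data.frame(vertebra = "B", endplate = "sup", rim = "post",
               x = (lower_c + depth / 2 * e(tl))[1],
               y = (lower_c + depth / 2 * e(tl))[2]),
    data.frame(vertebra = "B", endplate = "inf", rim = "ant",
               x = (lower_c - 12 * nup(tl) - depth / 2 * e(tl))[1],
               y = (lower_c - 12 * nup(tl) - depth / 2 * e(tl))[2]),
    data.frame(vertebra = "B", endplate = "inf", rim = "post",
               x = (lower_c - 12 * nup(tl) + depth / 2 * e(tl))[1],
               y = (lower_c - 12 * nup(tl) + depth / 2 * e(tl))[2]))
  landmark_set(pts, vertebrae = c("A", "B"))
}

test_that("parallel endplates give equal heights and unit ratio", {
  lm <- two_vertebra_landmarks(0, 0, 10)
  h <- disc_heights(lm, "A-B")
  expect_equal(c(h$anterior, h$central, h$posterior), rep(10, 3),
               tolerance = 1e-12)
  expect_equal(h$ratio, 1)
  expect_equal(segmental_lordosis(lm, "A-B"), 0, tolerance = 1e-12)
})

test_that("wedged discs match the trigonometric closed form", {
  # 6 degree opening split over the two faces, depth 30
  lm <- two_vertebra_landmarks(-3, 3, 10, depth = 30)
  h <- disc_heights(lm, "A-B")
  expect_equal(segmental_lordosis(lm, "A-B"), 6, tolerance = 1e-9)
  # gap(s) = g0 - 2 s sin(wedge/2): at the rims s = -/+ depth/2
  expect_equal(h$anterior, 10 + 30 * sin(3 * pi / 180), tolerance = 0.05)
  expect_equal(h$posterior, 10 - 30 * sin(3 * pi / 180), tolerance = 0.05)
  # anterior 12 / posterior 8 wedge: ratio 1.5
  geo <- spine_geometry(levels = 1, disc_anterior = 12, disc_posterior = 8)
  ph <- make_spine_phantom(geo, spacing = 2, seed = 2, blob_density = 0.002)
  expect_equal(disc_heights(ph$landmarks, ph$truth$disc$level[1])$ratio,
               1.5, tolerance = 1e-9)
})

test_that("lines at +/-5 degrees converging posteriorly give 10 degrees of lordosis", {
  lm <- two_vertebra_landmarks(-5, 5, 10)
  expect_equal(segmental_lordosis(lm, "A-B"), 10, tolerance = 1e-9)
  # kyphotic arrangement flips the sign
  lmk <- two_vertebra_landmarks(5, -5, 10)
  expect_equal(segmental_lordosis(lmk, "A-B"), -10, tolerance = 1e-9)
})

test_that("segmental angles sum to the lumbar lordosis on phantoms", {
  geo <- spine_geometry(levels = 4, wedge = c(3, 5, 8, 12),
                        disc_central = 9)
  ph <- make_spine_phantom(geo, spacing = 2, seed = 4, blob_density = 0.002)
  lm <- ph$landmarks
  segs <- vapply(ph$truth$disc$level, function(lv) {
    segmental_lordosis(lm, lv)
  }, numeric(1))
  gm <- global_metrics(lm)
  expect_equal(sum(segs), gm$lumbar_lordosis, tolerance = 1e-6)
  expect_equal(gm$lumbar_lordosis, 28, tolerance = 1e-6)
})

test_that("global metrics follow their constructions", {
  lm <- two_vertebra_landmarks(0, 0, 10)
  gm <- global_metrics(lm)
  expect_equal(gm$lumbar_lordosis, 0, tolerance = 1e-12)
  expect_equal(gm$sacral_angle, 0, tolerance = 1e-12)
  a_top <- landmark_point(lm, "A", "sup", "ant")
  a_bot <- landmark_point(lm, "B", "sup", "ant")
  expect_equal(gm$lumbar_height, sqrt(sum((a_top - a_bot)^2)))

  geo <- spine_geometry(levels = 2, sacral_angle = 40)
  ph <- make_spine_phantom(geo, spacing = 2, seed = 9, blob_density = 0.002)
  expect_equal(global_metrics(ph$landmarks)$sacral_angle, 40,
               tolerance = 0.1)
})

test_that("angles are invariant under co-rotation and track a fixed horizontal", {
  geo <- spine_geometry(levels = 2, sacral_angle = 30)
  ph <- make_spine_phantom(geo, spacing = 2, seed = 8, blob_density = 0.002)
  lm <- ph$landmarks
  th <- 12 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- lm$points
  xy <- as.matrix(pts[, c("x", "y")]) %*% t(R)
  pts$x <- xy[, 1]; pts$y <- xy[, 2]
  co <- landmark_set(pts, lm$vertebrae,
                     horizontal = as.numeric(R %*% c(1, 0)))
  fixed <- landmark_set(pts, lm$vertebrae, horizontal = c(1, 0))
  for (lv in ph$truth$disc$level) {
    expect_equal(segmental_lordosis(co, lv), segmental_lordosis(lm, lv),
                 tolerance = 1e-9)
    expect_equal(disc_heights(co, lv)$ratio, disc_heights(lm, lv)$ratio,
                 tolerance = 1e-9)
  }
  expect_equal(global_metrics(co)$sacral_angle,
               global_metrics(lm)$sacral_angle, tolerance = 1e-9)
  # without co-rotating the horizontal, the sacral angle shifts by exactly
  # the applied rotation
  expect_equal(global_metrics(fixed)$sacral_angle,
               global_metrics(lm)$sacral_angle + 12, tolerance = 1e-9)
})

test_that("missing and degenerate landmarks raise named errors", {
  lm <- two_vertebra_landmarks(0, 0, 10)
  lm$points <- lm$points[!(lm$points$vertebra == "B" &
                             lm$points$endplate == "sup" &
                             lm$points$rim == "ant"), ]
  expect_error(disc_heights(lm, "A-B"), "missing landmark: B sup ant")
  lm2 <- two_vertebra_landmarks(0, 0, 10)
  expect_error(disc_heights(lm2, "B-A"), "geometry error|missing")
})

test_that("Pfirrmann consensus rounds and bins as specified", {
  expect_equal(pfirrmann_consensus(c(2, 2, 2)),
               list(grade = 2L, bin = "ND"))
  expect_equal(pfirrmann_consensus(c(2, 3, 3)),
               list(grade = 3L, bin = "D"))
  expect_equal(pfirrmann_consensus(c(3, 4, 4)),
               list(grade = 4L, bin = "SD"))
  expect_equal(pfirrmann_consensus(c(2, 2, 3))$grade, 2L)
  # hypothetical even-rater half rounds away from zero
  expect_equal(pfirrmann_consensus(c(2, 3))$grade, 3L)
  expect_error(pfirrmann_consensus(c(0, 3, 3)), "input error")
  expect_error(pfirrmann_consensus(c(2, 3.5, 3)), "input error")
})

test_that("landmark sets survive a JSON round trip", {
  ph <- spine_small()
  path <- tempfile(fileext = ".json")
  write_landmarks(ph$landmarks, path)
  back <- read_landmarks(path)
  expect_equal(back$points$x, ph$landmarks$points$x)
  expect_equal(back$vertebrae, ph$landmarks$vertebrae)
  for (lv in ph$truth$disc$level) {
    expect_equal(disc_heights(back, lv), disc_heights(ph$landmarks, lv))
  }
})
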