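# Landmark-based clinical measures: disc heights and A:P ratio, Cobb
# segmental lordosis, lumbar lordosis / height / sacral angle, and the
# Pfirrmann consensus arithmetic.

# signed tilt (radians) of the endplate line from the horizontal reference,
# positive when the posterior rim is more cranial
endplate_tilt <- function(lm, vertebra, endplate) {
  a <- landmark_point(lm, vertebra, endplate, "ant")
  p <- landmark_point(lm, vertebra, endplate, "post")
  d <- p - a
  if (sqrt(sum(d^2)) < 1e-9) {
    stop_input("geometry error: coincident rim points on %s %s", vertebra,
               endplate)
  }
  h <- lm$horizontal
  atan2(h[1] * d[2] - h[2] * d[1], h[1] * d[1] + h[2] * d[2])
}

split_level <- function(level) {
  parts <- strsplit(level, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop_input("disc level must look like 'L4-L5', got '%s'", level)
  }
  parts
}

#' Disc heights and anterior-posterior height ratio
#'
#' Heights are measured between the inferior endplate of the superior
#' vertebra and the superior endplate of the inferior vertebra, orthogonal
#' to the mid-disc plane (the angle bisector of the two endplate lines), at
#' the anterior rims, the endplate midpoints, and the posterior rims. The
#' A:P ratio is the anterior height divided by the posterior height.
#'
#' @param lm a [landmark_set()].
#' @param level disc label, e.g. `"L4-L5"` (superior-inferior).
#' @return named list: `anterior`, `central`, `posterior` (mm), `ratio`.
#' @export
disc_heights <- function(lm, level) {
  v <- split_level(level)
  ua <- landmark_point(lm, v[1], "inf", "ant")
  up <- landmark_point(lm, v[1], "inf", "post")
  la <- landmark_point(lm, v[2], "sup", "ant")
  lp <- landmark_point(lm, v[2], "sup", "post")
  tu <- endplate_tilt(lm, v[1], "inf")
  tl <- endplate_tilt(lm, v[2], "sup")
  mu <- (tu + tl) / 2
  nrm <- c(-sin(mu), cos(mu)) # up-normal of the mid-disc plane
  gap <- function(upper, lower) sum((upper - lower) * nrm)
  a <- gap(ua, la)
  p <- gap(up, lp)
  ctr <- gap((ua + up) / 2, (la + lp) / 2)
  if (p <= 0 || a <= 0 || ctr <= 0) {
    stop_input("geometry error: non-positive disc height at %s", level)
  }
  list(anterior = a, central = ctr, posterior = p, ratio = a / p)
}

#' Segmental lordosis by the Cobb method
#'
#' Angle between a line parallel to the superior endplate of the superior
#' vertebral body and a line parallel to the inferior endplate of the
#' inferior vertebral body; positive for lordotic segments (endplate lines
#' converging posteriorly), negative for kyphotic ones. For concave
#' endplates the landmark line already joins the anterior and posterior rim
#' extremities.
#'
#' @inheritParams disc_heights
#' @return signed angle in degrees.
#' @export
segmental_lordosis <- function(lm, level) {
  v <- split_level(level)
  t_top <- endplate_tilt(lm, v[1], "sup")
  t_bot <- endplate_tilt(lm, v[2], "inf")
  (t_bot - t_top) * 180 / pi
}

#' Global sagittal alignment measures
#'
#' Lumbar lordosis (angle between the superior endplates of the most
#' cranial and most caudal vertebrae of the set, positive = lordotic),
#' lumbar height (distance from the most anterior point of the superior
#' endplate of the most cranial vertebra to the anterior superior endplate
#' of the most caudal one), and the sacral angle (tilt of the most caudal
#' superior endplate relative to the horizontal reference).
#'
#' @param lm a [landmark_set()] whose `vertebrae` are ordered cranial to
#'   caudal.
#' @return named list: `lumbar_lordosis` (deg), `lumbar_height` (mm),
#'   `sacral_angle` (deg).
#' @export
global_metrics <- function(lm) {
  top <- lm$vertebrae[1]
  bot <- lm$vertebrae[length(lm$vertebrae)]
  t_top <- endplate_tilt(lm, top, "sup")
  t_bot <- endplate_tilt(lm, bot, "sup")
  a_top <- landmark_point(lm, top, "sup", "ant")
  a_bot <- landmark_point(lm, bot, "sup", "ant")
  list(lumbar_lordosis = (t_bot - t_top) * 180 / pi,
       lumbar_height = sqrt(sum((a_top - a_bot)^2)),
       sacral_angle = t_bot * 180 / pi)
}

#' Pfirrmann consensus grade and degeneration bin
#'
#' The consensus grade is the rounded average of the individual ratings
#' (halves round away from zero, so a hypothetical mean of 2.5 gives 3);
#' grades 1-2 are binned "ND" (non-degenerated), grade 3 "D" (degenerated),
#' grades 4-5 "SD" (severely degenerated).
#'
#' @param grades integer ratings in 1..5 (typically three raters).
#' @return named list: `grade` (1-5) and `bin` (`"ND"`, `"D"` or `"SD"`).
#' @examples
#' pfirrmann_consensus(c(2, 3, 3)) # grade 3, D
#' @export
pfirrmann_consensus <- function(grades) {
  if (length(grades) < 1L || any(!is.finite(grades)) ||
      any(grades != round(grades)) || any(grades < 1) || any(grades > 5)) {
    stop_input("input error: grades must be integers in 1..5")
  }
  g <- floor(mean(grades) + 0.5) # half away from zero for positive means
  bin <- if (g <= 2) "ND" else if (g == 3) "D" else "SD"
  list(grade = as.integer(g), bin = bin)
}

#' All clinical metrics of a landmark set
#'
#' Per-level disc heights, A:P ratio, average disc height (mean of the
#' anterior, central and posterior heights) and segmental lordosis, plus
#' the global alignment measures, in one table.
#'
#' @param lm a [landmark_set()].
#' @param levels disc labels; default: consecutive pairs of the set's
#'   vertebrae.
#' @return list with `levels` (data.frame) and `global` (named list).
#' @export
spine_metrics <- function(lm, levels = NULL) {
  vs <- lm$vertebrae
  levels <- levels %||% paste(vs[-length(vs)], vs[-1], sep = "-")
  rows <- lapply(levels, function(lv) {
    h <- disc_heights(lm, lv)
    data.frame(level = lv, anterior = h$anterior, central = h$central,
               posterior = h$posterior, ratio = h$ratio,
               avg_height = (h$anterior + h$central + h$posterior) / 3,
               segmental_lordosis = segmental_lordosis(lm, lv))
  })
  list(levels = do.call(rbind, rows), global = global_metrics(lm))
}
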