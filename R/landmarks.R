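#' Mid-sagittal landmark set
#'
#' Named endplate-rim points in the mid-sagittal plane, the interface on
#' which all clinical geometry measures operate. Coordinates are 2D sagittal
#' mm: `x` anterior-posterior (positive = posterior), `y` cranial-caudal
#' (positive = cranial). Each vertebra contributes four rim points
#' (superior/inferior endplate x anterior/posterior rim). The horizontal
#' reference direction (default `(1, 0)`) anchors the sacral angle.
#'
#' @param points data.frame with columns `vertebra`, `endplate`
#'   (`"sup"`/`"inf"`), `rim` (`"ant"`/`"post"`), `x`, `y`.
#' @param vertebrae character vector of vertebra names ordered cranial to
#'   caudal (e.g. `c("L1", ..., "S1")`).
#' @param horizontal length-2 unit vector giving the horizontal reference.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, vertebrae, horizontal = c(1, 0)) {
  need <- c("vertebra", "endplate", "rim", "x", "y")
  if (!all(need %in% names(points))) {
    stop_input("`points` must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    stop_input("all landmark coordinates must be finite")
  }
  horizontal <- horizontal / sqrt(sum(horizontal^2))
  # invariant: anterior rim anterior to (smaller x than) posterior rim
  for (v in vertebrae) for (ep in c("sup", "inf")) {
    a <- points[points$vertebra == v & points$endplate == ep, ]
    if (nrow(a) == 2L) {
      xa <- a$x[a$rim == "ant"]; xp <- a$x[a$rim == "post"]
      if (length(xa) == 1L && length(xp) == 1L && xa >= xp) {
        stop_input("landmark invariant violated: %s %s anterior rim not anterior to posterior rim", v, ep)
      }
    }
  }
  structure(list(points = points, vertebrae = vertebrae,
                 horizontal = horizontal),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points over %d vertebrae (%s)\n",
              nrow(x$points), length(x$vertebrae),
              paste(x$vertebrae, collapse = ", ")))
  invisible(x)
}

# fetch one landmark as c(x, y); error names the missing point
landmark_point <- function(lm, vertebra, endplate, rim) {
  p <- lm$points
  row <- p[p$vertebra == vertebra & p$endplate == endplate & p$rim == rim, ]
  if (nrow(row) != 1L) {
    stop_input("missing landmark: %s %s %s", vertebra, endplate, rim)
  }
  c(row$x, row$y)
}

#' Landmark JSON serialisation
#'
#' @param lm a [landmark_set()].
#' @param path JSON file path.
#' @return `write_landmarks()` returns `path` invisibly; `read_landmarks()`
#'   returns a [landmark_set()].
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(
    list(vertebrae = lm$vertebrae, horizontal = lm$horizontal,
         points = lm$points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(as.data.frame(obj$points), vertebrae = obj$vertebrae,
               horizontal = obj$horizontal)
}
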