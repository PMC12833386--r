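#' Expand cohort predictors into a numeric design
#'
#' Gender and degeneration category enter regression models as indicator
#' variables (reference categories: female, and non-degenerated). Constant
#' columns (e.g. a degeneration bin absent at a level) are dropped and
#' reported.
#'
#' @param table cohort data.frame.
#' @param predictors character vector of predictor column names; `"gender"`
#'   expands to `gender_male`, `"degeneration"` expands to `deg_D` and
#'   `deg_SD`.
#' @return list with `design` (numeric data.frame) and `dropped`
#'   (character vector of constant columns removed).
#' @export
expand_predictors <- function(table, predictors) {
  cols <- list()
  for (p in predictors) {
    if (p == "gender") {
      cols$gender_male <- as.numeric(table$gender == "M")
    } else if (p == "degeneration") {
      cols$deg_D <- as.numeric(table$degeneration == "D")
      cols$deg_SD <- as.numeric(table$degeneration == "SD")
    } else if (p == "gender_male" && !"gender_male" %in% names(table)) {
      cols$gender_male <- as.numeric(table$gender == "M")
    } else if (p == "deg_D" && !"deg_D" %in% names(table)) {
      cols$deg_D <- as.numeric(table$degeneration == "D")
    } else if (p == "deg_SD" && !"deg_SD" %in% names(table)) {
      cols$deg_SD <- as.numeric(table$degeneration == "SD")
    } else {
      if (!p %in% names(table)) stop_input("predictor '%s' not in table", p)
      if (!is.numeric(table[[p]])) {
        stop_input("predictor '%s' is not numeric; only gender/degeneration are expanded", p)
      }
      cols[[p]] <- table[[p]]
    }
  }
  design <- as.data.frame(cols)
  const <- vapply(design, function(x) stats::sd(x) == 0, logical(1))
  list(design = design[, !const, drop = FALSE],
       dropped = names(design)[const])
}

#' The canonical predictor vocabulary of the regression layer
#' @return character vector of predictor names accepted by
#'   [expand_predictors()].
#' @export
cohort_predictors <- function() {
  c("age", "gender", "bmi", "avg_disc_height", "ap_ratio", "degeneration",
    "segmental_lordosis", "lumbar_height", "sacral_angle")
}

#' Generate a synthetic participant cohort
#'
#' Draws participant-level clinical predictors with marginals spanning the
#' plausible adult ranges (age 23-67, BMI around 24, A:P disc height ratio
#' 1-2, Pfirrmann grades 1-5 binned ND/D/SD, segmental lordosis a few
#' degrees, sacral angle around 38 degrees) and produces the outcome from a
#' known linear model plus Gaussian noise, so regression-recovery behaviour
#' can be tested against the generating coefficients.
#'
#' @param n number of participants (rows); must exceed the number of
#'   non-zero generating coefficients by at least 2.
#' @param true_betas named numeric vector of generating coefficients over
#'   design columns (see [expand_predictors()] for the expanded names,
#'   e.g. `gender_male`, `deg_D`, `deg_SD`).
#' @param noise_sd standard deviation of the Gaussian outcome noise
#'   (outcome units, >= 0).
#' @param seed RNG seed.
#' @param intercept outcome intercept.
#' @param level disc level tag attached to every row.
#' @return list with `table` (data.frame incl. `outcome`) and `truth`
#'   (generating betas, intercept, noise level).
#' @export
make_synthetic_cohort <- function(n, true_betas, noise_sd, seed,
                                  intercept = 0, level = "L4-L5") {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_input("parameter error: `noise_sd` must be >= 0")
  }
  if (n < length(true_betas) + 2) {
    stop_input("`n` must be at least length(true_betas) + 2")
  }
  tab <- with_seed(seed, {
    grade <- sample(1:5, n, replace = TRUE,
                    prob = c(0.20, 0.35, 0.25, 0.15, 0.05))
    data.frame(
      participant = seq_len(n),
      level = level,
      age = round(stats::runif(n, 23, 67)),
      gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
      bmi = round(stats::rnorm(n, 23.8, 2.6), 1),
      avg_disc_height = round(stats::rnorm(n, 9.6, 1.2), 2),
      ap_ratio = round(stats::runif(n, 1.0, 2.0), 2),
      pfirrmann = grade,
      degeneration = c("ND", "ND", "D", "SD", "SD")[grade],
      segmental_lordosis = round(stats::rnorm(n, 8, 3), 1),
      lumbar_height = round(stats::rnorm(n, 185, 12), 1),
      sacral_angle = round(stats::rnorm(n, 38, 6), 1))
  })
  ex <- expand_predictors(tab, cohort_predictors())
  betas <- stats::setNames(numeric(ncol(ex$design)), names(ex$design))
  if (length(true_betas)) {
    if (is.null(names(true_betas)) ||
        !all(names(true_betas) %in% c(names(ex$design), ex$dropped))) {
      stop_input("names of `true_betas` must be design columns (%s)",
                 paste(names(ex$design), collapse = ", "))
    }
    keep <- intersect(names(true_betas), names(ex$design))
    betas[keep] <- true_betas[keep]
  }
  lin <- intercept + as.matrix(ex$design) %*% betas
  noise <- with_seed(seed + 1L, stats::rnorm(n, 0, noise_sd))
  tab$outcome <- as.numeric(lin) + noise
  list(table = tab,
       truth = list(betas = betas, intercept = intercept,
                    noise_sd = noise_sd))
}
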