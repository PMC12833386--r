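# Statistics layer: VIF collinearity screen, backward multivariate linear
# regression, residual diagnostics, Hommel family-wise correction, and the
# inter-rater ICC.

# variance inflation factor of each column of a numeric design
vif_values <- function(design) {
  vapply(seq_along(design), function(j) {
    r2 <- summary(stats::lm(design[[j]] ~ .,
                            data = design[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor collinearity screen
#'
#' Iteratively removes the predictor with the largest VIF while any VIF is
#' at or above the threshold (VIF below 10 is considered acceptable).
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing predictor `j`
#' on the remaining predictors; exactly collinear predictors are removed
#' with an infinite-VIF ledger entry. Ties on the maximal VIF are broken by
#' removing the later predictor in the list.
#'
#' @param table cohort data.frame.
#' @param predictors predictor names (see [expand_predictors()]).
#' @param threshold removal threshold (default 10).
#' @return list with `retained` (character vector of design columns) and
#'   `ledger` (data.frame of removed columns with their VIF and reason).
#' @export
vif_screen <- function(table, predictors, threshold = 10) {
  ex <- expand_predictors(table, predictors)
  design <- ex$design
  if (ncol(design) < 2L) stop_input("need at least 2 predictors to screen")
  if (nrow(design) <= ncol(design)) {
    stop_input("need more rows than predictors")
  }
  ledger <- data.frame(predictor = character(), vif = numeric(),
                       reason = character())
  if (length(ex$dropped)) {
    ledger <- rbind(ledger, data.frame(predictor = ex$dropped, vif = NA,
                                       reason = "constant column"))
  }
  repeat {
    if (ncol(design) < 2L) break
    v <- vif_values(design)
    if (max(v) < threshold) break
    worst <- max(which(v == max(v))) # tie: drop the later column
    ledger <- rbind(ledger, data.frame(
      predictor = names(design)[worst], vif = v[worst],
      reason = if (is.infinite(v[worst])) "infinite VIF (exact collinearity)"
               else sprintf("VIF %.3g >= %.3g", v[worst], threshold)))
    design <- design[, -worst, drop = FALSE]
  }
  list(retained = names(design), ledger = ledger)
}

#' Backward multivariate linear regression
#'
#' Fits an ordinary-least-squares model of the outcome on all predictors,
#' then repeatedly drops the predictor with the largest partial p-value at
#' or above `p_out` and refits, stopping when every retained predictor has
#' p below `p_out`. Aliased predictors (exactly collinear with earlier
#' ones) are removed up front. If nothing survives, the intercept-only
#' model is reported and flagged.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column name.
#' @param predictors predictor names (see [expand_predictors()]).
#' @param p_out elimination threshold on the partial p-value (default
#'   0.10, the conventional backward-elimination default).
#' @return an object of class `regression_model`: coefficient table
#'   (`B`, `SE`, `t`, `p` per retained predictor and intercept), model `F`
#'   and degrees of freedom, `r2`, `adj_r2`, raw model `p`, the elimination
#'   trail, and the underlying `lm` fit.
#' @export
backward_fit <- function(table, outcome, predictors, p_out = 0.10) {
  if (!outcome %in% names(table)) stop_input("outcome '%s' not in table", outcome)
  ex <- expand_predictors(table, predictors)
  design <- ex$design
  y <- table[[outcome]]
  if (length(y) <= ncol(design) + 1L) {
    stop_input("need more rows than predictors + 1")
  }
  removed <- if (length(ex$dropped)) {
    data.frame(predictor = ex$dropped, p = NA_real_,
               reason = "constant column")
  } else {
    data.frame(predictor = character(), p = numeric(), reason = character())
  }
  refit <- function(design) {
    if (ncol(design) == 0L) {
      stats::lm(.outcome ~ 1, data = data.frame(.outcome = y))
    } else {
      stats::lm(.outcome ~ ., data = cbind(.outcome = y, design))
    }
  }
  fit <- refit(design)
  # drop aliased columns before elimination proper
  alias <- names(which(is.na(stats::coef(fit))))
  if (length(alias)) {
    alias <- gsub("`", "", alias)
    removed <- rbind(removed, data.frame(predictor = alias, p = NA_real_,
                                         reason = "aliased (exact collinearity)"))
    design <- design[, setdiff(names(design), alias), drop = FALSE]
    fit <- refit(design)
  }
  repeat {
    ct <- summary(fit)$coefficients
    keep <- rownames(ct) != "(Intercept)"
    pv <- stats::setNames(ct[keep, 4], gsub("`", "", rownames(ct)[keep]))
    if (length(pv) == 0L) break
    worst <- which.max(pv)
    if (pv[worst] < p_out) break
    removed <- rbind(removed, data.frame(
      predictor = names(pv)[worst], p = unname(pv[worst]),
      reason = sprintf("p %.3g >= %.3g", pv[worst], p_out)))
    design <- design[, setdiff(names(design), names(pv)[worst]),
                     drop = FALSE]
    fit <- refit(design)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coef_tab <- data.frame(term = gsub("`", "", rownames(ct)),
                         B = ct[, 1], SE = ct[, 2], t = ct[, 3],
                         p = ct[, 4], row.names = NULL)
  intercept_only <- ncol(design) == 0L
  fstat <- if (!intercept_only) unname(sm$fstatistic) else NULL
  structure(list(
    outcome = outcome,
    retained = names(design),
    coefficients = coef_tab,
    F = if (!is.null(fstat)) fstat[1] else NA_real_,
    df = if (!is.null(fstat)) fstat[2:3] else c(NA_real_, NA_real_),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    p_model = if (!is.null(fstat)) {
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    } else NA_real_,
    removed = removed, n = length(y), p_out = p_out,
    intercept_only = intercept_only,
    fit = fit), class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> %s ~ %s\n", x$outcome,
              if (x$intercept_only) "1 (intercept only)"
              else paste(x$retained, collapse = " + ")))
  if (!x$intercept_only) {
    cat(sprintf("  F(%g, %g) = %.3g, adj R2 = %.3g, p = %.3g\n",
                x$df[1], x$df[2], x$F, x$adj_r2, x$p_model))
  }
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Residual diagnostics for a fitted model
#'
#' Automates the visual assumption checks: residual normality
#' (Shapiro-Wilk) and homoscedasticity of the residuals against the fitted
#' values (studentised Breusch-Pagan). Models violating either assumption
#' at level `alpha` are marked excluded from further analysis. Degenerate
#' residuals (zero variance, e.g. a noise-free fit) pass both checks.
#'
#' @param model a `regression_model` from [backward_fit()].
#' @param alpha test level (default 0.05).
#' @param plot if `TRUE`, draws the normal Q-Q and residual-vs-fitted
#'   panels.
#' @return list with logical `normality`, `homoscedasticity`, `excluded`,
#'   and the two test p-values.
#' @export
model_diagnostics <- function(model, alpha = 0.05, plot = FALSE) {
  stopifnot(inherits(model, "regression_model"))
  res <- stats::residuals(model$fit)
  fitted <- stats::fitted(model$fit)
  if (plot) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    stats::qqnorm(res, main = "Residual normality")
    stats::qqline(res)
    graphics::plot(fitted, res, xlab = "Fitted", ylab = "Residual",
                   main = "Homoscedasticity")
    graphics::abline(h = 0, lty = 2)
  }
  degenerate <- stats::sd(res) < 1e-10 * max(abs(fitted), 1)
  p_norm <- if (degenerate) 1 else stats::shapiro.test(res)$p.value
  p_homo <- if (degenerate || model$intercept_only) 1 else {
    lmtest::bptest(model$fit, studentize = TRUE)$p.value
  }
  normality <- p_norm >= alpha
  homoscedasticity <- p_homo >= alpha
  list(normality = normality, homoscedasticity = homoscedasticity,
       excluded = !(normality && homoscedasticity),
       p_normality = unname(p_norm), p_homoscedasticity = unname(p_homo))
}

#' Hommel family-wise error correction
#'
#' Step-up adjusted p-values of Hommel's closed-testing procedure (Simes
#' local tests), applied within each family of models; adjusted values are
#' never below the raw ones and preserve their ordering.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
hommel_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_input("input error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "hommel")
}

#' Inter-rater intraclass correlation, two-way random, absolute agreement
#'
#' ICC(2,1): single-measurement intraclass correlation under a two-way
#' random-effects model for absolute agreement, computed from the two-way
#' ANOVA mean squares
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with subjects in rows (`n`) and raters in columns (`k`); the 95%
#' confidence interval uses the Satterthwaite approximation of
#' McGraw & Wong. Absolute agreement penalises systematic rater offsets,
#' unlike the consistency form.
#'
#' @param ratings complete numeric matrix, subjects x raters (>= 3
#'   subjects, >= 2 raters).
#' @param alpha 1 - confidence level (default 0.05).
#' @return an object of class `icc_result`: `estimate`, `lower`, `upper`,
#'   `model` descriptor, the mean squares, and a `degenerate` flag (set
#'   when there is no between-subject variance).
#' @export
icc_absolute <- function(ratings, alpha = 0.05) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop_input("need >= 3 subjects and >= 2 raters")
  if (anyNA(ratings)) stop_input("ratings matrix must be complete")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- msr < 1e-12 * max(sst / (n * k - 1), 1e-300)
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  est <- if (abs(denom) < 1e-300) 1 else (msr - mse) / denom
  ci <- tryCatch({
    if (mse <= 0 && msc <= 0) {
      c(est, est) # perfect agreement: interval collapses
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      c(lo, hi)
    }
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(estimate = est, lower = ci[1], upper = ci[2],
                 model = "two-way random, absolute agreement, single measurement (ICC(2,1))",
                 ms = c(msr = msr, msc = msc, mse = mse),
                 n = n, k = k, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (95%% CI %.3f-%.3f)%s\n",
              x$estimate, x$lower, x$upper,
              if (x$degenerate) " [degenerate: no between-subject variance]"
              else ""))
  invisible(x)
}

#' Fit and correct a family of models for one level
#'
#' Runs the VIF screen once per level, backward-fits every outcome on the
#' surviving predictors, attaches residual diagnostics, and applies the
#' Hommel correction to the family of raw model p-values (the group of
#' tests performed at that level).
#'
#' @param table cohort data.frame for one disc level.
#' @param outcomes outcome column names.
#' @param predictors predictor names.
#' @param p_out backward-elimination threshold.
#' @param vif_threshold VIF removal threshold.
#' @param alpha diagnostics level.
#' @return list with `models` (per outcome: `regression_model`,
#'   diagnostics, raw and corrected model p), `vif` (screen result) and
#'   `family_p` (data.frame of raw/adjusted model p-values).
#' @export
fit_level_models <- function(table, outcomes, predictors, p_out = 0.10,
                             vif_threshold = 10, alpha = 0.05) {
  screen <- vif_screen(table, predictors, vif_threshold)
  models <- lapply(outcomes, function(oc) {
    m <- backward_fit(table, oc, screen$retained, p_out)
    list(model = m, diagnostics = model_diagnostics(m, alpha))
  })
  names(models) <- outcomes
  raw_p <- vapply(models, function(m) m$model$p_model, numeric(1))
  keep <- is.finite(raw_p)
  adj <- rep(NA_real_, length(raw_p))
  if (any(keep)) adj[keep] <- hommel_adjust(raw_p[keep])
  for (i in seq_along(models)) models[[i]]$corrected_p <- adj[i]
  list(models = models, vif = screen,
       family_p = data.frame(outcome = outcomes, p = unname(raw_p),
                             corrected_p = adj))
}
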