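test_that("orthogonal predictors all carry unit VIF and survive", {
  n <- 16
  X <- stats::contr.helmert(n)[, 1:4] # mutually orthogonal columns
  tab <- as.data.frame(X)
  names(tab) <- paste0("p", 1:4)
  v <- vif_screen(tab, names(tab))
  expect_setequal(v$retained, names(tab))
  expect_equal(nrow(v$ledger), 0)
})

test_that("an exact duplicate column is removed with an infinite-VIF entry", {
  co <- make_synthetic_cohort(15, c(age = 0.1), noise_sd = 1, seed = 21)
  tab <- co$table
  tab$age_copy <- tab$age
  v <- suppressWarnings(vif_screen(tab, c(cohort_predictors(), "age_copy")))
  expect_true("age_copy" %in% v$ledger$predictor ||
                "age" %in% v$ledger$predictor)
  expect_true(any(is.infinite(v$ledger$vif)))
  expect_false(all(c("age", "age_copy") %in% v$retained))
})

test_that("VIF values match an independent R-squared computation", {
  set.seed(33)
  n <- 40
  z <- rnorm(n)
  tab <- data.frame(a = z + rnorm(n, sd = 0.5),
                    b = z + rnorm(n, sd = 0.5),
                    c = rnorm(n))
  ex <- expand_predictors(tab, c("a", "b", "c"))
  for (j in seq_along(ex$design)) {
    r2 <- summary(stats::lm(ex$design[[j]] ~ .,
                            data = ex$design[, -j, drop = FALSE]))$r.squared
    expect_equal(spinedvc:::vif_values(ex$design)[j], 1 / (1 - r2),
                 tolerance = 1e-10)
  }
  # threshold 1.5 forces removal of the most collinear of a/b
  v <- vif_screen(tab, c("a", "b", "c"), threshold = 1.5)
  expect_true(all(spinedvc:::vif_values(
    ex$design[, v$retained, drop = FALSE]) < 1.5))
})

test_that("backward elimination honours its stopping rules", {
  co <- make_synthetic_cohort(15, c(age = 0.1, ap_ratio = 5),
                              noise_sd = 0.9, seed = 41)
  full <- backward_fit(co$table, "outcome", cohort_predictors(), p_out = 1)
  ex <- expand_predictors(co$table, cohort_predictors())
  expect_setequal(full$retained, names(ex$design)) # p_out = 1: full model
  none <- backward_fit(co$table, "outcome", cohort_predictors(),
                       p_out = 1e-12)
  expect_true(none$intercept_only || length(none$retained) <
                length(ex$design))

  # pure noise with p_out -> 0 gives the flagged intercept-only model
  noise <- make_synthetic_cohort(15, numeric(0), noise_sd = 1, seed = 42)
  m0 <- backward_fit(noise$table, "outcome", cohort_predictors(),
                     p_out = 1e-6)
  expect_true(m0$intercept_only)
  expect_true(is.na(m0$F))
})

test_that("a single retained predictor has model F equal to its t squared", {
  co <- make_synthetic_cohort(18, c(ap_ratio = 6), noise_sd = 1, seed = 43)
  m <- backward_fit(co$table, "outcome", c("ap_ratio"), p_out = 0.1)
  expect_equal(m$retained, "ap_ratio")
  tval <- m$coefficients$t[m$coefficients$term == "ap_ratio"]
  expect_equal(m$F, tval^2, tolerance = 1e-10)
})

test_that("coefficient bias vanishes as the noise level shrinks", {
  bias_at <- function(noise_sd) {
    est <- vapply(1:20, function(s) {
      co <- make_synthetic_cohort(15, c(ap_ratio = 5), noise_sd = noise_sd,
                                  seed = 100 + s)
      m <- suppressWarnings(
        backward_fit(co$table, "outcome", cohort_predictors()))
      cf <- m$coefficients
      if ("ap_ratio" %in% cf$term) cf$B[cf$term == "ap_ratio"] else NA_real_
    }, numeric(1))
    abs(mean(est, na.rm = TRUE) - 5)
  }
  expect_lt(bias_at(0.001), 0.005)
  expect_lt(bias_at(0.2), bias_at(5) + 0.5)
})

test_that("diagnostics pass clean models and catch heteroscedasticity", {
  # constant (zero-noise) residuals pass both checks
  co0 <- make_synthetic_cohort(15, c(age = 0.1), noise_sd = 0, seed = 51)
  m0 <- suppressWarnings(backward_fit(co0$table, "outcome", c("age")))
  d0 <- model_diagnostics(m0)
  expect_true(d0$normality && d0$homoscedasticity)
  expect_false(d0$excluded)

  n <- 40
  passes <- 0; flagged <- 0
  for (s in 1:30) {
    set.seed(600 + s)
    x <- runif(n, 1, 10)
    tab_ok <- data.frame(x = x, y = 2 * x + rnorm(n))
    d_ok <- model_diagnostics(backward_fit(tab_ok, "y", "x", p_out = 1))
    passes <- passes + !d_ok$excluded
    tab_het <- data.frame(x = x, y = 2 * x + rnorm(n, sd = 0.8 * x))
    d_het <- model_diagnostics(backward_fit(tab_het, "y", "x", p_out = 1))
    flagged <- flagged + !d_het$homoscedasticity
  }
  expect_gte(passes, 27)  # >= 90% of clean models pass
  expect_gt(flagged, 15)  # heteroscedasticity caught in the majority
})

test_that("Hommel adjustment matches brute-force closed testing", {
  expect_equal(hommel_adjust(0.03), 0.03)
  expect_equal(hommel_adjust(rep(1, 5)), rep(1, 5))
  expect_error(hommel_adjust(c(0.2, 1.4)), "input error")
  set.seed(71)
  for (i in 1:200) {
    m <- sample(2:4, 1)
    p <- round(runif(m), 3)
    expect_equal(hommel_adjust(p), closed_testing_oracle(p),
                 tolerance = 1e-12)
  }
})

test_that("Hommel is never below the raw p and never above Hochberg or Holm", {
  # dominance: Hommel's closed test is uniformly more powerful than
  # Hochberg's shortcut, which is more powerful than Holm's, so the
  # adjusted p-values order as hommel <= hochberg <= holm
  set.seed(72)
  for (i in 1:50) {
    p <- runif(sample(3:8, 1))
    hom <- hommel_adjust(p)
    expect_true(all(hom >= p - 1e-15))
    hoch <- stats::p.adjust(p, "hochberg")
    holm <- stats::p.adjust(p, "holm")
    expect_true(all(hom <= hoch + 1e-12))
    expect_true(all(hoch <= holm + 1e-12))
  }
})

test_that("ICC(2,1) behaves at the definitional corners", {
  set.seed(81)
  base <- rnorm(12)
  perfect <- icc_absolute(cbind(base, base, base))
  expect_equal(perfect$estimate, 1)
  # a constant rater offset is penalised by absolute agreement
  offset <- icc_absolute(cbind(base, base + 1))
  expect_lt(offset$estimate, 1)
  expect_gt(offset$estimate, 0)
  # degenerate: no between-subject variance
  flat <- icc_absolute(matrix(c(rep(1, 6), rep(1, 6)), ncol = 2) +
                         cbind(rep(0, 6), rep(0.5, 6)))
  expect_true(flat$degenerate)
  expect_error(icc_absolute(matrix(1, 2, 2)), "subjects")
})

test_that("ICC(2,1) matches the aov mean-squares oracle with a sane CI", {
  set.seed(82)
  for (i in 1:20) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    subj <- rnorm(n, sd = 2)
    rat <- outer(subj, rep(1, k)) + matrix(rnorm(n * k), n, k) +
      outer(rep(1, n), rnorm(k, sd = 0.3))
    r <- icc_absolute(rat)
    expect_equal(r$estimate, aov_icc_oracle(rat), tolerance = 1e-10)
    expect_lte(r$lower, r$estimate + 1e-12)
    expect_gte(r$upper, r$estimate - 1e-12)
    expect_lte(r$estimate, 1)
  }
})

test_that("level model families get a Hommel-corrected model p", {
  co <- make_synthetic_cohort(15, c(age = 0.1, ap_ratio = 5),
                              noise_sd = 0.9, seed = 91)
  tab <- co$table
  tab$outcome2 <- tab$outcome + rnorm(15, sd = 0.5)
  fam <- fit_level_models(tab, c("outcome", "outcome2"),
                          cohort_predictors())
  expect_equal(nrow(fam$family_p), 2)
  expect_true(all(fam$family_p$corrected_p >= fam$family_p$p - 1e-12))
  expect_equal(sort(fam$family_p$corrected_p),
               sort(hommel_adjust(fam$family_p$p)))
})
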