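# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 48^3 speckle phantom used by the correlation unit tests
speckle48 <- function() {
  fixture("speckle48", function() {
    make_speckle_phantom(c(48, 48, 48), spacing = 1, blob_count = 6000,
                         seed = 424L)
  })
}

# two-level spine phantom at coarse spacing for geometry/summary tests
spine_small <- function() {
  fixture("spine_small", function() {
    make_spine_phantom(spine_geometry(levels = 2, depth = 28,
                                      vertebra_height = 18,
                                      disc_anterior = 11,
                                      disc_posterior = 8.5,
                                      sacral_angle = 38, width = 26),
                       spacing = 1.5, seed = 77L)
  })
}

# node centres of a displacement field in mm, expand.grid order
field_nodes_mm <- function(field) {
  g <- field$grid
  (as.matrix(expand.grid(g$centres[[1]], g$centres[[2]], g$centres[[3]],
                         KEEP.OUT.ATTRS = FALSE)) - 0.5) * g$spacing
}

# analytic displacement field on a grid (for rigid/strain tests that need
# exactly-known fields rather than correlation output)
analytic_field <- function(grid, ufun) {
  nodes_mm <- (as.matrix(expand.grid(grid$centres[[1]], grid$centres[[2]],
                                     grid$centres[[3]],
                                     KEEP.OUT.ATTRS = FALSE)) - 0.5) *
    grid$spacing
  displacement_field(grid, ufun(nodes_mm))
}

# brute-force closed-testing (Simes local tests) oracle for the Hommel
# adjustment: adjusted p_i = max over subsets S containing i of the Simes
# p-value of S
closed_testing_oracle <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  for (i in seq_len(m)) {
    worst <- 0
    for (r in seq_len(nrow(subsets))) {
      sel <- unlist(subsets[r, ])
      if (!sel[i]) next
      ps <- sort(p[sel])
      k <- length(ps)
      simes <- min(k * ps / seq_len(k))
      worst <- max(worst, simes)
    }
    adj[i] <- min(1, worst)
  }
  adj
}

# two-way ANOVA mean squares via aov(), as an independent ICC oracle
aov_icc_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
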