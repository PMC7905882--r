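# Distribution-level statistics: per-cell KDEs, mean curves with t bands,
# significance regions, crossover points, one-sided KS tests, and the
# calibration of the CI-overlap rule.

test_that("per-cell KDEs integrate to one and track the truth", {
  grid <- seq(-4, 4, length.out = 512)
  set.seed(1)
  x <- rnorm(500)
  y <- per_cell_kde(x, grid)
  expect_equal(sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2), 1,
               tolerance = 1e-6)
  expect_lt(max(abs(y - dnorm(grid))), 0.05)
  # all-equal sample: mode lands at the common value
  grid2 <- seq(0, 10, length.out = 512)
  y2 <- per_cell_kde(c(7, 7, 7), grid2)
  expect_lt(abs(grid2[which.max(y2)] - 7), diff(grid2[1:2]) * 2)
  # curve values depend only on position, not on the grid window
  g1 <- seq(-4, 4, by = 0.01)
  g2 <- seq(-6, 4, by = 0.01)  # same step; shares the [-4, 4] points
  y1 <- per_cell_kde(x, g1, bw = 0.3)
  y12 <- per_cell_kde(x, g2, bw = 0.3)[match(round(g1, 9), round(g2, 9))]
  # same evaluation points, different window: identical up to renormalization
  expect_equal(y12 / y1, rep(y12[1] / y1[1], length(y1)), tolerance = 1e-9)
  expect_error(per_cell_kde(3, grid), "at least 2")
})

test_that("truncated nonnegative grids renormalize to unit mass", {
  vals <- c(5, 8, 12, 30, 45, 60)  # Scott bandwidth pushes mass below 0
  grid <- kde_grid(vals, n = 400, nonnegative = TRUE)
  expect_identical(min(grid) >= 0, TRUE)
  y <- per_cell_kde(vals, grid)
  expect_equal(sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2), 1,
               tolerance = 1e-6)
})

test_that("mean curves carry pointwise t bands with the stated properties", {
  grid <- seq(0, 1, length.out = 64)
  same <- matrix(rep(dnorm(grid, 0.5, 0.2), 5), 5, byrow = TRUE)
  mc <- mean_kde_with_ci(same, grid)
  expect_equal(mc$ci_low, mc$mean, tolerance = 1e-12)
  expect_equal(mc$ci_high, mc$mean, tolerance = 1e-12)
  set.seed(2)
  curves <- matrix(rnorm(20 * 64, mean = 1), 20)
  m1 <- mean_kde_with_ci(curves, grid, level = 0.834)
  m2 <- mean_kde_with_ci(curves, grid, level = 0.95)
  expect_true(all(m2$ci_high - m2$ci_low > m1$ci_high - m1$ci_low))
  expect_true(all(m1$ci_low <= m1$mean & m1$mean <= m1$ci_high))
  expect_error(mean_kde_with_ci(curves[1:2, ], grid), "at least 3")
  # band width shrinks like 1/sqrt(n) for iid cells
  set.seed(3)
  w <- vapply(c(8, 32, 128), function(n) {
    cv <- matrix(rnorm(n * 64), n)
    m <- mean_kde_with_ci(cv, grid)
    mean(m$ci_high - m$ci_low)
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
  expect_equal(w[2] / w[3], 2, tolerance = 0.35)
})

test_that("the 83.4% band covers the true mean at its nominal rate", {
  # cells share one sampling distribution; fixed KDE bandwidth makes the
  # expected curve analytic: N(0,1) convolved with N(0, 0.3^2)
  grid <- seq(-5, 5, length.out = 64)
  truth <- dnorm(grid, 0, sqrt(1 + 0.09))
  probe <- which.min(abs(grid))  # x ~ 0
  set.seed(4)
  cover <- vapply(1:1000, function(r) {
    curves <- t(vapply(1:8, function(cell)
      per_cell_kde(rnorm(60), grid, bw = 0.3), numeric(length(grid))))
    m <- mean_kde_with_ci(curves, grid)
    m$ci_low[probe] <= truth[probe] && truth[probe] <= m$ci_high[probe]
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.834), 0.045)
})

test_that("significance regions are the maximal non-overlap intervals", {
  grid <- seq(0, 100, length.out = 201)
  mk <- function(m, half) {
    structure(list(grid = grid, mean = m, ci_low = m - half,
                   ci_high = m + half, n_cells = 10, level = 0.834,
                   label = NULL), class = "mean_curve_ci")
  }
  a <- mk(rep(1, 201), 0.1)
  expect_identical(nrow(significance_regions(a, a)), 0L)
  b <- mk(rep(2, 201), 0.1)
  full <- significance_regions(a, b)
  expect_identical(nrow(full), 1L)
  expect_equal(c(full$lo, full$hi), c(0, 100))
  # localized separation: region matches the construction
  m2 <- rep(1, 201); m2[81:121] <- 2
  loc <- significance_regions(a, mk(m2, 0.1))
  expect_identical(nrow(loc), 1L)
  expect_equal(c(loc$lo, loc$hi), c(40, 60))
  # symmetry
  expect_equal(significance_regions(mk(m2, 0.1), a), loc,
               ignore_attr = TRUE)
  other <- mk(rep(1, 201), 0.1)
  other$grid <- grid + 1
  expect_error(significance_regions(a, other), "grid")
})

test_that("localized group differences are detected reliably", {
  grid <- seq(0, 10, length.out = 256)
  base <- dnorm(grid, 5, 2)
  bump <- 0.08 * dnorm(grid, 7, 0.35) / dnorm(7, 7, 0.35)  # on [6.3, 7.7]
  set.seed(5)
  hits <- vapply(1:200, function(r) {
    ga <- t(vapply(1:10, function(i) base + rnorm(256, 0, 0.004),
                   numeric(256)))
    gb <- t(vapply(1:10, function(i) base + bump + rnorm(256, 0, 0.004),
                   numeric(256)))
    reg <- significance_regions(mean_kde_with_ci(ga, grid),
                                mean_kde_with_ci(gb, grid))
    any(reg$lo <= 6.65 & reg$hi >= 7.35)  # covers the bump's core
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("crossover points sit where cumulative differences peak", {
  grid <- seq(-6, 7, length.out = 1301)
  mk <- function(m) structure(list(grid = grid, mean = m, ci_low = m,
                                   ci_high = m, n_cells = 5, level = 0.834,
                                   label = NULL), class = "mean_curve_ci")
  a <- mk(dnorm(grid, 0, 1))
  b <- mk(dnorm(grid, 1, 1))
  cp <- crossover_point(a, b)
  expect_true(cp$crossed)
  expect_equal(cp$x, 0.5, tolerance = 0.01)
  expect_gt(cp$cumulative, 0)  # a has its mass below the crossover
  expect_false(crossover_point(a, a)$crossed)
  # piecewise-linear toy curves against a brute-force cumulative scan
  m1 <- pmax(0, 1 - abs(grid) / 2)
  m2 <- pmax(0, 1 - abs(grid - 1.5) / 2)
  cpl <- crossover_point(mk(m1), mk(m2))
  d <- m1 - m2
  cum <- cumsum(c(0, diff(grid) * (head(d, -1) + tail(d, -1)) / 2))
  expect_equal(cpl$x, grid[which.max(abs(cum))])
  # the largest pointwise density difference is a distinct summary;
  # oracle: continuous optimization of |phi(x) - phi(x - 1)|
  md <- max_density_difference(a, b)
  opt <- stats::optimize(function(x) abs(dnorm(x) - dnorm(x, 1)),
                         interval = c(-6, 0.5), maximum = TRUE)$maximum
  expect_equal(md$x, opt, tolerance = 0.02)
})

test_that("one-sided KS tests point in the documented direction", {
  set.seed(6)
  a <- rnorm(200, 1); b <- rnorm(200, 0)
  up <- ks_one_sided(a, b)   # a really is larger
  down <- ks_one_sided(b, a)
  expect_lt(up$p.value, 1e-6)
  expect_gt(down$p.value, 0.5)
  same <- ks_one_sided(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$statistic, 0)
  expect_error(ks_one_sided(1:3, 1:10), "at least 5")
})

test_that("small-sample KS p-values match an exhaustive permutation oracle", {
  perm_p <- function(a, b) {
    # exact permutation distribution of D+ = sup(ECDF_b - ECDF_a)
    n <- length(a); pool <- c(a, b)
    idx <- utils::combn(length(pool), n)
    dplus <- function(aa, bb) {
      xs <- sort(unique(pool))
      max(ecdf(bb)(xs) - ecdf(aa)(xs))
    }
    obs <- dplus(a, b)
    cnt <- 0L
    for (cidx in seq_len(ncol(idx))) {
      aa <- pool[idx[, cidx]]; bb <- pool[-idx[, cidx]]
      if (dplus(aa, bb) >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt / ncol(idx)
  }
  set.seed(7)
  for (rep in 1:5) {
    a <- round(rnorm(6, 0.5), 3); b <- round(rnorm(6), 3)
    if (anyDuplicated(c(a, b))) next  # oracle assumes no ties
    ks <- ks_one_sided(a, b)
    expect_lt(abs(ks$p.value - perm_p(a, b)), 0.02)
  }
})

test_that("KS p-values are super-uniform under the null", {
  set.seed(8)
  ps <- vapply(1:2000, function(r)
    ks_one_sided(rnorm(30), rnorm(30))$p.value, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
    mc <- 3 * sqrt(alpha * (1 - alpha) / 2000)
    expect_lte(mean(ps <= alpha), alpha + mc)
  }
})

test_that("CI non-overlap calibrates to ~5% for equal SEs and drifts off otherwise", {
  set.seed(9)
  nonoverlap <- function(sd_b) {
    mean(vapply(1:4000, function(r) {
      ca <- t_ci(rnorm(24)); cb <- t_ci(rnorm(24, 0, sd_b))
      ca[1] > cb[2] || cb[1] > ca[2]
    }, logical(1)))
  }
  equal <- nonoverlap(1)
  expect_lt(abs(equal - 0.05), 0.015)
  # with unequal SEs the non-overlap threshold 1.386 (se_a + se_b) falls
  # below the t-test's 1.96 sqrt(se_a^2 + se_b^2), so the rule rejects
  # more than 5% under the null: the equivalence needs comparable SEs
  uneq <- nonoverlap(3)
  expect_gt(uneq, 0.05)
  expect_lt(uneq, 0.12)
})
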