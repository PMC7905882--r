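# Cluster statistics: density maps and their peaks, k-NN distances,
# line profiles and Lorentzian FWHM sizing.

locs_df <- function(pts, ...) {
  cluster_locs(data.frame(x_nm = pts[, 1], y_nm = pts[, 2]), ...)
}

test_that("density maps use unit-peak kernels and add over point sets", {
  # cluster placed on a grid node: (51 - 0.5) * 20 = 1010 nm
  one <- locs_df(matrix(c(1010, 1010), 1), extent = c(2000, 2000),
                 pixel_size = px_nm)
  m1 <- density_map(one, bandwidth = 200)
  expect_equal(max(m1$grid), 1, tolerance = 1e-9)
  # m coincident clusters -> peak m (additivity)
  three <- locs_df(matrix(rep(c(1010, 1010), each = 3), 3),
                   extent = c(2000, 2000), pixel_size = px_nm)
  expect_equal(max(density_map(three, 200)$grid), 3, tolerance = 1e-9)
  # map additivity: map(union) == map(a) + map(b), exactly
  a <- locs_df(matrix(c(700, 800, 600, 900), 2), extent = c(2000, 2000),
               pixel_size = px_nm)
  b <- locs_df(matrix(c(1200, 1400, 1300, 1100), 2), extent = c(2000, 2000),
               pixel_size = px_nm)
  ab <- locs_df(rbind(as.matrix(as.data.frame(a)[1:2]),
                      as.matrix(as.data.frame(b)[1:2])),
                extent = c(2000, 2000), pixel_size = px_nm)
  expect_equal(density_map(ab, 200)$grid,
               density_map(a, 200)$grid + density_map(b, 200)$grid,
               tolerance = 1e-12)
  expect_error(density_map(locs_df(matrix(numeric(0), 0, 2))), "localization")
})

test_that("the midpoint of two clusters 200 nm apart at bw 200 reads 2*exp(-1/8)", {
  # put the midpoint exactly on a grid node: points at x = 900 and 1100,
  # grid spacing 20 -> node at 990 is 10 nm off; use spacing 200/2 = 100
  # with origin 0 so node centers are at 50, 150, ..., 950, 1050 ...
  two <- locs_df(matrix(c(950, 1150, 1050, 1050), 2), extent = c(2100, 2100))
  m <- density_map(two, bandwidth = 200, grid_spacing = 100)
  node <- m$grid[11, 11]  # center (1050, 1050) = the midpoint
  expect_equal(node, 2 * exp(-0.125), tolerance = 1e-9)
})

test_that("density peak intensities read local cluster counts", {
  # groups on grid nodes ((k - 0.5) * 20) so peak values are exact
  pts <- rbind(matrix(rep(c(510, 510), each = 3), 3),
               matrix(rep(c(1710, 1710), each = 5), 5))
  m <- density_map(locs_df(pts, extent = c(2200, 2200)), bandwidth = 150,
                   grid_spacing = 20)
  pk <- sort(density_peak_intensities(m))
  expect_length(pk, 2)
  expect_equal(pk, c(3, 5), tolerance = 1e-9)
  # a flat map has no peaks
  flat <- structure(list(grid = matrix(1, 32, 32), grid_spacing = 20,
                         bandwidth = 150, origin = c(0, 0)),
                    class = "density_map")
  expect_length(density_peak_intensities(flat), 0)
})

test_that("aggregated patterns show larger density peaks than CSR", {
  mask <- fixture_mask()
  csr <- point_process("csr", intensity = 8)
  tho <- point_process("thomas", intensity = 8, parent_intensity = 1,
                       offspring_per_parent = 8, offspring_sd = 80)
  peak90 <- function(proc, seed) {
    gt <- sample_cluster_points(proc, mask, seed = seed)
    if (nrow(gt$points) < 5) return(NA_real_)
    m <- density_map(locs_df(gt$points, extent = c(2560, 2560)),
                     bandwidth = 200, grid_spacing = 40)
    stats::quantile(density_peak_intensities(m), 0.9)
  }
  p_csr <- vapply(1:50, function(s) peak90(csr, s), numeric(1))
  p_tho <- vapply(51:100, function(s) peak90(tho, s), numeric(1))
  wt <- stats::wilcox.test(p_tho, p_csr, alternative = "greater")
  expect_lt(wt$p.value, 1e-3)
})

test_that("k-NN distances match hand geometry and the exhaustive oracle", {
  # 6 collinear points spaced 100 nm: distances from an end point
  pts <- cbind(seq(0, 500, by = 100), rep(0, 6))
  d <- knn_distances(locs_df(pts), k = 4)
  expect_equal(d[1:4], c(100, 200, 300, 400))
  expect_length(d, 24)
  # oracle equivalence on random configurations
  set.seed(99)
  for (n in c(6, 25, 120)) {
    p <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
    expect_equal(sort(knn_distances(locs_df(p), k = 4)),
                 sort(knn_oracle(p, 4)), tolerance = 1e-12)
  }
  expect_error(knn_distances(locs_df(pts[1:3, ]), k = 4), "more than k")
})

test_that("k-NN distances of isolated distant pairs equal the pair spacing", {
  # pairs at 202.3 nm, pair centers on a coarse grid >> 800 nm apart
  centers <- expand.grid(x = c(1000, 3000, 5000), y = c(1000, 3000, 5000))
  set.seed(4)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    ang <- runif(1, 0, 2 * pi)
    h <- 202.3 / 2 * c(cos(ang), sin(ang))
    rbind(as.numeric(centers[i, ]) + h, as.numeric(centers[i, ]) - h)
  }))
  d <- knn_distances(locs_df(pts), k = 1)
  expect_equal(d, rep(202.3, nrow(pts)), tolerance = 1e-9)
})

test_that("k-NN distances are exactly invariant under rigid rotation", {
  set.seed(12)
  p <- cbind(runif(40, 0, 2000), runif(40, 0, 2000))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pr <- p %*% R
  expect_equal(sort(knn_distances(locs_df(p), 4)),
               sort(knn_distances(locs_df(pr), 4)), tolerance = 1e-9)
})

test_that("line profiles respect symmetry, constancy and row alignment", {
  mask <- cell_mask(matrix(TRUE, 96, 96), px_nm)
  ctr <- c(47.5, 47.5) * px_nm  # a pixel center
  img <- render_points(c(ctr[1], ctr[2]), fwhm = 80, mask = mask,
                       spec = fixed_spec(80, bg = 0, out_bg = 0))
  prof <- extract_line_profiles(img, ctr)
  # radially symmetric spot: all four profiles agree
  for (p in prof[-1])
    expect_equal(p$value, prof[[1]]$value, tolerance = 0.02 * max(prof[[1]]$value))
  # 0 degree profile equals the pixel row through the center
  i <- 48; offs <- prof$deg0$offset_nm
  cols <- round(ctr[1] / px_nm + offs / px_nm + 0.5)
  expect_equal(prof$deg0$value, img$pixels[i, cols], tolerance = 1e-9)
  # constant image -> constant profiles
  cimg <- sted_image(matrix(3.5, 96, 96), px_nm)
  pc <- extract_line_profiles(cimg, ctr)
  for (p in pc) expect_equal(p$value, rep(3.5, length(p$value)),
                             tolerance = 1e-12)
  # center too close to the edge -> NULL
  expect_null(extract_line_profiles(img, c(100, 100)))
})

test_that("Lorentzian fits recover exact curves and reject noise", {
  x <- seq(-200, 200, by = 10)
  y <- 0.3 + 2 / (1 + (x / 34)^2)
  f <- fit_lorentzian(x, y)
  expect_true(f$ok)
  expect_equal(f$fwhm, 68, tolerance = 1e-6)
  expect_gt(f$r_squared, 1 - 1e-9)
  expect_equal(f$offset, 0.3, tolerance = 1e-6)
  # amplitude scaling leaves gamma and R^2 unchanged
  f2 <- fit_lorentzian(x, y * 12)
  expect_equal(f2$gamma, f$gamma, tolerance = 1e-6)
  expect_equal(f2$r_squared, f$r_squared, tolerance = 1e-9)
  # pure noise: rejected by the R^2 > 0.9 rule in most draws
  set.seed(8)
  rejected <- vapply(1:50, function(i) {
    fn <- fit_lorentzian(x, runif(length(x)))
    !(fn$ok && fn$r_squared > 0.9)
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
  expect_error(fit_lorentzian(1:5, 1:5), "8 samples")
})

test_that("cluster FWHM recovers isotropic sizes and the short axis", {
  mask <- cell_mask(matrix(TRUE, 96, 96), px_nm)
  set.seed(3)
  rec <- vapply(1:10, function(i) {
    ctr <- c(47.5, 47.5) * px_nm + runif(2, -10, 10)
    img <- render_points(c(ctr[1], ctr[2]), fwhm = 80, mask = mask,
                         spec = fixed_spec(80, bg = 0, out_bg = 0))
    locpix <- (round(ctr / px_nm - 0.5) + 0.5) * px_nm
    cluster_fwhm(img, locs_df(matrix(locpix, 1), pixel_size = px_nm))$values
  }, numeric(1))
  expect_true(all(abs(rec - 80) <= 15))
  # elongated spot (elliptical Lorentzian, 80 nm short / 160 nm long axis):
  # every line through the center is Lorentzian with gamma between the two
  # semi-axes, so the minimum rule returns the short axis
  ctr <- c(47.5, 47.5) * px_nm
  xs <- (seq_len(96) - 0.5) * px_nm
  el <- 300 / (1 + outer(((xs - ctr[2]) / 80)^2, ((xs - ctr[1]) / 40)^2, `+`))
  img <- sted_image(el, px_nm)
  v <- cluster_fwhm(img, locs_df(matrix(ctr, 1), pixel_size = px_nm))$values
  expect_lt(abs(v - 80), 15)
  # impossible R^2 threshold empties the distribution
  out <- cluster_fwhm(img, locs_df(matrix(ctr, 1), pixel_size = px_nm),
                      r2_threshold = 1.01)
  expect_length(out$values, 0)
  expect_identical(out$n_no_fit, 1L)
})
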