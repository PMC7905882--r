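# Distribution-level statistics: per-cell kernel density estimates, mean
# curves with pointwise 83.4% confidence bands, band-non-overlap
# significance regions, crossover points of cumulative differences, and
# one-sided two-sample Kolmogorov-Smirnov tests on pooled samples.

#' Scott's rule-of-thumb kernel bandwidth
#'
#' `h = sd(x) * n^(-1/5)`, the standard normal-reference rule for a
#' Gaussian kernel in one dimension.
#'
#' @param x numeric sample.
#' @return bandwidth on the scale of `x`.
#' @export
scott_bw <- function(x) {
  stats::sd(x) * length(x)^(-1 / 5)
}

#' Shared evaluation grid for per-cell density curves
#'
#' Spans the pooled sample range padded by 3 pooled-sample bandwidths, with
#' `n` equally spaced points. For intrinsically non-negative quantities
#' (distances, sizes, density-peak intensities) the grid is clipped at 0.
#'
#' @param values pooled sample across all cells.
#' @param n number of grid points (default 512).
#' @param nonnegative clip the lower end at 0 (default TRUE).
#' @param bw padding bandwidth; default Scott's rule on the pooled sample.
#' @return numeric grid.
#' @export
kde_grid <- function(values, n = 512L, nonnegative = TRUE, bw = NULL) {
  stopifnot(length(values) >= 2L)
  bw <- bw %||% scott_bw(values)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(values)) / 10 + 1e-9
  lo <- min(values) - 3 * bw
  hi <- max(values) + 3 * bw
  if (nonnegative) lo <- max(0, lo)
  seq(lo, hi, length.out = n)
}

#' Gaussian kernel density estimate of one cell's distribution
#'
#' Exact (unbinned) Gaussian KDE evaluated on the given grid. For grids
#' clipped at 0 the estimate is renormalized to integrate to 1 over the
#' grid, so truncation at a physical boundary does not deflate the curve.
#' With all values equal (zero sample sd) the bandwidth falls back to 1% of
#' the grid span, giving a narrow peak at the common value.
#'
#' @param values the cell's sample (>= 2 values).
#' @param grid evaluation grid (equally spaced, increasing).
#' @param bw `"scott"` (default, per-cell Scott's rule) or a fixed numeric
#'   bandwidth; a fixed value makes curves comparable across cells.
#' @return numeric density curve on `grid` (integrates to 1 over the grid).
#' @export
per_cell_kde <- function(values, grid, bw = "scott") {
  if (length(values) < 2L) stop("need at least 2 values for a per-cell KDE")
  h <- if (identical(bw, "scott")) scott_bw(values) else as.numeric(bw)
  if (!is.finite(h) || h <= 0) h <- diff(range(grid)) / 100
  y <- rowSums(stats::dnorm(outer(grid, values, `-`) / h)) / (length(values) * h)
  area <- trapz(grid, y)
  if (area <= 0) stop("degenerate density (zero mass on grid)")
  y / area
}

#' Mean density curve across cells with pointwise t confidence band
#'
#' Averages per-cell density curves pointwise and attaches a pointwise
#' Student-t confidence band `mean +/- t_{n-1,(1+level)/2} * SE`. The
#' default level of 83.4% is chosen so that non-overlap of two such bands
#' corresponds to a two-sided t-test at about the 5% level when the two
#' groups have comparable standard errors.
#'
#' @param curves matrix of per-cell curves (rows = cells, columns = grid
#'   points), or a list of equal-length numeric vectors; >= 3 cells.
#' @param grid the shared evaluation grid.
#' @param level confidence level (default 0.834).
#' @param label optional condition label.
#' @return object of class `mean_curve_ci` with `grid`, `mean`, `ci_low`,
#'   `ci_high`, `n_cells`, `level`, `label`.
#' @export
mean_kde_with_ci <- function(curves, grid, level = 0.834, label = NULL) {
  if (is.list(curves)) curves <- do.call(rbind, curves)
  stopifnot(is.matrix(curves), ncol(curves) == length(grid))
  n <- nrow(curves)
  if (n < 3L) stop("need at least 3 cells for a confidence band")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  m <- colMeans(curves)
  se <- apply(curves, 2L, stats::sd) / sqrt(n)
  tc <- stats::qt((1 + level) / 2, df = n - 1L)
  structure(list(grid = grid, mean = m, ci_low = m - tc * se,
                 ci_high = m + tc * se, n_cells = n, level = level,
                 label = label), class = "mean_curve_ci")
}

#' @export
print.mean_curve_ci <- function(x, ...) {
  cat(sprintf("<mean_curve_ci>%s %d cells, %.1f%% band, grid [%.3g, %.3g] (%d pts)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n_cells, 100 * x$level, min(x$grid), max(x$grid),
              length(x$grid)))
  invisible(x)
}

#' @export
plot.mean_curve_ci <- function(x, col = "steelblue", add = FALSE,
                               xlab = "value", ylab = "mean density", ...) {
  if (!add) graphics::plot(x$grid, x$mean, type = "n", xlab = xlab,
                           ylab = ylab,
                           ylim = c(0, max(x$ci_high)), ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor(col, 0.3), border = NA)
  graphics::lines(x$grid, x$mean, col = col, lwd = 2)
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b) {
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-9 * max(abs(a$grid), 1))
    stop("curves were evaluated on different grids")
}

#' Regions where two confidence bands do not overlap
#'
#' Returns the maximal contiguous grid intervals on which the two bands are
#' disjoint (`a.ci_low > b.ci_high` or `b.ci_low > a.ci_high`). Under the
#' 83.4% band convention these are the regions of pointwise significant
#' difference at about the 5% level. The operation is symmetric in its
#' arguments.
#'
#' @param a,b [mean_kde_with_ci()] results on the same grid.
#' @return data.frame with columns `lo`, `hi` (data units), possibly empty,
#'   with a `comparison` attribute naming the two labels.
#' @export
significance_regions <- function(a, b) {
  stopifnot(inherits(a, "mean_curve_ci"), inherits(b, "mean_curve_ci"))
  stop_if_grid_mismatch(a, b)
  apart <- (a$ci_low > b$ci_high) | (b$ci_low > a$ci_high)
  r <- rle(apart)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(lo = a$grid[starts[keep]], hi = a$grid[ends[keep]])
  attr(out, "comparison") <- c(a$label %||% "a", b$label %||% "b")
  out
}

#' Crossover point maximizing the cumulative difference of two mean curves
#'
#' The grid location where `|integral_0^x (a.mean - b.mean)|` is maximal.
#' When the two density curves cross, this is their crossover point: below
#' it one condition has accumulated the largest excess probability mass.
#' Ties break toward the smaller x. If the mean curves never cross the
#' result is flagged absent (`crossed = FALSE`, `x = NA`).
#'
#' @param a,b [mean_kde_with_ci()] results on the same grid.
#' @return list with `x` (data units), `cumulative` (signed cumulative
#'   difference at `x`; positive means `a` has more mass below `x`) and
#'   `crossed`.
#' @export
crossover_point <- function(a, b) {
  stopifnot(inherits(a, "mean_curve_ci"), inherits(b, "mean_curve_ci"))
  stop_if_grid_mismatch(a, b)
  d <- a$mean - b$mean
  s <- sign(d)[sign(d) != 0]
  crossed <- length(s) > 0 && any(diff(s) != 0)
  if (!crossed) return(list(x = NA_real_, cumulative = NA_real_,
                            crossed = FALSE))
  cum <- cumtrapz(a$grid, d)
  i <- which.max(abs(cum))
  list(x = a$grid[i], cumulative = cum[i], crossed = TRUE)
}

#' Location of the largest difference in mean probability density
#'
#' The grid point maximizing `|a.mean - b.mean|` (a distinct summary from
#' the cumulative-difference crossover).
#'
#' @param a,b [mean_kde_with_ci()] results on the same grid.
#' @return list with `x` and the signed `difference` at `x`.
#' @export
max_density_difference <- function(a, b) {
  stopifnot(inherits(a, "mean_curve_ci"), inherits(b, "mean_curve_ci"))
  stop_if_grid_mismatch(a, b)
  d <- a$mean - b$mean
  i <- which.max(abs(d))
  list(x = a$grid[i], difference = d[i])
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests the alternative that sample `a` is stochastically larger than
#' sample `b`, using the statistic `D+ = sup_x (ECDF_b(x) - ECDF_a(x))`
#' (when `a` tends to larger values its ECDF lies below `b`'s, making `D+`
#' large). The p-value comes from [stats::ks.test()]: exact for small
#' tie-free samples, otherwise the asymptotic one-sided formula
#' `exp(-2 D^2 n m / (n + m))`.
#'
#' @param a,b numeric samples of at least 5 values each.
#' @param exact passed to [stats::ks.test()] (default: exact when feasible).
#' @return list with `statistic` (D+), `p.value`, `n_a`, `n_b` and the
#'   `alternative` description.
#' @export
ks_one_sided <- function(a, b, exact = NULL) {
  if (length(a) < 5L || length(b) < 5L)
    stop("both samples must have at least 5 values")
  res <- suppressWarnings(stats::ks.test(b, a, alternative = "greater",
                                         exact = exact))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       n_a = length(a), n_b = length(b),
       alternative = "a stochastically larger than b")
}

#' Student-t confidence interval for a mean
#'
#' @param x numeric sample (>= 2 values).
#' @param level confidence level (default 0.834, the band level whose
#'   non-overlap across two groups approximates a 5% two-sided t-test).
#' @return `c(lo, hi)`.
#' @export
t_ci <- function(x, level = 0.834) {
  n <- length(x)
  stopifnot(n >= 2L)
  half <- stats::qt((1 + level) / 2, n - 1L) * stats::sd(x) / sqrt(n)
  c(mean(x) - half, mean(x) + half)
}
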