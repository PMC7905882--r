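# End-to-end pipeline: images -> localizations -> three per-cell
# distributions -> per-condition mean curves with confidence bands ->
# pairwise comparisons (significance regions, crossover points, largest
# density differences, one-sided KS tests).

#' Read and validate a cell manifest
#'
#' The manifest is a CSV with one row per cell and columns `cell_id`,
#' `condition`, `image` (TIFF path), `pixel_size_nm`, and optionally `mask`
#' (TIFF path of a precomputed cell mask). Paths are resolved relative to
#' the manifest's directory when not absolute.
#'
#' @param path manifest CSV path.
#' @return validated manifest data.frame (class `sted_manifest`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "image", "pixel_size_nm")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  m$image <- resolve(m$image)
  if ("mask" %in% names(m)) m$mask <- resolve(m$mask)
  bad <- character(0)
  dup <- m$cell_id[duplicated(m$cell_id)]
  if (length(dup)) bad <- c(bad, paste("duplicate cell_id:",
                                       paste(unique(dup), collapse = ", ")))
  gone <- m$cell_id[!file.exists(m$image)]
  if (length(gone)) bad <- c(bad, paste("missing image for:",
                                        paste(gone, collapse = ", ")))
  px_bad <- m$cell_id[!is.finite(m$pixel_size_nm) | m$pixel_size_nm <= 0]
  if (length(px_bad)) bad <- c(bad, paste("bad pixel size for:",
                                          paste(px_bad, collapse = ", ")))
  if (length(bad)) stop("invalid manifest:\n  ", paste(bad, collapse = "\n  "))
  if (length(unique(m$condition)) < 1L) stop("manifest has no condition groups")
  structure(m, class = c("sted_manifest", "data.frame"))
}

#' Analysis parameters for the cluster statistics stage
#'
#' @param k nearest neighbors per cluster (default 4).
#' @param density_bandwidth 2D density-map kernel bandwidth in nm
#'   (default 200).
#' @param profile_length line-profile length in nm (default 400).
#' @param r2_threshold minimum Lorentzian-fit R^2 (default 0.9).
#' @param ci_level confidence level of the mean band (default 0.834).
#' @param grid_n evaluation-grid size for density curves (default 512).
#' @param kde_bw per-cell KDE bandwidth: `"scott"` or a fixed value in the
#'   analysis' units.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(k = 4L, density_bandwidth = 200,
                            profile_length = 400, r2_threshold = 0.9,
                            ci_level = 0.834, grid_n = 512L,
                            kde_bw = "scott") {
  stopifnot(k >= 1L, density_bandwidth > 0, profile_length > 0,
            ci_level > 0, ci_level < 1, grid_n >= 16L)
  structure(list(k = as.integer(k), density_bandwidth = density_bandwidth,
                 profile_length = profile_length,
                 r2_threshold = r2_threshold, ci_level = ci_level,
                 grid_n = as.integer(grid_n), kde_bw = kde_bw),
            class = "analysis_params")
}

# The three per-cell analyses for one preprocessed cell.
analyze_cell <- function(loc, params) {
  out <- list()
  locs <- loc$localizations
  if (nrow(locs) >= 1L) {
    dm <- density_map(locs, bandwidth = params$density_bandwidth)
    out$density_peaks <- density_peak_intensities(dm)
  } else out$density_peaks <- numeric(0)
  out$nn_distance <- if (nrow(locs) > params$k)
    knn_distances(locs, k = params$k) else NULL
  fw <- cluster_fwhm(loc$image, locs, r2_threshold = params$r2_threshold,
                     profile_length = params$profile_length)
  out$fwhm <- fw$values
  out$log <- c(n_clusters = nrow(locs),
               nn_skipped = as.integer(is.null(out$nn_distance)),
               fwhm_edge_skipped = fw$n_edge_skipped,
               fwhm_no_fit = fw$n_no_fit)
  out
}

#' Run the full analysis pipeline
#'
#' Accepts either a synthetic [generate_dataset()] result, a manifest path,
#' or a [read_manifest()] data.frame; localizes clusters in every cell,
#' computes the three per-cell distributions (density-peak intensities,
#' k-nearest-neighbor distances, cluster FWHMs), and compares all condition
#' pairs per analysis: mean density curves with confidence bands,
#' band-non-overlap significance regions, crossover points, largest mean
#' density differences, and one-sided KS tests on the pooled samples (run
#' in both directions). Per-cell failures are caught, logged and skipped so
#' one bad cell never aborts a batch.
#'
#' @param x input dataset, manifest path, or manifest data.frame.
#' @param preprocess a [preprocess_params()] (its `peak_threshold` is the
#'   batch-level global threshold).
#' @param params an [analysis_params()].
#' @param ... unused.
#' @return object of class `sted_study`; see [print.sted_study()],
#'   [summary.sted_study()], [plot.sted_study()] and [write_study()].
#' @export
run_full_pipeline <- function(x, preprocess, params = analysis_params(), ...) {
  UseMethod("run_full_pipeline")
}

#' @export
run_full_pipeline.character <- function(x, preprocess,
                                        params = analysis_params(), ...) {
  run_full_pipeline(read_manifest(x), preprocess, params)
}

#' @export
run_full_pipeline.sted_manifest <- function(x, preprocess,
                                            params = analysis_params(), ...) {
  cells <- lapply(seq_len(nrow(x)), function(i) {
    list(cell_id = x$cell_id[i], condition = x$condition[i],
         image = read_sted_tiff(x$image[i], x$pixel_size_nm[i]))
  })
  pipeline_core(cells, preprocess, params)
}

#' @export
run_full_pipeline.sted_dataset <- function(x, preprocess,
                                           params = analysis_params(), ...) {
  cells <- lapply(x$cells, function(cl)
    list(cell_id = cl$cell_id, condition = cl$condition, image = cl$image))
  pipeline_core(cells, preprocess, params)
}

pipeline_core <- function(cells, preprocess, params) {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(params, "analysis_params"))
  per_cell <- list()
  loc_rows <- list()
  failures <- list()
  logs <- list()
  for (cl in cells) {
    res <- tryCatch({
      loc <- run_preprocessing(cl$image, preprocess)
      attr(loc$localizations, "cell_id") <- cl$cell_id
      a <- analyze_cell(loc, params)
      list(loc = loc, analysis = a)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[cl$cell_id]] <- conditionMessage(res)
      next
    }
    logs[[cl$cell_id]] <- res$analysis$log
    if (nrow(res$loc$localizations))
      loc_rows[[cl$cell_id]] <- data.frame(
        cell_id = cl$cell_id, condition = cl$condition,
        x_nm = res$loc$localizations$x_nm,
        y_nm = res$loc$localizations$y_nm,
        intensity = res$loc$localizations$intensity)
    per_cell[[cl$cell_id]] <- list(cell_id = cl$cell_id,
                                   condition = cl$condition,
                                   analysis = res$analysis)
  }
  if (!length(per_cell)) stop("every cell failed preprocessing")
  dist_rows <- list()
  for (pc in per_cell) for (an in c("density_peaks", "nn_distance", "fwhm")) {
    v <- pc$analysis[[an]]
    if (length(v))
      dist_rows[[paste(pc$cell_id, an)]] <- data.frame(
        cell_id = pc$cell_id, condition = pc$condition,
        analysis = an, value = v)
  }
  distributions <- do.call(rbind, c(dist_rows, list(make.row.names = FALSE)))
  if (is.null(distributions) || !nrow(distributions))
    stop("no distribution values produced in any cell; check the peak threshold")
  comparisons <- compare_conditions(distributions, params)
  structure(list(
    localizations = do.call(rbind, c(loc_rows, list(make.row.names = FALSE))),
    distributions = distributions,
    curves = comparisons$curves,
    comparisons = comparisons$pairs,
    skipped = comparisons$skipped,
    params = params, preprocess = preprocess,
    cell_log = logs, failures = failures), class = "sted_study")
}

# Build per-condition mean curves and all pairwise comparisons for each
# analysis. Cells with < 2 values are excluded from the curves (warning);
# conditions with < 3 usable cells are skipped in comparisons (warning).
compare_conditions <- function(distributions, params) {
  curves_out <- list(); pairs_out <- list(); skipped <- character(0)
  for (an in unique(distributions$analysis)) {
    sub <- distributions[distributions$analysis == an, ]
    grid <- kde_grid(sub$value, n = params$grid_n, nonnegative = TRUE)
    cond_curves <- list()
    for (cond in unique(sub$condition)) {
      cc <- sub[sub$condition == cond, ]
      mats <- list()
      for (id in unique(cc$cell_id)) {
        v <- cc$value[cc$cell_id == id]
        if (length(v) < 2L) {
          warning(sprintf("cell '%s' has < 2 %s values; excluded from curves",
                          id, an), call. = FALSE)
          next
        }
        mats[[id]] <- per_cell_kde(v, grid, bw = params$kde_bw)
      }
      if (length(mats) < 3L) {
        warning(sprintf("condition '%s' has < 3 usable cells for %s; comparisons skipped",
                        cond, an), call. = FALSE)
        skipped <- c(skipped, sprintf("%s/%s", an, cond))
        next
      }
      cond_curves[[cond]] <- mean_kde_with_ci(do.call(rbind, mats), grid,
                                              level = params$ci_level,
                                              label = cond)
    }
    curves_out[[an]] <- cond_curves
    conds <- names(cond_curves)
    if (length(conds) >= 2L) {
      cmb <- utils::combn(conds, 2L)
      for (ci in seq_len(ncol(cmb))) {
        a <- cmb[1L, ci]; b <- cmb[2L, ci]
        pa <- sub$value[sub$condition == a]
        pb <- sub$value[sub$condition == b]
        key <- sprintf("%s|%s_vs_%s", an, a, b)
        pairs_out[[key]] <- list(
          analysis = an, a = a, b = b,
          regions = significance_regions(cond_curves[[a]], cond_curves[[b]]),
          crossover = crossover_point(cond_curves[[a]], cond_curves[[b]]),
          max_diff = max_density_difference(cond_curves[[a]], cond_curves[[b]]),
          ks_a_gt_b = ks_one_sided(pa, pb),
          ks_b_gt_a = ks_one_sided(pb, pa))
      }
    }
  }
  list(curves = curves_out, pairs = pairs_out, skipped = skipped)
}

#' @export
print.sted_study <- function(x, ...) {
  nloc <- if (is.null(x$localizations)) 0L else nrow(x$localizations)
  cat(sprintf("<sted_study> %d cells, %d localizations, %d comparisons (%d analyses)\n",
              length(x$cell_log), nloc, length(x$comparisons),
              length(x$curves)))
  if (length(x$failures))
    cat("  failed cells:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sted_study <- function(object, ...) {
  cat(sprintf("STED nanocluster study: %d cells, %d localizations\n",
              length(object$cell_log),
              if (is.null(object$localizations)) 0L
              else nrow(object$localizations)))
  logm <- do.call(rbind, object$cell_log)
  if (!is.null(logm)) {
    cat(sprintf("  clusters/cell: median %.0f (range %d-%d)\n",
                stats::median(logm[, "n_clusters"]),
                min(logm[, "n_clusters"]), max(logm[, "n_clusters"])))
    cat(sprintf("  skipped: %d cells for k-NN, %d edge clusters, %d unfit clusters\n",
                sum(logm[, "nn_skipped"]), sum(logm[, "fwhm_edge_skipped"]),
                sum(logm[, "fwhm_no_fit"])))
  }
  for (key in names(object$comparisons)) {
    cmp <- object$comparisons[[key]]
    nr <- nrow(cmp$regions)
    cat(sprintf("  %s %s vs %s: %d significant region(s)%s; crossover %s; KS p(a>b)=%.3g, p(b>a)=%.3g\n",
                cmp$analysis, cmp$a, cmp$b, nr,
                if (nr) paste0(" [", paste(sprintf("%.0f-%.0f", cmp$regions$lo,
                                                   cmp$regions$hi),
                                           collapse = ", "), " nm]") else "",
                if (cmp$crossover$crossed) sprintf("%.0f", cmp$crossover$x)
                else "none",
                cmp$ks_a_gt_b$p.value, cmp$ks_b_gt_a$p.value))
  }
  invisible(object)
}

#' Plot mean density curves with confidence bands and significance bars
#'
#' One panel per analysis: per-condition mean curves, shaded pointwise
#' confidence bands, and colored bars under the curves marking the regions
#' where the bands of a condition pair do not overlap.
#'
#' @param x a `sted_study`.
#' @param analysis which analysis to plot (default all three present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sted_study <- function(x, analysis = names(x$curves), ...) {
  analysis <- match.arg(analysis, names(x$curves), several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(analysis)))
  on.exit(graphics::par(old))
  xlabs <- c(density_peaks = "density peak intensity (clusters/kernel)",
             nn_distance = "nearest-neighbor distance (nm)",
             fwhm = "cluster FWHM (nm)")
  for (an in analysis) {
    curves <- x$curves[[an]]
    if (!length(curves)) next
    cols <- grDevices::hcl.colors(max(3L, length(curves)), "Dark 3")
    ymax <- max(vapply(curves, function(cv) max(cv$ci_high), numeric(1)))
    graphics::plot(NA, xlim = range(curves[[1L]]$grid),
                   ylim = c(-0.12 * ymax, ymax),
                   xlab = xlabs[[an]] %||% an, ylab = "mean density",
                   main = an, ...)
    for (i in seq_along(curves))
      plot(curves[[i]], col = cols[i], add = TRUE)
    keys <- names(x$comparisons)[vapply(x$comparisons, function(cmp)
      cmp$analysis == an, logical(1))]
    for (ki in seq_along(keys)) {
      reg <- x$comparisons[[keys[ki]]]$regions
      if (nrow(reg))
        graphics::segments(reg$lo, -0.04 * ymax * ki, reg$hi,
                           -0.04 * ymax * ki, lwd = 4,
                           col = grDevices::adjustcolor(cols[ki], 0.8))
    }
    graphics::legend("topright", legend = names(curves), lwd = 2,
                     col = cols[seq_along(curves)], bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Write a study's outputs to disk
#'
#' Emits `localizations.csv`, `distributions.csv` (long format: cell_id,
#' condition, analysis, value), `statistics.json` (mean curves, bands,
#' significance regions, crossover points, KS results, run log and all
#' parameters) and one PNG figure per analysis.
#'
#' @param study a `sted_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sted_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(study$localizations))
    utils::write.csv(study$localizations,
                     file.path(dir, "localizations.csv"), row.names = FALSE)
  utils::write.csv(study$distributions,
                   file.path(dir, "distributions.csv"), row.names = FALSE)
  stats_out <- list(
    params = unclass(study$params),
    preprocess = unclass(study$preprocess),
    curves = lapply(study$curves, function(conds)
      lapply(conds, function(cv) cv[c("grid", "mean", "ci_low", "ci_high",
                                      "n_cells", "level")])),
    comparisons = lapply(study$comparisons, function(cmp)
      list(analysis = cmp$analysis, a = cmp$a, b = cmp$b,
           regions = cmp$regions, crossover = cmp$crossover,
           max_diff = cmp$max_diff,
           ks_a_gt_b = cmp$ks_a_gt_b, ks_b_gt_a = cmp$ks_b_gt_a)),
    cell_log = study$cell_log, failures = study$failures,
    skipped = study$skipped)
  jsonlite::write_json(stats_out, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (an in names(study$curves)) {
    if (!length(study$curves[[an]])) next
    grDevices::png(file.path(dir, paste0(an, ".png")), width = 900,
                   height = 600, res = 120)
    plot(study, analysis = an)
    grDevices::dev.off()
  }
  invisible(dir)
}
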