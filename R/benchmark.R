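#' Define a simulation grid over dataset sizes
#'
#' One axis (cells or genes) varies, the other is fixed, mirroring the
#' benchmark design: dispersion level on one axis of each heatmap, dataset
#' size on the other.
#'
#' @param vary_axis `"cells"` or `"genes"`.
#' @param sizes ordered integer vector of sizes for the varying axis.
#' @param fixed size of the fixed axis (genes when cells vary, and vice
#'   versa).
#' @return an object of class `simulation_grid`.
#' @examples
#' simulation_grid("cells", sizes = c(500, 1000, 2000), fixed = 2000)
#' @export
simulation_grid <- function(vary_axis = c("cells", "genes"), sizes, fixed) {
  vary_axis <- match.arg(vary_axis)
  sizes <- as.integer(sizes)
  if (length(sizes) < 1 || any(sizes < 1) || is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly increasing positive integers", call. = FALSE)
  if (fixed < 1) stop("fixed size must be >= 1", call. = FALSE)
  structure(list(
    vary_axis = vary_axis,
    n_genes_list = if (vary_axis == "genes") sizes else as.integer(fixed),
    n_cells_list = if (vary_axis == "cells") sizes else as.integer(fixed),
    sizes = sizes, fixed = as.integer(fixed)),
    class = "simulation_grid")
}

#' Run the dispersion-metric benchmark over a ladder x size grid
#'
#' For each (dispersion level, dataset size) cell, simulates a counts matrix
#' with a seed derived from `seed` and the cell's indices, computes the six
#' per-gene dispersion metrics, and stores their aggregate. With
#' `replicates > 1` the aggregate (never the raw counts) is averaged over
#' independently seeded replicate matrices.
#'
#' @param ladder a [make_ladder()] object.
#' @param grid a [simulation_grid()].
#' @param aggregation `"median"` (default) or `"mean"` across genes.
#' @param seed integer root seed.
#' @param replicates matrices per grid cell (default 1, as in the original
#'   single-matrix design).
#' @param max_entries guard: refuse any single matrix larger than this many
#'   entries (default 2e8).
#' @return an object of class `benchmark_grid`: list with `values` (3-d array
#'   level x size x metric, `NA` where an aggregate is undefined), `ladder`,
#'   `grid`, `aggregation`, `seed`.
#' @export
run_benchmark <- function(ladder, grid, aggregation = c("median", "mean"),
                          seed, replicates = 1L, max_entries = 2e8) {
  stopifnot(inherits(ladder, "dispersion_ladder"),
            inherits(grid, "simulation_grid"))
  aggregation <- match.arg(aggregation)
  sizes <- grid$sizes
  ng0 <- grid$n_genes_list; nc0 <- grid$n_cells_list
  biggest <- max(sizes) * grid$fixed
  if (biggest > max_entries)
    stop(sprintf("grid cell of %g entries exceeds the %g-entry budget; ",
                 biggest, max_entries),
         "raise max_entries to run a larger grid", call. = FALSE)
  values <- array(NA_real_,
                  dim = c(ladder$n_levels, length(sizes), length(.metric_names)),
                  dimnames = list(level = paste0("L", seq_len(ladder$n_levels)),
                                  size = as.character(sizes),
                                  metric = .metric_names))
  for (k in seq_len(ladder$n_levels)) {
    for (j in seq_along(sizes)) {
      ng <- if (grid$vary_axis == "genes") sizes[j] else ng0
      nc <- if (grid$vary_axis == "cells") sizes[j] else nc0
      acc <- matrix(NA_real_, replicates, length(.metric_names))
      for (r in seq_len(replicates)) {
        m <- sample_counts(ladder$levels[[k]], ng, nc,
                           seed = derive_seed(seed, k, j, r),
                           level_index = k)
        acc[r, ] <- metric_panel(m, aggregation)$aggregate
      }
      values[k, j, ] <- colMeans(acc)
    }
  }
  structure(list(values = values, ladder = ladder, grid = grid,
                 aggregation = aggregation, seed = as.integer(seed)),
            class = "benchmark_grid")
}

#' @exportS3Method base::print
print.benchmark_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<benchmark_grid> %s: %d levels x %d sizes x %d metrics\n",
              x$ladder$family, d[1], d[2], d[3]))
  invisible(x)
}

# Coerce the levels x sizes x metrics array out of the accepted inputs.
as_level_array <- function(grid) {
  if (inherits(grid, "benchmark_grid")) return(grid$values)
  if (is.matrix(grid)) {
    a <- array(grid, dim = c(dim(grid), 1),
               dimnames = c(dimnames(grid) %||% list(NULL, NULL),
                            list(metric = "value")))
    return(a)
  }
  if (is.array(grid) && length(dim(grid)) == 3) return(grid)
  stop("expected a benchmark_grid, a level x size matrix, ",
       "or a level x size x metric array", call. = FALSE)
}

#' Relative and ratio change of metric aggregates along the dispersion axis
#'
#' With per-level aggregates `m_1, ..., m_n` (per size, per metric), the
#' relative change is `(m_{k+1} - m_k) / m_k` and the ratio change
#' `m_{k+1} / m_k`, for `k = 1..n-1`. A metric that tracks the theoretical
#' variance exactly has constant relative change `variance_ratio - 1` along
#' the ladder. Entries with `m_k = 0` (or undefined `m`) are flagged `NA`,
#' never dropped silently.
#'
#' @param grid a [run_benchmark()] result, or a plain level x size matrix /
#'   level x size x metric array (levels on the first dimension) — useful for
#'   injecting oracle values such as theoretical variances.
#' @return an object of class `normalized_grid`: list with `relative` and
#'   `ratio` arrays, one shorter than the input along levels.
#' @examples
#' normalize_changes(matrix(c(2, 4, 8), ncol = 1))$relative  # 1, 1
#' @export
normalize_changes <- function(grid) {
  v <- as_level_array(grid)
  if (dim(v)[1] < 2)
    stop("need at least 2 dispersion levels", call. = FALSE)
  n <- dim(v)[1]
  cur <- v[-1, , , drop = FALSE]
  prev <- v[-n, , , drop = FALSE]
  prev_ok <- is.finite(prev) & prev != 0
  ratio <- ifelse(prev_ok & is.finite(cur), cur / prev, NA_real_)
  relative <- ratio - 1
  dn <- dimnames(v) %||% vector("list", 3)
  dn[[1]] <- paste0(dn[[1]][-n] %||% seq_len(n - 1), "->",
                    dn[[1]][-1] %||% (seq_len(n - 1) + 1))
  dim(ratio) <- dim(relative) <- c(n - 1, dim(v)[2:3])
  dimnames(ratio) <- dimnames(relative) <- dn
  structure(list(relative = relative, ratio = ratio),
            class = "normalized_grid")
}

#' Spread of the relative changes around their per-metric mean
#'
#' Quantifies how close a metric comes to the ideal of a constant relative
#' change: per metric, the mean relative change (over all defined entries),
#' every entry's absolute deviation from that mean, and the percentage of
#' entries within each threshold of the mean.
#'
#' @param norm a [normalize_changes()] result.
#' @param thresholds deviation thresholds (default `c(0.01, 0.005, 0.0025)`);
#'   sorted internally in decreasing order.
#' @return an object of class `spread_summary`: list with `mean_relative`
#'   (per metric), `deviations` (list of per-entry |relative - mean|), and
#'   `pct_within` (metric x threshold matrix of percentages).
#' @export
spread_summary <- function(norm, thresholds = c(0.01, 0.005, 0.0025)) {
  stopifnot(inherits(norm, "normalized_grid"))
  thresholds <- sort(thresholds, decreasing = TRUE)
  rel <- norm$relative
  metrics <- dimnames(rel)[[3]] %||% paste0("m", seq_len(dim(rel)[3]))
  mean_rel <- numeric(length(metrics)); names(mean_rel) <- metrics
  devs <- stats::setNames(vector("list", length(metrics)), metrics)
  pct <- matrix(NA_real_, length(metrics), length(thresholds),
                dimnames = list(metrics, format(thresholds)))
  for (i in seq_along(metrics)) {
    x <- rel[, , i]
    x <- x[is.finite(x)]
    if (!length(x)) { mean_rel[i] <- NA_real_; next }
    mean_rel[i] <- mean(x)
    devs[[i]] <- abs(x - mean_rel[i])
    pct[i, ] <- vapply(thresholds,
                       function(t) 100 * mean(devs[[i]] <= t), numeric(1))
  }
  structure(list(mean_relative = mean_rel, deviations = devs,
                 pct_within = pct, thresholds = thresholds),
            class = "spread_summary")
}

#' @exportS3Method base::print
print.spread_summary <- function(x, ...) {
  cat("<spread_summary> mean relative change and % within thresholds\n")
  print(cbind(mean = round(x$mean_relative, 5), round(x$pct_within, 1)))
  invisible(x)
}

#' Export per-metric heatmap tables and images
#'
#' Writes one tab-separated value table and one PNG per metric. Rows are
#' dispersion levels (increasing dispersion), columns dataset sizes; in the
#' images dispersion increases up the y-axis and size along the x-axis. The
#' tables are the testable surface; images are cosmetic.
#'
#' @param x a `benchmark_grid` or `normalized_grid`.
#' @param path output directory (created if needed).
#' @param which for a `normalized_grid`, `"relative"` (default) or `"ratio"`.
#' @param png write images too (default TRUE).
#' @return named character vector of the TSV paths, invisibly.
#' @export
export_heatmaps <- function(x, path, which = c("relative", "ratio"),
                            png = TRUE) {
  v <- if (inherits(x, "normalized_grid")) x[[match.arg(which)]]
       else as_level_array(x)
  if (any(dim(v) == 0)) stop("empty grid", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  metrics <- dimnames(v)[[3]] %||% paste0("m", seq_len(dim(v)[3]))
  out <- character(0)
  for (i in seq_along(metrics)) {
    tab <- v[, , i, drop = TRUE]
    if (is.null(dim(tab))) tab <- matrix(tab, ncol = 1,
                                         dimnames = dimnames(v)[1:2])
    f <- file.path(path, paste0(metrics[i], ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, col.names = NA,
                       na = "NA")
    out[metrics[i]] <- f
    if (png && any(is.finite(tab))) {
      pf <- file.path(path, paste0(metrics[i], ".png"))
      grDevices::png(pf, width = 640, height = 480)
      tryCatch({
        graphics::image(x = seq_len(ncol(tab)), y = seq_len(nrow(tab)),
                        z = t(tab), xlab = "dataset size",
                        ylab = "dispersion level", main = metrics[i],
                        axes = FALSE, col = grDevices::hcl.colors(64, "viridis"))
        graphics::axis(1, at = seq_len(ncol(tab)), labels = colnames(tab))
        graphics::axis(2, at = seq_len(nrow(tab)), labels = rownames(tab))
        graphics::box()
      }, finally = grDevices::dev.off())
    }
  }
  invisible(out)
}
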