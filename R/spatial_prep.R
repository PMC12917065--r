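#' Nearest cancer-cell distance
#'
#' Euclidean distance from each query point to its nearest cancer point.
#' Inputs are in mm (pattern scale); the result is reported in micrometres,
#' the unit of the TIL filter threshold. Computation is exact (all pairs),
#' chunked so memory stays bounded for slide-scale point sets.
#'
#' @param points two-column matrix/data.frame of query (CD8) coordinates, mm.
#' @param cancer_points two-column matrix/data.frame of cancer coordinates, mm.
#' @return numeric vector of distances in um.
#' @export
nearest_cancer_distance <- function(points, cancer_points) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  cancer <- as.matrix(cancer_points)[, 1:2, drop = FALSE]
  if (nrow(cancer) == 0L)
    stop("cancer point set is empty; subject should have been excluded")
  if (nrow(points) == 0L) return(numeric(0))
  out <- numeric(nrow(points))
  chunk <- 1024L
  cx <- cancer[, 1]; cy <- cancer[, 2]
  for (start in seq(1L, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(points))
    dx <- outer(points[idx, 1], cx, "-")
    dy <- outer(points[idx, 2], cy, "-")
    d2 <- dx * dx + dy * dy
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out * 1000
}

#' Select tumor-infiltrating CD8 cells by distance to cancer
#'
#' Restricts the CD8 set of a pattern to cells at most `threshold_um`
#' micrometres from cancer ("less than or equal to", so a cell at exactly
#' the threshold is kept). The platform-provided distance-to-gland column
#' is used when complete for the subject; otherwise the distance to the
#' nearest cancer-cell centroid is computed and the source is recorded on
#' the pattern. The cancer set is never modified.
#'
#' @param pattern `subject_pattern`.
#' @param threshold_um distance threshold in um (default 50).
#' @return filtered `subject_pattern` with `dist_source` set to
#'   `"platform"` or `"centroid"`.
#' @export
filter_tils <- function(pattern, threshold_um = 50) {
  stopifnot(inherits(pattern, "subject_pattern"), threshold_um > 0)
  if (nrow(pattern$cd8) == 0L) {
    pattern$dist_source <- "platform"
    return(pattern)
  }
  if (!anyNA(pattern$cd8$dist_um)) {
    d <- pattern$cd8$dist_um
    pattern$dist_source <- "platform"
  } else {
    d <- nearest_cancer_distance(pattern$cd8[, c("x", "y")], pattern$cancer)
    pattern$cd8$dist_um <- d
    pattern$dist_source <- "centroid"
  }
  pattern$cd8 <- pattern$cd8[d <= threshold_um, , drop = FALSE]
  rownames(pattern$cd8) <- NULL
  pattern
}

#' Tessellate a pattern into a fixed-size quadrat grid
#'
#' Lays a regular square grid over the subject's window, anchored at the
#' window's minimum corner, with `ceiling(extent / cell_size)` rows and
#' columns so partial edge quadrats are included. Each point falls in
#' exactly one quadrat: cells are half-open `[lo, hi)` with the final
#' row/column closed, so no point on the maximum edge is lost. Quadrats
#' with zero counts for both classes are flagged inactive and excluded
#' from all downstream statistics.
#'
#' @param pattern `subject_pattern`.
#' @param cell_size quadrat edge length in mm (default 0.5, i.e.
#'   500 um x 500 um).
#' @return `quadrat_grid` object with integer count matrices
#'   `cancer_counts`, `cd8_counts` (rows index y, columns x) and logical
#'   `active` mask.
#' @export
make_quadrat_grid <- function(pattern, cell_size = 0.5) {
  stopifnot(inherits(pattern, "subject_pattern"), cell_size > 0)
  w <- pattern$window
  width <- w[2] - w[1]; height <- w[4] - w[3]
  if (width <= 0 || height <= 0)
    stop("window has non-positive extent; cannot build quadrats")
  n_cols <- as.integer(ceiling(width / cell_size))
  n_rows <- as.integer(ceiling(height / cell_size))
  count_class <- function(pts) {
    m <- matrix(0L, n_rows, n_cols)
    if (nrow(pts)) {
      j <- pmin(floor((pts$x - w[1]) / cell_size), n_cols - 1L)
      i <- pmin(floor((pts$y - w[3]) / cell_size), n_rows - 1L)
      t <- tabulate(i * n_cols + j + 1L, nbins = n_rows * n_cols)
      m <- matrix(as.integer(t), n_rows, n_cols, byrow = TRUE)
    }
    m
  }
  cancer <- count_class(pattern$cancer)
  cd8 <- count_class(pattern$cd8)
  structure(list(
    subject_id = pattern$subject_id,
    origin = c(w[1], w[3]),
    cell_size = cell_size,
    n_rows = n_rows, n_cols = n_cols,
    cancer_counts = cancer,
    cd8_counts = cd8,
    active = cancer + cd8 > 0L
  ), class = "quadrat_grid")
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf("quadrat_grid: %s  %d x %d cells of %.3g mm (%d active)\n",
              x$subject_id, x$n_rows, x$n_cols, x$cell_size, sum(x$active)))
  cat(sprintf("  totals: %d cancer, %d cd8\n",
              sum(x$cancer_counts), sum(x$cd8_counts)))
  invisible(x)
}

#' Paired active-quadrat counts of a grid
#'
#' Long-format view of the grid restricted to active quadrats, the
#' observation unit of the per-subject count regression.
#'
#' @param grid `quadrat_grid`.
#' @return `data.frame(row, col, cancer, cd8)` over active quadrats.
#' @export
quadrat_counts <- function(grid) {
  stopifnot(inherits(grid, "quadrat_grid"))
  idx <- which(grid$active, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             cancer = grid$cancer_counts[idx],
             cd8 = grid$cd8_counts[idx])
}

#' Quadrat-wise summary statistics
#'
#' Mean and sample standard deviation (denominator n - 1) of the per-class
#' counts over active quadrats. The quadrat-wise SD of cancer counts is
#' the intratumoral-heterogeneity proxy used in the cohort heterogeneity
#' model.
#'
#' @param grid `quadrat_grid`.
#' @return one-row `data.frame`: `subject_id`, `n_active`,
#'   `quadrat_mean_cancer`, `quadrat_sd_cancer`, `quadrat_mean_cd8`,
#'   `quadrat_sd_cd8`.
#' @export
quadrat_summaries <- function(grid) {
  qc <- quadrat_counts(grid)
  if (nrow(qc) < 1L) stop("no active quadrats")
  safe_sd <- function(v) {
    if (length(v) == 1L) {
      warning("single active quadrat; SD reported as 0")
      return(0)
    }
    stats::sd(v)
  }
  data.frame(subject_id = grid$subject_id,
             n_active = nrow(qc),
             quadrat_mean_cancer = mean(qc$cancer),
             quadrat_sd_cancer = safe_sd(qc$cancer),
             quadrat_mean_cd8 = mean(qc$cd8),
             quadrat_sd_cd8 = safe_sd(qc$cd8),
             stringsAsFactors = FALSE)
}

#' Quartic-kernel smoothed intensity surface
#'
#' Kernel density estimate of a point set on a regular raster, using the
#' quartic (biweight) kernel K(u) = 3/pi (1 - |u|^2)^2 for |u| <= 1,
#' scaled to the bandwidth. Intensities are in points per mm^2; no edge
#' correction is applied (the maps are presentation-layer only, no
#' downstream statistic consumes them).
#'
#' @param points two-column matrix/data.frame, mm.
#' @param window `c(xmin, xmax, ymin, ymax)`, mm.
#' @param bandwidth kernel radius, mm (default 0.25 - half a quadrat).
#' @param resolution pixel edge, mm.
#' @return `density_map` object: `values` (rows index y), pixel-centre
#'   coordinates `x`, `y`, and the kernel metadata.
#' @export
density_map <- function(points, window, bandwidth = 0.25, resolution = 0.05) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(points) == 0L) stop("need at least one point")
  nx <- max(1L, as.integer(ceiling((window[2] - window[1]) / resolution)))
  ny <- max(1L, as.integer(ceiling((window[4] - window[3]) / resolution)))
  xc <- window[1] + (seq_len(nx) - 0.5) * resolution
  yc <- window[3] + (seq_len(ny) - 0.5) * resolution
  vals <- matrix(0, ny, nx)
  norm <- 3 / (pi * bandwidth^2)  # integrates to 1 over the support disc
  for (k in seq_len(nrow(points))) {
    px <- points[k, 1]; py <- points[k, 2]
    jx <- which(abs(xc - px) <= bandwidth)
    jy <- which(abs(yc - py) <= bandwidth)
    if (!length(jx) || !length(jy)) next
    u2 <- outer((yc[jy] - py)^2, (xc[jx] - px)^2, "+") / bandwidth^2
    contrib <- ifelse(u2 <= 1, norm * (1 - u2)^2, 0)
    vals[jy, jx] <- vals[jy, jx] + contrib
  }
  structure(list(values = vals, x = xc, y = yc, bandwidth = bandwidth,
                 kernel = "quartic", resolution = resolution,
                 window = window),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density_map: %d x %d pixels of %.3g mm, quartic kernel bw %.3g mm\n",
    nrow(x$values), ncol(x$values), x$resolution, x$bandwidth))
  cat(sprintf("  integral ~ %.2f points\n",
              sum(x$values) * x$resolution^2))
  invisible(x)
}

#' Export a quadrat grid in long format
#'
#' @param grid `quadrat_grid`.
#' @param path output CSV.
#' @export
write_quadrat_csv <- function(grid, path) {
  idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  df <- data.frame(subject_id = grid$subject_id, idx,
                   cancer_count = grid$cancer_counts[as.matrix(idx)],
                   cd8_count = grid$cd8_counts[as.matrix(idx)],
                   active = grid$active[as.matrix(idx)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
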