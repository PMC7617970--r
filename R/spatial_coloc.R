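#' Grid-average pixel intensities
#'
#' Divides one or more pixel-intensity images into non-overlapping
#' `grid_px`-pixel grids (~5 um at 10 px) and averages pixel intensity
#' within each grid; trailing partial grids are averaged over their
#' available pixels so the pixel-weighted global mean is conserved
#' exactly. Distance from each grid centroid to the nearest image edge is
#' reported in micrometres.
#'
#' @param pixels numeric matrix of pixel intensities, or a named list of
#'   such matrices (one per marker) with identical dimensions.
#' @param grid_px grid side length in pixels.
#' @param um_per_px physical pixel size (um).
#' @return a `SpatialGrid` data.frame: `grid_x`, `grid_y`,
#'   `distance_to_edge_um`, `n_pixels`, one intensity column per marker.
#' @export
#' @examples
#' g <- grid_average(matrix(1, 20, 20), grid_px = 10)
#' nrow(g)  # 4 grids
grid_average <- function(pixels, grid_px = 10, um_per_px = 0.5) {
  if (is.matrix(pixels)) pixels <- list(intensity = pixels)
  if (!length(pixels)) stop("empty pixel input", call. = FALSE)
  dims <- dim(pixels[[1]])
  if (any(dims == 0)) stop("empty pixel array", call. = FALSE)
  if (any(dims < grid_px)) {
    stop("image dimensions must be at least grid_px", call. = FALSE)
  }
  for (m in pixels) {
    if (!identical(dim(m), dims)) stop("marker images must share dimensions",
                                       call. = FALSE)
  }
  gx <- ceiling(dims[1] / grid_px)
  gy <- ceiling(dims[2] / grid_px)
  row_bin <- ceiling(seq_len(dims[1]) / grid_px)
  col_bin <- ceiling(seq_len(dims[2]) / grid_px)
  grid <- expand.grid(grid_x = seq_len(gx), grid_y = seq_len(gy),
                      KEEP.OUT.ATTRS = FALSE)
  n_px <- as.vector(table(row_bin)[grid$grid_x] * table(col_bin)[grid$grid_y])
  # centroid of each grid's pixel block, distance to nearest image edge
  row_lo <- (grid$grid_x - 1) * grid_px
  row_hi <- pmin(grid$grid_x * grid_px, dims[1])
  col_lo <- (grid$grid_y - 1) * grid_px
  col_hi <- pmin(grid$grid_y * grid_px, dims[2])
  cx <- (row_lo + row_hi) / 2
  cy <- (col_lo + col_hi) / 2
  grid$distance_to_edge_um <- pmin(cx, dims[1] - cx, cy, dims[2] - cy) * um_per_px
  grid$n_pixels <- n_px
  for (nm in names(pixels)) {
    sums <- tapply(as.vector(pixels[[nm]]),
                   list(row_bin[row(pixels[[nm]])], col_bin[col(pixels[[nm]])]),
                   sum)
    grid[[nm]] <- as.vector(sums[cbind(grid$grid_x, grid$grid_y)]) / n_px
  }
  grid
}

#' Intensity-weighted Gaussian KDE on a spatial grid
#'
#' Smooths a marker's grid intensities by evaluating an intensity-weighted
#' Gaussian kernel density estimate on the grid centroids (Scott's rule
#' bandwidth per dimension).
#'
#' @param grid a `SpatialGrid` data.frame (from [grid_average()] or
#'   [simulate_image_grids()]).
#' @param marker name of the intensity column to smooth.
#' @return numeric vector of non-negative smoothed densities, one per grid.
#' @export
kde_intensity <- function(grid, marker) {
  if (!marker %in% names(grid)) stop("marker column not found", call. = FALSE)
  if (nrow(grid) < 10) stop("need at least 10 grids", call. = FALSE)
  wgt <- grid[[marker]]
  if (all(wgt == 0)) stop("all-zero marker intensities", call. = FALSE)
  pts <- cbind(grid$grid_x, grid$grid_y)
  n <- nrow(pts)
  h <- apply(pts, 2, stats::sd) * n^(-1 / 6)
  h[h == 0] <- 1
  d1 <- outer(pts[, 1], pts[, 1], "-") / h[1]
  d2 <- outer(pts[, 2], pts[, 2], "-") / h[2]
  as.vector(exp(-0.5 * (d1^2 + d2^2)) %*% wgt) / sum(wgt)
}

#' Marker-ratio versus distance to the tumour edge
#'
#' Computes the per-grid F4/80-to-CD11b intensity ratio, its Spearman
#' rank correlation (average ranks for ties) with distance to the tumour
#' edge, and a core mask (`distance > core_cutoff_um`).
#'
#' @param grid a `SpatialGrid` data.frame with `F4_80`, `CD11b` and
#'   `distance_to_edge_um` columns.
#' @param core_cutoff_um grids farther than this from the edge form the
#'   tumour core.
#' @param num,den numerator and denominator intensity columns.
#' @return list with `ratio` (per included grid), `rho`, `p`,
#'   `core_mask`, `included` (row indices with a valid ratio).
#' @export
ratio_vs_edge <- function(grid, core_cutoff_um = 100, num = "F4_80",
                          den = "CD11b") {
  if (!all(c(num, den, "distance_to_edge_um") %in% names(grid))) {
    stop("grid must have intensity and distance columns", call. = FALSE)
  }
  ok <- which(grid[[den]] > 0)
  if (length(ok) < 3) stop("fewer than 3 grids with a valid ratio", call. = FALSE)
  ratio <- grid[[num]][ok] / grid[[den]][ok]
  dist <- grid$distance_to_edge_um[ok]
  ct <- suppressWarnings(
    stats::cor.test(ratio, dist, method = "spearman", exact = FALSE)
  )
  list(ratio = ratio,
       rho = unname(ct$estimate),
       p = ct$p.value,
       core_mask = grid$distance_to_edge_um > core_cutoff_um,
       included = ok)
}

#' Quality-control filtering of spatial spots
#'
#' Removes spots with fewer than `min_counts` total counts or with
#' mitochondrial content strictly above `max_mito`; then removes genes
#' detected in fewer than `min_spots_per_gene` of the retained spots.
#' Idempotent.
#'
#' @param spots a `SpotTable` data.frame: `spot_id`, `x`, `y`,
#'   `mito_fraction`, then one column per gene.
#' @param min_counts minimum total counts per spot (spots below are
#'   removed).
#' @param max_mito spots with mitochondrial fraction strictly above this
#'   are removed.
#' @param min_spots_per_gene genes kept only when detected in at least
#'   this many retained spots.
#' @return the filtered `SpotTable`.
#' @export
filter_spots <- function(spots, min_counts = 500, max_mito = 0.20,
                         min_spots_per_gene = 5) {
  meta_cols <- intersect(c("spot_id", "x", "y", "mito_fraction"), names(spots))
  gene_cols <- setdiff(names(spots), meta_cols)
  counts <- as.matrix(spots[, gene_cols, drop = FALSE])
  keep_spot <- rowSums(counts) >= min_counts & spots$mito_fraction <= max_mito
  if (!any(keep_spot)) stop("filter_spots removed every spot", call. = FALSE)
  counts <- counts[keep_spot, , drop = FALSE]
  keep_gene <- colSums(counts > 0) >= min_spots_per_gene
  if (!any(keep_gene)) stop("filter_spots removed every gene", call. = FALSE)
  out <- cbind(spots[keep_spot, meta_cols, drop = FALSE],
               as.data.frame(counts[, keep_gene, drop = FALSE],
                             check.names = FALSE),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Signature scoring of spatial spots
#'
#' Normalizes the spot-by-gene counts (library-size to 1e4, log1p) and
#' applies the binned-control gene-set score of [score_gene_set()] to
#' each spot.
#'
#' @param spots a (filtered) `SpotTable`.
#' @param signature a [gene_set()] or character vector (e.g. the
#'   monocyte/macrophage or CD4 T-cell marker panels).
#' @param n_bins,n_ctrl,seed passed to [score_gene_set()].
#' @return named numeric vector of per-spot scores.
#' @export
score_spots <- function(spots, signature, n_bins = 25, n_ctrl = 50, seed = 1L) {
  meta_cols <- intersect(c("spot_id", "x", "y", "mito_fraction"), names(spots))
  gene_cols <- setdiff(names(spots), meta_cols)
  counts <- t(as.matrix(spots[, gene_cols, drop = FALSE]))
  colnames(counts) <- spots$spot_id
  norm <- normalize_log1p(Matrix::Matrix(counts, sparse = TRUE))
  score_gene_set(norm, signature, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
}

#' Spot classification and chemokine co-localization
#'
#' Applies the raw-count positivity rules: a monocyte/macrophage spot has
#' CD68 > 0 and CD14 > 0; a CD4 T-cell spot has TRAC > 0 and CD4 > 0;
#' co-localized spots are the intersection. Among co-localized spots, the
#' chemokine-positive fraction is the share with CXCL9 > 0 or CXCL10 > 0
#' (missing when there are no co-localized spots).
#'
#' @param spots a (filtered) `SpotTable`.
#' @return list with `mac_spots`, `cd4_spots`, `coloc_spots` (character
#'   spot ids) and `chemokine_positive_fraction`.
#' @export
classify_and_colocalize <- function(spots) {
  need <- c("CD68", "CD14", "TRAC", "CD4")
  missing <- setdiff(need, names(spots))
  if (length(missing)) {
    stop("spot table lacks marker gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mac <- spots$CD68 > 0 & spots$CD14 > 0
  cd4 <- spots$TRAC > 0 & spots$CD4 > 0
  coloc <- mac & cd4
  chem9 <- if ("CXCL9" %in% names(spots)) spots$CXCL9 > 0 else FALSE
  chem10 <- if ("CXCL10" %in% names(spots)) spots$CXCL10 > 0 else FALSE
  chem <- chem9 | chem10
  frac <- if (any(coloc)) mean(chem[coloc]) else NA_real_
  list(
    mac_spots = spots$spot_id[mac],
    cd4_spots = spots$spot_id[cd4],
    coloc_spots = spots$spot_id[coloc],
    chemokine_positive_fraction = frac
  )
}
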