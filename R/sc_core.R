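#' Quality-control filtering of cells and genes
#'
#' Removes cells whose detected-gene count falls outside
#' `[min_genes, max_genes]` (cells with fewer than `min_genes` or more than
#' `max_genes` detected genes are filtered) or whose mitochondrial fraction
#' is at or above `max_mito`; then removes genes detected in fewer than
#' `min_cells_per_gene` of the retained cells. Order is preserved and the
#' operation is idempotent.
#'
#' @param x a [cell_matrix()].
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito cells are retained only when mitochondrial fraction is
#'   strictly below this cut-off.
#' @param min_cells_per_gene genes must be detected in at least this many
#'   retained cells.
#' @param mito_prefix gene-symbol prefix used to compute the mitochondrial
#'   fraction when the metadata lacks a `mito_fraction` column (mouse
#'   nomenclature by default).
#' @return the filtered [cell_matrix()].
#' @export
#' @examples
#' sim <- simulate_cell_matrix(sim_config(n_cells = 100, n_genes = 60, seed = 1))
#' qc <- qc_filter(sim$matrix, min_genes = 5, max_genes = 60)
qc_filter <- function(x, min_genes = 1000, max_genes = 6000, max_mito = 0.075,
                      min_cells_per_gene = 3, mito_prefix = "mt-") {
  stopifnot(inherits(x, "cell_matrix"))
  detected <- Matrix::colSums(x$counts > 0)
  mito <- x$cell_metadata$mito_fraction
  if (is.null(mito)) mito <- mito_fraction_from_counts(x, mito_prefix)
  keep_cells <- detected >= min_genes & detected <= max_genes & mito < max_mito
  if (!any(keep_cells)) {
    stop("qc_filter removed every cell; relax the thresholds", call. = FALSE)
  }
  out <- subset_cells(x, cells = which(keep_cells))
  gene_cells <- Matrix::rowSums(out$counts > 0)
  keep_genes <- gene_cells >= min_cells_per_gene
  if (!any(keep_genes)) {
    stop("qc_filter removed every gene; relax the thresholds", call. = FALSE)
  }
  subset_cells(out, genes = which(keep_genes))
}

#' Library-size normalization with log1p transform
#'
#' Scales each cell's counts to sum to `target_sum`, then applies
#' `log(1 + x)`. This is the standard "normalize to 1e4 and log1p"
#' transform of the single-cell ecosystem.
#'
#' @param x a [cell_matrix()] or a gene-by-cell count matrix.
#' @param target_sum per-cell total after scaling.
#' @return a gene-by-cell matrix (sparse when the input is sparse) of
#'   normalized log expression.
#' @export
#' @examples
#' m <- cell_matrix(matrix(c(1, 3, 6, 2, 2, 2), nrow = 3,
#'                         dimnames = list(c("a", "b", "c"), c("c1", "c2"))))
#' normalize_log1p(m, target_sum = 100)
normalize_log1p <- function(x, target_sum = 1e4) {
  counts <- if (inherits(x, "cell_matrix")) x$counts else x
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0] %||% which(tot == 0)
    stop(sprintf("cell(s) with zero total counts: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / tot)
  dimnames(scaled) <- dimnames(counts)
  log1p(scaled)
}

#' Highly-variable gene selection
#'
#' Computes per-gene mean and dispersion (variance / mean) of the
#' normalized expression, z-normalizes the dispersion within
#' equal-frequency bins of the mean, and keeps genes with
#' `min_mean <= mean <= max_mean` and normalized dispersion
#' `>= min_dispersion`.
#'
#' @param normalized gene-by-cell normalized expression matrix (output of
#'   [normalize_log1p()]).
#' @param min_mean,max_mean mean-expression bounds.
#' @param min_dispersion minimum normalized dispersion.
#' @param n_bins number of equal-frequency mean bins for dispersion
#'   normalization.
#' @return data.frame with `gene`, `mean`, `dispersion`,
#'   `dispersion_norm`, `highly_variable`; genes in input order.
#' @export
select_hvg <- function(normalized, min_mean = 0.0125, max_mean = 3,
                       min_dispersion = 0.5, n_bins = 20) {
  m <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  v <- (ex2 - m^2) * ncol(normalized) / max(ncol(normalized) - 1, 1)
  disp <- ifelse(m > 0, v / m, 0)
  # equal-frequency bins on the mean; z-score the dispersion within bins
  n_bins <- max(1L, min(n_bins, length(unique(m))))
  br <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2) {
    factor(rep(1L, length(m)))
  } else {
    cut(m, breaks = br, include.lowest = TRUE)
  }
  bin_mean <- stats::ave(disp, bin, FUN = mean)
  bin_sd <- stats::ave(disp, bin, FUN = stats::sd)
  bin_sd[is.na(bin_sd) | bin_sd == 0] <- 1
  disp_norm <- (disp - bin_mean) / bin_sd
  hv <- m >= min_mean & m <= max_mean & disp_norm >= min_dispersion
  if (sum(hv) < 2) {
    stop("fewer than 2 genes pass the highly-variable thresholds", call. = FALSE)
  }
  data.frame(
    gene = rownames(normalized) %||% sprintf("gene_%05d", seq_along(m)),
    mean = m, dispersion = disp, dispersion_norm = disp_norm,
    highly_variable = hv, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Gene-set scoring with expression-matched controls
#'
#' Scores each cell as the mean normalized expression of the set genes
#' minus the mean expression of control genes drawn from
#' expression-matched bins: genes are binned into `n_bins` equal-frequency
#' bins of their average expression, and for each set gene `n_ctrl`
#' controls are sampled (without replacement, set genes excluded) from its
#' bin. Deterministic given `seed`.
#'
#' @param normalized gene-by-cell normalized expression matrix.
#' @param gene_set a [gene_set()] or character vector of gene symbols.
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
score_gene_set <- function(normalized, gene_set, n_bins = 25, n_ctrl = 50,
                           seed = 1L) {
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else as.character(gene_set)
  all_genes <- rownames(normalized)
  if (is.null(all_genes)) stop("normalized matrix must have gene row names", call. = FALSE)
  present <- intersect(genes, all_genes)
  if (length(present) == 0) {
    stop(sprintf("no gene of the set is present in the matrix; missing: %s",
                 paste(utils::head(genes, 10), collapse = ", ")), call. = FALSE)
  }
  avg <- Matrix::rowMeans(normalized)
  n_bins <- max(1L, min(n_bins, length(unique(avg))))
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2) {
    rep(1L, length(avg))  # all means identical: a single bin
  } else {
    as.integer(cut(avg, breaks = br, include.lowest = TRUE))
  }
  names(bin) <- all_genes
  # per bin: sample up to n_ctrl controls per resident set gene (without
  # replacement); the control profile is the set-gene-weighted average of
  # the per-bin control means, so exhausted bins keep their proper weight
  ctrl_sum <- rep(0, ncol(normalized))
  wt_sum <- 0
  with_rng(sub_seed(seed, "score_gene_set"), {
    for (b in unique(bin[present])) {
      k_b <- sum(bin[present] == b)
      pool <- setdiff(all_genes[bin == b], present)
      if (length(pool) == 0) next
      want <- n_ctrl * k_b
      take <- if (length(pool) <= want) pool else sample(pool, want)
      ctrl_sum <- ctrl_sum +
        k_b * Matrix::colMeans(normalized[take, , drop = FALSE])
      wt_sum <- wt_sum + k_b
    }
  })
  set_mean <- Matrix::colMeans(normalized[present, , drop = FALSE])
  ctrl_mean <- if (wt_sum > 0) ctrl_sum / wt_sum else rep(0, ncol(normalized))
  score <- set_mean - ctrl_mean
  names(score) <- colnames(normalized)
  score
}

#' Per-cell embedding density by Gaussian KDE
#'
#' Evaluates, within each group, a Gaussian kernel density estimate of the
#' group's cells in a 2-D embedding at every cell, then rescales densities
#' to [0, 1] within the group. Bandwidths follow Scott's rule per
#' dimension.
#'
#' @param embedding n-by-2 matrix of coordinates (e.g. a UMAP).
#' @param group_labels per-cell grouping; a single group when NULL.
#' @return numeric vector of rescaled densities in [0, 1], one per cell.
#' @export
embedding_density <- function(embedding, group_labels = NULL) {
  embedding <- as.matrix(embedding)
  if (ncol(embedding) != 2) stop("embedding must have 2 columns", call. = FALSE)
  n <- nrow(embedding)
  if (is.null(group_labels)) group_labels <- rep("all", n)
  if (length(group_labels) != n) {
    stop("group_labels must have one entry per cell", call. = FALSE)
  }
  out <- numeric(n)
  for (g in unique(group_labels)) {
    idx <- which(group_labels == g)
    if (length(idx) < 10) {
      stop(sprintf("group '%s' has fewer than 10 cells", g), call. = FALSE)
    }
    pts <- embedding[idx, , drop = FALSE]
    sds <- apply(pts, 2, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("degenerate embedding in group '%s' (zero spread)", g),
           call. = FALSE)
    }
    h <- sds * length(idx)^(-1 / 6)  # Scott's rule, d = 2
    d1 <- outer(pts[, 1], pts[, 1], "-") / h[1]
    d2 <- outer(pts[, 2], pts[, 2], "-") / h[2]
    dens <- rowMeans(exp(-0.5 * (d1^2 + d2^2)))
    rng <- range(dens)
    out[idx] <- if (rng[2] > rng[1]) (dens - rng[1]) / (rng[2] - rng[1]) else 1
  }
  names(out) <- rownames(embedding)
  out
}
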