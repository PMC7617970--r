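#' Random partition of cells into artificial replicates
#'
#' Uniformly assigns cells to `n_replicates` pseudo-replicates whose sizes
#' differ by at most one, reproducibly given `seed`.
#'
#' @param cell_ids character or integer identifiers of the cells.
#' @param n_replicates number of replicates (>= 2, <= number of cells).
#' @param seed integer seed.
#' @return integer vector of replicate indices (1..n_replicates), named by
#'   cell id.
#' @export
#' @examples
#' table(partition_cells(letters[1:10], 3, seed = 1))
partition_cells <- function(cell_ids, n_replicates, seed = 1L) {
  n <- length(cell_ids)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (n_replicates > n) stop("n_replicates exceeds the number of cells", call. = FALSE)
  with_rng(seed, {
    assignment <- rep_len(seq_len(n_replicates), n)[sample.int(n)]
    names(assignment) <- as.character(cell_ids)
    assignment
  })
}

#' Aggregate raw counts into pseudo-bulk replicates
#'
#' Sums filtered, raw counts (prior to any normalization or transform)
#' over the cells of each replicate.
#'
#' @param x a [cell_matrix()] or gene-by-cell count matrix.
#' @param assignment replicate assignment as returned by
#'   [partition_cells()]; must cover every cell.
#' @return gene-by-replicate integer matrix.
#' @export
aggregate_counts <- function(x, assignment) {
  counts <- if (inherits(x, "cell_matrix")) x$counts else x
  if (length(assignment) != ncol(counts)) {
    stop("assignment must cover every cell", call. = FALSE)
  }
  if (anyNA(assignment)) stop("assignment contains unassigned cells", call. = FALSE)
  reps <- sort(unique(assignment))
  design <- Matrix::sparseMatrix(
    i = seq_along(assignment),
    j = match(assignment, reps),
    x = 1,
    dims = c(length(assignment), length(reps))
  )
  pb <- as.matrix(counts %*% design)
  dimnames(pb) <- list(rownames(counts), paste0("rep_", reps))
  pb
}

#' Median-of-ratios size factors
#'
#' For each replicate, the size factor is the median over reference genes
#' of the count divided by that gene's geometric mean across replicates.
#' Reference genes are those with nonzero counts in every replicate.
#'
#' @param pb gene-by-replicate count matrix.
#' @return positive numeric vector of size factors, one per replicate.
#' @export
#' @examples
#' pb <- rbind(g1 = c(2, 4), g2 = c(4, 8), g3 = c(6, 12))
#' size_factors_median_of_ratios(pb)  # 0.7071 1.4142
size_factors_median_of_ratios <- function(pb) {
  pb <- as.matrix(pb)
  ref <- rowSums(pb > 0) == ncol(pb)
  if (!any(ref)) {
    stop("no reference gene with nonzero counts in every replicate", call. = FALSE)
  }
  logg <- rowMeans(log(pb[ref, , drop = FALSE]))
  sf <- apply(pb[ref, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logg))
  })
  sf
}

#' Method-of-moments NB dispersion
#'
#' Estimates a per-gene negative-binomial dispersion alpha from normalized
#' counts by pooling the moment estimator `(s^2 - mu) / mu^2` within
#' groups (weighted by residual degrees of freedom) and flooring at
#' `floor`.
#'
#' @param pb gene-by-replicate count matrix.
#' @param size_factors per-replicate size factors.
#' @param groups optional per-replicate group labels; a single group when
#'   NULL.
#' @param floor lower bound applied to the estimate.
#' @return numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(pb, size_factors, groups = NULL, floor = 1e-8) {
  pb <- as.matrix(pb)
  y <- sweep(pb, 2L, size_factors, "/")
  if (is.null(groups)) groups <- rep("all", ncol(pb))
  groups <- as.factor(groups)
  num <- 0
  den <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    yg <- y[, cols, drop = FALSE]
    mu <- rowMeans(yg)
    s2 <- rowSums((yg - mu)^2) / (length(cols) - 1)
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    w <- length(cols) - 1
    num <- num + w * a
    den <- den + w
  }
  if (all(den == 0)) stop("need at least 2 replicates in some group", call. = FALSE)
  pmax(num / den, floor)
}

# Vectorized two-group NB GLM (log link, fixed dispersion) across genes.
# Returns MLE intercept/slope on the natural-log scale plus observed-
# information standard errors of the slope.
nb_glm_two_group <- function(pb, x_ind, size_factors, dispersions,
                             max_iter = 100L, tol = 1e-10, beta_cap = 30) {
  pb <- as.matrix(pb)
  G <- nrow(pb)
  nA <- sum(x_ind == 0)
  nB <- sum(x_ind == 1)
  y <- sweep(pb, 2L, size_factors, "/")
  mA <- rowSums(y[, x_ind == 0, drop = FALSE]) / nA
  mB <- rowSums(y[, x_ind == 1, drop = FALSE]) / nB
  eps <- 1e-8
  b0 <- log(pmax(mA, eps))
  b1 <- log(pmax(mB, eps)) - log(pmax(mA, eps))
  off <- matrix(log(size_factors), nrow = G, ncol = ncol(pb), byrow = TRUE)
  X1 <- matrix(x_ind, nrow = G, ncol = ncol(pb), byrow = TRUE)
  alpha <- rep_len(dispersions, G)
  for (iter in seq_len(max_iter)) {
    eta <- off + b0 + b1 * X1
    mu <- exp(pmin(eta, 700))
    w <- mu / (1 + alpha * mu)            # expected information weights
    u <- (pb - mu) * (1 / (1 + alpha * mu))  # score contribution d l / d eta
    s_w <- rowSums(w); s_wx <- rowSums(w * X1)
    s_u <- rowSums(u); s_ux <- rowSums(u * X1)
    det <- s_w * s_wx - s_wx^2  # X = [1, x]: A11=s_w, A12=A22=s_wx
    det <- pmax(det, 1e-300)
    d0 <- (s_wx * s_u - s_wx * s_ux) / det
    d1 <- (s_w * s_ux - s_wx * s_u) / det
    d0[!is.finite(d0)] <- 0
    d1[!is.finite(d1)] <- 0
    b0 <- pmin(pmax(b0 + d0, -beta_cap), beta_cap)
    b1 <- pmin(pmax(b1 + d1, -beta_cap), beta_cap)
    if (max(abs(d0), abs(d1)) < tol) break
  }
  eta <- off + b0 + b1 * X1
  mu <- exp(pmin(eta, 700))
  # observed information: d^2(-l)/d eta^2 = (k * alpha + 1) mu / (1 + alpha mu)^2
  wo <- (pb * alpha + 1) * mu / (1 + alpha * mu)^2
  s_w <- rowSums(wo); s_wx <- rowSums(wo * X1)
  det <- pmax(s_w * s_wx - s_wx^2, 1e-300)
  se1 <- sqrt(s_w / det)
  list(b0 = b0, b1 = b1, se1 = se1)
}

#' Per-gene NB Wald test between two groups
#'
#' Fits, per gene, a negative-binomial log-link model with a group
#' indicator (size factors as offsets, dispersion fixed) by Fisher-scoring
#' maximum likelihood. The statistic is the log2 fold change divided by
#' its standard error (observed Fisher information); p-values are
#' two-sided normal. Genes with zero counts everywhere are reported as
#' missing.
#'
#' @param pb gene-by-replicate count matrix.
#' @param groups per-replicate labels with exactly 2 levels; the fold
#'   change is second level over first.
#' @param size_factors per-replicate size factors.
#' @param dispersions per-gene NB dispersion (scalar recycled).
#' @return data.frame with `gene`, `lfc` (log2), `se`, `stat`, `p`.
#' @export
wald_test <- function(pb, groups, size_factors, dispersions) {
  pb <- as.matrix(pb)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly 2 groups are required", call. = FALSE)
  if (min(table(groups)) < 2) stop("need >= 2 replicates per group", call. = FALSE)
  x_ind <- as.integer(groups == levels(groups)[2])
  fit <- nb_glm_two_group(pb, x_ind, size_factors, dispersions)
  lfc <- fit$b1 / log(2)
  se <- fit$se1 / log(2)
  stat <- fit$b1 / fit$se1
  p <- 2 * stats::pnorm(-abs(stat))
  allzero <- rowSums(pb) == 0
  lfc[allzero] <- NA_real_; se[allzero] <- NA_real_
  stat[allzero] <- NA_real_; p[allzero] <- NA_real_
  data.frame(
    gene = rownames(pb) %||% sprintf("gene_%05d", seq_len(nrow(pb))),
    lfc = lfc, se = se, stat = stat, p = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Design for bootstrap pseudo-bulk differential expression
#'
#' @param group_labels per-cell labels with exactly 2 levels (e.g.
#'   Kaede-red vs Kaede-green, or anti-PD-L1 vs isotype).
#' @param n_replicates_per_group artificial replicates formed per group.
#' @param n_iterations random-partition iterations (>= 10 by default, to
#'   honour the more-than-ten-iterations averaging rule).
#' @param seed master seed.
#' @param resample_cells if TRUE, cells are resampled with replacement
#'   within each group before partitioning (bootstrap mode); default is
#'   plain random partitioning.
#' @param enforce_min_iterations set FALSE to permit fewer than 10
#'   iterations (test mode).
#' @return a `pseudobulk_design` list.
#' @export
pseudobulk_design <- function(group_labels, n_replicates_per_group = 3,
                              n_iterations = 11, seed = 1L,
                              resample_cells = FALSE,
                              enforce_min_iterations = TRUE) {
  groups <- as.factor(group_labels)
  if (nlevels(groups) != 2) stop("exactly 2 groups are required", call. = FALSE)
  check_positive_count(n_replicates_per_group, "n_replicates_per_group")
  check_positive_count(n_iterations, "n_iterations")
  if (enforce_min_iterations && n_iterations < 10) {
    stop("n_iterations must be >= 10 (set enforce_min_iterations = FALSE to override)",
         call. = FALSE)
  }
  if (min(table(groups)) < n_replicates_per_group) {
    stop("each group needs at least n_replicates_per_group cells", call. = FALSE)
  }
  structure(
    list(groups = groups, n_replicates_per_group = n_replicates_per_group,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         resample_cells = resample_cells),
    class = "pseudobulk_design"
  )
}

#' Bootstrap pseudo-bulk differential expression
#'
#' Repeats, for `n_iterations` independent sub-seeded iterations: random
#' sorting of each group's cells into artificial replicates, aggregation
#' of raw counts, median-of-ratios size factors, method-of-moments
#' dispersion, and a per-gene NB Wald test. The rank metric is the
#' arithmetic mean of the per-iteration Wald statistics; per-iteration
#' p-values are retained (they are never averaged).
#'
#' @param x a [cell_matrix()] or gene-by-cell count matrix of raw counts.
#' @param design a [pseudobulk_design()].
#' @return object of class `de_result`: list with `table` (per-gene
#'   summary: `gene`, `lfc_mean`, `wald_mean`, `wald_sd`, `p_min`,
#'   `p_median`), iteration matrices `wald_iterations`, `lfc_iterations`,
#'   `p_iterations`, per-iteration `size_factors` and `dispersions`, and
#'   the design.
#' @export
bootstrap_de <- function(x, design) {
  stopifnot(inherits(design, "pseudobulk_design"))
  counts <- if (inherits(x, "cell_matrix")) x$counts else x
  groups <- design$groups
  if (length(groups) != ncol(counts)) {
    stop("design group labels must cover every cell", call. = FALSE)
  }
  G <- nrow(counts)
  iters <- design$n_iterations
  lev <- levels(groups)
  stat_m <- matrix(NA_real_, G, iters)
  lfc_m <- matrix(NA_real_, G, iters)
  p_m <- matrix(NA_real_, G, iters)
  sf_list <- vector("list", iters)
  disp_list <- vector("list", iters)
  for (it in seq_len(iters)) {
    it_seed <- sub_seed(design$seed, "bootstrap_de", it)
    cols <- list()
    rep_groups <- character(0)
    for (gi in seq_along(lev)) {
      idx <- which(groups == lev[gi])
      if (design$resample_cells) {
        idx <- with_rng(sub_seed(it_seed, "resample", gi),
                        sample(idx, length(idx), replace = TRUE))
      }
      assign_g <- partition_cells(idx, design$n_replicates_per_group,
                                  seed = sub_seed(it_seed, "partition", gi))
      pb_g <- aggregate_counts(counts[, idx, drop = FALSE], unname(assign_g))
      colnames(pb_g) <- sprintf("%s_rep%d", lev[gi], seq_len(ncol(pb_g)))
      cols[[gi]] <- pb_g
      rep_groups <- c(rep_groups, rep(lev[gi], ncol(pb_g)))
    }
    pb <- do.call(cbind, cols)
    sf <- size_factors_median_of_ratios(pb)
    disp <- estimate_dispersion(pb, sf, groups = rep_groups)
    res <- wald_test(pb, rep_groups, sf, disp)
    stat_m[, it] <- res$stat
    lfc_m[, it] <- res$lfc
    p_m[, it] <- res$p
    sf_list[[it]] <- sf
    disp_list[[it]] <- disp
  }
  gene <- rownames(counts) %||% sprintf("gene_%05d", seq_len(G))
  rownames(stat_m) <- rownames(lfc_m) <- rownames(p_m) <- gene
  tab <- data.frame(
    gene = gene,
    lfc_mean = rowMeans(lfc_m),
    wald_mean = rowMeans(stat_m),
    wald_sd = apply(stat_m, 1, stats::sd),
    p_min = apply(p_m, 1, function(r) {
      if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)
    }),
    p_median = apply(p_m, 1, stats::median),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(table = tab, wald_iterations = stat_m, lfc_iterations = lfc_m,
         p_iterations = p_m, size_factors = sf_list,
         dispersions = disp_list, design = design),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes, %d iterations, groups: %s\n",
              nrow(x$table), ncol(x$wald_iterations),
              paste(levels(x$design$groups), collapse = " vs ")))
  print(utils::head(x$table))
  invisible(x)
}
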