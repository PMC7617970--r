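#' Rank metric from a differential-expression result
#'
#' Orders genes by the averaged Wald statistic, descending, breaking ties
#' lexicographically by gene identifier for determinism. Genes with a
#' missing statistic are dropped with a message.
#'
#' @param de a `de_result` from [bootstrap_de()], its `table`, or any
#'   data.frame with `gene` and a statistic column (`wald_mean` or `stat`).
#' @return named numeric vector of statistics, sorted descending; names
#'   are gene identifiers.
#' @export
rank_metric <- function(de) {
  tab <- if (inherits(de, "de_result")) de$table else as.data.frame(de)
  if (nrow(tab) == 0) stop("empty differential-expression result", call. = FALSE)
  stat_col <- intersect(c("wald_mean", "stat"), names(tab))[1]
  if (is.na(stat_col)) stop("no statistic column found", call. = FALSE)
  s <- tab[[stat_col]]
  names(s) <- tab$gene
  drop <- !is.finite(s)
  if (any(drop)) {
    message(sprintf("rank_metric: dropping %d gene(s) with missing statistics",
                    sum(drop)))
    s <- s[!drop]
  }
  if (length(s) == 0) stop("no gene with a finite statistic", call. = FALSE)
  ord <- order(-s, names(s), method = "radix")
  s[ord]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic pre-ranked GSEA running sum: walking down the ranked list, set
#' members ("hits") add `|score|^p / sum_set(|score|^p)` and non-members
#' subtract `1 / (N - N_set)`. The enrichment score is the running-sum
#' value of maximum absolute deviation from zero (signed; ties broken by
#' first occurrence along the list).
#'
#' @param ranked named numeric vector of scores, ordered as produced by
#'   [rank_metric()]. The given order is honoured.
#' @param set a [gene_set()] or character vector of member genes; must hit
#'   at least one ranked gene and not cover the whole list.
#' @param p hit-weight exponent (1 = classic weighted statistic).
#' @return list of class `gsea_es` with `es`, `running_sum`, `peak`
#'   (index of the extreme), `hit_positions`, `n`, `set_name`.
#' @export
#' @examples
#' r <- c(a = 4, b = 3, c = 2, d = 1)
#' enrichment_score(r, "a")$es  # 1
enrichment_score <- function(ranked, set, p = 1) {
  genes <- names(ranked)
  if (is.null(genes)) stop("ranked scores must be named by gene", call. = FALSE)
  set_name <- if (inherits(set, "gene_set")) set$name else NA_character_
  set_genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  hit <- genes %in% set_genes
  n <- length(ranked)
  m <- sum(hit)
  if (m == 0) stop("no set gene present in the ranked list", call. = FALSE)
  if (m == n) stop("set covers the whole ranked list", call. = FALSE)
  w <- abs(ranked)^p
  w_hit_sum <- sum(w[hit])
  inc <- if (w_hit_sum > 0) w / w_hit_sum else rep(1 / m, n)
  step <- ifelse(hit, inc, -1 / (n - m))
  running <- cumsum(step)
  peak <- which.max(abs(running))
  structure(
    list(es = running[[peak]], running_sum = unname(running), peak = peak,
         hit_positions = which(hit), n = n, set_name = set_name),
    class = "gsea_es"
  )
}

# ES from sorted hit positions only (O(m)); used by the permutation null.
# `w` = |score|^p over the full list; `pos` = sorted hit positions (matrix
# with one column per draw). Returns the signed ES per column.
es_from_positions <- function(w, pos) {
  pos <- as.matrix(pos)
  m <- nrow(pos); B <- ncol(pos); n <- length(w)
  wh <- matrix(w[pos], m, B)
  cumw <- apply(wh, 2L, cumsum)
  tot <- cumw[m, , drop = TRUE]
  zero <- tot == 0
  if (any(zero)) {
    cumw[, zero] <- matrix(seq_len(m) / m, m, sum(zero))
    tot[zero] <- 1
    wh[, zero] <- 1 / m
  }
  miss <- (pos - seq_len(m)) / (n - m)
  at_hit <- sweep(cumw, 2L, tot, "/") - miss          # value just after each hit
  before <- at_hit - sweep(wh, 2L, tot, "/")          # value just before each hit
  hi <- apply(at_hit, 2L, max)
  lo <- apply(before, 2L, min)
  ifelse(hi >= -lo, hi, lo)
}

#' Permutation test for a pre-ranked enrichment score
#'
#' Builds a null distribution of enrichment scores from `n_perm` random
#' gene-label permutations of the set (same size, positions drawn
#' uniformly), normalizes the observed score by the mean absolute null
#' score of matching sign (NES), and reports
#' `p = (1 + #{same-sign null at least as extreme}) / (1 + #same-sign null)`.
#'
#' @param ranked named numeric scores as in [enrichment_score()].
#' @param set gene set (vector or [gene_set()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param p hit-weight exponent.
#' @return list with `es`, `nes`, `p`, `n_perm`, `n_same_sign`, and the
#'   observed `gsea_es` object as `es_object`.
#' @export
permutation_test <- function(ranked, set, n_perm = 1000, seed = 1L, p = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- enrichment_score(ranked, set, p = p)
  n <- obs$n
  m <- length(obs$hit_positions)
  w <- abs(ranked)^p
  null_es <- with_rng(sub_seed(seed, "permutation_test"), {
    pos <- vapply(seq_len(n_perm),
                  function(i) sort.int(sample.int(n, m)),
                  integer(m))
    es_from_positions(w, matrix(pos, nrow = m))
  })
  same <- sign(null_es) == sign(obs$es) & null_es != 0
  if (!any(same)) {
    warning("no same-sign null enrichment scores; p floored at 1/(1 + n_perm)")
    nes <- obs$es / mean(abs(null_es))
    pval <- 1 / (1 + n_perm)
  } else {
    nes <- obs$es / mean(abs(null_es[same]))
    pval <- (1 + sum(abs(null_es[same]) >= abs(obs$es))) / (1 + sum(same))
  }
  list(es = obs$es, nes = nes, p = pval, n_perm = n_perm,
       n_same_sign = sum(same), es_object = obs)
}

#' Leading-edge genes of an enrichment score
#'
#' For a positive score, the set genes ranked at or before the
#' running-sum peak; for a negative score, the set genes at or after the
#' trough. A zero score has an empty leading edge.
#'
#' @param es a `gsea_es` object from [enrichment_score()].
#' @param ranked the named ranked scores the score was computed on.
#' @return character vector of leading-edge genes (a subset of the set).
#' @export
leading_edge <- function(es, ranked) {
  stopifnot(inherits(es, "gsea_es"))
  genes <- names(ranked)
  if (es$es == 0) return(character(0))
  keep <- if (es$es > 0) {
    es$hit_positions[es$hit_positions <= es$peak]
  } else {
    es$hit_positions[es$hit_positions >= es$peak]
  }
  genes[keep]
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Runs [enrichment_score()], [permutation_test()] and [leading_edge()]
#' for each set of a collection against one ranked list.
#'
#' @param ranked named ranked scores (see [rank_metric()]), or a
#'   `de_result` which is ranked first.
#' @param gene_sets list of [gene_set()] objects (e.g. from
#'   [read_gmt()]) or a named list of character vectors.
#' @param n_perm permutations per set.
#' @param seed master seed (sub-seeded per set).
#' @param p hit-weight exponent.
#' @param min_size sets hitting fewer ranked genes are skipped.
#' @return data.frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `p`, `leading_edge` (comma-separated); the per-set result
#'   objects are attached as attribute `"details"`.
#' @export
run_gsea <- function(ranked, gene_sets, n_perm = 1000, seed = 1L, p = 1,
                     min_size = 2) {
  if (inherits(ranked, "de_result")) ranked <- rank_metric(ranked)
  if (!length(gene_sets)) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- vapply(gene_sets, function(s) {
      if (inherits(s, "gene_set")) s$name else NA_character_
    }, character(1))
  }
  rows <- list()
  details <- list()
  for (nm in names(gene_sets)) {
    s <- gene_sets[[nm]]
    genes <- if (inherits(s, "gene_set")) s$genes else as.character(s)
    size <- sum(names(ranked) %in% genes)
    if (size < min_size || size == length(ranked)) next
    pt <- permutation_test(ranked, genes, n_perm = n_perm,
                           seed = sub_seed(seed, "run_gsea", match(nm, names(gene_sets))),
                           p = p)
    le <- leading_edge(pt$es_object, ranked)
    rows[[nm]] <- data.frame(set = nm, size = size, es = pt$es, nes = pt$nes,
                             p = pt$p, leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
    details[[nm]] <- pt
  }
  if (!length(rows)) stop("no gene set overlapped the ranked list", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
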