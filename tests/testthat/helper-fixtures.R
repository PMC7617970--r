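# Shared fixtures, all built in code at test time.

# Pure NB null population with log-normal libraries (no programs, no mito):
# the "one NB population" used by the DE calibration and spike-in tests.
null_population <- function(n_cells, n_genes, dispersion = 0.3, seed = 1L) {
  cfg <- sim_config(
    n_cells = n_cells, n_genes = n_genes,
    program_gene_counts = c(mhc2 = 0, inflammatory = 0),
    n_mito_genes = 0, dispersion = dispersion, seed = seed
  )
  simulate_cell_matrix(cfg)$matrix
}

# Independent brute-force running-sum oracle for the enrichment score.
brute_force_es <- function(scores, set_genes, p = 1) {
  hit <- names(scores) %in% set_genes
  n <- length(scores)
  m <- sum(hit)
  w <- abs(scores)^p
  W <- sum(w[hit])
  inc <- if (W > 0) w / W else rep(1 / m, n)
  running <- cumsum(ifelse(hit, inc, -1 / (n - m)))
  running[[which.max(abs(running))]]
}

# Small deterministic cell_matrix for QC-rule tests: detected-gene counts
# and mito fractions are constructed exactly.
toy_qc_matrix <- function() {
  n_genes <- 6100
  gene_ids <- c(sprintf("mt-%02d", 1:5), sprintf("g%05d", 1:(n_genes - 5)))
  detect <- c(a = 800, b = 1000, c = 3000, d = 3000, e = 6001)
  cells <- names(detect)
  i <- unlist(lapply(detect, seq_len))
  j <- rep(seq_along(detect), detect)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n_genes, 5),
                                 dimnames = list(gene_ids, cells))
  meta <- data.frame(
    barcode = cells,
    mito_fraction = c(0.01, 0.01, 0.05, 0.08, 0.01),
    stringsAsFactors = FALSE
  )
  cell_matrix(counts, gene_ids, meta)
}
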