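test_that("sim_config validates probabilities, rates and counts", {
  expect_error(sim_config(n_cells = 0), "positive integer")
  expect_error(sim_config(branch_prior = c(isotype = 1.2, `aPD-L1` = 0.5)),
               "\\[0, 1\\]")
  expect_error(sim_config(conversion_efficiency = 0.90), "0.95")
  expect_error(sim_config(dwell_decay_rate = -1), ">= 0")
  expect_error(sim_config(n_genes = 40, program_gene_counts =
                            c(mhc2 = 30, inflammatory = 30)), "exceed")
})

test_that("generator is deterministic and partitions Kaede labels", {
  cfg <- sim_config(n_cells = 150, n_genes = 80,
                    program_gene_counts = c(mhc2 = 10, inflammatory = 10),
                    n_mito_genes = 4, seed = 11)
  a <- simulate_cell_matrix(cfg)
  b <- simulate_cell_matrix(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth, b$truth)
  expect_true(all(a$matrix$cell_metadata$kaede_label %in% c("green", "red")))
  # exactly one truth record per cell, branch in {1,2}
  expect_identical(a$truth$cells$barcode, a$matrix$cell_metadata$barcode)
  expect_true(all(a$truth$cells$branch %in% 1:2))
})

test_that("branch prior controls the branch-1 fraction", {
  cfg <- sim_config(n_cells = 10000, n_genes = 30, n_mito_genes = 2,
                    program_gene_counts = c(mhc2 = 5, inflammatory = 5),
                    conditions = "isotype",
                    branch_prior = c(isotype = 0.4), seed = 21)
  sim <- simulate_cell_matrix(cfg)
  expect_equal(mean(sim$truth$cells$branch == 1), 0.40, tolerance = 0.05)
  expect_lt(abs(mean(sim$truth$cells$branch == 1) - 0.40), 0.02)
})

test_that("conversion efficiency sets the red fraction when all cells dwell", {
  # time_since_label 0: every dwell time exceeds it, so red = converted
  cfg <- sim_config(n_cells = 8000, n_genes = 30, n_mito_genes = 2,
                    program_gene_counts = c(mhc2 = 5, inflammatory = 5),
                    conversion_efficiency = 0.98,
                    time_since_label_h = 0, seed = 31)
  sim <- simulate_cell_matrix(cfg)
  frac_red <- mean(sim$truth$cells$kaede_label == "red")
  expect_lt(abs(frac_red - 0.98), 0.01)
})

test_that("zero dwell-decay makes inflammatory expression dwell-independent", {
  base_cfg <- function(rate, seed) {
    sim_config(n_cells = 800, n_genes = 200, dwell_decay_rate = rate,
               conditions = "isotype", branch_prior = c(isotype = 0.4),
               program_gene_counts = c(mhc2 = 20, inflammatory = 20),
               seed = seed)
  }
  slope_for <- function(sim) {
    norm <- normalize_log1p(sim$matrix)
    infl <- startsWith(rownames(norm), "infl_")
    v <- Matrix::colMeans(norm[infl, , drop = FALSE])
    unname(coef(lm(v ~ sim$truth$cells$dwell_h))[2])
  }
  sim0 <- simulate_cell_matrix(base_cfg(0, 41))
  sim1 <- simulate_cell_matrix(base_cfg(0.05, 41))
  s0 <- slope_for(sim0)
  s1 <- slope_for(sim1)
  expect_lt(s1, 0)             # decay produces a clearly negative slope
  expect_lt(abs(s0), abs(s1) / 10)  # rate zero: slope indistinguishable from 0
})

test_that("null-gene NB mean/variance matches the configured dispersion", {
  cfg <- sim_config(n_cells = 5000, n_genes = 200,
                    program_gene_counts = c(mhc2 = 0, inflammatory = 0),
                    n_mito_genes = 0, dispersion = 0.3,
                    library_size_log_sd = 0, seed = 51)
  counts <- as.matrix(simulate_cell_matrix(cfg)$matrix$counts)
  mu <- rowMeans(counts)
  v <- apply(counts, 1, var)
  alpha_hat <- (v - mu) / mu^2
  keep <- mu > 1  # moment estimate is unstable for near-zero means
  expect_equal(median(alpha_hat[keep]), 0.3, tolerance = 0.1)
})

test_that("turnover simulation follows exponential replacement", {
  # k = 0: expected red fraction equals the efficiency at any time
  tb0 <- simulate_turnover(c(p = 0), 72, 20000, efficiency = 0.95, seed = 3)
  expect_equal(tb0$n_red / 20000, 0.95, tolerance = 0.01)
  # closed form: half-life 24 h at t = 24 h, efficiency 1 -> 0.5
  tb1 <- simulate_turnover(c(p = log(2) / 24), 24, 50000, efficiency = 1, seed = 4)
  expect_equal(tb1$n_red / 50000, 0.5, tolerance = 0.01)
  expect_error(simulate_turnover(c(p = 0.1), 24, 0, seed = 1), "positive integer")
  expect_error(simulate_turnover(c(p = 0.1), numeric(0), 10, seed = 1),
               "non-empty")
  expect_error(simulate_turnover(c(p = -0.1), 24, 10, seed = 1), ">= 0")
})

test_that("spot generator honours co-localization and chemokine truth", {
  sim <- simulate_spots(800, coloc_fraction = 0.25, chemokine_given_coloc = 1,
                        seed = 5)
  coloc <- sim$truth$is_coloc
  chem_pos <- sim$spots$CXCL9 > 0 | sim$spots$CXCL10 > 0
  expect_true(all(chem_pos[coloc]))
  # coloc_fraction = 0: no spot passes both marker rules
  sim0 <- simulate_spots(500, coloc_fraction = 0, chemokine_given_coloc = 0.9,
                         seed = 6)
  both <- sim0$spots$CD68 > 0 & sim0$spots$CD14 > 0 &
    sim0$spots$TRAC > 0 & sim0$spots$CD4 > 0
  expect_false(any(both))
  # binomial bound on the chemokine fraction among true co-localized spots
  sim9 <- simulate_spots(1000, coloc_fraction = 0.3,
                         chemokine_given_coloc = 0.9, seed = 7)
  cc <- sim9$truth$is_coloc
  frac <- mean((sim9$spots$CXCL9 > 0 | sim9$spots$CXCL10 > 0)[cc])
  expect_lt(abs(frac - 0.9), 0.05)
  expect_error(simulate_spots(0, 0.2, 0.9), "positive integer")
})

test_that("image-grid generator produces the edge gradient and determinism", {
  g_null <- simulate_image_grids(20, 20, edge_gradient = FALSE, seed = 8)
  r_null <- ratio_vs_edge(g_null)
  expect_lt(abs(r_null$rho), 0.2)
  g_mono <- simulate_image_grids(20, 20, edge_gradient = TRUE, noise_sd = 0,
                                 seed = 8)
  expect_equal(ratio_vs_edge(g_mono)$rho, -1)
  expect_identical(simulate_image_grids(12, 9, TRUE, seed = 9),
                   simulate_image_grids(12, 9, TRUE, seed = 9))
  expect_error(simulate_image_grids(1, 5), ">= 2")
})
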