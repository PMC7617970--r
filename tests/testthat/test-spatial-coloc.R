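test_that("grid averaging partitions the image and conserves the mean", {
  const <- grid_average(matrix(3.5, 20, 20), grid_px = 10)
  expect_equal(nrow(const), 4)
  expect_equal(const$intensity, rep(3.5, 4))
  # partial trailing grids: 25 x 17 image, pixel-weighted mean conserved
  set.seed(1)
  img <- matrix(runif(25 * 17), 25, 17)
  g <- grid_average(img, grid_px = 10)
  expect_equal(sum(g$intensity * g$n_pixels) / sum(g$n_pixels), mean(img))
  expect_equal(sum(g$n_pixels), length(img))
  expect_error(grid_average(matrix(1, 5, 5), grid_px = 10), "at least")
})

test_that("intensity-weighted KDE peaks at hotspots and stays non-negative", {
  grid <- expand.grid(grid_x = 1:10, grid_y = 1:10)
  grid$marker <- 0
  grid$marker[grid$grid_x == 7 & grid$grid_y == 3] <- 10
  k <- kde_intensity(grid, "marker")
  expect_equal(which.max(k), which(grid$grid_x == 7 & grid$grid_y == 3))
  expect_true(all(k >= 0))
  # uniform intensity: smooth and flat over interior grids
  grid$flat <- 1
  kf <- kde_intensity(grid, "flat")
  interior <- grid$grid_x %in% 3:8 & grid$grid_y %in% 3:8
  expect_lt(sd(kf[interior]) / mean(kf[interior]), 0.1)
  expect_error(kde_intensity(grid, "missing_marker"), "not found")
  grid$zero <- 0
  expect_error(kde_intensity(grid, "zero"), "all-zero")
})

test_that("ratio_vs_edge computes Spearman correlation and the core mask", {
  g <- simulate_image_grids(15, 15, edge_gradient = TRUE, noise_sd = 0,
                            seed = 2)
  r <- ratio_vs_edge(g)
  expect_equal(r$rho, -1)
  expect_lt(r$p, 1e-10)
  # core mask: strictly beyond 100 um from the edge
  expect_identical(r$core_mask, g$distance_to_edge_um > 100)
  g150 <- data.frame(grid_x = 1:5, grid_y = 1, distance_to_edge_um =
                       c(150, 80, 120, 100, 20),
                     F4_80 = 1:5, CD11b = rep(1, 5))
  r150 <- ratio_vs_edge(g150)
  expect_identical(r150$core_mask, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # marker-independent noise: negligible correlation at 400 grids
  gn <- simulate_image_grids(20, 20, edge_gradient = FALSE, seed = 3)
  expect_lt(abs(ratio_vs_edge(gn)$rho), 0.2)
  expect_error(ratio_vs_edge(g150[1:2, ]), "3 grids")
})

test_that("spot filtering applies the count, mito and gene rules", {
  spots <- data.frame(
    spot_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    x = 1:6, y = 1:6,
    mito_fraction = c(0.05, 0.05, 0.25, 0.05, 0.05, 0.05),
    gA = c(400, 600, 600, 600, 600, 600),
    gB = c(50, 0, 0, 300, 200, 100),
    gC = c(0, 600, 0, 300, 400, 500),
    gRare = c(0, 1, 1, 1, 1, 0),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  spots$gA <- spots$gA - spots$gRare  # keep row totals tidy
  f <- filter_spots(spots, min_counts = 500, max_mito = 0.20,
                    min_spots_per_gene = 4)
  expect_false("s1" %in% f$spot_id)  # 500 total counts required
  expect_false("s3" %in% f$spot_id)  # mito 0.25 > 0.20
  expect_true(all(c("s2", "s4", "s5", "s6") %in% f$spot_id))
  expect_false("gRare" %in% names(f))  # detected in 3 < 4 retained spots
  expect_true("gA" %in% names(f))
  # idempotent
  expect_identical(filter_spots(f, 500, 0.20, 4), f)
})

test_that("spot scoring is control-matched, linear and deterministic", {
  sim <- simulate_spots(300, coloc_fraction = 0.3, chemokine_given_coloc = 0.9,
                        seed = 4)
  spots <- filter_spots(sim$spots, min_counts = 10, max_mito = 1,
                        min_spots_per_gene = 1)
  mac_sig <- c("CD68", "CCR2", "ITGAM", "CD14", "CX3CR1", "CD74", "CST3",
               "VCAN", "S100A8", "CD163", "CSF1R")
  sc1 <- score_spots(spots, mac_sig, seed = 5)
  expect_identical(sc1, score_spots(spots, mac_sig, seed = 5))
  # macrophage-true spots score higher than spots with no macrophage genes
  truth <- sim$truth[match(spots$spot_id, sim$truth$spot_id), ]
  expect_gt(mean(sc1[truth$is_mac]), mean(sc1[!truth$is_mac]))
  expect_error(score_spots(spots, c("NOPE1", "NOPE2")), "NOPE1")
  # constructed case: a spot with zero signature expression over a matched
  # uniform background scores at or below zero
  genes <- c(sprintf("sig%02d", 1:5), sprintf("bg%02d", 1:40))
  cnt <- matrix(10, nrow = 8, ncol = 45, dimnames = list(NULL, genes))
  cnt[1, 1:5] <- 0
  flat <- data.frame(spot_id = sprintf("s%d", 1:8), x = 1:8, y = 1,
                     mito_fraction = 0, cnt, check.names = FALSE,
                     stringsAsFactors = FALSE)
  sc_flat <- score_spots(flat, sprintf("sig%02d", 1:5), seed = 6)
  expect_lte(sc_flat[["s1"]], 0)
})

test_that("spot classification and chemokine fraction follow the rules", {
  spots <- data.frame(
    spot_id = c("coloc", "mac_only", "cd4_only", "none", "coloc_nochem"),
    x = 1:5, y = 1:5, mito_fraction = 0,
    CD68 = c(3, 3, 0, 0, 2), CD14 = c(1, 2, 0, 0, 1),
    TRAC = c(2, 0, 4, 0, 3), CD4 = c(1, 0, 2, 0, 2),
    CXCL9 = c(5, 5, 5, 0, 0), CXCL10 = c(0, 0, 0, 0, 0),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  cls <- classify_and_colocalize(spots)
  expect_setequal(cls$mac_spots, c("coloc", "mac_only", "coloc_nochem"))
  expect_setequal(cls$cd4_spots, c("coloc", "cd4_only", "coloc_nochem"))
  expect_setequal(cls$coloc_spots, c("coloc", "coloc_nochem"))
  expect_true(all(cls$coloc_spots %in% intersect(cls$mac_spots, cls$cd4_spots)))
  expect_equal(cls$chemokine_positive_fraction, 0.5)
  # no co-localized spots: fraction reported missing
  none <- spots[spots$spot_id %in% c("mac_only", "cd4_only"), ]
  expect_true(is.na(classify_and_colocalize(none)$chemokine_positive_fraction))
})

test_that("the estimated chemokine fraction matches the generator truth", {
  sim <- simulate_spots(1000, coloc_fraction = 0.3,
                        chemokine_given_coloc = 0.9, seed = 6)
  f <- filter_spots(sim$spots)
  cls <- classify_and_colocalize(f)
  expect_lt(abs(cls$chemokine_positive_fraction - 0.90), 0.05)
  # classification agrees with truth for retained spots
  truth_coloc <- sim$truth$spot_id[sim$truth$is_coloc]
  expect_setequal(cls$coloc_spots, intersect(truth_coloc, f$spot_id))
})
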