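test_that("partition_cells balances replicates and is seed-deterministic", {
  a <- partition_cells(letters[1:10], 3, seed = 1)
  expect_setequal(as.integer(table(a)), c(4, 3, 3))
  expect_identical(a, partition_cells(letters[1:10], 3, seed = 1))
  expect_false(identical(a, partition_cells(letters[1:10], 3, seed = 2)))
  # n cells into n replicates: all singletons
  s <- partition_cells(1:5, 5, seed = 3)
  expect_setequal(as.integer(table(s)), rep(1L, 5))
  expect_error(partition_cells(1:3, 4, seed = 1), "exceeds")
  expect_error(partition_cells(1:3, 1, seed = 1), ">= 2")
})

test_that("aggregate_counts sums raw counts and conserves totals", {
  set.seed(2)
  m <- matrix(rpois(60, 5), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), sprintf("c%02d", 1:10)))
  one <- aggregate_counts(m, rep(1L, 10))
  expect_equal(unname(one[, 1]), unname(rowSums(m)))
  singles <- aggregate_counts(m, 1:10)
  expect_equal(unname(singles), unname(m))
  pb <- aggregate_counts(m, partition_cells(colnames(m), 3, seed = 1))
  expect_equal(sum(pb), sum(m))
  expect_error(aggregate_counts(m, rep(1L, 5)), "cover")
  expect_error(aggregate_counts(m, c(rep(1L, 9), NA)), "unassigned")
})

test_that("median-of-ratios size factors reproduce the worked example", {
  pb <- rbind(g1 = c(2, 4), g2 = c(4, 8), g3 = c(6, 12))
  sf <- size_factors_median_of_ratios(pb)
  expect_equal(round(unname(sf), 4), c(0.7071, 1.4142))
})

test_that("size factors are scale-equivariant and equal for identical reps", {
  set.seed(4)
  pb <- matrix(rpois(200 * 4, 30), 200, 4) + 1
  sf <- size_factors_median_of_ratios(pb)
  pb_scaled <- pb
  pb_scaled[, 2] <- pb[, 2] * 3
  sf2 <- size_factors_median_of_ratios(pb_scaled)
  expect_lt(abs(sf2[2] - 3 * sf[2] * (sf2[1] / sf[1])), 1e-12)
  same <- cbind(pb[, 1], pb[, 1], pb[, 1])
  expect_equal(unname(size_factors_median_of_ratios(same)), rep(1, 3))
  zero <- rbind(c(0, 1), c(1, 0))
  expect_error(size_factors_median_of_ratios(zero), "reference gene")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(5)
  pb <- matrix(rnbinom(500 * 6, mu = 50, size = 5), 500, 6)
  ours <- size_factors_median_of_ratios(pb)
  ref <- DESeq2::estimateSizeFactorsForMatrix(pb)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("dispersion estimator recovers Poisson and NB simulations", {
  set.seed(6)
  # Poisson: alpha ~ 0
  pb_pois <- matrix(rpois(300 * 20, 100), 300, 20)
  a_pois <- estimate_dispersion(pb_pois, rep(1, 20))
  expect_lt(median(a_pois), 0.05)
  # NB alpha = 0.5 at 50 replicates: within 30%
  pb_nb <- matrix(rnbinom(300 * 50, mu = 100, size = 2), 300, 50)
  a_nb <- estimate_dispersion(pb_nb, rep(1, 50))
  expect_equal(median(a_nb), 0.5, tolerance = 0.3)
  # constant gene sits at the floor
  pb_const <- matrix(7, 3, 6)
  expect_true(all(estimate_dispersion(pb_const, rep(1, 6)) == 1e-8))
})

test_that("wald_test matches closed forms and is label-antisymmetric", {
  groups <- rep(c("A", "B"), each = 3)
  # identical group means: statistic exactly 0
  pb_eq <- matrix(rep(c(10, 20, 30), 6), 3, 6)
  r_eq <- wald_test(pb_eq, groups, rep(1, 6), rep(0.1, 3))
  expect_equal(r_eq$lfc, rep(0, 3), tolerance = 1e-8)
  expect_equal(r_eq$stat, rep(0, 3), tolerance = 1e-8)
  # 4x group mean at alpha -> 0: LFC -> 2 on the log2 scale
  pb_4x <- rbind(c(100, 100, 100, 400, 400, 400),
                 c(50, 50, 50, 200, 200, 200))
  r_4x <- wald_test(pb_4x, groups, rep(1, 6), rep(1e-8, 2))
  expect_equal(r_4x$lfc, c(2, 2), tolerance = 1e-6)
  # swapping labels negates LFC and statistic
  set.seed(7)
  pb <- matrix(rnbinom(50 * 6, mu = 80, size = 4), 50, 6)
  f1 <- wald_test(pb, groups, rep(1, 6), rep(0.2, 50))
  f2 <- wald_test(pb, rev(groups), rep(1, 6), rep(0.2, 50))
  expect_equal(f1$lfc, -f2$lfc, tolerance = 1e-8)
  expect_equal(f1$stat, -f2$stat, tolerance = 1e-8)
  # all-zero gene reported missing
  pb0 <- rbind(zero = rep(0, 6), ok = c(5, 6, 7, 8, 9, 10))
  r0 <- wald_test(pb0, groups, rep(1, 6), c(0.1, 0.1))
  expect_true(is.na(r0$stat[1]))
  expect_false(is.na(r0$stat[2]))
})

test_that("wald_test agrees with an independent numerical-MLE oracle", {
  set.seed(42)
  G <- 20
  sf <- c(0.8, 1.1, 1.0, 1.2, 0.9, 1.0)
  x <- c(0, 0, 0, 1, 1, 1)
  alpha <- runif(G, 0.05, 0.5)
  mu0 <- runif(G, 5, 200)
  lfc_true <- rnorm(G)
  pb <- t(sapply(seq_len(G), function(g) {
    rnbinom(6, mu = sf * mu0[g] * 2^(lfc_true[g] * x), size = 1 / alpha[g])
  }))
  fit <- wald_test(pb, c("A", "A", "A", "B", "B", "B"), sf, alpha)
  negll <- function(b, k, a) {
    -sum(dnbinom(k, size = 1 / a, mu = sf * exp(b[1] + b[2] * x), log = TRUE))
  }
  oracle_stat <- vapply(seq_len(G), function(g) {
    o <- optim(c(log(mean(pb[g, ] / sf) + 0.1), 0), negll, k = pb[g, ],
               a = alpha[g], method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    o <- optim(o$par, negll, k = pb[g, ], a = alpha[g], method = "BFGS",
               hessian = TRUE, control = list(reltol = 1e-14))
    se <- sqrt(diag(solve(o$hessian)))[2]
    o$par[2] / se
  }, numeric(1))
  expect_lt(max(abs(fit$stat - oracle_stat)), 1e-4)
})

test_that("bootstrap_de averages iterations and is reproducible", {
  x <- null_population(120, 100, seed = 8)
  groups <- rep(c("g1", "g2"), length.out = n_cells(x))
  d1 <- pseudobulk_design(groups, 3, 1, seed = 5,
                          enforce_min_iterations = FALSE)
  r1 <- bootstrap_de(x, d1)
  expect_equal(r1$table$wald_mean, unname(r1$wald_iterations[, 1]))
  d11 <- pseudobulk_design(groups, 3, 10, seed = 5)
  ra <- bootstrap_de(x, d11)
  rb <- bootstrap_de(x, d11)
  expect_identical(ra$table, rb$table)
  expect_identical(ra$wald_iterations, rb$wald_iterations)
  expect_error(pseudobulk_design(groups, 3, 9), ">= 10")
  expect_error(pseudobulk_design(rep("one", 10), 3, 11), "2 groups")
})

test_that("averaging the statistic across iterations reduces its spread", {
  x <- null_population(300, 400, seed = 9)
  groups <- rep(c("g1", "g2"), length.out = n_cells(x))
  res <- bootstrap_de(x, pseudobulk_design(groups, 3, 11, seed = 10))
  v_single <- apply(res$wald_iterations, 2, var, na.rm = TRUE)
  v_avg <- var(res$table$wald_mean, na.rm = TRUE)
  expect_lt(v_avg, mean(v_single))
})

test_that("genes spiked at LFC +1.5 get positive averaged statistics", {
  x <- null_population(300, 400, seed = 12)
  counts <- as.matrix(x$counts)
  groups <- rep(c("g1", "g2"), length.out = ncol(counts))
  set.seed(13)
  spike <- sample(rownames(counts), 40)
  a_cols <- which(groups == "g1")
  counts[spike, a_cols] <- matrix(
    rbinom(length(spike) * length(a_cols), counts[spike, a_cols], 2^-1.5),
    nrow = length(spike)
  )
  res <- bootstrap_de(counts, pseudobulk_design(groups, 3, 11, seed = 14))
  w <- res$table$wald_mean
  names(w) <- res$table$gene
  expect_gte(mean(w[spike] > 0), 0.99)
})
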