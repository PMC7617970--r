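#' Simulation configuration for Kaede-labelled single-cell data
#'
#' Collects every tunable of the single-cell generator in one validated
#' list. Defaults encode the study conditions the package's analyses
#' assume: a two-condition (isotype vs anti-PD-L1) experiment harvested
#' 48 h after photoconversion, near-complete conversion (98\%), a
#' monocyte-derived TAM pool replaced with a ~24 h half-life, two latent
#' differentiation branches (branch 1 = MHC-II+), an inflammatory gene
#' program decaying with tumour dwell time (slower under anti-PD-L1), and
#' gamma-Poisson (negative binomial) counts with log-normal library sizes.
#'
#' @param n_cells number of cells to simulate.
#' @param n_genes number of genes (including program and mitochondrial genes).
#' @param conditions character vector of condition labels; cells are split
#'   evenly across them.
#' @param branch_prior named probability of entering branch 1 (MHC-II+ fate)
#'   per condition.
#' @param conversion_efficiency fraction of cells photoconverted at the
#'   labelling event; must lie in [0.95, 1].
#' @param replacement_rate_per_population named per-hour replacement rates;
#'   the first entry drives the dwell-time distribution of the simulated pool.
#' @param dwell_decay_rate per-hour exponential decay rate of the
#'   inflammatory program with dwell time.
#' @param apdl1_decay_factor multiplier (< 1 attenuates) applied to
#'   `dwell_decay_rate` under the anti-PD-L1 condition.
#' @param program_gene_counts named integer vector: genes per program
#'   (`mhc2`, `inflammatory`). Zero disables a program.
#' @param mhc2_log2_effect log2 amplitude of the MHC-II program along
#'   branch-1 pseudotime.
#' @param inflammatory_log2_amplitude log2 amplitude of the inflammatory
#'   program at zero dwell time.
#' @param n_mito_genes number of mitochondrial ("mt-") genes.
#' @param dispersion NB dispersion, scalar or per-gene.
#' @param library_size_log_mean,library_size_log_sd log-normal library-size
#'   parameters.
#' @param time_since_label_h hours between photoconversion and harvest.
#' @param pseudotime_span_h dwell hours over which pseudotime advances
#'   linearly from 0 to 1.
#' @param embedding_noise_sd Gaussian noise added to the latent 2-D
#'   embedding coordinates.
#' @param root_pseudotime_cutoff cells below this true pseudotime are
#'   labelled as the root cluster ("mdTAM_1").
#' @param seed master integer seed; all randomness fans out from it via
#'   [sub_seed()].
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 100, n_genes = 50, seed = 1)
sim_config <- function(n_cells = 2000,
                       n_genes = 2000,
                       conditions = c("isotype", "aPD-L1"),
                       branch_prior = c(isotype = 0.40, `aPD-L1` = 0.55),
                       conversion_efficiency = 0.98,
                       replacement_rate_per_population = c(mdTAM = log(2) / 24,
                                                           TIL = log(2) / 150),
                       dwell_decay_rate = 0.05,
                       apdl1_decay_factor = 0.5,
                       program_gene_counts = c(mhc2 = 50, inflammatory = 50),
                       mhc2_log2_effect = 2,
                       inflammatory_log2_amplitude = 1.5,
                       n_mito_genes = 10,
                       dispersion = 0.3,
                       library_size_log_mean = log(5000),
                       library_size_log_sd = 0.3,
                       time_since_label_h = 48,
                       pseudotime_span_h = 72,
                       embedding_noise_sd = 0.05,
                       root_pseudotime_cutoff = 0.15,
                       seed = 1L) {
  check_positive_count(n_cells, "n_cells")
  check_positive_count(n_genes, "n_genes")
  stopifnot(length(conditions) >= 1)
  if (is.null(names(branch_prior)) || !all(conditions %in% names(branch_prior))) {
    stop("branch_prior must be named by condition", call. = FALSE)
  }
  check_prob(branch_prior, "branch_prior")
  check_prob(conversion_efficiency, "conversion_efficiency")
  if (conversion_efficiency < 0.95) {
    stop("conversion_efficiency below the 0.95 floor of complete conversion",
         call. = FALSE)
  }
  if (any(replacement_rate_per_population < 0) || dwell_decay_rate < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (any(program_gene_counts < 0) || any(program_gene_counts != floor(program_gene_counts))) {
    stop("program_gene_counts must be non-negative integers", call. = FALSE)
  }
  if (any(dispersion < 0)) stop("dispersion must be >= 0", call. = FALSE)
  if (sum(program_gene_counts) + n_mito_genes > n_genes) {
    stop("program and mitochondrial genes exceed n_genes", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a Kaede-labelled single-cell count matrix with ground truth
#'
#' Generates an integer gene-by-cell matrix in which each cell carries a
#' latent tumour dwell time (exponential, rate = the pool replacement rate),
#' a differentiation branch chosen once at tumour entry, and a pseudotime
#' that advances linearly with dwell. The Kaede label is derived from dwell
#' time versus time since photoconversion: cells present at the labelling
#' event are red with probability `conversion_efficiency`, later arrivals
#' are green. MHC-II program genes rise along branch-1 pseudotime;
#' inflammatory program genes decay exponentially with dwell time, more
#' slowly under anti-PD-L1. Counts are NB via a gamma-Poisson mixture with
#' log-normal library sizes.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (a [cell_matrix()]) and `truth`
#'   (list of per-cell and per-gene data.frames; the per-cell table carries
#'   branch, branch probability, true pseudotime, dwell hours and a latent
#'   2-D embedding usable as trajectory input).
#' @export
#' @examples
#' sim <- simulate_cell_matrix(sim_config(n_cells = 50, n_genes = 40, seed = 3))
#' dim(sim$matrix)
simulate_cell_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_rng(sub_seed(cfg$seed, "simulate_cell_matrix"), {
    n <- cfg$n_cells
    g <- cfg$n_genes
    condition <- rep(cfg$conditions, length.out = n)
    condition <- sample(condition)  # shuffle so ordering carries no signal

    k_pool <- cfg$replacement_rate_per_population[[1L]]
    dwell <- if (k_pool > 0) stats::rexp(n, rate = k_pool) else rep(Inf, n)
    s <- pmin(dwell / cfg$pseudotime_span_h, 1)

    prior <- cfg$branch_prior[condition]
    branch <- 1L + stats::rbinom(n, 1L, 1 - prior)  # branch 1 w.p. prior
    # commitment grows linearly with progression; at s = 0 only the prior
    branch_prob <- s + (1 - s) * ifelse(branch == 1L, prior, 1 - prior)

    converted <- stats::rbinom(n, 1L, cfg$conversion_efficiency) == 1L
    kaede <- ifelse(dwell >= cfg$time_since_label_h & converted, "red", "green")

    # gene panel: programs, mitochondrial, null filler
    n_mhc2 <- unname(cfg$program_gene_counts["mhc2"] %||% 0)
    if (is.na(n_mhc2)) n_mhc2 <- 0
    n_infl <- unname(cfg$program_gene_counts["inflammatory"] %||% 0)
    if (is.na(n_infl)) n_infl <- 0
    n_mito <- cfg$n_mito_genes
    n_null <- g - n_mhc2 - n_infl - n_mito
    gene_ids <- c(
      if (n_mhc2 > 0) sprintf("mhc2_%03d", seq_len(n_mhc2)),
      if (n_infl > 0) sprintf("infl_%03d", seq_len(n_infl)),
      if (n_mito > 0) sprintf("mt-%02d", seq_len(n_mito)),
      if (n_null > 0) sprintf("null_%04d", seq_len(n_null))
    )
    program <- c(rep("mhc2", n_mhc2), rep("inflammatory", n_infl),
                 rep("mito", n_mito), rep("null", n_null))

    base <- stats::rlnorm(g, meanlog = 0, sdlog = 1)
    # per-cell log2 fold of each program
    decay_rate <- cfg$dwell_decay_rate *
      ifelse(condition == "aPD-L1", cfg$apdl1_decay_factor, 1)
    infl_l2 <- cfg$inflammatory_log2_amplitude * exp(-decay_rate * dwell)
    mhc2_l2 <- cfg$mhc2_log2_effect * s * (branch == 1L)
    mito_mult <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)

    # relative expression per cell: base * program fold, renormalized
    fold <- matrix(1, nrow = g, ncol = n)
    if (n_mhc2 > 0) {
      fold[program == "mhc2", ] <- rep(2^mhc2_l2, each = n_mhc2)
    }
    if (n_infl > 0) {
      fold[program == "inflammatory", ] <- rep(2^infl_l2, each = n_infl)
    }
    if (n_mito > 0) {
      fold[program == "mito", ] <- rep(mito_mult, each = n_mito)
    }
    rel <- base * fold
    rel <- sweep(rel, 2L, colSums(rel), "/")
    lib <- stats::rlnorm(n, cfg$library_size_log_mean, cfg$library_size_log_sd)
    mu <- sweep(rel, 2L, lib, "*")

    disp <- rep_len(cfg$dispersion, g)
    counts <- matrix(0L, nrow = g, ncol = n)
    pos <- disp > 0
    if (any(pos)) {
      shape <- 1 / disp[pos]
      gam <- matrix(stats::rgamma(sum(pos) * n, shape = shape, rate = shape),
                    nrow = sum(pos), ncol = n)
      counts[pos, ] <- stats::rpois(sum(pos) * n, mu[pos, , drop = FALSE] * gam)
    }
    if (any(!pos)) {
      counts[!pos, ] <- stats::rpois(sum(!pos) * n, mu[!pos, , drop = FALSE])
    }

    # latent 2-D embedding: two branch rays from a common origin
    theta <- ifelse(branch == 1L, pi / 6, -pi / 6)
    emb1 <- s * cos(theta) + stats::rnorm(n, sd = cfg$embedding_noise_sd)
    emb2 <- s * sin(theta) + stats::rnorm(n, sd = cfg$embedding_noise_sd)

    cluster <- ifelse(s < cfg$root_pseudotime_cutoff, "mdTAM_1",
                      ifelse(branch == 1L, "mdTAM_3", "mdTAM_4"))
    barcode <- sprintf("cell_%06d", seq_len(n))
    dimnames(counts) <- list(gene_ids, barcode)
    tot <- colSums(counts)
    mito_frac <- if (n_mito > 0) {
      colSums(counts[program == "mito", , drop = FALSE]) / pmax(tot, 1)
    } else {
      rep(0, n)
    }

    meta <- data.frame(
      barcode = barcode,
      kaede_label = kaede,
      time_since_label_h = cfg$time_since_label_h,
      condition = condition,
      cluster = cluster,
      mito_fraction = mito_frac,
      stringsAsFactors = FALSE
    )
    truth_cells <- data.frame(
      barcode = barcode,
      condition = condition,
      branch = branch,
      branch_prob = branch_prob,
      pseudotime = s,
      dwell_h = dwell,
      kaede_label = kaede,
      emb1 = emb1,
      emb2 = emb2,
      stringsAsFactors = FALSE
    )
    truth_genes <- data.frame(
      gene = gene_ids,
      program = program,
      log2_effect = ifelse(program == "mhc2", cfg$mhc2_log2_effect,
                           ifelse(program == "inflammatory",
                                  cfg$inflammatory_log2_amplitude, 0)),
      stringsAsFactors = FALSE
    )
    list(
      matrix = cell_matrix(counts, gene_ids, meta),
      truth = list(cells = truth_cells, genes = truth_genes)
    )
  })
}

#' Simulate photoconversion label-turnover counts
#'
#' For each population and timepoint, draws the number of still-labelled
#' (Kaede-red) cells as Binomial(n, efficiency * exp(-k t)), the expected
#' fraction under constant exponential replacement at rate `k` per hour.
#'
#' @param rates named numeric vector of per-hour replacement rates, one per
#'   population.
#' @param timepoints hours post-conversion (>= 0).
#' @param n_cells_per_timepoint cells sampled per population, timepoint and
#'   mouse.
#' @param efficiency initial labelled fraction at t = 0.
#' @param n_mice biological replicates per timepoint.
#' @param seed integer seed.
#' @return a `TurnoverTable` data.frame with columns `population`,
#'   `timepoint_h`, `mouse`, `n_red`, `n_green`.
#' @export
#' @examples
#' simulate_turnover(c(mdTAM = log(2) / 24), c(5, 24, 72), 200, seed = 1)
simulate_turnover <- function(rates, timepoints, n_cells_per_timepoint,
                              efficiency = 0.98, n_mice = 1L, seed = 1L) {
  if (length(timepoints) == 0) stop("timepoints must be non-empty", call. = FALSE)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (any(timepoints < 0)) stop("timepoints must be >= 0", call. = FALSE)
  check_positive_count(n_cells_per_timepoint, "n_cells_per_timepoint")
  check_positive_count(n_mice, "n_mice")
  check_prob(efficiency, "efficiency")
  if (is.null(names(rates))) names(rates) <- sprintf("pop_%d", seq_along(rates))
  grid <- expand.grid(
    population = names(rates), timepoint_h = timepoints, mouse = seq_len(n_mice),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  with_rng(sub_seed(seed, "simulate_turnover"), {
    p <- efficiency * exp(-rates[grid$population] * grid$timepoint_h)
    grid$n_red <- stats::rbinom(nrow(grid), n_cells_per_timepoint, p)
    grid$n_green <- n_cells_per_timepoint - grid$n_red
    rownames(grid) <- NULL
    grid
  })
}

# gene panel used by the spot generator; gating genes are the spot rules'
# inputs (CD68 & CD14 for macrophage spots, TRAC & CD4 for CD4 T spots)
spot_gene_panel <- function(n_filler = 30L) {
  list(
    mac = c("CD68", "CCR2", "ITGAM", "CD14", "CX3CR1", "CD74", "CST3",
            "VCAN", "S100A8", "CD163", "CSF1R"),
    cd4 = c("CD3D", "CD3E", "CD4", "TRAC", "TRBC2", "CD40LG"),
    chemokine = c("CXCL9", "CXCL10"),
    mito = c("MT-CO1", "MT-ND1", "MT-CYB"),
    filler = sprintf("OTHER_%03d", seq_len(n_filler))
  )
}

#' Simulate Visium-like spots with macrophage/CD4 co-localization
#'
#' Spots carry counts for monocyte/macrophage markers, CD4 T-cell markers,
#' the chemokines CXCL9/CXCL10, mitochondrial genes, and background genes,
#' on a square-grid layout in micrometres. A fraction of spots truly
#' contain both cell types (co-localized); among those, a configurable
#' fraction expresses CXCL9 or CXCL10. Gating genes (CD68, CD14, TRAC, CD4,
#' CXCL9, CXCL10) are emitted only where the truth indicator holds, so the
#' ground truth defines the classification exactly; the remaining signature
#' genes carry negative-binomial background everywhere.
#'
#' @param n_spots number of spots (> 0).
#' @param coloc_fraction probability a spot truly contains both macrophages
#'   and CD4 T cells.
#' @param chemokine_given_coloc probability a truly co-localized spot
#'   expresses CXCL9 or CXCL10.
#' @param low_quality_fraction fraction of background-only spots downscaled
#'   below typical count/mito QC thresholds.
#' @param seed integer seed.
#' @return list with `spots` (a `SpotTable` data.frame: `spot_id`, `x`,
#'   `y`, `mito_fraction`, then one column per gene) and `truth`
#'   (per-spot indicator data.frame).
#' @export
#' @examples
#' sim <- simulate_spots(100, coloc_fraction = 0.2,
#'                       chemokine_given_coloc = 0.9, seed = 1)
#' head(sim$truth)
simulate_spots <- function(n_spots, coloc_fraction, chemokine_given_coloc,
                           low_quality_fraction = 0.02, seed = 1L) {
  if (length(n_spots) != 1 || !is.finite(n_spots) || n_spots <= 0 ||
      n_spots != floor(n_spots)) {
    stop("n_spots must be a positive integer", call. = FALSE)
  }
  check_prob(coloc_fraction, "coloc_fraction")
  check_prob(chemokine_given_coloc, "chemokine_given_coloc")
  check_prob(low_quality_fraction, "low_quality_fraction")
  panel <- spot_gene_panel()
  genes <- unlist(panel, use.names = FALSE)
  with_rng(sub_seed(seed, "simulate_spots"), {
    n <- as.integer(n_spots)
    is_coloc <- stats::rbinom(n, 1L, coloc_fraction) == 1L
    # remaining spots: macrophage-only, CD4-only, or neither
    rest_type <- sample(c("mac", "cd4", "neither"), n, replace = TRUE,
                        prob = c(0.4, 0.3, 0.3))
    is_mac <- is_coloc | rest_type == "mac"
    is_cd4 <- is_coloc | rest_type == "cd4"
    chem <- is_coloc & stats::rbinom(n, 1L, chemokine_given_coloc) == 1L

    counts <- matrix(stats::rpois(n * length(genes), 2), nrow = n,
                     dimnames = list(NULL, genes))
    gate_mac <- c("CD68", "CD14")
    gate_cd4 <- c("TRAC", "CD4")
    counts[, gate_mac] <- 0L
    counts[, gate_cd4] <- 0L
    counts[, panel$chemokine] <- 0L
    if (any(is_mac)) {
      counts[is_mac, gate_mac] <-
        1L + stats::rpois(sum(is_mac) * 2, 3)
      counts[is_mac, setdiff(panel$mac, gate_mac)] <-
        stats::rpois(sum(is_mac) * (length(panel$mac) - 2), 4)
    }
    if (any(is_cd4)) {
      counts[is_cd4, gate_cd4] <-
        1L + stats::rpois(sum(is_cd4) * 2, 2)
      counts[is_cd4, setdiff(panel$cd4, gate_cd4)] <-
        stats::rpois(sum(is_cd4) * (length(panel$cd4) - 2), 3)
    }
    if (any(chem)) {
      which_chem <- sample(c("CXCL9", "CXCL10", "both"), sum(chem),
                           replace = TRUE, prob = c(0.4, 0.4, 0.2))
      counts[chem, "CXCL9"][which_chem != "CXCL10"] <-
        1L + stats::rpois(sum(which_chem != "CXCL10"), 3)
      counts[chem, "CXCL10"][which_chem != "CXCL9"] <-
        1L + stats::rpois(sum(which_chem != "CXCL9"), 3)
    }
    counts[, panel$mito] <- stats::rpois(n * length(panel$mito), 1.5)
    counts[, panel$filler] <- stats::rpois(n * length(panel$filler), 20)

    # a few background-only spots fall below spot-level QC thresholds
    low <- !is_mac & !is_cd4 &
      stats::runif(n) < low_quality_fraction / max(mean(!is_mac & !is_cd4), 1e-9)
    if (any(low)) {
      counts[low, ] <- matrix(
        stats::rbinom(sum(low) * ncol(counts), counts[low, , drop = FALSE], 0.05),
        nrow = sum(low)
      )
    }

    side <- ceiling(sqrt(n))
    x <- ((seq_len(n) - 1L) %% side) * 100
    y <- ((seq_len(n) - 1L) %/% side) * 100
    tot <- rowSums(counts)
    mito_frac <- rowSums(counts[, panel$mito, drop = FALSE]) / pmax(tot, 1)
    spot_id <- sprintf("spot_%05d", seq_len(n))
    spots <- data.frame(spot_id = spot_id, x = x, y = y,
                        mito_fraction = mito_frac,
                        counts, check.names = FALSE, stringsAsFactors = FALSE)
    truth <- data.frame(spot_id = spot_id, is_mac = is_mac, is_cd4 = is_cd4,
                        is_coloc = is_coloc, chemokine_true = chem,
                        low_quality = low, stringsAsFactors = FALSE)
    list(spots = spots, truth = truth)
  })
}

#' Simulate grid-averaged imaging intensities
#'
#' Emulates grid-averaged immunofluorescence quantification: per-grid F4/80
#' and CD11b intensities on a `width` x `height` lattice of ~5 um grids,
#' with distance from each grid centroid to the nearest image edge in um.
#' With `edge_gradient = TRUE`, F4/80 decays exponentially with distance
#' from the edge (resident macrophages concentrate at the tumour-normal
#' interface) while CD11b stays spatially uniform.
#'
#' @param width,height number of grids per side (>= 2).
#' @param edge_gradient logical; add the F4/80 edge gradient?
#' @param noise_sd Gaussian intensity noise (0 gives the deterministic
#'   monotone construction).
#' @param grid_um physical grid size in micrometres.
#' @param seed integer seed.
#' @return a `SpatialGrid` data.frame: `grid_x`, `grid_y`,
#'   `distance_to_edge_um`, `F4_80`, `CD11b`.
#' @export
#' @examples
#' g <- simulate_image_grids(10, 10, edge_gradient = TRUE, noise_sd = 0, seed = 1)
#' cor(g$F4_80 / g$CD11b, g$distance_to_edge_um, method = "spearman")
simulate_image_grids <- function(width, height, edge_gradient = TRUE,
                                 noise_sd = 0.05, grid_um = 5, seed = 1L) {
  if (width < 2 || height < 2) stop("width and height must be >= 2", call. = FALSE)
  grid <- expand.grid(grid_x = seq_len(width), grid_y = seq_len(height),
                      KEEP.OUT.ATTRS = FALSE)
  dist_grids <- pmin(grid$grid_x - 1, width - grid$grid_x,
                     grid$grid_y - 1, height - grid$grid_y) + 0.5
  grid$distance_to_edge_um <- dist_grids * grid_um
  with_rng(sub_seed(seed, "simulate_image_grids"), {
    f480 <- if (edge_gradient) {
      0.2 + 2 * exp(-grid$distance_to_edge_um / 50)
    } else {
      rep(1, nrow(grid))
    }
    cd11b <- rep(1, nrow(grid))
    if (noise_sd > 0) {
      f480 <- pmax(f480 + stats::rnorm(nrow(grid), sd = noise_sd), 1e-6)
      cd11b <- pmax(cd11b + stats::rnorm(nrow(grid), sd = noise_sd), 1e-6)
    }
    grid$F4_80 <- f480
    grid$CD11b <- cd11b
    grid
  })
}
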