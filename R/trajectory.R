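#' Row-stochastic transition graph from an embedding
#'
#' Builds a symmetric k-nearest-neighbour graph on the supplied
#' coordinates with adaptive Gaussian kernel weights
#' `w_ij = exp(-d_ij^2 / (sigma_i * sigma_j))`, where `sigma_i` is the
#' distance from cell `i` to its `ceiling(k/3)`-th neighbour, and
#' normalizes rows to sum to one.
#'
#' @param embedding n-by-d matrix of per-cell coordinates (rows named by
#'   cell id where available).
#' @param k number of neighbours (default 30, matching the neighbourhood
#'   size used for graph construction throughout the package).
#' @return object of class `transition_graph`: list with `P` (row-
#'   stochastic dense matrix), `W` (symmetric kernel), `sigma`, and the
#'   input `embedding`.
#' @export
build_transition_graph <- function(embedding, k = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  d <- as.matrix(stats::dist(embedding))
  nn_rank <- t(apply(d, 1L, function(row) rank(row, ties.method = "first")))
  # rank 1 is the point itself (distance 0)
  adj <- nn_rank <= (k + 1)
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  kb <- ceiling(k / 3)
  sigma <- apply(d, 1L, function(row) sort(row)[kb + 1L])  # skip self
  if (any(sigma <= 0)) {
    stop("degenerate metric: duplicate points collapse the adaptive bandwidth",
         call. = FALSE)
  }
  W <- exp(-d^2 / outer(sigma, sigma))
  W[!adj] <- 0
  rs <- rowSums(W)
  if (any(rs == 0)) stop("isolated cell in the neighbour graph", call. = FALSE)
  P <- W / rs
  ids <- rownames(embedding) %||% sprintf("cell_%06d", seq_len(n))
  dimnames(P) <- dimnames(W) <- list(ids, ids)
  structure(list(P = P, W = W, sigma = sigma, embedding = embedding, k = k),
            class = "transition_graph")
}

# Non-trivial diffusion components of the transition structure.
# Eigen-decomposes the symmetrized operator D^-1/2 W D^-1/2 and maps the
# eigenvectors back (psi = D^-1/2 v), dropping the trivial stationary
# component.
diffusion_components <- function(graph, n_comps = 10) {
  W <- graph$W
  dvec <- rowSums(W)
  M <- W / sqrt(outer(dvec, dvec))
  eg <- eigen(M, symmetric = TRUE)
  keep <- seq(2L, min(n_comps + 1L, ncol(eg$vectors)))
  psi <- eg$vectors[, keep, drop = FALSE] / sqrt(dvec)
  # fix sign for determinism: largest-magnitude entry positive
  for (j in seq_len(ncol(psi))) {
    i <- which.max(abs(psi[, j]))
    if (psi[i, j] < 0) psi[, j] <- -psi[, j]
  }
  rownames(psi) <- rownames(W)
  list(psi = psi, lambda = eg$values[keep])
}

#' Select the trajectory root cell
#'
#' Within the designated root cluster (the Kaede-green dominant,
#' monocyte-like cluster in the motivating analysis), returns the cell at
#' the extremum (maximum absolute value) of the leading non-trivial
#' diffusion component restricted to that cluster.
#'
#' @param graph a [build_transition_graph()] result.
#' @param clusters per-cell cluster labels.
#' @param root_cluster label of the root cluster.
#' @param component which diffusion component to use (default the leading
#'   one).
#' @return the root cell id (character).
#' @export
select_root <- function(graph, clusters, root_cluster, component = 1L) {
  stopifnot(inherits(graph, "transition_graph"))
  ids <- rownames(graph$P)
  if (length(clusters) != length(ids)) {
    stop("clusters must have one label per cell", call. = FALSE)
  }
  in_cluster <- which(clusters == root_cluster)
  if (length(in_cluster) == 0) {
    stop(sprintf("root cluster '%s' absent", root_cluster), call. = FALSE)
  }
  if (length(in_cluster) == 1) return(ids[in_cluster])
  dc <- diffusion_components(graph, n_comps = max(2L, component))$psi[, component]
  ids[in_cluster[which.max(abs(dc[in_cluster]))]]
}

#' Diffusion pseudotime from a root cell
#'
#' Distance from the root in the eigenvalue-rescaled diffusion embedding
#' (coordinates `lambda/(1-lambda) * psi`), min-max rescaled to [0, 1].
#' The root maps to 0 and the farthest cell to 1. This stage is a
#' simplified, deterministic stand-in for published pseudotime algorithms:
#' it preserves their interface (root at zero, unit range) without
#' reproducing their internals.
#'
#' @param graph a [build_transition_graph()] result.
#' @param root root cell id or index.
#' @param n_comps number of diffusion components used.
#' @return named numeric vector of pseudotime values in [0, 1].
#' @export
pseudotime <- function(graph, root, n_comps = 10) {
  stopifnot(inherits(graph, "transition_graph"))
  ids <- rownames(graph$P)
  ri <- if (is.character(root)) match(root, ids) else as.integer(root)
  if (is.na(ri)) stop("root cell not found", call. = FALSE)
  dc <- diffusion_components(graph, n_comps)
  lam <- pmin(dc$lambda, 1 - 1e-12)
  if (any(dc$lambda > 1 - 1e-9)) {
    stop("graph appears disconnected: unreachable cells from the root",
         call. = FALSE)
  }
  coords <- sweep(dc$psi, 2L, lam / (1 - lam), "*")
  delta <- sweep(coords, 2L, coords[ri, ], "-")
  dist_root <- sqrt(rowSums(delta^2))
  rng <- range(dist_root)
  pt <- (dist_root - rng[1]) / (rng[2] - rng[1])
  names(pt) <- ids
  pt
}

# Auto-detect terminal cells: extrema of the top 2 non-trivial diffusion
# components outside the root cluster, de-duplicated by greedy selection —
# highest pseudotime first, then maximal minimum diffusion-space distance
# to the already-selected terminals.
detect_terminals <- function(graph, root, exclude = NULL, n_branches = 2,
                             n_comps = 10) {
  ids <- rownames(graph$P)
  dc <- diffusion_components(graph, n_comps)
  lam <- pmin(dc$lambda, 1 - 1e-12)
  coords <- sweep(dc$psi, 2L, lam / (1 - lam), "*")
  ok <- setdiff(seq_along(ids), exclude)
  cand <- integer(0)
  for (j in 1:2) {
    v <- dc$psi[, j]
    cand <- c(cand, ok[which.max(v[ok])], ok[which.min(v[ok])])
  }
  cand <- unique(cand)
  pt <- pseudotime(graph, root, n_comps)
  sel <- cand[which.max(pt[cand])]
  while (length(sel) < n_branches && length(setdiff(cand, sel)) > 0) {
    rest <- setdiff(cand, sel)
    min_d <- vapply(rest, function(i) {
      min(sqrt(rowSums(sweep(coords[sel, , drop = FALSE], 2L, coords[i, ], "-")^2)))
    }, numeric(1))
    sel <- c(sel, rest[which.max(min_d)])
  }
  ids[sel]
}

#' Branch absorption probabilities
#'
#' Makes the terminal cells absorbing states of the Markov chain defined
#' by the transition graph and solves for each cell's absorption
#' probability into each terminal (branch). Terminals are auto-detected
#' from diffusion-component extrema outside the root cluster when not
#' supplied.
#'
#' @param graph a [build_transition_graph()] result.
#' @param terminals character vector of terminal cell ids (one per
#'   branch), or NULL to auto-detect.
#' @param root root cell id (required for auto-detection).
#' @param exclude indices or ids excluded from terminal auto-detection
#'   (typically the root cluster).
#' @param n_branches number of terminals to auto-detect.
#' @return n-by-branches matrix of absorption probabilities; rows sum to
#'   1; columns named `branch_1..B` with terminal ids as an attribute.
#' @export
branch_probabilities <- function(graph, terminals = NULL, root = NULL,
                                 exclude = NULL, n_branches = 2) {
  stopifnot(inherits(graph, "transition_graph"))
  ids <- rownames(graph$P)
  if (is.character(exclude)) exclude <- match(exclude, ids)
  if (is.null(terminals)) {
    if (is.null(root)) stop("root is required to auto-detect terminals", call. = FALSE)
    terminals <- detect_terminals(graph, root, exclude = exclude,
                                  n_branches = n_branches)
  }
  ti <- if (is.character(terminals)) match(terminals, ids) else as.integer(terminals)
  if (anyNA(ti)) stop("terminal cell not found", call. = FALSE)
  B <- length(ti)
  trans <- setdiff(seq_along(ids), ti)
  P <- graph$P
  Q <- P[trans, trans, drop = FALSE]
  R <- P[trans, ti, drop = FALSE]
  A <- diag(length(trans)) - Q
  probs_t <- tryCatch(solve(A, R), error = function(e) {
    stop("no terminal reachable from some cells: ", conditionMessage(e),
         call. = FALSE)
  })
  probs <- matrix(0, nrow = length(ids), ncol = B,
                  dimnames = list(ids, paste0("branch_", seq_len(B))))
  probs[trans, ] <- probs_t
  probs[cbind(ti, seq_len(B))] <- 1
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("absorption probabilities do not sum to 1; graph may be disconnected",
         call. = FALSE)
  }
  probs <- probs / rs
  attr(probs, "terminals") <- ids[ti]
  probs
}

#' Classify cells into trajectories by branch probability
#'
#' Assigns each cell to the branch whose probability strictly exceeds
#' `cutoff` (ties and sub-threshold cells stay unassigned) and flags
#' high-confidence cells whose probability strictly exceeds `high_conf`.
#'
#' @param probabilities matrix from [branch_probabilities()].
#' @param cutoff assignment cut-off (default 0.5).
#' @param high_conf high-confidence cut-off (default 0.7).
#' @return data.frame with `cell`, `branch` (integer, NA when
#'   unassigned), `probability`, `high_confidence`.
#' @export
#' @examples
#' pr <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.6, 0.4))
#' assign_trajectory(pr)
assign_trajectory <- function(probabilities, cutoff = 0.5, high_conf = 0.7) {
  probabilities <- as.matrix(probabilities)
  best <- max.col(probabilities, ties.method = "first")
  pbest <- probabilities[cbind(seq_len(nrow(probabilities)), best)]
  branch <- ifelse(pbest > cutoff, best, NA_integer_)
  data.frame(
    cell = rownames(probabilities) %||% seq_len(nrow(probabilities)),
    branch = branch,
    probability = pbest,
    high_confidence = !is.na(branch) & pbest > high_conf,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fit the full trajectory stage
#'
#' Convenience wrapper: graph, root selection in the designated cluster,
#' pseudotime, branch probabilities with auto-detected terminals (root
#' cluster excluded), and probability-cutoff classification.
#'
#' @param embedding per-cell coordinates.
#' @param clusters per-cell cluster labels.
#' @param root_cluster label of the root (newly-infiltrating) cluster.
#' @param k neighbours for the graph.
#' @param n_branches number of terminal states.
#' @param cutoff,high_conf classification cut-offs.
#' @return object of class `trajectory_fit`: list with `pseudotime`,
#'   `probabilities`, `assignment`, `root`, `terminals`, `graph`.
#' @export
fit_trajectory <- function(embedding, clusters, root_cluster, k = 30,
                           n_branches = 2, cutoff = 0.5, high_conf = 0.7) {
  graph <- build_transition_graph(embedding, k = k)
  root <- select_root(graph, clusters, root_cluster)
  pt <- pseudotime(graph, root)
  probs <- branch_probabilities(
    graph, root = root,
    exclude = which(clusters == root_cluster),
    n_branches = n_branches
  )
  structure(
    list(pseudotime = pt, probabilities = probs,
         assignment = assign_trajectory(probs, cutoff, high_conf),
         root = root, terminals = attr(probs, "terminals"), graph = graph),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %d cells, %d branches; root %s\n",
              length(x$pseudotime), ncol(x$probabilities), x$root))
  invisible(x)
}

#' Loess smoothing of per-cell values over pseudotime
#'
#' Locally-weighted linear regression (tricube weights, degree 1)
#' evaluated on an evenly spaced pseudotime grid.
#'
#' @param values per-cell values (e.g. a gene-set score).
#' @param pt per-cell pseudotime.
#' @param span loess span.
#' @param n_grid number of grid points.
#' @return data.frame with `pseudotime` (grid) and `fitted`.
#' @export
smooth_over_pseudotime <- function(values, pt, span = 0.5, n_grid = 100) {
  if (length(values) != length(pt)) {
    stop("values and pseudotime must have equal length", call. = FALSE)
  }
  if (length(values) < 10) stop("need at least 10 cells", call. = FALSE)
  df <- data.frame(v = as.numeric(values), t = as.numeric(pt))
  fit <- tryCatch(
    stats::loess(v ~ t, data = df, span = span, degree = 1,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")),
    error = function(e) stop("loess failed (span too small for local fits?): ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("loess unstable (span too small for local fits?): ",
                               conditionMessage(w), call. = FALSE)
  )
  grid <- seq(min(df$t), max(df$t), length.out = n_grid)
  data.frame(pseudotime = grid, fitted = stats::predict(fit, newdata = data.frame(t = grid)))
}
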