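#' Labelled (Kaede-red) fraction with Wilson intervals
#'
#' Computes, per row of a turnover table, the still-labelled fraction
#' `n_red / (n_red + n_green)` with a 95\% Wilson score interval.
#'
#' @param table data.frame with integer columns `n_red` and `n_green`
#'   (plus any identifying columns, which are carried through).
#' @param conf_level confidence level of the interval.
#' @return the input with added columns `fraction_red`, `ci_lo`, `ci_hi`.
#' @export
#' @examples
#' red_fraction(data.frame(n_red = 98, n_green = 2))
red_fraction <- function(table, conf_level = 0.95) {
  table <- as.data.frame(table)
  if (!all(c("n_red", "n_green") %in% names(table))) {
    stop("table must have n_red and n_green columns", call. = FALSE)
  }
  n <- table$n_red + table$n_green
  if (any(n < 1)) stop("row with zero total cells", call. = FALSE)
  if (any(table$n_red < 0 | table$n_green < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  phat <- table$n_red / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  table$fraction_red <- phat
  # the Wilson interval contains phat analytically; guard float round-off
  table$ci_lo <- pmin(pmax(centre - half, 0), phat)
  table$ci_hi <- pmax(pmin(centre + half, 1), phat)
  table
}

#' Fit exponential label-replacement kinetics
#'
#' Models the labelled fraction as `f(t) = f0 * exp(-k t)` — the constant-
#' influx replacement model — and fits it per population by weighted least
#' squares of `log(fraction)` on time, weights equal to the inverse
#' binomial variance of the log fraction. Zero-fraction rows are excluded
#' with a warning. `k` is reported as a net replacement rate (influx and
#' egress are not separable from the readout).
#'
#' @param table a turnover table (see [red_fraction()]) with columns
#'   `population`, `timepoint_h`, `n_red`, `n_green`.
#' @param fix_f0 optional known initial labelled fraction (e.g. the
#'   photoconversion efficiency); when supplied only `k` is estimated.
#' @return data.frame of class `turnover_fit`, one row per population:
#'   `population`, `k_per_h`, `f0`, `half_life_h`, `n_points`,
#'   `residual_ss`.
#' @export
fit_replacement <- function(table, fix_f0 = NULL) {
  table <- as.data.frame(table)
  need <- c("population", "timepoint_h", "n_red", "n_green")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.null(fix_f0)) check_prob(fix_f0, "fix_f0")
  out <- lapply(split(table, table$population), function(tb) {
    n <- tb$n_red + tb$n_green
    f <- tb$n_red / n
    zero <- f == 0
    if (any(zero)) {
      warning(sprintf("population '%s': excluding %d zero-fraction timepoint(s)",
                      tb$population[1], sum(zero)))
      tb <- tb[!zero, , drop = FALSE]
      n <- n[!zero]; f <- f[!zero]
    }
    if (nrow(tb) == 0) {
      stop(sprintf("population '%s': all timepoints have zero labelled cells",
                   tb$population[1]), call. = FALSE)
    }
    if (length(unique(tb$timepoint_h)) < 3) {
      stop(sprintf("population '%s': need >= 3 distinct timepoints",
                   tb$population[1]), call. = FALSE)
    }
    # delta method: var(log f_hat) ~ (1 - f) / (n f)
    w <- (n * f) / pmax(1 - f, 1e-8)
    y <- log(f)
    t <- tb$timepoint_h
    if (is.null(fix_f0)) {
      fit <- stats::lm(y ~ t, weights = w)
      k <- max(0, -stats::coef(fit)[["t"]])
      f0 <- min(1, exp(stats::coef(fit)[["(Intercept)"]]))
      rss <- sum(w * stats::resid(fit)^2)
    } else {
      y0 <- y - log(fix_f0)
      fit <- stats::lm(y0 ~ t - 1, weights = w)
      k <- max(0, -stats::coef(fit)[["t"]])
      f0 <- fix_f0
      rss <- sum(w * stats::resid(fit)^2)
    }
    data.frame(population = tb$population[1], k_per_h = k, f0 = f0,
               half_life_h = ifelse(k > 0, log(2) / k, Inf),
               n_points = nrow(tb), residual_ss = rss,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("turnover_fit", class(res))
  res
}

#' Ellipsoid tumour volume
#'
#' `V = 0.5 * a * b^2` in cubic millimetres, with `a` the long and `b`
#' the short calliper diameter.
#'
#' @param a long diameter (mm).
#' @param b short diameter (mm); must satisfy `0 < b <= a`.
#' @return volume in mm^3 (vectorized).
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(a, b) {
  if (any(b <= 0)) stop("diameters must be positive", call. = FALSE)
  if (any(b > a)) stop("short diameter b exceeds long diameter a", call. = FALSE)
  0.5 * a * b^2
}
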