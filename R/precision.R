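# Localization-precision estimators: convergence filtering, clustering
# of repeated localizations, the cluster-spread curve sigma_cluster(N),
# the blocked standard error sigma_block(M), its power-law fit
# sigma_est(M) = a / (b + M)^c, and the stability decomposition
# sigma_cluster^2 = sigma_est^2 + s^2.

#' Precision-analysis configuration
#'
#' @param sigma_c Convergence threshold (nm): a localization passes if
#'   the standard deviation of its post-ramp center positions is
#'   strictly below `sigma_c` in both x and y.
#' @param cluster_max_diameter Complete-linkage diameter cap (nm) when
#'   grouping repeated localizations into binding-site clusters.
#' @param cluster_min_count Minimum localizations per cluster; smaller
#'   groups are discarded as noise.
#' @param block_fraction Blocks of size `M < (L - N_c + 1) /
#'   block_fraction` are admitted (at least that many independent
#'   blocks).
#' @param c_bounds Allowed interval for the power-law exponent
#'   (open below, closed above).
#' @param min_clusters_display Minimum number of clusters required for
#'   the cluster-spread statistic to be reported (otherwise `NA`).
#' @param min_block_count Minimum post-ramp detections for a
#'   single-trace block analysis.
#' @return An object of class `precision_config`.
#' @export
precision_config <- function(sigma_c = 4.2, cluster_max_diameter = 10,
                             cluster_min_count = 5, block_fraction = 5,
                             c_bounds = c(0.4, 0.5),
                             min_clusters_display = 10,
                             min_block_count = 10000) {
  stopifnot(sigma_c > 0, cluster_min_count >= 2, block_fraction >= 1,
            length(c_bounds) == 2, c_bounds[1] < c_bounds[2])
  structure(
    list(sigma_c = sigma_c, cluster_max_diameter = cluster_max_diameter,
         cluster_min_count = cluster_min_count,
         block_fraction = block_fraction, c_bounds = c_bounds,
         min_clusters_display = min_clusters_display,
         min_block_count = min_block_count),
    class = "precision_config")
}

#' Convergence filter for a localization trace
#'
#' Passes iff the standard deviation of the circle-center positions over
#' photon indices `n_c..L` is strictly below `sigma_c` in both the x and
#' the y direction. Traces that never completed the energy ramp
#' (`L < n_c`) fail with reason "not converged".
#'
#' @param trace A `minsted_trace`.
#' @param cfg A [precision_config()].
#' @return Logical scalar with attribute `reason` when failing.
#' @export
convergence_filter <- function(trace, cfg = precision_config()) {
  if (trace$L < trace$n_c) {
    return(structure(FALSE, reason = "not converged"))
  }
  j <- trace$n_c:trace$L
  sx <- stats::sd(trace$data$x_nm[j])
  sy <- stats::sd(trace$data$y_nm[j])
  if (is.na(sx) || is.na(sy)) return(structure(FALSE, reason = "too short"))
  ok <- (sx < cfg$sigma_c) && (sy < cfg$sigma_c)
  if (ok) TRUE else structure(FALSE, reason = "spread above sigma_c")
}

#' Cluster repeated localizations into binding sites
#'
#' Complete-linkage agglomerative clustering with a hard diameter cap:
#' the tree is cut at height `cluster_max_diameter`, so every cluster
#' spans at most that diameter (complete-linkage merge height is the
#' maximal inter-point distance). Clusters with fewer than
#' `cluster_min_count` members are relabeled 0 (noise).
#'
#' @param positions A two-column matrix or data.frame of positions (nm).
#' @param cfg A [precision_config()].
#' @return Integer vector of cluster labels (0 = noise), one per row.
#' @export
cluster_localizations <- function(positions, cfg = precision_config()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(n >= 1)
  if (n == 1L) {
    lab <- 1L
  } else {
    hc <- stats::hclust(stats::dist(positions), method = "complete")
    lab <- stats::cutree(hc, h = cfg$cluster_max_diameter)
  }
  tab <- tabulate(lab)
  lab[tab[lab] < cfg$cluster_min_count] <- 0L
  # renumber surviving clusters 1..k in order of appearance
  keep <- unique(lab[lab != 0L])
  out <- integer(n)
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

#' Per-cluster spread of position estimates
#'
#' Geometric mean of the per-axis standard deviations,
#' `sqrt(sd(x) * sd(y))`, of a set of positions.
#'
#' @param positions Two-column matrix of positions (nm), `>= 2` rows.
#' @return Spread in nm.
#' @export
cluster_spread <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2)
  sqrt(stats::sd(positions[, 1]) * stats::sd(positions[, 2]))
}

#' Cluster-spread precision curve sigma_cluster(N)
#'
#' For each requested photon number `N`, evaluates every trace's
#' position estimate at `N` (raw center for `N < n_c`, running mean from
#' `n_c` onward), takes the per-cluster geometric-mean-axis standard
#' deviation across the traces of each cluster, and reports the median
#' over clusters. Traces shorter than `N` are excluded from that `N`;
#' clusters falling below 2 members are skipped, and the median is `NA`
#' when fewer than `min_clusters_display` clusters remain.
#'
#' @param traces List of `minsted_trace` objects.
#' @param clusters Integer cluster labels from [cluster_localizations()]
#'   (0 = noise), aligned with `traces`.
#' @param N Vector of photon numbers.
#' @param cfg A [precision_config()].
#' @return data.frame with columns `N`, `sigma_cluster_nm`,
#'   `n_clusters`.
#' @export
sigma_cluster <- function(traces, clusters, N, cfg = precision_config()) {
  stopifnot(length(traces) == length(clusters))
  out <- data.frame(N = N, sigma_cluster_nm = NA_real_,
                    n_clusters = 0L)
  for (r in seq_along(N)) {
    n <- N[r]
    spreads <- c()
    for (k in setdiff(unique(clusters), 0L)) {
      idx <- which(clusters == k)
      idx <- idx[vapply(traces[idx], function(tr) tr$L >= n, logical(1))]
      if (length(idx) < 2L) next
      pos <- t(vapply(traces[idx], position_estimate, numeric(2), N = n))
      spreads <- c(spreads, cluster_spread(pos))
    }
    out$n_clusters[r] <- length(spreads)
    if (length(spreads) >= cfg$min_clusters_display)
      out$sigma_cluster_nm[r] <- stats::median(spreads)
  }
  out
}

#' Blocked standard error of a trace
#'
#' Moving mean (stride 1) of blocks of `M` consecutive post-ramp center
#' positions; the per-axis standard deviations of the block means are
#' combined as their geometric mean. Valid for
#' `1 <= M < (L - n_c + 1) / block_fraction` (at least `block_fraction`
#' independent blocks).
#'
#' @param trace A `minsted_trace` with `L >= n_c`.
#' @param M Block size(s); vectorized.
#' @param cfg A [precision_config()].
#' @return Numeric vector of sigma_block values (nm).
#' @export
sigma_block <- function(trace, M, cfg = precision_config()) {
  if (trace$L < trace$n_c) stop("sigma_block: trace did not complete the ramp")
  j <- trace$n_c:trace$L
  x <- trace$data$x_nm[j]; y <- trace$data$y_nm[j]
  n <- length(x)
  mmax <- n / cfg$block_fraction
  if (any(M < 1 | M >= mmax | M != round(M)))
    stop(sprintf("sigma_block: M must be an integer in [1, %g)", mmax))
  csx <- c(0, cumsum(x)); csy <- c(0, cumsum(y))
  vapply(M, function(m) {
    k <- seq_len(n - m + 1L)
    bx <- (csx[k + m] - csx[k]) / m
    by <- (csy[k + m] - csy[k]) / m
    sqrt(stats::sd(bx) * stats::sd(by))
  }, numeric(1))
}

#' Full blocked-standard-error curve
#'
#' [sigma_block()] evaluated at every admissible block size
#' `M = 1, 2, ..., ceiling((L - n_c + 1)/block_fraction) - 1`.
#'
#' @inheritParams sigma_block
#' @return data.frame with columns `M`, `sigma_nm`.
#' @export
sigma_block_curve <- function(trace, cfg = precision_config()) {
  n <- trace$L - trace$n_c + 1
  M <- seq_len(ceiling(n / cfg$block_fraction) - 1L)
  data.frame(M = M, sigma_nm = sigma_block(trace, M, cfg))
}

#' Fit the power-law precision model
#'
#' Bounded nonlinear least squares of `sigma_est(M) = a / (b + M)^c` to
#' a blocked-standard-error curve, on the log scale (multiplicative
#' residuals weight all decades of `M` equally). Bounds: `b > 0`,
#' `c` in `c_bounds` (open below, closed above). Initialization:
#' `a = sigma(1) * (1 + 1/alpha)^0.5`, `b = 1/alpha`, `c = 0.5`, using
#' the localizer's center-update fraction `alpha` (the fractional
#' updates correlate neighboring center positions over about `1/alpha`
#' photons, which is what `b` absorbs).
#'
#' @param M Block sizes.
#' @param sigma Corresponding sigma_block values (nm), positive.
#' @param cfg A [precision_config()].
#' @param alpha Center-update fraction used for initialization.
#' @return An object of class `power_law_fit` with fields `a`, `b`,
#'   `c`, `residual` (RMS of log residuals) and `n_c` slot left `NA`
#'   for the caller to fill.
#' @export
fit_power_law <- function(M, sigma, cfg = precision_config(), alpha = 0.15) {
  keep <- is.finite(sigma) & sigma > 0
  M <- M[keep]; sigma <- sigma[keep]
  if (length(M) < 5) stop("fit_power_law: need at least 5 (M, sigma) pairs")
  ls <- log(sigma)
  obj <- function(p) {
    pred <- p[1] - p[3] * log(exp(p[2]) + M)
    sum((ls - pred)^2)
  }
  c_lo <- cfg$c_bounds[1] + 1e-6
  c_hi <- cfg$c_bounds[2]
  init <- c(log(sigma[1] * sqrt(1 + 1 / alpha)), log(1 / alpha), 0.5)
  init[3] <- min(max(init[3], c_lo), c_hi)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(-20, log(1e-8), c_lo),
                      upper = c(20, 20, c_hi),
                      control = list(maxit = 500))
  if (fit$convergence != 0 && fit$convergence != 52) {
    stop(sprintf("fit_power_law: optimizer did not converge (code %d, a=%g b=%g c=%g)",
                 fit$convergence, exp(fit$par[1]), exp(fit$par[2]),
                 fit$par[3]))
  }
  structure(
    list(a = exp(fit$par[1]), b = exp(fit$par[2]), c = fit$par[3],
         residual = sqrt(fit$value / length(M))),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law precision fit: sigma(M) = %.4g / (%.4g + M)^%.4g  (log-RMS %.3g)\n",
              x$a, x$b, x$c, x$residual))
  invisible(x)
}

#' Extrapolated single-trace precision
#'
#' Evaluates the fitted power law at a total photon number `N`
#' (detections counted from the trace start, including the ramp):
#' `sigma_est = a / (b + M)^c` with `M = N - n_c + 1`.
#'
#' @param fit A `power_law_fit`.
#' @param N Total detections (vectorized), `>= n_c`.
#' @param n_c Photon index at which the minimal FWHM was reached.
#' @return Precision in nm.
#' @export
sigma_est <- function(fit, N, n_c) {
  if (any(N < n_c)) stop("sigma_est: N must be >= n_c")
  M <- N - n_c + 1
  fit$a / (fit$b + M)^fit$c
}

#' Stability decomposition of the cluster spread
#'
#' Least-squares fit of the scalar `s >= 0` in
#' `sigma_cluster(M) = sqrt(sigma_est(M)^2 + s^2)` given paired curves
#' on a common grid. Returns 0 when the cluster spread is nowhere above
#' the single-trace precision.
#'
#' @param sigma_cluster_vals Cluster-spread values (nm).
#' @param sigma_est_vals Single-trace precision values (nm), same
#'   length.
#' @return A list with element `s` (nm), class `stability_model`.
#' @export
fit_stability <- function(sigma_cluster_vals, sigma_est_vals) {
  keep <- is.finite(sigma_cluster_vals) & is.finite(sigma_est_vals)
  sc <- sigma_cluster_vals[keep]; se <- sigma_est_vals[keep]
  if (length(sc) == 0) stop("fit_stability: no overlapping finite values")
  if (all(sc <= se)) {
    return(structure(list(s = 0), class = "stability_model"))
  }
  obj <- function(s) sum((sc - sqrt(se^2 + s^2))^2)
  hi <- max(sc)
  opt <- stats::optimize(obj, c(0, hi))
  s <- opt$minimum
  if (obj(0) <= opt$objective) s <- 0
  structure(list(s = s), class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  cat(sprintf("site-stability model: s = %.3g nm\n", x$s))
  invisible(x)
}
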