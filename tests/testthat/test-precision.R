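# Precision estimators: convergence filter, clustering, cluster
# spread, blocked standard error (with brute-force oracle), power-law
# fit, extrapolated precision and the stability decomposition.

make_synthetic_trace <- function(x, y, n_c = 80) {
  structure(list(data = data.frame(i = seq_along(x), x_nm = x, y_nm = y),
                 n_c = n_c, L = length(x), initiated = TRUE,
                 converged_ramp = length(x) >= n_c,
                 truth = c(0, 0), termination = "budget"),
            class = "minsted_trace")
}

test_that("convergence filter thresholds the post-ramp spread strictly", {
  pc <- precision_config()
  n <- 500
  good <- make_synthetic_trace(rep(1, n), rep(-2, n))
  expect_true(isTRUE(convergence_filter(good, pc)))
  # linear drift over 30 nm: sd = 30/sqrt(12) ~ 8.66 > 4.2
  drift <- make_synthetic_trace(seq(0, 30, length.out = n), rep(0, n))
  res <- convergence_filter(drift, pc)
  expect_false(isTRUE(res))
  x <- drift$data$x_nm[80:n]
  expect_equal(stats::sd(x), 30 * (n - 80) / (n - 1) / sqrt(12),
               tolerance = 0.01)
  # spread exactly at sigma_c fails (strict inequality)
  set.seed(1)
  z <- stats::rnorm(n)
  z <- (z - mean(z[80:n])) / stats::sd(z[80:n]) * pc$sigma_c
  exact <- make_synthetic_trace(z, rep(0, n))
  expect_false(isTRUE(convergence_filter(exact, pc)))
  # ramp never completed
  short <- make_synthetic_trace(1:10, 1:10)
  res <- convergence_filter(short, pc)
  expect_false(isTRUE(res))
  expect_equal(attr(res, "reason"), "not converged")
})

test_that("cluster_localizations respects the diameter cap and minimum count", {
  pc <- precision_config()
  set.seed(5)
  a <- cbind(stats::rnorm(6, 0, 1), stats::rnorm(6, 0, 1))
  b <- cbind(stats::rnorm(6, 20, 1), stats::rnorm(6, 0, 1))
  lab <- cluster_localizations(rbind(a, b), pc)
  expect_equal(max(lab), 2)
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:12])), 1)
  # four points cannot form a cluster
  lab4 <- cluster_localizations(a[1:4, ], pc)
  expect_equal(lab4, rep(0L, 4))
  # every surviving cluster spans at most the diameter cap
  set.seed(6)
  pts <- cbind(stats::runif(300, 0, 80), stats::runif(300, 0, 80))
  lab <- cluster_localizations(pts, pc)
  for (k in setdiff(unique(lab), 0L)) {
    m <- pts[lab == k, , drop = FALSE]
    expect_lte(max(stats::dist(m)), pc$cluster_max_diameter)
  }
})

test_that("cluster recovery on a 144-site origami field matches generator truth", {
  # 16 grids of 3x3 sites, homogeneous DNA-PAINT statistics, direct
  # per-localization draws at the measured per-site spread
  set.seed(77)
  pc <- precision_config()
  sites <- NULL
  for (g in 1:16) {
    s <- make_origami(12)
    ox <- (g - 1) %% 4 * 500; oy <- (g - 1) %/% 4 * 500
    sites <- rbind(sites, cbind(s$x_nm + ox, s$y_nm + oy))
  }
  expect_equal(nrow(sites), 144)
  counts <- stats::rpois(144, 6.9) * stats::rbinom(144, 1, 0.85)
  pts <- NULL
  for (i in which(counts > 0)) {
    pts <- rbind(pts, cbind(sites[i, 1] + stats::rnorm(counts[i], 0, 1.5),
                            sites[i, 2] + stats::rnorm(counts[i], 0, 1.5)))
  }
  lab <- cluster_localizations(pts, pc)
  truth <- sum(counts >= pc$cluster_min_count)
  expect_lt(abs(max(lab) - truth) / truth, 0.2)
})

test_that("cluster_spread is the geometric mean of per-axis standard deviations", {
  p <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_equal(cluster_spread(p), 0)
  set.seed(2)
  q <- cbind(stats::rnorm(40), stats::rnorm(40))
  q[, 1] <- q[, 1] / stats::sd(q[, 1]) * 2
  q[, 2] <- q[, 2] / stats::sd(q[, 2]) * 8
  expect_equal(cluster_spread(q), 4, tolerance = 1e-9)
})

test_that("sigma_block equals a brute-force double-loop oracle exactly", {
  pc <- precision_config()
  set.seed(9)
  for (rep_ in 1:3) {
    n <- 1000
    x <- cumsum(stats::rnorm(n, sd = 0.3)) * 0.1 + stats::rnorm(n, sd = 2)
    y <- stats::rnorm(n, sd = 3)
    tr <- make_synthetic_trace(x, y, n_c = 1)
    for (M in c(1, 7, 50, 199)) {
      nb <- n - M + 1
      bx <- numeric(nb); by <- numeric(nb)
      for (k in seq_len(nb)) {           # independent double loop
        sx <- 0; sy <- 0
        for (j in k:(k + M - 1)) { sx <- sx + x[j]; sy <- sy + y[j] }
        bx[k] <- sx / M; by[k] <- sy / M
      }
      oracle <- sqrt(stats::sd(bx) * stats::sd(by))
      expect_equal(sigma_block(tr, M, pc), oracle, tolerance = 1e-12)
    }
    expect_error(sigma_block(tr, 200, pc), "M must be")
  }
  # constant series
  cst <- make_synthetic_trace(rep(3, 100), rep(-1, 100), n_c = 1)
  expect_equal(sigma_block(cst, c(1, 5, 19), pc), c(0, 0, 0))
})

test_that("sigma_block follows the iid 1/sqrt(M) law", {
  set.seed(13)
  n <- 1e5
  tr <- make_synthetic_trace(stats::rnorm(n, sd = 4), stats::rnorm(n, sd = 4),
                             n_c = 1)
  s <- sigma_block(tr, c(1, 100))
  expect_equal(s[1], 4, tolerance = 0.05)
  expect_equal(s[2], 0.4, tolerance = 0.1)
})

test_that("power-law fit recovers noiseless parameters and honors bounds", {
  pc <- precision_config()
  M <- 1:200
  fit <- fit_power_law(M, 10 / (5 + M)^0.5, pc)
  expect_equal(fit$a, 10, tolerance = 0.01)
  expect_equal(fit$b, 5, tolerance = 0.05)
  expect_equal(fit$c, 0.5, tolerance = 1e-4)
  # b -> 0 data: sigma_est(4) ~ a/2
  fit0 <- fit_power_law(M, 8 / M^0.5, pc)
  expect_lt(fit0$b, 0.1)
  expect_equal(sigma_est(fit0, N = 4, n_c = 1), 4, tolerance = 0.05)
  expect_error(fit_power_law(1:4, rep(1, 4), pc), "at least 5")
  # closed-form evaluation and range check of sigma_est
  f <- structure(list(a = 10, b = 1e-9, c = 0.5), class = "power_law_fit")
  expect_equal(sigma_est(f, N = 4, n_c = 1), 5, tolerance = 1e-6)
  expect_error(sigma_est(f, N = 3, n_c = 5), ">= n_c")
})

test_that("sigma_est and sigma_block agree on simulated traces", {
  ps <- static_precision()
  # common-range comparison at N = 2000: median |log ratio| < 10%
  lr <- abs(log(ps$est[, 2] / ps$block[, 2]))
  expect_lt(stats::median(lr, na.rm = TRUE), 0.1)
  # exponents within the allowed interval on >= 90% of traces
  cs <- vapply(ps$fits, function(f) f$c, numeric(1))
  expect_gte(mean(cs > 0.4 & cs <= 0.5), 0.9)
  bs <- vapply(ps$fits, function(f) f$b, numeric(1))
  expect_true(all(bs > 0))
})

test_that("sigma_cluster handles trivial geometry and the display minimum", {
  pc <- precision_config()
  mk <- function(x, y) make_synthetic_trace(rep(x, 120), rep(y, 120))
  traces <- c(lapply(1:6, function(i) mk(0, 0)),
              lapply(1:6, function(i) mk(30, 0)))
  cl <- c(rep(1L, 6), rep(2L, 6))
  sc <- sigma_cluster(traces, cl, N = c(80, 100), pc)
  # identical member positions -> zero spread, but below the
  # 10-cluster display minimum the median is withheld
  expect_true(all(is.na(sc$sigma_cluster_nm)))
  expect_equal(sc$n_clusters, c(2L, 2L))
  pc2 <- precision_config(min_clusters_display = 2)
  sc2 <- sigma_cluster(traces, cl, N = c(80, 100), pc2)
  expect_equal(sc2$sigma_cluster_nm, c(0, 0))
})

test_that("stability decomposition inverts exactly and recovers injected jitter", {
  se <- 3 / (1:50)^0.45
  expect_equal(fit_stability(sqrt(se^2 + 0.25), se)$s, 0.5,
               tolerance = 1e-4)
  expect_equal(fit_stability(se, se)$s, 0)
  expect_equal(fit_stability(se * 0.9, se)$s, 0)
  expect_error(fit_stability(numeric(0), numeric(0)), "no overlapping")
})
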