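# Online localization loop: ramp schedule, photon sampling, center
# updates, full runs, position estimates, and the steady-state
# properties (convergence to the emitter, AR(1) correlation time,
# alpha monotonicity).

test_that("ramp schedule starts confocal, shrinks geometrically, saturates", {
  opt <- default_optics(); cfg <- default_cfg(); tb <- default_tables()
  s <- ramp_schedule(c(1, 2, 80, 200), cfg, opt, tb)
  expect_equal(s$E_nJ[1], 0)
  expect_equal(s$fwhm_nm[1], opt$fwhm_conf)
  expect_equal(s$R_nm[1], opt$fwhm_conf / 2)
  gamma <- (24 / 250)^(1 / 79)
  expect_equal(tb$gamma, gamma, tolerance = 1e-9)
  expect_equal(gamma, 0.97077, tolerance = 1e-4)
  expect_equal(s$fwhm_nm[2], gamma * 250, tolerance = 1e-6)
  # saturated regime: E_max, 24 nm, R_min = 12 nm
  expect_equal(s$E_nJ[3:4], c(1, 1))
  expect_equal(s$fwhm_nm[3:4], c(24, 24), tolerance = 1e-9)
  expect_equal(s$R_nm[3:4], c(12, 12), tolerance = 1e-9)
  # invariant R_i = max(r_min, r_over_fwhm * FWHM_i) across the ramp
  full <- ramp_schedule(1:100, cfg, opt, tb)
  expect_equal(full$R_nm, pmax(tb$r_min, cfg$r_over_fwhm * full$fwhm_nm))
})

test_that("sample_photon: uniform azimuth for centered emitter, biased when displaced", {
  opt <- default_optics()
  set.seed(101)
  # centered emitter, no background: rotational symmetry => uniform phi
  phi <- replicate(1e4, sample_photon(c(0, 0), c(0, 0), R = 12, E = 1,
                                      opt, sbr = Inf)$phi)
  ks <- stats::ks.test(phi / (2 * pi), "punif")
  expect_gt(ks$p.value, 0.01)
  # displaced emitter: mean cos(phi) matches the quadrature oracle
  d <- 5
  draw <- replicate(1e4, sample_photon(c(d, 0), c(0, 0), R = 12, E = 1,
                                       opt, sbr = Inf)$phi)
  grid <- seq(0, 2 * pi, length.out = 20001)[-1]
  w <- epsf(sqrt((d - 12 * cos(grid))^2 + (12 * sin(grid))^2), 1, opt)
  oracle <- sum(cos(grid) * w) / sum(w)
  se <- stats::sd(cos(draw)) / sqrt(length(draw))
  expect_gt(oracle, 0)
  expect_lt(abs(mean(cos(draw)) - oracle), 3 * se)
  # sbr = 1 => background probability one half
  set.seed(42)
  bg <- replicate(2000, sample_photon(c(0, 0), c(0, 0), 12, 1, opt,
                                      sbr = 1)$is_background)
  expect_lt(abs(mean(bg) - 0.5), 3 * 0.5 / sqrt(2000))
})

test_that("update_center shifts by alpha * R toward the detection azimuth", {
  expect_equal(update_center(c(0, 0), R = 12, phi = 0, alpha = 0.15),
               c(1.8, 0))
  expect_equal(update_center(c(0, 0), R = 12, phi = pi / 2, alpha = 0.15),
               c(0, 1.8))
  expect_equal(update_center(c(3, -2), R = 10, phi = 1.1, alpha = 0),
               c(3, -2))
})

test_that("run_localization converges to a static emitter and honors the trace contract", {
  opt <- default_optics(); cfg <- default_cfg(); tb <- default_tables()
  set.seed(7)
  est <- t(replicate(100, {
    tr <- run_localization(emitter_static(0, 0), cfg, opt,
                           max_photons = 300, tables = tb)
    position_estimate(tr, tr$L)
  }))
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1])), 3 * se[1])
  expect_lt(abs(mean(est[, 2])), 3 * se[2])

  tr <- run_localization(emitter_static(4, -3), cfg, opt,
                         max_photons = 2000, tables = tb)
  d <- tr$data
  expect_equal(tr$L, 2000)
  expect_equal(tr$n_c, 80)
  # E and FWHM constant at the endpoint from n_c on; R at its floor
  expect_true(all(d$E_nJ[80:2000] == 1))
  expect_true(all(d$fwhm_nm[80:2000] == d$fwhm_nm[80]))
  expect_true(all(d$R_nm[80:2000] == d$R_nm[80]))
  # floor = half the calibrated minimal FWHM, 12 nm up to root-search
  # tolerance
  expect_equal(d$R_nm[80], 12, tolerance = 1e-6)
  expect_true(all(diff(d$t_ms) > 0))
  # scan-edge condition: after burn-in the center tracks the emitter
  # well within the scan radius
  dist_em <- sqrt((d$x_nm[200:2000] - 4)^2 + (d$y_nm[200:2000] + 3)^2)
  expect_lt(stats::quantile(dist_em, 0.95), 12)
})

test_that("unbinding triggers the low-rate termination near the unbinding time", {
  opt <- default_optics(); cfg <- default_cfg(); tb <- default_tables()
  set.seed(11)
  ends <- replicate(20, {
    tr <- run_localization(emitter_static(0, 0, t_off_ms = 5), cfg, opt,
                           tables = tb)
    expect_equal(tr$termination, "low_rate")
    max(tr$data$t_ms)
  })
  # terminates within a few termination windows of t_off = 5 ms; the
  # background-only rate (detect_rate / (1 + SBR) ~ 0.82/ms) sits just
  # above the 16-per-20-ms threshold rate, so the rule typically fires
  # within one or two windows but occasionally needs a few more
  expect_true(all(ends > 5 - 1e-9))
  expect_lt(stats::median(ends), 5 + 2 * cfg$term_window_ms)
  expect_lt(max(ends), 5 + 6 * cfg$term_window_ms)
  # an event too short to reach n_on detections is flagged not initiated
  set.seed(12)
  tr <- run_localization(emitter_static(0, 0, t_off_ms = 0.5), cfg, opt,
                         tables = tb)
  expect_false(tr$initiated)
  expect_lt(tr$L, cfg$n_on)
})

test_that("position_estimate averages centers from n_c and matches a running-sum oracle", {
  opt <- default_optics(); cfg <- default_cfg(); tb <- default_tables()
  tr <- list(data = data.frame(i = 1:100, x_nm = as.numeric(1:100),
                               y_nm = rep(2, 100)),
             n_c = 80, L = 100)
  class(tr) <- "minsted_trace"
  expect_equal(position_estimate(tr, 100), c(90, 2))
  expect_equal(position_estimate(tr, 50), c(50, 2))  # ramp regime: raw center
  expect_error(position_estimate(tr, 101), "exceeds")
  set.seed(3)
  rtr <- run_localization(emitter_static(0, 0), cfg, opt,
                          max_photons = 500, tables = tb)
  for (N in c(80, 123, 500)) {
    s <- c(0, 0)
    for (i in rtr$n_c:N)
      s <- s + c(rtr$data$x_nm[i], rtr$data$y_nm[i])
    expect_equal(position_estimate(rtr, N), s / (N - rtr$n_c + 1))
  }
})

test_that("steady state is mean-reverting with AR(1) time of order 1/alpha", {
  tr <- static_traces()[[1]]
  x <- tr$data$x_nm[tr$n_c:tr$L]
  fit <- stats::ar(x, order.max = 1, aic = FALSE, method = "yw")
  tau <- -1 / log(fit$ar)
  alpha <- default_cfg()$alpha
  expect_gt(tau, 0.5 / alpha)
  expect_lt(tau, 2.5 / alpha)
})

test_that("steady-state spread grows with alpha (background disabled)", {
  opt <- optics_model(sbr_max = 1e9)   # background off
  spreads <- vapply(c(0.05, 0.15, 0.3), function(a) {
    cfg <- localizer_config(alpha = a)
    tb <- localizer_tables(cfg, opt)
    set.seed(500 + round(1000 * a))
    sds <- replicate(3, {
      tr <- run_localization(emitter_static(0, 0), cfg, opt,
                             max_photons = 1600, tables = tb)
      j <- 200:tr$L
      sqrt(stats::sd(tr$data$x_nm[j]) * stats::sd(tr$data$y_nm[j]))
    })
    mean(sds)
  }, numeric(1))
  expect_true(all(diff(spreads) > 0))
})
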