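# Online MINSTED localization loop and the per-photon Monte-Carlo
# engine that drives it.
#
# The localizer circles the donut zero around the current position
# estimate at radius R_i = FWHM_i / 2, increases the STED pulse energy
# for every detected photon (shrinking the E-PSF geometrically until the
# minimal FWHM is reached at photon index N_c), and nudges the circle
# center toward the azimuth of each detection by alpha * R_i.
# Coordinates are continuous 2-D nm (x right, y up); randomness comes
# from R's global RNG, so experiments are reproduced with set.seed().

#' Localizer configuration
#'
#' Parameters of the online MINSTED localization loop. Defaults are the
#' single-molecule (DNA-origami) preset: maximal pulse energy 1 nJ,
#' minimal FWHM 24 nm, minimal scan radius 12 nm, center-update fraction
#' 0.15, energy ramp reaching the minimum at `n_c_target = 80` detected
#' photons, termination when fewer than 16 detections arrive within a
#' 20-ms window.
#'
#' `fwhm_min` and `r_min` are derived from the optics at run time
#' (`fwhm_min = epsf_fwhm(e_max)`, `r_min = r_over_fwhm * fwhm_min`)
#' unless `r_min` is given explicitly as a floor override (the cell
#' presets use 15 or 20 nm).
#'
#' @param alpha Center-update fraction of the scan radius per detection.
#' @param r_over_fwhm Scan-radius to FWHM ratio (1/2 keeps the emitter
#'   on the steep flank of the E-PSF).
#' @param e_max Maximal STED pulse energy, nJ.
#' @param r_min Minimal scan radius, nm, or `NULL` to derive it.
#' @param n_c_target Photon index at which the ramp reaches the minimal
#'   FWHM.
#' @param n_on Initiation threshold: a trace shorter than `n_on`
#'   detections is flagged "not initiated" (the confocal search scan
#'   would not have locked on).
#' @param term_window_ms,term_min_counts Termination rule: stop when
#'   fewer than `term_min_counts` detections fall within a trailing
#'   window of `term_window_ms` milliseconds.
#' @param max_duration_ms Optional hard cap on the localization
#'   duration (ms); `Inf` disables it (origami preset). The cell
#'   presets use 200 ms.
#' @param detect_rate_khz Mean detection rate while a fluorophore is
#'   bound (signal plus background), kHz.
#' @param start_sd_nm Standard deviation of the initial center error
#'   relative to the true emitter position; `NULL` uses the confocal
#'   centroid precision `fwhm_conf / (2.355 * sqrt(n_on))`.
#' @return An object of class `localizer_config`.
#' @export
localizer_config <- function(alpha = 0.15, r_over_fwhm = 0.5, e_max = 1.0,
                             r_min = NULL, n_c_target = 80, n_on = 110,
                             term_window_ms = 20, term_min_counts = 16,
                             max_duration_ms = Inf, detect_rate_khz = 50,
                             start_sd_nm = NULL) {
  stopifnot(alpha > 0, alpha < 1, r_over_fwhm > 0, e_max > 0,
            n_c_target >= 2, term_window_ms > 0, term_min_counts >= 1,
            detect_rate_khz > 0)
  if (n_on < 80 || n_on > 140)
    warning("n_on outside the standard initiation range [80, 140]")
  structure(
    list(alpha = alpha, r_over_fwhm = r_over_fwhm, e_max = e_max,
         r_min = r_min, n_c_target = n_c_target, n_on = n_on,
         term_window_ms = term_window_ms,
         term_min_counts = term_min_counts,
         max_duration_ms = max_duration_ms,
         detect_rate_khz = detect_rate_khz, start_sd_nm = start_sd_nm),
    class = "localizer_config")
}

#' Precomputed localizer tables
#'
#' Precomputes the per-photon ramp (energy, FWHM, scan radius) and the
#' background probabilities for a configuration/optics pair. Building
#' the tables inverts the FWHM-energy curve once on a fine grid;
#' [run_localization()] accepts the result so that batch simulations do
#' not repeat the work.
#'
#' @param cfg A [localizer_config()].
#' @param optics An [optics_model()].
#' @return A list with the ramp vectors (`E`, `fwhm`, `R`, `p_bg` for
#'   photon indices `1..n_c_target`), the steady-state constants and the
#'   derived `fwhm_min`, `r_min`, `gamma`.
#' @export
localizer_tables <- function(cfg, optics) {
  fwhm_min <- epsf_fwhm(cfg$e_max, optics)
  r_min <- if (is.null(cfg$r_min)) cfg$r_over_fwhm * fwhm_min else cfg$r_min
  nc <- cfg$n_c_target
  gamma <- (fwhm_min / optics$fwhm_conf)^(1 / (nc - 1))
  fwhm <- pmax(fwhm_min, gamma^(0:(nc - 1)) * optics$fwhm_conf)
  fwhm[nc] <- fwhm_min          # exact endpoint (gamma^(nc-1) rounds off)
  # invert epsf_fwhm by monotone interpolation on an energy grid dense
  # near zero (the FWHM falls fastest there)
  eg <- cfg$e_max * seq(0, 1, length.out = 256)^2
  fg <- epsf_fwhm(eg, optics)
  E <- stats::approx(rev(fg), rev(eg), xout = fwhm, rule = 2)$y
  E[1] <- 0
  E[fwhm <= fwhm_min] <- cfg$e_max
  R <- pmax(r_min, cfg$r_over_fwhm * fwhm)
  sbr <- sbr_model(E, optics)
  list(E = E, fwhm = fwhm, R = R, p_bg = 1 / (1 + sbr), sbr = sbr,
       fwhm_min = fwhm_min, r_min = r_min, gamma = gamma,
       sbr_steady = sbr_model(cfg$e_max, optics))
}

#' Per-photon ramp schedule
#'
#' Energy, E-PSF width and scan radius for detected photon `i`: the
#' FWHM shrinks geometrically from the confocal value to `fwhm_min`
#' over `n_c_target` photons, `FWHM_i = max(fwhm_min,
#' gamma^(i-1) * fwhm_conf)` with `gamma = (fwhm_min /
#' fwhm_conf)^(1/(n_c_target - 1))`; the energy is obtained by
#' inverting the FWHM-energy curve and the radius is
#' `R_i = max(r_min, r_over_fwhm * FWHM_i)`.
#'
#' @param i Photon index (vectorized), `>= 1`.
#' @param cfg A [localizer_config()].
#' @param optics An [optics_model()].
#' @param tables Optional precomputed [localizer_tables()].
#' @return A data.frame with columns `i`, `E_nJ`, `fwhm_nm`, `R_nm`.
#' @export
ramp_schedule <- function(i, cfg, optics, tables = NULL) {
  stopifnot(all(i >= 1), all(i == round(i)))
  tb <- if (is.null(tables)) localizer_tables(cfg, optics) else tables
  idx <- pmin(i, cfg$n_c_target)
  data.frame(i = i, E_nJ = tb$E[idx], fwhm_nm = tb$fwhm[idx],
             R_nm = tb$R[idx])
}

# shared azimuth discretization for photon sampling
.N_AZ_BINS <- 1024L
.AZ_COS <- cos((seq_len(.N_AZ_BINS) - 0.5) * 2 * pi / .N_AZ_BINS)
.AZ_SIN <- sin((seq_len(.N_AZ_BINS) - 0.5) * 2 * pi / .N_AZ_BINS)

#' Sample one photon detection
#'
#' With probability `p_bg = 1 / (1 + SBR(E))` the photon is background
#' and its azimuth on the scan circle is uniform; otherwise the azimuth
#' is drawn with density proportional to the E-PSF value at the distance
#' between the emitter and the scan point, via a 1024-bin discretized
#' inverse CDF (uniform within the selected bin).
#'
#' @param emitter_pos Emitter position `c(x, y)` in nm.
#' @param center Current circle center `c(x, y)` in nm.
#' @param R Scan radius, nm, positive.
#' @param E Pulse energy, nJ.
#' @param optics An [optics_model()].
#' @param sbr Signal-to-background ratio; `NULL` evaluates
#'   [sbr_model()] at `E`, `Inf` disables background.
#' @return A list with elements `phi` (azimuth in radians) and
#'   `is_background`.
#' @export
sample_photon <- function(emitter_pos, center, R, E, optics, sbr = NULL) {
  stopifnot(R > 0)
  if (is.null(sbr)) sbr <- sbr_model(E, optics)
  p_bg <- if (is.infinite(sbr)) 0 else 1 / (1 + sbr)
  if (stats::runif(1) < p_bg) {
    return(list(phi = stats::runif(1, 0, 2 * pi), is_background = TRUE))
  }
  dx <- emitter_pos[1] - center[1]
  dy <- emitter_pos[2] - center[2]
  d <- sqrt((dx - R * .AZ_COS)^2 + (dy - R * .AZ_SIN)^2)
  w <- epsf(d, E, optics)
  cw <- cumsum(w)
  k <- findInterval(stats::runif(1) * cw[.N_AZ_BINS], cw) + 1L
  phi <- (k - 1L + stats::runif(1)) * 2 * pi / .N_AZ_BINS
  list(phi = phi, is_background = FALSE)
}

#' Shift the circle center toward a detection
#'
#' `center + alpha * R * (cos phi, sin phi)`. Background photons update
#' the center identically because the instrument cannot tell them apart.
#'
#' @param center Current center `c(x, y)` nm.
#' @param R Scan radius nm, positive.
#' @param phi Detection azimuth, radians.
#' @param alpha Update fraction.
#' @return The new center, numeric length 2.
#' @export
update_center <- function(center, R, phi, alpha = 0.15) {
  stopifnot(R > 0)
  center + alpha * R * c(cos(phi), sin(phi))
}

#' Static emitter description
#'
#' A fluorophore at a fixed position, bound from `t_on = 0` until
#' `t_off_ms`, after which only background photons are detected (at the
#' reduced background-only rate).
#'
#' @param x,y Position in nm.
#' @param t_off_ms Unbinding time in ms relative to the trace start.
#' @return A list understood by [run_localization()].
#' @export
emitter_static <- function(x = 0, y = 0, t_off_ms = Inf) {
  list(position = c(x, y), t_off_ms = t_off_ms)
}

#' Run one MINSTED localization
#'
#' Iterates the ramp schedule, photon sampling and center update until a
#' termination rule fires: the trailing `term_min_counts` photons span
#' more than `term_window_ms` (low-rate rule, which also catches
#' unbinding), the optional duration cap, or an explicit photon budget.
#' Inter-photon waiting times are exponential with mean
#' `1 / detect_rate` while the emitter is bound, and with the
#' background-only rate `detect_rate * p_bg(E)` after unbinding.
#'
#' @param emitter An [emitter_static()] (or a bare length-2 numeric
#'   position, taken as bound forever).
#' @param cfg A [localizer_config()].
#' @param optics An [optics_model()].
#' @param max_photons Optional photon budget (detections) for the trace.
#' @param tables Optional precomputed [localizer_tables()].
#' @return An object of class `minsted_trace`: a list with `data` (a
#'   data.frame with per-photon columns `i, t_ms, x_nm, y_nm, E_nJ,
#'   R_nm, fwhm_nm, is_bg`), `n_c`, `L`, `initiated`, `converged_ramp`
#'   (whether the ramp completed), `truth` (emitter position) and the
#'   termination reason.
#' @export
run_localization <- function(emitter, cfg, optics, max_photons = Inf,
                             tables = NULL) {
  if (is.numeric(emitter)) emitter <- emitter_static(emitter[1], emitter[2])
  tb <- if (is.null(tables)) localizer_tables(cfg, optics) else tables
  nc <- cfg$n_c_target
  rate_ms <- cfg$detect_rate_khz            # detections per ms while bound
  p_bg_steady <- 1 / (1 + tb$sbr_steady)
  start_sd <- if (is.null(cfg$start_sd_nm)) {
    optics$fwhm_conf / (2.355 * sqrt(cfg$n_on))
  } else cfg$start_sd_nm
  cx <- emitter$position[1] + stats::rnorm(1, sd = start_sd)
  cy <- emitter$position[2] + stats::rnorm(1, sd = start_sd)
  ex <- emitter$position[1]; ey <- emitter$position[2]

  cap <- if (is.finite(max_photons)) as.integer(max_photons) else 16384L
  xs <- numeric(cap); ys <- numeric(cap); ts <- numeric(cap)
  bg <- logical(cap)
  t <- 0; i <- 0L
  reason <- "budget"
  W <- cfg$term_min_counts
  repeat {
    if (i >= max_photons) { reason <- "budget"; break }
    if (i == cap && !is.finite(max_photons)) {   # grow storage
      cap2 <- cap * 2L
      xs <- c(xs, numeric(cap)); ys <- c(ys, numeric(cap))
      ts <- c(ts, numeric(cap)); bg <- c(bg, logical(cap))
      cap <- cap2
    }
    ii <- min(i + 1L, nc)
    E <- tb$E[ii]; R <- tb$R[ii]; p_bg <- tb$p_bg[ii]
    bound <- t < emitter$t_off_ms
    rate <- if (bound) rate_ms else rate_ms * p_bg
    dt <- stats::rexp(1, rate)
    if (bound && t + dt > emitter$t_off_ms) {
      # re-draw the residual waiting time at the background-only rate
      t <- emitter$t_off_ms
      dt <- stats::rexp(1, rate_ms * p_bg)
      bound <- FALSE
    }
    if (dt > cfg$term_window_ms) { reason <- "low_rate"; break }
    t <- t + dt
    if (t > cfg$max_duration_ms) { reason <- "duration_cap"; break }
    is_bg <- if (!bound) TRUE else (stats::runif(1) < p_bg)
    if (is_bg) {
      phi <- stats::runif(1, 0, 2 * pi)
    } else {
      dxv <- (ex - cx) - R * .AZ_COS
      dyv <- (ey - cy) - R * .AZ_SIN
      w <- epsf(sqrt(dxv * dxv + dyv * dyv), E, optics)
      cw <- cumsum(w)
      k <- findInterval(stats::runif(1) * cw[.N_AZ_BINS], cw) + 1L
      phi <- (k - 1L + stats::runif(1)) * 2 * pi / .N_AZ_BINS
    }
    cx <- cx + cfg$alpha * R * cos(phi)
    cy <- cy + cfg$alpha * R * sin(phi)
    i <- i + 1L
    xs[i] <- cx; ys[i] <- cy; ts[i] <- t; bg[i] <- is_bg
    if (i >= W && (ts[i] - ts[i - W + 1L]) > cfg$term_window_ms) {
      reason <- "low_rate"; break
    }
  }
  L <- i
  idx <- seq_len(L)
  sched <- pmin(idx, nc)
  data <- data.frame(i = idx, t_ms = ts[idx], x_nm = xs[idx],
                     y_nm = ys[idx], E_nJ = tb$E[sched],
                     R_nm = tb$R[sched], fwhm_nm = tb$fwhm[sched],
                     is_bg = bg[idx])
  structure(
    list(data = data, n_c = nc, L = L,
         initiated = L >= cfg$n_on,
         converged_ramp = L >= nc,
         truth = emitter$position, termination = reason),
    class = "minsted_trace")
}

#' @export
print.minsted_trace <- function(x, ...) {
  cat(sprintf("MINSTED trace: L = %d detections, N_c = %d, %s, %s\n",
              x$L, x$n_c,
              if (x$initiated) "initiated" else "not initiated",
              paste("terminated by", x$termination)))
  if (x$L >= x$n_c) {
    est <- position_estimate(x, x$L)
    cat(sprintf("  estimate (%.2f, %.2f) nm over %d post-ramp detections\n",
                est[1], est[2], x$L - x$n_c + 1))
  }
  invisible(x)
}

#' Position estimate from a trace
#'
#' For `N >= n_c` the arithmetic mean of the circle centers over photon
#' indices `n_c..N`; for `N < n_c` (ramp still running) the raw center
#' at index `N`.
#'
#' @param trace A `minsted_trace`.
#' @param N Photon count at which to evaluate, `1 <= N <= L`.
#' @return Numeric `c(x, y)` in nm.
#' @export
position_estimate <- function(trace, N) {
  stopifnot(N >= 1, N == round(N))
  if (N > trace$L) stop("position_estimate: N exceeds trace length L")
  d <- trace$data
  if (N < trace$n_c) {
    c(d$x_nm[N], d$y_nm[N])
  } else {
    j <- trace$n_c:N
    c(mean(d$x_nm[j]), mean(d$y_nm[j]))
  }
}
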