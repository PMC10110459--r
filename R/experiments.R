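# Canned simulation experiments: batches of static-emitter traces for
# the single-trace precision analysis, repeated-binding origami
# experiments for the cluster analysis, and direct-draw NPC particle
# sets for the structure pipeline.

#' Simulate a batch of static-emitter localization traces
#'
#' Runs the localizer on a static, permanently bound emitter `n_traces`
#' times with a photon budget of `n_c_target + photons_after_nc`
#' detections, mirroring the single-molecule measurement in which long
#' emission traces are recorded without a duration cap.
#'
#' @param n_traces Number of traces.
#' @param photons_after_nc Post-ramp detections per trace.
#' @param cfg A [localizer_config()].
#' @param optics An [optics_model()].
#' @param emitter Emitter position `c(x, y)` nm.
#' @param seed Optional RNG seed (set once for the whole batch).
#' @return List of `minsted_trace` objects.
#' @export
simulate_static_traces <- function(n_traces = 39, photons_after_nc = 10000,
                                   cfg = localizer_config(),
                                   optics = optics_model(),
                                   emitter = c(0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- localizer_tables(cfg, optics)
  budget <- cfg$n_c_target + photons_after_nc
  lapply(seq_len(n_traces), function(k) {
    run_localization(emitter_static(emitter[1], emitter[2]), cfg, optics,
                     max_photons = budget, tables = tb)
  })
}

#' Per-trace precision analysis
#'
#' Computes the blocked-standard-error curve and its power-law fit for
#' every trace that completed the ramp, and evaluates `sigma_est` (and,
#' where the block constraint allows, `sigma_block` directly) at the
#' requested total photon numbers.
#'
#' @param traces List of `minsted_trace` objects.
#' @param N_eval Total photon numbers at which to evaluate.
#' @param cfg A [precision_config()].
#' @param alpha Center-update fraction (fit initialization).
#' @return A list with `fits` (per-trace `power_law_fit`s), `est` (a
#'   traces-by-N matrix of sigma_est, nm), `block` (same shape,
#'   sigma_block where admissible else NA) and `N_eval`.
#' @export
precision_summary <- function(traces, N_eval = c(400, 2000, 10000),
                              cfg = precision_config(), alpha = 0.15) {
  done <- Filter(function(tr) tr$L >= tr$n_c + 25, traces)
  fits <- vector("list", length(done))
  est <- matrix(NA_real_, length(done), length(N_eval))
  blk <- matrix(NA_real_, length(done), length(N_eval))
  for (k in seq_along(done)) {
    tr <- done[[k]]
    curve <- sigma_block_curve(tr, cfg)
    fits[[k]] <- fit_power_law(curve$M, curve$sigma_nm, cfg, alpha)
    mmax <- (tr$L - tr$n_c + 1) / cfg$block_fraction
    for (j in seq_along(N_eval)) {
      if (N_eval[j] < tr$n_c) next
      est[k, j] <- sigma_est(fits[[k]], N_eval[j], tr$n_c)
      M <- N_eval[j] - tr$n_c + 1
      if (M >= 1 && M < mmax) blk[k, j] <- sigma_block(tr, M, cfg)
    }
  }
  list(fits = fits, est = est, block = blk, N_eval = N_eval)
}

#' Simulate a repeated-binding DNA-origami experiment
#'
#' Lays out `n_origami` grids far apart (separate focal regions),
#' generates DNA-PAINT binding events per grid, and runs a MINSTED
#' localization for every non-overlapping event (two fluorophores
#' active at once in one focal region are excluded, as on the
#' instrument). Returns the traces together with the ground truth.
#'
#' @param n_origami Number of origami structures in the field.
#' @param spacing Grid pitch, nm.
#' @param layout `"rect"` or `"hex"`.
#' @param duration_s Experiment duration per structure, s.
#' @param kin A [kinetics_model()]; defaults to [origami_kinetics()].
#' @param cfg A [localizer_config()].
#' @param optics An [optics_model()].
#' @param pitch_nm Separation between origami centers, nm.
#' @param seed Optional RNG seed.
#' @return A list with `traces`, `events` (one row per localized
#'   event), `sites` (all ground-truth sites) and `site_of` (site id,
#'   globally unique, per trace).
#' @export
simulate_origami_experiment <- function(n_origami = 3, spacing = 12,
                                        layout = "rect", duration_s = 240,
                                        kin = origami_kinetics(),
                                        cfg = localizer_config(),
                                        optics = optics_model(),
                                        pitch_nm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- localizer_tables(cfg, optics)
  traces <- list(); site_of <- integer(); ev_rows <- list()
  all_sites <- list()
  for (g in seq_len(n_origami)) {
    sites <- make_origami(spacing, layout = layout)
    sites$x_nm <- sites$x_nm + (g - 1) * pitch_nm
    sites$site_id <- sites$site_id + (g - 1) * 1000L
    all_sites[[g]] <- sites
    ev <- generate_events(sites, kin, duration_s)
    ev <- ev[!ev$overlaps, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      dur_ms <- (ev$t_off_s[r] - ev$t_on_s[r]) * 1000
      tr <- run_localization(
        emitter_static(ev$x_nm[r], ev$y_nm[r], t_off_ms = dur_ms),
        cfg, optics, tables = tb)
      traces[[length(traces) + 1L]] <- tr
      site_of[length(site_of) + 1L] <- ev$site_id[r]
      ev_rows[[length(ev_rows) + 1L]] <- ev[r, ]
    }
  }
  list(traces = traces,
       events = if (length(ev_rows)) do.call(rbind, ev_rows) else NULL,
       sites = do.call(rbind, all_sites), site_of = site_of)
}

#' Localization table from traces
#'
#' Collapses traces into one localization per trace: the final position
#' estimate, the trace bookkeeping (`L`, `n_c`, duration) and a
#' per-localization precision. The precision is the power-law estimate
#' [sigma_est()] at `N = L` when the trace is long enough to fit
#' (at least 25 post-ramp detections), else the naive standard error
#' of the post-ramp centers.
#'
#' @param traces List of `minsted_trace` objects.
#' @param cfg A [precision_config()].
#' @param keep Optional logical vector: which traces to include.
#' @return data.frame with columns `id, x_nm, y_nm, sigma_nm, L, n_c,
#'   t_s` (and `truth_x_nm`, `truth_y_nm`).
#' @export
localization_table <- function(traces, cfg = precision_config(),
                               keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(traces))
  rows <- list()
  for (k in which(keep)) {
    tr <- traces[[k]]
    if (tr$L < tr$n_c) next
    pos <- position_estimate(tr, tr$L)
    m <- tr$L - tr$n_c + 1
    sig <- if (m >= 25) {
      curve <- sigma_block_curve(tr, cfg)
      fit <- fit_power_law(curve$M, curve$sigma_nm, cfg)
      sigma_est(fit, tr$L, tr$n_c)
    } else {
      j <- tr$n_c:tr$L
      sqrt(stats::sd(tr$data$x_nm[j]) * stats::sd(tr$data$y_nm[j])) / sqrt(m)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = k, x_nm = pos[1], y_nm = pos[2], sigma_nm = sig,
      L = tr$L, n_c = tr$n_c, t_s = max(tr$data$t_ms) / 1000,
      truth_x_nm = tr$truth[1], truth_y_nm = tr$truth[2])
  }
  if (length(rows) == 0L) {
    return(data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
                      sigma_nm = numeric(), L = integer(),
                      n_c = integer(), t_s = numeric(),
                      truth_x_nm = numeric(), truth_y_nm = numeric()))
  }
  do.call(rbind, rows)
}

#' Direct-draw synthetic NPC particle set
#'
#' Generates localization sets for `n_npc` nuclear pores without
#' running the full photon-level localizer: each site is detected with
#' probability `p_site`; a detected site contributes
#' `locs_per_site` localizations, each at the site position plus a
#' disk-uniform linker offset plus isotropic Gaussian localization
#' noise. Used for testing the structure-analysis pipeline at scale;
#' labeled synthetic throughout.
#'
#' @param n_npc Number of pores.
#' @param p_site Per-site detection probability.
#' @param locs_per_site Localizations per detected site.
#' @param sigma_loc Localization precision, nm.
#' @param linker_nm Linker disk radius, nm.
#' @param diameter Ring diameter, nm.
#' @param stagger_deg Corner stagger, degrees.
#' @param seed Optional RNG seed.
#' @return List of particles; each is a list with `points` (matrix) and
#'   `truth_center` = c(0,0) in its own frame.
#' @export
simulate_npc_particles <- function(n_npc = 100, p_site = 0.9,
                                   locs_per_site = 3, sigma_loc = 1,
                                   linker_nm = 7, diameter = 112,
                                   stagger_deg = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- make_npc(diameter = diameter, stagger_deg = stagger_deg)
  lapply(seq_len(n_npc), function(k) {
    det <- stats::runif(nrow(sites)) <= p_site
    pts <- NULL
    for (s in which(det)) {
      n <- locs_per_site
      off <- .disk_offset(n, linker_nm)
      pts <- rbind(pts, cbind(sites$x_nm[s] + off[, 1] +
                                stats::rnorm(n, sd = sigma_loc),
                              sites$y_nm[s] + off[, 2] +
                                stats::rnorm(n, sd = sigma_loc)))
    }
    list(points = pts, detected_sites = which(det))
  })
}
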