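# Synthetic ground-truth structures and DNA-PAINT binding kinetics.
#
# Site sets are plain data.frames (site_id, x_nm, y_nm) with a
# structure_kind attribute; event tables carry per-event fluorophore
# positions (site + linker offset + slow site jitter).

#' Build a site set
#'
#' @param x,y Site coordinates, nm.
#' @param kind Structure kind label.
#' @return data.frame of class `site_set` with columns `site_id`,
#'   `x_nm`, `y_nm`.
#' @export
site_set <- function(x, y, kind = "custom") {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  out <- data.frame(site_id = seq_along(x), x_nm = x, y_nm = y)
  attr(out, "structure_kind") <- kind
  class(out) <- c("site_set", "data.frame")
  out
}

#' DNA-origami binding-site grid
#'
#' A rows-by-cols grid of docking sites centered at the origin. The
#' rectangular layout places sites on a square lattice with the given
#' pitch; the hexagonal layout uses a triangular lattice in which every
#' interior site has six neighbors at exactly `spacing` nm (rows are
#' `spacing * sqrt(3)/2` apart and odd rows are shifted by half a
#' pitch).
#'
#' @param spacing Lattice pitch in nm, positive (12, 6 and 4 nm are the
#'   standard designs).
#' @param rows,cols Grid dimensions.
#' @param layout `"rect"` or `"hex"`.
#' @return A [site_set()] of `rows * cols` sites.
#' @export
make_origami <- function(spacing, rows = 3, cols = 3,
                         layout = c("rect", "hex")) {
  layout <- match.arg(layout)
  if (spacing <= 0) stop("make_origami: spacing must be positive")
  r <- rep(seq_len(rows), each = cols) - 1
  c_ <- rep(seq_len(cols), rows) - 1
  if (layout == "rect") {
    x <- c_ * spacing
    y <- r * spacing
  } else {
    x <- c_ * spacing + (r %% 2) * spacing / 2
    y <- r * spacing * sqrt(3) / 2
  }
  ss <- site_set(x - mean(x), y - mean(y), kind = "origami_grid")
  attr(ss, "spacing_nm") <- spacing
  ss
}

#' Nuclear-pore-complex site model
#'
#' Sites on a circle of the given diameter: `corners` corners (eight
#' for the NPC), each carrying `per_corner` sites (four NUP96 copies
#' per asymmetric unit, 32 in total) staggered along the circumference
#' by `stagger_deg` between neighbors. Corner centers sit at azimuths
#' `phase_deg + k * 360/corners`; the default phase of 22.5 deg centers
#' each corner inside a `[k*45, (k+1)*45)` occupancy sector.
#'
#' @param diameter Ring diameter, nm, positive (112 nm for NUP96
#'   C-termini).
#' @param corners Number of rotational units.
#' @param per_corner Sites per unit.
#' @param stagger_deg Angular spacing between the sites of one corner;
#'   0 collapses them onto the corner azimuth.
#' @param phase_deg Azimuth of the first corner center.
#' @return A [site_set()] of `corners * per_corner` sites, all at
#'   radius `diameter / 2`.
#' @export
make_npc <- function(diameter = 112, corners = 8, per_corner = 4,
                     stagger_deg = 7, phase_deg = 360 / (2 * corners)) {
  if (diameter <= 0) stop("make_npc: diameter must be positive")
  corner_az <- phase_deg + (seq_len(corners) - 1) * 360 / corners
  within <- (seq_len(per_corner) - (per_corner + 1) / 2) * stagger_deg
  az <- as.vector(outer(within, corner_az, `+`)) * pi / 180
  rr <- diameter / 2
  ss <- site_set(rr * cos(az), rr * sin(az), kind = "npc")
  attr(ss, "diameter_nm") <- diameter
  ss
}

#' DNA-PAINT kinetics model
#'
#' Per-site alternating renewal process: exponentially distributed dark
#' times (imager arrival) and bound times, with incomplete labeling,
#' a flexible-linker offset and a slow site-position jitter.
#'
#' Defaults describe the cell-labeling construct (nanobody + GFP +
#' linker, about 7 nm); use [origami_kinetics()] for origami grids
#' where the fluorophore docks at a reproducible position and the
#' per-event scatter is carried entirely by the jitter `s`.
#'
#' @param mean_bound_ms Mean bound (on) time, ms.
#' @param mean_dark_s Mean dark time per site, s.
#' @param labeling_efficiency Fraction of sites carrying a docking
#'   strand.
#' @param linker_length_nm Radius of the disk of possible fluorophore
#'   positions around the site (uniform over the disk, re-drawn per
#'   event); 0 disables.
#' @param site_jitter_nm Standard deviation `s` of the slow Gaussian
#'   wander of the site position. The wander decorrelates between
#'   events (its correlation time lies between the event duration and
#'   the inter-event dark time), so it is drawn independently per
#'   event.
#' @param bleach_cap_ms Optional cap on the usable event duration
#'   (docking-site protection); `Inf` disables.
#' @param single_shot Photoactivation mode: at most one event per site
#'   with an exponentially distributed photon budget.
#' @param single_shot_median_photons Median photon budget in
#'   single-shot mode.
#' @return An object of class `kinetics_model`.
#' @export
kinetics_model <- function(mean_bound_ms = 150, mean_dark_s = 30,
                           labeling_efficiency = 0.85,
                           linker_length_nm = 7, site_jitter_nm = 0.72,
                           bleach_cap_ms = 200, single_shot = FALSE,
                           single_shot_median_photons = 161) {
  stopifnot(mean_bound_ms > 0, mean_dark_s > 0,
            labeling_efficiency > 0, labeling_efficiency <= 1,
            linker_length_nm >= 0, site_jitter_nm >= 0)
  structure(
    list(mean_bound_ms = mean_bound_ms, mean_dark_s = mean_dark_s,
         labeling_efficiency = labeling_efficiency,
         linker_length_nm = linker_length_nm,
         site_jitter_nm = site_jitter_nm, bleach_cap_ms = bleach_cap_ms,
         single_shot = single_shot,
         single_shot_median_photons = single_shot_median_photons),
    class = "kinetics_model")
}

#' Origami kinetics preset
#'
#' Kinetics for DNA-origami grids: the imager docks at a reproducible
#' position (no flexible-linker disk), event-to-event scatter enters
#' only through the residual site jitter `s = 0.72 nm`, and events are
#' not capped (the single-molecule measurements run without a duration
#' limit).
#'
#' @param ... Overrides passed to [kinetics_model()].
#' @export
origami_kinetics <- function(...) {
  args <- utils::modifyList(
    list(linker_length_nm = 0, site_jitter_nm = 0.72,
         bleach_cap_ms = Inf),
    list(...))
  do.call(kinetics_model, args)
}

# uniform draw from a disk of the given radius
.disk_offset <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

#' Generate DNA-PAINT binding events
#'
#' Simulates the per-site alternating renewal process over the given
#' duration. Each labeled site alternates exponential dark and bound
#' intervals; each event's fluorophore position is the site position
#' plus a disk-uniform linker offset (re-drawn per event) plus an
#' independent Gaussian jitter draw of standard deviation
#' `site_jitter_nm` (the slow wander decorrelates between events).
#' Events overlapping in time with another event of the same structure
#' (one focal region) are flagged `overlaps = TRUE` for
#' "second fluorophore" filtering. In single-shot mode every labeled
#' site emits at most one event with an exponential photon budget.
#'
#' @param sites A [site_set()].
#' @param kin A [kinetics_model()].
#' @param duration_s Experiment duration in seconds, positive.
#' @return data.frame with columns `event_id`, `site_id`, `t_on_s`,
#'   `t_off_s`, `x_nm`, `y_nm`, `overlaps`, `photon_budget` (NA unless
#'   single-shot).
#' @export
generate_events <- function(sites, kin, duration_s) {
  if (duration_s <= 0) stop("generate_events: duration must be positive")
  labeled <- sites$site_id[stats::runif(nrow(sites)) <= kin$labeling_efficiency]
  rows <- list()
  for (sid in labeled) {
    sx <- sites$x_nm[sites$site_id == sid]
    sy <- sites$y_nm[sites$site_id == sid]
    if (kin$single_shot) {
      t_on <- stats::runif(1, 0, duration_s)
      budget <- stats::rexp(1, log(2) / kin$single_shot_median_photons)
      rows[[length(rows) + 1L]] <-
        data.frame(site_id = sid, t_on_s = t_on, t_off_s = NA_real_,
                   photon_budget = ceiling(budget))
      next
    }
    t <- 0
    repeat {
      t <- t + stats::rexp(1, 1 / kin$mean_dark_s)
      if (t >= duration_s) break
      dur_ms <- stats::rexp(1, 1 / kin$mean_bound_ms)
      if (is.finite(kin$bleach_cap_ms)) dur_ms <- min(dur_ms, kin$bleach_cap_ms)
      t_off <- min(t + dur_ms / 1000, duration_s)
      rows[[length(rows) + 1L]] <-
        data.frame(site_id = sid, t_on_s = t, t_off_s = t_off,
                   photon_budget = NA_real_)
      t <- t_off
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(event_id = integer(), site_id = integer(),
                      t_on_s = numeric(), t_off_s = numeric(),
                      x_nm = numeric(), y_nm = numeric(),
                      overlaps = logical(), photon_budget = numeric()))
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$t_on_s), , drop = FALSE]
  n <- nrow(ev)
  ev$event_id <- seq_len(n)
  off <- .disk_offset(n, kin$linker_length_nm)
  jit <- matrix(stats::rnorm(2 * n, sd = kin$site_jitter_nm), ncol = 2)
  ev$x_nm <- sites$x_nm[match(ev$site_id, sites$site_id)] + off[, 1] + jit[, 1]
  ev$y_nm <- sites$y_nm[match(ev$site_id, sites$site_id)] + off[, 2] + jit[, 2]
  # temporal overlap within the focal region (any pair of events)
  ev$overlaps <- FALSE
  if (n > 1 && !kin$single_shot) {
    for (i in seq_len(n - 1L)) {
      if (ev$t_off_s[i] > ev$t_on_s[i + 1L]) {
        ev$overlaps[c(i, i + 1L)] <- TRUE
      }
    }
  }
  ev[, c("event_id", "site_id", "t_on_s", "t_off_s", "x_nm", "y_nm",
         "overlaps", "photon_budget")]
}
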