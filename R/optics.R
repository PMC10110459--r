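# Effective-PSF model for a blue-shifted STED microscope.
#
# The E-PSF is the product of the excitation probability (a confocal
# Gaussian) and the survival probability under stimulated-emission
# depletion by a vortex (donut) beam, plus a weak "pedestal" caused by
# direct anti-Stokes excitation through the blue-shifted donut itself.
# All radial coordinates are in nm, pulse energies in nJ.

LN2 <- log(2)

#' Optical model of the MINSTED effective PSF
#'
#' Bundles the optical parameters needed to evaluate the effective point
#' spread function (E-PSF) of a STED microscope whose depletion beam is
#' blue-shifted into the emission band: a large stimulated-emission
#' cross-section at the price of a weak direct-excitation pedestal.
#'
#' Unless an explicit `e_sat` is supplied, the depletion saturation
#' energy is calibrated so that the E-PSF reaches `calibrate$fwhm` nm
#' full-width at half-maximum at a pulse energy of `calibrate$E` nJ
#' (defaults: 24 nm at 1 nJ, the operating point of the simulated
#' instrument).
#'
#' @param lambda_exc Excitation wavelength (nm).
#' @param lambda_sted Depletion wavelength (nm).
#' @param na Numerical aperture of the objective.
#' @param fwhm_conf FWHM of the confocal (zero-depletion) E-PSF in nm.
#' @param w_donut Donut scale length in nm: the donut intensity is
#'   `u * exp(1 - u)` with `u = 2 r^2 / w_donut^2`, peaking at
#'   `r = w_donut / sqrt(2)`.
#' @param e_sat Depletion saturation pulse energy (nJ). `NULL` means
#'   calibrate from the `calibrate` anchor.
#' @param beta_pedestal Direct-excitation coefficient per nJ: the
#'   pedestal term is `beta_pedestal * E * donut_profile(r)`.
#' @param sigma_rel Relative stimulated-emission cross-section at the
#'   depletion wavelength (fraction of its global maximum; metadata, not
#'   used in the radial model).
#' @param sbr_max Signal-to-background ratio at the reference energy
#'   `e_ref` (diffusing-imager background).
#' @param e_ref Pulse energy (nJ) at which `sbr_max` is anchored.
#' @param calibrate List with elements `fwhm` and `E`: the calibration
#'   anchor used when `e_sat` is `NULL`.
#' @return An object of class `optics_model`.
#' @examples
#' opt <- optics_model()
#' epsf_fwhm(1, opt)   # 24 by calibration
#' @export
optics_model <- function(lambda_exc = 560, lambda_sted = 636, na = 1.4,
                         fwhm_conf = 250, w_donut = 230, e_sat = NULL,
                         beta_pedestal = 0.02, sigma_rel = 0.28,
                         sbr_max = 60, e_ref = 1.0,
                         calibrate = list(fwhm = 24, E = 1.0)) {
  stopifnot(fwhm_conf > 0, w_donut > 0, beta_pedestal >= 0, sbr_max > 0,
            e_ref > 0, na > 0)
  opt <- structure(
    list(lambda_exc = lambda_exc, lambda_sted = lambda_sted, na = na,
         fwhm_conf = fwhm_conf, w_donut = w_donut, e_sat = NA_real_,
         beta_pedestal = beta_pedestal, sigma_rel = sigma_rel,
         sbr_max = sbr_max, e_ref = e_ref),
    class = "optics_model")
  if (is.null(e_sat)) {
    opt$e_sat <- calibrate_saturation(calibrate$fwhm, calibrate$E, opt)
  } else {
    stopifnot(e_sat > 0)
    opt$e_sat <- e_sat
  }
  opt
}

#' @export
print.optics_model <- function(x, ...) {
  cat("MINSTED optics model\n")
  cat(sprintf("  lambda_exc/sted: %g / %g nm, NA %g\n",
              x$lambda_exc, x$lambda_sted, x$na))
  cat(sprintf("  confocal FWHM: %g nm, donut scale: %g nm\n",
              x$fwhm_conf, x$w_donut))
  cat(sprintf("  e_sat: %.4g nJ, pedestal beta: %g /nJ\n",
              x$e_sat, x$beta_pedestal))
  cat(sprintf("  SBR %g at %g nJ\n", x$sbr_max, x$e_ref))
  invisible(x)
}

#' Radial donut (vortex beam) intensity profile
#'
#' Normalized intensity of the depletion donut: `u * exp(1 - u)` with
#' `u = 2 r^2 / w_donut^2`. Zero at the vortex center (quadratic zero),
#' exactly 1 at its maximum `r = w_donut / sqrt(2)`.
#'
#' @param r Radial offset(s) from the donut center, nm, non-negative.
#' @param optics An [optics_model()].
#' @return Relative intensity in `[0, 1]`.
#' @export
donut_profile <- function(r, optics) {
  if (any(r < 0)) stop("donut_profile: radial offset r must be >= 0")
  u <- 2 * r^2 / optics$w_donut^2
  u * exp(1 - u)
}

#' Effective PSF: relative emission probability
#'
#' Product of the excitation probability (confocal Gaussian plus the
#' direct-excitation pedestal of the blue-shifted donut) and the
#' survival probability under depletion,
#' `[exc(r) + beta * E * d(r)] * exp(-ln2 * (E / e_sat) * d(r))`,
#' where `exc(r) = exp(-4 ln2 r^2 / fwhm_conf^2)` and `d` is
#' [donut_profile()]. At `E = 0` this is the confocal Gaussian; the peak
#' `epsf(0, E) = 1` for every `E` because the donut zero spares the
#' center.
#'
#' @param r Radial offset(s), nm, non-negative.
#' @param E STED pulse energy, nJ, non-negative scalar.
#' @param optics An [optics_model()].
#' @return Relative emission probability (vector over `r`).
#' @export
epsf <- function(r, E, optics) {
  if (any(r < 0)) stop("epsf: radial offset r must be >= 0")
  if (length(E) != 1L || E < 0) stop("epsf: E must be a single energy >= 0")
  d <- donut_profile(r, optics)
  exc <- exp(-4 * LN2 * r^2 / optics$fwhm_conf^2)
  (exc + optics$beta_pedestal * E * d) * exp(-LN2 * (E / optics$e_sat) * d)
}

# First local minimum of the E-PSF central lobe (separates the central
# peak from the pedestal). Returns the grid radius of the minimum, or
# the grid end if the profile is monotone.
.central_lobe_edge <- function(E, optics, n = 4096) {
  r <- seq(0, 1.5 * optics$fwhm_conf, length.out = n)
  v <- epsf(r, E, optics)
  dv <- diff(v)
  up <- which(dv > 0)
  if (length(up) == 0L) r[n] else r[up[1L]]
}

#' FWHM of the effective PSF as a function of pulse energy
#'
#' Full width at half of the central-peak maximum of `epsf(., E)`,
#' obtained by a bracketed root search restricted to the central lobe
#' (radii below the first local minimum), so that the pedestal is
#' excluded. Monotone non-increasing in `E`.
#'
#' @param E STED pulse energy (nJ); may be a vector.
#' @param optics An [optics_model()].
#' @return FWHM in nm.
#' @export
epsf_fwhm <- function(E, optics) {
  if (any(E < 0)) stop("epsf_fwhm: E must be >= 0")
  one <- function(e) {
    if (e == 0) return(optics$fwhm_conf)
    edge <- .central_lobe_edge(e, optics)
    half <- 0.5 * epsf(0, e, optics)
    f <- function(r) epsf(r, e, optics) - half
    # value at the lobe edge is below half for any realistic setting
    root <- stats::uniroot(f, lower = 0, upper = edge, tol = 1e-6)$root
    2 * root
  }
  vapply(E, one, numeric(1))
}

#' Calibrate the depletion saturation energy
#'
#' Finds `e_sat` such that `epsf_fwhm(target_E) == target_fwhm` within
#' 0.01 nm (scalar root search on `log(e_sat)`); the FWHM at fixed `E`
#' is monotone increasing in `e_sat`, so the root is unique.
#'
#' @param target_fwhm Target FWHM (nm), must be below the confocal FWHM.
#' @param target_E Pulse energy (nJ) at which the target is met.
#' @param optics An [optics_model()] (its `e_sat` is ignored).
#' @return The calibrated saturation energy in nJ.
#' @export
calibrate_saturation <- function(target_fwhm, target_E, optics) {
  if (target_fwhm >= optics$fwhm_conf)
    stop("calibrate_saturation: target FWHM must be below the confocal FWHM")
  if (target_fwhm <= 0 || target_E <= 0)
    stop("calibrate_saturation: target FWHM and energy must be positive")
  f <- function(loges) {
    o <- optics
    o$e_sat <- exp(loges)
    epsf_fwhm(target_E, o) - target_fwhm
  }
  root <- stats::uniroot(f, lower = -14, upper = 14, tol = 1e-10)$root
  es <- exp(root)
  check <- optics; check$e_sat <- es
  if (abs(epsf_fwhm(target_E, check) - target_fwhm) > 0.01)
    stop("calibrate_saturation: root search did not reach 0.01 nm accuracy")
  es
}

# Focal-plane integral 2*pi * int epsf(r, E) r dr on the fixed radial
# grid r in [0, 3 * fwhm_conf], 4096 samples, trapezoid rule.
.epsf_area <- function(E, optics, n = 4096) {
  r <- seq(0, 3 * optics$fwhm_conf, length.out = n)
  v <- epsf(r, E, optics) * r
  h <- r[2] - r[1]
  2 * pi * h * (sum(v) - 0.5 * (v[1] + v[n]))
}

#' Signal-to-background ratio model
#'
#' Signal is proportional to the E-PSF peak `epsf(0, E) = 1`; background
#' from uniformly diffusing imagers is proportional to the focal-plane
#' integral of the E-PSF. The SBR gain over confocal is therefore the
#' area ratio `area(0) / area(E)`, and the absolute SBR is anchored so
#' that `sbr_model(e_ref) == sbr_max`.
#'
#' @param E STED pulse energy (nJ); may be a vector.
#' @param optics An [optics_model()].
#' @return SBR (dimensionless).
#' @seealso [sbr_gain()] for the fold-change over confocal.
#' @export
sbr_model <- function(E, optics) {
  if (any(E < 0)) stop("sbr_model: E must be >= 0")
  sbr_conf <- optics$sbr_max / sbr_gain(optics$e_ref, optics)
  sbr_conf * sbr_gain(E, optics)
}

#' SBR fold-change relative to confocal
#'
#' `gain(E) = [peak(E)/area(E)] / [peak(0)/area(0)]`; the peak is
#' invariant, so this is the confocal-to-depleted area ratio.
#'
#' @inheritParams sbr_model
#' @return Gain factor (1 at `E = 0`).
#' @export
sbr_gain <- function(E, optics) {
  if (any(E < 0)) stop("sbr_gain: E must be >= 0")
  a0 <- .epsf_area(0, optics)
  vapply(E, function(e) a0 / .epsf_area(e, optics), numeric(1))
}
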