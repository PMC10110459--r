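# Downstream structure analysis: NPC sector occupancy, ring fitting
# with radial Gaussian profile, ellipticity, radial outlier rejection,
# template-free particle overlay, reference coverage and density
# clustering.

#' Sector occupancy of a nuclear pore
#'
#' Divides the plane around `center` into eight 45-degree sectors with
#' boundaries at `k * 45` degrees (aligned frame) and counts the
#' sectors containing at least one point whose radial distance lies in
#' `[r_in, r_out]`.
#'
#' @param points Two-column matrix of positions, nm.
#' @param center Pore center `c(x, y)`.
#' @param r_in,r_out Radial band, nm.
#' @param n_sectors Number of sectors.
#' @return Integer count of occupied sectors, `0..n_sectors`.
#' @export
sector_occupancy <- function(points, center, r_in = 40, r_out = 70,
                             n_sectors = 8) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) return(0L)
  dx <- points[, 1] - center[1]; dy <- points[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  keep <- r >= r_in & r <= r_out
  if (!any(keep)) return(0L)
  az <- atan2(dy[keep], dx[keep]) %% (2 * pi)
  sec <- floor(az / (2 * pi / n_sectors))
  length(unique(sec))
}

# direct least-squares (Fitzgibbon) ellipse fit; returns the conic
# coefficients (A, B, C, D, E, F) with the ellipse constraint
# 4AC - B^2 = 1
.fit_conic_ellipse <- function(points) {
  x <- points[, 1] - mean(points[, 1])
  y <- points[, 2] - mean(points[, 2])
  s <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(s) || s == 0) stop("degenerate point set for conic fit")
  x <- x / s; y <- y / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("degenerate (collinear) points in conic fit")
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0L) stop("conic fit did not yield an ellipse")
  a1 <- vecs[, k[1]]
  c(a1, T_ %*% a1)   # scaled frame is fine: the axis RATIO is invariant
}

# semi-axis lengths of a central conic A x^2 + B xy + C y^2 + Dx + Ey + F
.conic_axes <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F_ <- co[6]
  Mq <- matrix(c(A, B / 2, B / 2, C), 2)
  ctr <- solve(2 * Mq, -c(D, E))
  c0 <- F_ + 0.5 * (D * ctr[1] + E * ctr[2])
  lam <- eigen(Mq, symmetric = TRUE, only.values = TRUE)$values
  ax2 <- -c0 / lam
  if (any(ax2 <= 0)) stop("conic is not a real ellipse")
  sort(sqrt(ax2), decreasing = TRUE)
}

#' Fit a ring with radial Gaussian profile
#'
#' The center minimizes the variance of the radial distances (a 2-D
#' Nelder-Mead search started at the centroid); under the radial
#' Gaussian model the maximum-likelihood ring radius is the mean radial
#' distance, so `diameter = 2 * mean(r)` and `radial_sigma = sd(r)`.
#' The aspect ratio comes from a direct least-squares conic (ellipse)
#' fit to the points.
#'
#' @param points Two-column matrix of positions (nm), at least 8 rows.
#' @return Object of class `ring_fit`: list with `center`, `diameter`,
#'   `radial_sigma`, `aspect_ratio`.
#' @export
fit_ring <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 8) stop("fit_ring: need at least 8 points")
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-10 * ev[1])
    stop("fit_ring: degenerate (collinear) point set")
  obj <- function(p) {
    r <- sqrt((points[, 1] - p[1])^2 + (points[, 2] - p[2])^2)
    stats::var(r)
  }
  ctr0 <- colMeans(points)
  opt <- stats::optim(ctr0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  ctr <- opt$par
  r <- sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2)
  ar <- tryCatch({
    ax <- .conic_axes(.fit_conic_ellipse(points))
    ax[1] / ax[2]
  }, error = function(e) NA_real_)
  structure(
    list(center = ctr, diameter = 2 * mean(r),
         radial_sigma = stats::sd(r), aspect_ratio = ar),
    class = "ring_fit")
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf(
    "ring fit: center (%.1f, %.1f) nm, diameter %.1f nm, radial sigma %.2f nm, aspect %.3f\n",
    x$center[1], x$center[2], x$diameter, x$radial_sigma, x$aspect_ratio))
  invisible(x)
}

#' Radial outlier filter
#'
#' Keeps points whose radial distance from the fitted center deviates
#' from the mean ring radius by at most `tol` nm (rejects localizations
#' from neighboring pores and unspecific binding).
#'
#' @param points Two-column matrix, nm.
#' @param fit A [fit_ring()] result.
#' @param tol Tolerance, nm.
#' @return The retained points (matrix).
#' @export
radial_outlier_filter <- function(points, fit, tol = 20) {
  points <- as.matrix(points)
  r <- sqrt((points[, 1] - fit$center[1])^2 +
              (points[, 2] - fit$center[2])^2)
  points[abs(r - fit$diameter / 2) <= tol, , drop = FALSE]
}

# Gaussian kernel correlation between a point set and a fixed set:
# sum_ij exp(-|x_i - y_j|^2 / (4 sigma^2)). Symmetric in the two sets.
.kernel_corr <- function(a, b, sigma) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sum(exp(-d2 / (4 * sigma^2)))
}

.apply_rigid <- function(points, theta, t) {
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * points[, 1] - st * points[, 2] + t[1],
        st * points[, 1] + ct * points[, 2] + t[2])
}

#' Template-free rigid particle alignment
#'
#' Overlays multiple realizations of the same structure by maximizing
#' the total pairwise Gaussian kernel correlation, the same objective
#' class as kernel-density template registration. Each iteration
#' refines every particle in turn against the union of all other
#' particles (leave-one-out), searching rotations on a coarse grid and
#' polishing rotation plus translation with Nelder-Mead; an update is
#' accepted only if it improves the particle's own correlation, which
#' makes the total objective non-decreasing. An optional
#' symmetry-randomization pass rotates each particle by a random
#' multiple of `360/symmetry_fold` degrees and re-refines with small
#' angular corrections only, removing the density-peak pile-up bias of
#' the plain overlay.
#'
#' @param particles List of two-column point matrices (or lists with a
#'   `points` element).
#' @param kernel_sigma Kernel bandwidth, nm.
#' @param n_iter Refinement iterations.
#' @param rot_grid_deg Coarse rotation-search step, degrees.
#' @param symmetry_fold Optional symmetry order for the randomization
#'   pass (e.g. 8 for the NPC); `NULL` disables.
#' @param refine_deg Angular bound for the small-correction pass.
#' @return List with `particles` (aligned point matrices),
#'   `transforms` (per-particle `theta`, `tx`, `ty`) and `objective`
#'   (total kernel correlation per iteration).
#' @export
align_particles <- function(particles, kernel_sigma = 5, n_iter = 4,
                            rot_grid_deg = 10, symmetry_fold = NULL,
                            refine_deg = 15) {
  pts <- lapply(particles, function(p) {
    m <- if (is.list(p) && !is.null(p$points)) p$points else as.matrix(p)
    m
  })
  np <- length(pts)
  stopifnot(np >= 1)
  # center each particle; transforms act on the centered coordinates
  centers <- lapply(pts, colMeans)
  cpts <- Map(function(m, c) sweep(m, 2, c), pts, centers)
  tf <- data.frame(theta = numeric(np), tx = numeric(np), ty = numeric(np))
  if (np == 1L) {
    return(list(particles = cpts, transforms = tf, objective = NA_real_))
  }
  cur <- cpts    # transformed copies
  total_obj <- function() {
    s <- 0
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np)
      s <- s + .kernel_corr(cur[[i]], cur[[j]], kernel_sigma)
    s
  }
  refine_once <- function(angles, local_only = FALSE) {
    for (i in seq_len(np)) {
      others <- do.call(rbind, cur[-i])
      score <- function(p) {
        .kernel_corr(.apply_rigid(cpts[[i]], p[1], p[2:3]), others,
                     kernel_sigma)
      }
      cur_par <- c(tf$theta[i], tf$tx[i], tf$ty[i])
      best <- cur_par; best_s <- score(cur_par)
      cand_angles <- if (local_only) {
        tf$theta[i] + seq(-refine_deg, refine_deg, by = 5) * pi / 180
      } else angles
      for (th in cand_angles) {
        p0 <- c(th, tf$tx[i], tf$ty[i])
        o <- stats::optim(p0, function(p) -score(p), method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-8))
        if (-o$value > best_s) { best_s <- -o$value; best <- o$par }
      }
      tf$theta[i] <<- best[1]; tf$tx[i] <<- best[2]; tf$ty[i] <<- best[3]
      cur[[i]] <<- .apply_rigid(cpts[[i]], best[1], best[2:3])
    }
  }
  angles <- seq(0, 2 * pi, by = rot_grid_deg * pi / 180)
  objective <- numeric(0)
  for (it in seq_len(n_iter)) {
    refine_once(angles, local_only = it > 1)
    objective <- c(objective, total_obj())
  }
  if (!is.null(symmetry_fold)) {
    step <- 2 * pi / symmetry_fold
    for (i in seq_len(np)) {
      tf$theta[i] <- tf$theta[i] + step * sample.int(symmetry_fold, 1)
      cur[[i]] <- .apply_rigid(cpts[[i]], tf$theta[i],
                               c(tf$tx[i], tf$ty[i]))
    }
    refine_once(NULL, local_only = TRUE)
    objective <- c(objective, total_obj())
  }
  list(particles = cur, transforms = tf, objective = objective)
}

#' Fraction of localizations covered by reference-site disks
#'
#' Fraction of points lying within the union of disks of the given
#' radius centered at the reference sites (both sets in one aligned
#' frame). The 7-nm default is the estimated reach of the
#' linker-GFP-nanobody construct.
#'
#' @param points Two-column matrix, nm.
#' @param reference_sites Two-column matrix (or [site_set()]) of
#'   reference positions, nm.
#' @param radius Disk radius, nm.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(points, reference_sites, radius = 7) {
  points <- as.matrix(points)
  if (inherits(reference_sites, "site_set"))
    reference_sites <- cbind(reference_sites$x_nm, reference_sites$y_nm)
  reference_sites <- as.matrix(reference_sites)
  if (nrow(points) == 0L) return(NA_real_)
  d2 <- outer(points[, 1], reference_sites[, 1], `-`)^2 +
    outer(points[, 2], reference_sites[, 2], `-`)^2
  mean(sqrt(apply(d2, 1, min)) <= radius)
}

# k-nearest-neighbor local density (points / nm^2): k / (pi r_k^2)
.knn_density <- function(points, k) {
  n <- nrow(points)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(points))
  rk <- apply(d, 1, function(row) sort(row)[k + 1L])
  k / (pi * rk^2)
}

#' Density-based cluster analysis
#'
#' Detects regions of high localization density: core points are those
#' whose local density (k-nearest-neighbor estimate, the tessellation
#' stand-in) exceeds `density_factor` times the average density of the
#' whole field (point count over bounding-box area, the tessellation
#' convention); cores are
#' linked by single-linkage at `core_link` nm; remaining points are
#' attached to their closest cluster if within `attach_radius` nm of
#' one of its members; clusters below `min_count` members are
#' discarded. The cluster diameter is `4 * sqrt(sigma_x * sigma_y)` of
#' the member positions.
#'
#' @param points Two-column matrix, nm.
#' @param min_count Minimum localizations per cluster.
#' @param attach_radius Straggler attachment radius, nm.
#' @param density_factor Core threshold as multiple of the average
#'   field density.
#' @param k Neighbors for the density estimate.
#' @param core_link Single-linkage cut distance for cores, nm.
#' @return List with `labels` (0 = noise) and `clusters` (data.frame
#'   with `cluster`, `n`, `x_nm`, `y_nm`, `diameter_nm`).
#' @export
density_cluster <- function(points, min_count = 10, attach_radius = 40,
                            density_factor = 2, k = 10,
                            core_link = attach_radius / 2) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1)
  empty <- data.frame(cluster = integer(), n = integer(),
                      x_nm = numeric(), y_nm = numeric(),
                      diameter_nm = numeric())
  if (n < 2L) return(list(labels = integer(n), clusters = empty))
  dens <- .knn_density(points, k)
  # average density of the field: n over bounding-box area (padded by
  # the knn radius scale so single tight blobs keep a finite area)
  span <- apply(points, 2, function(v) diff(range(v)))
  pad <- stats::median(sqrt(k / (pi * dens)))
  field_density <- n / prod(span + pad)
  core <- dens >= density_factor * field_density
  if (!any(core)) return(list(labels = integer(n), clusters = empty))
  labels <- integer(n)
  ci <- which(core)
  if (length(ci) == 1L) {
    labels[ci] <- 1L
  } else {
    hc <- stats::hclust(stats::dist(points[ci, , drop = FALSE]),
                        method = "single")
    labels[ci] <- stats::cutree(hc, h = core_link)
  }
  # attach stragglers within attach_radius of a cluster member
  free <- which(labels == 0L)
  if (length(free) > 0L) {
    dd <- as.matrix(stats::dist(points))
    for (i in free) {
      dmin <- Inf; best <- 0L
      for (kk in unique(labels[labels > 0L])) {
        dk <- min(dd[i, labels == kk])
        if (dk < dmin) { dmin <- dk; best <- kk }
      }
      if (dmin <= attach_radius) labels[i] <- best
    }
  }
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab)[tab < min_count])
  labels[labels %in% small] <- 0L
  ids <- sort(unique(labels[labels > 0L]))
  out <- labels
  rows <- lapply(seq_along(ids), function(j) {
    m <- points[labels == ids[j], , drop = FALSE]
    out[labels == ids[j]] <<- j
    data.frame(cluster = j, n = nrow(m),
               x_nm = mean(m[, 1]), y_nm = mean(m[, 2]),
               diameter_nm = 4 * sqrt(stats::sd(m[, 1]) * stats::sd(m[, 2])))
  })
  list(labels = out,
       clusters = if (length(rows)) do.call(rbind, rows) else empty)
}

#' Nuclear-pore analysis pipeline
#'
#' Applies the published filter cascade to a list of pore particles:
#' require full eight-sector occupancy in the 40-70 nm radial band,
#' fit the ring, exclude pores with aspect ratio above `max_aspect`,
#' and drop localizations farther than `radial_tol` nm from the mean
#' ring radius before the final diameter estimate.
#'
#' @param particles List of two-column point matrices (one pore each,
#'   in a frame where the pore is roughly centered).
#' @param r_in,r_out Occupancy radial band, nm.
#' @param max_aspect Ellipticity cutoff.
#' @param radial_tol Radial outlier tolerance, nm.
#' @return List with `per_pore` (data.frame: occupancy, aspect,
#'   diameter, n_locs, selected) and `summary` (mean and sd of the
#'   selected diameters, mean occupancy).
#' @export
npc_pipeline <- function(particles, r_in = 40, r_out = 70,
                         max_aspect = 1.25, radial_tol = 20) {
  rows <- lapply(seq_along(particles), function(k) {
    pts <- as.matrix(if (is.list(particles[[k]])) particles[[k]]$points
                     else particles[[k]])
    fit0 <- tryCatch(fit_ring(pts), error = function(e) NULL)
    if (is.null(fit0)) {
      return(data.frame(pore = k, occupancy = NA, aspect = NA,
                        diameter_nm = NA, n_locs = nrow(pts),
                        selected = FALSE))
    }
    occ <- sector_occupancy(pts, fit0$center, r_in, r_out)
    sel <- occ == 8 && is.finite(fit0$aspect_ratio) &&
      fit0$aspect_ratio <= max_aspect
    dia <- NA_real_
    if (sel) {
      kept <- radial_outlier_filter(pts, fit0, radial_tol)
      dia <- if (nrow(kept) >= 8) fit_ring(kept)$diameter else fit0$diameter
    }
    data.frame(pore = k, occupancy = occ, aspect = fit0$aspect_ratio,
               diameter_nm = dia, n_locs = nrow(pts), selected = sel)
  })
  per_pore <- do.call(rbind, rows)
  sel <- per_pore$selected %in% TRUE
  list(per_pore = per_pore,
       summary = list(
         mean_diameter_nm = mean(per_pore$diameter_nm[sel], na.rm = TRUE),
         sd_diameter_nm = stats::sd(per_pore$diameter_nm[sel]),
         mean_occupancy = mean(per_pore$occupancy, na.rm = TRUE),
         n_selected = sum(sel)))
}
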