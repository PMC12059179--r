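# Simplified inscribed-sphere pore profiler: at each plane along the channel
# axis, the radius of the largest probe sphere that fits between the van der
# Waals surfaces of the atoms, found by in-plane optimization of the probe
# center. A desk-scale stand-in for the classic pore-tracing approach; it
# reproduces the radius-vs-z curve for near-axial channels.

#' Construct a Structure object for pore profiling
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param element character vector of element symbols (used for Bondi vdW
#'   radii) or NULL if `vdw` is given.
#' @param vdw optional numeric vector of van der Waals radii (Angstrom);
#'   overrides the element lookup.
#' @param resid,chain optional labels.
#' @return List of class `pore_structure`.
#' @export
pore_structure <- function(xyz, element = NULL, vdw = NULL, resid = NULL,
                           chain = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0L) stop_invalid("structure has no atoms")
  if (!all(is.finite(xyz))) stop_invalid("coordinates must be finite")
  if (is.null(vdw)) {
    if (is.null(element)) element <- rep("C", nrow(xyz))
    vdw <- bondi_radius(element)
  }
  if (any(vdw <= 0)) stop_invalid("van der Waals radii must be positive")
  structure(list(xyz = xyz, vdw = vdw, element = element, resid = resid,
                 chain = chain), class = "pore_structure")
}

# largest-sphere radius at a probe center: min over atoms of
# (distance - vdw), clamped to [0, r_max]
probe_radius_at <- function(center, xyz, vdw, r_max) {
  d <- sqrt(colSums((t(xyz) - center)^2)) - vdw
  min(r_max, max(0, min(d)))
}

#' Pore-radius profile along the channel axis
#'
#' Scans planes perpendicular to the z axis. At each z the probe center is
#' optimized in-plane (coarse grid search followed by Nelder-Mead
#' refinement) to maximize the clearance radius
#' `min_i (|center - atom_i| - vdw_i)`, clamped to `[0, r_max]`. Supply a
#' structure already aligned so the pore runs along z (see
#' [align_structure_axis()]), or rely on the default axis through the
#' centroid.
#'
#' @param structure a [pore_structure()].
#' @param z_range length-2 numeric, z interval to scan (defaults to the
#'   structure's z extent).
#' @param step plane spacing in Angstrom (> 0).
#' @param r_max cap radius in Angstrom; planes with no atoms within reach
#'   report `r_max` (open channel).
#' @param search_radius half-width of the in-plane search box around the
#'   axis (Angstrom).
#' @param axis_xy in-plane position of the nominal axis (default: centroid
#'   of the structure).
#' @param coarse_step grid spacing of the global in-plane search (Angstrom).
#' @return data.frame of class `pore_profile` with columns `z`, `radius`,
#'   `cx`, `cy` (probe center), z strictly increasing.
#' @export
pore_radius_profile <- function(structure, z_range = NULL, step = 0.5,
                                r_max = 10, search_radius = 5,
                                axis_xy = NULL, coarse_step = 0.2) {
  if (!inherits(structure, "pore_structure"))
    stop_invalid("structure must be a pore_structure")
  if (step <= 0) stop_invalid("step must be positive")
  xyz <- structure$xyz
  vdw <- structure$vdw
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  if (is.null(axis_xy)) axis_xy <- colMeans(xyz[, 1:2, drop = FALSE])
  zs <- seq(z_range[1], z_range[2], by = step)
  g <- seq(-search_radius, search_radius, by = coarse_step)
  grid <- as.matrix(expand.grid(dx = g, dy = g))

  # clearance at a set of in-plane centers, vectorized over centers
  grid_radius <- function(centers, z, sub, svdw) {
    d2xy <- outer(centers[, 1], sub[, 1], "-")^2 +
      outer(centers[, 2], sub[, 2], "-")^2
    d <- sqrt(sweep(d2xy, 2, (sub[, 3] - z)^2, "+"))
    cl <- apply(sweep(d, 2, svdw), 1, min)
    pmin(r_max, pmax(0, cl))
  }

  out <- matrix(NA_real_, length(zs), 3)
  reach <- r_max + max(vdw)
  for (k in seq_along(zs)) {
    z <- zs[k]
    near <- abs(xyz[, 3] - z) <= reach
    if (!any(near)) { out[k, ] <- c(r_max, axis_xy); next }
    sub <- xyz[near, , drop = FALSE]
    svdw <- vdw[near]
    centers <- sweep(grid, 2, axis_xy, "+")
    vals <- grid_radius(centers, z, sub, svdw)
    best <- centers[which.max(vals), ]
    # local dense refinement around the global-grid optimum
    gf <- seq(-coarse_step, coarse_step, by = 0.02)
    fine <- sweep(as.matrix(expand.grid(dx = gf, dy = gf)), 2, best, "+")
    fv <- grid_radius(fine, z, sub, svdw)
    best <- fine[which.max(fv), ]
    # Nelder-Mead polish, clamped to the search box
    f <- function(cxy) {
      cl <- pmin(pmax(cxy, axis_xy - search_radius), axis_xy + search_radius)
      probe_radius_at(c(cl[1], cl[2], z), sub, svdw, r_max) -
        sqrt(sum((cxy - cl)^2))
    }
    opt <- stats::optim(best, function(c2) -f(c2), method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 200))
    ctr <- pmin(pmax(opt$par, axis_xy - search_radius),
                axis_xy + search_radius)
    val <- max(-opt$value, max(fv), max(vals))
    out[k, ] <- c(min(r_max, max(0, val)), ctr)
  }
  res <- data.frame(z = zs, radius = out[, 1], cx = out[, 2], cy = out[, 3])
  class(res) <- c("pore_profile", "data.frame")
  res
}

#' Minimum constriction of a pore profile
#'
#' Global minimum radius and its z position; ties are broken by the smallest
#' z. The matching diameter (2 x radius) is also reported, since channel
#' constrictions are usually quoted as diameters.
#'
#' @param profile a [pore_radius_profile()] result.
#' @return List with `z`, `radius`, `diameter`.
#' @export
min_constriction <- function(profile) {
  if (nrow(profile) == 0L) stop_invalid("empty pore profile")
  k <- which.min(profile$radius)  # which.min returns the first minimum
  list(z = profile$z[k], radius = profile$radius[k],
       diameter = 2 * profile$radius[k])
}

#' Align a structure so a fitted pore axis runs along z
#'
#' Fits the principal axis of the selected (pore-lining) atoms by PCA and
#' rotates the whole structure so that axis becomes z, centered on the
#' selection centroid.
#'
#' @param structure a [pore_structure()].
#' @param select optional integer atom indices defining the pore lining
#'   (default: all atoms).
#' @return The rotated [pore_structure()].
#' @export
align_structure_axis <- function(structure, select = NULL) {
  xyz <- structure$xyz
  if (is.null(select)) select <- seq_len(nrow(xyz))
  sub <- xyz[select, , drop = FALSE]
  ctr <- colMeans(sub)
  pc <- prcomp(sub, center = TRUE)
  ax <- pc$rotation[, 1]
  if (ax[3] < 0) ax <- -ax
  # rotation taking ax -> (0,0,1)
  v <- c(ax[2], -ax[1], 0)          # ax x ez (sign folded below)
  s <- sqrt(sum(v^2)); c_ <- ax[3]
  if (s < 1e-12) R <- diag(3) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  structure$xyz <- sweep(xyz, 2, ctr) %*% t(R)
  structure
}
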