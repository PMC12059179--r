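# Trajectory observables for the disordered terminus: fraction of native
# contacts with a logistic switching function, residue-lipid contact counts,
# membrane z-distance distributions, and end-to-end terminus length.

#' Contact-definition parameters
#'
#' Holds the cutoffs and the logistic smoothing/padding parameters of the
#' native-contact fraction. Defaults are the values used throughout the
#' analyses: native contacts are heavy-atom pairs closer than 4.5 A in the
#' reference structure; a residue and a lipid are in contact when any
#' heavy-atom pair is within 3.5 A; the switching function uses
#' beta = 5 A^-1 and lambda = 1.5.
#'
#' @param native_cutoff A; reference-structure distance defining a native
#'   pair (default 4.5).
#' @param lipid_cutoff A; residue-lipid contact distance (default 3.5).
#' @param beta A^-1; logistic smoothing steepness (default 5).
#' @param lambda dimensionless padding factor >= 1 on the reference distance
#'   (default 1.5).
#' @return List of class `contact_spec`.
#' @export
contact_spec <- function(native_cutoff = 4.5, lipid_cutoff = 3.5,
                         beta = 5, lambda = 1.5) {
  if (native_cutoff <= 0 || lipid_cutoff <= 0)
    stop_invalid("cutoffs must be positive")
  if (beta <= 0) stop_invalid("beta must be positive")
  if (lambda < 1) stop_invalid("lambda must be >= 1")
  structure(list(native_cutoff = native_cutoff, lipid_cutoff = lipid_cutoff,
                 beta = beta, lambda = lambda), class = "contact_spec")
}

#' Build the native-contact set from a reference frame
#'
#' Native contacts are defined as the heavy-atom pairs (i from `group_a`,
#' j from `group_b`) whose distance in the reference structure is below
#' `spec$native_cutoff`. The reference distances r0 are stored with each
#' pair.
#'
#' @param ref `n x 3` coordinate matrix of the reference frame (Angstrom),
#'   or an [md_trajectory()] whose frame `frame` is used.
#' @param group_a,group_b integer atom indices of the two groups (e.g. from
#'   [select_atoms()]; tail residues 7-13 vs the partner surface by
#'   default in the pipeline).
#' @param spec a [contact_spec()].
#' @param frame reference frame index when `ref` is a trajectory.
#' @return data.frame of class `native_contacts` with columns `i`, `j`, `r0`.
#' @export
build_native_contacts <- function(ref, group_a, group_b,
                                  spec = contact_spec(), frame = 1L) {
  if (inherits(ref, "md_trajectory")) ref <- get_frame(ref, frame)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop_invalid("contact groups must be non-empty")
  d <- cross_distances(ref[group_a, , drop = FALSE],
                       ref[group_b, , drop = FALSE])
  hit <- which(d < spec$native_cutoff, arr.ind = TRUE)
  out <- data.frame(i = group_a[hit[, 1]], j = group_b[hit[, 2]],
                    r0 = d[hit])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no atom pair below the native cutoff; empty contact set")
  class(out) <- c("native_contacts", "data.frame")
  out
}

# all-pairs distance matrix between two coordinate sets
cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fraction of native contacts Q of one configuration
#'
#' Q(X) = (1/N) * sum over native pairs of
#' 1 / (1 + exp(beta * (r_ij(X) - lambda * r0_ij))). The logistic switch
#' never reaches 0 or 1, so Q lies strictly in (0, 1).
#'
#' @param frame `n x 3` coordinate matrix (Angstrom).
#' @param contacts a [build_native_contacts()] result.
#' @param spec a [contact_spec()] supplying beta and lambda.
#' @return Scalar Q in (0, 1).
#' @export
#' @examples
#' ref <- rbind(c(0, 0, 0), c(4, 0, 0))
#' nc <- build_native_contacts(ref, 1, 2)
#' fraction_native_contacts(ref, nc)  # ~ 1/(1 + exp(-10))
fraction_native_contacts <- function(frame, contacts, spec = contact_spec()) {
  if (nrow(contacts) == 0L)
    stop_invalid("empty native-contact set (division by zero N)")
  dx <- frame[contacts$i, , drop = FALSE] - frame[contacts$j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  mean(1 / (1 + exp(spec$beta * (r - spec$lambda * contacts$r0))))
}

#' Per-frame native-contact fraction time series
#'
#' @param traj an [md_trajectory()].
#' @inheritParams fraction_native_contacts
#' @return data.frame `frame`, `Q` with one row per trajectory frame.
#' @export
q_timeseries <- function(traj, contacts, spec = contact_spec()) {
  q <- vapply(seq_len(n_frames(traj)), function(f)
    fraction_native_contacts(get_frame(traj, f), contacts, spec),
    numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), Q = q)
}

#' Residue-lipid contact counts along a trajectory
#'
#' A residue and a lipid molecule count as one contact per frame when at
#' least one heavy-atom pair between them is within `spec$lipid_cutoff`
#' (3.5 A by default), regardless of how many atom pairs qualify.
#'
#' @param traj an [md_trajectory()].
#' @param residues residue selection for the protein side (range string or
#'   integer vector, applied to the `tail` segment by default).
#' @param spec a [contact_spec()].
#' @param segment protein segment(s) the residue selection refers to.
#' @return List with `series` (data.frame `frame`, `count`: number of
#'   residue-lipid pairs in contact per frame) and `per_residue` (data.frame
#'   `resid`, `mean_contacts`: average per-frame lipid contacts of each
#'   residue).
#' @export
lipid_contacts <- function(traj, residues, spec = contact_spec(),
                           segment = "tail") {
  res_ids <- parse_residue_range(residues)
  prot_idx <- select_atoms(traj, segment = segment, resid = res_ids)
  if (length(prot_idx) == 0L) stop_invalid("residue selection is empty")
  lip_idx <- select_atoms(traj, segment = c("phosphate", "acyl"))
  if (length(lip_idx) == 0L) stop_invalid("trajectory contains no lipid atoms")
  prot_res <- traj$atoms$resid[prot_idx]
  lip_mol <- traj$atoms$resid[lip_idx]

  nf <- n_frames(traj)
  counts <- integer(nf)
  per_res <- matrix(0, nrow = nf, ncol = length(res_ids),
                    dimnames = list(NULL, res_ids))
  for (f in seq_len(nf)) {
    xyz <- get_frame(traj, f)
    d <- cross_distances(xyz[prot_idx, , drop = FALSE],
                         xyz[lip_idx, , drop = FALSE])
    hit <- d < spec$lipid_cutoff
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      pairs <- unique(data.frame(res = prot_res[idx[, 1]],
                                 mol = lip_mol[idx[, 2]]))
      counts[f] <- nrow(pairs)
      tab <- table(factor(pairs$res, levels = res_ids))
      per_res[f, ] <- as.integer(tab)
    }
  }
  list(series = data.frame(frame = seq_len(nf), count = counts),
       per_residue = data.frame(resid = res_ids,
                                mean_contacts = colMeans(per_res)))
}

#' Signed z-distance of residues from the membrane surface
#'
#' For every frame and selected residue, the vertical (z) distance of the
#' residue's heavy-atom centroid from the mean phosphate z of the proximal
#' leaflet, with z = 0 at the average phosphate position and negative values
#' below the membrane surface. The proximal leaflet is the one whose mean z
#' is nearest the selection's mean z.
#'
#' @param traj an [md_trajectory()].
#' @param residues residue selection (range string or integer vector).
#' @param segment protein segment(s) the selection refers to.
#' @param bin_width histogram bin width in Angstrom.
#' @return List with `z` (numeric vector, all frame x residue distances),
#'   `histogram` (data.frame `bin_left`, `bin_right`, `density`) and `mean`.
#' @export
z_distance_distribution <- function(traj, residues, segment = "tail",
                                    bin_width = 1) {
  res_ids <- parse_residue_range(residues)
  prot_idx <- select_atoms(traj, segment = segment, resid = res_ids)
  if (length(prot_idx) == 0L) stop_invalid("residue selection is empty")
  phos_idx <- select_atoms(traj, segment = "phosphate")
  if (length(phos_idx) == 0L) stop_invalid("trajectory contains no phosphate atoms")
  prot_res <- traj$atoms$resid[prot_idx]

  nf <- n_frames(traj)
  zs <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- get_frame(traj, f)
    # split phosphates into leaflets by z relative to their midplane
    pz <- xyz[phos_idx, 3]
    mid <- mean(range(pz))
    leafs <- list(lower = pz[pz <= mid], upper = pz[pz > mid])
    sel_z <- mean(xyz[prot_idx, 3])
    means <- vapply(leafs, mean, numeric(1))
    plane <- means[[which.min(abs(means - sel_z))]]
    cent_z <- vapply(split(xyz[prot_idx, 3], prot_res), mean, numeric(1))
    zs[[f]] <- cent_z - plane
  }
  z <- unlist(zs, use.names = FALSE)
  br <- seq(floor(min(z) / bin_width) * bin_width,
            ceiling(max(z) / bin_width) * bin_width + bin_width,
            by = bin_width)
  h <- graphics::hist(z, breaks = br, plot = FALSE)
  list(z = z,
       histogram = data.frame(bin_left = utils::head(h$breaks, -1),
                              bin_right = h$breaks[-1],
                              density = h$density),
       mean = mean(z))
}

#' End-to-end terminus length per frame
#'
#' Euclidean distance between the heavy-atom centroids of the first and last
#' residues of the range, per frame. This is an end-to-end measure (not a
#' contour length); for a bead-per-residue tail it is the span of the
#' disordered terminus.
#'
#' @param traj an [md_trajectory()].
#' @param residue_range range string or integer vector with >= 2 residues.
#' @param segment protein segment the range refers to.
#' @return data.frame `frame`, `length` (Angstrom).
#' @export
terminus_length <- function(traj, residue_range, segment = "tail") {
  res_ids <- parse_residue_range(residue_range)
  if (length(res_ids) < 2L) stop_invalid("range must contain >= 2 residues")
  i1 <- select_atoms(traj, segment = segment, resid = res_ids[1])
  i2 <- select_atoms(traj, segment = segment, resid = res_ids[length(res_ids)])
  if (length(i1) == 0L || length(i2) == 0L)
    stop_invalid("residue range outside trajectory")
  len <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- get_frame(traj, f)
    a <- colMeans(xyz[i1, , drop = FALSE])
    b <- colMeans(xyz[i2, , drop = FALSE])
    sqrt(sum((a - b)^2))
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), length = len)
}
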