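# Coarse-grained trajectory container shared by the generator, the contact
# statistics and the PDB I/O layer. One bead per residue for the flexible
# tail; explicit phosphate/acyl beads for the bilayer.

#' Construct an md_trajectory object
#'
#' A minimal trajectory container: a per-atom table plus an
#' `n_atoms x 3 x n_frames` coordinate array in Angstrom. Segment labels
#' partition the system into the flexible terminal tail (`"tail"`), the rigid
#' protein core (`"core"`), the static partner surface (`"partner"`, the
#' RCK-ring face the tail binds), and lipid beads (`"phosphate"`, `"acyl"`).
#'
#' @param atoms data.frame with columns `serial`, `name`, `resid` (integer),
#'   `resname`, `segment`, `element`, `heavy` (logical).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param timestep frame spacing label in ns (metadata only).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords, timestep = 1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L)
  if (dim(coords)[1] != nrow(atoms))
    stop_invalid("coords first dimension must match number of atoms")
  if (dim(coords)[2] != 3L) stop_invalid("coords second dimension must be 3")
  if (!all(is.finite(coords))) stop_invalid("coordinates must be finite")
  need <- c("serial", "name", "resid", "resname", "segment", "element", "heavy")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_invalid("atoms table missing columns: ",
                                 paste(miss, collapse = ", "))
  structure(list(atoms = atoms, coords = coords, timestep = timestep),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames,", nrow(x$atoms), "atoms (",
      paste(names(table(x$atoms$segment)), table(x$atoms$segment),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop_invalid("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

#' Select atom indices by segment / residue / heavy-atom flag
#'
#' @param atoms the `atoms` table of an `md_trajectory`, or the trajectory
#'   itself.
#' @param segment optional segment label(s) to keep.
#' @param resid optional residue selection: integer vector or range string
#'   (see [parse_residue_range()]).
#' @param heavy_only drop hydrogens (default TRUE; the contact statistics are
#'   defined on heavy atoms).
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(atoms, segment = NULL, resid = NULL,
                         heavy_only = TRUE) {
  if (inherits(atoms, "md_trajectory")) atoms <- atoms$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(segment)) keep <- keep & atoms$segment %in% segment
  if (!is.null(resid)) keep <- keep & atoms$resid %in% parse_residue_range(resid)
  if (heavy_only) keep <- keep & atoms$heavy
  which(keep)
}

#' Parameters for the toy IDR-membrane trajectory generator
#'
#' Defaults mirror the simulated system: a 20-residue flexible N-terminal
#' tail (residues 2-21 of the pore subunit) tethered below a bilayer slab
#' whose head-group layer carries the charge character of a 45% POPE /
#' 40% POPG / 15% cardiolipin membrane, plus a static partner surface
#' standing in for the RCK ring.
#'
#' @param n_frames number of frames (>= 1).
#' @param timestep ns per frame (label only).
#' @param tail_length number of tail beads, one per residue (>= 2).
#' @param anchor_z depth of the tail anchor below the phosphate plane
#'   (Angstrom, positive down).
#' @param membrane_affinity dimensionless >= 0; strength of the upward bias
#'   pulling basic/hydrophobic tail beads toward the slab. 0 gives an
#'   unbiased tethered random walk.
#' @param slab_z z position of the mean phosphate plane of the proximal
#'   (cytosolic) leaflet (Angstrom).
#' @param seed integer RNG seed; identical seeds give identical trajectories.
#' @return List of class `toy_trajectory_params`.
#' @export
toy_trajectory_params <- function(n_frames = 200, timestep = 1,
                                  tail_length = 20, anchor_z = 30,
                                  membrane_affinity = 0, slab_z = 0,
                                  seed = 1) {
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  if (tail_length < 2) stop_invalid("tail_length must be >= 2")
  if (membrane_affinity < 0) stop_invalid("membrane_affinity must be >= 0")
  structure(list(n_frames = as.integer(n_frames), timestep = timestep,
                 tail_length = as.integer(tail_length), anchor_z = anchor_z,
                 membrane_affinity = membrane_affinity, slab_z = slab_z,
                 seed = seed),
            class = "toy_trajectory_params")
}

# Sample the polar cosine u in [-1, 1] with density proportional to
# exp(a * u) by inverse CDF; a = 0 reduces to uniform.
sample_tilted_cosine <- function(n, a) {
  U <- stats::runif(n)
  if (abs(a) < 1e-12) return(2 * U - 1)
  # inverse CDF of exp(a u) / normalizer on [-1, 1]
  log(exp(-a) + U * (exp(a) - exp(-a))) / a
}

#' Generate a toy trajectory of a disordered tail below a membrane slab
#'
#' Builds a bead-per-residue model: a static protein core, a flexible tail of
#' `tail_length` beads re-sampled each frame as a tethered random walk with
#' fixed 3.8 A virtual bonds, a static partner bead row (the RCK-ring
#' surface; tail residues 7-13 sit within native-contact range of it in the
#' reference frame), and a bilayer slab of phosphate beads at `slab_z`
#' (proximal leaflet), a distal phosphate leaflet 38 A above, and acyl beads
#' between the leaflets. The walk's step directions are tilted toward the
#' slab with strength `membrane_affinity`; beads reflect at 1 A above the
#' proximal phosphate plane so the tail can touch, but not cross, the
#' membrane.
#'
#' @param params a [toy_trajectory_params()] object.
#' @return An [md_trajectory()].
#' @export
#' @examples
#' traj <- generate_idr_membrane_trajectory(
#'   toy_trajectory_params(n_frames = 10, seed = 42))
#' n_frames(traj)
generate_idr_membrane_trajectory <- function(params) {
  if (!inherits(params, "toy_trajectory_params"))
    params <- do.call(toy_trajectory_params, params)
  p <- params
  bond <- 3.8           # Calpha-Calpha virtual bond, Angstrom
  thick <- 38           # phosphate-to-phosphate bilayer thickness
  anchor <- c(0, 0, p$slab_z - p$anchor_z)

  # static pieces -----------------------------------------------------------
  # protein core: ring of 8 beads just below the anchor
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  core <- cbind(4 * cos(th), 4 * sin(th), anchor[3] - 5)
  # partner (RCK-ring surface): row of 12 beads flanking the reference tail
  partner <- cbind(seq(2, 24, by = 2), 3.5, anchor[3])
  # proximal phosphate leaflet: 2 A grid over a 40 x 40 A patch
  g <- seq(-20, 20, by = 2)
  low <- as.matrix(expand.grid(x = g, y = g))
  phos_lo <- cbind(low, p$slab_z)
  phos_hi <- cbind(low, p$slab_z + thick)
  ga <- seq(-20, 20, by = 4)
  acyl_grid <- as.matrix(expand.grid(x = ga, y = ga))
  acyl <- rbind(cbind(acyl_grid, p$slab_z + 10), cbind(acyl_grid, p$slab_z + 28))

  static <- rbind(core, partner, phos_lo, phos_hi, acyl)
  n_static <- nrow(static)
  n_atoms <- n_static + p$tail_length

  seg <- c(rep("core", nrow(core)), rep("partner", nrow(partner)),
           rep("phosphate", nrow(phos_lo) + nrow(phos_hi)),
           rep("acyl", nrow(acyl)), rep("tail", p$tail_length))
  # residue numbering: tail beads are residues 2..(tail_length+1), mirroring
  # the deleted stretch 2-19 plus flanks; every lipid bead is its own
  # "molecule" so residue-lipid contact counting is per lipid.
  resid <- c(rep(1L, nrow(core)), seq_len(nrow(partner)) + 1000L,
             seq_len(nrow(phos_lo) + nrow(phos_hi)) + 2000L,
             seq_len(nrow(acyl)) + 5000L,
             seq_len(p$tail_length) + 1L)
  resname <- c(rep("COR", nrow(core)), rep("PTR", nrow(partner)),
               rep("PHO", nrow(phos_lo) + nrow(phos_hi)),
               rep("ACY", nrow(acyl)), rep("TAL", p$tail_length))
  atoms <- data.frame(serial = seq_len(n_atoms), name = "CA", resid = resid,
                      resname = resname, segment = seg, element = "C",
                      heavy = TRUE, stringsAsFactors = FALSE)

  z_ceiling <- p$slab_z + 1   # reflective wall just above the phosphate plane
  coords <- array(NA_real_, dim = c(n_atoms, 3L, p$n_frames))
  with_local_seed(p$seed, {
    for (f in seq_len(p$n_frames)) {
      tail <- matrix(NA_real_, p$tail_length, 3)
      pos <- anchor
      tail[1, ] <- pos
      if (f == 1L) {
        # reference frame: extended tail running along the partner row so
        # that residues 7-13 are in native-contact range of partner beads
        for (k in 2:p$tail_length) tail[k, ] <- anchor + c((k - 1) * 2.0, 0, 0)
      } else {
        u <- sample_tilted_cosine(p$tail_length - 1L, p$membrane_affinity)
        phi <- stats::runif(p$tail_length - 1L, 0, 2 * pi)
        s <- sqrt(pmax(0, 1 - u^2))
        for (k in 2:p$tail_length) {
          step <- bond * c(s[k - 1] * cos(phi[k - 1]),
                           s[k - 1] * sin(phi[k - 1]), u[k - 1])
          pos <- pos + step
          if (pos[3] > z_ceiling) pos[3] <- 2 * z_ceiling - pos[3]
          tail[k, ] <- pos
        }
      }
      coords[, , f] <- rbind(static, tail)
    }
  })
  md_trajectory(atoms, coords, timestep = p$timestep)
}
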