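# In-code fixtures shared across the suite. Everything is built
# programmatically; no binary files.

# Minimal hand-built trajectory: a straight tail of `n` beads (residues
# 2..n+1, 3.8 A spacing along x) plus a phosphate plane at z = plane_z on a
# 2 A grid, optionally displaced per frame by `offsets` (list of length-3
# shifts applied to the tail only).
make_tail_trajectory <- function(n = 20, plane_z = 0, tail_z = -15,
                                 offsets = list(c(0, 0, 0))) {
  g <- seq(-10, 10, by = 2)
  phos <- as.matrix(expand.grid(x = g, y = g))
  phos <- cbind(phos, plane_z)
  tail0 <- cbind(seq(0, by = 3.8, length.out = n), 0, tail_z)
  atoms <- data.frame(
    serial = seq_len(nrow(phos) + n),
    name = "CA",
    resid = c(seq_len(nrow(phos)) + 2000L, seq_len(n) + 1L),
    resname = c(rep("PHO", nrow(phos)), rep("TAL", n)),
    segment = c(rep("phosphate", nrow(phos)), rep("tail", n)),
    element = "C", heavy = TRUE, stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3, length(offsets)))
  for (f in seq_along(offsets)) {
    tail <- sweep(tail0, 2, offsets[[f]], "+")
    coords[, , f] <- rbind(phos, tail)
  }
  md_trajectory(atoms, coords)
}

# Two-group toy frame for native-contact tests: n_a + n_b random atoms in a
# 12 A box, labelled as tail residues vs partner.
make_two_group_frame <- function(n_a = 25, n_b = 25, seed = 1) {
  set.seed(seed)
  xyz <- cbind(runif(n_a + n_b, 0, 12), runif(n_a + n_b, 0, 12),
               runif(n_a + n_b, 0, 12))
  list(xyz = xyz, group_a = seq_len(n_a), group_b = n_a + seq_len(n_b))
}

# Brute-force O(n^2) native-contact oracle.
brute_native_pairs <- function(xyz, group_a, group_b, cutoff) {
  out <- NULL
  for (i in group_a) for (j in group_b) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < cutoff) out <- rbind(out, data.frame(i = i, j = j, r0 = r))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(), r0 = numeric())
  else out[order(out$i, out$j), ]
}

# Brute-force residue-lipid contact count for one frame.
brute_lipid_count <- function(traj, frame, residues, cutoff = 3.5) {
  xyz <- get_frame(traj, frame)
  a <- traj$atoms
  res_ids <- parse_residue_range(residues)
  prot <- which(a$segment == "tail" & a$resid %in% res_ids)
  lip <- which(a$segment %in% c("phosphate", "acyl"))
  n <- 0L
  for (r in res_ids) {
    pi_ <- prot[a$resid[prot] == r]
    if (!length(pi_)) next
    for (m in unique(a$resid[lip])) {
      li <- lip[a$resid[lip] == m]
      dmin <- min(sqrt(outer(rowSums(xyz[pi_, , drop = FALSE]^2),
                             rowSums(xyz[li, , drop = FALSE]^2), "+") -
                       2 * tcrossprod(xyz[pi_, , drop = FALSE],
                                      xyz[li, , drop = FALSE])))
    if (dmin < cutoff) n <- n + 1L
    }
  }
  n
}

# rotation matrix about z by degrees
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
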