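# Native-contact fraction, lipid contacts, z-distributions and terminus
# length, all checked against closed forms or all-pairs brute force.

test_that("native-contact construction respects the 4.5 A cutoff", {
  xyz <- rbind(c(0, 0, 0), c(4.4, 0, 0))
  nc <- build_native_contacts(xyz, 1, 2)
  expect_equal(nrow(nc), 1L)
  expect_equal(nc$r0, 4.4)
  xyz2 <- rbind(c(0, 0, 0), c(4.6, 0, 0))
  expect_warning(nc2 <- build_native_contacts(xyz2, 1, 2), "empty")
  expect_equal(nrow(nc2), 0L)
  expect_error(build_native_contacts(xyz, integer(), 2), "non-empty")
})

test_that("native-contact pairs match the all-pairs brute-force oracle", {
  fr <- make_two_group_frame(n_a = 25, n_b = 25, seed = 4)
  nc <- build_native_contacts(fr$xyz, fr$group_a, fr$group_b)
  oracle <- brute_native_pairs(fr$xyz, fr$group_a, fr$group_b, 4.5)
  expect_equal(nc$i, oracle$i)
  expect_equal(nc$j, oracle$j)
  expect_equal(nc$r0, oracle$r0)
})

test_that("Q has the closed-form logistic values", {
  spec <- contact_spec()
  ref <- rbind(c(0, 0, 0), c(4, 0, 0))
  nc <- build_native_contacts(ref, 1, 2, spec)
  # r = lambda * r0 makes the exponent zero: the term is exactly 1/2
  half <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(fraction_native_contacts(half, nc, spec), 0.5)
  # native frame: exponent 5*(4 - 6) = -10
  expect_equal(fraction_native_contacts(ref, nc, spec), 1 / (1 + exp(-10)))
  # broken contact at 10 A: exponent +20
  far <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(fraction_native_contacts(far, nc, spec), 1 / (1 + exp(20)))
  expect_error(fraction_native_contacts(ref, nc[0, ], spec), "empty")
})

test_that("Q time series stays in (0,1) and collapses when the tail leaves", {
  fr <- make_two_group_frame(seed = 7)
  nc <- build_native_contacts(fr$xyz, fr$group_a, fr$group_b)
  shifted <- fr$xyz
  shifted[fr$group_a, 1] <- shifted[fr$group_a, 1] + 50
  atoms <- data.frame(serial = seq_len(nrow(fr$xyz)), name = "CA",
                      resid = seq_len(nrow(fr$xyz)), resname = "X",
                      segment = "core", element = "C", heavy = TRUE)
  coords <- array(c(fr$xyz, shifted, fr$xyz), dim = c(nrow(fr$xyz), 3, 3))
  traj <- md_trajectory(atoms, coords)
  qs <- q_timeseries(traj, nc)
  expect_equal(nrow(qs), 3L)
  expect_true(all(qs$Q > 0 & qs$Q < 1))
  expect_equal(qs$Q[1], qs$Q[3])
  expect_lt(qs$Q[2], 0.01)
  expect_gt(qs$Q[1], 0.95)  # all r0 <= 4.5 forces exponent <= -11.25
})

test_that("lipid contacts use the 3.5 A cutoff per residue-lipid pair", {
  traj <- make_tail_trajectory(n = 3, plane_z = 0, tail_z = -3.4,
                               offsets = list(c(0, 0, 0), c(0, 0, -0.2)))
  # frame 1: bead at z=-3.4 directly below a phosphate at grid node -> contact
  lc <- lipid_contacts(traj, "2-4")
  expect_equal(lc$series$count[1], 3L)  # beads at x=0, 3.8, 7.6: all near nodes?
  # frame 2 at z=-3.6: no contact possible
  expect_equal(lc$series$count[2], 0L)
  expect_error(lipid_contacts(traj, "40-50"), "empty")
})

test_that("lipid contact counts equal the brute-force oracle", {
  traj <- generate_idr_membrane_trajectory(
    toy_trajectory_params(n_frames = 5, membrane_affinity = 30,
                          anchor_z = 12, seed = 6))
  lc <- lipid_contacts(traj, "2-21")
  for (f in seq_len(5))
    expect_equal(lc$series$count[f], brute_lipid_count(traj, f, "2-21"))
})

test_that("z-distribution is signed, centered on the phosphate plane, and
           translation invariant", {
  traj <- make_tail_trajectory(n = 2, plane_z = 0, tail_z = -10,
                               offsets = list(c(0, 0, 0)))
  # place second bead at -20: adjust coords directly
  traj$coords[dim(traj$coords)[1], 3, 1] <- -20
  zd <- z_distance_distribution(traj, "2-3")
  expect_equal(zd$mean, -15)
  expect_equal(sort(zd$z), c(-20, -10))
  # rigid translation of everything in z leaves the distribution unchanged
  tr2 <- traj; tr2$coords[, 3, ] <- tr2$coords[, 3, ] + 7
  expect_equal(z_distance_distribution(tr2, "2-3")$z, zd$z)
  # spike at zero when beads sit on the plane
  tr3 <- traj; tr3$coords[, 3, ] <- 0
  expect_true(all(z_distance_distribution(tr3, "2-3")$z == 0))
})

test_that("terminus length matches arithmetic and is isometry invariant", {
  traj <- make_tail_trajectory(n = 20)
  tl <- terminus_length(traj, "2-21")
  expect_equal(tl$length, 19 * 3.8)
  # rotation about z applied to the whole frame
  R <- rot_z(33)
  tr2 <- traj
  tr2$coords[, , 1] <- traj$coords[, , 1] %*% t(R)
  expect_equal(terminus_length(tr2, "2-21")$length, tl$length)
  # coincident ends
  tr3 <- traj
  last <- dim(tr3$coords)[1]
  tr3$coords[last, , 1] <- tr3$coords[last - 19, , 1]
  expect_equal(terminus_length(tr3, "2-21")$length, 0)
  expect_error(terminus_length(traj, "2"), ">= 2")
  expect_error(terminus_length(traj, "90-95"), "outside")
})

test_that("higher membrane affinity does not lower mean lipid contacts", {
  seeds <- 1:10
  wins <- vapply(seeds, function(s) {
    lo <- generate_idr_membrane_trajectory(
      toy_trajectory_params(n_frames = 30, membrane_affinity = 1,
                            anchor_z = 20, seed = s))
    hi <- generate_idr_membrane_trajectory(
      toy_trajectory_params(n_frames = 30, membrane_affinity = 10,
                            anchor_z = 20, seed = s))
    mean(lipid_contacts(hi, "2-21")$series$count) >=
      mean(lipid_contacts(lo, "2-21")$series$count)
  }, logical(1))
  # sign test: at least 9/10 non-decreasing
  expect_gte(sum(wins), 9)
})
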