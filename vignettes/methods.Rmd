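---
title: "Methods: models, estimators and design choices in ktrabtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in ktrabtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktrabtools)
```

# Scope

ktrabtools bundles the quantitative analyses used in studies of allosteric
gating of the bacterial K⁺ channel KtrAB: trajectory observables for the
intrinsically disordered N-terminal region (IDR) of the pore subunit KtrB,
a pore-radius profiler for the channel constriction, shape classification
of negative-stain 2D class averages of the KtrA gating ring, the three
standard biophysical curve fits (DSF, ITC, Michaelis–Menten uptake), and
DEER distance-distribution inversion. A synthetic-data module generates
every input at desk scale, so each analysis stage can be verified by
parameter-recovery round trips without any external data.

# Trajectory observables

## Fraction of native contacts

Native contacts are heavy-atom pairs (i from the IDR-binding segment,
residues 7–13 of the tail; j from the partner/RCK-ring surface) closer than
4.5 Å in the reference structure. For a configuration \(X\),

\[
Q(X) = \frac{1}{N}\sum_{(i,j)}
\frac{1}{1 + e^{\beta\,(r_{ij}(X) - \lambda\, r^0_{ij})}},
\qquad \beta = 5\ \text{Å}^{-1},\ \lambda = 1.5 .
\]

The logistic switch makes \(Q\) strictly interior to \((0,1)\); at
\(r_{ij} = \lambda r^0_{ij}\) each term is exactly \(1/2\), and in the
native frame the exponent is at most \(\beta(4.5 - 1.5\cdot 4.5) = -11.25\),
forcing \(Q > 0.95\) for any valid contact set. All pairwise-distance code
is plain all-pairs arithmetic — at the system sizes here (≤ ~1200 beads) no
neighbor-list acceleration is warranted, and exact agreement with the
brute-force oracle is asserted in the tests rather than approximated.

## Lipid contacts, z-distances and terminus length

A residue and a lipid molecule are in contact in a frame when any
heavy-atom pair between them is within 3.5 Å; each residue–lipid pair
counts once per frame. Membrane distances are signed vertical distances of
the residue's heavy-atom centroid from the mean phosphate z of the
*proximal* leaflet (the leaflet whose mean height is nearest the
selection), with z = 0 at the average phosphate position — matching the
convention used when plotting IDR insertion depth. The terminus length is
the end-to-end distance between the centroids of the first and last
residues of the range; an end-to-end rather than contour definition was
chosen because the quantity is used as a coarse order parameter for
conformational spread, and the choice is configurable in the residue range.
The residue reference point is the heavy-atom centroid because no specific
atom is canonical for a coarse bead model; with one bead per residue the
two coincide. Distances use no periodic wrapping: the toy systems are
non-periodic by construction.

# The synthetic trajectory generator

The generator builds a bead-per-residue model: only inter-particle
distances matter for every statistic above, so chemistry-free beads
suffice. A static core, a 20-bead tail (mirroring KtrB residues 2–21)
tethered `anchor_z` Å below the membrane plane, a static partner row
standing in for the RCK-ring surface, and a bilayer of two phosphate
leaflets (2 Å grid, 38 Å apart — the head-group spacing of a fluid
PE/PG/cardiolipin bilayer) with acyl beads between. Tail conformations are
re-sampled each frame as a tethered random walk with fixed 3.8 Å virtual
bonds; step polar cosines are drawn from a density \(\propto e^{a u}\)
where \(a\) is `membrane_affinity`, so \(a = 0\) is an unbiased walk and
large \(a\) drives the tail to the slab, where a reflective wall 1 Å above
the phosphate plane stops penetration. This emulates the electrostatics-
driven recruitment of the basic cluster to the anionic membrane surface
without any force field; what it does *not* emulate is lateral lipid
diffusion, specific head-group chemistry, temperature dependence, or
bound-state kinetics — so passing round trips demonstrates correctness of
the statistics, not realism of membrane binding. Frame 1 is the reference
(native) conformation laid alongside the partner row so that residues 7–13
define a non-empty native-contact set.

Each generator derives its RNG stream from its own `seed` and restores the
caller's stream afterwards, so adding one generator call to a script never
shifts another's output, and identical parameters give bit-identical data.

# Pore profiling

The profiler scans planes along z. At each plane the probe center is
optimized in-plane to maximize the clearance
\(\min_i(\lVert c - x_i\rVert - \mathrm{vdW}_i)\), clamped to
\([0, r_{\max}]\): a global 0.2 Å grid over the search box, a local 0.02 Å
grid around the best node, then a Nelder–Mead polish whose objective is
clamped to the box (so the probe cannot escape through the open side of a
ring into bulk solvent). This 2D-per-slice strategy replaces the original
3D Monte-Carlo path search of HOLE; for near-axial channels it reproduces
the radius-vs-z curve, and `align_structure_axis()` (PCA of pore-lining
atoms) handles tilted channels. Van der Waals radii default to the Bondi
set by element; HOLE's own radius set differs slightly, so absolute values
near sub-Å constrictions are method-dependent — the profiler is validated
against dense-grid oracles, not against any printed constriction value.
Reported diameters are 2 × radius.

# Shape classification of 2D class averages

Class averages are smoothed (Gaussian, σ = 2 px), binarized by Otsu's
global threshold (class averages are high-contrast single objects, so a
global threshold is appropriate), hole-filled, and reduced to the largest
connected component. The long/short outer diameters are the axes of the
second-moment equivalent ellipse (4·√eigenvalues of the pixel covariance),
a sub-pixel-accurate and rotation-invariant estimator; Feret-caliper
measurement of a manually drawn outline would be the manual-workflow
analogue, and the outer (hole-filled) edge is used since ring images leave
the inner/outer choice open. The conformation call uses the diameter ratio
against the threshold 1.115: below → square (ATP-bound ring), at or above
→ oval (ADP-bound ring). The published rule states only the strict
inequalities; equality is assigned to oval so the two label sets partition
the line. Fractions over a dataset are weighted by per-class particle
counts and sum to 1 exactly.

# Biophysical fits

**DSF.** The melting temperature is the peak of the first derivative of
fluorescence vs temperature — the standard readout of SYPRO-Orange melts —
computed from finite differences, smoothed with a centered Savitzky–Golay
filter (quadratic, 5-point window on the 1 °C assay grid), and refined by
parabolic interpolation. The estimate is exactly invariant under positive
affine transforms of the fluorescence; a curve with no positive derivative
raises a no-transition error rather than returning a boundary value.

**ITC.** Per-injection heats follow the exact one-site mass-balance
isotherm: after each 2 µL injection into the 280 µL cell, concentrations
follow the well-mixed displacement recursion
\(M_i = M_{i-1}(1-f)\), \(X_i = X_{i-1}(1-f) + X_s f\) with
\(f = \Delta V/V_0\); bound ligand is the root of the binding quadratic;
the injection heat is the change in cell heat content with the expelled
volume's share removed, normalized per mole injectant. The fit optimizes
(log K_D, ΔH, n) by Levenberg–Marquardt; log-scale K_D keeps the problem
well-conditioned across the µM–mM range. Generator and fitter share this
forward model, which is what makes the noiseless round trip exact — the
point of the round-trip acceptance design.

**Uptake kinetics.** Initial velocities are OLS slopes over the early
window (≤ 4 min, i.e. the 1/2/3/4-min samples of the assay's
1–10 min schedule, with a 50%-of-plateau guard). The synthetic time
courses are linear over exactly that window (slope
\(V_{\max}S/(K_M+S)\)) and then approach a plateau at \(12\,v_0\) along a
C¹ exponential, mimicking substrate depletion. Velocities vs substrate are
fitted to \(Y = V_{\max}X/(K_M+X)\) by unweighted nonlinear least squares
(the conventional plain fit for such data; inverse-variance weighting is
available). Equal velocities at all substrate levels are the saturated
\(K_M \to 0\) boundary and are returned as such with a flag.

# DEER forward model and inversion

The powder-averaged dipolar kernel is
\(K(t,r) = \int_0^1 \cos[(1-3x^2)\,\omega_{dd}t]\,dx\) with
\(\omega_{dd} = 2\pi\cdot 52.04\ \text{MHz nm}^3/r^3\) (the free-electron
dipolar constant), evaluated by 201-node Gauss–Legendre quadrature
(agreement with adaptive quadrature to ≤ 10⁻⁶ is asserted in tests).
Traces are \(V(t) = [(1-\Delta) + \Delta F_\mathrm{intra}(t)]\,B(t)\) with
stretched-exponential background \(B(t) = e^{-k t^{d/3}}\). Background
correction fits \(\log V\) on the tail window (default: the final 40% of
the trace) linearly in \(t^{d/3}\); because \(V(0)=1\), the fitted
zero-time amplitude equals \(1-\Delta\), giving the modulation depth
without a separate fit. This assumes the intramolecular modulation has
decayed within the tail window — true for broad distributions; very narrow
distributions keep oscillating and bias the background fit, a known
limitation of tail-fit correction shared by the standard analysis tools.

Inversion solves, per regularization weight α,
\(\min_{p\ge 0}\ \lVert Kp - F\rVert^2 + \alpha^2\lVert Lp\rVert^2\)
with L the second-difference operator, by an active-set non-negative
least-squares solver (FNNLS on the precomputed normal equations,
warm-started along the α ladder — the exact KKT solution, just reached
faster). The default grid is 1.5–8 nm at 0.02 nm and the ladder 61
log-spaced α over 10⁻³–10³; α is chosen at the L-curve corner (maximum
finite-difference curvature of log residual vs log seminorm). The solution
is renormalized to unit trapezoid integral; mode (parabolically refined),
mean and central-95% width summarize it. Jackknife-style error bands over
background windows are not implemented; the uncertainty treatment here is
deliberately simpler than full validation in dedicated DEER packages.

# Problem sizes and numerical conventions

The suites run generators at 30–200 frames, ~1200 beads, 56-point melt
grids, 20-injection thermograms, 376-point DEER traces and 326-point
distance grids — sizes chosen so every stage, including the 61-point α
ladder, verifies in seconds while leaving all estimators at their
production defaults. Coordinates are Å throughout the trajectory and pore
code; DEER distances and ring axes are reported in nm, matching the units
in which such results are quoted. Ties in `min_constriction` break to the
smallest z; degenerate inputs (empty contact sets, flat melt curves,
zero-heat thermograms, all-zero distributions) raise typed errors rather
than returning NaN.

# The pipeline surface

`run_pipeline()` drives the stages from a validated config (R list or
YAML/JSON); unknown keys are rejected by name, defaults equal the analysis
defaults above (β = 5 Å⁻¹, λ = 1.5, 4.5 Å, 3.5 Å, ratio threshold 1.115),
and a run record with config hash and per-file md5 manifest makes reruns
checkable for bit-identical reproduction. The package is a library first:
the exported functions, this vignette and `scripts/acceptance.R` are the
intended entry points.

# Known limitations

- The toy trajectory is a statistics-faithful, physics-free bead model;
  nothing about real binding kinetics or lipid specificity transfers.
- The pore profiler is slice-wise 2D; strongly kinked channels need the
  axis alignment helper and remain approximate.
- Tail-fit background correction biases narrow-distribution DEER data
  (see above); the inversion itself is validated on form factors.
- ITC fits assume the one-site model; no competitive or two-site isotherms.
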