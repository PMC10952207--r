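---
title: "Methods: morphometry-aware SAR estimation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry-aware SAR estimation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

At 7 T the RF wavelength in tissue is comparable to the head, so the local
specific absorption rate (SAR) produced by a parallel-transmit (pTx) head
coil depends strongly on the individual head: its size, shape, position in
the coil, and tissue composition. Scanners enforce local-SAR limits through
precomputed electromagnetic simulations on generic voxel models, padded by a
population safety margin. A natural way to shrink that margin is to *morph*
a well-characterized reference voxel model into the geometry of the subject
actually being scanned — via affine or nonlinear registration of synthetic
T1-weighted images — and to simulate SAR on the morphed model. `ptxsar`
implements that whole workflow at desk scale on fully synthetic data:
phantom generation, registration, a surrogate field solver, 10 g-averaged
SAR, Q-matrix shimming, VOP compression, and all the agreement statistics
needed to quantify how much of the inter-subject SAR difference morphometry
explains.

Everything runs on one CPU in minutes. The package deliberately does *not*
attempt to reproduce numbers obtained with licensed anatomical models
(MIDA, Duke, Ella) and commercial full-wave FDTD solvers; what it preserves
is the structure of the pipeline, its exact operating constraints
(normalizations, averaging masses, compression margins), and the
qualitative orderings that make the scientific point.

# Synthetic phantoms as a stated world

`make_phantom()` builds a labeled head from nested ellipsoid shells —
skin, fat, skull, CSF, gray matter, white matter from the outside in — a
distinct cerebellum lobe, CSF ventricles, an optional muscle/skin neck slab,
and a low-order sinusoidal surface modulation (amplitude 2% by default,
phases seeded per subject) so no two "subjects" are exact ellipsoids. The
two built-in targets differ from the reference by anisotropic scaling
(8–10% per axis), global rotations below 10 degrees, shifted internal
structures, and slightly different shell thicknesses: enough that rigid
alignment alone leaves visible morphometric mismatch, which is the regime
the study design needs.

Tissue properties ship in `default_tissue_table()`: representative
conductivity and permittivity at 297.2 MHz, density, synthetic T1-weighted
intensity mean/sd per tissue, and the group used for Dice reporting (e.g.
cancellous bone reports under "skull", mirroring how deep gray nuclei are
pooled with gray matter in segmentation comparisons). Permittivity is
carried but unused by the surrogate solver (see below).

What the generator does *not* emulate: gyrification, vasculature, air
sinuses, anatomical asymmetry, realistic skull structure. A green test on
these phantoms therefore establishes the correctness of the *pipeline
machinery* — registration recovery, averaging arithmetic, superposition
identities, compression bounds — not field-pattern fidelity on real
anatomy.

The T1 noise model is Gaussian per tissue (mean and sd columns of the
tissue table, or a global `noise_sd`). The source study imported measured
T1-weighted intensities without stating a noise model; Gaussian per-tissue
noise is this package's own choice, made once.

# Registration

The affine stage (`register_affine()`) maximizes masked normalized
cross-correlation with a derivative-free Nelder-Mead search over 6 (rigid)
or 12 (affine) parameters, through a 3-level anti-aliased image pyramid
(Gaussian smoothing at sigma = factor/2 voxels before decimation — without
this the coarse levels alias the thin shells and the optimum is wrong).
Initialization is center-of-mass alignment of the brain masks; the affine
stage is *brain-driven*, mirroring the brain-extraction-first design of the
original workflow. Recovery accuracy on noiseless phantoms: translations to
well under 0.5 mm, scale to under 1%, rotations to under 1 degree
(asserted in the acceptance suite).

The nonlinear stage (`register_nonlinear()`) is a multi-resolution
demons-style method: intensity-difference forces along the warped-image
gradient, a Gaussian-smoothed update (fluid regularization, sigma 1.2
voxels) plus field smoothing (diffusion, sigma 0.6 voxels), driven by the
*whole-head* images and initialized by the affine transform. The result is
a dense per-voxel displacement field on the fixed grid (world mm), composed
with the affine at application time via pull-back resampling. A spline
control grid was the stated design alternative; demons was chosen because
it is simpler, deterministic, and passes the same recovery oracle (a 4 mm
Gaussian bump is recovered to < 1 mm residual RMS). Labels are always
warped nearest-neighbor; intensities trilinearly.

Brain masks come from the label model when available (union of gray
matter, white matter, cerebellum, plus enclosed CSF via hole filling) or
from Otsu thresholding + largest connected component + morphological
closing otherwise; the two agree to Dice >= 0.95 on noiseless phantoms
because the dark skull/CSF shell disconnects brain from scalp.

# The surrogate field solver

Full-wave FDTD is out of scope. `simulate_channel_fields()` uses a
quasi-static surrogate for an 8-channel loop array on a 300 mm cylinder
(110 x 220 mm rectangular elements, 297.2 MHz): per channel, **B** from a
Biot-Savart line integral over the discretized loop, **E** = -i omega **A**
from the same loop's vector potential, and both attenuated inside tissue by
exp(-d/delta) where d is the in-tissue path length from the element center
(ray marching) and delta the voxel-local skin depth from its conductivity.
This preserves exactly the properties the downstream analysis depends on:

* strict linear superposition over channels (the basis of Q matrices),
* tissue-dependent loss and periphery-loading/center-brightening structure,
* per-channel normalization to 1 W *conducted* power.

"Conducted power" is defined as power deposited in the model (coil
efficiency eta = 1, configurable): the surrogate has no radiation or
coil-loss channel, so this makes the two stated normalizations (1 W per
channel; 5 W total for shim sets) implementable and mutually consistent.
Inter-element coupling, tuning/matching (S-matrices), the gradient shield,
and permittivity-driven wavelength effects are not modeled — a documented
fidelity gap, not an approximation error: literature on this coil class
reports up to ~41% local-SAR variation from S-matrix differences alone.

B1+ is (Bx + i By)/2 with the static field along the cylinder axis.
Complex fields are peak phasors, so the loss density is sigma |E|^2 / 2 and
pointwise SAR is sigma |E|^2 / (2 rho); this convention is stated
prominently because nothing downstream is consistent without it.

# 10 g averaging and Q matrices

`sar_10g()` implements a simplified, oracle-verifiable reading of the
IEC/IEEE 62704-1 cube rule: a voxel-centered cube grows in odd side lengths
until the enclosed tissue mass reaches 10 g; the outermost layer is
weighted fractionally so the mass is met exactly; voxels whose cube would
exceed a 15-voxel side take the maximum over valid cubes containing them.
The standard's surface-face adjustment rules are deliberately simplified;
in exchange the implementation is provably identical to an exhaustive
brute-force cube search (asserted exactly on random grids up to 12^3).
Cube sums use 3D prefix tables, so the cost is O(voxels x sides), not
O(voxels x cube volume).

Because the growth rule depends only on mass, the region set is fixed
geometry: each region's 8 x 8 Hermitian Q matrix then satisfies
w^H Q w = (10 g SAR of that region under shim w) *identically*, and the
package asserts the Q path against the direct
combine-fields -> pointwise SAR -> cube-average path to 1e-6 relative over
random shims. Regions are stored sorted by largest eigenvalue, which makes
exact evaluation of thousands of shims cheap: the scan stops as soon as
`eigmax x |w|^2` cannot beat the current best (an exact bound, not a
heuristic).

# VOP compression and the overestimation margin

`compress_vop()` makes a greedy pass over regions in descending spectral
norm; a region joins an existing VOP core V when V + Z - Q is positive
semi-definite, else it seeds a new core. Two overestimation terms are
implemented, and the choice matters more than it first appears:

* **proportional** (default): Z = lambda V, membership test
  (1 + lambda) V - Q PSD. Since every core is itself a source matrix, the
  bound max_V (1+lambda) w^H V w both dominates the true maximum and can
  never exceed (1+lambda) times it: the *per-shim relative* overestimation
  is provably <= lambda. Measured on the built-in phantom over 5000 random
  shims the maximum overestimation is exactly 5.000% at lambda = 0.05. The
  price is weak compression on these smooth surrogate fields (most regions
  are nearly rank-one with distinct principal directions, which a 5%
  inflation cannot mutually dominate).
* **scaled_identity**: Z = lambda ||Q||_max I, the classic full-rank lift.
  It compresses dramatically (81 cores from ~19k regions at 5 mm — the
  same order as published head-model compressions) but only bounds the
  *absolute* overestimation by lambda ||Q||_max |w|^2; per-shim relative
  errors reached 87% in our measurements for shims whose true maximum is
  far below the worst case.

Because the package's stated contract is a per-shim relative bound
("VOP bound never underestimates, relative overestimation <= 5%"), the
proportional term is the default and the scaled-identity term is retained
as an option for studying compression behavior. The upper-bound direction
is always a hard assertion with no tolerance.

# CP mode and normalizations

`cp_mode()` forms the circularly polarized shim (equal magnitudes, phase
-azimuth per channel, i.e. 45 degree steps for 8 channels), scales all
fields so |B1+| at the coil isocenter is exactly 2 uT, and reports
head-averaged SAR, maximum 10 g SAR, the normalization factor, and total
absorbed power. Two identities are enforced at 1e-6 relative and tested on
every run: deposited power per normalized channel = 1 W, and
SAR_head x head mass = total absorbed power (the mass-weighted-mean
identity behind the four-row CP summary).

Random shim sets follow the stated recipe: per-channel magnitude
Uniform(0,1) and phase Uniform(0, 2 pi), then a global rescale to 5 W total
conducted power. "Random relative magnitude (0–1)" is read as per-channel
uniform (a normalized direction draw would be the other defensible
reading); the choice is recorded here and in the shim CSVs.

# Numerical choices and degenerate inputs

* Voxel indices are 0-based with a 4 x 4 voxel-to-world affine, all world
  units mm; volumes are written as uncompressed NIfTI-1 (the package
  carries a minimal reader/writer because no pre-installed R package
  provides one).
* PSD tests use a Cholesky attempt on M + tol I with
  tol = 1e-9 ||Q||_max; eigenvalue assertions in tests use the same
  relative floor.
* The comparison mask for property and |E|^2 difference maps defaults to
  the *union* of the two models' tissue supports (the stricter of the two
  readings the source material permits), with intersection available.
* The percent-difference denominator is the target-model series (errors
  framed as deviations from the native simulation); pairwise-mean is an
  option and the convention is stored in every report.
* Bland-Altman spread lines default to +/- 1 sd, with 1.96 as an option.
* Degenerate inputs fail loudly: all-air models cannot be normalized,
  heads lighter than 10 g cannot be averaged, singular affines and empty
  masks are errors, zero-magnitude shim draws are redrawn.
* Determinism: every stochastic operation takes a seed; the pipeline fans
  a single global seed into named per-stage substreams recorded in the run
  manifest, and identical configurations produce byte-identical reports.

# Known limitations

The surrogate solver's E-phase structure is simpler than full-wave reality
(per-channel phase varies only through geometry), so destructive
interference patterns are tamer than in a real coil; absolute SAR values
are not comparable to published head-model tables, and no in-vivo or
inter-solver validation is possible or claimed. The 10 g rule simplifies
the standard's surface-cube handling. The registration similarity metric
and pyramid schedule are this package's own (the original workflow names
only external tools); they are validated by synthetic-transform recovery,
not by equivalence to those tools. VOP counts depend on the Z term as
discussed and are not comparable across modes.
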