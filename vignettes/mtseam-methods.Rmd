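---
title: "Models and methods behind mtseam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtseam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtseam)
```

This vignette explains the models implemented in `mtseam`, the
assumptions behind them, the tunable parameters and why their defaults
are what they are, and the known limits of each estimator. It states
no number that the package's test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The parametric lattice

`mt_lattice()` builds an N-protofilament microtubule as point
monomers: each dimer is an α monomer and a β monomer 4 nm apart
axially, repeating every 8 nm along a protofilament (PF). PF k sits at
an azimuth given by the cumulative inter-PF angle profile (uniform
360/N by default) and at an axial offset proportional to the azimuth
travelled, accumulating `start_stagger` nanometres over one full turn.

* `radius = 11` nm — PF-center radius of a 13-PF microtubule; the
  standard order of magnitude for tubulin lattices, configurable.
* `dimer_rise = 8` nm — the tubulin dimer repeat.
* `start_stagger = 12` nm — a three-start monomer helix: 1.5 dimers of
  rise per turn. The closing junction is then mismatched by
  `12 mod 8 = 4` nm — half a dimer — which makes exactly that junction
  heterotypic (α against β): the B-lattice seam. An integer multiple
  of the dimer rise closes seamlessly; the constructor records the
  ground-truth seam only when the modular mismatch is non-zero.
* `seed_pf` anchors the numbering, so the labelled position of the
  ground-truth seam can be placed anywhere; by default the seam is
  junction (N, 1), the convention in which a seam binder touches
  α-tubulin of PF 1 and β-tubulin of PF N.

The dimer is deliberately a pair of points, not an atomic model:
every downstream stage (angles, seam parity, densities) needs only
positions and chain identities, and coordinate export (PDB/mmCIF/CSV)
is an I/O concern. Lattice defects, GTP-state and atomic detail are
out of scope.

## 2. Measuring lattice geometry

**Axis.** Plain PCA of a helical lattice is biased: the axial start
offsets correlate with azimuth, tilting the principal axis by several
degrees. For labelled sites `fit_filament_axis()` therefore averages
per-PF line directions (each PF is exactly parallel to the tube axis);
for unlabelled clouds it refines the PCA direction by minimising the
variance of the projected radius (a cylinder fit). Coplanar input has
no cross-sectional plane and is rejected.

**Inter-PF angles.** The literature rarely states how inter-PF angles
are measured. `compute_inter_pf_angles()` uses the *central angle*
convention: per axial repeat, dimer midpoints are projected onto the
plane perpendicular to the axis, an algebraic (Kåsa) least-squares
circle center is fitted, and the angle of each junction (i, i+1) is
the difference of polar angles about that center. This convention is
closed — the thirteen angles of a 13-PF tube sum to exactly 360° — and
reproduces 360/N on ideal tubes, which makes ideal references
comparable across N. The per-junction mean over repeats is returned
with its SD, so a user can distinguish a single-section measurement
from a per-repeat average. The alternative (turning angle of the PF
polygon) is not closed and is not implemented. Repeats missing a PF
are excluded with a warning; fewer than three usable repeats is an
error. The traversal direction is normalised so junctions follow
increasing PF labels regardless of how the model is oriented.

**Seam detection.** For each azimuthally adjacent PF pair,
`classify_junctions()` finds each monomer's nearest lateral neighbour
on the partner PF within a ±6 nm axial window (excludes next-nearest
repeats without tuning) and votes homotypic or heterotypic by chain
parity. The decision margin is applied to the *axial* mismatch of the
nearest same-chain vs cross-chain candidate (default 1 nm), not to the
3-D distance: at r = 11 nm the in-plane separation (~5.3 nm) is common
to both candidates and compresses 3-D distance differences to below
1 nm even on noise-free lattices, whereas the axial offsets (0.92 vs
3.08 nm for the canonical geometry) separate cleanly. Monomers whose
margin is not met vote "indeterminate"; a junction with a tied or
empty vote is reported indeterminate rather than forced.

**Unlabelled coordinates.** `assign_protofilaments()` clusters
projected azimuths by the largest relative jump in the sorted
circular-gap sequence, constrained to 8–20 clusters, and verifies the
count in three axial slabs; instability raises an error listing the
candidate counts. Labels are assigned in azimuthal order, so they
match original labels up to a cyclic shift.

## 3. Synthetic tomograms and volume analyses

`render_lattice_volume()` places a Gaussian blob (σ = 1.2 nm,
i.e. FWHM ≈ 2.8 nm — monomer-scale granularity) at every monomer site,
optional decoration blobs (σ = 1.5 nm, radial offset 4 nm outside the
PF radius) every 8 nm at chosen junction azimuths with Bernoulli
occupancy, Gaussian noise with SNR defined as sd(signal)/sd(noise),
and finally a missing wedge. The default voxel is 8 Å — far coarser
than the ~2 Å native pixel of high-end acquisitions, but the relevant
periodicities (80 Å repeat, 40 Å monomer spacing) remain well above
Nyquist and volumes stay desk-sized. Monomer σ matters: blobs much
wider than ~2 nm merge the 4-nm beads into smooth rods, which moves
all rotational contrast to the axially constant Fourier component —
precisely the region a missing wedge destroys.

**Missing wedge.** With the filament along z, beam along x and tilt
axis y, a ±`half_angle` tilt series covers Fourier components with
`atan2(|kx|, |kz|) <= half_angle`; `apply_missing_wedge()` zeroes the
rest. The operation is a Fourier mask, hence idempotent, and the DC
component lies in the covered region, so real-space mass is conserved.
The test suite checks the mask against a naive explicit-DFT oracle.

**PF-number classification.** The textbook N-fold rotational signature
lives at kz = 0, which the wedge removes (it would require resolution
along the beam). For an `n_start`-start helix, however, the monomer
layer line at 1/(4 nm) carries angular harmonics N − n_start and
N + n_start (the per-PF stagger is n_start/N of the monomer rise), and
those components sit inside the covered region for a ±60° wedge.
`classify_pf_number()` bins the annulus at the PF radius (estimated
from the radial profile of the z-projection) into 64 angular bins,
takes the 2-D power spectrum over (angle, z), integrates power at the
layer-line kz bins, and scores each candidate N by its two signature
harmonics normalised to the median background harmonic. The margin
between best and second-best candidate must exceed `margin_min = 4`:
pure-noise volumes produced margins no larger than about 3 over
hundreds of simulated draws, while genuine lattices at SNR 0.25–0.5
score an order of magnitude higher, so the default cleanly separates
"unclassified" from real decisions. The classifier assumes the
candidate lattices share the generator's three-start geometry; other
helix families need `n_start` set accordingly.

**Decoration scoring.** `junction_decoration_profile()` samples the
mean density in an external shell (2–6 nm beyond the PF radius,
azimuthal half-width half the junction's angular spacing) as a
function of z, detrends Welch segments of two dimer periods (50%
overlap), and averages the periodogram power at the dimer frequency.
The lattice itself contributes almost nothing there: with equal α and
β amplitudes the monomer ladder's power sits at 4 nm, not 8 nm. The
null for calling is built from the *background frequency bins of all
junctions pooled* (log scale, median/MAD): thirteen junction scores
alone estimate the spread too noisily for a z ≥ 3 rule, while the
pooled background gives a stable null in which a decorated minority
cannot mask itself. z ≥ 3 then yields a per-volume false-positive rate
of a few percent on undecorated volumes, which the acceptance run
measures. `call_seam_binder()` reports a unique call, a multi-site
list (several called junctions — the multiple-seam reading of
stabilized microtubules), or no call.

**Picking grids.** `interpolate_filament_grid()` arc-length
parameterises the traced polyline and places centers every 80 Å with
the local segment direction as tangent; joints use the following
segment. Densifying a polyline with collinear points does not move the
centers.

## 4. The two-state dynamic instability simulator

Events are resolved in continuous time — exponential waiting times for
nucleation (clock starting when the mix arrives between frames 1 and
2), catastrophe during growth and rescue during shrinkage, with
deterministic velocities in between — and only then sampled at the
frame grid (10 s/frame, 180 frames by default). Frame-quantised
simulation would distort short phases and break the closed-form
checks the suite relies on: mean maximal excursion v_g/f_cat,
single-excursion rescue probability 1 − exp(−f_res·(L₀−d)/v_s), and
exponential phase durations. A tip reaching the seed resets to the
pre-nucleation state and, by default, may renucleate.

Default rates describe a plausible reconstituted-tubulin control:
v_g = 1.2 µm/min, v_s = 6 µm/min, f_cat = 0.25/min, f_res = 0.5/min,
k_nuc = 0.3/min, seed 2 µm. v_s is at the slow end of reported
depolymerisation rates; it was chosen so that a typical shrinkage
phase spans several 10-s frames and therefore *has* a measurable slope
at the acquisition geometry the package emulates. The TIRF pixel is
0.1 µm (not stated by typical methods sections; typical for the
camera/objective class), which makes the 5-pixel rescue rule equal to
0.5 µm. `render_kymograph()` paints seed plus filament per frame,
convolves with a 1-px Gaussian line-spread and adds noise with SNR
defined as line amplitude over noise SD.

A stabilizer dose–response is *not* given a baked-in kinetic law; the
acceptance run uses one explicit choice (f_cat divided by, and f_res
multiplied by, 1 + c/600 with a mild nucleation speed-up) purely to
demonstrate the qualitative signature: length, lifetime and rescue
probability rise with concentration while the shrinkage rate stays
flat.

## 5. Kymograph quantification

`trace_tip()` thresholds at an Otsu level after light 3-pixel lateral
smoothing (averages pixel noise without moving edges), walks out from
the middle of the seed — the image edge itself is attenuated by the
PSF — bridging sub-threshold gaps up to 2 px, and takes the farthest
pixel contiguous with the seed. The temporal filter is a *conditional*
3-frame median: a frame is replaced only when it deviates from both
neighbours in opposite directions by more than 5 px (an isolated
mis-traced row). An unconditional median would clip every sharp
growth-to-shrinkage corner by design, which is exactly the frame the
segmentation needs intact. Pure-noise images fail either the
supra-threshold-rows check or the seed-consistency check (the
immobilized seed must be bright in ≥ 80% of rows) and raise "no
microtubule detected".

`segment_phases()` labels inter-frame steps as growth, shrinkage or
pause on a 3-frame median-smoothed copy (stable signs), while all
slope fits use the unsmoothed values (sharp corners). Runs shorter
than `min_phase_frames = 3` are absorbed into their longer neighbour —
unless they displace the tip by ≥ 4 px (a sub-resolution
catastrophe-plus-rescue excursion is an event, not jitter), and a
single-frame displacement ≥ 6 px overrides the smoothed label for the
same reason. Short pauses flanked by same-sign runs are merged.
Slopes are least squares over the phase frames, dropping the first and
last frame when the phase can afford it (event times fall between
frames, so boundary frames straddle phases), with one outlier-rejection
pass. Shrinkage fits additionally drop frames pinned at the seed floor
(≤ 3 px), drop a first/last frame whose adjacent step is growth-like
(it lies on the flanking growth line), and are reported `NA` when
fewer than two clean frames remain or the phase spans fewer than three
frames — a two-frame phase has no interval surely interior to the
shrinkage. This "missing, not zero" rule is why a summary can have
`censored = FALSE` yet `shrink_rate = NA`.

`compute_dynamics_summary()` implements the first-triangle convention:
length is the maximal extension within the first growth phase and its
terminating shrinkage; lifetime runs from the first frame after the
baseline (nucleation) to the peak frame; the growth rate converts the
growth slope via pixel size and frame interval; nucleation time is
measured from the mix frame. A movie ending mid-growth censors the
triangle: the shrinkage rate is missing, and aggregation excludes
missing values from the affected statistic only. Rescue events are
every shrinkage termination; `is_true_rescue` applies the 5-pixel
rule at the trough around the transition, and `rescue_probability()`
is true rescues over all events per replicate, averaged across
replicates.

## 6. What the generators do and do not emulate

The synthetic stages reproduce the *geometry* and *statistics* that
the estimators consume: lattice symmetry and seam parity, 8-nm
periodicities, wedge anisotropy, white Gaussian noise, two-state
kinetics with exponential waiting times, PSF blur and frame sampling.
They do not emulate CTF modulation, dose-dependent damage, structured
background (neighbouring filaments, carbon edges), lattice defects or
PF-number transitions within one filament, tubulin-concentration-
dependent rate laws, GTP-cap aging, photobleaching or stage drift.
Passing tests therefore demonstrate correctness of the computations
under the stated models, not robustness to every pathology of real
micrographs and movies.

## 7. Known limitations

* **Lifetime at 10-s sampling.** A first triangle must produce roughly
  two frames of visible growth to be detected. By memorylessness,
  conditioning an exponential lifetime on exceeding a detection floor
  δ shifts its mean from 1/f_cat to 1/f_cat + δ — about +8% at the
  default f_cat = 0.25/min — and catastrophe–rescue pairs that
  complete within a single frame interval (net tip drop of a pixel or
  so) are physically invisible and merge consecutive triangles,
  adding a few percent more. The end-to-end recovery check measures
  exactly this: growth and shrinkage velocities come back within a few
  percent, while the mean first-triangle lifetime sits 10–20% above
  1/f_cat depending on the random draw. This is a resolution property
  of kymograph analysis at the acquisition geometry itself, not a
  removable estimator defect; treat recovered lifetimes as upper
  estimates near the frame-rate limit.
* **Short shrinkage phases.** At 10 s/frame a fast-depolymerising
  microtubule crosses the field in one or two frames; such phases are
  reported as missing rather than fitted, so shrinkage statistics
  condition on phases long enough to measure (this selection is
  unbiased for a constant v_s).
* **PF classification** assumes the filament axis is aligned with the
  volume z axis (as produced by the bundled renderer or by upstream
  subtomogram alignment) and a known helix start number.
* **Angle measurement** assumes labels; unlabelled models must first
  pass through `assign_protofilaments()`, which requires clear angular
  clustering (jitter well below the inter-PF spacing).

## 8. Problem sizes used by the checks

The acceptance-style checks run at the scales a desk machine handles
comfortably: hundreds of rendered volumes per classification batch
(48–54 voxels across, 12 dimer repeats), 200 simulated movies for
parameter recovery, thousands of excursions for the closed-form laws,
and 800 microtubules per concentration for the dose series (sized so
the smallest dose step is a three-sigma difference against the
per-microtubule spread).
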