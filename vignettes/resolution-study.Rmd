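---
title: "How x-ray image resolution shapes model-based bone pose estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How x-ray image resolution shapes model-based bone pose estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radiopose)
```

## The question

Biplanar videoradiography (BVR) estimates the 6-DOF pose of a bone by
aligning a CT-derived attenuation volume with two calibrated high-speed
x-ray views: digitally reconstructed radiographs (DRRs) of the volume
are rendered into each view and an optimiser adjusts the pose until the
DRRs match the radiographs. Because the matching cost is driven by bone
*edges*, image resolution enters in a non-obvious way: full-resolution
captures have finer but noisier edges, while downsampled images trade
detail for per-pixel signal-to-noise. `radiopose` is a self-contained,
fully synthetic framework for studying this trade-off: it generates
phantom bones, calibrated camera rigs, gold-standard trajectories and
noisy radiographs; registers perturbed poses back to the images with a
particle swarm optimiser; and scores the result with helical (screw)
axis errors and robust nonparametric statistics. Everything is
deterministic given seeds, so every number is reproducible.

## The synthetic scene

`make_trial_scene()` builds an ankle-like arrangement of three bones:

* a **talus-like** bone (`enclosed`): compact, sitting at the origin,
  overlapped in projection by both neighbours — the hardest
  registration target;
* a **tibia-like** bone (`long-bone`): elongated at least 3:1, placed
  above the talus with its shaft leaving the field of view (as the
  diaphysis does in real ankle captures); an `exit_fov` excursion
  pushes it further out in the first and last ~15% of frames;
* a **calcaneus-like** bone (`isolated`): larger, mostly clear of the
  others, with its posterior-inferior edge slightly clipped by the
  field of view.

Each bone is a superellipsoid whose surface is modulated by a
low-frequency random field (peak excursion 45% of the local radius,
divided across three harmonics — features of roughly 3–8 mm), with a
cortical shell about two voxels thick at attenuation 0.06/mm, a
textured trabecular interior around 0.028/mm, and three dense
ellipsoidal inclusions at 92% of cortical attenuation. The surface
modulation and the internal structures are not cosmetic: a smooth
ellipsoid's projection is almost invariant under rotation about its own
axes, which makes rotation unidentifiable for *any* cost function. Real
bones are identifiable because they are irregular; the phantom has to
be too.

The camera rig is two pinhole projectors 60° apart whose principal
rays meet at the world origin (source–origin 1100 mm, source–detector
1300 mm, detector width 90 mm — plausible laboratory values, not taken
from any particular system; all configurable). World geometry is fixed
in millimetres: changing `image_size` or `grid_size` changes only the
sampling density, so a desk-scale scene and a full-scale scene image
the same physical phantom. The default desk scale is a 256×256 native
capture downsampled 4× to 64×64 — the same ratio as the full-scale
2048×2048 → 512×512 treatment — with 64³ bone volumes and 8 frames;
`paper_scale = TRUE` in `experiment_config()` raises the sizes towards
the full-scale study for users with time.

### Noise model

Detector counts are modelled per pixel as
`I = photon_scale * exp(-∫μ ds)`, Poisson-sampled, plus Gaussian read
noise (σ = 3 counts), clipped at zero — applied once at the *native*
resolution. Downsampled conditions reuse the same noisy images, so
condition comparisons isolate the resampling operator. The default
`photon_scale` of 45 counts at zero attenuation puts the native capture
in the photon-starved regime of high-speed radiography (hundreds of
frames per second at fine pixel pitch): behind bone, expected counts
drop to single digits, per-pixel edge contrast-to-noise at native
resolution falls below one, and 4×4 averaging during downsampling
recovers it several-fold. This is the regime in which resolution
matters at all — and the regime in which the three conditions behave
as the full-scale study describes: full-resolution registration
breaks down while both downsampled treatments keep working. With much
lower photon budgets nearest-neighbour decimation (which averages
nothing) collapses along with full resolution; with generous budgets
all three conditions register equally well and the study degenerates.

## Resolution treatments

`downsample_bicubic()` is separable cubic convolution with the Keys
kernel (a = −0.5). Output pixel `i` is centred at input coordinate
`(i + 0.5)·scale − 0.5`; when shrinking with `antialias = TRUE` (the
default, matching the common reference resize routines) the kernel is
widened by the scale factor so the weighted neighbourhood covers the
output pixel's footprint; weights are renormalised and out-of-range
taps are clamped to the nearest valid pixel (the convention of the
major numerical environments; note that some libraries instead drop and
renormalise boundary taps, which differs in the outermost output ring).
`downsample_nearest()` uses the same centre mapping with no
anti-aliasing and introduces no new pixel values. Bicubic overshoot is
not clipped by default.

## DRR rendering and the registration cost

`render_drr()` ray-marches the posed volume: for each detector pixel a
ray from the source is clipped to the world bounding box of the
volume's nonzero support and sampled by trilinear interpolation at a
fixed nominal step (default half the smallest voxel spacing; the step
is shrunk so an integer number of samples tiles the clipped segment).
Only pixels inside the projection of that box are marched; the rest
are exactly zero, which is identical to full casting because the box
contains the support. Renders are linear in attenuation and converge
as the step shrinks (halving the default step changes pixels by well
under 1%).

The registration cost sums `1 − NCC` over the two views. Both sides
are reduced to edge maps first: targets are mapped back to the
line-integral domain (`neglog`), then contrast-stretched (1st–99th
percentile) and passed through a Sobel magnitude filter; candidate DRRs
go through the same stretch–Sobel chain. The correlation is evaluated
over the DRR's *silhouette* (the pixels the DRR actually covers) rather
than its bounding rectangle: with an enclosed bone, the rectangle is
dominated by neighbouring bones' edges and the pose signal drowns. The
`neglog` mapping is also where photon starvation enters the cost:
`−log` of a near-zero count is a large spike, so full-resolution edge
maps carry heavy noise that spatial averaging would have removed.

`optimize_pose()` is a canonical global-best particle swarm over a
6-vector offset from the initial pose (axis-angle degrees about the
bone's inertial centre, translation in mm), with one particle pinned at
the zero offset, velocity update `v ← w·v + c1·r1·(pbest−x) +
c2·r2·(gbest−x)`, positions clamped to the bounds, and deterministic
behaviour given the seed. Defaults — 40 particles, 60 iterations,
w = 0.7, c1 = c2 = 1.5, bounds ±10° / ±10 mm — are standard settings
sized to the worst-case ±8° perturbation; the experiment configs in the
test-suite use smaller swarms, stated below.

## Perturbation scheme and error metric

Initial-guess error is emulated by rotating the gold pose about seven
axes through the bone's inertial centre: the three principal axes of
the intensity-weighted inertia tensor and the four normalised body
diagonals `(±1, ±1, ±1)/√3` (one of each sign pair, since both signs of
rotation are applied). With magnitudes {2°, 4°, 8°} and both signs this
yields 42 perturbed poses per bone and frame. Principal axes are
ordered by descending moment; the first two columns are signed so their
largest component is positive and the third is their cross product
(right-handed by construction). Whether the perturbation rotation is
composed before or after the gold transform is not observable from the
error metric (the helical angle of `perturbed ∘ gold⁻¹` equals the
requested magnitude either way); this package fixes
"perturbation ∘ gold" in the world frame.

Pose error is the Chasles decomposition of `estimated ∘ gold⁻¹`: the
helical angle φ (degrees, in [0, 180]) as rotational error and the
absolute translation along the helical axis (mm) as translational
error. φ is frame-invariant; the translation component depends on the
fixed world-frame convention, which is documented because it is a
choice. Angles below 10⁻⁶ degrees are treated as degenerate (pure
translation). Downstream summaries use absolute values throughout, so
limits of agreement can exceed 180° even though the metric cannot —
that is a property of the summary, not the measurement, and is left
unclamped.

## Statistics

Per bone × perturbation magnitude × condition, errors are pooled
across frames and axes and summarised by the median; the limits of
agreement `median ± 1.45 × IQR` (IQR from linear-interpolation
quantiles, type 7 — the LOA depends on this convention, so it is
pinned; negative lower bounds truncate to 0 because the data are
absolute errors); the cumulative error `Σ|x|`; the *unscaled* MAD
`median(|x − median|)` (no 1.4826 factor — it is a raw spread
descriptor here); and the Hampel identifier in modified z-score form,
`0.6745·|x − median|/MAD > 3.5`, the standard pairing for a 3.5
threshold (the unscaled variant is available behind a flag). When the
MAD is zero exactly the off-median points are flagged. A consequence
worth noting: when a condition fails so broadly that the median and
MAD are themselves large, huge errors stop being outliers — the
identifier goes quiet exactly when things are worst.

Across conditions, Kruskal–Wallis (via `stats::kruskal.test`, with tie
correction) gates Dunn's post-hoc z-tests at p < 0.05; Dunn's z is the
standardised mean-rank difference with the usual tie term, two-sided
normal p-values, Bonferroni-corrected within each
bone × magnitude × metric family of three pairs (no cross-family
correction, matching how such tables are organised).

## Problem sizes used by the tests and the acceptance script

The full-scale study (2048², 35 frames, three bones, 42 perturbations,
three conditions) is far beyond a desk run; the package's own
experiments are scaled down and the sizes are design choices, stated
here once:

* *Pose-recovery check*: single noiseless talus, 64×64 images, 32³
  volume, all 14 ±2° perturbations, the default 40×60 swarm.
* *Resolution mechanism check*: the full noisy three-bone scene at
  256×256 native / 64×64 downsampled, 40³ volumes (1.6 mm voxels —
  deliberately coarser than the native pixel pitch, as CT partial
  volumes are), ±8° perturbations about three axes per seed (both
  signs; the axis triplet rotates across seeds so all seven axes are
  exercised), a 12×25 swarm, integration step equal to one voxel,
  10 scene seeds.
* *Edge-strength check*: 20 noise seeds of the native scene, comparing
  mean Sobel magnitude of [0, 1]-normalised downsampled vs native
  radiographs.

## What passing does and does not show

The phantom emulates the *mechanisms* — edge-driven matching, photon
noise that downsampling averages away, neighbour overlap, partial
field-of-view — not any particular anatomy or imaging chain. Passing
the package's checks shows the pipeline reproduces the direction and
logic of the resolution effect under those mechanisms; it does not
certify accuracies for real ankle data, where soft tissue, scatter,
beam hardening, detector blur and calibration error all enter (none of
which are modelled), and where bone geometry is richer than any
superellipsoid. Absolute error magnitudes at desk scale are larger
than the full-scale study's because the images are ~8× coarser and the
optimiser budget ~10× smaller.

## Numerical choices and degenerate inputs

* Rotation matrices are validated to 1e-9 orthonormality and
  renormalised (SVD polar projection) after composition chains.
* Spherically symmetric volumes (equal principal moments to within
  1e-9 relative) get world-aligned inertial axes and a warning.
* All-zero volumes are an error for `inertial_frame()` and render to
  all-zero DRRs.
* A flat (zero-variance) image correlates to 0 with a `flat_image`
  flag rather than NaN.
* A pose whose DRR misses an image entirely contributes the worst cost
  (2 per view) with an `out_of_view` flag; per-record failures never
  abort a batch.
* Zero-count pixels would make `neglog` infinite; counts are floored
  at 10⁻⁶ of the image maximum, and the 1st–99th percentile stretch
  keeps the resulting spikes from dominating the edge maps.
* Transform CSVs are written at 17 significant digits so that rigid
  transforms round-trip bit-exactly.

## Known limitations

* The hop trajectory is a smooth analytic motion; it has no impact
  transients or soft-tissue artefact.
* The full-scale configuration (`paper_scale = TRUE`, 2048² images)
  is provided but has not been exercised at full size; expect hours of
  compute.
* `downsample_rendered` (render DRRs at native size, then downsample
  them with the condition's operator) is implemented behind
  `drr_policy` but the default — rendering DRRs directly at the
  condition's resolution — is how registration software typically
  matches DRR size to image size; neither is claimed to replicate any
  specific software's internals.
* The DRR integrator is fixed-step trilinear ray marching; exact
  radiological path lengths (Siddon) are not implemented.
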