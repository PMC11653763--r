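---
title: "Methods: quantifying micropost-suspended cardiac microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying micropost-suspended cardiac microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotug)
```

## The measurement problem

Engineered cardiac microtissues built from iPSC-derived cardiomyocytes on a
suspended fibrous matrix spanning two elastomeric posts turn contraction
into something measurable: every twitch deflects the posts, and a post of
calibrated bending stiffness converts deflection to force. Around that core
readout sit several quantitative assays — calcium-transient kinetics,
sarcomere/myofibril organization in titin reporter images, and 3D
morphometrics of adhesion and junction proteins — that together describe
how matrix mechanics and architecture shape tissue maturation. `cardiotug`
implements this full analysis stack, and pairs every analysis with a seeded
synthetic-data generator carrying machine-readable ground truth, so each
stage is testable end-to-end without microscopy data.

## Mechanics calibration

**Post bending stiffness.** A rod of known Young's modulus $E$, radius $r$
and free length $L$ deflects the post. With rod deflection
$d$ (manipulator travel minus post travel) the cantilever tip-load formula
gives $F_\mathrm{rod} = 3 d E I / L^3$, $I = \pi r^4/4$, and the stiffness
is $k = F_\mathrm{rod}/\delta$ where $\delta$ is the post displacement. A
zero post displacement means an effectively rigid post and is rejected as a
degenerate measurement. The experimental platform uses posts around
0.41, 0.9 and 1.2 N m$^{-1}$; these are configuration values, not
constants.

**Fiber-matrix modulus.** A transverse indenter pressed a depth $\Delta h$
into a matrix of span $L_0$ pulls each post inward by $\delta$. The
stretched half-length is
$$L_f = \sqrt{\Delta h^2 + (L_0/2 - \delta)^2},$$
the post force balances the horizontal component of matrix tension,
$F_p = T\sin\theta$ with $\sin\theta = (L_0/2-\delta)/L_f$, and the modulus
follows from uniaxial stress over engineering strain:
$$\sigma = T/A,\qquad \varepsilon = (2L_f - L_0)/L_0,\qquad
E = \frac{T L_0}{A\,(2L_f - L_0)}.$$
The stored span is always the full post-to-post length; the half-span
division happens internally. The cross-section $A$ (width × thickness) is
user-supplied. `gen_mechanics_case()` inverts this chain algebraically, so
the forward-inverse round trip is exact to machine precision and anchors
the whole calibration: the soft / adult / diseased regimes
(0.68, 10.1, 17.4 kPa) are used as standard test points. Geometries where
$2L_f \le L_0$ (a slack matrix) have no defined modulus and raise an error
rather than returning a sign-flipped value.

All lengths are SI meters internally; `um_to_m()`/`m_to_um()` are provided
because a silent µm/m mix-up is the single most likely user error at this
scale.

## Twitch contractility

The per-post deflection (mean of the two channels) is searched for twitch
peaks above a rolling 10th-percentile baseline (5 s window). Peaks are
filtered by **topographic prominence** — height above the higher of the two
valley minima separating the peak from higher ground — at 20% of the
largest prominence. Plain height-above-baseline thresholds double-count
noise wiggles on the decay shoulder of a twitch; topographic prominence
does not. As a second guard, of two detections closer than 45% of the
median beat interval the smaller is dropped.

Metrics follow the platform conventions: maximum force $F = k\delta_{max}$
per post (the two-post sum is derivable), stress $F/(wt)$ with a thin-tissue
default thickness of 15 µm, beat frequency from mean inter-peak interval,
fractional shortening $2\delta_{max}/L_\mathrm{diastolic}$, velocities from
a 5-frame Savitzky–Golay smoothed derivative, and 10%-amplitude crossing
durations. **Work per twitch is defined as the peak elastic energy stored in
both posts, $W = k\delta_{max}^2$** ($\tfrac12 k\delta^2$ per post, two
posts). This definition is stated prominently because "work" is reported
without a formula in much of the literature; users comparing against
force–length integrals should convert.

The amplitude $\delta_{max}$ uses a **split-half beat-averaged estimator**:
raw segments around each detected peak are averaged; with six or more beats
the extremum *locations* come from the average of one half of the beats and
the *values* are read off the other half's average (roles swapped and the
two estimates averaged). Picking the maximum or minimum of a single noisy
average selects in favor of noise and biases amplitude upward by 1–2% at
5% noise; the split removes that selection bias entirely. The peak value
receives a 3-point parabolic sub-sample refinement and the trough is
averaged over its flat decay side. On 60 s recordings (≥ 50 beats at any
spontaneous rate in 0.3–2 Hz) this keeps amplitude within 2% and frequency
within 1% of generator truth at 5% additive noise — the package's standard
recovery conditions.

`track_posts()` produces the deflection trace from a video: normalized
cross-correlation of a first-frame template over a local search window,
quadratic interpolation of the correlation peak for sub-pixel displacement
(≈ 0.06 px on clean synthetic blobs), and projection onto the unit vector
toward the tissue center. Tracking aborts when the correlation drops below
threshold in over 5% of frames.

## Calcium handling

Traces are normalized to $\Delta F/F_0$ with $F_0$ a rolling 10th-percentile
baseline, which tracks slow drift and bleaching while ignoring transients.
Metrics: beats per minute (60 / mean inter-peak interval), peak-to-peak
irregularity as the *sample* ($n-1$) SD of inter-peak intervals — with
typically tens of beats per recording the $n$ vs $n-1$ distinction is
material — 10→90% rise time, 90→10% decay time, and FWHM, all using linear
interpolation of threshold crossings so that piecewise-linear test pulses
are measured exactly. Irregularity needs at least 3 peaks; kinetics at
least 1; missing metrics are `NA` with a warning, never silent zeros.

The regional coherence statistic tiles the tissue mask into 16 equal-area
regions (quantile cuts along the mask's principal axes — the paper-style
"16 regions of equal area" without assuming a rectangle), extracts each
region's mean-intensity time course, and averages Pearson's $r$ over all
120 unordered pairs. A spatially uniform video scores exactly 1 regardless
of waveform; independent-noise regions score ≈ 0. Constant regions are
excluded with a warning.

## Sarcomere and myofibril structure

Z-discs are segmented from the titin channel by Otsu thresholding of the
(optionally background-subtracted, intensity-normalized) image and
connected-component labeling, with a 0.3 µm² minimum area. Because the
image is normalized before thresholding, areal density is invariant to
acquisition gain. Per-object orientation comes from the second-moment
principal axis; near-isotropic objects are flagged indeterminate rather
than given a meaningless angle.

Myofibrils are reconstructed by greedy deterministic chaining: z-discs lie
perpendicular to their myofibril, so from each chain end the next disc is
sought along the perpendicular of the end disc's orientation, within 3 µm
(≈ 1.5 sarcomere lengths), within 20° axial orientation difference, and
with the step direction within 20° of the chain axis. Discs are processed
in id order with nearest-then-lowest-id tie-breaking, so the partition is
reproducible and independent of input row order. Chains shorter than 3
discs are discarded.

**All orientation statistics are axial** ($\theta \equiv \theta + 180°$):
angles are doubled, the mean resultant length $R$ computed, and the
alignment deviation taken as $\tfrac12\sqrt{-2\ln R}$ in degrees. This is
invariant under global rotation and axial relabeling; the two-point check
(equal mass at ±20° → 20.9155°) pins the closed form. A plain Gaussian
reading (SD of signed deviations from the circular mean) is available as
`method = "gaussian"` since the two readings differ in principle; the
circular form is the default because it is the one that remains correct as
dispersion grows toward the axial-uniform limit.

The matrix fiber field uses the window-integrated structure tensor per grid
node: density as fiber-positive fraction, orientation as the stripe
direction (gradient-dominant direction rotated 90°), and dispersion as the
gradient-magnitude-weighted axial circular SD of per-pixel stripe normals.

## 3D adhesion morphometrics

EBImage's labeling and watershed are 2D, so the 3D primitives are
implemented directly: 26-connected component labeling by iterative
minimum-label propagation, a chamfer distance transform with anisotropic
physical steps, and ball dilation by explicit voxel offsets. Objects are
Otsu-thresholded, labeled, volume-filtered, and measured with anisotropic
voxel scaling applied before the principal-axis analysis; axis lengths
assume a solid ellipsoid (semi-axis $a = \sqrt{5\lambda}$ from covariance
eigenvalue $\lambda$) and eccentricity is $\sqrt{1-(b/a)^2}$ from the two
largest axes — reliable once every axis spans ≥ 6 voxels, and reported
as-is (noisier) for smaller puncta.

Colocalization is a voxel-overlap fraction: object voxels inside the
reference mask after dilating the reference by 0.25 µm (≈ one confocal
voxel) to absorb chromatic and registration offsets. It is monotone
non-decreasing in the dilation radius. Vinculin voxels overlapping the
dilated N-cadherin mask count as intercalated-disc (ICD) vinculin; voxels
overlapping titin only count as costameric; double-overlap voxels are
assigned to the ICD because ICDs are cell-boundary structures where
misassignment is costlier. Nuclei are counted by seeding local maxima of
the chamfer distance map (merged below 2 µm separation, tallest first),
which splits touching nuclei without a full watershed. The subregion
regression tiles the tissue into 30 µm squares ("roughly one
cardiomyocyte"; 20 µm in the compact synthetic bundle), takes per-region
mean intensities over mask pixels, and fits ordinary least squares of the
maturation marker on costameric vinculin (vinculin masked to
titin-overlapping pixels).

## What the generators emulate — and what they do not

Every generator is deterministic under a seed and returns the truth record
alongside the data; all randomness in the bundle flows from one master
seed through derived sub-seeds.

* **Twitches and calcium transients** are difference-of-exponential
  kernels at jittered beat times plus white noise. Twitch kinetics default
  to `rise_tau = 0.03`, `decay_tau = 0.08` s (a ≈ 0.25 s twitch): a tissue
  beating spontaneously at 2 Hz must relax within its 0.5 s period, and
  with materially slower decay the trace never returns to baseline between
  beats, at which point a "peak amplitude" relative to rest stops being an
  observable quantity at all. Calcium defaults are slower
  (`decay_tau = 0.2` s), matching indicator kinetics; the bundle's calcium
  runs at 0.5 Hz so a quiescent gap keeps baseline and single-transient
  kinetics identifiable from the summed trace. Recovery recordings are
  60 s (longer at slow rates) so every trace has ≥ 50 beats.
* **Sarcomere images** place myofibril tracks with wrapped-normal axial
  orientations and paint z-disc bands at 1.9 µm spacing. By default tracks
  are placed by rejection so bands never touch and the per-band truth is
  exact; each track's orientation is drawn once and only its center is
  retried, because deviant tracks collide more often and resampling the
  orientation would bias the realized dispersion low. Non-contact packing
  of randomly oriented tracks jams near 6–8% areal coverage, hence the 6%
  default; denser images (e.g. the 20% coverage density check) use
  `allow_overlap = TRUE`, where bands may merge — as real myofibrils do —
  and only the aggregate coverage truth remains exact.
* **Adhesion stacks** plant axis-aligned ellipsoidal puncta inside solid
  titin and N-cadherin reference blocks sized so a planted punctum lies
  wholly within its reference: a planted colocalization fraction of 0, 0.5
  or 1 is then recovered as ≈ 0, 0.5, 1 up to voxelization. Puncta keep a
  0.75 µm clearance (two in-plane voxels) so 26-connectivity never merges
  them. Nuclei are spheres on a jittered grid, or explicit centers for
  controlled touching-pair cases.

None of the generators simulate optics: no point-spread function, no
depth-dependent attenuation, no motion blur, no photobleaching beyond what
the rolling baseline absorbs. Passing the recovery suite therefore shows
the estimators are correct for well-resolved, calibrated data; it does not
certify performance on low-SNR or aberrated microscopy, where segmentation
thresholds and the coloc dilation radius would need tuning against real
images.

## Numerical choices and degenerate inputs

Detection prominence 20%, baseline percentile 10% in a 5 s window,
rise/decay thresholds 10%/90%, velocity smoothing window 5 frames: all are
stated defaults, exposed as arguments, chosen where the platform literature
states none. Threshold crossings are always linearly interpolated.
Degenerate inputs fail loudly: zero post displacement, slack matrices,
empty masks, zero nuclei in per-cell normalization, constant regression
predictors, and missing pixel calibration all raise errors; empty
segmentations and absent metrics warn and return empty/`NA`. Reports mark
absent sections explicitly and are bit-identical for identical inputs,
configuration and seed.

Problem sizes throughout (256² px images, 64×64×16 voxel stacks, 60 s
traces, 10-seed sweeps) are the package's standard verification sizes:
large enough that estimator bias is visible against the stated tolerances,
small enough that the full suite runs on a laptop in about a minute and a
half.

## Known limitations

* The myofibril chains are paths, not branched structures; a branching
  myofibril is split at the branch point.
* The beat-averaged amplitude assumes stereotyped twitches; strong beat-to-
  beat alternans would be averaged over (the per-event table in
  `detect_twitches()` retains the per-twitch amplitudes for such cases).
* `coloc_fraction` is geometric (voxel overlap), not intensity-based;
  Manders/Pearson-style intensity colocalization is out of scope.
* The fiber-field dispersion mixes orientation spread with edge noise in
  very low-signal windows; such windows are flagged absent rather than
  reported.
* The inverse tissue-level mechanical model that consumes the fiber field
  (a nonlinear finite-element problem) is intentionally outside this
  package.
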