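---
title: "Models and methods behind dualvsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualvsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualvsd)
```

`dualvsd` analyzes double-sided voltage-sensitive-dye (VSD) recordings of an
invertebrate ganglion: two synchronized cameras image the ventral and dorsal
cell-body surfaces, and each cell body's fluorescence tracks its membrane
potential linearly and fast. This vignette documents the models each stage
assumes, the parameters that matter, the numerical choices, and what the
synthetic benchmark does and does not establish about real data.

## The optical forward model and the synthetic generator

The generator exists so that every estimator in the package can be tested
against known ground truth. It emulates the statistical structure the
analysis assumes, stage by stage:

* **Geometry.** `generate_canonical_map()` lays out ~n cell bodies per
  surface inside an elliptical outline (default semi-axes 300 × 80 µm,
  matching a few-hundred-micrometre segmental ganglion), mostly as bilateral
  homolog pairs mirrored about the anterior–posterior midline, partitioned
  into six glial packets, with non-overlapping somata of 4–9 µm radius. The
  dorsal camera faces the opposite side of the preparation, so the dorsal
  view is rendered left–right mirrored; each aspect keeps its own canonical
  chart and no global un-mirroring step is needed.
* **Membrane potential.** Each cell's trace is baseline + behavior-locked
  term + spikes + EPSPs + white noise, sampled directly at the frame rate
  (20 Hz for crawling, 50 Hz otherwise). Swimming and crawling are sinusoids
  at a shared rhythm frequency (defaults 1.5 Hz and 0.1 Hz) with per-cell
  amplitude (4–8 mV when involved) and phase; local bending is a boxcar
  depolarization during each stimulus, with separate left- and right-trial
  amplitudes. Spikes briefer than one frame enter as their frame-integrated
  area — soma spikes in these preparations are strongly attenuated and
  undersampled at 50 Hz, and the package makes no attempt at spike
  reconstruction. Unitary EPSPs are 2–4 mV exponentials (decay 0.1 s).
  Membrane noise defaults to 1 mV sd, a plausible subthreshold level chosen
  once for the benchmark.
* **Fluorescence.** Cells render as 2-D Gaussian profiles (σ = radius / 2,
  floored at 1 px — sharper profiles are not band-limited and would break
  both the shift linearization and Fourier resampling). Pixel counts follow
  `F0 · (1 + s/100 · ΔV/100 mV) · bleach(t) · global(t)` with dye
  sensitivity `s = 2.7` % per 100 mV by default. Bleaching is one slow
  exponential (amplitude ≤ 10 %, τ ≥ 10 s) — exactly the smooth trend the
  cubic detrender is meant to remove. The global fluctuation is one low-pass
  multiplicative series shared by all pixels of both views, standing in for
  fluorescent crosstalk between the two optical paths. Shot noise is the
  Gaussian limit of Poisson photon counting, calibrated so the frame-to-frame
  relative sd of a median-cell-area mean equals `shot_noise_ppm` (default
  70 ppm, the photon-noise level of a cooled-CCD rig at these intensities);
  at the implied ~10⁸ photons per cell area the Gaussian and Poisson draws
  are indistinguishable.
* **Motion.** Per-view rigid drift is a low-pass random trajectory scaled to
  a peak amplitude (default 0.3 px) and applied *analytically* — the Gaussian
  centers move — so the stored truth trajectory is exact, not itself a
  resampling approximation.

One point the generator deliberately leaves open: reported EPSP sizes of
2–4 mV alongside optical deflections of 0.02–0.04 % ΔF/F imply an effective
sensitivity near 1 %/100 mV, inconsistent with the 2.7 %/100 mV calibration
the forward model defaults to. `sensitivity_pct_per_100mv` is therefore an
explicit parameter; the package takes no position on which number describes a
given preparation.

What passing tests on this generator establish is that the estimators are
correct and calibrated *under the stated model*: linear voltage-fluorescence
coupling, rigid motion, Gaussian-profile cells, stationary noise. Real
recordings add depth-of-focus blur of a curved cell layer, dye run-down,
non-rigid tissue deformation, and correlated physiological "noise"; none of
these are emulated, and performance numbers from the benchmark do not
transfer to them.

## Motion correction

The estimator compares each frame against the middle frame of the recording
through references resampled ±1 unit along one axis (1 px for x/y, 0.1° for
rotation). The formula
`Δx = 2 (I' − I_L)·(I_R − I_L)/‖I_R − I_L‖² − 1` is the closed-form
least-squares fit of the linearized model
`I' ≈ [(1 − Δx) I_L + (1 + Δx) I_R]/2` and is exact on that family; on real
shifted images it is first-order accurate for |Δx| ≲ 1.

Two numerical choices matter here:

* **Resampling.** Interpolation kernels (bilinear included) smooth by an
  amount that depends on the fractional offset. For cell profiles a few
  pixels wide this modulates ROI means at ~10⁻³ relative — the same order as
  the VSD signals themselves — so correcting frames by bilinear resampling
  would inject an artifact as large as the signal it protects. Pure
  translations are therefore applied via the Fourier shift theorem, which is
  exact for band-limited images; bilinear interpolation is retained for
  rotations (off by default) and for building the ±1-unit basis, where shifts
  are integral and interpolation is exact. Fourier shifts assume periodic
  boundaries; with a dim, slowly varying background the wrap-around is
  negligible.
* **Refinement.** Because the estimator is first-order, a raw estimate at
  0.4 px drift carries ~0.05 px bias. `estimate_trajectory()` iterates:
  shift the frame back by the current estimate, re-estimate, accumulate
  (up to 3 rounds or until the update is < 0.002 px). Frames whose first
  estimate exceeds one unit are first brought into the valid regime by
  integer shifts. The reference frame's trajectory entry is identically
  zero; a constant image raises a degenerate-basis error (there is no
  gradient to estimate against).

Axes are estimated independently, rotation after translation removal; the
correction acts on frames, not extracted traces, so ROI extraction is
agnostic to motion. Non-rigid (per-packet) motion is out of scope.

## Trace conditioning

The pipeline is raw ROI means → local cubic detrend → global background
subtraction → percent ΔF/F, in that order.

* **Detrending** subtracts a sliding centered cubic least-squares fit —
  realized as Savitzky–Golay smoothing (`signal::sgolayfilt`, order 3,
  window = 2 × time constant), with the off-center evaluations of the edge
  window covering the first and last half-windows. Any cubic-in-time trend is
  annihilated to round-off everywhere. The event-triggered restart logic of
  the original artifact-blanking algorithm is unnecessary here (no electrode
  artifacts) and is omitted. The time constant is the one tunable: 1–15 s,
  units seconds; longer preserves slower rhythms, shorter removes faster
  trend components. The pipeline default is `min(15, duration/4)` — a fixed
  15 s constant would demand a 30 s window and cannot fit a 15 s trial, so
  the default adapts while never exceeding the conventional range.
* **Global subtraction** averages all in-frame pixels outside every ROI
  (optionally restricted to a ganglion outline), detrends that series with
  the same parameters — the background bleaches too, and subtracting an
  undetrended background would reinject trend — and subtracts it from every
  trace of the view. Each view uses its own background.
* **ΔF/F** divides by the mean of the *raw* trace (before detrending), so
  percent units refer to absolute brightness. A nonzero camera background
  under the ROI dilutes ROI-mean ΔF/F relative to the dye's intrinsic
  sensitivity, exactly as in real measurements; the sensitivity round-trip in
  the acceptance script therefore renders on a zero background, where the
  multiplicative model makes the cell-mean ΔF/F equal the dye sensitivity to
  machine precision.

## Coherence and involvement

Coherence is estimated with Slepian (DPSS) multitapers, computed in-package
by the symmetric-tridiagonal eigenvector construction (no installed package
provides them) and cached per (n, NW, K). Defaults NW = 3, K = 5 over the
full trial (the source analyses do not state their taper settings; these are
conventional for 15–50 s trials and are configurable). The evaluation
frequency is the multitaper spectral peak of the reference within a band —
the stimulus train (a 0.5 Hz on/off series at frame resolution) for bending,
a reference cell's optical signal for swimming, an electrode signal for
crawling. Phase is reported with the convention that positive phase means
the trace leads the reference.

Under the null hypothesis of independence, the squared magnitude estimated
with K orthonormal tapers satisfies `P(|C|² > x) = (1 − x)^(K−1)`, giving the
threshold `sqrt(1 − α^(1/(K−1)))`. The cited construction in the source
literature is not reproducible from its text, so this analytic bound is
adopted and Monte-Carlo-validated: `simulate_null_coherence()` regenerates
the calibration (the test suite requires the 95 % bound to hold within
sampling error at 10⁴ replicates; K = 2, α = 0.05 gives √0.95 ≈ 0.9747). The
magnitude confidence interval is a leave-one-taper-out jackknife on the
arctanh scale.

The cross-animal rule is applied verbatim: involved if above the 95 % bound
in ≥ 4 of 6 animals; for the bilaterally symmetric behaviors both homologs
are included if and only if at least one passes the 97.5 % bound under the
same 4-of-6 rule; neurons measured in fewer than 4 animals are flagged
undetermined and excluded from the Venn tabulation, whose region counts sum
to the number of classified neurons by construction.

## Stimulus decoding

Per trial, the stimulus response is the mean ΔF/F over [onset, onset+0.5 s)
and the control response over [onset−1.0, onset−0.5 s), both relative to the
reference phase [onset−0.5, onset−0.1 s). Decoding removes the held-out
trial *and its partner* (next trial for odd indices, previous for even —
each (L,R) or (R,L) pair leaves together, keeping the training classes
balanced at 9:9 for 20 trials), computes class means from the rest, and
predicts the nearer mean. Responses are compared by plain absolute distance
on raw ΔF/F means, without variance normalization; a response exactly
equidistant from both means is scored incorrect — conservative, and
measure-zero under continuous noise. Trials are indexed 1-based so the
odd/even partner phrasing applies literally. The control-phase score uses the
identical machinery with the control response substituted.

One calibration subtlety: the 20 leave-one-out predictions of a single null
cell are *dependent* (each training set shares 18 of 20 trials), so while the
mean success is exactly at the 50 % chance level, the fraction of null cells
reaching the 75 % encoder criterion (~3.5 % by simulation) exceeds the
independent-binomial tail (≈ 2.1 %). The test suite asserts the simulated
rate, not the binomial one.

## Canonical-map registration

Coarse alignment fits `M = T2 ∘ S2 ∘ R ∘ S1 ∘ T1` per glial packet from the
confirmed pairs, in the stated sequence: centering translations, isotropic
scale as the spread ratio, rotation by orthogonal Procrustes restricted to
det = +1 (mirrored views are handled upstream by per-aspect maps, so
reflections are never fitted), then per-axis anisotropic scale by least
squares. The S1/S2 split is not separately identified when the data contain
anisotropic stretch — only the per-axis product is — and the tests assert
exactly that. Packets with fewer than 3 non-collinear anchors inherit the
whole-aspect fit; with no pairs at all, a correspondence-free moment match
(centroids, spreads, per-axis sd; rotation left at identity) bootstraps the
first round.

Fine alignment superposes Gaussian kernels at the anchors, each carrying that
anchor's residual. The kernel scale is `σ_k = √3 ×` the distance from the
anchor's ROI to its nearest neighboring ROI *among all ROIs* — the kernel
tracks local cell spacing, so an anchor's influence extends over a few cell
diameters. (Scaling by nearest-*anchor* distance instead would make
σ always exceed the anchor spacing, so the field could never localize;
with the all-ROI rule, anchors far apart relative to σ reproduce their
residuals essentially exactly, which the tests verify.) The field is a
smoother, not an exact interpolator: overlapping kernels trade accuracy at
one anchor for smoothness between them.

Automatic assignment proposes each free neuron to its nearest ROI in warped
space (candidates within 3 × the median nearest-neighbor ROI distance) and
resolves conflicts by the cost
`‖displacement‖² · r_neuron / median_radius + λ (log r_neuron − log r_ROI)²`,
λ = median nearest-neighbor distance squared — size-matched pairs are most
meritorious, and displacing a large cell costs more than displacing a small
one. The source procedure states those two principles but no formula; this
concretization is the package's own and is pinned by an enumeration oracle in
the tests. Resolution is globally greedy lowest-cost-first, with exhaustive
minimum-total-cost search on conflict components of ≤ 8 neurons. The result
is one-to-one; user pairs are never overridden; unresolved neurons and ROIs
are listed, not dropped. `iterate_registration()` emulates the interactive
confirm–align–assign loop in batch: after each round the most confident
automatic pairs (displacement below the round's median, size ratio within
[⅔, 3/2]) join the anchor set, plus any externally supplied confirmations;
iteration stops at a fixed point or after 5 rounds.

## Clustering and the integration coefficient

Cells are clustered per behavior on the correlation distance `1 − r` of their
ΔF/F traces over the whole analyzed episode. Linkage and cut rule are not
specified by the source analyses; the package uses average linkage cut at
height 0.7 (i.e. clusters cohere at mean correlation ≥ 0.3), both
configurable, and pins the behavior with a planted-partition recovery test.
Zero-variance traces are excluded with a warning. Cells in clusters smaller
than 3 are flagged excluded; the DVI of a cell is the dorsal fraction of its
cluster (identical across members), each *cell* is one histogram entry so
small clusters are not overrepresented, and
`CI = mean(1 − 2 |DVI − ½|)` over included cells. CI is 0 iff every cluster
is single-surface, 1 iff every cluster is exactly 50:50, and invariant to
swapping the surface labels. The tests verify that the CI ordering of
surface-segregated versus surface-mixed regimes is unchanged for minimum
cluster sizes 2, 3 and 5.

## Pipeline, configuration, determinism

`run_pipeline()` drives synthesize/load → motion → traces → analysis →
tables from one nested configuration (YAML-readable); `validate_config()`
reports violations with field names and constraints, distinguishing errors
(e.g. α outside (0,1)) from warnings (e.g. crawling at 50 Hz instead of the
conventional 20 Hz). Every stochastic step takes an explicit seed and
restores the caller's RNG state; identical configuration + seed reproduces
every table bit-for-bit, and the report carries an MD5 hash of the
configuration. The package exposes its stages as plain functions rather than
shell subcommands — the intended interface is R.

## Problem sizes

The test suite and acceptance script run on deliberately small instances
chosen by the package: ganglia of 8–60 cells per surface, frames of
48 × 80 to 64 × 192 px, trials of 1–8 s, 10⁴ replicates for the decoding and
coherence calibrations, 150–200 replicates for detection/phase-recovery
checks. These sizes give sampling error comfortably inside the asserted
tolerances; nothing in the methods depends on them, and the full-size
defaults (128 × 512 px, 15–50 s) run identically.

## Known limitations

* The registration assumes a mostly rigid, mildly warped layout; gross
  rearrangements or missing packets degrade the coarse fit silently (the
  moment fallback has no correspondence information).
* The motion model is rigid per view; non-rigid per-packet deformation is
  explicitly out of scope.
* Coherence is computed over the whole trial; time-resolved involvement and
  directionality measures are not provided.
* The decoder is univariate per cell; no population decoding.
* Spike-level analysis is absent by design: at 20–50 Hz frame rates brief
  action potentials are undersampled, and the generator models them only as
  frame-integrated area.
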