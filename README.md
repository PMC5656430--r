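# dualvsd

Analysis tools for **double-sided voltage-sensitive-dye (VSD) imaging** of
invertebrate ganglia — recordings in which two synchronized cameras image the
ventral and dorsal surfaces of a ganglion at once, so that (nearly) every
neuron's membrane potential is captured optically at the same time.

The package is aimed at physiologists analyzing such recordings (or building
and validating analysis methods for them). It implements the complete chain
from raw dual-view image stacks to population-level statistics, together with
a seeded synthetic generator that produces recordings with known ground truth
so every stage can be verified without animal data.

## What it computes

- **Sub-pixel rigid motion correction.** Every frame is compared with the
  middle reference frame through artificial references shifted ±1 unit along
  an axis. With `I_L`, `I_R` the shifted references and `I'` the frame, the
  displacement estimate is

  `Δx = 2 (I' − I_L) · (I_R − I_L) / ‖I_R − I_L‖² − 1`,

  the least-squares solution of the linearized shift model
  `I' ≈ [(1 − Δx) I_L + (1 + Δx) I_R] / 2`, valid for |Δx| ≲ 1 px
  (0.1° units for rotation). Frames are corrected by Fourier-shift
  resampling.
- **Trace conditioning.** ROI pixel means → local cubic (SALPA-style
  Savitzky–Golay) detrending with a 1–15 s time constant → subtraction of the
  non-ROI background series → percent ΔF/F relative to each cell's average
  raw fluorescence.
- **Coherence-based involvement.** Multitaper (Slepian, NW = 3, K = 5)
  coherence of each cell with a behavioral reference at the rhythm frequency.
  Under the null, `P(|C|² > x) = (1 − x)^(K−1)`, giving the analytic
  threshold `sqrt(1 − α^(1/(K−1)))`; a neuron is involved in a behavior if it
  exceeds the 95 % bound in ≥ 4 of 6 animals, with both homologs included
  when either passes the 97.5 % bound (symmetric behaviors).
- **Stimulus discriminability.** Partner-excluding leave-one-out
  nearest-class-mean decoding of left vs right stimulus identity from the
  mean ΔF/F in the first 0.5 s of each stimulus; ≥ 75 % prediction success
  marks an encoder, 50 % is chance.
- **Canonical-map registration.** Packet-wise affine alignment
  `M = T2 ∘ S2 ∘ R ∘ S1 ∘ T1` fitted sequentially from confirmed pairs, a
  Gaussian-kernel displacement field
  `δX(X,Y) = Σ_k ΔX_k exp(−((X−X_k)² + (Y−Y_k)²) / 2σ_k²)` with
  `σ_k = √3 ×` nearest-ROI distance, and size-aware automatic assignment.
- **Dorsoventral integration.** Average-linkage clustering on the
  correlation distance `1 − r`, a dorsoventrality index
  (DVI = fraction of dorsal cells in a cell's cluster, clusters < 3 cells
  excluded), and the integration coefficient `CI = ⟨1 − 2 |DVI − ½|⟩`
  (0 = clusters confined to one surface, 1 = all clusters 50:50).
- **Synthetic generator.** Canonical maps with mirrored homolog pairs and six
  glial packets; per-cell voltage programs (oscillations, stimulus-locked
  responses, spikes, 2–4 mV EPSPs, membrane noise); a linear forward model
  (default sensitivity 2.7 % ΔF/F per 100 mV) with bleaching, shared global
  fluctuation, calibrated shot noise (default 70 ppm per cell area) and slow
  sub-pixel drift — all seeded, with ground truth carried in the recording.

## Worked example

```r
library(dualvsd)

cfg <- list(behavior = "swim", seed = 7,
            synth = list(n_per_surface = 10, duration_s = 8,
                         frame_shape = c(64L, 192L)))
rep <- run_pipeline(cfg)
print(rep)
#> <run_report> behavior=swim seed=7 cells=20 (config 584892c4)
#>   integration coefficient: 0.500
#>   coherence: 13/20 cells above the null threshold

head(as.data.frame(rep$coherence)[, c("cell_id", "magnitude", "phase_rad",
                                      "null_threshold", "involved")], 5)
#>   cell_id magnitude  phase_rad null_threshold involved
#> 1   V001L 0.9990038 -0.1615550      0.7260366     TRUE
#> 2   V001R 0.9962664  1.5486144      0.7260366     TRUE
#> 3   V002L 0.4455196 -0.8593804      0.7260366    FALSE
#> 4   V002R 0.1554554  1.7720684      0.7260366    FALSE
#> 5   V003L 0.9993303 -1.0950038      0.7260366     TRUE
```

The report says: a 20-cell synthetic ganglion (10 per surface) was simulated
swimming for 8 s, both views were motion-corrected, traces conditioned to
ΔF/F, and each cell scored against the reference cell's optical signal at the
swim frequency. 13 cells exceed the 95 % null-coherence bound of 0.726
(the generator made 13 of these 20 cells rhythmic), their phases spread
around the cycle, and the activity clusters mix the two surfaces with an
integration coefficient of 0.5. Per-stage functions
(`estimate_trajectory()`, `condition_traces()`, `coherence_map()`,
`prediction_scores()`, `iterate_registration()`, `cluster_integration()`)
expose every intermediate step; `vignettes/dualvsd-methods.Rmd` documents the
models and parameter choices.

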