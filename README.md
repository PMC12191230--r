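# tfscope

Comparative analysis of a transcription factor and its missense variants,
for regulatory genomicists and single-molecule biophysicists: which genomic
targets a variant loses or gains, how its in-vitro sequence preference
shifts, and how its nuclear search kinetics change.

The package implements three analysis arms over a shared, seed-deterministic
synthetic-data module:

* **Peak-set comparison** — Jaccard footprinting over BED interval sets
  (`J = |A ∩ B| / |A ∪ B|` in base pairs), A/B/C target partitioning
  (A = lost, WT-only; B = retained, bound by both; C = off-target,
  variant-only), and GREAT-style basal-plus-extension peak-to-gene
  assignment (6.5 kb upstream / 2.5 kb downstream basal domain, extended up
  to 100 kb or the nearest neighbouring basal domain).
* **PBM E-scores** — the rank-based 8-mer enrichment score
  `E = U/(n_f n_b) − 0.5 ∈ [−0.5, 0.5]` over top-half foreground/background
  probe intensities, reverse-complement-collapsed, with the conventional
  E > 0.35 significance cutoff; motif-class assignment (high-affinity NKE
  `CCACTT` > low-affinity NKE `CACTT` > HOX-like `TAAT` > other) and
  flanking-base preference around the NKE core.
* **SMT kinetics** — MTT-style spot detection (GLRT at pfa 10^-6.5, 7 px
  box, Gaussian refinement) and nearest-neighbour linking (9 px radius,
  2 gap frames, minimum length 5); the three-state jump-distance model
  `P(R ≤ r | τ) = Σᵢ Fᵢ (1 − exp(−r²/(4(Dᵢτ + σ²))))` with bound/slow/fast
  D bounds 1e-5–0.1 / 1e-3–0.5 / 0.2–5 µm²/s fitted by multi-start
  constrained least squares on pooled jump CDFs (lags 1–6, 20 ms frames);
  dwell-time survival analysis with one/two-component exponential fits
  (500 ms frames); jump-angle anisotropy (fold ratio of reversals to
  continuations above 125 nm jumps) and confinement radius.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate_data.R   # synthetic peaks, PBM, SMT, Y2H
Rscript analysis/02_peak_comparison.R
Rscript analysis/03_motif_escore.R
Rscript analysis/04_smt_fast.R
Rscript analysis/05_smt_slow.R
```

Output of `02` on the shipped configuration (120 shared, 80 lost, 25
gained planted peaks):

```
Jaccard(WT, varL) = 0.533 over 200 + 145 peaks
A/B/C partition: 80 lost, 120 retained, 25 off-target
agreement with planted truth: 100.0%
```

`03` recovers the planted in-vivo flank preference and the in-vitro
specificity switch of the synthetic variant:

```
modal flanks around CACTT in WT peaks: 5'-C, 3'-A
significant 8-mers (E > 0.35): WT 91, varS 1319
HOX-like proportion: WT 0.00 vs varS 0.93 (Fisher p = 5e-92)
```

`04` and `05` fit the search kinetics: the WT three-state fit returns
`F = (0.36, 0.29, 0.34)` bound/slow/fast at `D = (0.010, 0.151, 0.99)`
µm²/s with σ = 35 nm (planted: 0.35/0.30/0.35, 0.01/0.15/1.0, 35 nm), and
the slow-modality survival fit gives

```
WT:   tau_long = 5.04 s, tau_short = 0.86 s, long/short ratio = 1.01
varL: tau_long = 3.86 s, tau_short = 0.66 s, long/short ratio = 0.87
```

i.e. the binding-depleted variant keeps the long/short ratio roughly
constant while both residence times shrink ~25%.

A quick interactive session:

```r
library(tfscope)
dw  <- simulate_dwell_data(tau_long = 5, tau_short = 0.9, frac_long = 0.5,
                           n_tracks = 2000, frame_interval = 0.5,
                           censor_at = 250, seed = 1)
fit <- fit_exponentials(survival_curve(dw), components = 2, seed = 1)
fit
#> survival_fit (2-exp)
#>   tau_long = 5.050 s, tau_short = 0.900 s, frac_long = 0.498
#>   long/short fraction ratio = 0.992, sse = 0.000432
```

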