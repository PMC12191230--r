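---
title: "Comparative TF-variant binding and chromatin search kinetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative TF-variant binding and chromatin search kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Missense variants in a homeodomain transcription factor (TF) can change
*which* genomic sites the factor occupies, *how tightly* it binds them in
vitro, and *how* it searches the nucleus for them. `tfscope` implements one
analysis arm for each of these questions:

1. **Comparative target analysis** over peak sets: Jaccard footprinting,
   partitioning of targets into lost (A), retained (B) and off-target (C)
   subsets, regulatory-domain gene assignment, k-mer motif logic and
   flanking-base preference.
2. **In-vitro specificity** from protein-binding microarrays (PBM):
   rank-based 8-mer E-scores, significance filtering, and WT-versus-variant
   landscape comparison by motif class.
3. **Single-molecule tracking (SMT) kinetics**: spot detection and
   trajectory linking, a three-state jump-distance diffusion model (fast
   modality, 20 ms frames), dwell-time survival analysis (slow modality,
   500 ms frames), jump-angle anisotropy and confinement radius.

Raw microarray, PBM and microscopy data for this kind of study are rarely
deposited, so the package ships a first-class synthetic-data module: every
generator returns its ground truth alongside the data, which is what the
test suite exercises.

# Peak-set comparison

Peak sets are allele-labelled interval sets in BED convention (0-based,
half-open). On construction, overlapping *and bookended* intervals are
merged (backed by `GenomicRanges::reduce`), so all set arithmetic operates
on disjoint intervals.

* **Jaccard.** `jaccard(a, b)` = intersecting bp / union bp. Both sets
  empty is an error, not a zero; `jaccard_matrix` flags empty sets as `NA`
  rows rather than silently writing 0.
* **A/B/C partition.** A WT peak is *retained* (B) if it overlaps any
  variant peak by at least `min_overlap_bp` (default 1 bp — the minimal
  defensible notion of "the same target"; exposed because array resolution
  may justify larger values), else *lost* (A); a variant peak overlapping
  no WT peak is *off-target* (C). The B-set is reported from the WT side;
  the variant-side twins are retained for gene unions. The partition is
  defined at peak level first and lifted to genes second — the opposite
  order (genes first) would conflate adjacent peaks sharing a gene.
* **Gene assignment.** Basal-plus-extension regulatory domains: a
  strand-aware basal domain 6.5 kb upstream / 2.5 kb downstream of the
  TSS, extended on each side to the nearest neighbouring basal domain or
  100 kb from the TSS, whichever is closer. A peak is assigned by its
  midpoint (the GREAT convention; an any-overlap rule would double-assign
  wide peaks). All three distances are parameters.

Tests check the Jaccard and domain logic against brute-force per-base-pair
oracles on toy genomes, and the partition against planted truth from the
generator.

# PBM E-scores

The E-score of an 8-mer is a Mann–Whitney-type rank statistic comparing
probes containing the 8-mer (on either strand) against all other probes:
within each group the top `ceiling(n/2)` probes by intensity are kept, and

```
E = U / (n_f * n_b) - 0.5,   U = #{(f, b) : I_f > I_b} + 0.5 #ties
```

bounded in [-0.5, 0.5]. Keys are reverse-complement-collapsed to the
lexicographically smaller 8-mer. Because E is rank-based it is invariant
to any strictly monotone intensity transform, which makes the pipeline
insensitive to upstream normalisation choices; the suite asserts this by
exponentiating intensities. Probes containing `N` are excluded.

`escore_table` computes all 8-mers via a single global intensity ordering
and per-8-mer rank walks (exact when intensities are untied; with ties it
falls back to the per-8-mer rank method). `escore` is the reference
implementation, tested against an O(n²) pair-counting oracle.

**Significance and coverage.** The conventional cutoff E > 0.35
(corresponding to FDR < 0.01 on universal arrays) is only calibrated when
every 8-mer occurs in enough probes. With random probe sequences the
expected coverage is roughly `n_probes * (L - 7) / 32896` probes per
collapsed 8-mer; below ~10 the null tail of rare 8-mers inflates past 1%.
This is a real property of array design, not an artifact: universal
"all 10-mer" arrays exist precisely to guarantee ~16–32 occurrences of
every 8-mer. The generator default (60,000 probes) reflects an 8x60K
array layout; the null-calibration test uses 20,000 probes of 36 nt
(coverage ≈ 18), the smallest size with realistic coverage.

The synthetic PBM model sets each probe's clean intensity from the
*maximum* affinity of any contained 8-mer (not the sum), which keeps
planted landscapes interpretable: the planted 8-mer must attain the
maximal E. Gaussian noise is added on top.

# Motif logic

`scan_kmer` does exact matching of a core and its reverse complement,
counting overlaps; `N` never matches. Flanking bases around the NKE core
`CACTT` are read on the strand of the match; edge occurrences contribute
only the flank they have. 8-mers are classed by substring precedence
`high_NKE` (contains `CCACTT`) > `low_NKE` (`CACTT`) > `HOX_like`
(`TAAT`) > `other`, on either strand. The precedence resolves 8-mers
containing several cores; it is a proxy for cluster membership derived
from E-profile clustering, and its fidelity to any particular clustering
is deliberately untested. Class proportions between two conditions are
compared per class with two-sided Fisher exact tests (class vs rest).

Motif enrichment is a permutation Z-score against per-sequence
dinucleotide-preserving shuffles (Altschul–Erickson Eulerian-path
shuffles, exact on mono- and dinucleotide counts). This is a deliberate
methodological substitution for exact known-motif enrichment statistics:
it is transparent, seed-deterministic, and adequate for planted-motif
recovery, but its null is conditional on each sequence's dinucleotide
composition only.

# SMT: detection and linking

Detection is a two-step procedure in the spirit of multiple-target
tracing: a generalized-likelihood-ratio test of a fixed-width Gaussian
spot versus flat background in a 7x7 window, thresholded at a per-pixel
false-alarm probability (default 10^-6.5) against a global robust (MAD)
noise estimate, followed by least-squares 2D Gaussian refinement
(<= 50 iterations, tolerance 10^-2) that rejects candidates moving more
than 1.5 px. The full MTT machinery (deflation, multi-hypothesis
reconnection) is not reproduced; on dense fields this simplification
under-detects overlapping spots, which is why the tracking-fidelity tests
use well-separated molecules.

The seeding factor 1.5 on the matched-filter amplitude mirrors a tracking
threshold whose exact semantics are not published; our interpretation
(amplitude over local noise) is a flagged choice, exposed as a parameter.

Linking is greedy nearest-neighbour with one-to-one enforcement inside a
radius of 9 px, gap closing up to 2 frames, and a minimum track length of
5. When a modality's maximum expected diffusion coefficient is supplied
(1.5 um²/s fast, 0.05 um²/s slow), the radius is capped at the Rayleigh
99.9th-percentile displacement `sqrt(4 D dt ln 1000)` — at 20 ms and
1.5 um²/s this gives 0.91 um, consistent with the 9 px setting at 100 nm
pixels.

# SMT: fast-modality kinetics

* **Per-track D** from one-frame jumps, `D = mean(r²)/(4 dt) - sigma²/dt`,
  floored at 1e-6; the mobile/immobile split threshold defaults to
  0.1 um²/s, matching the bound state's upper bound.
* **MSD** is time-averaged per track over lags up to 90% of the track
  length and fit with `4 D t^alpha + offset`. The published "offset of
  0.5" has unstated units; we treat it as the fit's initial offset value
  (a flagged choice — it only affects the optimizer's starting point).
* **Three-state model.** Jump distances pooled over lags 1..6 are fit via
  their empirical CDFs: `P(R <= r | lag tau) = sum_i F_i (1 - exp(-r² /
  (4 (D_i tau + sigma²))))`, with the simplex constraint parameterized
  exactly, printed D bounds (bound 1e-5–0.1, slow 1e-3–0.5, fast 0.2–5
  um²/s), the localization error fit from the data, and 10 random
  multi-starts (best SSE wins). CDF fitting avoids histogram binning
  choices; lags are weighted equally. Jumps spanning gap-closed frames
  are excluded from jump and angle statistics (their time base is
  ambiguous). Axial (defocalization) loss is neither simulated nor
  corrected; with real data this biases the fast fraction downward, and
  the recovery tests are only evidence for the in-plane model.
* **Angles and confinement.** Jump angles are folded to [0, 180]
  (0 = forward), computed only for consecutive one-frame jump pairs both
  above 125 nm; the anisotropy ratio counts reversals (within 30 deg of
  180) over forward continuations (within 30 deg of 0). Pure Brownian
  motion gives a uniform angle distribution and ratio 1; localization
  error alone induces apparent reversals, which the tests demonstrate —
  anisotropy comparisons are therefore only meaningful between conditions
  imaged identically. The confinement radius is the maximum distance from
  the trajectory centroid (radius of gyration available behind a flag);
  it grows with track length even for immobile molecules, so per-cell
  summaries should be compared at matched track-length distributions.
* **Per-cell features and PCA** (mean D, jump, confinement, anisotropy,
  mobile fraction) are standardized before PCA; components are oriented
  so the largest-magnitude loading is positive, making scores
  deterministic.

# SMT: slow-modality dwell analysis

Residence times are track spans `(last - first + 1) * dt` for tracks whose
apparent D stays below 0.05 um²/s. The survival function S(t) (fraction of
dwells >= t at observed times) is fit with one- or two-component
exponential decays by multi-start least squares with uniform weights.

Two numerical conventions matter:

* **Quantization shift.** Dwells are quantized upward to whole frames (a
  molecule present for part of a frame occupies it), so
  `P(T_q >= k dt) = exp(-(k-1) dt / tau)` for an exponential component.
  Fitting with the time axis shifted so the first observed time is zero
  makes the mixture model *exact* under this quantization; an unshifted
  fit overestimates the short time constant by about half a frame.
* **Identifiability guard.** If the two recovered time constants are
  closer than one frame interval the fit is flagged degenerate and
  collapses to the one-component answer.

Censoring at the acquisition limit is ignored (tracks touching the first
or last frame are counted) — a documented simplification; at a 250 s limit
and a 5 s long component the bias is negligible. No photobleaching
correction is applied by default; an optional correction would divide the
fitted rates by an independently measured bleach rate.

With 0.5 s frames, a 0.9 s short component is only ~2 bins wide; at
n = 2000 tracks the short time constant is recoverable to roughly +/-15%
and this is an information limit of the acquisition, not of the
estimator — a maximum-likelihood fit of the quantized mixture gives
essentially the same estimates.

# QC and Y2H

Per-cell outlier removal uses interquartile-range thresholding with
multiplier 1.5 (the conventional value; the source analyses leave it
unstated) and linear-interpolation quartiles. Y2H interactions are scored
as the T2/T1 fluorescence growth ratio normalised to the WT bait with the
same prey, and classified normal / perturbed / absent at 0.75 / 0.25 —
qualitative thresholds exposed in the interface, since the underlying
categorization is qualitative.

# What the generators emulate, and what they do not

* `simulate_peak_universe` plants non-overlapping shared/lost/gained peaks
  with motif-bearing sequences; it does not emulate array probe coverage,
  GATC-site granularity or peak-calling noise, so perfect A/B/C recovery
  on it validates the set algebra, not robustness to calling errors.
* `simulate_pbm` uses the max-affinity rule plus Gaussian noise; no
  spatial array artifacts or scanner saturation.
* `simulate_trajectories` draws per-axis Gaussian steps (variance
  `2 D dt`), adds Gaussian localization error, bleaches tracks
  geometrically and truncates at the field edge. States are static per
  track by default, matching the three-state model's assumption; a
  continuous-time switching matrix is available as a stress-test mode.
  Axial escape is not simulated.
* `simulate_dwell_data` draws from the bi-exponential mixture with frame
  quantization and censoring — the exact model the survival fit assumes.
* All generators take a required seed, use one local RNG scope, and are
  byte-reproducible.

# Problem sizes

The test suite and analysis scripts run at deliberately moderate sizes
chosen to make sampling error small relative to the tested tolerances:
5,000 tracks per three-state recovery (10 seeds), 2,000 dwells per
survival fit, 20,000–60,000 probes per E-score table, 100 random
interval-set pairs and 20 planted peak-universe configurations for the
interval algebra, 350 pure-noise frames for the false-positive
calibration. The full workflow (`analysis/01` … `05`) regenerates every
table from scratch in a few minutes.

# Known limitations

* Detection has no deflation step: overlapping spots are merged or lost.
* The three-state fit assumes static states over the pooled lags;
  fast-switching molecules bias fractions toward intermediate D.
* The anisotropy metric does not correct for localization-error-induced
  reversals (use matched acquisition conditions for comparisons).
* The E-score null calibration is coverage-dependent (see above).
* Gene assignment uses TSS tables as given; no transcript-model
  disambiguation.
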