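---
title: "Classifying selective sweeps from derived allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying selective sweeps from derived allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A hard selective sweep — a beneficial mutation rising to fixation — erases
linked variation around the selected site.  It leaves two signatures that a
classifier can learn from a window of single-nucleotide polymorphisms
(SNPs): a local deficit of polymorphism, and a site frequency spectrum
(SFS) skewed toward rare and high-frequency derived alleles.  Demographic
history confounds both signals: severe bottlenecks and ancient population
structure reshape the SFS in sweep-like ways, and recombination-rate
heterogeneity reshapes local SNP density.

Most CNN classifiers for this task consume the raw N x W genotype matrix
(N haplotypes by W SNPs), so their cost grows with the sample size and they
usually require row-sorting preprocessing that breaks translation
invariance.  `dafsweep` instead classifies a window from two 1D vectors of
length W:

* the **derived allele frequency** per locus,
  `DAF[i] = (# derived alleles at locus i) / (# non-missing alleles at
  locus i)` — the denominator shrinks with missing calls, the convention of
  likelihood-based scan methods; and
* the **inter-SNP distance**, `D[i] = P[i+1] - P[i]`, with the last entry
  defined as 0.  Distances, unlike positions, are translation invariant, so
  overlapping scan windows share feature values and the classifier cannot
  learn the absolute location of simulated sweeps.

Stacked as a 2 x W matrix (`featurize()`), this input is invariant to both
the sample size and any permutation of sample rows: the DAF channel carries
the SFS signature, the distance channel carries the local-polymorphism
signature.

**Distance scaling.** Frequencies live in [0, 1], but distance units are
arbitrary: fractional simulator positions make distances O(1e-4), base-pair
positions make them O(1e3).  Both extremes are pathological — a vanishing
channel carries no practical gradient, and an O(1) distance channel lets a
high-capacity model memorize training windows through their effectively
unique continuous distance patterns (training accuracy reaches 1.0 while
test accuracy collapses).  By default, fitting therefore divides distances
by `distance_scale(train)` — five times the mean positive training
distance, so the scaled channel averages 0.2: visible next to the
frequency channel, too small to dominate it.  The factor was selected by
validation accuracy among simple alternatives (identity, two linear
scales, log, square-root, standardization, winsorizing) on the reduced
hotspot dataset, and is stored in every checkpoint so that prediction and
scanning always reuse the training scale.  A global rescaling preserves
translation invariance and window-reuse exactly.

## Model family and architecture search

`build_1d_model()` constructs `n_layers` repeats of [1D convolution →
ReLU → max pool (width 2, stride 2)] followed by a flatten and a single
fully connected layer producing two class scores.  The hyperparameter grid
(`enumerate_grid()`) spans 2–5 layers, 8–80 channels, kernel widths 2–4 and
strides 1–3 — 180 candidates, searched exhaustively by `run_grid_search()`
and ranked by best validation accuracy.  The shipped default
(`model_spec(3, 80, 2, 1)`) is the 3-layer, 80-channel, width-2 winner of
that search on the old-migration scenario, the most confounded dataset.

Design choices that the architecture description leaves open:

* **Padding.** Convolutions use same-style padding (output width
  `ceiling(w / stride)`); pooling floors halved widths.  This keeps deep or
  strided grid cells feasible as long as the width stays at least 1;
  specs whose width collapses to 0 are flagged infeasible, skipped, and
  reported rather than scored.
* **Head.** The simplest head consistent with the reference 2D
  architecture: flatten plus one fully connected layer to two logits, with
  softmax probabilities.  No dropout or batch normalization; overfitting is
  handled by checkpointing at the best validation epoch.
* **Stride of the default model.** The winning architecture is identified
  by its layer count, channels and kernel width; stride defaults to 1 and
  the grid search can re-derive the full tuple.
* **Ties.** Validation-accuracy ties keep the earlier (less overfit)
  epoch; grid-search ties prefer fewer parameters, then fewer layers, then
  grid order.  Max-pool ties take the first element, deterministically.

The engine is written on base-R arrays: im2col patch extraction feeding
BLAS matrix products, with analytic backpropagation (verified against
numeric differentiation in the test suite) and Adam
(beta1 = 0.9, beta2 = 0.999, eps = 1e-8 — standard defaults, recorded
here because the protocol leaves them unstated).

Two-dimensional reference baselines (`build_reference_2d()`) consume the
raw N x W allele image with three position-fusion variants — none, late
(distances through a separate fully connected branch concatenated before
the final layer) and early (distances broadcast as a second input
channel) — sharing one convolutional trunk so that accuracy differences
isolate the fusion strategy.  Raw-image training supports per-epoch random
row shuffling (`shuffle_rows`), the standard augmentation for genotype
images; the fused 1D representation is already row-permutation invariant,
so it needs none.

## Training protocol

`fit_sweep_model()` trains with mini-batches of 8, learning rate 5e-4 and
Adam for a fixed budget of 100 epochs (no early stopping, no schedule),
evaluating validation accuracy after each epoch and returning the
parameter state of the best epoch.  Test data enter exactly once, through
`evaluate()` on the checkpoint.  All randomness (initialization, batch
order, augmentation) derives from one integer seed; two runs with the same
seed are bitwise identical.  `repeat_runs()` repeats the protocol with
seeds `seed + 1 .. seed + n_runs` and reports mean/min/max test accuracy,
the convention used for architecture comparisons.

## The simulation harness

`make_dataset()` builds labeled training data from backward-in-time
coalescent simulations, using msprime through a bundled Python bridge that
emits ms-dialect text (`parse_ms()` reads the same dialect from any
ms-family tool).  The six evaluation scenarios pair each confounder with a
hard sweep (selection coefficient 0.02) at the region center; the
present-day population is 50 000 diploids and 128 haplotypes are sampled
as 64 diploid individuals.  Times below are in units of 4N generations:

| id | confounder | parameters | sweep completion time |
|----|------------|------------|----------------------|
| D1 | mild bottleneck | size 0.5 N over [0.1, 0.101] | 0.016 |
| D2 | severe bottleneck | size 0.005 N over [0.01, 0.012] | 0.016 |
| D3 | recent structure | two demes joining at 0.003 | 0.005 |
| D4 | old structure | two demes joining at 3 | 0.005 |
| D5 | hotspot, low | 2x recombination in central 5 kb | 0.005 |
| D6 | hotspot, high | 20x recombination in central 5 kb | 0.005 |

Datasets follow the standard sizes — 1700 training, 300 validation, 2000
test replicates, each split exactly half neutral, half sweep
(`dataset_plan()` exposes the bookkeeping) — and every replicate's seed
derives deterministically from the master seed, so any single replicate
can be regenerated alone.  A 128-SNP window is cut from the center of each
replicate; replicates with fewer than 128 SNPs are retried with a derived
seed up to 10 times.

Choices the scenario table leaves open, fixed here once:

* **Region and rates.** The hotspot scenarios specify theta = rho = 2000;
  the others do not, and use theta = rho = 500 over a 100 kb region —
  chosen so that every scenario, including the severe bottleneck,
  comfortably exceeds 128 segregating sites per replicate.  These two
  values and the region length are package defaults rather than part of
  the scenario definitions, and are exposed as `scenario_config()` overrides.
* **Sweep timing.** The sweep time parameter is read as the time at which
  the beneficial allele reached fixation (the trajectory-end convention of
  structured-coalescent sweep tools); the sweep phase is simulated with
  msprime's conditioned-frequency-trajectory model
  (`SweepGenicSelection`, s = 0.02, start/end frequencies 1/2N and
  1 - 1/2N).
* **Structure scenarios.** Two equal demes with no gene flow, merging at
  the join time, sampled symmetrically (64 + 64 haplotypes).  Sampling
  everything from one deme would make the join event invisible (with no
  migration, lineages never change demes), so the symmetric split is the
  reading that makes the confounder real.  The sweep is placed in deme 1:
  for the recent join (D3) it post-dates the merge and therefore sweeps the
  single merged population; for the old join (D4) it completes while the
  demes are separate — a deme-local sweep, which is what makes D4 hard
  (half the sample never saw the sweep).  Because the sweep model is
  single-population, structured scenarios are composed in stages: each
  deme is simulated to the join, the partial tree sequences are disjoint-
  unioned, and ancestry completes in the merged population.  The staging
  is exact, not an approximation, for this no-migration model.
* **Hotspots.** A rate map with the central 5 kb elevated by the intensity
  factor over the background rate implied by rho.

## Binary window format

`write_sfw()`/`read_sfw()` implement a compact container for windows: a
24-byte little-endian header, then fixed-size records.  Raw records store
W single-precision distances plus bit-packed allele columns — 8 states per
byte, sample 0 in the least significant bit, or 4 states per byte in 2-bit
mode (00 ancestral, 01 derived, 10 missing, 11 reserved), required
whenever missing data are present.  Frequency records store W
single-precision DAFs and W distances: `W * (4 + ceiling(N/8))` bytes per
raw window versus a constant `W * 8` for frequencies, independent of the
sample size — at N = 2504 haplotypes a 97.5% reduction.  Values round-trip
exactly (alleles) or to full single precision (floats); positions are
recoverable from stored distances only up to translation, which is all the
classifier uses.

## Scanning

`scan_genome()` slides a fixed-width window (in SNP-index space; variable
SNP density is the distance channel's job) with a configurable step
(default 32 SNPs, an exposed choice — no canonical value exists), computes
the per-locus DAF and distance vectors once, shares them across
overlapping windows, and emits one sweep probability per window.  The
reuse path is bit-identical to recomputing each window independently
(the only subtlety: a window's final distance is redefined as 0).  For VCF
input (`read_vcf_windows()`), ALT is treated as derived unless an `AA`
INFO tag polarizes the record.  Scanning always applies the checkpoint's
stored distance divisor; when scanning data whose coordinate units differ
from the training units (base pairs versus fractional positions), the
divisor must be set to the training value times the unit ratio — the
`scale` arguments exist for exactly this.

## What the tests show, and what they cannot

The simulation harness emulates the evaluation conditions: panmictic or
two-deme populations, constant mutation rate, intrinsically polarized
haplotypes, no missing data, and hard complete sweeps exactly at the
region center.  Real data differ in all five respects — uncertain
polarization, missing genotypes, partial and soft sweeps, background
selection, and sweeps anywhere in the window.  Passing the suite therefore
demonstrates that the method recovers the simulated signal under the
stated confounders, not that it transfers to any particular empirical
cohort.

The test suite and the acceptance script run at desk scale, a deliberate
package choice so they complete in minutes on one core: scenario-accuracy
checks use 400 training / 100 validation / 160 test windows and 25
epochs, the acceptance run 1200/240/800 windows and 70 epochs (against the
protocol's 1700/300/2000 and 100), the search comparison an 8-cell
subgrid over three seeds, and the fusion comparison 64-haplotype,
64-SNP hotspot windows with three runs per variant.  At these sizes the
easy-scenario accuracy sits slightly below its full-scale value, and comparative claims (hard scenarios are harder; early fusion
beats late beats none; capacity helps on old migration) are asserted as
orderings rather than absolute values.  Full-scale runs use the same code
paths with the default `dataset_spec()` and `train_control()`.

## Known limitations

* Binary classification only: neutral versus hard complete sweep; no soft
  or partial sweep classes and no composite-likelihood localization
  within a window.
* The CNN engine is single-threaded base R.  It is fast enough for the 1D
  family (seconds per epoch at desk scale) but the 2D baselines exist for
  controlled comparison, not production training.
* Inference-level data reuse across overlapping scan windows (sharing
  convolution results, not just features) is enabled by the
  translation-invariant layout but not implemented; only feature-level
  reuse is.
* The Python bridge requires msprime at run time for simulation; parsing,
  training and scanning have no such dependency.
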