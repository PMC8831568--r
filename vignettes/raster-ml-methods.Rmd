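---
title: "Raster-plot machine learning for MEA seizure-liability screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raster-plot machine learning for MEA seizure-liability screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mearaster)
```

## The problem

Cultured neuronal networks on multiwell microelectrode arrays (MEAs) fire
in rhythmic network bursts, and seizurogenic compounds perturb that rhythm
in mechanism-dependent ways: some increase the number of network bursts,
some suppress overall firing, some change burst duration or size. A single
burst parameter is a poor screen, because the parameter that changes
depends on the mechanism, and occasional significant changes occur even
for seizure-free compounds. `mearaster` implements an image-based
alternative: each well's spiking is drawn as a raster plot, cut into
windows scaled by that well's own baseline burst rhythm, passed through a
fixed image-feature extractor, and classified by shallow pattern-recognition
networks — once for a binary seizure-liability call and once for 14-class
compound identification.

The package covers the full chain: spike detection from raw voltage traces,
network-burst detection with the five standard burst parameters,
percent-of-control dose–response analysis with Dunnett tests, IMFI-based
rasterization, 4096-d feature extraction with per-well vehicle
normalization, classifier training under grouped validation schemes, ROC
evaluation with a cost-slope operating point, SVM baselines, and a seeded
synthetic-data generator that stands in for the (non-public) recordings.

## Data model and conventions

A *well* carries 16 electrodes. A *dose series* is one well's cumulative
administration experiment: a 600-s vehicle epoch (0.1% DMSO) followed by
600-s epochs at strictly ascending concentrations of one compound. Spike
times are 0-based seconds within their epoch, strictly ascending per
electrode, and serialized at 1e-5 s resolution in a plain TSV
(`well, epoch, electrode, time_s`) with a YAML sidecar holding per-epoch
conditions; a write–read–write cycle is byte-identical.

## Spike detection

Raw traces (20 kHz) are high-pass filtered at 100 Hz. The filter is a
second-order Butterworth applied forward and backward
(`signal::filtfilt`), i.e. a fourth-order zero-phase response; zero phase
matters because spike times are read off the filtered trace. A spike is
called where the filtered signal strictly exceeds ±5.3 σ, where σ is the
baseline noise during quiescent periods. Because "quiescent" is not
observable directly, σ is estimated iteratively: take the SD of the whole
trace, mask ±2 ms around every sample beyond 4 σ, recompute, twice. Each
maximal supra-threshold run is one event; its spike time is the extreme
|amplitude| sample; events closer than a 1-ms dead time are merged into
the first. Thresholding is strict (`|v| > kσ`), so a sample at exactly
5.3 σ is not a spike — an arbitrary but testable convention.

## Network bursts and the five parameters

Network bursts are detected by a four-step pooled-ISI method: (1) pool all
16 electrodes into one sorted train; (2) candidate bursts are maximal runs
of pooled inter-spike intervals ≤ `isi_th_s` (default 0.1 s; an adaptive
variant takes the trough of the log-ISI histogram when it is bimodal);
(3) candidates separated by gaps < `merge_gap_s` (0.1 s) merge; (4)
candidates with fewer than `min_spikes` (50) spikes or `min_electrodes`
(4) participating electrodes are dropped. The four thresholds are explicit
stand-ins — the literature's four-step method does not fix them — and all
live in `burst_config()`. A brute-force spike-by-spike implementation of
the same rules serves as the oracle in the test suite, which requires
exact agreement on recordings up to 500 spikes.

Each epoch yields five parameters: TS (total spikes), NoB (number of
network bursts), IBI (mean inter-burst interval; end-of-burst to next
onset by default, onset-to-onset as an option), DoB (mean burst duration),
SiB (mean spikes per burst). IBI needs ≥ 2 bursts and DoB/SiB ≥ 1;
undefined values propagate as `NA` and are excluded from downstream means
with their counts reported. Dose–response tables express each parameter as
% of the same well's vehicle epoch (vehicle = 100%), averaged over wells
with SEM; each concentration is compared against vehicle by one-way ANOVA
followed by Dunnett's test (`multcomp`), with Dunnett significance flags
gatekept on the omnibus ANOVA at α = 0.05.

## IMFI windows and rendering

The raster window width of a well is four times its IMFI — the
inter-maximum-frequency interval, read here as the median spacing between
successive network bursts' pooled-rate peak times in the vehicle epoch
(peak located in 0.01-s bins, ties to the earliest bin; the median guards
against missed or split bursts). Peak-to-peak median is this package's
convention; the source phrase admits onset-to-onset or mean-based readings
too. Windows tile each epoch from t = 0 without overlap; the trailing
partial window is discarded; wells whose vehicle epoch has fewer than two
bursts fail loudly, naming the well. Windowing by the well's own rhythm is
the normalization that makes images comparable across wells whose baseline
burst frequency differs several-fold.

Rendering is deliberately plain: a 227 × 227 single-channel image (the
input size of the reference backbone), 16 equal horizontal bands with
electrode 0 on top, time mapped linearly to columns, each spike a single
black pixel on white. The dot size matters more than expected: with
~14-px electrode bands and ~10 spikes per burst and electrode, 2 × 2 dots
saturate the area a burst occupies, so burst-size changes (more spikes in
the same envelope) leave the image almost unchanged; 1-px dots keep local
darkness roughly proportional to spike count, which is what makes
burst-size mechanisms identifiable. Everything is deterministic; the vehicle epoch is
windowed at the same 4 × IMFI width as the drug epochs, since
normalization needs vehicle windows.

## Features and vehicle normalization

The reference feature extractor is the 4096-unit fc7 fully connected layer
of an AlexNet-class object-recognition network. Pretrained weights cannot
ship with this package, so `extractor_spec()` defines a pluggable contract
with a self-contained *fixture* backend: the image is block-averaged to
32 × 32, flattened, and multiplied by a fixed seeded Gaussian random
projection into 4096 dimensions. The projection is injective (1024 → 4096),
so no information in the downsampled image is lost, and every output is
reproducible from the seed. An optional rectification (`rectify = TRUE`,
the pipeline default) clamps negative outputs to zero, mirroring the fact
that fc7 emits post-ReLU activations. This matters more than it may seem:
for a signed random projection, drug-induced changes that preserve the
mean image but change its variability produce features whose *mean* is
unchanged — provably invisible to the first linear layer of a shallow
net — whereas the mean of a rectified projection responds to variance.

Features are normalized per well against that well's vehicle epoch:
centering (subtract the per-dimension vehicle mean; the default for the
`vehicle_normalize()` function) or z-scoring (additionally divide by the
per-dimension vehicle SD + ε; the pipeline default). The ε floor is 0.01
on the feature scale: rectified features can have zero vehicle variance in
a dimension, and a machine-precision ε would produce z-scores in the
thousands and saturate every downstream sigmoid. Vehicle windows are
themselves normalized (their per-well mean is exactly zero), and the
operation is idempotent and shift-invariant by construction.

## Classifiers and validation

The seizure-liability network is 4096 → 9 sigmoid units → 2-class softmax;
the drug-identification network is 4096 → 120 → 14 (13 compounds plus one
pooled seizure-free class). Training is full-batch Adam on the
cross-entropy with L2 weight decay (default 0.02), Glorot-uniform
initialization, and early stopping: the validation partition is scored
every iteration, training stops after 20 checks without improvement — but
never before 75 iterations, because Adam's initial transient can otherwise
freeze the network at near-initial weights — and the best-validation
weights are restored. Reproducibility is per-seed: same data, split and
seed give identical weights. The decay strength is not cosmetic: without
it the 9-unit net memorizes well-specific window patterns (which also
satisfy the window-level validation set, since validation windows come
from the training wells) and fails on unlearned wells.

The well is the biological unit everywhere. The holdout scheme holds
entire wells out and splits the remaining wells' windows 75/25 for
fitting/early stopping; a well appearing on both sides is a hard error
checked before any training. Leave-one-well-out trains
`replicates` (default 5) models per held-out well, differing only in seed,
and averages their class distributions. The pipeline's risk stage likewise
trains five replicate networks and averages window probabilities.

Risk aggregation follows the 50% convention: a window is called positive
at probability ≥ 0.5; a well's risk is the fraction of its windows called
positive (`"proportion"`, the default) or the mean probability
(`"mean_prob"`); a concentration's risk is the mean over its wells; the
final call is risk ≥ 50%. Training-set composition mirrors the source
design: seizure-causing compounds contribute positive windows only at
clearly supra-threshold concentrations (`training_concentration_min`,
default 10 µM on the synthetic panel, i.e. above the half-max
concentration of 3 µM), vehicles and seizure-free compounds are negative,
and lower concentrations are predicted as unlearned data. For drug
identification the negative class consists of the seizure-free compounds'
windows (not the drug wells' vehicle epochs), matching the published
dataset composition.

## Evaluation

`roc_curve()` sweeps the rule `score ≥ threshold` over all distinct scores
(plus an all-negative sentinel) and integrates by trapezoid, which equals
the pairwise concordance statistic — asserted against a brute-force
pairwise oracle in the tests. The optimal operating point slides a line of
slope `S = (Cost(P|N) − Cost(N|N)) / (Cost(N|P) − Cost(P|P)) · N/P` from
(FPR 0, TPR 1) until it touches the curve, equivalently maximizes
TPR − S·FPR over vertices; ties break toward the smaller FPR,
conservative against false positives. Unit misclassification costs with
the empirical N/P are the default, since the source does not state its
cost values. Metrics are Acc, PPV, Sen, Spec and F. The F default is the
standard F1 (2·PPV·Sen/(PPV+Sen)); the literal product-over-sum variant
(PPV·Sen/(PPV+Sen)), which yields 0.5 for a perfect classifier and is
inconsistent with published perfect-classifier rows of 1.000, is kept
behind `f_variant = "text_literal"` for fidelity.

## The synthetic-data generator

No recordings are public, so the generator defines the study conditions.
A vehicle well fires quasi-periodic network bursts: inter-burst intervals
are Gamma with mean `60/burst_rate` and SD `timing_jitter_s` (0.45 s,
~15% of the default period — quasi-periodic);
within-burst spike times follow a Beta(2, 2) envelope over
`burst_duration_s` (0.5 s) so a pooled-rate maximum exists for IMFI
estimation; spikes spread over the first 12 of 16 electrodes
(`spikes_per_burst` = 120), on top of 0.3 Hz Poisson background per
electrode. The default burst rate is 20/min: published per-well raster
counts (hundreds of windows per well across a dose series) imply baseline
burst periods of a few seconds, and 20/min yields ≈ 50 windows per 600-s
epoch under the 4 × IMFI rule. Per-well baseline variability (log-normal,
15% on burst rate, 10% on burst size) is drawn once per well. Everything
is seeded at panel, well and epoch level; identical seeds give identical
spike tables.

Drug mechanisms are saturating monotone multiplier curves
`m(c) = 1 + (max_mult − 1)·c^h/(c^h + ec50^h)` on burst rate, burst
duration, burst size and background rate (ec50 = 3 µM, Hill slope 2;
effect sizes small/medium/large map to maximal multipliers 1.2/2/3, with
reciprocals for decreases). The risk panel pairs four positive mechanisms
(burst-rate up; rate down with larger bursts; overall firing down; burst
shortening) with two null compounds whose epochs differ from vehicle only
by seed — so false-positive calls on them estimate the pipeline's
specificity directly. The drug-identification panel has 13 positive
mechanisms with distinct signed effect signatures plus one null.

What the generator does *not* emulate: electrode-level waveform shape,
burst propagation structure across the array, slow drift within an epoch,
plate effects shared between wells, or desensitization under cumulative
dosing. Passing tests therefore demonstrate that the pipeline's machinery
recovers mechanism-specific rhythm changes through the image pathway — not
that the specific published accuracies transfer to real recordings.

## Problem sizes and expected performance

The test suite and the end-to-end acceptance checks run the following
sizes, chosen to exercise the full pipeline at desk scale. The risk task
uses the six-compound panel at large effect size with four wells per
compound (three for training, one held out entirely), concentrations
1/3/10/30 µM and the half-max concentration at 3 µM; held-out risk calls
are correct for at least 90% of the at-or-above-half-max concentrations,
seizure-free compounds and vehicles are called negative throughout, and
the held-out window-level AUC exceeds 0.95. The identification task uses
the 14-mechanism panel with three wells per compound and recovers at
least 90% of the held-out concentration labels at the designated
(clearly supra-half-max) concentrations, with vehicles and the
seizure-free compound mapped to the pooled negative class. The residual
identification errors are confusions between mechanism pairs whose
signatures differ only in the burst-duration versus burst-size component,
which the 32 × 32 fixture representation resolves only marginally.

## Known limitations

The fixture extractor, however convenient, is not a convolutional
network: it has no translation invariance, so burst-phase variability
inside a window appears as feature noise, and fine within-burst structure
is coarsened by the 32 × 32 downsampling. Mechanisms that only reshape
bursts without changing pooled activity (pure burst-size inflation under
dot saturation, small duration changes) are correspondingly harder for it
than for a pretrained deep backbone. The `alexnet-fc7` backend slot
exists for environments that can supply weights; its outputs drop into
the identical normalization and classifier chain.
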