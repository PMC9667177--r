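---
title: "Decoding context reinstatement from oscillatory EEG: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding context reinstatement from oscillatory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegreplay)
```

## The analysis in one paragraph

`eegreplay` implements a time-resolved multivariate decoding pipeline for a
competitive-memory EEG experiment. During encoding, word-pairs are studied
inside one of three immersive movie contexts; a one-vs-all linear
support-vector classifier is trained on the oscillatory power pattern
(channels x frequencies) that each context evokes. During cued recall no
context is on screen, so any above-chance classification of the *encoding*
context from the retrieval EEG indicates that the context representation has
been incidentally reinstated. The pipeline tracks that reinstatement bin by
bin across the retrieval epoch, separately for noncompetitive (DE) and
competitive (AB, AC) retrieval, and asks when the *target* context and when
the *competitor* context (the other context sharing the retrieval cue) are
reactivated, and how this relates to retrieval success. All inference is
nonparametric: label-shuffle permutation nulls with percentile-of-t
thresholds, Monte-Carlo FDR corroboration, leave-one-subject-out (LOSO)
window selection for success contrasts, and cluster-based permutation tests
for the univariate power analyses.

Because no public recording of this paradigm exists, the package ships a
synthetic-cohort generator as a first-class, tested module. Every
statistical property claimed for the pipeline is demonstrated against
cohorts whose ground truth is known by construction.

## Signal model of the synthetic cohorts

A recorded epoch is modelled as

* a 1/f^alpha broadband background (alpha = 1 by default), independent per
  channel, synthesised by spectral shaping of white noise and standardised
  to unit variance, plus white sensor noise at 0.3 relative amplitude;
* band-limited oscillatory bursts carrying the context signatures.

Each context's *signature map* assigns a non-negative weight to every
(channel, frequency) cell; weights are non-zero only on the most posterior
40% of scalp channels and inside the 4-20 Hz band, mirroring where and at
which frequencies context information concentrates in recordings of this
kind. A burst at cell (c, f) is a cosine at frequency f with a
random phase per trial, amplitude `snr * amplitude * weight`, gated by a
cosine-ramped envelope over the event window. Encoding epochs carry their
context's signature for the whole 0-6 s movie span; retrieval epochs carry
only the bursts programmed in the *reinstatement schedule*. The default
schedule encodes the headline effects the pipeline is meant to recover:
target reinstatement at 0.9-1.0 s on noncompetitive trials, competitor
reinstatement at 2.35-2.45 s followed by target reinstatement at 2.5-2.8 s
on AC trials, and target reinstatement at 2.5-2.8 s on AB trials; target
effects occur only on successfully retrieved trials.

The three signature maps are redrawn until all pairwise correlations over
their support fall below `signature_cor_bound` (default 0.15). The bound is
deliberately strict: the experimental design uses three contexts chosen to
be perceptually and semantically as different as possible, and a low bound
reproduces the homogeneous cross-subject decodability such contexts give.

Design constants default to the study design the pipeline targets: 62 recorded channels (60
scalp + 2 mastoids) at 500 Hz, 18 blocks with four word-pairs per condition
per block, encoding epochs -1..7 s around movie onset, retrieval epochs
-2..6 s around cue onset with the probe at 2 s, about 63 encoding epochs
per context, and the analysed retrieval set of four DE plus two AB and two
AC cues per block (each cue used once). Recall success is drawn per
condition with probabilities 0.70 (AB), 0.62 (AC), 0.74 (DE); the ordering
(AC worst) encodes proactive interference, while the exact values are
conventional placeholders with no canonical reference.

What the generator does *not* emulate: volume conduction from realistic
sources, ocular/muscle artifacts, trial-to-trial latency jitter of
reinstatement, or stimulus identity. Passing recovery tests therefore show
that the pipeline detects context-specific oscillatory reactivation of the
programmed geometry under realistic noise - not that it would survive every
pathology of real recordings. Context drift is available as a slow
multiplicative random walk on signature amplitude (`drift_timescale`), off
by default, and cosmetic for decoding.

## Preprocessing and time-frequency decomposition

Preprocessing is minimal and deterministic: linked-mastoid
re-referencing (mean of the two mastoids subtracted, mastoids dropped),
whole-epoch mean baseline per trial and channel, and decimation behind a
zero-phase FIR low-pass (Hamming, order 32 per decimation step, cutoff 0.4
of the target rate; decimation filters are rarely reported for analyses of
this kind and any adequate low-pass serves). Manual artifact screening and ICA
are inherently irreproducible from a text description; the package instead
accepts an externally produced per-trial keep-mask (`apply_keep_mask()`).

The spectral front end is a complex Morlet transform: frequencies 4-45 Hz
in 1-Hz steps, output every 0.05 s, wavelet width 5 cycles
(`sigma_t = width / (2 pi f)`), L2-normalised, truncated at four standard
deviations of its Gaussian envelope. Power is the squared magnitude of the
inner product of the signal with the shifted wavelet, evaluated as two real
matrix products per frequency against the bank of shifted wavelets - at
epoch lengths of a few thousand samples this BLAS formulation outruns FFT
convolution and is exactly equal to it away from the edges. Bins whose
wavelet support overruns the epoch are flagged invalid per frequency and
refused by the feature constructors; at 4 Hz the margin is 0.8 s, so the
85-bin decoding grid (-0.2..4 s) and the 0-6 s encoding window sit safely
inside their epochs.

Encoding features are the TFR averaged over the 6-s movie span, flattened
channel-major to `channels x frequencies` columns (2520 at full scale). No
baseline correction is applied to decoding features; instead every feature
is z-scored across trials. Normalisation statistics are computed on
training data only and applied frozen to test folds and retrieval bins -
the leakage-free reading of across-trial normalisation. The literal pooled
variant exists behind `pooled = TRUE` but is used nowhere by default.

## Decoding

The context classifier is a one-vs-all linear-margin ensemble: three binary
soft-margin SVMs (C = 1 by default, exposed), prediction by argmax of the
decision values, exact ties to the lowest class index. The binary C-SVC
dual is solved in compiled code by sequential minimal optimisation with
maximal-violating-pair working-set selection on a precomputed Gram matrix
(stopping tolerance 1e-3 on the KKT gap). The Gram formulation is what
makes the permutation machinery affordable: a label shuffle changes only the
dual targets, so thousands of re-trainings reuse one Gram matrix, and
cross-phase decoding of all 85 retrieval bins is a single matrix product
against the stored bin-by-training-trial cross-Gram. The solver is
validated in the test suite against an independent SVM implementation
(libsvm via e1071) on matched problems.

Encoding performance is assessed by 10-fold cross-validation with a random
(unstratified) partition into folds differing by at most one trial, fold-wise
re-normalisation, and confusion counts accumulated over folds; confusion
matrices are row-normalised and accuracy is 100 times the mean diagonal.
Channel and frequency searchlights rerun the same cross-validation on
restricted feature sets (a channel with its montage neighbours across all
frequencies; a frequency with its immediate grid neighbours across all
channels) and are thresholded with Bonferroni-corrected one-sample t tests
against the 33.3% chance level (0.05/42 = 0.0012 for frequencies,
0.05/60 = 0.0008 for channels at full scale).

Retrieval decoding applies the frozen encoding decoder to single-bin
features at 85 bins from -0.2 to 4 s. Per bin the pipeline records, over
any condition and outcome subset, the proportion of trials predicted as the
target context (whose percentage is the reported accuracy), as the
competitor context, and as any other context; the three proportions sum to
one. Series are smoothed with a centred 0.1-s moving average (three bins;
edges shrink) before group statistics.

The montage is an approximate 2-D projection of the extended 10-20 layout
built programmatically; channel adjacency is a symmetrised 5-nearest-neighbour graph
on that projection, giving 5-7 neighbours per channel - inside the 4-8
range typical neighbour templates give at this electrode density. A
triangulation-based adjacency was considered and rejected because the
projected layout's irregular row spacing makes fixed-radius and
triangulation neighbourhoods erratic at the edges.

## Permutation inference

Group-level inference never uses parametric null distributions. For the
retrieval timecourse, each of `n_iter` iterations shuffles the encoding
context labels within subject, re-trains the decoder (the stricter reading;
a permute-test-labels-only mode exists behind a flag), re-decodes every
bin, and computes the one-sample group t of the smoothed per-subject
accuracies against 33.33%. The per-bin 2.5th and 97.5th percentiles of the
null t samples (linear-interpolation convention, `quantile` type 7) form
the two-tailed threshold. A Monte-Carlo FDR corroboration computes per-bin
two-tailed permutation p-values `(1 + #{|t_null| >= |t_obs|}) / (1 + n_iter)`
and applies Benjamini-Hochberg across bins at q = 0.05; reported
(`sig_joint`) bins must pass both procedures.

Two numerical facts about this machinery matter at reduced iteration
counts, and both are properties of the procedure rather than of this
implementation. First, the exceedance rate of an interpolated 97.5th
percentile of m samples is (approximately) `(m - 0.975(m-1) - 0.5)/(m+1)`
per tail: about 6.9% two-tailed at m = 100, 5.2% at m = 400, and the
nominal 5% only as m grows to the full-scale 1000. Calibration checks
therefore run their nulls at 300 iterations (exceedance about 5.3%). Second, the +1-corrected
permutation p has a floor of `1/(n_iter + 1)`; with 85 bins the BH line at
rank one is 0.05/85 = 0.000588, so no single bin can survive per-bin FDR
unless n_iter exceeds 1699 - and in practice a bin must beat *every* null
draw in several bins at once. At desk-scale subject counts the group t is
capped near 5 (see below), which that requirement cannot meet; recovery
checks therefore corroborate with the pooled-across-bins null variant the
module provides, which is exchangeable at the null and has a usable p
resolution of `1/(85 n_iter)`.

LOSO window selection re-derives, for each left-out subject, the group t
over the remaining subjects and that fold's own percentile thresholds (the
stored null accuracy array is re-aggregated without the left-out subject),
then selects the significant bins within 0.2 s of the reference window.
Empty selections fall back to the bin nearest the reference-window centre,
flagged and warned, so every subject stays in the contrast. Success
contrasts exclude subjects with fewer than `min_trials` (default 10,
matching the full-scale rule of more than ten trials per outcome) and use a
two-tailed paired t with Cohen's d for paired designs (mean difference over
the SD of differences; the d flavour is stated because conventions differ).
Factorial within-subject questions (time window x memory x context) go
through a standard repeated-measures ANOVA (`aov` with an
`Error(subject/...)` stratification, partial eta squared per term); all
factors in scope have two or three levels and no sphericity correction is
applied (none is needed for two-level factors).

The univariate analysis log-transforms power, subtracts the mean log power
of the -1..0 s baseline, and contrasts conditions with the familiar
cluster-based permutation test: cell-wise dependent t at alpha = 0.05,
clusters as connected components of same-sign supra-threshold cells
(channel neighbours at fixed frequency/time; one grid step along frequency
or time at fixed channel; a simultaneous step in two axes is *not*
adjacent), cluster mass as summed t, and a max-|mass| reference
distribution from within-subject condition swaps (sign flips of subject
difference maps). Positive and negative clusters are each tested at
alpha/2 against that null; 10,000 draws at full scale, 499 in desk runs.

## Numerical choices and degenerate inputs

* Zero across-subject variance in a group t (all subjects identical, e.g.
  all at ceiling) yields a finite sentinel t of magnitude 1e6 rather than
  NaN/Inf, keeping quantile machinery defined; at the reference value the t
  is 0.
* Subjects without trials of a requested outcome contribute NA series and
  are dropped column-wise from group statistics.
* Features with near-zero training SD are zeroed everywhere and counted.
* Zero power cells are floored at 1e-20 before the log transform, with a
  warning.
* Permutation p-values always carry the +1 correction, so they are valid
  and never zero.
* Decision-value ties (exactly equal class scores) go to the lowest class
  index, deterministically.

## Why a single bin cannot decode perfectly

Single-bin Morlet power of a short burst carries irreducible multiplicative
noise: within one wavelet bandwidth, neighbouring signature frequencies
interfere with trial-specific random phases, so the power pattern of even a
strong burst fluctuates trial to trial. Raising the programmed
signal-to-noise ratio raises both the mean and the spread of the pattern,
and single-bin decoding accuracy saturates well below 100% (real
reinstatement decoding studies likewise report accuracies only a few points
above chance). Group t values at a bin are
correspondingly capped by subject count - the reason the recovery suite
runs 14 synthetic subjects rather than 8.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script use reduced cohorts chosen
once, as a compromise between statistical power and a desk-scale runtime,
and stated here so that they are not mistaken for the design defaults:
8-14 subjects; 8-10 channels (including the mastoid pair); 60-100 Hz
sampling; 3-9 blocks; 8-30 encoding epochs per context; TFR grids spanning
the same 4-44/45 Hz range in 2-Hz steps; 50-300 permutation iterations
(calibration checks at 300, where the percentile exceedance arithmetic
above is within half a point of nominal); 499 cluster draws. The
calibration suites run at snr = 0; the recovery suite at snr = 3 with the
default reinstatement schedule; the full-scale iteration counts
(100/1000/10,000) remain one switch away via
`run_config(full_scale = TRUE)`.

## Known limitations

* The generator's bursts are phase-incoherent cosines; no cross-channel
  phase structure or forward-modelled topography is simulated.
* The LOSO procedure shares n-2 subjects between folds; under heavy
  noise-driven selection its success contrast retains a small residual
  optimism (folds select overlapping noise bins), though it stays within
  the nominal level in the shipped calibration and is dramatically better
  than circular max-bin selection - the property it exists to demonstrate.
* The montage is an approximate projection; analyses that depend on exact
  electrode geometry should not rely on it.
* `rm_anova` handles balanced complete within-subject designs only, which
  is all the pipeline produces.
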