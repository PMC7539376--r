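---
title: "Fingerprint classification of raw mass-spectrometry runs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint classification of raw mass-spectrometry runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

specswath classifies whole LC–MS/MS runs from the shape of their raw
spectra, skipping peptide/protein identification entirely. This
vignette explains the model, the parameters that matter, the numerical
conventions, and what the synthetic benchmark can and cannot show.

## The model

### Feature swath extraction

A centroided run is an ordered list of scans; each scan is a variable
number of (m/z, intensity) peaks. Variable-length scans cannot feed a
fixed-topology classifier, so the m/z axis is divided into `j`
contiguous equal-width windows and, per scan, all peak intensities
inside one window are summed. Scan `i` becomes the length-`j` row

    IM[i, j] = sum of intensities of scan i's peaks in window j.

Because absolute ion counts vary by orders of magnitude between scans,
runs and instruments, each row is divided by its own maximum:

    NIM[i, ] = IM[i, ] / max_j IM[i, j],

so every nonzero row has maximum exactly 1. This per-scan normalization
is deliberately local: it cancels any global per-run scale factor (the
generator injects one precisely so tests can verify the cancellation)
without requiring cross-run statistics that would leak information
between training and test sets.

The assumptions are worth stating. Summing within windows assumes class
signal lives in *where* intensity sits along m/z at window resolution,
not in fine isotopic structure; row-max normalization assumes the
*relative* bin pattern matters, not absolute intensity (which also
means a class whose only difference is overall intensity becomes
invisible — a deliberate robustness/expressiveness trade-off).

### The window grid

Windows are half-open `[lo, hi)` with the last window closed at the
upper bound, the usual histogram convention, so the windows tile the
range exactly and every in-range peak lands in exactly one window. A
peak sitting exactly on an interior boundary belongs to the window
starting there. Peaks outside the grid range are dropped and counted
(not clamped into edge windows, which would distort the edge bins); the
grid range is inferred as floor/ceiling of the pooled minimum/maximum
m/z across all runs of the experiment, so drops are rare by
construction. Training and test runs must share one grid — a model
trained on one feature space cannot score another — hence the range is
inferred from the whole pool (a per-scan operation, so no label
information crosses the split). MS1 and MS2 analyses infer their ranges
independently, since instruments scan different ranges at the two
levels.

The window spec `"NxN"` means N² one-dimensional bins; the square
notation exists only because fingerprints are displayed as N×N heat
maps. The default is `"32x32"` (1024 windows): empirically, mid-range
resolutions preserve class signal that very coarse grids merge away,
while much finer grids dilute counts per bin. `sweep_window_sizes()`
reruns the whole protocol across specs to let users pick for their own
data; the package deliberately ships no automatic selector.

### The scan classifier

The per-scan classifier is a small fully connected network: input =
number of windows, two rectified-linear hidden layers, and either one
sigmoid unit (two classes) or a softmax layer (more). The canonical
configuration on 1024 inputs uses hidden sizes (56, 41), which gives

    1024·56+56 + 56·41+41 + 41·1+1 = 59,779

trainable parameters. Only the layer count and this parameter total are
pinned by the reference architecture; the hidden sizes are the
(essentially unique) two-hidden-layer rectifier shape on 1024 inputs
reproducing that total, and other input sizes scale the hidden widths
proportionally (floor one unit). The network is authored directly in
base-R matrix arithmetic: forward pass, backpropagation, and the Adam
optimizer, seeded end to end so a (data, spec, config, seed) quadruple
reproduces weights and predictions bit-stably within one BLAS.

Training defaults: 30 epochs, minibatch 128, learning rate 1e-3,
binary/categorical cross-entropy, He-uniform init for rectifier layers
and Glorot-uniform for the output, 10% validation split (metrics only —
validation rows never contribute gradients), no early stopping, no
class reweighting (inverse-frequency weights are available behind
`class_weights = TRUE`). Per-epoch log loss/accuracy are running means
over minibatches, the convention deep-learning frameworks report.
Optional inverted dropout is available per hidden layer but off by
default. These defaults are modest on purpose: the datasets this
package targets have 10³–10⁵ scans per cohort, where this budget
converges (training loss reaches ~1e-4 on the synthetic benchmark) in
seconds per fold on one CPU.

### Leave-one-out cross prediction and the scan vote

For `n` labelled runs the protocol runs `n` iterations; in each, one
run is the independent test set and the rest are training data, so no
scan of the test run is ever seen in training. A fresh model is trained
per iteration with seed `master_seed + iteration`, giving
reproducibility with inter-iteration independence. Features are
extracted and normalized once per run before splitting — both are
strictly per-scan operations, so precomputation cannot leak.

The sample verdict is a majority vote: with the fraction of the test
run's scans predicted as its true label written `r`, the sample is
predicted correctly iff `r >= 0.5`. The boundary counts as correct —
where informal descriptions of such protocols say "more than 50%", the
formal rule here is ≥ 0.5, and the package follows the formal rule. In
a two-class task this vote pins the predicted label (the majority label
is the original one exactly when the verdict is correct). Multiclass
verdicts instead average the per-scan class-probability vectors and
predict the argmax, which uses the full probability mass rather than
hard votes; a sigmoid output of exactly 0.5 predicts the positive
class, mirroring the verdict boundary.

### Metrics

Precision (`TP/(TP+FP)`), recall (`TP/(TP+FN)`) and their harmonic mean
F1 are computed over **sample verdicts** — the granularity at which
such results are conventionally tabulated — with the positive class
configurable (swapping it swaps TP↔TN and FP↔FN). Zero denominators
yield 0 with a warning rather than NaN, so F1 stays defined. Cohort
accuracy is `N_predicted / N_total`.

ROC/AUC is computed at **scan granularity** over the per-scan
positive-class probabilities pooled across all leave-one-out
iterations: every distinct score is swept as a threshold (tied scores
grouped into one step), and the curve is integrated by trapezoid. This
is algebraically the concordant-pair (rank) statistic with ties counted
one half, and the test suite checks that identity against an O(n²)
pair-counting oracle as well as against an independent reference
implementation. Multiclass cohorts get one-vs-rest
precision/recall/F1 per class plus macro averages, and no pooled ROC.

## The synthetic benchmark

`generate_cohort()` emulates desk-scale DDA runs: per scan a
Poisson(150) number of background peaks uniform in m/z over 400–1400 Th
with log-normal(ln 1e4, 0.5) intensities, plus 8 signature peaks at
fixed m/z loci (log-normal around ln 8e4, ~0.05 Th jitter); retention
times are uniform over an hour-long gradient; each run draws one global
intensity scale in [0.5, 2]. All classes share the same base loci; a
class displaces each locus by `signature_shift` times a fixed
class-specific offset (uniform ±5 Th) and scales its intensity by
`exp(signature_shift ·` class-specific N(0, 0.8)`)`. Two properties
follow by construction and are tested: at `signature_shift = 0` the
classes are distributionally identical, and a global intensity rescale
changes nothing downstream of normalization. Defaults (2 classes, 5
runs/class, 300 scans/run, shift 1) were chosen once as a realistic
strongly-separated pilot-cohort scale that keeps a full leave-one-out
pass within a few minutes on one CPU; the optional MS2 mode emits
fragment scans from signature precursors with doubled noise, so MS1 ≥
MS2 accuracy is the expected ordering.

What the generator does *not* emulate: isotope envelopes, charge
states, chromatographic peak shapes, retention-time drift, instrument
duty cycles, or batch effects. Passing the synthetic benchmark
therefore shows the machinery is correct and sensitive to m/z-pattern
differences of the injected kind — it does not show that any particular
real cohort is separable, which depends on acquisition consistency
(column, gradient, instrument parameters) across samples.

## A limitation worth knowing: the null behavior of leave-one-out voting

With balanced classes and no signal, one might expect cohort accuracy
near 0.5. It is actually near **0**: holding out a class-0 run leaves
training data tilted (e.g. 4 vs 5 runs) *against* the held-out class,
the null model inherits that majority bias, the per-scan match
probability sits slightly below 0.5 (≈ 0.40 at 5+5 runs), and across
hundreds of scans the binomial vote concentrates — the probability that
half the scans still match collapses (≈ 1e-8 at 300 scans). This
anti-correlation between training majority and held-out label is a
known pathology of leave-one-out with majority-vote classifiers, and
the acceptance suite measures it: at `signature_shift = 0` the mean
accuracy over ten seeds is ~0.0, below a naive coin-flip band. The
practical reading is asymmetric: high leave-one-out accuracy is
evidence of signal (leakage bugs would show up as systematic 1.0 on
null data, which the construction excludes and the scale-invariance and
determinism tests guard), but null-data accuracy should be expected
near 0, not 0.5, and users comparing against a "chance level" should
calibrate with label permutations rather than assuming 1/k.

## Numerical conventions, in one place

- Half-open windows `[lo, hi)`, last closed; boundary peaks go to the
  window starting there; out-of-range peaks dropped and counted.
- All-zero rows (empty scans) survive normalization unchanged
  (0/0 := 0) and are retained as all-zero feature rows; empty scans are
  never silently dropped, only counted in messages.
- Double normalization is an error, not a no-op.
- Degenerate inferred m/z range (single value) is widened by 1 Th.
- Sigmoid probability exactly 0.5 → positive class; softmax ties →
  first (lowest) class; vote ratio exactly 0.5 → verdict correct.
- Zero-denominator precision/recall → 0 with a warning.
- Retention times are seconds internally regardless of source units.
- Seeds: one master seed governs a whole protocol run; per-iteration
  training seeds are `master + k`. Training restores the caller's RNG
  state afterwards.

## Problem sizes used by the test suite

Unit tests run on miniature cohorts (2–3 runs/class, 10–40 scans, ≤ 100
windows) chosen so each property is checked in milliseconds; the
oracle-equivalence property uses 50 random scans of up to 1000 peaks
against a brute-force per-peak loop. The end-to-end recovery check uses
the generator's full defaults (10 runs × 300 scans × 1024 windows, one
full leave-one-out pass), and the null-behavior check repeats that at
`signature_shift = 0` for ten seeds. These sizes are the package's own
benchmark definition and complete in a few minutes on a single CPU.
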