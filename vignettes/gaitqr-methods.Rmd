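---
title: "Methods: QR-encoded gait classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QR-encoded gait classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `gaitqr`, the
assumptions baked into each stage, the parameters that matter, and the
design choices made where the problem left the design open.

## 1. The data model

A *stride record* is one gait cycle described by 13 timing features, in
the fixed column order of the public neurodegenerative gait databases:
elapsed time since the start of the walk; left and right stride
intervals; left and right swing intervals; swing as a percentage of the
same-side stride; left and right stance intervals and percentages; and
the double-support interval with its percentage. Two identities tie
these together — per side, swing + stance equals the stride, and each
percentage column equals 100·(interval/stride). The loader checks both
at a 1% relative tolerance. Real recordings occasionally violate them
(sensor drop-outs, turn-around artefacts), so a violation *flags* the
record rather than rejecting it: no undeclared cleaning happens. The
double-support percentage is checked against the **left** stride; the
raw tables do not say which side the convention uses, and the left
stride also drives the elapsed-time column, so the package uses it
consistently in both the checker and the generator.

A row that is structurally malformed — not exactly 13 numeric fields —
is an error naming the line, not a flag: that indicates a wrong file,
not a noisy stride. Outlier removal (strides > 3 MAD from the subject
median) exists but is opt-in, because the upstream database
documentation suggests median filtering while the pipeline itself is
defined without a cleaning step; the default therefore keeps every row.

The modeling unit is the 12-feature vector left after dropping elapsed
time, which is a clock, not gait. Column order is never rearranged: the
serialized payload reads back as the record.

## 2. The synthetic gait generator

The generator exists so that the full pipeline — parsing, encoding,
rendering, training, evaluation — can be exercised and benchmarked with
no external data. Per subject, stride intervals are drawn **lognormally**
with a given arithmetic mean and coefficient of variation (CV):
lognormality guarantees positive intervals without truncation, and
(mean, CV) are the two interpretable knobs that control class
separation. Swing fractions are drawn normally (clamped to (0.1, 0.6)),
stance is stride − swing, percentages are computed exactly, and
double-support is the left stride minus both swings, floored at 0.01 s.
Consequently every generated record satisfies the timing identities to
machine precision — the generator is also the round-trip oracle for the
reader/writer pair (6-decimal fixed-point, tab-separated).

Default class profiles (synthetic benchmark parameters, **not** cohort
estimates; all overridable):

| class   | mean stride (s) | CV   | swing fraction |
|---------|-----------------|------|----------------|
| CONTROL | 1.10            | 0.02 | 0.38           |
| PD      | 1.05            | 0.05 | 0.33           |
| HD      | 1.15            | 0.09 | 0.37           |
| ALS     | 1.35            | 0.06 | 0.40           |

The directions follow the gait literature: disease increases
stride-to-stride variability, ALS-like gait is markedly slowed, a
Parkinsonian profile has reduced swing. Records are temporally
independent by default — the classifier treats strides independently, so
autocorrelation would not change what the benchmark measures — but an
AR(1) coefficient is accepted for experiments that need serial
dependence. What the generator deliberately does *not* emulate: raw
force-sensor waveforms, drift and drop-out artefacts, within-subject
fatigue trends, and the heavy-tailed outliers of real recordings. A
passing benchmark on synthetic data therefore demonstrates that the
pipeline is implemented correctly and can learn class-separated stride
statistics through the QR representation; it does not certify clinical
performance on real cohorts.

Determinism: every dataset is a pure function of its configuration. Each
subject's seed is derived from the master seed by a fixed integer map
(kept below 2^31), so subjects are independent streams yet fully
reproducible.

## 3. The QR codec

Payloads are comma-joined fixed-point decimals with 4 fraction digits.
This format was chosen (the payload text format is otherwise
unconstrained) because it is human-readable, scanner-verifiable, and
capacity-safe: gait values live in [0, 1000), so 12 fields take at most
12·8 + 11 = 107 octets against the 213-octet byte-mode capacity of a
version-10 level-M symbol ((216·8 − 4 − 16)/8, floored). Four fraction
digits keep the payload well within capacity while preserving ~0.1 ms
timing resolution; it is a serialization precision, not a claim about
sensor accuracy. Encoding is plain byte mode with Latin-1 octets and no
ECI header, matching common encoder defaults.

The symbology is implemented end to end for version 10-M: byte-mode
bitstream (mode 0100, 16-bit count, ≤4-bit terminator, 0xEC/0x11 pads);
Reed–Solomon parity over GF(256) with primitive polynomial 0x11D,
26 parity octets per block over the (43,43,43,43,44) data block split;
column-wise interleaving to 346 codewords; function patterns (finders,
alignment at centers {6,28,50}, timing, dark module); the two-column
zigzag placement skipping the timing column (exactly 2768 data modules —
version 10 has no remainder bits, which the constructor asserts);
BCH(15,5) format information XOR-masked with 0x5412 and BCH(18,6)
version information; and the eight mask patterns scored by the four
standard penalty rules (runs ≥5 score 3+(len−5); 2×2 blocks score 3;
finder-like 1:1:3:1:1 runs with a 4-light flank score 40 per
orientation; 10 points per full 5% dark-proportion deviation from 50%).
Mask selection is automatic with ties broken toward the lowest id; a
fixed mask can be forced for reproducibility experiments.

The decoder is an error-*detection* path for symbols produced by this
codec: it BCH-checks the format information, unmasks, de-interleaves,
verifies that all 26 Reed–Solomon syndromes of every block are zero, and
parses the bitstream. Full syndrome-decoding error *correction* is
intentionally not implemented — the decoder exists to prove
round-trip integrity, not to scan photographs — and a flipped module is
reported as corruption. Internals are version-parametric, but only
version 10-M is exercised and supported.

Correctness evidence, layered: GF multiplication against shift-and-add
reduction; Reed–Solomon parity against a brute-force long-division
oracle that uses no lookup tables, plus root-vanishing of the full
codeword; format/version words against independent bit-vector BCH
division; penalty components against hand-enumerated toy grids; 200
random payloads round-tripped; and bit-exact agreement with an
independent third-party reference encoder, frozen as plain-text module
grids in the test fixtures (the reference library auto-selects
alphanumeric mode and uses a nonstandard mask score, so byte mode and
the mask are forced when comparing).

## 4. Rendering

A symbol is rendered at 100×100 pixels with a light quiet zone of 4
modules — the standard minimum; the target resolution alone does not say
whether a quiet zone was included, and rendering without one would both
break scannability and change the CNN's input statistics, so the
standard border is the default and is configurable. 57 + 2·4 = 65
logical modules map onto 100 pixels by **nearest-neighbour** indexing
(pixel (r,c) reads module (⌊r·65/100⌋, ⌊c·65/100⌋)): anti-aliased
resampling would introduce grey levels into an inherently two-valued
signal. Since ⌊·⌋ maps the 100 pixel indices onto all 65 module indices,
every module influences at least one pixel — no information is lost at
this resolution (the mapping oracle in the tests verifies this). Images
are 8-bit grayscale PNGs, dark = 0, and the whole dataset build is
byte-deterministic.

## 5. The classifier

The network is fixed by its published dimension chain: a 64-filter 3×3
same-padding convolution (100→100), 3×3 max pooling with stride 3
(100→33, floor semantics), a 64-filter 3×3 valid convolution (33→31), a
second 3×3/3 pool (31→10), and a flatten of 64·10·10 = 6400 units into
the N-way output layer. Non-overlapping floor-semantics pooling is the
only pooling arithmetic that produces 100→33 and 31→10
simultaneously. The description of a "6400-unit dense layer" admits two
readings — the flatten itself, or an additional fully connected layer of
the same width. The default takes the first (the flatten feeds dense(N)
directly, ~1.25 M parameters for N = 2); `hidden_dense_units = 6400`
realizes the second (~42 M parameters). Both are implemented and
documented; the closed-form parameter counts for both appear in
`count_parameters()`.

Training hyperparameters are not dictated by the architecture and are
package choices, all config-exposed: ReLU activations, softmax output
with cross-entropy loss, Adam (learning rate 1e-3, β₁ = 0.9,
β₂ = 0.999), batch size 32, 30 epochs by default. Pixels are scaled to
[0, 1] by dividing by 255; with binary images no mean subtraction is
useful. The implementation is single-precision im2col + GEMM in
RcppArmadillo with all randomness (He-normal initialisation, epoch
shuffles) drawn from `std::mt19937`, so a seed fixes the run exactly on
a given platform; training history (per-epoch loss and accuracy) is
recorded, and checkpoints serialize to a JSON sidecar plus a text
parameter dump.

## 6. Evaluation protocol

Five tasks are defined over the four source labels: the 4-group problem,
all diseases pooled against control, and three single-disease problems
that *exclude* the other two diseases. Folds are stratified: record
mode (default) assigns records of each class round-robin after a seeded
shuffle, so per-fold class counts deviate by at most one — this matches
protocols whose sample counts are record-level, but lets strides of one
subject appear on both sides of a split; subject mode assigns whole
subjects to folds and is the leakage-safe option. Each fold trains a
fresh model (per-fold seeds derived from the protocol seed) and
evaluates on the held-out portion.

Metrics come from the confusion matrix: accuracy is the correct
proportion; precision, sensitivity and F1 are computed one-vs-rest per
class. For multi-class reports the per-class values are averaged —
**macro** (unweighted) by default, since a single reported
precision/sensitivity pair for a 4-class problem does not identify the
scheme; micro and weighted are selectable. For binary tasks the
reported precision/sensitivity/F1 are those of the disease (positive)
class. The report-level F1 is the harmonic combination of the
report-level precision and sensitivity, with per-class F1 also emitted;
a zero denominator (a class never predicted, or absent from a fold)
yields 0 with a warning rather than NaN. The mean row is the exact
arithmetic mean of the fold rows.

## 7. The synthetic benchmark

The package's end-to-end benchmark fixes, up front: default profiles,
10 subjects/class × 80 strides (1,600 records → 1,600 images), the
ALS-vs-control task, 3-fold cross-validation, 10 epochs, batch 32, Adam
1e-3. Ten epochs rather than the five-epoch floor because the mask layer
of the symbology makes the pixel-to-class mapping partly nonlinear (the
same payload digit can appear with either polarity depending on the
chosen mask), and a from-scratch CNN needs a few extra passes to absorb
that; 3 folds and ~1,600 images keep the run near 10 minutes on one
CPU. Under these conditions the pipeline reaches ~97% mean accuracy
(the acceptance test requires ≥90%). Smaller runs degrade sharply —
with 400 images the same task sits near 65% — because the network must
learn the symbology's layout before the class signal is accessible;
benchmark conclusions therefore hold at the stated problem size, not
below it.

## 8. Degenerate inputs, tie-breaks and numerical notes

* Empty payloads encode and decode (mode + zero count + terminator);
  payloads over 213 octets are capacity errors naming the length.
* NUL octets are legal payload bytes; only their text rendering is
  undefined (reported as `NA`), the octet round trip is exact.
* Mask-score ties choose the lowest mask id (first minimum).
* Pooling argmax ties take the first window element (row-major scan);
  prediction argmax ties take the first class.
* The consistency checker compares at 1% *relative* tolerance with a
  floor to avoid division by a zero stride; the generator's identities
  are tested at 1e-9.
* Single-precision training is reproducible bit-for-bit for a fixed
  seed on a given BLAS; across BLAS builds small last-digit differences
  are possible, which is why the reproducibility test allows 1e-4.

## 9. Known limitations

* The decoder handles only clean module grids from this codec — no
  geometric rectification, no error correction.
* Only QR version 10-M is supported at the surface; other versions would
  need their block tables and alignment layouts.
* Record-level folds overstate generalisation to new subjects (use
  subject mode for that question).
* The synthetic benchmark bounds implementation correctness, not
  clinical accuracy; real-cohort results additionally depend on data
  curation choices the pipeline deliberately leaves to the user.
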