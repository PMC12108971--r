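---
title: "Fusing categorical and numerical clinical data: the model behind tsfnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing categorical and numerical clinical data: the model behind tsfnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vertical root fracture (VRF) is a longitudinal fracture along the long axis
of a tooth root and a common late complication of root canal therapy. The
clinical record available at the time of treatment mixes two data types:
ten *categorical* items whose options have no measurable ordering (sex,
prior fractures and prostheses, pain status, endodontic retreatment, tooth
position, post placement, abutment role, previous apical surgery) and seven
*numerical* items (age, remaining tooth walls, time from root canal
completion to prosthetic installation, wear and periodontal scores,
remaining canal wall thickness, pericervical dentin thickness). Feeding
such a mixture into a single dense network treats option codes as if they
were magnitudes, and small clinical cohorts (here, on the order of 145
teeth) leave little room for the network to discover a better internal
representation on its own.

`tsfnn` implements a three-stage fusion classifier for this setting, along
with the ablation baselines needed to attribute its behaviour, and a
synthetic-data generator that emulates the 17-item schema so the whole
pipeline is testable without access to protected clinical records.

## The model

**Stage 1 — numerical branch.** Each numerical item is min-max normalized.
The default transform is

$$y = \frac{x - \min(x)}{\max(x) - \min(x)},$$

which maps the fitted range onto $[0,1]$. A `"literal"` variant,
$y = x/(\max(x)-\min(x))$, divides by the range without centring; the two
coincide exactly when $\min(x)=0$ and otherwise differ by the constant
$\min(x)/(\max(x)-\min(x))$, so the literal form does not in general land in
$[0,1]$. The standard form is the default because a common $[0,1]$ input
scale is the stated purpose of the normalization; the literal form remains
available by flag. Values met at prediction time outside the fitted range
are clamped to $[0,1]$ (they arise whenever parameters fitted on a training
fold meet a held-out record), and an item whose fitted range is degenerate
($\max=\min$) normalizes to 0 rather than erroring, so a constant training
fold never aborts a cross-validation sweep. The normalized 7-vector passes
through one dense hidden layer (default width 16).

**Stage 2 — categorical branch.** The ten categorical items are *globally*
ordinal encoded: walking the items in schema order and each item's options
in printed order, consecutive integers are assigned starting at 1, so the
default 30-option vocabulary spans codes 1–30 (sex/Male = 1 through root
amputation = 30) and every option owns a unique code. These codes are then
re-represented by an **embedding layer** built by pre-training: a
one-hidden-layer network (10 scaled codes in, 20 hidden nodes, one sigmoid
output) is trained on the fracture label with cross-entropy, and its output
nodes are removed. The surviving input-to-hidden transform maps any
categorical profile to a 20-dimensional real vector. Twenty hidden nodes is
the default width, kept from the original architecture description as the
smallest width that identified the task well. The branch then applies one
dense hidden layer (default width 16) to the embedded vector.

**Stage 3 — fusion.** The two branch outputs (16 + 16) are concatenated and
passed through a fusion sub-network (dense 32→16, then the one-node sigmoid
output). The ablation baselines differ only where they must:

* `two_way` concatenates the same two branches directly into the output
  node, with no fusion sub-network;
* `ann` feeds all 17 items (normalized numerics plus range-scaled codes)
  through a single 32-wide hidden layer;
* `nnn` and `cnn` are the numerical and categorical branches alone.

**Batch normalization** can be inserted after every hidden linear transform,
before its activation: within a training mini-batch, activations are
centred by the mini-batch mean and divided by the mini-batch standard
deviation (biased variance, $\varepsilon = 10^{-5}$ in the denominator),
then scaled and shifted by learned parameters. Inference uses exponential
running statistics (momentum 0.9). Placement before the activation is our
choice; the normalization arithmetic itself is fixed by its definition.

## Training procedure and its open choices

The embedding is pre-trained first (that step is explicit in the
architecture), after which the full network is trained end-to-end with the
embedding **frozen** by default; a `fine_tune_embedding` flag splices the
pre-trained transform in as trainable layers instead. Whether the original
three stages were trained separately or jointly is not reconstructable from
the architecture description, so both behaviours are exposed and the
end-to-end default is documented as this package's choice.

Everything not fixed by the architecture is a documented, configurable
default: rectified-linear hidden activations, sigmoid output, binary
cross-entropy loss, Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$), learning rate $10^{-3}$, 300 epochs, mini-batch
16, Glorot-uniform initialization. Hidden widths (16 per branch, 16 in the
fusion stage, 32 for the plain ANN) were set so that `two_way` (32 hidden
nodes) and `tsfnn` (48) use a similar number of hidden nodes — same branch
widths, differing only by the fusion stage whose presence is the very thing
being compared; a test pins this ratio. A probability exactly equal to the
decision threshold (default 0.5) is classified positive — a fixed,
documented tie rule. All randomness fans out deterministically from one
master seed: weight initialization, shuffling, embedding pre-training and
per-fold seeds are separate derived streams, so any run is bit-reproducible.

Two representation choices deserve note. The embedding consumes the ten
global codes rescaled linearly from 1–30 onto $[0,1]$ (`scaled_ordinal`),
the literal reading of "encodes 10 ordinal codes"; a 30-length `one_hot`
indicator representation is implemented as the alternative. The choice is
not cosmetic: under `scaled_ordinal`, adjacent options of one item differ
by only $1/29 \approx 0.034$ on the input scale, so the pre-training
network operates in an essentially linear regime over the codes — it picks
up monotone main effects but demonstrably cannot learn a pure option-pair
interaction (its training accuracy stays pinned at the majority proportion
even with an order of magnitude more epochs and a tenfold learning rate).
Under `one_hot`, each option owns an input, the hidden layer is genuinely
nonlinear per option combination, and the same interaction is mastered at
near-default settings. The ablation checks that exercise interaction
recovery therefore run the embedding in `one_hot` mode; `scaled_ordinal`
remains the package default as the literal reading of the architecture.
And the plain `ann` baseline consumes range-scaled codes rather than raw
integers so that its single input layer sees comparable scales across all
17 inputs.

## Evaluation

Validation is leave-one-out: with $n$ records, $n$ models are trained on
$n-1$ records each and the held-out record is scored once. Preprocessing
scope matters here: by default min-max parameters **and** embedding
pre-training are refitted inside every fold, so the held-out record never
influences any fitted artifact. A `"global"` scope (fit once on all
records) exists because the original protocol does not state which was
used; the fold-local default is the leakage-free reading. A fold whose
training records collapse to a single class is skipped with a warning and
reported in the effective fold count — with a singleton minority class this
is unavoidable, not an error.

The $n$ single predictions are pooled into one confusion matrix (fractured
= positive) from which accuracy, precision, recall and F1 are computed
once. For accuracy, pooling equals the average of per-fold 0/1 accuracies
exactly; for precision, recall and F1 it is the only well-defined
aggregation when each fold holds one test sample, since per-fold ratios are
0/0 whenever the lone sample's class empties a denominator. Metrics whose
denominator is zero are reported as `NA`, never silently 0. No significance
machinery is attached: the comparison tables report point metrics, plus
improvement rows (later model minus earlier) mirroring the ablation layout
for batch normalization, embedding and fusion effects.

## What the synthetic generator does and does not emulate

The real cohort is private, so the generator stands in for it. It fixes the
schema (exact option vocabularies) and the study composition — 97 fractured
versus 48 nonfractured by default — and draws numerical items from
class-conditional Gaussians on plausible clinical scales (age around 55
years, thicknesses in millimetres, score items on 0–4 ranges, draws clamped
to the schema's advisory ranges) and categorical items from
class-conditional option probabilities. The default planted effects are
mild, clinically sensible tilts (fractured teeth: fewer remaining walls,
thinner canal walls and pericervical dentin, more prior fractures and
percussion pain, more rigid posts); they are fixture constants of this
package and claim no resemblance to the true joint distribution,
correlations between items, or measurement noise of the clinical records.
Consequently, passing tests demonstrate that the *pipeline* behaves as
specified on data of this shape — not that the headline performance on the
private cohort would be reproduced.

Three named presets cover the study conditions the tests exercise:

* the **default** planted-effect spec above;
* a **null** spec with every effect removed, under which the label is
  independent of all items and any architecture's pooled leave-one-out
  accuracy should sit at the majority proportion $97/145 \approx 0.669$
  within Monte-Carlo error (the calibration check);
* an **interaction** spec in which two binary items are rewritten so their
  exclusive-or tracks the label with probability 0.9 while each item's
  marginal stays near-uniform, plus a mild numerical tilt. A model linear
  in the ordinal codes gains nothing from either item alone; recovering
  the signal requires exactly the nonlinear re-representation the
  embedding and fusion stages provide, which makes this the designated
  test bed for the embedding and fusion ablation directions.

A seed-pinned 97/48 dataset is shipped as
`synthetic_study_composition.csv` (clearly synthetic, as the name says) so
fold-accounting tests are bit-stable.

## Problem sizes and numerical tolerances in the shipped checks

The test-suite and the acceptance script rerun full leave-one-out sweeps at
$n = 145$ with reduced epoch budgets (tens of epochs, embedding
pre-training included) — our chosen operating point for routine runs, since
fold accounting is epoch-independent and the calibration and direction
checks do not require full convergence; the interactive defaults remain 300
epochs. Chance-level calibration is asserted within three binomial standard
errors of the majority proportion; gradient correctness is checked against
central finite differences at $10^{-4}$ relative tolerance; batch-norm
standardization is asserted up to its $\varepsilon$; model serialization
round-trips predictions to within $10^{-12}$ (JSON decimal text, not IEEE
bits).

## Known limitations

* Missing values are a hard error by design; no imputation is provided.
* The embedding is a dense encoder over all ten items jointly — not
  per-item lookup tables — matching the architecture it implements; the
  two styles are not interchangeable.
* Class imbalance is not reweighted by default (a `class_weight` flag
  exists).
* No ROC/AUC, k-fold, or bootstrap protocols: leave-one-out with pooled
  counts is the implemented protocol; a bootstrap interval would be an
  extension beyond it.
* Pure-R training: fine for these layer widths and cohort sizes (a full
  145-fold sweep runs in about a minute at reduced epochs), not intended
  for large tables.
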