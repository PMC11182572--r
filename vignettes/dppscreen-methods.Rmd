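---
title: "Methods: virtual proteolysis and classifier-based peptide screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual proteolysis and classifier-based peptide screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppscreen)
```

`dppscreen` implements an in-silico discovery loop for dipeptidyl peptidase
IV (DPP-4) inhibitory peptides: simulate enzymatic hydrolysis of candidate
substrate proteins, featurize the released peptides, score them with a
trained classifier, and map each promising peptide back to the hydrolysis
parameters — the (protein, enzyme) pair — that would produce it. This
vignette documents the underlying models, the tunable parameters and the
numerical and design choices, in enough detail that every result the
package produces can be reproduced and audited.

## Virtual proteolysis

Protease specificity is modeled as a context grammar around the scissile
bond, in the standard P2–P1|P1′–P2′ nomenclature (P1 is the residue
immediately N-terminal of the bond). An enzyme rule is a set of *site
specs*; each spec lists, per context position, an allow-set and/or a
deny-set of residues. A bond is cleaved iff at least one spec matches:
every allow position holds a listed residue and no deny position does.
Context positions that fall outside the protein can never satisfy an allow
constraint and never violate a deny constraint — i.e. terminal bonds are
judged only on the context that exists.

Digestion is *complete* (zero missed cleavages): the released peptides are
the maximal fragments between consecutive cut sites, so concatenating the
fragments always reconstructs the substrate. This models exhaustive
hydrolysis, the regime in which a screening campaign enumerates everything
an enzyme can release; partial digests are out of scope. Coordinates are
0-based half-open throughout (`protein[start:end] == fragment`), and cut
position *k* denotes the bond after the *k*-th residue, so cuts lie in
`[1, L-1]`.

Two rule tables ship as editable YAML (`inst/extdata/enzyme_rules_*.yaml`),
each tagged with a `dialect` and `version`:

* **`milk_panel`** (default): PeptideCutter/BIOPEP-style specificities for
  trypsin, chymotrypsin, two pepsin pH regimes, papain, stem bromelain and
  subtilisin, with the chymotrypsin "not before proline" exception
  *disabled*. The disabling is deliberate: the bovine β-casein C-terminus
  `…EPVLGPVRGPF|PIIV` can only release the validated heptapeptide GPVRGPF
  if the F|P bond is cleavable, so the hydrolysate provenance this package
  is checked against implies a dialect without that exception. The
  broad-specificity plant and microbial proteases (papain, stem bromelain,
  subtilisin) are written as explicit P1 allow-sets because their
  literature specificities are preferences rather than strict rules; the
  table makes the operational choice inspectable and overridable.
* **`expasy`**: the conventional strict form, identical except that
  chymotrypsin carries the P1′ = P exception.

Because published rule tables for these enzymes genuinely differ between
tools, the absolute size of a digest is dialect-dependent; the package
treats peptide counts as order-of-magnitude quantities and exact fragment
identities (provenance retracing) as the hard contract. `retrace()` is the
inverse operation: it returns exactly those (protein, enzyme, start, end)
tuples whose complete digest emits the query peptide.

## Type-2 pseudo amino acid composition

Peptides are encoded with type-2 (amphiphilic) pseudo amino acid
composition. Each of *n* physicochemical property scales is standardized
to zero mean and unit population SD over the 20 canonical residues (so any
affine rescaling of a published table is immaterial). For a peptide
`R_1 … R_L` and standardized scale `H`, the lag-*j* sequence-correlation
factor is

$$\tau_{s,j} = \frac{1}{L-j}\sum_{i=1}^{L-j} H_s(R_i)\,H_s(R_{i+j}),
\qquad j = 1, \dots, k .$$

With residue counts `f_1 … f_20`, the descriptor has `20 + n·k` components

$$x_u = \frac{f_u}{\sum_v f_v + \omega \sum_{s,j}\tau_{s,j}} \quad (u \le 20),
\qquad
x_{20+(s-1)k+j} = \frac{\omega\,\tau_{s,j}}{\sum_v f_v + \omega \sum_{s,j}\tau_{s,j}},$$

ordered scale-major, then lag. The shared normalizer makes the whole
vector sum to exactly 1 (a tested identity, tolerance 1e-9), and ω → 0
recovers plain relative amino-acid composition. Defaults are `k = 1`,
`n = 6`, `ω = 0.05`, giving 26 dimensions. `k` is the maximum lag over
which order information is accumulated (k = 1 already distinguishes most
permutations, but note that lag products are reversal-symmetric: a peptide
and its exact reverse share the same pseudo components); ω balances
composition against order information and at 0.05 keeps the pseudo block a
small perturbation of the composition block. Sequences must have
`L ≥ k + 1`, which for `k = 1` admits every dipeptide and longer.

The six packaged scales — hydrophobicity, hydrophilicity (Hopp–Woods),
side-chain mass, pK1 (α-COOH), pK2 (NH3) and isoelectric point at 25 °C —
are standard published tables shipped as a versioned CSV fixture
(`inst/extdata/property_scales.csv`) with their sources in the header.
Any 20-row table with the same layout can be swapped in; because scales
are standardized before use, only the *shape* of a scale matters.
Descriptors are validated against an independently coded brute-force
implementation in the test suite.

## Classifier benchmark

Five ensemble families are benchmarked under stratified five-fold
cross-validation: GBDT (200 trees, learning rate 0.1), XGBoost
(max_depth 5, learning rate 0.01, L1 α = 10), LightGBM-style leaf-wise
boosting (num_leaves 31, learning rate 0.05, max_bin 255), CatBoost-style
depth-wise boosting (depth 6, learning rate 0.05, 1000 iterations) and
random forest (150 trees, `sqrt` feature sampling).

A backend note: the three non-native boosting families are adapters over
the xgboost engine. The `lightgbm` family uses xgboost's histogram grower
with `grow_policy = "lossguide"` and a leaf cap — the leaf-wise,
binned-histogram algorithm LightGBM introduced — at LightGBM's published
hyperparameters; the `catboost` family uses depth-wise growth at
CatBoost's published depth, rate and iteration count (CatBoost's ordered
boosting and oblivious trees are not reproduced); `gbdt` is exact-greedy
depth-3 boosting. The harness — fold construction, thresholds, metrics,
seeds — is backend-independent and identical across families, so the
comparison isolates the growth strategy and hyperparameters. Grid search
and early stopping are deliberately off by default: they are exposed
nowhere silently, and any report records exactly the configuration that
produced it.

Evaluation uses accuracy, recall, precision and F1 at a *strict* 0.5
probability threshold (a probability of exactly 0.5 is a negative call,
matching the "greater than 50 %" screening gate), with the zero-denominator
conventions Pre := 0 when TP+FP = 0, Rec := 0 when TP+FN = 0, F1 := 0 when
Pre+Rec = 0, so reports are total. AUC is computed as the Mann–Whitney
rank statistic (ties count one half), which equals trapezoidal ROC
integration; the suite verifies both the exhaustive concordant-pair
equivalence (inputs up to 200 samples) and agreement with pROC at a pinned
orientation. Metrics are kept on the [0, 1] scale internally and
multiplied by 100 only for presentation. Cross-validation is a
deterministic function of `(data, seed)`: folds are assigned per class by
seeded shuffling with cyclic allocation, keeping per-fold class counts
within one sample of proportionality.

## The screening pipeline

`screen_peptides()` chains: complete digestion of every protein with every
enzyme → length window (default 3–15 residues, the tractable window for
synthesizable short peptides) → redundancy removal with provenance
merging → PseAAC featurization with the model artifact's *embedded*
configuration → probability prediction → strict `> threshold` gate →
a conjunctive chain of post filters → ranking by descending probability
with lexicographic tie-breaks. A stage log records the surviving count at
every step (tested to be non-increasing), and every retained candidate
carries its full provenance plus per-filter results.

Two deliberate safety properties: a screen aborts on any featurization
config mismatch between artifact and request (silent feature skew is the
classic failure mode of deployed featurized models), and external filter
tables *fail closed* — a candidate with no entry in an adjudication table
is dropped with a warning, never passed by default. The external
adjudication tools themselves (bioactivity ranking, intestinal absorption,
toxicity prediction) are not reimplemented; their outputs are ingested as
CSV tables keyed by sequence, and built-in stub filters support offline
testing. Because filters are conjunctive predicates, the retained set is
invariant under filter reordering (tested).

## Synthetic data: what it emulates, and what it does not

The generator provides the statistical structure the pipeline assumes,
so every stage is testable offline:

* **Labeled sets** — positives drawn residue-wise from a background
  distribution with A/G/L/P/V enriched by a multiplicative factor,
  negatives from the unmodified (uniform) background; lengths uniform on
  3–15. Defaults emulate the curated study conditions: 1,103 positives, an
  equally sized negative class, enrichment factor 3. Factor 1 is the null
  (no signal; cross-validated AUC must sit in [0.4, 0.6]); factor 3 plants
  a recoverable compositional signal (CV AUC ≥ 0.8). Sequences sampled
  into both classes would carry conflicting labels and are dropped from
  both.
* **Substrates with planted cleavage sites** — a peptide is plantable
  under a rule iff none of its internal residues matches the rule's P1
  allow-set and some flanking context cuts it free at both boundaries
  (deny-sets included: e.g. a peptide starting with proline is unplantable
  for trypsin because K|P and R|P bonds are protected). The constructor
  verifies viability by actually digesting the assembled substrate and
  errors on unplantable peptides, naming the offending residue.

What the generator does **not** emulate: real inhibitory peptides carry
positional and motif structure (e.g. penultimate-proline patterns), length
–activity coupling, and curation biases; the synthetic signal is purely
compositional. Consequently, passing the planted-signal tests shows the
pipeline recovers the signal it was given — it does not certify the
real-data metrics. On the emulated set at factor 3 the LightGBM-config CV
AUC is ≈ 0.83 (computed by `scripts/acceptance.R`), below the ≈ 0.92
reported for the real curated training set; the gap is the information the
real data carries beyond composition. Reproducing the published metrics
requires the original curated dataset, which is not redistributable with
this package.

## Problem sizes and numerical choices

The shipped test suite and acceptance script use: 1,000 random substrates
per enzyme (lengths 5–200) for the digestion/oracle equivalence and
reconstruction properties; 2,206 peptides (the emulated study scale) for
the CV benchmark; 250 + 250 for the null check and 500 + 500 for the
planted-signal check; and 150 + 150 planted peptides for the end-to-end
screen-enrichment check — the last chosen so the ranking-AUC estimator's
sampling noise (SE ≈ 0.026) is small relative to the 0.8 acceptance bound.
All randomness flows from explicit integer seeds through a private RNG
scope (callers' RNG state is never touched); identical seeds give
byte-identical folds, datasets, substrates and reports.

Degenerate inputs are defined rather than accidental: constant property
scales are rejected (standardization is undefined); identical feature
vectors give a zero-variance PCA with all-zero scores and explained
variance 0; single-class inputs are errors for training and AUC;
zero-candidate screens produce header-only reports and zeroed stage logs.

## Known limitations

* Cleavage rules are context grammars: no kinetics, pH/temperature
  dependence, hydrolysis degree or exopeptidase trimming; complete
  digestion only (missed-cleavage support would be a config extension).
* The enzyme dialect is an explicit editable choice, not ground truth;
  digest sizes are only comparable within a dialect.
* The `lightgbm`/`catboost` families reproduce those systems' growth
  strategies and hyperparameters on the xgboost engine, not the exact
  implementations; conclusions about family *rankings* transfer only to
  that extent.
* The packaged milk-protein FASTA is a versioned fixture of the canonical
  mature bovine chains; users reproducing a specific study should supply
  their own FASTA for the exact isoforms/variants of interest.
* Scores from external adjudication tools must be supplied as tables;
  the package makes no bioactivity, absorption or toxicity predictions of
  its own.
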