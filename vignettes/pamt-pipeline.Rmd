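---
title: "The pamtriage pipeline: model, evaluation protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pamtriage pipeline: model, evaluation protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamtriage)
```

## The task and its constraints

`pamtriage` classifies emergency-call transcripts into
prehospital-activated major trauma (PAMT) versus non-PAMT. The setting
imposes three constraints that shaped every design choice. First, the
documents are short, urgent and fragmentary, so word *presence* carries
most of the signal and important words tend to be repeated — which
motivates Boolean features and frequency-based term weighting. Second,
labeled corpora in this domain are small (on the order of a hundred
calls), ruling out models that need large samples and favoring a naïve
Bayes classifier that works without hyperparameter tuning. Third, the
costly error is undertriage, so ambiguity should resolve toward the
positive class and a high-sensitivity rule gate is allowed to overrule
the classifier.

## Preprocessing

`preprocess()` composes three operations, in order:

1. **Segmentation.** The default tokenizer case-folds, splits on
   whitespace, then greedily merges adjacent units — longest candidate
   first — whenever the joined string is a term of the segmentation
   dictionary. The dictionary thus acts as a forced-merge list; weight
   magnitudes are stored but only presence matters to the default
   tokenizer, because the scoring semantics of the external Mandarin
   segmenter this emulates are not recoverable and the synthetic data
   is generated at token level anyway. Any deterministic function from
   string to token vector can be plugged in for real text.
2. **Stop-word removal** — an order-preserving set filter.
3. **Synonym grouping.** The map is restricted to a single step: no
   canonical term may itself appear as a variant key, and the lexicon
   constructor rejects chained maps. This makes the operation
   order-independent, idempotent, and trivially testable; the
   alternative (transitive closure at load time) adds semantics the
   domain does not need.

Two invariants are tested property-style: preprocessing never increases
the token count, and it is deterministic and idempotent on re-joined
canonical token streams.

## Feature engineering

Terms are weighted by `tf(t, d) · ln(N / df(t))` with raw counts and an
unsmoothed idf — smoothing is unnecessary because idf is only evaluated
for observed terms, where `df ≥ 1`. Each term's importance is the
**maximum** of its tf-idf over documents: a word mentioned five times in
one call is a stronger severity cue than a word mentioned once in five
calls, and the maximum captures "importance in one specific text"
directly. Sum-over-documents ranking and log-tf / smoothed-idf variants
are available as configuration options for sensitivity analyses
(`term_stats(..., tf =, idf =, ranking =)`).

The top `K = 160` terms (the default mirrors selecting 160 of a ~7000
word vocabulary) form the feature space; ties are broken by bytewise
lexicographic order so selection is deterministic and
locale-independent. `union_with_expert()` appends expert keywords not
already selected, in lexicographic order after the TF-IDF block, and
tags overlaps as `both`. Documents become Boolean presence vectors;
multiplicity is deliberately discarded, which is exactly the Bernoulli
event model of the classifier.

By default the evaluation harness builds **one** feature space from the
whole corpus and reuses it across all CV repeats (`leakage_mode =
"shared_space"`), mirroring an evaluation design in which a single
preselected term list is shared by every repeat. This lets validation
documents influence term selection; the measured performance is
therefore an optimistic estimate of out-of-corpus performance. A
`"strict"` mode re-selects features inside each training fold for
leakage-free estimates. The default reproduces the reference protocol;
the mode switch exists precisely so the two can be compared.

## The classifier

`fit_bnb()` estimates, per class `k` and term `t`,

\[
P(t \mid k) = \frac{n_{kt} + \alpha}{n_k + 2\alpha}, \qquad \alpha = 1,
\]

where `n_kt` counts class-`k` training documents containing `t`. With
`α > 0` every conditional lies strictly in (0, 1), so absent and
never-seen terms contribute finite log-likelihood — the standard
Laplace answer to the zero-probability problem, and with α fixed at 1
the classifier has no hyperparameters to tune. Class priors are the
empirical training frequencies by default (`priors = "uniform"` is the
alternative; nothing in the reference protocol pins the choice, and
empirical priors are the textbook default for naïve Bayes).

Scoring is the full Bernoulli log-likelihood over presence *and*
absence plus the log prior; prediction is the argmax, with exact
posterior ties resolved to PAMT. The tie-break is a documented,
configurable policy choice: in triage, ambiguity should cost a false
alarm, not a missed severe case.

The implementation is validated two independent ways on random toy
instances: against brute-force enumeration of the Bernoulli joint
probability (no logs, no matrix algebra), and against an established
library implementation of Bernoulli naïve Bayes with the same
smoothing.

## The rule gate and model variants

`rule_gate()` fires when a document contains at least `m = 2` of the 37
expert keywords. "Contains at least 2 of the words" is read as two
*distinct* keyword types — one keyword shouted five times does not fire
the gate; `count_mode = "token_occurrences"` flips that reading.
Keywords are matched against post-preprocessing tokens, so they should
be supplied in canonical (post-synonym) form. Monotonicity in `m`
(lowering the threshold never un-fires a document) is tested as a
property.

The four variants wire these parts together: A = gate only (documents
the gate defers on are non-PAMT, since variant A has no other decision
rule); B = TF-IDF space + BNB; C = union space + BNB; PAMT = gate
first, then BNB on the union space. Because the gate can only add
positive predictions, PAMT-variant sensitivity dominates variant C's on
every shared fold when both use the same fitted classifier — a
structural invariant the acceptance suite checks fold-by-fold.

## Evaluation protocol

`split_fixed_composition()` draws exactly 3 positive and 7 negative
validation cases per repeat (without replacement; training on the
complement — 39 + 65 at the default corpus shape), deterministically
from `seed + repeat_index` so repeats are reproducible individually and
in parallel. Fixing the composition makes two identities exact for
*any* predictor: per-repeat `acc = (3·sens + 7·spec)/10`, hence the
same identity for means, and `youden = sens + spec − 1`. The test suite
asserts both to numerical precision, and the acceptance script uses
them to reproduce the published variant table's accuracy and Youden
columns from the sensitivity/specificity columns alone.

Repeats in which no positives (or no negatives) are predicted leave PPV
(or NPV) undefined; these repeats are excluded from that metric's mean
and counted in `undefined_ppv_repeats` / `undefined_npv_repeats` rather
than imputed — imputing 0 or 1 would bias small-validation-set means,
and the count itself is diagnostic (a constant-negative baseline shows
100 undefined-PPV repeats).

For certainty stratification, a case's level is the number of raters
(0–6) who were certain of their own judgment; levels 5–6 pool as
"certain", 0–4 as "uncertain". Model correctness per case is the
fraction of repeats in which the case fell in validation and was
predicted correctly, averaged within level. Averaging fractions (rather
than pooling prediction events) weights each case equally regardless of
how often the random splits sampled it; the reference protocol does not
state its aggregation, so the deterministic, case-weighted reading was
chosen.

`learning_curve()` keeps the validation composition fixed and
subsamples the training pool at each requested size (stratified so both
classes stay present), reporting mean training and validation accuracy
— the classic overfitting diagnostic: small training sets are easy to
fit and generalize poorly. `feature_cooccurrence_correlation()` is the
Pearson correlation of the Boolean indicator columns; constant columns
are flagged undefined instead of silently dropped.

## The synthetic generator

`generator_config()` defaults define the corpus the pipeline is
developed against: 114 calls with exactly 42 positives, a background
vocabulary of 7000 types with Zipf(1.1) frequencies, and 12 severity
keywords with class-conditional occurrence probabilities
(`p_pos > p_neg`, spanning strong cues like "unconscious",
0.55 vs 0.10, and weaker ones like "motorcycle", 0.45 vs 0.22).
Design choices worth stating:

* **Keywords are conditionally independent given the class** — exactly
  the naïve Bayes assumption — so fitted conditionals must recover the
  generator's probabilities and CV accuracy must approach the
  generator's analytic Bayes bound (`bayes_optimal_accuracy()`, exact
  enumeration over presence patterns up to 20 keywords, Monte-Carlo
  beyond). A `keyword_correlation` mode adds pairwise co-occurrence to
  break that assumption deliberately for robustness and
  correlation-analysis tests.
* **Present keywords are mentioned 1 + Poisson(1.5) times.** Urgent
  calls repeat their important words; without repetition a
  single-mention keyword has tf = 1 and max-tf-idf ranking cannot
  distinguish it from background noise, which degenerates the
  TF-IDF-based variants. Presence/absence — all the classifier sees —
  is unaffected.
* **The expert list** (37 entries) is the severity keywords (per
  `expert_overlap_fraction`) padded with *rare* background words from
  deep Zipf ranks. Padding with high-frequency words would make the
  gate fire on essentially every call — ubiquitous words are exactly
  what experts would not nominate.
* **Document lengths**: background token counts are truncated-normal
  (mean 30, SD 17, minimum 5); with ~5-character background words,
  separators, and keyword mentions on top, rendered strings land near
  the target character profile (mean ~241, SD ~107), with positive
  calls longer on average because they carry more keyword mentions.
* **Certainty votes**: each of six raters votes "certain" with
  probability `min(1, 0.1 + 0.18·k)` in the distinct-keyword count `k`,
  each vote replaced by a fair coin with probability `certainty_noise`
  (default 0.1). The slope makes keyword-free calls mostly uncertain
  and saturates at `k ≥ 5`, giving a monotone noiseless limit that is
  directly testable.

What the generator does *not* emulate: real lexical semantics and
discourse (tokens are abstract types), caller emotion, transcription
errors, class-dependent vocabulary beyond the keyword set, and any
correlation between background words and the label. Tests passing on
synthetic corpora therefore validate the *machinery* — estimation,
protocol arithmetic, determinism, structural invariants — not clinical
performance on real calls.

## Numerical and degenerate-input choices

* Tie-breaks: lexicographic (bytewise) for feature ranking; positive
  class for posterior ties; both configurable where meaningful.
* Log-domain scoring with `log1p(-p)` for the absence terms; posteriors
  are normalized via the max-subtraction trick only in tests (the
  classifier itself compares unnormalized log scores).
* Empty documents vectorize to all-false and are classified from priors
  plus absence terms; empty corpora and single-class training sets are
  validation errors, not silent results.
* Model serialization writes probabilities as 17-significant-digit
  decimal strings, so a reloaded model reproduces predictions
  bit-for-bit.
* All harness randomness flows from one master seed with per-repeat
  substreams (`seed + repeat_index`), and generator randomness from the
  config seed, so every artifact of a run is reproducible byte-for-byte.

## Problem sizes used in the checks

The bundled test and acceptance runs use: 200 random toy instances
(≤ 5 features) for the dual-oracle classifier check; 4000-case corpora
(2000 per class) for parameter recovery, with Bonferroni-adjusted
binomial intervals across the 24 simultaneous keyword-by-class
comparisons (family-wise 95% — two dozen marginal 95% intervals would
jointly fail most runs by construction); a 4000-case corpus at 30%
prevalence with 300 CV repeats for convergence to the Bayes bound (the
30% prevalence makes the empirical-prior classifier consistent with the
3:7 composition the bound is computed under); and 100-repeat CV on
study-shaped 114-case corpora for the structural checks. These sizes
put Monte-Carlo error well below the asserted tolerances while keeping
a full run in the seconds-to-minutes range.

## Limitations

The pipeline inherits the reference design's scope: unigram presence
features only (no n-grams, no embeddings), a fixed small feature
budget, and an evaluation that — in its faithful default — shares the
feature space across folds. The default tokenizer is a stand-in
adequate for token-level and Latin-script text; real Mandarin calls
need an external segmenter plugged into the tokenizer contract. And
synthetic validation bounds what can be claimed: the package
demonstrates that the method is implemented correctly, not that the
method's published real-data performance generalizes.
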