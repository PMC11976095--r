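---
title: "Scoring third molar extraction difficulty from report text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring third molar extraction difficulty from report text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molardiff)
```

## The problem and the model

Radiologists reporting cone-beam CT of impacted mandibular third molars
describe, in free prose, the anatomy that determines how hard the surgical
extraction will be. Four features carry most of that signal: the tooth's
angulation relative to its neighbours, the number of roots, the curvature of
those roots (dilaceration being the hard case), and the roots' relationship
to the mandibular canal (nerve-injury risk). `molardiff` turns each report
into an ordinal score per feature, sums the four scores into a total
`S ∈ [4, 14]`, and maps `S` to a difficulty class:
D1 (4–6, easy), D2 (7–8, slightly difficult), D3 (9–10, moderately
difficult), D4 (11 and up, very difficult).

One boundary decision was genuinely open: the published class ranges stop at
13, while the four scale maxima sum to 4+3+3+4 = 14. A total of 14 is
reachable (exactly one feature vector produces it — `enumerate_combinations()`
confirms this), and any total of 11 or more is unambiguously "very
difficult", so D4 here covers 11–14. The 13 is kept as metadata
(`difficulty_classes()$printed_hi`) rather than silently discarded.

```{r}
difficulty_classes()
```

## Preprocessing contract

Rather than binding to a particular NLP engine, the package fixes a
tokenization *contract* so results never depend on a tokenizer version:

* normalization lowercases, maps unicode dashes/quotes to ASCII, strips
  control characters and collapses whitespace — and is idempotent;
* sentences split at `.` and `;`, with guards for abbreviations ("e.g.",
  "no.", single letters) and decimal points;
* tokens are alphanumeric runs; intra-word hyphens and numerals survive
  ("3" in "3 roots" is a token, since root counts appear numerically);
* all offsets are 0-based half-open, and every sentence/token span indexes
  the normalized text exactly (property-tested).

## Concept extraction

Each of the 14 feature categories owns a set of lowercase synonym phrases
(its "concept"). The published description of this dictionary refers to
supplementary tables that are not available, so the default inventory in
`build_default_lexicon()` is an invented, clinically plausible stand-in —
flagged as such — and the whole dictionary is configuration, not algorithm:
it round-trips through YAML/JSON configs and users can load their own.

Matching is greedy longest-match per sentence, with priority = phrase token
length (ties broken lexicographically). Once a span is consumed, shorter
synonyms cannot match inside it; this is what guarantees "no contact" is
matched as the No-contact category and never as a negated "contact".
Explicit negation handling is minimal by design: a mention within three
tokens after a cue ("no", "not", "without", "denies") is dropped, unless the
cue is itself part of a matched phrase. This prevents "not dilacerated" from
scoring 3 without attempting hedge/uncertainty detection, which rule-based
report processing typically leaves out.

Resolution per feature: surviving mentions that agree resolve directly;
disagreements *across* sentences resolve to the last mentioning sentence,
because radiology reports conventionally end with the impression — the
conclusive statement; two categories of one feature inside a single sentence
are surfaced as CONFLICT rather than guessed. A report with any unresolved
feature is INCOMPLETE and is excluded from scoring and training (the same
exclusion applied when assembling real corpora of this kind), but counted
and logged. When a report is both incomplete and conflicted, INCOMPLETE wins:
the exclusion rule is about usability of the report, and an unresolvable
feature makes it unusable regardless of the conflict.

## Classifier

The learning stage is a feed-forward network with 4 input neurons (the
feature scores, each scaled to [0, 1] by its scale maximum — bounded inputs
stabilize training), ReLU hidden layers of 16 and 8 units, and a softmax
over the four classes. That is the smallest standard shape with multiple
hidden layers; the target function (a threshold rule on a weighted sum) is
comfortably inside its capacity, which the 144-combination oracle test
verifies exactly. Training is full-batch Adam (learning rate 0.01) on
cross-entropy, with 15% of the training data held out for early stopping
(patience 50 epochs, best-validation weights restored, cap 800 epochs).
Early stopping is the package's overfitting guard; the original description
of overfitting prevention is not available, so this standard mechanism is a
documented stand-in. Everything is driven by one integer seed: two runs with
the same inputs and seed are bitwise identical.

The implementation is plain base-R linear algebra inside the package. With
four inputs and corpora of a few hundred cases, training takes under a
second on one CPU; tests cross-check its predictions against an
independently fitted `nnet` model on the enumerated combinations.

## Synthetic corpus

Real report corpora of this kind are private, so the generator is a
first-class module that defines the study conditions: 738 reports split 556
train / 182 validation (stratified by class, per-class proportions within
one case of the global ratio), categories drawn uniformly within each
feature — the real prevalence is unpublished, and uniform sampling exercises
every category; the distribution is configurable for imbalance studies.
Each report renders one sentence per feature (random synonym × random
template) interleaved with 2–4 distractor sentences (demographics, sinus
findings, and similar), shuffled. Two noise knobs emulate real-world
degradation:

* `typo_rate` — per-token character perturbations. At most one token inside
  a synonym phrase is ever perturbed per report, so noise degrades but does
  not wholesale destroy extractability; the typical consequence of a synonym
  typo is an INCOMPLETE report (excluded), occasionally a concept error
  (e.g. "no contact" losing its "no" and matching "contact").
* `omission_rate` — drops a feature's sentence entirely, creating reports
  that are gold-incomplete by construction, emulating real reports excluded
  for lacking complete information.

What passing tests on this corpus shows — and does not show. The noise-free
round-trip property (extraction recovers gold on 100% of reports) is a joint
generator–extractor contract: it certifies the matching machinery, not
performance on real prose. Real reports vary in ways the generator does not
emulate (free word order, hedging, misspellings beyond single-character
typos, Persian/English mixtures, multi-tooth reports), so measured
accuracies here are upper bounds on real-data behaviour, not estimates of it.

## Evaluation

`confusion()` builds the 4×4 true-by-predicted matrix;
`classification_metrics()` reports per-class precision/recall/F1 with
zero-denominator cases yielding 0 (not NaN), plus aggregates. The headline
"total" row of such tables is interpreted as unweighted macro averages —
micro variants are also emitted. Pipeline mistakes are categorized, one
category per erroneous report, in fixed precedence:

1. **tokenizer errors** — a gold synonym occurs as a token sequence in the
   full text but inside no single sentence (segmentation broke it);
2. **concept errors** — extraction missed or mis-resolved a feature;
3. **classification errors** — correct features, wrong predicted class.

These operational definitions are declared interpretations: the error
taxonomy this mirrors was never defined operationally in print.

## Problem sizes and numerical choices

The test suite runs corpora of 60–150 reports for property checks and one
738-report run (556/182, `typo_rate = 0.01`) as the scaled analog of the
full experiment; the acceptance script repeats that run from scratch. These
sizes keep a full check-and-verify cycle in the order of a minute while
matching the published corpus dimensions where it matters. Other numerical
choices: softmax is computed with max-shifting; cross-entropy clamps
probabilities at 1e-12; early stopping uses a 1e-8 improvement threshold;
argmax ties break toward the lower class index (the conservative,
easier-difficulty side).

## Known limitations

* The default synonym inventory is a stand-in; serious use requires a
  site-specific lexicon config.
* Negation handling is a fixed 3-token window — no scope parsing.
* One tooth per report is assumed; multi-tooth reports would need mention
  grouping the package does not attempt.
* English-only templates and lexicon.
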