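---
title: "Methods: clinical NER evaluation, label properties, and the synthetic letter simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical NER evaluation, label properties, and the synthetic letter simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokener)
```

## The problem

Deciding whether an acute ischaemic stroke patient can safely receive
thrombolysis requires checking a list of contraindications — recent major
surgery, anticoagulant use, prior intracranial haemorrhage, and so on —
much of which lives in unstructured clinical letters. `strokener` treats
this as a span-level named entity recognition (NER) problem over an
86-entity ontology in five categories (Diagnosis, Symptom, Social history,
Medication, Treatment), and provides the full evaluation and analysis
machinery around it: standoff I/O, an IOB codec, a dictionary baseline, a
token-classifier ensemble contract, strict/lenient scoring, label-property
statistics, and a simulator that generates annotated letters so every
computation is exercisable without protected health data.

Real clinical corpora of this kind cannot be redistributed. The package is
therefore deliberately split into (a) exact, deterministic primitives whose
correctness is testable analytically, and (b) a simulator whose generative
parameters are known, so that statistical behaviour (recall under deletion
noise, the effect of surface-form diversity on dictionary performance) can
be checked against ground truth.

## Offsets, tokenization and the IOB codec

All character offsets are 0-based and half-open, matching the brat
standoff convention, so a `.ann` line `T1\twarfarin 3 11\twarfarin` covers
`substring(text, 4, 11)` in R's 1-based terms. Only text-bound `T` lines
are consumed; note/relation/attribute lines are skipped with a warning.

The tokenizer is deliberately simple and deterministic: a token is a
maximal alphanumeric run or a single non-space punctuation character.
Case is preserved so that offsets remain faithful to the letter text;
every case-insensitive operation normalizes downstream. One normalization
defines "the same span" everywhere in the package — lowercased token
surfaces joined by single spaces — shared by dictionary keys, the
distinct-form count of name regularity, and the in-dict/out-dict
partition. Using a single definition keeps these quantities mutually
consistent (a span is in-dict exactly when the dictionary could have
learned it).

IOB encoding assigns `B-label` to the first token overlapping a span and
`I-label` to the rest. Three boundary policies are worth stating:

- a token **partially** covered by a span is included in the span's tag
  run — the least destructive rule, and harmless under lenient matching;
- **overlapping spans** are rejected by default (the annotation protocol
  implies flat spans); a `keep-longest` flag resolves collisions by span
  length, then earlier start;
- on decoding, an **orphan `I-e`** (no preceding `B-e`/`I-e`) is read as
  `B-e`, the standard repair that keeps decoding total; a label switch
  inside an `I` run similarly opens a new span.

For token-aligned, collision-free spans, decode ∘ encode is the identity;
for spans with mid-token boundaries it snaps to token boundaries.

## The dictionary baseline

The string-search baseline compiles every normalized gold surface form
from training into a form → label map; a form observed under two or more
labels is ambiguous and excluded entirely (not resolved by majority).
Prediction scans token n-grams — matching is anchored at token boundaries,
so a form never fires inside a longer word ("rash" cannot fire inside
"parasthesia"); whether the original exact-string-search formulation
matched inside words is unstated, and boundary anchoring is the defensible
reading. Overlapping candidate hits resolve longest-match-first, then
leftmost. Two structural consequences are covered by tests: perfect strict
self-recall on a clean token-aligned corpus, and strict out-dict recall of
exactly zero (an exact hit implies the form/label pair was in training).

## Strict and lenient matching

A strict pair requires identical (start, end, label); a lenient pair
requires the same label and at least one shared character. Matching is
one-to-one: candidate pairs are ranked by descending character overlap
(ties by earlier gold start, then earlier predicted start), seeded
greedily, and completed by augmenting paths (Kuhn's algorithm) to maximum
cardinality. The published description of such evaluations rarely states
the matching cardinality; we chose maximum-cardinality one-to-one because
(i) it never double-counts a span, (ii) it makes the pair count
well-defined (greedy alone is order-sensitive in tie configurations and
can undercount by up to a factor of two), and (iii) it makes
precision/recall exactly symmetric under swapping gold and predicted
sides. The test suite verifies agreement with an exhaustive bipartite
enumeration on random documents of up to six spans per side.

Aggregation follows standard NER practice: micro metrics pool TP/FP/FN
over labels and documents; macro metrics average per-label metrics over
labels with any gold or predicted support. Zero-denominator convention:
precision (or recall) is 0 when its denominator is 0 and the other side is
non-empty; a label absent from both sides is excluded from the macro
average, keeping macro comparable across models. Because every strict pair
is also a lenient pair and matching is maximum-cardinality, lenient F1 ≥
strict F1 holds per label and overall.

Annotator agreement against consensus gold annotations is the same
computation with the annotator on the prediction side.

## Label properties

Three per-label properties quantify why some labels are harder than
others:

1. **Training-set frequency** N (and its log10).
2. **Name regularity** = (N − N_unique) / (N − 1), where N_unique counts
   distinct normalized forms. The statistic equals 1 when every span is
   identical and 0 when all are distinct. We use the multiplicative
   finite-sample-corrected form — algebraically (1 − N_unique/N) · N/(N−1)
   — because it is the only reading of the defining expression that
   attains both stated limits exactly at every N (an exponent reading
   gives (1 − 1/N)^(N/(N−1)) ≠ 1 for identical spans). N = 1 returns 1 by
   convention.
3. **Context regularity**: for each mention, take up to 5 tokens on each
   side (truncated at document bounds), average their word embeddings,
   L2-normalize, and report the mean pairwise dot product over all
   unordered mention pairs — i.e. the mean pairwise cosine similarity of
   mean context vectors. Out-of-vocabulary tokens are skipped rather than
   zero-filled (zero vectors would dilute the mean); mentions with no
   usable context token are dropped and counted; fewer than two usable
   mentions yields `NA`, not a number. Values lie in [−1, 1]; they are
   only guaranteed non-negative when the embedding space has non-negative
   pairwise similarities.

The embedding source is pluggable (any word2vec-format text table). The
package also ships a deterministic hash-based embedding: each word maps to
a fixed pseudo-random vector from a polynomial byte hash. It carries no
semantics — distinct words are near-orthogonal — but it makes
context-regularity computations deterministic and dependency-free, which
is exactly what the simulator tests need: identical context templates give
similarity 1, diverse templates give lower values.

The regression of per-label **lenient** F1 on [log10 frequency, name
regularity, context regularity] is ordinary least squares with intercept,
classical standard errors and two-sided t-based p-values; rank-deficient
designs raise an explicit singularity error, and labels with undefined
context regularity are dropped and counted.

## Ensembling

A token classifier maps a token sequence to a (tokens × 2N+1) logit
matrix over a shared, ordered tag space. The ensemble averages member
logits elementwise and takes the per-token argmax — averaging logits
rather than probabilities means member calibration matters: a strongly
confident minority can outvote a weak majority, which majority voting
cannot express. Tie-break at equal mean logits: `O` wins if among the
maxima, otherwise the lowest tag index — conservative toward precision.
Invalid transitions surviving the argmax are repaired by the IOB decoder.
A dictionary-backed member realizes the contract for testing (its
single-member ensemble reproduces the string-search predictions exactly),
and a delimited per-token logit file format lets externally trained models
join an ensemble.

## The simulator

`generate_corpus()` assembles letters from a type-specific header,
entity-bearing sentences, and entity-free fillers. Each mention
instantiates a sentence template (from a per-label subset of a 24-template
pool) with a surface form sampled from the label's synonym pool; offsets
are computed during assembly, so gold spans are exact and token-aligned by
construction. The generator is a pure function of its config, including
the mandatory seed.

Defaults emulate the shape of a realistic annotated stroke-letter corpus
at desk scale: 200 patients with 1–6 letters each (mean ≈ 2.8 letters per
patient), the six letter types in the proportions observed in such
collections (GP referrals dominating at ≈ 55%, then discharge and clinic
letters, with emergency-department letters and endoscopy reports rare),
5,000 spans distributed over the 86 labels by a Zipf law (exponent 1) for
a long-tailed label distribution, and the ontology's curated synonym pools.
The test suite scales n down further (typically 10–40 patients, a few
hundred to a few thousand spans) to keep runs fast; the statistical tests
state their binomial/multinomial error budgets explicitly.

Two dials map directly onto the label properties: synonym-pool size
controls name regularity (pool size 1 forces the statistic to 1;
measured regularity decreases strictly through pool sizes 1, 2, 4, 8, 16),
and per-label template-pool size controls context regularity (monotone
decreasing under the hash embeddings).

The noise model perturbs annotations, never text: deletions (the dominant
human error mode), label confusion, boundary jitter, and spurious spans.
Jitter moves one boundary *outward* by 1–`jitter_max` tokens, so a
jittered span always still overlaps the original — strict agreement
degrades while lenient agreement stays perfect, isolating boundary
disagreement from detection failure. Spurious spans cover a random
existing 1–3-token range with a label drawn from the corpus label
distribution; drawing a surface from the synonym pools and "inserting" it
is not possible without editing text and invalidating all other offsets,
so plausibility comes from the label distribution instead.

Patient-level splitting keeps all letters of a patient on one side of the
train/test split and in one fold (default 5 folds; fold sizes differ by at
most one patient), preventing leakage of patient-specific language.

### What passing tests do and do not show

The simulator's language is templated: it reproduces the *structural*
properties that drive the implemented statistics (long-tailed label
frequencies, surface-form diversity, context diversity, annotator error
modes, patient grouping) but not the linguistic messiness of real letters
— abbreviation collisions, negation, clinician shorthand, section
structure, or genuinely ambiguous mentions. Tests passing on simulator
output validate the *machinery* (offset bookkeeping, matching, statistics,
calibration of the noise model against its own parameters); they do not
certify any particular accuracy level on real clinical text, and
real-corpus headline scores are out of scope by design. Within the
simulator this shows up concretely: the dictionary baseline's test errors
are exclusively out-dict misses or ambiguity exclusions, each attributable
via `indict_partition()`.

## Numerical conventions, edge cases, limitations

- F1 is the harmonic mean of precision and recall, 0 when both are 0.
- `name_regularity()` errors on an empty list; N = 1 returns 1.
- Lenient overlap is measured in characters; one shared character
  suffices.
- The matcher's preference order (overlap desc, gold start, pred start)
  makes reports deterministic; augmentation can only add pairs.
- Discontinuous brat spans (semicolon fragments) are unsupported and
  raise an error; duplicated (start, end, label) triples collapse.
- The checklist linkage is display-only: the package surfaces mentions
  next to eligibility questions but never answers a question — answering
  requires modifiers (negation, timeframe) that span detection alone
  cannot provide.
- Numeric thresholds in checklist items (blood pressure, platelets,
  glucose, INR) are carried as text; no numeric extraction is attempted.
- Context regularity pools all mentions of a label across document types;
  computing it within document types would be a straightforward extension
  but fragments support for rare labels.
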