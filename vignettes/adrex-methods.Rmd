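---
title: "adrex: models, design choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{adrex: models, design choices and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical choices, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The task and the pipeline

A drug label is a set of text sections; the goal is (i) to locate mentions
of six entity types — AdverseReaction, Severity, Factor, DrugClass,
Negation, Animal — as exact character spans, and (ii) to map the
AdverseReaction mentions to MedDRA Preferred Terms (PTs), usually through a
Lowest Level Term (LLT) synonym that points at its parent PT.

Two recognition arms share one normalizer. The neural arm needs
sentence-split, tokenized, BIO2-encoded input; the dictionary arm scans raw
section text directly. Offsets are 0-based throughout: a token's `start` is
the number of characters before its first character in the section's raw
text. This convention is load-bearing — every stage (XML, CoNLL,
tokenizer, decoder) checks `substr(section, start + 1, start + length) ==
text`, and the test suite asserts it on every synthetic corpus.

## Preprocessing

**Sentence splitting.** Lines are first classified as table rows (a line
with ≥ 2 runs of ≥ 2 consecutive whitespace characters, or ≥ 2 `|`
delimiters) or prose. Table rows become one "sentence" per line; runs of
prose lines are merged and split at `[.!?]+` followed by whitespace. The
table heuristic is a contract of this package: drug labels contain tabular
blocks that break naive sentence splitters, and the thresholds (2 gaps of
2) are the smallest that do not misclassify ordinary double-spaced prose.
Sentence spans tile the section up to whitespace-only gaps (property
tested).

**Tokenization.** Whitespace split, then leading/trailing punctuation
peeled one character at a time into separate tokens; internal hyphens and
slashes are preserved. This dialect is pinned by a printed worked example
in which "Zydelig-treated" must survive as a single token of length 15
while a sentence-final period becomes its own token — a default Treebank
tokenizer does neither without configuration.

**BIO2.** `encode_bio2` tags the first token of each contiguous mention
fragment `B-<TYPE>`, subsequent tokens `I-<TYPE>`. A span not aligned to
token boundaries is expanded outward to the covering tokens with a warning,
never an error: misaligned gold is a data artifact, and dropping the
mention would silently bias training. `decode_bio2` repairs `I-X` after
`O` (or after a different type) to `B-X` — standard lenient decoding.
Encode and decode are mutually inverse on contiguous non-overlapping
mention sets (property tested on 1,000 seeded sentences).

**Irregular mentions.** Gold data contains overlapping and discontinuous
mentions ("Angioedema of the face, lips, tongue" style, where the head
fragment is shared by several mentions and the tails are discontinuous).
BIO2 cannot represent these, and the source material does not say how they
were flattened for training; the policy here is this package's explicit
choice. `flatten_irregular` cuts the union of each type's spans at every
span boundary, yielding atomic fragments: the shared head is emitted once
and each tail becomes its own contiguous piece. Cross-type overlaps are
resolved by a fixed priority — AdverseReaction > Severity > Factor >
DrugClass > Negation > Animal — chosen because the ADR class is the task's
target and must never lose characters to an auxiliary type. Alternatives
(dropping discontinuous mentions, or merging each mention to its covering
interval) either discard training signal or create spans whose surface text
is not an entity; the fragment policy keeps every gold character with its
type, at the cost of splitting long entities into adjacent chunks.

## The neural tagger

**Inputs.** Each token becomes the concatenation of three parts, 238
dimensions under the defaults:

* *Character CNN (30).* Characters map to learned 30-dimensional
  embeddings; tokens are padded to the length of the longest word in the
  training vocabulary (recomputed per corpus); 30 filters of width 3 and
  stride 1 convolve the character matrix and are max-pooled over windows.
  The padding embedding row is frozen at zero so padding is inconsequential
  to the features.
* *Word embedding (200).* Lookup falls back exact → lowercase → lowercase
  with digit runs replaced by `"0"` → OOV. A pre-trained table in the
  standard text format is an optional input; the default is seeded
  uniform(−0.25, 0.25) initialization, trained with the network, so the
  package builds and its tests run with no downloads.
* *Case one-hot (8).* The classes are numeric, mainly-numeric (> 50%
  digits), all-lower, all-upper, initial-upper, contains-digit, other,
  padding. Only the width (8) is pinned by the source recipe; this
  decomposition is the common one and is fixed here as the contract.

**Network.** Two stacked bidirectional LSTMs (100 then 75 units per
direction) feed a linear layer producing per-tag emission scores, and a
linear-chain CRF with learned `(K+2) × (K+2)` transitions (explicit start
and stop states) defines the sequence distribution. Training minimizes the
mean negative CRF log-likelihood with NADAM (learning rate 2e-3, the usual
default; the source recipe does not state one), batch size 32, and global
gradient-norm clipping at 1.0. Variational dropout (p = 0.25) applies one
mask per Bi-LSTM layer input, identical across time steps, sampled
independently per layer and direction per sentence — whether the original
shared masks across the two stacked layers is unknowable from the text, so
independent sampling (the less coupled choice) is used. Dropout is off at
inference; two predictions on the same input are identical (tested).

**Numerics.** Everything is base-R matrix arithmetic. The forward
algorithm and forward–backward gradients run in log space with
max-shifted `log-sum-exp`; Viterbi breaks ties toward the lowest tag index
at the earliest differing position (the tag set orders `O` first, so an
all-zero model predicts all-`O`). LSTM backpropagation-through-time and
the char-CNN max-routing are verified by finite differences at 1e-3
relative tolerance; CRF partition, Viterbi and gradients are verified
against exhaustive enumeration on instances with T ≤ 5, K ≤ 4 at 1e-8.
CRF transitions are unconstrained during training; BIO2 validity is
enforced only by lenient repair at decode time.

**Early stopping.** 10% of the training corpus (seeded split) is held out;
training stops when held-out mention F1 has not strictly improved for 5
epochs (`max_epochs` 50 as a cap — the source recipe altered the epoch
count without stating it). On F1 ties the most recent weights are kept:
the dev split is small and its F1 saturates within a few epochs, while the
training loss is still falling, and keeping the first saturating epoch
would systematically return an undertrained model.

## Dictionary arm and normalizer

The dictionary is two flat files (PT: id, name; LLT: id, name, parent PT).
Surface forms are normalized by case-folding, treating hyphens as spaces,
and collapsing whitespace. `expand_terms` adds regular plural/singular
variants (last word: consonant-y → -ies; s/x/z/ch/sh → -es; else -s, and
the inverse rules), pointing at the same entry; expansion is a no-op on an
already-expanded dictionary so derived plurals never inflect twice. The
inverse rules are ambiguous on words ending in -ches/-shes ("headaches"
could be headache+s or *headach+es); the rules are applied mechanically and
the spurious singular is a harmless extra index key, because the correct
plural form is always indexed alongside it. Only pluralization is
specified by the source platform's description; further expansion or
exclusion rules are out of contract, and the exclusion list ships empty as
a config input.

Matching scans each sentence left to right, longest token window first,
at token boundaries only (no mid-word hits: "scan" can never hit
"cancer"), skipping excluded forms, and resuming after a match — so
embedded shorter matches are suppressed. Matching is invariant to input
casing (property tested under random case perturbation).

Normalization looks a mention up PT-surface first, then LLT-surface
(resolving to the parent PT), then through inflected variants at each
level. PT-before-LLT makes provenance deterministic when a string is both
a PT name and an LLT (as real releases duplicate); either route yields the
same PT. Duplicate surface forms at one level keep the first mapping with
a warning at load time, so ambiguity is resolved before any matching
happens. Only AdverseReaction mentions are normalized; per label the
distinct PT set is reported, with unmappable mentions counted rather than
dropped.

## Evaluation

Mention scoring is exact-match: a prediction counts iff section, full span
set and type match a distinct gold mention (one-to-one). Conventions:
precision 0 with no predictions, recall 0 with no gold, F1 0 when
p + r = 0. Normalization scoring compares per-label PT sets: micro pools
TP/FP/FN over all (label, pt) pairs; macro averages per-label scores over
drug labels — "per drug" is read as macro-over-labels, not over PT
classes. A label with empty gold and empty prediction scores (1, 1, 1);
with that convention micro and macro are both 1 on a perfectly predicted
corpus that includes mention-free labels. Both scorers are tested against
independently coded brute-force counters on random set pairs.

## The synthetic world

`generate_dictionary` builds PTs from a pseudo-medical word stock (stem ×
suffix combinations like "cardiopathy"), each with a plural LLT, a
multi-word "X of the <organ>" synonym, and modifier variants; ids live in
ranges (2xxxxxxx/3xxxxxxx) that cannot collide with real codes, and no real
terminology strings are shipped. `generate_labels` produces 2–4 sections
of 3–8 template sentences each; a sentence carries planted mentions with
probability `mention_rate` (default 0.3; the corpus-scale tests use 0.5 so
a ~200-sentence corpus contains enough entities to learn from), always an
ADR surface drawn from the dictionary plus one auxiliary-type word from
fixed stocks, with exact offsets recorded at construction. The
`irregular_fraction` knob plants the shared-head discontinuous pattern.
Gold Reactions carry the true PT of every planted ADR. Distractor terms
(out-of-dictionary pseudo-drug names) appear in filler sentences at rate
0.1.

What a green test does establish: offset bookkeeping, round-trips, metric
definitions, CRF correctness, and that the full training loop can learn a
dictionary-membership tagging rule to held-out mention F1 ≥ 0.95 on a
~200-sentence corpus (majority of 3 fixed seeds, ~30 s per seed on one
CPU). What it does not establish: performance on real drug labels — real
sections have richer table structure, spelling variation, rarer entity
contexts and a six-figure terminology, and the published corpus-level
scores are not reproducible without the restricted corpus and licensed
MedDRA. The acceptance suite therefore substitutes property-based checks
(enumeration oracles, round-trip identities, metric oracles, the learning
property, and exact reproduction of the two printed worked examples) for
the published table.

## Known limitations

* The tagger is single-model over all six types; cascading or
  BIOHD-style schemes that handle discontinuous entities natively are
  deliberately out of scope.
* Normalization is dictionary/rule-based only — no fuzzy or
  embedding-similarity linking; an ADR phrased outside the dictionary's
  surface forms (plus regular inflection) is reported unmapped.
* Training is CPU-bound base R: fine at the toy scale it is tested at
  (hundreds of sentences), not engineered for the full 2,309-label corpus.
* The sixth CoNLL column is reserved and ignored; only five column
  semantics are defined by the interchange contract.
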