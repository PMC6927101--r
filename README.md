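# adrex

Extraction of adverse drug reaction (ADR) mentions from structured drug-label
documents, and their normalization to MedDRA Preferred Terms.

## The problem

Drug labels (prescribing information) describe the adverse reactions observed
with a medication in free text. Pharmacovigilance workflows need those
reactions as coded concepts: each textual mention ("cancer", "intestinal
perforation") must be found in the label and mapped to a **MedDRA Preferred
Term** (PT), usually via a **Lowest Level Term** (LLT) synonym. `adrex`
implements both halves of a TAC-ADR-style pipeline:

* **Recognition.** Two interchangeable arms:
  * a **neural sequence tagger** — per-token input vectors built from a
    character-level CNN (30 filters of width 3 over learned character
    embeddings, max-pooled), a 200-dimensional word embedding (with
    lowercase/digit-normalized fallback lookup), and an 8-class one-hot
    casing feature; the 238-dimensional vectors feed two stacked
    bidirectional LSTMs (100 and 75 units) whose outputs score a
    linear-chain **CRF** decoded with Viterbi. Training minimizes the CRF
    negative log-likelihood with NADAM, global gradient-norm clipping at 1,
    and variational dropout (p = 0.25, same mask across time steps). The
    whole network, including backpropagation, is implemented in base R and
    verified against enumeration oracles and finite differences.
  * a **dictionary/rule arm** — case-insensitive longest-match scanning at
    token boundaries against a two-level PT/LLT dictionary expanded with
    regular plural/singular variants, with hyphen/whitespace normalization
    and a configurable exclusion list.
* **Normalization.** Mention strings are looked up PT-surface first, then
  LLT-surface (resolving to the parent PT), then through inflected variants.
* **Evaluation.** Mention-level precision/recall/F1 with exact-span
  one-to-one matching, and micro-/macro-averaged PT-set scores per drug
  label, with the layout of the shared-task result tables.

Sequence labels use the **BIO2** scheme over six mention types
(AdverseReaction, Severity, Factor, DrugClass, Negation, Animal):
`B-ADR I-ADR ... O`, 13 tags in total.

The restricted shared-task corpus and the licensed MedDRA terminology are
**not** required: a seeded generator produces mini PT/LLT dictionaries and
annotated synthetic labels (including discontinuous/overlapping mentions)
with exact gold offsets, so every module is testable offline.

## Formats

* **Label XML** (TAC dialect): `Label/Text/Section` raw text,
  `Mentions/Mention` with 0-based `start`/`len` character offsets
  (comma-joined for discontinuous mentions), and
  `Reactions/Reaction/Normalization` with `meddra_pt_id` etc.
* **CoNLL**: 6 tab-separated columns — token, BIO2 tag, section id, start,
  length, reserved — with blank lines between sentences.
* **Dictionary**: tab-separated `pt.tsv` (`pt_id`, `pt_name`) and `llt.tsv`
  (`llt_id`, `llt_name`, `pt_id`).
* **Word vectors**: standard text format, one token + floats per line.

## Worked example

Offset-preserving tokenization and BIO2 encoding of a label sentence whose
section offset is 2763:

```r
library(adrex)
tok <- tokenize_with_offsets(
  "Fatal and serious intestinal perforation occurred in Zydelig-treated patients.",
  2763L)
tags <- encode_bio2(tok, list(
  adr_mention("Z1", "S3", "AdverseReaction", 2763L, 5L, "Fatal"),
  adr_mention("Z2", "S3", "Severity", 2773L, 7L, "serious"),
  adr_mention("Z3", "S3", "AdverseReaction", 2781L, 22L, "intestinal perforation")))
cbind(tok, tag = tags)
#>               text start length   tag
#> 1            Fatal  2763      5 B-ADR
#> 2              and  2769      3     O
#> 3          serious  2773      7 B-SEV
#> 4       intestinal  2781     10 B-ADR
#> 5      perforation  2792     11 I-ADR
#> 6         occurred  2804      8     O
#> 7               in  2813      2     O
#> 8  Zydelig-treated  2816     15     O
#> 9         patients  2832      8     O
#> 10               .  2840      1     O
```

Each row is one token with its section offset (characters before the token)
and length; `B-ADR`/`I-ADR` mark the beginning/inside of an adverse-reaction
mention, `B-SEV` a severity mention, `O` everything else. Hyphenated
compounds stay single tokens ("Zydelig-treated", length 15).

End-to-end dictionary arm on a synthetic corpus:

```r
gen <- generate_dictionary(8, 3, seed = 42, dir = "demo")
labels <- generate_labels(8, gen, mention_rate = 0.5, seed = 42)
for (k in seq_along(labels))
  write_label_xml(labels[[k]], sprintf("demo/label_%03d.xml", k))
res <- run_pipeline(list(
  arm = "dict", seed = 42, labels = "demo",
  dictionary = list(pt = "demo/pt.tsv", llt = "demo/llt.tsv"),
  output_dir = "demo/out"))
res$report
#> Identification  P 98.4  R 44.1  F1 60.9
#> Normalization (micro)  P 100.0  R 100.0  F1 100.0
#> Normalization (macro)  P 100.0  R 100.0  F1 100.0
```

The dictionary arm recovers every planted ADR and maps it to the right PT
(normalization F1 = 100%), but its identification recall is low by design:
gold mentions span all six types while the dictionary only recognizes ADRs —
the same asymmetry the shared-task tables show between the two arms. The
neural arm (`arm = "ml"`, trained via `train_labels`) tags all six types.

Training and normalizing directly:

```r
corpus <- unlist(lapply(labels, label_to_sentences), recursive = FALSE)
model  <- train_tagger(corpus, config = tagger_config(seed = 1))
pred   <- predict_tags(model, corpus[1])
d      <- expand_terms(gen$dictionary)
normalize_mention("myelosises", d)   # plural of a generated PT name
#> $pt_id   "20000001"
#> $pt_name "Myelosis"
#> $level   "PT"
```

## Command line

```sh
Rscript inst/cli/adrex synth   --out corpus --seed 3 --n-labels 10
Rscript inst/cli/adrex convert --labels corpus --out conll
Rscript inst/cli/adrex train   --labels corpus --model tagger.rds --seed 3
Rscript inst/cli/adrex predict --labels corpus --model tagger.rds --out pred
Rscript inst/cli/adrex dictner --labels corpus --pt corpus/pt.tsv --llt corpus/llt.tsv --out pred
Rscript inst/cli/adrex evaluate --gold corpus --pred pred --report report.json
Rscript inst/cli/adrex run     --config pipeline.yaml
```

`run` consumes a YAML config with the keys documented in `?run_pipeline`
(`arm`, `labels`, `dictionary`, `output_dir`, optional `seed`,
`train_labels`, `model`, `tagger`, `exclusions`, `evaluate`). Every pipeline
run writes a `manifest.json` with the config hash, seed, and input checksums.
Exit codes: 0 success, 2 config error, 3 data validation error.

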