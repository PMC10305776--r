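# strokener

Span-level clinical named entity recognition (NER) tooling for surfacing
**contraindications to thrombolysis** in acute ischaemic stroke from
unstructured clinical letters.

Thrombolysis (intravenous clot-dissolving treatment) is time-critical and
contraindicated by bleeding-risk factors — recent major surgery,
anticoagulant medication, prior intracranial haemorrhage — that are
typically buried in free-text discharge letters, referrals and clinic
letters. `strokener` provides the machinery to find and evaluate mentions
of the relevant concepts:

- an **86-entity stroke ontology** in five categories (Diagnosis, Symptom,
  Social history, Medication, Treatment), with per-entity synonym seed
  pools and the hospital eligibility-checklist linkage;
- **brat standoff I/O** (paired `.txt`/`.ann` files, 0-based half-open
  character offsets) and a line-delimited JSON corpus format;
- a deterministic, offset-preserving **tokenizer** and the **IOB tag
  codec**: N entity classes induce a 2N+1 tag space (86 entities → 173
  tags), `B-entity` on the first token of a span, `I-entity` on the rest,
  `O` elsewhere;
- an exact **string-search dictionary baseline**: every normalized surface
  form observed with exactly one label in training maps to that label;
  ambiguous forms are dropped; prediction is token-boundary-anchored,
  longest-match-first;
- **strict/lenient evaluation**: strict matching requires identical span
  boundaries and label, lenient requires the label plus any character
  overlap; one-to-one maximum-cardinality matching; micro (pooled counts)
  and macro (per-label average) precision/recall/F1, annotator-agreement
  scoring, and the in-dict/out-dict recall partition that diagnoses name
  memorisation;
- **logit-averaging ensembling** over a pluggable token-classifier
  contract (elementwise mean of member logits, per-token argmax), with a
  dictionary-backed member and a file-based logit interchange format;
- **label-property statistics**: training-set frequency; *name
  regularity* — for N spans of a label with N_unique distinct normalized
  forms,

  ```
  (N − N_unique) / (N − 1)
  ```

  which is 1 when every span is identical and 0 when every span is
  distinct; and *context regularity* — the mean pairwise cosine similarity
  of the mean word-embedding vectors of the ±5-token windows around a
  label's mentions — plus an OLS regression of per-label lenient F1 on
  these three properties;
- a **synthetic annotated-letter simulator** with controllable label
  frequencies (Zipf), synonym-pool and context-template diversity, an
  annotator-noise model (deletion, boundary jitter, label confusion,
  spurious spans) and patient-level train/test/fold splitting, so every
  computation above is testable without access to protected health data.

## Worked example

Generate a synthetic corpus whose 30 labels differ in synonym-pool size
(hence in name regularity), train the dictionary baseline, evaluate, and
regress per-label F1 on the label properties:

```r
library(strokener)
ont <- load_default_ontology()
labels30 <- ont$entities$entity[1:30]
pools <- setNames(lapply(seq_along(labels30), function(i) {
  k <- rep(c(1L, 2L, 4L, 8L, 16L), 6)[i]
  sprintf("%s variant %02d", gsub("-", " ", labels30[i]), seq_len(k))
}), labels30)
docs <- generate_corpus(corpus_config(seed = 912, n_patients = 120,
  total_spans = 6000, labels = labels30, synonym_pools = pools))
sp    <- split_patients(docs, seed = 913)
dict  <- compile_dictionary(sp$train)
preds <- lapply(sp$test, function(d)
  ner_document(d$text, dict_predict(d, dict), doc_id = d$doc_id,
               patient_id = d$patient_id, doc_type = d$doc_type))
score_corpus(sp$test, preds, "lenient")
#> <eval_report> lenient matching over 91 documents, 30 labels
#>   micro P/R/F1: 1.000 / 0.995 / 0.998
#>   macro P/R/F1: 1.000 / 0.984 / 0.991

indict_partition(sp$train, sp$test, preds, "strict")[1:2]
#> $recall_in_dict  [1] 1
#> $recall_out_dict [1] 0

props <- compute_label_properties(sp$train, hash_embeddings(16))
regress_f1(props, score_corpus(sp$test, preds, "lenient")$per_label)
#> <f1_regression> per-label F1 on label properties; n = 30 labels, r^2 = 0.575
#>                 term     beta     se        p
#> 1        (Intercept)  0.78304 0.0529 3.49e-14
#> 2    log10_frequency -0.00975 0.0164 5.58e-01
#> 3    name_regularity  0.27996 0.0520 1.21e-05
#> 4 context_regularity -0.03418 0.0449 4.54e-01
```

Reading the output: the dictionary baseline recalls every test span whose
normalized surface/label pair occurred in training (in-dict recall 1) and,
by construction, none of the novel surfaces (strict out-dict recall 0).
Across labels, **name regularity is the dominant predictor of per-label
F1** — labels with fewer distinct surface forms are easier — while raw
training frequency and context regularity add nothing here.

A per-letter surfacing report groups detected mentions by category with
context snippets and flags linked eligibility-checklist items:

```r
render_report(docs[[1]])
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "strokener-cli.R", package = "strokener"))')
Rscript $CLI generate --config cfg.yaml --out corpus
Rscript $CLI split --in corpus --out split --seed 3
Rscript $CLI compile-dict --in split/train --out dict.tsv
Rscript $CLI predict --in split/test --dict dict.tsv --out preds
Rscript $CLI evaluate --gold split/test --pred preds --mode lenient
Rscript $CLI report --in corpus --format html --out report.html
```

Subcommands: `generate`, `split`, `perturb`, `compile-dict`, `predict`,
`ensemble`, `evaluate`, `agreement`, `properties`, `regress`, `report`.

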