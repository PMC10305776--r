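test_that("generation is deterministic and spans satisfy all invariants", {
  cfg <- corpus_config(seed = 101, n_patients = 15, total_spans = 200,
                       labels = load_default_ontology()$entities$entity[1:12])
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(lapply(a, `[[`, "text"), lapply(b, `[[`, "text"))
  expect_identical(lapply(a, `[[`, "spans"), lapply(b, `[[`, "spans"))
  expect_equal(sum(vapply(a, function(d) nrow(d$spans), 0L)), 200L)
  for (d in a) {
    validate_spans(d$spans, d$text)
    tok <- tokenize(d$text)
    # every span is token-aligned under the package tokenizer
    expect_true(all(d$spans$start %in% tok$start))
    expect_true(all(d$spans$end %in% tok$end))
    expect_true(d$doc_type %in% c("GP referral", "IDL", "FDL", "OPCL",
                                  "ED Letter", "Endoscopy report"))
  }
})

test_that("single-form pools yield name regularity exactly 1 per label", {
  labels <- load_default_ontology()$entities$entity[c(1, 20, 50, 70)]
  cfg <- corpus_config(seed = 33, n_patients = 20, total_spans = 300,
                       labels = labels, pool_size = 1)
  props <- compute_label_properties(generate_corpus(cfg))
  expect_true(all(props$name_regularity == 1))
})

test_that("label frequencies follow the configured long-tail targets", {
  labels <- load_default_ontology()$entities$entity[1:10]
  cfg <- corpus_config(seed = 202, n_patients = 60, total_spans = 5000,
                       labels = labels, zipf_exponent = 1)
  docs <- generate_corpus(cfg)
  counts <- table(factor(unlist(lapply(docs, function(d) d$spans$label)),
                         levels = labels))
  w <- (1:10)^-1
  expected <- 5000 * w / sum(w)
  # multinomial sampling error: chi-square test should not reject
  pval <- stats::chisq.test(as.integer(counts), p = w / sum(w))$p.value
  expect_true(pval > 0.001)
  expect_true(all(abs(counts - expected) / sqrt(expected) < 5))
})

test_that("empty or unknown pools are rejected with the label named", {
  expect_error(corpus_config(seed = 1, labels = c("stroke", "nonexistent")),
               "nonexistent")
  expect_error(corpus_config(seed = 1, labels = "stroke",
                             synonym_pools = list(stroke = character())),
               "stroke")
  expect_error(corpus_config(n_patients = 5), "seed")
})

test_that("zero noise is the identity and deletion thins recall", {
  docs <- generate_corpus(corpus_config(
    seed = 71, n_patients = 30, total_spans = 2500,
    labels = load_default_ontology()$entities$entity[1:20]))
  clean <- perturb_annotations(docs, noise_config(), seed = 5)
  expect_identical(lapply(clean, `[[`, "spans"), lapply(docs, `[[`, "spans"))
  noisy <- perturb_annotations(docs, noise_config(deletion_prob = 0.1),
                               seed = 5)
  rep <- agreement(noisy, docs, "strict")
  n <- sum(vapply(docs, function(d) nrow(d$spans), 0L))
  se <- sqrt(0.9 * 0.1 / n)
  expect_true(abs(rep$micro["recall"] - 0.9) < 3 * se)
  expect_equal(unname(rep$micro["precision"]), 1)
})

test_that("boundary jitter breaks strict but never lenient agreement", {
  docs <- generate_corpus(corpus_config(
    seed = 72, n_patients = 20, total_spans = 400,
    labels = load_default_ontology()$entities$entity[1:10]))
  jit <- perturb_annotations(docs, noise_config(jitter_prob = 0.5,
                                                jitter_max = 2),
                             seed = 8)
  expect_equal(unname(agreement(jit, docs, "lenient")$micro["f1"]), 1)
  expect_true(agreement(jit, docs, "strict")$micro["f1"] < 1)
})

test_that("spurious and confusion noise create the expected error types", {
  docs <- generate_corpus(corpus_config(
    seed = 73, n_patients = 15, total_spans = 300,
    labels = load_default_ontology()$entities$entity[1:8]))
  spur <- perturb_annotations(docs, noise_config(spurious_rate = 1),
                              seed = 3)
  rep <- agreement(spur, docs, "strict")
  expect_true(rep$micro["precision"] < 1)
  expect_equal(unname(rep$micro["recall"]), 1)
  conf <- perturb_annotations(docs, noise_config(confusion_prob = 0.3),
                              seed = 3)
  rep2 <- agreement(conf, docs, "lenient")
  expect_true(rep2$micro["recall"] < 1)  # label flips hurt both sides
  expect_true(rep2$micro["precision"] < 1)
})

test_that("patient-level splits never straddle and folds balance", {
  docs <- generate_corpus(corpus_config(
    seed = 88, n_patients = 57, total_spans = 300, labels = "stroke"))
  sp <- split_patients(docs, test_fraction = 0.3, k_folds = 5, seed = 12)
  train_p <- unique(vapply(sp$train, `[[`, "", "patient_id"))
  test_p <- unique(vapply(sp$test, `[[`, "", "patient_id"))
  expect_equal(length(intersect(train_p, test_p)), 0L)
  expect_equal(length(sp$fold), length(sp$train))
  # all documents of one patient share a fold
  by_pat <- tapply(sp$fold, vapply(sp$train, `[[`, "", "patient_id"),
                   function(f) length(unique(f)))
  expect_true(all(by_pat == 1L))
  # fold sizes differ by at most one patient
  fold_pat <- table(sp$patient_folds[train_p])
  expect_true(max(fold_pat) - min(fold_pat) <= 1L)
  expect_equal(sort(unique(as.integer(names(fold_pat)))), 1:5)
  expect_error(split_patients(docs, k_folds = 1), "k_folds")
})

test_that("sweeping synonym pool size decreases measured name regularity", {
  labels <- c("warfarin", "aspirin", "stroke")
  pools <- lapply(c(1, 2, 4, 8, 16), function(k) {
    stats::setNames(lapply(labels, function(l)
      sprintf("%s variant %02d", l, seq_len(k))), labels)
  })
  vals <- vapply(pools, function(p) {
    docs <- generate_corpus(corpus_config(
      seed = 500, n_patients = 20, total_spans = 600, labels = labels,
      synonym_pools = p, zipf_exponent = 0))
    mean(compute_label_properties(docs)$name_regularity)
  }, 0)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1)
})

test_that("sweeping context template pool size decreases context regularity", {
  vals <- vapply(c(1L, 4L, 12L, 24L), function(k) {
    docs <- generate_corpus(corpus_config(
      seed = 600, n_patients = 20, total_spans = 400,
      labels = c("warfarin", "stroke"), context_pool_size = k,
      zipf_exponent = 0))
    mean(compute_label_properties(docs,
                                  hash_embeddings(16))$context_regularity)
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("YAML configs round-trip into equivalent corpora", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9",
               "n_patients: 6",
               "total_spans: 40",
               "labels: [warfarin, stroke]",
               "context_pool_size: 3",
               "synonym_pools:",
               "  warfarin: [warfarin, coumadin]",
               "  stroke: [stroke]"), path)
  cfg <- read_corpus_config(path)
  direct <- corpus_config(seed = 9, n_patients = 6, total_spans = 40,
                          labels = c("warfarin", "stroke"),
                          context_pool_size = 3,
                          synonym_pools = list(warfarin = c("warfarin",
                                                            "coumadin"),
                                               stroke = "stroke"))
  expect_identical(lapply(generate_corpus(cfg), `[[`, "text"),
                   lapply(generate_corpus(direct), `[[`, "text"))
})
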