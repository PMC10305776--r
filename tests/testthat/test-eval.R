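test_that("boundary-slack prediction matches leniently but not strictly", {
  text <- "Patient on warfarin"
  gold <- entity_spans(11, 19, "warfarin", text = text)   # [O, O, B-warfarin]
  pred <- entity_spans(8, 19, "warfarin", text = text)    # [O, B-w, I-w]
  len <- match_spans(gold, pred, "lenient")
  expect_equal(nrow(len$pairs), 1L)
  expect_equal(length(len$fp), 0L)
  expect_equal(length(len$fn), 0L)
  str <- match_spans(gold, pred, "strict")
  expect_equal(nrow(str$pairs), 0L)
  expect_equal(length(str$fp), 1L)
  expect_equal(length(str$fn), 1L)
})

test_that("matching is one-to-one and label-aware", {
  text <- "aaaa bbbb cccc"
  gold <- entity_spans(0, 9, "weakness", text = text)
  pred <- entity_spans(c(0, 5), c(4, 9), c("weakness", "weakness"),
                       text = text)
  m <- match_spans(gold, pred, "lenient")
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(length(m$fp), 1L)
  # label mismatch blocks a lenient pair
  wrong <- entity_spans(0, 9, "fever", text = text)
  expect_equal(nrow(match_spans(gold, wrong, "lenient")$pairs), 0L)
  # identical span sets pair fully in both modes
  m2 <- match_spans(pred, pred, "strict")
  expect_equal(nrow(m2$pairs), 2L)
})

test_that("greedy matching equals exhaustive bipartite pairing when small", {
  set.seed(404)
  labels <- c("stroke", "fever", "weakness")
  for (rep_i in 1:60) {
    n_g <- sample(0:6, 1); n_p <- sample(0:6, 1)
    mk <- function(n) {
      if (n == 0L) return(entity_spans())
      s <- sample(0:30, n, replace = TRUE)
      e <- s + sample(1:8, n, replace = TRUE)
      entity_spans(s, e, sample(labels, n, replace = TRUE),
                   surface = strrep("x", e - s))
    }
    gold <- mk(n_g); pred <- mk(n_p)
    for (mode in c("strict", "lenient")) {
      got <- nrow(match_spans(gold, pred, mode)$pairs)
      expect_equal(got, oracle_max_pairs(gold, pred, mode),
                   info = paste(mode, rep_i))
    }
  }
})

test_that("corpus scoring pools counts and averages correctly", {
  t1 <- "aspirin and warfarin and fever today"
  t2 <- "stroke with weakness noted"
  t3 <- "no entities in this one"
  gold <- list(
    make_doc(t1, c(0L, 12L, 25L), c(7L, 20L, 30L),
             c("aspirin", "warfarin", "fever"), doc_id = "d1"),
    make_doc(t2, c(0L, 12L), c(6L, 20L), c("stroke", "weakness"),
             doc_id = "d2"),
    make_doc(t3, doc_id = "d3"))
  pred <- list(
    # aspirin exact (TP), warfarin missed (FN), fever shifted (lenient TP),
    # one spurious aspirin (FP)
    make_doc(t1, c(0L, 21L, 32L), c(7L, 30L, 36L),
             c("aspirin", "fever", "aspirin"), doc_id = "d1"),
    make_doc(t2, c(0L), c(6L), "stroke", doc_id = "d2"),
    make_doc(t3, c(3L), c(11L), "weakness", doc_id = "d3"))
  rep <- score_corpus(gold, pred, "strict")
  # hand counts: TP aspirin 1, stroke 1; FP aspirin 1, fever 1, weakness 1;
  # FN warfarin 1, fever 1, weakness 1
  pl <- rep$per_label
  expect_equal(pl$tp[pl$label == "aspirin"], 1L)
  expect_equal(pl$fp[pl$label == "aspirin"], 1L)
  expect_equal(pl$fn[pl$label == "warfarin"], 1L)
  expect_equal(pl$fn[pl$label == "fever"], 1L)
  expect_equal(sum(pl$tp), 2L)
  expect_equal(sum(pl$fp), 3L)
  expect_equal(sum(pl$fn), 3L)
  expect_equal(unname(rep$micro["precision"]), 2 / 5)
  expect_equal(unname(rep$micro["recall"]), 2 / 5)
  lenient <- score_corpus(gold, pred, "lenient")
  expect_equal(sum(lenient$per_label$tp), 3L)  # fever now pairs
  # micro counts always equal the per-label sums
  expect_equal(sum(lenient$per_label$fp), 2L)
  expect_equal(sum(lenient$per_label$fn), 2L)
})

test_that("degenerate prediction sets follow the zero-denominator rules", {
  gold <- list(make_doc("stroke here", 0L, 6L, "stroke"))
  none <- list(make_doc("stroke here"))
  rep <- score_corpus(gold, none, "strict")
  expect_equal(unname(rep$micro), c(0, 0, 0))
  perfect <- score_corpus(gold, gold, "lenient")
  expect_equal(unname(perfect$micro), c(1, 1, 1))
  expect_equal(unname(perfect$macro), c(1, 1, 1))
  expect_error(score_corpus(gold, list(make_doc("x", doc_id = "zz"))),
               "doc_id")
})

test_that("lenient scores dominate strict and swapping sides swaps P and R", {
  docs <- generate_corpus(corpus_config(
    seed = 31, n_patients = 20, total_spans = 250,
    labels = load_default_ontology()$entities$entity[1:12]))
  noisy <- perturb_annotations(
    docs, noise_config(deletion_prob = 0.15, jitter_prob = 0.2,
                       spurious_rate = 0.5, confusion_prob = 0.05),
    seed = 99)
  str <- score_corpus(docs, noisy, "strict")
  len <- score_corpus(docs, noisy, "lenient")
  expect_true(len$micro["f1"] >= str$micro["f1"])
  expect_true(all(len$per_label$f1 >= str$per_label$f1 - 1e-12))
  swapped <- score_corpus(noisy, docs, "lenient")
  expect_equal(unname(swapped$micro["precision"]),
               unname(len$micro["recall"]))
  expect_equal(unname(swapped$micro["recall"]),
               unname(len$micro["precision"]))
})

test_that("annotator agreement reflects simulated deletion noise", {
  docs <- generate_corpus(corpus_config(
    seed = 77, n_patients = 40, total_spans = 600,
    labels = load_default_ontology()$entities$entity[1:15]))
  same <- agreement(docs, docs, "strict")
  expect_equal(unname(same$micro["f1"]), 1)
  half <- list(make_doc("stroke and fever", c(0L, 11L), c(6L, 16L),
                        c("stroke", "fever")))
  ann <- list(make_doc("stroke and fever", 0L, 6L, "stroke"))
  expect_equal(unname(agreement(ann, half, "strict")$micro["recall"]), 0.5)
})

test_that("in-dict/out-dict partition separates seen from novel surfaces", {
  train <- list(make_doc("on warfarin", 3L, 11L, "warfarin"))
  t2 <- "takes Warfarin or coumadin"
  gold <- list(make_doc(t2, c(6L, 18L), c(14L, 26L),
                        c("warfarin", "warfarin")))
  pred <- list(make_doc(t2, 6L, 14L, "warfarin"))
  pt <- indict_partition(train, gold, pred, "strict")
  expect_equal(pt$n_in, 1L)   # "Warfarin" normalizes to the seen form
  expect_equal(pt$n_out, 1L)  # "coumadin" is novel
  expect_equal(pt$recall_in_dict, 1)
  expect_equal(pt$recall_out_dict, 0)
  # dictionary baseline structurally has strict out-dict recall 0: an exact
  # hit implies the normalized form/label pair was compiled from training
  docs <- generate_corpus(corpus_config(
    seed = 13, n_patients = 40, total_spans = 500,
    labels = load_default_ontology()$entities$entity[40:60]))
  sp <- split_patients(docs, seed = 2)
  d <- compile_dictionary(sp$train)
  preds <- dict_predict_corpus(sp$test, d)
  pt2 <- indict_partition(sp$train, sp$test, preds, "strict")
  expect_true(pt2$n_out > 0L)
  expect_equal(pt2$recall_out_dict, 0)
  expect_true(pt2$recall_in_dict > 0.95)
})
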