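# Fixture builders and independent oracles used across the suite.

# Wrap a text + span triples into a document without an ontology check.
make_doc <- function(text, start = integer(), end = integer(),
                     label = character(), doc_id = "doc1",
                     patient_id = "pat1", doc_type = "FDL") {
  ner_document(text, entity_spans(start, end, label, text = text),
               doc_id = doc_id, patient_id = patient_id, doc_type = doc_type)
}

# Replace a document's spans (e.g. to carry predictions) keeping identity.
with_spans <- function(doc, spans) {
  ner_document(doc$text, spans, doc_id = doc$doc_id,
               patient_id = doc$patient_id, doc_type = doc$doc_type)
}

# Predict with the dictionary baseline over a corpus, as documents.
dict_predict_corpus <- function(docs, dict) {
  lapply(docs, function(d) with_spans(d, dict_predict(d, dict)))
}

# Exhaustive optimal one-to-one bipartite matcher: maximum number of
# admissible (gold, pred) pairs, by recursion over gold spans. Admissibility
# mirrors the match modes: exact triple (strict) or label + overlap
# (lenient). Independent of the greedy implementation under test.
oracle_max_pairs <- function(gold, pred, mode) {
  admissible <- function(g, p) {
    if (gold$label[g] != pred$label[p]) return(FALSE)
    if (mode == "strict") {
      gold$start[g] == pred$start[p] && gold$end[g] == pred$end[p]
    } else {
      min(gold$end[g], pred$end[p]) > max(gold$start[g], pred$start[p])
    }
  }
  best <- 0L
  recurse <- function(g, used_p, n_pairs) {
    if (g > nrow(gold)) {
      best <<- max(best, n_pairs)
      return(invisible())
    }
    recurse(g + 1L, used_p, n_pairs)  # leave gold span g unmatched
    for (p in seq_len(nrow(pred))) {
      if (!used_p[p] && admissible(g, p)) {
        used_p[p] <- TRUE
        recurse(g + 1L, used_p, n_pairs + 1L)
        used_p[p] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nrow(pred)), 0L)
  best
}

# Normal-equations OLS oracle: coefficients of y on columns of X (with
# intercept prepended), classical SEs, and r^2 -- no lm() involved.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  XtX <- t(X1) %*% X1
  beta <- solve(XtX, t(X1) %*% y)
  resid <- y - X1 %*% beta
  df <- length(y) - ncol(X1)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  tval <- beta / se
  list(beta = as.vector(beta), se = se, r2 = r2,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

# Small deterministic embedding table for word2vec round-trip tests.
write_tiny_word2vec <- function(path) {
  lines <- c("4 3",
             "patient 1 0 0",
             "on 0 1 0",
             "warfarin 0 0 1",
             "daily 0.6 0.8 0")
  writeLines(lines, path)
  path
}
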