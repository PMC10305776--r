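#' Match predicted spans against gold spans
#'
#' Strict matching pairs spans with identical (start, end, label). Lenient
#' matching pairs spans whose labels agree and whose character intervals
#' overlap by at least one character. Matching is one-to-one and of maximum
#' cardinality: an initial greedy pass ranks candidate pairs by descending
#' character overlap (ties broken by earlier gold start then earlier
#' predicted start), and an augmenting-path completion then guarantees the
#' pair count equals that of an optimal bipartite matching, so no span is
#' double-counted and none is left unmatched when a valid partner exists.
#'
#' @param gold,pred Entity span tibbles from one document.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return Object of class \code{match_result}: list with \code{pairs}
#'   (tibble of \code{gold}, \code{pred} row indices and \code{overlap}),
#'   \code{fn} (unmatched gold row indices), \code{fp} (unmatched predicted
#'   row indices) and \code{mode}.
#' @export
match_spans <- function(gold, pred, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  pairs <- tibble::tibble(gold = integer(), pred = integer(),
                          overlap = integer())
  if (ng > 0L && np > 0L) {
    cand <- expand.grid(g = seq_len(ng), p = seq_len(np))
    ov <- pmin(gold$end[cand$g], pred$end[cand$p]) -
      pmax(gold$start[cand$g], pred$start[cand$p])
    same_lab <- gold$label[cand$g] == pred$label[cand$p]
    keep <- if (mode == "strict") {
      same_lab & gold$start[cand$g] == pred$start[cand$p] &
        gold$end[cand$g] == pred$end[cand$p]
    } else {
      same_lab & ov > 0L
    }
    cand <- cand[keep, , drop = FALSE]; ov <- ov[keep]
    ord <- order(-ov, gold$start[cand$g], pred$start[cand$p])
    # adjacency per gold span, partners in descending-overlap preference
    adj <- vector("list", ng)
    for (k in ord) adj[[cand$g[k]]] <- c(adj[[cand$g[k]]], cand$p[k])
    match_of_p <- rep(NA_integer_, np)  # pred -> gold
    visited <- logical(np)              # shared per augmentation attempt
    try_assign <- function(g) {
      for (p in adj[[g]]) {
        if (visited[p]) next
        visited[p] <<- TRUE
        if (is.na(match_of_p[p]) || try_assign(match_of_p[p])) {
          match_of_p[p] <<- g
          return(TRUE)
        }
      }
      FALSE
    }
    # greedy pass in preference order, then augmenting-path completion
    g_free <- rep(TRUE, ng)
    for (k in ord) {
      g <- cand$g[k]; p <- cand$p[k]
      if (g_free[g] && is.na(match_of_p[p])) {
        g_free[g] <- FALSE; match_of_p[p] <- g
      }
    }
    for (g in which(g_free)) {
      visited <- logical(np)
      if (try_assign(g)) g_free[g] <- FALSE
    }
    matched_p <- which(!is.na(match_of_p))
    if (length(matched_p)) {
      gm <- match_of_p[matched_p]
      ovm <- pmin(gold$end[gm], pred$end[matched_p]) -
        pmax(gold$start[gm], pred$start[matched_p])
      o2 <- order(gm)
      pairs <- tibble::tibble(gold = gm[o2], pred = matched_p[o2],
                              overlap = as.integer(ovm[o2]))
    }
  }
  structure(list(pairs = pairs,
                 fn = setdiff(seq_len(ng), pairs$gold),
                 fp = setdiff(seq_len(np), pairs$pred),
                 mode = mode),
            class = "match_result")
}

prf <- function(tp, fp, fn) {
  # zero-denominator convention: a ratio with denominator 0 is 0 when the
  # other side is non-empty; a label with no gold and no predictions never
  # reaches this function (excluded upstream)
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Score predictions over a corpus
#'
#' Computes per-label true positives, false positives and false negatives
#' by matching spans document-by-document (see \code{\link{match_spans}}),
#' then aggregates. Micro metrics pool counts over all labels and documents;
#' macro metrics average per-label precision/recall/F1 over labels with any
#' gold or predicted support. Precision (or recall) is 0 when its
#' denominator is 0.
#'
#' @param gold_docs List of \code{ner_document} carrying gold spans.
#' @param pred_docs List of \code{ner_document} carrying predicted spans,
#'   aligned with \code{gold_docs} by \code{doc_id}.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return Object of class \code{eval_report}: list with \code{per_label}
#'   (tibble: label, tp, fp, fn, precision, recall, f1), \code{micro} and
#'   \code{macro} (named numeric vectors) and \code{mode}.
#' @export
score_corpus <- function(gold_docs, pred_docs, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  gid <- vapply(gold_docs, `[[`, "", "doc_id")
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!setequal(gid, pid) || anyDuplicated(gid) || anyDuplicated(pid))
    stop("gold and predicted document sets must carry the same unique doc_ids")
  pred_docs <- pred_docs[match(gid, pid)]
  labels <- sort(unique(c(
    unlist(lapply(gold_docs, function(d) d$spans$label)),
    unlist(lapply(pred_docs, function(d) d$spans$label)))))
  tp <- fp <- fn <- stats::setNames(integer(length(labels)), labels)
  for (i in seq_along(gold_docs)) {
    g <- gold_docs[[i]]$spans; p <- pred_docs[[i]]$spans
    m <- match_spans(g, p, mode)
    if (nrow(m$pairs)) {
      t <- table(g$label[m$pairs$gold])
      tp[names(t)] <- tp[names(t)] + as.integer(t)
    }
    if (length(m$fn)) {
      t <- table(g$label[m$fn]); fn[names(t)] <- fn[names(t)] + as.integer(t)
    }
    if (length(m$fp)) {
      t <- table(p$label[m$fp]); fp[names(t)] <- fp[names(t)] + as.integer(t)
    }
  }
  per <- tibble::tibble(label = labels, tp = as.integer(tp),
                        fp = as.integer(fp), fn = as.integer(fn))
  met <- t(vapply(seq_len(nrow(per)),
                  function(i) prf(per$tp[i], per$fp[i], per$fn[i]),
                  c(precision = 0, recall = 0, f1 = 0)))
  per <- cbind(per, tibble::as_tibble(met))
  micro <- prf(sum(per$tp), sum(per$fp), sum(per$fn))
  macro <- if (nrow(per)) {
    c(precision = mean(per$precision), recall = mean(per$recall),
      f1 = mean(per$f1))
  } else c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  structure(list(per_label = tibble::as_tibble(per), micro = micro,
                 macro = macro, mode = mode, n_docs = length(gold_docs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("<eval_report> ", x$mode, " matching over ", x$n_docs, " documents, ",
      nrow(x$per_label), " labels\n", sep = "")
  cat(sprintf("  micro P/R/F1: %.*f / %.*f / %.*f\n", digits,
              x$micro["precision"], digits, x$micro["recall"], digits,
              x$micro["f1"]))
  cat(sprintf("  macro P/R/F1: %.*f / %.*f / %.*f\n", digits,
              x$macro["precision"], digits, x$macro["recall"], digits,
              x$macro["f1"]))
  invisible(x)
}

#' Score one annotator against consensus gold annotations
#'
#' Identical computation to \code{\link{score_corpus}} with the annotator's
#' spans on the prediction side, as used for ongoing annotation quality
#' checks against a consensus gold standard.
#'
#' @param annotator_docs Documents with one annotator's spans.
#' @param gold_docs Documents with consensus gold spans.
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return An \code{eval_report}.
#' @export
agreement <- function(annotator_docs, gold_docs,
                      mode = c("strict", "lenient")) {
  score_corpus(gold_docs, annotator_docs, mode)
}

#' In-dict / out-dict recall partition
#'
#' Splits the gold test spans into those whose normalized surface form was
#' observed with the same label in the training set (in-dict) and the rest
#' (out-dict), then computes recall separately on both classes. A large
#' in-dict/out-dict recall gap diagnoses name memorisation: the model
#' recognises remembered strings rather than contexts.
#'
#' @param train_docs Training documents with gold spans.
#' @param test_gold,test_pred Aligned test document lists (gold and
#'   predicted spans).
#' @param mode \code{"strict"} or \code{"lenient"}.
#' @return List with \code{recall_in_dict}, \code{recall_out_dict} (each
#'   \code{NA} when its class is empty), and support counts \code{n_in},
#'   \code{n_out}.
#' @export
indict_partition <- function(train_docs, test_gold, test_pred,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  seen <- unique(unlist(lapply(train_docs, function(d) {
    if (nrow(d$spans) == 0L) return(character())
    paste0(normalize_form(d$spans$surface), "\r", d$spans$label)
  })))
  gid <- vapply(test_gold, `[[`, "", "doc_id")
  pid <- vapply(test_pred, `[[`, "", "doc_id")
  if (!setequal(gid, pid))
    stop("test gold and predicted document sets must match")
  test_pred <- test_pred[match(gid, pid)]
  hit_in <- n_in <- hit_out <- n_out <- 0L
  for (i in seq_along(test_gold)) {
    g <- test_gold[[i]]$spans
    if (nrow(g) == 0L) next
    m <- match_spans(g, test_pred[[i]]$spans, mode)
    matched <- seq_len(nrow(g)) %in% m$pairs$gold
    key <- paste0(normalize_form(g$surface), "\r", g$label)
    indict <- key %in% seen
    n_in <- n_in + sum(indict); n_out <- n_out + sum(!indict)
    hit_in <- hit_in + sum(matched & indict)
    hit_out <- hit_out + sum(matched & !indict)
  }
  list(recall_in_dict = if (n_in > 0L) hit_in / n_in else NA_real_,
       recall_out_dict = if (n_out > 0L) hit_out / n_out else NA_real_,
       n_in = n_in, n_out = n_out)
}

#' Write the per-label table of an evaluation report as TSV
#'
#' @param report An \code{eval_report}.
#' @param path Output file.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report$per_label, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
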