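#' Token classifier contract
#'
#' A token classifier maps a token sequence to a logit matrix with one row
#' per token and one column per tag in a shared, ordered IOB tag space (see
#' \code{\link{tag_space}}). Trained models plug in as in-process objects or
#' via the logit interchange format (\code{\link{write_logits}}).
#'
#' @param predict_fn Function \code{(tokens) -> matrix} of dimension
#'   (token count, length(tags)).
#' @param tags Ordered tag space the logit columns refer to.
#' @param name Optional display name.
#' @return Object of class \code{token_classifier}.
#' @export
token_classifier <- function(predict_fn, tags, name = "classifier") {
  stopifnot(is.function(predict_fn), is.character(tags), tags[1L] == "O")
  structure(list(predict_fn = predict_fn, tags = tags, name = name),
            class = "token_classifier")
}

#' @export
print.token_classifier <- function(x, ...) {
  cat("<token_classifier> ", x$name, ", ", length(x$tags), " tags\n",
      sep = "")
  invisible(x)
}

#' Compute a classifier's logits for a token sequence
#'
#' @param clf A \code{token_classifier}.
#' @param tokens Token tibble.
#' @return Numeric matrix (token count x tag count).
#' @export
predict_logits <- function(clf, tokens) {
  out <- clf$predict_fn(tokens)
  stopifnot(is.matrix(out), nrow(out) == nrow(tokens),
            ncol(out) == length(clf$tags), all(is.finite(out)))
  out
}

#' Ensemble prediction by logit averaging
#'
#' Averages member logits elementwise and takes the per-token argmax —
#' averaging raw logits rather than probabilities lets the confidence of
#' individual members weigh in (a strongly confident minority can outvote a
#' weak majority, unlike majority voting). At ties on the mean logit,
#' \code{O} wins if it is among the maxima, otherwise the lowest tag index —
#' a conservative rule favouring precision. The resulting tag sequence is a
#' valid IOB sequence up to orphan I-tags, which downstream
#' \code{\link{decode_iob}} repairs.
#'
#' @param tokens Token tibble.
#' @param members List of \code{token_classifier} with identical tag spaces.
#' @return Character vector of IOB tags (one per token).
#' @export
ensemble_predict <- function(tokens, members) {
  stopifnot(length(members) >= 1L)
  tags <- members[[1L]]$tags
  for (m in members) {
    if (!identical(m$tags, tags))
      stop("ensemble members disagree on the tag space")
  }
  if (nrow(tokens) == 0L) return(character())
  acc <- matrix(0, nrow(tokens), length(tags))
  for (m in members) acc <- acc + predict_logits(m, tokens)
  acc <- acc / length(members)
  o_idx <- match("O", tags)
  idx <- vapply(seq_len(nrow(acc)), function(i) {
    x <- acc[i, ]
    best <- which(x == max(x))
    if (o_idx %in% best) o_idx else min(best)
  }, 0L)
  tags[idx]
}

#' Ensemble prediction decoded to entity spans
#'
#' Convenience wrapper: \code{\link{ensemble_predict}} followed by
#' \code{\link{decode_iob}}.
#'
#' @param doc A \code{ner_document}.
#' @param members List of \code{token_classifier}.
#' @return Entity span tibble.
#' @export
ensemble_spans <- function(doc, members) {
  tok <- tokenize(doc$text)
  decode_iob(ensemble_predict(tok, members), tok, text = doc$text)
}

#' Dictionary-backed token classifier
#'
#' Wraps a compiled \code{span_dictionary} as a member of the token
#' classifier contract, so ensembling is exercisable without trained
#' models: tokens inside a dictionary match receive \code{+confidence} on
#' the matched \code{B-}/\code{I-} tag (and 0 on \code{O}); unmatched
#' tokens receive \code{+confidence} on \code{O}. With \code{confidence = 0}
#' every logit is 0 and the tie-break yields all-\code{O}.
#'
#' @param dict A \code{span_dictionary}.
#' @param tags Shared tag space (from \code{\link{tag_space}}).
#' @param confidence Positive logit magnitude.
#' @param name Display name.
#' @return A \code{token_classifier}.
#' @export
dictionary_classifier <- function(dict, tags, confidence = 1,
                                  name = "dictionary") {
  stopifnot(inherits(dict, "span_dictionary"), confidence >= 0)
  force(tags)
  token_classifier(function(tokens) {
    logits <- matrix(0, nrow(tokens), length(tags))
    if (nrow(tokens) > 0L) {
      logits[, match("O", tags)] <- confidence
      m <- dict_match_tokens(tokens, dict)
      for (k in seq_len(nrow(m))) {
        rng <- m$first[k]:m$last[k]
        iob <- c(paste0("B-", m$label[k]),
                 rep(paste0("I-", m$label[k]), length(rng) - 1L))
        cols <- match(iob, tags)
        if (anyNA(cols))
          stop("dictionary label outside the tag space: ", m$label[k])
        logits[rng, match("O", tags)] <- 0
        logits[cbind(rng, cols)] <- confidence
      }
    }
    logits
  }, tags = tags, name = name)
}

#' Logit interchange files
#'
#' Writes/reads per-token logits as TSV: columns \code{start}, \code{end},
#' \code{surface}, then one column per tag in tag-space order. This lets
#' externally trained models join an ensemble as file-backed members.
#'
#' @param tokens Token tibble the logits refer to.
#' @param logits Matrix (token count x tag count).
#' @param tags Ordered tag space.
#' @param path File path.
#' @export
write_logits <- function(tokens, logits, tags, path) {
  stopifnot(nrow(logits) == nrow(tokens), ncol(logits) == length(tags))
  df <- cbind(tokens[, c("start", "end", "surface")],
              stats::setNames(as.data.frame(logits), tags))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_logits
#' @return \code{read_logits}: list with \code{tokens}, \code{logits},
#'   \code{tags}.
#' @export
read_logits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  tags <- setdiff(names(df), c("start", "end", "surface"))
  list(tokens = tibble::tibble(surface = as.character(df$surface),
                               start = as.integer(df$start),
                               end = as.integer(df$end)),
       logits = as.matrix(df[, tags, drop = FALSE]),
       tags = tags)
}

#' File-backed ensemble member from a logit interchange file
#'
#' @param path Logit TSV written by \code{\link{write_logits}}.
#' @return A \code{token_classifier} that serves the stored logits (and
#'   refuses token sequences of a different length).
#' @export
logit_file_classifier <- function(path) {
  stored <- read_logits(path)
  token_classifier(function(tokens) {
    if (nrow(tokens) != nrow(stored$logits))
      stop("stored logits cover ", nrow(stored$logits),
           " tokens, got ", nrow(tokens))
    stored$logits
  }, tags = stored$tags, name = basename(path))
}
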