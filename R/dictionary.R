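#' Normalize a surface form
#'
#' The single definition of "the same span" used across the toolkit
#' (dictionary keys, span-uniqueness counts, in-dict/out-dict partition):
#' tokenize, lowercase, and join token surfaces with single spaces. This
#' makes normalization insensitive to casing and internal whitespace while
#' keeping punctuation-bearing forms (e.g. drug doses, "St John's wort")
#' well-defined.
#'
#' @param x Character vector of surface strings.
#' @return Character vector of normalized forms.
#' @export
normalize_form <- function(x) {
  vapply(x, function(s) {
    paste(tolower(tokenize(s)$surface), collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Compile a surface-form dictionary from training annotations
#'
#' Implements the exact string-search baseline's training step: every
#' normalized gold surface form observed with exactly one label maps to that
#' label; a form observed with two or more distinct labels is ambiguous and
#' excluded from the dictionary entirely (not assigned a majority label).
#'
#' @param train_docs List of \code{ner_document} carrying gold spans.
#' @return Object of class \code{span_dictionary}: list with \code{forms}
#'   (named character vector, normalized form -> label), \code{ambiguous}
#'   (character vector of excluded forms) and \code{counts} (tibble of
#'   form/label observation counts for diagnostics).
#' @export
compile_dictionary <- function(train_docs) {
  surf <- unlist(lapply(train_docs, function(d) d$spans$surface))
  labs <- unlist(lapply(train_docs, function(d) d$spans$label))
  if (length(surf) == 0L) {
    return(structure(list(forms = stats::setNames(character(), character()),
                          ambiguous = character(),
                          counts = tibble::tibble(form = character(),
                                                  label = character(),
                                                  n = integer())),
                     class = "span_dictionary"))
  }
  form <- normalize_form(surf)
  keep <- nzchar(form)
  form <- form[keep]; labs <- labs[keep]
  counts <- stats::aggregate(list(n = rep(1L, length(form))),
                             by = list(form = form, label = labs), FUN = sum)
  counts <- counts[order(counts$form, counts$label), ]
  nlab <- tapply(counts$label, counts$form, function(l) length(unique(l)))
  ambiguous <- names(nlab)[nlab > 1L]
  uni <- counts[!counts$form %in% ambiguous, ]
  structure(list(forms = stats::setNames(uni$label, uni$form),
                 ambiguous = ambiguous,
                 counts = tibble::as_tibble(counts)),
            class = "span_dictionary")
}

#' @export
print.span_dictionary <- function(x, ...) {
  cat("<span_dictionary> ", length(x$forms), " forms (",
      length(x$ambiguous), " ambiguous excluded)\n", sep = "")
  invisible(x)
}

# Token-level dictionary matching shared by dict_predict() and the
# dictionary-backed token classifier. Returns tibble(first, last, label) of
# token index ranges; longest match first, then leftmost, non-overlapping.
dict_match_tokens <- function(tokens, dict) {
  out <- tibble::tibble(first = integer(), last = integer(),
                        label = character())
  n <- nrow(tokens)
  if (n == 0L || length(dict$forms) == 0L) return(out)
  low <- tolower(tokens$surface)
  form_len <- lengths(strsplit(names(dict$forms), " ", fixed = TRUE))
  max_len <- min(max(form_len), n)
  taken <- logical(n)
  cand <- list()
  for (L in seq_len(max_len)) {
    keys <- names(dict$forms)[form_len == L]
    if (length(keys) == 0L) next
    for (i in seq_len(n - L + 1L)) {
      key <- paste(low[i:(i + L - 1L)], collapse = " ")
      hit <- match(key, keys)
      if (!is.na(hit)) {
        cand[[length(cand) + 1L]] <-
          c(first = i, last = i + L - 1L,
            label_i = match(key, names(dict$forms)))
      }
    }
  }
  if (length(cand) == 0L) return(out)
  cm <- do.call(rbind, cand)
  ord <- order(-(cm[, "last"] - cm[, "first"]), cm[, "first"])
  for (k in ord) {
    rng <- cm[k, "first"]:cm[k, "last"]
    if (any(taken[rng])) next
    taken[rng] <- TRUE
    out <- rbind(out, tibble::tibble(
      first = unname(cm[k, "first"]), last = unname(cm[k, "last"]),
      label = unname(dict$forms[cm[k, "label_i"]])))
  }
  out[order(out$first), ]
}

#' Predict entity spans by exact string search
#'
#' Searches the document for occurrences of every dictionary form, anchored
#' at token boundaries (a form never fires inside a longer word), and labels
#' each hit with the form's dictionary label. Overlapping candidate hits are
#' resolved longest-match-first, then leftmost-first.
#'
#' @param doc A \code{ner_document} (gold spans, if any, are ignored).
#' @param dict A \code{span_dictionary}.
#' @return Entity span tibble with character offsets into \code{doc$text}.
#' @export
dict_predict <- function(doc, dict) {
  stopifnot(inherits(doc, "ner_document"), inherits(dict, "span_dictionary"))
  tok <- tokenize(doc$text)
  m <- dict_match_tokens(tok, dict)
  if (nrow(m) == 0L) return(entity_spans())
  entity_spans(tok$start[m$first], tok$end[m$last], m$label, text = doc$text)
}

#' Serialize / load a span dictionary as TSV
#'
#' Two-column table \code{form\tlabel}; ambiguous (excluded) forms are
#' written with the reserved label \code{<ambiguous>}.
#'
#' @param dict A \code{span_dictionary}.
#' @param path File path.
#' @export
write_dictionary <- function(dict, path) {
  df <- rbind(data.frame(form = names(dict$forms),
                         label = unname(dict$forms)),
              if (length(dict$ambiguous))
                data.frame(form = dict$ambiguous, label = "<ambiguous>"))
  utils::write.table(df[order(df$form), ], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  amb <- df$form[df$label == "<ambiguous>"]
  uni <- df[df$label != "<ambiguous>", ]
  structure(list(forms = stats::setNames(uni$label, uni$form),
                 ambiguous = amb,
                 counts = tibble::tibble(form = uni$form, label = uni$label,
                                         n = NA_integer_)),
            class = "span_dictionary")
}
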