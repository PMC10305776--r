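#' Deterministic word-level tokenizer with character offsets
#'
#' Splits on whitespace and splits off every punctuation character as a
#' single-character token: a token is either a maximal run of alphanumeric
#' characters or one non-space, non-alphanumeric character. Case is
#' preserved so that offsets stay faithful to the letter text; all case
#' normalization happens downstream (dictionary keys, span-uniqueness
#' counts).
#'
#' @param text A single string.
#' @return Tibble with columns \code{surface}, \code{start}, \code{end}
#'   (0-based, half-open offsets into \code{text}); zero rows for empty text.
#' @export
#' @examples
#' tokenize("Patient on warfarin")
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(surface = character(), start = integer(),
                          end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1L]]
  if (m[1L] == -1L) {
    return(tibble::tibble(surface = character(), start = integer(),
                          end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(surface = substring(text, m, m + len - 1L),
                 start = as.integer(m - 1L),
                 end = as.integer(m + len - 1L))
}

#' The IOB tag space over an ontology
#'
#' For N entity classes the tag space has 2N+1 members: \code{O} first, then
#' \code{B-}/\code{I-} pairs in ontology order. The ordering is stable and
#' shared by all classifiers in an ensemble.
#'
#' @param ontology A \code{ner_ontology}.
#' @return Character vector of length 2N+1.
#' @export
tag_space <- function(ontology) {
  ents <- ontology$entities$entity
  stopifnot(length(ents) > 0L)
  c("O", as.vector(rbind(paste0("B-", ents), paste0("I-", ents))))
}

#' Encode entity spans as an IOB tag sequence
#'
#' The first token overlapping a span receives \code{B-label}, subsequent
#' overlapping tokens \code{I-label}, all other tokens \code{O}. A token
#' partially covered by a span (span boundary falls mid-token) is included
#' in the span's run: lenient evaluation tolerates the boundary slack and
#' this is the least destructive rule. Overlapping spans with conflicting
#' token claims are rejected unless \code{collision = "keep-longest"}, which
#' gives priority to longer (then earlier) spans.
#'
#' @param tokens Token tibble from \code{\link{tokenize}}.
#' @param spans Entity span tibble.
#' @param collision \code{"error"} (default) or \code{"keep-longest"}.
#' @return Character vector of tags, one per token.
#' @export
encode_iob <- function(tokens, spans, collision = c("error", "keep-longest")) {
  collision <- match.arg(collision)
  tags <- rep("O", nrow(tokens))
  if (nrow(spans) == 0L) return(tags)
  ord <- order(-(spans$end - spans$start), spans$start)
  claimed <- rep(NA_integer_, nrow(tokens))
  for (si in ord) {
    hit <- which(tokens$start < spans$end[si] & tokens$end > spans$start[si])
    if (length(hit) == 0L) next
    clash <- !is.na(claimed[hit])
    if (any(clash)) {
      if (collision == "error")
        stop(sprintf(
          "overlapping spans claim token %s; use collision = \"keep-longest\"",
          dQuote(tokens$surface[hit[clash][1L]])))
      next  # keep-longest: earlier (longer) span wins, drop this one
    }
    claimed[hit] <- si
    tags[hit] <- c(paste0("B-", spans$label[si]),
                   rep(paste0("I-", spans$label[si]), length(hit) - 1L))
  }
  tags
}

#' Decode an IOB tag sequence back to entity spans
#'
#' Maximal \code{B,I...I} runs of one label become spans from the first
#' token's start to the last token's end. An orphan \code{I-e} (not preceded
#' by \code{B-e} or \code{I-e}) is repaired to \code{B-e} — the standard
#' repair that keeps decoding total.
#'
#' @param tags Character vector of IOB tags.
#' @param tokens Token tibble aligned with \code{tags}.
#' @param text Optional parent text used to fill span surfaces; when absent
#'   surfaces are reconstructed from token surfaces.
#' @return Entity span tibble.
#' @export
decode_iob <- function(tags, tokens, text = NULL) {
  stopifnot(length(tags) == nrow(tokens))
  start <- end <- integer(0); label <- character(0)
  cur_lab <- NA_character_; cur_first <- NA_integer_; cur_last <- NA_integer_
  flush <- function() {
    if (!is.na(cur_lab)) {
      start <<- c(start, tokens$start[cur_first])
      end <<- c(end, tokens$end[cur_last])
      label <<- c(label, cur_lab)
    }
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      flush(); cur_lab <- NA_character_
    } else {
      kind <- substring(t, 1L, 1L)
      lab <- substring(t, 3L)
      if (kind == "B" || is.na(cur_lab) || lab != cur_lab) {
        flush()  # orphan/label-switching I- starts a fresh span (I -> B repair)
        cur_lab <- lab; cur_first <- i
      }
      cur_last <- i
    }
  }
  flush()
  surface <- if (!is.null(text)) substring(text, start + 1L, end) else
    vapply(seq_along(start), function(k) {
      idx <- which(tokens$start >= start[k] & tokens$end <= end[k])
      paste(tokens$surface[idx], collapse = " ")
    }, "")
  sp <- tibble::tibble(start = start, end = end, label = label,
                       surface = surface)
  sp[order(sp$start, sp$end), ]
}
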