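DOC_TYPES <- c("GP referral", "IDL", "FDL", "OPCL", "ED Letter",
               "Endoscopy report")

#' Construct an entity span table
#'
#' Spans use brat's character-offset convention: 0-based, half-open
#' \code{[start, end)}. The \code{surface} column is filled from \code{text}
#' when supplied and verified otherwise.
#'
#' @param start,end Integer character offsets.
#' @param label Entity labels.
#' @param surface Covered text; computed from \code{text} when missing.
#' @param text Parent document text used to slice/validate surfaces.
#' @return Tibble with columns \code{start}, \code{end}, \code{label},
#'   \code{surface}, sorted by (start, end).
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         label = character(), surface = NULL, text = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), length(start) == length(label))
  if (is.null(surface)) {
    if (is.null(text) && length(start) > 0L)
      stop("need either surface or text to build spans")
    surface <- if (length(start)) substring(text, start + 1L, end) else character()
  }
  sp <- tibble::tibble(start = start, end = end,
                       label = as.character(label),
                       surface = as.character(surface))
  sp[order(sp$start, sp$end), ]
}

validate_spans <- function(spans, text, ontology = NULL) {
  if (nrow(spans) == 0L) return(invisible(spans))
  n <- nchar(text)
  bad <- spans$start < 0L | spans$end > n | spans$start >= spans$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed span [%d,%d) on text of length %d",
                 spans$start[i], spans$end[i], n))
  }
  got <- substring(text, spans$start + 1L, spans$end)
  if (any(got != spans$surface)) {
    i <- which(got != spans$surface)[1L]
    stop(sprintf("span surface mismatch at [%d,%d): annotation %s, text %s",
                 spans$start[i], spans$end[i],
                 dQuote(spans$surface[i]), dQuote(got[i])))
  }
  if (!is.null(ontology)) {
    unknown <- setdiff(spans$label, ontology$entities$entity)
    if (length(unknown))
      stop("span labels not in ontology: ", paste(unknown, collapse = ", "))
  }
  invisible(spans)
}

#' Construct an annotated clinical document
#'
#' @param text Full letter text.
#' @param spans Entity span tibble (see \code{\link{entity_spans}}).
#' @param doc_id,patient_id Opaque identifiers.
#' @param doc_type One of the six letter types (GP referral, IDL, FDL, OPCL,
#'   ED Letter, Endoscopy report).
#' @param ontology Optional ontology; when given, span labels are validated
#'   against it.
#' @return Object of class \code{ner_document}.
#' @export
ner_document <- function(text, spans = entity_spans(), doc_id = "doc1",
                         patient_id = "pat1", doc_type = "FDL",
                         ontology = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!doc_type %in% DOC_TYPES)
    stop("unknown doc_type ", dQuote(doc_type))
  spans <- spans[order(spans$start, spans$end), ]
  dup <- duplicated(spans[, c("start", "end", "label")])
  spans <- spans[!dup, ]
  validate_spans(spans, text, ontology)
  structure(list(doc_id = doc_id, patient_id = patient_id,
                 doc_type = doc_type, text = text, spans = spans),
            class = "ner_document")
}

#' @export
print.ner_document <- function(x, ...) {
  cat("<ner_document> ", x$doc_id, " (patient ", x$patient_id, ", ",
      x$doc_type, "): ", nchar(x$text), " chars, ", nrow(x$spans),
      " spans\n", sep = "")
  invisible(x)
}

#' Parse a brat standoff annotation pair
#'
#' Consumes the text content and the \code{.ann} content of one document.
#' Only text-bound ("T") lines are read; other line types (notes, relations,
#' attributes) are skipped with a warning. Discontinuous spans
#' (semicolon-separated fragments) are not supported and raise an error.
#'
#' @param text_content Document text as a single string.
#' @param ann_content Annotation file content (lines or single string).
#' @param ontology Ontology for label validation.
#' @param lenient_labels If \code{TRUE}, spans with labels outside the
#'   ontology are dropped with a warning instead of raising an error.
#' @param ... Passed to \code{\link{ner_document}} (ids, doc_type).
#' @return A \code{ner_document}.
#' @export
read_standoff <- function(text_content, ann_content, ontology = NULL,
                          lenient_labels = FALSE, ...) {
  lines <- unlist(strsplit(ann_content, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  is_tb <- grepl("^T[0-9]+\t", lines)
  if (any(!is_tb)) {
    warning("ignoring ", sum(!is_tb), " non text-bound annotation line(s)")
    lines <- lines[is_tb]
  }
  start <- end <- integer(0); label <- surface <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed annotation line: ", dQuote(ln))
    mid <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
    if (length(mid) != 3L || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
      if (grepl(";", parts[2L], fixed = TRUE))
        stop("discontinuous spans are not supported: ", dQuote(ln))
      stop("malformed annotation line: ", dQuote(ln))
    }
    s <- as.integer(mid[2L]); e <- as.integer(mid[3L])
    if (s < 0L || e > nchar(text_content) || s >= e)
      stop(sprintf("offsets out of range in line %s (text length %d)",
                   dQuote(ln), nchar(text_content)))
    lab <- mid[1L]
    if (!is.null(ontology) && !lab %in% ontology$entities$entity) {
      if (lenient_labels) {
        warning("dropping span with unknown label ", dQuote(lab))
        next
      }
      stop("unknown label ", dQuote(lab), " in line ", dQuote(ln))
    }
    start <- c(start, s); end <- c(end, e); label <- c(label, lab)
    surface <- c(surface, substring(text_content, s + 1L, e))
    if (length(parts) >= 3L && parts[3L] != surface[length(surface)])
      stop(sprintf("surface mismatch in line %s: text slice is %s",
                   dQuote(ln), dQuote(surface[length(surface)])))
  }
  ner_document(text_content,
               entity_spans(start, end, label, surface),
               ontology = ontology, ...)
}

#' Serialize a document to brat standoff
#'
#' @param doc A \code{ner_document}.
#' @return List with elements \code{text} and \code{ann}; \code{ann} lines
#'   are \code{T<k>\tlabel start end\tsurface} in span order.
#' @export
write_standoff <- function(doc) {
  stopifnot(inherits(doc, "ner_document"))
  sp <- doc$spans
  ann <- if (nrow(sp) == 0L) "" else
    paste(sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(sp)), sp$label,
                  sp$start, sp$end, sp$surface),
          collapse = "\n")
  list(text = doc$text, ann = ann)
}

#' Write a corpus as a brat standoff directory
#'
#' One \code{<doc_id>.txt} / \code{<doc_id>.ann} pair per document, plus a
#' \code{manifest.tsv} recording patient id and document type (brat has no
#' native field for either).
#'
#' @param docs List of \code{ner_document}.
#' @param dir Output directory (created if needed).
#' @export
write_standoff_dir <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- tibble::tibble(doc_id = vapply(docs, `[[`, "", "doc_id"),
                        patient_id = vapply(docs, `[[`, "", "patient_id"),
                        doc_type = vapply(docs, `[[`, "", "doc_type"))
  for (d in docs) {
    out <- write_standoff(d)
    writeLines(out$text, file.path(dir, paste0(d$doc_id, ".txt")), sep = "")
    writeLines(out$ann, file.path(dir, paste0(d$doc_id, ".ann")), sep = "")
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a brat standoff directory written by \code{write_standoff_dir}
#'
#' @param dir Directory of \code{.txt}/\code{.ann} pairs.
#' @param ontology Ontology for label validation.
#' @return List of \code{ner_document}.
#' @export
read_standoff_dir <- function(dir, ontology = NULL) {
  man_path <- file.path(dir, "manifest.tsv")
  man <- if (file.exists(man_path)) {
    utils::read.delim(man_path, stringsAsFactors = FALSE, quote = "")
  } else NULL
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tp) {
    id <- sub("\\.txt$", "", basename(tp))
    ap <- file.path(dir, paste0(id, ".ann"))
    txt <- readChar(tp, file.size(tp), useBytes = FALSE)
    ann <- if (file.exists(ap) && file.size(ap) > 0)
      readChar(ap, file.size(ap)) else ""
    pid <- "unknown"; dtype <- "FDL"
    if (!is.null(man) && id %in% man$doc_id) {
      row <- man[man$doc_id == id, ]
      pid <- row$patient_id[1L]; dtype <- row$doc_type[1L]
    }
    read_standoff(txt, ann, ontology = ontology, doc_id = id,
                  patient_id = pid, doc_type = dtype)
  })
}

#' Export/import a corpus as line-delimited JSON records
#'
#' One JSON object per line with fields \code{doc_id}, \code{patient_id},
#' \code{doc_type}, \code{text} and \code{spans} (array of objects with
#' \code{start}, \code{end}, \code{label}, \code{surface}).
#'
#' @param docs List of \code{ner_document}.
#' @param path Output file.
#' @export
write_corpus_ndjson <- function(docs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in docs) {
    rec <- list(doc_id = d$doc_id, patient_id = d$patient_id,
                doc_type = d$doc_type, text = d$text,
                spans = d$spans)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_corpus_ndjson
#' @param ontology Ontology for label validation on import.
#' @export
read_corpus_ndjson <- function(path, ontology = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    sp <- if (length(rec$spans) == 0L) entity_spans() else
      entity_spans(rec$spans$start, rec$spans$end, rec$spans$label,
                   rec$spans$surface)
    ner_document(rec$text, sp, doc_id = rec$doc_id,
                 patient_id = rec$patient_id, doc_type = rec$doc_type,
                 ontology = ontology)
  })
}
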