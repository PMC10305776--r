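#' Contraindication surfacing report for one letter
#'
#' Groups detected entity mentions by category then entity, attaches a
#' context snippet for each mention (the span plus surrounding characters,
#' truncated at document bounds), and lists the thrombolysis eligibility
#' checklist items linked to any detected entity. The report is advisory
#' display only: no checklist question is answered, the clinician judges
#' the surfaced mentions.
#'
#' @param doc A \code{ner_document}.
#' @param spans Predicted entity spans for \code{doc} (defaults to the
#'   document's own spans).
#' @param context_chars Characters of context on each side of a mention.
#' @param ontology Ontology supplying category membership.
#' @param checklist Checklist table (\code{\link{load_checklist}}) or
#'   \code{NULL} to omit the checklist section.
#' @return Object of class \code{surface_report}: list with \code{doc_id},
#'   \code{mentions} (tibble: category, entity, start, end, surface,
#'   snippet, in deterministic category/offset order) and \code{checklist}
#'   (tibble of linked items).
#' @export
render_report <- function(doc, spans = doc$spans, context_chars = 40L,
                          ontology = load_default_ontology(),
                          checklist = load_checklist(ontology)) {
  stopifnot(inherits(doc, "ner_document"))
  validate_spans(spans, doc$text)
  n <- nchar(doc$text)
  if (nrow(spans) > 0L) {
    cat_of <- ontology$entities$category[
      match(spans$label, ontology$entities$entity)]
    snip_s <- pmax(spans$start - context_chars, 0L)
    snip_e <- pmin(spans$end + context_chars, n)
    snippet <- gsub("\n", " ", substring(doc$text, snip_s + 1L, snip_e),
                    fixed = TRUE)
    mentions <- tibble::tibble(category = cat_of, entity = spans$label,
                               start = spans$start, end = spans$end,
                               surface = spans$surface, snippet = snippet)
    ord <- order(match(mentions$category, ontology$categories),
                 mentions$entity, mentions$start)
    mentions <- mentions[ord, ]
  } else {
    mentions <- tibble::tibble(category = character(), entity = character(),
                               start = integer(), end = integer(),
                               surface = character(), snippet = character())
  }
  check <- NULL
  if (!is.null(checklist)) {
    hit <- vapply(checklist$linked_entities, function(ents)
      any(ents %in% mentions$entity), NA)
    check <- checklist[hit, c("question", "polarity")]
    check$entities <- vapply(checklist$linked_entities[hit], function(ents)
      paste(intersect(ents, mentions$entity), collapse = ", "), "")
  }
  structure(list(doc_id = doc$doc_id, mentions = mentions,
                 checklist = check),
            class = "surface_report")
}

#' Format a surfacing report as plain text or single-file HTML
#'
#' The HTML rendering is a static two-pane layout: detected entities by
#' category on the left, mention snippets in context on the right.
#' Formatting is pure — the same report always yields byte-identical
#' output.
#'
#' @param report A \code{surface_report}.
#' @param format \code{"text"} or \code{"html"}.
#' @return A single string.
#' @export
format_report <- function(report, format = c("text", "html")) {
  format <- match.arg(format)
  m <- report$mentions
  if (format == "text") {
    out <- c(paste0("Entity report for document ", report$doc_id),
             strrep("=", 40))
    if (nrow(m) == 0L) {
      out <- c(out, "no entities detected")
    } else {
      for (cat in unique(m$category)) {
        out <- c(out, paste0("[", cat, "]"))
        sub <- m[m$category == cat, ]
        for (i in seq_len(nrow(sub))) {
          out <- c(out, sprintf("  %s @ [%d,%d): ...%s...", sub$entity[i],
                                sub$start[i], sub$end[i], sub$snippet[i]))
        }
      }
    }
    if (!is.null(report$checklist) && nrow(report$checklist) > 0L) {
      out <- c(out, "", "Checklist items linked to detected entities:")
      ck <- report$checklist
      out <- c(out, sprintf("  (%s) %s [%s]", ck$polarity, ck$question,
                            ck$entities))
    }
    paste(out, collapse = "\n")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    left <- if (nrow(m) == 0L) "<p>no entities detected</p>" else
      paste(vapply(unique(m$category), function(cat) {
        sub <- m[m$category == cat, ]
        paste0("<h3>", esc(cat), "</h3><ul>",
               paste0("<li>", esc(sub$entity), " (", esc(sub$surface), ")",
                      "</li>", collapse = ""),
               "</ul>")
      }, ""), collapse = "")
    right <- if (nrow(m) == 0L) "" else
      paste0("<p class=\"snippet\"><b>", esc(m$entity), "</b> [",
             m$start, ",", m$end, "): &hellip;", esc(m$snippet),
             "&hellip;</p>", collapse = "")
    check <- ""
    if (!is.null(report$checklist) && nrow(report$checklist) > 0L) {
      ck <- report$checklist
      check <- paste0("<h3>Checklist items</h3><ul>",
                      paste0("<li>(", esc(ck$polarity), ") ",
                             esc(ck$question), " [", esc(ck$entities),
                             "]</li>", collapse = ""),
                      "</ul>")
    }
    paste0("<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
           "<title>Entity report ", esc(report$doc_id), "</title>",
           "<style>body{font-family:sans-serif;display:flex}",
           ".pane{flex:1;padding:1em;border-right:1px solid #ccc}",
           ".snippet{background:#f6f6f6;padding:.3em}</style></head>",
           "<body><div class=\"pane\">", left, check,
           "</div><div class=\"pane\">", right, "</div></body></html>")
  }
}

#' @export
print.surface_report <- function(x, ...) {
  cat(format_report(x, "text"), "\n")
  invisible(x)
}
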