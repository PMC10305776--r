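#' Load the packaged stroke entity ontology
#'
#' The default ontology enumerates 86 entities relevant to the decision to
#' administer thrombolysis in acute ischaemic stroke, grouped into five
#' categories: Diagnosis, Symptom, Social history, Medication and Treatment.
#' Each entity carries a pool of synonym seed surface forms used by the
#' corpus simulator; seeds are not lookup keys.
#'
#' @return An object of class \code{ner_ontology}: a list with elements
#'   \code{entities} (tibble with columns \code{entity}, \code{category},
#'   \code{synonyms} where \code{synonyms} is a list column of character
#'   vectors) and \code{categories} (character vector of the five category
#'   names, in display order).
#' @export
#' @examples
#' ont <- load_default_ontology()
#' nrow(ont$entities)  # 86
load_default_ontology <- function() {
  path <- system.file("extdata", "ontology.tsv", package = "strokener")
  load_ontology(path)
}

#' Load an ontology from a tab-separated file
#'
#' The file format is documented in the packaged \code{ontology.tsv}: comment
#' lines start with \code{#}, then a header \code{entity\tcategory\tsynonyms},
#' then one row per entity with pipe-separated synonym seeds. Validation of
#' the default-ontology shape (86 entities, 5 categories) only applies to the
#' packaged file; custom ontologies may have any non-zero size.
#'
#' @param path Path to the ontology file.
#' @param expect_default If \code{TRUE}, additionally assert the packaged
#'   86-entity / 5-category shape.
#' @return A \code{ner_ontology} object.
#' @export
load_ontology <- function(path, expect_default = FALSE) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           quote = "", check.names = FALSE)
  stopifnot(all(c("entity", "category", "synonyms") %in% names(raw)))
  if (nrow(raw) == 0L) stop("ontology is empty: ", path)
  if (anyDuplicated(raw$entity)) {
    stop("duplicate entity names in ontology: ",
         paste(unique(raw$entity[duplicated(raw$entity)]), collapse = ", "))
  }
  syn <- strsplit(raw$synonyms, "|", fixed = TRUE)
  syn <- lapply(seq_along(syn), function(i) {
    s <- trimws(syn[[i]])
    s <- s[nzchar(s)]
    # canonical id is always a usable surface form
    unique(c(s, gsub("-", " ", raw$entity[i], fixed = TRUE)))
  })
  if (any(lengths(syn) == 0L)) stop("entity with empty synonym pool")
  ont <- structure(
    list(
      entities = tibble::tibble(entity = raw$entity,
                                category = raw$category,
                                synonyms = syn),
      categories = unique(raw$category)
    ),
    class = "ner_ontology"
  )
  if (expect_default) {
    stopifnot(nrow(ont$entities) == 86L, length(ont$categories) == 5L)
  }
  ont
}

#' @export
print.ner_ontology <- function(x, ...) {
  cat("<ner_ontology> ", nrow(x$entities), " entities in ",
      length(x$categories), " categories (",
      paste(x$categories, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Look up an entity by canonical name
#'
#' Case-insensitive exact match on canonical entity identifiers. Synonym
#' seeds are deliberately not consulted: they seed the simulator's surface
#' form pools and are not identifiers.
#'
#' @param ontology A \code{ner_ontology}.
#' @param name Entity name to look up.
#' @return A one-row tibble (\code{entity}, \code{category}) or \code{NULL}
#'   when the name is unknown.
#' @export
ont_lookup <- function(ontology, name) {
  stopifnot(inherits(ontology, "ner_ontology"), is.character(name),
            length(name) == 1L)
  i <- match(tolower(name), tolower(ontology$entities$entity))
  if (is.na(i)) return(NULL)
  ontology$entities[i, c("entity", "category")]
}

#' Synonym seed surface forms for one entity
#'
#' @param ontology A \code{ner_ontology}.
#' @param entity Canonical entity identifier.
#' @return Character vector of seed surface forms (always non-empty; includes
#'   a spelled-out form of the canonical identifier).
#' @export
synonym_seeds <- function(ontology, entity) {
  hit <- ont_lookup(ontology, entity)
  if (is.null(hit)) stop("unknown entity: ", entity)
  i <- match(hit$entity, ontology$entities$entity)
  ontology$entities$synonyms[[i]]
}

#' Load the thrombolysis eligibility checklist
#'
#' The checklist is display metadata for reports: each item has a question,
#' a polarity (\code{must-be-yes}, \code{must-be-no}, \code{should-be-no})
#' and a set of linked ontology entities. The toolkit never answers checklist
#' questions; items are surfaced alongside detected entities only.
#'
#' @param ontology Ontology used to validate linked entity names.
#' @return Tibble with columns \code{question}, \code{polarity},
#'   \code{linked_entities} (list column).
#' @export
load_checklist <- function(ontology = load_default_ontology()) {
  path <- system.file("extdata", "checklist.tsv", package = "strokener")
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           quote = "", check.names = FALSE)
  linked <- lapply(strsplit(ifelse(is.na(raw$linked_entities), "",
                                   raw$linked_entities),
                            "|", fixed = TRUE),
                   function(s) s[nzchar(s)])
  unknown <- setdiff(unlist(linked), ontology$entities$entity)
  if (length(unknown)) stop("checklist links unknown entities: ",
                            paste(unknown, collapse = ", "))
  tibble::tibble(question = raw$question, polarity = raw$polarity,
                 linked_entities = linked)
}
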