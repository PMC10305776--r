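# Sentence templates with one entity slot {E}. The clinical flavour mimics
# discharge-letter prose (medication lists, PMHx blocks, social history
# lines) without reproducing any real letter. Kept entity-free outside the
# slot: no template word is a surface form of any packaged entity.
SENTENCE_TEMPLATES <- c(
  "PMHx includes {E}.",
  "Background of {E} noted in the records.",
  "There is a documented history of {E}.",
  "The patient reports {E} over recent weeks.",
  "On direct questioning, {E} was elicited.",
  "Admission was precipitated by {E}.",
  "Examination findings were consistent with {E}.",
  "Imaging demonstrated features of {E}.",
  "The impression at clinic was {E}.",
  "Currently prescribed {E} once daily.",
  "Medication list: {E}, to continue on discharge.",
  "Commenced on {E} during this admission.",
  "The GP was asked to review {E} at the next appointment.",
  "Previously underwent {E} at this hospital.",
  "Referred for consideration of {E}.",
  "Plan: continue {E} and review in six weeks.",
  "Social history is notable for {E}.",
  "Family are aware of the {E}.",
  "No recurrence of {E} since the last review.",
  "Declined {E} after discussion of the risks.",
  "The ward round noted ongoing {E}.",
  "Discharge summary mentions {E} from a prior episode.",
  "Nursing staff observed {E} overnight.",
  "Clinic letter documents {E} dating back several years.")

FILLER_SENTENCES <- c(
  "Bloods were unremarkable on admission.",
  "Observations remained stable throughout the stay.",
  "The patient was reviewed by the physiotherapy team.",
  "Follow up has been arranged in the outpatient clinic.",
  "Thank you for your ongoing care of this patient.",
  "Routine investigations were requested.",
  "The family were updated by telephone.",
  "No acute concerns were raised at the board round.")

DOC_HEADERS <- c(
  "GP referral" = "GP REFERRAL LETTER\nDear colleague,\n\n",
  "IDL" = "IMMEDIATE DISCHARGE LETTER\nWard 5\n\n",
  "FDL" = "FINAL DISCHARGE LETTER\nDear Dr,\n\n",
  "OPCL" = "OUTPATIENT CLINIC LETTER\nNeurovascular clinic\n\n",
  "ED Letter" = "EMERGENCY DEPARTMENT LETTER\n\n",
  "Endoscopy report" = "ENDOSCOPY REPORT\nProcedure note\n\n")

# run code under a seeded, restorable RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulator configuration
#'
#' Describes the shape of a synthetic annotated-letter corpus. Defaults
#' emulate the study-corpus shape at a scale suited to desk experiments:
#' 200 patients with 1-6 letters each (mean about 2.8, matching the
#' documents-per-patient ratio of the emulated corpus), the six letter
#' types in their observed proportions, and a long-tailed (Zipf) label
#' frequency distribution over the packaged ontology.
#'
#' @param seed Mandatory RNG seed; the corpus is a pure function of the
#'   config including the seed.
#' @param n_patients Number of patients.
#' @param total_spans Total entity spans to distribute over the corpus.
#' @param labels Labels to generate (default: all ontology entities).
#' @param zipf_exponent Exponent of the rank-frequency law for label
#'   frequencies (1 gives the classic long tail; 0 is uniform).
#' @param synonym_pools Named list label -> character vector of surface
#'   forms; defaults to the ontology synonym seeds.
#' @param pool_size Optional cap on synonym pool sizes (first n forms);
#'   used for name-regularity sweeps.
#' @param context_pool_size Number of sentence templates each label draws
#'   its mention contexts from (1-24); smaller means more regular contexts.
#' @param docs_per_patient Probability weights for 1..k letters per patient.
#' @param doc_type_mix Named weights over the six document types.
#' @param fillers_per_doc Max entity-free filler sentences per letter.
#' @param ontology Ontology supplying labels and default pools.
#' @return Object of class \code{corpus_config}.
#' @export
corpus_config <- function(seed,
                          n_patients = 200L,
                          total_spans = 5000L,
                          labels = NULL,
                          zipf_exponent = 1,
                          synonym_pools = NULL,
                          pool_size = NULL,
                          context_pool_size = 5L,
                          docs_per_patient = c(0.25, 0.25, 0.2, 0.15,
                                               0.1, 0.05),
                          doc_type_mix = c("GP referral" = 4403, "IDL" = 1850,
                                           "FDL" = 1474, "OPCL" = 582,
                                           "ED Letter" = 56,
                                           "Endoscopy report" = 192),
                          fillers_per_doc = 3L,
                          ontology = load_default_ontology()) {
  if (missing(seed)) stop("corpus_config requires an explicit seed")
  if (is.null(labels)) labels <- ontology$entities$entity
  unknown <- setdiff(labels, ontology$entities$entity)
  if (length(unknown))
    stop("labels not in ontology: ", paste(unknown, collapse = ", "))
  if (is.null(synonym_pools)) {
    synonym_pools <- stats::setNames(
      lapply(labels, function(l) synonym_seeds(ontology, l)), labels)
  }
  if (!is.null(pool_size)) {
    synonym_pools <- lapply(synonym_pools, function(p)
      p[seq_len(min(pool_size, length(p)))])
  }
  for (l in labels) {
    pool <- synonym_pools[[l]]
    if (is.null(pool) || length(pool) == 0L || !all(nzchar(pool)))
      stop("unsatisfiable config: empty synonym pool for label ", dQuote(l))
  }
  stopifnot(context_pool_size >= 1L,
            context_pool_size <= length(SENTENCE_TEMPLATES),
            all(docs_per_patient >= 0), sum(docs_per_patient) > 0,
            setequal(names(doc_type_mix), names(DOC_HEADERS)),
            all(doc_type_mix >= 0), sum(doc_type_mix) > 0,
            n_patients >= 1L, total_spans >= 1L)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 total_spans = as.integer(total_spans), labels = labels,
                 zipf_exponent = zipf_exponent,
                 synonym_pools = synonym_pools,
                 context_pool_size = as.integer(context_pool_size),
                 docs_per_patient = docs_per_patient / sum(docs_per_patient),
                 doc_type_mix = doc_type_mix / sum(doc_type_mix),
                 fillers_per_doc = as.integer(fillers_per_doc),
                 ontology = ontology),
            class = "corpus_config")
}

#' Generate a synthetic annotated corpus
#'
#' Assembles clinical letters from type-specific headers, entity-bearing
#' sentences instantiated from each label's template pool with surface
#' forms sampled from its synonym pool, and entity-free filler sentences.
#' Gold spans carry exact character offsets and are token-aligned under the
#' package tokenizer. Byte-identical output for identical configs.
#'
#' @param config A \code{corpus_config}.
#' @return List of \code{ner_document}.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  with_seed(config$seed, {
    labels <- config$labels
    # long-tailed label frequencies: weight ~ rank^(-s), multinomial totals
    w <- seq_along(labels)^(-config$zipf_exponent)
    counts <- as.vector(stats::rmultinom(1L, config$total_spans, w / sum(w)))
    # each label mentions its contexts from a fixed template subset
    tmpl_pool <- lapply(seq_along(labels), function(i)
      sample(SENTENCE_TEMPLATES, config$context_pool_size))
    # patients and letters
    n_docs_per <- sample(seq_along(config$docs_per_patient),
                         config$n_patients, replace = TRUE,
                         prob = config$docs_per_patient)
    pat_id <- rep(sprintf("pat%04d", seq_len(config$n_patients)), n_docs_per)
    n_docs <- length(pat_id)
    doc_type <- sample(names(config$doc_type_mix), n_docs, replace = TRUE,
                       prob = config$doc_type_mix)
    # distribute spans over letters
    doc_labels <- vector("list", n_docs)
    for (i in seq_along(labels)) {
      if (counts[i] == 0L) next
      tgt <- sample.int(n_docs, counts[i], replace = TRUE)
      for (d in tgt) doc_labels[[d]] <- c(doc_labels[[d]], labels[i])
    }
    docs <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      text <- DOC_HEADERS[[doc_type[d]]]
      cursor <- nchar(text)
      start <- end <- integer(0); lab <- character(0)
      mention_labels <- sample(doc_labels[[d]])
      n_fill <- sample.int(config$fillers_per_doc + 1L, 1L) - 1L
      fill_at <- sort(sample.int(length(mention_labels) + n_fill, n_fill))
      slot <- 1L; mi <- 1L
      for (s in seq_len(length(mention_labels) + n_fill)) {
        if (s %in% fill_at) {
          sent <- sample(FILLER_SENTENCES, 1L)
        } else {
          l <- mention_labels[mi]; mi <- mi + 1L
          li <- match(l, labels)
          tmpl <- sample(tmpl_pool[[li]], 1L)
          form <- sample(config$synonym_pools[[l]], 1L)
          pos <- regexpr("{E}", tmpl, fixed = TRUE)
          sent <- sub("{E}", form, tmpl, fixed = TRUE)
          start <- c(start, cursor + pos - 1L)
          end <- c(end, cursor + pos - 1L + nchar(form))
          lab <- c(lab, l)
        }
        text <- paste0(text, sent, "\n")
        cursor <- cursor + nchar(sent) + 1L
        slot <- slot + 1L
      }
      docs[[d]] <- ner_document(
        text, entity_spans(start, end, lab, text = text),
        doc_id = sprintf("doc%05d", d), patient_id = pat_id[d],
        doc_type = doc_type[d], ontology = config$ontology)
    }
    docs
  })
}

#' Annotator-noise configuration
#'
#' Emulates human annotation error modes: missed spans (deletions — the
#' dominant human error mode), boundary jitter (disagreement about span
#' extent), label confusion, and spurious annotations.
#'
#' @param deletion_prob Per-span deletion probability.
#' @param jitter_prob Per-span probability of a boundary jitter; a jittered
#'   span has one boundary moved outward by 1..\code{jitter_max} tokens, so
#'   it always still overlaps the original.
#' @param jitter_max Maximum jitter in tokens.
#' @param confusion_prob Per-span probability of relabeling to a random
#'   other label.
#' @param spurious_rate Expected number of spurious spans per document
#'   (Poisson); each covers a random 1-3 token range with a label drawn
#'   from the corpus label distribution.
#' @return Object of class \code{noise_config}.
#' @export
noise_config <- function(deletion_prob = 0, jitter_prob = 0, jitter_max = 1L,
                         confusion_prob = 0, spurious_rate = 0) {
  stopifnot(deletion_prob >= 0, deletion_prob <= 1,
            jitter_prob >= 0, jitter_prob <= 1,
            confusion_prob >= 0, confusion_prob <= 1,
            spurious_rate >= 0, jitter_max >= 1L)
  structure(list(deletion_prob = deletion_prob, jitter_prob = jitter_prob,
                 jitter_max = as.integer(jitter_max),
                 confusion_prob = confusion_prob,
                 spurious_rate = spurious_rate),
            class = "noise_config")
}

#' Perturb gold annotations with simulated annotator noise
#'
#' Applies, in order: span deletion, label confusion, boundary jitter and
#' spurious insertion (see \code{\link{noise_config}}). Document text is
#' never modified — only the annotations. Deterministic given the seed.
#'
#' @param gold_docs List of \code{ner_document}.
#' @param noise A \code{noise_config}.
#' @param seed RNG seed.
#' @return List of \code{ner_document} with perturbed spans.
#' @export
perturb_annotations <- function(gold_docs, noise, seed) {
  stopifnot(inherits(noise, "noise_config"))
  all_labels <- unlist(lapply(gold_docs, function(d) d$spans$label))
  label_pool <- if (length(all_labels)) all_labels else "stroke"
  with_seed(seed, {
    lapply(gold_docs, function(doc) {
      sp <- doc$spans
      tok <- tokenize(doc$text)
      if (nrow(sp) > 0L) {
        keep <- stats::runif(nrow(sp)) >= noise$deletion_prob
        sp <- sp[keep, , drop = FALSE]
      }
      if (nrow(sp) > 0L && noise$confusion_prob > 0) {
        flip <- stats::runif(nrow(sp)) < noise$confusion_prob
        for (i in which(flip)) {
          others <- setdiff(unique(label_pool), sp$label[i])
          if (length(others))
            sp$label[i] <- sample(others, 1L)
        }
      }
      if (nrow(sp) > 0L && noise$jitter_prob > 0 && nrow(tok) > 0L) {
        jit <- stats::runif(nrow(sp)) < noise$jitter_prob
        for (i in which(jit)) {
          amt <- sample.int(noise$jitter_max, 1L)
          first <- which(tok$end > sp$start[i])[1L]
          last <- utils::tail(which(tok$start < sp$end[i]), 1L)
          if (stats::runif(1) < 0.5 && !is.na(first) && first - amt >= 1L) {
            sp$start[i] <- tok$start[max(first - amt, 1L)]
          } else if (!is.na(last) && last + amt <= nrow(tok)) {
            sp$end[i] <- tok$end[min(last + amt, nrow(tok))]
          } else if (!is.na(first) && first > 1L) {
            sp$start[i] <- tok$start[max(first - amt, 1L)]
          }  # span at both document bounds: left unchanged
        }
        sp$surface <- substring(doc$text, sp$start + 1L, sp$end)
      }
      n_spur <- stats::rpois(1L, noise$spurious_rate)
      if (n_spur > 0L && nrow(tok) > 0L) {
        for (k in seq_len(n_spur)) {
          i <- sample.int(nrow(tok), 1L)
          j <- min(i + sample.int(3L, 1L) - 1L, nrow(tok))
          sp <- rbind(sp, tibble::tibble(
            start = tok$start[i], end = tok$end[j],
            label = sample(label_pool, 1L),
            surface = substring(doc$text, tok$start[i] + 1L, tok$end[j])))
        }
      }
      ner_document(doc$text, sp, doc_id = doc$doc_id,
                   patient_id = doc$patient_id, doc_type = doc$doc_type)
    })
  })
}

#' Patient-level train/test split with cross-validation folds
#'
#' All letters of one patient land on the same side of the split and in the
#' same fold, preventing leakage of patient-specific language. Default
#' proportions follow the emulated study design: roughly 71.5/28.5
#' train/test at patient level, and five folds over the training patients.
#'
#' @param docs List of \code{ner_document}.
#' @param test_fraction Fraction of patients held out.
#' @param k_folds Number of cross-validation folds over training patients.
#' @param seed RNG seed.
#' @return List with \code{train}, \code{test} (document lists),
#'   \code{fold} (integer fold id aligned with \code{train}), and
#'   \code{patient_folds} (named vector patient -> fold; \code{NA} = test).
#' @export
split_patients <- function(docs, test_fraction = 831 / 2912, k_folds = 5L,
                           seed = 1L) {
  if (k_folds < 2L) stop("k_folds must be at least 2")
  pats <- vapply(docs, `[[`, "", "patient_id")
  upats <- unique(pats)
  with_seed(seed, {
    shuffled <- sample(upats)
    n_test <- round(test_fraction * length(upats))
    test_pats <- shuffled[seq_len(n_test)]
    train_pats <- setdiff(shuffled, test_pats)
    fold_of <- stats::setNames(rep(NA_integer_, length(upats)), upats)
    fold_of[train_pats] <- rep_len(seq_len(k_folds), length(train_pats))
    is_test <- pats %in% test_pats
    list(train = docs[!is_test], test = docs[is_test],
         fold = unname(fold_of[pats[!is_test]]),
         patient_folds = fold_of)
  })
}

#' Read a simulator configuration from YAML
#'
#' Accepts the \code{\link{corpus_config}} fields as top-level YAML keys
#' (\code{synonym_pools} as a mapping label -> list of forms,
#' \code{doc_type_mix} as a mapping type -> weight).
#'
#' @param path YAML file.
#' @param ontology Ontology passed through to \code{corpus_config}.
#' @return A \code{corpus_config}.
#' @export
read_corpus_config <- function(path, ontology = load_default_ontology()) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("seed", "n_patients", "total_spans", "labels",
                        "zipf_exponent", "pool_size", "context_pool_size",
                        "docs_per_patient", "fillers_per_doc"))]
  if (!is.null(y$synonym_pools))
    args$synonym_pools <- lapply(y$synonym_pools, as.character)
  if (!is.null(y$doc_type_mix))
    args$doc_type_mix <- unlist(y$doc_type_mix)
  if (!is.null(args$docs_per_patient))
    args$docs_per_patient <- as.numeric(args$docs_per_patient)
  args$ontology <- ontology
  do.call(corpus_config, args)
}
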