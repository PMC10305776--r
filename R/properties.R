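#' Name regularity of a label's surface forms
#'
#' Measures how repetitive the surface forms of one entity label are:
#' \deqn{(N - N_{unique}) / (N - 1)}
#' where \eqn{N} is the number of spans and \eqn{N_{unique}} the number of
#' distinct normalized forms (see \code{\link{normalize_form}}). The
#' statistic is 1 when every span is identical, 0 when every span is
#' different, and interpolates in between with a finite-sample correction
#' (the \eqn{N/(N-1)} factor) so both limits are attained exactly at any
#' \eqn{N}. A single-span list returns 1 by convention.
#'
#' @param surfaces Character vector of surface strings for one label.
#' @return Numeric value in [0, 1].
#' @export
#' @examples
#' name_regularity(rep("aspirin", 10))                   # 1
#' name_regularity(sprintf("form%02d", 1:10))            # 0
#' name_regularity(c("warfarin", "warfarin",
#'                   "warfarin sodium", "coumadin"))     # 1/3
name_regularity <- function(surfaces) {
  if (length(surfaces) == 0L) stop("name_regularity of an empty span list")
  n <- length(surfaces)
  if (n == 1L) return(1)
  nu <- length(unique(normalize_form(surfaces)))
  (n - nu) / (n - 1)
}

#' Word embeddings from a word2vec text file
#'
#' Reads the plain-text word2vec format: a header line \code{<n> <dim>}
#' followed by one \code{word v1 ... v_dim} line per word. Lookup is by
#' lowercased word.
#'
#' @param path Path to the embedding table.
#' @return Object of class \code{word_embeddings}.
#' @export
word2vec_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  stopifnot(length(hdr) == 2L, !anyNA(hdr))
  body <- lines[-1L][nzchar(lines[-1L])]
  parts <- strsplit(trimws(body), "\\s+")
  words <- tolower(vapply(parts, `[[`, "", 1L))
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                  numeric(hdr[2L])))
  rownames(mat) <- words
  structure(list(kind = "table", dim = hdr[2L], table = mat),
            class = "word_embeddings")
}

#' Deterministic hash-based word embeddings
#'
#' A vocabulary-free embedding for testing and simulation: each word maps to
#' a fixed pseudo-random unit-scale vector derived from a polynomial byte
#' hash of the word, so distinct words get near-orthogonal vectors and the
#' same word always gets the same vector. These embeddings carry no
#' semantics; they make context-regularity computations deterministic and
#' dependency-free.
#'
#' @param dim Embedding dimensionality.
#' @return Object of class \code{word_embeddings}.
#' @export
hash_embeddings <- function(dim = 16L) {
  structure(list(kind = "hash", dim = as.integer(dim)),
            class = "word_embeddings")
}

#' @export
print.word_embeddings <- function(x, ...) {
  cat("<word_embeddings> ", x$kind, ", dim ", x$dim,
      if (x$kind == "table") paste0(", ", nrow(x$table), " words"),
      "\n", sep = "")
  invisible(x)
}

hash01 <- function(word, salt) {
  b <- utf8ToInt(paste0(word, "\r", salt))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  h / 2147483646
}

.hash_vec_cache <- new.env(parent = emptyenv())

hash_vector <- function(word, dim) {
  key <- paste0(dim, "\r", word)
  v <- .hash_vec_cache[[key]]
  if (is.null(v)) {
    v <- vapply(seq_len(dim), function(j) 2 * hash01(word, j) - 1, 0)
    .hash_vec_cache[[key]] <- v
  }
  v
}

# Look up lowercased words; OOV rows are NA (hash embeddings have no OOV).
embedding_lookup <- function(emb, words) {
  words <- tolower(words)
  if (emb$kind == "table") {
    idx <- match(words, rownames(emb$table))
    out <- matrix(NA_real_, length(words), emb$dim)
    ok <- !is.na(idx)
    out[ok, ] <- emb$table[idx[ok], , drop = FALSE]
    out
  } else {
    t(vapply(words, hash_vector, numeric(emb$dim), dim = emb$dim))
  }
}

# Mean embedding of the +/- window tokens around one span; NULL when no
# in-vocabulary context token exists.
context_vector <- function(tokens, start, end, emb, window = 5L) {
  left <- which(tokens$end <= start)
  right <- which(tokens$start >= end)
  left <- utils::tail(left, window)
  right <- utils::head(right, window)
  ctx <- tokens$surface[c(left, right)]
  if (length(ctx) == 0L) return(NULL)
  vecs <- embedding_lookup(emb, ctx)
  vecs <- vecs[stats::complete.cases(vecs), , drop = FALSE]
  if (nrow(vecs) == 0L) return(NULL)
  colMeans(vecs)
}

#' Semantic context regularity of a label's mentions
#'
#' For every mention, the up-to-5 tokens on either side of the span are
#' collected (truncated at document bounds), their word embeddings averaged,
#' and the mean vector L2-normalized. The statistic is the mean pairwise
#' cosine similarity over all unordered mention pairs:
#' \deqn{\frac{2}{N(N-1)} \sum_i \sum_{j>i} x_i \cdot x_j .}
#' Out-of-vocabulary context tokens are skipped rather than zero-filled;
#' mentions with no usable context token are dropped and counted. The value
#' lies in [-1, 1]; it is only guaranteed non-negative in embedding spaces
#' with non-negative pairwise similarities.
#'
#' @param mentions Tibble with columns \code{text}, \code{start}, \code{end}
#'   — one row per mention, \code{text} being the mention's full document
#'   text.
#' @param embeddings A \code{word_embeddings} object.
#' @param window Tokens taken on each side (default 5).
#' @return Numeric value, with attributes \code{n_used} and \code{n_skipped};
#'   \code{NA} when fewer than two mentions have usable context.
#' @export
context_regularity <- function(mentions, embeddings, window = 5L) {
  stopifnot(all(c("text", "start", "end") %in% names(mentions)))
  texts <- unique(mentions$text)
  toks <- lapply(texts, tokenize)
  vecs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(mentions))) {
    tok <- toks[[match(mentions$text[i], texts)]]
    v <- context_vector(tok, mentions$start[i], mentions$end[i],
                        embeddings, window)
    if (is.null(v)) { skipped <- skipped + 1L; next }
    nv <- sqrt(sum(v^2))
    if (nv == 0) { skipped <- skipped + 1L; next }
    vecs[[length(vecs) + 1L]] <- v / nv
  }
  mean_pairwise_cosine(vecs, skipped)
}

# Mean pairwise dot product over a list of unit vectors; NA below 2 vectors.
mean_pairwise_cosine <- function(vecs, skipped = 0L) {
  n <- length(vecs)
  if (n < 2L) {
    return(structure(NA_real_, n_used = n, n_skipped = skipped))
  }
  x <- do.call(rbind, vecs)
  gram <- tcrossprod(x)
  val <- sum(gram[upper.tri(gram)]) * 2 / (n * (n - 1))
  structure(val, n_used = n, n_skipped = skipped)
}

#' Per-label property table from a training corpus
#'
#' Computes, for every label with at least one gold span: training-set
#' frequency, its log10, the number of distinct normalized forms, name
#' regularity, and (when embeddings are supplied) context regularity.
#'
#' @param train_docs List of \code{ner_document} with gold spans.
#' @param embeddings Optional \code{word_embeddings}; without it the
#'   context-regularity column is \code{NA}.
#' @param window Context window size per side.
#' @return Tibble with one row per observed label.
#' @export
compute_label_properties <- function(train_docs, embeddings = NULL,
                                     window = 5L) {
  rows <- list()
  for (i in seq_along(train_docs)) {
    sp <- train_docs[[i]]$spans
    if (nrow(sp) == 0L) next
    rows[[length(rows) + 1L]] <-
      tibble::tibble(doc = i, start = sp$start, end = sp$end,
                     label = sp$label, surface = sp$surface)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(label = character(), frequency = integer(),
                          log10_frequency = numeric(), n_unique = integer(),
                          name_regularity = numeric(),
                          context_regularity = numeric(),
                          n_context_used = integer()))
  }
  all <- do.call(rbind, rows)
  labs <- sort(unique(all$label))
  toks <- if (!is.null(embeddings)) {
    lapply(train_docs, function(d) tokenize(d$text))  # tokenize once per doc
  }
  out <- lapply(labs, function(lab) {
    sub <- all[all$label == lab, ]
    cr <- NA_real_; used <- 0L
    if (!is.null(embeddings)) {
      vecs <- list()
      skipped <- 0L
      for (k in seq_len(nrow(sub))) {
        v <- context_vector(toks[[sub$doc[k]]], sub$start[k], sub$end[k],
                            embeddings, window)
        nv <- if (is.null(v)) 0 else sqrt(sum(v^2))
        if (nv == 0) { skipped <- skipped + 1L; next }
        vecs[[length(vecs) + 1L]] <- v / nv
      }
      cr <- mean_pairwise_cosine(vecs, skipped)
      used <- attr(cr, "n_used")
      cr <- as.numeric(cr)
    }
    tibble::tibble(label = lab, frequency = nrow(sub),
                   log10_frequency = log10(nrow(sub)),
                   n_unique = length(unique(normalize_form(sub$surface))),
                   name_regularity = name_regularity(sub$surface),
                   context_regularity = cr, n_context_used = used)
  })
  do.call(rbind, out)
}

#' Regress per-label F1 on the three label properties
#'
#' Ordinary least squares of per-label (lenient) F1 on log10 frequency,
#' name regularity and context regularity, with intercept. Labels with
#' undefined context regularity are dropped and counted. Standard errors
#' are classical; p-values are two-sided from the t distribution.
#'
#' @param properties Tibble from \code{\link{compute_label_properties}}.
#' @param per_label_f1 Tibble with columns \code{label}, \code{f1} (e.g. the
#'   \code{per_label} table of a lenient \code{eval_report}).
#' @return Object of class \code{f1_regression}: list with
#'   \code{coefficients} (tibble term/beta/se/p), \code{r_squared},
#'   \code{n_labels}, \code{n_dropped}, and the underlying \code{lm} fit.
#' @export
regress_f1 <- function(properties, per_label_f1) {
  df <- merge(properties, per_label_f1[, c("label", "f1")], by = "label")
  keep <- stats::complete.cases(
    df[, c("f1", "log10_frequency", "name_regularity",
           "context_regularity")])
  dropped <- sum(!keep)
  df <- df[keep, ]
  if (nrow(df) < 5L)
    stop("need at least 5 labels with all three predictors defined")
  X <- cbind(1, df$log10_frequency, df$name_regularity,
             df$context_regularity)
  if (qr(X)$rank < ncol(X))
    stop("singular design: a predictor is constant or collinear")
  fit <- stats::lm(f1 ~ log10_frequency + name_regularity +
                     context_regularity, data = df)
  s <- summary(fit)
  co <- s$coefficients
  structure(list(
    coefficients = tibble::tibble(term = rownames(co),
                                  beta = unname(co[, 1L]),
                                  se = unname(co[, 2L]),
                                  p = unname(co[, 4L])),
    r_squared = s$r.squared,
    n_labels = nrow(df), n_dropped = dropped, fit = fit),
    class = "f1_regression")
}

#' @export
print.f1_regression <- function(x, ...) {
  cat("<f1_regression> per-label F1 on label properties; n =", x$n_labels,
      "labels")
  if (x$n_dropped) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat(", r^2 =", round(x$r_squared, 3), "\n")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}
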