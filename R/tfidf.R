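# TF-IDF paragraph features. The weighting is implemented exactly as the
# pipeline defines it: TF(t,d) = log(1 + freq(t,d)) with natural logs and
# unsmoothed IDF(t,D) = log(N / df(t)), so a term present in every document
# receives weight 0. Tokenization is lowercase with splits on
# non-alphanumeric runs; both choices are fixed for determinism. A smoothed
# IDF variant (log((1+N)/(1+df)) + 1) is available behind a flag, off by
# default.

fe_tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(v) v[nzchar(v)])
}

#' Fit a TF-IDF vocabulary on a paragraph corpus
#'
#' Records the vocabulary (every token seen), per-term document frequencies
#' and the corpus size N.
#'
#' @param corpus Character vector of documents (>= 1).
#' @param smooth Use smoothed IDF `log((1 + N) / (1 + df)) + 1` instead of
#'   the plain `log(N / df)`. Default `FALSE`.
#' @return A `tfidf_model` with elements `vocabulary` (term -> column
#'   index), `doc_freq`, `n_docs`, `smooth`.
#' @examples
#' m <- tfidf_fit(c("food effect", "absorption rate"))
#' m$doc_freq[["food"]]
#' @export
tfidf_fit <- function(corpus, smooth = FALSE) {
  stopifnot(is.character(corpus))
  if (!length(corpus)) {
    stop("cannot fit TF-IDF on an empty corpus", call. = FALSE)
  }
  toks <- fe_tokenize(corpus)
  terms <- sort(unique(unlist(toks)))
  df <- table(factor(unlist(lapply(toks, unique)), levels = terms))
  structure(
    list(
      vocabulary = setNames(seq_along(terms), terms),
      doc_freq = setNames(as.integer(df), terms),
      n_docs = length(corpus),
      smooth = isTRUE(smooth)
    ),
    class = "tfidf_model"
  )
}

tfidf_idf <- function(model) {
  df <- model$doc_freq
  if (model$smooth) {
    log((1 + model$n_docs) / (1 + df)) + 1
  } else {
    log(model$n_docs / df)
  }
}

#' Transform paragraphs to sparse TF-IDF weight vectors
#'
#' `weight(t, d) = log(1 + freq(t, d)) * IDF(t, D)` for vocabulary terms
#' present in d; out-of-vocabulary tokens are ignored.
#'
#' @param model A fitted `tfidf_model`.
#' @param paragraphs Character vector.
#' @return A sparse `dgCMatrix`, `length(paragraphs)` rows by vocabulary
#'   columns (term names as colnames).
#' @export
tfidf_transform <- function(model, paragraphs) {
  stopifnot(inherits(model, "tfidf_model"), is.character(paragraphs))
  vocab <- model$vocabulary
  idf <- tfidf_idf(model)
  toks <- fe_tokenize(paragraphs)
  triplets <- purrr::imap(toks, function(tk, i) {
    tk <- tk[tk %in% names(vocab)]
    if (!length(tk)) {
      return(NULL)
    }
    counts <- table(tk)
    j <- vocab[names(counts)]
    list(
      i = rep.int(i, length(j)),
      j = unname(j),
      x = log(1 + as.numeric(counts)) * idf[names(counts)]
    )
  })
  triplets <- purrr::compact(triplets)
  Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")) %||% integer(),
    j = unlist(lapply(triplets, `[[`, "j")) %||% integer(),
    x = as.numeric(unlist(lapply(triplets, `[[`, "x")) %||% numeric()),
    dims = c(length(paragraphs), length(vocab)),
    dimnames = list(NULL, names(vocab))
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(
    "<tfidf_model> ", length(x$vocabulary), " terms over ",
    x$n_docs, " documents (", if (x$smooth) "smoothed" else "plain",
    " IDF)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a TF-IDF model
#'
#' @param x A `tfidf_model`.
#' @param ... Unused.
#' @return One row per vocabulary term: `term`, `index`, `doc_freq`, `idf`.
#' @method tidy tfidf_model
#' @export
tidy.tfidf_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$vocabulary),
    index = unname(x$vocabulary),
    doc_freq = unname(x$doc_freq),
    idf = unname(tfidf_idf(x))
  )
}

#' @rdname tidy.tfidf_model
#' @return `glance()` returns a one-row summary: `n_terms`, `n_docs`,
#'   `smooth`.
#' @method glance tfidf_model
#' @export
glance.tfidf_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$vocabulary),
    n_docs = x$n_docs,
    smooth = x$smooth
  )
}
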