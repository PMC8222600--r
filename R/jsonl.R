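# JSON Lines serialization for document and paragraph tables. One record per
# line, UTF-8, deterministic field order so pipeline reruns are byte-identical.

fmt_date <- function(d) {
  if (is.na(d)) NULL else format(d, "%Y-%m-%d")
}

#' Read and write labeling documents as JSON Lines
#'
#' One `LabelDocument` per line. Field order and formatting are fixed so
#' that two runs over identical inputs produce byte-identical files.
#'
#' @param docs A documents tibble (see [label_document()]). Extra columns
#'   beyond the document fields (e.g. `app_number` on an integrated table)
#'   are ignored on write.
#' @param path File path.
#' @return `write_label_documents()` returns `path` invisibly;
#'   `read_label_documents()` returns a documents tibble.
#' @export
write_label_documents <- function(docs, path) {
  lines <- purrr::pmap_chr(
    list(
      docs$source, docs$native_id, docs$app_numbers,
      docs$effective_date, docs$version, docs$sections
    ),
    function(source, native_id, app_numbers, effective_date, version, sections) {
      rec <- list(
        source = jsonlite::unbox(source),
        native_id = jsonlite::unbox(native_id),
        app_numbers = as.character(app_numbers),
        effective_date = fmt_date(effective_date),
        version = if (is.na(version)) NULL else jsonlite::unbox(version),
        sections = as.list(sections)
      )
      jsonlite::toJSON(rec, null = "null", digits = NA)
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_label_documents
#' @export
read_label_documents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) {
    return(empty_document_table())
  }
  purrr::map_dfr(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    label_document(
      source = rec$source,
      native_id = rec$native_id,
      app_numbers = as.character(rec$app_numbers %||% character()),
      effective_date = as.Date(rec$effective_date %||% NA),
      version = as.integer(rec$version %||% NA_integer_),
      sections = unlist(rec$sections) %||% character()
    )
  })
}

empty_document_table <- function() {
  tibble::tibble(
    source = character(), native_id = character(),
    app_numbers = list(), effective_date = as.Date(character()),
    version = integer(), sections = list()
  )
}

#' Read and write labeled paragraphs as JSON Lines
#'
#' One labeled paragraph per line, with its class label, provenance and
#' annotation method.
#'
#' @param paragraphs Tibble with columns `text`, `label`, `source`,
#'   `doc_ref`, `annotation_method` (additional columns are preserved if
#'   atomic).
#' @param path File path.
#' @return `write_labeled_paragraphs()` returns `path` invisibly;
#'   `read_labeled_paragraphs()` a tibble.
#' @export
write_labeled_paragraphs <- function(paragraphs, path) {
  cols <- names(paragraphs)[vapply(paragraphs, is.atomic, logical(1))]
  lines <- vapply(seq_len(nrow(paragraphs)), function(i) {
    rec <- lapply(paragraphs[i, cols, drop = FALSE], function(v) {
      if (is.na(v[[1]])) NULL else jsonlite::unbox(v[[1]])
    })
    as.character(jsonlite::toJSON(rec, null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_labeled_paragraphs
#' @export
read_labeled_paragraphs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  purrr::map_dfr(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l, simplifyVector = TRUE))
  })
}
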