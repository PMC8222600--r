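# Free-text label section extraction. Drugs@FDA labels arrive as PDFs; after
# PDF-to-text conversion (out of scope here - plain text is the input) the
# twelve target sections are located by regex heading detection. A heading
# must occupy a whole line (optionally preceded by an outline number like
# "12.3" and followed by trailing punctuation), which prevents false
# positives on sentences that merely mention a section name. ADMEF headings
# are only recognised inside an already-detected pharmacokinetics region,
# via the same subtitle splitter used for SPL.

#' Heading lexicon for free-text section extraction
#'
#' Maps each section kind to one or more title phrases. Phrases are plain
#' strings compiled to case-insensitive, heading-anchored regexes allowing
#' an optional leading outline number. The lexicon ships as a JSON data
#' file (not code) so deployments can override it wholesale.
#'
#' @param path Optional path to a JSON lexicon; defaults to the packaged
#'   one.
#' @return Named list: section kind -> character vector of phrases.
#' @export
heading_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "heading_lexicon.json",
    package = "druglabel"
  )
  lex <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lex <- lapply(lex, as.character)
  stopifnot(all(names(lex) %in% section_kinds()))
  if (!all(vapply(lex[section_kinds()[section_kinds() %in% names(lex)]],
    length, integer(1)) >= 1L)) {
    stop("every section kind in the lexicon needs at least one pattern")
  }
  lex
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

heading_regex <- function(phrases) {
  sprintf(
    "^(?:[0-9]+(?:\\.[0-9]+)*\\.?\\s+)?(?:%s)\\s*[:.-]?\\s*$",
    paste(escape_regex(phrases), collapse = "|")
  )
}

# Top-level heading kinds; ADMEF + food effect are handled inside the
# pharmacokinetics region by split_pk_subsections().
toplevel_kinds <- function() {
  c(
    "boxed_warning", "indication", "dosage_admin", "pregnancy", "lactation",
    "mechanism_of_action", "pharmacodynamics", "pharmacokinetics"
  )
}

#' Extract labeling sections from free text by heading detection
#'
#' Scans the text line by line for headings of the eight top-level kinds.
#' Each section's content runs from its heading to the next recognised
#' heading (or end of text); headings are excluded from content. The
#' pharmacokinetics content is then split into ADMEF subsections with
#' [split_pk_subsections()]. Matching is case-insensitive and tolerant of
#' outline numbers ("12.3 Pharmacokinetics"). Sections absent from the text
#' are absent from the result.
#'
#' @param text Label text (normalized internally).
#' @param lexicon Heading lexicon, default [heading_lexicon()].
#' @return Named character vector keyed by section kind; empty when no
#'   heading is found.
#' @examples
#' extract_sections_from_text(
#'   "INDICATIONS AND USAGE\ntreats X\n\nDOSAGE AND ADMINISTRATION\ntake Y"
#' )
#' @export
extract_sections_from_text <- function(text, lexicon = heading_lexicon()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- normalize_text(text)
  empty <- setNames(character(0), character(0))
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  kinds <- intersect(toplevel_kinds(), names(lexicon))
  res <- vapply(lexicon[kinds], heading_regex, character(1))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  bufs <- list()
  current <- NA_character_
  for (line in lines) {
    hit <- which(vapply(res, grepl, logical(1),
      x = line, ignore.case = TRUE, perl = TRUE
    ))
    if (length(hit)) {
      current <- kinds[hit[1]]
      if (is.null(bufs[[current]])) bufs[[current]] <- character()
      next
    }
    if (!is.na(current)) {
      bufs[[current]] <- c(bufs[[current]], line)
    }
  }
  if (!length(bufs)) {
    return(empty)
  }
  out <- vapply(bufs, function(x) normalize_text(paste(x, collapse = "\n")),
    character(1)
  )
  out <- out[nzchar(out)]
  if ("pharmacokinetics" %in% names(out)) {
    pk <- split_pk_subsections(out[["pharmacokinetics"]])
    out <- out[names(out) != "pharmacokinetics"]
    out <- c(out, pk)
  }
  if (!length(out)) empty else out
}

parse_freetext_filename <- function(fname) {
  m <- regmatches(
    fname,
    regexec("^((?:NDA|ANDA)?[0-9]{1,6})_([0-9]{8})\\.txt$", fname,
      ignore.case = TRUE
    )
  )[[1]]
  if (!length(m)) {
    return(NULL)
  }
  list(
    app_number = normalize_app_number(m[2])$value,
    date = as.Date(m[3], format = "%Y%m%d")
  )
}

#' Load a plain-text drug label as a document
#'
#' Reads a UTF-8 text file, extracts sections with
#' [extract_sections_from_text()], and attaches the application number and
#' effective date from sidecar metadata: a manifest entry when provided
#' (manifest wins), otherwise the `NDAnnnnnn_YYYYMMDD.txt` filename
#' convention. A file with no metadata anywhere yields an unmapped document
#' (empty application numbers) with a warning.
#'
#' @param path Path to the `.txt` file.
#' @param manifest Optional named list keyed by file name, each entry a list
#'   with `app_number` and/or `date`.
#' @param lexicon Heading lexicon, default [heading_lexicon()].
#' @return A one-row documents tibble with `source = "drugs_at_fda"` and
#'   `native_id` equal to the file name.
#' @export
load_label_text <- function(path, manifest = NULL,
                            lexicon = heading_lexicon()) {
  fname <- basename(path)
  meta <- manifest[[fname]] %||% parse_freetext_filename(fname)
  if (is.null(meta)) {
    warning("no metadata for ", fname, "; document flagged unmapped")
    meta <- list(app_number = character(), date = as.Date(NA))
  }
  app <- meta$app_number %||% character()
  if (length(app)) {
    app <- normalize_app_number(as.character(app))$value
  }
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
    collapse = "\n"
  )
  label_document(
    source = "drugs_at_fda",
    native_id = fname,
    app_numbers = app,
    effective_date = as.Date(meta$date %||% NA),
    sections = extract_sections_from_text(text, lexicon)
  )
}

#' Load a directory of plain-text labels
#'
#' @param dir Directory containing `.txt` label files.
#' @param manifest_path Optional path to a JSON manifest
#'   (`filename -> {app_number, date}`); manifest entries take precedence
#'   over filename metadata.
#' @param lexicon Heading lexicon.
#' @return Documents tibble in sorted file order.
#' @export
read_freetext_corpus <- function(dir, manifest_path = NULL,
                                 lexicon = heading_lexicon()) {
  manifest <- if (!is.null(manifest_path)) {
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  }
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) {
    warning("no .txt files found under ", dir)
    return(empty_document_table())
  }
  purrr::map_dfr(files, load_label_text, manifest = manifest, lexicon = lexicon)
}
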