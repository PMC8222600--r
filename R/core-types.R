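# Shared domain vocabulary and text/identifier plumbing used by every parser.

#' Section vocabulary of the labeling pipeline
#'
#' The pipeline extracts twelve target labeling sections plus their parent
#' section `pharmacokinetics`, which is captured only so that it can be split
#' into its ADMEF subsections (absorption, distribution, metabolism,
#' excretion, food effect).
#'
#' @return `section_kinds()` returns the 13-member closed vocabulary;
#'   `target_sections()` the 12 target sections (everything except
#'   `pharmacokinetics`); `pk_subsections()` the five ADMEF subsection kinds;
#'   `source_names()` the four recognised data sources.
#' @examples
#' section_kinds()
#' setdiff(section_kinds(), target_sections())
#' @export
section_kinds <- function() {
  c(
    "boxed_warning", "indication", "dosage_admin", "pregnancy", "lactation",
    "mechanism_of_action", "pharmacodynamics", "pharmacokinetics",
    "absorption", "distribution", "metabolism", "excretion", "food_effect"
  )
}

#' @rdname section_kinds
#' @export
target_sections <- function() setdiff(section_kinds(), "pharmacokinetics")

#' @rdname section_kinds
#' @export
pk_subsections <- function() {
  c("absorption", "distribution", "metabolism", "excretion", "food_effect")
}

#' @rdname section_kinds
#' @export
source_names <- function() {
  c("orange_book", "drugs_at_fda", "dailymed", "drugbank")
}

#' Normalize raw application-number strings to six-digit FDA form
#'
#' FDA application numbers are unique six-digit identifiers. Sources carry
#' them in assorted spellings (`"NDA021436"`, `"N012345"`, bare `"12345"`);
#' a canonical zero-padded form is required before numbers from different
#' sources can be joined. The application type is inferred from an optional
#' `NDA`/`ANDA`/`N`/`A` prefix.
#'
#' @param raw Character vector. Each element must contain 1--6 digits,
#'   optionally prefixed by `NDA`, `ANDA`, `N` or `A` (case-insensitive).
#' @return A tibble with columns `value` (six-digit, zero-padded character)
#'   and `app_type` (`"NDA"`, `"ANDA"` or `"unknown"`), one row per input.
#' @examples
#' normalize_app_number(c("NDA021436", "12345", "ANDA076543"))
#' @export
normalize_app_number <- function(raw) {
  stopifnot(is.character(raw))
  core <- toupper(trimws(raw))
  app_type <- dplyr::case_when(
    grepl("^ANDA", core) ~ "ANDA",
    grepl("^NDA", core) ~ "NDA",
    grepl("^A[0-9]", core) ~ "ANDA",
    grepl("^N[0-9]", core) ~ "NDA",
    TRUE ~ "unknown"
  )
  digits <- gsub("[^0-9]", "", core)
  bad <- !nzchar(digits) | nchar(digits) > 6L
  if (any(bad)) {
    stop(
      "cannot normalize application number(s): ",
      paste(utils::head(raw[bad], 5L), collapse = ", "),
      " (need 1-6 digits)",
      call. = FALSE
    )
  }
  tibble::tibble(
    value = stringr::str_pad(digits, 6L, pad = "0"),
    app_type = app_type
  )
}

#' Whitespace-normalize labeling text
#'
#' Converts CRLF to LF, collapses runs of horizontal whitespace to a single
#' space, trims every line, and collapses runs of blank lines to exactly one
#' blank line (so paragraph boundaries are preserved as a single blank
#' line). Idempotent.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @examples
#' normalize_text("a  b\r\n\r\n\r\nc")
#' @export
normalize_text <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s)) {
      return(NA_character_)
    }
    s <- gsub("\r\n?", "\n", s)
    s <- gsub("[\t\f\v\u00a0 ]+", " ", s)
    lines <- trimws(strsplit(s, "\n", fixed = TRUE)[[1]])
    if (!length(lines)) {
      return("")
    }
    blank <- !nzchar(lines)
    run_start <- c(TRUE, !blank[-length(blank)])
    lines <- lines[!blank | run_start]
    blank <- !nzchar(lines)
    keep <- cumsum(!blank) > 0 & rev(cumsum(rev(!blank))) > 0
    paste(lines[keep], collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
}

#' Split normalized text into paragraphs
#'
#' The paragraph is the pipeline's minimum text unit. Paragraph boundaries
#' are blank lines; joining the result back with blank-line separators
#' round-trips to the (normalized) input.
#'
#' @param text A single normalized string (see [normalize_text()]).
#' @return Character vector of non-empty paragraphs (possibly length 0).
#' @examples
#' split_paragraphs("A\n\nB")
#' @export
split_paragraphs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(character(0))
  }
  out <- strsplit(text, "\n{2,}")[[1]]
  out[nzchar(trimws(out))]
}

#' Construct a labeling-document record
#'
#' A `LabelDocument` captures one labeling document from one source: its
#' provenance, identifiers, effective date, version, and the extracted
#' section texts. Collections of documents are ordinary tibbles (one row per
#' document, list-columns for `app_numbers` and `sections`) so they compose
#' with dplyr verbs.
#'
#' @param source One of [source_names()].
#' @param native_id The source's own identifier (Set ID for SPL, DrugBank-ID
#'   for DrugBank, file name for free text). Must be non-empty.
#' @param app_numbers Character vector of six-digit FDA application numbers
#'   (possibly empty: an "unmapped" document).
#' @param effective_date A `Date` or `NA`.
#' @param version Integer version number or `NA`.
#' @param sections Named character vector; names must be a subset of
#'   [section_kinds()]. Text is whitespace-normalized on construction.
#' @return A one-row tibble with columns `source`, `native_id`,
#'   `app_numbers` (list), `effective_date`, `version`, `sections` (list).
#' @examples
#' label_document("dailymed", "abc-123", sections = c(indication = "Treats X."))
#' @export
label_document <- function(source, native_id, app_numbers = character(),
                           effective_date = as.Date(NA),
                           version = NA_integer_, sections = character()) {
  stopifnot(
    is.character(source), length(source) == 1L, source %in% source_names(),
    is.character(native_id), length(native_id) == 1L, nzchar(native_id)
  )
  sections <- unlist(sections) %||% character()
  if (length(sections)) {
    bad <- setdiff(names(sections), section_kinds())
    if (length(bad)) {
      stop("unknown section kind(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    sections <- setNames(normalize_text(as.character(sections)), names(sections))
    sections <- sections[nzchar(sections)]
  } else {
    sections <- setNames(character(0), character(0))
  }
  tibble::tibble(
    source = source,
    native_id = native_id,
    app_numbers = list(as.character(app_numbers)),
    effective_date = as.Date(effective_date),
    version = as.integer(version),
    sections = list(sections)
  )
}
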