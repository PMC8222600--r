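# HL7 v3 Structured Product Labeling (SPL) ingestion. DailyMed distributes
# labeling as SPL XML whose sections are keyed by LOINC codes; the five
# pharmacokinetics subsections (ADMEF) have no LOINC codes of their own and
# are recovered by subtitle detection inside the pharmacokinetics section.

#' LOINC code to section-kind map for SPL sections
#'
#' The eight labeling sections that carry LOINC codes in SPL. The ADMEF
#' subsections have no codes and are split out of `43682-4`
#' (pharmacokinetics) by [split_pk_subsections()].
#'
#' @return Named character vector: LOINC code -> section kind.
#' @examples
#' loinc_section_map()
#' @export
loinc_section_map <- function() {
  c(
    "34066-1" = "boxed_warning",
    "34067-9" = "indication",
    "34068-7" = "dosage_admin",
    "42228-7" = "pregnancy",
    "77290-5" = "lactation",
    "43679-0" = "mechanism_of_action",
    "43681-6" = "pharmacodynamics",
    "43682-4" = "pharmacokinetics"
  )
}

# Food-effect subtitle synonyms, exactly as used for annotation.
food_effect_alternation <- function() {
  "food effect|food effects|effect of food|effects of food"
}

pk_subtitle_patterns <- function() {
  c(
    absorption = "absorption",
    distribution = "distribution",
    metabolism = "metabolism",
    excretion = "excretion",
    food_effect = food_effect_alternation()
  )
}

#' Split pharmacokinetics text into ADMEF subsections
#'
#' Detects the subsection subtitles absorption, distribution, metabolism,
#' excretion and food effect (with its synonyms "food effects", "effect of
#' food", "effects of food") appearing either as standalone title lines or
#' as paragraph-leading prefixes followed by `:` or `-`. Content following a
#' subtitle is assigned to that subsection until the next subtitle; content
#' before any subtitle is retained under `pharmacokinetics`. Subtitle text
#' itself is removed from stored content. Matching is case-insensitive.
#'
#' @param pk_text Pharmacokinetics section text (normalized or not).
#' @return Named character vector keyed by section kind. Text without any
#'   subtitle yields only the `pharmacokinetics` key.
#' @examples
#' split_pk_subsections("Absorption:\nA text\n\nFood Effect:\nF text")
#' @export
split_pk_subsections <- function(pk_text) {
  stopifnot(is.character(pk_text), length(pk_text) == 1L)
  pk_text <- normalize_text(pk_text)
  empty <- setNames(character(0), character(0))
  if (is.na(pk_text) || !nzchar(pk_text)) {
    return(empty)
  }
  pats <- pk_subtitle_patterns()
  title_res <- sprintf("^(?:%s)\\s*[:-]?\\s*$", pats)
  prefix_res <- sprintf("^(?:%s)\\s*[:-]\\s*", pats)
  lines <- strsplit(pk_text, "\n", fixed = TRUE)[[1]]
  bufs <- list()
  current <- "pharmacokinetics"
  prev_blank <- TRUE
  for (line in lines) {
    title_hit <- which(vapply(
      title_res, grepl, logical(1),
      x = line, ignore.case = TRUE, perl = TRUE
    ))
    if (length(title_hit)) {
      current <- names(pats)[title_hit[1]]
      prev_blank <- FALSE
      next
    }
    if (prev_blank) {
      prefix_hit <- which(vapply(
        prefix_res, grepl, logical(1),
        x = line, ignore.case = TRUE, perl = TRUE
      ))
      if (length(prefix_hit)) {
        current <- names(pats)[prefix_hit[1]]
        rest <- sub(prefix_res[prefix_hit[1]], "", line,
          ignore.case = TRUE, perl = TRUE
        )
        bufs[[current]] <- c(bufs[[current]], rest)
        prev_blank <- FALSE
        next
      }
    }
    bufs[[current]] <- c(bufs[[current]], line)
    prev_blank <- !nzchar(line)
  }
  out <- vapply(bufs, function(x) normalize_text(paste(x, collapse = "\n")),
    character(1)
  )
  out <- out[nzchar(out)]
  if (!length(out)) {
    return(empty)
  }
  out
}

spl_local <- function(node, name) {
  xml2::xml_find_first(node, sprintf("./*[local-name()='%s']", name))
}

parse_spl_date <- function(value) {
  if (is.na(value) || !nzchar(value)) {
    return(as.Date(NA))
  }
  as.Date(gsub("-", "", value), format = "%Y%m%d")
}

#' Parse an SPL labeling document
#'
#' Extracts the Set ID, version number, effective date (SPL `YYYYMMDD` or
#' `YYYY-MM-DD`), the LOINC-coded sections of [loinc_section_map()] (section
#' text is assembled from the markup's paragraphs, joined with blank lines,
#' and whitespace-normalized), and the FDA application numbers carried by
#' approval elements. The pharmacokinetics section is further split into
#' ADMEF subsections with [split_pk_subsections()]. Element matching is
#' namespace-agnostic because real SPL files vary in namespace declarations.
#'
#' @param x Path to an SPL XML file, or an `xml_document`.
#' @return A one-row documents tibble with `source = "dailymed"` and
#'   `native_id` equal to the Set ID. A document with no Set ID is kept
#'   (flagged by a `spl:`-prefixed fallback id and a warning), not dropped.
#' @export
parse_spl <- function(x) {
  ident <- if (is.character(x)) x else "spl document"
  doc <- tryCatch(
    if (inherits(x, "xml_document")) x else xml2::read_xml(x),
    error = function(e) {
      stop("failed to parse SPL XML [", ident, "]: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  root <- xml2::xml_root(doc)
  set_id <- xml2::xml_attr(spl_local(root, "setId"), "root")
  if (is.na(set_id) || !nzchar(set_id)) {
    warning("SPL document has no setId; flagged unmapped [", ident, "]")
    set_id <- paste0("spl:", basename(ident))
  }
  version <- suppressWarnings(
    as.integer(xml2::xml_attr(spl_local(root, "versionNumber"), "value"))
  )
  eff <- parse_spl_date(xml2::xml_attr(spl_local(root, "effectiveTime"), "value"))

  map <- loinc_section_map()
  sections <- character()
  for (code in names(map)) {
    sec <- xml2::xml_find_first(root, sprintf(
      "//*[local-name()='section'][*[local-name()='code'][@code='%s']]", code
    ))
    if (inherits(sec, "xml_missing")) next
    paras <- xml2::xml_find_all(
      sec, "./*[local-name()='text']/*[local-name()='paragraph']"
    )
    txt <- if (length(paras)) {
      paste(xml2::xml_text(paras), collapse = "\n\n")
    } else {
      xml2::xml_text(spl_local(sec, "text")) %||% ""
    }
    txt <- normalize_text(txt)
    if (!is.na(txt) && nzchar(txt)) {
      sections[[map[[code]]]] <- txt
    }
  }
  if ("pharmacokinetics" %in% names(sections)) {
    pk <- split_pk_subsections(sections[["pharmacokinetics"]])
    sections <- sections[names(sections) != "pharmacokinetics"]
    sections <- c(sections, pk)
  }

  label_document(
    source = "dailymed",
    native_id = set_id,
    app_numbers = extract_app_numbers_spl(doc),
    effective_date = eff,
    version = version,
    sections = sections
  )
}

#' Extract FDA application numbers from an SPL document
#'
#' Collects the identifiers carried by `approval` elements (their `id`
#' extensions, e.g. `NDA021436`), normalizes them with
#' [normalize_app_number()], and de-duplicates preserving document order.
#' An empty result signals an unmapped document.
#'
#' @param x Path to an SPL XML file, or an `xml_document`.
#' @return Character vector of six-digit application numbers (possibly
#'   empty).
#' @export
extract_app_numbers_spl <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  ids <- xml2::xml_find_all(
    doc, "//*[local-name()='approval']/*[local-name()='id']"
  )
  raw <- xml2::xml_attr(ids, "extension")
  raw <- raw[!is.na(raw) & nzchar(raw)]
  if (!length(raw)) {
    return(character())
  }
  unique(normalize_app_number(raw)$value)
}

#' Parse a directory of SPL files
#'
#' @param dir Directory containing `.xml` SPL files.
#' @return Documents tibble, one row per file, in sorted file order.
#' @export
read_spl_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) {
    warning("no .xml files found under ", dir)
    return(empty_document_table())
  }
  purrr::map_dfr(files, parse_spl)
}
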