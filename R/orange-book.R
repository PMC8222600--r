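# Orange Book products-file parsing. The Orange Book is the reference list
# of currently valid FDA-approved drugs; only its NDA application numbers
# are used downstream, as the point of reference for integration.

#' Parse an Orange Book products datafile into an NDA reference set
#'
#' Reads a delimited products file (the distributed file is tilde-delimited
#' with `Appl_Type` and `Appl_No` columns; both are configurable), keeps the
#' New Drug Application rows (`Appl_Type` `"N"`/`"NDA"`), normalizes the
#' application numbers to six-digit form and de-duplicates them. ANDA rows
#' are excluded: the reference set covers NDA numbers only. Rows whose
#' application number cannot be normalized are skipped with a warning
#' rather than aborting.
#'
#' @param path Path to the delimited products file (with header).
#' @param delim Field delimiter, default `"~"`.
#' @param type_col,no_col Names of the application-type and
#'   application-number columns. Defaults `Appl_Type`, `Appl_No`.
#' @param source_version Free-text tag recording the file's date/version.
#' @return A `reference_set`: a tibble with columns `app_number` (sorted,
#'   unique, six-digit) and `app_type` (all `"NDA"`), carrying the
#'   `source_version` attribute.
#' @export
read_orange_book <- function(path, delim = "~",
                             type_col = "Appl_Type", no_col = "Appl_No",
                             source_version = NA_character_) {
  df <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE,
    trim_ws = TRUE
  )
  missing_cols <- setdiff(c(type_col, no_col), names(df))
  if (length(missing_cols)) {
    stop(
      "Orange Book file is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!nrow(df)) {
    warning("Orange Book products file has no rows; reference set is empty")
    return(new_reference_set(character(), source_version))
  }
  type <- toupper(trimws(df[[type_col]]))
  nda <- df[[no_col]][type %in% c("N", "NDA")]
  ok <- vapply(nda, function(x) {
    !is.na(x) && grepl("[0-9]", x) && nchar(gsub("[^0-9]", "", x)) <= 6L
  }, logical(1))
  if (any(!ok)) {
    warning(
      sum(!ok), " row(s) with malformed application numbers skipped"
    )
  }
  values <- if (any(ok)) normalize_app_number(nda[ok])$value else character()
  new_reference_set(sort(unique(values)), source_version)
}

new_reference_set <- function(app_numbers, source_version = NA_character_) {
  out <- tibble::tibble(
    app_number = app_numbers,
    app_type = rep("NDA", length(app_numbers))
  )
  attr(out, "source_version") <- source_version
  class(out) <- c("reference_set", class(out))
  out
}

#' Export a reference set to JSON
#'
#' @param reference A `reference_set` from [read_orange_book()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(reference, path) {
  jsonlite::write_json(
    list(
      source_version = attr(reference, "source_version"),
      app_numbers = reference$app_number
    ),
    path,
    auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}
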