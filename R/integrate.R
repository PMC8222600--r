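# Cross-source integration: explode documents to (application number,
# document) pairs, keep the latest version per (application number, source),
# restrict to the Orange Book reference set, and summarise per-source
# coverage and overlap of drugs and labeling sections.

#' Explode documents to one row per application number
#'
#' Each document appears once under every FDA application number it lists
#' (one-to-many mappings are preserved). Documents with no application
#' numbers are retained with `app_number = NA` - the "unmapped" bucket -
#' so that source-completeness diagnostics remain possible; use
#' [unmapped_documents()] to inspect them. Every input document appears in
#' exactly one of the mapped rows (>= 1 times) or the unmapped bucket.
#'
#' @param docs Documents tibble.
#' @return The documents tibble with an additional leading `app_number`
#'   column (`NA` for unmapped documents) and an internal `.doc_id` column
#'   identifying the originating row.
#' @export
unify_ids <- function(docs) {
  docs <- dplyr::mutate(docs, .doc_id = dplyr::row_number())
  out <- dplyr::mutate(
    docs,
    app_number = purrr::map(.data$app_numbers, function(a) {
      a <- unique(as.character(a))
      if (length(a)) a else NA_character_
    })
  )
  out <- tidyr::unnest(out, "app_number")
  dplyr::select(out, "app_number", dplyr::everything())
}

#' @rdname unify_ids
#' @param unified Output of `unify_ids()`.
#' @export
unmapped_documents <- function(unified) {
  dplyr::filter(unified, is.na(.data$app_number))
}

#' Keep the latest labeling document per application number and source
#'
#' Within each (application number, source) group the candidate with the
#' maximum effective date wins; ties are broken by maximum version number,
#' then by lexicographically greatest native id, making the choice
#' deterministic and invariant to row order. Documents without a date lose
#' to any dated document. Unmapped rows are dropped here.
#'
#' @param unified Output of [unify_ids()].
#' @return One row per (app_number, source).
#' @export
filter_latest <- function(unified) {
  unified <- dplyr::filter(unified, !is.na(.data$app_number))
  date_key <- as.numeric(unified$effective_date)
  date_key[is.na(date_key)] <- -Inf
  version_key <- as.numeric(unified$version)
  version_key[is.na(version_key)] <- -Inf
  unified$.date_key <- date_key
  unified$.version_key <- version_key
  out <- unified |>
    dplyr::group_by(.data$app_number, .data$source) |>
    dplyr::arrange(
      dplyr::desc(.data$.date_key), dplyr::desc(.data$.version_key),
      dplyr::desc(.data$native_id),
      .by_group = TRUE
    ) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$app_number, .data$source)
  dplyr::select(out, -".date_key", -".version_key")
}

#' Restrict an integrated table to the Orange Book reference set
#'
#' Drops rows whose application number is not in the reference, recording
#' the number of rows dropped per source. An empty reference is an error:
#' it would silently empty the table.
#'
#' @param table Output of [filter_latest()].
#' @param reference A `reference_set` from [read_orange_book()].
#' @return The filtered table, classed `integrated_labels`, carrying the
#'   reference (attribute `reference`) and per-source drop counts
#'   (attribute `dropped`).
#' @export
restrict_to_reference <- function(table, reference) {
  if (is.null(reference) || !nrow(reference)) {
    stop("reference set is empty; refusing to drop every row", call. = FALSE)
  }
  keep <- table$app_number %in% reference$app_number
  dropped <- table[!keep, , drop = FALSE] |>
    dplyr::count(.data$source, name = "n_dropped")
  out <- table[keep, , drop = FALSE]
  attr(out, "reference") <- reference
  attr(out, "dropped") <- dropped
  class(out) <- unique(c("integrated_labels", class(out)))
  out
}

#' Integrate parsed documents against a reference set
#'
#' Convenience wrapper: [unify_ids()] then [filter_latest()] then
#' [restrict_to_reference()].
#'
#' @param docs Documents tibble (all sources row-bound).
#' @param reference A `reference_set`.
#' @return An `integrated_labels` table.
#' @export
integrate_documents <- function(docs, reference) {
  restrict_to_reference(filter_latest(unify_ids(docs)), reference)
}

provider_table <- function(table) {
  table |>
    dplyr::transmute(
      app_number = .data$app_number,
      source = .data$source,
      kind = purrr::map(.data$sections, names)
    ) |>
    tidyr::unnest("kind") |>
    dplyr::distinct()
}

#' Per-source coverage of drugs and labeling sections
#'
#' For each section kind the denominator is the number of distinct
#' application numbers for which *any* source provides that section;
#' coverage of source S is the percentage of those applications for which S
#' provides it. The `drug` row uses the reference-set size as denominator
#' and counts the applications each source covers at all. Sections no
#' source provides are absent; a source that never provides a section gets
#' coverage 0.
#'
#' @param table An `integrated_labels` table.
#' @return Tibble with columns `section`, `source`, `n_provided`,
#'   `n_items`, `coverage` (percent in \[0, 100\]).
#' @export
section_coverage <- function(table) {
  if (!nrow(table)) {
    return(tibble::tibble(
      section = character(), source = character(),
      n_provided = integer(), n_items = integer(), coverage = numeric()
    ))
  }
  sources <- sort(unique(table$source))
  prov <- provider_table(table)
  denom <- prov |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(n_items = dplyr::n_distinct(.data$app_number))
  counts <- prov |>
    dplyr::group_by(.data$kind, .data$source) |>
    dplyr::summarise(n_provided = dplyr::n_distinct(.data$app_number),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(kind = denom$kind, source = sources) |>
    dplyr::left_join(counts, by = c("kind", "source")) |>
    dplyr::mutate(n_provided = dplyr::coalesce(.data$n_provided, 0L)) |>
    dplyr::left_join(denom, by = "kind") |>
    dplyr::mutate(coverage = 100 * .data$n_provided / .data$n_items)
  reference <- attr(table, "reference")
  drug <- table |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(n_provided = dplyr::n_distinct(.data$app_number)) |>
    dplyr::mutate(
      kind = "drug",
      n_items = nrow(reference),
      coverage = 100 * .data$n_provided / .data$n_items
    )
  dplyr::bind_rows(grid, drug) |>
    dplyr::transmute(
      section = .data$kind, source = .data$source,
      n_provided = .data$n_provided, n_items = .data$n_items,
      coverage = .data$coverage
    ) |>
    order_report_rows()
}

#' Per-source overlap of drugs and labeling sections
#'
#' Overlap quantifies how much of a source's contribution is shared with
#' the other sources. For section kind k let M be the number of sources
#' providing k for at least one application, and for application i let n_i
#' be the number of sources providing k for i. Then
#' `overlap(S, k) = 100 * mean over i covered by S of (n_i - 1) / (M - 1)`.
#' This is the unique linear form matching both calibration endpoints: a
#' source that is the sole provider everywhere scores 0%, and a source
#' whose every covered application is also covered by all other providers
#' scores 100%. When M = 1 no sharing is possible and overlap is reported
#' as `NA`; a source that never provides k has no overlap value (`NA`).
#'
#' @param table An `integrated_labels` table.
#' @return Tibble with columns `section`, `source`, `overlap` (percent in
#'   \[0, 100\] or `NA`).
#' @export
section_overlap <- function(table) {
  if (!nrow(table)) {
    return(tibble::tibble(
      section = character(), source = character(), overlap = numeric()
    ))
  }
  sources <- sort(unique(table$source))
  prov <- provider_table(table)
  drug_rows <- table |>
    dplyr::distinct(.data$app_number, .data$source) |>
    dplyr::mutate(kind = "drug")
  prov <- dplyr::bind_rows(prov, drug_rows)
  per_item <- prov |>
    dplyr::group_by(.data$kind, .data$app_number) |>
    dplyr::summarise(n_i = dplyr::n_distinct(.data$source), .groups = "drop")
  m_k <- prov |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(m = dplyr::n_distinct(.data$source))
  scored <- prov |>
    dplyr::left_join(per_item, by = c("kind", "app_number")) |>
    dplyr::left_join(m_k, by = "kind") |>
    dplyr::group_by(.data$kind, .data$source) |>
    dplyr::summarise(
      overlap = if (dplyr::first(.data$m) == 1L) {
        NA_real_
      } else {
        100 * mean((.data$n_i - 1) / (.data$m - 1))
      },
      .groups = "drop"
    )
  tidyr::expand_grid(kind = unique(prov$kind), source = sources) |>
    dplyr::left_join(scored, by = c("kind", "source")) |>
    dplyr::transmute(
      section = .data$kind, source = .data$source, overlap = .data$overlap
    ) |>
    order_report_rows()
}

order_report_rows <- function(df) {
  lev <- c(section_kinds(), "drug")
  df |>
    dplyr::mutate(.ord = match(.data$section, lev)) |>
    dplyr::arrange(.data$.ord, .data$source) |>
    dplyr::select(-".ord")
}

#' Combined coverage/overlap report
#'
#' Joins [section_coverage()] and [section_overlap()] into one tidy report,
#' one row per (section, source).
#'
#' @param table An `integrated_labels` table.
#' @return A `coverage_report` tibble with columns `section`, `source`,
#'   `n_provided`, `n_items`, `coverage`, `overlap`.
#' @export
coverage_report <- function(table) {
  out <- dplyr::left_join(
    section_coverage(table), section_overlap(table),
    by = c("section", "source")
  )
  class(out) <- unique(c("coverage_report", class(out)))
  out
}

#' Write a coverage/overlap report as a wide CSV
#'
#' Rows are section kinds (plus the `drug` row); columns are
#' source x (coverage, overlap).
#'
#' @param report A `coverage_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(report, path) {
  wide <- report |>
    dplyr::select("section", "source", "coverage", "overlap") |>
    tidyr::pivot_wider(
      names_from = "source",
      values_from = c("coverage", "overlap"),
      names_glue = "{source}_{.value}"
    )
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
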