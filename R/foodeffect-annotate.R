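# Regex annotation of food-effect paragraphs, and the two rule-based
# baselines. Food-effect content announces itself in two typographic forms:
# a standalone subtitle line ("Food Effect") whose following paragraph is
# the content, or a bold-style prefix at the head of a paragraph
# ("Effect of Food: ..."). Everything else under an absorption heading is
# non-food-effect by default. All matching is case-insensitive.

#' Annotation and rule regexes for food-effect labeling
#'
#' @return A list with the compiled (character) patterns: `title_pattern`
#'   (anchored subtitle line), `prefix_pattern` (paragraph-leading prefix
#'   followed by `:` or `-`), `absorption_title`, `rule1_pattern`
#'   (unanchored phrase match) and `rule2_keyword` (`"food"`). The rule-1
#'   language is a subset of the rule-2 language: every rule-1 phrase
#'   contains "food".
#' @export
annotation_regexes <- function() {
  alt <- food_effect_alternation()
  list(
    title_pattern = sprintf("^(%s)$", alt),
    prefix_pattern = sprintf("^(%s)\\s*(:|-)", alt),
    absorption_title = "^absorption$",
    rule1_pattern = sprintf("(%s)", alt),
    rule2_keyword = "food"
  )
}

#' Annotate absorption-section paragraphs of a document
#'
#' Applies the regex annotation rules to a document's absorption section
#' (and, when the parser already separated it, its food-effect section):
#'
#' * a paragraph immediately following a standalone subtitle line matching
#'   the food-effect title pattern is labeled `food_effect`
#'   (method `regex_title`; the title line is removed);
#' * a paragraph whose head matches the food-effect prefix pattern is
#'   labeled `food_effect` (method `regex_prefix`; the matched prefix is
#'   removed);
#' * every remaining paragraph under the absorption heading is labeled
#'   `non_food_effect` (method `absorption_default`).
#'
#' Paragraphs of an already-extracted `food_effect` section are labeled
#' `food_effect` with method `regex_title` (their subtitle was removed at
#' parse time).
#'
#' @param docs Documents tibble (one or more rows).
#' @return Labeled-paragraph tibble: `text`, `label`, `source`, `doc_ref`,
#'   `annotation_method`. Documents lacking all relevant sections yield no
#'   rows.
#' @export
annotate_absorption_paragraphs <- function(docs) {
  rx <- annotation_regexes()
  rows <- purrr::pmap(
    list(docs$source, docs$native_id, docs$sections),
    function(source, native_id, sections) {
      out <- list()
      if ("absorption" %in% names(sections)) {
        paras <- split_paragraphs(sections[["absorption"]])
        pending_title <- FALSE
        for (p in paras) {
          lines <- strsplit(p, "\n", fixed = TRUE)[[1]]
          if (length(lines) == 1L &&
            grepl(rx$title_pattern, trimws(p), ignore.case = TRUE)) {
            pending_title <- TRUE
            next
          }
          if (pending_title) {
            out[[length(out) + 1L]] <- list(p, "food_effect", "regex_title")
            pending_title <- FALSE
            next
          }
          if (grepl(rx$title_pattern, trimws(lines[1]), ignore.case = TRUE)) {
            body <- normalize_text(paste(lines[-1], collapse = "\n"))
            if (nzchar(body)) {
              out[[length(out) + 1L]] <- list(body, "food_effect", "regex_title")
            }
            next
          }
          if (grepl(rx$prefix_pattern, p, ignore.case = TRUE)) {
            body <- normalize_text(
              sub(rx$prefix_pattern, "", p, ignore.case = TRUE)
            )
            if (nzchar(body)) {
              out[[length(out) + 1L]] <- list(
                body, "food_effect", "regex_prefix"
              )
            }
            next
          }
          out[[length(out) + 1L]] <- list(p, "non_food_effect", "absorption_default")
        }
      }
      if ("food_effect" %in% names(sections)) {
        for (p in split_paragraphs(sections[["food_effect"]])) {
          out[[length(out) + 1L]] <- list(p, "food_effect", "regex_title")
        }
      }
      if (!length(out)) {
        return(NULL)
      }
      tibble::tibble(
        text = vapply(out, `[[`, character(1), 1L),
        label = vapply(out, `[[`, character(1), 2L),
        source = source,
        doc_ref = native_id,
        annotation_method = vapply(out, `[[`, character(1), 3L)
      )
    }
  )
  rows <- purrr::compact(rows)
  if (!length(rows)) {
    return(tibble::tibble(
      text = character(), label = character(), source = character(),
      doc_ref = character(), annotation_method = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Rule-based food-effect baselines
#'
#' Rule 1 labels a paragraph `food_effect` iff the phrase alternation
#' "food effect(s) / effect(s) of food" matches anywhere
#' (case-insensitive). Rule 2 labels it `food_effect` iff the keyword
#' "food" occurs as a substring. Since every rule-1 phrase contains
#' "food", a rule-1 positive is always a rule-2 positive. Both rules have
#' known failure modes: boilerplate such as "Effect of food ... has not
#' been evaluated" is a false positive, and meal-effect wording that never
#' uses the word "food" is a false negative.
#'
#' @param paragraphs Character vector of normalized paragraphs.
#' @return Character vector of labels (`"food_effect"` /
#'   `"non_food_effect"`).
#' @examples
#' rule_based_1("A high-fat meal increased absorption.") # misses
#' rule_based_2("Take with food.")
#' @export
rule_based_1 <- function(paragraphs) {
  rx <- annotation_regexes()
  ifelse(
    grepl(rx$rule1_pattern, paragraphs, ignore.case = TRUE),
    "food_effect", "non_food_effect"
  )
}

#' @rdname rule_based_1
#' @export
rule_based_2 <- function(paragraphs) {
  rx <- annotation_regexes()
  ifelse(
    grepl(rx$rule2_keyword, paragraphs, ignore.case = TRUE, fixed = FALSE),
    "food_effect", "non_food_effect"
  )
}
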