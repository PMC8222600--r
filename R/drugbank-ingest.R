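# DrugBank-style XML datafile ingestion. DrugBank ships one XML file whose
# top-level repeated <drug> elements carry pharmacology text in well-defined
# tags plus commercial product records with FDA application numbers. It has
# no boxed-warning, dosage, pregnancy, lactation or food-effect fields, so
# those kinds are never emitted here.

#' Tag-name to section-kind map for DrugBank drugs
#'
#' The seven content-bearing tags extracted from each `<drug>` element; the
#' eighth extracted element is the FDA application number carried under the
#' drug's products. DrugBank's native spellings are used for distribution
#' (`volume-of-distribution`) and excretion (`route-of-elimination`). The
#' map is overridable via the `field_map` argument of [parse_drugbank()].
#'
#' @return Named character vector: tag name -> section kind.
#' @export
drugbank_field_map <- function() {
  c(
    "indication" = "indication",
    "mechanism-of-action" = "mechanism_of_action",
    "pharmacodynamics" = "pharmacodynamics",
    "absorption" = "absorption",
    "volume-of-distribution" = "distribution",
    "metabolism" = "metabolism",
    "route-of-elimination" = "excretion"
  )
}

#' Parse a DrugBank-style XML datafile
#'
#' Produces one document per `<drug>` element, in file order:
#' `source = "drugbank"`, `native_id` = the primary DrugBank-ID, sections
#' populated from the non-empty [drugbank_field_map()] tags, and
#' application numbers collected from `fda-application-number` elements
#' under the drug's products (a drug may map to several numbers, or none).
#' Drugs with no primary ID are skipped with a warning.
#'
#' @param path Path to the XML datafile.
#' @param field_map Tag-to-kind map, default [drugbank_field_map()].
#' @return Documents tibble, one row per drug.
#' @export
parse_drugbank <- function(path, field_map = drugbank_field_map()) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("failed to parse DrugBank XML [", path, "]: ", conditionMessage(e),
      call. = FALSE
    )
  })
  drugs <- xml2::xml_find_all(doc, "/*/*[local-name()='drug']")
  if (!length(drugs)) {
    return(empty_document_table())
  }
  out <- purrr::map(drugs, function(drug) {
    id_nodes <- xml2::xml_find_all(
      drug, "./*[local-name()='drugbank-id']"
    )
    primary <- xml2::xml_text(
      id_nodes[xml2::xml_attr(id_nodes, "primary") %in% "true"]
    )
    if (!length(primary)) {
      primary <- xml2::xml_text(id_nodes)
    }
    primary <- primary[nzchar(primary)][1]
    if (is.na(primary) || !length(primary)) {
      warning("DrugBank drug element with no primary ID skipped")
      return(NULL)
    }
    sections <- character()
    for (tag in names(field_map)) {
      node <- xml2::xml_find_first(
        drug, sprintf("./*[local-name()='%s']", tag)
      )
      if (inherits(node, "xml_missing")) next
      txt <- normalize_text(xml2::xml_text(node))
      if (!is.na(txt) && nzchar(txt)) {
        sections[[field_map[[tag]]]] <- txt
      }
    }
    app_nodes <- xml2::xml_find_all(
      drug,
      paste0(
        "./*[local-name()='products']/*[local-name()='product']",
        "/*[local-name()='fda-application-number']"
      )
    )
    raw <- xml2::xml_text(app_nodes)
    raw <- raw[nzchar(raw)]
    app_numbers <- if (length(raw)) {
      unique(normalize_app_number(raw)$value)
    } else {
      character()
    }
    label_document(
      source = "drugbank",
      native_id = primary,
      app_numbers = app_numbers,
      sections = sections
    )
  })
  out <- purrr::compact(out)
  if (!length(out)) {
    return(empty_document_table())
  }
  dplyr::bind_rows(out)
}
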