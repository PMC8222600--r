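# In-code fixture builders shared across test files. These are written
# independently of the package's own corpus generator so that parser tests
# do not check the generator against itself.

# Minimal hand-built SPL document string.
spl_xml <- function(set_id = "c040bd1d-45b7-49f2-93ea-aed7220b30ac",
                    version = NULL, effective = NULL,
                    approvals = character(),
                    sections = list(),
                    namespace = "urn:hl7-org:v3") {
  sec <- vapply(names(sections), function(code) {
    paras <- paste0("<paragraph>", sections[[code]], "</paragraph>",
      collapse = ""
    )
    sprintf(
      "<component><section><code code=\"%s\"/><text>%s</text></section></component>",
      code, paras
    )
  }, character(1))
  appr <- vapply(approvals, function(a) {
    sprintf("<approval><id extension=\"%s\"/></approval>", a)
  }, character(1))
  paste0(
    "<?xml version=\"1.0\"?>",
    sprintf("<document xmlns=\"%s\">", namespace),
    if (!is.null(set_id)) sprintf("<setId root=\"%s\"/>", set_id),
    if (!is.null(version)) sprintf("<versionNumber value=\"%s\"/>", version),
    if (!is.null(effective)) sprintf("<effectiveTime value=\"%s\"/>", effective),
    paste0(appr, collapse = ""),
    "<component><structuredBody>",
    paste0(sec, collapse = ""),
    "</structuredBody></component></document>"
  )
}

write_spl_tmp <- function(..., dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "doc.xml")
  writeLines(spl_xml(...), path)
  path
}

# Minimal hand-built DrugBank-style datafile.
drugbank_xml <- function(drugs) {
  body <- vapply(drugs, function(d) {
    fields <- if (is.null(d$fields)) list() else d$fields
    field_xml <- paste0(
      vapply(names(fields), function(tag) {
        sprintf("<%s>%s</%s>", tag, fields[[tag]], tag)
      }, character(1)),
      collapse = ""
    )
    products <- paste0(
      vapply(if (is.null(d$apps)) character() else d$apps, function(a) {
        sprintf(
          "<product><fda-application-number>%s</fda-application-number></product>",
          a
        )
      }, character(1)),
      collapse = ""
    )
    paste0(
      "<drug>",
      if (!is.null(d$id)) sprintf("<drugbank-id primary=\"true\">%s</drugbank-id>", d$id),
      field_xml,
      "<products>", products, "</products>",
      "</drug>"
    )
  }, character(1))
  paste0(
    "<?xml version=\"1.0\"?><drugbank xmlns=\"http://www.drugbank.ca\">",
    paste0(body, collapse = ""), "</drugbank>"
  )
}

write_drugbank_tmp <- function(drugs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "drugbank.xml")
  writeLines(drugbank_xml(drugs), path)
  path
}

# Orange Book-style delimited file from (type, number) pairs.
write_orange_book_tmp <- function(types, numbers, delim = "~",
                                  type_col = "Appl_Type", no_col = "Appl_No",
                                  dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "products.txt")
  lines <- c(
    paste(type_col, no_col, "Trade_Name", sep = delim),
    paste(types, numbers, "X", sep = delim)
  )
  writeLines(lines, path)
  path
}

# Integrated toy table: provide docs as a list of lists
# (app, source, kinds) and a reference vector of app numbers.
toy_integrated <- function(entries, reference) {
  docs <- dplyr::bind_rows(lapply(entries, function(e) {
    label_document(
      source = e$source,
      native_id = paste0(e$source, "-", e$app),
      app_numbers = e$app,
      effective_date = as.Date("2020-01-01"),
      sections = setNames(
        rep("content text", length(e$kinds)), e$kinds
      )
    )
  }))
  restrict_to_reference(
    filter_latest(unify_ids(docs)),
    druglabel:::new_reference_set(reference)
  )
}
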