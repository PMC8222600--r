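make_doc <- function(source, id, apps, date = as.Date("2020-01-01"),
                     version = NA_integer_, kinds = "indication") {
  label_document(source, id,
    app_numbers = apps, effective_date = date, version = version,
    sections = setNames(rep("t", length(kinds)), kinds)
  )
}

test_that("unify_ids preserves one-to-many mappings and routes unmapped documents", {
  docs <- dplyr::bind_rows(
    make_doc("dailymed", "s1", c("000001", "000002")),
    make_doc("drugbank", "d1", character()),
    make_doc("drugs_at_fda", "f1", "000001")
  )
  u <- unify_ids(docs)
  expect_equal(sum(u$native_id == "s1"), 2L)
  expect_setequal(u$app_number[u$native_id == "s1"], c("000001", "000002"))
  expect_equal(unmapped_documents(u)$native_id, "d1")
  expect_equal(sum(u$app_number == "000001", na.rm = TRUE), 2L)
  # conservation: every document lands in the multimap or the unmapped bucket
  expect_setequal(unique(u$.doc_id), seq_len(nrow(docs)))
})

test_that("filter_latest picks max date, then version, then native id, regardless of order", {
  docs <- dplyr::bind_rows(
    make_doc("dailymed", "old", "000001", as.Date("2020-01-01")),
    make_doc("dailymed", "new", "000001", as.Date("2020-06-01")),
    make_doc("dailymed", "v3", "000002", as.Date("2020-06-01"), 3L),
    make_doc("dailymed", "v5", "000002", as.Date("2020-06-01"), 5L),
    make_doc("dailymed", "aaa", "000003", as.Date("2020-06-01"), 1L),
    make_doc("dailymed", "zzz", "000003", as.Date("2020-06-01"), 1L),
    make_doc("dailymed", "undated", "000004", as.Date(NA)),
    make_doc("dailymed", "dated", "000004", as.Date("2019-01-01")),
    make_doc("dailymed", "single", "000005")
  )
  pick <- function(d) {
    out <- filter_latest(unify_ids(d))
    setNames(out$native_id, out$app_number)
  }
  expected <- c(
    "000001" = "new", "000002" = "v5", "000003" = "zzz",
    "000004" = "dated", "000005" = "single"
  )
  expect_equal(pick(docs), expected)
  withr::with_seed(5, {
    for (i in 1:10) {
      expect_equal(pick(docs[sample(nrow(docs)), ]), expected)
    }
  })
})

test_that("reference restriction drops non-reference rows and rejects empty references", {
  docs <- dplyr::bind_rows(
    make_doc("dailymed", "a", "000001"),
    make_doc("drugs_at_fda", "b", "000002")
  )
  table <- filter_latest(unify_ids(docs))
  ref <- druglabel:::new_reference_set("000001")
  out <- restrict_to_reference(table, ref)
  expect_equal(out$app_number, "000001")
  expect_equal(attr(out, "dropped")$n_dropped, 1L)
  expect_lte(nrow(out), nrow(table))
  # superset reference leaves the table unchanged
  ref2 <- druglabel:::new_reference_set(c("000001", "000002", "000003"))
  expect_equal(nrow(restrict_to_reference(table, ref2)), nrow(table))
  expect_error(
    restrict_to_reference(table, druglabel:::new_reference_set(character())),
    "empty"
  )
})

test_that("coverage uses the any-source denominator per section", {
  # boxed_warning: dailymed covers X,Y; drugs_at_fda covers Y; Z lacks it
  it <- toy_integrated(
    list(
      list(app = "000010", source = "dailymed", kinds = c("boxed_warning", "indication")),
      list(app = "000011", source = "dailymed", kinds = c("boxed_warning", "indication")),
      list(app = "000011", source = "drugs_at_fda", kinds = "boxed_warning"),
      list(app = "000012", source = "dailymed", kinds = "indication")
    ),
    reference = c("000010", "000011", "000012")
  )
  cov <- section_coverage(it)
  bw <- cov[cov$section == "boxed_warning", ]
  expect_equal(bw$n_items, rep(2L, nrow(bw)))
  expect_equal(bw$coverage[bw$source == "dailymed"], 100)
  expect_equal(bw$coverage[bw$source == "drugs_at_fda"], 50)
  drug <- cov[cov$section == "drug", ]
  expect_equal(drug$coverage[drug$source == "dailymed"], 100)
  expect_equal(drug$coverage[drug$source == "drugs_at_fda"], 100 / 3)
})

test_that("a source providing a section nowhere has coverage 0 and no overlap", {
  it <- toy_integrated(
    list(
      list(app = "000020", source = "dailymed", kinds = "boxed_warning"),
      list(app = "000020", source = "drugs_at_fda", kinds = "indication")
    ),
    reference = "000020"
  )
  rep <- coverage_report(it)
  row <- rep[rep$section == "boxed_warning" & rep$source == "drugs_at_fda", ]
  expect_equal(row$coverage, 0)
  expect_true(is.na(row$overlap))
})

test_that("overlap endpoints calibrate to 0 and 100 percent", {
  # sole provider everywhere -> 0
  it <- toy_integrated(
    list(
      list(app = "000030", source = "dailymed", kinds = "indication"),
      list(app = "000031", source = "dailymed", kinds = "indication"),
      list(app = "000030", source = "drugbank", kinds = "pharmacodynamics"),
      list(app = "000031", source = "drugbank", kinds = "pharmacodynamics")
    ),
    reference = c("000030", "000031")
  )
  ov <- section_overlap(it)
  # both sources provide their section for disjoint kinds; M = 1 -> NA
  expect_true(is.na(ov$overlap[ov$section == "indication" & ov$source == "dailymed"]))

  # a source sharing none of its items while other providers exist -> 0
  it2 <- toy_integrated(
    list(
      list(app = "000040", source = "dailymed", kinds = "indication"),
      list(app = "000041", source = "drugbank", kinds = "indication"),
      list(app = "000041", source = "drugs_at_fda", kinds = "indication")
    ),
    reference = c("000040", "000041")
  )
  ov2 <- section_overlap(it2)
  expect_equal(
    ov2$overlap[ov2$section == "indication" & ov2$source == "dailymed"], 0
  )

  # every provider always shares with the other two -> 100 for each
  it3 <- toy_integrated(
    unlist(lapply(c("dailymed", "drugbank", "drugs_at_fda"), function(s) {
      list(
        list(app = "000042", source = s, kinds = "indication"),
        list(app = "000043", source = s, kinds = "indication")
      )
    }), recursive = FALSE),
    reference = c("000042", "000043")
  )
  ov3 <- section_overlap(it3)
  expect_equal(ov3$overlap[ov3$section == "indication"], rep(100, 3))
})

test_that("overlap percentages stay within [0, 100] on generated tables", {
  corpus <- generate_corpus(corpus_spec(n_drugs = 15L, seed = 77L), withr::local_tempdir())
  docs <- dplyr::bind_rows(
    read_spl_corpus(corpus$paths$spl_dir),
    read_freetext_corpus(corpus$paths$freetext_dir),
    parse_drugbank(corpus$paths$drugbank_xml)
  )
  it <- integrate_documents(docs, read_orange_book(corpus$paths$orange_book))
  rep <- coverage_report(it)
  expect_true(all(rep$coverage >= 0 & rep$coverage <= 100))
  ovl <- rep$overlap[!is.na(rep$overlap)]
  expect_true(all(ovl >= 0 & ovl <= 100))
})

test_that("the wide CSV report mirrors the section-by-source layout", {
  it <- toy_integrated(
    list(
      list(app = "000050", source = "dailymed", kinds = c("indication", "absorption")),
      list(app = "000050", source = "drugbank", kinds = "indication")
    ),
    reference = "000050"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_coverage_csv(coverage_report(it), path)
  wide <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c("dailymed_coverage", "dailymed_overlap", "drugbank_coverage") %in% names(wide)))
  expect_true("drug" %in% wide$section)
})
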