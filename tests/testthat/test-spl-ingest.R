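test_that("a minimal coded section is extracted under its LOINC kind", {
  path <- write_spl_tmp(sections = list("34066-1" = "X"))
  doc <- parse_spl(path)
  expect_equal(doc$source, "dailymed")
  expect_equal(doc$sections[[1]], c(boxed_warning = "X"))
})

test_that("the Set ID becomes the native id and metadata fields are captured", {
  path <- write_spl_tmp(
    set_id = "c040bd1d-45b7-49f2-93ea-aed7220b30ac",
    version = 4, effective = "20200601",
    sections = list("34067-9" = "treats X")
  )
  doc <- parse_spl(path)
  expect_equal(doc$native_id, "c040bd1d-45b7-49f2-93ea-aed7220b30ac")
  expect_equal(doc$version, 4L)
  expect_equal(doc$effective_date, as.Date("2020-06-01"))
  # dashed date form also accepted
  p2 <- write_spl_tmp(effective = "2020-06-01")
  expect_equal(parse_spl(p2)$effective_date, as.Date("2020-06-01"))
})

test_that("documents without a pharmacokinetics section have no ADMEF subsections", {
  path <- write_spl_tmp(sections = list("34067-9" = "I"))
  doc <- parse_spl(path)
  expect_false(any(pk_subsections() %in% names(doc$sections[[1]])))
})

test_that("the pharmacokinetics section is split into planted ADMEF subsections", {
  path <- write_spl_tmp(sections = list(
    "43682-4" = c("Overview paragraph.", "Absorption:", "A text", "Food Effect: F text")
  ))
  doc <- parse_spl(path)
  secs <- doc$sections[[1]]
  expect_equal(secs[["pharmacokinetics"]], "Overview paragraph.")
  expect_equal(secs[["absorption"]], "A text")
  expect_equal(secs[["food_effect"]], "F text")
})

test_that("approval identifiers are collected, normalized and de-duplicated in order", {
  p1 <- write_spl_tmp(approvals = "NDA021436")
  expect_equal(parse_spl(p1)$app_numbers[[1]], "021436")
  p2 <- write_spl_tmp(approvals = c("NDA021436", "NDA021437", "NDA021436"))
  expect_equal(extract_app_numbers_spl(p2), c("021436", "021437"))
  p3 <- write_spl_tmp()
  expect_equal(extract_app_numbers_spl(p3), character(0))
})

test_that("a document with no setId is flagged unmapped but kept", {
  path <- write_spl_tmp(set_id = NULL, sections = list("34067-9" = "I"))
  expect_warning(doc <- parse_spl(path), "unmapped")
  expect_true(nzchar(doc$native_id))
  expect_equal(doc$sections[[1]], c(indication = "I"))
})

test_that("malformed XML raises a parse error naming the document", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "broken.xml")
  writeLines("<document><unclosed>", path)
  expect_error(parse_spl(path), "broken.xml")
})

test_that("parsing is namespace-agnostic", {
  p1 <- write_spl_tmp(sections = list("34066-1" = "X"), namespace = "urn:hl7-org:v3")
  p2_dir <- withr::local_tempdir()
  p2 <- file.path(p2_dir, "doc.xml")
  writeLines(gsub("xmlns=\"urn:hl7-org:v3\"", "", spl_xml(sections = list("34066-1" = "X"))), p2)
  expect_equal(parse_spl(p1)$sections[[1]], parse_spl(p2)$sections[[1]])
})

test_that("pharmacokinetics subtitle synonyms and prefix styles are recognized", {
  out <- split_pk_subsections("Effect of Food\nF text")
  expect_equal(out, c(food_effect = "F text"))
  out2 <- split_pk_subsections("Distribution - plasma binding text")
  expect_equal(out2, c(distribution = "plasma binding text"))
  out3 <- split_pk_subsections("no subtitles here")
  expect_equal(out3, c(pharmacokinetics = "no subtitles here"))
  expect_equal(split_pk_subsections(""), setNames(character(0), character(0)))
})

test_that("subsection splitting loses no non-title content", {
  withr::with_seed(31, {
    kinds <- c("Absorption", "Distribution", "Metabolism", "Excretion", "Food Effect")
    for (i in 1:20) {
      chosen <- sample(kinds, sample(1:5, 1))
      contents <- vapply(seq_along(chosen), function(k) {
        paste(sample(c("alpha", "beta", "gamma", "delta", "kappa"), 6, replace = TRUE),
          collapse = " "
        )
      }, character(1))
      text <- paste(paste0(chosen, ":\n", contents), collapse = "\n\n")
      out <- split_pk_subsections(text)
      for (ct in contents) {
        expect_true(any(vapply(out, function(o) grepl(ct, o, fixed = TRUE), logical(1))))
      }
    }
  })
})
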