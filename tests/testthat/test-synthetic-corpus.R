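small_spec <- function(seed = 11L, ...) corpus_spec(n_drugs = 12L, seed = seed, ...)

test_that("generators are pure functions of the spec: reruns are byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(small_spec(), d1)
  generate_corpus(small_spec(), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, f1))),
    unname(tools::md5sum(file.path(d2, f2)))
  )
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  generate_corpus(small_spec(seed = 12L), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, f1))),
    unname(tools::md5sum(file.path(d3, sort(list.files(d3, recursive = TRUE)))))
  ))
})

test_that("SPL documents round-trip exactly against the manifest", {
  dir <- withr::local_tempdir()
  manifest <- generate_spl_corpus(small_spec(), dir)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    doc <- parse_spl(row$file)
    expect_identical(doc$native_id, row$set_id)
    expect_identical(doc$version, as.integer(row$version))
    expect_identical(doc$effective_date, row$effective_date)
    expect_identical(doc$app_numbers[[1]], row$app_numbers[[1]])
    exp <- row$sections[[1]]
    got <- doc$sections[[1]]
    expect_identical(sort(names(got)), sort(names(exp)))
    expect_identical(unname(got[names(exp)]), unname(exp))
  }
})

test_that("free-text labels round-trip exactly at noise rate zero", {
  dir <- withr::local_tempdir()
  manifest <- generate_freetext_labels(small_spec(), dir)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    doc <- load_label_text(row$file)
    expect_identical(doc$app_numbers[[1]], row$app_number)
    expect_identical(doc$effective_date, row$effective_date)
    exp <- row$sections[[1]]
    got <- doc$sections[[1]]
    expect_identical(sort(names(got)), sort(names(exp)))
    expect_identical(unname(got[names(exp)]), unname(exp))
  }
})

test_that("noisy free-text labels still yield only planted section kinds", {
  dir <- withr::local_tempdir()
  manifest <- generate_freetext_labels(small_spec(noise_rate = 0.5), dir)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    got <- load_label_text(row$file)$sections[[1]]
    expect_true(all(names(got) %in% names(row$sections[[1]])))
  }
})

test_that("the DrugBank datafile round-trips against the manifest", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "drugbank.xml")
  manifest <- generate_drugbank_xml(small_spec(), path)
  docs <- parse_drugbank(path)
  expect_equal(nrow(docs), nrow(manifest))
  expect_identical(docs$native_id, manifest$drugbank_id)
  for (i in seq_len(nrow(manifest))) {
    expect_identical(docs$app_numbers[[i]], manifest$app_numbers[[i]])
    exp <- manifest$sections[[i]]
    got <- docs$sections[[i]]
    expect_identical(sort(names(got)), sort(names(exp)))
    expect_identical(unname(got[names(exp)]), unname(exp))
  }
})

test_that("the default corpus exercises every parser branch", {
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(corpus_spec(n_drugs = 30L, seed = 5L), dir)
  spl <- corpus$spl
  # unmapped documents and one-to-many identifier mappings
  expect_true(any(lengths(spl$app_numbers) == 0L))
  expect_true(any(lengths(spl$app_numbers) == 2L))
  expect_true(any(lengths(corpus$drugbank$app_numbers) == 0L))
  expect_true(any(lengths(corpus$drugbank$app_numbers) == 2L))
  # multi-version documents share a Set ID with increasing dates
  multi <- spl |>
    dplyr::group_by(set_id) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::arrange(version, .by_group = TRUE)
  expect_gt(nrow(multi), 0L)
  by_set <- split(multi$effective_date, multi$set_id)
  expect_true(all(vapply(by_set, function(d) all(diff(d) > 0), logical(1))))
  # some sections absent, PK with and without subtitles
  kinds <- lapply(spl$sections, names)
  expect_true(any(!vapply(kinds, function(k) "boxed_warning" %in% k, logical(1))))
  expect_true(any(vapply(kinds, function(k) "pharmacokinetics" %in% k, logical(1))))
  expect_true(any(vapply(kinds, function(k) "food_effect" %in% k, logical(1))))
  # non-reference labels exist so the restriction step has work to do
  expect_true(any(!corpus$freetext$in_reference))
  # orange book reference excludes the planted ANDA rows
  ref <- read_orange_book(corpus$paths$orange_book)
  expect_identical(ref$app_number, corpus$reference)
})

test_that("labeled paragraph generation is deterministic with exact class counts", {
  p1 <- generate_foodeffect_paragraphs(50, 30, adversarial_fraction = 0.2, seed = 9)
  p2 <- generate_foodeffect_paragraphs(50, 30, adversarial_fraction = 0.2, seed = 9)
  expect_identical(p1, p2)
  expect_equal(sum(p1$label == "food_effect"), 50L)
  expect_equal(sum(p1$label == "non_food_effect"), 30L)
  expect_equal(sum(p1$adversarial & p1$label == "food_effect"), 10L)
  expect_equal(sum(p1$adversarial & p1$label == "non_food_effect"), 6L)
  expect_setequal(unique(p1$source), c("dailymed", "drugs_at_fda"))
})

test_that("non-adversarial paragraphs are rule-separable by construction", {
  p <- generate_foodeffect_paragraphs(50, 50, adversarial_fraction = 0, seed = 13)
  rep1 <- evaluate_labels(rule_based_1(p$text), p$label)
  expect_equal(rep1$f1, 1)
  rep2 <- evaluate_labels(rule_based_2(p$text), p$label)
  expect_equal(rep2$f1, 1)
})

test_that("rule-based errors occur exactly on the adversarial flags", {
  p <- generate_foodeffect_paragraphs(50, 50, adversarial_fraction = 0.2, seed = 17)
  expect_identical(rule_based_1(p$text) != p$label, p$adversarial)
  expect_identical(rule_based_2(p$text) != p$label, p$adversarial)
})

test_that("archetype templates carry their defining lexical properties", {
  p <- generate_foodeffect_paragraphs(40, 40, adversarial_fraction = 0.5, seed = 19)
  nal <- p$text[p$archetype %in% "naloxegol"]
  met <- p$text[p$archetype %in% "methadone"]
  expect_gt(length(nal), 0L)
  expect_gt(length(met), 0L)
  expect_false(any(grepl("food", nal, ignore.case = TRUE)))
  expect_true(all(grepl("effect", met, ignore.case = TRUE) &
    grepl("food", met, ignore.case = TRUE)))
})
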