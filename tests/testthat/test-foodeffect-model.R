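test_that("evaluation metrics match their closed forms and flag degenerate cases", {
  rep <- evaluate_labels(
    c(rep("food_effect", 10), rep("non_food_effect", 2)),
    c(rep("food_effect", 9), "non_food_effect", "food_effect", "non_food_effect")
  )
  expect_equal(rep$tp, 9L)
  expect_equal(rep$fp, 1L)
  expect_equal(rep$fn, 1L)
  expect_equal(rep$precision, 0.9)
  expect_equal(rep$recall, 0.9)
  expect_equal(rep$f1, 0.9)
  expect_false(rep$degenerate)

  perfect <- evaluate_labels(rep("food_effect", 5), rep("food_effect", 5))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  degen <- evaluate_labels(
    c("non_food_effect", "food_effect"),
    c("food_effect", "non_food_effect")
  )
  expect_equal(c(degen$precision, degen$recall, degen$f1), c(0, 0, 0))
  expect_true(degen$degenerate)

  expect_error(evaluate_labels("food_effect", character()), "equal length")
})

test_that("evaluation matches brute-force confusion counting on random vectors", {
  lv <- c("food_effect", "non_food_effect")
  withr::with_seed(303, {
    for (i in 1:200) {
      n <- sample(1:40, 1)
      pred <- sample(lv, n, replace = TRUE)
      truth <- sample(lv, n, replace = TRUE)
      rep <- evaluate_labels(pred, truth)
      tp <- 0L
      fp <- 0L
      fn <- 0L
      for (j in seq_len(n)) {
        if (pred[j] == "food_effect" && truth[j] == "food_effect") tp <- tp + 1L
        if (pred[j] == "food_effect" && truth[j] == "non_food_effect") fp <- fp + 1L
        if (pred[j] == "non_food_effect" && truth[j] == "food_effect") fn <- fn + 1L
      }
      expect_identical(c(rep$tp, rep$fp, rep$fn), c(tp, fp, fn))
    }
  })
})

test_that("classifier training validates inputs", {
  m <- tfidf_fit(c("meal increased auc", "bioavailability is high"))
  x <- tfidf_transform(m, c("meal increased auc", "bioavailability is high"))
  expect_error(
    train_classifier(x, rep("food_effect", 2), "logreg"),
    "single class"
  )
  expect_error(
    train_classifier(x, c("food_effect", "non_food_effect"), "xgboost"),
    "should be one of"
  )
})

test_that("TF-IDF classifiers separate an easy synthetic set and repeat deterministically", {
  pool <- generate_foodeffect_paragraphs(120, 120, adversarial_fraction = 0, seed = 21)
  parts <- split_train_test(pool, 0.8, seed = 22)
  for (algo in c("logreg", "linear_svc", "random_forest")) {
    model <- fe_train(parts$train, algo = algo, seed = 23)
    rep <- evaluate_labels(predict(model, parts$test), parts$test$label)
    expect_gte(rep$f1, 0.95)
    model2 <- fe_train(parts$train, algo = algo, seed = 23)
    expect_identical(predict(model, parts$test), predict(model2, parts$test))
  }
})

test_that("dataset assembly is source-balanced, seed-deterministic and guarded", {
  pool <- generate_foodeffect_paragraphs(100, 100, seed = 31)
  ds <- build_dataset(pool, 10, seed = 32)
  expect_equal(nrow(ds), 20L)
  expect_equal(as.integer(table(ds$source)), c(10L, 10L))
  expect_identical(ds, build_dataset(pool, 10, seed = 32))
  expect_error(build_dataset(pool, 150, seed = 32), "pool too small")
})

test_that("train/test splitting is disjoint, exhaustive and source-stratified", {
  pool <- generate_foodeffect_paragraphs(50, 50, seed = 41)
  parts <- split_train_test(pool, 0.8, seed = 42)
  expect_equal(nrow(parts$train), 80L)
  expect_equal(nrow(parts$test), 20L)
  joined <- dplyr::bind_rows(parts$train, parts$test)
  expect_setequal(joined$doc_ref, pool$doc_ref)
  expect_length(intersect(parts$train$doc_ref, parts$test$doc_ref), 0L)
  expect_equal(as.integer(table(parts$train$source)), c(40L, 40L))
  parts2 <- split_train_test(pool, 0.8, seed = 42)
  expect_identical(parts, parts2)
  expect_error(split_train_test(pool, 1.2), "train_fraction")
})

test_that("the cross-source grid has nine leakage-free combinations in table order", {
  pool <- generate_foodeffect_paragraphs(120, 120, adversarial_fraction = 0.1, seed = 51)
  grid <- cross_source_eval(pool, algo = "logreg", seed = 52)
  expect_equal(nrow(grid), 9L)
  combos <- c("combined", "dailymed", "drugs_at_fda")
  expect_equal(grid$test, rep(combos, each = 3))
  expect_equal(grid$train, rep(combos, times = 3))
  expect_true(all(grid$f1 >= 0 & grid$f1 <= 1))
  combined_f1 <- grid$f1[grid$train == "combined" & grid$test == "combined"]
  single <- grid$f1[grid$train != "combined" & grid$test == grid$train]
  expect_gte(combined_f1, max(single) - 0.05)
})

test_that("learning curves have one point per algorithm and size, with guards", {
  pool <- generate_foodeffect_paragraphs(80, 80, seed = 61)
  parts <- split_train_test(pool, 0.8, seed = 62)
  lc <- learning_curve(parts$train, parts$test,
    algos = c("logreg", "random_forest"),
    sizes = c(40, 80), seed = 63, reps = 1
  )
  expect_equal(nrow(lc), 4L)
  expect_true(all(lc$mean_f1 >= 0 & lc$mean_f1 <= 1))
  lc2 <- learning_curve(parts$train, parts$test,
    algos = c("logreg", "random_forest"),
    sizes = c(40, 80), seed = 63, reps = 1
  )
  expect_identical(lc, lc2)
  expect_error(
    learning_curve(parts$train, parts$test, sizes = 10000, seed = 1),
    "exceeds"
  )
})

test_that("manual review corrections override automatic labels", {
  pool <- generate_foodeffect_paragraphs(5, 5, seed = 71)
  pool$id <- seq_len(nrow(pool))
  flipped <- pool$label[1]
  review <- tibble::tibble(
    id = 1L,
    label = ifelse(flipped == "food_effect", "non_food_effect", "food_effect")
  )
  out <- apply_manual_review(pool, review)
  expect_equal(out$label[1], review$label)
  expect_equal(out$annotation_method[1], "manual")
  expect_identical(apply_manual_review(pool, NULL), pool)
})

test_that("tidy and glance expose classifier structure", {
  pool <- generate_foodeffect_paragraphs(40, 40, seed = 81)
  for (algo in c("logreg", "linear_svc", "random_forest")) {
    model <- fe_train(pool, algo = algo, seed = 82)
    td <- tidy(model)
    expect_true(all(c("term", "weight") %in% names(td)))
    expect_gt(nrow(td), 10L)
    gl <- glance(model)
    expect_equal(gl$algo, algo)
    expect_equal(gl$n_train, 80L)
  }
})
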