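# Food-effect paragraph classification: dataset assembly, train/test
# splitting, classical classifiers over TF-IDF features, evaluation
# metrics, cross-source generalization grids and learning curves.

fe_label_levels <- function() c("non_food_effect", "food_effect")

#' Precision/recall/F1 evaluation of paragraph labels
#'
#' Counts true positives, false positives and false negatives with
#' `food_effect` as the positive class, then derives precision
#' TP/(TP+FP), recall TP/(TP+FN) and F1 = 2PR/(P+R). When a denominator
#' vanishes the metric is reported as 0 and the `degenerate` flag is set,
#' keeping reports total.
#'
#' @param pred,truth Equal-length character vectors of labels.
#' @param positive Positive class, default `"food_effect"`.
#' @return An `eval_report`: one-row tibble `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `degenerate`.
#' @examples
#' evaluate_labels(
#'   rep(c("food_effect", "non_food_effect"), c(10, 2)),
#'   rep(c("food_effect", "non_food_effect"), c(9, 3))
#' )
#' @export
evaluate_labels <- function(pred, truth, positive = "food_effect") {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- TRUE
    0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- TRUE
    0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- TRUE
    0
  }
  out <- tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    degenerate = degenerate
  )
  class(out) <- unique(c("eval_report", class(out)))
  out
}

#' Train a food-effect classifier on precomputed features
#'
#' Fits one of the three supported algorithms on a feature matrix:
#' `logreg` (ridge-penalized logistic regression via glmnet with a small
#' fixed penalty), `linear_svc` (linear-kernel SVM, cost 1), or
#' `random_forest` (ranger, 300 trees, single-threaded for
#' reproducibility). Training is deterministic given `seed`. A training
#' set with a single class, or an unknown algorithm name, is an error.
#'
#' @param features Numeric matrix or sparse `dgCMatrix` (rows = examples).
#' @param labels Character labels aligned with the rows.
#' @param algo One of `"logreg"`, `"linear_svc"`, `"random_forest"`.
#' @param seed Integer seed.
#' @return An `fe_fit` object with a [predict][predict.fe_fit] method.
#' @export
train_classifier <- function(features, labels,
                             algo = c("logreg", "linear_svc", "random_forest"),
                             seed = 1L) {
  algo <- match.arg(algo)
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  y <- factor(labels, levels = fe_label_levels())
  fit <- withr::with_seed(seed, switch(algo,
    logreg = glmnet::glmnet(
      features, y,
      family = "binomial", alpha = 0, lambda = 0.01
    ),
    linear_svc = e1071::svm(
      as.matrix(features), y,
      kernel = "linear", cost = 1, scale = FALSE
    ),
    random_forest = ranger::ranger(
      x = as.matrix(features), y = y,
      num.trees = 300, seed = seed, num.threads = 1,
      importance = "impurity"
    )
  ))
  structure(
    list(algo = algo, fit = fit, seed = seed, n_train = length(labels)),
    class = "fe_fit"
  )
}

#' @export
predict.fe_fit <- function(object, features, ...) {
  out <- switch(object$algo,
    logreg = as.character(
      predict(object$fit, features, type = "class")[, 1]
    ),
    linear_svc = as.character(predict(object$fit, as.matrix(features))),
    random_forest = as.character(
      predict(object$fit,
        data = as.matrix(features), num.threads = 1
      )$predictions
    )
  )
  unname(out)
}

#' Fit a TF-IDF classifier pipeline on labeled paragraphs
#'
#' Fits the TF-IDF vocabulary on the training paragraphs and a classifier
#' on the resulting features; the returned object predicts labels directly
#' from raw paragraph text.
#'
#' @param train Tibble with columns `text` and `label`.
#' @param algo Classifier name, see [train_classifier()].
#' @param seed Integer seed.
#' @param smooth Smoothed IDF flag, see [tfidf_fit()].
#' @return An `fe_classifier` holding the `tfidf_model` and the `fe_fit`.
#' @export
fe_train <- function(train, algo = "random_forest", seed = 1L,
                     smooth = FALSE) {
  stopifnot(all(c("text", "label") %in% names(train)))
  tfidf <- tfidf_fit(train$text, smooth = smooth)
  fit <- train_classifier(
    tfidf_transform(tfidf, train$text), train$label,
    algo = algo, seed = seed
  )
  structure(
    list(tfidf = tfidf, fit = fit, algo = algo, seed = seed),
    class = "fe_classifier"
  )
}

#' @export
predict.fe_classifier <- function(object, newdata, ...) {
  text <- if (is.data.frame(newdata)) newdata$text else newdata
  predict(object$fit, tfidf_transform(object$tfidf, text))
}

#' @export
print.fe_classifier <- function(x, ...) {
  cat(
    "<fe_classifier> ", x$algo, " on ", length(x$tfidf$vocabulary),
    " TF-IDF terms (n_train = ", x$fit$n_train, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a fitted food-effect classifier
#'
#' Returns per-term weights: glmnet coefficients for `logreg`, the primal
#' weight vector for `linear_svc`, impurity importance for
#' `random_forest`.
#'
#' @param x An `fe_classifier`.
#' @param ... Unused.
#' @return Tibble `term`, `weight`, sorted by decreasing absolute weight.
#' @method tidy fe_classifier
#' @export
tidy.fe_classifier <- function(x, ...) {
  w <- switch(x$algo,
    logreg = {
      beta <- x$fit$fit$beta[, 1]
      setNames(as.numeric(beta), rownames(x$fit$fit$beta))
    },
    linear_svc = {
      sv <- x$fit$fit
      setNames(
        as.numeric(crossprod(sv$coefs, sv$SV)),
        colnames(sv$SV)
      )
    },
    random_forest = x$fit$fit$variable.importance
  )
  tibble::tibble(term = names(w), weight = unname(w)) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @rdname tidy.fe_classifier
#' @method glance fe_classifier
#' @export
glance.fe_classifier <- function(x, ...) {
  tibble::tibble(
    algo = x$algo,
    n_terms = length(x$tfidf$vocabulary),
    n_train = x$fit$n_train,
    seed = x$seed
  )
}

#' Assemble a source-balanced modeling dataset
#'
#' Draws a uniform random sample without replacement of `n_per_source`
#' paragraphs from each source's pool. Sources are balanced by design;
#' class proportions follow the pools (no class re-balancing). The
#' selection is deterministic given `seed`.
#'
#' @param pools Labeled-paragraph tibble with a `source` column.
#' @param n_per_source Records to draw from each source.
#' @param seed Integer seed.
#' @return Tibble of `n_per_source * n_sources` rows.
#' @export
build_dataset <- function(pools, n_per_source, seed = 1L) {
  stopifnot(all(c("text", "label", "source") %in% names(pools)))
  sources <- sort(unique(pools$source))
  counts <- table(pools$source)
  short <- sources[counts[sources] < n_per_source]
  if (length(short)) {
    stop(
      "pool too small for source(s): ", paste(short, collapse = ", "),
      " (need ", n_per_source, ")",
      call. = FALSE
    )
  }
  withr::with_seed(seed, {
    picked <- lapply(sources, function(s) {
      rows <- which(pools$source == s)
      sort(sample(rows, n_per_source))
    })
    pools[unlist(picked), , drop = FALSE]
  })
}

#' Split a dataset into train and test partitions
#'
#' Random, disjoint, exhaustive split at `train_fraction`, stratified by
#' source so each source keeps the same train/test ratio (to rounding).
#' Deterministic given `seed`.
#'
#' @param dataset Labeled-paragraph tibble (with a `source` column for
#'   stratification; a missing column means a single stratum).
#' @param train_fraction Fraction for training, strictly between 0 and 1.
#'   Default 0.8.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  if (!nrow(dataset)) stop("dataset is empty", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  strata <- if ("source" %in% names(dataset)) dataset$source else
    rep("all", nrow(dataset))
  withr::with_seed(seed, {
    train_idx <- unlist(lapply(sort(unique(strata)), function(s) {
      rows <- which(strata == s)
      n_train <- round(length(rows) * train_fraction)
      n_train <- max(1L, min(length(rows) - 1L, n_train))
      sample(rows, n_train)
    }))
  })
  train_idx <- sort(train_idx)
  list(
    train = dataset[train_idx, , drop = FALSE],
    test = dataset[-train_idx, , drop = FALSE]
  )
}

#' Compare rule-based and TF-IDF methods on one split
#'
#' Evaluates the two rule-based baselines and the requested classifiers on
#' a common train/test split, producing one report row per method.
#'
#' @param train,test Labeled-paragraph tibbles.
#' @param algos Classifier names to fit.
#' @param seed Integer seed.
#' @return Tibble with a `method` column followed by the
#'   [evaluate_labels()] columns.
#' @export
eval_methods <- function(train, test,
                         algos = c("logreg", "linear_svc", "random_forest"),
                         seed = 1L) {
  rule_rows <- list(
    rule_based_1 = evaluate_labels(rule_based_1(test$text), test$label),
    rule_based_2 = evaluate_labels(rule_based_2(test$text), test$label)
  )
  ml_rows <- lapply(setNames(algos, algos), function(a) {
    model <- fe_train(train, algo = a, seed = seed)
    evaluate_labels(predict(model, test), test$label)
  })
  dplyr::bind_rows(c(rule_rows, ml_rows), .id = "method")
}

#' Cross-source train/test generalization grid
#'
#' Splits each source's records with a common seed, forms the `combined`
#' partition as the union of the per-source partitions (so no test record
#' ever appears in any train set), and fits/evaluates the classifier for
#' all nine train x test combinations, in the grid order combined,
#' dailymed, drugs_at_fda within each test block.
#'
#' @param dataset Labeled-paragraph tibble with a two-source `source`
#'   column.
#' @param algo Classifier name.
#' @param seed Integer seed.
#' @param train_fraction Per-source split fraction, default 0.8.
#' @return Tibble of nine rows: `train`, `test`, then the metric columns.
#' @export
cross_source_eval <- function(dataset, algo = "random_forest", seed = 1L,
                              train_fraction = 0.8) {
  sources <- sort(unique(dataset$source))
  dataset <- dplyr::mutate(dataset, .id = dplyr::row_number())
  parts <- lapply(setNames(sources, sources), function(s) {
    split_train_test(
      dplyr::filter(dataset, .data$source == s),
      train_fraction = train_fraction, seed = seed
    )
  })
  combined <- list(
    train = dplyr::bind_rows(lapply(parts, `[[`, "train")),
    test = dplyr::bind_rows(lapply(parts, `[[`, "test"))
  )
  parts$combined <- combined
  order_names <- c("combined", sources)
  train_ids <- lapply(parts, function(p) p$train$.id)
  test_ids <- lapply(parts, function(p) p$test$.id)
  for (tr in names(parts)) {
    for (te in names(parts)) {
      if (length(intersect(train_ids[[tr]], test_ids[[te]]))) {
        stop("train/test leakage between partitions ", tr, " and ", te,
          call. = FALSE
        )
      }
    }
  }
  models <- lapply(parts, function(p) fe_train(p$train, algo = algo, seed = seed))
  grid <- expand.grid(
    train = order_names, test = order_names,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("train", "test")]
  grid <- grid[order(match(grid$test, order_names)), ]
  out <- purrr::pmap(grid, function(train, test) {
    rep <- evaluate_labels(
      predict(models[[train]], parts[[test]]$test),
      parts[[test]]$test$label
    )
    dplyr::bind_cols(tibble::tibble(train = train, test = test), rep)
  })
  dplyr::bind_rows(out)
}

#' Learning curve of test F1 against training-set size
#'
#' For each algorithm and size, subsamples the training set without
#' replacement, fits the TF-IDF classifier, and evaluates F1 on the fixed
#' test set; results are averaged over `reps` repetitions. Deterministic
#' given `seed`. A requested size larger than the training set is an
#' error. Subsampling is uniform, so at very small sizes a draw can be
#' single-class and fail to train; choose sizes accordingly.
#'
#' @param train,test Labeled-paragraph tibbles.
#' @param algos Classifier names.
#' @param sizes Increasing vector of training-set sizes.
#' @param seed Integer seed.
#' @param reps Repetitions per point, default 3.
#' @return A `fe_learning_curve` tibble: `algo`, `size`, `mean_f1`,
#'   `n_reps`.
#' @export
learning_curve <- function(train, test,
                           algos = c("logreg", "linear_svc", "random_forest"),
                           sizes, seed = 1L, reps = 3L) {
  stopifnot(reps >= 1L)
  if (max(sizes) > nrow(train)) {
    stop("requested size ", max(sizes), " exceeds training set (",
      nrow(train), ")",
      call. = FALSE
    )
  }
  grid <- expand.grid(
    algo = algos, size = sort(sizes), rep = seq_len(reps),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  f1 <- purrr::pmap_dbl(grid, function(algo, size, rep) {
    idx <- withr::with_seed(
      seed + 7919L * rep + size,
      sample(nrow(train), size)
    )
    model <- fe_train(train[idx, , drop = FALSE],
      algo = algo, seed = seed + rep
    )
    evaluate_labels(predict(model, test), test$label)$f1
  })
  grid$f1 <- f1
  out <- grid |>
    dplyr::group_by(.data$algo, .data$size) |>
    dplyr::summarise(
      mean_f1 = mean(.data$f1), n_reps = dplyr::n(), .groups = "drop"
    )
  class(out) <- unique(c("fe_learning_curve", class(out)))
  out
}

#' Merge a manual review file into an annotated paragraph set
#'
#' The automatic regex annotation is designed to be manually checked; this
#' merges a review table of corrected labels (paragraph id -> label) over
#' the automatic ones. With an empty review (the default situation) the
#' input is returned unchanged.
#'
#' @param paragraphs Labeled-paragraph tibble with an `id` column (one is
#'   added from the row number when absent).
#' @param review Tibble with columns `id` and `label`, or `NULL`.
#' @return The paragraph tibble with corrected labels and
#'   `annotation_method = "manual"` on corrected rows.
#' @export
apply_manual_review <- function(paragraphs, review = NULL) {
  if (!"id" %in% names(paragraphs)) {
    paragraphs <- dplyr::mutate(paragraphs, id = dplyr::row_number())
  }
  if (is.null(review) || !nrow(review)) {
    return(paragraphs)
  }
  stopifnot(all(c("id", "label") %in% names(review)))
  idx <- match(review$id, paragraphs$id)
  changed <- !is.na(idx) & paragraphs$label[idx] != review$label
  paragraphs$label[idx[changed]] <- review$label[changed]
  paragraphs$annotation_method[idx[changed]] <- "manual"
  paragraphs
}
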