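# End-to-end offline pipeline: generate the synthetic corpus, ingest all
# four formats, integrate against the Orange Book reference, and run the
# food-effect classification study. Every artifact is written in a
# deterministic text format (JSONL/CSV) so that identical configurations
# produce byte-identical output trees.

#' Run the full labeling-extraction pipeline on a synthetic corpus
#'
#' Stages: (1) generate the four-format corpus from `spec`; (2) parse SPL,
#' free-text and DrugBank documents; (3) unify identifiers, keep latest
#' versions, restrict to the Orange Book reference and write the
#' coverage/overlap report; (4) build the source-balanced food-effect
#' dataset, split 80/20, fit the rule-based baselines and TF-IDF
#' classifiers, and write the method-comparison and cross-source reports.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer master seed; every random stage derives from it.
#' @param spec Corpus spec; default `corpus_spec(n_drugs = 30, seed = seed)`.
#' @param n_pos,n_neg,adversarial_fraction Food-effect pool composition.
#' @param n_per_source Dataset records drawn per source.
#' @param algos Classifier names for the method comparison.
#' @param train_fraction Train share of the dataset, default 0.8.
#' @return (Invisibly) a list with the in-memory results (`docs`,
#'   `integrated`, `coverage`, `dataset`, `methods`, `cross_source`) and
#'   the written `paths`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         spec = corpus_spec(n_drugs = 30L, seed = seed),
                         n_pos = 150L, n_neg = 150L,
                         adversarial_fraction = 0.2,
                         n_per_source = 100L,
                         algos = c("logreg", "linear_svc", "random_forest"),
                         train_fraction = 0.8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    corpus = file.path(out_dir, "corpus"),
    docs = file.path(out_dir, "documents.jsonl"),
    integrated = file.path(out_dir, "integrated.jsonl"),
    coverage = file.path(out_dir, "coverage_overlap.csv"),
    dataset = file.path(out_dir, "foodeffect_dataset.jsonl"),
    methods = file.path(out_dir, "method_comparison.csv"),
    cross_source = file.path(out_dir, "cross_source_grid.csv")
  )

  corpus <- generate_corpus(spec, paths$corpus)
  reference <- read_orange_book(corpus$paths$orange_book)
  docs <- dplyr::bind_rows(
    read_spl_corpus(corpus$paths$spl_dir),
    read_freetext_corpus(corpus$paths$freetext_dir),
    parse_drugbank(corpus$paths$drugbank_xml)
  )
  write_label_documents(docs, paths$docs)

  integrated <- integrate_documents(docs, reference)
  write_label_documents(integrated, paths$integrated)
  coverage <- coverage_report(integrated)
  write_coverage_csv(coverage, paths$coverage)

  pools <- generate_foodeffect_paragraphs(
    n_pos, n_neg,
    adversarial_fraction = adversarial_fraction, seed = seed + 1L
  )
  dataset <- build_dataset(pools, n_per_source = n_per_source, seed = seed + 2L)
  write_labeled_paragraphs(dataset, paths$dataset)
  parts <- split_train_test(dataset,
    train_fraction = train_fraction, seed = seed + 3L
  )
  methods <- eval_methods(parts$train, parts$test,
    algos = algos, seed = seed + 4L
  )
  readr::write_csv(methods, paths$methods, progress = FALSE)
  grid <- cross_source_eval(dataset,
    algo = "random_forest", seed = seed + 5L,
    train_fraction = train_fraction
  )
  readr::write_csv(grid, paths$cross_source, progress = FALSE)

  invisible(list(
    docs = docs, reference = reference, integrated = integrated,
    coverage = coverage, dataset = dataset, methods = methods,
    cross_source = grid, paths = paths
  ))
}
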