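# End-to-end orchestration: generate -> preprocess -> extract (excluding
# INCOMPLETE reports, mirroring the study's exclusion of reports lacking
# complete information) -> score -> train the classifier on the training
# split -> predict on both splits -> metrics, confusion matrices and the
# error breakdown. Deterministic under one seed.

#' Run the full difficulty-prediction pipeline on a synthetic corpus
#'
#' Generates a seeded corpus, extracts the four features from every report,
#' excludes non-COMPLETE extractions, trains the neural classifier on the
#' training split (extracted features, gold class labels) and evaluates
#' predictions against gold classes on both splits.
#'
#' @param gen_cfg A [generator_config()].
#' @param clf_cfg A [classifier_config()].
#' @param lex A `feature_lexicon`.
#' @param seed Optional master seed; when given it overrides `gen_cfg$seed`
#'   and sets `clf_cfg$seed` to `seed + 1`.
#' @return A `pipeline_result` list: `corpus`, `results` (per-report gold +
#'   extraction + prediction table), `model`, per-split `confusion`
#'   matrices, `metrics`, `errors`, `excluded` counts and `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(generator_config(n_reports = 80, train_count = 60,
#'                                      val_count = 20, seed = 3))
#' res$metrics$validation$accuracy
#' }
#' @export
run_pipeline <- function(gen_cfg = generator_config(),
                         clf_cfg = classifier_config(),
                         lex = build_default_lexicon(),
                         seed = NULL) {
  if (!is.null(seed)) {
    gen_cfg$seed <- as.integer(seed)
    clf_cfg$seed <- as.integer(seed) + 1L
  }
  corpus <- generate_corpus(gen_cfg, lex)
  ext <- extract_corpus(corpus, lex)
  names(ext)[names(ext) %in% unname(FEATURE_COLS)] <-
    paste0("ex_", unname(FEATURE_COLS))
  names(ext)[names(ext) == "total"] <- "ex_total"
  names(ext)[names(ext) == "class"] <- "rule_class"
  results <- cbind(corpus[, setdiff(names(corpus), "text")],
                   ext[, setdiff(names(ext), "report_id")])
  results$text <- corpus$text
  results <- tibble::as_tibble(results)

  complete <- results$status == "COMPLETE"
  train_rows <- which(results$split == "train" & complete)
  val_rows <- which(results$split == "validation" & complete)
  excluded <- list(
    train = sum(results$split == "train" & !complete),
    validation = sum(results$split == "validation" & !complete)
  )
  feat_cols <- paste0("ex_", unname(FEATURE_COLS))
  train_X <- results[train_rows, feat_cols]
  names(train_X) <- unname(FEATURE_COLS)
  model <- train_classifier(train_X, results$gold_class[train_rows], clf_cfg)

  results$pred_class <- NA_character_
  for (rows in list(train_rows, val_rows)) {
    if (length(rows) == 0L) next
    X <- results[rows, feat_cols]
    names(X) <- unname(FEATURE_COLS)
    results$pred_class[rows] <- predict(model, X)
  }

  split_eval <- function(rows, split_name) {
    cm <- confusion(results$gold_class[rows], results$pred_class[rows])
    err <- categorize_errors(
      results[results$split == split_name, , drop = FALSE], lex
    )
    list(confusion = cm, metrics = classification_metrics(cm), errors = err)
  }
  tr <- split_eval(train_rows, "train")
  va <- split_eval(val_rows, "validation")

  structure(
    list(
      corpus = corpus,
      results = results,
      model = model,
      confusion = list(train = tr$confusion, validation = va$confusion),
      metrics = list(train = tr$metrics, validation = va$metrics),
      errors = list(train = tr$errors, validation = va$errors),
      excluded = excluded,
      config = list(generator = gen_cfg, classifier = clf_cfg)
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$corpus), "reports;",
      "train accuracy", round(x$metrics$train$accuracy, 4),
      "/ validation accuracy", round(x$metrics$validation$accuracy, 4), "\n")
  cat("  excluded as incomplete: train", x$excluded$train,
      "validation", x$excluded$validation, "\n")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes the corpus JSONL, the per-report feature/prediction table (CSV),
#' per-split confusion matrices (CSV), metrics (JSON) and the error
#' breakdown (JSON).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus_jsonl(result$corpus, file.path(dir, "corpus.jsonl"))
  utils::write.csv(
    result$results[, setdiff(names(result$results), c("text", "omitted"))],
    file.path(dir, "features.csv"), row.names = FALSE
  )
  for (split in c("train", "validation")) {
    utils::write.csv(result$confusion[[split]],
                     file.path(dir, paste0("confusion_", split, ".csv")))
  }
  metrics <- lapply(result$metrics, function(m) {
    list(per_class = m$per_class, macro = m$macro, micro = m$micro,
         accuracy = m$accuracy)
  })
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$errors, file.path(dir, "errors.json"),
                       auto_unbox = TRUE)
  utils::write.csv(result$model$training_history,
                   file.path(dir, "training_history.csv"), row.names = FALSE)
  invisible(dir)
}
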