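# Multiclass evaluation: confusion matrix, precision/recall/F1 per class
# with macro (and micro) aggregates, and a three-way error taxonomy for
# pipeline mistakes: tokenizer errors (segmentation broke an
# otherwise-matching synonym), concept errors (wrong or missed feature
# extraction) and classification errors (correct features, wrong class).
# The categories are mutually exclusive per erroneous report, assigned in
# the order tokenizer -> concept -> classification.

#' Confusion matrix over the four difficulty classes
#'
#' @param gold,pred Character or factor vectors of class labels (D1..D4),
#'   equal length. Rows are the true classes, columns the predictions.
#' @return A 4x4 integer matrix with dimnames `gold` and `pred`.
#' @examples
#' confusion(c("D1", "D2"), c("D1", "D3"))
#' @export
confusion <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred differ in length (", length(gold), " vs ",
         length(pred), ")", call. = FALSE)
  }
  if (length(gold) == 0L) stop("need at least one case", call. = FALSE)
  g <- factor(as.character(gold), levels = DIFFICULTY_LABELS)
  p <- factor(as.character(pred), levels = DIFFICULTY_LABELS)
  if (anyNA(g) || anyNA(p)) {
    stop("labels must be one of ", paste(DIFFICULTY_LABELS, collapse = ", "),
         call. = FALSE)
  }
  m <- table(gold = g, pred = p)
  matrix(as.integer(m), 4L, 4L,
         dimnames = list(gold = DIFFICULTY_LABELS, pred = DIFFICULTY_LABELS))
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class: precision is the diagonal over the column sum, recall the
#' diagonal over the row sum, F1 their harmonic mean; empty denominators
#' yield 0 rather than NaN. The `macro` aggregates are unweighted means over
#' the four classes; `micro` aggregates pool counts (for single-label
#' multiclass they all equal the accuracy).
#'
#' @param cm 4x4 confusion matrix from [confusion()].
#' @return A list: `per_class` tibble (class, precision, recall, f1,
#'   support), `macro` and `micro` lists of precision/recall/f1, and
#'   `accuracy`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 4L))
  if (sum(cm) < 1L) stop("confusion matrix is empty", call. = FALSE)
  diagv <- diag(cm)
  colv <- colSums(cm)
  rowv <- rowSums(cm)
  precision <- ifelse(colv > 0, diagv / colv, 0)
  recall <- ifelse(rowv > 0, diagv / rowv, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  acc <- sum(diagv) / sum(cm)
  list(
    per_class = tibble::tibble(
      class = DIFFICULTY_LABELS,
      precision = unname(precision),
      recall = unname(recall),
      f1 = unname(f1),
      support = as.integer(unname(rowv))
    ),
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    micro = list(precision = acc, recall = acc, f1 = acc),
    accuracy = acc
  )
}

# does the token sequence `phrase_tokens` occur in `tokens`?
.contains_seq <- function(tokens, phrase_tokens) {
  k <- length(phrase_tokens)
  n <- length(tokens)
  if (k == 0L || k > n) return(FALSE)
  for (p in which(tokens == phrase_tokens[[1L]])) {
    if (p + k - 1L <= n && all(tokens[p:(p + k - 1L)] == phrase_tokens)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Categorize pipeline errors per evaluated report
#'
#' Each erroneous report receives exactly one category, checked in order:
#' `tokenizer_errors` — a synonym of a wrongly-extracted feature's gold
#' category occurs as a token sequence in the full normalized text but
#' within no single sentence, i.e. segmentation broke the phrase;
#' `concept_errors` — extraction resolved a wrong category or missed one
#' present in the gold annotation; `classification_errors` — the feature
#' vector is correct but the predicted class is not. Reports that are
#' gold-incomplete by construction and correctly flagged INCOMPLETE are not
#' errors.
#'
#' @param results A data frame with one row per evaluated report and
#'   columns `text`, the four gold score columns (`angulation`,
#'   `root_count`, `root_curvature`, `canal`), `gold_class`,
#'   `gold_incomplete` (logical), `status`, extracted score columns
#'   prefixed `ex_`, and `pred_class` (NA when the report was excluded).
#' @param lex The `feature_lexicon` used for extraction (needed for the
#'   tokenizer-error check).
#' @return A list: `tokenizer_errors`, `concept_errors`,
#'   `classification_errors`, `total_errors`.
#' @export
categorize_errors <- function(results, lex) {
  cols <- unname(FEATURE_COLS)
  tab <- lexicon_table(lex)
  tok_err <- 0L; con_err <- 0L; cls_err <- 0L
  for (i in seq_len(nrow(results))) {
    row <- results[i, ]
    if (isTRUE(row$gold_incomplete)) {
      if (identical(row$status, "INCOMPLETE")) next
    }
    extracted_ok <- identical(row$status, "COMPLETE") &&
      all(vapply(cols, function(c) {
        isTRUE(row[[paste0("ex_", c)]] == row[[c]])
      }, logical(1)))
    if (!extracted_ok) {
      wrong <- cols[vapply(cols, function(c) {
        !isTRUE(row[[paste0("ex_", c)]] == row[[c]])
      }, logical(1))]
      doc <- segment_report(row$text)
      all_tokens <- tokenize(doc$normalized_text)$tokens
      is_tok <- FALSE
      for (col in wrong) {
        fid <- names(FEATURE_COLS)[FEATURE_COLS == col]
        gold_cat_score <- row[[col]]
        syns <- tab$synonym[tab$feature_id == fid & tab$score == gold_cat_score]
        for (s in syns) {
          st <- tokenize(s)$tokens
          in_full <- .contains_seq(all_tokens, st)
          in_sent <- any(vapply(doc$sentences$tokens, .contains_seq,
                                logical(1), phrase_tokens = st))
          if (in_full && !in_sent) {
            is_tok <- TRUE
            break
          }
        }
        if (is_tok) break
      }
      if (is_tok) tok_err <- tok_err + 1L else con_err <- con_err + 1L
    } else if (!is.na(row$pred_class) && row$pred_class != row$gold_class) {
      cls_err <- cls_err + 1L
    }
  }
  list(
    tokenizer_errors = tok_err,
    concept_errors = con_err,
    classification_errors = cls_err,
    total_errors = tok_err + con_err + cls_err
  )
}
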