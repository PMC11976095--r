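# Rule-based concept extraction.
#
# Greedy longest-match dictionary scan over each sentence's token sequence,
# followed by per-feature resolution with negation handling, a last-sentence
# tie-break across sentences, and the exclusion contract for reports lacking
# complete information.

NEGATION_CUES <- c("no", "not", "without", "denies")
NEGATION_WINDOW <- 3L

# precompute tokenized synonyms for fast per-sentence scanning
compile_lexicon_index <- function(lex) {
  tab <- lexicon_table(lex)
  tab$syn_tokens <- lapply(tab$synonym, function(s) tokenize(s)$tokens)
  tab$n_tokens <- vapply(tab$syn_tokens, length, integer(1))
  tab$first_token <- vapply(
    tab$syn_tokens, function(t) if (length(t)) t[[1L]] else "", character(1)
  )
  # longest-match priority: token count desc, then lexicographic on phrase
  tab[order(-tab$n_tokens, tab$synonym), ]
}

#' Match lexicon concepts in a segmented document
#'
#' Scans each sentence greedily, longest phrase first: once a token span is
#' consumed by a match, shorter overlapping synonyms cannot match inside it
#' (so "no contact" is never read as "contact"). A surviving mention is
#' flagged `negated` when a negation cue ("no", "not", "without", "denies")
#' occurs within 3 tokens before it and that cue is not itself part of a
#' matched phrase.
#'
#' @param doc A `cbct_document` from [segment_report()].
#' @param lex A `feature_lexicon`.
#' @param index Optional precompiled index from an internal call; computed
#'   from `lex` when missing.
#' @return A tibble of concept mentions: `feature_id`, `category`, `score`,
#'   `matched_phrase`, `sentence_index`, `start`, `end` (0-based half-open,
#'   within the sentence) and `negated`.
#' @examples
#' lex <- build_default_lexicon()
#' doc <- segment_report("the roots show no contact with the mandibular canal")
#' match_concepts(doc, lex)
#' @export
match_concepts <- function(doc, lex, index = NULL) {
  stopifnot(inherits(doc, "cbct_document"))
  if (is.null(index)) index <- compile_lexicon_index(lex)
  out <- list()
  for (si in seq_len(nrow(doc$sentences))) {
    toks <- doc$sentences$tokens[[si]]
    starts <- doc$sentences$token_starts[[si]]
    stext <- doc$sentences$text[[si]]
    n <- length(toks)
    if (n == 0L) next
    # candidate spans in priority order
    cand <- list()
    present <- unique(toks)
    for (r in which(index$first_token %in% present)) {
      st <- index$syn_tokens[[r]]
      k <- length(st)
      if (k > n) next
      for (p in which(toks == st[[1L]])) {
        if (p + k - 1L > n) next
        if (k == 1L || all(toks[p:(p + k - 1L)] == st)) {
          cand[[length(cand) + 1L]] <- list(row = r, at = p, len = k)
        }
      }
    }
    if (length(cand) == 0L) next
    occupied <- rep(FALSE, n)
    accepted <- list()
    for (cd in cand) {      # `cand` inherits the index's priority order
      span <- cd$at:(cd$at + cd$len - 1L)
      if (any(occupied[span])) next
      occupied[span] <- TRUE
      accepted[[length(accepted) + 1L]] <- cd
    }
    covered <- occupied
    for (cd in accepted) {
      i0 <- cd$at
      i1 <- cd$at + cd$len - 1L
      ch_start <- starts[[i0]]
      ch_end <- starts[[i1]] + nchar(toks[[i1]])
      win <- seq.int(max(1L, i0 - NEGATION_WINDOW), i0 - 1L)
      win <- win[win >= 1L & win < i0]
      negated <- length(win) > 0L &&
        any(toks[win] %in% NEGATION_CUES & !covered[win])
      r <- cd$row
      out[[length(out) + 1L]] <- tibble::tibble(
        feature_id = index$feature_id[[r]],
        category = index$category[[r]],
        score = index$score[[r]],
        matched_phrase = substr(stext, ch_start + 1L, ch_end),
        sentence_index = doc$sentences$index[[si]],
        start = ch_start,
        end = ch_end,
        negated = negated
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      feature_id = character(0), category = character(0), score = integer(0),
      matched_phrase = character(0), sentence_index = integer(0),
      start = integer(0), end = integer(0), negated = logical(0)
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$sentence_index, res$start), ]
}

#' Resolve concept mentions to one category per feature
#'
#' Per feature: negated mentions are dropped; if the survivors agree on one
#' category it is resolved; if they disagree across sentences the category
#' from the last mentioning sentence wins (radiology impressions
#' conventionally conclude the report); two categories of the same feature in
#' one sentence make the feature conflicting. A report with any unresolved
#' feature is INCOMPLETE — mirroring the exclusion of reports lacking
#' complete information — and INCOMPLETE takes precedence over CONFLICT when
#' both occur; otherwise a same-sentence contradiction yields CONFLICT.
#'
#' @param mentions Mention tibble from [match_concepts()] (single report).
#' @param report_id Report identifier carried into the result.
#' @return An `extraction_result`: list with `report_id`, `status`
#'   ("COMPLETE", "INCOMPLETE" or "CONFLICT"), `scores` (named integer
#'   vector, NA where unresolved), `categories` (named character),
#'   `features` (complete named score vector, only when COMPLETE),
#'   `missing_features`, `conflicting_features` and `mentions`.
#' @export
resolve_features <- function(mentions, report_id = "doc") {
  scores <- stats::setNames(rep(NA_integer_, 4L), unname(FEATURE_COLS))
  categories <- stats::setNames(rep(NA_character_, 4L), unname(FEATURE_COLS))
  missing <- character(0)
  conflicting <- character(0)
  for (fid in FEATURE_IDS) {
    col <- FEATURE_COLS[[fid]]
    m <- mentions[mentions$feature_id == fid & !mentions$negated, , drop = FALSE]
    if (nrow(m) == 0L) {
      missing <- c(missing, fid)
      next
    }
    conflict <- FALSE
    for (s in unique(m$sentence_index)) {
      if (length(unique(m$category[m$sentence_index == s])) > 1L) {
        conflict <- TRUE
        break
      }
    }
    if (conflict) {
      conflicting <- c(conflicting, fid)
      next
    }
    last <- m[m$sentence_index == max(m$sentence_index), , drop = FALSE]
    scores[[col]] <- last$score[[nrow(last)]]
    categories[[col]] <- last$category[[nrow(last)]]
  }
  status <- if (length(missing) > 0L) {
    "INCOMPLETE"
  } else if (length(conflicting) > 0L) {
    "CONFLICT"
  } else {
    "COMPLETE"
  }
  structure(
    list(
      report_id = report_id,
      status = status,
      scores = scores,
      categories = categories,
      features = if (status == "COMPLETE") scores else NULL,
      missing_features = missing,
      conflicting_features = conflicting,
      mentions = mentions
    ),
    class = "extraction_result"
  )
}

#' Extract the four features from one report
#'
#' Convenience wrapper: segments, matches concepts and resolves features.
#'
#' @param text Raw report text (or a `cbct_document`).
#' @param lex A `feature_lexicon`.
#' @param report_id Identifier for the report.
#' @inheritParams match_concepts
#' @return An `extraction_result`; see [resolve_features()].
#' @examples
#' lex <- build_default_lexicon()
#' extract_features("the third molar is distoangular", lex)$scores
#' @export
extract_features <- function(text, lex, report_id = "doc", index = NULL) {
  doc <- if (inherits(text, "cbct_document")) text else segment_report(text, report_id)
  resolve_features(match_concepts(doc, lex, index = index), doc$report_id)
}

#' Extract features from every report in a corpus
#'
#' @param corpus A data frame with columns `report_id` and `text` (for
#'   example the output of [generate_corpus()]).
#' @param lex A `feature_lexicon`.
#' @return A tibble with one row per report: `report_id`, `status`, the four
#'   score columns (`angulation`, `root_count`, `root_curvature`, `canal`,
#'   NA where unresolved), `total` and the rule-based `class` for COMPLETE
#'   reports.
#' @export
extract_corpus <- function(corpus, lex) {
  stopifnot(all(c("report_id", "text") %in% names(corpus)))
  index <- compile_lexicon_index(lex)
  rows <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    res <- extract_features(corpus$text[[i]], lex,
                            report_id = corpus$report_id[[i]], index = index)
    total <- if (res$status == "COMPLETE") sum(res$scores) else NA_integer_
    rows[[i]] <- tibble::tibble(
      report_id = res$report_id,
      status = res$status,
      angulation = res$scores[["angulation"]],
      root_count = res$scores[["root_count"]],
      root_curvature = res$scores[["root_curvature"]],
      canal = res$scores[["canal"]],
      total = as.integer(total),
      class = if (is.na(total)) NA_character_ else classify_score(total)$label
    )
  }
  do.call(rbind, rows)
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result>", x$report_id, "status:", x$status, "\n")
  if (!is.null(x$features)) {
    cat("  scores:", paste(names(x$features), x$features, sep = "=",
                           collapse = " "), "\n")
  }
  invisible(x)
}
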