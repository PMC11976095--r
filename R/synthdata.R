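# Seeded synthetic CBCT-report generator with gold labels.
#
# Stands in for the private corpus of 738 real reports: each synthetic
# report states the four anatomical features in varied phrasing (random
# synonym + sentence template), embedded among distractor clinical
# sentences, with optional per-token typo noise and optional feature
# omission (emulating real reports that lack complete information).
# Everything is driven by one seeded RNG stream, so a config reproduces its
# corpus byte for byte.

# sentence templates; {syn} is replaced by a category synonym
FEATURE_TEMPLATES <- list(
  ANGULATION = c(
    "The third molar is {syn}.",
    "The impacted tooth appears {syn} on the reconstructed views.",
    "Angulation: {syn}.",
    "The lower right third molar shows a {syn} orientation."
  ),
  ROOT_COUNT = c(
    "The tooth has {syn}.",
    "Root number: {syn}.",
    "Examination of the root complex reveals {syn}.",
    "The radiograph demonstrates {syn}."
  ),
  ROOT_CURVATURE = c(
    "Root curvature: {syn}.",
    "The root morphology shows {syn}.",
    "Sagittal sections reveal {syn}.",
    "Assessment of root form indicates {syn}."
  ),
  CANAL_RELATION = c(
    "Relation to the mandibular canal: {syn}.",
    "The radiologist notes {syn} in relation to the mandibular canal.",
    "Regarding the inferior alveolar nerve, the report describes {syn}.",
    "Canal relationship assessment: {syn}."
  )
)

# unrelated clinical sentences; none contains a lexicon synonym
DISTRACTOR_TEMPLATES <- c(
  "The patient is a {age} year old {sex} referred for evaluation.",
  "The maxillary sinuses appear clear bilaterally.",
  "Bone density is within normal limits for age.",
  "No periapical radiolucency is detected around the adjacent teeth.",
  "The temporomandibular joints are unremarkable.",
  "The adjacent second molar shows an intact restoration.",
  "Soft tissue outlines are normal.",
  "The scan was acquired with a standard field of view.",
  "Overlying bone thickness is adequate.",
  "The periodontal ligament space of the second molar is preserved."
)

#' Synthetic corpus configuration
#'
#' Defaults emulate the study conditions: 738 reports split into 556
#' training and 182 validation cases, uniform category prevalence (real
#' prevalence is unpublished), two to four distractor sentences per report
#' and no noise.
#'
#' @param n_reports Number of reports.
#' @param train_count,val_count Split sizes; must sum to `n_reports`.
#' @param seed Integer RNG seed for the whole corpus.
#' @param feature_probs Optional named list (`angulation`, `root_count`,
#'   `root_curvature`, `canal`) of category probability vectors; default
#'   uniform within each feature.
#' @param distractor_range Length-2 integer range of distractor sentences
#'   per report.
#' @param typo_rate Per-token probability of a character perturbation, in
#'   \[0, 1\]. Within synonym phrases at most one token per report is ever
#'   perturbed, so noise degrades but rarely destroys extractability.
#' @param omission_rate Per-feature probability that a report omits the
#'   feature's sentence entirely (a gold-incomplete report), in \[0, 1\].
#' @param paraphrase If `FALSE`, always use each feature's first template
#'   and first synonym instead of sampling.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_reports = 738L, train_count = 556L,
                             val_count = 182L, seed = 1L,
                             feature_probs = NULL,
                             distractor_range = c(2L, 4L),
                             typo_rate = 0, omission_rate = 0,
                             paraphrase = TRUE) {
  stopifnot(
    n_reports >= 1L, train_count >= 0L, val_count >= 0L,
    train_count + val_count == n_reports,
    length(distractor_range) == 2L,
    distractor_range[1] >= 0L, distractor_range[2] >= distractor_range[1],
    typo_rate >= 0, typo_rate <= 1, omission_rate >= 0, omission_rate <= 1
  )
  if (!is.null(feature_probs)) {
    stopifnot(all(names(feature_probs) %in% unname(FEATURE_COLS)))
  }
  structure(
    list(
      n_reports = as.integer(n_reports), train_count = as.integer(train_count),
      val_count = as.integer(val_count), seed = as.integer(seed),
      feature_probs = feature_probs,
      distractor_range = as.integer(distractor_range),
      typo_rate = typo_rate, omission_rate = omission_rate,
      paraphrase = isTRUE(paraphrase)
    ),
    class = "generator_config"
  )
}

#' Sample gold cases (categories, scores, classes; no text)
#'
#' Categories are drawn independently per feature from the configured
#' distribution; the gold class is derived through the scoring rule, so
#' every case satisfies `gold_class == classify_score(total_score(scores))`.
#'
#' @param n Number of cases.
#' @param cfg A [generator_config()] (its `feature_probs` is used; the RNG
#'   stream of the caller is consumed, so seed outside or via
#'   [generate_corpus()]).
#' @return A tibble: `report_id`, four `*_cat` category columns, the four
#'   score columns, `total`, `gold_class`.
#' @export
sample_cases <- function(n, cfg = generator_config(n_reports = n,
                                                   train_count = n,
                                                   val_count = 0L)) {
  schema <- feature_scales()
  out <- tibble::tibble(report_id = sprintf("R%05d", seq_len(n)))
  totals <- rep(0L, n)
  for (fid in FEATURE_IDS) {
    col <- FEATURE_COLS[[fid]]
    cats <- schema[schema$feature_id == fid, ]
    probs <- cfg$feature_probs[[col]]
    if (is.null(probs)) probs <- rep(1 / nrow(cats), nrow(cats))
    pick <- sample.int(nrow(cats), n, replace = TRUE, prob = probs)
    out[[paste0(col, "_cat")]] <- cats$category[pick]
    out[[col]] <- cats$score[pick]
    totals <- totals + cats$score[pick]
  }
  out$total <- totals
  out$gold_class <- classify_score(totals)$label
  out
}

# perturb one token: swap two adjacent characters, or mutate one character
# for very short tokens
.typo <- function(token) {
  k <- nchar(token)
  if (k >= 2L) {
    i <- sample.int(k - 1L, 1L)
    paste0(substr(token, 1L, i - 1L),
           substr(token, i + 1L, i + 1L), substr(token, i, i),
           substr(token, i + 2L, k))
  } else {
    sample(letters, 1L)
  }
}

.apply_typos <- function(words, protected, typo_rate, state) {
  # `protected` marks synonym-phrase tokens; at most one of these per report
  # may be perturbed (state$syn_typo_done tracks it)
  for (i in seq_along(words)) {
    if (typo_rate <= 0) break
    if (stats::runif(1L) >= typo_rate) next
    if (protected[i]) {
      if (state$syn_typo_done) next
      state$syn_typo_done <- TRUE
    }
    words[i] <- .typo(words[i])
  }
  words
}

#' Render one gold case as report text
#'
#' One sentence per feature (random synonym of the gold category inserted in
#' a random template), interleaved with distractor sentences at random
#' positions. With `typo_rate > 0`, tokens are perturbed at that rate,
#' except that at most one token inside a synonym phrase is ever perturbed
#' per report. A feature hit by `omission_rate` loses its sentence, making
#' the report gold-incomplete.
#'
#' @param case One-row tibble from [sample_cases()].
#' @param cfg A [generator_config()].
#' @param lex A `feature_lexicon` supplying the synonyms.
#' @return A list: `text` (the report) and `omitted` (character vector of
#'   omitted feature ids).
#' @export
render_report <- function(case, cfg, lex) {
  pick <- function(x) if (cfg$paraphrase) x[[sample.int(length(x), 1L)]] else x[[1L]]
  sentences <- list()
  omitted <- character(0)
  for (fid in FEATURE_IDS) {
    col <- FEATURE_COLS[[fid]]
    if (cfg$omission_rate > 0 && stats::runif(1L) < cfg$omission_rate) {
      omitted <- c(omitted, fid)
      next
    }
    cat_label <- case[[paste0(col, "_cat")]]
    cats <- lex$features[[fid]]
    syns <- cats[[which(vapply(cats, `[[`, character(1), "label") == cat_label)]]$synonyms
    syn <- pick(syns)
    tmpl <- pick(FEATURE_TEMPLATES[[fid]])
    sent <- sub("{syn}", syn, tmpl, fixed = TRUE)
    # mark which space-separated words came from the synonym
    prefix <- sub("\\{syn\\}.*$", "", tmpl)
    n_before <- length(strsplit(trimws(prefix), " +")[[1L]])
    if (!nzchar(trimws(prefix))) n_before <- 0L
    syn_len <- length(strsplit(syn, " ", fixed = TRUE)[[1L]])
    words <- strsplit(sent, " ", fixed = TRUE)[[1L]]
    protected <- rep(FALSE, length(words))
    protected[seq.int(n_before + 1L, n_before + syn_len)] <- TRUE
    sentences[[length(sentences) + 1L]] <- list(words = words,
                                                protected = protected)
  }
  n_d <- sample(seq.int(cfg$distractor_range[1], cfg$distractor_range[2]), 1L)
  if (n_d > 0L) {
    for (d in sample(DISTRACTOR_TEMPLATES, n_d, replace = FALSE)) {
      d <- sub("{age}", sample(18:45, 1L), d, fixed = TRUE)
      d <- sub("{sex}", sample(c("male", "female"), 1L), d, fixed = TRUE)
      words <- strsplit(d, " ", fixed = TRUE)[[1L]]
      sentences[[length(sentences) + 1L]] <- list(
        words = words, protected = rep(FALSE, length(words))
      )
    }
  }
  sentences <- sentences[sample.int(length(sentences))]
  state <- new.env(parent = emptyenv())
  state$syn_typo_done <- FALSE
  rendered <- vapply(sentences, function(s) {
    paste(.apply_typos(s$words, s$protected, cfg$typo_rate, state),
          collapse = " ")
  }, character(1))
  list(text = paste(rendered, collapse = " "), omitted = omitted)
}

# largest-remainder stratified allocation of train slots per class
.stratified_split <- function(classes, train_count) {
  n <- length(classes)
  lv <- intersect(DIFFICULTY_LABELS, unique(classes))
  counts <- vapply(lv, function(l) sum(classes == l), integer(1))
  if (any(counts < 2L) && train_count > 0L && train_count < n) {
    warning("class(es) too small for stratification (",
            paste(lv[counts < 2L], collapse = ", "),
            "); falling back to a random split", call. = FALSE)
    idx <- sample.int(n, train_count)
    split <- rep("validation", n)
    split[idx] <- "train"
    return(split)
  }
  exact <- counts * train_count / n
  base <- floor(exact)
  rem <- exact - base
  short <- train_count - sum(base)
  if (short > 0L) {
    bump <- order(-rem, seq_along(lv))[seq_len(short)]
    base[bump] <- base[bump] + 1L
  }
  split <- rep("validation", n)
  for (i in seq_along(lv)) {
    members <- which(classes == lv[i])
    k <- min(base[i], length(members))
    take <- members[sample.int(length(members), k)]
    split[take] <- "train"
  }
  # correct any rounding slack
  excess <- sum(split == "train") - train_count
  if (excess > 0L) {
    pool <- which(split == "train")
    split[pool[sample.int(length(pool), excess)]] <- "validation"
  } else if (excess < 0L) {
    pool <- which(split == "validation")
    split[pool[sample.int(length(pool), -excess)]] <- "train"
  }
  split
}

#' Generate a seeded synthetic report corpus
#'
#' Samples gold cases, renders their text and assigns a train/validation
#' split stratified by gold class (per-class training proportions within one
#' case of the global ratio). Fully deterministic under `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @param lex A `feature_lexicon`; defaults to [build_default_lexicon()].
#' @return A tibble with one row per report: `report_id`, `text`, the four
#'   `*_cat` columns, the four score columns, `total`, `gold_class`,
#'   `split`, `gold_incomplete` and list-column `omitted`.
#' @examples
#' cfg <- generator_config(n_reports = 10, train_count = 7, val_count = 3,
#'                         seed = 42)
#' corpus <- generate_corpus(cfg)
#' corpus[, c("report_id", "gold_class", "split")]
#' @export
generate_corpus <- function(cfg = generator_config(),
                            lex = build_default_lexicon()) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, function() {
    cases <- sample_cases(cfg$n_reports, cfg)
    rendered <- lapply(seq_len(cfg$n_reports), function(i) {
      render_report(cases[i, ], cfg, lex)
    })
    cases$text <- vapply(rendered, `[[`, character(1), "text")
    cases$omitted <- lapply(rendered, `[[`, "omitted")
    cases$gold_incomplete <- lengths(cases$omitted) > 0L
    cases$split <- .stratified_split(cases$gold_class, cfg$train_count)
    cases[, c("report_id", "text", paste0(unname(FEATURE_COLS), "_cat"),
              unname(FEATURE_COLS), "total", "gold_class", "split",
              "gold_incomplete", "omitted")]
  })
}

#' Write a corpus to JSON Lines
#'
#' One JSON object per report; byte-identical across runs with the same
#' config and seed.
#'
#' @param corpus Corpus tibble from [generate_corpus()].
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    jsonlite::toJSON(list(
      report_id = row$report_id,
      text = row$text,
      gold_categories = list(
        angulation = row$angulation_cat, root_count = row$root_count_cat,
        root_curvature = row$root_curvature_cat, canal = row$canal_cat
      ),
      gold_vector = list(
        angulation = row$angulation, root_count = row$root_count,
        root_curvature = row$root_curvature, canal = row$canal
      ),
      total = row$total,
      gold_class = row$gold_class,
      split = row$split,
      gold_incomplete = row$gold_incomplete,
      omitted = I(row$omitted[[1]])
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus written by [write_corpus_jsonl()]
#'
#' @param path Path to the `.jsonl` file.
#' @return A corpus tibble in the same shape as [generate_corpus()] output.
#' @export
read_corpus_jsonl <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  rows <- lapply(recs, function(r) {
    tibble::tibble(
      report_id = r$report_id, text = r$text,
      angulation_cat = r$gold_categories$angulation,
      root_count_cat = r$gold_categories$root_count,
      root_curvature_cat = r$gold_categories$root_curvature,
      canal_cat = r$gold_categories$canal,
      angulation = as.integer(r$gold_vector$angulation),
      root_count = as.integer(r$gold_vector$root_count),
      root_curvature = as.integer(r$gold_vector$root_curvature),
      canal = as.integer(r$gold_vector$canal),
      total = as.integer(r$total),
      gold_class = r$gold_class,
      split = r$split,
      gold_incomplete = isTRUE(r$gold_incomplete),
      omitted = list(as.character(unlist(r$omitted)))
    )
  })
  do.call(rbind, rows)
}
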