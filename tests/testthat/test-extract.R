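test_that("direct dictionary hits produce one mention per phrase", {
  doc <- segment_report("tooth is mesioangular with two roots")
  m <- match_concepts(doc, default_lex)
  expect_setequal(m$category, c("Mesioangular", "Two roots"))
  expect_setequal(m$feature_id, c("ANGULATION", "ROOT_COUNT"))
  expect_false(any(m$negated))
  # matched_phrase equals the sentence substring at its char span
  for (i in seq_len(nrow(m))) {
    stext <- doc$sentences$text[[m$sentence_index[i] + 1L]]
    expect_identical(substr(stext, m$start[i] + 1L, m$end[i]),
                     m$matched_phrase[i])
  }
})

test_that("longest match wins: 'no contact' is never consumed as 'contact'", {
  doc <- segment_report("the roots show no contact with the mandibular canal")
  m <- match_concepts(doc, default_lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$category, "No contact")
  expect_equal(m$score, 1L)
  expect_false(m$negated)
})

test_that("sentences without lexicon phrases yield no mentions", {
  doc <- segment_report("the maxillary sinus appears entirely clear today")
  expect_equal(nrow(match_concepts(doc, default_lex)), 0L)
})

test_that("negation within three tokens marks a mention negated", {
  m <- match_concepts(segment_report("the roots are not dilacerated"),
                      default_lex)
  expect_true(m$negated[m$category == "Dilacerated roots"])
  # cue further than three tokens away does not negate
  m2 <- match_concepts(
    segment_report("no evidence of any lesion but dilacerated roots are seen"),
    default_lex
  )
  expect_false(m2$negated[m2$category == "Dilacerated roots"])
})

test_that("a complete report resolves all four features", {
  res <- extract_features(
    paste("the tooth is distoangular. three roots are noted.",
          "dilacerated roots are present.",
          "the apex is inside the mandibular canal."),
    default_lex
  )
  expect_equal(res$status, "COMPLETE")
  expect_equal(unname(res$features), c(4L, 3L, 3L, 4L))
  expect_equal(classify_score(total_score(res$features))$label, "D4")
})

test_that("missing features yield INCOMPLETE with the feature listed", {
  res <- extract_features(
    "the tooth is vertical with two roots. contact with the mandibular canal.",
    default_lex
  )
  expect_equal(res$status, "INCOMPLETE")
  expect_equal(res$missing_features, "ROOT_CURVATURE")
  expect_null(res$features)
  # resolved features are still reported partially
  expect_equal(res$scores[["angulation"]], 3L)
})

test_that("cross-sentence disagreement resolves to the last mentioning sentence", {
  res <- extract_features(
    paste("the tooth appears vertical. two roots. straight roots.",
          "no contact. on closer inspection the tooth is distoangular."),
    default_lex
  )
  expect_equal(res$status, "COMPLETE")
  expect_equal(res$scores[["angulation"]], 4L)
  expect_equal(res$categories[["angulation"]], "Distoangular")
})

test_that("two categories of one feature in one sentence give CONFLICT", {
  res <- extract_features(
    paste("the tooth is both mesioangular and distoangular.",
          "two roots. straight roots. no contact."),
    default_lex
  )
  expect_equal(res$status, "CONFLICT")
  expect_equal(res$conflicting_features, "ANGULATION")
})

test_that("noise-free synthetic reports round-trip to gold on every report", {
  cfg <- generator_config(n_reports = 80, train_count = 60, val_count = 20,
                          seed = 17, typo_rate = 0, omission_rate = 0)
  corpus <- generate_corpus(cfg, default_lex)
  ext <- extract_corpus(corpus, default_lex)
  expect_true(all(ext$status == "COMPLETE"))
  for (col in c("angulation", "root_count", "root_curvature", "canal")) {
    expect_identical(ext[[col]], corpus[[col]])
  }
  expect_identical(ext$class, corpus$gold_class)
})

test_that("shuffling distractor sentences does not change the resolution", {
  feature_sents <- c(
    "the third molar is horizontal.",
    "the tooth has two roots.",
    "root curvature: dilacerated roots.",
    "relation to the mandibular canal: approximation."
  )
  distractors <- c(
    "bone density is within normal limits.",
    "the maxillary sinuses appear clear.",
    "soft tissue outlines are normal."
  )
  ref <- extract_features(paste(c(feature_sents, distractors), collapse = " "),
                          default_lex)
  set.seed(41)
  for (rep in 1:10) {
    shuffled <- sample(c(feature_sents, distractors))
    res <- extract_features(paste(shuffled, collapse = " "), default_lex)
    expect_equal(res$status, "COMPLETE")
    expect_identical(res$features, ref$features)
  }
})
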