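test_that("confusion matrix counts true-by-predicted cases", {
  perfect <- confusion(rep(c("D1", "D2", "D3", "D4"), times = c(1, 2, 3, 4)),
                       rep(c("D1", "D2", "D3", "D4"), times = c(1, 2, 3, 4)))
  expect_equal(sum(diag(perfect)), 10L)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  single <- confusion("D1", "D4")
  expect_equal(single["D1", "D4"], 1L)
  expect_equal(sum(single), 1L)

  set.seed(8)
  g <- sample(c("D1", "D2", "D3", "D4"), 200, replace = TRUE)
  p <- sample(c("D1", "D2", "D3", "D4"), 200, replace = TRUE)
  cm <- confusion(g, p)
  expect_equal(sum(cm), 200L)                          # conservation
  expect_equal(sum(diag(cm)) / sum(cm), mean(g == p))  # micro accuracy
  expect_error(confusion(c("D1", "D2"), "D1"), "length")
})

test_that("metrics match hand-computed values on a toy matrix", {
  cm <- matrix(0L, 4, 4, dimnames = list(gold = c("D1", "D2", "D3", "D4"),
                                         pred = c("D1", "D2", "D3", "D4")))
  cm["D1", "D1"] <- 8L; cm["D1", "D2"] <- 2L; cm["D2", "D2"] <- 10L
  m <- classification_metrics(cm)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$precision[2], 10 / 12)
  expect_equal(m$per_class$precision[1], 1.0)
  # empty classes contribute zero, not NaN
  expect_equal(m$per_class$precision[3], 0)
  expect_equal(m$per_class$f1[4], 0)
  expect_equal(m$accuracy, 18 / 20)
})

test_that("macro aggregates are unweighted means of per-class values", {
  set.seed(19)
  for (rep in 1:5) {
    cm <- matrix(as.integer(rpois(16, 6)), 4, 4,
                 dimnames = list(gold = c("D1", "D2", "D3", "D4"),
                                 pred = c("D1", "D2", "D3", "D4")))
    m <- classification_metrics(cm)
    expect_equal(m$macro$precision, mean(m$per_class$precision))
    expect_equal(m$macro$recall, mean(m$per_class$recall))
    expect_equal(m$macro$f1, mean(m$per_class$f1))
    expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
    expect_true(all(unlist(m$macro) >= 0 & unlist(m$macro) <= 1))
    # f1 is the harmonic mean of its precision and recall
    pc <- m$per_class
    hm <- ifelse(pc$precision + pc$recall > 0,
                 2 * pc$precision * pc$recall / (pc$precision + pc$recall), 0)
    expect_equal(pc$f1, hm)
  }
})

test_that("perfect predictions give all-ones metrics", {
  cm <- confusion(rep(c("D1", "D2", "D3", "D4"), 3),
                  rep(c("D1", "D2", "D3", "D4"), 3))
  m <- classification_metrics(cm)
  expect_equal(m$per_class$precision, rep(1, 4))
  expect_equal(m$per_class$recall, rep(1, 4))
  expect_equal(m$macro$f1, 1)
  expect_equal(m$accuracy, 1)
})

make_case <- function(text, gold, status, extracted, pred, gold_inc = FALSE) {
  tibble::tibble(
    text = text,
    angulation = gold[1], root_count = gold[2],
    root_curvature = gold[3], canal = gold[4],
    gold_class = classify_score(sum(gold))$label,
    gold_incomplete = gold_inc,
    status = status,
    ex_angulation = extracted[1], ex_root_count = extracted[2],
    ex_root_curvature = extracted[3], ex_canal = extracted[4],
    pred_class = pred
  )
}

test_that("error taxonomy assigns exactly one category per erroneous case", {
  good_text <- paste("the tooth is vertical. two roots. straight roots.",
                     "contact with the mandibular canal.")
  all_ok <- make_case(good_text, c(3, 2, 2, 3), "COMPLETE",
                      c(3, 2, 2, 3), "D3")
  expect_equal(categorize_errors(all_ok, default_lex)$total_errors, 0L)

  # wrong extracted curvature, synonym simply absent -> concept error
  concept <- make_case(
    "the tooth is vertical. two roots. contact with the mandibular canal.",
    c(3, 2, 3, 3), "INCOMPLETE", c(3, 2, NA, 3), NA_character_
  )
  err <- categorize_errors(concept, default_lex)
  expect_equal(err$concept_errors, 1L)
  expect_equal(err$total_errors, 1L)

  # correct features, wrong predicted class -> classification error
  cls <- make_case(good_text, c(3, 2, 2, 3), "COMPLETE", c(3, 2, 2, 3), "D4")
  err2 <- categorize_errors(cls, default_lex)
  expect_equal(err2$classification_errors, 1L)
  expect_equal(err2$concept_errors, 0L)

  # synonym present in the full text but broken across a sentence boundary
  # -> tokenizer error takes precedence over concept
  broken <- make_case(
    paste("the tooth is vertical. straight roots. no contact.",
          "the tooth has three or. more roots."),
    c(3, 3, 2, 1), "INCOMPLETE", c(3, NA, 2, 1), NA_character_
  )
  err3 <- categorize_errors(broken, default_lex)
  expect_equal(err3$tokenizer_errors, 1L)
  expect_equal(err3$concept_errors, 0L)

  # gold-incomplete reports correctly flagged INCOMPLETE are not errors
  inc <- make_case(
    "the tooth is vertical. two roots. straight roots.",
    c(3, 2, 2, 3), "INCOMPLETE", c(3, 2, 2, NA), NA_character_,
    gold_inc = TRUE
  )
  expect_equal(categorize_errors(inc, default_lex)$total_errors, 0L)

  # the three categories are exclusive: one per erroneous report
  stacked <- rbind(all_ok, concept, cls, inc)
  errs <- categorize_errors(stacked, default_lex)
  expect_equal(errs$total_errors, 2L)
})
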