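test_that("gold classes always derive from the scoring rule", {
  cfg <- generator_config(n_reports = 120, train_count = 90, val_count = 30,
                          seed = 21)
  corpus <- generate_corpus(cfg, default_lex)
  expect_equal(nrow(corpus), 120L)
  for (i in seq_len(nrow(corpus))) {
    fv <- unlist(corpus[i, c("angulation", "root_count", "root_curvature",
                             "canal")])
    expect_equal(corpus$gold_class[i], classify_score(total_score(fv))$label)
  }
  # noise-free text mentions a synonym of every gold category
  tab <- lexicon_table(default_lex)
  for (i in sample.int(nrow(corpus), 20)) {
    norm <- normalize_text(corpus$text[i])
    for (fid in unique(tab$feature_id)) {
      col <- c(ANGULATION = "angulation", ROOT_COUNT = "root_count",
               ROOT_CURVATURE = "root_curvature", CANAL_RELATION = "canal")[[fid]]
      syns <- tab$synonym[tab$feature_id == fid &
                            tab$category == corpus[[paste0(col, "_cat")]][i]]
      expect_true(any(vapply(syns, grepl, logical(1), x = norm, fixed = TRUE)),
                  info = paste(corpus$report_id[i], fid))
    }
  }
})

test_that("category sampling follows the configured distribution", {
  cfg <- generator_config(n_reports = 10000, train_count = 10000,
                          val_count = 0, seed = 77)
  set.seed(cfg$seed)
  cases <- sample_cases(10000, cfg)
  # uniform over 4 angulation categories: within 3 s.e. of 0.25
  freq <- table(cases$angulation) / nrow(cases)
  se <- sqrt(0.25 * 0.75 / nrow(cases))
  expect_true(all(abs(freq - 0.25) < 3 * se))
  # point mass on the minima forces D1
  cfg2 <- generator_config(
    n_reports = 50, train_count = 50, val_count = 0, seed = 5,
    feature_probs = list(angulation = c(1, 0, 0, 0), root_count = c(1, 0, 0),
                         root_curvature = c(1, 0, 0), canal = c(1, 0, 0, 0))
  )
  set.seed(cfg2$seed)
  cases2 <- sample_cases(50, cfg2)
  expect_true(all(cases2$gold_class == "D1"))
  expect_true(all(cases2$total == 4L))
})

test_that("the corpus is byte-identical across runs with the same seed", {
  cfg <- generator_config(n_reports = 40, train_count = 30, val_count = 10,
                          seed = 9, typo_rate = 0.02)
  a <- withr::local_tempfile(fileext = ".jsonl")
  b <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(generate_corpus(cfg, default_lex), a)
  write_corpus_jsonl(generate_corpus(cfg, default_lex), b)
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
  # a different seed changes the text but not the size invariants
  cfg2 <- generator_config(n_reports = 40, train_count = 30, val_count = 10,
                           seed = 10, typo_rate = 0.02)
  other <- generate_corpus(cfg2, default_lex)
  expect_false(identical(other$text, generate_corpus(cfg, default_lex)$text))
  expect_equal(sum(other$split == "train"), 30L)
})

test_that("corpus JSONL round-trips", {
  cfg <- generator_config(n_reports = 15, train_count = 10, val_count = 5,
                          seed = 33, omission_rate = 0.3)
  # tiny corpus: the sparse-class fallback to a random split is expected
  corpus <- suppressWarnings(generate_corpus(cfg, default_lex))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  back <- read_corpus_jsonl(path)
  expect_equal(as.data.frame(back), as.data.frame(corpus))
})

test_that("forced omission produces gold-incomplete reports", {
  cfg <- generator_config(n_reports = 25, train_count = 20, val_count = 5,
                          seed = 13, omission_rate = 1)
  corpus <- suppressWarnings(generate_corpus(cfg, default_lex))
  expect_true(all(corpus$gold_incomplete))
  ext <- extract_corpus(corpus, default_lex)
  expect_true(all(ext$status == "INCOMPLETE"))
})

test_that("the split is stratified by gold class within one case", {
  cfg <- generator_config(n_reports = 738, train_count = 556, val_count = 182,
                          seed = 51)
  corpus <- generate_corpus(cfg, default_lex)
  expect_equal(sum(corpus$split == "train"), 556L)
  expect_equal(sum(corpus$split == "validation"), 182L)
  ratio <- 556 / 738
  for (cl in unique(corpus$gold_class)) {
    n_cl <- sum(corpus$gold_class == cl)
    n_tr <- sum(corpus$gold_class == cl & corpus$split == "train")
    expect_lte(abs(n_tr - n_cl * ratio), 1 + 1e-9, label = cl)
  }
})

test_that("typo noise leaves at most one corrupted synonym token per report", {
  cfg <- generator_config(n_reports = 60, train_count = 45, val_count = 15,
                          seed = 29, typo_rate = 0.05)
  corpus <- generate_corpus(cfg, default_lex)
  ext <- extract_corpus(corpus, default_lex)
  # at most one feature can have lost its (single) synonym mention
  n_missing <- vapply(seq_len(nrow(ext)), function(i) {
    sum(is.na(unlist(ext[i, c("angulation", "root_count", "root_curvature",
                              "canal")])))
  }, integer(1))
  expect_true(all(n_missing <= 1L))
  # noise degrades but does not destroy extraction: the overwhelming
  # majority of resolved feature values still match gold (a typo can, very
  # rarely, flip a phrase to a shorter synonym, e.g. "no contact" losing
  # its "no" -- that is a legitimate concept error, as real pipelines see)
  matches <- 0L; resolved <- 0L
  for (col in c("angulation", "root_count", "root_curvature", "canal")) {
    ok <- !is.na(ext[[col]])
    resolved <- resolved + sum(ok)
    matches <- matches + sum(ext[[col]][ok] == corpus[[col]][ok])
  }
  expect_gte(matches / resolved, 0.95)
})

test_that("generator_config validates its invariants", {
  expect_error(generator_config(n_reports = 10, train_count = 8, val_count = 3))
  expect_error(generator_config(typo_rate = 1.5))
  expect_error(generator_config(omission_rate = -0.1))
})

test_that("a class too sparse to stratify falls back to a random split with a warning", {
  cfg <- generator_config(n_reports = 8, train_count = 6, val_count = 2,
                          seed = 3)
  expect_warning(corpus <- generate_corpus(cfg, default_lex),
                 "falling back to a random split")
  expect_equal(sum(corpus$split == "train"), 6L)
})
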