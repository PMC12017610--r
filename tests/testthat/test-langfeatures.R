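test_that("token normalization lowercases, strips punctuation, and is idempotent", {
  expect_equal(normalize_tokens("La macchina, correva!"),
               c("la", "macchina", "correva"))
  expect_equal(normalize_tokens(""), character(0))
  toks <- normalize_tokens("Un. Due; TRE -- quattro?")
  expect_equal(normalize_tokens(paste(toks, collapse = " ")), toks)
})

test_that("word and story-match counts follow type-level membership", {
  story <- reference_story("a b c")
  tr <- timed_transcript(data.frame(token = c("a", "b", "b", "z"),
                                    onset_s = 0:3, offset_s = 0:3 + 0.5))
  cf <- count_features(tr, story)
  expect_equal(cf$n_words, 4)
  expect_equal(cf$n_matched, 3)
  empty <- timed_transcript(data.frame())
  expect_equal(unlist(count_features(empty, story)), c(n_words = 0, n_matched = 0))
  verb <- timed_transcript(data.frame(token = c("a", "b", "c"),
                                      onset_s = 0:2, offset_s = 0:2 + 0.4))
  cv <- count_features(verb, story)
  expect_equal(cv$n_matched, cv$n_words)
})

test_that("latency and mean intraword time follow the onset conventions", {
  tr <- timed_transcript(data.frame(token = c("x", "y", "z"),
                                    onset_s = c(0.0, 0.5, 1.5),
                                    offset_s = c(0.2, 0.9, 1.8)))
  ts <- timing_scores(tr)
  expect_equal(ts$latency_s, 0)
  expect_equal(ts$mean_intraword_s, 0.75)
  gap <- timing_scores(tr, intraword = "gap")
  expect_equal(gap$mean_intraword_s, mean(c(0.5 - 0.2, 1.5 - 0.9)))
  one <- timed_transcript(data.frame(token = "solo", onset_s = 2.3, offset_s = 2.6))
  t1 <- timing_scores(one)
  expect_equal(t1$latency_s, 2.3)
  expect_true(is.na(t1$mean_intraword_s))
  none <- timing_scores(timed_transcript(data.frame()))
  expect_true(is.na(none$latency_s) && is.na(none$mean_intraword_s))
})

test_that("invalid transcripts are rejected", {
  expect_error(timed_transcript(data.frame(token = "a", onset_s = 1, offset_s = 0.5)))
  expect_error(timed_transcript(data.frame(token = c("a", "b"),
                                           onset_s = c(0, 0.1),
                                           offset_s = c(0.3, 0.4))),
               "overlap")
})

test_that("transcripts round-trip through the JSON schema", {
  tr <- timed_transcript(data.frame(token = c("uno", "due"),
                                    onset_s = c(0.5, 1.25),
                                    offset_s = c(0.9, 1.5)),
                         task_start_s = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript_json(tr, path)
  back <- read_transcript_json(path)
  expect_equal(back$words$token, tr$words$token)
  expect_equal(back$words$onset_s, tr$words$onset_s)
  expect_equal(back$task_start_s, 0.25)
})

test_that("embedding reader handles the word2vec text format and rejects defects", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "cane 0.1 0.2", "gatto -0.5 1.0", "pane 0 0.25"), path)
  emb <- read_embeddings(path)
  expect_equal(rownames(emb), c("cane", "gatto", "pane"))
  expect_equal(unname(emb["gatto", ]), c(-0.5, 1.0))
  writeLines(c("cane 0.1 0.2", "cane 0.3 0.4"), path)
  expect_error(read_embeddings(path), "duplicate")
  writeLines(c("cane 0.1 0.2", "gatto 0.3"), path)
  expect_error(read_embeddings(path), "dimension")
})

test_that("WMD equals the exhaustive transport oracle on random toy pairs", {
  emb <- toy_embedding()
  set.seed(99)
  for (k in 1:60) {
    doc <- sample(letters[1:6], sample(1:5, 1), replace = TRUE)
    ref <- sample(letters[1:6], sample(1:5, 1), replace = TRUE)
    w <- as.numeric(word_movers_distance(doc, ref, emb))
    expect_equal(w, oracle_wmd(doc, ref, unclass(emb)), tolerance = 1e-6)
    expect_gte(w, 0)
    expect_equal(w, as.numeric(word_movers_distance(ref, doc, emb)),
                 tolerance = 1e-9)
  }
})

test_that("WMD is zero on identical distributions and exact on single-mass pairs", {
  emb <- toy_embedding()
  expect_equal(as.numeric(word_movers_distance(c("a", "b", "b"),
                                               c("b", "a", "b"), emb)), 0)
  d <- sqrt(sum((unclass(emb)["a", ] - unclass(emb)["b", ])^2))
  expect_equal(as.numeric(word_movers_distance("a", "b", emb)), d)
})

test_that("WMD respects the bounded-perturbation property", {
  emb <- toy_embedding()
  set.seed(7)
  C <- as.matrix(stats::dist(unclass(emb)))
  for (k in 1:10) {
    doc <- sample(letters[1:4], 3, replace = TRUE)
    ref <- sample(letters[1:4], 3, replace = TRUE)
    w0 <- as.numeric(word_movers_distance(doc, ref, emb))
    w1 <- as.numeric(word_movers_distance(c(doc, "f"), c(ref, "f"), emb))
    # adding the same word to both sides shifts mass by at most 1/4 of the
    # distribution across at most the embedding diameter
    expect_lte(w1, w0 + 0.25 * max(C) + 1e-9)
  }
})

test_that("triangle inequality holds on random toy triples", {
  emb <- toy_embedding()
  set.seed(17)
  for (k in 1:15) {
    a <- sample(letters[1:6], 3, replace = TRUE)
    b <- sample(letters[1:6], 3, replace = TRUE)
    c3 <- sample(letters[1:6], 3, replace = TRUE)
    ab <- as.numeric(word_movers_distance(a, b, emb))
    bc <- as.numeric(word_movers_distance(b, c3, emb))
    ac <- as.numeric(word_movers_distance(a, c3, emb))
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("out-of-vocabulary tokens are dropped and counted; empty side is missing", {
  emb <- toy_embedding()
  res <- word_movers_distance(c("a", "zzz"), c("b"), emb)
  expect_equal(attr(res, "n_oov_doc"), 1)
  all_oov <- word_movers_distance(c("xxx", "yyy"), c("a"), emb)
  expect_true(is.na(all_oov))
  expect_equal(attr(all_oov, "n_oov_doc"), 2)
})

test_that("count and timing features ignore the audio entirely", {
  story <- reference_story("la macchina correva")
  tr <- timed_transcript(data.frame(token = c("la", "macchina"),
                                    onset_s = c(0.3, 1.0),
                                    offset_s = c(0.6, 1.4)))
  f1 <- cbind(count_features(tr, story), timing_scores(tr))
  f2 <- cbind(count_features(tr, story), timing_scores(tr))
  expect_identical(f1, f2)
})
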