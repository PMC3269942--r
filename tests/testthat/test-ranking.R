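mk_ng <- function(gene_id, mentions, vote = NULL, match_kind = "exact",
                  mention_texts = "X1") {
  list(gene_id = gene_id, taxon_id = "9606", mention_texts = mention_texts,
       mentions = mentions, stage = 1L, vote = vote,
       match_kind = match_kind)
}

feat_article <- function() make_article("FA", list(
  list(kind = "title", heading = "Title", text = "About X1"),
  list(kind = "abstract", heading = "Abstract",
       text = "One. Two. Three. Four."),
  list(kind = "introduction", heading = "Introduction",
       text = "A. B. C. D. E."),
  list(kind = "results", heading = "Results", text = "R1. R2.")),
  keywords = "X1")

test_that("feature extraction fills the 32-dimension manifest", {
  a <- feat_article()
  md <- init_metadata(a)
  occ <- function(si, sj) data.frame(section_index = si, sentence_index = sj,
                                     start = 0L, end = 2L, text = "X1",
                                     source = "tagger",
                                     stringsAsFactors = FALSE)
  # an id mentioned only in the title
  v <- extract_features(mk_ng("G1", occ(1L, 1L)), a, md)
  expect_identical(names(v), feature_names())
  expect_equal(unname(v["loc_title"]), 1)
  expect_equal(sum(v[grep("^loc_", names(v))]), 1)
  expect_equal(unname(v["keyword_match"]), 1)   # author keyword "X1"

  # 4 mentions, 2 in Results
  m4 <- rbind(occ(2L, 2L), occ(3L, 1L), occ(4L, 1L), occ(4L, 2L))
  v4 <- extract_features(mk_ng("G1", m4), a, md)
  expect_equal(unname(v4["freq_article"]), log1p(4))
  expect_equal(unname(v4["freq_results_pct"]), 0.5)
  expect_equal(unname(v4["loc_results"]), 1)
  # last-n sentence features: abstract sentence 4 of 4 is in the last 3
  expect_equal(unname(v4["loc_abstract_last_n1"]), 1)
  # introduction sentence 1 of 5 is not in the last 3
  expect_equal(unname(v4["loc_first_section_last_n2"]), 0)

  expect_error(extract_features(mk_ng("G1", occ(1L, 1L)[0, ]), a, md),
               "no recorded mentions")
  # purity: identical inputs give identical vectors
  expect_identical(v4, extract_features(mk_ng("G1", m4), a, md))
})

test_that("training separates separable data and learns the vote signal", {
  X <- rbind(c(rep(0, 2), 5, rep(0, 29)), c(rep(0, 2), -5, rep(0, 29)))
  colnames(X) <- feature_names()
  m <- train_ranker(X, c("correct", "incorrect"), seed = 1)
  conf <- score_ids(m, X)
  expect_gt(conf[1], 0.5); expect_lt(conf[2], 0.5)  # training accuracy 1

  set.seed(1)
  lf <- gen_labeled_features(400)
  m2 <- train_ranker(lf$X, lf$y, seed = 1)
  expect_gt(m2$weights[["vote_total"]], 0)

  expect_error(train_ranker(X, c("correct", "correct")), "single-class")
  expect_error(train_ranker(X[0, , drop = FALSE], character()),
               "no examples")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(train_ranker(Xb, c("correct", "incorrect")), "non-finite")
})

test_that("scores are monotone confidences in (0,1)", {
  w <- setNames(rep(0, length(feature_names())), feature_names())
  w["vote_total"] <- 1; w["loc_title"] <- 0.5
  m <- make_ranker(w)
  lo <- setNames(rep(0, length(w)), names(w))
  hi <- lo; hi["vote_total"] <- 2; hi["loc_title"] <- 1
  conf <- score_ids(m, rbind(lo, hi, hi))
  expect_gt(conf[2], conf[1])            # dominance raises confidence
  expect_identical(conf[2], conf[3])     # equal vectors tie
  expect_true(all(conf > 0 & conf < 1))
  expect_identical(score_ids(m, matrix(numeric(), 0, length(w))), numeric())
  expect_error(score_ids(m, matrix(0, 1, 3)), "mismatch")
})

test_that("article ranking orders by confidence then gene id", {
  a <- feat_article(); md <- init_metadata(a)
  occ <- function(si) data.frame(section_index = si, sentence_index = 1L,
                                 start = 0L, end = 2L, text = "X1",
                                 source = "tagger", stringsAsFactors = FALSE)
  w <- setNames(rep(0, length(feature_names())), feature_names())
  w["loc_title"] <- 2
  m <- make_ranker(w)
  ngs <- list(mk_ng("G2", occ(4L)), mk_ng("G1", occ(1L)),
              mk_ng("G3", occ(4L)))
  r <- rank_article(m, ngs, a, md)
  expect_identical(r$gene_id, c("G1", "G2", "G3"))  # title first, then ids
  expect_true(all(diff(r$confidence) <= 0))
  # permutation invariance
  r2 <- rank_article(m, rev(ngs), a, md)
  expect_identical(r, r2)
})

test_that("a model trained on labeled fixtures ranks correct ids high", {
  set.seed(1)
  train <- gen_labeled_features(500)
  model <- train_ranker(train$X, train$y, seed = 1)
  held <- gen_labeled_features(200)
  conf <- score_ids(model, held$X)
  ord <- order(-conf)
  top_half <- ord[seq_len(100)]
  frac <- mean(which(held$y == "correct") %in% top_half)
  expect_gte(frac, 0.8)
})

test_that("ranker models survive a JSON round trip", {
  set.seed(4)
  lf <- gen_labeled_features(100)
  m <- train_ranker(lf$X, lf$y, seed = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_ranker(m, p)
  m2 <- read_ranker(p)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(score_ids(m2, lf$X), score_ids(m, lf$X), tolerance = 1e-12)
  # the shipped default model matches the manifest
  dm <- default_ranker()
  expect_identical(dm$feature_order, feature_names())
})
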