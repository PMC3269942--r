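# context: G1 = human TP53, G2 = mouse TP53, G3 = human IL6 (toy_kb)

ctx <- function(article, si = 3L, sj = 1L, mention = "TP53")
  list(article = article, section_index = si, sentence_index = sj,
       mention_text = mention)

test_that("rules grade evidence by proximity and honour two-valued rules", {
  kb <- toy_kb()
  # HeLa in the Results section but a different sentence -> same section
  a <- make_article("D1", list(
    list(kind = "title", heading = "Title", text = "TP53"),
    list(kind = "abstract", heading = "Abstract", text = "About TP53."),
    list(kind = "results", heading = "Results",
         text = "TP53 was measured. HeLa cells were transfected.")))
  md <- init_metadata(a)
  r <- apply_rule("Cell", "G1", ctx(a, si = 3L, sj = 1L), kb, md)
  expect_equal(r$y, 1); expect_equal(r$w, 0.5); expect_equal(r$value, 0.5)
  # same sentence gives full weight
  r1 <- apply_rule("Cell", "G1", ctx(a, si = 3L, sj = 2L), kb, md)
  expect_equal(r1$value, 1)
  # no cell keyword anywhere -> vote against (three-valued)
  b <- make_article("D2", list(
    list(kind = "results", heading = "Results", text = "TP53 only here.")))
  mdb <- init_metadata(b)
  expect_equal(apply_rule("Cell", "G1", ctx(b, 1L, 1L), kb, mdb)$y, -1)
  # chromosome location never votes against
  expect_equal(apply_rule("ChromosomeLocation", "G1", ctx(b, 1L, 1L),
                          kb, mdb)$y, 0)
  expect_equal(apply_rule("Mass", "G1", ctx(b, 1L, 1L), kb, mdb)$y, 0)
  expect_error(apply_rule("NoSuchRule", "G1", ctx(b, 1L, 1L), kb, mdb),
               "unknown rule")
})

test_that("numeric and metadata rules fire on their evidence", {
  kb <- toy_kb()
  a <- make_article("D3", list(
    list(kind = "results", heading = "Results", text = paste(
      "The 43.7 kDa product of 393 aa maps to 17p13 near rs1042522 and",
      "is linked to apoptosis in liver."))))
  md <- init_metadata(a)
  cc <- ctx(a, 1L, 1L)
  for (rid in c("Mass", "SequenceLength", "ChromosomeLocation", "RSNumber",
                "GeneOntology", "Tissue"))
    expect_equal(apply_rule(rid, "G1", cc, kb, md)$value, 1, info = rid)
  # mass tolerance is relative 5%: 45 kDa still matches 43.7
  a2 <- make_article("D4", list(
    list(kind = "results", heading = "Results",
         text = "A 45 kDa band was seen.")))
  expect_equal(apply_rule("Mass", "G1", ctx(a2, 1L, 1L), kb,
                          init_metadata(a2))$y, 1)
  a3 <- make_article("D5", list(
    list(kind = "results", heading = "Results",
         text = "A 60 kDa band was seen.")))
  expect_equal(apply_rule("Mass", "G1", ctx(a3, 1L, 1L), kb,
                          init_metadata(a3))$y, 0)

  # History and PPI read the normalized memory
  b <- toy_article()
  mdb <- init_metadata(b)
  expect_equal(apply_rule("History", "G1", ctx(b), kb, mdb)$y, 0)
  expect_equal(apply_rule("PPI", "G1", ctx(b), kb, mdb)$y, 0)
  mdb$normalized[["interleukin6"]] <- list(gene_id = "G3")
  expect_equal(apply_rule("PPI", "G1", ctx(b), kb, mdb)$y, 1)  # G1-G3 pair
  mdb$normalized[["tp53"]] <- list(gene_id = "G1")
  expect_equal(apply_rule("History", "G1", ctx(b), kb, mdb)$y, 1)

  # FullNameAcronym: the stored long form of the mention matches a kb name
  c1 <- make_article("D6", list(
    list(kind = "introduction", heading = "Introduction",
         text = "The tumor protein p53 (TP53) is central.")))
  mdc <- init_metadata(c1)
  expect_equal(apply_rule("FullNameAcronym", "G1", ctx(c1, 1L, 1L), kb,
                          mdc)$y, 1)
  expect_equal(apply_rule("FullNameAcronym", "G3", ctx(c1, 1L, 1L), kb,
                          mdc)$y, 0)
})

test_that("moving evidence closer never lowers a rule's value", {
  kb <- toy_kb()
  scopes <- list(
    sentence = "TP53 rose in HeLa cells.",
    section = "TP53 rose. HeLa cells were used.",
    article = "TP53 rose.||Separate section: HeLa cells.",
    none = "TP53 rose.")
  vals <- vapply(names(scopes), function(sc) {
    secs <- if (sc == "article") {
      parts <- strsplit(scopes[[sc]], "||", fixed = TRUE)[[1]]
      list(list(kind = "results", heading = "Results", text = parts[1]),
           list(kind = "other", heading = "Discussion", text = parts[2]))
    } else list(list(kind = "results", heading = "Results",
                     text = scopes[[sc]]))
    a <- make_article("MV", secs)
    apply_rule("Cell", "G1", ctx(a, 1L, 1L), kb, init_metadata(a))$value
  }, 0)
  expect_equal(unname(vals), c(1, 0.5, 0, -1))  # strictly graded
})

test_that("the weighted vote sums rule values and counts votes against", {
  kb <- toy_kb()
  a <- toy_article()
  md <- init_metadata(a)
  v1 <- weighted_vote("G1", ctx(a, 3L, 1L, "TP53"), kb, md)
  expect_s3_class(v1, "gn_vote")
  expect_equal(v1$total,
               sum(vapply(v1$results, `[[`, 0, "value")))
  expect_equal(v1$votes_against,
               sum(vapply(v1$results, `[[`, 0L, "y") == -1L))
  expect_lte(v1$votes_against, 5)  # only three-valued rules can oppose
  expect_true(v1$total >= -13 && v1$total <= 13)

  # species keyword in-sentence separates the two TP53 candidates
  v2 <- weighted_vote("G2", ctx(a, 3L, 1L, "TP53"), kb, md)
  expect_equal(v1$results$Species$value, 1)   # Homo sapiens in sentence
  expect_gt(v1$total, v2$total)
})

test_that("the planted species wins on random two-species fixtures", {
  set.seed(9)
  kb <- toy_kb()
  for (i in 1:200) {
    planted <- sample(c("G1", "G2"), 1)
    sp <- if (planted == "G1") "Homo sapiens" else "Mus musculus"
    filler <- paste(sample(c("signalling", "analysis", "levels", "assay"),
                           2), collapse = " ")
    a <- make_article("F", list(
      list(kind = "introduction", heading = "Introduction",
           text = sprintf("TP53 %s was studied in %s.", filler, sp))))
    md <- init_metadata(a)
    cands <- lapply(c("G1", "G2"), function(g)
      list(gene_id = g, mention_text = "TP53",
           vote = weighted_vote(g, ctx(a, 1L, 1L, "TP53"), kb, md)))
    expect_identical(select_candidate(cands)$gene_id, planted)
  }
})

test_that("candidate selection is a deterministic total order", {
  mkv <- function(against, total) {
    structure(list(gene_id = "x", results = list(), total = total,
                   votes_against = against), class = "gn_vote")
  }
  cand <- function(id, text, against = 0, total = 0)
    list(gene_id = id, mention_text = text, vote = mkv(against, total))

  # longest mention wins regardless of votes
  expect_identical(select_candidate(list(
    cand("A", strrep("x", 25), against = 3),
    cand("B", strrep("y", 6), against = 0)))$gene_id, "A")
  # equal lengths: fewest votes against
  expect_identical(select_candidate(list(
    cand("A", "name1", against = 2), cand("B", "name2", against = 0)))$gene_id,
    "B")
  # then highest total, then smallest gene id
  expect_identical(select_candidate(list(
    cand("A", "name", 1, total = 0.5), cand("B", "name", 1, total = 2)))$gene_id,
    "B")
  expect_identical(select_candidate(list(
    cand("B", "name"), cand("A", "name")))$gene_id, "A")
  expect_error(select_candidate(list()), "empty candidate")

  # permutation invariance
  set.seed(21)
  base <- list(cand("C", "abcd", 1, 1), cand("A", "abcde", 2, 0),
               cand("B", "abcd", 0, 3), cand("D", "abcd", 0, 3))
  winner <- select_candidate(base)$gene_id
  for (i in 1:25)
    expect_identical(select_candidate(sample(base))$gene_id, winner)
})
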