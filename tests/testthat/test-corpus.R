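test_that("article JSON round-trips and headings map to section kinds", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "article_id": "A1",
    "keywords": ["TP53"],
    "sections": [
      {"kind": "title", "heading": "Title", "text": "A title"},
      {"kind": "abstract", "heading": "Abstract", "text": "An abstract."},
      {"heading": "Introduction", "text": "First body section."},
      {"heading": "Nonstandard Heading", "text": "Body."},
      {"heading": "Results", "text": "Findings."}
    ]
  }', p)
  a <- read_article(p)
  expect_s3_class(a, "gn_article")
  expect_length(a$sections, 5)
  expect_equal(vapply(a$sections, `[[`, "", "kind"),
               c("title", "abstract", "introduction", "other", "results"))
  expect_equal(a$keywords, "TP53")

  # canonical write -> read -> write is byte-identical
  p2 <- withr::local_tempfile(fileext = ".json")
  p3 <- withr::local_tempfile(fileext = ".json")
  write_article(a, p2)
  write_article(read_article(p2), p3)
  expect_identical(readLines(p2), readLines(p3))

  # duplicate abstract violates the at-most-one invariant
  pd <- withr::local_tempfile(fileext = ".json")
  writeLines('{"article_id":"A2","sections":[
    {"kind":"abstract","heading":"Abstract","text":"x"},
    {"kind":"abstract","heading":"Abstract","text":"y"}]}', pd)
  expect_error(read_article(pd), "abstract")
  expect_error(read_article(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("sentence segmentation respects protected tokens and spans", {
  expect_length(split_sentences("A binds B. C binds D."), 2)
  expect_length(split_sentences(""), 0)
  expect_length(split_sentences("See Fig. 2 for details."), 1)
  expect_length(split_sentences("As shown by Smith et al. 2001, it binds."), 1)

  texts <- c(
    "A binds B. C binds D.",
    "One sentence only",
    "What is it? It is a kinase! Indeed.",
    "See Fig. 2 for details. The protein (p53) is shown.",
    "  Leading space. Trailing too.  ")
  for (txt in texts) {
    sens <- split_sentences(txt)
    prev_end <- -1L
    for (s in sens) {
      expect_gt(s$end, s$start)
      expect_gte(s$start, prev_end)       # non-overlapping, ordered
      expect_identical(s$text, substr(txt, s$start + 1L, s$end))
      prev_end <- s$end
    }
    covered <- paste(vapply(sens, `[[`, "", "text"), collapse = " ")
    expect_identical(gsub("[[:space:]]+", "", covered),
                     gsub("[[:space:]]+", "", txt))
  }
})

test_that("collapsed ranges expand under the prefix rules", {
  r <- expand_ranges("the SOCS1-SOCS7 family")
  expect_length(r, 1)
  expect_equal(r[[1]]$names, paste0("SOCS", 1:7))
  expect_equal(expand_ranges("VDAC1-3")[[1]]$names, paste0("VDAC", 1:3))
  expect_length(expand_ranges("ABC"), 0)
  expect_length(expand_ranges("SOCS7-SOCS1"), 0)       # descending
  expect_length(expand_ranges("GENE1-200", cap = 100), 0)  # over cap

  # property: length, uniqueness, shared prefix
  set.seed(11)
  for (i in 1:20) {
    lo <- sample(1:5, 1); hi <- lo + sample(1:8, 1)
    pref <- paste0(sample(LETTERS, 4), collapse = "")
    txt <- sprintf("flanked %s%d-%s%d here", pref, lo, pref, hi)
    r <- expand_ranges(txt)
    expect_length(r, 1)
    expect_length(r[[1]]$names, hi - lo + 1)
    expect_false(anyDuplicated(r[[1]]$names) > 0)
    expect_true(all(startsWith(r[[1]]$names, pref)))
    expect_identical(substr(txt, r[[1]]$start + 1, r[[1]]$end), r[[1]]$text)
  }
})

test_that("abbreviation pairs follow right-to-left character matching", {
  a <- make_article("AB1", list(
    list(kind = "introduction", heading = "Introduction", text = paste(
      "The transforming growth factor-beta stimulated clone-22 (TSC-22)",
      "prevents apoptosis. We raised five mice (n = 5) and studied",
      "sonic hedgehog (Shh) signalling."))))
  ab <- extract_abbreviations(a)
  expect_setequal(ab$short, c("TSC-22", "Shh"))
  expect_true("sonic hedgehog" %in% ab$long)
  expect_true(
    "transforming growth factor-beta stimulated clone-22" %in% ab$long)

  # deterministic and insensitive to surrounding sentences
  b <- make_article("AB2", list(
    list(kind = "introduction", heading = "Introduction", text = paste(
      "Unrelated first sentence. We studied sonic hedgehog (Shh)",
      "signalling. Another unrelated sentence."))))
  expect_identical(extract_abbreviations(b)$long, "sonic hedgehog")
  expect_identical(extract_abbreviations(b), extract_abbreviations(b))
})

test_that("init_metadata populates abbreviations and keywords", {
  a <- make_article("M1", list(
    list(kind = "introduction", heading = "Introduction", text = paste(
      "The bone morphogenetic protein (BMP) and sonic hedgehog (Shh)",
      "pathways interact."))), keywords = c("BMP", "signalling"))
  md <- init_metadata(a)
  expect_equal(nrow(md$abbreviations), 2)
  expect_identical(md$keywords, c("BMP", "signalling"))
  expect_length(md$normalized, 0)
  expect_true(is.na(md$focus_species))

  b <- make_article("M2", list(
    list(kind = "introduction", heading = "Introduction",
         text = "No parentheses at all here.")))
  expect_equal(nrow(init_metadata(b)$abbreviations), 0)
})
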