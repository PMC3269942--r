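test_that("dictionary loading groups rows and validates the schema", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttaxon_id\tname\tname_type",
               "G1\t9606\tTP53\tofficial",
               "G1\t9606\tTP53\tsynonym",          # duplicate name
               "G2\t10090\tTrp53\tofficial"), p)
  d <- load_dictionary(p)
  expect_equal(d$n_entries, 2)
  expect_equal(d$entries$G1$names, "TP53")          # deduplicated
  expect_equal(unname(d$gene_taxon["G2"]), "10090")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttaxon_id\tname", "G1\t9606\tTP53"), bad)
  expect_error(load_dictionary(bad), "missing column")
  blank <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttaxon_id\tname\tname_type",
               "G1\t9606\t\tofficial"), blank)
  expect_error(load_dictionary(blank), "row 1")
})

test_that("variant generation covers the rule set and is idempotent", {
  v <- generate_variants("TGF-beta")
  expect_true(all(c("tgf beta", "tgfbeta", "tgf-β") %in% tolower(v)))
  expect_setequal(generate_variants("p53"), c("p53", "P53")[1])
  expect_true("factor 2" %in% generate_variants("factor II"))
  expect_true("interleukin 6" %in%
                generate_variants("interleukin 6 protein"))
  expect_error(generate_variants(""), "empty")

  set.seed(3)
  names <- c("TGF-beta", "factor II", "BRCA1 gene", "NF-kappa-B",
             "p53", "sonic hedgehog protein")
  for (nm in names) {
    v <- generate_variants(nm)
    expect_true(nm %in% v)
    again <- unique(unlist(lapply(v, generate_variants)))
    expect_setequal(again, v)                       # closure is a fixpoint
  }
})

test_that("exact_match agrees with a brute-force scan on random dictionaries", {
  set.seed(42)
  stems <- replicate(120, paste0(
    paste0(sample(letters, 4), collapse = ""), sample(1:9, 1)))
  df <- data.frame(gene_id = sprintf("R%03d", seq_along(stems)),
                   taxon_id = as.character(sample(c(9606, 10090, 4565),
                                                  length(stems), TRUE)),
                   name = toupper(stems), name_type = "official",
                   stringsAsFactors = FALSE)
  d <- make_dictionary(df)
  brute <- function(q, enabled) {
    hits <- character()
    for (gid in names(d$entries)) {
      e <- d$entries[[gid]]
      if (e$taxon_id %in% enabled &&
          normalize_name(q) %in% normalize_name(e$variants))
        hits <- c(hits, gid)
    }
    sort(hits)
  }
  for (i in 1:50) {
    gid <- sample(names(d$entries), 1)
    q <- sample(d$entries[[gid]]$variants, 1)
    if (runif(1) < 0.5) q <- tolower(q)
    enabled <- sample(c("9606", "10090", "4565"), sample(1:3, 1))
    expect_identical(exact_match(q, d, enabled), brute(q, enabled))
  }
  expect_identical(exact_match("nosuchname", d, "9606"), character())
  expect_error(exact_match("", d, "9606"), "empty mention")
})

test_that("ambiguous names filter by enabled taxa", {
  d <- toy_dictionary()
  expect_setequal(exact_match("TP53", d, c("9606", "10090")), c("G1", "G2"))
  expect_identical(exact_match("TP53", d, "10090"), "G2")
  expect_identical(exact_match("Tumor Protein P53", d, "9606"), "G1")
})

test_that("partial matching ranks by idf-weighted token overlap", {
  df <- data.frame(
    gene_id = sprintf("P%02d", 1:10), taxon_id = "9606",
    name = c("tumor necrosis factor alpha", "tumor suppressor candidate 2",
             "necrosis associated factor", "interleukin 6",
             "interleukin 10", "growth factor receptor 2",
             "alpha synuclein", "beta catenin", "zinc finger protein 1",
             "heat shock factor 4"),
    name_type = "official", stringsAsFactors = FALSE)
  d <- make_dictionary(df)
  pm <- partial_match("tumor necrosis factor", d, "9606")
  expect_identical(pm$gene_id[1], "P01")   # only a trailing token missing
  expect_true(all(pm$score > 0 & pm$score <= 1))
  expect_true(all(diff(pm$score) <= 0))
  expect_equal(nrow(partial_match("completely unrelated words", d, "9606")), 0)
  # identical scores break ties by ascending gene id
  pm2 <- partial_match("interleukin", d, "9606", top_n = 5)
  two <- pm2[pm2$score == pm2$score[1], ]
  expect_identical(two$gene_id, sort(two$gene_id))
  expect_lte(nrow(partial_match("factor", d, "9606", top_n = 2)), 2)
  expect_error(partial_match("", d, "9606"), "empty mention")
})

test_that("species detection matches declared patterns only", {
  tb <- toy_species_table()
  expect_true("4565" %in% detect_species("fields of Triticum aestivum", tb))
  expect_true("4932" %in% detect_species("the yeast S. cerevisiae", tb))
  expect_true("9606" %in% detect_species("in HUMAN tissue", tb))
  expect_identical(detect_species("", tb), character())
  expect_identical(detect_species("no species here", tb), character())
})

test_that("entry-selection strategies produce the specified scopes", {
  tb <- toy_species_table()
  d <- toy_dictionary()
  art <- toy_article()   # mentions Homo sapiens only (a common species)
  common <- c("9606", "10090")

  st <- select_entries(art, d, strategy_config("static",
                                               common_species = common), tb)
  expect_identical(st, list(article = common))

  dyn <- select_entries(art, d,
                        strategy_config("dynamic_article",
                                        common_species = common), tb)
  expect_setequal(dyn$article, common)     # detected ⊆ common here

  # a rare detected taxon joins the common list
  art2 <- make_article("R1", list(
    list(kind = "introduction", heading = "Introduction",
         text = "EXPB11 was cloned from Triticum aestivum.")))
  dyn2 <- select_entries(art2, d,
                         strategy_config("dynamic_article",
                                         common_species = common), tb)
  expect_setequal(dyn2$article, c(common, "4565"))

  orc <- select_entries(art, d,
                        strategy_config("oracle", oracle_taxa = "4565",
                                        common_species = common), tb)
  expect_identical(orc$article, "4565")
  expect_error(strategy_config("oracle"), "oracle_taxa")

  # section scopes are nested inside the article scope
  sec <- select_entries(art2, d,
                        strategy_config("dynamic_section",
                                        common_species = common), tb)
  for (key in names(sec))
    expect_true(all(sec[[key]] %in% dyn2$article))
  # determinism
  expect_identical(sec, select_entries(art2, d,
                                       strategy_config("dynamic_section",
                                                       common_species = common),
                                       tb))
})
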