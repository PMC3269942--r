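# Fixtures are built in code: toy dictionaries/KBs, an independent
# brute-force TAP oracle, random query generators, and a labeled-feature
# generator for the ranking contract.

toy_dict_df <- function() {
  data.frame(
    gene_id = c("G1", "G1", "G2", "G3", "G4", "G5"),
    taxon_id = c("9606", "9606", "10090", "9606", "10116", "4565"),
    name = c("TP53", "tumor protein p53", "TP53", "interleukin 6",
             "BDNF2", "EXPB11"),
    name_type = c("official", "synonym", "official", "official",
                  "official", "official"),
    stringsAsFactors = FALSE)
}

toy_dictionary <- function() make_dictionary(toy_dict_df())

toy_species_table <- function() {
  make_species_table(data.frame(
    taxon_id = c("9606", "9606", "10090", "10116", "4565", "4932"),
    pattern = c("Homo sapiens", "human", "Mus musculus|mouse|mice",
                "Rattus norvegicus|\\brats?\\b", "Triticum aestivum",
                "S\\. ?cerevisiae"),
    case_sensitive = "0", stringsAsFactors = FALSE))
}

toy_kb <- function() {
  make_kb(list(
    G1 = list(taxon_id = "9606", cell_keywords = "HeLa",
              tissue_keywords = "liver", domain_keywords = "zinc finger",
              family_keywords = "p53 family", go_terms = "apoptosis",
              chromosome_locations = "17p13", sequence_lengths = 393L,
              masses = 43.7, rs_numbers = "rs1042522",
              ppi_partners = "G3", full_names = "tumor protein p53"),
    G2 = list(taxon_id = "10090", cell_keywords = "NIH3T3",
              tissue_keywords = "brain", domain_keywords = "zinc finger",
              family_keywords = "p53 family", go_terms = "DNA repair",
              chromosome_locations = "11qE1", sequence_lengths = 390L,
              masses = 43.1, rs_numbers = character(),
              ppi_partners = character(), full_names = "tumor protein p53"),
    G3 = list(taxon_id = "9606", cell_keywords = "K562",
              tissue_keywords = "spleen", domain_keywords = "SH2 domain",
              family_keywords = "interleukin family",
              go_terms = "signal transduction",
              chromosome_locations = "7p15", sequence_lengths = 212L,
              masses = 23.7, rs_numbers = character(),
              ppi_partners = "G1", full_names = "interleukin 6")),
    species_table = toy_species_table())
}

# article with an ambiguous TP53 plus the human species keyword in-sentence
toy_article <- function(intro = paste(
  "The tumor protein p53 (TP53) is mutated in many cancers of Homo",
  "sapiens. Interleukin 6 signaling activates TP53.")) {
  make_article("TOY1", list(
    list(kind = "title", heading = "Title", text = "A study of TP53"),
    list(kind = "abstract", heading = "Abstract",
         text = "We analysed TP53 in human cells."),
    list(kind = "introduction", heading = "Introduction", text = intro),
    list(kind = "results", heading = "Results",
         text = "TP53 expression rose in HeLa cells (Fig. 1).")))
}

# independent brute-force TAP: recomputes every prefix precision directly
tap_oracle <- function(gold, ids, evs, E0) {
  sentinel <- 0L
  for (i in seq_along(ids)) if (evs[i] <= E0) sentinel <- i
  if (sentinel == 0L) return(0)
  total <- 0
  for (i in seq_len(sentinel)) {
    if (ids[i] %in% gold && evs[i] <= E0) {
      ncorr <- 0L
      for (j in seq_len(i)) if (ids[j] %in% gold) ncorr <- ncorr + 1L
      total <- total + ncorr / i
    }
  }
  ncorr <- 0L
  for (j in seq_len(sentinel)) if (ids[j] %in% gold) ncorr <- ncorr + 1L
  total <- total + ncorr / sentinel
  total / (length(gold) + 1)
}

# random small query: R <= 5 gold ids, retrieved list <= 12
rand_query <- function(qid) {
  R <- sample(1:5, 1)
  pool <- sprintf("id%02d", 1:20)
  gold <- sample(pool, R)
  n <- sample(0:12, 1)
  ids <- sample(pool, n)
  query_result(qid, gold, ids, e_value = sort(round(stats::runif(n), 3)))
}

# labeled feature fixtures: correct ids carry higher vote totals and richer
# locations by construction
gen_labeled_features <- function(n) {
  nf <- length(feature_names())
  X <- matrix(0, n, nf, dimnames = list(NULL, feature_names()))
  y <- rep(c("correct", "incorrect"), length.out = n)
  for (i in seq_len(n)) {
    pos <- y[i] == "correct"
    X[i, "match_exact"] <- as.numeric(pos || stats::runif(1) < 0.5)
    X[i, "match_partial"] <- 1 - X[i, "match_exact"]
    X[i, "vote_total"] <- stats::rnorm(1, if (pos) 3 else 0.5, 1)
    X[i, paste0("rule_", RULE_IDS)] <-
      stats::rbinom(length(RULE_IDS), 1, if (pos) 0.5 else 0.2)
    X[i, "freq_article"] <- log1p(stats::rpois(1, if (pos) 5 else 1) + 1)
    X[i, "freq_results_pct"] <- stats::runif(1)
    loc <- grep("^loc_", feature_names())
    X[i, loc] <- stats::rbinom(length(loc), 1, if (pos) 0.6 else 0.2)
    X[i, c("keyword_match", "fullname_abbrev_match")] <-
      stats::rbinom(2, 1, if (pos) 0.5 else 0.1)
  }
  list(X = X, y = y)
}
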