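# Deterministic synthetic-corpus generator: dictionaries with controllable
# cross-species name ambiguity, knowledge bases, species keyword tables,
# full-text articles with planted gene mentions (Schwartz-Hearst-parsable
# definitions, abbreviation reuse, species keywords, collapsed ranges), and
# gold-standard id lists. Everything derives from one seed.

SYN_CONSONANTS <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                    "t", "v", "z")
SYN_VOWELS <- c("a", "e", "i", "o", "u")

# one word per initial so long forms derive deterministically from symbols
SYN_WORDS <- c(a = "activated", b = "binding", c = "catalytic",
               d = "dependent", e = "enhancer", f = "factor", g = "growth",
               h = "homolog", i = "inducible", j = "junction", k = "kinase",
               l = "ligand", m = "membrane", n = "nuclear", o = "oxidase",
               p = "polymerase", q = "quiescence", r = "regulator",
               s = "signaling", t = "transporter", u = "ubiquitin",
               v = "vesicular", w = "tryptophan", x = "xenobiotic",
               y = "tyrosine", z = "zinc")

SYN_CELLS <- c("HeLa", "CHO", "3T3-L1", "K562", "COS-7", "NIH3T3")
SYN_TISSUES <- c("liver", "brain", "kidney", "muscle", "heart", "spleen")
SYN_DOMAINS <- c("kinase domain", "zinc finger", "SH2 domain",
                 "leucine zipper", "PDZ domain")
SYN_FAMILIES <- c("cyclin family", "solute carrier family",
                  "homeobox family", "ABC transporter family")
SYN_GO <- c("apoptosis", "cell cycle arrest", "signal transduction",
            "DNA repair", "transcription regulation")

syn_stem <- function(n_syllables = 2L) {
  paste0(paste0(sample(SYN_CONSONANTS, n_syllables, replace = TRUE),
                sample(SYN_VOWELS, n_syllables, replace = TRUE)),
         collapse = "")
}

syn_symbol <- function() {
  toupper(paste0(syn_stem(2L), sample(1:9, 1L)))
}

syn_long_form <- function(symbol) {
  stem <- tolower(gsub("[0-9]+$", "", symbol))
  num <- sub("^[A-Za-z]+", "", symbol)
  letters_of <- strsplit(stem, "")[[1]]
  paste(c(SYN_WORDS[letters_of], num), collapse = " ")
}

#' Simulation configuration for the synthetic corpus
#'
#' Defaults describe the stated test world: a 30-species dictionary of which
#' 10 are "common", 15 genes per species, 30% of names shared across
#' species, 50 articles with 4 planted genes each, abbreviation-style
#' definitions for 80% of plants, in-sentence species keywords for 70%, and
#' collapsed ranges injected into 20% of articles.
#'
#' @param seed integer seed; identical config + seed regenerate the corpus
#'   byte-identically.
#' @param n_species number of taxa in the dictionary.
#' @param n_common number of taxa treated as "common" (<= n_species).
#' @param genes_per_species genes per taxon.
#' @param ambiguity_rate fraction of genes whose name is shared across
#'   at least two taxa.
#' @param articles number of articles.
#' @param sections_per_article number of sections (prefix of title,
#'   abstract, introduction, results, other, figure_caption, table_caption,
#'   conclusion, appendix).
#' @param plants_per_article planted genes per article.
#' @param abbreviation_rate fraction of plants introduced with a
#'   Schwartz-Hearst-parsable full-name definition.
#' @param range_rate fraction of articles receiving a collapsed-range
#'   sentence.
#' @param species_keyword_rate fraction of planted mention sentences
#'   carrying an in-sentence species keyword.
#' @return object of class `gn_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 30L,
                       n_common = min(10L, n_species),
                       genes_per_species = 15L, ambiguity_rate = 0.3,
                       articles = 50L, sections_per_article = 6L,
                       plants_per_article = 4L, abbreviation_rate = 0.8,
                       range_rate = 0.2, species_keyword_rate = 0.7) {
  rates <- c(ambiguity_rate, abbreviation_rate, range_rate,
             species_keyword_rate)
  if (any(rates < 0 | rates > 1)) gn_stop("rates must be in [0, 1]")
  counts <- c(n_species, n_common, genes_per_species, articles,
              sections_per_article, plants_per_article)
  if (any(counts < 1)) gn_stop("counts must be >= 1")
  if (n_common > n_species) gn_stop("n_common must be <= n_species")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_common = as.integer(n_common),
                 genes_per_species = as.integer(genes_per_species),
                 ambiguity_rate = ambiguity_rate,
                 articles = as.integer(articles),
                 sections_per_article = as.integer(sections_per_article),
                 plants_per_article = as.integer(plants_per_article),
                 abbreviation_rate = abbreviation_rate,
                 range_rate = range_rate,
                 species_keyword_rate = species_keyword_rate),
            class = "gn_sim_config")
}

#' Generate a synthetic dictionary and species keyword table
#'
#' Gene names are pronounceable stems plus a numeral; a fraction
#' `ambiguity_rate` of genes share their name (symbol and derived long
#' form) with a gene of another taxon. Each taxon gets a binomial-like
#' species pattern and its abbreviated form.
#'
#' @param cfg a `gn_sim_config`.
#' @return list with `dict` (a `gn_dictionary`), `table`
#'   (a `gn_species_table`), the backing data frames `dict_df` and
#'   `species_df`, `taxa`, `common_species`, and the per-gene `genes`
#'   data.frame (gene_id, taxon_id, symbol, long).
#' @export
gen_dictionary <- function(cfg) {
  set.seed(cfg$seed)
  taxa <- as.character(9000L + seq_len(cfg$n_species))
  genus <- character(); epithet <- character()
  for (i in seq_len(cfg$n_species)) {
    repeat {
      g <- paste0(toupper(substr(syn_stem(2L), 1, 1)),
                  substr(syn_stem(2L), 2, 4), syn_stem(1L))
      e <- syn_stem(3L)
      if (!paste(g, e) %in% paste(genus, epithet)) break
    }
    genus <- c(genus, g); epithet <- c(epithet, e)
  }
  n_genes <- cfg$n_species * cfg$genes_per_species
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  taxon_of <- rep(taxa, each = cfg$genes_per_species)
  symbols <- character(n_genes)
  for (i in seq_len(n_genes)) {
    repeat {
      s <- syn_symbol()
      if (!s %in% symbols) break
    }
    symbols[i] <- s
  }
  # share names pairwise across taxa so ~ambiguity_rate of genes carry a
  # name borne by >= 2 gene ids
  n_pairs <- floor(cfg$ambiguity_rate * n_genes / 2)
  if (n_pairs > 0L) {
    perm <- sample(n_genes)
    made <- 0L; p <- 1L
    while (made < n_pairs && p < length(perm)) {
      i <- perm[p]; j <- perm[p + 1L]
      if (taxon_of[i] != taxon_of[j]) {
        symbols[j] <- symbols[i]
        made <- made + 1L
        p <- p + 2L
      } else p <- p + 1L
    }
  }
  longs <- vapply(symbols, syn_long_form, "")
  genes <- data.frame(gene_id = gene_id, taxon_id = taxon_of,
                      symbol = symbols, long = unname(longs),
                      stringsAsFactors = FALSE)
  dict_df <- rbind(
    data.frame(gene_id = gene_id, taxon_id = taxon_of, name = symbols,
               name_type = "official", stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, taxon_id = taxon_of, name = unname(longs),
               name_type = "synonym", stringsAsFactors = FALSE))
  dict_df <- dict_df[order(dict_df$gene_id, dict_df$name_type), ]
  row.names(dict_df) <- NULL
  species_df <- rbind(
    data.frame(taxon_id = taxa,
               pattern = paste(genus, epithet),
               case_sensitive = "0", stringsAsFactors = FALSE),
    data.frame(taxon_id = taxa,
               pattern = paste0(substr(genus, 1, 1), "\\. ?", epithet),
               case_sensitive = "0", stringsAsFactors = FALSE))
  species_df <- species_df[order(species_df$taxon_id, species_df$pattern), ]
  row.names(species_df) <- NULL
  list(dict = make_dictionary(dict_df), table = make_species_table(species_df),
       dict_df = dict_df, species_df = species_df, taxa = taxa,
       common_species = taxa[seq_len(cfg$n_common)], genes = genes,
       binomial = setNames(paste(genus, epithet), taxa))
}

#' Generate a synthetic knowledge base for a dictionary
#'
#' Each gene gets its taxon, 1-3 cell/tissue/domain/family keywords, a
#' mass, a sequence length, an rs number, 1-2 GO terms, a chromosome
#' location, its full name, and 0-2 symmetric PPI partners.
#'
#' @param dict_info output of [gen_dictionary()].
#' @param cfg a `gn_sim_config`.
#' @return a `gn_kb` (carrying the species table for the Species rule).
#' @export
gen_kb <- function(dict_info, cfg) {
  set.seed(cfg$seed + 1L)
  genes <- dict_info$genes
  n <- nrow(genes)
  kb_genes <- vector("list", n)
  names(kb_genes) <- genes$gene_id
  for (i in seq_len(n)) {
    kb_genes[[i]] <- list(
      taxon_id = genes$taxon_id[i],
      cell_keywords = sample(SYN_CELLS, sample(1:3, 1)),
      tissue_keywords = sample(SYN_TISSUES, sample(1:3, 1)),
      domain_keywords = sample(SYN_DOMAINS, sample(1:2, 1)),
      family_keywords = sample(SYN_FAMILIES, sample(1:2, 1)),
      go_terms = sample(SYN_GO, sample(1:2, 1)),
      chromosome_locations = paste0(sample(1:22, 1), "q",
                                    sample(11:25, 1)),
      sequence_lengths = sample(100:3000, 1),
      masses = round(stats::runif(1, 10, 300), 1),
      rs_numbers = sprintf("rs%06d", sample(1e5:999999, 1)),
      ppi_partners = character(),
      full_names = genes$long[i])
  }
  # symmetric PPI pairs, preferentially within the same taxon
  n_ppi <- max(1L, floor(n / 3))
  for (p in seq_len(n_ppi)) {
    i <- sample(n, 1)
    same <- setdiff(which(genes$taxon_id == genes$taxon_id[i]), i)
    j <- if (length(same)) same[sample(length(same), 1)] else
      sample(setdiff(seq_len(n), i), 1)
    kb_genes[[i]]$ppi_partners <-
      unique(c(kb_genes[[i]]$ppi_partners, genes$gene_id[j]))
    kb_genes[[j]]$ppi_partners <-
      unique(c(kb_genes[[j]]$ppi_partners, genes$gene_id[i]))
  }
  make_kb(kb_genes, dict_info$table)
}

SYN_SECTION_ORDER <- list(
  list(kind = "title", heading = "Title"),
  list(kind = "abstract", heading = "Abstract"),
  list(kind = "introduction", heading = "Introduction"),
  list(kind = "results", heading = "Results"),
  list(kind = "other", heading = "Discussion"),
  list(kind = "figure_caption", heading = "Figure 1"),
  list(kind = "table_caption", heading = "Table 1"),
  list(kind = "conclusion", heading = "Conclusion"),
  list(kind = "appendix", heading = "Appendix"))

#' Generate one synthetic article with planted gene mentions
#'
#' Plants are introduced in the Introduction (with a
#' Schwartz-Hearst-parsable full-name definition at `abbreviation_rate`),
#' re-mentioned by symbol in the Abstract, Results and captions, with
#' in-sentence species keywords at `species_keyword_rate` and a
#' collapsed-range sentence at `range_rate`. Deterministic per
#' (config, article_index).
#'
#' @param dict_info output of [gen_dictionary()].
#' @param kb a `gn_kb` from [gen_kb()].
#' @param table a `gn_species_table` (normally `dict_info$table`).
#' @param cfg a `gn_sim_config`.
#' @param article_index 1-based article number.
#' @return list(article = `gn_article`, gold = data.frame(gene_id,
#'   taxon_id), manifest = data.frame(gene_id, symbol, long)).
#' @export
gen_article <- function(dict_info, kb, table, cfg, article_index) {
  set.seed((cfg$seed * 1000003L + article_index) %% .Machine$integer.max)
  genes <- dict_info$genes
  plant_rows <- sample(nrow(genes), min(cfg$plants_per_article, nrow(genes)))
  plants <- genes[plant_rows, , drop = FALSE]
  binom <- dict_info$binomial
  sp_of <- function(i) unname(binom[plants$taxon_id[i]])
  with_sp <- function(i) stats::runif(1) < cfg$species_keyword_rate
  g_kb <- function(i) kb_entry(kb, plants$gene_id[i])

  intro <- character()
  for (i in seq_len(nrow(plants))) {
    if (stats::runif(1) < cfg$abbreviation_rate) {
      s <- sprintf("The %s (%s) is a conserved %s.", plants$long[i],
                   plants$symbol[i], sample(g_kb(i)$domain_keywords, 1))
    } else {
      s <- sprintf("%s acts as a key regulator of %s.", plants$symbol[i],
                   sample(g_kb(i)$go_terms, 1))
    }
    if (with_sp(i))
      s <- sub("\\.$", sprintf(" in %s.", sp_of(i)), s)
    intro <- c(intro, s)
  }
  intro <- c(intro, "Previous studies established this regulatory network.")

  abstract <- c(
    sprintf("We investigated %s in %s.",
            paste(plants$symbol, collapse = ", "), sp_of(1)),
    sprintf("Our data show that %s controls %s.",
            plants$symbol[1], sample(SYN_GO, 1)))

  results <- character()
  for (i in seq_len(nrow(plants))) {
    s <- sprintf("Expression of %s increased in %s samples (Fig. %d).",
                 plants$symbol[i], sample(g_kb(i)$tissue_keywords, 1), i)
    if (with_sp(i))
      s <- sub("\\.$", sprintf(" from %s.", sp_of(i)), s)
    results <- c(results, s)
  }
  if (stats::runif(1) < cfg$range_rate) {
    stem <- gsub("[0-9]+$", "", plants$symbol[1])
    results <- c(results,
                 sprintf("We also profiled the related genes %s1-%s3.",
                         stem, stem))
  }

  discussion <- sprintf(
    "These findings suggest that %s acts together with %s in %s cells.",
    plants$symbol[1], plants$symbol[min(2L, nrow(plants))],
    sample(g_kb(1)$cell_keywords, 1))
  caption <- sprintf("Fig. 1. %s protein levels in %s cells.",
                     plants$symbol[nrow(plants)],
                     sample(g_kb(nrow(plants))$cell_keywords, 1))
  caption2 <- sprintf("Table 1. Summary of %s variants.", plants$symbol[1])
  conclusion <- sprintf("In conclusion, %s is a central regulator.",
                        plants$symbol[1])
  appendix <- sprintf("Supplementary data for %s are available.",
                      plants$symbol[min(2L, nrow(plants))])

  texts <- list(
    title = sprintf("Functional analysis of %s in %s", plants$symbol[1],
                    sp_of(1)),
    abstract = paste(abstract, collapse = " "),
    introduction = paste(intro, collapse = " "),
    results = paste(results, collapse = " "),
    other = discussion,
    figure_caption = caption,
    table_caption = caption2,
    conclusion = conclusion,
    appendix = appendix)

  n_sec <- min(cfg$sections_per_article, length(SYN_SECTION_ORDER))
  secs <- lapply(SYN_SECTION_ORDER[seq_len(n_sec)], function(s)
    list(kind = s$kind, heading = s$heading, text = texts[[s$kind]]))
  art <- make_article(sprintf("SYN%04d", article_index), secs,
                      keywords = plants$symbol[1])
  list(article = art,
       gold = data.frame(gene_id = plants$gene_id,
                         taxon_id = plants$taxon_id,
                         stringsAsFactors = FALSE),
       manifest = data.frame(gene_id = plants$gene_id,
                             symbol = plants$symbol, long = plants$long,
                             stringsAsFactors = FALSE))
}

# bundle of all generated resources (dictionary, kb, table)
gen_resources <- function(cfg) {
  di <- gen_dictionary(cfg)
  kb <- gen_kb(di, cfg)
  c(di, list(kb = kb))
}

#' Generate and write a full synthetic corpus
#'
#' Writes `articles/article_<i>.json`, `dict.tsv`, `kb.json`,
#' `species.tsv`, `gold.tsv` and a `manifest.json` recording config and
#' seed. Identical config + seed produce byte-identical files.
#'
#' @param cfg a `gn_sim_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the written paths plus the in-memory
#'   resources.
#' @export
gen_corpus <- function(cfg, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    gn_stop("I/O error: cannot create %s", out_dir)
  art_dir <- file.path(out_dir, "articles")
  dir.create(art_dir, showWarnings = FALSE)
  res <- gen_resources(cfg)
  utils::write.table(res$dict_df, file.path(out_dir, "dict.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$species_df, file.path(out_dir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$kb$genes, file.path(out_dir, "kb.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  gold_all <- list(); paths <- character()
  for (i in seq_len(cfg$articles)) {
    ga <- gen_article(res, res$kb, res$table, cfg, i)
    p <- file.path(art_dir, sprintf("article_%03d.json", i))
    write_article(ga$article, p)
    paths <- c(paths, p)
    g <- ga$gold
    g$article_id <- ga$article$article_id
    gold_all[[i]] <- g[c("article_id", "gene_id", "taxon_id")]
  }
  gold <- do.call(rbind, gold_all)
  utils::write.table(gold, file.path(out_dir, "gold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, config = unclass(cfg)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(out_dir = out_dir, articles = paths,
                 dict = file.path(out_dir, "dict.tsv"),
                 kb = file.path(out_dir, "kb.json"),
                 species = file.path(out_dir, "species.tsv"),
                 gold = file.path(out_dir, "gold.tsv"),
                 resources = res))
}
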