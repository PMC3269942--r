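# Gene-name dictionary: orthographic variant generation, exact and partial
# matching over name/token indices, species-keyword detection, and the
# static/dynamic/oracle dictionary-entry selection strategies.

GREEK_MAP <- c(alpha = "α", beta = "β", gamma = "γ",
               delta = "δ", epsilon = "ε", kappa = "κ",
               lambda = "λ", sigma = "σ", omega = "ω")

ROMAN_MAP <- c(i = 1L, ii = 2L, iii = 3L, iv = 4L, v = 5L,
               vi = 6L, vii = 7L, viii = 8L, ix = 9L, x = 10L)

#' Generate orthographic variants of a gene name
#'
#' Closure under a fixed rule set: case folding, hyphen to space and hyphen
#' deletion, Greek letter word/symbol interchange ("beta" and "β"),
#' Roman/Arabic trailing numerals, and optional removal of the tokens
#' "protein" and "gene". The original name is always included; the closure
#' is idempotent.
#'
#' @param name non-empty character scalar.
#' @param cap maximum closure size (guard, default 64).
#' @return character vector of variants including `name`.
#' @export
generate_variants <- function(name, cap = 64L) {
  if (is.null(name) || is.na(name) || !nzchar(name))
    gn_stop("argument error: empty name")
  derive <- function(x) {
    out <- character()
    out <- c(out, tolower(x))
    if (grepl("[-‐-―]", x)) {
      out <- c(out, gsub("[[:space:]]+", " ", gsub("[-‐-―]", " ", x)),
               gsub("[-‐-―]", "", x))
    }
    for (w in names(GREEK_MAP)) {
      if (grepl(paste0("(?i)\\b", w, "\\b"), x, perl = TRUE))
        out <- c(out, gsub(paste0("(?i)\\b", w, "\\b"), GREEK_MAP[[w]], x, perl = TRUE))
      if (grepl(GREEK_MAP[[w]], x, fixed = TRUE))
        out <- c(out, gsub(GREEK_MAP[[w]], w, x, fixed = TRUE))
    }
    m <- regmatches(x, regexec("^(.*[ -])([IiVvXx]+)$", x))[[1]]
    if (length(m) == 3L && tolower(m[3]) %in% names(ROMAN_MAP))
      out <- c(out, paste0(m[2], ROMAN_MAP[[tolower(m[3])]]))
    m <- regmatches(x, regexec("^(.*[ -])([1-9]|10)$", x))[[1]]
    if (length(m) == 3L) {
      rom <- names(ROMAN_MAP)[match(as.integer(m[3]), ROMAN_MAP)]
      out <- c(out, paste0(m[2], toupper(rom)))
    }
    if (grepl("(?i)\\b(protein|gene)\\b", x, perl = TRUE)) {
      stripped <- gsub("[[:space:]]+", " ",
                       gsub("(?i)\\b(protein|gene)\\b", "", x, perl = TRUE))
      stripped <- trimws(stripped)
      if (nzchar(stripped)) out <- c(out, stripped)
    }
    out
  }
  vars <- name
  repeat {
    new <- setdiff(unique(unlist(lapply(vars, derive))), vars)
    if (!length(new) || length(vars) >= cap) break
    vars <- c(vars, new)[seq_len(min(cap, length(vars) + length(new)))]
  }
  unique(vars)
}

#' Build a gene dictionary from a data frame
#'
#' Rows are grouped by (gene_id, taxon_id); a name index (normalized variant
#' to gene ids) and an inverted token index are built deterministically.
#'
#' @param df data.frame with columns `gene_id`, `taxon_id`, `name`,
#'   `name_type`.
#' @param variants generate orthographic variants (default TRUE).
#' @return object of class `gn_dictionary`.
#' @export
make_dictionary <- function(df, variants = TRUE) {
  req <- c("gene_id", "taxon_id", "name", "name_type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    gn_stop("schema error: missing column(s) %s",
            paste(missing_cols, collapse = ", "))
  blank <- which(is.na(df$name) | !nzchar(trimws(df$name)))
  if (length(blank))
    gn_stop("row %d: blank name", blank[1])
  df$gene_id <- as.character(df$gene_id)
  df$taxon_id <- as.character(df$taxon_id)
  if (nrow(df) == 0L) warning("empty dictionary")

  entries <- list()
  for (gid in unique(df$gene_id)) {
    rows <- df[df$gene_id == gid, , drop = FALSE]
    nm <- unique(rows$name)
    vs <- if (variants) unique(unlist(lapply(nm, generate_variants))) else nm
    entries[[gid]] <- list(gene_id = gid, taxon_id = rows$taxon_id[1],
                           names = nm, variants = vs)
  }
  dict <- new.env(parent = emptyenv())
  dict$entries <- entries
  dict$gene_taxon <- vapply(entries, `[[`, "", "taxon_id")
  dict$n_entries <- length(entries)

  name_index <- new.env(parent = emptyenv())
  token_index <- new.env(parent = emptyenv())
  phrase_index <- new.env(parent = emptyenv())
  entry_tokens <- list()
  for (gid in names(entries)) {
    e <- entries[[gid]]
    toks_all <- character()
    seen_phrases <- character()
    for (v in e$variants) {
      key <- normalize_name(v)
      if (!nzchar(key)) next
      name_index[[key]] <- unique(c(name_index[[key]], gid))
      toks <- gn_name_tokens(v)
      toks_all <- c(toks_all, toks)
      if (length(toks)) {
        pk <- paste(toks, collapse = " ")
        if (!pk %in% seen_phrases) {
          seen_phrases <- c(seen_phrases, pk)
          first <- toks[1]
          phrase_index[[first]] <- c(phrase_index[[first]],
                                     list(list(tokens = toks, gene_id = gid,
                                               taxon_id = e$taxon_id)))
        }
      }
    }
    toks_all <- unique(toks_all)
    entry_tokens[[gid]] <- toks_all
    for (t in toks_all) token_index[[t]] <- unique(c(token_index[[t]], gid))
  }
  dict$name_index <- name_index
  dict$token_index <- token_index
  dict$phrase_index <- phrase_index
  dict$entry_tokens <- entry_tokens
  class(dict) <- c("gn_dictionary", "environment")
  dict
}

#' Load a gene dictionary from TSV
#'
#' Expected columns: `gene_id`, `taxon_id`, `name`,
#' `name_type` (official|synonym|variant).
#'
#' @param path TSV file path.
#' @param variants generate orthographic variants (default TRUE).
#' @return a `gn_dictionary`.
#' @export
load_dictionary <- function(path, variants = TRUE) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  make_dictionary(df, variants = variants)
}

#' Exact dictionary lookup of a mention
#'
#' The mention is normalized and looked up in the name index; results are
#' restricted to entries whose taxon is enabled.
#'
#' @param mention non-empty string.
#' @param dict a `gn_dictionary`.
#' @param enabled character vector of enabled taxon ids.
#' @return character vector of gene ids (possibly empty), sorted.
#' @export
exact_match <- function(mention, dict, enabled) {
  if (is.null(mention) || is.na(mention) || !nzchar(mention))
    gn_stop("argument error: empty mention")
  key <- normalize_name(mention)
  ids <- dict$name_index[[key]]
  if (is.null(ids)) return(character())
  sort(ids[dict$gene_taxon[ids] %in% enabled])
}

#' Partial (token-overlap) dictionary matching
#'
#' Inverted-index retrieval: candidate entries share at least one token with
#' the mention; the score is the idf-weighted fraction of mention tokens
#' present in the entry's token set, so score is in (0, 1]. Ties are broken
#' by ascending gene id.
#'
#' @param mention non-empty string.
#' @param dict a `gn_dictionary`.
#' @param enabled enabled taxon ids.
#' @param top_n maximum number of results (default 5).
#' @return data.frame with columns `gene_id`, `score`, best first.
#' @export
partial_match <- function(mention, dict, enabled, top_n = 5L) {
  if (is.null(mention) || is.na(mention) || !nzchar(mention))
    gn_stop("argument error: empty mention")
  toks <- unique(gn_name_tokens(mention))
  empty <- data.frame(gene_id = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(toks)) return(empty)
  N <- max(dict$n_entries, 1L)
  idf <- vapply(toks, function(t) {
    df_t <- length(dict$token_index[[t]])
    if (df_t == 0L) log(1 + N) else log(1 + N / df_t)
  }, 0)
  cand <- unique(unlist(lapply(toks, function(t) dict$token_index[[t]])))
  cand <- cand[dict$gene_taxon[cand] %in% enabled]
  if (!length(cand)) return(empty)
  scores <- vapply(cand, function(gid) {
    shared <- toks %in% dict$entry_tokens[[gid]]
    sum(idf[shared]) / sum(idf)
  }, 0)
  keep <- scores > 0
  cand <- cand[keep]; scores <- scores[keep]
  if (!length(cand)) return(empty)
  ord <- order(-scores, cand)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(gene_id = cand[ord], score = scores[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- species keyword table -------------------------------------------------

#' Build a species keyword table
#'
#' @param df data.frame with columns `taxon_id`, `pattern` (a regular
#'   expression), `case_sensitive` (0/1).
#' @return object of class `gn_species_table`.
#' @export
make_species_table <- function(df) {
  req <- c("taxon_id", "pattern", "case_sensitive")
  if (length(setdiff(req, names(df))))
    gn_stop("schema error: species table needs columns %s",
            paste(req, collapse = ", "))
  df$taxon_id <- as.character(df$taxon_id)
  df$case_sensitive <- as.integer(df$case_sensitive)
  split_df <- split(df[c("pattern", "case_sensitive")], df$taxon_id)
  structure(list(taxa = names(split_df), patterns = split_df),
            class = "gn_species_table")
}

#' Load a species keyword table from TSV
#'
#' Columns: `taxon_id`, `pattern`, `case_sensitive` (0|1).
#'
#' @param path TSV file path.
#' @return a `gn_species_table`.
#' @export
load_species_table <- function(path) {
  make_species_table(utils::read.delim(path, colClasses = "character",
                                       stringsAsFactors = FALSE, quote = ""))
}

#' Detect species mentioned in a text scope
#'
#' A taxon is reported iff at least one of its surface patterns (regular
#' expressions; case-insensitive unless declared sensitive) matches.
#'
#' @param text_scope character scalar.
#' @param table a `gn_species_table`.
#' @return character vector of detected taxon ids.
#' @export
detect_species <- function(text_scope, table) {
  if (is.null(text_scope) || is.na(text_scope) || !nzchar(text_scope))
    return(character())
  hit <- vapply(table$taxa, function(tx) {
    p <- table$patterns[[tx]]
    any(vapply(seq_len(nrow(p)), function(i)
      grepl(p$pattern[i], text_scope, perl = TRUE,
            ignore.case = p$case_sensitive[i] == 0L), logical(1)))
  }, logical(1))
  table$taxa[hit]
}

# total count of species-keyword matches per taxon (used for focus species)
count_species <- function(text_scope, table) {
  counts <- setNames(integer(length(table$taxa)), table$taxa)
  if (is.null(text_scope) || !nzchar(text_scope)) return(counts)
  for (tx in table$taxa) {
    p <- table$patterns[[tx]]
    n <- 0L
    for (i in seq_len(nrow(p))) {
      m <- gregexpr(p$pattern[i], text_scope, perl = TRUE,
                    ignore.case = p$case_sensitive[i] == 0L)[[1]]
      if (m[1] != -1L) n <- n + length(m)
    }
    counts[[tx]] <- n
  }
  counts
}

# ---- strategy configuration ------------------------------------------------

#' Dictionary-entry selection strategy configuration
#'
#' @param mode one of `static`, `dynamic_article`, `dynamic_section`,
#'   `oracle`.
#' @param common_species ordered character vector of taxon ids; defaults to
#'   the shipped 22-entry common-species list.
#' @param oracle_taxa taxa of the gold-standard ids (oracle mode only).
#' @param default_taxon fallback focus species.
#' @param range_cap maximum range-expansion length.
#' @param partial_top_n maximum partial-match results.
#' @param n1,n2 sizes of the "last sentences" location features for the
#'   abstract and first section.
#' @return object of class `gn_strategy`.
#' @export
strategy_config <- function(mode = c("static", "dynamic_article",
                                     "dynamic_section", "oracle"),
                            common_species = common_species_default(),
                            oracle_taxa = character(),
                            default_taxon = NULL,
                            range_cap = 100L, partial_top_n = 5L,
                            n1 = 3L, n2 = 3L) {
  mode <- match.arg(mode)
  common_species <- as.character(common_species)
  oracle_taxa <- as.character(oracle_taxa)
  if (mode == "oracle" && !length(oracle_taxa))
    gn_stop("config error: oracle mode requires non-empty oracle_taxa")
  if (mode == "static" && !length(common_species))
    gn_stop("config error: static mode requires non-empty common_species")
  structure(list(mode = mode, common_species = common_species,
                 oracle_taxa = oracle_taxa,
                 default_taxon = default_taxon %||% common_species[1],
                 range_cap = as.integer(range_cap),
                 partial_top_n = as.integer(partial_top_n),
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "gn_strategy")
}

#' The shipped default common-species list
#'
#' Taxon ids of 22 popular model organisms, shipped as editable TSV in
#' `extdata/common_species.tsv`; list content is configuration, not code.
#'
#' @return character vector of taxon ids.
#' @export
common_species_default <- function() {
  path <- system.file("extdata", "common_species.tsv", package = "genorm")
  if (!nzchar(path)) return(as.character(c(9606, 10090, 10116)))
  utils::read.delim(path, colClasses = "character")$taxon_id
}

#' Select enabled dictionary taxa per scope
#'
#' Static: one scope with the common-species list. Dynamic article-wide: one
#' scope with common species plus those detected anywhere in the article.
#' Dynamic section-wide: one scope per section, common species plus those
#' detected in that section. Oracle: the gold-standard taxa.
#'
#' @param article a `gn_article`.
#' @param dict a `gn_dictionary` (unused for selection itself; kept for
#'   interface symmetry).
#' @param cfg a `gn_strategy`.
#' @param table a `gn_species_table`.
#' @return named list: scope key (`"article"` or `"section:<i>"`) to
#'   character vector of enabled taxon ids.
#' @export
select_entries <- function(article, dict, cfg, table) {
  switch(cfg$mode,
    static = list(article = cfg$common_species),
    oracle = {
      if (!length(cfg$oracle_taxa))
        gn_stop("config error: oracle mode requires oracle_taxa")
      list(article = sort(unique(cfg$oracle_taxa)))
    },
    dynamic_article = {
      detected <- detect_species(article_text(article), table)
      list(article = sort(unique(c(cfg$common_species, detected))))
    },
    dynamic_section = {
      out <- list()
      for (i in seq_along(article$sections)) {
        detected <- detect_species(article$sections[[i]]$text, table)
        out[[paste0("section:", i)]] <-
          sort(unique(c(cfg$common_species, detected)))
      }
      out
    })
}

article_text <- function(article) {
  article$full_text %||%
    paste(vapply(article$sections, `[[`, "", "text"), collapse = "\n")
}

# enabled taxa for a given section under a scope map
scope_taxa <- function(scope_map, section_index) {
  key <- paste0("section:", section_index)
  scope_map[[key]] %||% scope_map[["article"]] %||% character()
}
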