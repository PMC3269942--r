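# Rule-based disambiguation: 13 context classifiers of the form
# r: (Condition) -> y * w, the weighted linear vote over them, and the
# candidate-selection order used when boundaries or identifiers disagree.

RULE_IDS <- c("Species", "Cell", "PPI", "History", "FullNameAcronym",
              "Tissue", "Domain", "Family", "Mass", "GeneOntology",
              "ChromosomeLocation", "SequenceLength", "RSNumber")

# rules that may vote against an identifier (y = -1 when evidence is absent
# article-wide); the remainder are two-valued because their information "may
# not always be described" (chromosome location et al.) or is metadata-driven
THREE_VALUED_RULES <- c("Species", "Cell", "Tissue", "Domain", "Family")

#' Build a gene knowledge base
#'
#' @param genes named list (by gene_id) of lists with fields `taxon_id`,
#'   `cell_keywords`, `tissue_keywords`, `domain_keywords`,
#'   `family_keywords`, `go_terms`, `chromosome_locations`,
#'   `sequence_lengths`, `masses`, `rs_numbers`, `ppi_partners`,
#'   `full_names`. Missing fields default to empty.
#' @param species_table optional `gn_species_table` used by the Species rule.
#' @return object of class `gn_kb`.
#' @export
make_kb <- function(genes, species_table = NULL) {
  for (gid in names(genes)) {
    if (is.null(genes[[gid]]$taxon_id))
      gn_stop("kb invariant violation: gene %s lacks taxon_id", gid)
  }
  structure(list(genes = genes, species_table = species_table),
            class = "gn_kb")
}

#' Load a knowledge base from JSON
#'
#' One object per gene_id, keyed by gene_id, with the fields of [make_kb()].
#'
#' @param path JSON file path.
#' @param species_table optional `gn_species_table`.
#' @return a `gn_kb`.
#' @export
load_kb <- function(path, species_table = NULL) {
  genes <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  genes <- lapply(genes, function(g) {
    g$sequence_lengths <- as.integer(g$sequence_lengths)
    g$masses <- as.numeric(g$masses)
    g
  })
  make_kb(genes, species_table)
}

kb_entry <- function(kb, gene_id) {
  g <- kb$genes[[gene_id]]
  if (is.null(g)) g <- list(taxon_id = NA_character_)
  defaults <- list(cell_keywords = character(), tissue_keywords = character(),
                   domain_keywords = character(), domain = character(),
                   family_keywords = character(), go_terms = character(),
                   chromosome_locations = character(),
                   sequence_lengths = integer(), masses = numeric(),
                   rs_numbers = character(), ppi_partners = character(),
                   full_names = character())
  for (f in names(defaults)) if (is.null(g[[f]])) g[[f]] <- defaults[[f]]
  g
}

# context scope texts; indices are 1-based positions in the R lists
context_scopes <- function(context) {
  art <- context$article
  sec <- art$sections[[context$section_index]]
  sen <- sec$sentences[[context$sentence_index]]
  list(sentence = sen$text, section = sec$text, article = article_text(art))
}

# fixed-string case-insensitive containment
str_found <- function(strings, text) {
  strings <- strings[nzchar(strings)]
  if (!length(strings)) return(FALSE)
  lt <- tolower(text)
  any(vapply(tolower(strings), function(s) grepl(s, lt, fixed = TRUE),
             logical(1)))
}

extract_masses <- function(text) {
  m <- regmatches(text,
                  gregexpr("([0-9]+(?:\\.[0-9]+)?)\\s*kDa", text,
                           perl = TRUE, ignore.case = TRUE))[[1]]
  as.numeric(sub("(?i)\\s*kDa", "", m, perl = TRUE))
}

extract_lengths <- function(text) {
  m <- regmatches(text, gregexpr("([0-9]+)\\s*(aa|bp)\\b", text,
                                 perl = TRUE, ignore.case = TRUE))[[1]]
  as.integer(sub("\\s*(aa|bp)\\b", "", m, ignore.case = TRUE))
}

extract_rs <- function(text) {
  tolower(regmatches(text, gregexpr("\\brs[0-9]+\\b", text,
                                    perl = TRUE, ignore.case = TRUE))[[1]])
}

species_found <- function(kb, taxon_id, text) {
  tb <- kb$species_table
  if (is.null(tb) || is.na(taxon_id) || !taxon_id %in% tb$taxa) return(FALSE)
  p <- tb$patterns[[taxon_id]]
  any(vapply(seq_len(nrow(p)), function(i)
    grepl(p$pattern[i], text, perl = TRUE,
          ignore.case = p$case_sensitive[i] == 0L), logical(1)))
}

new_rule_result <- function(rule_id, y, w) {
  structure(list(rule_id = rule_id, y = y, w = w, value = y * w),
            class = "gn_rule_result")
}

#' Apply one disambiguation rule to a candidate identifier
#'
#' Text-evidence rules search sentence, then section, then the rest of the
#' article: evidence in the same sentence gives y=1, w=1; in the same
#' section y=1, w=0.5; elsewhere in the article y=0; absent article-wide
#' y=-1 for three-valued rules and y=0 for two-valued rules
#' (ChromosomeLocation, Mass, SequenceLength, RSNumber, GeneOntology). PPI,
#' History and FullNameAcronym read the metadata memory and are two-valued
#' with w=1.
#'
#' @param rule_id one of the 13 rule names in `RULE_IDS`.
#' @param gene_id candidate identifier.
#' @param context list(article, section_index, sentence_index, mention_text);
#'   indices 1-based into the R lists.
#' @param kb a `gn_kb`.
#' @param metadata a `gn_metadata`.
#' @param three_valued which rules may vote -1 (config-overridable).
#' @return a `gn_rule_result` with `value = y * w` in {1, 0.5, 0, -0.5, -1}.
#' @export
apply_rule <- function(rule_id, gene_id, context, kb, metadata,
                       three_valued = THREE_VALUED_RULES) {
  if (!rule_id %in% RULE_IDS)
    gn_stop("argument error: unknown rule '%s'", rule_id)
  g <- kb_entry(kb, gene_id)
  nids <- vapply(metadata$normalized, `[[`, "", "gene_id")

  if (rule_id == "PPI") {
    hit <- length(nids) > 0L && any(nids %in% g$ppi_partners)
    return(new_rule_result(rule_id, as.integer(hit), 1))
  }
  if (rule_id == "History") {
    return(new_rule_result(rule_id, as.integer(gene_id %in% nids), 1))
  }
  if (rule_id == "FullNameAcronym") {
    mt <- context$mention_text %||% ""
    ab <- metadata$abbreviations
    longs <- character()
    if (!is.null(ab) && nrow(ab) > 0L && nzchar(mt)) {
      longs <- ab$long[normalize_name(ab$short) == normalize_name(mt)]
    }
    fn <- normalize_name(g$full_names)
    hit <- nzchar(mt) &&
      (any(normalize_name(longs) %in% fn) || normalize_name(mt) %in% fn)
    return(new_rule_result(rule_id, as.integer(hit), 1))
  }

  found <- switch(rule_id,
    Species = function(txt) species_found(kb, g$taxon_id, txt),
    Cell = function(txt) str_found(g$cell_keywords, txt),
    Tissue = function(txt) str_found(g$tissue_keywords, txt),
    Domain = function(txt) str_found(g$domain_keywords, txt),
    Family = function(txt) str_found(g$family_keywords, txt),
    GeneOntology = function(txt) str_found(g$go_terms, txt),
    ChromosomeLocation = function(txt) str_found(g$chromosome_locations, txt),
    Mass = function(txt) {
      if (!length(g$masses)) return(FALSE)
      obs <- extract_masses(txt)
      length(obs) > 0L &&
        any(outer(obs, g$masses, function(o, m) abs(o - m) / m <= 0.05))
    },
    SequenceLength = function(txt) {
      obs <- extract_lengths(txt)
      length(obs) > 0L && any(obs %in% g$sequence_lengths)
    },
    RSNumber = function(txt) {
      obs <- extract_rs(txt)
      length(obs) > 0L && any(obs %in% tolower(g$rs_numbers))
    })

  scopes <- context_scopes(context)
  if (found(scopes$sentence)) return(new_rule_result(rule_id, 1L, 1))
  if (found(scopes$section)) return(new_rule_result(rule_id, 1L, 0.5))
  if (found(scopes$article)) return(new_rule_result(rule_id, 0L, 1))
  y_absent <- if (rule_id %in% three_valued) -1L else 0L
  new_rule_result(rule_id, y_absent, 1)
}

#' Weighted linear vote over all 13 disambiguation rules
#'
#' @inheritParams apply_rule
#' @return object of class `gn_vote`: per-rule results, the summed value
#'   `total`, and `votes_against` (count of rules with y = -1).
#' @export
weighted_vote <- function(gene_id, context, kb, metadata,
                          three_valued = THREE_VALUED_RULES) {
  results <- lapply(RULE_IDS, apply_rule, gene_id = gene_id,
                    context = context, kb = kb, metadata = metadata,
                    three_valued = three_valued)
  names(results) <- RULE_IDS
  structure(list(gene_id = gene_id, results = results,
                 total = sum(vapply(results, `[[`, 0, "value")),
                 votes_against = sum(vapply(results, `[[`, 0L, "y") == -1L)),
            class = "gn_vote")
}

#' Candidate selection among competing (mention, identifier) pairs
#'
#' Deterministic total order: longest mention string first, then fewest
#' rule votes against, then highest vote total, then smallest gene id.
#'
#' @param candidates non-empty list of `list(gene_id, mention_text, vote)`
#'   where `vote` is a `gn_vote`.
#' @return the winning element of `candidates`.
#' @export
select_candidate <- function(candidates) {
  if (!length(candidates))
    gn_stop("argument error: empty candidate list")
  len <- vapply(candidates, function(c) nchar(c$mention_text), 0L)
  va <- vapply(candidates, function(c) c$vote$votes_against, 0)
  tot <- vapply(candidates, function(c) c$vote$total, 0)
  gid <- vapply(candidates, function(c) c$gene_id, "")
  candidates[[order(-len, va, -tot, gid)[1]]]
}
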