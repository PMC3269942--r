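# Three-stage gene normalization over one article. Stage 1 walks
# Introduction -> Abstract -> Title (richest context first) filling the
# metadata memory; stage 2 propagates the memory over the whole article with
# sentence-level species checks and the focus species; stage 3 runs
# recognition + normalization over the remaining sections, resolving
# tagger/dictionary disagreements by candidate selection.

TAI_KINDS <- c("title", "abstract", "introduction")

new_normalized <- function(key, gene_id, taxon_id, occ, stage, vote,
                           match_kind, mention_text) {
  structure(list(key = key, gene_id = gene_id, taxon_id = taxon_id,
                 mention_texts = mention_text, mentions = occ,
                 stage = stage, vote = vote, match_kind = match_kind),
            class = "gn_normalized")
}

occ_row <- function(si, sj, m) {
  data.frame(section_index = si, sentence_index = sj,
             start = m$start, end = m$end, text = m$text,
             source = m$source %||% "tagger", stringsAsFactors = FALSE)
}

append_occurrence <- function(md, key, occ, mention_text = NULL) {
  rec <- md$normalized[[key]]
  dup <- any(rec$mentions$section_index == occ$section_index &
               rec$mentions$sentence_index == occ$sentence_index &
               rec$mentions$start == occ$start)
  if (!dup) {
    rec$mentions <- rbind(rec$mentions, occ)
    if (!is.null(mention_text))
      rec$mention_texts <- unique(c(rec$mention_texts, mention_text))
    md$normalized[[key]] <- rec
  }
  invisible(md)
}

# stage-1-style normalization of one mention row; mutates md
process_mention <- function(md, m, si, sj, article, dict, kb, cfg, enabled,
                            stage) {
  key <- normalize_name(m$text)
  if (!nzchar(key)) return(invisible(NULL))
  occ <- occ_row(si, sj, m)
  if (!is.null(md$normalized[[key]])) {
    append_occurrence(md, key, occ)
    return(invisible(NULL))
  }
  ids <- exact_match(m$text, dict, enabled)
  kind <- "exact"
  if (!length(ids) && !is.na(m$original_text)) {
    ids <- exact_match(m$original_text, dict, enabled)
  }
  if (!length(ids)) {
    pm <- partial_match(m$text, dict, enabled, cfg$partial_top_n)
    ids <- pm$gene_id
    kind <- "partial"
  }
  if (!length(ids)) return(invisible(NULL))
  context <- list(article = article, section_index = si,
                  sentence_index = sj, mention_text = m$text)
  votes <- lapply(ids, weighted_vote, context = context, kb = kb,
                  metadata = md)
  if (length(ids) == 1L) {
    win <- list(gene_id = ids[1], mention_text = m$text, vote = votes[[1]])
  } else {
    cands <- Map(function(g, v) list(gene_id = g, mention_text = m$text,
                                     vote = v), ids, votes)
    win <- select_candidate(unname(cands))
  }
  taxon <- dict$gene_taxon[[win$gene_id]] %||% NA_character_
  md$normalized[[key]] <- new_normalized(key, win$gene_id, taxon, occ,
                                         stage, win$vote, kind, m$text)
  invisible(NULL)
}

sentence_mentions <- function(sentence, dict, enabled, md, bl, tagger) {
  tg <- if (is.null(tagger)) dictionary_tagger(dict, enabled) else tagger
  m <- tag_mentions(sentence, tg)
  m <- adjust_boundaries(m, sentence, md)
  filter_blacklist(m, bl)
}

stage1_section_order <- function(article) {
  kinds <- vapply(article$sections, `[[`, "", "kind")
  intro <- which(kinds == "introduction")[1]
  if (is.na(intro)) intro <- which(!kinds %in% c("title", "abstract"))[1]
  abst <- which(kinds == "abstract")[1]
  titl <- which(kinds == "title")[1]
  idx <- c(intro, abst, titl)
  idx[!is.na(idx)]
}

#' Stage 1: normalize the information-rich sections
#'
#' Processes the Introduction, then Abstract, then Title: mention tagging,
#' boundary adjustment, blacklist filtering, dictionary matching restricted
#' to the enabled taxa, weighted-vote disambiguation and candidate
#' selection. Normalized identifiers are stored in the metadata memory so
#' that the memory-driven rules (PPI, History, Full name/Acronym) become
#' informative for the later, more concise sections.
#'
#' @param article a preprocessed `gn_article` (metadata attached).
#' @param dict a `gn_dictionary`.
#' @param kb a `gn_kb`.
#' @param cfg a `gn_strategy`.
#' @param table a `gn_species_table`.
#' @param tagger optional tagger closure; defaults to the dictionary tagger.
#' @param blacklist optional `gn_blacklist`.
#' @param scope_map enabled-taxa map from [select_entries()]; computed when
#'   missing.
#' @return the mutated `gn_metadata`, invisibly.
#' @export
run_stage1 <- function(article, dict, kb, cfg, table, tagger = NULL,
                       blacklist = NULL, scope_map = NULL) {
  md <- article$metadata
  if (is.null(md)) gn_stop("article not preprocessed: metadata missing")
  if (is.null(scope_map)) scope_map <- select_entries(article, dict, cfg, table)
  bl <- update_blacklist(blacklist %||% make_blacklist(), md)
  for (si in stage1_section_order(article)) {
    sec <- article$sections[[si]]
    enabled <- scope_taxa(scope_map, si)
    for (sj in seq_along(sec$sentences)) {
      mm <- sentence_mentions(sec$sentences[[sj]], dict, enabled, md, bl,
                              tagger)
      for (r in seq_len(nrow(mm)))
        process_mention(md, mm[r, ], si, sj, article, dict, kb, cfg,
                        enabled, stage = 1L)
    }
  }
  invisible(md)
}

#' Determine the focus species of an article
#'
#' Counts species-keyword pattern occurrences per taxon over the whole
#' article and returns the most frequent taxon. Ties prefer the taxon
#' earlier in the configured common-species order, then the smaller taxon
#' id; with no keyword at all the configured default taxon is returned with
#' a warning. Stored in the metadata when present.
#'
#' @param article a `gn_article`.
#' @param table a `gn_species_table`.
#' @param cfg a `gn_strategy` (supplies the tie order and default taxon).
#' @return a taxon id (character scalar).
#' @export
determine_focus_species <- function(article, table, cfg = strategy_config("static")) {
  counts <- count_species(article_text(article), table)
  if (!length(counts) || all(counts == 0L)) {
    warning("no species keyword found; using default taxon")
    focus <- as.character(cfg$default_taxon)
  } else {
    top <- names(counts)[counts == max(counts)]
    pos <- match(top, cfg$common_species)
    pos[is.na(pos)] <- length(cfg$common_species) + 1L
    focus <- top[order(pos, top)][1]
  }
  if (!is.null(article$metadata)) article$metadata$focus_species <- focus
  focus
}

# mini-dictionary built from the normalized memory: token phrase ->
# candidate records. Includes abbreviation partners of normalized strings.
build_minidict <- function(md) {
  index <- new.env(parent = emptyenv())
  add <- function(string, key) {
    toks <- gn_name_tokens(string)
    if (!length(toks)) return(invisible())
    first <- toks[1]
    index[[first]] <- c(index[[first]], list(list(tokens = toks, key = key)))
    invisible()
  }
  ab <- md$abbreviations
  for (key in names(md$normalized)) {
    rec <- md$normalized[[key]]
    for (s in rec$mention_texts) {
      add(s, key)
      if (!is.null(ab) && nrow(ab) > 0L) {
        partners <- c(ab$short[normalize_name(ab$long) == normalize_name(s)],
                      ab$long[normalize_name(ab$short) == normalize_name(s)])
        for (p in partners) add(p, key)
      }
    }
  }
  index
}

mini_match <- function(sentence_text, index) {
  toks <- gn_tokenize(sentence_text)
  low <- tolower(toks$token)
  nt <- nrow(toks)
  hits <- list()
  i <- 1L
  while (i <= nt) {
    cands <- index[[low[i]]]
    best_len <- 0L; best_keys <- character()
    if (!is.null(cands)) {
      for (cd in cands) {
        L <- length(cd$tokens)
        if (i + L - 1L > nt) next
        if (all(cd$tokens == low[i:(i + L - 1L)])) {
          if (L > best_len) { best_len <- L; best_keys <- cd$key }
          else if (L == best_len) best_keys <- unique(c(best_keys, cd$key))
        }
      }
    }
    if (best_len > 0L) {
      hits[[length(hits) + 1L]] <- list(
        start = toks$start[i], end = toks$end[i + best_len - 1L],
        keys = best_keys)
      i <- i + best_len
    } else i <- i + 1L
  }
  hits
}

# choose among candidate records for one surface match: in-sentence species
# keyword first, then the focus species, then smallest gene id
resolve_record <- function(keys, md, table, sentence_text) {
  recs <- md$normalized[keys]
  if (length(recs) == 1L) return(keys[1])
  taxa <- vapply(recs, `[[`, "", "taxon_id")
  detected <- detect_species(sentence_text, table)
  hit <- which(taxa %in% detected)
  if (length(hit)) recs <- recs[hit]
  else {
    fh <- which(taxa == md$focus_species)
    if (length(fh)) recs <- recs[fh]
  }
  gids <- vapply(recs, `[[`, "", "gene_id")
  names(recs)[order(gids)][1]
}

#' Stage 2: propagate the normalized memory over the whole article
#'
#' Builds a mini-dictionary from the mention strings normalized in stage 1
#' (plus their abbreviation partners) and scans every sentence. The Title,
#' Abstract and Introduction are rechecked, adding missed occurrences only.
#' Outside those sections, a species keyword in the same sentence that
#' matches a candidate identifier's taxon decides; otherwise the
#' focus-species candidate is assigned. The mini-dictionary is exempt from
#' species filtering: its identifiers were already disambiguated.
#'
#' @param article a `gn_article` with metadata.
#' @param metadata the article's `gn_metadata` (defaults to
#'   `article$metadata`).
#' @param kb a `gn_kb` (interface symmetry; the memory drives this stage).
#' @param table a `gn_species_table`.
#' @return the mutated metadata, invisibly.
#' @export
run_stage2 <- function(article, metadata = article$metadata, kb = NULL,
                       table) {
  md <- metadata
  if (is.null(md$focus_species) || is.na(md$focus_species)) {
    # focus species is normally set between stages 1 and 2
    md$focus_species <- NA_character_
  }
  index <- build_minidict(md)
  stage1_idx <- stage1_section_order(article)
  for (si in seq_along(article$sections)) {
    sec <- article$sections[[si]]
    for (sj in seq_along(sec$sentences)) {
      sen <- sec$sentences[[sj]]
      for (h in mini_match(sen$text, index)) {
        key <- if (si %in% stage1_idx && length(h$keys) == 1L) h$keys[1]
               else resolve_record(h$keys, md, table, sen$text)
        m <- list(text = substr(sen$text, h$start + 1L, h$end),
                  start = h$start, end = h$end, source = "dictionary")
        append_occurrence(md, key, occ_row(si, sj, m))
      }
    }
  }
  invisible(md)
}

#' Stage 3: recognize and normalize the remaining sections
#'
#' Runs mention recognition plus normalization over every section outside
#' Title/Abstract/Introduction (results, captions, appendix, ...). Where a
#' tagger mention and a stage-2 mini-dictionary match overlap with different
#' identifiers or boundaries, [select_candidate()] resolves the winner.
#'
#' @inheritParams run_stage1
#' @param table a `gn_species_table`.
#' @return the mutated metadata, invisibly.
#' @export
run_stage3 <- function(article, dict, kb, cfg, table, tagger = NULL,
                       blacklist = NULL, scope_map = NULL) {
  md <- article$metadata
  if (is.null(scope_map)) scope_map <- select_entries(article, dict, cfg, table)
  bl <- update_blacklist(blacklist %||% make_blacklist(), md)
  index <- build_minidict(md)
  done <- stage1_section_order(article)
  for (si in setdiff(seq_along(article$sections), done)) {
    sec <- article$sections[[si]]
    if (sec$kind %in% TAI_KINDS) next
    enabled <- scope_taxa(scope_map, si)
    for (sj in seq_along(sec$sentences)) {
      sen <- sec$sentences[[sj]]
      mm <- sentence_mentions(sen, dict, enabled, md, bl, tagger)
      hits <- mini_match(sen$text, index)
      used_hits <- logical(length(hits))
      for (r in seq_len(nrow(mm))) {
        m <- mm[r, ]
        ov <- which(!used_hits &
                      vapply(hits, function(h)
                        h$start < m$end && m$start < h$end, logical(1)))
        if (!length(ov)) {
          process_mention(md, m, si, sj, article, dict, kb, cfg, enabled,
                          stage = 3L)
          next
        }
        used_hits[ov] <- TRUE
        # disagreement: pit tagger candidates against memory candidates
        context <- list(article = article, section_index = si,
                        sentence_index = sj, mention_text = m$text)
        ids <- exact_match(m$text, dict, enabled)
        if (!length(ids)) {
          pm <- partial_match(m$text, dict, enabled, cfg$partial_top_n)
          ids <- pm$gene_id
        }
        cands <- lapply(ids, function(g)
          list(gene_id = g, mention_text = m$text, source = "tagger",
               vote = weighted_vote(g, context, kb, md)))
        for (oi in ov) {
          h <- hits[[oi]]
          htxt <- substr(sen$text, h$start + 1L, h$end)
          hctx <- context; hctx$mention_text <- htxt
          for (key in h$keys) {
            rec <- md$normalized[[key]]
            cands <- c(cands, list(list(
              gene_id = rec$gene_id, mention_text = htxt, key = key,
              source = "dictionary",
              vote = weighted_vote(rec$gene_id, hctx, kb, md))))
          }
        }
        if (!length(cands)) next
        win <- select_candidate(cands)
        wkey <- win$key %||% normalize_name(win$mention_text)
        wocc <- occ_row(si, sj, list(text = win$mention_text,
                                     start = m$start, end = m$end,
                                     source = win$source))
        if (!is.null(md$normalized[[wkey]])) {
          append_occurrence(md, wkey, wocc, win$mention_text)
        } else {
          taxon <- dict$gene_taxon[[win$gene_id]] %||% NA_character_
          md$normalized[[wkey]] <- new_normalized(
            wkey, win$gene_id, taxon, wocc, 3L, win$vote, "exact",
            win$mention_text)
        }
      }
      # memory matches not overlapped by any tagger mention
      for (oi in which(!used_hits)) {
        h <- hits[[oi]]
        key <- resolve_record(h$keys, md, table, sen$text)
        m <- list(text = substr(sen$text, h$start + 1L, h$end),
                  start = h$start, end = h$end, source = "dictionary")
        append_occurrence(md, key, occ_row(si, sj, m))
      }
    }
  }
  invisible(md)
}

#' Preprocess an article: metadata, full-text cache, range report
#'
#' @param article a `gn_article`.
#' @param range_cap maximum range-expansion length.
#' @return the article with `metadata` (a `gn_metadata`) and cached full
#'   text attached.
#' @export
preprocess_article <- function(article, range_cap = 100L) {
  article$full_text <- paste(vapply(article$sections, `[[`, "", "text"),
                             collapse = "\n")
  article$metadata <- init_metadata(article)
  ranges <- list()
  for (sec in article$sections)
    for (sen in sec$sentences)
      ranges <- c(ranges, expand_ranges(sen$text, cap = range_cap))
  article$metadata$ranges <- ranges
  article
}

#' Normalize an article end to end
#'
#' Full workflow: preprocessing, dictionary-entry selection, three GN
#' stages, and identifier ranking. Output is sorted by confidence
#' descending (gene id ascending on ties) and is deterministic given a
#' fixed ranker.
#'
#' @param article a `gn_article` (preprocessed or not).
#' @param dict a `gn_dictionary`.
#' @param kb a `gn_kb`.
#' @param cfg a `gn_strategy`.
#' @param table a `gn_species_table`.
#' @param tagger optional tagger closure.
#' @param ranker optional `gn_ranker` model; defaults to the shipped model.
#' @param blacklist optional `gn_blacklist`.
#' @return data.frame(gene_id, confidence), ranked; the article metadata is
#'   attached as attribute `"metadata"`.
#' @export
normalize_article <- function(article, dict, kb, cfg, table, tagger = NULL,
                              ranker = NULL, blacklist = NULL) {
  if (is.null(article$metadata)) article <- preprocess_article(article,
                                                              cfg$range_cap)
  md <- article$metadata
  scope_map <- select_entries(article, dict, cfg, table)
  run_stage1(article, dict, kb, cfg, table, tagger, blacklist, scope_map)
  determine_focus_species(article, table, cfg)
  run_stage2(article, md, kb, table)
  run_stage3(article, dict, kb, cfg, table, tagger, blacklist, scope_map)
  ngs <- group_normalized(md)
  if (!length(ngs)) {
    out <- data.frame(gene_id = character(), confidence = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "metadata") <- md
    return(out)
  }
  if (is.null(ranker)) ranker <- default_ranker()
  out <- rank_article(ranker, ngs, article, md)
  attr(out, "metadata") <- md
  out
}

# merge normalized records by gene id for ranking
group_normalized <- function(md) {
  recs <- md$normalized
  if (!length(recs)) return(list())
  gids <- sort(unique(vapply(recs, `[[`, "", "gene_id")))
  lapply(setNames(gids, gids), function(g) {
    sub <- recs[vapply(recs, function(r) r$gene_id == g, logical(1))]
    mentions <- do.call(rbind, lapply(sub, `[[`, "mentions"))
    row.names(mentions) <- NULL
    votes <- lapply(sub, `[[`, "vote")
    votes <- votes[!vapply(votes, is.null, logical(1))]
    best <- if (length(votes))
      votes[[which.max(vapply(votes, `[[`, 0, "total"))]] else NULL
    list(gene_id = g, taxon_id = sub[[1]]$taxon_id,
         mention_texts = unique(unlist(lapply(sub, `[[`, "mention_texts"))),
         mentions = mentions,
         stage = min(vapply(sub, `[[`, 0L, "stage")),
         vote = best,
         match_kind = if (any(vapply(sub, `[[`, "", "match_kind") == "exact"))
           "exact" else "partial")
  })
}
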