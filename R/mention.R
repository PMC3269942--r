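# Gene-mention recognition: a pluggable tagger contract with a
# dictionary-driven default, boundary-adjustment post-processing against the
# metadata memory, and blacklist filtering with per-article synonym updates.

empty_mentions <- function() {
  data.frame(text = character(), start = integer(), end = integer(),
             source = character(), original_text = character(),
             stringsAsFactors = FALSE)
}

#' Default dictionary-based gene-mention tagger
#'
#' Longest-match tagging over the variants of all dictionary entries whose
#' taxon is enabled. Matching is token-based and case-insensitive, so
#' hyphen/space variation is absorbed by tokenization. Returns a tagger
#' closure satisfying the tagger contract: sentence text in, non-overlapping
#' 0-based half-open spans out.
#'
#' @param dict a `gn_dictionary`.
#' @param enabled character vector of enabled taxon ids.
#' @return function(sentence_text) -> data.frame(start, end).
#' @export
dictionary_tagger <- function(dict, enabled) {
  force(dict); force(enabled)
  function(sentence_text) {
    toks <- gn_tokenize(sentence_text)
    out_start <- integer(); out_end <- integer()
    nt <- nrow(toks)
    low <- tolower(toks$token)
    i <- 1L
    while (i <= nt) {
      cands <- dict$phrase_index[[low[i]]]
      best_len <- 0L
      if (!is.null(cands)) {
        for (cd in cands) {
          L <- length(cd$tokens)
          if (L <= best_len || i + L - 1L > nt) next
          if (!cd$taxon_id %in% enabled) next
          if (all(cd$tokens == low[i:(i + L - 1L)])) best_len <- L
        }
      }
      if (best_len > 0L) {
        out_start <- c(out_start, toks$start[i])
        out_end <- c(out_end, toks$end[i + best_len - 1L])
        i <- i + best_len
      } else {
        i <- i + 1L
      }
    }
    data.frame(start = out_start, end = out_end)
  }
}

#' Tag gene mentions in a sentence
#'
#' Applies a tagger satisfying the contract and validates its output:
#' non-overlapping spans, each within the sentence. Mentions are returned
#' ordered by start offset with `source = "tagger"` (the default dictionary
#' tagger is itself span-producing, so its mentions carry the same source).
#'
#' @param sentence a `gn_sentence`.
#' @param tagger function(sentence_text) -> data.frame(start, end), 0-based
#'   half-open spans.
#' @return mention data.frame (`text`, `start`, `end`, `source`,
#'   `original_text`).
#' @export
tag_mentions <- function(sentence, tagger) {
  spans <- tagger(sentence$text)
  if (is.null(spans) || nrow(spans) == 0L) return(empty_mentions())
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$end <= spans$start) ||
      any(spans$start < 0) || any(spans$end > nchar(sentence$text)))
    gn_stop("tagger contract violation: span outside sentence")
  if (nrow(spans) > 1L &&
      any(spans$start[-1L] < spans$end[-nrow(spans)]))
    gn_stop("tagger contract violation: overlapping spans")
  data.frame(text = substring(sentence$text, spans$start + 1L, spans$end),
             start = as.integer(spans$start), end = as.integer(spans$end),
             source = "tagger", original_text = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

# longest stored string (metadata full names / abbreviations / keywords)
# that contains `needle` and occurs in `haystack` overlapping [s, e)
find_covering_store <- function(needle, s, e, haystack, stores) {
  best <- NULL
  hay_low <- tolower(haystack)
  for (st in stores) {
    if (nchar(st) <= nchar(needle)) next
    if (!grepl(tolower(needle), tolower(st), fixed = TRUE)) next
    m <- gregexpr(tolower(st), hay_low, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (pos in m) {
      st0 <- pos - 1L; en0 <- st0 + nchar(st)
      if (st0 <= s && en0 >= e) {
        if (is.null(best) || nchar(st) > (best$end - best$start))
          best <- list(start = st0, end = en0)
      }
    }
  }
  best
}

#' Adjust gene-mention boundaries against the metadata memory
#'
#' Two post-processing rules: (i) a mention whose text is a proper substring
#' of a stored full name, abbreviation or author keyword that occurs in the
#' same sentence is extended to the full stored string, keeping the
#' pre-adjustment text in `original_text` (and in
#' `metadata$original_strings`); (ii) a parenthesized phrase (at most 5
#' tokens, no sentence punctuation) immediately following a mention becomes
#' an additional mention with `source = "parenthetical"`. Spans never
#' shrink and never overlap on output.
#'
#' @param mentions mention data.frame from [tag_mentions()].
#' @param sentence the `gn_sentence` the mentions came from.
#' @param metadata a `gn_metadata` environment.
#' @return adjusted mention data.frame.
#' @export
adjust_boundaries <- function(mentions, sentence, metadata) {
  if (nrow(mentions) == 0L) return(mentions)
  stores <- unique(c(metadata$abbreviations$long,
                     metadata$abbreviations$short,
                     metadata$keywords))
  stores <- stores[nzchar(stores)]
  txt <- sentence$text
  extra <- empty_mentions()
  for (r in seq_len(nrow(mentions))) {
    hit <- find_covering_store(mentions$text[r], mentions$start[r],
                               mentions$end[r], txt, stores)
    if (!is.null(hit)) {
      old <- mentions$text[r]
      mentions$start[r] <- hit$start
      mentions$end[r] <- hit$end
      mentions$text[r] <- substr(txt, hit$start + 1L, hit$end)
      if (mentions$text[r] != old) {
        mentions$original_text[r] <- old
        metadata$original_strings[[mentions$text[r]]] <- old
      }
    }
    # parenthetical capture
    after <- substr(txt, mentions$end[r] + 1L, nchar(txt))
    pm <- regmatches(after, regexec("^\\s*\\(([^()]+)\\)", after))[[1]]
    if (length(pm) == 2L) {
      inner <- pm[2]
      if (!grepl("[.;!?]", inner) &&
          length(strsplit(trimws(inner), "[[:space:]]+")[[1]]) <= 5L &&
          grepl("[[:alpha:]]", inner)) {
        open_at <- mentions$end[r] + regexpr("(", after, fixed = TRUE)
        s0 <- open_at  # 0-based start of inner text
        extra <- rbind(extra, data.frame(
          text = inner, start = as.integer(s0),
          end = as.integer(s0 + nchar(inner)),
          source = "parenthetical", original_text = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  all_m <- rbind(mentions, extra)
  all_m <- all_m[order(all_m$start, -(all_m$end - all_m$start)), , drop = FALSE]
  # drop spans overlapping an earlier (or containing) span
  keep <- logical(nrow(all_m)); last_end <- -1L
  for (r in seq_len(nrow(all_m))) {
    if (all_m$start[r] >= last_end) {
      keep[r] <- TRUE
      last_end <- all_m$end[r]
    }
  }
  out <- all_m[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Construct a blacklist
#'
#' @param terms character vector of terms (normalized on storage).
#' @return object of class `gn_blacklist`.
#' @export
make_blacklist <- function(terms = character()) {
  structure(list(terms = unique(normalize_name(terms[nzchar(terms)])),
                 dynamic_additions = character()),
            class = "gn_blacklist")
}

#' Load a blacklist file
#'
#' One term per line, UTF-8, `#` starts a comment.
#'
#' @param path file path.
#' @return a `gn_blacklist`.
#' @export
load_blacklist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  make_blacklist(lines[nzchar(lines)])
}

#' Filter mentions against the blacklist
#'
#' Removes mentions whose normalized text is in the static terms or the
#' per-article dynamic additions; order is preserved. Idempotent.
#'
#' @param mentions mention data.frame.
#' @param bl a `gn_blacklist`.
#' @return filtered mention data.frame.
#' @export
filter_blacklist <- function(mentions, bl) {
  if (nrow(mentions) == 0L) return(mentions)
  bad <- normalize_name(mentions$text) %in%
    c(bl$terms, bl$dynamic_additions)
  out <- mentions[!bad, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Propagate blacklisting across abbreviation pairs
#'
#' For each full-name/abbreviation pair in the metadata where one side is
#' blacklisted, the other side joins the per-article dynamic additions.
#'
#' @param bl a `gn_blacklist`.
#' @param metadata a `gn_metadata`.
#' @return updated `gn_blacklist`.
#' @export
update_blacklist <- function(bl, metadata) {
  ab <- metadata$abbreviations
  if (is.null(ab) || nrow(ab) == 0L) return(bl)
  lookup <- c(bl$terms, bl$dynamic_additions)
  for (r in seq_len(nrow(ab))) {
    nl <- normalize_name(ab$long[r]); ns <- normalize_name(ab$short[r])
    if (nl %in% lookup && !ns %in% lookup)
      bl$dynamic_additions <- unique(c(bl$dynamic_additions, ns))
    if (ns %in% lookup && !nl %in% lookup)
      bl$dynamic_additions <- unique(c(bl$dynamic_additions, nl))
  }
  bl
}
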