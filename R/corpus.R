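# Article data model, JSON I/O, sentence segmentation, and the
# preprocessing that populates the per-article metadata memory.

SECTION_KINDS <- c("title", "abstract", "introduction", "results",
                   "conclusion", "other", "figure_caption", "table_caption",
                   "appendix", "section_title")

# headings are matched case-insensitively on the whole heading string
DEFAULT_HEADING_MAP <- c(
  "title"        = "title",
  "abstract"     = "abstract",
  "introduction" = "introduction",
  "background"   = "introduction",
  "results"      = "results",
  "results and discussion" = "results",
  "discussion"   = "other",
  "methods"      = "other",
  "materials and methods" = "other",
  "conclusion"   = "conclusion",
  "conclusions"  = "conclusion",
  "appendix"     = "appendix"
)

new_sentence <- function(text, index, start, end) {
  structure(list(text = text, index = as.integer(index),
                 start = as.integer(start), end = as.integer(end)),
            class = "gn_sentence")
}

new_section <- function(kind, heading, text, sentences = NULL) {
  if (!kind %in% SECTION_KINDS)
    gn_stop("unknown section kind '%s'", kind)
  if (is.null(sentences)) sentences <- split_sentences(text)
  structure(list(kind = kind, heading = heading, text = text,
                 sentences = sentences),
            class = "gn_section")
}

#' Construct an article in code
#'
#' Programmatic counterpart of [read_article()], used by the fixture
#' generator and tests. Each element of `sections` is a list with `kind`,
#' `heading` and `text`; sentences are segmented on construction.
#'
#' @param article_id opaque identifier string.
#' @param sections list of lists with fields `kind`, `heading`, `text`.
#' @param keywords character vector of author keywords.
#' @return object of class `gn_article`.
#' @export
make_article <- function(article_id, sections, keywords = character()) {
  secs <- lapply(sections, function(s) {
    new_section(s$kind %||% map_heading_kind(s$heading %||% ""),
                s$heading %||% "", s$text %||% "")
  })
  validate_sections(secs)
  structure(list(article_id = article_id,
                 keywords = as.character(keywords),
                 sections = secs,
                 metadata = NULL),
            class = "gn_article")
}

validate_sections <- function(secs) {
  kinds <- vapply(secs, `[[`, "", "kind")
  if (sum(kinds == "title") > 1L)
    gn_stop("validation error: more than one 'title' section")
  if (sum(kinds == "abstract") > 1L)
    gn_stop("validation error: more than one 'abstract' section")
  invisible(TRUE)
}

map_heading_kind <- function(heading, map = DEFAULT_HEADING_MAP) {
  key <- tolower(trimws(heading))
  if (nzchar(key) && key %in% names(map)) unname(map[[key]]) else "other"
}

#' Read a canonical-JSON full-text article
#'
#' The canonical schema is
#' `{article_id, keywords: [...], sections: [{kind, heading, text}]}`.
#' `kind` may be omitted per section, in which case the heading is mapped
#' through a configurable table; unknown headings map to `other`. When no
#' section carries an explicit or mappable kind, the first body section
#' (not title/abstract) defaults to `introduction` and the last to
#' `conclusion`.
#'
#' @param path path to a JSON file.
#' @param format only `"json"` is supported.
#' @return object of class `gn_article`.
#' @export
read_article <- function(path, format = "json") {
  format <- match.arg(format, "json")
  if (!file.exists(path)) gn_stop("file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) gn_stop("parse error: %s", conditionMessage(e)))
  if (is.null(doc$article_id))
    gn_stop("parse error: missing field 'article_id'")
  if (is.null(doc$sections))
    gn_stop("parse error: missing field 'sections'")
  secs <- lapply(doc$sections, function(s) {
    if (is.null(s$text)) gn_stop("parse error: section missing field 'text'")
    kind <- s$kind %||% map_heading_kind(s$heading %||% "")
    if (!kind %in% SECTION_KINDS)
      gn_stop("parse error: unknown section kind '%s'", kind)
    new_section(kind, s$heading %||% "", s$text)
  })
  # unheaded body-section defaults: first -> introduction, last -> conclusion
  kinds <- vapply(secs, `[[`, "", "kind")
  body <- which(!kinds %in% c("title", "abstract"))
  explicit <- vapply(doc$sections, function(s) !is.null(s$kind) ||
                       nzchar(trimws(s$heading %||% "")), logical(1))
  if (length(body) && !any(kinds == "introduction")) {
    i <- body[1]
    if (!explicit[i]) secs[[i]]$kind <- "introduction"
  }
  if (length(body) > 1L && !any(vapply(secs, `[[`, "", "kind") == "conclusion")) {
    i <- body[length(body)]
    if (!explicit[i]) secs[[i]]$kind <- "conclusion"
  }
  validate_sections(secs)
  structure(list(article_id = doc$article_id,
                 keywords = as.character(unlist(doc$keywords)),
                 sections = secs,
                 metadata = NULL),
            class = "gn_article")
}

#' Write an article back to canonical JSON
#'
#' Inverse of [read_article()]: writing a round-tripped canonical file is
#' byte-identical.
#'
#' @param article a `gn_article`.
#' @param path output path.
#' @export
write_article <- function(article, path) {
  doc <- list(
    article_id = jsonlite::unbox(article$article_id),
    keywords = as.list(article$keywords),
    sections = lapply(article$sections, function(s)
      list(kind = jsonlite::unbox(s$kind),
           heading = jsonlite::unbox(s$heading),
           text = jsonlite::unbox(s$text)))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = FALSE, pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# tokens that protect a following period from ending a sentence
PROTECTED_ABBREVS <- c("fig", "figs", "eq", "eqs", "al", "e.g", "i.e", "vs",
                       "cf", "ca", "etc", "no", "dr", "st", "sp", "spp",
                       "approx", "ref", "refs")

#' Split section text into sentences
#'
#' Splits at sentence-final `.?!` followed by whitespace and an upper-case
#' letter, digit or opening bracket; protected tokens such as "Fig." and
#' "et al." do not split. Returned spans are 0-based half-open offsets into
#' the section text and cover all non-whitespace characters.
#'
#' @param section_text character scalar.
#' @return list of `gn_sentence`.
#' @export
split_sentences <- function(section_text) {
  if (is.null(section_text) || is.na(section_text) || !nzchar(trimws(section_text)))
    return(list())
  txt <- section_text
  n <- nchar(txt)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  boundaries <- integer()  # positions (1-based) of last char of a sentence
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "?", "!")) {
      # lookahead: end of text, or whitespace then sentence-initial char
      j <- i + 1L
      while (j <= n && chars[j] %in% c(".", "?", "!", "\"", ")")) j <- j + 1L
      k <- j
      while (k <= n && grepl("^[[:space:]]$", chars[k])) k <- k + 1L
      starts_new <- k > n || (k > j && grepl("^[[:upper:][:digit:](\"“]$", chars[k]))
      if (starts_new && ch == ".") {
        # preceding word must not be a protected abbreviation or initial
        prev <- sub(".*?([A-Za-z.]+)$", "\\1", substr(txt, max(1L, i - 12L), i - 1L))
        w <- tolower(sub("\\.$", "", prev))
        if (w %in% PROTECTED_ABBREVS || w == "et")
          starts_new <- FALSE
      }
      if (starts_new) {
        boundaries <- c(boundaries, j - 1L)
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  if (length(boundaries) == 0L || boundaries[length(boundaries)] < n)
    boundaries <- c(boundaries, n)
  out <- list()
  begin <- 1L
  for (b in boundaries) {
    piece <- substr(txt, begin, b)
    lead <- nchar(piece) - nchar(sub("^[[:space:]]+", "", piece))
    trail <- nchar(piece) - nchar(sub("[[:space:]]+$", "", piece))
    s0 <- begin + lead
    e0 <- b - trail
    if (e0 >= s0) {
      out[[length(out) + 1L]] <- new_sentence(substr(txt, s0, e0),
                                             length(out), s0 - 1L, e0)
    }
    begin <- b + 1L
  }
  out
}

#' Expand collapsed gene-name ranges
#'
#' Detects `PREFIX<lo>-PREFIX<hi>` (same prefix) and `PREFIX<lo>-<hi>`
#' patterns with ascending integers and enumerates the individual names,
#' e.g. "SOCS1-SOCS7" or "VDAC1-3". Ranges longer than `cap` components and
#' descending ranges are left unexpanded.
#'
#' @param sentence_text character scalar.
#' @param cap maximum number of components to enumerate (default 100).
#' @return list of `list(text, start, end, names)`; offsets 0-based half-open.
#' @export
expand_ranges <- function(sentence_text, cap = 100L) {
  if (is.null(sentence_text) || !nzchar(sentence_text)) return(list())
  out <- list()
  taken <- logical(nchar(sentence_text))
  scan <- function(pattern, hi_from_prefix) {
    m <- gregexpr(pattern, sentence_text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(invisible())
    len <- attr(m, "match.length")
    for (q in seq_along(m)) {
      s <- m[q]; e <- m[q] + len[q] - 1L
      if (any(taken[s:e])) next
      frag <- substr(sentence_text, s, e)
      g <- regmatches(frag, regexec(pattern, frag, perl = TRUE))[[1]]
      prefix <- g[2]
      lo <- as.integer(g[3])
      hi <- as.integer(g[length(g)])
      if (is.na(lo) || is.na(hi) || hi <= lo) next
      if (hi - lo + 1L > cap) next
      out[[length(out) + 1L]] <<- list(
        text = frag, start = s - 1L, end = e,
        names = paste0(prefix, lo:hi))
      taken[s:e] <<- TRUE
    }
    invisible()
  }
  # same-prefix form first (SOCS1-SOCS7), then bare-number form (VDAC1-3)
  scan("\\b([A-Za-z][A-Za-z]*)([0-9]+)[-–]\\1([0-9]+)\\b", TRUE)
  scan("\\b([A-Za-z][A-Za-z]*)([0-9]+)[-–]([0-9]+)\\b(?![-–]?[A-Za-z0-9])", FALSE)
  out[order(vapply(out, `[[`, 0L, "start"))]
}

# ---- Schwartz-Hearst abbreviation extraction -------------------------------

sh_valid_short_form <- function(sf) {
  nc <- nchar(sf)
  nc >= 2L && nc <= 10L &&
    length(strsplit(trimws(sf), "[[:space:]]+")[[1]]) <= 2L &&
    grepl("[[:alpha:]]", sf) &&
    grepl("^[[:alnum:]]", sf)
}

# right-to-left character matching; the first short-form character must match
# at the start of a word in the long form. Returns the long form or NULL.
sh_find_long_form <- function(long, sf) {
  si <- nchar(sf); li <- nchar(long)
  while (si >= 1L) {
    cch <- tolower(substr(sf, si, si))
    if (!grepl("[[:alnum:]]", cch)) { si <- si - 1L; next }
    repeat {
      if (li < 1L) return(NULL)
      lch <- tolower(substr(long, li, li))
      word_start <- li == 1L || !grepl("[[:alnum:]]", substr(long, li - 1L, li - 1L))
      if (lch == cch && (si > 1L || word_start)) break
      li <- li - 1L
    }
    si <- si - 1L; li <- li - 1L
  }
  lf <- substr(long, li + 1L, nchar(long))
  lf <- trimws(lf)
  if (!nzchar(lf)) return(NULL)
  lf
}

sh_pairs_in_text <- function(text) {
  pairs <- list()
  m <- gregexpr("\\(([^()]{1,60})\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(pairs)
  len <- attr(m, "match.length")
  for (q in seq_along(m)) {
    sf <- substr(text, m[q] + 1L, m[q] + len[q] - 2L)
    sf <- trimws(sf)
    if (!sh_valid_short_form(sf)) next
    before <- trimws(substr(text, 1L, m[q] - 1L))
    if (!nzchar(before)) next
    words <- strsplit(before, "[[:space:]]+")[[1]]
    max_words <- min(nchar(sf) + 5L, nchar(sf) * 2L)
    cand <- paste(utils::tail(words, max_words), collapse = " ")
    lf <- sh_find_long_form(cand, sf)
    if (is.null(lf)) next
    if (nchar(lf) <= nchar(sf)) next
    if (tolower(lf) == tolower(sf)) next
    if (grepl(tolower(sf), tolower(lf), fixed = TRUE) &&
        length(strsplit(lf, "[[:space:]]+")[[1]]) == 1L) next
    pairs[[length(pairs) + 1L]] <- c(long = lf, short = sf)
  }
  pairs
}

#' Extract full-name/abbreviation pairs (Schwartz-Hearst)
#'
#' Scans every sentence for parenthesized candidate short forms and pairs
#' them with a preceding long form by right-to-left character matching: every
#' short-form character must appear in the long form in order, and the first
#' must match the start of a long-form word.
#'
#' @param article a `gn_article`.
#' @return data.frame with columns `long` and `short`, unique pairs.
#' @export
extract_abbreviations <- function(article) {
  acc <- list()
  for (sec in article$sections) {
    for (sen in sec$sentences) {
      acc <- c(acc, sh_pairs_in_text(sen$text))
    }
  }
  if (!length(acc)) {
    return(data.frame(long = character(), short = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(long = vapply(acc, `[[`, "", "long"),
                   short = vapply(acc, `[[`, "", "short"),
                   stringsAsFactors = FALSE)
  unique(df)
}

#' Initialize the per-article metadata memory
#'
#' Populates abbreviation pairs (Schwartz-Hearst), copies author keywords,
#' and creates the empty normalized-ID memory shared across pipeline stages.
#' The metadata is an environment: stages mutate it in place.
#'
#' @param article a `gn_article`.
#' @return environment of class `gn_metadata`, also attached to the article
#'   when the caller reassigns the returned article (see [normalize_article()]).
#' @export
init_metadata <- function(article) {
  md <- new.env(parent = emptyenv())
  ab <- extract_abbreviations(article)
  md$abbreviations <- ab
  md$keywords <- article$keywords
  md$normalized <- list()        # normalize_name(mention) -> gn_normalized
  md$original_strings <- list()  # adjusted mention -> pre-adjustment string
  md$focus_species <- NA_character_
  md$blacklist_additions <- character()
  class(md) <- c("gn_metadata", "environment")
  md
}
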