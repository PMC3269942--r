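#' @keywords internal
"_PACKAGE"

#' Tokenize text into alphanumeric tokens with character offsets
#'
#' Tokens are maximal runs of letters and digits (Unicode aware, so Greek
#' symbols count as letters). Offsets are 0-based, half-open.
#'
#' @param text character scalar.
#' @return data.frame with columns `token`, `start`, `end`.
#' @keywords internal
gn_tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L),
             end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

#' Canonical name normalization used for dictionary lookup
#'
#' Case-folds and strips hyphens and whitespace so that all members of the
#' hyphen/space/deletion variant family collapse onto one key.
#'
#' @param x character vector.
#' @return character vector of normalized keys.
#' @export
normalize_name <- function(x) {
  gsub("[-‐-―[:space:]]+", "", tolower(x))
}

# lowercased token sequence of a name, used by the tagger and partial matcher
gn_name_tokens <- function(x) {
  tolower(gn_tokenize(x)$token)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gn_stop <- function(...) stop(sprintf(...), call. = FALSE)
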