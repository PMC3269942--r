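# Threshold Average Precision at a median of k errors per query (TAP-k):
# per-query TAP with the sentinel-precision term, the E_k(A) threshold
# search, query averaging, and printed-table improvement arithmetic.

#' Construct a query result
#'
#' @param query_id article identifier.
#' @param gold character vector of correct gene ids (R >= 1).
#' @param gene_id retrieved gene ids, in list order.
#' @param e_value reliability scores, non-decreasing down the list (lower =
#'   more reliable). Mutually exclusive with `confidence`.
#' @param confidence system confidences in (0, 1]; adapted to e-values via
#'   `e_value = 1 - confidence` (order-reversing, monotone).
#' @return object of class `gn_query`.
#' @export
query_result <- function(query_id, gold, gene_id, e_value = NULL,
                         confidence = NULL) {
  if (!length(gold)) gn_stop("undefined-query error: empty gold set")
  if (is.null(e_value)) {
    if (is.null(confidence))
      gn_stop("one of e_value or confidence is required")
    e_value <- 1 - confidence
  }
  if (length(gene_id) != length(e_value))
    gn_stop("gene_id and e_value lengths differ")
  if (anyDuplicated(gene_id))
    gn_stop("retrieved ids must be unique per query")
  if (is.unsorted(e_value))
    gn_stop("e_values must be non-decreasing down the list")
  structure(list(query_id = query_id, gold = unique(as.character(gold)),
                 gene_id = as.character(gene_id),
                 e_value = as.numeric(e_value)),
            class = "gn_query")
}

#' Per-query threshold average precision
#'
#' TAP(E0) = (sum of precisions at each correct id with e-value <= E0, plus
#' the sentinel precision p(E0)) / (R + 1), where the sentinel is the last
#' id with e-value <= E0 and p(E0) is the fraction of ids up to and
#' including the sentinel that are correct. Terminal pre-threshold incorrect
#' ids (TPIIs) therefore depress the score. Returns 0 when nothing is at or
#' below the threshold; a perfect list scores 1.
#'
#' @param q a `gn_query`.
#' @param E0 e-value threshold.
#' @return number in \[0, 1\].
#' @export
query_tap <- function(q, E0) {
  R <- length(q$gold)
  if (R == 0L) gn_stop("undefined-query error: R = 0")
  within <- which(q$e_value <= E0)
  if (!length(within)) return(0)
  sentinel <- max(within)
  correct <- q$gene_id %in% q$gold
  prec <- cumsum(correct) / seq_along(correct)
  correct_within <- which(correct & seq_along(correct) <= sentinel)
  (sum(prec[correct_within]) + prec[sentinel]) / (R + 1)
}

#' Smallest e-value threshold reaching a median of k errors per query
#'
#' Scans the sorted union of retrieved e-values and returns the smallest
#' candidate threshold at which the median (lower median for even counts,
#' i.e. the order statistic at ceiling(n/2)) over queries of the number of
#' incorrect ids at or below the threshold reaches at least `k`. If the
#' median never reaches `k`, the maximum e-value is returned. For any
#' strictly larger threshold, at least 50% of the queries have at least k
#' errors.
#'
#' @param queries non-empty list of `gn_query`.
#' @param k tolerated errors per query, k >= 1.
#' @return the threshold E_k(A).
#' @export
find_threshold_Ek <- function(queries, k) {
  if (!length(queries)) gn_stop("argument error: no queries")
  if (k < 1L) gn_stop("argument error: k must be >= 1")
  evs <- sort(unique(unlist(lapply(queries, `[[`, "e_value"))))
  if (!length(evs)) gn_stop("argument error: no retrieved ids")
  n <- length(queries)
  med_pos <- ceiling(n / 2)
  for (E0 in evs) {
    errs <- vapply(queries, function(q)
      sum(q$e_value <= E0 & !(q$gene_id %in% q$gold)), 0L)
    if (sort(errs)[med_pos] >= k) return(E0)
  }
  evs[length(evs)]
}

#' Query-averaged TAP-k
#'
#' @param queries list of `gn_query`.
#' @param k tolerated errors per query.
#' @return object of class `gn_tap_result`: per-query TAP values, the
#'   threshold E_k, k, and the arithmetic mean TAP.
#' @export
mean_tapk <- function(queries, k) {
  E0 <- find_threshold_Ek(queries, k)
  per <- vapply(queries, query_tap, 0, E0 = E0)
  names(per) <- vapply(queries, `[[`, "", "query_id")
  structure(list(per_query_tap = per, threshold_Ek = E0, k = as.integer(k),
                 mean_tap = mean(per)),
            class = "gn_tap_result")
}

#' Improvement arithmetic for printed comparison tables
#'
#' @param baseline baseline score (> 0).
#' @param system system score.
#' @return list(delta, relative_pct): the absolute difference and the
#'   relative improvement in percent, reported to 2 decimals.
#' @export
improvement_report <- function(baseline, system) {
  if (!is.numeric(baseline) || baseline <= 0)
    gn_stop("argument error: baseline must be > 0")
  delta <- system - baseline
  list(delta = delta, relative_pct = round(100 * delta / baseline, 2))
}

#' Read a gold-standard TSV (article_id, gene_id)
#'
#' @param path TSV file, no header requirement beyond the two columns.
#' @return data.frame(article_id, gene_id).
#' @export
read_gold <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("article_id", "gene_id") %in% names(df)))
    gn_stop("schema error: gold file needs article_id and gene_id columns")
  df[c("article_id", "gene_id")]
}

#' Read a ranked-prediction TSV
#'
#' Columns `article_id`, `gene_id`, `rank`, and `confidence` (default) or
#' `e_value` (with `evalue = TRUE`).
#'
#' @param path TSV file.
#' @param evalue interpret the score column as an e-value instead of a
#'   confidence.
#' @return data.frame(article_id, gene_id, rank, e_value).
#' @export
read_ranked <- function(path, evalue = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$rank <- as.integer(df$rank)
  if (evalue) {
    df$e_value <- as.numeric(df$e_value)
  } else {
    df$e_value <- 1 - as.numeric(df$confidence)
  }
  df <- df[order(df$article_id, df$rank), ]
  df[c("article_id", "gene_id", "rank", "e_value")]
}

#' Assemble queries from gold and prediction tables
#'
#' Articles present in the gold standard but absent from the predictions
#' contribute an empty retrieval list (TAP 0).
#'
#' @param gold data.frame from [read_gold()].
#' @param pred data.frame from [read_ranked()].
#' @return list of `gn_query`.
#' @export
build_queries <- function(gold, pred) {
  lapply(unique(gold$article_id), function(a) {
    p <- pred[pred$article_id == a, , drop = FALSE]
    query_result(a, gold$gene_id[gold$article_id == a],
                 gene_id = p$gene_id, e_value = p$e_value)
  })
}
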