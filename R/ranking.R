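# Identifier ranking: the five feature families extracted from the
# metadata memory, a linear margin-classifier contract with a logistic
# confidence map, and article-level ranking.

#' Feature-order manifest for the ranking model
#'
#' 32 named dimensions: the two matching-method booleans, the weighted vote
#' total plus 13 per-rule vote booleans, the two frequency features
#' (article frequency log-scaled, Results-section percentage), 12 location
#' booleans, and the two author-provided-information booleans.
#'
#' @return character vector of feature names, in order.
#' @export
feature_names <- function() {
  c("match_exact", "match_partial", "vote_total",
    paste0("rule_", RULE_IDS),
    "freq_article", "freq_results_pct",
    "loc_title", "loc_abstract", "loc_abstract_last_n1",
    "loc_first_section", "loc_first_section_last_n2", "loc_results",
    "loc_other", "loc_last_section", "loc_section_title", "loc_appendix",
    "loc_figure_caption", "loc_table_caption",
    "keyword_match", "fullname_abbrev_match")
}

#' Extract the ranking feature vector for a normalized identifier
#'
#' @param ng a grouped normalized-identifier record (one element of
#'   [group_normalized()]'s output, or a `gn_normalized`).
#' @param article the `gn_article`.
#' @param metadata the article's `gn_metadata`.
#' @param n1 number of trailing abstract sentences in the "last n1" location
#'   feature (default 3).
#' @param n2 number of trailing first-section sentences (default 3).
#' @return named numeric vector following [feature_names()].
#' @export
extract_features <- function(ng, article, metadata, n1 = 3L, n2 = 3L) {
  if (is.null(ng$mentions) || nrow(ng$mentions) == 0L)
    gn_stop("argument error: identifier has no recorded mentions")
  v <- setNames(numeric(length(feature_names())), feature_names())
  v["match_exact"] <- as.numeric(identical(ng$match_kind, "exact"))
  v["match_partial"] <- as.numeric(identical(ng$match_kind, "partial"))
  if (!is.null(ng$vote)) {
    v["vote_total"] <- ng$vote$total
    for (rid in RULE_IDS)
      v[paste0("rule_", rid)] <- as.numeric(ng$vote$results[[rid]]$y == 1L)
  }
  kinds <- vapply(article$sections, `[[`, "", "kind")
  body <- which(!kinds %in% c("title", "abstract"))
  first_sec <- if (length(body)) body[1] else NA_integer_
  last_sec <- if (length(body)) body[length(body)] else NA_integer_
  n_res <- 0L
  for (r in seq_len(nrow(ng$mentions))) {
    si <- ng$mentions$section_index[r]
    sj <- ng$mentions$sentence_index[r]
    kind <- kinds[si]
    nsen <- length(article$sections[[si]]$sentences)
    if (kind == "title") v["loc_title"] <- 1
    if (kind == "abstract") {
      v["loc_abstract"] <- 1
      if (sj > nsen - n1) v["loc_abstract_last_n1"] <- 1
    }
    if (!is.na(first_sec) && si == first_sec) {
      v["loc_first_section"] <- 1
      if (sj > nsen - n2) v["loc_first_section_last_n2"] <- 1
    }
    if (kind == "results") { v["loc_results"] <- 1; n_res <- n_res + 1L }
    if (kind == "other") v["loc_other"] <- 1
    if (!is.na(last_sec) && si == last_sec) v["loc_last_section"] <- 1
    if (kind == "section_title") v["loc_section_title"] <- 1
    if (kind == "appendix") v["loc_appendix"] <- 1
    if (kind == "figure_caption") v["loc_figure_caption"] <- 1
    if (kind == "table_caption") v["loc_table_caption"] <- 1
  }
  freq <- nrow(ng$mentions)
  v["freq_article"] <- log1p(freq)
  v["freq_results_pct"] <- n_res / freq
  keys <- normalize_name(ng$mention_texts)
  if (length(metadata$keywords) &&
      any(keys %in% normalize_name(metadata$keywords)))
    v["keyword_match"] <- 1
  ab <- metadata$abbreviations
  if (!is.null(ab) && nrow(ab) > 0L &&
      any(keys %in% normalize_name(c(ab$long, ab$short))))
    v["fullname_abbrev_match"] <- 1
  v
}

#' Construct a linear ranker model
#'
#' @param weights named numeric vector over [feature_names()].
#' @param bias intercept.
#' @param calibration `c(a, b)`: confidence = plogis(a * decision + b),
#'   strictly increasing in the decision value (a > 0).
#' @return object of class `gn_ranker`.
#' @export
make_ranker <- function(weights, bias = 0,
                        calibration = c(a = 1, b = 0)) {
  if (is.null(names(weights))) names(weights) <- feature_names()
  if (calibration[["a"]] <= 0)
    gn_stop("calibration slope must be positive")
  structure(list(version = 1L, weights = weights, bias = bias,
                 calibration = calibration,
                 feature_order = names(weights)),
            class = "gn_ranker")
}

#' Train the identifier ranker
#'
#' A linear margin classifier fitted as ridge-penalized logistic regression
#' by Newton/IRLS iterations (deterministic; the seed argument is part of
#' the contract and fixes any future stochastic backend). The small L2
#' penalty keeps weights finite on separable data while still separating
#' separable toy sets exactly. Confidences come from the logistic map of
#' the decision value.
#'
#' @param features numeric matrix (rows = examples) whose columns follow
#'   [feature_names()], or a list of feature vectors.
#' @param labels vector with two classes, `"correct"`/`"incorrect"` (or
#'   logical/0-1).
#' @param seed integer seed.
#' @param lambda L2 penalty on the weights (intercept unpenalized).
#' @return a `gn_ranker`.
#' @export
train_ranker <- function(features, labels, seed = 1L, lambda = 0.01) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  features <- as.matrix(features)
  if (nrow(features) == 0L) gn_stop("training error: no examples")
  if (is.character(labels) || is.factor(labels))
    y <- as.integer(as.character(labels) == "correct")
  else y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L)
    gn_stop("training error: single-class input")
  if (any(!is.finite(features)))
    gn_stop("training error: non-finite feature values")
  set.seed(as.integer(seed))
  X <- cbind(1, features)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(200L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, mu - y)) + drop(pen %*% beta)
    W <- pmax(mu * (1 - mu), 1e-6)
    H <- crossprod(X * W, X) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta - step
    if (max(abs(step)) < 1e-8) break
  }
  w <- beta[-1]
  names(w) <- colnames(features) %||% feature_names()[seq_along(w)]
  make_ranker(w, bias = beta[1])
}

#' Score feature vectors into confidences
#'
#' @param model a `gn_ranker`.
#' @param vectors numeric matrix of feature rows (or list of vectors).
#' @return numeric vector of confidences in (0, 1), strictly monotone in
#'   the decision value.
#' @export
score_ids <- function(model, vectors) {
  if (is.list(vectors) && !is.data.frame(vectors))
    vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0L) return(numeric())
  if (ncol(vectors) != length(model$weights))
    gn_stop("dimensionality mismatch: model has %d features, input %d",
            length(model$weights), ncol(vectors))
  d <- drop(vectors %*% model$weights) + model$bias
  conf <- stats::plogis(model$calibration[["a"]] * d +
                          model$calibration[["b"]])
  pmin(pmax(conf, 1e-12), 1 - 1e-12)
}

#' Rank an article's normalized identifiers
#'
#' @param model a `gn_ranker`.
#' @param ngs grouped normalized records ([group_normalized()]).
#' @param article the `gn_article`.
#' @param metadata its `gn_metadata`.
#' @param n1,n2 location-feature window sizes.
#' @return data.frame(gene_id, confidence), confidence descending, gene id
#'   ascending on exact ties.
#' @export
rank_article <- function(model, ngs, article, metadata, n1 = 3L, n2 = 3L) {
  if (!length(ngs))
    return(data.frame(gene_id = character(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  X <- do.call(rbind, lapply(ngs, extract_features, article = article,
                             metadata = metadata, n1 = n1, n2 = n2))
  conf <- score_ids(model, X)
  gid <- vapply(ngs, `[[`, "", "gene_id")
  ord <- order(-conf, gid)
  data.frame(gene_id = gid[ord], confidence = conf[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a ranker model to versioned JSON
#'
#' @param model a `gn_ranker`.
#' @param path output path.
#' @export
write_ranker <- function(model, path) {
  jsonlite::write_json(list(version = model$version,
                            feature_order = model$feature_order,
                            weights = as.list(model$weights),
                            bias = model$bias,
                            calibration = as.list(model$calibration)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ranker model from JSON
#'
#' @param path model file.
#' @return a `gn_ranker`.
#' @export
read_ranker <- function(path) {
  m <- jsonlite::fromJSON(path)
  w <- unlist(m$weights)
  make_ranker(w[m$feature_order], bias = m$bias,
              calibration = unlist(m$calibration))
}

.genorm_env <- new.env(parent = emptyenv())

#' The shipped default ranker
#'
#' Trained at build time on synthetic labeled fixtures with a fixed seed and
#' shipped as `extdata/default_model.json`; any model file with the same
#' manifest can be plugged in via [read_ranker()].
#'
#' @return a `gn_ranker`.
#' @export
default_ranker <- function() {
  if (!is.null(.genorm_env$default_ranker)) return(.genorm_env$default_ranker)
  path <- system.file("extdata", "default_model.json", package = "genorm")
  model <- if (nzchar(path)) read_ranker(path) else
    make_ranker(setNames(rep(0, length(feature_names())), feature_names()))
  .genorm_env$default_ranker <- model
  model
}

#' Train the default ranker on synthetic fixtures
#'
#' Generates a labeled training set by running the full pipeline (with a
#' zero-weight placeholder ranker) over a synthetic corpus and labeling each
#' emitted identifier by gold-standard membership, then fits the linear
#' ranker. Correct identifiers carry richer votes and locations by
#' construction of the generator.
#'
#' @param seed integer seed driving corpus generation.
#' @param n_articles corpus size (default 20).
#' @return a `gn_ranker`.
#' @export
train_default_ranker <- function(seed = 42L, n_articles = 20L) {
  cfg <- sim_config(seed = seed, articles = n_articles)
  res <- gen_resources(cfg)
  placeholder <- make_ranker(setNames(rep(0, length(feature_names())),
                                      feature_names()))
  X <- list(); y <- character()
  for (i in seq_len(cfg$articles)) {
    ga <- gen_article(res, res$kb, res$table, cfg, i)
    art <- preprocess_article(ga$article)
    scfg <- strategy_config("dynamic_article",
                            common_species = res$common_species)
    ranked <- normalize_article(art, res$dict, res$kb, scfg, res$table,
                                ranker = placeholder)
    md <- attr(ranked, "metadata")
    ngs <- group_normalized(md)
    for (ng in ngs) {
      X <- c(X, list(extract_features(ng, art, md)))
      y <- c(y, if (ng$gene_id %in% ga$gold$gene_id) "correct" else
        "incorrect")
    }
  }
  train_ranker(do.call(rbind, X), y, seed = seed)
}
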