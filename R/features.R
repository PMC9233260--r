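# Step-2 feature engineering: TF-IDF weighting, importance ranking,
# top-K selection, expert-keyword union, boolean vectorization.

#' Term frequencies of one document
#'
#' @param doc Character vector of tokens.
#' @return Named integer vector of raw occurrence counts (empty for an
#'   empty document). Counts sum to the token count.
#' @export
compute_tf <- function(doc) {
  if (!length(doc)) return(stats::setNames(integer(0), character(0)))
  tab <- table(doc)
  stats::setNames(as.integer(tab), names(tab))
}

#' Inverse document frequencies of a corpus
#'
#' idf(t) = ln(N / df(t)) with N the number of documents and df(t) the
#' number of documents containing t; defined only for observed terms, so
#' df >= 1 always holds. The `smoothed` variant uses
#' ln((1 + N) / (1 + df)) + 1.
#'
#' @param x A preprocessed `corpus` (or a list of token vectors).
#' @param variant `"plain"` (default) or `"smoothed"`.
#' @return Named numeric vector term -> idf.
#' @export
compute_idf <- function(x, variant = c("plain", "smoothed")) {
  variant <- match.arg(variant)
  docs <- if (inherits(x, "corpus")) corpus_tokens(x) else x
  if (!length(docs)) stop("corpus is empty", call. = FALSE)
  n <- length(docs)
  df_tab <- table(unlist(lapply(docs, unique), use.names = FALSE))
  df <- stats::setNames(as.integer(df_tab), names(df_tab))
  idf <- switch(variant,
    plain    = log(n / df),
    smoothed = log((1 + n) / (1 + df)) + 1
  )
  idf
}

#' Per-corpus term statistics
#'
#' @param x A preprocessed `corpus`.
#' @param tf `"raw"` (default) or `"log"` (1 + ln tf) term frequency.
#' @param idf `"plain"` or `"smoothed"`, see [compute_idf()].
#' @param ranking `"max"` (default) or `"sum"`: aggregate tf-idf over
#'   documents by its maximum or its sum.
#' @return A data.frame with columns `term`, `df`, `score`, sorted by
#'   decreasing score with lexicographic (bytewise) tie-break.
#' @export
term_stats <- function(x, tf = c("raw", "log"), idf = c("plain", "smoothed"),
                       ranking = c("max", "sum")) {
  tf <- match.arg(tf); idf <- match.arg(idf); ranking <- match.arg(ranking)
  docs <- if (inherits(x, "corpus")) corpus_tokens(x) else x
  idf_vec <- compute_idf(docs, idf)
  terms <- names(idf_vec)
  score <- stats::setNames(rep(0, length(terms)), terms)
  df <- stats::setNames(rep(0L, length(terms)), terms)
  for (d in docs) {
    cnt <- compute_tf(d)
    if (!length(cnt)) next
    w <- if (tf == "raw") as.numeric(cnt) else 1 + log(as.numeric(cnt))
    tfidf <- w * idf_vec[names(cnt)]
    if (ranking == "max") {
      score[names(cnt)] <- pmax(score[names(cnt)], tfidf)
    } else {
      score[names(cnt)] <- score[names(cnt)] + tfidf
    }
    df[names(cnt)] <- df[names(cnt)] + 1L
  }
  ord <- order(-score, terms, method = "radix")
  data.frame(term = terms[ord], df = unname(df[ord]),
             score = unname(score[ord]), stringsAsFactors = FALSE)
}

#' Rank terms by TF-IDF importance and keep the top K
#'
#' Each term is scored by the maximum (default) over documents of its
#' tf-idf weight; the K highest-scoring terms form the feature space.
#' This mirrors selecting the most important 160 of ~7000 vocabulary
#' words in the original pipeline. Ties are broken by bytewise
#' lexicographic term order so selection is deterministic and
#' locale-independent.
#'
#' @param x A preprocessed `corpus`.
#' @param k Number of terms to keep (all terms if `k` >= vocabulary size).
#' @param tf,idf,ranking Scoring variants, see [term_stats()].
#' @return A `feature_space`: list with `terms` (ordered character
#'   vector), `origin` (per-term `"tfidf_selected"`), and `config`.
#' @export
rank_and_select <- function(x, k = 160, tf = c("raw", "log"),
                            idf = c("plain", "smoothed"),
                            ranking = c("max", "sum")) {
  stopifnot(k >= 1)
  tf <- match.arg(tf); idf <- match.arg(idf); ranking <- match.arg(ranking)
  st <- term_stats(x, tf, idf, ranking)
  keep <- st$term[seq_len(min(k, nrow(st)))]
  feature_space(keep, origin = rep("tfidf_selected", length(keep)),
                config = list(k = k, tf = tf, idf = idf, ranking = ranking))
}

#' Construct a feature space
#'
#' @param terms Ordered character vector of distinct terms.
#' @param origin Per-term tag: `"tfidf_selected"`, `"expert"`, or `"both"`.
#' @param config Optional list recording how the space was built.
#' @return An object of class `feature_space`.
#' @export
feature_space <- function(terms, origin = rep("tfidf_selected", length(terms)),
                          config = list()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate terms in feature space", call. = FALSE)
  stopifnot(length(origin) == length(terms),
            all(origin %in% c("tfidf_selected", "expert", "both")))
  structure(list(terms = terms, origin = origin, config = config),
            class = "feature_space")
}

#' @export
length.feature_space <- function(x) length(x$terms)

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d terms (%d tfidf, %d expert, %d both)\n",
              length(x$terms), sum(x$origin == "tfidf_selected"),
              sum(x$origin == "expert"), sum(x$origin == "both")))
  invisible(x)
}

#' Union a feature space with expert keywords
#'
#' Step-4.1 manual feature addition: the TF-IDF-selected space is merged
#' with the expert keyword list (nominally 37 words). Terms present in
#' both are tagged `"both"`; new expert terms are appended after the
#' TF-IDF-selected block in lexicographic order.
#'
#' @param fs A `feature_space`.
#' @param expert_keywords Character vector.
#' @return The enlarged `feature_space`.
#' @export
union_with_expert <- function(fs, expert_keywords) {
  stopifnot(inherits(fs, "feature_space"))
  expert_keywords <- unique(as.character(expert_keywords))
  if (!length(expert_keywords)) return(fs)
  origin <- fs$origin
  origin[fs$terms %in% expert_keywords & origin == "tfidf_selected"] <- "both"
  new_terms <- setdiff(expert_keywords, fs$terms)
  new_terms <- new_terms[order(new_terms, method = "radix")]
  feature_space(c(fs$terms, new_terms),
                origin = c(origin, rep("expert", length(new_terms))),
                config = fs$config)
}

#' Vectorize one document as boolean term presence
#'
#' Bit i is TRUE iff term i of the feature space occurs at least once in
#' the document; multiplicity is ignored (the Bernoulli representation).
#'
#' @param doc Character vector of tokens.
#' @param fs A `feature_space`.
#' @return Logical vector aligned to `fs$terms`.
#' @export
vectorize <- function(doc, fs) {
  stopifnot(inherits(fs, "feature_space"))
  fs$terms %in% doc
}

#' Vectorize a whole corpus
#'
#' @param x A preprocessed `corpus` (or list of token vectors).
#' @param fs A `feature_space`.
#' @return Logical matrix, documents x terms, with document ids as row
#'   names and terms as column names.
#' @export
vectorize_corpus <- function(x, fs) {
  docs <- if (inherits(x, "corpus")) corpus_tokens(x) else x
  m <- t(vapply(docs, vectorize, logical(length(fs$terms)), fs = fs))
  if (length(fs$terms) == 1L) m <- matrix(m, ncol = 1L,
                                          dimnames = list(names(docs), NULL))
  colnames(m) <- fs$terms
  m
}

#' Serialize / deserialize a feature space as JSON
#'
#' @param fs A `feature_space`.
#' @param path File path.
#' @return `path` invisibly / the reloaded `feature_space`.
#' @export
write_feature_space <- function(fs, path) {
  jsonlite::write_json(list(terms = fs$terms, origin = fs$origin,
                            config = fs$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  feature_space(obj$terms, obj$origin, as.list(obj$config))
}
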