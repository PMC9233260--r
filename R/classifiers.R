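# Step-3/4 classification: Bernoulli naive Bayes with Laplace smoothing,
# the expert-keyword rule gate, and the four model variants (A, B, C, PAMT).

POSITIVE <- "pamt"
NEGATIVE <- "non_pamt"

#' Fit a Bernoulli naive Bayes classifier
#'
#' Class-conditional term probabilities use additive (Laplace) smoothing:
#' P(t|k) = (n_kt + alpha) / (n_k + 2 alpha), where n_kt is the number of
#' class-k training documents containing term t and n_k the number of
#' class-k documents. With alpha > 0 every probability lies strictly in
#' (0, 1), so unseen terms never produce zero likelihoods. Class priors
#' are the empirical class frequencies by default; `priors = "uniform"`
#' uses 1/2 each.
#'
#' @param vectors Logical matrix, documents x terms (see
#'   [vectorize_corpus()]).
#' @param labels Character vector of `"pamt"` / `"non_pamt"`, one per row.
#' @param alpha Smoothing parameter (default 1, i.e. Laplace smoothing).
#' @param priors `"empirical"` (default) or `"uniform"`.
#' @param feature_space Optional `feature_space` the vectors are aligned
#'   to; stored for alignment checks at prediction time.
#' @return An object of class `bnb_params` with `class_log_prior` and the
#'   per-class conditional probability matrix `term_cond_prob`
#'   (terms x classes).
#' @export
fit_bnb <- function(vectors, labels, alpha = 1,
                    priors = c("empirical", "uniform"), feature_space = NULL) {
  priors <- match.arg(priors)
  stopifnot(is.matrix(vectors), alpha > 0)
  if (nrow(vectors) != length(labels)) {
    stop("number of vectors and labels differ", call. = FALSE)
  }
  if (!all(labels %in% c(POSITIVE, NEGATIVE))) {
    stop("labels must be 'pamt' or 'non_pamt'", call. = FALSE)
  }
  n_pos <- sum(labels == POSITIVE)
  n_neg <- sum(labels == NEGATIVE)
  if (n_pos == 0L || n_neg == 0L) {
    stop("training set must contain both classes (got ", n_pos, " pamt, ",
         n_neg, " non_pamt)", call. = FALSE)
  }
  mode(vectors) <- "numeric"
  n_kt <- cbind(
    pamt     = colSums(vectors[labels == POSITIVE, , drop = FALSE]),
    non_pamt = colSums(vectors[labels == NEGATIVE, , drop = FALSE])
  )
  cond <- sweep(n_kt + alpha, 2, c(n_pos, n_neg) + 2 * alpha, "/")
  log_prior <- if (priors == "empirical") {
    log(c(pamt = n_pos, non_pamt = n_neg) / (n_pos + n_neg))
  } else {
    c(pamt = log(0.5), non_pamt = log(0.5))
  }
  structure(
    list(class_log_prior = log_prior, term_cond_prob = cond, alpha = alpha,
         priors = priors, n_train = c(pamt = n_pos, non_pamt = n_neg),
         feature_space = feature_space),
    class = "bnb_params"
  )
}

#' @export
print.bnb_params <- function(x, ...) {
  cat(sprintf("<bnb_params> %d terms, alpha = %g, priors = %s (n = %d pamt / %d non_pamt)\n",
              nrow(x$term_cond_prob), x$alpha, x$priors,
              x$n_train["pamt"], x$n_train["non_pamt"]))
  invisible(x)
}

check_alignment <- function(params, v) {
  k <- nrow(params$term_cond_prob)
  len <- if (is.matrix(v)) ncol(v) else length(v)
  if (len != k) {
    stop("vector length ", len, " does not match feature space size ", k,
         call. = FALSE)
  }
  if (!is.null(params$feature_space)) {
    nm <- if (is.matrix(v)) colnames(v) else names(v)
    if (!is.null(nm) && !identical(nm, params$feature_space$terms)) {
      stop("vector term order does not match the fitted feature space",
           call. = FALSE)
    }
  }
}

#' Per-class log posterior of a document vector
#'
#' score(k) = log pi_k + sum_t [ x_t log P(t|k) + (1 - x_t) log(1 - P(t|k)) ],
#' the log of the Bernoulli likelihood of the presence/absence pattern
#' times the class prior. Maximum a posteriori classification picks the
#' larger score.
#'
#' @param params A `bnb_params`.
#' @param v Logical vector aligned to the fitted feature space, or a
#'   logical matrix of such rows.
#' @return Named numeric vector `c(pamt=, non_pamt=)`, or a two-column
#'   matrix when `v` is a matrix.
#' @export
bnb_log_posterior <- function(params, v) {
  stopifnot(inherits(params, "bnb_params"))
  check_alignment(params, v)
  p <- params$term_cond_prob
  x <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  mode(x) <- "numeric"
  scores <- x %*% log(p) + (1 - x) %*% log1p(-p)
  scores <- sweep(scores, 2, params$class_log_prior, "+")
  colnames(scores) <- colnames(p)
  if (is.matrix(v)) scores else scores[1L, ]
}

#' Predict with a fitted Bernoulli naive Bayes model
#'
#' The class with the higher posterior wins; exact ties go to the
#' positive (PAMT) class -- in a triage setting the costlier error is
#' undertriage, so ambiguity resolves toward severity. Set
#' `tie_break = "non_pamt"` to flip that convention.
#'
#' @param params A `bnb_params`.
#' @param v Logical vector or matrix, see [bnb_log_posterior()].
#' @param tie_break Label returned on an exact posterior tie.
#' @return `"pamt"`/`"non_pamt"`, or a character vector for a matrix input.
#' @export
predict_bnb <- function(params, v, tie_break = c("pamt", "non_pamt")) {
  tie_break <- match.arg(tie_break)
  s <- bnb_log_posterior(params, v)
  scalar <- !is.matrix(s)
  if (scalar) s <- matrix(s, nrow = 1L, dimnames = list(NULL, names(s)))
  out <- ifelse(s[, POSITIVE] > s[, NEGATIVE], POSITIVE,
                ifelse(s[, POSITIVE] < s[, NEGATIVE], NEGATIVE, tie_break))
  if (scalar) unname(out) else out
}

#' Construct an expert-keyword rule gate
#'
#' The gate classifies a document as PAMT outright when it contains at
#' least `m` of the expert keywords (default m = 2 of the 37-word list),
#' and defers to the downstream classifier otherwise. By default the
#' count is over distinct keyword types; `count_mode =
#' "token_occurrences"` counts every occurrence instead.
#'
#' @param keywords Character vector of expert keywords, in canonical
#'   (post-synonym-grouping) form.
#' @param m Minimum count to fire (default 2).
#' @param count_mode `"distinct_types"` (default) or `"token_occurrences"`.
#' @return An object of class `rule_gate`.
#' @export
rule_gate <- function(keywords, m = 2,
                      count_mode = c("distinct_types", "token_occurrences")) {
  count_mode <- match.arg(count_mode)
  keywords <- unique(as.character(keywords))
  if (!length(keywords)) stop("gate keywords must be non-empty", call. = FALSE)
  stopifnot(m >= 1)
  structure(list(keywords = keywords, m = as.integer(m),
                 count_mode = count_mode),
            class = "rule_gate")
}

#' Apply a rule gate to a token list
#'
#' @param tokens Character vector of (preprocessed) tokens.
#' @param gate A `rule_gate`.
#' @return `"fire_positive"` when the keyword count reaches the gate
#'   threshold, `"defer"` otherwise.
#' @export
apply_gate <- function(tokens, gate) {
  stopifnot(inherits(gate, "rule_gate"))
  count <- switch(gate$count_mode,
    distinct_types    = length(intersect(gate$keywords, tokens)),
    token_occurrences = sum(tokens %in% gate$keywords)
  )
  if (count >= gate$m) "fire_positive" else "defer"
}

#' Model variant definitions
#'
#' The four variants combine the pipeline steps differently:
#' \describe{
#'   \item{A}{expert features with rule gate only -- documents that do
#'     not fire the gate are non-PAMT (no fallback classifier).}
#'   \item{B}{TF-IDF feature space with BNB classification.}
#'   \item{C}{TF-IDF-plus-expert union space with BNB classification.}
#'   \item{PAMT}{the full model: rule gate first, BNB on the union space
#'     for documents the gate defers on.}
#' }
#'
#' @param name `"A"`, `"B"`, `"C"`, or `"PAMT"`.
#' @return An object of class `model_variant` with logical fields
#'   `uses_tfidf_features`, `uses_expert_features`, `uses_rule_gate`,
#'   `uses_bnb`.
#' @export
model_variant <- function(name = c("PAMT", "A", "B", "C")) {
  name <- match.arg(name)
  spec <- switch(name,
    A    = c(tfidf = FALSE, expert = TRUE,  gate = TRUE,  bnb = FALSE),
    B    = c(tfidf = TRUE,  expert = FALSE, gate = FALSE, bnb = TRUE),
    C    = c(tfidf = TRUE,  expert = TRUE,  gate = FALSE, bnb = TRUE),
    PAMT = c(tfidf = TRUE,  expert = TRUE,  gate = TRUE,  bnb = TRUE)
  )
  structure(list(name = name,
                 uses_tfidf_features = unname(spec["tfidf"]),
                 uses_expert_features = unname(spec["expert"]),
                 uses_rule_gate = unname(spec["gate"]),
                 uses_bnb = unname(spec["bnb"])),
            class = "model_variant")
}

#' Predict one document under a model variant
#'
#' @param variant A `model_variant`.
#' @param doc A preprocessed `transcript` (tokens present).
#' @param fs The `feature_space` the fitted model uses (required when the
#'   variant uses BNB).
#' @param fitted A `bnb_params` (required when the variant uses BNB).
#' @param gate A `rule_gate` (required when the variant uses the gate).
#' @return `"pamt"` or `"non_pamt"`.
#' @export
predict_variant <- function(variant, doc, fs = NULL, fitted = NULL,
                            gate = NULL) {
  stopifnot(inherits(variant, "model_variant"), inherits(doc, "transcript"))
  if (variant$uses_rule_gate && is.null(gate)) {
    stop("variant ", variant$name, " requires a rule gate", call. = FALSE)
  }
  if (variant$uses_bnb && (is.null(fitted) || is.null(fs))) {
    stop("variant ", variant$name, " requires a fitted BNB model and its ",
         "feature space", call. = FALSE)
  }
  toks <- doc$tokens %||% character(0)
  if (variant$uses_rule_gate && apply_gate(toks, gate) == "fire_positive") {
    return(POSITIVE)
  }
  if (!variant$uses_bnb) return(NEGATIVE)
  predict_bnb(fitted, vectorize(toks, fs))
}

#' Fit a model variant on a training corpus
#'
#' Bundles feature-space construction (per the variant's definition),
#' BNB fitting, and gate configuration into one fitted model object
#' usable with [predict_variant()] or directly via `predict()`.
#'
#' @param variant A `model_variant` (or variant name).
#' @param train A preprocessed, labeled `corpus`.
#' @param lex A `lexicon` supplying the expert keywords.
#' @param k Number of TF-IDF-selected terms (default 160).
#' @param alpha Laplace smoothing parameter (default 1).
#' @param m Gate threshold (default 2).
#' @param feature_space Optional precomputed `feature_space`; when given,
#'   selection is skipped (used by the evaluation harness to share one
#'   space across folds).
#' @param ... Further arguments to [rank_and_select()].
#' @return An object of class `pamt_model`.
#' @export
fit_variant <- function(variant, train, lex, k = 160, alpha = 1, m = 2,
                        feature_space = NULL, ...) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(inherits(train, "corpus"), inherits(lex, "lexicon"))
  fs <- feature_space
  if (is.null(fs)) {
    fs <- build_variant_space(variant, train, lex, k, ...)
  }
  gate <- if (variant$uses_rule_gate) rule_gate(lex$expert_keywords, m = m)
  fitted <- NULL
  if (variant$uses_bnb) {
    vec <- vectorize_corpus(train, fs)
    fitted <- fit_bnb(vec, corpus_labels(train), alpha = alpha,
                      feature_space = fs)
  }
  structure(list(variant = variant, feature_space = fs, fitted = fitted,
                 gate = gate),
            class = "pamt_model")
}

#' Build the feature space a variant calls for
#'
#' @inheritParams fit_variant
#' @param x The corpus selection runs on.
#' @return A `feature_space`.
#' @export
build_variant_space <- function(variant, x, lex, k = 160, ...) {
  if (is.character(variant)) variant <- model_variant(variant)
  if (variant$uses_tfidf_features) {
    fs <- rank_and_select(x, k = k, ...)
    if (variant$uses_expert_features) {
      fs <- union_with_expert(fs, lex$expert_keywords)
    }
    fs
  } else {
    kw <- lex$expert_keywords
    feature_space(kw[order(kw, method = "radix")],
                  origin = rep("expert", length(kw)))
  }
}

#' @export
predict.pamt_model <- function(object, newdata, ...) {
  docs <- if (inherits(newdata, "corpus")) newdata$transcripts
          else if (inherits(newdata, "transcript")) list(newdata)
          else newdata
  vapply(docs, function(d) {
    predict_variant(object$variant, d, fs = object$feature_space,
                    fitted = object$fitted, gate = object$gate)
  }, character(1))
}

#' @export
print.pamt_model <- function(x, ...) {
  cat(sprintf("<pamt_model> variant %s: %d features%s%s\n", x$variant$name,
              length(x$feature_space$terms),
              if (!is.null(x$gate))
                sprintf(", gate (m >= %d of %d keywords)", x$gate$m,
                        length(x$gate$keywords)) else "",
              if (!is.null(x$fitted)) ", BNB fitted" else ""))
  invisible(x)
}

#' Serialize / reload a fitted model as JSON
#'
#' Probabilities are written as full-precision decimal strings so a
#' reloaded model reproduces predictions bit-for-bit.
#'
#' @param model A `pamt_model`.
#' @param path File path.
#' @return `path` invisibly / the reloaded `pamt_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pamt_model"))
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    variant = model$variant$name,
    feature_space = list(terms = model$feature_space$terms,
                         origin = model$feature_space$origin,
                         config = model$feature_space$config)
  )
  if (!is.null(model$fitted)) {
    f <- model$fitted
    obj$bnb <- list(
      class_log_prior = as.list(stats::setNames(num(f$class_log_prior),
                                                names(f$class_log_prior))),
      term_cond_prob = list(pamt = num(f$term_cond_prob[, "pamt"]),
                            non_pamt = num(f$term_cond_prob[, "non_pamt"])),
      alpha = f$alpha, priors = f$priors,
      n_train = as.list(f$n_train)
    )
  }
  if (!is.null(model$gate)) {
    obj$gate <- list(keywords = model$gate$keywords, m = model$gate$m,
                     count_mode = model$gate$count_mode)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fs <- feature_space(obj$feature_space$terms, obj$feature_space$origin,
                      as.list(obj$feature_space$config))
  fitted <- NULL
  if (!is.null(obj$bnb)) {
    cond <- cbind(pamt = as.numeric(obj$bnb$term_cond_prob$pamt),
                  non_pamt = as.numeric(obj$bnb$term_cond_prob$non_pamt))
    rownames(cond) <- fs$terms
    fitted <- structure(
      list(class_log_prior = c(pamt = as.numeric(obj$bnb$class_log_prior$pamt),
                               non_pamt = as.numeric(obj$bnb$class_log_prior$non_pamt)),
           term_cond_prob = cond, alpha = obj$bnb$alpha,
           priors = obj$bnb$priors,
           n_train = unlist(obj$bnb$n_train), feature_space = fs),
      class = "bnb_params")
  }
  gate <- if (!is.null(obj$gate)) {
    rule_gate(obj$gate$keywords, m = obj$gate$m, count_mode = obj$gate$count_mode)
  }
  structure(list(variant = model_variant(obj$variant), feature_space = fs,
                 fitted = fitted, gate = gate),
            class = "pamt_model")
}
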