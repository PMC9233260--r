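# Evaluation harness: diagnostic metrics, repeated random subsampling
# cross-validation with fixed validation composition, certainty-level
# stratification, learning curves, feature co-occurrence correlation.

#' Construct a metric set from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integers.
#' @return An object of class `metric_set` with sensitivity, specificity,
#'   PPV, NPV, accuracy and the Youden index (sens + spec - 1). PPV/NPV
#'   are `NA` (flagged undefined) when no positives/negatives were
#'   predicted, never silently zeroed.
#' @export
metric_set <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  structure(
    list(sens = sens, spec = spec,
         ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
         acc = (tp + tn) / (tp + fp + tn + fn),
         youden = sens + spec - 1,
         counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("sens %.3f  spec %.3f  ppv %s  npv %s  acc %.3f  youden %.3f\n",
              x$sens, x$spec,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.3f", x$npv)),
              x$acc, x$youden))
  invisible(x)
}

#' Diagnostic metrics from paired label vectors
#'
#' @param y_true,y_pred Character vectors of `"pamt"` / `"non_pamt"`,
#'   equal length, non-empty.
#' @return A `metric_set`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  if (!length(y_true)) stop("empty label vectors", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(POSITIVE, NEGATIVE))) {
    stop("labels must be 'pamt' or 'non_pamt'", call. = FALSE)
  }
  metric_set(tp = sum(y_true == POSITIVE & y_pred == POSITIVE),
             fp = sum(y_true == NEGATIVE & y_pred == POSITIVE),
             tn = sum(y_true == NEGATIVE & y_pred == NEGATIVE),
             fn = sum(y_true == POSITIVE & y_pred == NEGATIVE))
}

#' Cross-validation configuration
#'
#' Defaults follow the evaluation design for the 114-call study corpus:
#' 100 repeats, each holding out a validation set of exactly 3 PAMT and
#' 7 non-PAMT cases drawn without replacement, training on the remaining
#' 104 (39 PAMT, 65 non-PAMT at the study prevalence).
#'
#' @param repeats Number of repeats R (default 100).
#' @param val_pos,val_neg Validation composition (defaults 3 and 7).
#' @param seed Master RNG seed; repeat r uses substream `seed + r`.
#' @param leakage_mode `"shared_space"` builds one feature space from
#'   the whole corpus and reuses it across repeats (mirroring a single
#'   preselected feature set); `"strict"` re-selects features inside each
#'   training fold so the validation fold never influences selection.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(repeats = 100, val_pos = 3, val_neg = 7, seed = 1,
                      leakage_mode = c("shared_space", "strict")) {
  leakage_mode <- match.arg(leakage_mode)
  stopifnot(repeats >= 1, val_pos >= 1, val_neg >= 0)
  structure(list(repeats = as.integer(repeats), val_pos = as.integer(val_pos),
                 val_neg = as.integer(val_neg), seed = as.integer(seed),
                 leakage_mode = leakage_mode),
            class = "cv_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Split a corpus with fixed validation composition
#'
#' Draws exactly `val_pos` positive and `val_neg` negative cases, without
#' replacement, as the validation fold; the complement is the training
#' fold. Deterministic given `(cfg$seed, repeat_index)`.
#'
#' @param x A labeled `corpus`.
#' @param cfg A `cv_config`.
#' @param repeat_index Integer repeat number (1-based).
#' @return List with character vectors `train_ids` and `val_ids`.
#' @export
split_fixed_composition <- function(x, cfg, repeat_index) {
  stopifnot(inherits(x, "corpus"), inherits(cfg, "cv_config"))
  lab <- corpus_labels(x)
  ids <- corpus_ids(x)
  pos_ids <- ids[!is.na(lab) & lab == POSITIVE]
  neg_ids <- ids[!is.na(lab) & lab == NEGATIVE]
  if (length(pos_ids) < cfg$val_pos || length(neg_ids) < cfg$val_neg) {
    stop(sprintf(paste0("infeasible validation composition: need %d pamt and ",
                        "%d non_pamt, corpus has %d and %d"),
                 cfg$val_pos, cfg$val_neg, length(pos_ids), length(neg_ids)),
         call. = FALSE)
  }
  val <- with_seed(cfg$seed + repeat_index, {
    c(sample(pos_ids, cfg$val_pos), sample(neg_ids, cfg$val_neg))
  })
  list(train_ids = setdiff(ids, val), val_ids = val)
}

#' Repeated random subsampling cross-validation
#'
#' For each repeat the corpus is split with fixed validation composition
#' ([split_fixed_composition()]), a model is fitted on the training fold,
#' the validation fold is predicted, and a [metric_set] is recorded.
#' Reported means are arithmetic means over repeats; repeats with
#' undefined PPV or NPV (no predicted positives/negatives) are excluded
#' from that metric's mean and counted separately rather than imputed.
#'
#' @param x A labeled `corpus`.
#' @param model_builder Function `(train_ids) -> predictor`, where
#'   `predictor` is a function `(ids) -> character vector` of predicted
#'   labels for those corpus ids. See [variant_model_builder()].
#' @param cfg A `cv_config`.
#' @return An object of class `cv_result`: `per_repeat` (list of
#'   `metric_set`), `mean` (list of metric means), `predictions` (long
#'   data.frame: repeat, id, truth, pred), and the undefined-PPV/NPV
#'   repeat counts.
#' @export
rrs_cv <- function(x, model_builder, cfg = cv_config()) {
  stopifnot(inherits(x, "corpus"))
  lab <- corpus_labels(x)
  per_repeat <- vector("list", cfg$repeats)
  preds <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    sp <- split_fixed_composition(x, cfg, r)
    predictor <- model_builder(sp$train_ids)
    y_pred <- predictor(sp$val_ids)
    y_true <- unname(lab[sp$val_ids])
    per_repeat[[r]] <- confusion_metrics(y_true, y_pred)
    preds[[r]] <- data.frame(repeat_index = r, id = sp$val_ids,
                             truth = y_true, pred = unname(y_pred),
                             stringsAsFactors = FALSE)
  }
  cv_result(per_repeat, do.call(rbind, preds), cfg)
}

cv_result <- function(per_repeat, predictions, cfg) {
  get <- function(f) vapply(per_repeat, `[[`, numeric(1), f)
  mean_def <- function(v) mean(v[!is.na(v)])
  means <- list(sens = mean_def(get("sens")), spec = mean_def(get("spec")),
                ppv = mean_def(get("ppv")), npv = mean_def(get("npv")),
                acc = mean_def(get("acc")))
  means$youden <- means$sens + means$spec - 1
  structure(
    list(per_repeat = per_repeat, mean = means, predictions = predictions,
         undefined_ppv_repeats = sum(is.na(get("ppv"))),
         undefined_npv_repeats = sum(is.na(get("npv"))),
         config = cfg),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$mean
  cat(sprintf("<cv_result> %d repeats (val %d pamt / %d non_pamt)\n",
              length(x$per_repeat), x$config$val_pos, x$config$val_neg))
  cat(sprintf("  mean: sens %.3f  spec %.3f  ppv %.3f  npv %.3f  acc %.3f  youden %.3f\n",
              m$sens, m$spec, m$ppv, m$npv, m$acc, m$youden))
  if (x$undefined_ppv_repeats + x$undefined_npv_repeats > 0) {
    cat(sprintf("  undefined repeats excluded: ppv %d, npv %d\n",
                x$undefined_ppv_repeats, x$undefined_npv_repeats))
  }
  invisible(x)
}

#' Tabulate a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Data.frame with one row per repeat plus a final `"mean"` row.
#' @export
as.data.frame.cv_result <- function(x, ...) {
  rows <- lapply(seq_along(x$per_repeat), function(r) {
    m <- x$per_repeat[[r]]
    data.frame(repeat_index = as.character(r), sens = m$sens, spec = m$spec,
               ppv = m$ppv, npv = m$npv, acc = m$acc, youden = m$youden,
               stringsAsFactors = FALSE)
  })
  mu <- x$mean
  rbind(do.call(rbind, rows),
        data.frame(repeat_index = "mean", sens = mu$sens, spec = mu$spec,
                   ppv = mu$ppv, npv = mu$npv, acc = mu$acc,
                   youden = mu$youden, stringsAsFactors = FALSE))
}

#' Cross-validation model builder for a pipeline variant
#'
#' Returns the `(train_ids) -> predictor` closure [rrs_cv()] expects,
#' wired to [fit_variant()]. Under `leakage_mode = "shared_space"`
#' (the default in [cv_config()]) the feature space is built once from
#' the full corpus and shared across folds, matching a design where a
#' single preselected term list is reused for every repeat; note this
#' lets validation documents influence term selection. `"strict"`
#' re-runs selection inside each training fold.
#'
#' @param x The full preprocessed, labeled `corpus`.
#' @param lex A `lexicon`.
#' @param variant A `model_variant` or name.
#' @param cfg A `cv_config` (supplies the leakage mode).
#' @param k,alpha,m Pipeline parameters, see [fit_variant()].
#' @param ... Further arguments to [rank_and_select()].
#' @return A model-builder function.
#' @export
variant_model_builder <- function(x, lex, variant = "PAMT",
                                  cfg = cv_config(), k = 160, alpha = 1,
                                  m = 2, ...) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(inherits(x, "corpus"))
  shared_fs <- NULL
  if (cfg$leakage_mode == "shared_space") {
    shared_fs <- build_variant_space(variant, x, lex, k, ...)
  }
  function(train_ids) {
    train <- corpus(x$transcripts[train_ids])
    model <- fit_variant(variant, train, lex, k = k, alpha = alpha, m = m,
                         feature_space = shared_fs, ...)
    function(ids) predict(model, corpus(x$transcripts[ids]))
  }
}

#' Certainty-stratified model accuracy
#'
#' Each case's certainty level is the number of raters (out of 6) who
#' were certain of their own judgment on it. Model correctness per case
#' is the fraction of CV repeats in which the case fell in the
#' validation fold and was predicted correctly; per-level accuracy is
#' the mean of that fraction within the level. Levels 5-6 are pooled as
#' "certain", levels 0-4 as "uncertain".
#'
#' @param x A `corpus` whose transcripts carry `certainty_votes`.
#' @param predictions The `predictions` data.frame of a [rrs_cv()] result
#'   (or a compatible data.frame with columns id, truth, pred).
#' @return An object of class `certainty_profile`: per-case table,
#'   per-level accuracy table, and the certain/uncertain group accuracies.
#' @export
certainty_stratified_accuracy <- function(x, predictions) {
  stopifnot(inherits(x, "corpus"), is.data.frame(predictions))
  votes <- lapply(x$transcripts, `[[`, "certainty_votes")
  missing <- vapply(votes, is.null, logical(1))
  if (any(missing)) {
    stop("transcript(s) without certainty votes: ",
         paste(utils::head(corpus_ids(x)[missing], 5), collapse = ", "),
         call. = FALSE)
  }
  level <- vapply(votes, sum, numeric(1))
  correct <- predictions$truth == predictions$pred
  per_case <- stats::aggregate(correct,
                               by = list(id = predictions$id), FUN = mean)
  names(per_case)[2] <- "correctness"
  n_eval <- stats::aggregate(correct, by = list(id = predictions$id),
                             FUN = length)
  per_case$n_repeats <- n_eval$x[match(per_case$id, n_eval$id)]
  per_case$level <- level[per_case$id]
  per_level <- stats::aggregate(per_case$correctness,
                                by = list(level = per_case$level), FUN = mean)
  names(per_level)[2] <- "accuracy"
  per_level$n_cases <- as.integer(table(per_case$level)[as.character(per_level$level)])
  grp <- function(lv) mean(per_case$correctness[per_case$level %in% lv])
  structure(
    list(per_case = per_case, per_level = per_level,
         certain_accuracy = grp(5:6), uncertain_accuracy = grp(0:4)),
    class = "certainty_profile"
  )
}

#' @export
print.certainty_profile <- function(x, ...) {
  cat("<certainty_profile>\n")
  print(x$per_level, row.names = FALSE)
  cat(sprintf("  certain (5-6): %.4f   uncertain (0-4): %.4f\n",
              x$certain_accuracy, x$uncertain_accuracy))
  invisible(x)
}

#' Learning curve under fixed validation composition
#'
#' For each requested training-set size, repeats of: draw a validation
#' fold of the configured composition, subsample that many training
#' cases from the remainder (stratified so both classes stay present),
#' fit, and record training and validation accuracy.
#'
#' @param x A labeled `corpus`.
#' @param model_builder As in [rrs_cv()].
#' @param train_sizes Integer vector of training-set sizes.
#' @param cfg A `cv_config` (`repeats` controls repeats per size).
#' @return Data.frame with one row per size: `size`, `train_acc`,
#'   `val_acc`.
#' @export
learning_curve <- function(x, model_builder, train_sizes, cfg = cv_config()) {
  stopifnot(inherits(x, "corpus"))
  lab <- corpus_labels(x)
  pool_max <- length(x) - cfg$val_pos - cfg$val_neg
  if (any(train_sizes < 2 | train_sizes > pool_max)) {
    stop("train_sizes must lie in [2, ", pool_max, "]", call. = FALSE)
  }
  rows <- lapply(train_sizes, function(size) {
    tr_acc <- val_acc <- numeric(cfg$repeats)
    for (r in seq_len(cfg$repeats)) {
      sp <- split_fixed_composition(x, cfg, r)
      pool <- sp$train_ids
      pool_pos <- pool[lab[pool] == POSITIVE]
      pool_neg <- pool[lab[pool] == NEGATIVE]
      n_pos <- max(1L, min(length(pool_pos),
                           round(size * length(pool_pos) / length(pool))))
      n_pos <- min(n_pos, size - 1L)
      n_neg <- size - n_pos
      if (n_neg > length(pool_neg)) {
        n_neg <- length(pool_neg)
        n_pos <- size - n_neg
      }
      train_ids <- with_seed(cfg$seed + 100000L + r, {
        c(sample(pool_pos, n_pos), sample(pool_neg, n_neg))
      })
      predictor <- model_builder(train_ids)
      tr_acc[r] <- mean(predictor(train_ids) == lab[train_ids])
      val_acc[r] <- mean(predictor(sp$val_ids) == lab[sp$val_ids])
    }
    data.frame(size = size, train_acc = mean(tr_acc), val_acc = mean(val_acc))
  })
  do.call(rbind, rows)
}

#' Pairwise co-occurrence correlation of features
#'
#' Pearson correlation between the boolean occurrence indicators of
#' every pair of feature-space terms across documents. Highly correlated
#' pairs are words that tend to appear in the same calls. Terms that are
#' constant across the corpus (always or never present) have undefined
#' correlations; their rows/columns are `NA` and their names are
#' recorded in the `undefined_terms` attribute.
#'
#' @param vectors Logical document-vector matrix ([vectorize_corpus()]),
#'   at least 2 rows.
#' @return Terms x terms correlation matrix.
#' @export
feature_cooccurrence_correlation <- function(vectors) {
  stopifnot(is.matrix(vectors))
  if (nrow(vectors) < 2L) stop("need at least 2 documents", call. = FALSE)
  m <- vectors
  mode(m) <- "numeric"
  constant <- apply(m, 2, function(col) stats::var(col) == 0)
  cc <- suppressWarnings(stats::cor(m))
  attr(cc, "undefined_terms") <- colnames(m)[constant]
  cc
}
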