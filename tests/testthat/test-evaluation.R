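study_sized_corpus <- function(seed = 21) {
  sim <- generate_corpus(generator_config(seed = seed))
  list(corpus = sim$corpus,
       lex = lexicon(expert_keywords = sim$ground_truth$expert_keywords))
}

test_that("confusion metrics reproduce hand arithmetic and flag undefined ratios", {
  y_true <- c(rep("pamt", 3), rep("non_pamt", 7))
  y_pred <- c("pamt", "pamt", "non_pamt",          # TP=2 FN=1
              "pamt", rep("non_pamt", 6))           # FP=1 TN=6
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(m$sens, 2 / 3)
  expect_equal(m$spec, 6 / 7)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 6 / 7)
  expect_equal(m$acc, 0.8)
  expect_equal(m$youden, 2 / 3 + 6 / 7 - 1)
  perfect <- confusion_metrics(y_true, y_true)
  expect_equal(unlist(perfect[c("sens", "spec", "ppv", "npv", "acc",
                                "youden")]),
               c(sens = 1, spec = 1, ppv = 1, npv = 1, acc = 1, youden = 1))
  # no predicted positives: PPV undefined, not zero
  allneg <- confusion_metrics(y_true, rep("non_pamt", 10))
  expect_true(is.na(allneg$ppv))
  expect_equal(allneg$npv, 0.7)
  expect_error(confusion_metrics(y_true, y_pred[-1]), "lengths differ")
})

test_that("fixed-composition splits hit 39/65 train and 3/7 validation", {
  fx <- study_sized_corpus()
  cfg <- cv_config(seed = 5)
  lab <- corpus_labels(fx$corpus)
  for (r in c(1, 50, 100)) {
    sp <- split_fixed_composition(fx$corpus, cfg, r)
    expect_identical(sum(lab[sp$val_ids] == "pamt"), 3L)
    expect_identical(sum(lab[sp$val_ids] == "non_pamt"), 7L)
    expect_identical(sum(lab[sp$train_ids] == "pamt"), 39L)
    expect_identical(sum(lab[sp$train_ids] == "non_pamt"), 65L)
    # partition
    expect_length(intersect(sp$train_ids, sp$val_ids), 0)
    expect_setequal(c(sp$train_ids, sp$val_ids), corpus_ids(fx$corpus))
    # determinism
    expect_identical(sp, split_fixed_composition(fx$corpus, cfg, r))
  }
  # different repeats draw different folds
  expect_false(identical(split_fixed_composition(fx$corpus, cfg, 1)$val_ids,
                         split_fixed_composition(fx$corpus, cfg, 2)$val_ids))
  tiny <- corpus(list(transcript("x", tokens = "a", label = "pamt"),
                      transcript("y", tokens = "b", label = "non_pamt")))
  expect_error(split_fixed_composition(tiny, cfg, 1), "infeasible")
})

test_that("constant predictors yield the 3:7 composition arithmetic", {
  fx <- study_sized_corpus()
  cfg <- cv_config(repeats = 10, seed = 2)
  const <- function(label) function(train_ids) {
    function(ids) rep(label, length(ids))
  }
  neg <- rrs_cv(fx$corpus, const("non_pamt"), cfg)
  expect_equal(neg$mean$sens, 0)
  expect_equal(neg$mean$spec, 1)
  expect_equal(neg$mean$acc, 0.7)
  expect_identical(neg$undefined_ppv_repeats, 10L)
  pos <- rrs_cv(fx$corpus, const("pamt"), cfg)
  expect_equal(pos$mean$sens, 1)
  expect_equal(pos$mean$spec, 0)
  expect_equal(pos$mean$acc, 0.3)
})

test_that("mean metrics satisfy the composition and Youden identities exactly", {
  fx <- study_sized_corpus()
  cfg <- cv_config(repeats = 15, seed = 8)
  builder <- variant_model_builder(fx$corpus, fx$lex, "PAMT", cfg, k = 60)
  res <- rrs_cv(fx$corpus, builder, cfg)
  expect_equal(res$mean$acc,
               (3 * res$mean$sens + 7 * res$mean$spec) / 10,
               tolerance = 1e-12)
  expect_equal(res$mean$youden, res$mean$sens + res$mean$spec - 1,
               tolerance = 1e-12)
  per_youden <- vapply(res$per_repeat, `[[`, numeric(1), "youden")
  expect_equal(mean(per_youden), res$mean$youden, tolerance = 1e-12)
})

test_that("the harness is deterministic given corpus, seed and config", {
  fx <- study_sized_corpus()
  cfg <- cv_config(repeats = 6, seed = 33)
  builder <- variant_model_builder(fx$corpus, fx$lex, "C", cfg, k = 40)
  r1 <- rrs_cv(fx$corpus, builder, cfg)
  r2 <- rrs_cv(fx$corpus, builder, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(r1$predictions, r2$predictions)
})

test_that("a fully separable synthetic corpus is classified perfectly", {
  kw <- data.frame(keyword = "fatalsign", p_pos = 1, p_neg = 0)
  cfg_gen <- generator_config(n_cases = 60, n_positive = 22,
                              severity_keywords = kw,
                              n_expert_keywords = 1, seed = 17)
  sim <- generate_corpus(cfg_gen)
  lex <- lexicon(expert_keywords = "fatalsign")
  cfg <- cv_config(repeats = 10, seed = 4)
  builder <- variant_model_builder(sim$corpus, lex, "PAMT", cfg, k = 30,
                                   m = 1)
  res <- rrs_cv(sim$corpus, builder, cfg)
  expect_equal(res$mean$acc, 1)
})

test_that("certainty stratification averages per-case correctness by level", {
  crp <- corpus(list(
    transcript("a", tokens = "x", label = "pamt",
               certainty_votes = rep(1, 6)),
    transcript("b", tokens = "y", label = "non_pamt",
               certainty_votes = c(1, 1, 1, 1, 1, 0)),
    transcript("c", tokens = "z", label = "non_pamt",
               certainty_votes = c(1, 0, 0, 0, 0, 0))
  ))
  preds <- data.frame(
    repeat_index = c(1, 2, 3, 4, 1, 2),
    id = c("a", "a", "a", "a", "b", "c"),
    truth = c(rep("pamt", 4), "non_pamt", "non_pamt"),
    pred = c("pamt", "pamt", "pamt", "non_pamt", "non_pamt", "pamt"),
    stringsAsFactors = FALSE
  )
  prof <- certainty_stratified_accuracy(crp, preds)
  pc <- prof$per_case
  expect_equal(pc$correctness[pc$id == "a"], 0.75)  # 3 of 4 repeats correct
  expect_identical(pc$level[pc$id == "a"], 6)
  expect_equal(prof$per_level$accuracy[prof$per_level$level == 6], 0.75)
  # levels 5 and 6 pool as "certain"
  expect_equal(prof$certain_accuracy, mean(c(0.75, 1)))
  expect_equal(prof$uncertain_accuracy, 0)
  noV <- corpus(list(transcript("a", tokens = "x", label = "pamt")))
  expect_error(certainty_stratified_accuracy(noV, preds[1, ]),
               "certainty votes")
})

test_that("all-certain raters collapse the profile to level 6", {
  crp <- generate_corpus(generator_config(n_cases = 30, n_positive = 12,
                                          seed = 6))$corpus
  crp$transcripts <- lapply(crp$transcripts, function(t) {
    t$certainty_votes <- rep(1L, 6)
    t
  })
  preds <- data.frame(repeat_index = 1, id = corpus_ids(crp),
                      truth = corpus_labels(crp),
                      pred = corpus_labels(crp), stringsAsFactors = FALSE)
  prof <- certainty_stratified_accuracy(crp, preds)
  expect_identical(prof$per_level$level, 6)
  expect_identical(prof$per_level$n_cases, 30L)
})

test_that("learning curves expose overfitting at small training sizes", {
  fx <- study_sized_corpus(seed = 19)
  cfg <- cv_config(repeats = 5, seed = 12)
  builder <- variant_model_builder(fx$corpus, fx$lex, "B", cfg, k = 40)
  lc <- learning_curve(fx$corpus, builder, c(6, 40, 104), cfg)
  expect_identical(nrow(lc), 3L)
  expect_identical(lc$size, c(6, 40, 104))
  # tiny training sets are easier to fit than the full pool
  expect_gte(lc$train_acc[1], lc$train_acc[3])
  # full-pool size reproduces the plain CV validation mean
  res <- rrs_cv(fx$corpus, builder, cfg)
  expect_equal(lc$val_acc[3], res$mean$acc, tolerance = 1e-12)
  expect_error(learning_curve(fx$corpus, builder, 1000, cfg), "train_sizes")
})

test_that("feature co-occurrence correlation matches the hand formula", {
  m <- matrix(c(1, 0, 1, 1, 0,
                1, 0, 1, 1, 0,
                0, 1, 1, 0, 1) == 1, ncol = 3,
              dimnames = list(NULL, c("p", "q", "r")))
  cc <- feature_cooccurrence_correlation(m)
  expect_equal(unname(diag(cc)[c("p", "q")]), c(1, 1))
  expect_equal(cc["p", "q"], 1)  # identical indicator columns
  # hand Pearson formula for p vs r
  hand <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
  }
  expect_equal(cc["p", "r"], hand(as.numeric(m[, "p"]), as.numeric(m[, "r"])))
  # constant column undefined, flagged
  m2 <- cbind(m, s = rep(TRUE, 5))
  cc2 <- feature_cooccurrence_correlation(m2)
  expect_true(is.na(cc2["s", "p"]))
  expect_identical(attr(cc2, "undefined_terms"), "s")
  expect_error(feature_cooccurrence_correlation(m[1, , drop = FALSE]),
               "at least 2")
})
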