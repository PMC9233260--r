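test_that("Laplace-smoothed conditionals match hand arithmetic", {
  X <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(NULL, "t"))
  fit <- fit_bnb(X, c("pamt", "non_pamt"), alpha = 1)
  expect_equal(unname(fit$term_cond_prob["t", "pamt"]), 2 / 3)
  expect_equal(unname(fit$term_cond_prob["t", "non_pamt"]), 1 / 3)
  expect_equal(exp(unname(fit$class_log_prior)), c(0.5, 0.5))
  # smoothing keeps every conditional strictly inside (0, 1)
  X2 <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 3, 2)
  fit2 <- fit_bnb(X2, c("pamt", "pamt", "non_pamt"), alpha = 1)
  expect_true(all(fit2$term_cond_prob > 0 & fit2$term_cond_prob < 1))
  expect_error(fit_bnb(X, c("pamt", "pamt")), "both classes")
})

test_that("log posteriors normalize, respect symmetry, and match brute force", {
  withr::with_seed(11, {
    X <- matrix(runif(30) < 0.5, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- c(rep("pamt", 4), rep("non_pamt", 6))
    fit <- fit_bnb(X, y)
    for (i in 0:7) {
      v <- as.logical(intToBits(i)[1:3])
      names(v) <- c("a", "b", "c")
      lp <- bnb_log_posterior(fit, v)
      post <- exp(lp) / sum(exp(lp))
      expect_equal(sum(post), 1)
      oracle <- brute_force_bnb(X, y, v)
      expect_equal(unname(post["pamt"]), unname(oracle$posterior["pamt"]),
                   tolerance = 1e-12)
    }
  })
  # symmetric parameters give equal scores
  Xs <- matrix(c(TRUE, FALSE, TRUE, FALSE), 4, 1)
  fits <- fit_bnb(Xs, c("pamt", "pamt", "non_pamt", "non_pamt"))
  lp <- bnb_log_posterior(fits, TRUE)
  expect_equal(unname(lp["pamt"]), unname(lp["non_pamt"]))
  expect_error(bnb_log_posterior(fits, c(TRUE, FALSE)), "does not match")
})

test_that("prediction is argmax with ties resolved to the positive class", {
  X <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1)
  y <- c("pamt", "pamt", "non_pamt", "non_pamt")
  fit <- fit_bnb(X, y)
  expect_identical(predict_bnb(fit, TRUE), "pamt")
  expect_identical(predict_bnb(fit, FALSE), "non_pamt")
  # fully symmetric model: every input is an exact tie
  Xs <- matrix(c(TRUE, FALSE, TRUE, FALSE), 4, 1)
  fits <- fit_bnb(Xs, y)
  expect_identical(predict_bnb(fits, TRUE), "pamt")
  expect_identical(predict_bnb(fits, TRUE, tie_break = "non_pamt"),
                   "non_pamt")
})

test_that("predictions agree with an off-the-shelf Bernoulli NB on random instances", {
  skip_if_not_installed("e1071")
  withr::with_seed(2024, {
    for (trial in 1:8) {
      k <- sample(2:5, 1)
      n <- sample(10:24, 1)
      X <- matrix(runif(n * k) < runif(1, 0.3, 0.7), n, k,
                  dimnames = list(NULL, paste0("t", seq_len(k))))
      y <- sample(c("pamt", "non_pamt"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      fit <- fit_bnb(X, y, alpha = 1)
      df <- as.data.frame(lapply(as.data.frame(X),
                                 function(col) factor(as.integer(col),
                                                      levels = c(0, 1))))
      ref <- e1071::naiveBayes(df, factor(y, levels = c("pamt", "non_pamt")),
                               laplace = 1)
      Xn <- matrix(runif(30 * k) < 0.5, 30, k,
                   dimnames = list(NULL, colnames(X)))
      dfn <- as.data.frame(lapply(as.data.frame(Xn),
                                  function(col) factor(as.integer(col),
                                                       levels = c(0, 1))))
      raw <- predict(ref, dfn, type = "raw")
      lp <- bnb_log_posterior(fit, Xn)
      post <- exp(lp - apply(lp, 1, max))
      post <- post / rowSums(post)
      expect_equal(unname(post[, "pamt"]), unname(raw[, "pamt"]),
                   tolerance = 1e-10)
      # compare hard labels away from numerical ties
      clear <- abs(raw[, "pamt"] - 0.5) > 1e-9
      expect_identical(unname(predict_bnb(fit, Xn))[clear],
                       as.character(predict(ref, dfn))[clear])
    }
  })
})

test_that("the rule gate counts distinct keywords against its threshold", {
  gate <- rule_gate(c("bleeding", "unconscious", "trapped"), m = 2)
  expect_identical(apply_gate(c("x", "bleeding", "unconscious"), gate),
                   "fire_positive")
  expect_identical(apply_gate(rep("bleeding", 5), gate), "defer")
  expect_identical(apply_gate(c("calm", "fine"), gate), "defer")
  occ <- rule_gate(c("bleeding", "unconscious"), m = 2,
                   count_mode = "token_occurrences")
  expect_identical(apply_gate(rep("bleeding", 5), occ), "fire_positive")
  expect_error(rule_gate(character(0)), "non-empty")
})

test_that("lowering the gate threshold never loses a firing document", {
  kw <- c("k1", "k2", "k3", "k4")
  withr::with_seed(7, {
    docs <- lapply(1:50, function(i) {
      sample(c(kw, paste0("b", 1:10)), sample(1:12, 1), replace = TRUE)
    })
    g1 <- rule_gate(kw, m = 1)
    g2 <- rule_gate(kw, m = 2)
    fired1 <- vapply(docs, function(d) apply_gate(d, g1), character(1))
    fired2 <- vapply(docs, function(d) apply_gate(d, g2), character(1))
    expect_true(all(fired1[fired2 == "fire_positive"] == "fire_positive"))
  })
})

test_that("variants wire the gate and classifier per their definitions", {
  crp <- generate_corpus(generator_config(n_cases = 40, n_positive = 15,
                                          seed = 3))$corpus
  lex <- lexicon(expert_keywords = default_severity_keywords()$keyword)
  gate_doc <- transcript("g", tokens = c("bleeding", "unconscious", "w0009"))
  quiet_doc <- transcript("q", tokens = c("w0001", "w0002"))

  a <- fit_variant("A", crp, lex, k = 30)
  expect_null(a$fitted)
  expect_identical(unname(predict(a, gate_doc)), "pamt")
  expect_identical(unname(predict(a, quiet_doc)), "non_pamt")  # no fallback

  b <- fit_variant("B", crp, lex, k = 30)
  expect_null(b$gate)
  expect_false(any(c("expert", "both") %in% b$feature_space$origin))

  p <- fit_variant("PAMT", crp, lex, k = 30)
  # gate precedes BNB: a firing doc is positive regardless of the classifier
  expect_identical(unname(predict(p, gate_doc)), "pamt")
  expect_identical(unname(predict_variant(p$variant, gate_doc,
                                          fs = p$feature_space,
                                          fitted = p$fitted, gate = p$gate)),
                   "pamt")
  # B ignores any gate: supplying one must not change predictions
  expect_identical(
    predict_variant(model_variant("B"), quiet_doc, fs = b$feature_space,
                    fitted = b$fitted),
    predict_variant(model_variant("B"), quiet_doc, fs = b$feature_space,
                    fitted = b$fitted, gate = p$gate))
  expect_error(predict_variant(model_variant("PAMT"), gate_doc), "requires")
})

test_that("serialized models reload to bit-identical predictions", {
  sim <- generate_corpus(generator_config(n_cases = 60, n_positive = 22,
                                          seed = 13))
  crp <- sim$corpus
  lex <- lexicon(expert_keywords = sim$ground_truth$expert_keywords)
  model <- fit_variant("PAMT", crp, lex, k = 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$feature_space$terms, model$feature_space$terms)
  expect_identical(back$fitted$term_cond_prob, model$fitted$term_cond_prob)
  expect_identical(predict(back, crp), predict(model, crp))
})
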