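# Shared fixtures: tiny corpora built in code, plus an independent
# brute-force Bernoulli joint-probability oracle used to cross-check the
# classifier.

toy_corpus <- function() {
  corpus(list(
    transcript("d1", tokens = c("a", "a", "b"), label = "pamt"),
    transcript("d2", tokens = c("b", "c"), label = "non_pamt"),
    transcript("d3", tokens = c("c", "c", "c"), label = "non_pamt")
  ))
}

random_labeled_corpus <- function(n = 20, vocab = letters[1:6], seed = 1) {
  withr::with_seed(seed, {
    corpus(lapply(seq_len(n), function(i) {
      transcript(sprintf("r%03d", i),
                 tokens = sample(vocab, sample(2:8, 1), replace = TRUE),
                 label = sample(c("pamt", "non_pamt"), 1))
    }))
  })
}

# Brute-force Bernoulli naive Bayes: explicit product of Bernoulli terms
# and the class prior, no logs, no vectorization. Independent of the
# package's fitting path except for the smoothing definition itself.
brute_force_bnb <- function(X_train, y_train, x_new, alpha = 1) {
  classes <- c("pamt", "non_pamt")
  joint <- vapply(classes, function(k) {
    rows <- X_train[y_train == k, , drop = FALSE]
    prior <- nrow(rows) / nrow(X_train)
    p <- 1
    for (j in seq_len(ncol(X_train))) {
      cond <- (sum(rows[, j]) + alpha) / (nrow(rows) + 2 * alpha)
      p <- p * (if (x_new[j]) cond else 1 - cond)
    }
    prior * p
  }, numeric(1))
  list(posterior = joint / sum(joint),
       label = if (joint["pamt"] >= joint["non_pamt"]) "pamt" else "non_pamt")
}
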