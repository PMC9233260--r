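# Synthetic emergency-call corpus generator: class-conditional keyword
# model over a Zipf background vocabulary, simulated rater certainty
# votes, and the analytic Bayes-accuracy oracle implied by the model.

#' Default severity-keyword model
#'
#' Twelve severity keywords with class-conditional occurrence
#' probabilities: `p_pos` in PAMT calls, `p_neg` in non-PAMT calls,
#' always `p_pos > p_neg` so keyword presence carries the class signal.
#'
#' @return Data.frame with columns `keyword`, `p_pos`, `p_neg`.
#' @export
default_severity_keywords <- function() {
  data.frame(
    keyword = c("unconscious", "unresponsive", "bleeding", "headwound",
                "trapped", "pinned", "rollover", "highspeed", "fracture",
                "motorcycle", "pale", "vomiting"),
    p_pos = c(0.55, 0.50, 0.60, 0.40, 0.35, 0.25, 0.30, 0.35, 0.45,
              0.45, 0.35, 0.30),
    p_neg = c(0.10, 0.07, 0.20, 0.08, 0.05, 0.04, 0.06, 0.08, 0.15,
              0.22, 0.12, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the study corpus the pipeline was designed for:
#' 114 calls of which 42 are PAMT, a background vocabulary of ~7000
#' word meanings with a Zipf-like frequency profile, short documents
#' whose rendered character lengths land near mean 241 (SD ~107), and a
#' small severity-keyword set occurring more often in positive calls.
#'
#' @param n_cases Corpus size (default 114).
#' @param n_positive Number of PAMT cases (default 42); class balance is
#'   exact, not stochastic.
#' @param background_vocab_size Background vocabulary size (default 7000).
#' @param zipf_exponent Zipf exponent s of the background frequency
#'   profile p(rank) proportional to rank^-s (default 1.1).
#' @param severity_keywords Data.frame as [default_severity_keywords()].
#' @param doc_length_mean,doc_length_sd Mean/SD of the background token
#'   count per document (truncated normal, minimum `doc_length_min`).
#'   Defaults 30 and 17 tokens: with ~5-character background words plus
#'   separators, and keyword mentions on top, this renders to roughly
#'   the target character lengths (mean ~241, SD ~107).
#' @param doc_length_min Minimum tokens per document (default 5).
#' @param n_expert_keywords Size of the expert list handed to the rule
#'   gate (default 37): the covered severity keywords padded with
#'   high-frequency background words.
#' @param expert_overlap_fraction Fraction of severity keywords included
#'   in the expert list (default 1).
#' @param keyword_repeat_lambda When a severity keyword is present in a
#'   call it is mentioned 1 + Poisson(lambda) times (default 1.5),
#'   mimicking how important words are repeated in short urgent calls;
#'   repetition is what lets frequency-based (TF-IDF) ranking find them.
#'   Presence/absence -- all the Bernoulli classifier sees -- is
#'   unaffected.
#' @param keyword_correlation Pairwise co-occurrence boost in \[0, 1):
#'   with this probability each even-indexed keyword copies the presence
#'   flag of its predecessor instead of drawing independently (default 0,
#'   i.e. conditionally independent keywords -- the Bernoulli naive Bayes
#'   assumption).
#' @param certainty_noise Probability a simulated rater's vote is random
#'   rather than driven by keyword count (default 0.1).
#' @param seed RNG seed for all generator randomness.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cases = 114, n_positive = 42,
                             background_vocab_size = 7000,
                             zipf_exponent = 1.1,
                             severity_keywords = default_severity_keywords(),
                             doc_length_mean = 30, doc_length_sd = 17,
                             doc_length_min = 5,
                             n_expert_keywords = 37,
                             expert_overlap_fraction = 1,
                             keyword_repeat_lambda = 1.5,
                             keyword_correlation = 0,
                             certainty_noise = 0.1,
                             seed = 1L) {
  stopifnot(n_positive <= n_cases, n_positive >= 1,
            background_vocab_size >= 1, doc_length_min >= 1,
            doc_length_mean >= doc_length_min,
            keyword_repeat_lambda >= 0,
            keyword_correlation >= 0, keyword_correlation < 1,
            certainty_noise >= 0, certainty_noise <= 1,
            expert_overlap_fraction >= 0, expert_overlap_fraction <= 1)
  kw <- severity_keywords
  if (!all(c("keyword", "p_pos", "p_neg") %in% names(kw))) {
    stop("severity_keywords needs columns keyword, p_pos, p_neg",
         call. = FALSE)
  }
  if (!all(kw$p_pos > kw$p_neg) || any(kw$p_neg < 0) || any(kw$p_pos > 1)) {
    stop("keyword probabilities must satisfy 0 <= p_neg < p_pos <= 1",
         call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_positive = as.integer(n_positive),
         background_vocab_size = as.integer(background_vocab_size),
         zipf_exponent = zipf_exponent, severity_keywords = kw,
         doc_length_mean = doc_length_mean, doc_length_sd = doc_length_sd,
         doc_length_min = as.integer(doc_length_min),
         n_expert_keywords = as.integer(n_expert_keywords),
         expert_overlap_fraction = expert_overlap_fraction,
         keyword_repeat_lambda = keyword_repeat_lambda,
         keyword_correlation = keyword_correlation,
         certainty_noise = certainty_noise, seed = as.integer(seed)),
    class = "generator_config"
  )
}

background_vocab <- function(cfg) {
  sprintf("w%04d", seq_len(cfg$background_vocab_size))
}

zipf_probs <- function(cfg) {
  w <- seq_len(cfg$background_vocab_size)^(-cfg$zipf_exponent)
  w / sum(w)
}

#' Expert keyword list implied by a generator config
#'
#' The first `expert_overlap_fraction` share of the severity keywords,
#' padded up to `n_expert_keywords` with rare background words (drawn
#' from deep Zipf ranks, starting at rank 501). Padding words carry no
#' class signal and essentially never trip the gate, emulating expert
#' suggestions that turn out not to be discriminative.
#'
#' @param cfg A `generator_config`.
#' @return Character vector of keywords.
#' @export
expert_keyword_list <- function(cfg) {
  kw <- cfg$severity_keywords$keyword
  n_overlap <- round(cfg$expert_overlap_fraction * length(kw))
  covered <- kw[seq_len(n_overlap)]
  n_pad <- max(0L, cfg$n_expert_keywords - length(covered))
  pad_start <- min(501L, cfg$background_vocab_size)
  pad <- background_vocab(cfg)[seq(pad_start, length.out = n_pad)]
  c(covered, pad[!is.na(pad)])
}

#' Generate a labeled synthetic call corpus
#'
#' Each document receives a background token count from a truncated
#' normal, background tokens drawn from the Zipf vocabulary, and each
#' severity keyword independently with its class-conditional probability
#' (inserted at a random position). Class counts are exact. The ground
#' truth sidecar records every generator probability so downstream
#' parameter-recovery checks can compare against it.
#'
#' @param cfg A `generator_config`.
#' @param as_text When TRUE, render each document to a character string
#'   (space-joined tokens) for end-to-end preprocessing tests; default
#'   emits token lists directly.
#' @return List with elements `corpus` (a [corpus()]) and `ground_truth`
#'   (list: config, keyword table, expert keyword list).
#' @export
generate_corpus <- function(cfg = generator_config(), as_text = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  kw <- cfg$severity_keywords
  vocab <- background_vocab(cfg)
  zp <- zipf_probs(cfg)
  n <- cfg$n_cases
  labels <- with_seed(cfg$seed, {
    sample(c(rep(POSITIVE, cfg$n_positive),
             rep(NEGATIVE, n - cfg$n_positive)))
  })
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("case_%0", width, "d"), seq_len(n))
  transcripts <- with_seed(cfg$seed + 1L, {
    lapply(seq_len(n), function(i) {
      len <- max(cfg$doc_length_min,
                 round(stats::rnorm(1, cfg$doc_length_mean, cfg$doc_length_sd)))
      toks <- sample(vocab, len, replace = TRUE, prob = zp)
      p <- if (labels[i] == POSITIVE) kw$p_pos else kw$p_neg
      present <- stats::runif(nrow(kw)) < p
      if (cfg$keyword_correlation > 0 && nrow(kw) >= 2) {
        for (j in seq(2, nrow(kw), by = 2)) {
          if (stats::runif(1) < cfg$keyword_correlation) {
            present[j] <- present[j - 1]
          }
        }
      }
      for (w in kw$keyword[present]) {
        reps <- 1L + stats::rpois(1, cfg$keyword_repeat_lambda)
        for (j in seq_len(reps)) {
          pos <- sample.int(length(toks) + 1L, 1L)
          toks <- append(toks, w, after = pos - 1L)
        }
      }
      if (as_text) {
        transcript(ids[i], text = paste(toks, collapse = " "),
                   label = labels[i])
      } else {
        transcript(ids[i], tokens = toks, label = labels[i])
      }
    })
  })
  gt <- list(config = cfg, keywords = kw,
             expert_keywords = expert_keyword_list(cfg))
  list(corpus = corpus(transcripts,
                       provenance = list(source = "synthetic",
                                         seed = cfg$seed)),
       ground_truth = gt)
}

#' Simulate rater certainty votes
#'
#' Six simulated raters each vote "certain" with probability increasing
#' in the document's distinct severity-keyword count k:
#' p = min(1, 0.1 + 0.18 k), so keyword-free calls are mostly uncertain
#' and calls with five or more keywords are unanimously certain. With
#' probability `certainty_noise` a vote is replaced by a fair coin flip.
#'
#' @param cfg A `generator_config`.
#' @param x A `corpus` from [generate_corpus()].
#' @return The corpus with `certainty_votes` filled in on every
#'   transcript.
#' @export
generate_certainty_votes <- function(cfg, x) {
  stopifnot(inherits(cfg, "generator_config"), inherits(x, "corpus"))
  kw <- cfg$severity_keywords$keyword
  x$transcripts <- with_seed(cfg$seed + 2L, {
    lapply(x$transcripts, function(t) {
      toks <- t$tokens %||% strsplit(t$text, "\\s+")[[1]]
      k <- length(intersect(kw, toks))
      p <- min(1, 0.1 + 0.18 * k)
      votes <- as.integer(stats::runif(6) < p)
      noisy <- stats::runif(6) < cfg$certainty_noise
      votes[noisy] <- as.integer(stats::runif(sum(noisy)) < 0.5)
      t$certainty_votes <- votes
      t
    })
  })
  x
}

#' Analytic Bayes-optimal accuracy of the generator's keyword model
#'
#' Background tokens are uninformative, so the Bayes classifier depends
#' only on the severity-keyword presence pattern x: predict PAMT iff
#' prior_pos * P(x|pos) >= prior_neg * P(x|neg) (ties to positive, the
#' package's triage convention). Expected accuracy under a validation
#' prior is sum over patterns of max(prior_pos P(x|pos),
#' prior_neg P(x|neg)), computed by exact enumeration for up to 20
#' keywords; beyond that exact mode refuses (2^K blow-up) and a
#' Monte-Carlo estimate is offered instead.
#'
#' @param cfg A `generator_config` (keyword correlation must be 0 for the
#'   independence factorization to hold).
#' @param prior_pos Positive-class prevalence at evaluation time
#'   (default 0.3, the 3:7 validation composition).
#' @param mode `"exact"` (default, K <= 20) or `"monte_carlo"`.
#' @param mc_samples Samples for Monte-Carlo mode.
#' @return Expected accuracy of the Bayes-optimal classifier.
#' @export
bayes_optimal_accuracy <- function(cfg, prior_pos = 0.3,
                                   mode = c("exact", "monte_carlo"),
                                   mc_samples = 200000) {
  stopifnot(inherits(cfg, "generator_config"))
  mode <- match.arg(mode)
  if (cfg$keyword_correlation != 0) {
    stop("analytic oracle requires keyword_correlation = 0", call. = FALSE)
  }
  kw <- cfg$severity_keywords
  K <- nrow(kw)
  prior_neg <- 1 - prior_pos
  lik <- function(x, p) prod(ifelse(x == 1, p, 1 - p))
  if (mode == "exact") {
    if (K > 20) {
      stop("exact enumeration refused for K = ", K,
           " > 20 keywords; use mode = 'monte_carlo'", call. = FALSE)
    }
    acc <- 0
    for (i in 0:(2^K - 1)) {
      x <- as.integer(intToBits(i)[seq_len(K)])
      acc <- acc + max(prior_pos * lik(x, kw$p_pos),
                       prior_neg * lik(x, kw$p_neg))
    }
    acc
  } else {
    with_seed(cfg$seed + 3L, {
      cls <- stats::runif(mc_samples) < prior_pos
      correct <- vapply(seq_len(mc_samples), function(i) {
        p <- if (cls[i]) kw$p_pos else kw$p_neg
        x <- as.integer(stats::runif(K) < p)
        pred_pos <- prior_pos * lik(x, kw$p_pos) >=
          prior_neg * lik(x, kw$p_neg)
        pred_pos == cls[i]
      }, logical(1))
      mean(correct)
    })
  }
}

#' Write the generator ground truth sidecar as JSON
#'
#' @param gt The `ground_truth` element of [generate_corpus()] output.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  cfg <- gt$config
  obj <- list(
    config = list(
      n_cases = cfg$n_cases, n_positive = cfg$n_positive,
      background_vocab_size = cfg$background_vocab_size,
      zipf_exponent = cfg$zipf_exponent,
      doc_length_mean = cfg$doc_length_mean,
      doc_length_sd = cfg$doc_length_sd,
      doc_length_min = cfg$doc_length_min,
      n_expert_keywords = cfg$n_expert_keywords,
      expert_overlap_fraction = cfg$expert_overlap_fraction,
      keyword_repeat_lambda = cfg$keyword_repeat_lambda,
      keyword_correlation = cfg$keyword_correlation,
      certainty_noise = cfg$certainty_noise, seed = cfg$seed
    ),
    keywords = gt$keywords,
    expert_keywords = gt$expert_keywords
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
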