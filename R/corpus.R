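# Corpus containers and step-1 text preprocessing: word segmentation,
# stop-word removal, synonym grouping.

#' Construct a transcript
#'
#' A transcript is one emergency call: an identifier, the raw text as
#' transcribed, an optional token sequence (filled in by [preprocess()]),
#' a binary severity label, and optionally the six per-rater certainty
#' votes collected alongside the human judgments.
#'
#' @param id Unique identifier (character scalar).
#' @param text Raw transcript text. May be `NA` if `tokens` are supplied
#'   directly (e.g. by the synthetic generator).
#' @param tokens Character vector of tokens, or `NULL` before preprocessing.
#' @param label `"pamt"`, `"non_pamt"`, or `NA` for unlabeled.
#' @param certainty_votes Integer vector of exactly 6 zero/one flags
#'   (certain = 1), or `NULL`.
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, text = NA_character_, tokens = NULL,
                       label = NA_character_, certainty_votes = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("transcript 'id' must be a non-empty character scalar", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c("pamt", "non_pamt")) {
    stop("label must be 'pamt', 'non_pamt' or NA, got: ", label, call. = FALSE)
  }
  if (!is.null(certainty_votes)) {
    certainty_votes <- as.integer(certainty_votes)
    if (length(certainty_votes) != 6L || anyNA(certainty_votes) ||
        !all(certainty_votes %in% c(0L, 1L))) {
      stop("certainty_votes must be exactly 6 binary flags", call. = FALSE)
    }
  }
  structure(
    list(id = id, text = text, tokens = tokens, label = label,
         certainty_votes = certainty_votes),
    class = "transcript"
  )
}

#' Construct a corpus of transcripts
#'
#' @param transcripts List of [transcript()] objects.
#' @param provenance Free-text metadata (source, generator config, seed).
#' @return An object of class `corpus`. Transcript order is preserved;
#'   ids must be distinct.
#' @export
corpus <- function(transcripts, provenance = list()) {
  stopifnot(is.list(transcripts))
  ok <- vapply(transcripts, inherits, logical(1), "transcript")
  if (!all(ok)) stop("all elements must be transcript objects", call. = FALSE)
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(transcripts) <- ids
  structure(list(transcripts = transcripts, provenance = provenance),
            class = "corpus")
}

#' @export
length.corpus <- function(x) length(x$transcripts)

#' @export
print.corpus <- function(x, ...) {
  lab <- corpus_labels(x)
  cat(sprintf("<corpus> %d transcripts (%d pamt, %d non_pamt, %d unlabeled)\n",
              length(x), sum(lab == "pamt", na.rm = TRUE),
              sum(lab == "non_pamt", na.rm = TRUE), sum(is.na(lab))))
  invisible(x)
}

#' Transcript ids of a corpus
#' @param x A `corpus`.
#' @return Character vector of ids in corpus order.
#' @export
corpus_ids <- function(x) {
  unname(vapply(x$transcripts, `[[`, character(1), "id"))
}

#' Labels of a corpus
#' @param x A `corpus`.
#' @return Character vector (`"pamt"`/`"non_pamt"`/`NA`), named by id.
#' @export
corpus_labels <- function(x) {
  vapply(x$transcripts, function(t) t$label %||% NA_character_, character(1))
}

#' Token lists of a corpus
#' @param x A `corpus`.
#' @return Named list of character vectors (empty vector when untokenized).
#' @export
corpus_tokens <- function(x) {
  lapply(x$transcripts, function(t) t$tokens %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a corpus from disk
#'
#' Two dialects are supported. `jsonl` has one JSON object per line with
#' fields `id`, `text` and/or `tokens`, optional `label`
#' (`"pamt"`/`"non_pamt"`/null) and optional `certainty_votes` (6 flags).
#' `tsv` has three tab-separated columns: id, label, space-joined tokens
#' (label may be empty for unlabeled).
#'
#' @param path File path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return A `corpus`, preserving record order. Missing labels are unlabeled.
#' @export
load_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- switch(format,
      jsonl = parse_jsonl_record(lines[[i]], i),
      tsv   = parse_tsv_record(lines[[i]], i)
    )
  }
  corpus(recs, provenance = list(source = path, format = format))
}

parse_jsonl_record <- function(line, lineno) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e) {
    stop(sprintf("parse error at line %d: %s", lineno, conditionMessage(e)),
         call. = FALSE)
  })
  if (is.null(obj$id)) {
    stop(sprintf("parse error at line %d: record missing 'id'", lineno),
         call. = FALSE)
  }
  if (is.null(obj$text) && is.null(obj$tokens)) {
    stop(sprintf("parse error at line %d: record needs 'text' or 'tokens'",
                 lineno), call. = FALSE)
  }
  transcript(
    id = as.character(obj$id),
    text = if (is.null(obj$text)) NA_character_ else as.character(obj$text),
    tokens = if (is.null(obj$tokens)) NULL else as.character(obj$tokens),
    label = if (is.null(obj$label) || is.na(obj$label)) NA_character_
            else as.character(obj$label),
    certainty_votes = obj$certainty_votes
  )
}

parse_tsv_record <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3L) {
    stop(sprintf("parse error at line %d: expected 3 tab-separated fields",
                 lineno), call. = FALSE)
  }
  toks <- strsplit(trimws(parts[3]), "\\s+")[[1]]
  transcript(
    id = parts[1],
    tokens = toks[nzchar(toks)],
    label = if (nzchar(parts[2])) parts[2] else NA_character_
  )
}

#' Write a corpus to disk
#'
#' Inverse of [load_corpus()]: `load_corpus(write_corpus(x, p), fmt)`
#' reproduces `x` field-for-field (the TSV dialect keeps only id, label
#' and tokens).
#'
#' @param x A `corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "corpus"))
  lines <- vapply(x$transcripts, function(t) {
    if (format == "jsonl") {
      rec <- list(id = t$id)
      if (!is.na(t$text %||% NA_character_)) rec$text <- t$text
      if (!is.null(t$tokens)) rec$tokens <- I(t$tokens)
      rec$label <- if (is.na(t$label)) NULL else t$label
      if (!is.null(t$certainty_votes)) rec$certainty_votes <- I(t$certainty_votes)
      jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
    } else {
      paste(t$id, if (is.na(t$label)) "" else t$label,
            paste(t$tokens %||% character(0), collapse = " "), sep = "\t")
    }
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a lexicon
#'
#' Bundles the four resources used in preprocessing and gating: the
#' segmentation dictionary (multi-word terms forced to merge, with
#' positive weights), the stop-word set, the single-step synonym map,
#' and the expert keyword list (nominally 37 words) used by the rule gate.
#'
#' @param seg_dict Named numeric vector: term -> positive weight. Terms may
#'   contain spaces; the default tokenizer merges adjacent units that form
#'   a dictionary term.
#' @param stopwords Character vector.
#' @param synonyms Named character vector: variant -> canonical. Must be
#'   single-step: no canonical value may itself appear as a variant key.
#' @param expert_keywords Character vector (canonical forms).
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(seg_dict = numeric(0), stopwords = character(0),
                    synonyms = character(0), expert_keywords = character(0)) {
  if (length(seg_dict)) {
    if (is.null(names(seg_dict)) || any(!nzchar(names(seg_dict)))) {
      stop("seg_dict must be a named numeric vector", call. = FALSE)
    }
    if (any(seg_dict <= 0)) stop("seg_dict weights must be > 0", call. = FALSE)
  }
  if (length(synonyms)) {
    if (is.null(names(synonyms))) {
      stop("synonyms must be a named character vector (variant -> canonical)",
           call. = FALSE)
    }
    chained <- intersect(unname(synonyms), names(synonyms))
    if (length(chained)) {
      stop("synonym map contains chain(s) via: ",
           paste(unique(chained), collapse = ", "),
           " (canonical terms must not appear as variant keys)", call. = FALSE)
    }
  }
  structure(
    list(seg_dict = seg_dict, stopwords = unique(stopwords),
         synonyms = synonyms, expert_keywords = unique(expert_keywords)),
    class = "lexicon"
  )
}

#' Read lexicon resources from plain-text files
#'
#' Any component may be omitted. Stop words and expert keywords are one
#' term per line; the segmentation dictionary is 2-column TSV
#' `term<TAB>weight`; synonyms are 2-column TSV `variant<TAB>canonical`.
#' All files are UTF-8.
#'
#' @param seg_dict_path,stopwords_path,synonyms_path,expert_keywords_path
#'   File paths or `NULL`.
#' @return A `lexicon`.
#' @export
load_lexicon <- function(seg_dict_path = NULL, stopwords_path = NULL,
                         synonyms_path = NULL, expert_keywords_path = NULL) {
  read_lines <- function(p) {
    x <- readLines(p, encoding = "UTF-8", warn = FALSE)
    x[nzchar(trimws(x))]
  }
  seg_dict <- numeric(0)
  if (!is.null(seg_dict_path)) {
    rows <- strsplit(read_lines(seg_dict_path), "\t", fixed = TRUE)
    seg_dict <- stats::setNames(
      vapply(rows, function(r) as.numeric(r[2]), numeric(1)),
      vapply(rows, `[`, character(1), 1)
    )
  }
  synonyms <- character(0)
  if (!is.null(synonyms_path)) {
    rows <- strsplit(read_lines(synonyms_path), "\t", fixed = TRUE)
    synonyms <- stats::setNames(
      vapply(rows, `[`, character(1), 2),
      vapply(rows, `[`, character(1), 1)
    )
  }
  lexicon(
    seg_dict = seg_dict,
    stopwords = if (is.null(stopwords_path)) character(0)
                else read_lines(stopwords_path),
    synonyms = synonyms,
    expert_keywords = if (is.null(expert_keywords_path)) character(0)
                      else read_lines(expert_keywords_path)
  )
}

#' Segment raw text into tokens
#'
#' The default tokenizer case-folds, splits on whitespace, then greedily
#' merges adjacent units (longest match first) whenever the joined string
#' is a segmentation-dictionary term. Dictionary presence forces a merge;
#' weight magnitude is not otherwise interpreted. A custom tokenizer
#' (any deterministic function: string in, character vector out) may be
#' plugged in instead, e.g. a Mandarin segmenter for real call text.
#'
#' @param raw_text Character scalar (may be empty).
#' @param seg_dict Named numeric vector of merge terms, as in [lexicon()].
#' @param tokenizer Optional replacement tokenizer; when supplied it
#'   receives `raw_text` and its output is returned as-is.
#' @return Character vector of tokens (empty for empty input).
#' @export
segment <- function(raw_text, seg_dict = numeric(0), tokenizer = NULL) {
  if (is.null(raw_text) || is.na(raw_text)) {
    stop("raw_text must be a non-null string", call. = FALSE)
  }
  if (!is.null(tokenizer)) return(as.character(tokenizer(raw_text)))
  units <- strsplit(tolower(trimws(raw_text)), "\\s+")[[1]]
  units <- units[nzchar(units)]
  if (!length(units) || !length(seg_dict)) return(units)
  dict_terms <- tolower(names(seg_dict))
  # longest dictionary term caps the merge window
  max_span <- max(lengths(strsplit(dict_terms, " ", fixed = TRUE)))
  out <- character(0)
  i <- 1L
  n <- length(units)
  while (i <= n) {
    matched <- FALSE
    top <- min(max_span, n - i + 1L)
    for (span in (if (top >= 2L) seq(top, 2L) else integer(0))) {
      cand <- paste(units[i:(i + span - 1L)], collapse = " ")
      if (cand %in% dict_terms) {
        out <- c(out, cand)
        i <- i + span
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      out <- c(out, units[i])
      i <- i + 1L
    }
  }
  out
}

#' Remove stop words from a token list
#'
#' Order-preserving filter: every token found in the stop-word set is
#' dropped, everything else passes through unchanged.
#'
#' @param tokens Character vector.
#' @param stopwords Character vector (set semantics).
#' @return Filtered character vector.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!tokens %in% stopwords]
}

#' Map synonyms to canonical forms
#'
#' Each token that appears as a variant key is replaced by its canonical
#' form, exactly once -- there is no transitive chaining, which the
#' [lexicon()] constructor enforces by rejecting chained maps.
#'
#' @param tokens Character vector.
#' @param synonyms Named character vector: variant -> canonical.
#' @return Character vector of the same length.
#' @export
map_synonyms <- function(tokens, synonyms) {
  if (!length(synonyms) || !length(tokens)) return(tokens)
  hit <- tokens %in% names(synonyms)
  tokens[hit] <- unname(synonyms[tokens[hit]])
  tokens
}

#' Preprocess a transcript
#'
#' Step-1 composition: segmentation, then stop-word removal, then synonym
#' grouping. With an empty lexicon this reduces to a case-folded
#' whitespace split. Transcripts that already carry tokens and no raw
#' text (token-level synthetic data) keep their tokens but still pass
#' through stop-word removal and synonym grouping.
#'
#' @param t A `transcript`.
#' @param lex A `lexicon`.
#' @param tokenizer Optional tokenizer override, see [segment()].
#' @return The transcript with `tokens` filled in.
#' @export
preprocess <- function(t, lex = lexicon(), tokenizer = NULL) {
  stopifnot(inherits(t, "transcript"), inherits(lex, "lexicon"))
  toks <- if (!is.na(t$text %||% NA_character_)) {
    segment(t$text, lex$seg_dict, tokenizer)
  } else if (!is.null(t$tokens)) {
    t$tokens
  } else {
    stop("transcript '", t$id, "' has neither text nor tokens", call. = FALSE)
  }
  t$tokens <- map_synonyms(remove_stopwords(toks, lex$stopwords), lex$synonyms)
  t
}

#' Preprocess every transcript in a corpus
#'
#' @param x A `corpus`.
#' @param lex A `lexicon`.
#' @param tokenizer Optional tokenizer override.
#' @return The corpus with all transcripts tokenized.
#' @export
preprocess_corpus <- function(x, lex = lexicon(), tokenizer = NULL) {
  stopifnot(inherits(x, "corpus"))
  x$transcripts <- lapply(x$transcripts, preprocess, lex = lex,
                          tokenizer = tokenizer)
  x
}
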