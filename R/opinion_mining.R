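#' Mining configuration
#'
#' @param threshold minimum support: the fraction of corpus sentences that
#'   must contain a noun phrase for it to count as a frequent feature.
#'   Must lie in (0, 1].
#' @param max_adjective_distance maximum token distance from a feature span
#'   to its opinion adjective; \code{Inf} (default) places no limit.
#' @return an object of class \code{mining_config}.
#' @export
mining_config <- function(threshold = 0.1, max_adjective_distance = Inf) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1,
            is.numeric(max_adjective_distance), max_adjective_distance > 0)
  structure(list(threshold = threshold,
                 max_adjective_distance = max_adjective_distance),
            class = "mining_config")
}

.check_corpus <- function(corpus) {
  if (!is.list(corpus) || !length(corpus) ||
      !all(vapply(corpus, inherits, logical(1), "tagged_document"))) {
    stop("corpus must be a non-empty list of tagged_document", call. = FALSE)
  }
  n_sent <- sum(vapply(corpus, function(d) length(d$sentences), integer(1)))
  if (n_sent == 0L) stop("corpus has zero sentences", call. = FALSE)
  invisible(n_sent)
}

# Maximal runs of consecutive NOUN tokens in one sentence.
# Returns list of list(phrase = lower-cased space-joined, start, end).
.noun_runs <- function(sentence) {
  is_noun <- sentence$pos == "NOUN"
  if (!any(is_noun)) return(list())
  r <- rle(is_noun)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(j) {
    list(phrase = paste(tolower(sentence$surface[starts[j]:ends[j]]),
                        collapse = " "),
         start = starts[j], end = ends[j])
  })
}

# Does run phrase `hay` contain `needle` as a contiguous token subsequence?
.phrase_contains <- function(hay, needle) {
  h <- strsplit(hay, " ", fixed = TRUE)[[1L]]
  n <- strsplit(needle, " ", fixed = TRUE)[[1L]]
  if (length(n) > length(h)) return(FALSE)
  for (s in seq_len(length(h) - length(n) + 1L)) {
    if (identical(h[s:(s + length(n) - 1L)], n)) return(TRUE)
  }
  FALSE
}

#' Extract candidate features (nouns and noun phrases) with support
#'
#' Noun phrases are maximal runs of consecutive noun-tagged tokens. Each
#' distinct phrase becomes one candidate; its support is the fraction of
#' corpus sentences whose noun runs contain the phrase as a contiguous
#' token subsequence (so a head noun occurring alone and inside a longer
#' phrase is supported by both kinds of sentence).
#'
#' @param corpus non-empty list of \code{\link{tagged_document}}.
#' @return data.frame with columns \code{phrase}, \code{support},
#'   \code{n_sentences} and a list-column \code{sentence_ids} of
#'   \code{"doc_id#index"} keys.
#' @export
extract_candidates <- function(corpus) {
  total <- .check_corpus(corpus)
  phrase_sent <- list()  # phrase -> character vector of sentence keys
  for (doc in corpus) {
    for (si in seq_along(doc$sentences)) {
      key <- paste0(doc$doc_id, "#", si)
      runs <- .noun_runs(doc$sentences[[si]])
      if (!length(runs)) next
      run_phrases <- vapply(runs, `[[`, character(1), "phrase")
      for (p in unique(run_phrases)) {
        phrase_sent[[p]] <- c(phrase_sent[[p]], key)
      }
    }
  }
  phrases <- names(phrase_sent)
  if (!length(phrases)) {
    return(data.frame(phrase = character(0), support = numeric(0),
                      n_sentences = integer(0)))
  }
  # containment pass: credit each phrase with sentences whose (longer) runs
  # contain it
  sent_ids <- lapply(phrases, function(p) {
    hits <- unlist(lapply(phrases, function(q) {
      if (identical(p, q) || .phrase_contains(q, p)) phrase_sent[[q]]
    }), use.names = FALSE)
    sort(unique(hits))
  })
  out <- data.frame(phrase = phrases,
                    support = vapply(sent_ids, length, integer(1)) / total,
                    n_sentences = vapply(sent_ids, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$sentence_ids <- sent_ids
  out[order(-out$support, out$phrase), , drop = FALSE]
}

#' Filter candidates down to frequent features
#'
#' Keeps exactly the candidates whose support meets the minimum-support
#' threshold, sorted by descending support then lexicographically.
#'
#' @param candidates data.frame from \code{\link{extract_candidates}}.
#' @param config a \code{\link{mining_config}}.
#' @return the filtered, sorted data.frame.
#' @export
find_frequent_features <- function(candidates, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  keep <- candidates$support >= config$threshold
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(-out$support, out$phrase), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Locate occurrences of a feature phrase (token vector) inside one
# sentence's noun runs; returns list of c(start, end) spans.
.feature_spans <- function(sentence, feature) {
  ftoks <- strsplit(feature, " ", fixed = TRUE)[[1L]]
  spans <- list()
  for (run in .noun_runs(sentence)) {
    rtoks <- tolower(sentence$surface[run$start:run$end])
    if (length(ftoks) > length(rtoks)) next
    for (s in seq_len(length(rtoks) - length(ftoks) + 1L)) {
      if (identical(rtoks[s:(s + length(ftoks) - 1L)], ftoks)) {
        spans[[length(spans) + 1L]] <-
          c(run$start + s - 1L, run$start + s + length(ftoks) - 2L)
      }
    }
  }
  spans
}

#' Pair each frequent feature with the closest adjective per sentence
#'
#' For every sentence that contains a frequent feature, the adjective with
#' the smallest token distance to the feature span (measured from the
#' nearest span edge) becomes the feature's opinion word in that sentence.
#' Ties are broken toward the adjective preceding the feature (the English
#' premodifier convention). Sentences with no adjective, or whose nearest
#' adjective is farther than \code{max_adjective_distance}, contribute
#' nothing.
#'
#' @param corpus list of \code{\link{tagged_document}}.
#' @param features frequent features from \code{\link{find_frequent_features}}.
#' @param config a \code{\link{mining_config}}.
#' @return data.frame with columns \code{feature}, \code{opinion_word},
#'   \code{doc_id}, \code{sentence_index}, \code{distance}.
#' @export
extract_opinion_words <- function(corpus, features,
                                  config = mining_config()) {
  .check_corpus(corpus)
  rows <- list()
  for (doc in corpus) {
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      adj_idx <- which(sent$pos == "ADJ")
      if (!length(adj_idx)) next
      for (feat in features$phrase) {
        spans <- .feature_spans(sent, feat)
        if (!length(spans)) next
        best <- NULL
        for (span in spans) {
          d <- ifelse(adj_idx < span[1L], span[1L] - adj_idx,
               ifelse(adj_idx > span[2L], adj_idx - span[2L], 0L))
          preceding <- adj_idx < span[1L]
          for (j in seq_along(adj_idx)) {
            cand <- list(idx = adj_idx[j], d = d[j], pre = preceding[j])
            if (is.null(best) || cand$d < best$d ||
                (cand$d == best$d && cand$pre && !best$pre)) {
              best <- cand
            }
          }
        }
        if (best$d <= config$max_adjective_distance) {
          rows[[length(rows) + 1L]] <- data.frame(
            feature = feat,
            opinion_word = tolower(sent$surface[best$idx]),
            doc_id = doc$doc_id, sentence_index = si,
            distance = best$d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(feature = character(0), opinion_word = character(0),
                      doc_id = character(0), sentence_index = integer(0),
                      distance = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Propagate seed polarities to mined opinion words
#'
#' Iterative seed-list expansion: every sweep resolves each still-unknown
#' opinion word through \code{\link{lookup_polarity}} (seeded synonyms
#' first, then antonyms with flipped polarity) and adds resolved words to
#' the seed list; sweeps repeat until a full pass adds no word. Words that
#' never resolve are recorded as invalid and yield no opinion.
#'
#' @param pairs data.frame from \code{\link{extract_opinion_words}}.
#' @param seeds a \code{\link{seed_lexicon}} (non-empty).
#' @param hood a \code{\link{lexicon_neighborhood}}.
#' @return a list with \code{opinions} (an \code{opinion_set}) and
#'   \code{seeds} (the expanded seed lexicon).
#' @export
propagate_polarity <- function(pairs, seeds, hood) {
  stopifnot(inherits(seeds, "seed_lexicon"), length(seeds$entries) > 0L)
  words <- sort(unique(.normalize_word(pairs$opinion_word)))
  unresolved <- setdiff(words, names(seeds$entries))
  repeat {
    added <- FALSE
    for (w in unresolved) {
      p <- lookup_polarity(w, seeds, hood)
      if (!is.na(p)) {
        seeds <- add_seed(seeds, w, p)
        added <- TRUE
      }
    }
    unresolved <- setdiff(unresolved, names(seeds$entries))
    if (!added || !length(unresolved)) break
  }
  resolved <- pairs[.normalize_word(pairs$opinion_word) %in%
                      names(seeds$entries), , drop = FALSE]
  if (nrow(resolved)) {
    resolved$polarity <- unname(
      seeds$entries[.normalize_word(resolved$opinion_word)])
  } else {
    resolved$polarity <- character(0)
  }
  rownames(resolved) <- NULL
  ops <- structure(list(opinions = resolved, invalid_words = unresolved),
                   class = "opinion_set")
  list(opinions = ops, seeds = seeds)
}

#' @export
print.opinion_set <- function(x, ...) {
  cat(sprintf("<opinion_set> %d opinion(s), %d invalid word(s)\n",
              nrow(x$opinions), length(x$invalid_words)))
  if (nrow(x$opinions)) {
    print(utils::head(x$opinions[, c("feature", "opinion_word", "polarity",
                                     "doc_id", "sentence_index")], 10L))
    if (nrow(x$opinions) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
summary.opinion_set <- function(object, ...) {
  ops <- object$opinions
  cat(sprintf("Opinions: %d over %d feature(s); invalid words: %d\n",
              nrow(ops), length(unique(ops$feature)),
              length(object$invalid_words)))
  if (nrow(ops)) {
    print(table(feature = ops$feature, polarity = ops$polarity))
  }
  invisible(object)
}

#' Mine feature-level opinions from a tagged corpus
#'
#' The full opinion-mining pass: candidate noun phrases with support,
#' minimum-support filtering, closest-adjective pairing, and iterative
#' seed-list polarity propagation.
#'
#' @param corpus list of \code{\link{tagged_document}}.
#' @param seeds seed lexicon; defaults to the shipped 30-adjective list.
#' @param hood synonym/antonym neighbourhood; defaults to the shipped one.
#' @param config a \code{\link{mining_config}}.
#' @return an \code{opinion_set}; attributes \code{frequent_features}
#'   (the feature table) and \code{expanded_seeds} (seed lexicon after
#'   propagation) carry the intermediate results.
#' @examples
#' fx <- worked_example_fixture()
#' theta <- mine_opinions(list(fx$document))
#' theta$opinions[, c("feature", "opinion_word", "polarity")]
#' @export
mine_opinions <- function(corpus, seeds = NULL, hood = NULL,
                          config = mining_config()) {
  if (is.null(seeds) || is.null(hood)) {
    lex <- default_lexicon()
    if (is.null(seeds)) seeds <- lex$seeds
    if (is.null(hood)) hood <- lex$neighborhood
  }
  cand <- extract_candidates(corpus)
  freq <- find_frequent_features(cand, config)
  pairs <- extract_opinion_words(corpus, freq, config)
  res <- propagate_polarity(pairs, seeds, hood)
  out <- res$opinions
  attr(out, "frequent_features") <- freq
  attr(out, "expanded_seeds") <- res$seeds
  out
}

.NEGATORS <- c("not", "no", "never", "n't", "without")

#' Score a whole sentence's polarity by seed-lexicon vote
#'
#' Counts tokens seeded positive versus negative; the majority wins and a
#' tie (or no seeded token) is neutral. This transparent lexicon vote
#' replaces pretrained sentence-sentiment models so results are exactly
#' reproducible. With \code{negation = TRUE}, a negator token within three
#' tokens before a seeded word flips that word's vote; the extension is off
#' by default.
#'
#' @param sentence one sentence (data.frame of \code{surface}, \code{pos}).
#' @param seeds a \code{\link{seed_lexicon}}.
#' @param negation flip votes after nearby negators?
#' @return a polarity string.
#' @export
score_sentence <- function(sentence, seeds, negation = FALSE) {
  sentence <- .as_sentence(sentence)
  low <- tolower(sentence$surface)
  votes <- character(0)
  for (i in seq_along(low)) {
    p <- seeds$entries[low[[i]]]
    if (is.na(p)) next
    p <- unname(p)
    if (negation) {
      window <- low[max(1L, i - 3L):max(1L, i - 1L)]
      if (i > 1L && any(window %in% .NEGATORS)) p <- opposite_polarity(p)
    }
    votes <- c(votes, p)
  }
  if (!length(votes)) return("neutral")
  .majority_polarity(votes)
}

#' Write / read the mined opinion table as TSV
#'
#' Columns: doc_id, sentence_index, feature, opinion_word, polarity.
#'
#' @param opinions an \code{opinion_set}.
#' @param path output path.
#' @return \code{path} invisibly (write); data.frame (read).
#' @export
write_opinions_tsv <- function(opinions, path) {
  df <- opinions$opinions[, c("doc_id", "sentence_index", "feature",
                              "opinion_word", "polarity")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_opinions_tsv
#' @export
read_opinions_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(sentence_index = "integer"))
}
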