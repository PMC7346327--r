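#' Coarse part-of-speech tagset
#'
#' The pipeline only distinguishes nouns (opinion targets), adjectives
#' (opinion words) and everything else, so tokens carry one of the coarse
#' tags \code{"NOUN"}, \code{"ADJ"}, \code{"OTHER"}.
#'
#' @format character vector of the three tags.
#' @export
COARSE_TAGS <- c("NOUN", "ADJ", "OTHER")

.as_sentence <- function(s, where = "sentence") {
  if (is.data.frame(s)) {
    stopifnot(all(c("surface", "pos") %in% names(s)))
    s <- data.frame(surface = as.character(s$surface),
                    pos = as.character(s$pos), stringsAsFactors = FALSE)
  } else if (is.list(s)) {
    s <- data.frame(
      surface = vapply(s, function(t) as.character(t$surface), character(1)),
      pos = vapply(s, function(t) as.character(t$pos), character(1)),
      stringsAsFactors = FALSE)
  } else {
    stop(where, " must be a data.frame or list of (surface, pos) tokens",
         call. = FALSE)
  }
  if (nrow(s) == 0L) stop(where, " must be non-empty", call. = FALSE)
  if (any(!nzchar(s$surface))) stop("empty token surface in ", where,
                                    call. = FALSE)
  bad <- setdiff(unique(s$pos), COARSE_TAGS)
  if (length(bad)) {
    stop("unknown POS tag(s) in ", where, ": ", paste(bad, collapse = ", "),
         "; expected one of ", paste(COARSE_TAGS, collapse = "/"),
         call. = FALSE)
  }
  s
}

#' Construct a tagged review document
#'
#' @param doc_id document identifier, unique within a corpus.
#' @param sentences a list; each element is one sentence given either as a
#'   data.frame with columns \code{surface}, \code{pos} or a list of
#'   \code{list(surface=, pos=)} tokens. Tags must come from
#'   \code{\link{COARSE_TAGS}}.
#' @return an object of class \code{tagged_document}.
#' @export
tagged_document <- function(doc_id, sentences) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.list(sentences) || !length(sentences)) {
    stop("sentences must be a non-empty list", call. = FALSE)
  }
  sentences <- lapply(seq_along(sentences), function(i) {
    .as_sentence(sentences[[i]], where = sprintf("sentence %d", i))
  })
  structure(list(doc_id = doc_id, sentences = sentences),
            class = "tagged_document")
}

#' @export
print.tagged_document <- function(x, ...) {
  cat(sprintf("<tagged_document> '%s': %d sentence(s), %d token(s)\n",
              x$doc_id, length(x$sentences),
              sum(vapply(x$sentences, nrow, integer(1)))))
  invisible(x)
}

.STOPWORDS <- c(
  "the", "a", "an", "and", "or", "but", "of", "in", "on", "at", "to", "for",
  "from", "with", "without", "by", "was", "were", "is", "are", "am", "be",
  "been", "being", "it", "its", "i", "me", "my", "mine", "we", "our", "you",
  "your", "he", "she", "his", "her", "they", "them", "their", "this", "that",
  "these", "those", "not", "no", "never", "very", "so", "too", "again",
  "after", "before", "during", "had", "has", "have", "will", "would",
  "could", "should", "do", "does", "did", "went", "through", "as", "than",
  "then", "there", "here", "when", "while", "felt", "feel", "feels",
  "performed", "scheduled", "recommended", "carried", "out", "go")

.ADJ_SUFFIXES <- c("ful$", "ous$", "ive$", "able$", "ible$", "less$", "ing$")

#' Tag raw review text with the coarse tagset
#'
#' A deliberately simple dictionary/suffix tagger used only as a fallback
#' when a corpus arrives without POS annotations: words known to the
#' sentiment lexicon (seeds or neighbourhood) are adjectives, a small
#' stopword list is \code{OTHER}, common adjectival suffixes are
#' \code{ADJ}, and everything else is treated as a noun. Ground-truth
#' corpora from the synthetic generator always carry explicit tags and do
#' not pass through here.
#'
#' @param doc_id document identifier.
#' @param text raw review text; sentences split on \code{.!?;}.
#' @param lexicon a list as from \code{\link{read_lexicon}}, used as the
#'   adjective dictionary; defaults to the shipped lexicon.
#' @return a \code{\link{tagged_document}}.
#' @export
tag_text <- function(doc_id, text, lexicon = default_lexicon()) {
  adj_dict <- unique(c(names(lexicon$seeds$entries),
                       names(lexicon$neighborhood$synonyms),
                       unlist(lexicon$neighborhood$synonyms, use.names = FALSE),
                       names(lexicon$neighborhood$antonyms),
                       unlist(lexicon$neighborhood$antonyms, use.names = FALSE)))
  raw_sentences <- strsplit(text, "[.!?;]+")[[1L]]
  raw_sentences <- trimws(raw_sentences)
  raw_sentences <- raw_sentences[nzchar(raw_sentences)]
  if (!length(raw_sentences)) stop("text contains no sentences", call. = FALSE)
  sentences <- lapply(raw_sentences, function(s) {
    toks <- regmatches(s, gregexpr("[A-Za-z']+", s))[[1L]]
    toks <- toks[nzchar(gsub("'", "", toks))]
    low <- tolower(toks)
    pos <- ifelse(low %in% adj_dict, "ADJ",
           ifelse(low %in% .STOPWORDS, "OTHER",
           ifelse(vapply(low, function(w) {
             any(vapply(.ADJ_SUFFIXES, grepl, logical(1), x = w))
           }, logical(1)), "ADJ", "NOUN")))
    data.frame(surface = toks, pos = pos, stringsAsFactors = FALSE)
  })
  tagged_document(doc_id, sentences)
}

#' Read a review corpus from JSON-lines
#'
#' One review per line. Each JSON object must have \code{doc_id} and either
#' \code{sentences} (a list of sentences, each a list of
#' \code{{"surface":, "pos":}} tokens) or \code{text} (raw text, tagged
#' internally with \code{\link{tag_text}}).
#'
#' @param path path to a \code{.jsonl} file.
#' @param lexicon lexicon used by the fallback tagger.
#' @return list of \code{\link{tagged_document}}.
#' @export
read_corpus_jsonl <- function(path, lexicon = default_lexicon()) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      stop("corpus parse error at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(obj$doc_id)) {
      stop("corpus parse error at line ", i, ": missing doc_id", call. = FALSE)
    }
    if (!is.null(obj$sentences)) {
      tagged_document(obj$doc_id, obj$sentences)
    } else if (!is.null(obj$text)) {
      tag_text(obj$doc_id, obj$text, lexicon)
    } else {
      stop("corpus parse error at line ", i,
           ": need 'sentences' or 'text'", call. = FALSE)
    }
  })
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  docs
}

#' Write a tagged corpus to JSON-lines
#' @param corpus list of \code{\link{tagged_document}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    jsonlite::toJSON(list(
      doc_id = doc$doc_id,
      sentences = lapply(doc$sentences, function(s) {
        lapply(seq_len(nrow(s)), function(i) {
          list(surface = s$surface[[i]], pos = s$pos[[i]])
        })
      })), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
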