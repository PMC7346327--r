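#' Three-way sentiment polarity
#'
#' Polarities are plain character scalars drawn from
#' \code{c("positive", "negative", "neutral")}. \code{opposite_polarity()}
#' maps positive to negative and vice versa; neutral is its own opposite.
#'
#' @param p a polarity string.
#' @return the opposite polarity string.
#' @examples
#' opposite_polarity("positive")
#' @export
opposite_polarity <- function(p) {
  p <- match.arg(p, c("positive", "negative", "neutral"))
  switch(p, positive = "negative", negative = "positive", neutral = "neutral")
}

.assert_polarity <- function(p, what = "polarity") {
  if (!is.character(p) || length(p) != 1L ||
      !p %in% c("positive", "negative", "neutral")) {
    stop(what, " must be one of 'positive', 'negative', 'neutral'",
         call. = FALSE)
  }
  p
}

.normalize_word <- function(w) {
  w <- tolower(trimws(w))
  gsub("\\s+", " ", w)
}

#' Create a seed lexicon of polarity-labelled words
#'
#' The seed lexicon is the set of opinion words of known polarity from which
#' polarity propagation starts. Its \code{initial_size} is fixed at creation
#' and never changes, even as propagation enlarges \code{entries}.
#'
#' @param words character vector of words (case-folded internally).
#' @param polarities character vector of matching polarities.
#' @return an object of class \code{seed_lexicon} with elements
#'   \code{entries} (named character vector word -> polarity) and
#'   \code{initial_size}.
#' @export
seed_lexicon <- function(words, polarities) {
  stopifnot(length(words) == length(polarities))
  words <- .normalize_word(words)
  vapply(polarities, .assert_polarity, character(1))
  if (anyDuplicated(words)) {
    dup <- words[duplicated(words)]
    conflicting <- vapply(unique(dup), function(w) {
      length(unique(polarities[words == w])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("duplicate seed word(s) with conflicting polarity: ",
           paste(unique(dup)[conflicting], collapse = ", "), call. = FALSE)
    }
    keep <- !duplicated(words)
    words <- words[keep]
    polarities <- polarities[keep]
  }
  entries <- stats::setNames(as.character(polarities), words)
  structure(list(entries = entries, initial_size = length(entries)),
            class = "seed_lexicon")
}

#' @export
print.seed_lexicon <- function(x, ...) {
  cat(sprintf("<seed_lexicon> %d entries (%d initial seeds)\n",
              length(x$entries), x$initial_size))
  tab <- table(factor(x$entries, c("positive", "negative", "neutral")))
  cat(sprintf("  positive: %d  negative: %d  neutral: %d\n",
              tab[["positive"]], tab[["negative"]], tab[["neutral"]]))
  invisible(x)
}

#' @export
length.seed_lexicon <- function(x) length(x$entries)

#' Add a word to a seed lexicon
#'
#' Used by polarity propagation when a word is resolved. Re-adding an
#' existing word with the same polarity is a no-op; a conflicting polarity
#' is an error. \code{initial_size} is unchanged.
#'
#' @param seeds a \code{seed_lexicon}.
#' @param word the word to add (case-folded).
#' @param polarity its polarity.
#' @return the enlarged \code{seed_lexicon}.
#' @export
add_seed <- function(seeds, word, polarity) {
  stopifnot(inherits(seeds, "seed_lexicon"))
  word <- .normalize_word(word)
  .assert_polarity(polarity)
  if (word %in% names(seeds$entries)) {
    if (!identical(unname(seeds$entries[[word]]), polarity)) {
      stop("word '", word, "' already seeded with polarity '",
           seeds$entries[[word]], "'", call. = FALSE)
    }
    return(seeds)
  }
  seeds$entries[word] <- polarity
  seeds
}

#' Query seed membership
#' @param seeds a \code{seed_lexicon}.
#' @param word a word.
#' @return \code{TRUE} if the word is in the (possibly expanded) seed list.
#' @export
is_seeded <- function(seeds, word) .normalize_word(word) %in% names(seeds$entries)

.symmetric_closure <- function(m) {
  # m: named list word -> character vector of partners
  pairs <- list()
  for (w in names(m)) {
    ps <- .normalize_word(m[[w]])
    w <- .normalize_word(w)
    ps <- setdiff(ps, w)
    for (p in ps) pairs[[length(pairs) + 1L]] <- c(w, p)
  }
  if (!length(pairs)) return(list())
  edges <- unique(do.call(rbind, lapply(pairs, function(e) {
    rbind(e, rev(e))
  })))
  out <- split(edges[, 2L], edges[, 1L])
  lapply(out, function(v) sort(unique(v)))
}

#' Build a synonym/antonym neighbourhood
#'
#' The neighbourhood is the package's stand-in for a WordNet-style lexical
#' graph: each word maps to its synonyms (same polarity) and antonyms
#' (opposite polarity). Both relations are made symmetric by closure; a pair
#' of words related both as synonyms and antonyms is rejected.
#'
#' @param synonyms named list: word -> character vector of synonyms.
#' @param antonyms named list: word -> character vector of antonyms.
#' @return an object of class \code{lexicon_neighborhood} with symmetric
#'   \code{synonyms} and \code{antonyms} maps.
#' @export
lexicon_neighborhood <- function(synonyms = list(), antonyms = list()) {
  syn <- .symmetric_closure(synonyms)
  ant <- .symmetric_closure(antonyms)
  for (w in intersect(names(syn), names(ant))) {
    both <- intersect(syn[[w]], ant[[w]])
    if (length(both)) {
      stop("word pair related as both synonym and antonym: '", w, "' / '",
           both[[1L]], "'", call. = FALSE)
    }
  }
  structure(list(synonyms = syn, antonyms = ant),
            class = "lexicon_neighborhood")
}

#' @export
print.lexicon_neighborhood <- function(x, ...) {
  cat(sprintf("<lexicon_neighborhood> %d words with synonyms, %d with antonyms\n",
              length(x$synonyms), length(x$antonyms)))
  invisible(x)
}

#' Read a lexicon file
#'
#' The lexicon file format has three bracketed sections. \code{[seeds]}
#' lines are \code{word <whitespace> polarity}; \code{[synonyms]} and
#' \code{[antonyms]} lines are \code{word: partner, partner, ...}. Blank
#' lines and lines starting with \code{#} are ignored. Synonym/antonym
#' relations are symmetrized on load.
#'
#' @param path path to a lexicon file.
#' @return a list with elements \code{seeds} (a \code{seed_lexicon}) and
#'   \code{neighborhood} (a \code{lexicon_neighborhood}).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  seed_w <- character(0); seed_p <- character(0)
  syn <- list(); ant <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^\\[(seeds|synonyms|antonyms)\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (is.na(section)) {
      stop("lexicon parse error at line ", i, ": content before any section",
           call. = FALSE)
    }
    if (section == "seeds") {
      parts <- strsplit(ln, "\\s+")[[1L]]
      if (length(parts) != 2L ||
          !parts[[2L]] %in% c("positive", "negative", "neutral")) {
        stop("lexicon parse error at line ", i,
             ": expected 'word polarity', got '", ln, "'", call. = FALSE)
      }
      w <- .normalize_word(parts[[1L]])
      if (w %in% seed_w && seed_p[match(w, seed_w)] != parts[[2L]]) {
        stop("lexicon validation error at line ", i, ": seed word '", w,
             "' re-declared with conflicting polarity", call. = FALSE)
      }
      seed_w <- c(seed_w, w); seed_p <- c(seed_p, parts[[2L]])
    } else {
      if (!grepl(":", ln, fixed = TRUE)) {
        stop("lexicon parse error at line ", i,
             ": expected 'word: partner, ...', got '", ln, "'", call. = FALSE)
      }
      key <- .normalize_word(sub(":.*$", "", ln))
      vals <- strsplit(sub("^[^:]*:", "", ln), ",")[[1L]]
      vals <- .normalize_word(vals[trimws(vals) != ""])
      if (key == "" || !length(vals)) {
        stop("lexicon parse error at line ", i, ": empty word or partner list",
             call. = FALSE)
      }
      tgt <- if (section == "synonyms") "syn" else "ant"
      cur <- if (tgt == "syn") syn else ant
      cur[[key]] <- c(cur[[key]], vals)
      if (tgt == "syn") syn <- cur else ant <- cur
    }
  }
  keep <- !duplicated(seed_w)
  list(seeds = seed_lexicon(seed_w[keep], seed_p[keep]),
       neighborhood = lexicon_neighborhood(syn, ant))
}

#' The shipped default sentiment lexicon
#'
#' Thirty polarity-labelled adjectives (the seed list) plus a small
#' synonym/antonym neighbourhood tuned to patient-review vocabulary
#' (e.g. "excruciating", "unbearable", "radical" are reachable from the
#' seeds by one or two lexical hops).
#'
#' @return as \code{\link{read_lexicon}}.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "default_lexicon.txt",
                           package = "experia", mustWork = TRUE))
}

.majority_polarity <- function(pols) {
  # majority over positive/negative votes; exact tie (or only neutrals) -> neutral
  npos <- sum(pols == "positive")
  nneg <- sum(pols == "negative")
  if (npos > nneg) "positive" else if (nneg > npos) "negative" else "neutral"
}

#' Look up the polarity of a word via seeds and one-hop neighbours
#'
#' Resolution order follows seed-list expansion: a seeded word returns its
#' own polarity; otherwise seeded synonyms are consulted (same polarity);
#' only if no synonym is seeded are antonyms consulted (opposite polarity).
#' When several seeded neighbours disagree, the majority polarity wins and
#' an exact tie resolves to neutral. A word with no seeded neighbour is
#' unresolved and \code{NA_character_} is returned.
#'
#' @param word the word (case-folded internally).
#' @param seeds a \code{seed_lexicon}.
#' @param hood a \code{lexicon_neighborhood}.
#' @return a polarity string, or \code{NA_character_} if unresolved.
#' @export
lookup_polarity <- function(word, seeds, hood) {
  stopifnot(inherits(seeds, "seed_lexicon"),
            inherits(hood, "lexicon_neighborhood"))
  word <- .normalize_word(word)
  if (!nzchar(word)) stop("word must be non-empty", call. = FALSE)
  if (word %in% names(seeds$entries)) {
    return(unname(seeds$entries[[word]]))
  }
  syn <- hood$synonyms[[word]]
  hit <- syn[syn %in% names(seeds$entries)]
  if (length(hit)) {
    return(.majority_polarity(unname(seeds$entries[hit])))
  }
  ant <- hood$antonyms[[word]]
  hit <- ant[ant %in% names(seeds$entries)]
  if (length(hit)) {
    opp <- vapply(unname(seeds$entries[hit]), opposite_polarity, character(1))
    return(.majority_polarity(opp))
  }
  NA_character_
}

#' Invert every seed polarity
#'
#' Utility for antisymmetry checks: positive and negative are swapped,
#' neutral is unchanged.
#'
#' @param seeds a \code{seed_lexicon}.
#' @return the inverted \code{seed_lexicon}.
#' @export
invert_lexicon <- function(seeds) {
  stopifnot(inherits(seeds, "seed_lexicon"))
  seeds$entries[] <- vapply(unname(seeds$entries), opposite_polarity,
                            character(1))
  seeds
}
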