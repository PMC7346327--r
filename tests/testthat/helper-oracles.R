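# Independent oracles and random-input generators used across tests.
# These deliberately re-derive expected results by brute force rather than
# calling the code paths they check.

# Random lexicon graph with a hidden sign per word, so synonym edges join
# same-sign words and antonym edges join opposite-sign words: the graph is
# free of sign conflicts by construction.
random_lexicon_graph <- function(n_words, n_seeds = 3L, extra_edges = n_words,
                                 seed = 1L) {
  set.seed(seed)
  words <- sprintf("w%03d", seq_len(n_words))
  hidden <- sample(c("positive", "negative"), n_words, replace = TRUE)
  names(hidden) <- words
  syn <- list(); ant <- list()
  link <- function(a, b) {
    if (hidden[[a]] == hidden[[b]]) {
      syn[[a]] <<- c(syn[[a]], b)
    } else {
      ant[[a]] <<- c(ant[[a]], b)
    }
  }
  # random forest: each word after the first few attaches to an earlier word
  # with probability 0.8 (leaving some isolated components)
  for (i in 2:n_words) {
    if (stats::runif(1) < 0.8) link(words[[i]], words[[sample.int(i - 1L, 1L)]])
  }
  for (j in seq_len(extra_edges)) {
    ab <- sample.int(n_words, 2L)
    link(words[[ab[[1L]]]], words[[ab[[2L]]]])
  }
  seed_idx <- sample.int(n_words, min(n_seeds, n_words))
  list(words = words, hidden = hidden,
       seeds = seed_lexicon(words[seed_idx], unname(hidden[seed_idx])),
       hood = lexicon_neighborhood(syn, ant))
}

# Signed breadth-first search over the synonym/antonym graph: polarity of a
# reachable word is the seed polarity carried along the path, flipped at
# every antonym edge. Returns a named polarity vector for reachable words.
oracle_signed_bfs <- function(seeds, hood) {
  pol <- seeds$entries
  queue <- names(pol)
  while (length(queue)) {
    w <- queue[[1L]]; queue <- queue[-1L]
    for (s in hood$synonyms[[w]]) {
      if (!s %in% names(pol)) {
        pol[s] <- pol[[w]]
        queue <- c(queue, s)
      }
    }
    for (a in hood$antonyms[[w]]) {
      if (!a %in% names(pol)) {
        pol[a] <- opposite_polarity(pol[[w]])
        queue <- c(queue, a)
      }
    }
  }
  pol
}

# Exhaustive nearest-case sort: condition filter (subset rule), then plain
# Euclidean distance on /100-normalized preference values aligned by
# attribute name, sorted by (distance, case_id).
oracle_knn <- function(q, cases, k) {
  match_ok <- vapply(cases, function(cs) {
    all(q$conditions %in% cs$conditions)
  }, logical(1))
  cases <- cases[match_ok]
  if (!length(cases)) return(data.frame(case_id = character(0),
                                        distance = numeric(0)))
  d <- vapply(cases, function(cs) {
    m <- match(q$preference_vector$attribute, cs$preference_vector$attribute)
    sqrt(sum(((q$preference_vector$value -
                 cs$preference_vector$value[m]) / 100)^2))
  }, numeric(1))
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  ord <- order(d, ids)
  utils::head(data.frame(case_id = ids[ord], distance = d[ord],
                         stringsAsFactors = FALSE), k)
}

# One-hop seed-list scan, re-deriving the lookup contract independently:
# synonyms first (majority; tie neutral), then antonyms with flipped votes.
oracle_one_hop_lookup <- function(word, seeds, hood) {
  if (word %in% names(seeds$entries)) return(unname(seeds$entries[[word]]))
  tally <- function(pols) {
    if (!length(pols)) return(NULL)
    d <- sum(pols == "positive") - sum(pols == "negative")
    if (d > 0) "positive" else if (d < 0) "negative" else "neutral"
  }
  syn <- intersect(hood$synonyms[[word]], names(seeds$entries))
  r <- tally(unname(seeds$entries[syn]))
  if (!is.null(r)) return(r)
  ant <- intersect(hood$antonyms[[word]], names(seeds$entries))
  r <- tally(vapply(unname(seeds$entries[ant]), opposite_polarity,
                    character(1)))
  if (!is.null(r)) return(r)
  NA_character_
}

# Direct constructor for small case bases with explicit vectors.
make_case <- function(id, values, decision, conditions = "breast cancer",
                      ranks = seq_along(values)) {
  experience_case(
    case_id = id, conditions = conditions,
    preference_vector = data.frame(
      attribute = names(values), value = unname(values), rank = ranks,
      stringsAsFactors = FALSE),
    decision = decision)
}

random_case_base <- function(n, n_attr = 5L, seed = 1L) {
  set.seed(seed)
  attrs <- paste0("attr", seq_len(n_attr))
  lapply(seq_len(n), function(i) {
    make_case(sprintf("case-%04d", i),
              stats::setNames(stats::runif(n_attr, 0, 100), attrs),
              decision = sample(c("A", "B", "C"), 1L))
  })
}

random_query <- function(n_attr = 5L, seed = 1L) {
  set.seed(seed)
  attrs <- paste0("attr", seq_len(n_attr))
  query_patient("breast cancer", data.frame(
    attribute = attrs, value = stats::runif(n_attr, 0, 100),
    rank = sample.int(n_attr), stringsAsFactors = FALSE))
}

# Tagged one-sentence helper for mining tests.
sent <- function(surfaces, tags) {
  data.frame(surface = surfaces, pos = tags, stringsAsFactors = FALSE)
}
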