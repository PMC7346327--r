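doc1 <- function(id, s) tagged_document(id, list(s))

test_that("candidate support is the fraction of sentences containing the phrase", {
  d <- doc1("d1", sent(c("the", "pain", "was", "excruciating"),
                       c("OTHER", "NOUN", "OTHER", "ADJ")))
  cand <- extract_candidates(list(d))
  expect_equal(cand$phrase, "pain")
  expect_equal(cand$support, 1.0)

  # 10 sentences, "biopsy" in exactly 4 -> support 0.4
  docs <- lapply(1:10, function(i) {
    if (i <= 4) {
      doc1(paste0("d", i), sent(c("the", "biopsy"), c("OTHER", "NOUN")))
    } else {
      doc1(paste0("d", i), sent(c("it", "was", "fine"),
                                c("OTHER", "OTHER", "OTHER")))
    }
  })
  cand <- extract_candidates(docs)
  expect_equal(cand$support[cand$phrase == "biopsy"], 0.4)

  # adjacent nouns merge into a phrase; the head noun is credited by
  # containment
  d2 <- doc1("m1", sent(c("the", "stereotactic", "biopsy"),
                        c("OTHER", "NOUN", "NOUN")))
  d3 <- doc1("m2", sent(c("the", "biopsy"), c("OTHER", "NOUN")))
  cand <- extract_candidates(list(d2, d3))
  expect_equal(cand$support[cand$phrase == "stereotactic biopsy"], 0.5)
  expect_equal(cand$support[cand$phrase == "biopsy"], 1.0)

  expect_error(extract_candidates(list()), "non-empty")
})

test_that("frequent-feature filtering keeps exactly the above-threshold set", {
  cand <- data.frame(phrase = c("a", "b", "c"),
                     support = c(0.5, 0.3, 0.1),
                     n_sentences = c(5L, 3L, 1L), stringsAsFactors = FALSE)
  expect_equal(find_frequent_features(cand, mining_config(0.3))$phrase,
               c("a", "b"))
  expect_equal(find_frequent_features(cand, mining_config(1e-9))$phrase,
               c("a", "b", "c"))
  expect_equal(nrow(find_frequent_features(cand, mining_config(1.0))), 0L)
  # sorted by descending support then lexicographically
  cand2 <- data.frame(phrase = c("z", "m", "a"), support = c(0.3, 0.3, 0.5),
                      n_sentences = c(3L, 3L, 5L), stringsAsFactors = FALSE)
  expect_equal(find_frequent_features(cand2, mining_config(0.1))$phrase,
               c("a", "m", "z"))
})

test_that("raising the threshold never adds a frequent feature", {
  for (s in 1:10) {
    gen <- generate_corpus(corpus_plan(
      n_reviews = 15L,
      features = data.frame(phrase = c("biopsy", "scan", "therapy"),
                            support = stats::runif(3, 0.1, 0.9)),
      adjectives = data.frame(feature = c("biopsy", "scan", "therapy"),
                              word = c("painful", "quick", "gentle"),
                              polarity = c("negative", "positive",
                                           "positive")),
      seed = s))
    cand <- extract_candidates(gen$corpus)
    grid <- sort(stats::runif(4, 0.05, 1))
    sets <- lapply(grid, function(t) {
      find_frequent_features(cand, mining_config(t))$phrase
    })
    for (j in seq_along(sets)[-1]) {
      expect_true(all(sets[[j]] %in% sets[[j - 1L]]))
    }
  }
})

test_that("the nearest adjective is paired, ties preferring the premodifier", {
  feats <- data.frame(phrase = "biopsy", support = 1, n_sentences = 1L,
                      stringsAsFactors = FALSE)
  # adjectives at distance 2 and 5: the distance-2 one wins
  d <- doc1("d", sent(c("biopsy", "was", "painful", "but", "it", "was",
                        "quick"),
                      c("NOUN", "OTHER", "ADJ", "OTHER", "OTHER", "OTHER",
                        "ADJ")))
  # brute-force check of all (feature-token, adjective) distances
  expect_equal(extract_opinion_words(list(d), feats)$opinion_word, "painful")

  # equal distance before and after: the preceding adjective wins
  d2 <- doc1("d2", sent(c("slow", "the", "biopsy", "was", "quick"),
                        c("ADJ", "OTHER", "NOUN", "OTHER", "ADJ")))
  ow <- extract_opinion_words(list(d2), feats)
  expect_equal(ow$distance, 2L)
  expect_equal(ow$opinion_word, "slow")

  # no adjective in the sentence -> no pair
  d3 <- doc1("d3", sent(c("the", "biopsy"), c("OTHER", "NOUN")))
  expect_equal(nrow(extract_opinion_words(list(d3), feats)), 0L)

  # beyond max_adjective_distance -> no pair
  cfgn <- mining_config(0.1, max_adjective_distance = 1)
  expect_equal(nrow(extract_opinion_words(list(d), feats, cfgn)), 0L)
})

test_that("polarity propagation iterates to the signed-BFS fixpoint", {
  seeds <- seed_lexicon("w1", "negative")
  hood <- lexicon_neighborhood(synonyms = list(w2 = "w1", w3 = "w2"))
  pairs <- data.frame(feature = "f", opinion_word = c("w1", "w2", "w3", "w9"),
                      doc_id = "d", sentence_index = 1L,
                      stringsAsFactors = FALSE)
  res <- propagate_polarity(pairs, seeds, hood)
  expect_equal(unname(res$seeds$entries[c("w2", "w3")]),
               c("negative", "negative"))
  expect_equal(res$opinions$invalid_words, "w9")
  expect_equal(nrow(res$opinions$opinions), 3L)
  # already-seeded words leave the seed list size unchanged for them
  res2 <- propagate_polarity(pairs[1, ], seeds, hood)
  expect_length(res2$seeds$entries, 1L)
  # initial_size is immutable through propagation
  expect_equal(res$seeds$initial_size, 1L)
})

test_that("mining the worked review fixture recovers the planted opinions", {
  fx <- worked_example_fixture()
  theta <- mine_opinions(list(fx$document), config = mining_config(0.25))
  got <- theta$opinions[order(theta$opinions$sentence_index,
                              theta$opinions$feature),
                        c("feature", "opinion_word", "polarity", "doc_id",
                          "sentence_index")]
  want <- fx$expected_opinions[order(fx$expected_opinions$sentence_index,
                                     fx$expected_opinions$feature), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  ff <- attr(theta, "frequent_features")$phrase
  expect_true(all(c("stereotactic biopsy", "left breast", "mastectomy")
                  %in% ff))
  # every opinion's feature meets the support threshold
  sup <- attr(theta, "frequent_features")
  expect_true(all(sup$support[match(theta$opinions$feature, sup$phrase)]
                  >= 0.25))
})

test_that("a corpus without nouns yields an empty opinion set", {
  d <- doc1("d", sent(c("it", "was", "awful"), c("OTHER", "OTHER", "ADJ")))
  theta <- mine_opinions(list(d))
  expect_equal(nrow(theta$opinions), 0L)
})

test_that("global seed inversion flips every non-neutral mined polarity", {
  gen <- generate_corpus(default_corpus_plan(n_reviews = 12L, seed = 5L))
  lex <- default_lexicon()
  a <- mine_opinions(gen$corpus, lex$seeds, lex$neighborhood)
  b <- mine_opinions(gen$corpus, invert_lexicon(lex$seeds),
                     lex$neighborhood)
  key <- function(x) paste(x$feature, x$opinion_word, x$doc_id)
  expect_equal(key(a$opinions), key(b$opinions))
  flip <- vapply(a$opinions$polarity, opposite_polarity, character(1))
  expect_equal(unname(flip), b$opinions$polarity)
})

test_that("sentence scoring is a seed-lexicon majority vote", {
  seeds <- seed_lexicon(c("good", "great", "bad"),
                        c("positive", "positive", "negative"))
  s1 <- sent(c("the", "care", "was", "bad"),
             c("OTHER", "NOUN", "OTHER", "ADJ"))
  expect_equal(score_sentence(s1, seeds), "negative")
  s2 <- sent(c("nothing", "here"), c("NOUN", "OTHER"))
  expect_equal(score_sentence(s2, seeds), "neutral")
  s3 <- sent(c("good", "great", "but", "bad"),
             c("ADJ", "ADJ", "OTHER", "ADJ"))
  expect_equal(score_sentence(s3, seeds), "positive")
  # tie -> neutral
  s4 <- sent(c("good", "bad"), c("ADJ", "ADJ"))
  expect_equal(score_sentence(s4, seeds), "neutral")
  # optional negation handling flips a vote within the 3-token window
  s5 <- sent(c("not", "good"), c("OTHER", "ADJ"))
  expect_equal(score_sentence(s5, seeds), "positive")
  expect_equal(score_sentence(s5, seeds, negation = TRUE), "negative")
})

test_that("opinion tables round-trip through TSV", {
  fx <- worked_example_fixture()
  theta <- mine_opinions(list(fx$document))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_opinions_tsv(theta, path)
  back <- read_opinions_tsv(path)
  expect_equal(back,
               theta$opinions[, c("doc_id", "sentence_index", "feature",
                                  "opinion_word", "polarity")],
               ignore_attr = TRUE)
})
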