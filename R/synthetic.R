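#' Plan a synthetic tagged review corpus with planted opinions
#'
#' Each planned feature is planted into a chosen fraction of reviews
#' (one sentence per review, so planted support is realized to within
#' 1/n of the plan), always together with its planned opinion adjective.
#' Sentence templates carry their POS tags explicitly, so the ground truth
#' does not depend on any tagger.
#'
#' @param n_reviews number of single-sentence reviews.
#' @param features data.frame with columns \code{phrase} (nouns, lower
#'   case) and \code{support} in (0, 1].
#' @param adjectives data.frame with columns \code{feature}, \code{word},
#'   \code{polarity}: the opinion adjective planted next to each feature
#'   and its intended polarity (the word must be resolvable by the lexicon
#'   in use for mined polarity to match the plan).
#' @param seed random seed making the plan's realization reproducible.
#' @return an object of class \code{corpus_plan}.
#' @export
corpus_plan <- function(n_reviews, features, adjectives, seed = 1L) {
  stopifnot(n_reviews >= 1L, is.data.frame(features),
            all(c("phrase", "support") %in% names(features)),
            is.data.frame(adjectives),
            all(c("feature", "word", "polarity") %in% names(adjectives)))
  if (any(features$support <= 0 | features$support > 1)) {
    stop("planted supports must lie in (0, 1]", call. = FALSE)
  }
  if (!setequal(features$phrase, adjectives$feature)) {
    stop("adjective map must cover exactly the planned features",
         call. = FALSE)
  }
  vapply(adjectives$polarity, .assert_polarity, character(1))
  structure(list(n_reviews = as.integer(n_reviews), features = features,
                 adjectives = adjectives, seed = as.integer(seed)),
            class = "corpus_plan")
}

#' A default corpus plan emulating patient-review mining
#'
#' Breast-cancer triple-assessment vocabulary with adjectives drawn from
#' the shipped seed list so every planted polarity resolves.
#'
#' @param n_reviews number of reviews.
#' @param seed random seed.
#' @return a \code{\link{corpus_plan}}.
#' @export
default_corpus_plan <- function(n_reviews = 20L, seed = 1L) {
  corpus_plan(
    n_reviews = n_reviews,
    features = data.frame(
      phrase = c("biopsy", "mammogram", "chemotherapy", "recovery"),
      support = c(0.5, 0.4, 0.3, 0.2), stringsAsFactors = FALSE),
    adjectives = data.frame(
      feature = c("biopsy", "mammogram", "chemotherapy", "recovery"),
      word = c("painful", "quick", "severe", "slow"),
      polarity = c("negative", "positive", "negative", "negative"),
      stringsAsFactors = FALSE),
    seed = seed)
}

.clause_tokens <- function(feature, adjective) {
  ftoks <- strsplit(feature, " ", fixed = TRUE)[[1L]]
  data.frame(
    surface = c("the", ftoks, "was", adjective),
    pos = c("OTHER", rep("NOUN", length(ftoks)), "OTHER", "ADJ"),
    stringsAsFactors = FALSE)
}

.FILLER <- data.frame(
  surface = c("it", "went", "as", "expected", "overall"),
  pos = rep("OTHER", 5L), stringsAsFactors = FALSE)

#' Generate a tagged corpus from a plan, with ground truth
#'
#' Realizes the plan as \code{n_reviews} one-sentence reviews built from
#' "the <feature> was <adjective>" clauses (clauses joined by "and" when a
#' sentence hosts several features); reviews hosting no feature get a
#' noun-free filler sentence. The returned ground truth is exactly the
#' opinion table \code{\link{mine_opinions}} must produce at any support
#' threshold not above the smallest realized support.
#'
#' @param plan a \code{\link{corpus_plan}}.
#' @return list with \code{corpus} (list of \code{tagged_document}),
#'   \code{truth} (data.frame feature/opinion_word/polarity/doc_id/
#'   sentence_index) and \code{realized_support} (named numeric).
#' @export
generate_corpus <- function(plan) {
  stopifnot(inherits(plan, "corpus_plan"))
  set.seed(plan$seed)
  n <- plan$n_reviews
  feats <- plan$features
  slots <- lapply(seq_len(nrow(feats)), function(i) {
    k <- max(1L, round(feats$support[[i]] * n))
    sort(sample.int(n, k))
  })
  names(slots) <- feats$phrase
  doc_ids <- sprintf("r%03d", seq_len(n))
  corpus <- vector("list", n)
  truth <- list()
  for (r in seq_len(n)) {
    present <- feats$phrase[vapply(slots, function(s) r %in% s, logical(1))]
    if (!length(present)) {
      corpus[[r]] <- tagged_document(doc_ids[[r]], list(.FILLER))
      next
    }
    clauses <- lapply(present, function(f) {
      adj <- plan$adjectives$word[plan$adjectives$feature == f][[1L]]
      .clause_tokens(f, adj)
    })
    sent <- clauses[[1L]]
    if (length(clauses) > 1L) {
      for (cl in clauses[-1L]) {
        sent <- rbind(sent,
                      data.frame(surface = "and", pos = "OTHER",
                                 stringsAsFactors = FALSE),
                      cl)
      }
    }
    corpus[[r]] <- tagged_document(doc_ids[[r]], list(sent))
    for (f in present) {
      row <- plan$adjectives[plan$adjectives$feature == f, , drop = FALSE]
      truth[[length(truth) + 1L]] <- data.frame(
        feature = f, opinion_word = row$word[[1L]],
        polarity = row$polarity[[1L]], doc_id = doc_ids[[r]],
        sentence_index = 1L, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(feature = character(0), opinion_word = character(0),
               polarity = character(0), doc_id = character(0),
               sentence_index = integer(0))
  list(corpus = corpus, truth = truth,
       realized_support = stats::setNames(
         vapply(slots, length, integer(1)) / n, feats$phrase))
}

#' The worked patient-review fixture
#'
#' A hand-tagged four-sentence review about stereotactic biopsy of the
#' left breast and a subsequent mastectomy, built so mining it with the
#' shipped lexicon recovers the frequent features "stereotactic biopsy",
#' "left breast" and "mastectomy" and the negative opinion words
#' "excruciating", "unbearable" and "radical" ("unbearable" resolves only
#' after "excruciating" joins the seed list, exercising the iterative
#' expansion). Deterministic: no randomness is involved.
#'
#' @return list with \code{document} (a \code{tagged_document}),
#'   \code{expected_opinions} (the opinion table mining must produce at
#'   threshold 0.25 or lower), and \code{meta} (case metadata matching the
#'   worked ontology example: condition breast cancer, procedure
#'   stereotactic biopsy of the left breast).
#' @export
worked_example_fixture <- function() {
  tok <- function(surfaces, tags) {
    data.frame(surface = surfaces, pos = tags, stringsAsFactors = FALSE)
  }
  s1 <- tok(c("the", "radiologist", "performed", "a", "Stereotactic",
              "Biopsy", "on", "my", "Left", "Breast"),
            c("OTHER", "NOUN", "OTHER", "OTHER", "NOUN", "NOUN", "OTHER",
              "OTHER", "NOUN", "NOUN"))
  s2 <- tok(c("the", "pain", "from", "the", "stereotactic", "biopsy", "was",
              "excruciating", "and", "Unbearable"),
            c("OTHER", "NOUN", "OTHER", "OTHER", "NOUN", "NOUN", "OTHER",
              "ADJ", "OTHER", "ADJ"))
  s3 <- tok(c("my", "Radical", "Mastectomy", "was", "scheduled", "after",
              "the", "biopsy"),
            c("OTHER", "ADJ", "NOUN", "OTHER", "OTHER", "OTHER", "OTHER",
              "NOUN"))
  s4 <- tok(c("the", "recovery", "after", "the", "mastectomy", "felt",
              "unbearable"),
            c("OTHER", "NOUN", "OTHER", "OTHER", "NOUN", "OTHER", "ADJ"))
  doc <- tagged_document("plm-review-1", list(s1, s2, s3, s4))
  expected <- data.frame(
    feature = c("pain", "stereotactic biopsy", "biopsy", "mastectomy",
                "biopsy", "recovery", "mastectomy"),
    opinion_word = c("excruciating", "excruciating", "excruciating",
                     "radical", "radical", "unbearable", "unbearable"),
    polarity = rep("negative", 7L),
    doc_id = rep("plm-review-1", 7L),
    sentence_index = c(2L, 2L, 2L, 3L, 3L, 4L, 4L),
    stringsAsFactors = FALSE)
  list(document = doc, expected_opinions = expected,
       meta = list(case_id = "plm-review-1",
                   conditions = "breast cancer",
                   procedure = "stereotactic biopsy of the left breast",
                   source_text = paste("the pain was excruciating and",
                                       "unbearable, stereotactic biopsy is",
                                       "not recommended")))
}

#' Plan a synthetic case base with planted preference archetypes
#'
#' @param n_cases total number of cases, split as evenly as possible
#'   across archetypes.
#' @param archetypes list; each element a list with \code{centroid} (named
#'   numeric VAS vector in [0,100]), \code{conditions}, \code{decision},
#'   \code{dispersion} (pre-clipping standard deviation of the
#'   truncated-Gaussian VAS noise).
#' @param seed random seed.
#' @return an object of class \code{case_base_plan}.
#' @export
case_base_plan <- function(n_cases, archetypes, seed = 1L) {
  stopifnot(n_cases >= 1L, is.list(archetypes), length(archetypes) >= 1L)
  attrs <- names(archetypes[[1L]]$centroid)
  for (a in archetypes) {
    stopifnot(!is.null(a$centroid), !is.null(a$conditions),
              !is.null(a$decision), !is.null(a$dispersion))
    if (!identical(names(a$centroid), attrs)) {
      stop("all archetype centroids must share one attribute schema",
           call. = FALSE)
    }
    if (any(a$centroid < 0 | a$centroid > 100)) {
      stop("centroids must lie in [0, 100]", call. = FALSE)
    }
  }
  structure(list(n_cases = as.integer(n_cases), archetypes = archetypes,
                 seed = as.integer(seed)),
            class = "case_base_plan")
}

#' Default two-archetype plan (breast-cancer triple assessment)
#'
#' Two preference archetypes over five VAS attributes (pain tolerance,
#' survival priority, cost sensitivity, recovery speed, cosmetic concern),
#' each deterministically mapped to a decision; centroids are separated by
#' well over three times the dispersion, so nearest-case retrieval should
#' recover the archetype.
#'
#' @param n_cases number of cases.
#' @param dispersion VAS noise standard deviation.
#' @param seed random seed.
#' @return a \code{\link{case_base_plan}}.
#' @export
default_case_base_plan <- function(n_cases = 100L, dispersion = 10,
                                   seed = 1L) {
  attrs <- c(pain_tolerance = NA, survival_priority = NA,
             cost_sensitivity = NA, recovery_speed = NA,
             cosmetic_concern = NA)
  case_base_plan(
    n_cases = n_cases,
    archetypes = list(
      list(centroid = stats::setNames(c(20, 80, 50, 40, 60), names(attrs)),
           conditions = c("breast cancer", "palpable lump"),
           decision = "core needle biopsy", dispersion = dispersion),
      list(centroid = stats::setNames(c(80, 70, 30, 80, 20), names(attrs)),
           conditions = c("breast cancer", "palpable lump"),
           decision = "stereotactic biopsy", dispersion = dispersion)),
    seed = seed)
}

.rtruncnorm_vas <- function(mean, sd) {
  pmin(100, pmax(0, stats::rnorm(length(mean), mean, sd)))
}

#' Generate an experience case base from a plan, with archetype labels
#'
#' Preference vectors are drawn around each archetype's centroid with
#' truncated-Gaussian noise (clipped to [0,100]); conditions and decisions
#' are inherited from the archetype; priority ranks are a random
#' permutation per case. Reproducible from the plan's seed.
#'
#' @param plan a \code{\link{case_base_plan}}.
#' @return list with \code{cases} (list of \code{experience_case}) and
#'   \code{labels} (integer archetype index per case).
#' @export
generate_case_base <- function(plan) {
  stopifnot(inherits(plan, "case_base_plan"))
  set.seed(plan$seed)
  n <- plan$n_cases
  narc <- length(plan$archetypes)
  labels <- rep(seq_len(narc), length.out = n)
  attrs <- names(plan$archetypes[[1L]]$centroid)
  cases <- lapply(seq_len(n), function(i) {
    a <- plan$archetypes[[labels[[i]]]]
    vals <- .rtruncnorm_vas(a$centroid, a$dispersion)
    experience_case(
      case_id = sprintf("case-%04d", i),
      conditions = a$conditions,
      procedure = a$decision,
      preference_vector = data.frame(
        attribute = attrs, value = unname(vals),
        rank = sample.int(length(attrs)), stringsAsFactors = FALSE),
      decision = a$decision,
      overall_polarity = sample(c("positive", "negative", "neutral"), 1L,
                                prob = c(0.6, 0.2, 0.2)))
  })
  list(cases = cases, labels = labels)
}
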