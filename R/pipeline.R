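#' Run the full mine -> map -> store -> retrieve -> re-rank pipeline
#'
#' Executes opinion mining over a corpus, maps each review's opinions to
#' ontology individuals, persists the knowledge base as Turtle, retrieves
#' the nearest experience cases for a query patient and re-ranks the
#' objective candidate decisions. Every stage failure aborts with the
#' stage name; outputs (\code{opinions.tsv}, \code{pekb.ttl},
#' \code{ranked.json}, \code{manifest.json}) land in \code{out_dir}. With
#' a fixed seed and config the run is deterministic: the manifest records
#' md5 digests of the artifacts plus the effective configuration.
#'
#' @param config a named list (or path to a JSON/YAML file with the same
#'   fields): \code{corpus} (path to JSON-lines reviews, or \code{NULL} to
#'   synthesize from the default corpus plan), \code{lexicon} (path, or
#'   \code{NULL} for the shipped lexicon), \code{cases} (path to a JSON
#'   case store, or \code{NULL} to synthesize from the default case-base
#'   plan), \code{query} (list with \code{conditions} and
#'   \code{preference_vector}, or \code{NULL} for a default query),
#'   \code{candidates} (ordered character vector of objective decisions),
#'   \code{threshold}, \code{k}, \code{condition_match_rule},
#'   \code{seed}, \code{out_dir}.
#' @return invisibly, a list with the opinion set, the triple store, the
#'   retrieval, the ranked decisions and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    corpus = NULL, lexicon = NULL, cases = NULL, query = NULL,
    candidates = c("core needle biopsy", "stereotactic biopsy",
                   "open surgical biopsy"),
    threshold = 0.1, k = 5L, condition_match_rule = "subset",
    seed = 1L, out_dir = tempfile("experia-run-")), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  lex <- stage("lexicon", {
    if (is.null(cfg$lexicon)) default_lexicon() else read_lexicon(cfg$lexicon)
  })
  corpus <- stage("corpus", {
    if (is.null(cfg$corpus)) {
      generate_corpus(default_corpus_plan(seed = cfg$seed))$corpus
    } else {
      read_corpus_jsonl(cfg$corpus, lex)
    }
  })
  theta <- stage("mine", {
    mine_opinions(corpus, lex$seeds, lex$neighborhood,
                  mining_config(threshold = cfg$threshold))
  })
  opinions_path <- file.path(cfg$out_dir, "opinions.tsv")
  write_opinions_tsv(theta, opinions_path)

  cases <- stage("cases", {
    if (is.null(cfg$cases)) {
      generate_case_base(default_case_base_plan(seed = cfg$seed))$cases
    } else {
      cases_from_json(cfg$cases)
    }
  })
  store <- stage("build-pekb", build_pekb(cases))
  # attach the mined review opinions as ontology individuals too
  store <- stage("map-opinions", {
    by_doc <- split(theta$opinions, theta$opinions$doc_id)
    for (doc_id in names(by_doc)) {
      st <- map_opinions_to_individuals(
        by_doc[[doc_id]],
        list(case_id = paste0("review-", doc_id),
             conditions = "breast cancer"))
      store <- ts_union(store, st)
    }
    store
  })
  pekb_path <- file.path(cfg$out_dir, "pekb.ttl")
  save_pekb(store, pekb_path)

  q <- stage("query", {
    if (is.null(cfg$query)) {
      plan <- default_case_base_plan(seed = cfg$seed)
      a <- plan$archetypes[[1L]]
      query_patient(a$conditions, data.frame(
        attribute = names(a$centroid), value = unname(a$centroid),
        rank = seq_along(a$centroid), stringsAsFactors = FALSE))
    } else {
      query_patient(cfg$query$conditions,
                    as.data.frame(cfg$query$preference_vector))
    }
  })
  icfg <- inference_config(k = cfg$k,
                           condition_match_rule = cfg$condition_match_rule)
  retrieval <- stage("recommend", knn_retrieve(q, cases, icfg))
  ranked <- stage("rerank", rerank_decisions(cfg$candidates, retrieval))

  ranked_path <- file.path(cfg$out_dir, "ranked.json")
  jsonlite::write_json(
    list(status = retrieval$status,
         cases = retrieval$results[, c("case_id", "distance", "weight",
                                       "decision")],
         ranked = as.data.frame(ranked)),
    ranked_path, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    config = cfg[c("threshold", "k", "condition_match_rule", "seed",
                   "candidates")],
    digests = as.list(tools::md5sum(c(opinions_path, pekb_path,
                                      ranked_path))))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(opinions = theta, store = store, retrieval = retrieval,
                 ranked = ranked, manifest = manifest,
                 out_dir = cfg$out_dir))
}

#' Read a pipeline configuration file (JSON or YAML)
#' @param path path to the config file.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
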