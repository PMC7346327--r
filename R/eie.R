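#' Inference engine configuration
#'
#' @param k number of nearest cases to retrieve (\code{k >= 1}).
#' @param condition_match_rule how query conditions must match a case's:
#'   \code{"subset"} (query conditions contained in the case's, the
#'   default), \code{"exact"} or \code{"jaccard"}.
#' @param jaccard_theta overlap threshold for the Jaccard rule.
#' @param weight_scheme \code{"inverse_distance"} (normalized reciprocal
#'   distances, default) or \code{"rank"} (linearly decaying by retrieval
#'   rank).
#' @param use_rank_weights weight each preference attribute inside the
#'   Euclidean distance by its elicited priority rank
#'   (\code{w_i = (n - rank_i + 1) / sum(1..n)}); off by default, which
#'   gives the plain Euclidean distance.
#' @param epsilon guard added to distances before taking reciprocals, so an
#'   exact match dominates without collapsing the weight vector.
#' @return an object of class \code{inference_config}.
#' @export
inference_config <- function(k = 5L,
                             condition_match_rule = c("subset", "exact",
                                                      "jaccard"),
                             jaccard_theta = 0.5,
                             weight_scheme = c("inverse_distance", "rank"),
                             use_rank_weights = FALSE,
                             epsilon = 1e-6) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  structure(list(k = as.integer(k),
                 condition_match_rule = match.arg(condition_match_rule),
                 jaccard_theta = jaccard_theta,
                 weight_scheme = match.arg(weight_scheme),
                 use_rank_weights = isTRUE(use_rank_weights),
                 epsilon = epsilon),
            class = "inference_config")
}

#' Construct a query patient
#'
#' @param conditions character vector of the patient's condition terms.
#' @param preference_vector data.frame with columns \code{attribute},
#'   \code{value} (VAS in [0,100]) and \code{rank} (permutation of 1..n).
#' @return an object of class \code{query_patient}.
#' @export
query_patient <- function(conditions, preference_vector) {
  pv <- preference_vector
  stopifnot(is.data.frame(pv),
            all(c("attribute", "value", "rank") %in% names(pv)))
  if (any(pv$value < 0 | pv$value > 100)) {
    stop("VAS values must lie in [0, 100]", call. = FALSE)
  }
  if (!setequal(pv$rank, seq_len(nrow(pv)))) {
    stop("priority ranks must be a permutation of 1..n", call. = FALSE)
  }
  structure(list(conditions = .normalize_condition(conditions),
                 preference_vector = data.frame(
                   attribute = as.character(pv$attribute),
                   value = as.numeric(pv$value),
                   rank = as.integer(pv$rank), stringsAsFactors = FALSE)),
            class = "query_patient")
}

#' Local similarity between two VAS values
#'
#' \code{1 - |a - b| / 100}: 1 for identical values, 0 at the extremes of
#' the scale. Symmetric.
#'
#' @param a_query,a_case VAS values in [0, 100] (vectorized).
#' @return similarity in [0, 1].
#' @examples
#' local_similarity(30, 70)  # 0.6
#' @export
local_similarity <- function(a_query, a_case) {
  if (any(a_query < 0 | a_query > 100 | a_case < 0 | a_case > 100)) {
    stop("VAS values must lie in [0, 100]", call. = FALSE)
  }
  1 - abs(a_query - a_case) / 100
}

.aligned_values <- function(q, cs) {
  qa <- q$preference_vector$attribute
  ca <- cs$preference_vector$attribute
  if (!setequal(qa, ca) || anyDuplicated(qa) || anyDuplicated(ca)) {
    stop("preference attribute schemas do not match (query: ",
         paste(qa, collapse = ","), "; case: ",
         paste(ca, collapse = ","), ")", call. = FALSE)
  }
  m <- match(qa, ca)
  list(q = q$preference_vector$value,
       c = cs$preference_vector$value[m],
       rank = q$preference_vector$rank,
       attr = qa)
}

#' Global preference distance between a query and a stored case
#'
#' Euclidean norm of the attribute-wise VAS differences on the normalized
#' [0,1] scale (each difference divided by 100). With
#' \code{use_rank_weights} the squared differences are weighted by the
#' query's priority ranks.
#'
#' @param q a \code{\link{query_patient}}.
#' @param cs an \code{\link{experience_case}} sharing the attribute schema.
#' @param use_rank_weights see \code{\link{inference_config}}.
#' @return non-negative distance; 0 iff the vectors are identical.
#' @export
global_distance <- function(q, cs, use_rank_weights = FALSE) {
  al <- .aligned_values(q, cs)
  diffs <- (al$q - al$c) / 100
  if (use_rank_weights) {
    n <- length(al$rank)
    w <- (n - al$rank + 1) / sum(seq_len(n))
    sqrt(sum(w * diffs^2))
  } else {
    sqrt(sum(diffs^2))
  }
}

#' Retrieve the k nearest experience cases for a query patient
#'
#' The engine first hard-filters the knowledge base by condition match,
#' then ranks the surviving cases by global preference distance and keeps
#' the \code{min(k, n)} nearest, with deterministic ties broken by case id.
#' If no case matches the conditions the result is empty with status
#' \code{"no_experience"} rather than an error.
#'
#' @param q a \code{\link{query_patient}}.
#' @param store a \code{triple_store} or list of
#'   \code{\link{experience_case}}.
#' @param cfg an \code{\link{inference_config}}.
#' @return an object of class \code{eie_retrieval}: \code{results}
#'   (data.frame of case_id, distance, weight, decision, plus a
#'   list-column \code{local_similarities}), \code{cases} (the retrieved
#'   case objects) and \code{status} (\code{"ok"} or
#'   \code{"no_experience"}).
#' @export
knn_retrieve <- function(q, store, cfg = inference_config()) {
  stopifnot(inherits(q, "query_patient"), inherits(cfg, "inference_config"))
  matched <- query_cases_by_condition(store, q$conditions,
                                      rule = cfg$condition_match_rule,
                                      theta = cfg$jaccard_theta)
  if (!length(matched)) {
    return(structure(list(
      results = data.frame(case_id = character(0), distance = numeric(0),
                           weight = numeric(0), decision = character(0),
                           stringsAsFactors = FALSE),
      cases = list(), status = "no_experience", query = q, config = cfg),
      class = "eie_retrieval"))
  }
  dists <- vapply(matched, function(cs) {
    global_distance(q, cs, cfg$use_rank_weights)
  }, numeric(1))
  ids <- vapply(matched, `[[`, character(1), "case_id")
  ord <- order(dists, ids)
  keep <- ord[seq_len(min(cfg$k, length(ord)))]
  res <- data.frame(case_id = ids[keep], distance = dists[keep],
                    weight = NA_real_,
                    decision = vapply(matched[keep], `[[`, character(1),
                                      "decision"),
                    stringsAsFactors = FALSE)
  res$local_similarities <- lapply(matched[keep], function(cs) {
    al <- .aligned_values(q, cs)
    stats::setNames(local_similarity(al$q, al$c), al$attr)
  })
  out <- structure(list(results = res, cases = matched[keep], status = "ok",
                        query = q, config = cfg),
                   class = "eie_retrieval")
  compute_weights(out, cfg)
}

#' Turn retrieval distances into normalized case weights
#'
#' Inverse-distance scheme: \code{w_i = (1/(d_i + eps)) / sum_j 1/(d_j +
#' eps)}; weights sum to one and strictly decrease with distance. The
#' \code{"rank"} scheme instead decays linearly with retrieval rank.
#'
#' @param retrieval an \code{eie_retrieval} (or its \code{results}
#'   data.frame with a \code{distance} column).
#' @param cfg an \code{\link{inference_config}}.
#' @return the input with the \code{weight} column filled.
#' @export
compute_weights <- function(retrieval, cfg = inference_config()) {
  is_obj <- inherits(retrieval, "eie_retrieval")
  res <- if (is_obj) retrieval$results else retrieval
  if (nrow(res)) {
    w <- switch(cfg$weight_scheme,
                inverse_distance = 1 / (res$distance + cfg$epsilon),
                rank = rev(seq_len(nrow(res))))
    res$weight <- w / sum(w)
  }
  if (is_obj) {
    retrieval$results <- res
    retrieval
  } else {
    res
  }
}

#' @export
print.eie_retrieval <- function(x, ...) {
  if (x$status == "no_experience") {
    cat("<eie_retrieval> no experience available for these conditions\n")
    return(invisible(x))
  }
  cat(sprintf("<eie_retrieval> %d case(s) (k = %d, rule = %s)\n",
              nrow(x$results), x$config$k, x$config$condition_match_rule))
  print(x$results[, c("case_id", "distance", "weight", "decision")],
        digits = 4)
  invisible(x)
}

#' @export
summary.eie_retrieval <- function(object, ...) {
  print(object)
  if (object$status == "ok") {
    sims <- do.call(rbind, object$results$local_similarities)
    cat("\nLocal similarities per preference attribute:\n")
    print(round(sims, 3))
  }
  invisible(object)
}

#' Re-rank objective candidate decisions by retrieved experience
#'
#' Each candidate decision accumulates the weights of the retrieved cases
#' that chose it; candidates are then sorted by accumulated experience
#' weight (descending), ties broken by their original objective rank, and
#' candidates no retrieved case chose keep their relative objective order
#' after the weighted ones. With an empty retrieval the objective order is
#' returned unchanged.
#'
#' @param objective ordered character vector of candidate decision terms
#'   (best objective candidate first).
#' @param retrieval an \code{eie_retrieval}.
#' @return an object of class \code{ranked_decisions}: a data.frame with
#'   \code{decision}, \code{experience_weight}, \code{original_rank},
#'   \code{final_rank}.
#' @export
rerank_decisions <- function(objective, retrieval) {
  stopifnot(length(objective) >= 1L)
  objective <- as.character(objective)
  res <- retrieval$results
  wsum <- vapply(objective, function(d) {
    sum(res$weight[.normalize_condition(res$decision) ==
                     .normalize_condition(d)])
  }, numeric(1))
  df <- data.frame(decision = objective, experience_weight = unname(wsum),
                   original_rank = seq_along(objective),
                   stringsAsFactors = FALSE)
  ord <- order(-df$experience_weight, df$original_rank)
  df <- df[ord, , drop = FALSE]
  df$final_rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("ranked_decisions", "data.frame"))
}

#' @export
print.ranked_decisions <- function(x, ...) {
  cat("<ranked_decisions>\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Recompute the recommendation under a modified preference
#'
#' What-if exploration: one preference attribute of the query is
#' substituted and the retrieval (and, when candidates are given, the
#' re-ranking) is recomputed. The original query object is not modified.
#'
#' @param q a \code{\link{query_patient}}.
#' @param attribute name of the preference attribute to change.
#' @param new_value new VAS value in [0, 100].
#' @param store case source (triple store or case list).
#' @param cfg an \code{\link{inference_config}}.
#' @param objective optional ordered candidate decisions to re-rank.
#' @return list with \code{retrieval} (an \code{eie_retrieval}) and
#'   \code{ranked} (a \code{ranked_decisions}, or \code{NULL}).
#' @export
what_if <- function(q, attribute, new_value, store,
                    cfg = inference_config(), objective = NULL) {
  pv <- q$preference_vector
  i <- match(attribute, pv$attribute)
  if (is.na(i)) {
    stop("unknown preference attribute: '", attribute, "' (schema: ",
         paste(pv$attribute, collapse = ", "), ")", call. = FALSE)
  }
  if (new_value < 0 || new_value > 100) {
    stop("VAS values must lie in [0, 100]", call. = FALSE)
  }
  pv$value[[i]] <- new_value
  q2 <- query_patient(q$conditions, pv)
  retrieval <- knn_retrieve(q2, store, cfg)
  ranked <- if (!is.null(objective)) rerank_decisions(objective, retrieval)
  list(retrieval = retrieval, ranked = ranked)
}
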