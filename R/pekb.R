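#' Namespace prefixes used by the knowledge base
#'
#' @format named character vector: prefix -> namespace IRI.
#' @export
PEKB_PREFIXES <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  cso  = "http://example.org/cso#",
  marl = "http://www.gsi.upm.es/ontologies/marl/ns#",
  OGMS = "http://purl.obolibrary.org/obo/ogms#",
  ex   = "http://example.org/pekb/")

# Classes of the merged Clinical Sentiment Ontology schema (clinical
# diagnosis layer, Marl opinion layer, application layer).
.CSO_CLASSES <- c(
  "OGMS:disease", "OGMS:diagnosis", "OGMS:therapeuticProcedure",
  "cso:Problem", "cso:Complication", "cso:Therapy",
  "marl:SentimentAnalysis", "marl:Opinion", "marl:SourceText",
  "marl:DescribedObject", "marl:DescribedObjectFeature",
  "cso:AnalysisResult", "cso:AnalyzedExperience",
  "cso:AnalyzedExperienceAspect", "cso:ClinicalConditionSet",
  "cso:ClinicalOpinionSet")

.CSO_SUBCLASS <- c("cso:ClinicalConditionSet" = "cso:AnalysisResult",
                   "cso:ClinicalOpinionSet" = "cso:AnalysisResult")

# Properties; the ones marked ext are artifact extensions needed to store
# preference vectors, decisions and provenance that the ontology diagram
# does not draw.
.CSO_PROPERTIES <- c(
  "cso:hasConditions", "cso:hasOpinionSet", "cso:hasCondition",
  "cso:hasProcedure", "marl:hasPolarity", "marl:describesObject",
  "marl:hasOpinion",
  # extensions
  "cso:containsOpinion", "cso:caseId", "cso:opinionWord", "cso:docId",
  "cso:sentenceIndex", "cso:hasPreferenceAttribute", "cso:attributeName",
  "cso:attributeIndex", "cso:vasValue", "cso:priorityRank",
  "cso:hasDecision", "rdf:type", "rdfs:label", "rdfs:subClassOf")

#' The Clinical Sentiment Ontology schema
#'
#' Returns the merged schema (clinical diagnosis concepts, the Marl opinion
#' vocabulary and the application layer) as declared class and property
#' names with their subclass axioms. Every triple the package emits uses
#' only declared properties; \code{\link{validate_store}} enforces this
#' closure.
#'
#' @return a list with \code{classes}, \code{properties},
#'   \code{subclass_of} (named character vector child -> parent) and
#'   \code{prefixes}.
#' @export
cso_schema <- function() {
  list(classes = .CSO_CLASSES, properties = .CSO_PROPERTIES,
       subclass_of = .CSO_SUBCLASS, prefixes = PEKB_PREFIXES)
}

#' Create an (empty) triple store
#'
#' A minimal in-memory RDF store: a data.frame of
#' (subject, predicate, object, object_type) rows with set semantics;
#' \code{object_type} is \code{"iri"} or \code{"literal"}.
#'
#' @param triples optional data.frame with those four columns.
#' @return an object of class \code{triple_store}.
#' @export
triple_store <- function(triples = NULL) {
  if (is.null(triples)) {
    triples <- data.frame(subject = character(0), predicate = character(0),
                          object = character(0), object_type = character(0),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("subject", "predicate", "object", "object_type") %in%
                  names(triples)))
  stopifnot(all(triples$object_type %in% c("iri", "literal")))
  triples <- unique(triples[, c("subject", "predicate", "object",
                                "object_type")])
  rownames(triples) <- NULL
  structure(list(triples = triples), class = "triple_store")
}

#' @export
print.triple_store <- function(x, ...) {
  cat(sprintf("<triple_store> %d triple(s), %d subject(s)\n",
              nrow(x$triples), length(unique(x$triples$subject))))
  invisible(x)
}

.ts_key <- function(df) {
  paste(df$subject, df$predicate, df$object, df$object_type, sep = "\r")
}

#' Add triples / merge stores / compare stores as sets
#'
#' @param store a \code{triple_store}.
#' @param subject,predicate,object triple components (vectors recycle).
#' @param object_type \code{"iri"} or \code{"literal"}.
#' @return the grown \code{triple_store}.
#' @export
ts_add <- function(store, subject, predicate, object, object_type = "iri") {
  new <- data.frame(subject = subject, predicate = predicate,
                    object = object, object_type = object_type,
                    stringsAsFactors = FALSE)
  triple_store(rbind(store$triples, new))
}

#' @rdname ts_add
#' @param a,b two \code{triple_store}s.
#' @export
ts_union <- function(a, b) triple_store(rbind(a$triples, b$triples))

#' @rdname ts_add
#' @export
ts_equal <- function(a, b) {
  setequal(.ts_key(a$triples), .ts_key(b$triples))
}

#' Check schema closure of a store
#'
#' Every predicate must be a declared property and every \code{rdf:type}
#' object a declared class of the CSO schema.
#'
#' @param store a \code{triple_store}.
#' @return \code{TRUE} invisibly; otherwise an error naming the violation.
#' @export
validate_store <- function(store) {
  schema <- cso_schema()
  bad_p <- setdiff(unique(store$triples$predicate), schema$properties)
  if (length(bad_p)) {
    stop("schema violation: undeclared predicate(s): ",
         paste(bad_p, collapse = ", "), call. = FALSE)
  }
  types <- store$triples$object[store$triples$predicate == "rdf:type"]
  bad_c <- setdiff(unique(types), schema$classes)
  if (length(bad_c)) {
    stop("schema violation: undeclared class(es): ",
         paste(bad_c, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescape_literal <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[[k]], "", fixed = TRUE)[[1L]]
    buf <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[[i]]
      if (ch == "\\" && i < length(chars)) {
        nx <- chars[[i + 1L]]
        buf <- c(buf, switch(nx, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nx))
        i <- i + 2L
      } else {
        buf <- c(buf, ch)
        i <- i + 1L
      }
    }
    out[[k]] <- paste(buf, collapse = "")
  }
  out
}

#' Save a triple store as Turtle
#'
#' Writes prefix declarations followed by one triple per statement
#' (\code{rdf:type} abbreviated to \code{a}); literals are quoted and
#' escaped. \code{load_pekb(save_pekb(x))} reproduces the identical triple
#' set.
#'
#' @param store a \code{triple_store}.
#' @param path output \code{.ttl} path.
#' @return \code{path}, invisibly.
#' @export
save_pekb <- function(store, path) {
  stopifnot(inherits(store, "triple_store"))
  hdr <- sprintf("@prefix %s: <%s> .", names(PEKB_PREFIXES), PEKB_PREFIXES)
  df <- store$triples
  if (nrow(df)) {
    df <- df[order(df$subject, df$predicate, df$object), , drop = FALSE]
    obj <- ifelse(df$object_type == "literal",
                  paste0("\"", .escape_literal(df$object), "\""),
                  df$object)
    pred <- ifelse(df$predicate == "rdf:type", "a", df$predicate)
    body <- sprintf("%s %s %s .", df$subject, pred, obj)
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, "", body), path)
  invisible(path)
}

#' Load a triple store from Turtle
#'
#' Parses the single-statement Turtle subset written by
#' \code{\link{save_pekb}} (prefixed names, quoted literals, \code{a} for
#' \code{rdf:type}).
#'
#' @param path path to a \code{.ttl} file.
#' @return a \code{triple_store}.
#' @export
load_pekb <- function(path) {
  if (!file.exists(path)) stop("PEKB file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  subj <- character(0); pred <- character(0)
  obj <- character(0); typ <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "@prefix")) next
    m <- regexec("^(\\S+)\\s+(\\S+)\\s+(.+?)\\s*\\.$", ln)[[1L]]
    if (m[1L] == -1L) {
      stop("Turtle parse error at line ", i, ": '", ln, "'", call. = FALSE)
    }
    parts <- regmatches(ln, list(m))[[1L]]
    s <- parts[[2L]]; p <- parts[[3L]]; o <- parts[[4L]]
    if (p == "a") p <- "rdf:type"
    if (startsWith(o, "\"")) {
      if (!grepl("\"$", o) || nchar(o) < 2L) {
        stop("Turtle parse error at line ", i, ": unterminated literal",
             call. = FALSE)
      }
      o_val <- .unescape_literal(substr(o, 2L, nchar(o) - 1L))
      t_val <- "literal"
    } else {
      o_val <- o
      t_val <- "iri"
    }
    subj <- c(subj, s); pred <- c(pred, p); obj <- c(obj, o_val)
    typ <- c(typ, t_val)
  }
  triple_store(data.frame(subject = subj, predicate = pred, object = obj,
                          object_type = typ, stringsAsFactors = FALSE))
}

.normalize_condition <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

.slug <- function(x) gsub("[^a-z0-9]+", "-", tolower(trimws(x)))

#' Construct a patient experience case
#'
#' One record of the Patient Experience Knowledge Base: the patient's
#' clinical conditions, the procedure they went through, their mined
#' opinions, a preference vector on the visual analogue scale (VAS,
#' 0--100 per attribute, each attribute also ranked by priority), the
#' decision they took and the overall outcome polarity.
#'
#' @param case_id unique identifier.
#' @param conditions non-empty character vector of condition terms
#'   (free-text normalized: lower case, collapsed whitespace).
#' @param procedure procedure term (may be \code{NA}).
#' @param preference_vector data.frame with columns \code{attribute},
#'   \code{value} (VAS in [0,100]) and \code{rank} (a permutation of
#'   \code{1..n}).
#' @param decision decision term.
#' @param overall_polarity polarity of the reported outcome.
#' @param opinions optional data.frame slice with columns \code{feature},
#'   \code{opinion_word}, \code{polarity}, \code{doc_id},
#'   \code{sentence_index}.
#' @return an object of class \code{experience_case}.
#' @export
experience_case <- function(case_id, conditions, procedure = NA_character_,
                            preference_vector, decision,
                            overall_polarity = "neutral", opinions = NULL) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  conditions <- .normalize_condition(conditions)
  if (!length(conditions) || any(!nzchar(conditions))) {
    stop("conditions must be non-empty", call. = FALSE)
  }
  pv <- preference_vector
  stopifnot(is.data.frame(pv), all(c("attribute", "value", "rank") %in%
                                     names(pv)))
  if (any(pv$value < 0 | pv$value > 100)) {
    stop("VAS values must lie in [0, 100]", call. = FALSE)
  }
  if (!setequal(pv$rank, seq_len(nrow(pv)))) {
    stop("priority ranks must be a permutation of 1..n", call. = FALSE)
  }
  .assert_polarity(overall_polarity, "overall_polarity")
  if (is.null(opinions)) {
    opinions <- data.frame(feature = character(0), opinion_word = character(0),
                           polarity = character(0), doc_id = character(0),
                           sentence_index = integer(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(case_id = case_id, conditions = sort(unique(conditions)),
                 procedure = procedure,
                 preference_vector = data.frame(
                   attribute = as.character(pv$attribute),
                   value = as.numeric(pv$value),
                   rank = as.integer(pv$rank), stringsAsFactors = FALSE),
                 decision = as.character(decision),
                 overall_polarity = overall_polarity,
                 opinions = opinions),
            class = "experience_case")
}

#' @export
print.experience_case <- function(x, ...) {
  cat(sprintf("<experience_case> %s\n  conditions: %s\n  decision: %s (%s)\n",
              x$case_id, paste(x$conditions, collapse = ", "),
              x$decision, x$overall_polarity))
  cat(sprintf("  preferences: %s\n",
              paste(sprintf("%s=%g(r%d)", x$preference_vector$attribute,
                            x$preference_vector$value,
                            x$preference_vector$rank), collapse = " ")))
  invisible(x)
}

# ---- opinion mapping ------------------------------------------------------

#' Map mined opinions and patient metadata to ontology individuals
#'
#' Emits the individual graph: the case node is a
#' \code{cso:AnalyzedExperience} carrying conditions
#' (\code{cso:hasCondition}), the procedure node
#' (\code{cso:hasProcedure}, typed \code{OGMS:therapeuticProcedure}) and an
#' aggregate \code{marl:hasPolarity}; a \code{cso:ClinicalOpinionSet} node
#' groups one \code{marl:Opinion} individual per mined opinion, each
#' pointing at a shared \code{marl:DescribedObject} node for its feature
#' and carrying polarity, the opinion word and a textual gloss
#' (\code{marl:hasOpinion}).
#'
#' @param opinions an \code{opinion_set} (or its \code{$opinions}
#'   data.frame).
#' @param meta list with \code{case_id}, \code{conditions}, optional
#'   \code{procedure} and \code{source_text}.
#' @return a schema-valid \code{triple_store}.
#' @export
map_opinions_to_individuals <- function(opinions, meta) {
  ops <- if (inherits(opinions, "opinion_set")) opinions$opinions else opinions
  stopifnot(!is.null(meta$case_id), !is.null(meta$conditions))
  case <- paste0("ex:case-", .slug(meta$case_id))
  st <- triple_store()
  st <- ts_add(st, case, "rdf:type", "cso:AnalyzedExperience")
  st <- ts_add(st, case, "cso:caseId", as.character(meta$case_id), "literal")
  for (cond in .normalize_condition(meta$conditions)) {
    st <- ts_add(st, case, "cso:hasCondition", cond, "literal")
  }
  if (!is.null(meta$procedure) && !is.na(meta$procedure)) {
    proc <- paste0(case, "-proc")
    st <- ts_add(st, case, "cso:hasProcedure", proc)
    st <- ts_add(st, proc, "rdf:type", "OGMS:therapeuticProcedure")
    st <- ts_add(st, proc, "rdfs:label", as.character(meta$procedure),
                 "literal")
  }
  if (!is.null(meta$source_text)) {
    st <- ts_add(st, case, "marl:hasOpinion", as.character(meta$source_text),
                 "literal")
  }
  if (nrow(ops)) {
    st <- ts_add(st, case, "marl:hasPolarity",
                 .majority_polarity(ops$polarity), "literal")
    opset <- paste0(case, "-ops")
    st <- ts_add(st, case, "cso:hasOpinionSet", opset)
    st <- ts_add(st, opset, "rdf:type", "cso:ClinicalOpinionSet")
    for (i in seq_len(nrow(ops))) {
      op <- sprintf("%s-op%d", case, i)
      objn <- paste0(case, "-obj-", .slug(ops$feature[[i]]))
      st <- ts_add(st, opset, "cso:containsOpinion", op)
      st <- ts_add(st, op, "rdf:type", "marl:Opinion")
      st <- ts_add(st, op, "marl:describesObject", objn)
      st <- ts_add(st, op, "marl:hasPolarity", ops$polarity[[i]], "literal")
      st <- ts_add(st, op, "cso:opinionWord", ops$opinion_word[[i]], "literal")
      st <- ts_add(st, op, "marl:hasOpinion",
                   sprintf("%s: %s", ops$feature[[i]], ops$opinion_word[[i]]),
                   "literal")
      if ("doc_id" %in% names(ops)) {
        st <- ts_add(st, op, "cso:docId", as.character(ops$doc_id[[i]]),
                     "literal")
        st <- ts_add(st, op, "cso:sentenceIndex",
                     as.character(ops$sentence_index[[i]]), "literal")
      }
      st <- ts_add(st, objn, "rdf:type", "marl:DescribedObject")
      st <- ts_add(st, objn, "rdfs:label", ops$feature[[i]], "literal")
    }
  }
  validate_store(st)
  st
}

# ---- experience cases <-> triples ----------------------------------------

#' Convert an experience case to / from triples
#'
#' The conversion is lossless for every schema field (conditions,
#' procedure, preference vector including attribute order, decision,
#' outcome polarity, opinion slice).
#'
#' @param case an \code{\link{experience_case}}.
#' @return a \code{triple_store} (\code{case_to_triples}) or an
#'   \code{experience_case} (\code{triples_to_case}).
#' @export
case_to_triples <- function(case) {
  stopifnot(inherits(case, "experience_case"))
  st <- map_opinions_to_individuals(
    case$opinions,
    list(case_id = case$case_id, conditions = case$conditions,
         procedure = case$procedure))
  node <- paste0("ex:case-", .slug(case$case_id))
  st <- ts_add(st, node, "cso:hasDecision", case$decision, "literal")
  st <- ts_add(st, node, "marl:hasPolarity", case$overall_polarity, "literal")
  pv <- case$preference_vector
  for (i in seq_len(nrow(pv))) {
    pn <- sprintf("%s-pref%d", node, i)
    st <- ts_add(st, node, "cso:hasPreferenceAttribute", pn)
    st <- ts_add(st, pn, "rdf:type", "cso:AnalyzedExperienceAspect")
    st <- ts_add(st, pn, "cso:attributeName", pv$attribute[[i]], "literal")
    st <- ts_add(st, pn, "cso:attributeIndex", as.character(i), "literal")
    st <- ts_add(st, pn, "cso:vasValue",
                 format(pv$value[[i]], digits = 15L), "literal")
    st <- ts_add(st, pn, "cso:priorityRank", as.character(pv$rank[[i]]),
                 "literal")
  }
  validate_store(st)
  st
}

.subject_objects <- function(df, s, p) {
  df$object[df$subject == s & df$predicate == p]
}

#' @rdname case_to_triples
#' @param store a \code{triple_store} holding the case's triples.
#' @param case_node the case's subject node (e.g. \code{"ex:case-c1"}).
#' @export
triples_to_case <- function(store, case_node) {
  df <- store$triples
  cid <- .subject_objects(df, case_node, "cso:caseId")
  if (!length(cid)) stop("no case at node ", case_node, call. = FALSE)
  conds <- .subject_objects(df, case_node, "cso:hasCondition")
  proc_node <- .subject_objects(df, case_node, "cso:hasProcedure")
  proc <- if (length(proc_node)) {
    .subject_objects(df, proc_node[[1L]], "rdfs:label")[[1L]]
  } else NA_character_
  decision <- .subject_objects(df, case_node, "cso:hasDecision")
  pols <- .subject_objects(df, case_node, "marl:hasPolarity")
  pref_nodes <- .subject_objects(df, case_node, "cso:hasPreferenceAttribute")
  pv <- do.call(rbind, lapply(pref_nodes, function(pn) {
    data.frame(
      attribute = .subject_objects(df, pn, "cso:attributeName")[[1L]],
      value = as.numeric(.subject_objects(df, pn, "cso:vasValue")[[1L]]),
      rank = as.integer(.subject_objects(df, pn, "cso:priorityRank")[[1L]]),
      idx = as.integer(.subject_objects(df, pn, "cso:attributeIndex")[[1L]]),
      stringsAsFactors = FALSE)
  }))
  pv <- pv[order(pv$idx), c("attribute", "value", "rank"), drop = FALSE]
  opset <- .subject_objects(df, case_node, "cso:hasOpinionSet")
  ops <- NULL
  if (length(opset)) {
    op_nodes <- sort(.subject_objects(df, opset[[1L]], "cso:containsOpinion"))
    ops <- do.call(rbind, lapply(op_nodes, function(op) {
      objn <- .subject_objects(df, op, "marl:describesObject")[[1L]]
      si <- .subject_objects(df, op, "cso:sentenceIndex")
      data.frame(
        feature = .subject_objects(df, objn, "rdfs:label")[[1L]],
        opinion_word = .subject_objects(df, op, "cso:opinionWord")[[1L]],
        polarity = .subject_objects(df, op, "marl:hasPolarity")[[1L]],
        doc_id = c(.subject_objects(df, op, "cso:docId"), NA_character_)[[1L]],
        sentence_index = if (length(si)) as.integer(si[[1L]]) else NA_integer_,
        stringsAsFactors = FALSE)
    }))
  }
  # the case-level aggregate polarity may coincide with the stored outcome
  # polarity; the outcome is the one written by case_to_triples (both are
  # present when opinions exist; outcome is recovered as the value that is
  # not the opinion aggregate, or the single value otherwise)
  outcome <- if (length(pols) == 1L) {
    pols[[1L]]
  } else {
    agg <- .majority_polarity(ops$polarity)
    rest <- setdiff(pols, agg)
    if (length(rest)) rest[[1L]] else agg
  }
  experience_case(case_id = cid[[1L]], conditions = conds, procedure = proc,
                  preference_vector = pv, decision = decision[[1L]],
                  overall_polarity = outcome, opinions = ops)
}

#' List case nodes in a store
#' @param store a \code{triple_store}.
#' @return character vector of subject nodes carrying a \code{cso:caseId}.
#' @export
case_nodes <- function(store) {
  df <- store$triples
  sort(unique(df$subject[df$predicate == "cso:caseId" &
                           df$subject %in%
                             df$subject[df$predicate == "rdf:type" &
                                          df$object == "cso:AnalyzedExperience"]]))
}

.match_conditions <- function(query, case_conds, rule, theta) {
  query <- .normalize_condition(query)
  case_conds <- .normalize_condition(case_conds)
  switch(rule,
         exact = setequal(query, case_conds),
         subset = all(query %in% case_conds),
         jaccard = {
           u <- union(query, case_conds)
           length(intersect(query, case_conds)) / max(length(u), 1L) >= theta
         },
         stop("unknown condition match rule: ", rule, call. = FALSE))
}

#' Retrieve cases whose conditions match a query
#'
#' Condition matching is the hard pre-filter of the inference engine. The
#' default rule requires the query's conditions to be a subset of the
#' case's; \code{"exact"} demands set equality and \code{"jaccard"} accepts
#' overlap of at least \code{theta}.
#'
#' @param store a \code{triple_store} or a list of
#'   \code{\link{experience_case}}.
#' @param conditions character vector of query condition terms.
#' @param rule one of \code{"subset"}, \code{"exact"}, \code{"jaccard"}.
#' @param theta Jaccard threshold for \code{rule = "jaccard"}.
#' @return list of matching \code{experience_case}, ordered by case id.
#' @export
query_cases_by_condition <- function(store, conditions, rule = "subset",
                                     theta = 0.5) {
  cases <- if (inherits(store, "triple_store")) {
    lapply(case_nodes(store), function(n) triples_to_case(store, n))
  } else {
    store
  }
  hits <- Filter(function(cs) {
    .match_conditions(conditions, cs$conditions, rule, theta)
  }, cases)
  hits[order(vapply(hits, `[[`, character(1), "case_id"))]
}

#' Add a newly learned case to the knowledge base
#'
#' Self-learning step: the case's triples are appended so later condition
#' queries see it. A duplicate case id is a conflict and leaves the store
#' unchanged.
#'
#' @param store a \code{triple_store}.
#' @param case an \code{\link{experience_case}}.
#' @return the grown \code{triple_store}.
#' @export
register_learned_case <- function(store, case) {
  stopifnot(inherits(store, "triple_store"),
            inherits(case, "experience_case"))
  ids <- store$triples$object[store$triples$predicate == "cso:caseId"]
  if (case$case_id %in% ids) {
    stop("conflict: case_id '", case$case_id, "' already present",
         call. = FALSE)
  }
  ts_union(store, case_to_triples(case))
}

#' Build a knowledge base from a list of cases
#' @param cases list of \code{\link{experience_case}}.
#' @return a \code{triple_store}.
#' @export
build_pekb <- function(cases) {
  st <- triple_store()
  for (cs in cases) st <- register_learned_case(st, cs)
  st
}

# ---- JSON mirror ----------------------------------------------------------

#' Read / write experience cases as JSON
#'
#' The JSON case store mirrors the Turtle knowledge base for the inference
#' engine's hot path; \code{cases_from_json(cases_to_json(x))} is the
#' identity and building a store from either side yields equal triple sets.
#'
#' @param cases list of \code{\link{experience_case}}.
#' @param path file path.
#' @return \code{path} invisibly (write); list of cases (read).
#' @export
cases_to_json <- function(cases, path) {
  payload <- lapply(cases, function(cs) {
    list(case_id = cs$case_id, conditions = as.list(cs$conditions),
         procedure = cs$procedure,
         preference_vector = cs$preference_vector,
         decision = cs$decision, overall_polarity = cs$overall_polarity,
         opinions = cs$opinions)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname cases_to_json
#' @export
cases_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
  n <- if (is.data.frame(payload)) nrow(payload) else length(payload)
  lapply(seq_len(n), function(i) {
    item <- if (is.data.frame(payload)) lapply(payload, `[[`, i) else payload[[i]]
    ops <- item$opinions
    if (!is.null(ops) && is.data.frame(ops) && nrow(ops)) {
      ops$sentence_index <- as.integer(ops$sentence_index)
    } else {
      ops <- NULL
    }
    experience_case(
      case_id = item$case_id,
      conditions = unlist(item$conditions),
      procedure = if (is.null(item$procedure)) NA_character_ else item$procedure,
      preference_vector = as.data.frame(item$preference_vector),
      decision = item$decision,
      overall_polarity = item$overall_polarity,
      opinions = ops)
  })
}
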