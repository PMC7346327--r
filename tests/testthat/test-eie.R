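test_that("local similarity is 1 - |a-b|/100 on the VAS scale", {
  expect_equal(local_similarity(50, 50), 1.0)
  expect_equal(local_similarity(0, 100), 0.0)
  expect_equal(local_similarity(30, 70), 0.6)
  expect_equal(local_similarity(70, 30), 0.6)  # symmetric
  expect_error(local_similarity(-1, 50), "\\[0, 100\\]")
  expect_error(local_similarity(10, 101), "\\[0, 100\\]")
})

test_that("global distance is the normalized Euclidean preference norm", {
  q <- query_patient("breast cancer", data.frame(
    attribute = c("a", "b"), value = c(0, 50), rank = 1:2))
  same <- make_case("c1", c(a = 0, b = 50), "A")
  expect_equal(global_distance(q, same), 0)
  far <- make_case("c2", c(a = 100, b = 50), "A")
  expect_equal(global_distance(q, far), 1)  # sqrt(1^2 + 0^2)
  # attribute alignment is by name, not order
  swapped <- experience_case("c3", "breast cancer",
                             preference_vector = data.frame(
                               attribute = c("b", "a"), value = c(50, 0),
                               rank = 1:2),
                             decision = "A")
  expect_equal(global_distance(q, swapped), 0)
  # random vectors match an independent recomputation
  set.seed(42)
  for (i in 1:20) {
    qv <- stats::runif(5, 0, 100); cv <- stats::runif(5, 0, 100)
    qq <- query_patient("x", data.frame(attribute = letters[1:5],
                                        value = qv, rank = 1:5))
    cc <- make_case("c", stats::setNames(cv, letters[1:5]), "A",
                    conditions = "x")
    expect_equal(global_distance(qq, cc), sqrt(sum(((qv - cv) / 100)^2)))
  }
  # mismatched schemas are an error
  bad <- make_case("c4", c(a = 1, z = 2), "A")
  expect_error(global_distance(q, bad), "schemas do not match")
})

test_that("knn retrieval equals the exhaustive sort, with sane edge cases", {
  q <- random_query(seed = 1)
  # single matching case with k = 3: weight 1
  one <- random_case_base(1, seed = 2)
  r <- knn_retrieve(q, one, inference_config(k = 3))
  expect_equal(nrow(r$results), 1L)
  expect_equal(r$results$weight, 1.0)
  # planted exact-match case comes first at distance 0
  base <- random_case_base(50, seed = 3)
  planted <- make_case("case-planted",
                       stats::setNames(q$preference_vector$value,
                                       q$preference_vector$attribute), "Z")
  r2 <- knn_retrieve(q, c(base, list(planted)), inference_config(k = 5))
  expect_equal(r2$results$case_id[[1L]], "case-planted")
  expect_equal(r2$results$distance[[1L]], 0)
  # agreement with the oracle on random bases
  for (s in 1:10) {
    cases <- random_case_base(sample(5:60, 1), seed = s + 10)
    qq <- random_query(seed = s + 50)
    got <- knn_retrieve(qq, cases, inference_config(k = 5))$results
    want <- oracle_knn(qq, cases, 5)
    expect_equal(got$case_id, want$case_id)
    expect_equal(got$distance, want$distance)
  }
  # no condition-matched case: empty result with a status flag, no error
  qx <- query_patient("unheard-of condition", q$preference_vector)
  r3 <- knn_retrieve(qx, base, inference_config())
  expect_equal(r3$status, "no_experience")
  expect_equal(nrow(r3$results), 0L)
})

test_that("inverse-distance weights are normalized and distance-monotone", {
  mk <- function(d) data.frame(case_id = paste0("c", seq_along(d)),
                               distance = d, weight = NA_real_,
                               decision = "A", stringsAsFactors = FALSE)
  cfg <- inference_config()
  expect_equal(compute_weights(mk(0.3), cfg)$weight, 1.0)
  expect_equal(compute_weights(mk(c(0.2, 0.2)), cfg)$weight, c(0.5, 0.5))
  d <- c(0.1, 0.3, 0.6)
  w <- compute_weights(mk(d), cfg)$weight
  raw <- 1 / (d + 1e-6)
  expect_equal(w, raw / sum(raw))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  # rank scheme decays linearly with retrieval rank
  wr <- compute_weights(mk(d), inference_config(weight_scheme = "rank"))$weight
  expect_equal(wr, c(3, 2, 1) / 6)
})

test_that("re-ranking accumulates case weights and is a permutation", {
  q <- random_query(seed = 7)
  base <- list(
    make_case("c1", c(attr1 = 10, attr2 = 10, attr3 = 10, attr4 = 10,
                      attr5 = 10), "second choice"),
    make_case("c2", c(attr1 = 12, attr2 = 12, attr3 = 12, attr4 = 12,
                      attr5 = 12), "second choice"),
    make_case("c3", c(attr1 = 90, attr2 = 90, attr3 = 90, attr4 = 90,
                      attr5 = 90), "first choice"))
  objective <- c("first choice", "second choice", "third choice")
  qq <- query_patient("breast cancer", data.frame(
    attribute = paste0("attr", 1:5), value = rep(11, 5), rank = 1:5))
  r <- knn_retrieve(qq, base, inference_config(k = 2))
  ranked <- rerank_decisions(objective, r)
  # all k nearest chose the objective #2 decision: promoted to rank 1
  expect_equal(ranked$decision[[1L]], "second choice")
  expect_equal(ranked$final_rank, 1:3)
  expect_setequal(ranked$decision, objective)
  # unweighted decisions keep their relative objective order
  expect_equal(ranked$decision[2:3], c("first choice", "third choice"))
  # weight comparison dominates objective order
  w <- vapply(objective, function(d) {
    sum(r$results$weight[r$results$decision == d])
  }, numeric(1))
  expect_true(all(diff(ranked$experience_weight) <= 0))
  expect_equal(sort(unname(w), decreasing = TRUE), ranked$experience_weight)
  # empty retrieval: objective order passes through
  r0 <- knn_retrieve(query_patient("none", qq$preference_vector), base,
                     inference_config())
  ranked0 <- rerank_decisions(objective, r0)
  expect_equal(ranked0$decision, objective)
  expect_equal(ranked0$experience_weight, rep(0, 3))
})

test_that("re-ranked output is always a permutation of the candidates", {
  for (s in 1:10) {
    cases <- random_case_base(30, seed = s)
    q <- random_query(seed = s + 200)
    r <- knn_retrieve(q, cases, inference_config(k = sample(1:8, 1)))
    objective <- sample(c("A", "B", "C", "D"))
    ranked <- rerank_decisions(objective, r)
    expect_setequal(ranked$decision, objective)
    expect_equal(sort(ranked$final_rank), seq_along(objective))
    expect_lte(sum(ranked$experience_weight), 1 + 1e-9)
  }
})

test_that("what-if recomputation is pure and coordinate-monotone", {
  cases <- random_case_base(40, seed = 9)
  q <- random_query(seed = 10)
  cfg <- inference_config(k = 5)
  base <- knn_retrieve(q, cases, cfg)
  # substituting the current value is a no-op
  a1 <- q$preference_vector$attribute[[1L]]
  same <- what_if(q, a1, q$preference_vector$value[[1L]], cases, cfg)
  expect_equal(same$retrieval$results, base$results)
  # the query object itself is untouched
  what_if(q, a1, 0, cases, cfg)
  expect_equal(q, random_query(seed = 10))
  # moving one attribute toward a case's value cannot increase its distance
  target <- cases[[1L]]
  tv <- target$preference_vector$value[
    match(a1, target$preference_vector$attribute)]
  qv <- q$preference_vector$value[[1L]]
  midway <- qv + (tv - qv) / 2
  moved <- what_if(q, a1, midway, cases, cfg)
  d0 <- global_distance(q, target)
  q2 <- query_patient(q$conditions, transform(
    q$preference_vector, value = replace(value, 1L, midway)))
  expect_lte(global_distance(q2, target), d0)
  # substitution to an exact stored vector retrieves it at distance 0
  exact <- q$preference_vector
  solo <- make_case("solo", stats::setNames(exact$value, exact$attribute),
                    "A")
  res <- what_if(q, a1, exact$value[[1L]], list(solo), cfg,
                 objective = c("A", "B"))
  expect_equal(res$retrieval$results$distance, 0)
  expect_equal(res$ranked$decision[[1L]], "A")
  # unknown attribute is a schema error
  expect_error(what_if(q, "nope", 50, cases, cfg), "unknown preference")
})

test_that("rescaling the whole VAS range leaves the retrieval order fixed", {
  cases <- random_case_base(30, seed = 21)
  q <- random_query(seed = 22)
  order0 <- knn_retrieve(q, cases, inference_config(k = 10))$results$case_id
  for (c_scale in c(0.25, 0.5, 0.9)) {
    scaled_cases <- lapply(cases, function(cs) {
      pv <- cs$preference_vector
      pv$value <- pv$value * c_scale
      experience_case(cs$case_id, cs$conditions, cs$procedure, pv,
                      cs$decision, cs$overall_polarity)
    })
    pv <- q$preference_vector
    pv$value <- pv$value * c_scale
    qs <- query_patient(q$conditions, pv)
    order1 <- knn_retrieve(qs, scaled_cases,
                           inference_config(k = 10))$results$case_id
    expect_equal(order1, order0)
  }
})

test_that("rank-weighted distance uses priority weights that sum to one", {
  q <- query_patient("x", data.frame(attribute = c("a", "b"),
                                     value = c(0, 0), rank = c(1L, 2L)))
  cs <- make_case("c", c(a = 100, b = 100), "A", conditions = "x",
                  ranks = c(1L, 2L))
  # weights (2/3, 1/3) on squared unit differences
  expect_equal(global_distance(q, cs, use_rank_weights = TRUE),
               sqrt(2 / 3 + 1 / 3))
  expect_equal(global_distance(q, cs), sqrt(2))
})
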