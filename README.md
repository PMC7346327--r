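# experia

Patient experience as evidence for clinical decision support.

Objective decision support ranks candidate clinical decisions from
guidelines and trials — evidence about *groups*. `experia` adds the missing
subjective side: it mines what similar patients actually said about the
procedures they went through, stores those opinions in an ontology-backed
knowledge base, and uses the experiences of the most similar patients to
re-rank the objective candidates for an individual. It is aimed at
researchers building patient-centred decision-support prototypes and at
anyone studying aspect-based opinion mining over health social-network
reviews.

## What it computes

**Opinion mining.** From POS-tagged reviews, noun phrases (maximal runs of
noun tokens) whose sentence support reaches a minimum-support threshold
become *frequent features*; the closest adjective in each sentence is the
feature's *opinion word*. Polarity comes from a 30-adjective seed lexicon
expanded to a fixpoint over a synonym/antonym graph: seeded synonyms give
the same polarity, antonyms the opposite, and the enlarged seed list feeds
the next sweep until nothing new resolves. The result is a table of
`(feature, opinion word, polarity)` opinions Θ.

**Knowledge base.** Opinions and case metadata are mapped to Clinical
Sentiment Ontology individuals (OGMS clinical concepts + the Marl opinion
vocabulary + an application layer) and persisted as RDF Turtle — the
Patient Experience Knowledge Base (PEKB). Save→load is the identity on
triple sets, and newly learned cases are registered incrementally.

**Experience inference.** A query patient brings a set of condition terms
and a preference vector on the visual analogue scale (VAS, 0–100 per
attribute). After a hard condition-match filter, stored cases are ranked by
Euclidean distance on the normalized preference vectors,

    d(q, c) = sqrt( Σ_i ((q_i − c_i) / 100)² ),

the k nearest are weighted by normalized inverse distance,
`w_i ∝ 1/(d_i + ε)`, and each objective candidate decision accumulates the
weights of the cases that chose it; candidates are re-ordered by that
experience weight (ties keep objective order). `what_if()` re-runs the
whole computation with one preference substituted.

## Worked example

Mine the shipped worked review (a breast-cancer patient describing a
stereotactic biopsy), then retrieve similar cases and re-rank candidates:

```r
library(experia)

fx <- worked_example_fixture()
theta <- mine_opinions(list(fx$document))
theta
#> <opinion_set> 7 opinion(s), 0 invalid word(s)
#>               feature opinion_word polarity       doc_id sentence_index
#> 1              biopsy excruciating negative plm-review-1              2
#> 2 stereotactic biopsy excruciating negative plm-review-1              2
#> 3                pain excruciating negative plm-review-1              2
#> 4              biopsy      radical negative plm-review-1              3
#> 5          mastectomy      radical negative plm-review-1              3
#> 6          mastectomy   unbearable negative plm-review-1              4
#> 7            recovery   unbearable negative plm-review-1              4
```

Every opinion is negative: "excruciating" resolves through its synonym
"painful" (a seed), "unbearable" through "excruciating" one sweep later,
"radical" through "extreme". Mapping Θ to the ontology
(`map_opinions_to_individuals(theta, fx$meta)`) yields the case individual
with `cso:hasCondition "breast cancer"`, a `cso:hasProcedure` node
labelled "stereotactic biopsy of the left breast" and
`marl:hasPolarity "negative"`.

```r
gen <- generate_case_base(default_case_base_plan(seed = 7))
plan <- default_case_base_plan(seed = 7)
a <- plan$archetypes[[1]]   # pain-averse archetype -> core needle biopsy
q <- query_patient(a$conditions,
                   data.frame(attribute = names(a$centroid),
                              value = unname(a$centroid), rank = 1:5))
r <- knn_retrieve(q, gen$cases, inference_config(k = 5))
r
#> <eie_retrieval> 5 case(s) (k = 5, rule = subset)
#>     case_id distance weight           decision
#> 1 case-0005  0.05001 0.3170 core needle biopsy
#> 2 case-0035  0.07252 0.2186 core needle biopsy
#> 3 case-0017  0.09345 0.1696 core needle biopsy
#> 4 case-0097  0.09798 0.1618 core needle biopsy
#> 5 case-0069  0.11912 0.1331 core needle biopsy

rerank_decisions(c("open surgical biopsy", "stereotactic biopsy",
                   "core needle biopsy"), r)
#> <ranked_decisions>
#>               decision experience_weight original_rank final_rank
#> 1   core needle biopsy                 1             3          1
#> 2 open surgical biopsy                 0             1          2
#> 3  stereotactic biopsy                 0             2          3
```

All five nearest patients chose a core needle biopsy, so it accumulates the
full experience weight 1 and is promoted from objective rank 3 to final
rank 1; the other candidates keep their relative objective order.

`run_pipeline()` wires the stages end to end and writes `opinions.tsv`,
`pekb.ttl`, `ranked.json` and a manifest with md5 digests;
`inst/cli/experia.R` exposes `synth`, `mine`, `build-pekb`, `recommend`,
`what-if` and `pipeline` subcommands.

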