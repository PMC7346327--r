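---
title: "From patient reviews to re-ranked clinical decisions: the experia pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From patient reviews to re-ranked clinical decisions: the experia pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(experia)
```

## The problem

Evidence-based decision support draws its recommendations from trials over
coarse-grained patient groups; it says little about how patients *like this
one* actually experienced a procedure, and nothing about the patient's own
preferences. `experia` turns free-text patient reviews from health social
networks into structured, queryable *experience evidence* and uses it to
re-order an already-computed list of objective candidate decisions for a
query patient. The pipeline has three stages:

1. **Opinion mining** — aspect-level opinions `(feature, opinion word,
   polarity)` are extracted from POS-tagged reviews via minimum-support
   frequent-feature mining and iterative seed-lexicon polarity propagation.
2. **Knowledge base** — opinions plus case metadata become ontology
   individuals in a Clinical Sentiment Ontology and are persisted as RDF
   Turtle: the Patient Experience Knowledge Base (PEKB).
3. **Experience inference** — a k-nearest-neighbour engine matches a query
   patient's clinical conditions and visual-analogue-scale (VAS) preference
   vector against stored cases and re-ranks candidate decisions by the
   weight of similar patients' choices.

## Opinion mining

A review is an ordered list of sentences of `(token, POS)` pairs over the
coarse tagset `NOUN` / `ADJ` / `OTHER`. Mining proceeds in four stages.

**Candidate features.** Noun phrases are maximal runs of consecutive
noun-tagged tokens (the data show two-word features such as "left breast";
no richer chunking rule is assumed). Each distinct phrase is one candidate;
its *support* is the fraction of corpus sentences whose noun runs contain
the phrase as a contiguous token subsequence. Counting by containment means
a head noun ("biopsy") is credited both when it occurs alone and inside a
longer phrase ("stereotactic biopsy") — the natural reading of "sentences
containing the phrase" once runs are merged. Support is a fraction of
*sentences* (not documents or token windows) because opinions are assembled
sentence by sentence.

**Frequent features.** Candidates with support at or above the
minimum-support `threshold` survive. The default `threshold = 0.1` is a
deliberate low bar suited to short review corpora, where even salient
procedures rarely exceed a few mentions per ten sentences; it is a tunable
of `mining_config()`. Single-item support filtering plus run merging is all
the pipeline ever consumes; the operation is structured so that true
itemset expansion could be added without changing callers.

**Opinion words.** In each sentence containing a frequent feature, the
adjective with minimal token distance to the feature span (measured from
the nearer span edge) becomes its opinion word. Distance ties prefer the
*preceding* adjective, following the English premodifier convention
("radical mastectomy"). `max_adjective_distance` (default unbounded) can
drop long-range pairings.

**Polarity propagation.** The seed lexicon starts with 30 adjectives of
known polarity. Each sweep resolves every still-unknown opinion word by a
one-hop lookup: seeded synonyms first (same polarity), then — only if no
synonym is seeded — antonyms (opposite polarity), mirroring the stated
order of seed-list expansion. Resolved words join the seed list; sweeps
repeat until a full pass adds nothing, so multi-hop chains resolve across
sweeps ("unbearable" resolves one sweep after "excruciating"). Words that
never resolve are *invalid* and yield no opinion. When several seeded
neighbours disagree, the majority polarity wins and an exact tie is
neutral; majority voting is our choice where no rule is stated, being the
least surprising deterministic one. Termination is guaranteed: the seed
list grows strictly on productive sweeps and is bounded by the vocabulary.
On conflict-free lexicon graphs the fixpoint provably equals a signed
breadth-first search from the seeds (antonym edges flip the sign), and the
test suite checks that equivalence on random graphs.

`score_sentence()` is a transparent seed-lexicon vote over whole sentences
(majority of seeded positive vs negative tokens, tie → neutral). It
replaces pretrained sentence-sentiment models so that every number the
package produces is reproducible from the shipped lexicon alone; this is a
stated substitution, not a claimed equivalence to any pretrained model. An
optional negation toggle (off by default, for fidelity to the plain
algorithm) flips a vote when "not"/"no"/"never" occur within three tokens
before a seeded word; it affects sentence scoring only, never the
feature-level opinion table.

## The knowledge base

The Clinical Sentiment Ontology merges three layers under one schema file
(`inst/extdata/cso_schema.ttl`): clinical diagnosis concepts (reusing
OGMS disease/diagnosis/therapeutic-procedure classes), the Marl opinion
vocabulary (`marl:Opinion`, `marl:DescribedObject`, `marl:hasPolarity`,
...) and an application layer (`cso:AnalyzedExperience`,
`cso:ClinicalConditionSet` / `cso:ClinicalOpinionSet` under
`cso:AnalysisResult`). Preference vectors and decisions are not part of the
drawn ontology; they are stored under clearly marked `cso:`-namespaced
extension properties (`cso:hasPreferenceAttribute`, `cso:hasDecision`, ...)
because the inference engine needs them in every case record.

The store itself is a minimal in-memory set of
`(subject, predicate, object)` triples with a Turtle writer/reader for the
one-statement-per-line subset it emits (no installed R package provides
RDF, so the package carries its own small, fully round-trip-tested
implementation; the test suite additionally checks the output parses under
an independent RDF library). Procedure and described-object nodes are
scoped per case, which keeps triple counts additive across case
registration and queries lossless. Schema closure — every emitted predicate
declared, every `rdf:type` object a declared class — is enforced by
`validate_store()` at mapping time.

Condition terms are free-text-normalized strings (lower-cased, whitespace
collapsed). Mapping to a standard terminology such as SNOMED CT is
deliberately out of scope. A JSON case-store mirror
(`cases_to_json()` / `cases_from_json()`) exists for the inference engine's
hot path; the test suite verifies the bijection between the two
serializations.

## The experience inference engine

Patient features split into *conditions* (the clinical situation) and
*preferences* (a VAS vector: each attribute scored 0–100 and ranked by
priority). Retrieval proceeds in the stated order:

1. **Condition matching is a hard pre-filter**, not a term blended into the
   distance. The default rule demands the query's conditions be a subset of
   the case's; `exact` and `jaccard ≥ θ` are configurable alternatives,
   because the matching rule itself is genuinely open — "global similarity
   over all attributes" could also be read as blending condition overlap
   into the distance. The hard filter follows the procedural order
   (match conditions, *then* compute distances); the Jaccard relaxation
   recovers most of the blended reading when needed.
2. **Distance** on the survivors is the Euclidean norm of attribute-wise
   VAS differences on the normalized scale: `d = sqrt(Σ ((q_i − c_i)/100)²)`.
   Per-attribute *local* similarity is `1 − |q_i − c_i|/100`. Optionally the
   squared differences are weighted by elicited priority ranks
   (`w_i = (n − rank_i + 1)/Σ ranks`); this is off by default since the
   plain Euclidean distance is the stated rule, but the elicitation does
   collect ranks, so the toggle is provided.
3. **k nearest** cases are kept (`k = 5` by default — k is "set by
   experience" and 5 is the conventional odd small default), ties broken
   deterministically by case id. Zero matched cases yields an empty result
   with status `"no_experience"`, never an error: no experience is a valid
   answer the caller must surface.
4. **Weights.** The "probability of similarity" is realized as normalized
   inverse distance: `w_i = (1/(d_i+ε)) / Σ_j (1/(d_j+ε))` with `ε = 1e-6`.
   No explicit formula is stated for this step; inverse-distance weighting
   is the standard KNN choice, and ε lets an exact-match case dominate
   without collapsing the weight vector to a delta. A rank-decay scheme is
   available as an alternative.
5. **Re-ranking.** Each objective candidate decision accumulates the
   weights of retrieved cases that chose it; candidates sort by accumulated
   weight, ties and zero-weight candidates falling back to their objective
   order. The output is always a permutation of the input candidates, and
   an empty retrieval passes the objective order through unchanged — the
   experience evidence can only re-order, never invent or delete options.

`what_if()` recomputes retrieval and re-ranking with one preference
attribute substituted, leaving the query untouched — the programmatic core
of interactive preference exploration ("would my recommendation change if I
cared less about recovery speed?").

## Synthetic data: what it emulates, what it does not

All inputs are generated in code so the pipeline is testable offline.

* **Corpora** (`generate_corpus()`): one-sentence reviews built from
  "the *feature* was *adjective*" clauses with explicit POS tags, planted
  at chosen supports (realized within 1/n of plan). The returned ground
  truth is exactly the opinion table mining must produce, so generator and
  miner check each other. Templates carry their tags so tagger variation
  cannot corrupt ground truth.
* **Case bases** (`generate_case_base()`): preference vectors drawn around
  archetype centroids with truncated-Gaussian noise (the dispersion
  parameter is the pre-clipping standard deviation; values clip to
  [0,100]); conditions and decisions inherit from the archetype. The
  default two-archetype plan uses five preference attributes
  (pain tolerance, survival priority, cost sensitivity, recovery speed,
  cosmetic concern) in a breast-cancer triple-assessment setting, centroids
  about 85 VAS units apart with dispersion 10 — comfortably more than three
  dispersions of separation, the regime where nearest-case retrieval should
  recover the archetype essentially always.
* **The worked fixture** (`worked_example_fixture()`): a deterministic hand-tagged
  review whose mining recovers the frequent features "stereotactic biopsy",
  "left breast" and "mastectomy" and the negative opinion words
  "excruciating", "unbearable" and "radical", and whose ontology mapping
  produces the expected case individual (condition breast cancer, procedure
  stereotactic biopsy of the left breast, negative polarity).

What the generators do *not* emulate: real review language (anaphora,
sarcasm, misspellings, multi-aspect sentences), tagger error, correlated
preference attributes, or condition sets that differ within an archetype.
Passing tests therefore demonstrate the algorithms' correctness on inputs
satisfying their assumptions, not robustness to noisy clinical text — the
naive fallback tagger in `tag_text()` in particular is a convenience, not a
claim.

## Numerical and degenerate-input choices

* VAS values outside [0,100], non-permutation priority ranks, empty
  condition sets and malformed lexicon/Turtle files are rejected with
  specific errors at construction or parse time (parse errors name their
  line).
* Weight normalization is exact up to floating point; the test suite
  asserts `|Σw − 1| ≤ 1e-9`.
* All orderings (feature tables, retrieval, re-ranking) have deterministic
  tie-breaks (lexicographic, case id, original objective rank), so a fixed
  seed reproduces byte-identical pipeline artifacts; the run manifest
  records md5 digests to make that checkable.
* Words are case-folded before every lexicon operation, so capitalized
  surface forms ("Unbearable") match their lexicon entries.

## Problem sizes in the shipped checks

The test suite and the acceptance script exercise: 100 random lexicon
graphs of 20–200 words for the propagation/BFS equivalence; 50 random
corpora with 5-point threshold grids for monotonicity; 100 random case
bases of 10–500 cases for the retrieval oracle; 200 two-archetype trials
(100 cases each) for decision recovery; 50 generated stores for Turtle
round-trips. These sizes give stable rates while keeping a full run in the
order of a minute or two on one core.

## Known limitations

* The lexicon lookup is one-hop per sweep by design; polarity conflicts in
  a cyclic lexicon (a word reachable with both signs) resolve by sweep
  order and majority vote rather than by any global optimization.
* Condition matching is exact string matching after normalization; synonymy
  between condition terms ("breast carcinoma" vs "breast cancer") requires
  a terminology mapping the package deliberately does not include.
* The objective candidate list is consumed as given; generating it (rules,
  guidelines, argumentation) is outside this package's scope.
* The Turtle reader parses the package's own output subset, not arbitrary
  Turtle documents.
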