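---
title: "Network- and function-based candidate prioritization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network- and function-based candidate prioritization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbanet)
```

# Scope and model

`gbanet` prioritizes candidate bait-binding proteins from an
affinity-purification screen by guilt by association against a seed set of
known disease proteins. The evidence channels are deliberately heterogeneous
— interactome proximity, shared biological processes, semantic functional
similarity, and independent genetic screens — because each is noisy in a
different way: public interactome data over-represent well-studied proteins
and complex co-membership, GO annotation carries a knowledge bias toward
characterized genes, and cross-species genetic screens capture pathway
membership rather than physical contact. The decision tree that combines
them is intentionally simple and auditable: a strict first-match cascade
over boolean/ordinal features, not a trained scorer, so every assignment can
be traced to a single rule.

## Interactome

Interaction records are either binary or complexes (≥ 3 members with
unspecified internal contacts). Complexes are expanded under the *matrix*
model — all k(k−1)/2 pairs — rather than the spoke model, because the bait
of a purification record is not identified in the input format and the
matrix model is the conservative closure. The resulting graph is simple and
undirected; self-interactions are discarded and duplicate pairs are merged
with OR-combined binary/complex provenance. The features this graph feeds
(network distance, degree) presuppose a simple graph.

Records whose detection method contains (case-insensitive substring) any of
"predicted", "interologs mapping", "confirmational text mining" are dropped
before expansion. Case-insensitivity is our choice; detection-method strings
in aggregated databases are not case-normalized.

Two-member records declared as complexes are demoted to binary with a
warning: they carry pairwise evidence but calling them complexes would
inflate complex provenance (which the `not_complex` specificity flag
consumes downstream).

The shortest-path subnetwork between candidates and seeds contains both end
sets, every node on at least one geodesic between any candidate–seed pair
(v is on an a–b geodesic iff d(a,v) + d(v,b) = d(a,b)), and any caller-
supplied extra sets (the bait and known-interactor lists in the standard
workflow). Geodesics among the candidates themselves are *not* included;
only candidate↔seed paths define membership. This follows the narrower of
the two readings the construction admits; the alternative (candidate–
candidate paths as well) would only add nodes, never change a
candidate–seed distance, so the features are unaffected and the narrower
network is cheaper and easier to reason about.

Distances are unweighted breadth-first distances. `#ND` counts *distinct
seed proteins* attaining the minimum distance — not distinct geodesics —
which is the only reading consistent with a count of 2 accompanied by
exactly two named interactors in the reference data this package
reproduces.

## Enrichment

The "classic" score is the hypergeometric upper tail, identical to the
one-sided Fisher exact test on the 2×2 table (the equivalence is
property-tested), computed through `stats::phyper` and BH-adjusted with
`stats::p.adjust` across all tested terms. The universe defaults to all
annotated proteins in the supplied corpus; it is a parameter because
enrichment p-values move substantially with the universe and published
values tied to historical database releases cannot be reproduced desk-side.

The locally adjusted score addresses the parent–child dependence of GO: a
generic term inherits the annotations — and hence the apparent signal — of
its specific descendants. We implement the *elim* strategy: terms are
processed in order of decreasing depth (longest path to the root); whenever
a term scores at or below the removal cutoff (default 0.01), the universe
proteins annotated to it are removed from all of its ancestors before those
are tested. Each term's reported `local_p` is its p-value at test time.
With cutoff 0 the procedure reduces exactly to the classic score (tested).
This is a published, fully specifiable topology adjustment with the same
intent as other local dependence corrections — down-weighting generic terms
against their descendants — and we label its output `local_p` rather than
claiming equivalence to any specific tool's internal score.

The shared-term (GOComp) flags are defined over a comparison-term list:
terms significant (classic p ≤ 1e−3) in both the candidate set and the
disease-related reference set, optionally extended by terms chosen on the
local score. Because the historical term list depends on annotation-release
vintages, the list is configurable and may be passed explicitly; a
candidate is flagged if directly annotated to a comparison term or any
descendant.

## Functional similarity

Information content is corpus-based: IC(t) = −ln p(t) with p(t) the
fraction of annotated proteins annotated to t or a descendant after
propagation; the root has IC 0 and terms annotating nothing are excluded.
Term similarity goes through the most informative common ancestor: Lin
(default) or simRel, which multiplies Lin by (1 − p(MICA)) to damp
similarity through shallow ancestors. Protein similarity is the best-match
average over *direct* annotation sets. The original analysis delegated
scoring to an external similarity server whose exact variant is not
recoverable; both kernels are provided and the network semantics (edge iff
score ≥ 0.7, inclusive) are preserved exactly. Where one gene maps to
several protein entries, the convention is the maximum score over variants;
the annotation union achieves the same monotone effect in this corpus
model.

Cluster detection is greedy cohesiveness growth over the weighted
similarity graph: f(C) = w_in / (w_in + w_bound + penalty·|C|), seeded from
the highest-weighted-degree unclaimed node, grown/shrunk to a local
maximum, with clusters merged when the match coefficient |A∩B|²/(|A||B|)
reaches 0.8. The penalty (default 2) models unobserved edges; both defaults
follow the established overlapping-clustering method this mirrors.
Significance is empirical: edge weights are permuted over the fixed
topology (degree-preserving) and f(C) recomputed for the same node set;
p = (1 + #{f_perm ≥ f_obs}) / (B + 1) with B = 1000 permutations and a
fixed default seed (17) so results are reproducible. Note this null tests
the weight *placement*, not the topology: on an unweighted graph every
permutation is a tie and p is 1 by construction.

## Selection levels

The cascade (levels 0–8, first match wins) is documented in
`?assign_selection_level` and in the README. Three design points deserve
record:

* **Level 7 keys on slim membership, not the shared-term flag.** In the
  reference table every level-7 row is slim-annotated, while rows carrying
  only the shared-term flag do not appear above level 5 through that flag
  alone; "annotated to disease processes" therefore means the slim.
* **`not_complex` and the tag-interactor flag do not gate any level.** No
  assignment in the reference table requires them; they are reported as
  interpretive columns (interaction specificity; potential purification
  artifacts via the tag-binding protein) only.
* **Ranking.** Within a level, candidates absent from the network sort
  last; the rest sort by degree ascending — low-degree candidates make more
  specific, more informative interactions — then by bait distance
  ascending, then lexicographically by id. The bait-distance key is our
  addition: degree alone leaves ties that the published order resolves
  consistently with bait proximity, and the packaged table is reproduced
  exactly under this key (guarded by a fixture test). Missing evidence is
  always treated as absence (`FALSE` / not interacting), never imputed.

The tree is total and monotone: setting any single evidence flag from false
to true never demotes a candidate (property-tested).

## Synthetic universe

The generator emulates the *structure* of the real inputs, not their scale:
an ontology of ~45 terms (a slim branch, a comparison-term branch, rare
per-seed terms, two functional-family terms, and a random background
subtree with occasional double parents), ~120 background proteins with 1–3
annotations each, a connected background interactome (~150 binary records,
8 complexes of 3–6 members), a bait adjacent to every seed, and a
configurable share (default 20%) of records carrying blacklisted detection
methods — including one adversarial predicted bait edge that must be
filtered out or a tier-7 candidate would surface at level 0.

Planted candidates are *adversarially minimal*: each satisfies exactly its
target rule and no higher rule, so tier recovery tests the cascade order,
not just rule reachability. Forced functional similarity uses an analytic
construction: giving a candidate a seed's rare direct term guarantees a
best-match average of 1 when that is the only term, and ≥ 0.75 when a slim
term is added — both above the 0.7 threshold regardless of corpus
randomness. Tier counts default to two per level, covering both variants of
the disjunctive rules (levels 3, 4 and 6).

What passing these tests does *not* show: robustness to the scale and bias
of real interactome data (degree distributions over four orders of
magnitude, literature bias, complex-expansion density inflation), to
annotation incompleteness, or to identifier-mapping noise. The synthetic
DAG is shallow (depth ≈ 4) compared to GO (depth > 10), so the elim
adjustment is exercised, not stress-tested.

## Numerical choices and degenerate inputs

* Hypergeometric tails go through `phyper` (log-space internals); the test
  oracle is exhaustive enumeration of all draws for N ≤ 12 at 1e−12.
* Density is reported as a fraction; networks with < 2 nodes report 0 with
  a warning rather than NaN.
* Empty study sets, empty universes, unknown labels and cyclic ontologies
  are errors or warnings at the boundary, never silent propagation.
* Greedy growth uses a 1e−12 improvement tolerance to avoid cycling on
  floating-point ties; cluster membership lists are kept sorted so results
  are order-independent.
* All randomness (generator, permutation tests) is seed-controlled;
  identical seeds give byte-identical generated files.

## Problem sizes used in validation

The suite validates primitives on enumerable sizes (all hypergeometric
configurations with N ≤ 12; 200 random graphs of ≤ 20 nodes against
Floyd–Warshall) and the pipeline end-to-end on the default synthetic
universe across ten seeds — sizes chosen so the full suite documents the
method rather than benchmarks it. The packaged 90-row reference table is
the one full-scale artifact: its selection levels and rank order are
reproduced exactly from the feature columns.

## Known limitations

* Enrichment p-values printed in historical analyses depend on database
  releases (interactome, annotation corpus, pathway collections) and are
  not reproduction targets; the package reproduces the *procedures* and
  validates them against oracles instead.
* The functional-similarity kernel of the original external server is not
  recoverable; Lin/simRel with BMA are provided with identical threshold
  semantics.
* The interactome model is unweighted; confidence scores, directionality
  and spoke expansion are out of scope.
* Identifier handling is by opaque string with static many-to-many maps; no
  live resolution or versioned identifier history.
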