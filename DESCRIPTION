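Package: gbanet
Title: Network- and Function-Based Prioritization of Affinity-Purification Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Guilt-by-association prioritization of candidate bait-binding
    proteins from tandem affinity purification (TAP) interaction screens.
    Builds a protein-protein interaction network from binary and complex
    records (matrix expansion of complexes, filtering of predicted
    interactions), computes shortest-path network distances of candidates to
    the bait and to a seed set of disease proteins, performs GO
    hypergeometric enrichment with FDR and an elim-style locally adjusted
    score, derives GO slim membership flags, scores GO semantic functional
    similarity (Lin and simRel kernels, best-match average) and builds
    similarity networks with overlapping cohesiveness-based clustering,
    tests overlaps against external gene sets with ortholog mapping, and
    assigns each candidate a selection level (0 highest to 8 lowest
    priority) via a first-match decision tree. Includes a synthetic-data
    generator producing complete toy universes with candidates planted at
    known selection tiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
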