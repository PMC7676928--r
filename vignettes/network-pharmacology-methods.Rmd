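---
title: "Methods: network pharmacology with herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology with herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The inference chain

herbnet implements the standard network-pharmacology chain used to propose
mechanisms for multi-compound herbal medicines:

1. **ADME screen.** Candidate compounds from a database export (TCMSP-style)
   are kept when oral bioavailability (OB, percent) and drug-likeness (DL,
   unitless in [0, 1]) both pass their cutoffs. The conventional thresholds
   are OB ≥ 30% and DL ≥ 0.18, and both inequalities are *inclusive* —
   a compound sitting exactly on both cutoffs is active. A strict mode
   (`inclusive = FALSE`) exists for sensitivity analysis only.
2. **Therapeutic targets.** The targets of the active compounds are
   deduplicated (`union_targets()`), disease gene lists from several
   sources/keyword queries are merged (`merge_disease_sources()`), and the
   drug ∩ disease intersection (`intersect_targets()`) is the
   therapeutic-target set. All set algebra runs on *normalized* symbols:
   uppercase, whitespace-trimmed, hyphens removed, Greek letters
   transliterated ("IL-1β" → "IL1B"), then an extensible alias table
   (`read_alias_table()`). Published tables mix these styles freely, and a
   single unharmonized symbol silently shrinks the intersection — which is
   why `near_miss_report()` lists pairs that match only after
   normalization.
3. **Typed networks.** C-T (compounds × all their targets), C-OT
   (restricted to therapeutic targets), PPI (confidence-filtered
   interactions among therapeutic targets) and C-T-P (compounds, targets,
   enriched pathways) are simple undirected graphs whose nodes carry a
   class label. Bipartite and tripartite structure gives exact edge
   identities — C-OT edges = Σ compound degrees = Σ target degrees; every
   C-T-P edge has exactly one target endpoint, so C-T-P edges = Σ target
   degrees — which the test suite asserts on every constructed network.
4. **Topology and node selection.** Degree centrality (DC) is the incident
   edge count. Betweenness centrality (BC) is computed exactly by Brandes'
   dependency accumulation over unweighted shortest paths. Two selection
   statistics are supported: the *hub rule* (DC and BC greater than 2× the
   network median) and the *above-average rule* (greater than the class
   mean), both expressed as a `selection_rule(statistic, multiplier,
   combine, strict)`.
5. **Enrichment.** Pathway over-representation of the therapeutic targets
   is the hypergeometric upper tail P(X ≥ k) for an overlap of k between
   the n-gene query and a K-gene set in an N-gene universe, with
   Benjamini–Hochberg adjustment reported alongside. Screening defaults to
   raw p < 0.05 — the convention of the annotation services this replaces —
   but `use_adjusted = TRUE` switches the screen to FDR. `screen_top()`
   then applies a user-supplied blocklist (case-insensitive substring on
   term names; it ships empty because "uncorrelated pathway" removal is a
   manual curation act) and keeps the top N (default 20).

`run_pipeline()` drives all stages from one YAML/list config and writes a
JSON report whose counts are mutually consistent by construction.

## Numerical and convention choices

**BC normalization.** Normalized BC divides raw accumulation by
(n−1)(n−2)/2 (n = node count; 0 for n < 3), the Cytoscape NetworkAnalyzer
convention; the ≪ 1 betweenness magnitudes in published hub tables are
only consistent with this normalization, so it is the default. Raw values
are available with `normalized = FALSE`.

**Disconnected graphs.** Pair dependencies accumulate within connected
components only, while normalization still uses the full n. This matches
NetworkAnalyzer, but it means fragmenting a PPI deflates every BC value —
worth remembering when `keep_isolates = TRUE`.

**Graphs are simple and undirected.** Repeated compound–target evidence
collapses to one edge (published compound degrees count *distinct*
targets), and PPI semantics are symmetric. Shortest paths are unweighted;
confidence scores gate edge existence but never weight paths.

**Isolates.** STRING-style queries routinely return fewer network nodes
than query proteins; `build_ppi()` therefore drops members with no
surviving edge by default (`keep_isolates` retains them with DC 0 and
BC 0). Whether missing proteins were score-filtered isolates or unmapped
identifiers is not recoverable from a published node count, so both
behaviours are reachable.

**Score scales.** STRING exports use 0–999 integers. The scale is declared
(`score_scale = "thousand"`), never guessed from magnitude: a silently
misread scale corrupts the 0.7 high-confidence cutoff. Duplicate unordered
pairs keep the maximum score; self-loops are dropped with a count.

**Selection tie-breaks.** Selected nodes are ordered by DC descending,
then BC descending, then node id — a total order so reports are
deterministic. Thresholds always use full precision; rounding happens only
at reporting time.

**Degenerate inputs.** Empty compound tables, empty overlaps and
zero-pathway screens flow through: every stage returns empty structures of
the right shape, and the C-T-P stage is skipped with a notice when no
pathway survives.

## The hub-rule ambiguity

The hub rule as usually stated — "DC **and** BC greater than 2× the
median" — does not always reproduce published hub lists: hub tables
sometimes contain nodes whose BC falls below twice the network median BC,
implying the BC criterion was not applied (or a different statistic was).
The published 18-hub table in the shipped case study is an example: all 18
rows clear the DC threshold (2 × 7 = 14), but two (MAPK14, BC 0.004943;
NOS3, BC 0.003683) fall below 2 × 0.00287026. herbnet's default remains
the strict AND rule exactly as stated; `combine = "DC_ONLY"` reproduces
such published lists, and `run_pipeline()` puts a rule-sensitivity warning
in the report whenever the two disagree, rather than silently picking one.
Similarly, on C-T-P networks the published 15-target selection is only
reproduced by thresholding targets on DC alone (three listed targets sit
below the printed class-mean BC), while compounds and pathways reproduce
under strict AND — hence the per-class defaults
`ctp_target_combine = "DC_ONLY"`, `ctp_compound_combine =
ctp_pathway_combine = "AND"` in the pipeline.

## Enrichment model choices

The statistic is the plain hypergeometric upper tail computed via
`stats::phyper` (log-space internally); DAVID-style EASE corrections are
deliberately not applied, so p-values from web services will not match
numerically — published term counts depend on annotation snapshots anyway
and are out of scope. The default universe is every gene annotated in the
loaded collection; `universe = "targets"` in the pipeline restricts the
background to the drug-target set. Neither choice is made implicitly: the
universe is always echoed in the output columns (N), because the
hypergeometric p is meaningless without it.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the package ships as
its reference shape: 60 candidate compounds with 11 ADME-passing actives,
a compound-degree profile with one dominant compound and a long tail
(68, 37, 32, 27, 24, 16, 11, 5, 4, 4, 3), 126 drug targets, 2207 disease
targets with an overlap of exactly 83, 766 scored protein pairs of which
exactly half reach high confidence (so 383 survive the 0.7 cutoff), and
90 pathway gene sets of 10–60 genes with one planted enriched term at
strength 0.75. Counts are *constructed exactly* (the overlap set is chosen
first and padded, the high-confidence edge count is fixed, the active
count is fixed) rather than arising in expectation, so downstream
assertions are deterministic. Each generator draws from its own RNG stream
derived from the master seed, so adding a generator never perturbs
another, and gene symbols are `G000001`-style tokens that cannot collide
with the alias table.

A planted term of strength *s* draws each member from the query with
probability *s* and from the non-query universe otherwise, so its query
overlap is Binomial(m, s); at *s* = |query|/|universe| this is
approximately the central hypergeometric null (binomial variance is
slightly larger — visible only at small universes).

What the generator does **not** emulate: real chemistry (no structures;
OB/DL are drawn uniformly on the passing/failing ranges), correlated
target profiles between similar compounds, scale-free PPI topology
(edges are uniform over pairs), overlapping/nested pathway structure, and
annotation bias. Passing the recovery tests therefore demonstrates that
the pipeline's bookkeeping and statistics are correct under controlled
structure — not that the method is robust to the pathologies of real
databases (symbol drift, redundant isoform annotations, relevance-ranked
disease lists).

## Verification strategy and problem sizes

The suite cross-checks every statistic against an independent route:
Brandes BC against brute-force enumeration of all shortest paths on 200
random graphs of ≤ 8 nodes (tolerance 1e−12) and against igraph;
hypergeometric tails against direct combinatorial summation on every
instance with N ≤ 20; BH against hand-computed step-up values; selection
against an exhaustive row filter. End-to-end, the pipeline is run at the
full reference scale (2207 disease targets, 766 scored pairs, 90 gene
sets) across 20 seeds for parameter recovery, and the enrichment screen's
type-I error is checked against its exact null expectation over 1000 null
terms in a 2000-gene universe. These sizes keep the whole suite in the
tens of seconds while exercising the same code paths as full-scale runs.

## Known limitations

* Symbol normalization is intentionally shallow: no Entrez/UniProt
  mapping, no history-aware HGNC resolution — only case/hyphen/Greek
  rules plus the alias table. Cross-database identity beyond that is the
  user's curation problem, surfaced by `near_miss_report()`.
* BC assumes unweighted undirected paths; no closeness/eigenvector
  centralities, and no weighted variants.
* The enrichment model is the plain hypergeometric; no EASE score, no
  permutation-based null, no GSEA-style ranked statistics.
* The pipeline is single-herb: multi-herb formulas would need a
  herb–compound layer that the typed-network classes do not currently
  model.
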