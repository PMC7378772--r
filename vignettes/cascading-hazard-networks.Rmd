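---
title: "Cascading hazard networks from coded accident chains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascading hazard networks from coded accident chains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cehn)
```

## The problem and the data model

Injury surveillance at metro escalators produces, for each accident, an
ordered chain of coded hazards reconstructed from the narrative by a
five-step task-driven decomposition: what the casualty intended, what went
wrong, the attempted recovery, the last passive action, and the injurious
interaction with the machine. `cehn` takes these chains — not the free-text
narratives, whose coding stays a human task — and studies the *relations*
between hazards rather than their marginal frequencies.

Chains of a single hazard carry no relation and are removed by
`filter_valid()`, which counts rather than silently drops them; every
retained chain has length ≥ 2. Chains may legitimately revisit a hazard
(`36→52→28→52`), so parsing preserves duplicates, and both the typographic
`→` and the ASCII `->` arrow are accepted on ingest.

## Network construction

`build_network()` uses the L-space convention from transit-network
analysis: consecutive chain elements are joined by a directed edge, and the
number of times a transition is observed becomes the integer weight of the
single edge between that ordered pair. Weight is therefore an *event
frequency*, the unit in which strengths are expressed.

Two construction choices deserve note:

- **Node set.** The network's nodes are the hazards of the codebook when
  one is supplied, not merely those appearing in some chain. Hazards
  identified in the accident sample but absent from every retained chain
  remain visible as isolated nodes — they are part of the surveillance
  picture (they classify as `isolated` rather than being dropped), and the
  node count `n` used in betweenness normalization refers to this full set.
- **Self-loops.** An immediate repeat in a chain would create a self-loop.
  These are retained in the weight map (the event happened) but excluded
  from neighbour sets, degrees, clustering and path finding, where they are
  meaningless. The packaged corpus contains none.

## The metric suite

**Degree and strength.** Degree counts distinct neighbours (in, out, and
undirected); strength sums event frequencies. The identity
`Σ_i s_in(i) = Σ_i s_out(i) = Σ_chains (length − 1)` holds by construction
and is asserted in the tests.

**Clustering.** Direction is discarded for clustering: the question is
whether a hazard's neighbourhood is internally connected, not which way the
cascade flowed. Reciprocal directed weights must therefore be combined per
unordered pair; the package sums them by default (weights are event counts,
so the total interaction count is the natural symmetrization) and offers
`rule = "max"` as a sensitivity switch, since the choice affects weighted
clustering. The un-weighted coefficient is the classical
`2e(i)/(k(k−1))`; the weighted variant credits each closed triangle with
the product of its three max-normalized weights
(`w̃ = u / max(u)`), which keeps every value in `[0, 1]` and bounded by the
un-weighted coefficient, and reduces exactly to it when all weights are
equal — both properties are tested. The triangle sum runs over unordered
neighbour pairs, as the `2/(k(k−1))` prefactor implies. Nodes with fewer
than two neighbours have no defined coefficient; network averages are taken
over the defined nodes by default (`undefined = "zero"` averages over all
`n` instead, for sensitivity checks), and the count of defined nodes is
always reported alongside.

**Betweenness.** Path length is hop count — weights measure frequency, not
distance — and direction is respected by default (an `"undirected"` option
exists because ranking software conventions vary). `shortest_path_counts()`
runs a breadth-first search from every node, recording the distance matrix
`D` and the exact shortest-path multiplicity matrix `S`. Node betweenness
then uses the exact decomposition `p_jk(i) = S[j,i]·S[i,k]` whenever
`D[j,i] + D[i,k] = D[j,k]`, and edge betweenness
`p_jk(u→v) = S[j,u]·S[v,k]` whenever `D[j,u] + 1 + D[v,k] = D[j,k]` — a
closed-form count over the BFS products that is exact, vectorizes cleanly,
and is easy to audit at the package's scale (n ≤ a few hundred). Unreachable
origin–destination pairs contribute zero without shrinking the denominator.
The normalizing constants are the ordered-pair counts `(n−1)(n−2)` for
nodes and `n(n−1)` for edges, landing values in `[0,1]`; halved
(unordered-pair) constants are exposed as `norm = "unordered"` because
published rankings do not always state their convention. The entire
machinery is validated in the test suite against an exhaustive
simple-path-enumeration oracle on 200 seeded random digraphs and
cross-checked against igraph on the fixture.

## Role classification

The field's reading of strength bar charts — "out-strength ball well above
the in-strength ball means trigger" — is operationalized as a threshold on
the relative asymmetry `(s_out − s_in)/s ∈ [−1, 1]`: trigger above `τ`,
consequence below `−τ`, transitional between, isolated when `s = 0`. A
rank-gap comparison was considered and rejected as the default because
ranks are unstable under the many ties that small corpora produce; the
value-based asymmetry is continuous and monotone in `τ` (raising `τ` can
only move hazards toward transitional, a property the tests assert).
The default `τ = 0.2` means a hazard is directional when one direction
carries at least 60/40 of its events; the parameter is free and every
report records it. Ranked tables default to depth 10 and break ties by
ascending hazard code so reports are byte-reproducible.

## The packaged fixture and its limits

The package ships the Beijing metro escalator sample: a 61-hazard codebook
in 7 categories and 327 coded chains (lengths 3–6), both transcribed
verbatim from the published tables. The printed chain table carries visible
transcription defects — its case numbering skips 184 and 239, its final row
is misaligned leaving two chains unnumbered (stored under ids `x1`, `x2`) —
and quantities recomputed from it differ materially from the summary
statistics published alongside it (886 transition instances rather than
1015; 134 distinct edges rather than 224; 49 of the 61 hazards appearing in
at least one chain). The fixture is deliberately preserved as printed
rather than "repaired" toward the published summaries: the package reports
what the data it is given actually contain. Comparisons with the published
per-hazard clustering and betweenness tables should therefore be read as
qualitative (the same hazards dominate) rather than numeric.

## The synthetic generator

`generator_model()` defines a first-order (memoryless) transition process:
an initial distribution over designated trigger hazards, a row-stochastic
transition matrix, absorbing consequence hazards (all-zero rows), and a
hard length cap. First-order is sufficient by design: observed chains are
short (3–6) and the L-space network itself encodes only first-order
structure, so higher-order generation would add nothing the analysis could
detect. The default scenario (`default_generator_model()`) uses real
codebook hazards — three triggers, four transitional hazards, three
absorbing consequences, per-step absorption probability 0.45 and cap 6 —
chosen to reproduce the observed length profile (mean ≈ 4). Generation is
fully reproducible from the stored seed.

What passing the recovery tests shows: chains produced by a process with
designated source-only triggers and absorbing consequences, pushed through
the identical ingest–network–classification path, recover those roles
exactly for any `τ ∈ (0,1)`, and empirical transition frequencies converge
to the generating probabilities (±0.02 at 10,000 chains). What it does not
show: real accident chains are not memoryless samples — coding error,
narrative truncation and reporting bias have no counterpart in the
generator — so these tests validate the *machinery*, not the fidelity of
any particular corpus.

`model_from_corpus()` additionally builds the empirical bootstrap model of
an observed corpus (its empirical transition matrix and start
distribution), allowing resampling of corpora that mimic the fixture.

## Numerical and degenerate-input choices

- Empty corpora build empty networks rather than erroring; summaries are
  all zero.
- Betweenness requires `n ≥ 3` (the node normalization is otherwise
  undefined) and errors explicitly below that.
- Codes unknown to the codebook are a hard error on ingest, downgradeable
  to a warning — silent acceptance would mask coding drift.
- Pajek export indexes vertices 1..n by ascending hazard code; codes are
  identifiers and never positional indices.
- All ranked outputs break ties deterministically by ascending code.

## Problem sizes

The analysis scripts and tests run the full 327-chain fixture (61 nodes)
everywhere; the oracle-validated betweenness property uses 200 random
digraphs of 3–8 nodes, where exhaustive path enumeration is exact; the
generator checks use 10,000 chains. These sizes were chosen so every
documented quantity is recomputed, not cached, on an ordinary laptop in
seconds.
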