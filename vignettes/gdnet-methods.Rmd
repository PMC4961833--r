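---
title: "Methods: building and querying an extended gene-disease network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and querying an extended gene-disease network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdnet)
```

## Motivation and model overview

Curated archives of gene–disease associations are precise but frozen: once
curation stops, newly studied pairs are absent even when they are only one
or two evidence hops away from recorded knowledge. `gdnet` widens such an
archive in both directions. On the gene side, genes that share pathway,
interaction or annotation features are linked by a similarity network; on
the disease side, the free-text disease names of the archive are attached
to a disease ontology, whose is-a backbone then connects related diseases.
The result is a single undirected network with three edge classes —
`gene_gene`, `disease_disease`, `gene_disease` — on which any (disease,
gene) query becomes a bounded path search, and every retrieved path carries
a confidence score.

## Gene similarity

Each gene is represented by one feature-token set per source database. For
token sets $L_1, L_2$ of one source the overlap score is

$$\frac{|L_1 \cap L_2| - |L_1 \cup L_2|/2}{|L_1 \cup L_2|/2} = 2J - 1,$$

with $J$ the Jaccard index, so identical non-empty sets score $1$ and
disjoint sets $-1$. The gene-pair similarity is the weighted sum over
sources, $S = \sum_m \alpha_m\,\mathrm{score}_m$, $\sum_m \alpha_m = 1$,
uniform by default. Two numerical choices deserve note:

* **Empty-evidence sources.** When both genes have an empty set in a
  source, the union is empty and the score is undefined. We treat such a
  source as contributing no evidence and renormalize $\alpha$ over the
  evidence-bearing sources; with no evidence anywhere the pair is neutral
  ($S = 0$). This keeps the weight semantics while avoiding division by
  zero, and keeps $S = 1$ / $S = -1$ attainable exactly when every
  evidence-bearing source is identical / disjoint.
* **Threshold strictness.** An edge is created when $S$ strictly exceeds
  the threshold (default 0), so "not similar" pairs at $S \le 0$ are
  excluded at the default. Raising the threshold can only remove edges.

Node significance $\exp(|\sum_{m \ne n} \mathrm{sign}\,S(g_m, g_n)|/(N-1))
\in [1, e]$ is exposed purely as a diagnostic for threshold selection. Its
defining formula admits more than one reading; we implement the sign-sum
form, which matches the verbal description of summing sign values and
exponentiating, and provide a raw-sum alternative behind the `reading`
argument. It feeds nothing downstream.

## Disease-name normalization

Tokenization rotates at the first comma (inverted-header names such as
"Diabetes, Type 2" put the head noun last), case-folds, and strips other
punctuation; further commas act as separators. Word initial values halve
from the last token toward the first, the first token duplicating the
second, rescaled to sum to exactly 1 — reproducing $(0.125, 0.125, 0.25,
0.5)$ for a four-word name, $(0.5, 0.5)$ for two words, and $1$ for one.
The name-pair score $SC$ is the product of the two matched-initial-value
sums; it is symmetric, lies in $[0,1]$, and is 1 iff the token sets are
equal.

The mapping cascade runs direct → half-ambiguous → xref → ambiguous, the
order of cumulative coverage, with the first hit winning:

* *direct*: normalized equality with a term name or synonym (score 1);
* *half-ambiguous*: the query token set is contained in a term-name token
  set after rotation; the score is $SC$, not forced to 1 — containment is
  the weakest reading that covers inverted-header names whose canonical
  term carries extra qualifiers (e.g. a trailing "Mellitus");
* *xref*: the query equals a supplementary-thesaurus entry whose code
  appears among a term's cross-references (score 1) — this is how plural
  variants resolve, since we deliberately do not fold plurals;
* *ambiguous*: among terms sharing at least one token, those maximizing
  $SC$, kept only if that maximum reaches the floor (default 0.2 — a pure
  tunable, low enough to admit single-head-noun matches at $0.25$, high
  enough to reject matches through a minor shared token). Ties keep all
  argmax terms, reported in lexicographic order.

Names failing all tiers are recorded unmapped in a separate chart; they are
typically assay names, initials, or other non-disease strings.

## Network assembly

Ontology terms become disease nodes; is-a links become weight-1
`disease_disease` edges. A mapped association name at the direct or xref
tier *is* its term (score 1 implies identity), so its association edges
anchor directly at the term node. A half-ambiguous or ambiguous name keeps
its own node, bridged to each matched term by a `disease_disease` edge
weighted by the mapping score — preserving the distinction between
ontology structure and name-resolution evidence. Association edges have
weight 1 (curated links are taken as reliable); rows naming a gene outside
the gene universe are skipped and counted. Assembly output is canonical
(sorted, deduplicated), so equal inputs serialize byte-identically.

## Path confidence

A path is scored from its edge weights only: $SC$ values from
`disease_disease` edges, $S$ values from `gene_gene` edges, identity for
`gene_disease` edges. The raw confidence $\prod SC \cdot \prod S$ is
annihilated by any $S = 0$ edge even though a path exists; the optimized
confidence repairs this:

$$DGI' = 10^{\prod SC} \times 10^{\prod (S+1)/2} \in (0, 100].$$

Three readings fixed here: the products run over the *path's* edges (a
universe-wide product would be near zero always and contradict the
path-wise use); $(S+1)/2$ is the affine map of $[-1,1]$ onto $[0,1]$ (the
alternative $S + 0.5$ breaks the range); and the interval is closed above,
since 100 denotes exactly the verified direct association (both products
empty). Appending any sub-unit edge can only lower the confidence, and
raising any single edge score strictly raises it.

## Path search

The search is bidirectional: each query term owns a frontier of nodes with
parent pointers. In heuristic mode a frontier expands its best unexpanded
node by priority $W(n) = e^{E_o - E_i} \cdot E_o \cdot \varepsilon$, where
$E_i$ counts edges to either input term (both inputs, the more
conservative of the two possible readings), $E_o$ the rest, and
$\varepsilon \in [0.5, 1]$ is a seeded random factor — zero for nodes
already held in either frontier, which both implements the duplicate rule
and guards against revisiting. Search stops when the frontier depths
together exceed `maxlength` (lengths count edges) or both frontiers are
exhausted; the first intersection yields the path. Ties in $W$ break
lexicographically. Heuristic retrieval is sound (returned paths are
validated edge-by-edge) but not complete.

Exhaustive mode replaces the priority order with full breadth-first
layers, alternating the shallower side, and returns the minimum-total
shared node; a standard bidirectional-BFS argument (and the brute-force
oracle tests) give completeness: a shortest path of at most `maxlength`
edges is found iff one exists. The seeded $\varepsilon$ makes heuristic
runs bit-reproducible per seed, and the search restores the caller's RNG
state.

## Synthetic fixtures

`generate_fixture()` emits a complete toy input bundle — per-source feature
TSVs, an OBO ontology with synonyms and xrefs, a thesaurus stand-in, an
association table, a manifest — plus a truth file with closed-form
expectations computed by the generator itself. It plants, by construction:
gene pairs at similarity exactly $1$, exactly $-1$, and at a controlled
partial overlap; one disease name per mapping tier (including an
unmappable one); and one disease–gene path per requested length (1–4
edges) whose exact confidence the truth file records. Default sizes — 30
genes, 3 sources, 12 filler terms, 15 association rows — keep every
planted structure unambiguous (filler vocabularies are disjoint from
planted ones) while exercising all code paths in well under a second.

What the fixtures do *not* emulate: the scale (hundreds of millions of
gene-gene edges), the heavy-tailed degree distributions, the noisy
near-duplicate disease vocabulary, or the identifier-conversion ambiguity
of real source databases. Passing the recovery tests therefore shows the
machinery is exact on known ground truth, not that mapping rates or path
yields on real archives would match any published figure.

## Problem sizes and numerical choices

The test suite runs the full pipeline on 30-gene fixtures, checks the
exhaustive search against an all-pairs brute-force oracle on 200 random
typed graphs of up to 30 nodes, and the ambiguous tier against exhaustive
argmax over ontologies of up to 50 terms — sizes chosen so ground truth is
enumerable exactly. Tolerances: planted confidences to $10^{-9}$;
worked-example scores exactly. Weight sums and initial-value sums are
validated at $10^{-9}$. Similarity matrices are stored dense; at tool
scale ($10^2$–$10^3$ genes) this is the simple and adequate choice.

## Known limitations

* The heuristic mode trades completeness for speed by design; use
  `exhaustive = TRUE` when a miss matters.
* Half-ambiguous containment is one reading of an underspecified rule;
  the cascade order is configurable via `tier_order` for users preferring
  the narrative order (direct, xref before token-based tiers).
* Node significance is a diagnostic only, and its formula is an
  interpretation (see above).
* Disease-name matching does no stemming or plural folding; coverage of
  morphological variants is delegated entirely to synonyms and xrefs.
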