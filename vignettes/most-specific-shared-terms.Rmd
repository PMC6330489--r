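---
title: "Finding the most specific GO terms shared by gene lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the most specific GO terms shared by gene lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goleaf)
```

## The method

The Gene Ontology is a directed acyclic graph in three namespaces
(biological process, molecular function, cellular component); a term
may have several parents and several children, and terms get more
specific going down the graph.  goleaf answers one question: *which
terms does a set of genes share, at the most specific level the
annotation supports?*  The procedure has three stages.

**Shared-term detection.**  Annotations are read from a GAF file,
records whose qualifier contains `NOT` are discarded (they assert the
absence of a function), an optional evidence-code filter is applied,
and by default every annotation is propagated to all ancestors of its
term (the true-path rule).  A term is *shared* when at least
`threshold` input genes are annotated to it.  In `between` mode the
input is two lists; a shared term must in addition be supported by at
least one gene from each list.  A gene occurring in both lists is
counted once and satisfies both sides (with a warning), since double
counting would inflate sharing.

**Pruning.**  Every shared term with a shared *strict descendant* is
removed.  The survivors are the leaves of the subgraph induced by the
shared set — an antichain by construction.  The test is deliberately
against descendants *within the shared set*, not against children in
the full ontology: a term that is a non-leaf of the full GO survives
whenever none of its refinements is itself shared.  With propagation
on, the two readings coincide (any shared descendant forces a shared
direct child on the path up); the descendant form stays correct when
propagation is switched off.

**Scoring.**  Each surviving term is ranked by
$$\mathrm{score}(t) = -\log_2 p(t), \qquad p(t) = \frac{2}{g(t)},$$
where $g(t)$ is the number of *background* genes — all genes in the
filtered annotation file, not just the input — annotated to $t$, and
the constant 2 is the minimum background a shared term can have.  The
score is $\log_2 g(t) - 1$: zero at $g = 2$, strictly increasing in
$g$.  The logarithm base is fixed at 2 because it is the unique base
under which the reference operating points of the score (e.g.
$g = 27 \to 3.7549$, $g = 38 \to 4.2479$, $g = 66 \to 5.0444$) are all
reproduced to four decimal places; the test suite asserts all ten such
points.  Output is sorted ascending by score — most specific first —
with ties broken by term id for determinism.

```{r score}
round(go_term_score(c(2, 27, 38, 66)), 4)
```

## Parameters that matter

* `threshold` (integer, default 2, minimum 2): the number of input
  genes that must share a term.  This is the navigation dial: raising
  it drives the surviving terms toward the (well-populated) top of the
  hierarchy, lowering it toward the leaves.  Values below 2 are
  rejected — a "shared" term needs two genes, and $p(t)$ would exceed 1.
* `relations` (default `is_a`, `part_of`): the relationship types that
  count as parent edges.  The regulates family can be opted in; the
  default mirrors the parent maps of the classic Bioconductor GO
  builds.  Shrinking the set can only shrink ancestor sets (a tested
  monotonicity property).
* `propagate` (default `TRUE`): whether annotations are extended to
  ancestors before counting.  Background counts in the reference
  top tables are consistent with ancestor-inclusive counting, so
  propagation is the default; it is switchable because the direct
  counting convention is also defensible, and the pruning rule is
  correct either way.
* `evidence_filter` (default all codes): restricts annotations by GO
  evidence code (e.g. `IDA`, `IMP` for experimental-only analyses).
* Genes are keyed by the GAF database object id; symbols are a
  case-insensitive matching convenience, since symbols collide across
  sources.  Unmatched identifiers are always reported, never dropped.

## Synthetic fixtures and what they show

`simulate_go_fixture()` writes a seeded, byte-reproducible world: a
three-namespace OBO whose graph is acyclic by construction (edges only
run from later to earlier terms in a random topological order), with
multi-parent terms, occasional cross-namespace `part_of` links, a
planted alternate id and obsolete term, a GAF 2.2 file with mixed
evidence codes and a planted `NOT` record, and two gene lists with a
planted shared leaf (one gene from each list annotated to the same
childless term).  Defaults are 12 terms per namespace and 20 genes with
about two direct annotations each — big enough for depth ≥ 4 and
diamond motifs, small enough that an exhaustive reference is instant.
The validation sweep uses 100 seeds at 8 terms per namespace and 16
genes, thresholds 2–6, both modes.

`goleaf_oracle()` recomputes the expected output directly from the
generator's manifest with none of the package's machinery: ancestor
sets by iterated single-step parent expansion to a fixpoint, exhaustive
term scans for the mode condition, pruning by pairwise descendant
checks, and scores from first principles.  The suite requires the
pipeline and the oracle to agree exactly on every seed.

The generator aims only for *structural* realism (multi-parents, depth,
shared paths across lists).  It does not emulate GO's heavy-tailed
term-size distribution, biased annotation depth, inter-annotator
redundancy, or taxon structure.  Passing the sweep therefore shows the
algorithm is implemented correctly on arbitrary DAG-shaped worlds; it
says nothing about which thresholds are scientifically sensible on a
particular real corpus, and corpus-scale term counts depend strongly on
the annotation snapshot used.

## Numerical and degenerate-input choices

* Scores are exact binary logarithms; the TSV writer prints them with
  four decimals (IEEE round-half-even via `sprintf`), and two runs on
  identical inputs are byte-identical — there is no randomness anywhere
  in the main pipeline.
* Obsolete terms are dropped from the graph but kept in an index, so
  annotations pointing at them are *quarantined with a count* rather
  than silently lost; the same applies to unknown term ids.  Alternate
  ids resolve to their primaries before anything else happens.
* A cycle in the input ontology (impossible in a valid GO release, easy
  in a corrupted file) aborts parsing with one witness cycle in the
  message.
* Fewer mapped genes than the threshold is an input error (no term
  could qualify), as is an empty gene list after comment stripping.
* An empty result is legal and writes a header-only table.

## Design decisions taken where the design was open

* **Descendants-in-shared-set pruning** (see above) rather than
  has-any-child-in-full-GO: reference outputs retain terms that are
  non-leaves of the full ontology, so the latter reading is ruled out.
* **Between-mode thresholds above 2** are interpreted as "at least
  `threshold` supporting genes in total, at least one from each list";
  per-list minimums beyond one are not offered, since only the total
  form has a reference behaviour.
* **Background counts over the whole filtered GAF**, not the input
  list: $g(t)$ measures how generic a term is in the annotation corpus.
* **Cross-namespace edges are retained** and never special-cased;
  results carry their namespace (BP/MF/CC) and can be filtered
  afterwards.
* The run object is tidyverse-shaped: `tidy()` for the ranked table,
  `glance()` for the run report, `autoplot()` for a score chart —
  results compose with dplyr/ggplot2 workflows.

## Limitations

* No enrichment statistics, by design: the method is a deterministic
  set operation plus a specificity score, complementary to (not a
  replacement for) hypergeometric-style testing.
* No identifier mapping beyond case-insensitive symbol/id matching;
  cross-species merging and GPAD/GPI inputs are out of scope.
* Published corpus-scale figures tied to specific 2018-era annotation
  databases are not reproduced here; correctness is instead
  demonstrated against the independent oracle on synthetic corpora.
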