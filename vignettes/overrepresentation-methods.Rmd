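---
title: "Methods: hypergeometric over-representation analysis against curated gene-set collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypergeometric over-representation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperora)
```

## The problem

Genomic experiments — bulk RNA-seq contrasts, single-cell clusterings —
produce lists of genes that need biological characterization. Standard
ontology-based enrichment tools return generic terms when the question is
domain-specific (for example, distinguishing monocyte-derived from
tissue-resident macrophage signatures). `hyperora` instead tests query
lists against *curated collections*: GMT files of gene sets taken directly
from published studies, each collection carrying its own gene universe.
The package ships no curated content; it ships the machinery plus seeded
synthetic generators shaped like real collections, so everything is
testable offline.

## The model

For one query list and one annotated gene set, let

* $N$ — number of genes in the (effective) background,
* $n$ — number of genes in the query list,
* $K$ — number of background genes carrying the annotation,
* $k$ — number of query genes carrying the annotation.

Under the null that the query is an exchangeable draw of $n$ genes without
replacement from the background, the enrichment p-value is the
hypergeometric upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
  \frac{\binom{n}{i}\,\binom{N-n}{K-i}}{\binom{N}{K}},$$

computed through the survival function of the hypergeometric distribution
(`stats::phyper`), which evaluates in log space and is stable for
collection-scale parameters. The test suite pins this route to two
independent oracles: exhaustive enumeration of all $\binom{N}{K}$
annotation placements for every admissible parameter combination with
$N \le 12$, and exact big-integer rational arithmetic for 200 random cases
with $N \le 2000$, both to $10^{-12}$ absolute.

**Depletion.** Depletion significance is reported as the literal
complement $1 - P(X \ge k)$, i.e. $P(X \le k - 1)$. This is deliberately
*not* the conventional lower tail $P(X \le k)$; the complement convention
keeps one number per test driving both ends of a single classification
slider (enriched below one cutoff, depleted above the other), and the
difference of one probability mass point is immaterial at the cutoffs
used. The convention is stated here so nobody mistakes `p_deplete` for a
standalone lower-tail p-value.

**Multiple testing.** Every (query list × gene set) pair is a separate
hypothesis. Benjamini–Hochberg step-up adjustment is applied *once,
globally*, with the comparison count $m$ equal to the number of tests
actually performed across all query lists and all selected datasets —
never per dataset. Gene sets that cannot be tested (no annotated gene in
the effective background, $K = 0$) are skipped, reported, and excluded
from $m$: counting hypotheses that were never evaluated would make the
correction arbitrary. `bh_adjust()` delegates the step-up computation to
`stats::p.adjust(method = "BH", n = m)`, which supports a divisor larger
than the vector length.

## Background resolution

Two settings control $N$ and $n$ per dataset:

* **intersect** (default): background and query are intersected with the
  dataset's gene universe before counting. This conditions the test on
  genes the study could in principle have annotated, and makes results
  invariant to padding the user background with genes no dataset has ever
  seen (a property the suite asserts bit-for-bit).
* **user**: background and query are used as supplied — preferable when
  the overlap between the user's background and a dataset's universe is
  small enough that intersection would gut the test.

A dataset's universe defaults to the union of its gene-set members, since
a GMT file carries nothing else; an explicit universe (for instance the
study's full expressed-gene list) can be supplied and may exceed the
union. Under `intersect`, an empty effective background or query makes
that dataset *degenerate*: it is skipped and reported rather than raising
an error, and only if every dataset degenerates does the run fail, with a
pointer to `user` mode.

## Identifier handling

Gene labels are matched on a normalized key: trimmed, upper-cased, with
any `.NN` version suffix stripped from Ensembl mouse gene IDs
(`ENSMUSG...`). Matching is therefore case-insensitive for symbols and
version-insensitive for Ensembl IDs; no translation between the two kinds
is attempted, because curated files record both without a mapping. Labels
that are empty or contain internal whitespace are rejected outright — a
silent repair could merge distinct records. Query genes absent from the
background are dropped and reported per list (or rejected under
`strict = TRUE`), which keeps the subset relation $query \subseteq
background$ that the model requires.

## The annotation network

Gene sets become nodes (grouped by dataset through a node attribute —
layout is the consumer's concern), and two sets are connected when their
shared-gene proportion exceeds `min_weight` (default 0.05, a readability
floor for dense collections). The proportion is the **Jaccard index**
$|A \cap B| / |A \cup B|$: among the candidate readings of
"proportion of shared genes" it is the one with a standard name, a
symmetric definition, and an intuitive [0, 1] scale; the overlap
coefficient $|A \cap B| / \min(|A|,|B|)$ is available behind
`weight_method = "overlap"` for users who want containment emphasized.
Cross-dataset edges are included — the point of the graph is to show when
annotations from different studies describe the same genes. Per-query
significance is overlaid as a node attribute $-\log_{10} p$ without
touching topology, so the graph stays constant for a given dataset choice
and overlays are freely replaceable. Exports: GraphML (via igraph) and
Cytoscape-style JSON.

## Reporting choices

* Cutoffs default to raw p-values of 0.05 (enrichment) and 0.95
  (depletion); comparisons are inclusive (`<=` / `>=`). `--use-fdr`
  switches both the table filter and the heatmap classification to
  BH-adjusted values.
* The gradient heatmap uses a signed score: $-\log_{10} p$ on the
  enrichment side ($p < 0.5$, positive red) and $\log_{10}(1-p)$ on the
  depletion side (negative blue), clamped to $\pm 300$ so deterministic
  overlaps (where a tail is exactly 0 or 1) stay finite.
* The significant-hits table carries the full hypergeometric
  parameterization and the sorted, semicolon-joined overlap genes, so a
  row is auditable without re-running anything.
* The unmatched report lists query genes in no dataset universe (with
  their source list), background genes in no universe, and universe genes
  missing from the background — the three places identifier problems
  hide.

## Numerical and degenerate-input policy

* `p_deplete = 1 - p_enrich` holds *exactly* as a floating-point
  identity. One consequence: when `p_enrich` underflows below machine
  epsilon, `p_deplete` rounds to exactly 1.0 — the half-open range
  $[0, 1)$ is a real-arithmetic statement, not an IEEE one.
* The upper tail equals exactly 1 for every $k \le \max(0, n + K - N)$,
  the smallest achievable overlap; strict monotonicity in $k$ holds only
  above that bound. Both facts are asserted against the enumeration
  oracle.
* Results are emitted in a deterministic order (dataset input order,
  gene-set line order within a dataset, query input order), and the table
  sorts by p-value with lexicographic (dataset, annotation) tie-breaks —
  two identical runs produce byte-identical CSV and GraphML artifacts.

## What the synthetic generators emulate — and what they do not

`make_universe()` produces positional labels (`GENE000001`, ...);
`make_annotation_dataset()` draws sets of uniformly distributed sizes,
sampled independently without replacement within each set;
`make_null_query()` is a uniform draw from the background; and
`make_enriched_query()` plants a known fraction of a target set into an
otherwise-null query. The shipped demonstration fixture mirrors the shape
of a typical curated corpus — three datasets of 11, 7 and 5 sets over a
3348-gene universe, the scale of a study reporting k-means clusters over
its differentially expressed genes — without claiming any real content.

Real collections differ in ways these generators deliberately ignore:
set sizes are long-tailed rather than uniform, sets within a study are
near-disjoint (cluster partitions) or nested (marker hierarchies) rather
than independent, and gene usage across studies is correlated. Passing
the calibration and recovery checks therefore demonstrates that the
statistics are implemented correctly under the stated null — uniform
exchangeable draws — not that any particular biological collection will
behave this way. On real data the exact test remains valid but
conservative on discrete support, which is the direction the calibration
check asserts (observed false-positive rate at or below nominal).

## Problem sizes used by the checks

The validation suite works at desk scale, chosen to exercise every code
path while staying comfortably reproducible: enumeration to $N \le 12$;
exact-rational spot checks to $N \le 2000$; a 10,000-test
complementarity sweep (20 queries × 500 sets); 1000 null queries of 50
genes against a 100-gene set in a 2000-gene background (the
super-uniformity bound is $0.05 + 3\sqrt{0.05 \cdot 0.95 / 1000}$);
and 200 planted-recovery replicates (query 100, target 120, planted
fraction 0.8, universe 2000), where the planted tail at $k = 80$ is so
extreme that recovery failures would indicate a bookkeeping bug, not bad
luck. All randomness flows through explicit integer seeds.

## Known limitations

* No odds-ratio or effect-size output; p-values order hypotheses but do
  not rank effect magnitudes across tests.
* No ranked-list (GSEA-style) statistics and no permutation nulls; the
  model is draw-without-replacement on unordered lists.
* No identifier translation across species or between symbol and Ensembl
  namespaces; users must harmonize identifiers upstream.
* The heatmap and network renderings are static exports; interactive
  exploration is out of scope.
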