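---
title: "Methods: phylogenetic function propagation, slim construction and enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic function propagation, slim construction and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofam)
```

`gofam` models the pipeline that turns curated, branch-level statements
about gene function into leaf-level annotations, a usage-driven GO-slim,
and gene-list statistics. This vignette records the model, its
assumptions, and the design decisions taken where the underlying
procedure is genuinely open.

## The ontology model

An ontology is a DAG of terms connected by `is_a` and `part_of` edges
only; these are the two relations followed for every closure operation
(annotation expansion, branch-usage counting, slim mapping). Other GO
relations (`regulates`, `occurs_in`, ...) are parsed and *dropped with a
warning*: traversing them would change counting semantics, and the
closure rules here are defined over the two containment-like relations.
Each aspect (biological process, molecular function, cellular component)
has exactly one root, detected as the term with no parents; a second
parentless term in an aspect is a structural error rather than a second
root, because every operation downstream assumes a unique traceable
root. Cross-aspect edges are forbidden — historical inter-aspect
`part_of` links would let closure leak between aspects, so the parser
rejects them. Obsolete terms are kept as isolated records: an annotation
file referencing one fails loudly at lookup instead of silently
vanishing.

## Event-labeled trees, subfamilies, orthologs

Gene family trees are rooted, with every internal node labeled
speciation, duplication or horizontal transfer, and every leaf carrying
a gene and a species. Three operations are defined on them.

**Subfamilies.** A duplication creates functional novelty, so a new
subfamily is founded at each duplication node for the more diverged
duplicate, while the less diverged copy keeps the parental subfamily.
"More diverged" needs a metric the curation literature does not pin
down; here it is the mean root-to-leaf path length of each child
subtree, measured in summed branch lengths from the duplication node —
the simplest length-based divergence proxy. Ties keep the parental
label on the child whose smallest leaf gene id sorts first, making the
partition deterministic. A *recent* duplication confined to a single
reference species (all leaves below the node belong to one species, and
that species is in the reference set) creates no subfamily; "recent" is
operationalized purely by that species pattern since no time calibration
is available.

**Orthologs.** A pair of genes is called orthologous iff the LCA of
their leaves is a speciation node and their species differ.
Horizontal-transfer nodes are deliberately treated like duplications
(no calls): ortholog semantics across a transfer are undefined here.
Same-species pairs under a speciation LCA — possible when lineages are
lost or unsampled — are excluded because orthology is cross-species by
definition.

**Gain/loss propagation.** Curated events attach to the branch *above*
a node and take effect for that node and all descendants (the
coordinate convention; the data model stores the node below the
branch). A valid event set has at most one event per (node, term) and
every loss strictly below a gain of the same term. Propagation walks
from the root switching terms on at gains and off at losses; the event
nearest a leaf on its root path wins, so a re-gain below a loss
re-activates the term for that clade. Whether re-gain after loss should
be legal at all is a modeling choice; nearest-event-wins is the
simplest semantics consistent with layered gains and losses, and the
validator treats such sets as valid. `NOT`-qualified GAF rows never
enter propagation or counting; they are retained only for audit.

## Slim construction

The slim is built from usage, in two steps:

1. **Selection.** A term is selected when it was used on strictly more
   than `min_branches` (default 5) distinct (family, branch) pairs,
   where a branch "uses" a term if the term *or any descendant* was
   gained there. A branch gaining two siblings counts once for their
   parent (distinct-branch semantics), and losses never count — they
   are negations of usage. The strict inequality follows the stated
   rule even though a 5–10 histogram bin straddles it.
2. **Ancestor completion.** Every term of the full graph with at least
   two distinct selected descendants is added. This is deliberately
   implemented as "≥ 2 selected descendants" rather than only pairwise
   LCAs: it is the reading that by itself guarantees each slim term can
   be traced to its aspect root inside the slim, with no separate
   patch-up step. Aspect roots are always included. Provenance
   (`selected_by_count` / `added_as_ancestor` / `root`) is recorded per
   term.

Slim edges are the transitive reduction of full-graph reachability
restricted to slim terms, keeping the slim a minimal DAG; where a
reduced edge coincides with an original edge its relation is kept,
otherwise it is written as `is_a`. Whether published slims transitively
reduce their edges is not documented; reduction was chosen because it
is canonical and makes the output unique, hence byte-reproducible.
Usage is counted globally rather than per aspect — terms are
aspect-bound anyway, so the two readings coincide on valid data.

Mapping annotations onto a slim rewrites each record to its
*most-specific* slim ancestors (the minimal elements of the slim
ancestors of the term; the term itself when it is in the slim). A
record may map to several incomparable slim terms; one with no slim
ancestor maps to the aspect root.

## Family-boundary diagnostics

Four criteria flag families whose alignments undermine tree inference.
The published thresholds are kept exactly: E1 fires when strictly more
than 50% of members fail to align to the retained core; E2 when the
core is shorter than 100 columns and the total alignment at least 4
times longer; P1 when at least 10% of members each align to fewer than
30 columns; P2 when some tree split separates subtrees sharing fewer
than 30 alignment sites.

Three definitions had to be supplied:

* The *core alignment* is columns with non-gap occupancy ≥ 0.5. The
  original trimming recipe is unpublished; occupancy trimming is the
  standard stand-in, and the threshold is an argument.
* *Does not align to the core* (E1) and P1's column floor both use the
  30-column threshold that the criteria already use elsewhere, for
  internal consistency; P1 counts residues within core columns so junk
  columns do not inflate coverage. Both are arguments.
* A P2 *shared site* is a column where at least half the members on
  each side of the split are non-gap; splits are enumerated over
  internal edges (leaf edges give degenerate one-member subtrees). A
  tree with no internal edge reports the full width as shared.

Column indices are 1-based throughout, as everywhere in R.

Identifier forward-tracking after reclustering maps each old family to
the cluster holding the largest number of its former members, ties to
the lexicographically smallest cluster id; unclaimed clusters get fresh
ids and fully lost families are reported as retired.

## Enrichment statistics

Fisher's exact test is the default overrepresentation test: the
hypergeometric tail for one-sided alternatives, and for two-sided tests
the point-probability rule (sum of all outcomes whose probability is at
most that observed, within a relative tolerance of 1e-7 — the
convention used by `stats::fisher.test`, against which the
implementation is cross-checked in the tests). The binomial test is
retained as the legacy option with `p0 = K/N`. The default report is
two-sided with a separate over/under direction label (sign of
`k − nK/N`), since both directions are of interest and the upstream
tool's exact sidedness is not printed anywhere.

The value-based enrichment test compares each class's values against
the distribution for *all* genes — class included — with the
Mann–Whitney U test, following the stated comparison literally rather
than class-vs-complement. Midranks handle ties; p-values are exact by
full enumeration up to a combined size of 20 (184 756 subsets, well
under a second) and use the tie-corrected normal approximation with
continuity correction beyond that.

Benjamini–Hochberg step-up FDR is the default correction, Bonferroni
the option; both delegate to `stats::p.adjust` and the tests verify the
step-up formula independently. The correction family is all tested
terms within one aspect of one annotation set — the correction universe
is not specified upstream, and per-aspect families match how results
are reported per ontology. Genes with no annotation form an
`UNCLASSIFIED` pseudo-class so list coverage is visible; list genes
missing from the reference are an error unless explicitly coerced,
because silent coercion hides upload mistakes.

## What the generators emulate — and what they do not

The fixture generators reproduce *structural* properties: DAGs are
acyclic and single-rooted by construction (edges only point from later
to earlier terms); planted event sets always validate (losses are only
planted below an active gain); split alignments have exactly the
overlap requested. They do not simulate sequence evolution, realistic
branch lengths, species-tree-consistent speciation patterns, or
curation bias in term choice. Green tests therefore demonstrate the
correctness of the algorithms under their stated contracts, not the
biological fidelity of any particular annotation corpus.

Default study conditions used by the tests and the acceptance script,
chosen once as representative desk-scale sizes: ontologies of 25–120
terms, families of 4–64 leaves with duplication probability ≈ 0.3, gain
rate 0.1–0.2 and loss rate ≈ 0.05 per branch-term, 200 propagation and
100 slim fixtures, a 2000-gene reference with 200-gene lists and
150-gene classes for the null calibration (sized so the discrete
hypergeometric null is near-continuous and a 1000-test fraction
resolves 0.05 within three binomial standard errors), and 100
replicates of 40 null + 10 signal classes for the FDR check — signal is
included because the false discovery *proportion* is only informative
when there is something true to discover.

## Numerical choices and degenerate inputs

* Hypergeometric/binomial tails use `phyper`/`pbinom` directly; the
  two-sided sum is capped at 1 to absorb floating-point accumulation.
* Equality comparisons in the exact Mann–Whitney enumeration use a
  1e-9 slack so midrank arithmetic cannot flip a boundary outcome.
* Degenerate tables (list = reference, `K = 0`, constant values) all
  return p = 1 rather than erroring; an empty slim selection returns a
  roots-only slim with a warning.
* OBO and NHX writers emit sorted, canonical output, so equal objects
  produce byte-identical files; parse∘write is the identity on every
  generated fixture.
* Branch lengths are optional in NHX input (`NA` for the root); missing
  lengths count as 0 in divergence means.

## Known limitations

* Ortholog calls ignore least-diverged-paralog conventions some
  resources export; only the speciation-LCA rule is implemented.
* Subfamily divergence uses mean leaf depth, not sequence divergence;
  with strongly rate-heterogeneous clades the two can disagree.
* The QC criteria P2 enumerates edge-induced bipartitions only; curated
  multi-way subtree groupings are out of scope.
* The slim builder assumes counts computed on the same graph it is
  given; it does not re-derive counts.
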