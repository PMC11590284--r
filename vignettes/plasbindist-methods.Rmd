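---
title: "A repeat-aware split/join dissimilarity for plasmid bin sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A repeat-aware split/join dissimilarity for plasmid bin sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasbindist)
```

## The problem

Plasmid binning tools group the contigs of a draft bacterial assembly into
*plasmid bins*, each bin meant to hold the contigs of one plasmid. Different
tools disagree, and high-level statistics such as precision, recall and F1
say *how much* two bin sets disagree but not *how*: are bins fragmented,
merged, padded with chromosomal contigs, or missing plasmidic ones?
`plasbindist` answers this with an edit-style dissimilarity between two bin
sets whose value decomposes into exactly those four error kinds.

## The model

Let $\mathcal{A}$ and $\mathcal{B}$ be two sets of plasmid bins over a contig
universe, each contig $c$ carrying a length $\ell(c)$ in bp. For a set of
contigs $X$ define the weighted size
$L_\alpha(X) = \left(\sum_{c\in X} \ell(c)\right)^\alpha$ with
$\alpha \in [0,1]$: $\alpha = 0$ makes every non-empty set weigh 1 (pure
counting), $\alpha = 1$ weighs sets by their full length.

**Splits and joins.** Splitting a bin $P$ into disjoint non-empty halves
$P', P''$ costs $\min(L_\alpha(P'), L_\alpha(P''))$; joining two bins costs
the same by symmetry.

**Repeat-free dissimilarity.** When no contig occurs twice on a side, the
dissimilarity is

$$D_\alpha(\mathcal{A},\mathcal{B}) =
  \sum_{c\ \mathrm{unique}} \ell(c)^\alpha
  + \sum_{P \in \mathcal{A}'} c_\alpha(P; P_1,\dots,P_k)
  + \sum_{Q \in \mathcal{B}'} c_\alpha(Q_1,\dots,Q_k; Q),$$

where *unique* contigs occur on one side only (they are discarded first and
billed $\ell(c)^\alpha$ each), $\mathcal{A}'$ and $\mathcal{B}'$ are the sets
after that removal, and the $P_i$ are the parts of the *refinement* of $P$ —
the unique partition of $P$ grouping contigs by which bin of the other set
holds them. The cheapest sequence of binary splits producing a refinement has
the closed form

$$c_\alpha(P; P_1,\dots,P_k) = \sum_i L_\alpha(P_i) - \max_i L_\alpha(P_i):$$

carve the parts off from smallest to largest, paying for each part except the
largest. The join phase is the mirror image over $\mathcal{B}'$. The four
terms — unique-to-left (*extra*), unique-to-right (*missing*), *splits* and
*joins* — are reported separately by `bin_dissimilarity()` and always sum to
the total (asserted to $10^{-9}$ relative tolerance in the tests).

**Repeats.** A contig held by $k_1$ left bins and $k_2$ right bins with
$k_1 + k_2 > 2$ forms a *repeat family*. A maximal matching pairs
$\min(k_1,k_2)$ copies across the sides — there are
$\binom{\max(k_1,k_2)}{\min(k_1,k_2)} \min(k_1,k_2)!$ of them — after which
matched copies share a fresh id, unmatched copies become side-local (hence
unique), and the instance is repeat-free. The dissimilarity is the **minimum**
of the repeat-free value over all combinations of matchings, found exactly by
branch-and-bound (below). The normalisation

$$d_\alpha(\mathcal{A},\mathcal{B}) = \frac{D_\alpha(\mathcal{A},\mathcal{B})}
 {\sum_{P\in\mathcal{A}}\sum_{c\in P}\ell(c)^\alpha +
  \sum_{Q\in\mathcal{B}}\sum_{c\in Q}\ell(c)^\alpha}$$

counts each contig once per bin it occupies, giving $d_\alpha \in [0,1]$ with
$d_\alpha = 0$ iff the sets are equal and $d_\alpha = 1$ iff they share no
contig.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | length-weight exponent; 0 = pure event counting, 1 = pure length. 0.5 is a practical compromise: at $\alpha = 1$ fragmentation of a true bin into many singletons is invisible (see below), at $\alpha = 0$ a 100 bp and a 100 kb contig weigh the same. |
| `min_len` | 0 bp | contigs shorter than this are discarded (and excluded from the normalisation) before comparison; raising it shrinks the matching search space on assemblies with thousands of short contigs. |

The fragmentation blind spot of $\alpha = 1$: take one true bin of $2k$
equal-length contigs and compare (i) two predicted bins of $k$ contigs and
(ii) one bin of $k$ plus $k$ singletons. Both give $d_1 = 0.25$ — evaluating
the definitions above, the join costs are $kL$ in both cases over a
denominator of $4kL$ — while any $\alpha < 1$ ranks the shattered prediction
strictly worse. The test suite asserts the equality and the ordering for
$k = 2..5$.

## The branch-and-bound

* **Root**: the instance restricted to non-repeat contigs (contigs duplicated
  twice on a single side, which are repeats but not repeat families, are
  resolved here the only way possible: both copies renamed, hence unique).
* **Levels**: each level adds all copies of one repeat family, once per
  matching. Families are processed in decreasing number of matchings (ties:
  decreasing length, then id) so the widest branching happens where the bound
  prunes most.
* **Bound**: the partial dissimilarity never decreases when contigs are
  added, so a subtree is entered only if its root value is strictly below the
  incumbent. The first incumbent is the "identity" resolution (copies paired
  in sorted bin-id order), making pruning active from the first node.
* **Ties**: among equal-cost optima the first in the deterministic
  enumeration order is reported, so results are reproducible.
* **Verification**: `exhaustive_dissimilarity()` evaluates every combination
  of matchings (refusing above a configurable cap, default $10^5$) and the
  suite checks exact agreement with the search on hundreds of random
  instances, with pruning on and off.

Fresh ids for resolved copies use the reserved `#` character
(`ctg#1`, `ctg#A1`, …), which is rejected in user input, so renaming can
never collide.

## Classic scores and ground truth

`precision_recall_f1()` implements the length-weighted precision (each
predicted bin credited with its best overlap against any truth bin, over
total predicted length), the mirrored recall, and $F_1 = 2pr/(p+r)$.
`build_truth_bins()` reconstructs ground-truth bins from alignment hits of
short-read contigs against hybrid-assembly contigs: circular hybrid contigs
longer than 500,000 bp are chromosomes, circular ones shorter are plasmids,
the rest ambiguous; hits below 95% identity or covering less than 80% of the
query are discarded (thresholds inclusive: a hit at exactly 95/80 survives,
the conservative reading of the strict-inequality rules; a circular contig of
exactly 500,000 bp is labelled plasmid and flagged). Coverage is per hit by
default; `union_coverage = TRUE` merges the query intervals of fragmented
hits per (query, subject) pair first — useful for mappers that split
alignments, not the default because a single spurious short hit should not be
rescued by another.

## Synthetic data: what it does and does not emulate

`generate_binset()` draws bin sets with 5 bins of 2–6 contigs and lengths
uniform in 500–50,000 bp by default — the scale of real plasmid complements,
where bins hold a few contigs and plasmids run from a few kb to a few hundred
kb. `perturb_binset()` applies a controlled number of drops, additions,
duplications, splits and joins (in that fixed kind order, seeded within each
kind) and returns a replayable log. This gives fixtures with *known* edit
structure: split-only perturbations must surface purely in the joins
component, additions purely in extra, and with $\alpha = 0$ the total equals
the split count exactly.

What the generator does **not** emulate: realistic contig length
distributions (real short-read assemblies are heavily skewed to short
contigs), assembly-graph structure, shared repeats between chromosome and
plasmids, or correlated errors between tools. Passing tests therefore
establish the correctness of the metric and its implementation, not how any
binning tool will score on real data.

## Numerical choices and degenerate inputs

* Costs accumulate in double precision; component additivity is exact up to
  $10^{-9}$ relative tolerance.
* Ties in the refinement maximum need no tie-break: the cost is unchanged
  whichever maximal part is retained.
* Two empty bin sets compare at $d = 0$ (and score 1 on precision/recall/F1,
  with a message); one empty set gives $d = 1$ and scores 0 — consistent with
  the 0/1 iff characterisations.
* Batch summaries use the sample (n−1) standard deviation; with a single row
  the sd is reported as 0 and flagged.
* Bins emptied by the minimum-length filter are dropped: an empty bin has no
  defined split cost.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
50-seed fixture sweeps for the 0/1 axioms, 200 random repeat instances
(≤ 3 families, ≤ 3 copies per side) for search-vs-enumeration agreement,
brute-force split-sequence minimisation up to 6 parts, and perturbation
ladders of 30–60 seeds. These sizes exercise every code path, including
multi-family branch-and-bound with pruning, while keeping the whole suite
under a minute on one CPU.

## Known limitations

* The measure considers splits followed by joins only; translocations
  (exchanging contig subsets between bins) and interleaved split/join
  sequences are out of scope, so complex bin mixtures are billed as a split
  plus a join.
* The matching search is exponential in the number of repeat families in the
  worst case; `min_len` is the practical lever on real assemblies.
* Native output formats of specific binning tools are not parsed; inputs are
  the documented TSV (`plasmid`, `contig`, `contig_len`).
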