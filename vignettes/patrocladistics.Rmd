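---
title: "Patrocladistic classification: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patrocladistic classification: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patroclad)
```

## The problem

When a genus turns out to be paraphyletic — other named taxa are nested
inside it on the molecular tree — taxonomists face a choice between
splitting the genus or widening it. Two kinds of evidence inform that
choice: branching order (which groups are monophyletic, where the
"intruder" taxa sit) and divergence (how much character change separates
the taxa). `patroclad` implements the full analytic chain used to weigh
both: genetic distances with group means, parsimony analysis with
bootstrap support, parsimony character mapping, monophyly diagnosis with
independent-origin counting, and the patrocladistic classification that
combines branching order and divergence into a single clustering.

## Distances

`p_distance()` is the proportion of differing sites among compared sites.
`k2p_components()` corrects it with Kimura's two-parameter model, which
separates transitions (A↔G, C↔T; proportion $P$) from transversions
(proportion $Q$):

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

Both use **pairwise deletion**: a site enters a pair's comparison only
when both sequences show an unambiguous base. Gaps, `?`, `N` and IUPAC
ambiguity letters are excluded — the standard default of distance
software, adopted here because nothing in the workflow depends on
complete-deletion semantics. When $1-2P-Q \le 0$ or $1-2Q \le 0$ the
distance is undefined (saturation); the package returns an `NA` sentinel
rather than an error so full matrices can still be written, and
`upgma()` refuses such matrices explicitly. A pair with *zero* comparable
sites is a hard error: no number would be meaningful.

## Parsimony

Characters are unordered and unweighted; gaps are coded as missing data,
i.e. a missing observation carries the full state set of its column.
Lengths and ancestral sets are computed with the count-based
generalization of the Fitch downpass (Hartigan's rule), which is exact on
multifurcating nodes: with per-state child counts $c(s)$ and
$K = \max_s c(s)$, the node's preliminary set is $\{s : c(s) = K\}$ and
the length increment is $(\#\text{children} - K)$. On binary nodes this
is the familiar intersection/union rule. Exactness on polytomies matters
because consensus trees are legitimate inputs for character mapping.

Most-parsimonious state *sets* per node come from the matching uppass.
Where a single reconstruction is needed (per-branch change counts, the
patristic distance), ambiguity must be resolved; the package uses a
deterministic parent-state-preferring rule: the root takes the smallest
state in its downpass set, and every other node takes its parent's state
whenever that is in its own downpass set, otherwise its smallest downpass
state. This delays changes toward the tips (DELTRAN-like) and provably
attains the minimum length. The choice is a convention — reference
implementations of ancestral reconstruction leave ambiguity resolution
unspecified — so it is documented here, deterministic, and its
conservation property (branch changes sum exactly to the matrix length)
is enforced by tests.

`min_state_origins()` asks a different question: over *all*
most-parsimonious reconstructions, what is the minimum number of branches
on which a focal state is gained? This is computed by a two-criterion
dynamic program (minimize changes, then gains among minimum-change
labelings), not by enumerating reconstructions. Gains are counted on
branches; a root resolved to the focal state counts as one further origin
and is flagged separately, so "the state evolved at least twice" claims
are exactly the reported `origins` value.

### Tree search

The search module is desk-scale by design. `exhaustive_search()`
enumerates all $(2n-5)!!$ unrooted topologies (capped at nine taxa, where
that is 135,135); `nni_search()` hill-climbs over nearest-neighbor
interchanges from a greedy random-addition start. Large-neighborhood
swapping (TBR/SPR) as used by full phylogenetics programs is out of
scope; on the problem sizes this package targets, NNI from a greedy start
matches the exhaustive optimum in well over 90% of random datasets (the
acceptance suite measures this). Bootstrap support resamples columns with
replacement, takes the strict consensus of each replicate's optima, and
reports clade frequencies on the majority-rule consensus. All
stochastic steps run from an explicit seed.

Search outputs are rooted on the edge of the lexicographically smallest
taxon so that clade sets are comparable across replicates; this is a
display/bookkeeping convention, not a rooting claim.

## Patrocladistics

The patrocladistic combination uses two matrices read off a single
reference cladogram (any rooted tree the user trusts — typically a
well-supported consensus):

* **cladistic distance**: the number of internal nodes on the path
  between two leaves (sister taxa are 1 apart). The literature does not
  pin down this definition precisely; counting nodes is the default
  here, and counting branches is available via
  `cladistic_distance_matrix(count = "branches")`.
* **patristic distance**: the sum of per-branch apomorphic step counts
  along the path, with the step counts taken from the deterministic
  parsimony resolution above.

`combine_distances()` forms $w_c \cdot d_{clad} + w_p \cdot d_{patr}$,
default $w_c = w_p = 1$ (plain addition, as the method was originally
stated); an optional `standardize` flag divides each matrix by its
maximum first, for users who want scale-free weighting. `upgma()`
clusters the combined matrix; the merge height is half the average
between-cluster distance, cluster updates are member-count weighted, and
ties are broken by the lexicographically smallest pair of cluster labels
(a cluster is labeled by its smallest member), so the patrocladogram is
fully deterministic. Ultrametricity of the output is enforced by
construction and by tests.

## Synthetic data

The simulators exist so every stage is testable without downloads, and
their defaults emulate a small-genus study:

* `simulate_yule_tree()`: pure-birth trees, optionally rescaled to a
  given height. Branch lengths are in expected substitutions per site.
* `evolve_sequences()`: K2P process with ratio `kappa` (default 2), the
  same model the distance estimator inverts — so estimator recovery is a
  closed loop, which the acceptance suite exploits (truth 0.2, mean
  estimate within ±0.01 over 100 replicates of 10,000 sites).
* `evolve_morphology()`: symmetric k-state Mk process, default 45 binary
  characters — the scale of a genus-level morphological matrix.
* `make_paraphyly_scenario()`: a 12-taxon focal clade of height 0.05
  substitutions/site (within-genus ITS-scale divergence), a 4-taxon
  outgroup on a 0.15 stem (between-genera scale), and two intruders
  grafted onto leaf branches in the two basal focal subclades. A binary
  convergent character marks each intruder and its host leaf, so the
  derived state needs at least two independent gains on the true tree.
  Morphological rate is 8 changes per character per unit length, giving
  moderately variable matrices at these depths.

What the generator does *not* emulate: indels (gaps enter only via
missing-data handling), among-site rate variation, base-composition
bias, alignment error, and correlated characters. Passing tests
therefore demonstrate correctness of the algorithms under the stated
models, not robustness of the biological conclusions to those real-data
complications.

## Numerical and degenerate-input choices

* Newick output is canonical: children ordered by smallest descendant
  label, so equal topologies serialize identically (diff-stable).
* Numeric internal-node labels are interpreted as bootstrap percentages
  when > 1 and posterior probabilities when ≤ 1, matching the dual
  annotation convention of published trees.
* UPGMA tie tolerance is `1e-12` on distances; distance-matrix symmetry
  is validated to `1e-9` on read.
* All-missing morphological columns are treated as single-state (zero
  length); empty matrices score 0 everywhere.
* Group means require two members within a group (a singleton
  within-group mean is an error, not `NaN`).
* Alignment concatenation pads taxa missing from a partition with `?`
  and records which taxa were padded.

## Problem sizes

The test and acceptance workloads are sized for a single CPU: brute-force
parsimony oracles enumerate labelings on trees of up to 6–7 leaves (200
random cases), search comparisons use 7 taxa (945 topologies per
exhaustive run, 50–100 datasets), bootstrap checks use 5 taxa with up to
500 replicates, and the scenario checks run 50 seeds. These sizes give
the property checks enough replication to be meaningful while keeping
the whole suite in the low minutes.

## Known limitations

* Parsimony only; no likelihood or Bayesian methods, no model selection.
* NNI is the only heuristic neighborhood; very rugged landscapes can
  strand it on local optima (quantified, not hidden, by the acceptance
  rate above).
* The cladistic/patristic definitions follow one published reading of
  the patrocladistic protocol; where the original is silent
  (standardization before addition, node- vs branch-counting) the
  defaults are plain addition and node counts, with flags for the
  alternatives.
* `assess_monophyly()` reports non-monophyly plus intruders; it does not
  distinguish paraphyly from polyphyly, which requires character
  polarity judgments outside its scope.
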