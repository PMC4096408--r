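---
title: "Delimiting bacterial species from multilocus sequence data"
author: "mlsadelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting bacterial species from multilocus sequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsadelim)
```

## The problem

The 16S rRNA gene, the default marker for bacterial phylogeny, is often too
conserved to separate closely related species: within many genera, strains
belonging to distinct genomospecies share 16S identities at or near 100%.
Multilocus sequence analysis (MLSA) addresses this by concatenating several
single-copy protein-coding housekeeping genes and working with their pairwise
percent identities. A species hypothesis then rests on three mutually
supporting observations:

1. strains fall into clades on a tree built from the concatenated genes,
   with high bootstrap support;
2. pairwise similarities separate into an *intraspecies* band and an
   *interspecies* band with an empty gap between them, so any cutoff inside
   the gap yields the same grouping;
3. the grouping agrees with a genome-level relatedness standard — digital
   DNA–DNA hybridization (DDH), where pairs at or above 70% are conspecific.

`mlsadelim` implements this workflow end to end: per-locus diversity
statistics, neighbor-joining trees with bootstrap, threshold clustering,
gap diagnostics, and calibration of per-gene similarity cutoffs against a
DDH matrix. A seeded simulator generates complete synthetic studies so every
stage is testable without sequence downloads.

## Model and definitions

For two aligned sequences the **p-distance** is the proportion of differing
sites among comparable columns; **similarity** is the percent-identity
convention \(s = 100\,(1 - p)\). Under the default *complete deletion*
policy a column containing a gap or `N` in any strain is excluded for all
pairs; *pairwise deletion* excludes it only for the pairs it affects.
A column is **polymorphic** if at least two of `A,C,G,T` occur in it (gaps
and `N` carry no state); an **allele** is a distinct row string, with `N`
treated literally, so two rows differing only in `N` placement are distinct
alleles (sequencing ambiguity is not collapsed; the alternative would make
allele counts depend on an arbitrary imputation).

Trees are inferred with the Saitou–Nei neighbor-joining agglomeration on the
p-distance matrix. Two policies make the implementation deterministic where
the textbook algorithm is silent:

* **ties** in the Q-criterion are resolved toward the lexicographically
  smallest pair of current node labels;
* **negative branch lengths**, which the NJ formulas can produce on
  non-additive input, are clamped to zero with the deficit moved to the
  sibling edge, preserving the path length through the parent node.

Bootstrap support resamples alignment columns with replacement; replicate
*r* uses a sub-seed derived deterministically from the root seed and *r*, so
any replicate can be reproduced in isolation. Supports are reported as
integer percentages on internal edges. An alignment with no polymorphic
sites carries no signal at all: the package returns a star tree with zero
support and a warning rather than an arbitrary resolution.

**Delimitation** at cutoff \(c\) uses single linkage: groups are the
connected components of the graph with an edge wherever similarity
\(\ge c\). Single linkage operationalizes clade-based grouping — inside a
supported clade every strain is connected through its neighbors — and is
monotone: raising the cutoff can only refine the partition. Complete
linkage is available as a sensitivity check. Pairs exactly at the cutoff
join (\(\ge\), not \(>\)). Groups are labeled I, II, … by decreasing size,
ties by smallest member identifier.

**Calibration.** Given a DDH matrix over a strain subset, pairs are labeled
different-species when DDH \(< 70\%\). The calibrated per-gene threshold is
the *maximum similarity observed among different-species pairs* — the
tightest cutoff guaranteeing no different-species pair is merged. Reading
the value off a similarity-vs-DDH scatter by eye amounts to the same rule.
Same-species pairs falling *below* that threshold are reported as conflicts;
a marker with conflicts cannot delimit these species at any cutoff (the 16S
crossover failure mode). Spearman rank correlation summarises the
similarity–DDH relationship; it is preferred over Pearson because the
mapping is strongly nonlinear, but Pearson is available via
`cor_method = "pearson"`.

When `mlsa()` is asked to delimit without an explicit cutoff it places the
cutoff at the midpoint between the calibrated threshold (the interspecies
ceiling) and the smallest same-species similarity among the DDH pairs (the
intraspecies floor). The calibrated threshold itself is *attained* by an
interspecies pair, so clustering exactly at it would merge that pair under
the \(\ge\) rule; the midpoint sits inside the calibrated gap and is
maximally distant from both bands.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `deletion` | – | `complete` | matches the common distance-estimation default in desktop phylogenetics tools; `pairwise` keeps more sites for gappy data |
| `boundary` | % DDH | 70 | the classical species boundary |
| `cutoff` | % identity | calibrated-gap midpoint | see above; supply explicitly when no DDH is available |
| `linkage` | – | `single` | clade-consistent; `complete` for sensitivity |
| `bootstrap` | replicates | 0 (fit), 1000 typical | standard practice for publication trees |
| percentage rounding | decimals | 1, half away from zero | reproduces conventional reporting (e.g. 81/1419 → 5.7%) |

## The synthetic benchmark

`mlsa_sim_config()` defines a study: species with unequal strain counts, an
ultrametric species tree whose between-species node depths are drawn from
`t_inter_range`, star-shaped within-species clades of depth `t_intra`,
Jukes–Cantor (JC69) substitution with per-locus rate multipliers and G+C
composition, and a DDH matrix obtained by mapping concatenated p-distances
through \(100\,e^{-d/\lambda}\) plus optional Gaussian noise. The
exponential map was chosen because it is strictly decreasing and invertible,
so tests can predict exactly where it crosses the 70% boundary
(\(d^\ast = \lambda \ln(10/7)\)); a logistic variant would behave similarly
near the boundary but has no closed-form inverse advantage.

The defaults emulate a genus-scale survey: 42 strains in 12 species with a
dominant 20-strain group, two 5-strain groups, a 3-strain group, one
2-strain group (whose two members both enter the DDH panel, mimicking a pair
of separately named type strains that turn out conspecific) and seven
singletons; six loci of 1419/774/648/504/657/855 bp; a near-invariant
16S-like locus (rate multiplier 0.07) beside five variable coding loci with
rate multipliers proportional to their observed relative divergences;
`t_intra = 0.002` and `t_inter_range = (0.05, 0.10)` so that intraspecies
concatenated similarity stays above ~96% and interspecies similarity below
~93%; `ddh_lambda = 0.12` so every between-species pair falls well below 70%
DDH while within-species pairs stay far above it.

What the generator does *not* emulate, and what that means for test
interpretation:

* **No across-site rate heterogeneity.** Real coding genes concentrate
  substitutions on a subset of sites (third codon positions), which is how a
  real dataset can combine deep pairwise divergence with only ~40%
  polymorphic sites. Under homogeneous JC69, a 12-species tree deep enough
  to push interspecies similarity below 93% necessarily shows ~55–65%
  polymorphic sites at the coding loci. The 16S-like locus, being shallow,
  does land near its empirical ~6%. Tests that pass on the benchmark
  therefore validate the *analysis logic* at realistic similarity bands, not
  the site-pattern composition of real genes.
* **No recombination, no rate variation among lineages, no alignment
  error.** Real MLSA data can violate the clean gap structure; the gap
  diagnostic and conflict report exist precisely to surface that.
* **Star-shaped species clades** understate within-species tree structure;
  intraspecies similarity spreads narrower than in real surveys.

## Numerical choices and degenerate inputs

* NJ on fewer than 3 strains, asymmetric matrices, or pairs with zero
  comparable columns raise classed errors naming the offender.
* All reported percentages round half away from zero to one decimal;
  distances are reported to three decimals.
* Bootstrap replicates whose resampled columns are all gap/N are counted as
  supporting no split (they cannot occur under complete deletion unless the
  original alignment is degenerate).
* An intraspecies range over a partition of singletons is reported as an
  empty scope (`n_pairs = 0`), and the gap is then undefined rather than
  silently infinite.
* Equality at boundaries is always explicit: similarity equal to the cutoff
  merges; DDH equal to the boundary is same-species; a gap requires strict
  `intra.min > inter.max`.

## Design decisions that were genuinely open

* **Groups from threshold vs from tree clades.** The package delimits by
  threshold clustering; the tree (with bootstrap support and
  `shared_bipartitions()` against externally supplied trees) is
  confirmatory. An externally derived grouping can be imported with
  `as_partition()` and compared via the same range/gap machinery.
* **Maximum-likelihood / maximum-parsimony inference** is out of scope; the
  agreement marks consume external newick files instead. The delimitation
  logic depends only on distances, and NJ plus agreement marks is the
  decision-bearing combination.
* **Locus ranking** orders by gap width (intra.min − inter.max), descending,
  ties by lower calibrated threshold: a wider gap tolerates more sampling
  noise around the cutoff, which is what "resolution" means operationally.

## Problem sizes used in the test suite

The suite exercises NJ exactness on 200 random additive matrices of 4–8
taxa and checks NJ against an exhaustive least-squares search over all
unrooted topologies up to 7 taxa (945 topologies); partition recovery runs
the full 42-strain benchmark over 20 seeds; bootstrap checks use 100–300
replicates on 6–8 strain alignments; the JC69 closed form is verified at
10,000 sites. These sizes give each stochastic check a comfortable margin
(3–4 Monte-Carlo standard errors) while keeping the default run fast.

## Known limitations

* Calibration quality is bounded by the DDH panel: with one representative
  per species the intraspecies floor rests on few pairs (here, one
  two-member species), so the default cutoff midpoint leans on the
  interspecies ceiling. Supplying DDH for more strains tightens it.
* The calibrated threshold is a *lower-bound style* estimator (max over
  observed different-species pairs); with few pairs near the boundary it can
  sit well below the true crossing similarity. The reported pair counts
  quantify this.
* p-distances are uncorrected by design (the convention in similarity-based
  taxonomy); model-corrected distances are out of scope.
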