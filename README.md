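# mlsadelim

Species delimitation from multilocus sequence data (MLSA) for bacterial
taxonomy.

## The problem

In many bacterial genera the 16S rRNA gene is too conserved to tell species
apart: distinct genomospecies can share 16S identities at or near 100%, so
the conventional 97% cutoff collapses them into a handful of groups.
Multilocus sequence analysis concatenates several single-copy protein-coding
housekeeping genes (e.g. *leuA*, *clpA*, *pyrH*, *gatA*, *rpoD*) and works
with their pairwise percent identities instead. A species hypothesis is
accepted when three things line up:

1. the strains form well-supported clades on a neighbor-joining tree of the
   concatenated genes;
2. pairwise similarities split into an intraspecies band and an
   interspecies band with an empty **gap** between them, so any cutoff
   inside the gap yields the same grouping; and
3. the grouping agrees with digital DNA–DNA hybridization (DDH), the
   genome-level relatedness standard where pairs at or above 70% are
   conspecific.

The core quantitative step is the **calibration**: for each gene, the
species-boundary similarity cutoff is the maximum sequence similarity
observed among strain pairs whose DDH falls below 70% — the tightest cutoff
at which no different-species pair is merged. Writing \(p\) for the
uncorrected p-distance, similarity is \(s = 100\,(1-p)\), and the calibrated
threshold for a marker is

\[
\hat{c} \;=\; \max \{\, s_{ij} : \mathrm{DDH}_{ij} < 70\% \,\}.
\]

Same-species pairs with \(s_{ij} < \hat{c}\) are *conflicts*: the marker
cannot delimit those species at any cutoff (the 16S failure mode).

`mlsadelim` implements the whole workflow — alignment I/O and concatenation,
per-locus diversity statistics (alleles, polymorphic sites, G+C content,
p-distance ranges), Saitou–Nei neighbor joining with nonparametric bootstrap,
single-linkage threshold clustering, gap diagnostics, DDH calibration and
locus ranking — plus a seeded simulator (Jukes–Cantor substitution along an
ultrametric species tree, with a matched synthetic DDH matrix) so the whole
pipeline is testable without downloading sequences. It is aimed at
microbial taxonomists evaluating MLSA schemes and at method developers who
need a transparent, scriptable reference implementation.

## Worked example

Simulate a genus-scale study (42 strains, 12 species, six loci — a
near-invariant 16S-like marker and five variable coding genes) and fit the
full analysis:

```r
library(mlsadelim)

bench <- make_benchmark(mlsa_sim_config(seed = 42))
fit <- mlsa(bench$loci, ddh = bench$ddh)
fit
#> Multilocus sequence analysis
#>   42 strains, 6 loci (+ concatenation, 3438 bp)
#>   delimitation: 12 groups at 94.9% similarity (single linkage)
#>   concatenated similarity gap: (90.2, 99.1)%
#>   DDH-calibrated thresholds over 13 strains: 16S 99.4%, leuA 90.1%,
#>   clpA 92.4%, pyrH 89.5%, gatA 89.3%, rpoD 90.5%, MLSA 90.2%
```

The fit delimits the planted 12 species. The concatenated similarities show
an empty band between the largest interspecies similarity (90.2%) and the
smallest intraspecies similarity (99.1%); the delimitation cutoff (94.9%)
is the midpoint of the calibrated band, and any cutoff inside the gap gives
the same partition. `coef()` returns the calibrated per-gene
species-boundary thresholds:

```r
coef(fit)
#>      16S     leuA     clpA     pyrH     gatA     rpoD     MLSA
#> 99.36575 90.05168 92.43827 89.48413 89.34551 90.52632 90.22688
```

Note the 16S-like threshold sits at ~99.4% — different species are nearly
indistinguishable on that marker — while the coding genes separate species
around 89–92%. `summary(fit)$table2` reproduces the locus-characteristics
panel (length, alleles, G+C, polymorphic sites, p-distance range/mean), e.g.

```r
summary(fit)$table2[c(1, 7), ]
#>  Locus Length (bp) No. of alleles Average G+C content (mol%)
#>    16S        1419             19                       52.8
#>   MLSA        3438             42                       59.3
#>  Polymorphic sites No. Polymorphic sites % P-distance Range P-distance Mean
#>                    100                 7.0          0-0.023           0.010
#>                   2142                62.3      0.002-0.188           0.126
```

`plot(fit, which = "gap")` draws the per-locus intra/inter similarity
ranges; `plot(fit, which = "ddh")` the similarity-vs-DDH scatter with the
70% boundary and the calibrated threshold; `plot(fit, which = "tree")` the
NJ tree with bootstrap labels (request them with `mlsa(..., bootstrap =
1000, seed = 1)`).

File-based runs go through a YAML config (`loci:` name→FASTA manifest in
concatenation order, optional `ddh:` TSV, flags) and
`run_pipeline("run.yaml")`, which writes the report set — characteristics
table, similarity/distance matrices, newick tree, groups, ranges,
calibration report — with a checksum manifest; outputs are byte-identical
for a fixed seed.

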