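---
title: "Rank-feature phylogenies from dinucleotide-classified 8-mer spectra"
author: "kmerphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-feature phylogenies from dinucleotide-classified 8-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerphylo)
```

## The method

`kmerphylo` builds whole-genome phylogenies without alignment. The model of
the data is compositional: each genome is summarised by the occurrence
counts of all $4^8 = 65{,}536$ 8-mers, obtained with a sliding window of 8
bp and step 1 on the forward strand of every chromosome or contig
(`count_kmers()`). Windows never span record boundaries, and any window
containing a base outside A/C/G/T is skipped, so counts are deterministic
functions of the input sequence.

The central idea is that not all 8-mers are equally informative about
evolution. Ordered dinucleotides — above all CpG, and in invertebrates also
TpA — are depleted by directional mutational processes, and the 8-mers that
*contain* them carry that signal. `partition_by_dinucleotide()` classifies
every 8-mer by its number of (overlapping) occurrences of an ordered
dinucleotide XY into three subsets: XY0 (none), XY1 (exactly one) and XY2
(two or more). At $k = 8$ this census is a fixed combinatorial fact:

| pair type | n0 | n1 | n2 |
|---|---|---|---|
| X ≠ Y (e.g. CG, TA) | 40,545 | 21,468 | 3,523 |
| X = Y (e.g. AA) | 44,631 | 14,931 | 5,974 |

The package cross-checks these against two transfer-matrix recurrences for
the number of length-$n$ words avoiding a fixed dinucleotide:
$g(n) = 4g(n-1) - g(n-2)$ for non-self-overlapping pairs and
$f(n) = 3f(n-1) + 3f(n-2)$ for self-overlapping pairs such as AA, both
anchored at $g(0)=1$, $g(1)=4$.

### Spectra and separability

For each of the 48 (XY, class) subsets a genome has a *spectrum*: the
distribution of the relative motif number $\mathrm{RMN}(i) = N_i / 4^8$,
where $N_i$ is the number of subset members occurring exactly $i$ times
(members absent from the genome are counted at $i = 0$). The location of a
spectrum is compared with the *random center* $\bar{x}$, the mean count over
the full 8-mer universe, through the separability

$$\delta_{XYi} = \frac{\bar{x}}{\bar{x}_{XYi}},$$

where $\bar{x}_{XYi}$ is the mean count over the subset (zero-count members
included in the denominator — the only convention under which all 48 values
stay defined for every genome). $\delta > 1$ places the subset at the
low-frequency end of the spectrum; $\delta = 1$ means it is
indistinguishable from the random background. $\delta$ is invariant under
genome-size scaling, so it is comparable across genomes. When a subset has
zero total count, $\delta$ is reported as `NA` with a warning rather than
infinity, keeping tabular output finite.

### Rank features and the distance

CpG depletion makes the counts of CG-containing 8-mers systematically small
and heavy-tailed, so raw counts overweight a few high-frequency words. The
evolutionary feature used here is therefore the *relative frequency*: the
members of a feature set are sorted by count from small to large and the
1-based position in that order is the feature value. The distance between
genomes $a$ and $b$ is the root-mean-square difference over the $N$ members
of the set,

$$D_{ab} = \sqrt{\frac{1}{N}\sum_{i=1}^{N} (x_{ai} - x_{bi})^2},$$

which on rank vectors is a Euclidean metric scaled by $1/\sqrt{N}$ and is
invariant under any strictly increasing transformation of the counts —
sequencing depth, genome size and monotone count distortions cancel out.
The recommended feature set is `CG12` (the union CG1 ∪ CG2, $N = 24{,}991$);
`TA12` is the analogue for lineages where TpA selection is still active,
and `CG0`/`TOTAL` are provided for comparison. The distance matrix feeds
`neighbor_joining()`, and the result is an unrooted tree.

## Tunable parameters

* `k` (default 8): word length. The guideline `minimum_k(L)` =
  $\lceil 0.7 \log_4 L\rceil$ says what a sequence of length $L$ can
  support: $k = 8$ needs roughly 60 kb or more, and a 3 Gb genome would
  support $k = 12$. Counting is dense over $4^k$ words, so $k \le 12$ is
  the practical range.
* `feature_set` (default `"CG12"`): which 8-mers enter the rank vector.
* `tie_policy` (default `"ordinal"`): `"numerical order"` implies ordinal
  ranks; count ties are broken by ascending canonical k-mer index, which
  makes all outputs byte-deterministic. `"average"` (mid-ranks) is offered
  because published distance-matrix workflows do not always state their tie
  handling; the default is documented in every manifest.
* `rank_scope` (default `"union"`): ranks are computed jointly over the
  whole feature set. The alternative reading — rank within each XYi class,
  then assemble (`"per_class"`) — is preserved as an option.

## The simulator: what it emulates and what it does not

`simulate_genomes()` exists so the whole pipeline can be validated against
a known truth without downloading genomes. A root genome is drawn from a
first-order Markov chain built by taking the independence transition matrix
for a target G+C content, multiplying the C→G entry by `lambda_cg` and the
T→A entry by `lambda_ta` (values in (0,1]; 1 = no suppression), and
renormalising rows. This is the simplest generator that reproduces the
phenomenon the method exploits — CG-containing 8-mers pushed to the
low-frequency end of the spectrum, $\delta_{CG1} > 1$, increasing with
suppression strength. It does **not** model the biological mechanism
(methylation–deamination, selection), indels, rate heterogeneity or
repeats; passing tests therefore demonstrate the pipeline's statistical
correctness under dinucleotide bias, not its performance on real
heterogeneous chromatin.

Evolution along the tree is Jukes–Cantor: on a branch of length $b$
(expected substitutions/site) each site independently substitutes with
probability $\tfrac{3}{4}(1 - e^{-4b/3})$, the new base uniform over the
other three. i.i.d. substitution slowly erodes the dinucleotide bias along
branches; that is acceptable because recovery is scored on topology, not on
$\delta$. One master seed drives everything; each branch uses a stream
derived from (seed, child node id), so outputs are byte-reproducible.

Defaults were fixed once as the package's benchmark conditions: 8 taxa on a
balanced tree, branch length 0.05, 200 kb genomes, `gc_target = 0.5`,
`lambda_cg = 0.3`, `lambda_ta = 1`. 200 kb is ~3 windows per 8-mer — enough
for stable CG12 ranks while keeping a ten-replicate benchmark fast;
`lambda_cg = 0.3` matches the strength of CpG depletion seen in vertebrate
genomes (observed/expected CpG ≈ 0.2–0.3); `gc_target = 0.5` makes the
unsuppressed chain uniform, so with `lambda = 1` all 48 separabilities
converge to 1 and the background invariant is exact rather than
composition-confounded. The monotone-response check uses 500 kb genomes
(~7.6 windows per 8-mer) so subset means are tight.

## Numerical and design choices

* **Strand**: forward only. CG and TA are reverse-complement palindromes,
  so the targeted signal is strand-robust; no strand-collapsing is done.
* **Ambiguity codes**: windows containing any non-ACGT code are skipped
  deterministically, never randomly resolved.
* **"Two or more"**: class 2 is $\min(2, \text{occurrences})$, with
  overlapping occurrences counted (AAAAAAAA contains seven AA).
* **minimum_k rounding**: the formula is a minimum, so the conservative
  ceiling is used, with a $10^{-9}$ guard so that exact multiples (e.g.
  $0.7 \times 10 = 7$) are not pushed up by floating-point residue.
* **NJ tie-breaking**: among pairs with equal Q the smallest (row, column)
  index pair is joined, so identical inputs give identical Newick strings.
* **Negative NJ branch lengths**: clamped to zero with the deficit
  transferred to the sister branch (preserving the joined pair's distance);
  at the final three-cluster step negatives are simply clamped. Additive
  inputs never trigger clamping.
* **Zero matrices**: NJ still returns a fully resolved tree (ties resolved
  by the index rule) whose branch lengths are all zero — equivalent to a
  star once zero-length edges are collapsed.
* **Subset means**: zero-count members stay in the denominator; an all-zero
  subset yields `NA` separability, not `Inf`.
* **Precision contracts**: PHYLIP distances are written with 6 decimals,
  TSV reals with 6 significant digits, Newick branch lengths with a
  configurable number of significant digits (default 6); all numeric
  comparisons in tests use tolerances, never string equality.

## Worked example

```{r example}
sim <- simulate_genomes(suppressWarnings(
  sim_config(n_taxa = 8, root_length = 60000, seed = 2)
))
out <- tempfile()
res <- run_pipeline(genomes = sim$genomes, out_dir = out, quiet = TRUE,
                    write_tables = FALSE)
robinson_foulds(res$tree, sim$tree)
round(res$distances[1:4, 1:4], 1)
```

The separability table of one simulated genome shows the planted signal:
`CG1`/`CG2` sit far above 1 while every other subset hovers near the random
center.

```{r delta}
cnt <- count_kmers(sim$genomes[[1]], 8)
tab <- separability_table(cnt)
subset(tab, xy %in% c("CG", "TA"))
```

## Problem sizes used in validation

The test suite validates NJ on 100 random binary trees with 5–12 leaves and
branch lengths in [0.1, 2] (exact recovery, branch lengths to $10^{-9}$),
and the end-to-end benchmark on ten 8-taxon / 200 kb simulations (requiring
at least 9/10 perfect recoveries) plus five 500 kb genomes per suppression
level for the monotone $\delta_{CG1}$ response. These sizes were chosen as
the smallest at which the statistics of interest are stable.

## Known limitations

* Published-scale analyses (hundreds of vertebrate genomes from NCBI) are
  out of scope here; nothing in the package downloads data.
* No bootstrap or other support values; the tree is a point estimate.
* Dense counting limits $k$ to about 12; no canonical (strand-collapsed)
  k-mer mode.
* The simulator's i.i.d. substitution model slightly decays dinucleotide
  bias over long branches, so simulated $\delta$ values drift toward 1 with
  distance from the root.
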