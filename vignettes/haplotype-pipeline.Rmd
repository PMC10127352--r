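---
title: "Methods: haplotype diversity, differentiation, networks and dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity, differentiation, networks and dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapnet)
```

hapnet analyses aligned haploid sequence data — the typical input is a
mitochondrial gene fragment such as a ~550-bp cytochrome-*b* window
sequenced across a few dozen specimens from several localities — and
answers the standard population-genetic questions asked of such surveys:
how many haplotypes are there and how are they shared among populations;
how divergent are species and populations; how much diversity does each
population hold; are populations differentiated or panmictic; how do
haplotypes relate as a network; and how old are the major splits under a
molecular clock. This vignette documents the models, estimators,
parameters and numerical choices behind each stage, and what the
simulation-based validation does and does not establish.

## Alignments and haplotypes

Sequences must arrive pre-aligned and equal-length; the package
deliberately does no alignment. Characters are restricted to A/C/G/T,
gap (`-`), `N` and the IUPAC ambiguity codes; lower case is uppercased on
read and `U` is mapped to `T` with a warning. An optional window
(`window_alignment()`) selects a 1-based inclusive column range *on the
alignment at hand* — mapping those columns to full-gene numbering is the
caller's concern, since a stated full-gene interval and a stated fragment
length can disagree by an off-by-one in published coordinates; the
alignment length is treated as authoritative.

Haplotype collapsing (`collapse_haplotypes()`) uses **exact string
equality**. An `N` never wildcard-matches a base: two sequences differing
only at an ambiguous position are distinct haplotypes. This mirrors the
behaviour of the standard haplotype-collapsing web tools and keeps the
operation involutive (expanding the table reconstructs the input
multiset exactly). Haplotype ids `H1..Hk` follow order of first
appearance, so input order affects labels but nothing else.

## Distances

Pairwise divergence uses the Kimura 2-parameter model, which separates
transitions (A↔G, C↔T) from transversions:

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$$

with $P$ and $Q$ the transition and transversion proportions over the
sites compared. Sites where either sequence carries a gap or ambiguity
code are excluded *per pair* (pairwise deletion) rather than across the
whole alignment — for short fragments this maximises the sites usable in
each comparison. When $1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is
undefined (saturation); such pairs are flagged `NA` and dropped from
group means with a warning. At the divergences this package targets
(≤ ~12% between congeneric species) saturation signals corrupt input, not
a modelling regime worth supporting.

Group summaries (`group_distances()`) weight **haplotypes equally** — one
sequence per distinct haplotype per group — rather than weighting by
specimen frequency, matching the convention of published interspecies
distance tables whose group sizes are haplotype counts. Standard errors
come from site bootstrapping: alignment columns are resampled with
replacement, the group mean recomputed, and the standard deviation across
replicates reported. The default is 1000 replicates with an exposed seed;
an alignment with no variable sites yields an SE of exactly 0.

## Diversity

Haplotype (gene) diversity uses Nei's unbiased estimator
$H = \frac{n}{n-1}\,(1 - \sum_i p_i^2)$; a sample of $n$ singletons
attains exactly 1 and a monomorphic sample exactly 0. Nucleotide
diversity is the unbiased expected per-site difference between two random
sequences, $\pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j d_{ij}$, with
$d_{ij}$ the **raw proportion** of differing sites (pairwise deletion)
between haplotypes $i$ and $j$. Raw proportions are the convention for
$\pi$; a `corrected = TRUE` flag substitutes the K2P distance for users
who want a model-corrected variant, and the report prints $\pi$ in
percent while storing per-site values. Published $\pi$ values for small
samples are sensitive to the computing software's settings, so the test
suite pins $\pi$ to closed-form and brute-force oracles on planted data
rather than to any printed survey value. No variances are attached to
$H$ or $\pi$ (the tables this reproduces print none). Strata with one
specimen are reported with $H$ and $\pi$ as `NA` rather than dropped.

## Differentiation

Pairwise population structure is measured by one-level AMOVA on the
matrix of specimen-pair distances $\delta_{ij}$:

* `metric = "frequency"`: $\delta = 0/1$ by haplotype identity — the
  classical frequency-based $F_{st}$;
* `metric = "differences"` (default): $\delta$ = count of differing
  sites — the molecular $\Phi_{st}$;
* `metric = "k2p"`: model-corrected distances.

The sums of squares are $SSD_{total} = \frac{1}{2N}\sum_{ij}\delta_{ij}$
and within-population analogues; variance components follow from the mean
squares with the average-sample-size coefficient
$n' = (N - \sum_k n_k^2/N)/(K-1)$, and
$\Phi = \sigma^2_{among}/(\sigma^2_{among}+\sigma^2_{within})$. Negative
estimates are reported as-is — they are the expected sampling behaviour
near zero differentiation, and suppressing them would bias panmixia
checks. $\delta$ for `"differences"` is the raw count, not its square:
for haplotype data this is the conventional AMOVA-on-differences, and
$\Phi$ is invariant to any global rescaling of $\delta$ anyway (a tested
property).

Significance comes from shuffling specimens between the two populations,
sizes preserved. The Monte-Carlo p-value uses the add-one convention
$p = (1 + \#\{\Phi^* \ge \Phi\})/(1 + n_{perm})$ so that $p$ is never 0,
with ties counting as exceeding; the default is 10,000 permutations with
a mandatory seed. For small samples `exhaustive = TRUE` enumerates all
assignments and divides by the total count (on a 2+2 complete-fixation
design that gives exactly $2/6$, since both extreme assignments attain
the observed statistic).

## Median-joining networks

The network stage implements the median-joining construction: build the
**minimum spanning network** (union of all minimum spanning trees) over
the current node set, where an edge is admitted when its integer
site-difference weight is at most the bottleneck (minimax) MST-path
weight between its endpoints plus a tolerance `epsilon` (default 0, the
conventional default); then propose **median vectors** — position-wise
majority consensus sequences of each linked triple (a node with two of
its MSN neighbours). A proposed median is adopted only if it reduces the
network cost, defined as the minimal spanning cost of the node set (the
Steiner criterion); one best median is added per round, ties broken
lexicographically for reproducibility, and the loop repeats until no
median helps. A position where all three characters differ generates all
three variants, capped at 32 candidates per triple in deterministic
lexicographic order. Only variable sites enter the computation; constant
columns are stripped and restored on output.

After convergence, median vectors that are redundant — degree ≤ 2 in the
MSN or on no shortest path between observed haplotypes — are removed
whenever removal does not increase the spanning cost, iterating to a
fixpoint. Survivors are renamed `mv1..mvK` in creation order, the naming
convention users of network software expect for unsampled intermediate
haplotypes. The classic three-haplotype example (variable sites `000`,
`110`, `011` in binary coding) yields exactly one median (`010`) and
drops the cost from 4 to 3; a star of one-step satellites around an
observed centre yields none. Exact agreement with any particular GUI
implementation's figure is not guaranteed for tied configurations — tie
handling differs between implementations — so real-data median counts
should be read qualitatively.

## Strict-clock dating

The dating stage is deliberately deterministic: UPGMA (average linkage)
on the K2P matrix gives an ultrametric tree whose node heights are half
the join distance, i.e. per-lineage substitutions/site under a strict
clock. Agglomeration ties follow the deterministic merge order of the
underlying `hclust`; all worked examples are tie-free. Two conversions
to absolute time are offered:

* **Rate grid** (`ages_from_rates()`): for each rate $r$ expressed as
  *pairwise divergence* per million years, $age = 2h/r$. The default grid
  3, 5, 10, 20, 40%/Myr spans the range conventionally entertained for
  rodent mitochondrial cytochrome *b*. A `per_lineage = TRUE` flag
  switches to $age = h/r$; both conventions are used in the literature
  and published analyses rarely say which they mean, so the choice is
  explicit here. Ages are exactly inversely proportional to rate — a
  tested invariant. Bayesian-dated tables generally do *not* show this
  inverse scaling because calibration priors dominate their posteriors;
  such tables are comparable to this stage only qualitatively (ordering
  of nodes, monotone decrease with rate).
* **Calibration** (`calibrate()`): given one or more (tip pair → MRCA
  age) constraints, a single least-squares scale factor
  $s = \sum h_i a_i / \sum h_i^2$ converts heights to ages. One
  calibration is reproduced exactly; conflicting calibrations take the
  closed-form compromise and report the RMS residual. Typical calibration
  sets for house-mouse-group cytochrome *b* place the root of the species
  group at 1.7 Ma with internal points near 0.914 and 0.459 Ma.

## The synthetic-data generator

Because field datasets of this kind are small and rarely redistributable,
validation rests on a structured-coalescent simulator
(`simulate_dataset()`). Time is in coalescent units (one unit = N
generations for a haploid population): each within-deme lineage pair
coalesces at rate 1, and each lineage migrates at rate $M$ to a uniform
other deme (island model). Mutations are Poisson with mean
$\tfrac{\theta}{2}\,\ell\,L$ per branch of length $\ell$ over $L$ sites,
hitting a uniform site; each event is a transition with probability
$\kappa/(\kappa+1)$. This yields the standard expectations used as
oracles: $E[T_2] = 1$ and $E[\hat\pi] = \theta$.

Defaults emulate a small-mammal mtDNA survey: 4 demes with uneven sample
sizes (3, 7, 17, 16 — a realistic skew for trap-based sampling of ~43
specimens), 549 sites, $\theta = 0.001$ per site — in a $K$-deme island
model the within-deme coalescence time is inflated roughly $K$-fold, so
this puts expected within-population $\pi$ at a few tenths of a percent,
the scale such surveys report — migration $M = 10$ (high gene flow, the
panmictic regime such surveys typically find), and $\kappa = 10$ (strong
transition bias, as in mammalian mtDNA). One seed drives the
whole dataset; the stream order is genealogy first, then mutations. No
recombination (mtDNA is effectively clonal), no selection, no growth.

The generator reproduces the *distributional* features the pipeline is
sensitive to — skewed haplotype frequency spectra, transition-biased
low-divergence variation, tunable structure — but not alignment
artefacts, sequencing error, heteroplasmy, or nuclear copies of
mitochondrial genes. Passing tests therefore establish estimator
correctness, not robustness to upstream data-quality problems.

Three deterministic planted fixtures (`make_fixture()`) pin exact values:
`table4_like` (one locality, two species: counts 5/1/1 with pairwise
differences 1/1/2 giving $H = 0.524$, plus three singletons giving
$H = 1$), `two_pop_fixed` ($\Phi_{st} = 1$), and `star` (no median
vectors).

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which the statistical checks are decisive: closed-form oracles on pairs
and triples; exhaustive permutation enumeration on ≤ 6 specimens;
brute-force Steiner search on ≤ 6 haplotypes over ≤ 8 binary variable
sites; 2000 coalescent replicates of $n = 5$, 549 bp for $\pi$-recovery
(the mean $\hat\pi/\theta$ must sit within 5%); and 250 replicates per
point of a 3-point migration grid (0.5, 5, 50) for the
$\Phi_{st}$–migration monotonicity check. Comparisons of derived reals
use absolute slack $10^{-12}$; permutation ties count as exceeding;
p-values never hit 0 by construction.

## Known limitations

* Only the K2P model is offered; no model selection, no Γ rate
  heterogeneity.
* One-level AMOVA only; no hierarchical designs or exact tests.
* The median-joining search is greedy (one cost-reducing median per
  round); for pathological tied configurations it may return a
  near-minimal rather than minimal Steiner network — the tests bound this
  gap on small cases.
* UPGMA assumes rate constancy outright; strongly clock-violating data
  will misplace nodes, and the NJ-style diagnostics offered by dedicated
  phylogenetics packages should be consulted before dating.
* Calibration fits a single proportional scale; it cannot reconcile
  calibrations that imply different rates on different subtrees.
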