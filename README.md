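# hapnet

Population-genetic analysis of aligned haploid (mitochondrial) sequence
data, built for the common design of small-mammal mtDNA surveys: a
~550-bp cytochrome-*b* fragment sequenced for tens of specimens across a
handful of localities, with questions about haplotype sharing, species
and population divergence, within-population diversity, differentiation
versus panmixia, haplotype relationships, and divergence times.

The package provides, as pipe-friendly functions over tibbles:

* **Haplotypes** — exact-match collapsing of aligned sequences into
  haplotypes (`collapse_haplotypes()`), frequency shares, base
  composition.
* **Distances** — Kimura 2-parameter distances
  (`d = -½ln(1−2P−Q) − ¼ln(1−2Q)`, transitions vs transversions,
  pairwise deletion), within/between-group means weighted one sequence
  per haplotype, and site-bootstrap standard errors.
* **Diversity** — Nei haplotype diversity `H = n/(n−1)·(1−Σp²)` and
  unbiased nucleotide diversity
  `π = n/(n−1)·Σᵢ<ⱼ 2pᵢpⱼdᵢⱼ` per population (`diversity_report()`).
* **Differentiation** — one-level AMOVA giving frequency-based Fst
  (0/1 haplotype identity) or molecular Φst (site differences), with
  permutation p-values under the add-one convention
  (`pairwise_differentiation()`), laid out statistic/lower,
  p-value/upper as in the field's tables.
* **Networks** — median-joining haplotype networks: minimum spanning
  network (union of MSTs, ε-relaxed) plus majority-consensus median
  vectors (`mv1..mvK`) added under a Steiner cost criterion and pruned
  to fixpoint (`median_joining()`), exported to GraphML/GML, plotted
  with `autoplot()`.
* **Dating** — UPGMA strict-clock tree from K2P distances, node ages
  over a divergence-rate grid (default 3/5/10/20/40%/Myr, `age = 2h/r`),
  and least-squares calibration against absolute node ages
  (`calibrate()`).
* **Simulation** — a structured-coalescent generator with island-model
  migration and transition-biased mutation (`simulate_dataset()`), the
  basis of the package's parameter-recovery validation.

Results carry broom-style `tidy()`/`glance()` methods, and
`run_pipeline()` drives everything end-to-end from a FASTA + popmap pair
into one output directory with a JSON summary. A thin command-line
dispatcher with subcommands (`haplotypes`, `distances`, `diversity`,
`fst`, `network`, `dates`, `simulate`, `run-all`) ships in
`inst/cli/hapnet.R`.

## Worked example

Simulate a survey-shaped dataset (4 demes, 43 specimens, 549 bp, high
gene flow) and run the stages:

```r
library(hapnet)

ds  <- simulate_dataset(sim_config(seed = 42))
aln <- ds$alignment
tab <- collapse_haplotypes(aln)
glance(tab)
#> # A tibble: 1 × 3
#>   n_haplotypes n_specimens n_sites
#>          <int>       <int>   <int>
#> 1            8          43     549

diversity_report(aln)
#> # A tibble: 4 × 7
#>   species population     n n_haplotypes      pi pi_percent     H
#>   <chr>   <chr>      <int>        <int>   <dbl>      <dbl> <dbl>
#> 1 <NA>    deme1          3            2 0.00243      0.243 0.667
#> 2 <NA>    deme2          7            3 0.00486      0.486 0.524
#> 3 <NA>    deme3         17            4 0.00512      0.512 0.5
#> 4 <NA>    deme4         16            3 0.00179      0.179 0.342

pairwise_differentiation(aln, "differences", n_perm = 1000, seed = 1)
#> <hap_differentiation> metric=differences, 4 populations, 1000 permutations
#>          deme1    deme2   deme3  deme4
#> deme1       NA 0.240759 0.36364 0.3327
#> deme2  0.03922       NA 0.29670 0.2018
#> deme3 -0.01145 0.004425      NA 0.1369
#> deme4  0.05403 0.076242 0.04958     NA
```

Nucleotide diversity sits at a few tenths of a percent per deme,
haplotype diversity is moderate, and every pairwise Φst is small (lower
triangle, −0.011…0.076) with permutation p-values (upper triangle) all
above 0.05 — the panmixia pattern expected at migration rate 10. The
network and dating stages continue from the haplotype table:

```r
net <- median_joining(tab)
glance(net)
#> # A tibble: 1 × 5
#>   n_observed n_median_vectors n_edges  cost epsilon
#>        <int>            <int>   <int> <dbl>   <dbl>
#> 1          8                0       7    17       0

tree <- upgma_tree(k2p_matrix(tab))
cal  <- calibrate(tree, data.frame(tip_a = "H1", tip_b = "H2",
                                   age_ma = 0.459))
max(cal$ages$age_ma)   # root age implied by the one calibration
#> [1] 1.746396
```

Here the eight observed haplotypes connect without inferred
intermediates (cost 17 mutation steps), and anchoring one shallow node
at 0.459 Ma dates the root to ~1.75 Ma.

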