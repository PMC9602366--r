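# mitopop

Population-structure analysis of mitochondrial control-region haplotypes.

`mitopop` is for researchers who have a pre-aligned set of mtDNA
control-region sequences from several sampling localities and want the
standard intraspecific phylogeography workup — the kind of analysis usually
assembled by hand across DnaSP, Arlequin and POPART — as one scripted,
seeded, testable pipeline:

- **Molecular diversity** per population: haplotype diversity
  *h* = n/(n−1)·(1 − Σp<sub>i</sub>²) and nucleotide diversity
  π = k̂/L with Nei's standard errors, segregating sites *S*, and
  transition/transversion site counts.
- **Differentiation**: two-level AMOVA on pairwise nucleotide differences
  (Excoffier–Smouse–Quattro), yielding Φ<sub>ST</sub> = σ²<sub>a</sub>/(σ²<sub>a</sub>+σ²<sub>w</sub>)
  with permutation p-values, plus Wright's gene-flow transformation
  Nm = (1/F<sub>ST</sub> − 1)/2 graded high (≥1.0) / medium (0.250–0.99) /
  low (0.0–0.249).
- **Neutrality tests**: Tajima's D = (k̂ − S/a₁)/√(e₁S + e₂S(S−1)) and
  Fu's F<sub>s</sub> = ln(S′/(1−S′)) with S′ = Pr(K ≥ k₀ | θ̂ = k̂)
  from the Ewens sampling formula (log-space Stirling numbers), with
  significance from constant-size coalescent simulation.
- **Demographic history**: mismatch distributions, least-squares fit of
  the Rogers–Harpending sudden-expansion model (τ, θ₀, θ₁), and dating
  via t = τ/(2u) with u = L·r (default r = 3.6×10⁻⁸ per site per year,
  i.e. 3.6%/Myr sequence divergence).
- **Median-joining networks** (Bandelt–Forster–Röhl): ε-relaxed minimum
  spanning networks, quasi-median closure, parsimony pruning of median
  vectors, TSV/GraphML export.
- **Synthetic data**: a finite-sites structured-coalescent generator
  (piecewise-constant size for sudden expansion, two demes with symmetric
  migration, transition bias κ) so every stage is testable offline.

## Worked example

A study-shaped synthetic dataset: 45 sequences × 473 bp, three
populations (E, S, W) of 15, with the E+S deme and the W deme split by an
old divergence and a sudden expansion.

```r
library(mitopop)

ds <- make_study_like_fixture(seed = 1)
a  <- mask_sites(ds$alignment)      # complete deletion of gap/N columns
pm <- ds$popmap

diversity_table(a, pm)
#>   population  n nh     h   se_h      pi   se_pi k_hat  S ti tv
#> 1          E 15  5 0.562 0.1434 0.00189 0.00156 0.895  5  5  0
#> 2          S 15  7 0.657 0.1384 0.00354 0.00247 1.676 10 10  0
#> 3          W 15  6 0.743 0.0943 0.00330 0.00234 1.562  7  7  0
#> 4      Total 45 13 0.770 0.0556 0.00479 0.00298 2.265 16 16  0

d      <- pairwise_differences(a)
pooled <- pool_populations(pm, list(ES = c("E", "S")))
am     <- amova_two_level(d, pooled, n_perm = 1000, seed = 1)
am
#> AMOVA (ES, W)
#>   among:  df=1  SSD=20.156  sigma2=0.9733  (58.52%)
#>   within: df=43  SSD=29.667  sigma2=0.6899  (41.48%)
#>   Phi_ST = 0.5852   p = 0.000999  (1000 permutations)

gene_flow(am$fst)
#> $nm
#> [1] 0.3544311
#> $category
#> [1] "medium"
```

58.5% of the molecular variance lies between the pooled ES group and W —
strong, significant structure — while the implied gene flow is "medium"
(about 0.35 females per generation): the signature of an old divergence
rather than complete ongoing isolation.

```r
w <- names(pooled)[pooled == "W"]
tajimas_d(subset_alignment(a, w), n_sims = 1000, seed = 2)
#> Tajima's D = -0.9885  (n = 15, S = 7, k_hat = 1.562)
#>   simulated p = 0.2181

fit <- fit_expansion(observed_mismatch(d, w), seed = 1)
fit
#> sudden-expansion fit: tau = 0.596, theta0 = 0.8350, theta1 = 20000.000 (SSD = 0.0313)
#>   bound saturated: theta1
expansion_time(fit$tau, n_sites(a))$t_years
#> [1] 17509.73
```

The fitted τ̂ = 0.596 recovers the generator's true τ = 0.6; with 473
sites at 3.6%/Myr that corresponds to an expansion roughly 17.5 kyr ago.
A saturated θ₁ upper bound is typical for mismatch fits (the
post-expansion size is effectively unbounded by these data) and is
flagged rather than hidden.

```r
net <- median_joining(collapse_haplotypes(a, pm))
net
#> haplotype_network: 13 observed haplotypes, 0 median vectors, 12 edges (epsilon = 0 )
export_network(net, "network.tsv", "edge_tsv")
```

## Command line

The full layout (diversity, pairwise Φ<sub>ST</sub>/Nm, AMOVA,
neutrality + mismatch + dating, network, JSON manifest) in one command:

```sh
Rscript inst/cli/mitopop.R run --fasta aln.fasta --popmap pops.tsv \
    --group ES=E,S --seed 1 --out results/
```

Subcommands `diversity`, `fst`, `amova`, `neutrality`, `mismatch`,
`network`, `simulate` wrap the corresponding library calls; identical
inputs and seeds give byte-identical reports.

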