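---
title: "Models and methods behind mitopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopop)
```

`mitopop` implements the classical intraspecific phylogeography workup
for haploid, non-recombining mitochondrial control-region data: diversity
indices, AMOVA-based fixation indices, neutrality tests,
mismatch-distribution demography, and median-joining haplotype networks,
plus a coalescent generator that produces data of exactly the shape these
methods expect. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and the limits of what the
test suite establishes.

## Data model and site masking

The unit of analysis is a pre-aligned set of equal-length sequences over
`{A,C,G,T,N,-}` with unique sample ids, plus a sample-to-population map.
Alignment is deliberately out of scope: control-region fragments are
short and alignment choices are best made (and inspected) upstream.

Gap and ambiguity handling is *complete deletion*: every column
containing `-` or `N` in any sequence is removed before any statistic is
computed, and a 1-based map from analyzed to original coordinates is kept
for reporting. The alternative would be pairwise deletion, which uses
more data but makes every pairwise distance live on a different site set,
so that AMOVA sums of squares, mismatch histograms and network edge
labels stop being mutually consistent. One fixed site set keeps every
downstream number commensurable. A `pairwise` policy flag exists but only
defers masking; distances currently treat any residual `N`/`-` mismatch
as a difference, which is why masking first is the documented default.

Haplotype identity is exact string equality on the analyzed sites — no
IUPAC expansion, no indel tolerance — and haplotypes are numbered
`H1..Hk` by order of first appearance, which makes collapse results
reproducible and order-invariant up to relabeling.

## Diversity

Haplotype diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with sampling variance

$$V(h) = \frac{2}{n(n-1)}\Bigl\{2(n-2)\bigl[\textstyle\sum p_i^3 -
(\sum p_i^2)^2\bigr] + \sum p_i^2 - (\sum p_i^2)^2\Bigr\},$$

and nucleotide diversity is $\pi = \hat k / L$ with $\hat k$ the mean
pairwise difference count, with total variance (including the stochastic
component)

$$V(\pi) = \frac{n+1}{3(n-1)L}\,\pi + \frac{2(n^2+n+3)}{9n(n-1)}\,\pi^2.$$

These are the standard textbook estimators; the package reports standard
errors as their square roots. Sites with more than two states contribute
one transition/transversion count per observed unordered state pair
(`A/G` and `C/T` are transitions), a convention chosen because it
degrades gracefully to the biallelic case and keeps
$ti + tv \ge$ the number of polymorphic sites.

## AMOVA, Φ~ST~ and gene flow

Differentiation uses the distance-based AMOVA framework with pairwise
nucleotide-difference counts as squared Euclidean distances. For $P$
populations with sizes $n_p$, $N = \sum n_p$:

- $SSD_{total} = \frac{1}{N}\sum_{i<j} d_{ij}$ over all pairs,
  $SSD_{within} = \sum_p \frac{1}{n_p} \sum_{i<j \in p} d_{ij}$,
  $SSD_{among}$ by subtraction;
- $\sigma^2_w = SSD_{within}/(N-P)$,
  $\sigma^2_a = (SSD_{among}/(P-1) - \sigma^2_w)/\bar n$ with
  $\bar n = (N - \sum n_p^2/N)/(P-1)$;
- $\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$.

Significance comes from permuting individuals among populations with
sizes held fixed. The p-value is $(x+1)/(B+1)$ where $x$ counts permuted
statistics $\ge$ the observed one: the `+1` avoids impossible zero
p-values and counting ties as extreme is conservative. Default $B$ is
10,000 and the seed is a required, logged argument. Negative variance
components (hence slightly negative Φ~ST~) are retained unclamped; they
are legitimate estimates under the method-of-moments decomposition and
clamping would bias permutation calibration.

Gene flow is Wright's island-model transformation
$Nm = (1/F_{ST} - 1)/2$, graded high ($\ge 1.0$), medium
($0.250$–$0.99$) or low ($0.0$–$0.249$). The transformation assumes
equilibrium island-model migration, which real recently-diverged
populations violate; the grade is a conventional descriptive label, not
an inference.

## Neutrality tests

Tajima's D contrasts $\hat k$ with $S/a_1$:

$$D = \frac{\hat k - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}},$$

with the usual constants $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$
computed from $n$. It is undefined for $S = 0$ or $n < 4$ and the package
says so rather than returning 0.

Fu's F~s~ takes $\hat\theta = \hat k$ (the pairwise estimator, the
statistic's original formulation), computes
$S' = \Pr(K \ge k_0 \mid \hat\theta, n)$ under the Ewens sampling
formula, and reports $F_s = \ln\bigl(S'/(1-S')\bigr)$. The Ewens
probabilities use unsigned Stirling numbers of the first kind via the
triangular recurrence carried entirely in log space — at $n = 45$ the
raw numbers overflow doubles long before the recurrence finishes. The
pmf is validated to sum to 1 within $10^{-12}$ up to $n = 50$.

Both tests get significance from simulation under a constant-size
neutral coalescent conditioned on $n$ and $\hat\theta$ (1,000 replicates
by default), using the *lower* tail, since both statistics flag
expansion through negative values. Following the statistic's own
convention, F~s~ is flagged significant at $p < 0.02$, Tajima's D at
$p < 0.05$.

## Mismatch distributions and expansion dating

The sudden-expansion model: a population at equilibrium $\theta_0$ jumps
instantaneously to $\theta_1$ at mutational time $\tau$ before present.
The expected distribution of pairwise differences is

$$F_j = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
\sum_{i=0}^{j} \frac{\tau^i}{i!}\bigl[\hat F_{j-i}(\theta_0) -
\hat F_{j-i}(\theta_1)\bigr], \qquad
\hat F_j(\theta) = \frac{\theta^j}{(\theta+1)^{j+1}}.$$

Equilibrium terms and Poisson weights are evaluated in log space (the
naive $\theta^j$ overflows for $\theta$ in the thousands at $j$ in the
hundreds). Truncation mass beyond the evaluated range is tracked and
asserted below $10^{-6}$ at $j_{max} = L$ for fitted parameter scales.

Fitting minimizes the plain sum of squared deviations between observed
relative pair frequencies and $F_j$ over $(\tau, \theta_0, \theta_1)$.
Arlequin's weighting scheme for this objective is not publicly specified
in detail, so unweighted least squares is used and documented; the SSD is
reported with the fit. The optimizer is Nelder–Mead on
$(\tau, \log\theta_0, \log\theta_1)$, multi-started from a coarse grid
plus 20 seeded random starts; ties break by lowest SSD then lowest τ.
Bounds default to $\tau \in [0, 50]$, $\theta_0 \in [10^{-6}, 50]$,
$\theta_1 \in [\theta_0, 20000]$: mismatch likelihood surfaces are
nearly flat in $\theta_1$ once it is large, so fits routinely run to the
ceiling; the ceiling must therefore sit well above any biologically
reportable value, and saturation is flagged per parameter
(`bounds_hit`) instead of silently reported as an interior optimum.

Dating uses $\tau = 2ut$ with the per-sequence rate $u = L r$, where $r$
is a sequence *divergence* rate per site per year (default
$3.6\times10^{-8}$, i.e. 3.6%/Myr) plugged in directly. Divergence rates
are per pair of lineages, so purists would halve $r$ for a per-lineage
mutation rate; the direct convention is the one in common use for
control-region dating in the cetacean literature this package targets,
and it is stated in the output so the alternative is a one-line rescale.

## Median-joining networks

The network stage follows the median-joining construction: build the
ε-relaxed minimum spanning network (links admitted within ε of the
minimal inter-component connection cost; the union of all minimum
spanning trees at ε = 0), then repeatedly add quasi-medians of mutually
linked triplets — per-column majority state, with all combinations kept
for columns where all three states differ — until closure, and finally
delete median vectors that lie on no minimal path between observed
haplotypes. That last step is a documented simplification of full
Polzin-style maximum-parsimony pruning; it removes the same obviously
redundant vectors without implementing a Steiner-tree solver.

Defaults and determinism: ε = 0 (the common default in practice; larger
ε admits more alternative links and more medians); all tie-breaking —
link admission order, median insertion — is lexicographic by sequence
then node id, so output is reproducible without an RNG. Quasi-median
combinatorics are capped at $3^4$ per triplet (surplus all-different
columns resolve to the first state); with transition-biased mtDNA data
columns with three observed states are already rare, and the cap has
never been reached in testing. Exports preserve all node and edge
attributes (kind, frequency, per-population composition, mutated
positions) as TSV or GraphML.

## The synthetic-data generator

The generator is a haploid structured coalescent with piecewise-constant
population size and finite-sites mutation:

- **Time scaling.** Time is measured in units of $N_1$ (present-day)
  generations: a pair of lineages in one deme coalesces at rate 1 and
  mutations fall at rate $\theta_1/2$ per lineage, so a constant
  population has $E[\text{pairwise differences}] = \theta$ and the
  expansion epoch sits at time $\tau/\theta_1$ — the same
  parameterization the mismatch module fits, which makes
  generate-then-fit recovery tests meaningful.
- **Sudden expansion.** Before the epoch the coalescence rate is
  multiplied by $\theta_1/\theta_0$; nothing else changes.
- **Structure.** Two demes of equal size with symmetric per-lineage
  migration rate $M/2$ ($M = 2N_1 m$).
- **Mutation.** Finite sites: each mutation picks a uniform site (repeat
  hits allowed, so homoplasy is possible, as on a real 473 bp fragment)
  and is a transition with probability $\kappa/(\kappa+1)$ (default
  $\kappa = 10$, a typical control-region bias). Root sequence is
  uniform random.

All draws are controlled by one mandatory seed; sub-streams for
genealogy and mutations are derived so repeated calls are bit-identical.

### The study-like fixture

`make_study_like_fixture()` emulates a 45-sample survey: three
populations of 15 × 473 bp, the `E` and `S` labels sharing one deme and
`W` the other, with $\theta_0 = 0.1$, $\theta_1 = 50$, $\tau = 0.6$,
$M = 15$, $\kappa = 10$. The targets for the calibration were: median
realized π within 0.002–0.006, median Φ~ST~ (pooled ES vs W) within
0.25–0.6, a unimodal within-deme mismatch distribution, and a haplotype
network that splits into two clusters with one cluster exclusive to the
`W` deme.

Two consequences of this model are worth stating plainly. First, with
ongoing migration the deme-exclusivity of a network cluster is a
probabilistic event: a lineage sampled in one deme occasionally carries
the other deme's cluster haplotype. Given the π constraint (which pins
the between-deme divergence term $\theta_1/M$), the expected migrant
contamination scales with $\tau$ alone, so exclusivity cannot be pushed
arbitrarily high without flattening within-deme diversity. The test
suite therefore checks the qualitative claim over a fixed panel of 12
seeds (two clusters in ≥10, an exclusive cluster in ≥7) rather than on
one draw. Second, the same trade-off caps the realized haplotype count:
at the chosen τ the fixture typically yields ~13 distinct haplotypes,
fewer than a real survey of comparable diversity might show, because all
its variation is recent. Tests that need many haplotypes generate them
directly rather than through the fixture.

What a green suite establishes: the estimators agree with independent
brute-force implementations; the permutation and simulation nulls are
calibrated; generate-then-fit recovers expansion parameters; the
qualitative two-cluster structure emerges. What it does not establish:
agreement with any particular empirical dataset (the generator has no
rate heterogeneity across sites, no saturation beyond repeat hits, no
sex-biased dispersal, no sampling heterogeneity), nor correctness of the
dating convention beyond its own algebra.

## Degenerate inputs and edge behavior

- Monomorphic alignments: π = 0; Tajima's D and Fu's F~s~ raise
  undefined-statistic errors; AMOVA warns and reports Φ~ST~ = 0;
  mismatch fitting drives τ to the 0 boundary and flags it.
- A population of one sample is rejected by AMOVA (no within-group
  degrees of freedom).
- All-gap columns leave nothing to analyze: masking errors out rather
  than returning an empty alignment.
- p-values are never exactly 0 by construction ($+1/(B+1)$), except the
  simulation-based neutrality p-value, which reports the raw fraction
  and can be 0 when the observed statistic lies beyond all simulated
  support.

## Known limitations

- AMOVA is two-level only (populations within one total); no
  group/population/individual hierarchy.
- Mismatch fitting reports SSD but not its parametric-bootstrap p-value.
- The fixation index is the distance-based Φ~ST~; haplotype-frequency
  F~ST~ variants (e.g. for comparing against microsatellite studies) are
  not provided.
- The network stage does not lay out coordinates; export to GraphML and
  use a graph tool for drawing.
- The coalescent generator supports at most two demes and no
  recombination (appropriate for mtDNA, not for nuclear loci).
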