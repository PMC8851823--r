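---
title: "Verifying first-degree relationships and estimating genotyping error by genetic exclusion"
author: "kinreject"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying first-degree relationships and estimating genotyping error by genetic exclusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinreject)
```

## The exclusion statistic

A parent transmits one allele to its offspring at every autosomal locus, so
a parent-offspring pair can never be homozygous for alternative alleles at
a biallelic SNP. Full sibs can be — but only when both parents are
heterozygous, and then with probability exactly 1/8 (each sib is
independently one homozygote with probability 1/4, and the two must be
*opposite* homozygotes):

```{r}
fullSibOpposingProb()
```

For a pair of individuals $i,j$ genotyped at many SNPs, `kinreject` counts
the opposing-homozygote SNPs $\delta_{ij}$ and forms the rate of rejection

$$\tau_{ij} = \delta_{ij} / N_{ij},$$

where $N_{ij}$ is the number of SNPs at which *both* calls are non-missing.
Using the per-pair comparable count rather than a fixed panel size is the
package's one generalization of the statistic: with stringent call-rate QC
the two coincide, while under uneven missingness the per-pair count removes
a downward bias in $\tau$. $N_{ij}$ is carried into the mixture likelihood
below for the same reason.

Dosages count copies of the *reference* allele (VCF `0/0` is dosage 2).
Every statistic in the package is invariant to swapping allele labels at
any subset of SNPs, so the convention is inert; it is fixed so that all
readers and writers agree. Multiallelic VCF records are skipped, not split:
the statistic is defined for biallelic markers.

The pairwise computation is formulated as three cross-products of 0/1
indicator matrices (homozygous-reference, homozygous-alternative,
non-missing), so all $n(n-1)/2$ pairs are counted in a handful of BLAS
calls rather than a per-pair loop; 300 samples at 50,000 SNPs take seconds.

## The two-component binomial mixture

Genotyping errors make $\tau > 0$ even for true parent-offspring pairs, so
a threshold at zero is useless in practice. Within a relationship group
(dam-offspring, sire-offspring, ...), each pair's rejection count is
modelled as a mixture of two binomials: an *error component* with rate
$\tau_g$ (true first-degree pairs, rejections caused only by miscalls) and
a *rejection component* with rate $\tau_r$ (non-first-degree pairs), with
mixing proportion $\gamma$:

$$L_i = \gamma\,\mathrm{Bin}(\delta_i; N_i, \tau_g)
      + (1-\gamma)\,\mathrm{Bin}(\delta_i; N_i, \tau_r).$$

### E-step

At array scale the binomial masses underflow double precision, so
responsibilities are computed from the log-likelihood *difference*:

$$r_i = \frac{1}{1 + e^{\ln L_i(\tau_r) - \ln L_i(\tau_g)}}.$$

As written the posterior ratio carries no $\gamma$ prior; `eStep()` also
offers the prior-weighted variant (`gammaWeighted = TRUE`). At the
component separations this method is built for — $\tau_g$ and $\tau_r$
differing by an order of magnitude at tens of thousands of SNPs — the
log-likelihood difference is so large that both variants give identical
assignments; the unweighted form is the default because it is the form the
estimator family is defined with.

### M-step

The rate updates weight each pair by its responsibility *scaled by its
rejection count*:

$$\tau_g' = \frac{\sum_i r_i\,\delta_i\,(\delta_i/N_i)}{\sum_i r_i\,\delta_i},$$

and mirrored with weights $(1-r_i)\,\delta_i$ for $\tau_r'$. Two
consequences are worth knowing. First, pairs with $\delta_i = 0$ carry no
weight, so $\hat\tau_g$ is driven by pairs with at least one rejection (a
component consisting entirely of zero-count pairs collapses; the fit is
returned flagged). Second, the $\delta$-scaled weighting makes the update a
count-weighted mean whose expectation is $\tau + (1-\tau)/N$ rather than
$\tau$: a relative offset of about $1/(N\tau)$, under 3% for
$\tau_g \approx 7\times10^{-4}$ at $N = 50{,}000$ and negligible for
$\tau_r$. Because the update is not the exact maximizer, a single step is
not guaranteed to increase the observed-data log-likelihood; over full runs
at realistic separations the trace is non-decreasing (the test suite
asserts this across all replicates), and the parameter recovery targets are
met with the offset included.

The mixing proportion is updated as the normalized responsibility sum,
$\gamma' = \sum_i r_i / n_r$. A $\delta$-scaled normalized sum is not used
here: it is not a proportion (it exceeds 1 whenever the mean
responsibility-weighted count does), while $\gamma$ must stay in $[0,1]$.

Components are re-ordered ($\tau_g \le \tau_r$) after every M-step, which
prevents label switching and makes the fit invariant to swapping the
initial values.

### Initialization and convergence

EM on this mixture converges only from starting values near the two modes
of the $\tau$ distribution. `defaultInit()` takes the 5th and 60th
percentiles of the observed per-pair rates — in a parentage screen the true
pairs are the small low-$\tau$ minority, so a low and a central percentile
straddle the modes — and falls back to the means of a largest-gap
two-cluster split when the percentiles coincide. Because the true-pair
fraction varies by design (it can be far below 5%), `fitMixture()` runs
three starts by default (percentiles, largest-gap split, interquartile
pair) and keeps the fit with the highest observed-data log-likelihood.
Convergence is declared when the maximum relative change in
$(\tau_g, \tau_r, \gamma)$ falls below $10^{-8}$ (cap 1000 iterations);
with well-separated components the responsibilities saturate at 0/1
immediately and the fit converges in two iterations.

A pair is assigned as a true first-degree relationship when $r_i > 0.5$;
a tie at exactly 0.5 is *not* assigned — the conservative direction for a
parentage claim. The threshold is configurable.

### Offspring-offspring fits

The same machinery applied to the offspring-offspring group detects
full-sib candidates, but its error component also captures half-sibs when
parents within a breed are related: the $0.125$ per-informative-locus
rejection rate of full sibs and the corresponding half-sib rate produce
overlapping components. `runPipeline()` therefore fits the
parent-offspring groups by default and treats offspring-offspring output
as candidate labels only.

## Genotyping-error estimation

$\hat\tau_g$ is a *lower bound* on the per-genotype miscall rate $e$: a
miscall is observable only when it turns a true pair into opposing
homozygotes. At a locus with allele frequency $p$ (Hardy-Weinberg parents,
Mendelian transmission), the first-order probability that a single miscall
is detected this way — the detection factor $c(p)$ — depends on what a
miscall does:

* **`genotype_uniform`** (default): a miscalled genotype becomes one of the
  other two genotypes with equal probability. A rejection then needs the
  partner to be truly homozygous and the miscall to land on the opposite
  homozygote, giving $c(p) = p^2 + (1-p)^2$. As $p \to 0$ or $1$,
  $c \to 1$: at low MAF the rejection rate approaches the error rate
  itself, because true rejections essentially cannot occur there.
* **`allele_flip`**: each allele is miscalled independently at rate $e/2$.
  Only heterozygote-to-homozygote single flips can create a rejection at
  first order, giving $c(p) = p(1-p)$.

Both forms were derived by enumerating all
(parent genotype, offspring genotype, miscall) configurations, and the test
suite re-validates them against an exhaustive-enumeration oracle and
Monte-Carlo simulation. The adjusted estimate is

$$\hat e = \hat\tau_g \,/\, \overline{c(p)},$$

averaging $c$ over the panel's frequency spectrum (monomorphic and
undefined-MAF SNPs excluded). The adjustment is model-dependent — that is
exactly why the model is an explicit argument rather than an assumption
buried in a constant. The two models are empirically distinguishable: under
`genotype_uniform` low-MAF SNPs are *enriched* among SNPs that reject
verified pairs ($c$ is largest there), while under `allele_flip` they are
*depleted* (a rejection needs a true heterozygote, rare at low MAF).
Array cluster-calling artefacts that displace calls to adjacent clusters
behave like `allele_flip` in this respect; the depletion property test
simulates under that model. `genotype_uniform` remains the default
adjustment because it is the least structured single-parameter model, but
when the observed MAF profile of rejecting SNPs shows strong depletion the
`allele_flip` adjustment is the more defensible choice.

For a two-breed cross the detection factor strictly involves both parental
pools. Averaged over the sire-offspring and dam-offspring groups the
two-pool factor reduces to $1 - 2\bar p\bar q$ at the mid-parent frequency
$\bar p$ — which is the crossbred offspring frequency that dominates the
pooled MAF estimate — so the pooled-spectrum adjustment applied to the
*joint* parent-offspring fit is approximately correctly specified for the
cross; the round-trip tests confirm recovery within 15% under both the
common-pool and the divergent-breeds regimes.

## Failing SNPs

Among verified pairs, every opposing-homozygote site is a Mendelian
inconsistency. Counting per SNP how many verified pairs it rejects
localizes recurrent problems; a SNP rejecting at least 5 verified pairs is
flagged as *failing* (miscalling, mismapping, structural variation). The
threshold is an argument; flagged SNPs are reported with their MAF and
position, never silently removed — re-running after exclusion is the
caller's decision. Note that no Hardy-Weinberg filter is applied anywhere:
in a crossbred design markers are expected to depart from HWE, so such a
filter would discard exactly the informative markers.

## Duplicate samples

Two samples of the same animal differ only through two independent error
draws, so their expected genotype discordance is about $2e$ — far below
any pair of distinct individuals (even parent-offspring pairs agree at most
at ~90% of calls under array MAF spectra). `detectDuplicates()` flags pairs
with concordance at or above 0.98 by default: tolerant of per-genotype
error rates up to about 1% on both copies, while retaining a wide margin
above non-duplicates. A stricter 0.99 would already miss true duplicates
at the ~0.6% error rates this method itself estimates for real arrays,
which is why 0.98 is the shipped default. Duplicates matter for parentage
directly: an offspring apparently assigned two dams is resolved by
collapsing the two dam samples if they are concordance-duplicates, and
reported as a conflict otherwise.

## Power: how many SNPs are needed?

To decide whether a pair's rate belongs to $\tau_g$ or $\tau_r$ among $n_i$
individuals, all $n_i(n_i-1)/2$ pairs are tested; the global level
$\alpha$ is Bonferroni-divided by that count. The required SNP count uses
the normal approximation to the binomial,

$$n = \left\lceil \frac{\left(z_{1-\alpha'/2}\sqrt{p_0(1-p_0)} +
  z_{\beta}\sqrt{p_1(1-p_1)}\right)^2}{(p_1-p_0)^2} \right\rceil,$$

two-sided in the adjusted level by default and without continuity
correction; both conventions are exposed (`sided = "one"` gives the
slightly smaller one-sided requirement). The inverse, `achievedPower()`,
satisfies the round-trip consistency asserted in the tests. At
$p_0 = 0.000735$, $p_1 = 0.01$, $\alpha = 0.01$, power 0.99 and 300
individuals the two-sided requirement is 1,611 SNPs — low-density arrays
suffice unless the cohort is very large.

## The simulator

`simulateCross()` provides ground truth for every stage. It emulates a
two-breed terminal cross: candidate sires and dams drawn from
Hardy-Weinberg proportions at breed-specific frequencies, offspring by
strict Mendelian transmission, then — in this order — per-genotype
miscalls, duplicated samples (fresh error draws on the *pre-error*
genotype, as resubmitted DNA would show), assay-level failing SNPs, and
missing calls. Two frequency regimes ship: `divergentFreqs()`
(opposite-skew Beta spectra, reproducing the large sire-dam rejection rates
of a real cross) and `uniformFreqs()` (a common pool, for null testing and
error round trips where the adjustment model should be exactly specified).
The default failing-SNP mechanism, `force_homozygote`, miscalls every
heterozygote to a random homozygote — the cluster-collapse failure mode
seen on arrays, and one that rejects true pairs through *both* pair
members.

The default configuration is the crossbred study design the package is
validated against: 9 candidate sires, 55 dams, 214 offspring, 50,000 SNPs,
a per-genotype miscall rate of 0.00588 (an array-realistic 0.6% scale), 1%
missingness, 60% of true parents ungenotyped, 2 duplicated dams, 20 failing
SNPs. What the simulator deliberately does *not* emulate: linkage and LD
(the statistic is single-SNP; loci are independent), platform intensity
data and cluster calling, within-breed pedigree structure among the
candidate parents, and batch- or sample-specific error rates. Passing tests
therefore demonstrate correctness of the statistics under the stated
generative model, not robustness to correlated markers or related
founders — on real data the offspring-offspring overlap caveat above is
the first symptom of the latter.

Problem sizes in the test suite follow the study design where the property
under test needs it (the end-to-end recovery runs the full 280-sample,
50,000-SNP design; mixture recovery uses 500 pairs at 50,000 SNPs over 50
replicates) and drop to a few thousand SNPs for unit-level oracles, where
the quantities compared are exact counts and scale adds nothing.

## Numerical and degenerate-input choices

* Binomial masses go through `stats::dbinom` (log scale); tests verify
  against independent `lchoose`-arithmetic at $N = 546{,}220$.
* $\tau = 0$ boundaries are exact: log-likelihood 0 for $\delta = 0$,
  $-\infty$ otherwise; a group whose pairs all have $\delta = 0$ returns a
  flagged single-component fit with $\gamma = 1$.
* Pairs with no overlapping calls ($N_{ij} = 0$) get $\tau$ = `NA` and are
  excluded from fits.
* `defaultInit()` refuses single-mode inputs rather than fabricating a
  second component.
* All simulator randomness flows from one integer seed; identical seeds
  give identical output.

## Limitations

The method verifies or discovers *first-degree* relationships only; second-
and third-degree relatives sit inside the rejection component by design,
and full-sib detection among offspring is contaminated by half-sibs when
founders are related. The error estimate is a per-genotype rate under a
declared miscall model, not a per-allele or per-cluster characterization,
and its headline value moves with the model chosen. Sex chromosomes are not
treated specially: restrict to autosomes via `filterSnps(chromosomes =
as.character(1:18))` (the default autosome set of the pig) or the
equivalent for the species at hand.
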