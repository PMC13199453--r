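---
title: "Calling freshwater-adaptive loci and testing jackpot-mediated adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling freshwater-adaptive loci and testing jackpot-mediated adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When anadromous (marine-breeding) threespine stickleback colonize a lake,
freshwater-adaptive alleles at a few hundred loci rise in frequency within a
handful of generations. The transporter hypothesis holds that these alleles
persist at low frequency in the ocean — maintained by gene flow from
established freshwater populations against selection — and that colonization
succeeds when the founding fish include rare *jackpot carriers*: individuals
carrying large contiguous haploblocks of freshwater alleles, typically recent
oceanic–freshwater hybrids. `sticklejack` implements the computational side
of testing that idea from low-coverage whole genomes: genotype calling at
multi-SNP adaptive loci, quantification of freshwater content and
haploblocks, mixture-model classification of carriers, population-genetic
summaries, and a forward Wright–Fisher simulation of the whole
metapopulation. A synthetic-data module generates every input with known
ground truth, so the full pipeline runs and is verified at desk scale
without any sequencing data.

## The locus panel and the genotype caller

Each adaptive locus is represented as a multi-SNP haplotype: 3 to several
thousand tightly correlated SNPs on one chromosome, each labelled with its
oceanic and freshwater allele. The diploid state of a locus is OO
(homozygous oceanic), HET, or FF, equivalently a freshwater-allele dosage
g ∈ {0, 1, 2}.

At ~1× coverage individual SNP genotypes cannot be called reliably, but the
correlated SNPs within a locus can be pooled. For a read with base $b$ at a
SNP with error probability $e$,

$$P(b \mid g) = \frac{g}{2}\,P(b \mid \text{fw}) + \Big(1 - \frac{g}{2}\Big) P(b \mid \text{oc}),
\qquad P(b \mid a) = \begin{cases} 1 - e & b = a\\ e/3 & b \ne a,\end{cases}$$

the four-base error model. Per-SNP log-likelihoods are summed over reads,
then summed across the locus's SNPs in panel orientation to give the triple
$(L_{OO}, L_{HET}, L_{FF})$; the call is the argmax. Three rules guard the
call:

* reads must pass quality filters — mapping error < 0.001 and base error
  < 0.01, applied as phred thresholds MQ ≥ 30 and BQ ≥ 20;
* a locus needs at least 3 SNPs with at least one passing read each
  (`min_snps`, configurable), otherwise it is missing;
* an exact tie among the three likelihoods (for instance the flat triple
  from zero informative reads) is missing rather than an arbitrary state.
  This is a deliberate conservative choice: flat likelihoods should not
  fabricate heterozygotes.

Reads matching neither panel allele contribute the same $e/3$ factor to all
three states; they are retained because they shift the triple uniformly and
keep the bookkeeping honest. Loci with any missing call across the cohort
are dropped (`filter_complete_loci()`) before content and haploblock
analyses, mirroring the complete-case design of the genotype matrix. The
caller is validated two ways: exact agreement with brute-force enumeration
of the three-state likelihood on small pileups, and Mendelian consistency
on simulated crosses — offspring of OO × FF parents must be called HET.

## Content, haploblocks, and the carrier classifier

Freshwater content is the fraction of freshwater alleles over the complete
loci, $\sum_j g_{ij} / 2L$. A haploblock is a maximal run of consecutive
panel loci (same chromosome) with dosage ≥ 1; HET stretches count because
observed carrier blocks are predominantly heterozygous. Physical span runs
from the first SNP of the first member locus to the last SNP of the last;
genetic span interpolates the recombination map linearly (positions outside
the map extrapolate at the terminal rate, with a warning). Single-locus
runs are reported as counts but excluded from span distributions — a block
needs two or more loci. An optional maximum-gap rule (default analysis
value 0.8 Mb, twice the largest locus) splits runs whose adjacent member
loci are further apart than the threshold, measured from the last SNP of
one locus to the first SNP of the next.

Carrier classification works on the content distribution. Bimodality is
checked with Hartigan's dip statistic — implemented natively in the package
(no dip implementation exists in the installed stack) via the greatest
convex minorant / least concave majorant cycling algorithm, with a
uniform-null bootstrap p-value. The classifier is a univariate variational
Bayesian Gaussian mixture with a symmetric Dirichlet weight prior of
concentration 1/K (the truncated surrogate of a Dirichlet-process prior
that lets surplus components empty themselves) and Normal–Gamma priors on
component parameters. Candidate counts K = 1..4 are compared by BIC
evaluated at posterior-mean parameters with the effective parameter count;
components with weight below 1/n count as empty. The fit is pooled across
timepoints, labels are assigned per timepoint, and the jackpot component is
the effective component with the larger mean, thresholded at posterior 0.5.
The initialization is quantile-based and deterministic, so fits are
reproducible without RNG state. On well-separated synthetic modes the dip
test rejects, BIC selects two components, doubling the component budget
changes nothing, and label accuracy exceeds 99%; the real-data operating
points (posterior 0.95 at 5% content) are data-dependent and are not
asserted on synthetic fits.

## Population-genetic summaries

The folded SFS is computed from allele counts by hypergeometric projection:
a site with k derived copies among N chromosomes contributes
$\binom{k}{j}\binom{N-k}{n-j}/\binom{N}{n}$ to class j of an n = 40 sample,
monomorphic classes are discarded, and classes fold by minor allele. θ_W, π
and Tajima's D use the standard constants; the count-based estimator is
exact on synthetic data (the genotype-likelihood SFS machinery of
low-coverage pipelines is out of scope, and site-class analyses such as
0-fold/4-fold contrasts enter as user-supplied masks). LD decay is the
squared Pearson correlation of locus dosage vectors (coding direction is
immaterial), binned by physical distance between locus midpoints with
log-spaced default bins, and bootstrapped over individuals (percentile 95%
intervals). Cohen's D, Welch's t, exact binomial carrier-sampling tails,
and the relatedness permutation test (count induced related pairs among
random 20-fish subsamples; closed-form expectation
$|E|\binom{n-2}{s-2}/\binom{n}{s}$) complete the toolkit.

## The transporter simulation

A marine deme exchanges migrants with 10 freshwater demes; freshwater demes
never exchange directly. All 341 loci start fixed freshwater in one
freshwater deme and oceanic everywhere else; there is no de novo mutation.
Selection is environment-dependent and multiplicative across loci (1,
1 + hs, 1 + s per locus with h = 0.5; s = +0.01 in freshwater, −0.01 in the
ocean — the ocean-side coefficient is the package's symmetric default, and
configurable). Generations are non-overlapping: each offspring draws its
parents' deme by backward migration rates (0.001 into each freshwater deme,
0.01 into the marine deme from each freshwater deme — the per-source-deme
convention of forward simulators), draws two parents
fitness-proportionally, and receives one recombinant gamete per parent.
Crossovers follow a no-interference Poisson process on the genetic map,
realized exactly as independent per-interval Bernoulli switches at Haldane
fractions and sampled by exponential skipping on the cumulative hazard (an
O(#crossovers) algorithm, implemented in C++).

After a 1000-generation burn-in, a lake is founded by sampling marine
individuals: scenario A uniformly, scenario B restricted to non-jackpots
(content below 0.05, restriction applied before sampling). No migration
occurs after founding; content is recorded at generations 2, 3, 4, 6 and 9,
the sampled years.

Deme sizes are not published for the original simulations and are
configuration here (defaults N_m = 2000, N_f = 500, founders
min(3000, 0.3 N_m)). The package's desk-scale study configuration is
N_m = 1000, N_f = 30, founders 300. The small freshwater demes are
deliberate: at this scale the jackpot-arrival × establishment rate keeps
the nine initially-oceanic freshwater demes from fixing freshwater alleles
within the burn-in, which holds the marine deme at the low (~1%) jackpot
frequency regime on which the scenario contrast rests; with larger
freshwater demes, secondary demes flip during burn-in and the marine pool
is swamped — a finite-size cascade, not a feature of the modelled system.
Under these conditions scenario A lakes sweep to high content within nine
generations whenever the founders include carriers, scenario B lakes never
leave the baseline, and the per-founder allele pools of the two scenarios
are statistically indistinguishable (KS) because carriers are a ~1%
minority of founders.

Because the simulator has no mutation, neutral stationarity for the
SFS/Tajima's-D checks comes from a dedicated single-deme run
(`neutral_stationary_deme()`): the spectrum is initialized at the 1/k
neutral equilibrium shape, and drift generations (s = 0, same meiosis
engine) are balanced by Poisson singleton influx with fixed sites recycled
as substitutions. Tests use N = 50, a 1500-site pool, 0.5 mutations per
haploid genome per generation and 250 generations, sizes chosen so 50
replicates run in about a minute while keeping roughly 400 segregating
sites per replicate.

## What the synthetic data does and does not emulate

The generator reproduces the features the pipeline's logic depends on:
panel geometry (344 loci, 3–3658 SNPs, ~27 kb median span, 21
chromosomes), bimodal per-individual content with contiguous haploblock
placement, Mendelian crosses with map-based recombination, per-SNP Poisson
read depth with the four-base error model and phred-stamped quality
classes, and labelled relatedness graphs. It does not emulate alignment
artifacts, indels, correlated coverage along the genome,
machine-specific error profiles, linked-selection background, or the
empirical SNP-density heterogeneity across loci — so green tests certify
the algorithms, not robustness to every pathology of real sequencing data.
Conversely the caller's validation at 30× and the monotone
coverage-accuracy sweep say exactly what they measure: the likelihood
machinery recovers truth in the limit and degrades gracefully, per this
error model.

## Numerical choices

* Tie-breaking: exact likelihood ties → missing call.
* Dip statistic: count-unit arithmetic, final division by 2n; constant
  samples return 0 with p = 1; bootstrap p-values use the add-one rule
  (d + 1)/(B + 1).
* BGMM: convergence is declared at a relative surrogate-likelihood change
  below 1e-8 (500-iteration cap, non-convergence warns); variances use the
  posterior-mean precision.
* SFS projection: per-site mass is conserved exactly before discarding
  monomorphic classes; the central folded class of an even projection is
  not double-counted.
* Genetic spans: linear interpolation; uniform-map spans equal bp × rate up
  to floating-point round-off (~1e-6 relative).
* Meiosis: per-interval switch probabilities are exact Haldane fractions;
  chromosome boundaries get r = 0.5.
* Seeds: every stochastic entry point takes a `seed`; sub-seeds derived in
  scripts stay below 2^31.

## Limitations

Genotype imputation, phasing, kinship-coefficient estimation, ROH and
GL-based SFS estimation are intentionally out of scope. The BGMM operating
points quoted for real data depend on the empirical content distribution.
The transporter simulation's quantitative trajectories depend on the
unpublished deme sizes; only the qualitative scenario contrast — rapid
adaptation requires jackpot carriers among the founders — is asserted, at
the scaled sizes stated above.
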