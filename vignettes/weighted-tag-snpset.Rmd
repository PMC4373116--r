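---
title: "Weighted tag SNP-set association testing: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted tag SNP-set association testing: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagassoc)
```

## The problem

Gene-level (SNP-set) association tests pool the evidence of all SNPs in a
gene against a binary disease phenotype.  Their power depends strongly on the
quality of the SNP-set: redundant SNPs in strong linkage disequilibrium (LD)
dilute the signal, and genotyping every SNP is wasteful when a few *tag SNPs*
carry nearly the same information.  `tagassoc` implements a three-part
strategy:

1. **Tag selection.**  From a phased haplotype sample, compute pairwise LD as
   the squared Pearson correlation $r^2$ of allele indicators, connect SNP
   pairs with $r^2 > t$ (default $t = 0.9$), take connected components of
   this LD graph as clusters, and pick as each cluster's tag the SNP with the
   largest within-cluster LD row sum $\sum_{j \in Q} R_{ij}$ (ties to the
   smallest index).
2. **Weighting.**  Each SNP $i$ receives the weight
   $w_i = \left\{ \frac{(ad-bc)^2 (a+b+c+d)}{(a+b)(a+c)(c+d)(b+d)} \right\}^2,$
   the *square* of its single-SNP allelic $\chi^2$ statistic, computed from
   the 2×2 case–control allele-count table $(a, b, c, d)$.
3. **Testing.**  Two SNP-set statistics, each unweighted or weighted, on the
   original or the tag SNP-set:
   * **KBAT** — with the allele-match kernel
     $h(g_1, g_2) \in \{0, \tfrac12, 1\}$ (fraction of matching allele
     cross-comparisons), form per-SNP U-statistics
     $\bar U_l = \sum_{i<j} h(g_i, g_j) / m_l$ within each group
     ($m_l = \binom{n_l}{2}$), the within-group sum of squares
     $W_k = \sum_l \sum_{i<j} [h - \bar U_l]^2$, the between-group sum
     $B_k = \sum_l m_l (\bar U_l - \bar U)^2$ with
     $\bar U = (\bar U_1 + \bar U_2)/2$, and the ratio
     $\mathrm{KBAT} = \sum_k B_k / \sum_k W_k$
     (weighted: $\sum_k w_k B_k / \sum_k w_k W_k$).  The null distribution is
     estimated by permuting phenotype labels.
   * **SKAT** — the variance-component score test of the logistic
     kernel-machine model
     $\operatorname{logit} P(y_i = 1) = \alpha_0 + \alpha' x_i + h(Z_i)$,
     with $Q = \tfrac12 (y - \hat p_0)' K (y - \hat p_0)$ and the weighted
     linear kernel $K = G\,\mathrm{diag}(w)\,G'$.  Under the null, $Q$ is
     approximated by a scaled chi-squared $\kappa \chi^2_\nu$ matched to the
     first two moments of $Q$.

## Model choices that were genuinely open

**The between-group sum is squared.**  The source formulation of $B_k$ can be
read without the square on $(\bar U_l - \bar U)$, but the unsquared version
is negative half the time and cannot be a between-group *sum of squares*; with
two groups and the simple mean $\bar U$, it is in fact identically zero.  We
use the squared form, which reduces KBAT to a one-way-ANOVA-style F ratio per
SNP.

**$S_i$ in the LD formula is a standard deviation.**  Reading it as a
variance would let $R_{ij}$ exceed 1 and destroy the meaning of a threshold
in $[0,1]$; as the sample standard deviation (denominator $2m-1$), $R_{ij}$
is exactly the familiar $r^2$ LD measure.

**Allele counts, not genotype counts.**  The weight's 2×2 table counts allele
copies: $a + b = 2 n_\text{case}$.  This is the standard single-SNP allelic
test in GWAS; a zero margin (monomorphic SNP or empty group) gives weight 0,
which silently removes the SNP from weighted sums — the right behaviour,
since such a SNP carries no association information.

**How weights enter each statistic.**  The weighted KBAT applies $w_k$ to
both the numerator and denominator sums, which keeps the statistic invariant
to rescaling all weights and reduces to the single-SNP statistic when one
weight dominates.  The weighted SKAT uses the standard weighted linear
kernel.  Neither choice affects the unweighted tests.

**Weights are recomputed inside every permutation.**  The weights depend on
the phenotype.  A valid randomisation test must apply the *identical*
statistic to permuted labels, so each permutation recomputes the allele
tables and weights from the permuted phenotype.  Freezing the observed
weights would break exchangeability and inflate the type-I error of the
weighted tests.

**Analytic vs permutation p-values.**  Unweighted SKAT uses the
Satterthwaite two-moment scaled-chi-squared null
($\mu = \operatorname{tr}(P_0 K)/2$,
$\sigma^2 = \operatorname{tr}(P_0 K P_0 K)/2$,
$\kappa = \sigma^2 / 2\mu$, $\nu = 2\mu^2/\sigma^2$, with
$P_0 = V - VX(X'VX)^{-1}X'V$ and $V = \mathrm{diag}(\hat p_0 (1 - \hat
p_0))$).  Weighted SKAT defaults to permutation p-values because
data-dependent weights invalidate that null; both routes are exposed.
Permutation p-values use the add-one estimator
$p = (1 + \#\{T_r \ge T_0\})/(R+1)$, which is exactly valid and, at
$R = 199$, makes rejection at $\alpha = 0.05$ an exact level-0.05 event.

**Connected components, not random traversal.**  The cluster-growing step of
tag selection visits SNPs in arbitrary order; the resulting blocks are just
the connected components of the thresholded LD graph, so the random start
mandated by the algorithm affects only the order in which clusters are
emitted, never their contents (tested).  The threshold is strict
($R_{ij} > t$), so $t = 1$ leaves every SNP its own tag and $t = 0$ collapses
any connected panel to a single tag — the Max-single limit.

**Two-stage genotyping ambiguity.**  In the envisaged design only a small
haplotyped subsample informs tag selection, and the remaining subjects are
genotyped at tag loci only.  What happens to the haplotyped subjects'
association genotypes is ambiguous; we use all subjects' genotypes at the
tested loci throughout.

## The synthetic data generator

No real reference panel ships with the package, so the simulator stands in
for reference-panel resampling on real haplotypes (the HAPGEN approach):

* **Panel.**  `simulate_panel()` builds a panel (default: 169 SNPs, 1000
  haplotypes) of independent LD blocks with mean size ≈ 3.  Each block draws
  one MAF uniformly from $[0.05, 0.5]$ (jittered per SNP, s.d. 0.005) and a
  latent equicorrelation; block members are indicators of a thresholded
  shared Gaussian factor.  Near-equal MAFs within a block are essential:
  binary indicator correlation is capped by marginal frequency mismatch, so
  per-SNP independent MAFs would make $r^2 > 0.9$ unattainable.
  Thresholding attenuates correlation (latent 0.99 → allele $r \approx
  0.91$), so "tight" blocks draw latent correlation from $[0.999, 0.99995]$
  (92% of blocks) and "loose" blocks from $[0.3, 0.9]$.  This mixture is
  calibrated so tag selection at $t = 0.9$ keeps roughly a third of the
  SNPs, the compression a dense single-gene panel typically shows.
* **Genotypes.**  Subjects are sums of two panel haplotypes drawn uniformly
  with replacement, giving Hardy–Weinberg genotype frequencies at the panel
  allele frequencies.
* **Disease.**  Case–control status is assigned prospectively with
  probability $\text{baseline} \times \prod_c rr(g_c)$ over causal SNPs
  ($rr(0)=1$, $rr(1)=1.25$, $rr(2)=1.5$ by default, multiplicative across
  SNPs, capped at 1; baseline 0.1), and subjects are rejection-sampled to
  quotas of 500 cases and 500 controls.  The implied case-genotype
  enrichment is analytic — at MAF 0.5 and risks (1, 1.25, 1.5) the case
  genotype distribution is exactly (0.2, 0.5, 0.3) — and is verified by
  simulation in the tests.
* **Scenario bundles.**  `make_scenario()` reserves a 200-haplotype
  subsample (100 subjects' worth) for tag selection, drawn per replicate so
  replicates stay independent, and can mask causal SNPs from the genotyped
  set to emulate arrays that missed the causal variant.

What the generator does **not** emulate: recombination-distance LD decay,
long-range and cross-block LD, allele-frequency spectra skewed toward rare
variants, population structure, genotyping error and missingness.
Consequently, passing simulations show correct *calibration* and the right
*directional* behaviour of weighting and tagging, not the numeric power
levels reported for any particular real gene: those depend on that gene's
empirical LD matrix.  In particular, at the weak per-genotype risks
(1.25/1.5) the weighting gain that a long-range-LD panel shows does not
materialise on this block-independent panel — the directional power checks
therefore use a strong-signal fixture (one genotyped causal SNP, risks
1.7/3), where the causal SNP's $\chi^2$ dominates the null weight noise.

## Numerical and computational choices

* KBAT's per-SNP decomposition is computed from genotype-category counts in
  closed form (O(n) per SNP), and all permutations are evaluated as three
  matrix cross-products (category indicators × permuted label matrix); the
  O(n²) pair loop exists only as a test oracle.  Both routes agree to 1e-12.
* SKAT moments are computed in SNP space ($G'P_0G$, O(np²)) rather than via
  the n×n kernel; the kernel-space route exists as the reference
  implementation and both agree to 1e-10.
* The logistic null is fitted by IRLS (`glm.fit`, tolerance 1e-8, max 50
  iterations); separation raises an error rather than a silent fallback.
* Degenerate inputs fail loudly: monomorphic columns are rejected by LD
  computation (a `drop_monomorphic()` filter is provided), an all-constant
  SNP-set raises "degenerate SNP-set", and permutation statistics that are
  undefined (0/0) never count as exceedances.
* Tie-breaks: the cluster representative takes the smallest index among row
  -sum maximisers; this is the only order-sensitive rule, and column
  permutation invariance up to that rule is tested.
* All simulation entry points accept a seed; the replicate harnesses derive
  per-replicate seeds as a fixed affine function of (master seed, replicate
  index), so any subset of replicates can be reproduced independently.

## Problem sizes used in the shipped checks

Type-I error is estimated on the default geometry (169 SNPs, 500 cases /
500 controls, 199 permutations) over 500 null replicates in the test suite
and 400 in the acceptance script — large enough that the ±3 binomial-SE
bands around 0.05 and 0.01 are informative (±0.029 and ±0.013 at 500
replicates) while a full eight-variant table still runs in minutes on one
CPU.  Power comparisons use 300 replicates of the strong-signal scenario.
Oracle-equivalence checks run at n ≤ 30, p ≤ 12 where brute force is exact
and instant.

## Known limitations

* Binary traits only; quantitative traits would need a Gaussian working
  model for SKAT and a different KBAT grouping.
* No covariates inside the permutation path (permutation assumes
  exchangeability; with confounders, use the analytic SKAT route, which
  does adjust).
* No missing-genotype handling: missingness must be resolved upstream.
* The analytic SKAT tail is a two-moment approximation; far-tail p-values
  (≪ 1e-4) are less accurate than an eigenvalue-based method.
* Tag selection assumes phased haplotypes; unphased data would require an
  EM phasing step that is out of scope.
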