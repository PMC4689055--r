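---
title: "Local versus whole-genome Bayesian prediction of QTL genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local versus whole-genome Bayesian prediction of QTL genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Whole-genome regression predicts genetic merit from thousands of SNPs at
once. When a trait is controlled by a quantitative trait locus (QTL), how
much of that predictive ability actually comes from markers in close
physical proximity to the QTL, and how much is diluted — or spuriously
contributed — by distant markers? `qtlflank` studies this with simulated
genotypes and deterministic (heritability-one) phenotypes: the phenotype
*is* the QTL dosage, so prediction accuracy equals the accuracy of
genetic-merit prediction and every difference between training strategies
is attributable to linkage disequilibrium (LD) structure rather than noise.

Two strategies are compared for each QTL and each flanking half-window size
$k \in \{1, 2, 5, 10, 50, 100\}$:

1. **Local training and prediction** — marker effects are estimated from
   only the $\pm k$ SNPs flanking the QTL, and the direct genomic value
   (DGV) is formed from those same SNPs.
2. **Whole-genome training with local prediction** — effects are estimated
   once from all SNPs except the designated QTL, and the DGV is formed from
   the $\pm k$ flanking SNPs using their genome-wide estimates.

Accuracy is the Pearson correlation between phenotype and DGV.

## The model and its samplers

All methods fit, by single-site Gibbs sampling,

$$y_i = \mu + \sum_j z_{ij}\,\beta_j\,\delta_j + e_i,$$

where $z_{ij} \in \{0,1,2\}$ is the allele dosage, $\beta_j$ the allele
substitution effect, and $\delta_j \in \{0,1\}$ an inclusion indicator that
is 0 with prior probability $\pi$. Effect variances have scaled inverse
chi-square priors with $\nu_\beta$ degrees of freedom and scale $S_\beta$;
the family members differ only in $\pi$ and in whether that variance is
marker-specific or common:

| method   | $\pi$                 | effect variance  |
|----------|-----------------------|------------------|
| BayesA   | 0                     | per marker       |
| BayesB   | fixed $> 0$           | per marker       |
| BayesC / BayesC0 | fixed ($0$ for C0) | common     |
| BayesC$\pi$ | estimated, uniform prior | common     |

Per iteration the sampler draws: $\mu$ from its normal full conditional;
each $\delta_j$ (fixed ascending marker order) from a Bernoulli full
conditional with $\beta_j$ integrated out — the two marginal likelihoods of
the residual-adjusted right-hand side $r_j = \mathbf z_j'\mathbf e_{-j}$
under $r_j \sim N(0,\, z'z\,\sigma^2_e)$ versus
$N(0,\, z'z\,\sigma^2_e + (z'z)^2\sigma^2_{\beta_j})$; $\beta_j$ from its
normal full conditional when included; the effect variance(s) from scaled
inverse chi-square conditionals, an excluded BayesB locus redrawing its
variance from the prior; $\sigma^2_e$ from its conditional; and, for
BayesC$\pi$, $\pi \sim \mathrm{Beta}(\#\text{excluded}+1,
\#\text{included}+1)$. Posterior means of $\beta_j\delta_j$ over
post-burn-in samples are the substitution-effect estimates; the mean of
$\delta_j$ is the marker's model frequency.

Numerical choices:

* Dosages are centered before fitting and the intercept absorbs the mean;
  this is algebraically irrelevant for prediction correlations and
  numerically safer than raw 0/1/2 coding.
* With $h^2 = 1$ the residual variance collapses towards zero; it is
  floored at $10^{-8}$ to keep the conditionals proper. Results are
  insensitive to the residual prior for the same reason.
* Hyperparameter defaults: $\nu_\beta = 4.2$, $\nu_e = 4$; $S_\beta$ is
  derived so the prior-implied genetic variance
  $(1-\pi)\,p\,\overline{2pq}\,E[\sigma^2_\beta]$ matches $\mathrm{var}(y)$
  (`derive_scale_beta()`), and $S_e$ from a nominal residual variance of
  $0.01\,\mathrm{var}(y)$.
* The marker update order is fixed ascending, and all random draws go
  through R's RNG, so a seed fully determines a chain. Monomorphic columns
  are skipped with zero effect.
* BayesA is run as the $\pi = 0$, per-marker-variance member of the same
  machinery.

The BayesC0 sampler is checked against its closed-form ridge (SNP-BLUP)
equivalent $(\mathbf Z'\mathbf Z + \mathbf I\,\sigma^2_e/\sigma^2_\beta)^{-1}
\mathbf Z'\mathbf y$ with both variances held fixed; posterior-mean effects
correlate above 0.98 with the closed form on 100-observation,
200-marker instances.

## What the generator emulates

Real studies of this design used ~2700 cattle genotyped at 54,555 SNPs,
with a high-density 764,830-SNP panel imputed from a reference population —
proprietary data. The generator reproduces the *statistical structure* of
that setting at desk scale:

* **Genome**: 10 chromosomes × 500 markers at ~50 kb spacing (a 50K-array
  analogue). A dense panel is simulated at 14× density (the 764,830 :
  54,555 ratio) and thinned to the sparse panel, so both densities share
  the same QTL columns.
* **LD**: founder haplotypes follow a first-order Markov process along each
  chromosome with allele correlation $\rho^{d/d_0}$ between markers $d$ bp
  apart ($\rho = 0.5$ at $d_0 = 50$ kb). This yields adjacent-marker
  $r^2 \approx 0.23$ on the sparse panel — the level reported for bovine
  50K data — and geometric decay with distance. Allele frequencies are
  uniform on [0.01, 0.5]; conditional probabilities are clamped to [0, 1],
  which caps the correlation attainable between markers of very different
  frequency, as in real data.
* **Family structure**: founders' haplotypes are gene-dropped through a
  random-mating pedigree (250 founders, 3 generations of 2 offspring per
  mating by default, 1000 individuals in total) with Haldane recombination
  at 1 cM/Mb; crossovers are resampled per gamete, so close markers are
  co-inherited and the pedigree induces the relatedness that
  cross-validation grouping exploits.
* **QTL and phenotypes**: every m-th ordered sparse marker is a candidate
  QTL (m = 250 gives 20), monomorphic candidates are dropped — mirroring
  the retention of 42 of 54 evenly spaced candidates in the motivating
  study. Phenotypes are the QTL dosage itself (single-QTL trait) or the
  unweighted sum over all QTL (polygenic trait); no residual is ever added,
  so $h^2 = 1$ exactly.

What it does *not* emulate: ascertainment bias of array SNPs (all simulated
markers share one frequency distribution), selection-induced long-range LD,
mutation, X-linked inheritance, imputation error, or a realistic
site-frequency spectrum with near-monomorphic QTL. The last point matters
for the minor-allele-frequency analysis: real studies see strong positive
correlations (0.37–0.67) between QTL MAF and accuracy, driven by QTL with
MAF near zero that no common marker can tag. In this generator rare QTL are
only mildly harder to tag, so the MAF–accuracy correlation is positive but
much weaker (~0.1 on the study replicate). Passing the direction check here
does not demonstrate the magnitude of the effect on real data.

## Cross-validation by relatedness

The additive (numerator) relationship matrix **A** is built from the
pedigree with the tabular recursion
$a_{ij} = \tfrac12 (a_{i,s(j)} + a_{i,d(j)})$,
$a_{jj} = 1 + \tfrac12 a_{s(j),d(j)}$, which handles inbreeding implicitly
and is verified exactly against a memoized top-down implementation of the
definition. Individuals are clustered into K = 6 groups by standard
K-means on the raw rows of **A** (Euclidean distance, 10 random restarts,
best within-cluster sum of squares; the citation trail for the original
procedure does not pin down the feature construction, so the simplest
faithful reading is used). Each group is predicted once from a model
trained on the other five. Because groups collect relatives, the held-out
accuracy is the harder, more honest measure; on the bundled replicates it
is far below the training accuracy, the standard overfitting direction.

## Problem sizes and chain lengths

The package defaults to 4000-iteration chains with 500 burn-in. Study-scale
runs (the test suite and `scripts/acceptance.R`) use 2000/400 for local
windows and 800/200 for whole-genome chains on the main replicate of 1000
individuals × 5000 markers × 20 QTL. At $h^2 = 1$ the predictive ability of
a chain plateaus essentially at burn-in — the convergence monitor
(`monitor_convergence()`) shows the training correlation changing by less
than 0.005 over the second half of such chains, and shortening the
whole-genome chains from 1500 to 800 iterations changes accuracies by under
0.003 — so these lengths trade nothing measurable for a large saving. Replicate data seeds
(77 for the main replicate, 33 for the density comparison, 41–43/401–406
for the cross-validation families) are fixed study conditions; chain seeds
are user-supplied.

## Design choices that were genuinely open

* **Flank windows at chromosome ends** are truncated; a QTL alone on its
  chromosome is an error rather than an empty window.
* **Overlapping windows of the summed trait**: local prediction uses the
  union of per-QTL flank sets, each marker counted once.
* **Whole-genome training is run once per method and panel** and reused for
  every window's local prediction, since the strategy estimates one set of
  genome-wide effects.
* **Thinning** keeps every 14th dense marker plus any designated QTL. A
  thinned panel has slightly weaker LD than a directly simulated sparse
  panel because clamping accumulates over the 14 dense intervals; the two
  construction routes are otherwise consistent (the Markov process is
  closed under thinning).
* **QTL-averaged figures** are unweighted means over per-QTL accuracies;
  undefined accuracies (zero-variance DGV, possible when all flank effects
  shrink to zero) are dropped from the mean and flagged with a warning at
  computation time.
* **Child seeds** for the many chains inside an experiment are derived from
  the master seed and the run index by a fixed Lehmer-style map
  (`derive_seed()`), keeping every record reproducible from one seed.

## Known limitations

Beyond the generator simplifications above: accuracies on simulated data
are not comparable in level to published values on real cattle genotypes
(different LD, different $n$); the K-means grouping can produce unbalanced
groups on loosely structured pedigrees; and the samplers are single-trait,
single-chain — no BayesR, no antedependence, no parallel tempering.
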