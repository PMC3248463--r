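---
title: "Polygenic scores in the tails: models, simulation design and inference"
author: "polytail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores in the tails: models, simulation design and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(polytail)
```

## The question

Common variants discovered by GWAS explain a modest fraction of the variance
of polygenic traits such as adult height. `polytail` asks whether those same
variants behave as the additive polygenic model predicts in individuals at
the *extremes* of the trait distribution — or whether, at some point in the
tail, other factors (rare variants of large effect, non-additive genetics,
environment) take over. The package implements the full chain of methods for
answering this with tail-ascertained case-control samples: a weighted allele
score, closed-form expected odds ratios under tail ascertainment, an
ascertainment-mimicking cohort simulator, replicate-based null distributions
for the mean score, and a sibling regression-to-the-mean benchmark.

## The model

Standardized height is modelled as

$$Z = \mathrm{WAS} + \varepsilon, \qquad
  \varepsilon \sim N(0,\ \sigma^2_{\mathrm{remaining}}),$$

where the weighted allele score of individual $i$ is the centered,
effect-size-weighted dosage sum over the panel of $N$ SNPs

$$\mathrm{WAS}_i = \sum_{j=1}^{N} \beta_j\, d_{ij} - \alpha, \qquad
  \alpha = \sum_j \beta_j\, 2p_j ,$$

with $\beta_j$ the per-allele effect in SD units, $d_{ij} \in \{0,1,2\}$ the
effect-allele dosage and $p_j$ the effect-allele frequency. Under
independent SNPs with Binomial$(2, p_j)$ dosages,
$\mathrm{var}(\mathrm{WAS}) = \sum_j \beta_j^2\, 2 p_j (1-p_j)$, and
$\sigma^2_{\mathrm{remaining}} = 1 - \mathrm{var}(\mathrm{WAS})$ makes $Z$
marginally standard normal. Rare-variant scenarios add a second centered
score with its own $(n, B, F)$ specification and reduce
$\sigma^2_{\mathrm{remaining}}$ accordingly; the WAS itself is always
computed from the common panel only, so planted rare effects show up as a
*discrepancy* between observed and simulated scores.

Under missing genotypes the score is centered per individual over that
individual's observed SNPs. This keeps the expectation at zero for any
missingness pattern, which is the property that defines $\alpha$; the
alternative (full-panel centering) biases scores of individuals with missing
high-frequency SNPs.

### Expected tail odds ratios

For a single SNP, conditioning on one allele copy splits the trait into two
normal components with means $M_i = \beta p$ and $M_d = -\beta(1-p)$ and
common variance $V = 1 - \beta^2 p(1-p)$. The odds of observing the
trait-increasing allele beyond a cutoff $c$ are
$p\,\bar\Phi_{M_i,V}(c) \,/\, (1-p)\,\bar\Phi_{M_d,V}(c)$, and the expected
case-control odds ratio is the ratio of these odds in the upper and lower
tails (`expected_odds_ratio()`). Two numerical notes:

* the frequency-weighted mixture of the two conditional means vanishes with
  weights $(1-p, p)$ in this labeling; the expected odds ratio itself is
  *exactly* invariant to swapping the two labelings under a symmetric
  design, which we verified to machine precision, so downstream results do
  not depend on the labeling;
* tail probabilities use complementary-CDF routines, never $1-\Phi$, so
  cutoffs out to $|c| \approx 37$ do not cancel; beyond that the function
  errors rather than returning noise.

The approximate SE of the expected log OR recomputes the OR at
$\beta \pm 1.96\,\mathrm{se}(\beta)$ and divides the log-range by
$2 \times 1.96$. The observed-vs-expected Z-test combines observed and
expected log-scale SEs in quadrature — the expected-side SE is not
negligible and ignoring it would overstate discrepancies.

A genotype-level Monte-Carlo check (counting alleles in the $\pm 2.326$
tails of $5\times10^6$ simulated single-SNP individuals) agrees with the
closed form within 2% for $\beta \le 0.1$; the residual discrepancy is
dominated by Monte-Carlo noise (log-OR SE $\approx$ 1.3–1.5% at $p = 0.1$),
not by the allele-level approximation.

### Power equivalence of tail ascertainment

`equivalent_population_n()` converts a two-tail band design into the
population sample size of equal power. The allele-frequency shift per tail
is $\beta p(1-p) E[Z \mid Z \in \text{band}]$ with $\beta$ solved from
$2p(1-p)\beta^2 = v$ (variance explained $v$); the noncentrality of the
frequency contrast divided by $v$ is the equivalent population $N$, since a
quantitative-trait test on $N$ random individuals has noncentrality
$N\,v$. For 923 individuals in the $2.326 < |Z| < 2.81$ bands and
$v = 0.001$ this gives:

```{r}
equivalent_population_n(2.326, 2.81, 461, 462,
                        variance_explained = 0.001, freq = 0.3)
```

The construction is insensitive to the reference frequency through the
$\beta$-parametrization (it cancels), entering only via the band means.

## The simulator and what it emulates

`simulate_cohort()` reproduces the ascertainment of extreme-sample surveys:

* **Quota designs** (`quota_scheme()`): several subpopulations (e.g.
  geography × gender strata of sizes 4271/6582/5025/7610), the most extreme
  ~50 individuals per tail from each, pooled, then randomly dropped to exact
  final sizes (181 short, 192 tall). Stratum labels are retained for the
  stratified CMH test. Rank ties at quota boundaries are broken by seeded
  uniform jitter.
* **Threshold designs** (`threshold_scheme()`): all individuals beyond
  $\pm 2.14$ from a pool of 50,000, optionally subsampled to target sizes
  (385 short, 456 tall), with optional outer bounds giving band
  ("doughnut") strata and an optional middle group.

Dosages are independent Binomial$(2, p_j)$ draws — no linkage
disequilibrium, no assortative mating, no age or gender structure (inputs
are assumed pre-standardized Z-scores). Genotyping dropout is emulated by
per-SNP independent missingness; inference mirrors the *observed* cohort's
per-SNP missing rates into every null replicate. Where the original surveys
drew a large genotype pool and then subsampled individuals, we simulate the
subsample size directly — distributionally identical and cheaper.

The bundled `synthetic_panel()` stands in for a real GWAS summary-statistic
panel, whose values are not redistributable: 160 SNPs, exponentially
decaying $|\beta|$ with mean 0.028 SD, random signs, frequencies uniform on
$(0.1, 0.9)$. These defaults make the panel explain $\approx$ 10% of trait
variance, the level reported for common-variant height panels. Because the
panel is synthetic, passing tests demonstrate correctness of the *methods*
under the stated generative model, not properties of any real cohort;
features of real data that the generator deliberately omits (LD between
panel SNPs, frequency-dependent effect sizes, population stratification)
are exactly the features the real-data quality-control pipeline, which is
out of scope here, exists to handle.

## Inference

`null_mean_was_distribution()` repeats simulate → ascertain → apply
missingness → score, and summarizes the per-group mean WAS across
replicates by $(\mu_{\mathrm{sim}}, \sigma^2_{\mathrm{sim}})$. The central
fit, `was_tail_test()`, evaluates the observed group means against
$N(\mu_{\mathrm{sim}}, \sigma^2_{\mathrm{sim}})$ with a two-sided p-value
$2\min(\Phi(t), 1-\Phi(t))$ capped at 1. The normal evaluation is justified
empirically: replicate mean scores pass Shapiro-Wilk normality at the group
sizes used (hundreds of individuals), and under the self-consistent null
the p-values are uniform (KS-checked in the test suite). The default
replicate count is 1000; publication-grade p-values for effects near
$10^{-6}$ warrant the 10,000 used in the original analyses, while the test
suite uses 300–500 with Monte-Carlo error on p below 10% relative for
p > 0.01.

`stratified_tail_analysis()` re-selects the observed individuals per
stratum (Z bands for threshold designs; per-subpopulation floor-rule quotas
for quota designs, e.g. 21/32/25/38 per tail for a 0.5% stratum) and
re-simulates the null with matched group sizes under a stratum-matched
scheme. Using the *same* selection rule on both the observed and simulated
sides is what makes the stratified p-values valid.
`scenario_comparison()` rebuilds the null under candidate rare-variant
models and flags each as consistent (p > 0.05) or not; a scenario stronger
than the truth produces a rejection with the observed short-group mean
*below* the scenario null mean — the direction, not just the rejection,
identifies over-fitted scenarios.

For the sibling analysis, pairs are modelled as standard bivariate normal
with correlation $r$; siblings of probands beyond a cutoff $c$ then have
expected Z-score $r\,\phi(c)/\bar\Phi(c)$ (times $-1$ for the lower tail).
With $r = 0.466$ and $c = 2.81$ the additive benchmark is $\mp 1.45$; a
symmetric model shows no differential regression between tails, so an
observed asymmetry is a model violation, not a selection artifact.
Families with several siblings should be averaged to one pair before
analysis to avoid pseudo-replication.

## Numerical and design choices

* Two-sided p-values are $2\min(\text{tail}, 1-\text{tail})$, capped at 1.
* CMH: Mantel-Haenszel common OR with the Robins-Breslow-Greenland log-OR
  SE (no HWE assumption within groups); the 1-df chi-square uses raw counts
  without continuity correction. Strata with a zero cell get the
  Haldane-Anscombe 0.5 correction for the OR/SE only, flagged in the
  output. Allele-level (not genotype-level) tables, matching the
  odds-of-allele framing of the expected OR.
* Logistic association fits by IRLS to gradient tolerance $10^{-8}$;
  complete separation is flagged and no estimate returned.
* The inverse normal transform uses Blom's offset $(r - 3/8)/(n + 1/4)$
  with average ranks for ties — the standard choice in stature genetics.
* Allele alignment happens at the file boundary: the VCF reader matches
  allele strings exactly, flips swapped REF/ALT orientations, and *refuses*
  strand-ambiguous mismatches rather than guessing; the scoring code never
  flips.
* Replicate RNG: a single seed governs a run; `run_pipeline()` records it
  in every output header and identical seeds reproduce outputs byte for
  byte.
* Frequency source: the panel carries one frequency column; whether those
  are cohort-specific or consortium estimates is the caller's choice and is
  recorded, not guessed, since the expected ORs and $\alpha$ both depend
  on it.

### Scales used by the test suite

Simulation-heavy checks run at reduced but internally consistent scales,
stated here as the package's chosen study designs: calibration uses a pool
of 20,000 with all $\pm 2.14$ extremes, 500 inner replicates and 200
meta-replicates; scenario recovery uses the 50,000-pool threshold design
with all extremes kept ($\approx$ 810 per tail, comparable to the
923-extreme band analysis), shared 300-replicate scenario nulls and 50
paired seeds; the expected-OR cross-check counts alleles in the tails of
$5\times10^6$ single-SNP individuals per parameter combination. Pilot runs
showed that a 20,000 pool leaves the planted $(n{=}10, B{=}-1, F{=}0.005)$
scenario's short-tail shift at only $\approx 2\sigma$, so scenario recovery
is run at the larger scale where the shift is $\approx 3\sigma$ — a power
consideration fixed at design time.

## Known limitations

* No LD: the independent-SNP model slightly understates the variance of
  real panels with residual LD.
* The expected-OR closed form is an allele-level approximation; its error
  grows with $\beta^2$ and is negligible for $|\beta| \le 0.15$.
* Quota ascertainment assumes the subpopulation assignment is random with
  respect to genotype.
* The normal evaluation of the mean-score null can misstate extremely
  small p-values (far outside the simulated range); an empirical-quantile
  option would bound them instead and is noted as future work.
* The sibling benchmark conditions only on the proband's tail membership;
  ascertainment of *pairs* (both sibs extreme) would need a different
  truncation.
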