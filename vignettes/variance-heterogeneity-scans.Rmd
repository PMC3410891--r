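---
title: "Variance-heterogeneity genome scans in inbred panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-heterogeneity genome scans in inbred panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vargwas)
```

## The problem

In a panel of fully homozygous lines, each biallelic marker partitions the
lines into two homozygote classes. A locus can influence a quantitative
trait in two distinguishable ways: by shifting the phenotypic *mean* between
the classes, or by making one class more *variable* than the other. The
second kind of effect — genetic variance heterogeneity — is invisible to a
mean-based association scan, yet it is genuinely genetic: which class a line
belongs to is inherited, and with it the amount of phenotypic dispersion its
genotype permits. `vargwas` scans for such variance-controlling loci,
quantifies their contribution to the phenotypic variance, and validates the
procedure by simulation.

The unit of observation is one phenotypic value per line per trait. Within-
line replicate measurements, if they existed, are assumed to have been
collapsed upstream; the scan therefore addresses *between-genotype* variance
heterogeneity in the population and says nothing about heterogeneity between
repeated measurements of the same line.

## The variance test

For marker with genotype groups $j = 1, \dots, K$ ($K = 2$ here), each
observation is replaced by its absolute deviation from its group median,
$z_{ij} = |y_{ij} - m_j|$, and a one-way ANOVA is run on $z$:

$$F = \frac{\sum_j n_j (\bar z_j - \bar z)^2 / (K - 1)}
          {\sum_{ij} (z_{ij} - \bar z_j)^2 / (N - K)},$$

the Brown–Forsythe (median-centred Levene) statistic, with $F(K-1, N-K)$ as
reference distribution. Median centring, rather than mean centring, is what
makes the test robust to skewed and heavy-tailed phenotypes. At the panel
sizes the scan targets ($N \approx 200$), $(K-1)F$ is well approximated by a
$\chi^2_{K-1}$ score; this score is what genomic control operates on, and
the $\chi^2$-based p-value is the one used downstream (the exact-F p-value
is reported alongside). The mean-effect comparator run on the same markers
is the two-sided Wilcoxon rank-sum test, whose squared normal deviate
$Z^2$ provides the corresponding 1-df score.

Numerical conventions, chosen once and fixed:

- group medians use the midpoint of the two central order statistics for
  even group sizes; tied ranks in the Wilcoxon test receive average ranks;
- the Wilcoxon normal approximation applies the tie-corrected variance and a
  continuity correction; exact enumeration is available for $N \le 20$ with
  untied data (`exact = TRUE`). Whether a continuity correction or exact
  p-values are "the" convention is genuinely open; the default here is
  declared, not inferred, and the choice is exposed;
- degenerate dispersion patterns are resolved deterministically: when both
  the between- and within-group sums of squares of $z$ are zero the marker
  carries no dispersion signal ($F = 0$, $p = 1$); when only the within-group
  sum is zero the separation is perfect and the smallest representable
  positive p-value is returned with a `degenerate` flag. This ensures
  monomorphic-dispersion markers can never become spuriously significant;
- groups smaller than `min_group_size` (default 2) are not tested: a
  singleton group contributes no within-group dispersion information.

## Genomic control

Population structure inflates both scans' score distributions. Since most
markers are expected to be null, the bulk of the genome-wide 1-df $\chi^2$
scores should resemble the null distribution; the inflation factor
$\lambda$ is estimated by sorting the observed scores and regressing them
through the origin on the null quantiles (evaluated at the symmetric
plotting positions $(i - 0.5)/n$), taking the slope. This estimator is
exactly scale-equivariant and tends to be at least as conservative as the
alternative median ratio, $\mathrm{med}(\chi^2_{obs}) / \mathrm{med}(\chi^2_1)$,
which is also provided. Corrected scores are $\chi^2/\lambda$ with upper-tail
$\chi^2_1$ p-values.

Two behaviours the literature leaves open are exposed as switches with
conservative defaults: $\lambda$ is floored at 1 before correction
(`gc_clamp = TRUE`), so apparent deflation is never amplified into extra
significance; and $\lambda$ is estimated separately per trait and per test
(the variance and mean scans inflate differently).

## The scan pipeline

`vgwas()` aligns the genotype panel with the phenotyped lines (complete
cases, genotype-matrix order), filters markers, runs both tests, applies
genomic control, and decomposes every tested marker. Defaults:

| parameter | default | role |
|---|---|---|
| `maf_min` | 0.10 | markers below this minor-allele (= minor-genotype) frequency are skipped |
| `alpha` | 0.05 | nominal level before Bonferroni correction |
| `gc_method` | regression | $\lambda$ estimator |
| `gc_clamp` | TRUE | never amplify deflation |
| `lambda_max` | 1.5 | trait triage: flag (strictly) higher variance-scan inflation |
| `min_group_size` | 2 | smallest testable genotype group |
| `bonferroni_m` | "tested" | threshold denominator |

Design choices where the convention was genuinely open:

- allele frequencies are computed on the per-trait analysed sample, not the
  full panel — the conservative reading of the MAF filter, since missing
  phenotypes change the effective sample;
- the Bonferroni denominator defaults to the number of markers actually
  tested for the trait; using the full panel size instead is a
  configuration switch (`bonferroni_m = "all"`);
- trait triage uses strictly-greater comparison against `lambda_max`;
  flagged traits keep their full results (the flag marks them as
  structure-confounded rather than suppressing them);
- no correction across traits is applied: each trait is scanned and
  thresholded on its own;
- the decomposition is computed for *all* tested markers, not only
  significant ones, so that mean-shift and variance-heterogeneity
  contributions can be compared genome-wide;
- genomes with a single tested marker carry no information about inflation:
  the scan then reports nominal p-values and no $\lambda$.

Heterozygote policy at ingestion: residual heterozygous calls in a
nominally inbred panel are treated as noise and set missing by default
(`het_policy = "missing"`), preserving the two-genotype structure; a
stricter `"drop"` policy removes affected markers entirely. Multiallelic
sites are rejected rather than recoded. Coordinates are 1-based inclusive;
BED-like candidate intervals are converted from 0-based half-open on read.

## Single-locus variance decomposition

With low-variance allele frequency $p$ (LAF; $q = 1 - p$), per-genotype
means $\mu_{low}, \mu_{high}$ and standard deviations
$\sigma_{low} \le \sigma_{high}$, and differences $d_\mu$, $d_\sigma$:

$$\sigma^2_P = \underbrace{pq\,d_\mu^2}_{\sigma^2_m}
  + \underbrace{pq\,d_\sigma^2}_{\sigma^2_d}
  + \underbrace{(p\,\sigma_{low} + q\,\sigma_{high})^2}_{\sigma^2_\epsilon}.$$

$\sigma^2_m$ is the variance from the mean shift — for inbred biallelic
loci there is no dominance, so it equals the locus's additive variance.
$\sigma^2_d$ is the variance of the per-genotype standard deviation: the
genetically controlled part of what a mean-based analysis would call
residual variance. $\sigma^2_\epsilon$, the squared frequency-weighted mean
of the per-genotype SD, is the remaining environmental variance. This form
of $\sigma^2_\epsilon$ is adopted precisely so that the three components
sum to $\sigma^2_P$ *exactly* (to machine precision), which is also
verifiable through the equivalent closed form
$\sigma^2_P = pq\,d_\mu^2 + p\,\sigma_{low}^2 + q\,\sigma_{high}^2$; both
identities are enforced by property tests. The ratios
$h^2_m = \sigma^2_m/\sigma^2_P$ and $h^2_d = \sigma^2_d/\sigma^2_P$ satisfy
$h^2_m + h^2_d \le 1$.

At fixed per-genotype moments, both $h^2_m$ and $h^2_d$ are maximised at

$$p^\ast = \frac{\sigma_{high}}{\sigma_{high} + \sigma_{low}},$$

independent of $d_\mu$; only without variance heterogeneity does the
optimum sit at $p = 0.5$. This explains why the strongest
variance-controlling signals tend to have common low-variance alleles
(LAF > 0.5). `h2_curves()` traces both ratios across the LAF range.

Estimation is plug-in: sample genotype frequencies and sample moments
($n-1$ SD denominator) replace population quantities, with no small-sample
bias correction. Labels are canonical: the genotype with the larger sample
SD is "high" ($d_\sigma \ge 0$), with an exact tie resolved to the
`allele_a` homozygote as "low". The decomposition is invariant to
exchanging the labels together with $p \leftrightarrow q$.

Two helper operations support descriptive analyses: the per-genotype
coefficient of variation ($\sigma/\mu$, undefined at $\mu = 0$), and
Spearman rank correlations of per-trait deviations from the trait median
(`median_deviation_correlation()`), used to ask whether strongly deviating
lines deviate jointly across traits, e.g. along an expression pathway. Its
default mode is the *signed* deviation; the absolute-value mode is provided
where dispersion magnitude, not direction, is of interest.

## Candidate-gene rank enrichment

Tested markers are ranked by ascending GC-corrected p-value; ties get the
average of the tied positions rounded down, keeping ranks deterministic
integers. A gene's rank is the best SNP rank within `window` bp of its
interval (default 20 kb — a conventional SNP-to-gene assignment distance,
declared rather than derived). Merging a mean-scan and a variance-scan rank
map takes the element-wise minimum; a gene counts as *improved* when the
combined rank is strictly smaller than its mean-scan rank. The summary is
descriptive (counts, fraction, mean rank change); no permutation p-value is
attached.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates panels under the standard-deviation model:
each line is fully homozygous; the causal marker assigns genotype-specific
mean $\mu_g$ and standard deviation $\sigma_g$ (a model additive on the SD
scale); phenotypes are $y = \mu_g + \sigma_g\,\varepsilon$ with
standardised noise. Defaults emulate the target study design: ~200 lines,
a common causal variant (LAF 0.5), unit baseline SD. Population structure,
when requested, draws subpopulation allele frequencies from a
Balding–Nichols beta distribution with parameter $F_{st}$ around the
ancestral frequency and adds a per-subpopulation phenotype mean offset
(drawn once per dataset with SD `subpop_shift`); this is a deliberately
simple stratification model, declared rather than inferred from any
particular dataset. The noise distribution is pluggable (`"normal"`,
`"heavy"` = scaled $t_3$, or any standardised function) so the robustness
of the median-centred test to non-normality can be probed.

Features of real panels the simulator does **not** reproduce: linkage
disequilibrium (markers are independent given subpopulation frequencies),
missing genotype calls, multi-locus and epistatic architectures,
within-line replicate structure, and selection-driven confounding beyond
simple mean offsets. Passing simulation studies therefore demonstrates the
statistical behaviour of the tests under the stated model, not performance
on any particular real dataset.

## Simulation studies and problem sizes

The package's standard validation runs, also exercised by the test suite
and the acceptance script, use these sizes (chosen to give Monte-Carlo
standard errors well below the effects being checked, while keeping each
study in the seconds-to-a-couple-of-minutes range):

- **Type-I error**: 10,000 null replicates at $n = 200$, LAF 0.3; the
  empirical rejection rate at $\alpha = 0.05$ is compared against the 99%
  binomial band. Replicates whose marker comes out untestable are dropped
  (at these sizes, essentially none).
- **Power**: 400–1,000 replicates per cell over grids of SD ratio, LAF and
  $n$; power is monotone in the SD ratio and $n$ within Monte-Carlo error
  and collapses to $\alpha$ at SD ratio 1.
- **h²_d recovery**: 1,000 datasets of $n = 500$ at LAF 0.5, means 0/1,
  SDs 1/2; the mean plug-in estimate lands within ±0.01 of the theoretical
  $pq\,d_\sigma^2 / \sigma^2_P = 1/11$.
- **Structure and GC**: 100 structured null genomes (200 lines, 500
  markers, 3 subpopulations, $F_{st} = 0.3$, unit mean offsets); the median
  pre-correction $\lambda$ exceeds 1 while the post-correction $\lambda$,
  recomputed on corrected scores, returns to 1 (exactly so for the
  regression estimator, by its scale equivariance).

All studies are reproducible from a single integer seed; replicate $r$
re-seeds the generator at `seed + r` (or a fixed offset scheme in the
acceptance script), so results are independent of execution order.

## Known limitations

- Only biallelic, two-genotype (inbred) markers: no heterozygote class, no
  additive three-genotype coding, no covariates, and no double generalized
  linear models for joint mean–dispersion modelling.
- Genomic control absorbs only an affine inflation of the score
  distribution; strong or localised stratification calls for mixed-model
  corrections outside this package's scope.
- No joint mean-plus-variance test is offered; loci with intermediate
  effects on both moments can escape both scans.
- The plug-in decomposition carries small-sample bias in extreme allele
  frequency or tiny group sizes; no correction is applied.
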