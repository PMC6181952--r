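---
title: "Multi-cohort consistency screening and prognostic signature evaluation: methods"
author: "CohortScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort consistency screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CohortScreen)
```

## Scope

CohortScreen implements the statistical core of a candidate-gene
discovery workflow that is common in cancer transcriptomics: starting
from a gene of interest (the *anchor*), screen a panel of candidate
regulators or effectors across several independent patient expression
cohorts, requiring each candidate to behave consistently — correlated
with the anchor *and* altered in tumors — in a majority of the cohorts
where it can be evaluated; characterize a perturbation experiment with
empirical-Bayes moderated t-statistics; test candidate gene lists for
category over-representation; and evaluate single-gene and composite
expression signatures as prognostic markers for disease-free survival
(DFS). A seeded synthetic-data generator produces complete
multi-cohort worlds with planted ground truth so that every stage can
be validated end to end without access to patient data.

## Normalization

Array cohorts are brought to the analysis scale by a standard chain:

1. **Background correction.** The default mode shifts the whole matrix
   by `min(matrix) - 1` when the minimum is at or below zero, leaving
   already-positive matrices untouched. Model-based background
   adjustment (e.g. from bead-level controls) requires information a
   downloaded matrix does not carry; the minimum-shift rule is
   deterministic, order-preserving, and recorded in the report's
   config echo. The mode is configurable (`"none"` disables it).
2. **log2 transform**, with an explicit error naming offending
   features if nonpositive values remain.
3. **Quantile normalization.** Every sample is mapped onto the
   reference distribution formed by the row-wise mean of the
   column-sorted matrix, the classical procedure used by array
   pipelines. Ties within a column receive the mean of the reference
   values over their rank span, which makes the operation
   deterministic and idempotent (`limma::normalizeQuantiles` with
   `ties = TRUE` provides exactly these semantics).
4. **Detection filtering.** A probe is *expressed* when its detection
   p-value is strictly below 0.01 in at least one sample — the usual
   Illumina convention; both the threshold and the minimum sample
   count are configurable. Whether the original pipelines filtered
   before or after quantile normalization is rarely documented; we
   filter after, because the filter is rank-based per probe and
   unaffected by the monotone per-column quantile map, while
   normalizing first keeps the reference distribution independent of
   the filter settings.

RNA-seq cohorts distributed as upper-quartile-normalized counts take a
separate branch: `log2(count + 1)` and nothing else, since they arrive
already between-sample normalized.

## The consistency screen

For each cohort and candidate, the screen computes the Spearman
correlation between the candidate's and the anchor's
isoform-collapsed signals on primary-tumor samples. The gene signal is
the unweighted mean of all probes mapping to the gene on the log2
scale (a median option exists); averaging after normalization keeps
the collapse independent of the normalization reference. A cohort
passes for a candidate when `rho >= 0.2` **and** `p <= 0.05`, both
boundaries inclusive. Only positive correlations count by default —
the screen seeks candidates that move with the anchor — with
`require_positive_rho = FALSE` switching to a two-sided magnitude
rule.

Spearman p-values are exact for `n <= 8` by enumeration of all `n!`
rank permutations (valid under ties, since mid-ranks are permuted
wholesale) and use the `t = rho * sqrt((n-2)/(1-rho^2))`
approximation on `n - 2` df otherwise. The alteration arm compares
tumor against normal samples with a two-sided Mann–Whitney test
(exact for small tie-free groups, tie- and continuity-corrected
normal approximation otherwise) and requires the tumor-minus-normal
median shift to point in the configured direction (`down` by
default). With `alteration_direction = "any"`, only each gene's
majority direction accumulates, so a gene that is up in some cohorts
and down in others can never ride both to a verdict.

Verdicts apply a strict-majority rule per arm: a gene is selected
when it passes in strictly more than 50% of its *evaluable* cohorts,
where cohorts that do not measure the gene (platform gaps, detection
filtering) shrink the denominator rather than counting as failures.
This mirrors how such screens are run in practice — a candidate absent
from an older array should not be penalized for the platform.

## Moderated-t differential expression

The perturbation stage fits a per-probe two-group contrast on the
log2 scale: fold change = treated mean − control mean, pooled
within-group variance `s^2` on `n_t + n_c - 2` df. Per-probe variances
are then shrunk toward a prior: assuming
`s^2 ~ s0^2 * chi^2_df / df` given the true variance and a scaled
inverse-chi-square prior with `d0` df and scale `s0^2`, the moments of
`z = log(s^2)` give

- `var(z) = trigamma(df/2) + trigamma(d0/2)`, solved for `d0` by
  Newton inversion of the strictly decreasing trigamma function, and
- `mean(z) = log(s0^2) + digamma(df/2) - log(df/2) + log(d0/2) -
  digamma(d0/2)`, solved for `s0^2`.

When the observed log-variance dispersion does not exceed the
sampling dispersion `trigamma(df/2)`, the prior is degenerate
(`d0 = Inf`) and `s0^2` is the bias-corrected geometric mean.
Zero-variance probes are excluded from the moment fit. The moderated
statistic divides the fold change by the posterior standard error
built from `(d0*s0^2 + df*s^2)/(d0 + df)` and is tested on `d0 + df`
df; `d0 = 0` reduces exactly to the classical pooled t, and the test
suite verifies agreement with an independent implementation
(`limma::eBayes`) to near machine precision. P-values are adjusted by
Benjamini–Hochberg.

Selection is staged deliberately: *significant* probes
(`adj_p < 0.05`) and *fold-change-filtered* probes
(additionally `|linear FC| >= 1.5`) are reported separately, because
workflows differ in whether the fold-change cut defines the DE set or
prunes it; both readings are reproducible from one run. Signed linear
fold changes use the convention `2^lfc` for up and `-2^(-lfc)` for
down, so magnitudes are always at least 1.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X >= k)` of drawing `k` set members in a query of size `n` from a
universe of `N` genes containing `K` members, computed through the
distribution's log-space tail for stability and verified against
brute-force mass summation. The default universe is the set of genes
measured on the platform after detection filtering — the natural
background for an array experiment — and is echoed into the run
report. Gene sets come from user-supplied GMT files; no ontology is
bundled, because bundled ontologies go stale and silently change
results.

## Survival stratification

Prognostic evaluation compares the lowest expression quartile (Q1)
against the pooled remainder. The composite signature is the
unweighted mean of the member genes' log2 signals (the convention
when genes share a platform and scale); a z-scored mean is available
because cross-gene scale differences can otherwise dominate the raw
mean. Q1 contains the samples at or below the type-7
(linear-interpolation) lower quartile, with boundary ties assigned to
Q1 so the low group is never empty — the quantile definition and tie
rule are stated because no convention is universal.

The Kaplan–Meier estimator handles right-censoring with the
events-first convention at tied times. The log-rank (Mantel–Cox) test
accumulates observed and expected events over the pooled risk table,
and the hazard ratio is reported in the O/E form
`(O_Q1/E_Q1)/(O_rest/E_rest)` — the convention of common survival
software for this test — rather than from a Cox fit, because the
workflow reports KM/log-rank quantities only; HR > 1 means the
low-expression group recurs faster. A group with expected but no
observed events yields a divergent HR, reported as `Inf`/`0` with an
explicit flag rather than an arbitrary large number.

## The synthetic world

`simulateCohorts()` emulates exactly the statistical structure the
screen assumes, with defaults chosen to resemble a typical
multi-cohort prostate study: 7 cohorts of 12 normal + 50 tumor
samples, 200 genes with 1–4 isoform probes each (probe = gene signal
plus independent N(0, 0.25) noise), log2 signals N(8, 1), detection
p-values that remove a 5% noise fraction of probes, and one planted
candidate correlated with the anchor at Spearman 0.45, shifted −1
log2 in tumors, and present in 5 of the 7 cohorts (absent cohorts do
not measure it, as with genes missing from older platforms).

Two generator design points deserve emphasis:

- **Correlation calibration.** Target Spearman correlations are
  converted to latent Pearson correlations through the Gaussian
  relation `rho_P = 2 sin(pi * rho_S / 6)` and then inflated by the
  analytic attenuation factor `sqrt(1 + sigma_iso^2/(k sigma^2))` per
  gene, so the *collapsed gene signal* — the quantity every
  downstream analysis consumes — attains the target in population.
- **Sub-seeded streams.** Every (cohort, gene) pair draws from its own
  deterministic sub-seed, so enlarging the gene panel never perturbs
  existing genes' draws, and identical seeds give bit-identical
  worlds.

Survival times follow an exponential proportional-hazards model with
linear predictor `sum(coef_g * z_g)` over standardized collapsed gene
signals (negative coefficients make high expression protective).
Censoring is independent uniform `U(0, u)` with `u` solved
numerically so the expected censored fraction — including truncation
at the maximum follow-up, which also censors — matches the target
rate; the closed-form expected-event probability under exponential
times and uniform censoring makes this calibration exact in
expectation.

What the generator does **not** emulate: platform-specific intensity
distributions, probe GC/affinity effects, batch structure, or
non-proportional hazards. Tests passing on this world therefore
demonstrate the correctness and calibration of the *methods*, not
robustness to every artifact of real cohort data.

## Validation studies and problem sizes

The package's own evaluation (the acceptance script and test suite)
runs four seeded studies, sized to be informative while keeping a
full run in the minutes range:

- **Screen recovery**: 100 seeds of the default 7-cohort world with
  the planted candidate among 15 null candidates; the screen is
  expected to select exactly the planted gene in at least 95% of
  seeds. Under these conditions each present cohort passes the
  correlation arm with probability ≈ 0.9, and the strict-majority
  rule over 5 present cohorts absorbs the remainder.
- **Null calibration**: 5000 null probes (3 + 3 samples) give a raw
  p < 0.05 fraction inside [0.04, 0.06], and 20 seeds of 500-probe
  null experiments give an adjusted-p false-positive rate at or
  below 2%.
- **Prior recovery**: 2000 variances simulated at `d0 = 4`,
  `s0^2 = 0.05`, 4 df return `d0` in [2.5, 6.5] and `s0^2` within
  30%.
- **Composite signature**: 200 cohorts of 130 tumors with two genes
  each protective at 0.5 log-hazard per SD and 50% censoring; the
  mean-signal composite's Q1-vs-rest log-rank p is at or below the
  better single gene's in at least 70% of replicates (the composite
  correlates with the true risk score by `1` vs `1/sqrt(2)` for a
  single gene), and Q1's hazard ratio exceeds 1 in at least 95%.
  This world plants no detection dropouts so both signature genes
  are always measured.

## Known limitations

- The screen treats cohorts independently; there is no cross-cohort
  normalization or meta-analytic weighting, by design — the
  consistency rule *is* the aggregation.
- No multiple-testing correction is applied across screen candidates
  (the per-cohort thresholds plus the majority rule play that role in
  this workflow); the DE stage, in contrast, is FDR-controlled.
- Survival analysis is univariable Q1-vs-rest; no Cox covariate
  adjustment, time-dependent effects, or competing risks.
- qPCR relative quantification fixes the amplification efficiency at
  2 per cycle (configurable) and does not fit standard curves.
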