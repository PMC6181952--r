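# CohortScreen

Multi-cohort consistency screening and prognostic signature evaluation
for cancer transcriptomics.

## What it does, and for whom

Discovery studies in cancer transcriptomics often start from one gene
of interest — a regulator whose loss drives disease — and ask which
other genes move with it, reproducibly, across every public patient
cohort that measured them. CohortScreen packages that workflow for
analysts working with multiple expression cohorts (array or RNA-seq)
plus clinical annotation:

- **Consistency screen.** For an anchor gene *a* and candidate *g*,
  each cohort contributes a Spearman correlation on primary-tumor
  samples and a tumor-vs-normal Mann–Whitney alteration test on the
  isoform-collapsed gene signals. A candidate is selected when
  `rho >= 0.2` and `p <= 0.05` hold in **more than 50%** of its
  evaluable cohorts, and the alteration test (direction-constrained,
  default down in tumors) does too. Cohorts that do not measure a
  gene shrink its denominator instead of counting against it.
- **Perturbation differential expression.** Two-group empirical-Bayes
  moderated t: per-probe pooled variance `s²` on `df` degrees of
  freedom is shrunk toward a scaled-inverse-chi-square prior
  (`d0`, `s0²`) estimated by moment inversion on `log s²`, giving
  `t = Δ / sqrt(s̃²(1/n_t + 1/n_c))` with
  `s̃² = (d0·s0² + df·s²)/(d0 + df)` on `d0 + df` df, then
  Benjamini–Hochberg adjustment and a staged `adj p < 0.05` /
  `|FC| ≥ 1.5` selection.
- **Enrichment.** Upper-tail hypergeometric over-representation of a
  query list against GMT gene sets with BH correction.
- **Survival stratification.** Quartile 1 (low expression) versus the
  rest on a single gene or a mean-signal composite signature:
  Kaplan–Meier curves, log-rank (Mantel–Cox) chi-square, and the O/E
  hazard ratio `(O_Q1/E_Q1)/(O_rest/E_rest)`.
- **Synthetic multi-cohort worlds.** A seeded generator with planted
  correlations, tumor shifts, isoform probes, detection p-values, and
  proportional-hazards survival, so the full pipeline is testable
  without patient data.

Cohorts live in an `ExpressionCohort` (a `SummarizedExperiment` with
an expression assay, optional detection p-values, and clinical
columns), read from plain TSV or GenomeStudio-final-report-style probe
profiles.

## Worked example

Simulate the default seven-cohort world — one candidate correlated
with the anchor at Spearman 0.45 and shifted −1 log2 in tumors,
present in five of the seven cohorts — and screen it against 15 null
candidates:

```r
library(CohortScreen)

world <- simulateCohorts(syntheticConfig(), seed = 7)
world$cohorts[[1]]
#> ExpressionCohort 'cohort1': 506 features x 62 samples [raw_intensity]
#>   tissue_class: normal=12, primary_tumor=50
#>   survival: 50 samples with DFS time, 20 events
#>   detectionP: present

report <- runCandidateScreen(list(
  cohorts = world$cohorts, probe_map = world$probe_map,
  anchor = "ANCHOR", candidates = c("CAND01", sprintf("NULL%04d", 1:15))))
report
#> ScreenReport
#>   candidates screened: 16; selected: CAND01

head(report$verdicts, 3)
#>       gene n_evaluable_corr n_pass_corr n_evaluable_alt n_pass_alt selected
#> 1   CAND01                5           5               5          3     TRUE
#> 2 NULL0003                7           1               7          0    FALSE
#> 3 NULL0007                7           1               7          0    FALSE
```

The planted candidate passes the correlation arm in 5 of its 5
evaluable cohorts and the alteration arm in 3 of 5 (both strict
majorities), so it is selected; the nulls are evaluable in all seven
cohorts and never reach a majority in either arm. The same world
carries survival annotation tied to the candidate's expression
(protective: higher expression, lower hazard), so the low-expression
quartile recurs faster:

```r
ds <- normalizeCohort(world$cohorts[[1]])
stratifyDFS(ds, world$probe_map, "CAND01")
#> Q1 vs rest DFS stratification: n_Q1 = 13, n_rest = 37
#> Log-rank (Mantel-Cox): chi_sq = 7.795 (1 df), p = 0.005239
#>   O = (9, 11), E = (4.05, 15.9), HR (O/E) = 3.22
```

Nine recurrences were observed in the 13 low-expression patients
against 4.05 expected under equal hazards — a hazard ratio of 3.22
for Q1 versus the rest.

See `vignettes/cohort-screening-methods.Rmd` for the model details,
parameter conventions, and the design choices behind the generator.

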