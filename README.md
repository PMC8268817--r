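# mifquant

Quantification and relapse-risk association for multiplex
immunofluorescence (mIF) tissue-microarray studies.

After cell segmentation, an mIF TMA experiment yields one row per cell
with a mean fluorescence intensity per marker. The scientific question
this package serves: does the density of tumor cells co-expressing an
epithelial gate (pan-cytokeratin/E-cadherin, "CK") and a candidate
biomarker (e.g. the antioxidant-response regulator NRF2, or thioredoxin
reductase 1) predict relapse — in particular relapse in the central
nervous system (CNS) — in surgically treated early-stage NSCLC?

The pipeline implements, as tested reusable functions:

* **Mixture thresholding** — per marker, pooled cell intensities are
  modeled as a scaled chi-squared noise component plus a normal signal
  component, $f(x) = \pi_0 f_{\chi^2}(x; k, s) + (1-\pi_0)\,\mathcal N(x;
  \mu, \sigma^2)$, fitted by EM; the positivity threshold sits at the
  intersection of the two weighted densities (the fitted model's Bayes
  boundary).
* **Compartment densities** — CK+ and double-positive cells per mm² per
  patient in tumor, stroma and the whole core, pooling duplicate cores by
  ratio of sums.
* **Dichotomization** — median split (ties low), ROC/Youden exploration
  of alternative cut-offs, SPSS-style adjusted skewness/kurtosis.
* **Association** — cross-product odds ratio with Woolf 95% CI
  ($\exp(\log\mathrm{OR} \pm 1.96\sqrt{\sum 1/n_{ij}})$), uncorrected
  Pearson chi-square, two-sided Fisher exact test, univariate and
  multivariate logistic regression with separation flagging.
* **Survival** — Kaplan–Meier curves and the log-rank test for CNS-relapse
  patients vs everyone else.
* **Synthetic cohorts** — a generator with the same statistical
  structure (duplicate 1-mm cores, mixture intensities, logistic relapse
  link to the true double-positive density), so the whole chain is
  testable without patient data; `paperlike_cohort()` is a study-sized
  preset of 304 patients, 258 of them with known relapse outcome.

## Worked example

Fit the intensity mixture on data with a known truth:

```r
library(mifquant)
set.seed(42)
x <- c(rchisq(7000, df = 2), rnorm(3000, mean = 8, sd = 1.5))
fit_mixture(x)
#> Chi-squared + normal intensity mixture fit
#>   n = 10000 cells, loglik = -21915.026, 67 EM iterations (converged)
#>   noise : pi = 0.702, chi2(df = 2.002, scale = 0.998)
#>   signal: pi = 0.298, normal(mu = 8.018, sigma = 1.501)
#>   threshold = 5.58998
```

The generating values (70% noise, chi-squared df 2, signal N(8, 1.5²))
are recovered, and the threshold lands where the weighted signal density
overtakes the noise.

Run the full pipeline on the study-sized synthetic preset:

```r
res <- run_pipeline(pipeline_config(simulate = list(preset = "paperlike"),
                                    seed = 42))
#> [simulate] 109711 cells / 304 patients
#> [threshold] CK: threshold 6.377 (pi_noise 0.395, converged)
#> [threshold] NRF2: threshold 5.62 (pi_noise 0.713, converged)
#> [threshold] TrxR1: threshold 5.555 (pi_noise 0.692, converged)
#> [densities] 304 patients x 14 columns
#> [cutoff] nrf2_ck_density_whole: median cutoff 43.98 (high 152 / low 152)
#> [associate] nrf2_ck_density_whole vs CNS relapse: OR 7.12 (1.57-32.21)
#> [survival] log-rank p <0.0001

res$contingency$table
#>         outcome
#> exposure FALSE TRUE
#>     low    127    2
#>     high   116   13
odds_ratio(res$contingency$table)
#> OR 7.12 (95% CI 1.57-32.21), log-OR SE 0.7703 [woolf]
```

Among the 258 outcome-complete synthetic patients, 13 of 15 CNS relapses
fall in the high-density half, giving a seven-fold odds ratio whose Woolf
interval excludes 1 (chi-square p 0.0034) — the generating model plants a
logistic effect of the true NRF2+/CK+ density of exactly this size. The
multivariate model retains the density effect (OR 7.52, 95% CI 1.58–35.9)
while age, histology and stage, which are generated independently of
outcome, stay null; a stage level with no events is flagged as separated
and its OR reported as undefined rather than rescued:

```r
res$screens$multivariate[, c("term", "or", "ci_low", "ci_high", "p")]
#>   term                          or ci_low ci_high      p
#> 1 nrf2_ck_density_wholehigh  7.52   1.58    35.9  0.0114
#> 2 age                        1.00   0.930    1.08 0.942
#> 3 histologyadenocarcinoma    0.667  0.219    2.02 0.474
#> 4 stageIB                    0.969  0.174    5.39 0.971
#> 5 stageIIA                  NA     NA       NA    0.999
#> ...
```

Patients relapsing in the CNS have sharply worse overall survival
(log-rank p < 0.0001 under the preset's 12 vs 60 month exponential
medians).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/run_pipeline.R", package="mifquant"))')" \
  --preset paperlike --seed 42 --out report/
```

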