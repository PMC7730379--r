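# spoturine

Monte Carlo simulation of how reliably **spot-urine biomarker
measurements** capture internal exposure to **non-persistent chemicals**
(bisphenols, phthalates, short half-life pesticides), as a function of the
number of urine samples collected and pooled.

It is aimed at exposure scientists and epidemiologists designing
biomonitoring studies — and at reviewers of such designs — who need a
quantitative answer to "how many urine samples are enough?" for a given
chemical, exposure pattern, sampling scheme and dilution standardization.

## What it computes

A simulated population of individuals is exposed orally with log-normal
between-person (GSD $\sigma_b$) and within-person (GSD $\sigma_w$)
variability. Disposition follows a one-compartment model with first-order
absorption and elimination; each dose $D$ at time $t_0$ contributes the
Bateman profile

$$A(t) = D\,\frac{k_a}{k_a - k_e}\left(e^{-k_e (t-t_0)} - e^{-k_a (t-t_0)}\right),$$

superposed in closed form over all exposure events. The "true" exposure
metric is the AUC of $A(t)$ over the exposure window of interest. Urinary
concentrations are generated void by void on realistic synthetic
urination schedules (times, volumes, creatinine, specific gravity), urine
samples are "collected" under the chosen design (random void, first
morning/evening void, or whole-day composite; at most one per day), and
equal-volume pools of 1..n samples are formed. Three reliability surfaces
are reported against the number of samples $n$:

* **R²** of log AUC vs. log pooled mean concentration;
* **tertile/quartile classification accuracy** (% of individuals placed in
  the same exposure quantile by both rankings);
* the **intraclass correlation coefficient** from a balanced one-way
  random-effects ANOVA on log concentrations,
  $\mathrm{ICC} = (MS_B - MS_W) / (MS_B + (k-1) MS_W)$.

## Worked example

Moderately variable exposure to a chemical with a 4-hour half-life, dosed
once daily at a random time, with up to 14 random spot samples over a
14-day window:

```r
library(spoturine)

sc <- scenario(
  biological_half_life = 4,     # hours
  within_gsd = 3, between_gsd = 2,
  window_days = 14, max_samples = 14,
  n_individuals = 500, seed = 2024
)
rep <- run_scenario(sc)
rep
#> <reliability_report>
#>   500 individuals, 14 samples (random_void, none)
#>   R^2        : 0.094 (n=1) -> 0.493 (n=14)
#>   tertiles   : 42.4% (n=1) -> 58.0% (n=14)
#>   quartiles  : 33.6% (n=1) -> 46.6% (n=14)
#>   ANOVA ICC  : 0.114 (k = 14)
```

A single spot sample explains under 10% of the variance in true internal
dose (R² = 0.094) and classifies barely better than chance; pooling four
samples triples the R² (0.275), and fourteen samples reach R² ≈ 0.49 —
the curve is still rising, telling the designer that even two weeks of
daily spots leaves substantial misclassification for so short a half-life.
The ICC of 0.11 says that about 11% of the variance of a single log spot
concentration is between-person signal.

`tidy(rep)` returns the full curve as a tibble, `glance(rep)` a one-row
summary, and `autoplot(rep)` (or `plot_r2()`, `plot_accuracy()`,
`plot_scatter()`) the three result panels. `write_report(rep, dir)` writes
the tables as CSV with a manifest; `export_temporal(rep, i, dir)` exports
one individual's intake and void-by-void concentration series.

Scenarios can live in YAML files (`read_scenario()` /
`write_scenario()`), real urination diaries can replace the synthetic
schedule bank (`read_schedules()`), and
`inst/cli/spoturine.R` is a command-line front end mirroring every
scenario field:

```sh
Rscript inst/cli/spoturine.R --config scenario.yml --out-dir results/
```

See the vignette `vignettes/reliability-methods.Rmd` for the model,
the synthetic urination-schedule generator, and the reasoning behind the
design choices.

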