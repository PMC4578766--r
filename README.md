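# growthbayes

Bayesian fitting and comparison of bacterial growth curves.

Microbiologists routinely need to decide whether two growth curves —
different strains, media, temperatures — have different maximum specific
growth rates. With few, noisy viable-count measurements that decision is
hard: point-estimate fits overstate certainty, and small rate differences
drown in the noise. `growthbayes` addresses this with a fully Bayesian
treatment of the four-parameter Baranyi–Roberts growth model

$$
y(t) = y_0 + \mu_{\max} A(t)
  - \ln\!\left(1 + \frac{e^{\mu_{\max} A(t)} - 1}{e^{y_{\max}-y_0}}\right),
\qquad
A(t) = t - \frac{h_0}{\mu_{\max}}
  + \frac{\ln\!\left(1 - e^{-\mu_{\max} t} + e^{-(\mu_{\max} t - h_0)}\right)}
         {\mu_{\max}},
$$

with parameters $y_0$, $y_{\max}$ (initial/maximum log concentration),
$\mu_{\max}$ (maximum specific growth rate) and $h_0 = \lambda\mu_{\max}$
(lag parameter). The package:

* computes the **model evidence** $Z = \int \mathcal{L}\,\pi\,d\mathbf{p}$
  and weighted posterior samples by **nested sampling**, with the noise
  level $\sigma$ inferred under a Jeffreys prior (or prescribed) and
  below-detection observations handled by a uniform-below-threshold
  likelihood;
* compares a pair of curves through **Bayes factors** over three
  hypotheses — H1: replicates; H2: same growth rate, all else free;
  H3: nothing shared — read on **Jeffreys' scale**, declaring rates
  different on substantial evidence ($2\ln B_{32} \ge 2$);
* builds **informative Gaussian or Cauchy priors for the growth rate from
  clusters of previously analysed curves** via the law of total variance,
  which improves detection of small rate differences in noisy data;
* provides the classical **F-test** on separated (8-parameter) vs unified
  (7-parameter, shared rate) least-squares fits as a frequentist baseline;
* ships simulation drivers (`perturbation_sweep()`,
  `detection_comparison()`, `cluster_ranking_sweep()`) that measure
  detection power and prior effects on synthetic curves.

Everything user-facing is tidyverse-shaped: curves are tibbles, fitted
objects have `tidy()`, `glance()` and `autoplot()` methods, and the
experiment drivers return tibbles ready for dplyr/ggplot2.

## Worked example

Simulate a viable-count-like curve (six-decade rise, rate 0.11 log10/h,
noise 0.1) and fit it:

```r
library(growthbayes)

curve <- simulate_growth_curve(growth_params(y0 = 3, mu_max = 0.11,
                                             h0 = 1, ymax = 9),
                               sigma = 0.1, seed = 42)
fit <- growth_fit(curve, config = ns_config(seed = 1))
fit
#> Bayesian growth-curve fit (baranyi model, inferred noise)
#> Nested sampling: ln Z = 4.7641 +/- 0.4098 (H = 16.79 nats, 3296 iterations)
#>      term   estimate  std.error
#>        y0  3.0386850 0.07460448
#>    mu_max  0.1060036 0.00176444
#>        h0  0.8314269 0.24593348
#>      ymax 10.2398752 0.76738978
#>     sigma  0.1214160 0.01624535
#>  lag_time  3.4296925 0.97578052
```

`ln Z` is the log evidence with its nested-sampling uncertainty; the table
gives posterior means and standard deviations on the log10 scale. The
generating values (3, 0.11, 1, 9, σ = 0.1) are recovered within their
posterior uncertainty; the lag time (hours) is derived from the posterior
draws of `h0` and `mu_max`. `autoplot(fit)` overlays posterior trajectories
on the data.

Compare against a curve growing twice as fast (0.22 log10/h):

```r
fast <- simulate_growth_curve(growth_params(3, 0.22, 1, 9),
                              t_max = time_to_fraction(growth_params(3, 0.11, 1, 9), 0.95),
                              sigma = 0.1, seed = 7)
cmp <- compare_growth_rates(curve, fast, config = ns_config(seed = 1))
cmp
#> Bayesian growth-rate comparison
#>  hypothesis log_evidence log_evidence_sd information n_iterations converged
#>          H1   -102.45166       0.3559132    12.66742         2912      TRUE
#>          H2    -55.24098       0.4966654    24.66765         4316      TRUE
#>          H3      8.22927       0.6335045    40.13280         5954      TRUE
#>
#> 2 ln B (row vs column):
#>        H1     H2      H3
#> H1   0.00 -94.42 -221.36
#> H2  94.42   0.00 -126.94
#> H3 221.36 126.94    0.00
#>
#> Verdict: growth rates judged different (2 ln B32 = 126.94, very strong)

growth_f_test(curve, fast, seed = 1)
#> F-test for equal growth rates: F = 702.9 on (1, 57) df, p = 9.522e-34
#> Growth rates differ at the 0.05 level.
```

H3 (independent parameters) wins by a huge margin — `2 ln B32 = 126.9`,
far beyond the "very strong" band — and the F-test agrees. With small rate
differences and noisy data the two methods diverge, and cluster-derived
priors (`cluster_prior()`, passed as `mu_prior =`) tip the balance; the
methods vignette (`vignettes/growth-rate-comparison.Rmd`) describes the
model, priors and sampler in detail.

Command-line wrappers mirroring the two main workflows live in
`inst/scripts/`: `bayesfit.R` (single-curve inference), `bayescompare.R`
(pair comparison + F-test) and `growthsim.R` (the simulation drivers),
all `Rscript`-runnable with `--config`/`--seed`/`--out` options.

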