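---
title: "Bayesian comparison of bacterial growth rates: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian comparison of bacterial growth rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(growthbayes)
```

## The growth model

Bacterial batch cultures pass through a lag phase, an exponential phase and
a stationary phase. `growthbayes` describes the log cell concentration
$y(t) = \ln x(t)$ with the four-parameter Baranyi–Roberts model

$$
y(t) = y_0 + \mu_{\max} A(t)
  - \ln\!\left(1 + \frac{e^{\mu_{\max} A(t)} - 1}{e^{y_{\max} - y_0}}\right),
\qquad
A(t) = t - \frac{h_0}{\mu_{\max}}
  + \frac{\ln\!\left(1 - e^{-\mu_{\max} t} + e^{-(\mu_{\max} t - h_0)}\right)}
         {\mu_{\max}},
$$

where $y_0$ and $y_{\max}$ are the initial and maximum log concentrations,
$\mu_{\max}$ is the maximum specific growth rate (per hour) and $h_0 =
\lambda\,\mu_{\max}$ is a dimensionless lag parameter ($\lambda$ is the lag
time in hours). The adjustment function $A(t)$ is close to zero during lag
and approaches $t - \lambda$ afterwards, so the model interpolates smoothly
between the three phases.

Two numerical points matter in practice:

* **Scales.** The equations are written on the natural-log scale, but
  viable-count data and parameters are conventionally reported on the
  log10 scale. The package computes internally on the natural-log scale
  and converts at the boundary: concentrations, $y_0$, $y_{\max}$ and
  $\mu_{\max}$ scale by $\ln 10$; $h_0$, being dimensionless, does not.
  One consequence worth stating explicitly: for log10-scale parameters the
  lag time is $\lambda = h_0 / (\mu_{\max}^{(10)} \ln 10)$. Everything
  user-facing (data files, priors, reported posteriors) is log10.
* **Stability.** Both interior logarithms are rewritten in log-sum-exp
  form, so predictions remain finite and accurate for $\mu_{\max} t$ well
  past 700 — far beyond the overflow point of the naive expressions. This
  is exercised directly in the test suite.

Restricted variants are exposed as parameter restrictions of the same
equations: no lag ($h_0 = 0$, 3 parameters), no stationary phase
($y_{\max} \to \infty$, 3 parameters) and pure exponential growth
(2 parameters). They share all code paths with the full model.

## The likelihood

Viable-count concentrations are obtained by serial dilution, so
measurement errors are multiplicative: errors in $x$ are log-normal and
errors in $y = \log_{10} x$ are Gaussian. The likelihood of a curve with
$N$ points is therefore Gaussian on the log10 scale with a single constant
noise level $\sigma$:

$$
\log \mathcal{L} = -N \log(\sigma\sqrt{2\pi})
  - \frac{1}{2\sigma^2} \sum_{i=1}^N (d_i - y_i)^2 .
$$

$\sigma$ may be prescribed (`noise = "fixed"`) or, recommended, inferred
as an extra parameter under the scale-invariant Jeffreys prior
$\pi(\sigma) \propto 1/\sigma$.

**Below-detection observations.** Plate counts below the detection limit
$T$ (typically 0.7 or 1.3 log10 units, depending on assay sensitivity)
carry only the information that the concentration is somewhere in
$[0, T]$. Such points contribute a uniform density $1/T$ whenever the
model prediction is at or below $T$. A hard zero above $T$ would make the
log-likelihood singular, so a small Gaussian tail is attached instead:
$\log(1/T) - (y - T)^2 / (2\tau^2)$ for $y > T$. The tail width defaults
to $\tau = 0.05$ log10 units — well below typical viable-count noise — so
it acts as a soft barrier rather than a data term. The factor is left
unnormalized on purpose: it is a regularisation device, not a density.

**Pairs of curves.** Two curves are independent given their parameters, so
the joint log-likelihood is a sum. Within each hypothesis a single
$\sigma$ is shared across both curves; whether the noise level should be
per-curve is genuinely open, and the shared choice keeps the hypothesis
spaces minimal (a per-curve extension would only add one parameter to H3).

## Priors

With no prior knowledge, every parameter gets a uniform prior whose bounds
scale with the data (observed range $r = d_{\max} - d_{\min}$, floored at
1 for degenerate curves, and time span $T_s$):

| parameter | bounds |
|---|---|
| $y_0$ | $[d_{\min} - r/2,\; d_{\max}]$ |
| $y_{\max}$ | $[d_{\min},\; d_{\max} + r/2]$ |
| $\mu_{\max}$ | $(10^{-6},\; 10\,r/T_s]$ |
| $h_0$ | $[0,\; \mu_{\mathrm{upper}}\, t_{\max}]$ |
| $\sigma$ | Jeffreys on $[10^{-3},\; r]$ |

The $10^{-6}$ floor on $\mu_{\max}$ keeps the adjustment function
well-defined; the joint constraint $y_{\max} > y_0$ is enforced by
assigning zero prior mass (the sampler simply rejects such points) rather
than by reparameterising — simpler, and it keeps the per-parameter bounds
independent.

**Cluster-informed priors.** When curves measured under similar conditions
have already been analysed, their inferred rates $(\mu_i, \sigma_i^2)$ can
inform the prior for a new curve's $\mu_{\max}$. The cluster is summarised
by the law of total variance:

$$
\mu_{\mathrm{cluster}} = \frac{1}{N}\sum_i \mu_i, \qquad
\sigma_{\mathrm{cluster}}^2 = \frac{1}{N}\sum_i \mu_i^2
  - \Big(\frac{1}{N}\sum_i \mu_i\Big)^2 + \frac{1}{N}\sum_i \sigma_i^2 ,
$$

i.e. the spread of the member means plus the mean member uncertainty.
These moments parameterise either an informative Gaussian or a weakly
informative, heavy-tailed Cauchy prior. No rule fixes the Cauchy scale, so
the package uses $\sqrt{\sigma_{\mathrm{cluster}}^2}$ for both — the two
priors then differ only in tail weight, which is exactly the contrast of
interest. Informative entries are truncated to the data-scaled default
bounds and renormalised over the truncation interval, so evidences under
different priors remain comparable.

All priors are specified through their inverse CDF (a map from the unit
hypercube), which is also how the sampler explores them.

## Nested sampling

The model evidence $Z = \int \mathcal{L}(\mathbf{p})\,
\pi(\mathbf{p})\,d\mathbf{p}$ is computed by nested sampling: an active
set of $n$ live points drawn from the prior is evolved by repeatedly
removing the point with the lowest likelihood $L^*$ and replacing it with
a fresh prior draw constrained to $\mathcal{L} > L^*$. Sorting by
likelihood turns the multidimensional integral into a one-dimensional one
over prior mass $X$, approximated as $Z \approx \sum_k h_k L_k$ with
$h_k = X_{k-1} - X_k$.

Design choices, all surfaced in `ns_config()`:

* **Shrinkage.** The deterministic schedule $X_k = e^{-k/n}$ (the
  expectation of the shrinkage factor) rather than sampling it; standard,
  simple, and the bookkeeping identity $\sum_k h_k + X_{\mathrm{final}} = 1$
  is tested to $10^{-9}$.
* **Termination.** The run stops when the largest possible remaining
  contribution, $\max(L_{\mathrm{live}})\,X_k$, falls below `tolerance`
  (default $10^{-6}$) times the accumulated $Z$; the remaining live points
  are then folded in with equal widths $X_{\mathrm{final}}/n$. Hitting the
  iteration cap instead is flagged (`converged = FALSE`), never silent.
* **Constrained draws.** A Metropolis random walk in the unit cube (where
  the prior is uniform by construction), started from a uniformly chosen
  surviving live point; proposals at or below $L^*$ are rejected and the
  walk is reflected at the cube boundary. The step size adapts between
  iterations toward an acceptance rate in $[0.2, 0.6]$ and is frozen
  within each walk. Defaults: $n = 100$ live points, 20 walk steps.
* **Numerics.** All evidence accumulation is in log space via
  log-sum-exp; the reported uncertainty is $\sqrt{H/n}$ with $H$ the
  information. A repeated-run check in the test suite confirms the
  empirical spread of $\ln Z$ is within a factor two of this estimate.
* **Reproducibility.** Every source of randomness flows from the seed in
  `ns_config()`; seeded runs are bit-for-bit reproducible and the caller's
  RNG state is restored.

Posterior summaries use the weighted samples directly
($\mathrm{mean} = \sum_k w_k p_k$, $w_k = h_k L_k / Z$); staircase
resampling converts them to equally weighted draws for trajectory plots
and derived quantities such as the lag time.

## Comparing growth rates

For a pair of curves three hypotheses are scored by evidence: H1 — the
curves are replicates (one shared parameter set); H2 — the curves share
$\mu_{\max}$ but nothing else; H3 — no shared parameters. With equal prior
probabilities the posterior odds reduce to the Bayes factor
$B_{ij} = Z_i / Z_j$, read on Jeffreys' scale for $2\ln B$: 0–2 hardly
worth mentioning, 2–6 has some substance, 6–10 strong, above 10 very
strong. The package declares the rates *different* when there is
substantial evidence for H3 over H2, i.e. $2 \ln B_{32} \ge 2$. H1 is
scored as well (when requested) because ranking all three hypotheses is
often informative — e.g. true replicates should rank H1 first purely by
the Occam penalty on the extra parameters.

Under H2 the per-curve parameters take each curve's own data-scaled
bounds, and the shared rate takes the union of the two curves' rate
bounds. When cluster priors are supplied for a comparison, each curve's
rate under H3 uses its own cluster, and the shared rate under H1/H2 uses
the pooled members of both clusters — a deliberate choice: pooling is the
natural "the rates are the same" counterpart of the two per-curve priors.

**The F-test baseline.** Both curves are fitted by least squares under a
*separated* model (two independent 4-parameter fits) and a *unified* model
(7 parameters, shared rate), using multistart `nlminb` within the default
bounds (a data-driven heuristic start plus random starts, best of 10). The
statistic is

$$
F = \frac{\sum_i (y_i^u - y_i^s)^2}
         {\sum_i (d_i - y_i^s)^2 / (N_1 + N_2 - 1)},
$$

referred to $F(1,\, N_1 + N_2 - 7)$, rejecting at $p < 0.05$. Note the
denominator divisor $N_1 + N_2 - 1$: this is implemented exactly as
printed in the formulation this package follows, although a conventional
extra-sum-of-squares test would divide the residual sum by $N - 8$. The
conventional form, $((SSR_u - SSR_s)/1)/(SSR_s/(N-8))$ on
$F(1, N - 8)$, is available behind `conventional = TRUE` for users who
prefer it; at the curve sizes involved the two differ little.

## The synthetic-data generator

`simulate_growth_curve()` places `n_points` observations on an even grid
over $[0, t_{\max}]$, evaluates the model, and adds i.i.d. Gaussian noise
on the log10 scale; values below an optional detection threshold are
flagged censored. Defaults emulate a viable-count experiment: $y_0 = 3$,
$y_{\max} = 9$ log10 cfu (a six-decade rise), $h_0 = 1$,
$\mu_{\max} = 0.11$ log10 units/h, 32 points, and a horizon reaching 95 %
of the rise (about 66 h at the default rate). Noise levels of interest
span 0.05–0.8 log10 units. These values were fixed once, as what a
predictive-microbiology practitioner would call realistic, and are not
tuned per experiment.

What the generator does *not* emulate: correlated errors between
neighbouring time points, heteroscedastic noise (e.g. larger errors near
the detection limit), irregular sampling grids, and replicate-plate
structure. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the machinery under the stated error
model, not robustness to real-data pathologies outside it.

The three experiment drivers reproduce the package's study designs at
desk scale: `perturbation_sweep()` (one fixed curve at rate 0.11, the
second regenerated per replicate at increasing rate offsets, reporting
mean and sd of $\ln B_{23}$), `detection_comparison()` (percent-correct of
the F-test and of Bayes factors with uniform or cluster-informed priors
across noise levels; prior-knowledge clusters are built from four
previously analysed curves simulated at rates within $\pm 0.01$ of each
curve's own rate at noise 0.1), and `cluster_ranking_sweep()` (evidence
under uniform/Gaussian/Cauchy priors as a target curve's rate moves
between a cluster at 0.09–0.11 and one at 0.15–0.17). Every emitted row
carries its generating configuration, and the whole table is reproducible
from the top-level seed.

## Problem sizes and runtimes

The test suite and the bundled `scripts/acceptance.R` run everything at
desk scale, chosen so a full check completes on a single CPU in well under
an hour: toy-evidence checks at $n_{\mathrm{live}} = 400$ over 20 seeds,
parameter recovery over 20 seeded fits at $n_{\mathrm{live}} = 100$,
detection experiments with 10–20 replicates per condition at
$n_{\mathrm{live}} = 75$, and 50–200 simulated pairs for the F-test's
type-I error. Larger replicate counts sharpen the Monte-Carlo estimates
but do not change the directions tested.

## Known limitations

* The constrained walk is a simple random-walk sampler; strongly
  multimodal likelihoods (not typical for sigmoidal growth fits) would
  need many more walk steps or a smarter constrained sampler.
* Evidence values carry the usual $O(\sqrt{H/n})$ nested-sampling noise;
  single comparisons near the decision boundary ($2\ln B_{32} \approx 2$)
  should be repeated over seeds, as the experiment drivers do.
* The censored-point factor is unnormalized above the threshold (by
  design); evidences of models that place substantial posterior mass in
  the tail region should be interpreted with care.
* One $\sigma$ is shared across the two curves of a comparison; curves
  with genuinely different noise levels are better compared after
  per-curve inspection with `growth_fit()`.
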