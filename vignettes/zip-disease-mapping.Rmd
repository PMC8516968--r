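---
title: "Zero-inflated Poisson disease mapping with CAR spatial priors"
author: "spzip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflated Poisson disease mapping with CAR spatial priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spzip)
```

## The problem

Routine surveillance of childhood pneumonia (and many other notifiable
diseases) produces monthly case counts per small administrative area,
stratified by age group and sex, together with district-level climate
series and yearly population denominators. Three features dominate such
panels: a large excess of zero counts (many area-month strata report no
cases at all), strong seasonality linked to climate, and spatial
heterogeneity between areas that covariates only partly explain. `spzip`
implements a complete analysis pipeline for data of this shape:
descriptive incidence and standardized morbidity ratios, seasonal-trend
decomposition, climate covariate screening, and a family of Bayesian
zero-inflated Poisson (ZIP) hierarchical models with spatial random
effects, fitted by Markov chain Monte Carlo and compared by the deviance
information criterion (DIC).

Because the surveillance records this model class is designed for are
typically confidential and not redistributable, the package ships a
first-class synthetic-data generator with known ground truth. Every
stage of the pipeline is exercised and tested against data whose
generating parameters are known exactly.

## The model

For area $i$, month $j$ and stratum (age group $a$, sex $g$), the
observed count is a ZIP mixture

$$P(Y = y) = \begin{cases}
\omega + (1-\omega) e^{-\mu}, & y = 0\\
(1-\omega) e^{-\mu} \mu^{y} / y!, & y > 0
\end{cases}$$

with Poisson mean $\mu = E \, e^{\theta}$, where $E$ is the expected
count of the stratum under internal standardization (the overall rate,
total cases over total person-months, times the stratum person-months;
by construction $\sum E = \sum y$), and $\theta$ is the log relative
risk

$$\theta = \alpha + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} +
\beta_3\,\mathrm{trend}_j + \beta_4\,\mathrm{altitude}_i +
\beta_5\,\mathrm{rainfall}_{ij} + \beta_6\,\mathrm{humidity}_{ij} +
\beta_7\,\mathrm{tempmax}_{ij} + u_i + s_i + \delta_i\,
(\mathrm{trend}_j - \overline{\mathrm{trend}}).$$

Covariates carry reporting-convention units: altitude in 100 m,
rainfall in 10 mm, relative humidity in 10 % (lagged three months by
default), maximum temperature in °C. Indicators: age 1 = under-5 (5–14
reference), sex 1 = female (male reference). Three variants differ in
the area effects: Model I has the exchangeable (unstructured) effect
$u_i \sim N(0, 1/\tau_u)$ only; Model II the intrinsic conditional
autoregressive (ICAR) spatially structured effect $s_i$ only; Model III
(convolution, BYM-type) both. All three carry per-area trend slopes
$\delta_i$ — the spatio-temporal component — so each area's burden may
rise or fall relative to the overall monthly trend $\beta_3$.

The ICAR prior is defined through the pairwise-difference kernel
$-(\tau_s/2)\sum_{i \sim k}(s_i - s_k)^2$ over queen-contiguity
neighbour pairs (areas sharing any boundary point, including a single
corner; binary weights). Each area's full conditional is Gaussian around
its neighbours' mean with variance $1/(\tau_s m_i)$.

### Priors and identifiability conventions

* intercept: effectively flat (normal with precision $10^{-10}$);
* coefficients: vague normal, mean 0, precision $10^{-5}$;
* $\omega$: uniform on $(0,1)$, i.e. Beta(1, 1) — a single shared
  scalar. The extra-zero probability is reported once per model, so a
  stratum-specific $\omega$ is not identifiable at this reporting
  granularity and is not attempted;
* random-effect precisions $\tau_u, \tau_s, \tau_w$: gamma with shape
  0.5 and **rate** 0.001 (the parameterization used by the BUGS family
  of samplers, where this prior is conventional for CAR models).

The ICAR prior is improper along constants, so $s$ is recentred to mean
zero after every sweep with the mean absorbed into the intercept
($\theta$ unchanged). The trend slopes $\delta$ are likewise recentred
with the mean absorbed into $\beta_3$; consequently $\delta_i = 0$ *is*
the national-average trend, and exceedance probabilities
$P(\delta_i > 0)$ classify areas against that baseline directly. In
Model I, $\delta$ has an exchangeable Gaussian prior constrained to the
sum-to-zero subspace, and its precision update uses $n-1$ degrees of
freedom accordingly; in Models II/III, $\delta$ has an ICAR prior (rank
$n$ minus the number of non-singleton graph components). Areas with no
neighbours (islands) receive an independent zero-mean Gaussian with the
structured precision, keeping the prior proper per island.

The trend covariate is the raw month index in the assembled design and
is centred at its midpoint inside the sampler (centring affects only the
intercept, which the posterior summary reports back in the uncentred
frame). Centring removes the strong intercept–slope posterior
correlation that otherwise cripples random-walk updates.

## The sampler

`fit_zip()` runs a Metropolis-within-Gibbs scheme (C++ core, R front
end), one chain per `mcmc_config()$chains`:

1. latent structural-zero indicators $z$ at observed zeros: Gibbs,
   Bernoulli with $p = \omega / (\omega + (1-\omega)e^{-\mu})$;
2. $\omega \mid z$: Gibbs, Beta$(1 + \sum z, 1 + n - \sum z)$;
3. $\alpha$ and each $\beta_k$: adaptive random-walk Metropolis on the
   strata currently assigned to the Poisson component;
4. each $u_i$, $s_i$, $\delta_i$: per-area random-walk Metropolis with
   the appropriate Gaussian/ICAR prior term;
5. precisions: gamma Gibbs updates;
6. recentring of $s$ and $\delta$ as above.

Proposal standard deviations adapt toward a 0.44 acceptance rate in
windows of 50 iterations during burn-in and are frozen afterwards, so
the retained draws come from a fixed-kernel chain; a warning is raised
if any fixed-effect acceptance rate leaves $[0.1, 0.6]$ after
adaptation.

Two extra *translation moves* walk along exact likelihood ridges and are
accepted on the prior ratio alone (the likelihood is invariant):
$(\alpha, u) \to (\alpha + c,\, u - c)$, and for the altitude
coefficient — a per-area-constant covariate that the free area effects
can absorb entirely — $(\beta_4, u_i) \to (\beta_4 + c,\, u_i - c\,
\mathrm{alt}_i)$ (or the analogous move on $s$ in Model II). Without
these, the intercept and altitude coefficient mix an order of magnitude
more slowly; with them, their potential scale reduction factors drop
from about 2.0 and 1.6 to below 1.02 in desk-scale runs.

The per-draw deviance is the *marginal* ZIP deviance
$-2\sum \log \mathrm{ZIP}(y \mid \mu, \omega)$ over all strata (the
augmentation variable is integrated out), and
`dic()` computes $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\text{posterior means of all parameters, including }
\omega \text{ and the area effects})$. Convergence reporting uses the
two-part Gelman–Rubin statistic (floored at 1; values below 1 are
sampling noise) with a pass rule of $\hat R < 1.05$ on the intercept,
coefficients, $\omega$ and precisions, falling back to Geweke z-scores
for single chains; effective sample sizes use the AR-spectral estimator.

### Degenerate inputs and numerical conventions

* `mcmc_config(iterations = burnin)` is rejected: no retained draws.
* `assemble_design()` refuses to run on an already-assembled design, so
  unit scalings can never be applied twice; rows are ordered
  (area, month, age, sex) so results are bit-reproducible under a seed.
* A lag of $k$ months drops the first $\max(k)$ months from fitting;
  covariate screening drops the same window at every lag so AICs are
  comparable across the lag grid. Ties in the lag selection break toward
  the smaller lag.
* Perfectly collinear screening covariates yield an infinite VIF rather
  than an error; constant covariates are rejected.
* Quantile credible intervals are equal-tailed; relative-risk interval
  endpoints are the exponentials of the coefficient endpoints (exact
  monotone-transform equivariance). Significance is "the RR interval
  excludes 1". Exceedance probabilities split ties at exactly zero
  evenly, so degenerate all-zero draws give 0.5.
* The seasonal decomposition logs the series as $\log(y + 1)$ because
  sub-national monthly slices can contain zero counts; the additive
  identity seasonal + trend + remainder = logged series holds to
  machine precision by construction.

## The synthetic-data generator

`make_lattice()` builds a rectangular grid of unit-square areas grouped
into contiguous district blocks — an abstract stand-in for an
administrative map of sub-districts nested in districts (a real map of
20 districts and 205 sub-districts is the scale the model family
targets; tests use smaller lattices). `simulate_climate()` produces
district-shared seasonal series: sinusoidal maximum temperature,
offset-sinusoidal relative humidity clamped to $[0,100]$ %, and
exponentiated-sinusoid rainfall (non-negative, monsoon-like). Climate
is constant across the areas of a district, mirroring how district-level
weather stations are broadcast to sub-districts in practice.
`simulate_populations()` draws log-normal area child populations
(median 900, log-sd 0.5) split 30 % / 70 % between under-5 and 5–14 —
the approximate ratio seen in national child population tables — and
50/50 by sex. `simulate_altitude()` draws per-area altitudes uniformly
over 75–7000 m, a Himalayan span.

`simulate_counts()` inverts the fitted model: it computes $\theta$ from
a `ground_truth()` over the same unit-scaled covariates the fit uses,
sets $\mu = E\, e^{\theta}$ with $E$ = `base_rate` × stratum population,
draws a structural zero with probability $\omega$, otherwise a Poisson
count. The realized structural-zero indicators are returned — they are
never observable in real data, but they let tests check the
augmentation sampler against the truth. For the first `lag` months the
lagged humidity value is clamped to month 1; those months are dropped at
fitting time, so the clamp never enters inference.

Default ground truth: $\alpha = -2.28$, $\beta$ = (2.658, −0.120,
−0.00343, 1.32e−5, 7.67e−4, −1.25e−3, 0.0131), $\omega = 0.169$ — a
strong under-5 excess (RR ≈ 14), a small female deficit, a slow monthly
decline, weak climate effects. Unstructured heterogeneity uses variance
1.694 on the log-risk scale. The area trend slopes use sd 0.003 per
month: a published trend-heterogeneity summary for this model class
(0.188) does not state its scale, and read as a monthly-slope variance
it would imply implausible order-of-magnitude risk swings within a few
years, so the generator instead chooses a slope spread commensurate with
the mean trend itself ($|\beta_3| \approx 0.0034$), which yields a
realistic mix of clearly rising, clearly falling and indeterminate
areas. `base_rate = 0.0032` per child-month calibrates the generated
panels to roughly 72 % zero strata at the default truth, the zero
fraction characteristic of sub-district childhood-pneumonia panels.

What the generator does *not* emulate: real topography or climate
magnitudes calibrated to any particular country, reporting
completeness artifacts, overdispersion beyond the ZIP mixture,
month-to-month population change (denominators are constant within a
year, as yearly population estimates imply), or health-seeking
behaviour. Passing recovery tests therefore demonstrates that the
sampler inverts its own generative model at surveillance-like scale —
not that the model is adequate for any particular real dataset.

## Study sizes used by the tests and the acceptance script

The package's experiments run at deliberately desk-sized scales chosen
to keep the full suite in minutes while leaving each check
well-powered: recovery and acceptance use a 40-area × 48-month × 4-strata
panel (7,200 modelled strata after lag truncation) with the
desk-scale sampler defaults (5,000 burn-in, 20,000 iterations, thin 5,
2 chains); replicate experiments (credible-interval coverage over 20
panels, DIC model choice over 10) use shorter single chains; the
known-truth trend-classification experiment uses a 72-month window so
that ±0.02/month slopes are detectable at the 95 % exceedance
threshold. The production-scale protocol for this model family (10,000
burn-in, ~100,000 iterations) remains available through
`mcmc_config()`.

## Known limitations

* The altitude coefficient (any per-area-constant covariate) is
  identified only through the random-effect prior; its posterior mostly
  reflects the realized correlation between the area effects and
  altitude. The translation moves make the sampler honest about this
  uncertainty but cannot create information that is not there.
* DIC differences between Models I and III are small by construction —
  an exchangeable effect can absorb a structured one — and the
  preference manifests mainly through the effective-parameter count.
  Expect single-digit DIC gaps on desk-scale panels.
* Humidity and maximum temperature are seasonally collinear; their
  individual coefficients mix more slowly than the rest (this is the
  motivation for the VIF screen in the covariate module).
* `queen_contiguity()` detects boundary contact by segment distance with
  a tolerance; GeoJSON inputs whose nominally shared borders are
  digitized further apart than the tolerance need an explicit
  neighbour list (`read_adjacency()`), which bypasses geometry entirely.
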