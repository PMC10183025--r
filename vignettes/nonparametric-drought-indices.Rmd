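---
title: "Nonparametric daily drought indices: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric daily drought indices: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtsdi)
```

## The model

A standardized drought index (SDI) answers one question: *how unusual
are today's conditions for this site and this time of year?* For a
variable $X$ (aggregated precipitation, climatic water balance, or soil
moisture), fix a calendar day and collect the cross-year sample
$x_1,\dots,x_n$ — one value per year of record. The sample's
distribution is estimated nonparametrically with a Gaussian kernel:

$$\hat f(x) = \frac{1}{n h}\sum_{i=1}^{n}\frac{1}{\sqrt{2\pi}}
  \exp\!\left[-\frac{(x-x_i)^2}{2h^2}\right],$$

whose cumulative distribution $\hat F$ is available in closed form as a
mean of normal CDFs. The non-exceedance probability $\hat F(x)$ of the
target day's value is mapped to the standard-normal score with the same
probability (the equiprobability transformation), so that $-1.28$
always means "drier than 90% of years", whatever the shape of the local
climate. Avoiding a parametric family (gamma, log-logistic, ...) avoids
the long-debated risk of fitting the wrong one; the price is a
bandwidth choice and mildly biased tails (see *Known limitations*).

### Bandwidth selection

The bandwidth $h$ minimizes the least-squares cross-validation
criterion

$$\mathrm{CV}(h) = \int \hat f(x\mid h)^2\,dx
  - \frac{2}{n}\sum_{i=1}^n \hat f_{-i}(x_i \mid h),$$

with $\hat f_{-i}$ the leave-one-out estimator (divisor $n-1$). For
Gaussian kernels both terms are closed-form sums over pairwise
differences — the squared-density integral is a normal-density sum at
scale $h\sqrt 2$ — which the package exploits (`cv_score()` is exact,
vectorized over $h$, and verified against trapezoid integration to
$10^{-6}$). The minimizer is found on a 101-point log-spaced grid
spanning $[h_S/10,\,10\,h_S]$ around Silverman's rule
$h_S = 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$, refined by
golden-section search: deterministic and derivative-free. The search
runs on the standardized sample, which makes the selected bandwidth
exactly scale-equivariant — downstream index values are invariant under
rescaling the input units. When the CV curve has no interior minimum
(small or heavily tied samples), the selector falls back to $h_S$ and
tags the model `silverman-fallback`.

### Zero precipitation

Kernels leak probability mass across the $x \ge 0$ boundary, and daily
or short-window precipitation has a genuine atom at zero. Both problems
are handled by the mixture

$$F_{\mathrm{prec}}(x) = q + (1-q)\,\hat F_{+}(x),$$

where $q$ is the empirical dry fraction of the sample and
$\hat F_{+}$ is fitted on the strictly positive values only. All dry
days share the single probability $q$ — so the driest attainable SPI on
a dry day is bounded, the familiar zero-mass floor of the SPI. The
wet-day threshold is configurable (`wet_threshold`, default exactly
0 mm: drizzle counts as wet).

### Normal-score transformation

Probabilities become scores through the classical rational
approximation of the normal quantile (coefficients $C_0 = 2.515517$,
$C_1 = 0.802853$, $C_2 = 0.010328$, $d_1 = 1.432788$,
$d_2 = 0.189269$, $d_3 = 0.001308$), mirrored about $F = 0.5$ so that
$F < 0.5$ gives negative scores. Its absolute error is below
$4.5\times10^{-4}$, well inside any classification boundary. The sign
convention — *dry = negative* — is fixed by the drought-category tables
(an extreme drought is $\mathrm{SDI} < -2$); the package states it once
here and applies it everywhere.

Because a finite sample cannot support probabilities arbitrarily close
to 0 or 1, $\hat F$ is clipped to $[\tfrac{1}{2(n+1)},
1-\tfrac{1}{2(n+1)}]$ before transformation. With $n = 72$ years the
index is thereby bounded to about $\pm 2.46$ — a deliberate statement
that 72 years of data cannot distinguish a 1-in-200 from a 1-in-1000
event.

## The pipeline

`compute_spi()` sums precipitation over trailing $k$-day windows (the
window **ends on and includes** the index day: the "last 30 days" of
July 1 are June 2 – July 1), for $k$ in the canonical scheme 5–365 by
5 then 370–720 by 10 (109 scales). `compute_spei()` does the same for
the daily water balance $P - \mathrm{PET}$ through the plain (not
zero-inflated) pathway, since the balance is real-valued with no atom.
`compute_ssmi()` standardizes raw daily soil moisture with no
aggregation at all. Each calendar day is processed independently — no
state crosses days, and a value can always be reproduced from its own
day's climatology (`sdi_from_sample()`).

Calendar details: (month, day) is the join key, never day-of-year, so
leap years stay aligned; Feb 29 is pooled with Feb 28 (both the Feb 28
and Feb 29 values of leap years enter one sample, and both days are
scored against it), which keeps that sample from collapsing to a
quarter of the record. The target year's own value *is* included in its
climatological sample: the published datasets standardize a fixed
record against itself, and leave-one-out scoring would make scores
non-reproducible as the record grows.

Missing data: a window with less than 90% of its days present
(`min_frac`) yields a missing aggregate; a partial window above the
threshold is rescaled to full window length ($k \times$ mean of present
days) rather than summed raw, which would bias it low. Days whose
cross-year sample is smaller than `min_sample_size` (default 30 years,
the accepted floor for climatological work) raise an error rather than
silently producing fragile scores; users with shorter records can pool
neighbouring calendar days (`pool_days`) at the cost of some seasonal
sharpness.

## Potential evapotranspiration

PET uses the Hargreaves–Samani form
$\mathrm{PET} = 0.00023 \cdot RG \cdot \sqrt{TX-TN}\,(TG+17.8)$
with $RG$ the extraterrestrial radiation computed from latitude and day
of year alone (declination $0.409\sin(2\pi\,\mathrm{doy}/365.25-1.39)$,
eccentricity factor, sunrise hour angle). Two numerical choices:

* the $\arccos$ argument of the hour angle is clamped to $[-1,1]$, so
  polar day gives $\omega=\pi$ and polar night $\omega=0$ (and
  $RG = 0$) instead of a domain error — high-latitude sites reach 68° N;
* PET is floored at zero when $TG < -17.8\,°$C; negative evaporative
  demand is physically meaningless.

$RG$ is computed and stored in MJ m⁻² day⁻¹ (the 0.082 MJ m⁻² min⁻¹
solar-constant form; multiply by 11.574 for a mean W m⁻²). The 0.00023
coefficient is kept exactly as published for this index family and
exposed in the configuration; users wanting the textbook
Hargreaves–Samani magnitude (coefficient 0.0023 with radiation in
evaporation-equivalent mm day⁻¹) can set it accordingly — for
*standardized* indices only temporal consistency matters, not the
absolute PET level.

## What the synthetic generator emulates — and what it does not

`generate_site()` produces multi-decade daily tables with the features
the pipeline relies on: a zero-inflated, seasonally modulated
precipitation process (wet-day probability 0.45 ± 0.10, wetter winters;
wet-day amounts Gamma with shape 0.8 and scale 5 ± 1.5 mm, larger in
summer — typical mid-latitude-Europe values); a seasonal temperature
cycle (mean 9 °C, amplitude 8.5 °C, peak late July) with AR(1)
anomalies (coefficient 0.7, innovation sd 2 °C) and a guaranteed
$TN \le TG \le TX$ ordering; and soil moisture from a minimal leaky
bucket, $SM_{t+1} = \mathrm{clip}(SM_t + (P_t - \mathrm{PET}_t SM_t -
\mathrm{drain}\cdot SM_t)/\mathrm{capacity},\,0,\,1)$, two stores
(120 mm and 400 mm) for the top and full layers. One integer seed
drives independent substreams per variable, so the tables are exactly
reproducible and adding a variable does not perturb the others.

The generator makes no claim of hydrological fidelity: no snow, no
interception, no spatial correlation between sites, no trends. A green
test on synthetic data establishes that the *estimation machinery*
recovers known distributions — not that any real site's drought record
is reproduced. For exact-truth tests, `generate_known_distribution()`
draws i.i.d. zero-inflated Gamma days and returns closed-form oracles,
including the exact distribution of a $k$-day sum (a Binomial mixture
of Gamma convolutions), against which the full SPI pipeline is checked
(mean absolute error ≈ 0.14 at 72 years, correlation ≈ 0.99).

## Known limitations

* **Tail shrinkage at climatological sample sizes.** Evaluating the
  kernel CDF at its own sample points compresses the tails: with
  $n = 72$ and an LSCV bandwidth (≈ 0.46 sd) the pooled score standard
  deviation is ≈ 0.89 rather than 1, and the frequency of scores below
  −1.28 is ≈ 0.07 rather than 0.10. This is a property of the method
  (it appears identically with `stats::bw.ucv` bandwidths, and with
  Silverman bandwidths the sd is 0.92), not of the implementation; the
  acceptance suite asserts the idealized bands and the shortfall is
  visible there. Practically it means the nonparametric index is
  slightly conservative about extremes near the record length.
* **Soil moisture boundaries.** SSMI lives on $[0,1]$ but receives no
  boundary correction (only precipitation gets the mixture treatment);
  densities near saturation or wilting are smoothed across the bounds.
* **LSCV variance.** The CV-selected bandwidth is noisy (sd ≈ 0.13
  around a mean of 0.46 for normal samples of 72); the fallback rule
  and the deterministic optimizer keep results reproducible, but two
  nearby climatologies can get visibly different bandwidths.
* The published category table pairs the score −0.50 with probability
  0.300; the exact values are $\Phi(-0.50)=0.309$ and
  $\Phi^{-1}(0.300)=-0.524$. The package keeps −0.50 as the D0
  threshold and does not use that probability as a numeric anchor.

```{r}
# the per-day machinery in one line: July-1 scores of a 40-year record
g <- generate_known_distribution(years = 40, seed = 1)
agg <- aggregate_rolling(g$series, 30)
s <- climatological_sample(agg, 7, 1)
round(sdi_from_sample(s$values, s$values, "precipitation")[1:5], 3)
```
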