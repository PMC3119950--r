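---
title: "Cell-survival models and isoeffect calculations with elqiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-survival models and isoeffect calculations with elqiso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elqiso)
```

## The models

The linear-quadratic (LQ) model is the standard description of clonogenic
cell survival at conventional doses per fraction:

$$\ln S = -\alpha d - \beta d^2,$$

with $\alpha$ (Gy$^{-1}$) the initial slope and $\beta$ (Gy$^{-2}$) the
quadratic coefficient.  The $\alpha/\beta$ ratio (Gy) — the dose at which
linear and quadratic killing contribute equally — governs how sensitive a
cell population is to changes in fractionation.

Several cell lines show linear, not quadratic, log-survival falloff at
high dose.  One mechanism is dose protraction: sublethal damage is partly
repaired during the exposure itself, attenuating the quadratic term by the
Lea–Catcheside factor.  For a constant dose rate $R$ and first-order
repair rate $\lambda$,

$$G(\lambda T) = \frac{2}{(\lambda T)^2}\left(e^{-\lambda T} + \lambda T -
1\right), \qquad T = d/R,$$

which `protraction_factor()` evaluates (a three-term Taylor series is used
below $\lambda T = 10^{-4}$, where the closed form loses all significant
digits to cancellation).  Substituting $G$ into the LQ and reparameterising
gives the extended linear-quadratic (ELQ) model implemented by
`elq_log_survival()`:

$$\ln S = -(\alpha+\gamma)\,d + \frac{\gamma^2}{2\beta}
\left(1 - e^{-2\beta d/\gamma}\right).$$

Here $\alpha$ and $\beta$ retain their low-dose meaning (the expansion at
small $d$ is $-\alpha d - \beta d^2 + \tfrac{2\beta^2}{3\gamma}d^3 +
\dots$, see `elq_low_dose_series()`), while the high-dose behaviour is
linear with slope $-(\alpha+\gamma)$ and extrapolation number
$\gamma^2/(2\beta)$ (`elq_high_dose_asymptote()`).  In the protraction
picture $\gamma = 2\beta/(\delta + \lambda/R)$
(`gamma_from_protraction()`), with $\delta$ a dose-rate-independent term;
$\delta = 0$ recovers the pure constant-dose-rate form.  As
$\gamma \to \infty$ the ELQ collapses to the LQ; the package represents
this limit by the exact sentinel `gamma = Inf`, which dispatches every
evaluation to the LQ branch rather than relying on a large finite value.
Doses are in Gy throughout; $\lambda$ and $R$ must share one time unit
(hours by convention) — the package documents, and does not convert,
units.

## Fitting

`fit_lq()` and `fit_elq()` minimise a weighted sum of squared residuals
(WSSR).  When error bars are unavailable the proportional-SD convention is
applied: the standard deviation of a point equals a constant $c$ times its
value ($c = 1$ by default; $c$ rescales the WSSR but not the estimates, so
reported WSSR values are only comparable within one choice of $c$).  The
default residual space is linear survival, $(S_i - \hat S_i)/sd_i$, which
under proportional SDs is relative least squares; log-space residuals
(with delta-method SDs) are available via `fit_space = "log"`, and the two
give estimates well inside each other's standard errors on data that
satisfy the error model.

The optimiser is bound-constrained Levenberg–Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-10`), multistarted from five
deterministic initial points; one start is the LQ solution with
$\gamma = 10^5$, which guarantees the nesting property
$\mathrm{WSSR}_{ELQ} \le \mathrm{WSSR}_{LQ}$ and lets data without
high-dose linearity remain in the LQ limit.  Ties are broken by lowest
WSSR, then lowest $\gamma$.  Two conventions familiar from the
radiobiology literature are built in:

* **Negative-$\alpha$ refit.**  The ELQ fit is first run with $\alpha$
  unconstrained.  If the estimate is negative, the fit is repeated with
  $\alpha$ fixed at exactly zero and flagged (`alpha_fixed_to_zero`).
  This happens for cells whose survival curves are almost purely quadratic
  at low dose, and with 5 % proportional noise on $\alpha = 0$ truth it
  triggers in roughly 40 % of replicates.
* **$\gamma$ divergence ceiling.**  If the fitted $\gamma$ exceeds
  $10^4$ Gy$^{-1}$ the data carry no information about high-dose
  linearity; the result is reported as the LQ limit with `gamma = Inf`.

Parameter uncertainty is the Gauss–Newton (Jacobian) covariance at the
optimum scaled by reduced chi-square, reported as percentages of the
estimates (`parameter_uncertainty()`; set `scale_by_residual = FALSE` for
the unit-weight covariance, under which doubling all SDs doubles every
standard error).  Singular curvature yields `Inf` percentages, not an
error.  The $\alpha/\beta$ ratio of a fit carries a first-order
uncertainty obtained by quadrature of the two percentage uncertainties,
assuming independence — a deliberate simplification; the full covariance
is retained in the fit object for users who want the correlated version.

## Isoeffect calculations

Assuming complete interfraction repair and no repopulation, the effect of
$n$ fractions totalling $D$ Gy is $E = -\ln S_{total} = n\,(-\ln S(D/n))$.
For the LQ this is $E = \alpha D + \beta D^2/n$ and the isoeffective total
dose has the closed form implemented in `lq_isoeffect_dose()` (with a
pure-quadratic branch for $\alpha = 0$).  For the ELQ the relation

$$(\alpha+\gamma) D - n\frac{\gamma^2}{2\beta}
\left(1 - e^{-2\beta D/(n\gamma)}\right) = E$$

is implicit.  `elq_isoeffect_dose()` exploits that the effect is strictly
increasing in $D$ and brackets the unique root analytically: dropping the
(positive) repair term gives the lower bound $E/(\alpha+\gamma)$, and
adding the asymptote offset $n\gamma^2/(2\beta(\alpha+\gamma))$ gives an
upper bound.  `stats::uniroot()` on that bracket is polished with two
Newton steps, leaving an effect residual below $10^{-9}$ (the unit tests
verify round-trip inversion to $10^{-8}$ and agreement with an
independent dense bisection oracle to $10^{-6}$ Gy).  Fraction numbers may
be real, so curves can be traced continuously; presentation layers round
doses to 0.1 Gy while all internal values keep full precision.

`isoeffect_curve()` anchors a curve to a reference schedule (for example
40 × 2 Gy), through which every model's curve passes by construction.
`fraction_ratio()` expresses the low-dose model disagreement as the factor
$\ln S_{LQ}(d)/\ln S_{ELQ}(d)$ by which the fraction number must change
for equal effect.  `lq_params_from_ratio()` builds LQ parameters with a
prescribed $\alpha/\beta$; because anchored LQ isoeffect doses depend only
on the ratio (the biologically-effective-dose cancellation), the absolute
scale is fixed by the immaterial convention $\alpha = 1$, and
`lq_approximation_report()` uses this to measure over which contiguous
range of fraction numbers a small-$\alpha/\beta$ LQ curve tracks an ELQ
curve within a stated tolerance (1 Gy by default).

No formula for isoeffect uncertainty bands is standard, so
`isoeffect_uncertainty_band()` adopts a deterministic convention: every
corner of the $\pm 1$-standard-error box over the free parameters is
evaluated (re-deriving the reference effect at each corner), corners
violating the parameter domain are clipped to it and flagged, and the
per-$n$ envelope over the corners and the nominal curve is reported.
Corner evaluation was chosen over Monte-Carlo sampling for reproducibility;
it ignores parameter correlations and is therefore conservative when
$\alpha$ and $\beta$ are anticorrelated, as they typically are.

## Synthetic data

The four reference cell lines (CHO, NCIH841, PC3, CP3) were digitized from
earlier publications and the underlying tables are not available, so the
package ships a generator rather than data.  `generate_dataset()` draws
surviving fractions from a positive-support distribution with mean equal
to the model value and standard deviation `noise_cv` times that value —
exactly the proportional-SD structure the fitting assumes.  The default
distribution is lognormal, parameterised to match the mean and CV
(a redrawn truncated normal is available; both satisfy the proportional-SD
contract).  Draws above 1 are clamped to 1, with a warning if more than
1 % of draws are affected; at low doses with S near 1 and 5 % noise, the
occasional clamp is expected and harmless.  A master seed derives an
independent substream per dose, so extending the grid never reshuffles
existing draws, and a fixed seed gives bit-identical datasets.

Defaults were chosen once to mirror a realistic extended-dose-range
clonogenic experiment: 12 doses from 0.5 to 15 Gy (denser below 6 Gy,
where curvature identifies $\alpha$ and $\beta$) and a 5 % proportional
CV.  `cell_line_fixtures()` wires the published ELQ parameter sets (CHO as
the LQ limit) into ready-made configurations, with the published
measurement dose rates attached as metadata.  What the generator does
*not* emulate: colony-count (Poisson plating) statistics, plating-
efficiency normalisation error, inter-experiment batch effects, or
low-dose-rate exposures.  Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the assumed error model,
not robustness to the full error structure of real clonogenic assays.

The recovery study run by the test suite uses 200 seeded replicates per
cell line at 5 % noise — large enough that the median absolute relative
error of each free parameter (observed at 1–4 %, required < 10 %) and the
~40 % trigger rate of the negative-$\alpha$ refit are stable, while the
~800 fits complete in a few seconds.

## Known limitations

* WSSR magnitudes are comparable only under a common proportionality
  constant $c$; published WSSR values for the reference cell lines cannot
  be reproduced without the original digitized datasets.
* The uncertainty band is a convention (see above), not a likelihood
  region.
* No overall-treatment-time, repopulation, or incomplete-repair terms:
  isoeffects assume complete interfraction repair, which becomes
  questionable for strongly accelerated schedules.
* The generator's independence across doses ignores the correlated errors
  a shared plating-efficiency denominator induces in real experiments.
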