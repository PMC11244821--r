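---
title: "Models and methods: inferring mutational effect distributions from microcolony growth data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(madfe)
```

This vignette is the package's own account of its statistical machinery:
the measurement model for microcolony growth rates, the
characteristic-function representation of the distribution of mutational
effects (DME), the two likelihood routes, and the numerical and design
choices behind them.

## The measurement model

A mutation-accumulation (MA) assay measures thousands of microcolony
growth rates per strain, organized hierarchically: colonies within
imaging fields within wells within plates. The growth rate of colony *a*
of strain *i* is modeled as a two-component Gaussian mixture,

$$g_{ai} \sim (1-\rho_i)\,N(\mu_i, \sigma^2_{\text{nonpetite-bio}}) +
  \rho_i\,N(\mu_{\text{petite}}, \sigma^2_{\text{petite-bio}}),$$

because laboratory yeast strains stochastically generate
respiration-deficient *petite* cells that grow slower for reasons
unrelated to the strain's nuclear mutations. The petite proportion
$\rho_i$ varies across strains through founder-sampling jackpots, so it
is a per-strain nuisance parameter, while the quantity of interest is
the non-petite rate through the selection coefficient
$s_i = \mu_i/\mu_{\text{ancestor}} - 1$.

Each observation additionally carries colony-level measurement noise
($\sigma_{\text{col}}$) and additive plate and well batch effects
($\sigma_{\text{plate}}, \sigma_{\text{well}}$). The colony noise is not
separately identifiable from biological colony variation, so the fitter
works only with the combined variances
$\sigma^2_{\text{nonpetite}} = \sigma^2_{\text{col}} +
\sigma^2_{\text{nonpetite-bio}}$ (and likewise for petites); the
simulator keeps the two components separate so tests can verify the
combination rule.

**Batch-effect cancellation.** Rather than fitting a mixed model to raw
rates, the likelihood is built on differences $D$ between an MA colony
and a reference colony from the same plate, well, and imaging field.
Additive batch effects cancel exactly in $D$; with petite statuses
unknown, $D$ follows a four-component Gaussian mixture over the
$2 \times 2$ petite outcomes (`diff_loglik()`). Pairs are drawn at
random without replacement within each field and surplus colonies are
discarded, keeping the differences independent. Petite-only control
wells on every plate anchor $\mu_{\text{petite}}$,
$\sigma_{\text{petite}}$, and the batch-effect scales through a
closed-form per-well random-intercept marginal likelihood
(`petite_control_loglik()`); wells are treated as independent, which
ignores the weaker plate-level correlation between control wells on the
same plate.

`fit_colony_model()` maximizes the combined likelihood nestedly:
per-strain $(s_i, \rho_i)$ are profiled out inside a quasi-Newton search
over the seven general parameters, with positive parameters on the log
scale and proportions on the logit scale. One caveat is intrinsic to the
difference design: when petite proportions approach zero, only the
product $\mu_{\text{ancestor}} \cdot s_i$ is identified, so the
ancestral-rate direction of the likelihood is flat. The optimizer is
started at the non-petite mean of the raw reference colonies, which pins
that flat direction at the data's own scale. Relatedly, the absolute
rate scale is confounded with the realized mean plate effect; it
averages out over plates but contributes scale error of order
$\sigma_{\text{plate}}/\sqrt{n_{\text{plates}}}$ on few-plate designs.

Profile-likelihood 95% intervals on each $s_i$ use a log-likelihood
drop of 2.5 (the value used throughout this modeling tradition for
these data, slightly more conservative than the textbook
$\chi^2_1$ value of 1.92; both are exposed via `ci_drop`), with
quadratic interpolation between scan points; the per-strain standard
error is the sd of a quadratic fit to the profile. Per-strain p-values
are likelihood-ratio tests of $s_i = 0$ with $\rho_i$ re-optimized under
the null, referred to $\chi^2_1$; strains are flagged at a
Benjamini–Hochberg FDR of 0.05 (the FDR procedure is not dictated by
the experimental design; BH is recorded in the output metadata).
`compare_petite_vs_nopetite()` refits with every petite proportion
pinned at zero; because the null sits on the boundary of the parameter
space the $\chi^2$ reference is conservative, and the package's
calibration test accordingly asserts that the size does not exceed the
nominal level rather than that it equals it.

**Baseline convention.** In designs where the in-well GFP reference is
not the biological baseline (the slippage-repair-deficient assay, where
the deletion ancestor itself is assayed in nine wells per plate),
selection coefficients are re-expressed relative to the designated
baseline strain: $s^{\text{rel}}_i = (1+s_i)/(1+s_b) - 1$, with the
baseline's estimate treated as fixed in the transformed intervals and
p-values computed against $s_i = \hat s_b$.

## The DME models

Single-mutation effects $Z$ follow a reflected gamma distribution:
gamma-distributed magnitudes with mean $m$ and shape $k$ (scale
$m/k$), beneficial with probability $q$. A proportion $p_0$ of
mutations is exactly neutral. Strains carry a Poisson number of
mutations; with the SNM rate per haploid strain fixed at
$M_{\text{diploid}}/2$ from sequencing of the diploid parents, the
non-neutral rate is $U = (M_{\text{diploid}}/2)(1-p_0)$. The default
$M_{\text{diploid}} = 8$ reflects the mean substitution count per
diploid MA line; it is configurable.

The per-strain combined effect $S$ is a compound Poisson sum, handled
entirely through characteristic functions:
$F_S(\omega) = \exp\{U(F_Z(\omega) - 1)\}$. Four variants differ in how
mutations invisible to the sequencing pipeline are treated:

* **snm_only** — sequenced substitutions are everything;
* **single_dme** — one reflected gamma with free Poisson mean `U_free`
  (mutation count unconstrained; `p0` is then redundant and fixed at 0);
* **two_gamma** — an independent second compound-Poisson reflected
  gamma for unidentified mutations. This variant is fitted but flagged
  `reliable = FALSE`: with the unidentified mutation count unknown, its
  parameters are strongly confounded and profiles can be non-monotone;
* **gaussian_unid** — one Gaussian draw per strain,
  $N(\mu_{\text{unid}}, \sigma^2_{\text{unid}})$, for the combined
  unidentified effect.

`dme_tail_probability()` evaluates the proportion of all mutations with
individual effects beyond a cutoff analytically from the regularized
incomplete gamma function — no grid is involved.

## Fourier-domain density evaluation

`cf_to_pdf()` evaluates the model CF on the conjugate frequency grid of
a $2^n$-point selection-coefficient grid (default $2^{14}$ points on
$[-0.5, 0.5)$; observed effects lie within about $\pm 0.15$), multiplies
by a narrow Gaussian kernel CF, inverse-FFTs, clips negative ringing,
and renormalizes. Numerical choices worth recording:

* **Kernel width.** The kernel's nominal sd is $2^{-16} \approx
  1.5\times10^{-5}$; the literature this follows writes the kernel as
  $N(0, 2^{-16})$ without saying whether that is a variance or an sd —
  we read it as the sd and expose it. A kernel narrower than the grid
  spacing cannot do its job (suppressing ringing around the
  near-atom at $S = 0$), so the total Gaussian smoothing
  (kernel + measurement error) is floored at one grid spacing.
* **Zero atom.** The probability of zero effective mutations,
  $e^{-U}$, is kept exact: in the summary likelihood it is part of the
  CF (the strain-level error convolution smooths it anyway); in the
  full-data likelihood it is split off analytically and only the
  continuous CF remainder is inverted, which keeps thinned quadrature
  from mis-weighting a spike.
* **Aliasing guard.** If more than $10^{-4}$ of the mass lands in the
  outer 1/128 of the grid, the density has wrapped; the grid is widened
  by doubling (up to six times) before erroring.

`strain_summary_loglik()` adds each strain's estimation-error CF
$e^{-\omega^2\sigma^2_{MA_i}/2}$ to the product, inverts, and linearly
interpolates the density at the strain's estimated effect, flooring at
$10^{-300}$.

## Two likelihood routes

**Summary route** (`fit_dme(…, mode = "summary")`): per-strain point
estimates and standard errors from the colony fit are treated as
Gaussian-error observations of $S_i$. Fast, but treats the strain
errors as independent, ignoring their correlation through the shared
general parameters.

**Full route** (`fit_dme(…, mode = "full")`): for each strain the
likelihood integrates the DME density against the product of
paired-difference mixture densities,
$\int P(S_i = s)\prod_j P(D^{(i)}_j \mid s, \rho_i)\,ds$, with
$\rho_i$ profiled out. The integral is a trapezoid rule over the part
of the FFT grid carrying all but $10^{-12}$ of the continuous mass,
thinned to at most 257 points and renormalized to the known continuous
mass (the inner product is accumulated in log space and exponentiated
with max-subtraction; the four mixture component densities are
precomputed per strain since only the weights depend on $\rho_i$). The
free-parameter count for AIC in this mode is DME parameters + 7 general
parameters + one petite proportion per strain — the bookkeeping that
gives 81 free parameters for the SNM-only model on a 70-strain
dataset and 83 for the Gaussian variant. By default the general
parameters are held at values from a preceding `fit_colony_model()`
run (`optimize_general = TRUE` enables the fully nested search, which
is substantially slower).

Model comparison (`compare_models()`) uses AIC differences against a
named baseline and likelihood-ratio tests for nested pairs (SNM-only is
nested in both the two-gamma and Gaussian variants). Fits carry a data
fingerprint; comparing fits of different data is refused.

Profile CIs for DME parameters (`profile_ci()`) scan on the
optimization scale (log/logit), re-maximize the remaining parameters at
each point, and interpolate the 2.5-drop crossings quadratically;
hitting a box bound yields a one-sided interval, and a non-monotone
profile is flagged unreliable rather than raising.

## The synthetic-data generator

`simulate_strain_effects()` and `simulate_colony_table()` generate
exactly the structure the inference assumes: compound-Poisson strain
effects (mutation counts recorded so recovery tests can condition on
them), Bernoulli petite statuses, hierarchical Gaussian noise with
shared plate/well effects, and petite-only control wells per plate that
share their plate's batch effect. Ready-made designs mirror the two
assays: `design_2000gen()` (70 strains, one well each across 14 plates,
~500 colonies per side per well) and `design_msh3()` (18 strains, 3
wells per strain per plate across 10 plates, the deletion ancestor in 9
wells per plate as baseline). Growth rates are in 1/hour with an
ancestral mean of 0.35 — a plausible scale for this kind of assay,
since only relative rates matter to the inference (an invariance that
is itself tested). Default petite parameters (petite mean 0.22/h,
petite proportions around 5–15%, across-colony sds of about 10% of the
mean, plate/well batch sds of 0.01/0.005) were chosen once as realistic
for the assay class. The `s_reference` knob offsets the in-well
reference from the baseline strain to exercise the baseline-convention
logic.

What the generator deliberately does not emulate: non-Gaussian tails in
colony growth rates, correlation of noise across time within an imaging
field, petite proportion drift within wells, and aneuploid strains with
rate effects outside the DME. Passing tests therefore demonstrate
correctness of the inference under its own assumptions, not robustness
to these real-data departures.

## Problem sizes used in the automated checks

The calibration studies in `tests/testthat/test-acceptance.R` run at
reduced problem sizes chosen so the whole suite completes in minutes in
plain R: density-vs-Monte-Carlo agreement uses 20 random parameter sets
with $10^6$ simulated strains each (Kolmogorov–Smirnov distance below
0.005, with the smoothing kernel applied to both sides); parameter
recovery uses 5 replicates of 24 strains × 100 colonies per side with
pooled CI coverage of $(m, k, q)$; LRT size and power use 8 replicates
each of 5 strains × 100 colonies per side; batch-effect immunity uses
10 strains over 10 plates with the plate sd inflated tenfold. The
corresponding binomial tolerances are matched to these replicate
counts. Determinism is checked by byte-comparison of all artifacts from
two runs of the same configuration; every source of randomness flows
from named seeds.

## Known limitations

* The summary route inherits the correlated-error caveat above; the
  full route addresses it but is slower and, by default, conditions on
  the general parameters rather than re-optimizing them jointly.
* Per-strain profile CIs condition on the fitted general parameters,
  slightly understating uncertainty relative to a full joint profile.
* The two-gamma variant is weakly identified by construction; its
  parameter estimates should not be interpreted even when the fit
  converges.
* The LRT for the petite mixture tests a boundary hypothesis; its
  p-values are conservative.
* $M_{\text{diploid}}$ enters as a known constant; errors in the
  sequencing-derived mutation rate propagate directly into $p_0$ and
  $m$.
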