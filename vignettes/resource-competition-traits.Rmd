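---
title: "Estimating the evolution of resource-competition traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the evolution of resource-competition traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rstarevo)
library(dplyr)
```

This vignette is the package's own account of its models, its numerical
choices, and the places where the design was genuinely open.

## The growth models

Population biomass is proxied by chlorophyll-*a* relative fluorescence
(RFU). Within a short (3-day) assay the population is assumed to grow
exponentially at a rate set by the resource level of its well,

$$F(t) = F(0)\, e^{\mu(R)\,t},$$

and the resource dependence of the rate is a Monod curve,

$$\mu(R) = \mu_{max}\frac{R}{k_s + R},$$

with $\mu_{max}$ (day⁻¹) the maximum growth rate and $k_s$ the
half-saturation constant in the resource's own units (µmol L⁻¹ for N and P,
µmol photons m⁻² s⁻¹ for light). Units are carried as opaque labels — the
package never converts them. The assumptions worth stating: no lag phase
(all readings within the assay window are treated as exponential; there is
no automated phase trimming), no density dependence within the window, and
no instrument blank (background-corrected input is the caller's job).

The trait of interest is the minimum resource requirement, obtained by
balancing growth against a constant mortality $m$:

$$R^* = \frac{m\,k_s}{\mu_{max} - m}.$$

`m` defaults to 0.56 day⁻¹ — the dilution rate of the chemostat design the
package emulates — and is overridable in every function that uses it. The
same machinery with $R$ = irradiance gives the minimum light requirement
I*; we use one shared `m` for all assays. A population whose fitted
$\mu_{max} \le m$ cannot persist at any resource level; its fit is flagged
non-persistent and carries no R* (the package never emits a negative or
infinite trait).

Salt tolerance uses a declining logistic,

$$\mu(S) = \frac{a}{1 + e^{b (S - c)}},$$

where $a$ is the growth rate in fresh medium, $b > 0$ the steepness of the
decline (L g⁻¹) and $c$ the tolerance: the concentration (g L⁻¹) at which
growth is half-maximal, exactly. The sign convention is chosen so that the
curve *declines* with salt, which is the biological meaning of the model;
with the opposite sign the same algebra describes growth increasing with
salt, which the fitter flags as `no_detectable_tolerance` instead of
reporting a spurious tolerance.

For light, a photoinhibition alternative is available: the Eilers–Peeters
form $\mu(I) = I / (p_1 I^2 + p_2 I + p_3)$, zero in darkness with a single
interior optimum at $I_{opt} = \sqrt{p_3/p_1}$. `ep_from_peak()` maps the
interpretable quantities (initial slope, optimal irradiance, peak rate)
onto $(p_1, p_2, p_3)$. Under this form I* is the smaller root of
$\mu(I) = m$, from the closed-form quadratic.

## Fitting and its numerical choices

`fit_monod()` minimises the residual sum of squares on the RFU scale over
all wells jointly, using the Levenberg–Marquardt algorithm
(`minpack.lm::nls.lm`) with analytic Jacobians and a parameter-change
tolerance of 1e-8.

Two choices deserve justification:

* **F(0) handling.** The initial fluorescence of each resource level is
  fixed at that level's earliest observed reading rather than estimated.
  This halves the parameter count, stabilises the optimisation on sparse
  (4-time-point) series, and matches how plate assays are normalised in
  practice. A shared free F(0) can be requested via
  `fit_control(estimate_f0 = TRUE)`.
* **Starting values and restarts.** $\mu_{max}$ starts at the largest
  per-level log-linear slope, $k_s$ at the median gradient level; if the
  first start fails, a deterministic grid of jittered restarts (scanning
  $k_s$ over 0.15–6× the guess) is tried before the fit is declared failed.
  Deterministic restarts keep fitting reproducible without consuming random
  numbers.

`fit_salt()` first reduces each salt level to an exponential growth rate
(ordinary least-squares slope of log RFU on time) and then fits the
logistic to rate versus salt — rates, unlike raw RFU, have approximately
homoskedastic errors, which is what least squares assumes at that stage.

## The bootstrap, and why it resamples on the log scale

Uncertainty comes from a non-parametric bootstrap of mean-centred
residuals: resample, recombine with the fitted values, refit, repeat; the
95% interval is the 2.5th–97.5th percentile range over converged
replicates (999 by default, matching the emulated study design; replicates
that fail to converge or are non-persistent are dropped and counted, and an
interval built on fewer than half the replicates is flagged unreliable).

Fluorescence error is scale-dependent: a 5% wobble on a reading of 1800 RFU
is a 90-RFU residual, on 50 RFU it is 2.5. Resampling *raw* residuals
therefore assigns large-absolute-value residuals from bright wells to dim
wells and vice versa, and in simulation under multiplicative lognormal
noise this mis-calibration is severe (interval coverage for R* near 57%
instead of 95%). The package instead resamples the mean-centred residuals
of log-fluorescence, so pseudo-data are `fitted * exp(eps*)`.

The per-level-F(0) design adds one subtlety. Each level's anchor reading
reproduces its fitted value exactly, so every non-anchor log-residual is
the *difference* between that reading's noise and its level's anchor noise:
pooled residuals carry twice the per-reading noise variance, and residuals
within a level share the anchor term. The bootstrap accounts for this by
excluding the structurally zero anchor residuals, scaling the centred pool
by $1/\sqrt{2}$ back to the per-reading noise scale, perturbing *every*
reading (anchors included), and re-deriving F(0) from the perturbed anchors
— so each replicate passes through exactly the pipeline the data did.
Simpler variants (unscaled pools, anchors held fixed) under- or over-state
the spread by 10–30% in simulation; with this scheme 95% intervals cover
the true R* in ~95% of simulated assays on both the nitrogen and the
phosphorus assay designs.

## Trait change and the trade-off analyses

The change in a trait is descendant minus ancestor. Because the two assays
are independent experiments, the sampling distribution of the difference is
formed by pairing independent bootstrap replicates of the two fits; the
change is significant when the 95% percentile interval of that
distribution excludes zero. No multiple-testing correction is applied —
intervals are reported per population and per trait, and the output notes
this. Percent changes are reported on point estimates only.

The trade-off analyses operate on the assembled trait table:
`gleaner_opportunist_test()` regresses $\mu_{max}$ on R* per resource
(a positive slope whose CI excludes zero indicates that fast growers need
more resource); `tradeoff_regression()` centres and scales all trait
variables and adds ancestor identity as treatment-contrast fixed effects
(first ancestor by sorted label as reference), returning partial slopes and
added-variable plot data; `trait_pca()` eigendecomposes the correlation
matrix of competitive abilities ($1/R^*$) and biovolume, with the sign
convention that each axis's dominant loading is positive.

One estimation caveat: $\mu_{max}$ and R* are fitted from the same curve,
and an overestimate of $\mu_{max}$ mechanically lowers the fitted R*.
Estimation error therefore induces a *negative* correlation between the
two, which works against — not for — detecting a gleaner–opportunist
trade-off. On synthetic data generated without any true
$\mu_{max}$–$R^*$ association the regression accordingly tends to show a
weak negative slope, and a positive finding on real data is conservative
with respect to this artefact.

## Competition: graphical classification and the mechanistic oracle

For two essential resources (N on the x-axis, P on the y-axis) a
population's zero-net-growth isocline (ZNGI) is the L-shaped boundary at
$(N^*, P^*)$, and its consumption vector has slope equal to the P:N molar
ratio of its biomass. `classify_pair()` applies the three classical
conditions: crossing ZNGIs, each population consuming more of its own
limiting resource, and the supply point lying above both ZNGIs between the
consumption vectors. All three give stable coexistence; crossing plus
supply position without the consumption condition gives unstable
coexistence (priority effects); anything else is exclusion, with the winner
determined by which resource the supply direction leaves effectively
scarce.

Two semantics are first-class, because outcome *proportions* across a trait
table are often wanted without committing to one environment:

* `supply = NULL` ("feasible" mode): a pair is stable/unstable if a
  qualifying supply point *exists* — the wedge above both ZNGIs is
  non-empty, which holds whenever the ZNGIs cross and the slopes differ.
* an explicit supply point: the classification for that environment.

Comparisons of R* and slopes use a relative tolerance (default 1e-6); ties
are reported as `degenerate`, never silently resolved into one of the three
outcome classes.

The classifier is validated against a mechanistic chemostat model
integrated with `deSolve` (lsoda, rtol 1e-8): Monod growth on both
resources under Liebig's law of the minimum, dilution `D = m`, quotas
$q_N = 1$ and $q_P$ = the consumption slope, half-saturation constants
back-computed from each population's R* via the exact inverse of the R*
formula. A population is extinct when its final biomass falls below 1e-6 of
its start at `t_end = 2000` days. `chemostat_verdict()` maps persistence
patterns across starts to a verdict; its first two starts are the extreme
asymmetric configurations (each population with a 10⁴-fold initial
advantage) precisely because priority-effect basins can be very unequal and
random starts alone can miss the smaller basin; the remaining starts are
random log-uniform draws. On 200 randomly generated non-degenerate pairs
with supply points the graphical classification and the oracle verdict
agree in all cases.

## What the synthetic generator does and does not emulate

`generate_scenario()` mirrors the emulated study design: 5 ancestral
populations (four isoclonal, one flagged genotypically diverse) × 7
selection environments (C, N, P, L, S, B, BS) with 3 descendant lines lost,
giving 37 populations; 10-level gradients per resource assayed on days
0–3; multiplicative lognormal RFU noise (σ = 0.05 by default — plate
fluorescence CVs of a few percent are typical). Ancestral truths are
lognormal around plausible central values for a freshwater green alga
(e.g. $k_s^N$ = 3 µmol L⁻¹, $k_s^P$ = 0.3 µmol L⁻¹, salt tolerance 3
g L⁻¹) with 5% CV; the diverse ancestor gets the same marginal
distribution. Environment effects are stylized multipliers encoding the
qualitative pattern the pipeline should detect — P* down 43–85% under
P-limitation, salt tolerance up 93–369% under salt, N* and I* shifts mixed
and small, consumption vectors down under N- and up under P-limitation —
and shifts of the three minimum requirements share a latent factor
(correlation 0.5) to emulate positively associated trait change.

The salt assay gradient spans 0–16 g L⁻¹: evolved tolerances reach ~14
g L⁻¹ under the configured salt effects, and a gradient must span the trait
it measures — with a narrower gradient the logistic's half-maximum is
unidentifiable even from noiseless data.

Deliberately *not* emulated: any true association between $\mu_{max}$ and
R* (so the generator makes no claim about gleaner–opportunist structure),
measurement noise on stoichiometry and cell size, lag phases, blank drift,
plate effects, wall growth, and within-population genotype dynamics.
Passing tests on this generator therefore show that the estimators recover
the *assumed* data-generating process at realistic noise; they cannot show
robustness to the instrument pathologies real data carry.

## Problem sizes and determinism

The test-suite calibration studies use 100 replicate datasets for
parameter recovery, 200 datasets × 199 bootstrap iterations for interval
coverage, 200 null pairs and 100 shifted pairs at the full 999-iteration
bootstrap for the trait-change error rates (percentile tails from short
replicate sets are noisy enough to visibly inflate the false-positive
rate), and 200 random pairs for the classifier–oracle comparison — sizes at
which the Monte-Carlo error of each proportion is comfortably below the
width of the band being checked. Every stochastic operation takes an
explicit seed; a pipeline run records its seed and a hash of its full
configuration in every output, and rerunning with the same seed and
configuration reproduces the outputs byte for byte (the timing log aside).

## Known limitations

* R* inference conditions on a known, constant `m`; uncertainty in the
  dilution rate is not propagated.
* The exponential-phase assumption is untested within the package; badly
  saturating series will bias $\mu_{max}$ downward.
* The coexistence engine covers exactly two essential resources (N and P);
  light competition is not part of the pairwise classification.
* Feasible-mode proportions depend only on trait geometry, not on any real
  environment's supply; the two modes can legitimately disagree.
* The trait-change test treats ancestor and descendant bootstrap
  distributions as independent, which is exact for separately assayed
  populations but ignores shared plate effects if assays were run together.

```{r example, eval = FALSE}
# the full pipeline on the default synthetic scenario
res <- run_pipeline(pipeline_config(seed = 1))
res$outcomes$all$summary
```
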