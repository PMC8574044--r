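---
title: "Methods: modelling competitive dCas9 repression and derepression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling competitive dCas9 repression and derepression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprDerep)
```

# The model and its assumptions

A repressing dCas9:sgRNA complex (concentration $S_R$) and a derepressing
complex ($S_D$) bind a locus mutually exclusively, with association
constants $K_R$ and $K_D$. At equilibrium the locus distributes over the
free, sgR-bound and sgD-bound states with weights $1 : K_R S_R : K_D S_D$,
normalised by the partition function $1 + K_R S_R + K_D S_D$
(`occupancy()`). Transcription from a bound locus is reduced by the binder's
repression strength $\alpha$ — the ratio of the maximal production rate
(free locus) to the rate when that species saturates the locus — giving the
mRNA balance

$$\frac{dm}{dt} = \beta_m\,
  \frac{1 + \alpha_R^{-1} K_R S_R + \alpha_D^{-1} K_D S_D}
       {1 + K_R S_R + K_D S_D} + \beta - \delta_m m .$$

Setting $dm/dt = 0$ gives the steady state implemented in
`mrnaSteadyState()`. The exponent notation deserves one prominent note: the
production term uses the *reciprocal* $\alpha^{-1}$, the only reading
consistent with the definition of $\alpha$ (saturated production
$\beta_m/\alpha$) and with the saturated response floor
$(y_{max}-y_{min})/\alpha + y_{min}$.

On the observable scale, inputs are the activities $x_R, x_D$ (au of
fluorescence) of the promoters transcribing each guide, assuming guide and
dCas9:guide pools track those activities linearly (unsaturated dCas9
loading), and the output is reporter fluorescence:

$$y = (y_{max}-y_{min})\,
  \frac{1 + \alpha_R^{-1}\kappa_R x_R + \alpha_D^{-1}\kappa_D x_D}
       {1 + \kappa_R x_R + \kappa_D x_D} + y_{min}.$$

The leaky-transcription term is absorbed into $y_{min}$: the response at
zero inputs is exactly $y_{max}$ and $y_{min}$ anchors the fully repressed
floor. Constraints: $y_{max} > y_{min} \ge 0$, $\kappa > 0$, and
$\alpha \ge 1$ by default — a steric blocker cannot activate — with a
`relaxAlpha` escape hatch for exploratory fits.

Equilibrium occupancy is itself an idealisation: dCas9 unbinding is
extremely slow, so real occupancy is largely first-come-first-served and is
reset by DNA replication at the growth rate. The equilibrium form is what
the steady-state data constrain, and it is what this package fits; the
kinetic caveat matters mainly for predicting transient behaviour far from
balanced growth.

# Identifiability of the single-guide fit

The single-guide response can be rewritten exactly as

$$y = A + \frac{y_{max}-A}{1+\kappa_R x_R}, \qquad
  A = y_{min} + \frac{y_{max}-y_{min}}{\alpha_R},$$

so an induction curve — however many points, whatever the noise level —
identifies only three quantities: the ceiling $y_{max}$, the floor $A$ and
$\kappa_R$. The pair $(y_{min}, \alpha_R)$ lies on an exact ridge: any
$y_{min} \in [0, A)$ with $\alpha_R = (y_{max}-y_{min})/(A-y_{min})$
produces the identical curve. A four-parameter optimiser therefore stops at
an arbitrary ridge point determined by its path, and reporting that point as
"the" $\alpha_R$ would be meaningless.

`fitSingle()` handles this explicitly:

* **Default (`yMin = NULL`)**: the identifiable triple $(A, y_{max},
  \kappa_R)$ is fit, and the result is reported under the fixed convention
  $y_{min} = 0$, $\alpha_R = y_{max}/A$, with `yMin` and `alphaR` flagged in
  `unidentifiable()`. The fitted curve, `kappaR` and `yMax` do not depend on
  the convention.
* **Measured floor (`yMin = value`)**: $y_{min}$ is a *measured* quantity
  (the output of a saturating-repression or no-reporter control), not a
  curve-shape parameter. Supplying it pins the ridge and makes
  $\alpha_R = (y_{max}-y_{min})/(A-y_{min})$ identifiable; noiseless
  generate-then-fit round trips then recover the generating parameters to
  better than $10^{-4}$ relative. This is the mode used throughout the
  package's recovery checks, and it mirrors how the floor enters dual-guide
  parameter tables in practice.

The dual-guide stage is free of this problem: with $(y_{min}, y_{max},
\kappa_R, \alpha_R)$ frozen at their single-guide values — they pass through
`fitDual()` bit-identically — the grid identifies $(\kappa_D, \alpha_D)$
directly, with $\alpha_D = 1$ sitting on the lower bound (a fully neutral
derepressor).

# Fitting choices

* **Objective.** Unweighted least squares on the linear fluorescence scale
  by default, matching generic nonlinear curve fitting of replicate means.
  `scale = "log10"` switches to log-residuals. For multiplicative lognormal
  noise the log scale is the variance-matched choice: under the package's
  synthetic noise conventions (geometric SD 1.2, 3 replicates) the linear
  objective leaves the floor dominated by the bright points and the median
  $\alpha_R$ error across simulations is several-fold worse than on the log
  scale, which keeps median $\kappa_R$ and $\alpha_R$ errors under 15%.
  Replicate means are fit (as plotted in dose-response figures); replicate
  SDs are carried for reporting only, and cells are unweighted.
* **Optimiser.** Levenberg-Marquardt (`minpack.lm::nls.lm`) with box
  bounds, `ftol = ptol = 1e-15`, at most 200 iterations. Starts: floor at
  half the smallest observation, ceiling at the largest observation,
  $\kappa$ at `1/median(x > 0)`, and for the dual stage $\alpha_D$ at 1.5.
  Non-convergence is flagged on the `FitResult`, never thrown.
* **Identifiability flags.** A curve spanning less than a 1.2-fold output
  range flags `kappaR`/`alphaR`; a grid with no derepressor induction flags
  `kappaD`/`alphaD`. The 1.2-fold threshold is a convention, documented
  here.
* **Ratio estimators.** $\hat\alpha = A/B$ from off/on means with
  first-order propagated uncertainty
  $\sigma = |A/B|\sqrt{(\sigma_A/A)^2 + (\sigma_B/B)^2}$; the same contract
  serves relative-expression summaries against a guide-free reference.
  $R^2$ is computed on the linear scale over all fitted points.

# Transfer functions

Inducer-to-activity response functions are Hill-shaped,
$a(c) = basal + (maximal-basal)\,c^n/(h^n+c^n)$, strictly increasing, with
an algebraic inverse. The shipped presets for the IPTG-, vanillic-acid- and
choline-inducible systems are **placeholders with plausible shapes**, not
measurements; every downstream stage accepts activity-unit inputs directly,
so no quantitative result in this package depends on them. The inducer
concentration series used for synthetic experiment layouts (12-level
titrations, the 11 x 7 dual grid) ship as `inducerLayout()` constants.

# Guide-pair geometry

Conventions, used everywhere and chosen once:

* Reference coordinates are 1-based, top-strand, inclusive. Promoter
  coordinates are signed around the TSS (+1) with no position 0. "Distance"
  counts intervening bases plus one: adjacent bases are at distance 1,
  overlap is 0.
* A `GuideSite`'s `strand` is the strand carrying the 20-nt protospacer and
  its 3' NGG PAM; the sgRNA base-pairs with the opposite strand.
* The inter-site gap is measured between protospacer+PAM *footprint* edges
  (23 bp blocks) by default, because the experimentally validated "14 bp"
  spacing is not operationally defined; `gapConvention = "protospacer"`
  switches to protospacer edges (footprint gap + 6 bp for facing pairs).
* Competition: dCas9 overhangs ~9 bp beyond its PAM-proximal target edge
  and ~1 bp beyond the PAM-distal edge, so footprints of non-overlapping
  sites can only collide when both PAMs face the gap (overhang sum
  $9+9=18$). Facing pairs with gap $\le 14$ bp are `validated`
  (experimentally confirmed); facing pairs at 15-18 bp are `marginal` —
  inside the overhang arithmetic but untested; everything else is
  `independent`.
* Derepressor self-repression risk, promoter context: `none` when the sgD
  protospacer sits wholly upstream of $-60$, `partial` for nearest base in
  $-60..-28$, `high` otherwise. No strand constraint is imposed on
  promoter-context sgDs (both orientations were tested experimentally
  without a reported strand effect). Elongation context: `none` when sgD
  base-pairs with the template strand (RNAP meets the PAM-distal face and
  reads through), `high` on the non-template strand.
* Degenerate bases (N etc.) are rejected, not expanded.

The scanner is exhaustively cross-checked against a brute-force window scan,
and the classifier is invariant under reverse-complementing the reference
with coordinates, promoter orientation and template strand remapped.

# Dynamics

The mRNA balance is integrated piecewise over the induction schedule
(`deSolve::lsoda`, `rtol = 1e-10`, `atol = 1e-12`), with inputs constant
within a phase and changing instantaneously at events; guide pools track
their driving promoters instantaneously (quasi-steady sgRNA). A reporter
observable $df/dt = k_{tl} m - \mu f$ adds a lumped translation/maturation
rate and first-order dilution at the growth rate $\mu = \ln 2 / \tau$; the
reporter protein is stable (no active degradation). The default doubling
time of 36 min is a documented placeholder for rich-medium exponential
growth, and $k_{tl}$ sets only the fluorescence scale; fold-change
observables are independent of both, so time-course fold numbers are
qualitative shape targets rather than calibrated predictions. Washout is a
schedule event that changes inputs while the per-cell state stays continuous
(per-cell fluorescence is dilution-invariant at constant growth). Under
complete repression the floor-subtracted reporter decays with a halving time
equal to the doubling time — the expected dilution-limited behaviour.

# Ratiometric analysis

When both inputs are deep in saturation ($\kappa x \gg 1$) the dual response
depends on the inputs only through their ratio $r = x_D/x_R$ — the analytic
core of reading the circuit as a ratio sensor. `collapseToRatio()` keeps
every doubly-induced grid cell exactly once and counts the excluded
zero-input cells; the dynamic range convention uses ratios $\ge 1$.
`ratioSpan()` aggregates points into log-spaced bins (5 per decade, medians;
reporting-only, the raw points are preserved), demands monotonicity — the
monotone cumulative-extreme envelope is substituted and flagged otherwise —
and reports the log10 extent over which the binned response traverses the
central 90% (threshold 0.05 per tail) of its observed range. Note the span
is measured against the *observed* extremes: on a hyperbolic response
sampled over few decades it is accordingly narrower than the asymptotic
$2\log_{10} 19 \approx 2.56$ decades, which it approaches as the sampled
range widens.

# Synthetic data

The generators emulate the structure of flow-cytometry induction
experiments: 12-level single-guide titrations, 7 x 11 dual-induction grids,
30-min time courses, and lognormal event clouds summarised by geometric
means. Observation noise is multiplicative lognormal applied at the
replicate level (defaults: geometric SD 1.2, 3 replicates — synthetic
conventions, since only replicate SDs, not a noise model, are available for
the modelled experiments). All generators are bit-reproducible for a fixed
seed and restore the caller's RNG state.

What the generators deliberately do **not** emulate: autofluorescence
background, forward/side-scatter structure and gating, day-to-day batch
effects, growth-rate feedback from circuit burden, and dCas9 resource
competition between co-expressed guides. Passing recovery tests on these
synthetic data therefore demonstrates the correctness and stability of the
estimation machinery under the stated noise model — not that real cytometry
data meet that model.

# Problem sizes and numerical conventions

The recovery and property suites use: 12-point curves (zero plus 11
log-spaced activities over 1-8000 au) and 7 x 11 grids (zero plus 6 and 10
log-spaced levels to 8000 au); 40 random noiseless and 50-200 noisy
generate-then-fit round trips; 50 random parameter sets for
integrator-versus-closed-form agreement at $10^{-6}$ relative; 1000 random
200-nt sequences for the PAM scanner cross-check; 2000 random draws for the
occupancy partition invariants. Saturation limits are evaluated at
$\kappa x = 10^9$; infinite inputs are handled algebraically (both inputs
infinite is indeterminate and errors). Equal-ratio comparisons treat ratios
as equal after rounding $\log_{10} r$ to 9 decimals.

# Known limitations

* Equilibrium occupancy, not first-come-first-served kinetics with
  replication resetting; transient predictions far from balanced growth are
  approximate.
* Shared-dCas9 resource competition is out of scope; derepression by
  titrating dCas9 away would be misattributed to steric competition if
  present.
* Transfer-function presets are placeholders; calibrate against measured
  inducer responses before converting concentrations.
* The marginal 15-18 bp competition zone is extrapolated from footprint
  arithmetic and experimentally untested.
* Propagated-σ ratio uncertainties are first-order; no bootstrap or
  Bayesian intervals.
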