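---
title: "Modelling glucose-insulin-glucagon dynamics in IIGI experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose-insulin-glucagon dynamics in IIGI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iigidyn)
```

## The experiment and the model

In an isoglycemic intravenous glucose infusion (IIGI) experiment the
plasma glucose profile of a prior 75-g oral glucose tolerance test is
replicated by a manually adjusted intravenous infusion.  Because the gut
is bypassed, the insulin and glucagon responses seen during an IIGI are
free of incretin and other gut-mediated effects, which makes the
experiment an ideal substrate for estimating glucose-dependent hormone
dose-response parameters.

`iigidyn` implements a parsimonious three-state delay differential
equation model of the experiment:

$$\frac{dG}{dt} = -(S_G + a_1 I)\,G + a_2 A + R_{IIGI}(t-\tau)/V$$
$$\frac{dI}{dt} = -n_1 I + \gamma_1\,\psi(G(t-\tau_1))$$
$$\frac{dA}{dt} = -n_2 A + \gamma_2\,\phi(G(t-\tau_2))$$

with plasma glucose $G$, insulin $I$ and glucagon $A$.  Glucose is
cleared in proportion to itself ($S_G$) and to insulin (insulin
sensitivity $a_1$), and produced in proportion to glucagon (glucagon
action $a_2$); exogenous glucose arrives at the piecewise-constant rate
$R_{IIGI}$ built from the recorded grams infused per 15-min block.
Hormone kinetics are first-order decays ($n_1$, $n_2$) driven by
glucose-dependent secretion terms.

Insulin secretion drive $\psi$ comes in two variants.  The single-Hill
variant is

$$\psi(G) = 1.5\,\frac{G^h}{K^h + G^h}, \qquad K = 17\ \mathrm{mM},$$

with $K$ fixed at the value obtained from in-vitro islet dose-response
data.  The hysteresis variant uses a rising-branch Hill coefficient
$h_1$ before the glucose-curve maximum and a falling-branch coefficient
$h_2$ after it, with the matching constant $C_1$ chosen so the two
branches meet at the maximum (the *hysteresis anchor*
$(G_{hyst}, t_{hyst})$).

Glucagon secretion drive is exponentially suppressed in glucose with a
suppression constant $k_1$ while glucose rises and a recovery constant
$k_2$ after the anchor:

$$\phi(G) = \begin{cases} e^{-k_1 G}, & t < t_{hyst}\\
e^{-k_2 G} + e^{-k_1 G_{hyst}}, & t \ge t_{hyst}.\end{cases}$$

As written, the two branches differ by $e^{-k_2 G_{hyst}}$ at the
switch.  We implement the formula exactly as printed; an optional
continuity-corrected mode
(`glucagon_dose_response(..., continuity_correction = TRUE)`) replaces
the shift by $e^{-k_1 G_{hyst}} - e^{-k_2 G_{hyst}}$, which closes the
jump.  The printed form is the default because it is the form the
published parameter values were estimated under.  Branch selection uses
the undelayed clock time $t$; using the delayed time would shift the
switch by $\tau_2$ (or $\tau_1$), which is unspecified in the source
material, and the undelayed convention keeps the anchor aligned with
the observed glucose maximum.

## Units

The glucose mass-balance equation runs in mg/dL (consistent with the
units of $a_2$ and of $R_{IIGI}/V$, $V = 1.35$ dL/kg), while both
dose-response functions take glucose in mM (consistent with $K = 17$ mM
and $k_1, k_2$ in mM$^{-1}$); the conversion factor is fixed at 18.016
mg/dL per mM.  Insulin is carried internally in 10-pM units so $a_1$
has its conventional $(10\ \mathrm{pM\,min})^{-1}$ scale.  Data files
always use mM / pM / pM; conversion happens only at the I/O boundary.
Only this mixed convention reproduces the magnitudes of the published
parameter tables.

## Fixed, estimated and manually adjusted parameters

| set | symbols | treatment |
|---|---|---|
| fixed | $S_G = 0.014$ min$^{-1}$, $n_1 = 0.14$ min$^{-1}$, $n_2 = 0.08$ min$^{-1}$, $V = 1.35$ dL/kg, $K = 17$ mM, prefactor 1.5 | literature values, overridable only via explicit config |
| estimated | $a_1, a_2, \gamma_1, \gamma_2, k_1$, and $h$ or $(h_1, h_2)$ | weighted Levenberg-Marquardt |
| manual | $\tau, \tau_1, \tau_2, k_2$ | supplied values or grid search (`grid_adjust_manual()`) |

The delays cannot be estimated by gradient methods because the arrival
rate is continuous but not smooth; they were adjusted by eye in the
original analysis.  `grid_adjust_manual()` reproduces that step
objectively by minimising the weighted SSE over a finite grid, breaking
ties toward smaller delays and then smaller $k_2$.

## Simulation: method of steps

`simulate_iigi()` integrates the system by the method of steps.  The
time axis is split at every point where the right-hand side loses
smoothness — infusion block edges shifted by $\tau$, the anchor time,
and their first- and second-order delay images under $\tau_1, \tau_2$ —
and each segment is integrated with `deSolve::lsoda` (default
tolerances $10^{-8}$/$10^{-10}$), restarting at each breakpoint so the
integrator never steps across a derivative discontinuity.  Segments are
additionally capped at the smallest positive state delay so delayed
glucose lookups always fall in already-integrated history, which is
stored on a fine grid (0.25 min by default) and interpolated linearly.
The history for $t \le 0$ is the constant fasting state, reflecting the
overnight-fast steady state of the subjects.  Negative concentrations
are never reflected; solver round-off in $[-10^{-8}, 0)$ is clamped to
zero at sampling only, and anything more negative is an error.

Verification (in the test suite): an equilibrium initial state stays
constant to better than $10^{-6}$ relative over 240 min; the decoupled
system matches $G_0 e^{-S_G t}$ to $10^{-6}$; and solutions match an
independent fixed-step RK4 method-of-steps reference at
$\Delta t = 0.01$ min to better than 0.1% sup-norm across random
parameter draws.

## Fitting

`fit_model()` minimises CV-weighted residuals
$r = (y - \hat y)/(\mathrm{CV}\,y)$ with assay CVs 2% (glucose), 3%
(insulin) and 5.5% (glucagon), stacked analyte-major, using
`minpack.lm::nls.lm`.  Unweighted mode is available as a flag because
the original analysis used weighting only for some subjects.  The
weight denominator uses the observed values with a configurable
assay-floor so points near the glucagon detection limit cannot acquire
unbounded influence.

Numerical choices worth knowing:

* **Finite-difference step.** The residuals carry integration noise at
  the solver tolerance, so the default `epsfcn` is $10^{-8}$ (step
  $\approx 10^{-4}$ relative) rather than minpack's machine-epsilon
  default; with the default step the Jacobians are dominated by solver
  noise and the optimizer stalls far from the optimum.
* **Starts.** The default start inverts the fasting-equilibrium algebra
  on the baseline samples to initialise $\gamma_1, \gamma_2, a_2$, and
  uses mid-range values for $a_1, k_1, h$.  Additional seeded uniform
  starts (5 by default) guard against the initial-guess sensitivity
  observed in some subjects; the best converged SSE is kept.
* **Bounds.** All free parameters are constrained positive and the Hill
  coefficients to $[0.5, 4]$, spanning all published values with room.
* **Baseline.** The initial state is the mean of the $t \le 0$ samples
  per analyte; no steady-state constraint is imposed during fitting
  (equilibrium is enforced only in the generator).
* **Statistics.** Standard errors come from $(J^TJ)^{-1}s^2$ with a
  central-difference Jacobian at the optimum; p-values are two-sided
  $t$ with $n - p$ df.  Adjusted $R^2$ is computed on the weighted
  scale with per-analyte means in the total sum of squares (the
  reference software's exact convention under weighting is not
  documented; this one is, here).  AICc uses the Gaussian profile form
  $n\log(\mathrm{RSS}/n) + 2p + 2p(p+1)/(n-p-1)$ with additive
  constants dropped — valid because only differences on a shared
  dataset are ever interpreted.

## The synthetic-subject generator

Because the clinical series are not deposited, `gen_subject()` /
`gen_cohort()` generate complete subjects that emulate the study
conditions:

* infusion profiles: controls get a bimodal shape (bumps near ~20 and
  ~65 min, finished by 120 min), the diabetes group a single prolonged
  bump extending to 180 min, discretised to 15-min blocks and
  normalised to the requested total (at most 75 g, matching the oral
  load);
* parameters drawn uniformly within the published per-group ranges
  (`iigi_param_ranges()`), or resampled verbatim from the published
  per-subject tables; delays are rounded to the 5-min grid of the
  infusion-adjustment protocol;
* fasting glucose drawn from 4.8-6.0 mM (controls) / 7.0-10.0 mM
  (diabetes group) and totals 20-50 g / 45-75 g respectively — the
  published subject-level fasting values are not printed, so these are
  conventional physiological ranges; the narrower control totals
  reflect the stronger incretin sparing in controls;
* the fasting state is closed by `solve_equilibrium()`: given the draw
  and $G_0$, the hormone baselines that make the system stationary are
  computed and $a_2$ is replaced by its equilibrium-consistent value,
  guaranteeing flat pre-infusion trajectories as in the data (a
  range-uniform $a_2$ without the equilibrium constraint remains
  available by using the drawn parameters directly);
* noise is independent multiplicative Gaussian per analyte at the assay
  CVs, truncated at zero.  The assay specification gives only CVs, not
  a law; Gaussian is chosen to match the weighted-least-squares
  likelihood.

One generator subtlety: the hysteresis anchor of a generated subject is
the argmax of the *sampled* noiseless series (iterated to a fixed
point), not of the dense solution.  The fitter necessarily detects the
anchor from sampled data, so anchoring the generator the same way makes
the noiseless refit exactly self-consistent; the dense-grid anchor
remains available through `trajectory_anchor()`.

What the generator does **not** emulate: oral-challenge gut absorption
and incretin responses, first-phase secretion bursts (subjects showing
them were excluded from the original analysis), assay drift, and
correlated measurement error.  Passing recovery tests therefore show
that the estimator inverts the model's own data-generating process at
realistic noise — not that the model is correct for any given clinical
series.

## Study problem sizes

The packaged studies use a 20-subject control cohort at assay CVs for
parameter recovery (median relative errors; single data-informed start
per fit; fit-stage integration tolerances $10^{-7}/10^{-9}$ and a
0.5-min history grid, which move estimates by less than one part in
$10^3$ relative to the tight setting) and 20 + 6 replicates for the
AICc model-comparison study at one quarter of the assay CVs ("low
noise").  Noiseless refits use 3 subjects.  These sizes give stable
medians and majorities while keeping a full run in the minutes range.

## Known limitations

* The glucagon branch switch follows the printed formula and is
  therefore discontinuous by $e^{-k_2 G_{hyst}}$ at the anchor; the
  continuity-corrected mode changes fitted $\gamma_2$/$k_2$ slightly.
* $a_2$ trades off against $\gamma_2$ through the glucagon baseline, so
  its recovery error is intrinsically wider than the other parameters'.
* The manual set $(\tau, \tau_1, \tau_2, k_2)$ is held fixed during
  estimation; uncertainty in those values is not propagated into the
  reported standard errors.
* Infusion records are 15-min block averages of an infusion that was
  actually adjusted every 5 min; the block width is configurable but
  finer records were not available to the original analysis either.

## A minimal session

```{r example, eval = FALSE}
s <- gen_subject("CS", seed = 42)
fit <- fit_model(s$noisy, s$schedule,
                 manual = list(tau = s$params$tau, tau1 = s$params$tau1,
                               tau2 = s$params$tau2, k2 = s$params$k2),
                 group = "CS")
print(fit)

# published-table summary (fixture tables)
tabs <- rbind(iigi_fixture_table("cs_model1"),
              iigi_fixture_table("t2d_model1"))
summarize_parameters(tabs)

# group contrast of glucagon suppression
mann_whitney_exact(iigi_fixture_table("t2d_model1")$k1,
                   iigi_fixture_table("cs_model1")$k1)
```
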