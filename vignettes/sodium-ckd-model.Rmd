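---
title: "Modelling sodium reduction and chronic kidney disease burden with a proportional multistate lifetable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sodium reduction and chronic kidney disease burden with a proportional multistate lifetable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sodiumCKD` simulates what happens to chronic kidney disease (CKD) burden in
an adult population when average dietary sodium falls. The causal chain is
modelled in three steps:

1. **Sodium to blood pressure.** A policy scenario prescribes a sodium
   trajectory: a steady linear reduction from the baseline intake to a target
   over a ten-year ramp, then constant. Each year's cumulative sodium
   reduction is converted into a reduction of mean systolic blood pressure
   (SBP), scaled linearly from trial evidence in which a 4.4 g/day salt
   reduction (about 1720 mg sodium) lowered SBP by 5.39 mmHg in people with
   hypertension and 2.42 mmHg in people without. The two effects are weighted
   by the cohort's probability mass above and below 140 mmHg under a normal
   SBP model, so cohorts with more hypertension respond more strongly. Only
   the mean of the SBP distribution moves; the standard deviation is held
   fixed, consistent with survey evidence that dispersion changes little
   under modest mean shifts.

2. **Blood pressure to CKD incidence.** The effect of an SBP shift on
   incidence is the potential impact fraction (PIF) computed by the
   distribution-shift method:
   $$\mathrm{PIF} = \frac{\int RR(x)\,\phi_0(x)\,dx - \int RR(x)\,\phi_1(x)\,dx}
                         {\int RR(x)\,\phi_0(x)\,dx},$$
   where $\phi_0$ and $\phi_1$ are the baseline and shifted normal SBP
   densities and $RR(x)$ is a log-linear relative-risk function,
   $RR(x) = r^{\max(0,\,x - 115)/10}$: risk multiplies by $r$ per 10 mmHg
   above a theoretical minimum risk exposure level (TMREL) of 115 mmHg and is
   clamped to 1 below it (no protective extrapolation). Four CKD causes are
   modelled with separate relative risks: hypertensive CKD, diabetic CKD,
   CKD due to glomerulonephritis, and other/unspecified CKD.

3. **CKD to population health and costs.** Each cause runs as an independent
   illness–death Markov submodel in annual cycles (healthy → diseased →
   dead-from-cause, zero remission), coupled to an age–sex cohort lifetable.
   The intervention arm's incidence is the baseline hazard scaled by
   $1 - \mathrm{PIF}_t$; lower incidence lowers prevalence over time, and
   cause mortality follows prevalence through the case-fatality hazard. The
   lifetable subtracts the per-cause reduction in death flows from all-cause
   mortality, accumulates survivorship and person-years, and weights life
   years by $1 - \mathrm{YLD}$ (all-cause, for the comparator arm) plus the
   disability averted through prevented CKD prevalence, yielding
   health-adjusted life years (HALYs). Prevented prevalent cases times
   per-case annual expenditure gives healthcare-cost offsets, discounted to
   the base year.

Both arms — business-as-usual (BAU) and intervention — are simulated
simultaneously for a closed cohort of adults alive in 2019 (fifteen
five-year age bands from 25–29 to 95–99, by sex), in annual cycles until
death or age 100. Differences between the arms are the policy impact.

## Key equations and numerical choices

**Markov cycle.** With constant hazards $i$ (incidence) and $f$ (case
fatality) within a cycle, the illness–death ODEs
$S' = -iS$, $C' = iS - fC$ have the exact solution used for each one-year
step:
$$S_{t+1} = S_t e^{-i},\qquad
  C_{t+1} = C_t e^{-f} + i S_t \frac{e^{-f} - e^{-i}}{i - f},$$
with the limit form $i S_t e^{-i}$ taken when $|i - f| < 10^{-12}$.
The closed form is exact for constant hazards, so there is no step-size
error; tests verify it against fourth-order Runge–Kutta integration at
$dt = 10^{-4}$ to within $10^{-6}$. Proportions are conditional on survival
from other causes, which is what makes the submodels "proportional" and
lets them couple to the lifetable through death-flow differences only.

**Case fatality.** Cause-specific mortality among prevalent cases is rarely
observed, so it is derived from the observed epidemiology. The default
`ode_consistent` method inverts the illness–death dynamics: marching up the
age bands, it finds by bisection (tolerance $10^{-8}$) the case-fatality
hazard under which observed prevalence at one band evolves into observed
prevalence at the next. This exploits the fact that the prevalent proportion
$u = C/(S+C)$ obeys $du/da = (1-u)(i - fu)$, independent of the absorbed
states, so the inversion is exact when the inputs are internally consistent.
The `ratio` method ($f = m_d / p_d$) is the fast fallback and the default
inside the probabilistic sensitivity analysis, where thousands of bisections
per draw would add cost without changing the headline uncertainty. Where
observed prevalence rises faster than incidence alone can explain, the
hazard is clamped at zero; the terminal band uses the ratio.

**PIF quadrature.** Risk integrals use adaptive quadrature on
$[\mu - 10\sigma,\ \mu + 10\sigma]$ with absolute tolerance $10^{-10}$; the
truncated tail mass is negligible at ten standard deviations. A
million-sample Monte-Carlo oracle agrees to within $10^{-3}$ across a grid
of means and standard deviations spanning the survey range. Because the
sodium ramp is flat after ten decrements, only eleven distinct PIF values
exist per stratum and cause; the engine computes exactly those.

**Lifetable.** Survivorship declines as $l_{t+1} = l_t e^{-M_t}$; person
years use the trapezoid $L_t = (l_t + l_{t+1})/2$. The intervention
all-cause rate is the BAU rate minus the summed per-cause reductions in
death flows — an additive adjustment on rates, the standard proportional
multistate lifetable practice. A negative adjusted rate is an error, never
silently clamped.

**Background disability.** Crude disability weights are cause YLD divided by
cause prevalence. The background correction is multiplicative:
$dw_{adj} = dw_{crude} \times (1 - \mathrm{YLD}_{other})$, where
$\mathrm{YLD}_{other}$ excludes the four CKD causes. This treats background
disability as multiplicative comorbidity, so the HALY gain per prevented
case is the disability that case would actually have added. A subtractive
form is available (`correction = "subtractive"`) for comparison; it is more
conservative and can floor at zero.

**Horizons and discounting.** The "2030" reporting window covers the eleven
annual cycles 2019–2029 (the ramp reaches its target at the start of the
2029 cycle, so the target holds throughout the final reported year); the
lifetime horizon runs to 2093, when the youngest 2019 cohort reaches 100.
Discounting divides by $(1+r)^{y-2019}$, so the base year is undiscounted
and discounting first bites in 2020. Defaults follow the reference analysis:
HALYs undiscounted and costs at 3%, with 3%/5% sensitivity settings. Costs
accrue to prevalent cases counted at each cycle start for the full year; no
mid-year accrual.

## Design choices where the design was open

- **Exposure is cohort-attached.** Each cohort carries the sodium level and
  SBP distribution of its 2019 age band throughout the simulation, with the
  scenario's reductions applied over calendar time; disease rates (incidence,
  case fatality, background mortality and YLD, costs) are age-attached and
  looked up at the cohort's current band. This matches a design in which
  age–sex cohorts are the simulation unit and exposure trends are assumed
  stable.
- **Sodium–salt conversion** is fixed at the NaCl mass fraction, 393.4 mg
  sodium per gram of salt. Published figures often pair 9.6 g salt with
  3700 mg sodium and 5 g with 2000 mg; those roundings are mutually
  inconsistent, so scenario targets stated in sodium (the 2000 mg dietary
  target) are applied in sodium units directly and salt-denominated
  scenarios convert at 393.4.
- **Absolute sodium targets** are met as a population-weighted mean, with
  every stratum reduced by the same relative factor. A per-stratum cap
  (`stratum_cap = TRUE`) is available: it reduces only strata above the
  target, leaving low-intake strata untouched.
- **A single relative-risk function per cause applies to incidence.**
  Mortality responds through the chain incidence → prevalence → case
  fatality, not through a second direct risk function, so morbidity and
  mortality effects cannot be double-counted.
- **PSA correlation structure.** One draw of each uncertain parameter
  applies to all strata (fully correlated across age and sex): the
  uncertainties are survey- or meta-analysis-level, not stratum-level
  sampling noise. Scenario contrasts reuse the same draw stream (common
  random numbers), which removes draw noise from between-scenario
  differences. Lognormal relative-risk draws are centred on the central
  estimate (as the median) with the CI supplying the log-scale width, so
  degenerate intervals collapse exactly onto the point estimate.
- **Uncertainty intervals** are empirical 2.5th/97.5th order statistics of
  the draws, never a normal approximation.

## The synthetic-data generator

Real inputs of this kind come from burden-of-disease tools, national health
surveys and health-expenditure databases, stratified by five-year age group
and sex. The generator produces a complete synthetic substitute with the
same structure and realistic magnitudes:

- an adult (25+) population pyramid of about 17.1 million with a declining
  male share at older ages;
- Gompertz all-cause mortality by sex, with the terminal (95–99) band
  inflated so survivorship effectively closes by age 100;
- baseline SBP distributions fixed to an embedded survey table
  (`table1_fixture()`), ten-year bands mapped onto the five-year grid by
  duplication;
- a midlife-peaked, male-dominant sodium pattern rescaled so the
  population-weighted mean is exactly 3700 mg/day (about 9.6 g salt) — the
  age/sex pattern itself is a smooth stand-in, since the underlying survey
  pattern is not published;
- per-cause CKD incidence and case-fatality hazards rising with age, with
  prevalence obtained by forward-simulating the illness–death process from
  age 25. This makes the bundle epidemiologically self-consistent: the
  case-fatality derivation can recover the generating hazards, and with no
  intervention the submodels track the input prevalence;
- cause YLD generated as a fixed true disability weight (0.08–0.15 by
  cause) times prevalence, so weights recovered downstream are plausible by
  construction;
- annual CKD expenditure of roughly AUD 2.4 billion distributed over strata
  in proportion to prevalent cases, with cause-specific per-case costs.

The `realism = "noisy"` mode perturbs scales with lognormal jitter and adds
a smooth age wiggle to incidence while preserving every invariant
(monotone age gradients, prevalences summing below 1, cause mortality below
all-cause mortality). Identical seeds give identical bundles.

What the generator does **not** emulate: survey design effects and sampling
weights, secular trends in sodium or blood pressure, within-person
comorbidity between the CKD causes, CKD staging, and the true (unpublished)
age–sex sodium pattern. Passing tests on synthetic bundles therefore
demonstrate that the machinery is correct and internally consistent — the
arithmetic identities, conservation laws, orderings and uncertainty
behaviour — not that any particular national estimate is reproduced.
Headline national results depend on the actual stratified inputs, which are
not distributed with this package.

## Problem sizes used in the test suite

The suite exercises the full 30-stratum, 4-cause, 75-year model — a single
scenario run takes under a second — and scales the Monte-Carlo components
to what the properties need: a $10^6$-sample oracle for the PIF grid, 100
random hazard pairs against RK4 for the Markov cycle, and a 200-draw
sensitivity analysis for interval behaviour (the production default is
2000 draws; interval endpoints stabilise long before that, and the
point-inside-interval and zero-width properties being tested do not depend
on the draw count).

## Known limitations

- The sodium effect on CKD is modelled entirely through systolic blood
  pressure; any direct renal effect of sodium is excluded, which likely
  makes estimates conservative.
- A single case-fatality hazard per cause and stratum pools all CKD stages.
- The closed cohort excludes births and migration, so "lifetime" totals
  refer to adults alive in 2019 only.
- Relative risks default to age-constant within each cause; the underlying
  evidence suggests attenuation at old age. Age-specific risk tables can be
  supplied through the bundle's effect parameters if available.
- The equal-relative-factor interpretation of an absolute population target
  is one of several defensible readings; the stratum-cap alternative is
  provided but not the default.
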