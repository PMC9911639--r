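---
title: "Methods: a discrete-event microsimulation of advanced NSCLC treatment strategies"
author: "nsclcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete-event microsimulation of advanced NSCLC treatment strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclcsim)
```

## The model

`nsclcsim` simulates individual patients with advanced (inoperable)
non-squamous non-small cell lung cancer from diagnosis to death in continuous
time. The pathway has five events — diagnosis (DIAG), the starts of up to
three systemic treatment lines (L1T, L2T, L3T) and death — and seven
transitions:

* `diag_l1t` and `diag_death_bsc`: after diagnosis a patient either starts
  first-line treatment or receives best supportive care (BSC) until death.
  The treated-vs-BSC split is a logistic regression on baseline attributes;
  *given* that decision, the time to first-line start and the BSC survival
  time are drawn from two independent parametric distributions. These two
  transitions are deliberately not modelled as competing events: the decision
  is made once, at diagnosis.
* `l1t_l2t`/`l1t_death`, `l2t_l3t`/`l2t_death`, `l3t_death`: from each
  treatment line the start of the next line competes with death from disease.

Competing transitions use *event-specific distributions*: each cause keeps
its own cause-specific time-to-event law, one time is drawn per cause, and
the earliest event wins. This makes it possible to modify a single
transition's hazard (for instance a treatment effect on progression) without
re-deriving a joint event-type model. Exact ties are broken deterministically
with death taking precedence over a next-line start; in continuous time this
is a probability-zero event, but the rule keeps runs bit-reproducible.

All transition clocks are **semi-Markov**: each clock restarts at 0 on entry
into a line. This is the only clock convention the package supports, and it
matches how the transition models are estimated (each line's rows start at
line-local time 0).

Death from other causes (background mortality) runs on the global clock. It
is sampled once per patient at diagnosis from an age- and sex-specific life
table and compared with every disease event: if it comes first, the patient
dies of other causes. Because the background hazard is a deterministic
function of attained age, drawing the full background time once at diagnosis
is equivalent to re-drawing conditionally at every line entry, and much
cheaper.

## Parametric families

Five families are available, in two groups.

Proportional-hazards families, parameterized through the baseline cumulative
hazard $H_0(t)$ with covariates and external hazard ratios acting
multiplicatively on the hazard ($h(t\mid x) = h_0(t)\,e^{x'\beta}\,\mathrm{HR}$):

| family | baseline | parameters |
|---|---|---|
| exponential | $H_0(t)=\lambda t$ | rate $\lambda$ |
| Weibull (PH form) | $H_0(t)=\lambda t^{\gamma}$ | shape $\gamma$, rate $\lambda$ |
| Gompertz | $h_0(t)=\lambda e^{\gamma t}$ | shape $\gamma$ (any sign), rate $\lambda$ |

The Weibull is used in its proportional-hazards parameterization (not the
accelerated-failure-time form of `stats::rweibull`) so that covariate
coefficients are log hazard ratios in every PH family. A negative-shape
Gompertz is improper: $S(\infty)=\exp(\lambda/\gamma) > 0$, and the sampler
returns `Inf` for the patients who never experience the event. This is a
feature, not an edge case — it is how a real-world fit expresses that a
fraction of first-line patients never progress.

Accelerated-failure-time families (log-logistic, log-normal) act on the time
scale, $S(t\mid x)=S_0(t\,e^{-x'\beta})$, and are used for the two
DIAG-phase transitions, where the PH constraint is not needed. An external
hazard ratio is undefined for them and is rejected.

Event times are sampled by inversion of the covariate-adjusted cumulative
hazard ($t = H^{-1}(E\mid x)$ with $E\sim\mathrm{Exp}(1)$), which handles
proper and improper laws, external hazard ratios and the wear-out composite
uniformly.

## Fitting

`fit_parmssm()` estimates the whole pathway from a one-row-per-patient
registry. `prep_multistate()` expands the registry into long-format
transition rows: the competing transition that did not occur is censored at
the time of the one that did, and patients alive at the end of follow-up are
administratively censored. Records with inconsistent event times are rejected
with a per-record reason rather than silently dropped.

Each transition is fitted by right-censored maximum likelihood
(`flexsurv::flexsurvreg`), maximizing
$\sum_{\text{events}}\log h(t_i\mid x_i) + \sum_{\text{all}}\log S(t_i\mid x_i)$.
Covariates are chosen by backward selection on Wald p-values with a cutoff of
0.05 by default: refit, remove the largest p-value above the cutoff, repeat.
Wald tests keep the procedure at one fit per step and make it deterministic
given the data; likelihood-ratio tests would double the fits for no change in
the selected sets at these sample sizes. Two practical safeguards matter on
sparse transitions (a few dozen third-line patients): candidate covariates
without variation in a transition's rows, or collinear with others, are
inestimable and are dropped with a record on the fit object; and if the
default optimizer start fails, the fit is retried from crude moment starting
values before reporting an estimation error.

The default family plan is log-logistic for `diag_l1t`, log-normal for
`diag_death_bsc`, Gompertz for the two first-line transitions and exponential
for the later lines — the third line has too few patients to support more
than one parameter. Family choice beyond the defaults is the user's: the
`plan` argument takes any family per transition, and `AIC`/`logLik` are
reported per fit for ranking; the package does not attempt automatic family
selection by eye.

## Personalized strategies

A strategy object bundles everything that distinguishes personalized care
from uniform chemotherapy:

* **Biomarker prevalences.** A driver alteration (classic/non-classic EGFR,
  ALK, ROS1, BRAF, NTRK, KRAS, MET, RET, or none) and a PD-L1 category
  (≥50%, 1–49%, <1%) are drawn independently per patient — independence of
  biomarkers from clinical baseline attributes is an explicit model
  assumption, not a fact about biology.
* **A decision tree.** Patients with a targetable driver (EGFR, ALK, ROS1,
  BRAF, NTRK) receive the corresponding first-line targeted therapy; all
  other patients — including KRAS/MET/RET, for which no targeted first-line
  therapy is configured — are routed through the PD-L1 branch to
  pembrolizumab alone or with chemotherapy. Second-line treatment depends on
  the first-line treatment (alectinib → lorlatinib; the BRAF combination
  falls back to the PD-L1 branch; everything else → chemotherapy). Third-line
  treatment is always chemotherapy. Tree entries may be mixtures (the classic
  EGFR branch splits 50/50 between gefitinib and erlotinib by default, a
  configurable proportion); mixtures consume one uniform draw and are
  deterministic given it. `validate_strategy()` proves totality — every
  reachable (line, driver, PD-L1, previous-treatment) combination resolves to
  exactly one treatment — at load time, and reports all violations at once.
* **Hazard ratios.** Each treatment carries a hazard ratio applied to *both*
  competing transitions of its line. Only a progression hazard ratio is
  usually available from trials, so assuming the same effect on the
  time-to-next-line and time-to-death transitions is forced; the config
  nevertheless accepts transition-specific ratios (`next_line`/`death`
  entries) where evidence exists. A prognostic hazard ratio per driver
  (default: 0.82 for classic EGFR, 0.80 for ALK) multiplies onto the
  first-line transitions regardless of treatment.
* **Wear-out.** First-line targeted therapy benefit is limited: after a
  switch time $\tau$ (15 months by default) the hazard reverts to the
  unmodified baseline fit, via the composite
  $H(t) = H_{\text{pre}}(\min(t,\tau)) + [H_{\text{post}}(t)-H_{\text{post}}(\tau)]_+$,
  which keeps survival continuous at the switch. Alectinib is exempt
  (durable benefit). `calibrate_wearout()` estimates $\tau$ from data as the
  earliest time at which a modelled durable-benefit curve deviates from a
  reference curve by more than a threshold (default 0.02 absolute survival
  difference) for a sustained run of grid points (default 3) — "starts to
  deviate" has no canonical definition, so both knobs are explicit.
* **Mixture cure for immunotherapy.** A fraction $f$ (default 0.23) of
  patients starting first-line immunotherapy are long-term survivors: they
  leave the disease pathway entirely, are ineligible for second-line
  treatment, and die only of background mortality. The rest (the moderate
  group) progress under the immunotherapy hazard ratio. Whole-arm survival is
  then $S(t) = f\,S_{\text{background}}(t) + (1-f)\,S_{\text{moderate}}(t)$.
  Setting $f=0$ recovers the standard time-to-event distribution.

The hazard-ratio table shipped in `default_strategy()` carries the values the
model's evidence base names explicitly (gefitinib 0.43, erlotinib 0.36,
prognostic EGFR 0.82, larotrectinib 0.82, pembrolizumab 0.5 with $f=0.23$);
the remaining entries (afatinib, alectinib, crizotinib, the BRAF combination,
pembrolizumab–chemotherapy, lorlatinib) are illustrative, literature-typical
defaults and should be replaced by the user's own evidence table for any
substantive analysis.

## Calibrating the input hazard ratio

With a cure fraction $f>0$, applying the trial hazard ratio directly to the
moderate group would double-count benefit: the cured fraction already
improves the arm. `calibrate_in_hr()` therefore root-finds the moderate-group
("input") hazard ratio such that the *whole-arm* ("output") hazard ratio
versus chemotherapy matches the trial target. Three numerical choices make
this robust:

* **Common random numbers.** Every bisection iterate re-simulates both arms
  from the same seed, making the objective effectively deterministic and
  monotone, so bisection converges (about 5–7 iterations for a tolerance of
  0.01 at 50,000 patients per arm, the defaults).
* **Covariate-adjusted Cox estimation.** The output hazard ratio is estimated
  by Cox partial likelihood with the baseline covariates in the model. The
  marginal (unadjusted) arm coefficient is attenuated over heterogeneous
  baselines even when every patient-level hazard is scaled exactly
  (non-collapsibility); adjustment recovers the conditional scale that the
  input hazard ratios live on. Without it, the $f=0$ case would calibrate to
  an input ratio visibly different from the target.
* **Disease-only endpoint.** The calibration endpoint (first-line PFS by
  default: next line or disease death) excludes other-cause mortality for the
  non-cured groups, because the trial ratios being matched describe disease
  events; the cured group's endpoint time is its background-mortality time,
  the only risk it retains. Including background mortality in the comparator
  would attenuate the arm ratio and break the $f=0$ identity.

With $f=0$ the calibrated input ratio equals the target (identity check);
with $f=0.23$ it is larger than the target, and re-simulating under a fresh
seed reproduces the target within twice the calibration tolerance (fixed
point check). Both are asserted in the test suite.

## Validation protocols

`run_internal_validation()` simulates many registry-sized cohorts under the
non-personalized strategy and compares them with an observed registry: per
endpoint (first-/second-/third-line PFS and OS) and per month 1–60, the
observed Kaplan–Meier estimate with Greenwood 95% CI against the distribution
of simulated survival probabilities; plus medians and restricted means.
Simulated cohorts are fully observed (everyone dies), so their survival
probabilities are plain proportions and their means are plain averages;
observed means are restricted to the evaluation horizon, and the simulated
mean is restricted to the same horizon for that comparison. Months beyond the
observed curve's last event are flagged and excluded.

Two coverage numbers are reported, and the distinction matters. The headline
(`overall_coverage`) asks whether the *model's central estimate* — the mean
simulated probability over runs — lies inside the observed CI, per
endpoint-month; under self-consistency (an "observed" registry generated from
the fitted models themselves) this behaves like nominal CI coverage, ~95% on
average. The run-level number (`run_level_coverage`) asks how often an
*individual run* of the same size lands inside the observed CI; even for a
perfectly calibrated model this is capped near
$P(|N(0,2\sigma^2)|<1.96\sigma)\approx0.83$, because the run adds its own
sampling noise on top of the interval's. Judging a model by the run-level
number against a nominal-looking threshold would reject correct models by
construction. Both are reported so users can see the two different questions
answered. Note also that single-realization coverage fractions are volatile:
deviations are strongly correlated across adjacent months of one KM curve, so
the effective number of independent comparisons is far smaller than
5 endpoints × 60 months (we observed central coverage between 0.85 and 1.00
across self-consistency realizations at 100–200 runs).

`run_dsa()` varies the long-term survivor fraction over
$\{0, 0.14, 0.19, 0.24, 0.29, 0.34\}$ (optionally plus the base 0.23),
re-simulating with common random numbers so that the 5-year OS and mean OS
are strictly increasing in $f$.

`reconstruct_ipd()` rebuilds pseudo patient-level data from digitized curve
coordinates plus a numbers-at-risk table, for external validation against
published curves. The dialect: coordinates in $(T_k, T_{k+1}]$ belong to
at-risk interval $k$; candidate events at a coordinate are
$\mathrm{round}(n\,(1-S_j/S_{\text{prev}}))$ with $S_{\text{prev}}$ the
*reconstructed* KM level (so rounding drift self-corrects); censorings are
spread at midpoints of equal subdivisions of the interval, and their count is
iterated until the reconstructed at-risk count matches the published one at
the next interval start. Round trips on simulated 200-patient cohorts with
0–50% censoring reproduce the digitized coordinates within 0.02.

## The synthetic registry generator

Real registries of this kind cannot be shipped, so `generate_registry()`
produces one with the statistical structure the pipeline assumes, and the
whole test suite runs against it. The default `registry_spec()` emulates a
2008–2014 teaching-hospital cohort followed to early 2017: n = 2196; about
65% BSC (logistic decision on performance status, age and comorbidity); BSC
median survival around 2.3 months (log-normal, shorter for bad performance
status and for females); first-line start a median of ~1 month after
diagnosis (log-logistic); Gompertz first-line transitions — with a negative
progression shape, so some treated patients never progress — and exponential
later lines, giving a treated median OS in the 7-month range; administrative
censoring at the follow-up end leaves ~2% of patients alive. All magnitudes
are synthetic defaults chosen once to land in those regimes; they are not
estimates from any real dataset.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: correlation between biomarkers and clinical
attributes (assumed independent), non-proportional covariate effects,
informative censoring, measurement error in event dates, treatment duration
and toxicity, and any post-progression benefit of first-line treatment
(survival after progression is independent of the treatment received). Tests
against the generator establish that the machinery is self-consistent, not
that the shipped parameter values describe any particular population.

## Numerical conventions and problem sizes

* Time unit: months, continuous; event times are never rounded.
* Annual life-table probabilities become constant within-year rates
  $r=-\log(1-q)$; attained age advances on the simulation clock; the last
  tabulated age is a terminal open band.
* Randomness is split into named streams derived from one user seed
  (baseline/BSC draws vs strategy-dependent draws), so the BSC subgroup is
  identical across strategies under a shared seed, and calibration and the
  DSA can hold everything but the parameter of interest fixed.
* Simulated cohorts without a life table and with improper disease laws can
  leave patients alive forever (`t_death = Inf`); supplying a life table
  guarantees termination.
* Suite problem sizes: distribution and competing-risk checks use $10^5$
  draws against Dvoretzky–Kiefer–Wolfowitz bands and 3–4 standard-error
  bounds; parameter recovery uses 100 replicate registries of n = 2196;
  calibration checks use 50,000 patients per arm; the self-consistency
  validation uses 200 runs × 2196. These sizes keep every Monte-Carlo
  tolerance a derived quantity (bands from n) rather than a tuned constant.

## Limitations

Costs, quality-of-life weights and discounting are out of scope (the model
simulates time-to-event outcomes only). No post-progression treatment
benefit is modelled. The cure fraction applies to first-line immunotherapy
only, and cured patients' survival equals general-population survival — an
optimistic assumption that the sensitivity analysis is designed to probe.
The shipped hazard-ratio table is illustrative outside the explicitly
documented values. Generalized-gamma fitting is not provided; the five
shipped families cover the default plan.
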