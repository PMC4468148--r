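---
title: "Value-of-information trial design for a non-inferiority question"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-of-information trial design for a non-inferiority question}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voidesign)
```

## The decision problem

After a deep vein thrombosis (DVT), 20–50% of patients develop
post-thrombotic syndrome (PTS), a chronic and sometimes severe condition
with no effective treatment. Elastic compression stockings (ECS) worn for
two years roughly halve PTS incidence, but they are uncomfortable, a share
of patients needs daily home care to apply them, and more than half of
patients would never have developed PTS anyway. An individually *tailored*
strategy keeps everyone in stockings for six months and then lets patients
without signs of PTS stop. Before adoption, a randomized non-inferiority
trial is needed — and its size can be chosen in two very different ways:

1. **Frequentist**: the sample size needed to show, at one-sided level
   $\alpha$ and power $1-\beta$, that the loss of preventive effect is
   below a margin $\delta$.
2. **Decision-theoretic**: the sample size at which the expected net
   benefit of sampling — the societal value of the information the trial
   will produce, minus its cost — is maximal.

This vignette documents the model behind the second approach, the
parameters that drive it, and the numerical choices made where the design
was genuinely open.

## The cohort model

Four states: *No PTS*, *Mild-to-moderate PTS*, *Severe PTS*, *Death*.
Cycles are 6 months for the first two cycles and 1 year thereafter;
"lifetime" is implemented as a run-until-age-100 cap from a starting age of
60. The cohort starts in *No PTS*.

PTS onset happens only in the three cycles covering months 0–24 — the
window covered by the incidence evidence; no later onset is modelled. The
cumulative incidences at 6, 12 and 24 months under two-year ECS therapy
(21.1%, 22.2%, 24.5%, each with a standard error) are converted to
interval-conditional onset probabilities

$$q_1 = c_6,\qquad q_2 = \frac{c_{12}-c_6}{1-c_6},\qquad
  q_3 = \frac{c_{24}-c_{12}}{1-c_{12}},$$

which recompose the cumulative curve exactly. New PTS splits
mild-to-moderate vs severe by a fixed proportion (default 0.8/0.2); the
severe state is entered directly, with no later progression between PTS
severities — the evidence names the states but no transitions among them,
so the simplest consistent structure is used.

The tailored strategy differs in three ways:

- a **relative risk** $rr \ge 1$ multiplies $q_2$ and $q_3$ (tailoring
  starts at the 6-month visit, so the first interval is common);
- only a fraction of patients (default 50%) continues wearing stockings
  after month 6, reducing ECS costs and ECS disutility;
- nothing else: PTS care costs and disutilities are identical across arms.

Background mortality is age-specific Gompertz, $h(a) = A e^{Ba}$, with
$A = 3.785631\times 10^{-5}$, $B = 0.09$ — a synthetic life table
calibrated so that life expectancy at birth is 80 years (about 23 remaining
years at age 60), a realistic figure for the population of interest. PTS
confers no excess mortality.

Rewards accrue on the occupancy at cycle start; discounting uses annual
compounding evaluated at cycle start (no half-cycle correction — the
convention is isolated in `discounted_ce()`, so changing it is a one-line
edit). Discount rates follow Dutch guidance: 4% for costs, 1.5% for
effects. Costs per cycle are PTS state costs plus ECS costs (stocking plus
the home-care share) while worn; QALYs are an age-declining norm utility
minus PTS and ECS disutilities, clamped at zero with a warning if a draw
pushes a utility negative.

## Parameters and priors

| parameter | prior | default (SE) | units | source status |
|---|---|---|---|---|
| $c_6, c_{12}, c_{24}$ | Beta (moment-matched, on interval scale) | 0.211 (0.0429), 0.222 (0.0431), 0.245 (0.0454) | probability | published |
| $rr$ | lognormal, median 1, censored at 1 | $\sigma_{\log} = 0.612$ | ratio | published |
| disutility mild/severe PTS | Beta | 0.117 (0.050) / 0.218 (0.040) | utility | published |
| ECS disutility | Beta | 0.02 (0.01) | utility | placeholder |
| PTS cost mild/severe | Gamma | 3000 (750) / 6000 (1500) | EUR/yr | placeholder |
| stocking cost | fixed | 100 | EUR/yr | placeholder |
| home-care share, cost | Beta, Gamma | 0.075 (0.02), 10000 (2500) | –, EUR/yr | placeholder |

Distribution families follow standard health-economic practice: Beta for
proportions and (dis)utilities, Gamma for non-negative costs, both fitted
by moment matching so the analytic mean and SE equal the published numbers
to $10^{-10}$ relative error.

Two choices deserve emphasis:

**Joint incidence sampling.** The three cumulative incidences are published
with SEs but without their dependence. Sampling them independently would
produce non-monotone draws. Instead the three *interval-conditional*
probabilities are sampled independently from moment-matched Betas and the
cumulative values recomposed — monotone by construction, with interval SEs
obtained by variance differencing on the cumulative scale so the recomposed
spread approximates the published one. This avoids ad-hoc rejection
sampling.

**The censored relative risk.** The prior has log-scale mean 0 and
$\sigma_{\log} = 0.612$, putting the upper 95% limit at
$e^{1.96 \times 0.612} \approx 3.32$ — the relative risk that maps the
24.5% two-year incidence to about 32%, i.e. the 7.5-point margin expressed
on the incidence scale. Draws below 1 are rounded up to 1: tailored therapy
is assumed at best equal to two-year therapy. Consequently the censored
prior mean is $\Phi(0) + e^{\sigma^2/2}\Phi(\sigma) \approx 1.38$.

Placeholder values (marked `appendix_default` in the shipped YAML) stand in
for quantities the published evidence base does not report in full:
PTS treatment costs sit at the literature's "$7000 per patient per year"
scale, split across severities; the stocking (EUR 100/yr) and home-care
(7.5% of patients at EUR 10,000/yr) figures follow the case description;
utility norms decline linearly from 0.85 at age 60. They were chosen once,
on field-typical scales, and are all overridable; euro-denominated outputs
are therefore scale-faithful, not exact reproductions.

## Bayesian updating of trial evidence

A simulated trial of total size $n$ (1:1 allocation) yields per-arm
multinomial counts over {onset in 0–6, 6–12, 12–24 months, PTS-free}. The
updating mechanism is conjugate and closed-form:

- **Interval incidences** (standard arm only, since these parameters
  describe standard therapy): interval $i$ with $x_i$ onsets among $m_i$
  at risk gives $\mathrm{Beta}(\alpha_i + x_i,\ \beta_i + m_i - x_i)$.
- **Log relative risk**: because $rr$ acts on the post-6-month
  probabilities, the data summary is the ratio of post-6-month onset
  proportions among patients PTS-free at month 6 (using the 24-month
  marginal ratio instead would attenuate the estimate — a true $rr = 2$
  would look like 1.14). The summary's delta-method SE feeds a
  precision-weighted normal update of $(\mu_0 = 0, \sigma_0 = 0.612)$;
  posterior draws are censored at 1 like the prior. Trials with zero
  post-6-month events (or non-events) in either arm keep the prior and are
  counted in the EVSI diagnostics rather than silently continuity-corrected
  — at $n = 25$ most simulated trials are in this category, which is
  itself informative about tiny trials.

Parameter-recovery simulations (true $rr = 2$, $n = 5000$) recover the
posterior median within 10%, and all posteriors match brute-force grid
posteriors to 3 decimals on small counts (see the test suite).

## Value-of-information estimators

With NMB $= \lambda H - C$ at $\lambda = €20{,}000$/QALY and common random
parameters across strategies within a draw:

- **EVPI** $= E_\theta[\max_j \mathrm{NMB}] - \max_j E_\theta[\mathrm{NMB}]$,
  from the PSA directly.
- **Population scaling** uses the discounted effective population
  $p = I\,(1-(1+r)^{-L})/r$ (25,000 patients/yr, $L = 10$ years,
  $r = 4\%$ — the cost discount rate — giving $\approx 202{,}772$); for
  EVSI the $n$ trial participants are subtracted from the first-year
  cohort, as they cannot benefit from the information.
- **EVPPI** uses the plain nested (two-level) Monte Carlo estimator —
  no regression metamodels — with the complement parameters redrawn from
  their independent priors.
- **EVSI** simulates a trial per outer iteration, updates the priors, and
  evaluates the posterior decision by an inner PSA in which non-updated
  parameters are redrawn from their priors.

One numerical device matters: in both nested estimators the conditional
expected NMBs are **centred on the comparator strategy** before the max is
taken (the incremental-net-benefit form). Since the conditional expectation
of the comparator's NMB integrates back to its prior mean, the estimand is
unchanged, but the large common NMB level (≈ €287,000 per patient) drops
out of the outer-loop variance; without centring, the Monte Carlo SE at
200×1000 exceeds the EVSI signal itself. Every VOI quantity is returned
with its outer-loop standard error, and the package's tests use 3-SE
tolerances.

## Monte Carlo sizes

The case-study defaults are 10,000 PSA draws and 200 outer × 1000 inner
iterations for EVPPI/EVSI over the grid
(25, 100, 400, 500, 700, 1000, 1500, 5000) — the full analysis completes in
well under a minute on one CPU thanks to the vectorised cohort engine. The
test suite and the `"scaled-down"` case-study mode use smaller loops
(e.g. 50×200 on a 4-point grid), sized so the whole suite runs in tens of
seconds; the scaled-down EVSI estimates carry proportionally larger SEs and
the tests account for that.

## What the synthetic trials do and do not emulate

The trial generator draws a *true* parameter vector from the priors and
produces exact multinomial interval counts under perfect follow-up. It does
not model dropout, non-adherence, interim analyses, or misclassification of
PTS; no treatment switching exists beyond the single 6-month decision
point. Passing tests therefore demonstrate the internal coherence of the
decision-theoretic machinery — prior-to-posterior contraction, the VOI
ordering $0 \le \mathrm{EVSI}(n) \le \mathrm{EVPPI} \le \mathrm{EVPI}$,
enumeration-oracle agreement on discrete toys — not the operating
characteristics of any real trial.

## Known limitations

- The euro outputs depend on the placeholder inputs; with them, EVPI is
  ≈ €550/patient and population EVPI ≈ €112M. How quickly EVSI approaches
  its EVPPI ceiling depends on the updating mechanism: under the conjugate
  scheme here a 500-patient trial resolves roughly half the incidence/RR
  uncertainty, and the ENBS argmax can land higher on the grid than it
  would under a more informative (or more optimistic) update model.
- The severity split is applied at onset with no later progression.
- Ties in the per-draw best strategy are broken toward the comparator;
  under continuous priors they have probability zero.
- Background mortality is synthetic Gompertz rather than a national life
  table; utilities decline linearly with age. Both are config-replaceable.
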