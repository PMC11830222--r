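---
title: "Estimating social inequalities in disability-scheme eligibility, plan allocation, and spending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating social inequalities in disability-scheme eligibility, plan allocation, and spending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndisineq)
```

## The problem

Australia's National Disability Insurance Scheme (NDIS) allocates
individualised support budgets to people with permanent and significant
disability. Whether the scheme operates equitably can be asked at three
stages: who is deemed *eligible* when they apply; how large a *plan*
(personal budget) eligible participants are allocated; and how much of the
available support they actually *spend*. `ndisineq` implements a causal
pipeline for quantifying inequalities at each stage between an inequality
group of interest (women and girls; residents of socio-economically
disadvantaged areas, defined as the three lowest deciles of the Index of
Relative Socioeconomic Disadvantage; or people aged 55 years or older at
the decision date) and its complement, within strata of seven broad
primary-disability groups (sensory, autism, intellectual disability other
than autism, physical, psychosocial, brain injury or stroke, other).

Because the real scheme's unit-record data are confidential, the package
ships a synthetic-data generator whose causal structure is known exactly.
Everything downstream — cohort filters, model fitting, g-computation,
mediation, bootstrap — is exercised and validated against that known truth
and against the marginal counts the scheme has published.

## Causal estimands and estimators

Write $A$ for the exposure flag, $C$ for measured confounders, $M$ for
annualised plan size (dollars), and $Y$ for the outcome (eligibility, or
annualised spending in dollars).

**Total causal effect (TCE).** The TCE is the difference in standardized
mean outcome between setting $A$ to the exposure level and to the
comparator level, averaged over the *standard population* — the stratum's
empirical confounder distribution with both exposure groups combined:
$\mathrm{TCE} = E_C\,[\,E(Y \mid A{=}1, C)\,] - E_C\,[\,E(Y \mid A{=}0, C)\,]$.
For eligibility this is reported per 1000 access requests (a risk
difference times 1000); for plan size and spending, in dollars.

The estimator is Monte Carlo simulation-based g-computation
(`estimate_tce()`): fit a working outcome model, replicate the stratum's
covariate rows with $A$ set to each level, simulate `n_mc` outcome draws
per row from the fitted model, and difference the arm means. Noise draws
are shared between arms (the same uniforms or normals), which removes
between-arm Monte Carlo noise from the contrast and makes swapping the arm
labels negate the estimate exactly. A deterministic plug-in version
(`standardize_analytic()`) averages expected outcomes instead of draws; it
is the package's internal cross-check and the fast estimator used inside
the bootstrap.

**Interventional direct and indirect effects (IDE/IIE).** For spending,
plan size is assumed to mediate part of the effect: budget allocation
differences flow through to spending. `decompose()` emulates a three-arm
target trial on the standard population:

* arm 1: $A$ at comparator; $M$ drawn from the fitted mediator model at the
  comparator level (given $C$);
* arm 2: $A$ at exposure; $M$ drawn at the exposure level;
* arm 3: $A$ at exposure, with the plan-size distribution shifted to the
  comparator level's conditional distribution given $C$.

Then $\mathrm{TCE} = \bar Y_2 - \bar Y_1$,
$\mathrm{IIE} = \bar Y_2 - \bar Y_3$ (the spending difference attributable
to plan-size allocation), and $\mathrm{IDE} = \bar Y_3 - \bar Y_1$
(spending differences at matched plan-size distributions). Because the
same mediator and outcome noise matrices are used in all three arms,
$\mathrm{TCE} = \mathrm{IDE} + \mathrm{IIE}$ is an algebraic identity, and
the suite asserts it to machine precision. Interventional (rather than
natural) effects are used because they intervene on the mediator's
*distribution* and so avoid cross-world assumptions; only the two-way
decomposition is provided.

Arm 3 draws the mediator from its conditional distribution given $C$ at
the comparator exposure level, not from the marginal comparator
distribution and not as a rank-preserving shift. This was a genuinely open
design choice; conditioning on $C$ keeps the intervention comparable
within covariate patterns and, with shared noise, yields the exact
additivity above.

## Working models

* Eligibility: main-effects logistic regression of access-met on exposure
  and prior source of disability support (Australian government, state
  government, none).
* Plan size: Gaussian regression on **log** annualised dollars — plan
  budgets are positive and right-skewed — on exposure plus age group,
  remoteness, severity band, years-in-scheme band, accommodation-program
  flags and prior support.
* Spending: Gaussian regression on annualised dollars, same adjustment
  set, plus the mediator and an exposure-by-mediator interaction
  (included by default, switchable via `causal_spec(interaction =)`);
  including the interaction is standard interventional-effects practice.

All models are fitted within disability-group stratum, never pooled with
group indicators, so every coefficient is stratum-specific. Categorical
covariates enter as full dummy sets with the first level as reference.
Strata with fewer than `min_n = 50` records, or with a single exposure
level, are reported as not estimable rather than extrapolated. Separation
(a constant binary outcome or fitted probabilities collapsing to 0/1) and
zero-variance mediators are errors, not silent results.

## Inference

All intervals are nonparametric percentile bootstraps (`bootstrap_ci()`):
records are resampled with replacement within stratum, the **entire**
fit-and-simulate estimator is re-run per replicate — so intervals reflect
nuisance-model estimation uncertainty end-to-end — and the 2.5th/97.5th
percentiles are reported. The default is 200 replicates, a desk-scale
choice; raise `n_boot` to 1000 for production runs. Replicates in which
the estimator fails are dropped and counted, with an error if more than
10% fail. The interval method is a package design choice (the percentile
bootstrap is the simplest method consistent with reporting 95% CIs on
standardized contrasts); BCa and analytic intervals are out of scope.

## The synthetic-data generator

`synth_config()` fixes the study conditions. Its defaults emulate the
published 2016–22 marginal composition of the scheme: the decision-type
mix (about 69% of access requests decided, 19% cancelled/withdrawn, 7% in
progress, 4% revoked/ceased), the age, prior-support, remoteness and
primary-disability mixes of applicants, and severity/years-in-scheme/
accommodation-flag mixes of participants. The causal coefficients are
fixed plausible magnitudes chosen once: a logit intercept of 1.05 with
prior-support effects (0.40, 0.60) giving a marginal eligibility around
0.74–0.81; an adverse exposure effect of −0.45 on the eligibility logit; a
−0.06 exposure effect on log plan size; and a +0.08 exposure effect on the
logit of budget utilization, so the exposure group spends slightly *more*
than expected given plan size — the qualitative pattern the analysis is
designed to detect (a positive IDE against a negative IIE).

Two DGP families are provided. The default `"scheme"` family draws
annualised plan size log-normally and spending as plan × utilization with
utilization Beta-distributed (precision `phi = 10`) and mean linked to
$A$ and $C$, which guarantees spending never exceeds the plan while
admitting a nonzero direct effect. The `"linear"` family uses identity
links and Gaussian noise throughout; under it the closed forms
$\mathrm{IDE} = d_A$ and $\mathrm{IIE} = b_M\,g_A$
(product of coefficients) hold, which the tests use as an independent
oracle. Confounders are drawn independently — the joint dependence of the
real data is unpublished — unless a correlation structure is added by the
user; an optional `confounding_violation` switch adds a shared latent term
to both $A$ and the outcomes for sensitivity experiments, and is off
everywhere else.

`calibrate_counts()` is the generator's exact mode: a targets table of
integer cell counts is expanded deterministically (no sampling), so the
published access-flow totals — 705 594 requests; 136 199 cancelled or
withdrawn; 52 584 in progress; 30 444 revoked or ceased; 691 with
incomplete demographics; 485 676 included; 393 152 eligible — are
reproduced integer-for-integer and pushed through the real filters. The
printed cancelled/withdrawn total is split evenly between the two types;
both are removed by the same rule, so the split is inconsequential.

What the generator does *not* emulate: joint confounder dependence,
within-person correlation across repeated requests, calendar-time trends,
regional clustering, and any re-identification-realistic microdata
structure. Passing tests therefore demonstrate estimator correctness under
the stated DGP, not fidelity of any particular dollar estimate to the
confidential data.

## Numerical and procedural choices

* **Filter order** follows the published narrative (decision completeness
  → age → most recent request → decided → demographics complete); order
  changes per-line counts but not the final cohort, and the exclusion log
  always conserves totals.
* **Tie-breaks** for "most recent" request/plan: latest date, then highest
  row sequence number.
* **Annualisation** uses a 365.25-day year.
* **Exposure boundaries**: IRSD decile ≤ 3; age ≥ 55 at the decision date
  (applications) or plan start (participants); the strict `> 180 days`
  plan rule.
* **Seeds**: stratum-level seeds are `root + stratum index`; bootstrap
  replicate seeds are drawn once from the root seed. Identical
  (config, seed) runs are byte-identical.
* **Suppression**: output cells with stratum n below 15 (the scheme's own
  disclosure rule) are suppressed in written tables only, after
  estimation.
* **Age-related inequality** is computed for eligibility only: support
  needs rise with age, so an age contrast in plan size or spending is not
  a meaningful inequality; requesting it is a validation error.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at sizes chosen to make Monte
Carlo error small relative to the tolerances while staying desk-scale:
coefficient recovery at n = 50 000; parameter recovery of TCE/IDE/IIE over
200 replicates at n = 20 000 with 20 draws per row (bias below 5% of
truth); bootstrap coverage over 200 simulated datasets of ~1600
applications at 150 replicates each, compared with the exact binomial 99%
band around 0.95; and the discrete-toy oracle comparison at 10 000 draws
per row. The analysis drivers under `analysis/` default to 100 000
applications and 60 000 participants.

## Known limitations

Only measured confounding is handled; the generator's latent-confounding
switch exists precisely to show what unadjusted shared causes do. The
working models are parametric and, under the `"scheme"` family, the
spending model (linear in the mediator with one interaction) is a
deliberate simplification of the generating plan × Beta-utilization
process — the recovery tests that demand exact unbiasedness therefore run
under the correctly specified linear family, and the scheme family is held
to sign/shape and additivity properties. No inverse-probability weighting,
TMLE, machine-learning nuisance estimators, continuous exposures, multiple
mediators, or natural direct/indirect effects are provided.
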