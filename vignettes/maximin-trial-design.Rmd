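---
title: "Maximin planning of two-treatment trials with treatment-dependent costs and variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximin planning of two-treatment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maximindesign)
```

## The planning problem

A two-treatment randomized trial can be run as a parallel group design
(each subject gets A or B once), an extended parallel design (AA or BB over
two periods), or an AB/BA crossover. When the outcome is continuous and
there is no carryover, the crossover is usually the most efficient — but
that received wisdom assumes equal allocation, equal outcome variances
under both treatments, and known intraclass correlations. This package
relaxes all three assumptions and supports a second estimand, the
treatment-by-period interaction, which the two-period designs can test.

## Model and parameterization

All computations start from a heteroscedastic linear mixed model: outcome
`y_ij` for subject `j` at period `i`,

$$y_{ij} = \beta_0 + \beta_1\,\mathrm{treat}_{ij} + \beta_2\,\mathrm{time}_{ij}
 + \beta_3\,\mathrm{treat}_{ij}\mathrm{time}_{ij} + u_{0j} + \varepsilon_{ij},$$

with `treat` and `time` coded 0/1, a between-subject intercept
$u_{0j} \sim N(0, \sigma_0^2)$ shared across periods, and within-subject
errors with treatment-specific variances $\sigma_{\varepsilon A}^2$,
$\sigma_{\varepsilon B}^2$. The estimands are $\beta_1$ (treatment effect;
$\beta_3$ set to zero) and $\beta_3$ (interaction). Results are invariant to
the 0/1 coding, so no alternative codings are offered.

The natural planning parameters are the treatment-specific intraclass
correlations $\rho_A = \sigma_0^2/(\sigma_0^2+\sigma_{\varepsilon A}^2)$
and $\rho_B$, because every design comparison depends on the variance
components only through $(\rho_A, \rho_B)$ and the total variance scale
$\sigma_y^2 = \sigma_A^2 + \sigma_B^2$. `icc_to_variance_components()`
inverts the parameterization; the common between-subject variance
assumption means the variance ratio is $\phi = \rho_B/\rho_A$. A zero ICC
is excluded (the closed forms divide by the ICCs); $\rho = 1$ — zero
within-subject error — is allowed and handled throughout, including in the
simulator, where a zero-variance pooled t-test is resolved by the exact
separation convention (reject iff the mean difference is nonzero).

Effect sizes are standardized as $ES = \beta_x / \sqrt{0.5\,\sigma_y^2}$.
The package defaults to $\sigma_y^2 = 2$ wherever a scale must be fixed, so
that `ES` and the raw effect coincide; every reported comparison is
scale-free, so this is purely a convenience.

## Budget and optimal allocation

The budget function charges `c_A`, `c_B` per treatment per subject, `c_t`
per measurement, `c_sp` (one-period) or `c_s2p` (two-period) per subject,
and `c_ts` per sequence. Since all three designs have two sequences, the
net budget `C = C* - 2 c_ts` is comparable across designs. Two special
cases are built in: `subject_count_costs()` (budget = number of subjects)
and `measurement_count_costs()` (budget = number of measurements).

For each design, `variance_at_allocation()` gives the asymptotic variance
of the ML estimator at any split `p` of subjects over the sequences, and
`optimal_allocation()` / `optimal_variance()` give the minimizing ratio and
its variance in closed form. A deliberate internal convention: the
per-subject cost coefficients of the extended parallel design are
`2c_A + 2c_t + c_s2p` and `2c_B + 2c_t + c_s2p` — each subject is measured
twice — which keeps `optimal_variance()` exactly equal to
`variance_at_allocation()` at the optimal `p` under the budget identity.
That consistency is enforced by tests over randomized costs, ICCs, and
budgets, alongside a dense-grid check that no allocation beats the closed
form (tolerance 1e-9).

## Maximin designs

Intraclass correlations are rarely known before the trial; plausible ranges
are. Given a rectangle $[\rho_A^L,\rho_A^U]\times[\rho_B^L,\rho_B^U]$,
`maximin_params()` finds the ICC pair with the largest optimal-allocation
variance. Planning at that pair guarantees the power target everywhere in
the rectangle, and the design minimizing this worst-case variance is the
maximin choice.

For the crossover the worst case is simply the lower-left corner (treatment
effect; the variance is decreasing in both ICCs) or the upper-right corner
(interaction; increasing in both). For the parallel design the variance
depends on the ICCs only through $\phi = \rho_B/\rho_A$, maximized at
$\phi^* = (c_A+c_t+c_{sp})/(c_B+c_t+c_{sp})$; if the $\phi^*$ locus crosses
the rectangle the maximin value is constant along it and the reported pair
is a representative point (the one with the largest feasible $\rho_B$),
otherwise the nearer corner in $\phi$ wins. For the extended parallel
design a five-branch cascade selects among edge stationary points and
corners, driven by the cost ratio
$\lambda = (2c_A+2c_t+c_{s2p})/(2c_B+2c_t+c_{s2p})$.

Cascades transcribed from printed conditions are fragile, so the
implementation never trusts them alone: every call also evaluates the
variance over the full candidate set — the four corners, the feasible edge
stationary points, and the $\phi^*$ locus representative — and takes the
arg-max. A disagreement between cascade and candidate set raises a warning
and the candidate answer wins. A brute-force grid oracle
(`maximin_grid_oracle()`, default 201 x 201, which locates the maximin pair
to better than 0.005 on a unit range) provides a third, independent route;
the test suite checks agreement on 500 randomized cost/rectangle instances
and verifies the defining dominance property (maximin variance at least the
optimal variance at every grid point) directly.

Two qualitative results are verified as properties rather than assumed:
for the interaction effect the maximin extended parallel design is always
at least as efficient as the maximin crossover, and under a subject-count
budget the maximin crossover never needs more subjects than the maximin
parallel design for the treatment effect. `evaluation_grid()` reproduces
the systematic sweep over cost ratios `CR_A`, `CR_B` in {100, 20, 10, 1,
0.1, 0.05, 0.01} and `CR_p` in {1, 2} with ICC ranges of width 0.10, 0.30,
0.60 and lower bounds 0.01, 0.05, 0.10, ... — e.g. with equal treatment
costs and `CR_p = 1` the crossover is the uniformly best choice once both
ICC lower bounds reach 0.15.

## Sample size and small-sample corrections

`raw_sample_size()` inverts the normal-approximation power relation
$\mathrm{Var} = (\beta_x/(z_{1-\alpha/2}+z_{1-\gamma}))^2$: it computes the
budget at which the optimal variance meets the target and divides by the
per-subject cost at the optimal allocation. This budget route is
algebraically identical to the closed effect-size formulas (e.g.
$n_c = 2((z_{1-\alpha/2}+z_{1-\gamma})/ES)^2(1 - 2\rho_A\rho_B/(\rho_A+\rho_B))$
for the crossover and treatment effect), which the tests verify against an
independent transcription of those formulas; implementing the inversion
once guarantees sample size, variance, and power close the loop to 1e-9.

`maximin_sample_size()` plugs in the maximin ICC pair and converts the
unrounded total into a per-sequence plan. The rounding and correction
rules were chosen to reproduce every checkable published plan and are
stated exactly:

* crossover (analyzed by a pooled-variance t-test, 1:1 allocation): each
  sequence gets the ceiling of half the raw total, then +1 subject per
  sequence at $\alpha = 0.05$ or +2 at $\alpha = 0.01$;
* parallel and extended parallel (unpooled-variance t-tests): the raw total
  is rounded up, split by the optimal proportion to the nearest integer,
  then +2 per arm at $\alpha = 0.05$ when both arms have at least 8
  subjects (else +3), and +4 per arm at $\alpha = 0.01$.

The corrections compensate for planning with normal quantiles while
analyzing with exact t-tests whose variances are estimated; they are
sufficient (slightly conservative) for 80–90% power targets. Two published
interaction-table cells (15 and 51) are not reproducible under any single
rounding order we could find consistent with the other twelve; the package
yields 16 and 52 for them, one or two subjects more, on the conservative
side. They are flagged here rather than special-cased.

## Monte Carlo verification

`simulate_trial()` draws trials from the generating mixed model;
`analyze_trial()` applies the analysis implied by the model, which is exact
at any sample size: pooled-variance two-sample t-tests on within-subject
difference scores (crossover, treatment) or subject means (crossover,
interaction), and Welch unpooled t-tests on raw scores, subject means, or
differences for the parallel designs (the Welch–Satterthwaite degrees of
freedom are used; the summary-score variances are treatment-dependent
there, equal across sequences for the crossover). The tests are validated
against `stats::t.test` on the same summary scores.

`monte_carlo_power()` plans with `maximin_sample_size()` and simulates at a
chosen ICC pair — by default the maximin pair, the worst case the plan must
cover. Replications are individually seeded from a master seed, so results
are reproducible and independent of evaluation order. Simulated power is
judged against the predictive interval
$\pi \pm z_{0.975}\sqrt{\pi(1-\pi)/N_{sim}}$, which separates Monte Carlo
noise from systematic shortfall; at the reference 25,000 replications and
$\pi = 0.80$ this is [0.795, 0.805]. The test suite runs the full set of
published planning scenarios at 2,500 replications (predictive lower bound
0.784) to stay fast; `scripts/acceptance.R` runs the pivotal smallest
scenario (N = 10 crossover, $\rho_A = \rho_B = 0.70$, ES = 0.8) at the full
25,000, where the simulated power lands near 0.813 — above target, as the
corrections are designed to be sufficient rather than exact. Type-I error
calibration at $\beta = 0$ confirms the exactness of the analyses down to
N = 6.

## What the simulator does and does not emulate

The generator matches the planning model exactly: normal outcomes, a
common between-subject variance, treatment-dependent within-subject
variances, no carryover, no dropout, no missing data, and no
prerandomization covariates. Passing simulations therefore confirm the
internal consistency of planning and analysis, not robustness to
violations of those assumptions. Carryover in particular would erode the
crossover's advantage and is deliberately out of scope; treatment-dependent
*between*-subject variances are not modeled.

## Numerical choices

* Normal quantiles come from `stats::qnorm` at double precision; no table
  lookups.
* Ceilings of raw sample sizes subtract 1e-9 first so that a total that is
  an integer up to representation error is not inflated.
* Reported whole-percent and two-decimal efficiencies round half away from
  zero, matching how such tables are conventionally printed (base R rounds
  half to even).
* Ties between designs in `relative_efficiency()` (tolerance 1e-9) are
  reported as co-best; `evaluation_grid()` joins co-best designs with "+".
* In the extended-parallel interaction allocation at $\rho = 1$ the closed
  ratio divides by $1-\rho$; the allocation is then found by direct
  minimization of the variance objective over $p \in (10^{-6}, 1-10^{-6})$.
* ES enters planning through its absolute value (two-tailed tests).

## Limitations

Only two treatments, two periods, and the sequence sets {A, B}, {AA, BB},
{AB, BA} are supported. The engine evaluates closed-form asymptotic
variances; it does not fit mixed models to data (the simulator's exact
t-tests are the intended analyses). Exact noncentral-t sample sizes are
intentionally not used: planning follows the normal approximation plus the
additive corrections, and the simulations verify that this is sufficient.
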