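---
title: "Inferring required activity changes by control analysis and bound contraction"
author: "mcaBounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring required activity changes by control analysis and bound contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcaBounds)
```

## The problem

A metabolic adaptation - say, a tumour cell line responding to a drug - is
usually observed at the systemic level: fluxes change, some metabolite
concentrations change. The interesting causes, however, live at the
molecular level: which transporter and enzyme *activities* had to go up or
down to produce the observed systemic reprogramming? Most activities are
never measured directly. `mcaBounds` infers, for every individual activity,
the tightest interval of log2 fold change consistent with everything that
was measured, and flags the activities whose interval excludes zero: these
are *required* decreases or increases - molecular drivers of the
adaptation - even though they need not be *sufficient* on their own.

## The model

The machinery is Metabolic Control Analysis. For a network of $n$ internal
metabolites and $m$ reactions at steady state, the scaled control
coefficients $C^{x_i}_{v_k} = \partial\log x_i/\partial\log v_k$ and
$C^{J_j}_{v_k} = \partial\log J_j/\partial\log v_k$ describe how every
concentration and flux responds to a fractional change of one activity.
For a finite adaptation the first-order expansion links the log2 fold
changes of all three variable kinds:

$$\Delta\log x_i = \sum_k C^{x_i}_{v_k}\, \Delta\log v_k, \qquad
  \Delta\log J_j = \sum_k C^{J_j}_{v_k}\, \Delta\log v_k .$$

Treating the $n + 2m$ log2 fold changes as decision variables, these
equalities plus box bounds define a polytope. Measured variables carry
tight boxes (their measured confidence intervals, transformed to log2
fold changes); unmeasured variables carry a generic enclosure
$[-E, +E]$. For every variable the package solves two linear programs -
minimise and maximise that coordinate over the polytope - i.e. $2n + 4m$
LPs per problem, yielding the exact interval projection (the analogue of
flux variability analysis, but over concentrations, fluxes *and*
activities simultaneously). A final interval that excludes zero is a fixed
sign. Because the formulation is a linearization, conclusions are
qualitative (signs and trends), not quantitative fold-change predictions.

Interdependent activities can be constrained to move together
(`couplings`): each group adds equalities
$\Delta\log v_a = \Delta\log v_b$, used for isoenzyme pairs catalysing two
network steps and for transcription-factor-driven coordinated blocks.

## Where control coefficients come from

With a fully specified kinetic model (the fixture models shipped in the
package) the control matrix is exact. Under partial knowledge, the package
instead samples *elasticities* under mechanistic constraints and builds an
ensemble of control matrices:

* **Saturation bounds.** A scaled forward-rate elasticity of a
  Michaelis-Menten-type step lies in $(0, 1)$ for substrates and $(-1, 0)$
  for products; cooperative steps extend the bound to the Hill coefficient
  $h$ (`elasticity_upper`). Sampling is uniform on the open interval; the
  distribution is a modelling choice (nothing stronger than the bounds is
  known), opened by a margin $\delta = 10^{-3}$ to avoid exact-saturation
  degeneracies.
* **Thermodynamics.** With the disequilibrium ratio
  $\rho = v_r/v_f \in [0, 1)$ the net-rate elasticity is the sampled
  forward part plus a mass-action term:
  $\varepsilon^v_S = \rho/(1-\rho) + \varepsilon^{v_f}_S$ and
  $\varepsilon^v_P = -\rho/(1-\rho) + \varepsilon^{v_f}_P$. Reverse-rate
  elasticities are never sampled; they follow from
  $\varepsilon^{v_f} - \varepsilon^{v_r} = \pm 1$. Near equilibrium the
  mass-action term diverges, which is why near-equilibrium steps dominate
  uncertainty. Products keep a nonzero elasticity even at $\rho = 0$.
* **Competitive substrate/product pairs.** For a declared pair the sum
  $\varepsilon^{v_f}_S + \varepsilon^{v_f}_P$ must lie in $(0, 1)$; the
  sampler draws the sum first and splits it (direct construction, no
  rejection loop). The thermodynamic terms cancel in the sum, so the
  constraint transfers to the net rate at any $\rho$ - asserted to
  $10^{-12}$ in the tests.
* **Allosteric modifiers** are sampled directly on the net rate:
  activators in $(0,1)$, inhibitors in $(-1,0)$. A metabolite that is both
  reactant and modifier of the same reaction contributes the sum of both
  terms; this is an interpretation (the two effects are mechanistically
  distinct sites) and is documented as such.
* **Moiety conservation** (e.g. NADP + NADPH constant) enters through the
  link matrix with literature concentration *ratios*; absolute
  concentrations are never needed. The control computation uses the scaled
  link-matrix formulation
  $C^x = -L_s (M\varepsilon L_s)^{-1} M$, $C^J = I + \varepsilon C^x$ with
  $M = N_R\,\mathrm{diag}(J)$, which consumes only flux ratios, elasticities
  and moiety ratios; the classical matrix formulations in the MCA
  literature are algebraically equivalent, and equivalence is enforced
  operationally by the theorem suite (summation, connectivity, moiety and
  flux-dependency identities at $10^{-8}$) plus a finite-difference oracle
  on the kinetic fixtures (agreement to $10^{-4}$ relative).
* **Screening.** Matrices with any $|C| > 3.5$ are discarded as
  unrealistically sensitive (the generation tally is recorded); samples
  with condition number above $10^{12}$ in the system matrix are discarded
  as singular.

Each accepted matrix defines one contraction problem; problems whose
constraints are incompatible with the measured domains are counted and
discarded. Sign percentages over the solved problems, and coordinatewise
unions/intersections of the final intervals, summarise the ensemble;
union = intersection marks a conclusion independent of the sampling.
A driver report compares expected directions (from differential gene
expression) with the sign percentages; with the default thresholds
(`strong = 80`, `oppositeMax = 0`) a driver is *supported* when at least
80 % of solved problems fix the expected sign and none fixes the opposite.
The thresholds are package defaults chosen to reproduce the qualitative
labels such published tables use; they are configuration, not measurement.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `enclosure` | 3 | generic bound $E$ on every log2 fold change |
| `sigma` | 0 | additive volume-correction on measured bounds (log2) |
| `ccBound` | 3.5 | control-coefficient magnitude filter |
| `nProblems` | 100 | ensemble size |
| `eps` | 1e-6 | sign tolerance (log2); a bound exactly at 0 fixes no sign |
| `margin` | 1e-3 | open-interval margin of the elasticity sampler |
| `strong`, `oppositeMax` | 80, 0 | driver-verdict thresholds (percent) |

All logs are base 2 end to end; the inference itself is base-invariant,
but every table and report states log2 units. The sign tolerance and the
LP agreement tolerance ($10^{-6}$ against a vertex-enumeration oracle) are
package choices; the LP backend is a bounded-variable two-phase simplex
(dense tableau, Dantzig pricing with Bland fallback) written for this
package because no production LP solver is available in the supporting
stack; it is cross-checked in the tests against an independent
demonstration simplex and against exhaustive vertex enumeration.

## The synthetic data generator

Fixture kinetic models (`fixtureChain()`, `fixtureBranch()`,
`fixtureGlycolysis()`) provide ground truth: mass-action, reversible
Michaelis-Menten and Hill ($h = 2$) rate laws, solved to steady state by a
damped Newton iteration in log-concentration space (residual below
$10^{-11}$ relative, ODE-integration fallback), with analytic elasticities
cross-checked by central finite differences. The glycolysis-style fixture
(5 metabolites, 6 reactions, one NADP/NADPH moiety cycle, one branch)
mirrors the topology a small upper-glycolysis + oxidative-PPP model would
have; its parameter values are package-chosen, not literature values.
`simulateAdaptation()` perturbs limiting rates, re-solves, and emits
measurement tables with lognormal noise (defaults: CV 10 % for fluxes
reported as 95 % CIs, 20 % for concentrations reported as mean ± SD).

At realistic scale, `syntheticCancerNetwork()` builds a deterministic
53-metabolite / 76-reaction central-carbon-style system: a pathway
backbone with shortcut branches, six conserved cofactor pairs with
literature concentration ratios (AcCoA/CoA 0.019 and 0.33, ATP/ADP 8,
NAD/NADH 120 and 6, NADP/NADPH 0.52), fourteen near-equilibrium steps
($\rho = 0.9$), eight competitive pairs, ten modifier assignments, a
coupled reaction pair plus a four-reaction coordinated block, and twenty
boundary processes whose activity domains are slaved to their measured
fluxes. Fluxes are a strictly positive point of the mass-balance null
space within $[0.5, 5]$ (core central-carbon fluxes span about one order
of magnitude; wider spreads give unrealistically extreme scaled
sensitivities on minor branches). `syntheticCancerMeasurements()` plants a
known reprogramming (a coordinated glycolysis-like block down 1 log2 unit,
a coupled pair up 0.5, one oxidative step down 0.7, one anaplerotic step
up 0.8), propagates it through a reference sampled control matrix, and
reports all 76 fluxes (half-width 0.15 log2) and eight concentrations
(half-width 0.25). Interval centers scatter with correlated flux noise
(an activity jitter of 0.1 log2 units propagated through the reference
matrix - joint stoichiometric flux fits satisfy the flux dependencies by
construction - plus independent errors of 0.06 for fluxes and 0.15 for
concentrations), so that a minority of ensemble formulations is genuinely
incompatible and is discarded, as happens with real data.

What passing tests on these fixtures do **not** show about real data: the
generator draws from the same rate-law families the sampler's bounds
assume, its noise is exactly lognormal, its "measured" fluxes come from a
self-consistent linear response rather than an isotope-tracing fit, and
the synthetic network - while matched in scale and structural character -
is not any published network. Conclusions about a real system still hinge
on the quality of its flux estimates, disequilibrium ratios and declared
regulation.

## Numerical choices and degenerate inputs

* Reactions are oriented so net fluxes are nonnegative at load time;
  $\rho$ always refers to the oriented direction. $\rho = 1$ (equilibrium)
  is rejected: net-rate elasticities are indeterminate there.
* Zero net flux is allowed only for boundary processes (scaled
  coefficients are undefined on a zero flux).
* Measured intervals exceeding the enclosure are clipped with a warning
  rather than rejected - the enclosure is an assumption, not data. An
  interval that becomes empty after clipping is an error.
* Feasibility of each problem is decided once (phase-1 LP); per-variable
  LPs reuse the polytope. The reported LP count is $2n + 4m$ even when
  couplings make some activity LPs redundant; `dedupe = TRUE` skips the
  redundant ones and reports the smaller count.
* Final bounds are clipped into the initial box to absorb solver roundoff
  (order $10^{-9}$); idempotence and monotonicity of the contraction are
  property-tested.
* Sign recovery experiments use perturbations of 0.28-0.30 log2 units
  against a measurement slack of 0.04 (noiseless arm): identifiability is
  only well-posed when the perturbation clearly exceeds the data
  uncertainty, and with partial concentration data some perturbed
  activities legitimately keep an unfixed sign - the degree of
  identifiability depends on the degrees of freedom around each process.

## Problem sizes used in the shipped checks

The theorem suite samples 200 elasticity sets on each of five topologies
(1000 checks); the projection oracle enumerates polytope vertices on the
two smallest chains for 100 random domain configurations; sign recovery
runs 200 seeded trials over two fixtures; the paper-scale ensemble runs
100 problems (about 41 000 LPs) on the 53 x 76 synthetic network. These
sizes were chosen to exercise every code path at full method scale while
keeping a complete run of the suite comfortably interactive.

## Known limitations

* First-order inference: large adaptations are handled qualitatively;
  no quantitative fold-change prediction is attempted or reported.
* One conservation relation per moiety group (simple conserved sums with
  unit coefficients); general left-null-space conservations beyond moiety
  pools are not modelled.
* The elasticity sampling distribution (uniform within bounds) is an
  assumption; percentages over the ensemble have no formal statistical
  calibration - they quantify sampling dependence, not probability.
* SBML import is out of scope; networks are described in the package's
  JSON schema (`inst/extdata/network-schema.json`).
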