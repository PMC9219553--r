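---
title: "A minimal model family for FT3 homeostasis and adaptation in the HPT axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal model family for FT3 homeostasis and adaptation in the HPT axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hptaxis)
```

## The model

The hypothalamic–pituitary–thyroid (HPT) axis regulates the circulating
thyroid hormones through a cascade: hypothalamic TRH stimulates pituitary
TSH, TSH stimulates thyroidal FT4 production, and FT3 — the biologically
active hormone and the homeostatic target — is produced from FT4 under TSH
stimulation.  The free hormones feed back negatively on both TRH and TSH.
`hptaxis` implements a minimal dimensionless description of this network
as four coupled nonlinear ODEs (variant `sys1`):

$$
\begin{aligned}
\frac{d[\mathrm{TRH}]}{dt} &= \frac{s_1}{k_{134}\,[\mathrm{FT4}][\mathrm{FT3}]} - a_1 [\mathrm{TRH}]\\
\frac{d[\mathrm{TSH}]}{dt} &= k_{21} [\mathrm{TRH}] + \frac{c_2}{k_{234}\,[\mathrm{FT4}][\mathrm{FT3}]} - a_2 [\mathrm{TSH}]\\
\frac{d[\mathrm{FT4}]}{dt} &= k_{32} [\mathrm{TSH}] - a_3 [\mathrm{FT4}]\\
\frac{d[\mathrm{FT3}]}{dt} &= k_{423} [\mathrm{TSH}][\mathrm{FT4}] - a_4 [\mathrm{FT3}]
\end{aligned}
$$

The $1/([\mathrm{FT4}][\mathrm{FT3}])$ feedback terms are the
strong-inhibition limit of Michaelis–Menten repression: in the euthyroid
state the free hormone levels sit far above their Michaelis constants, so
$1/(k + [\mathrm{FT3}]) \approx 1/[\mathrm{FT3}]$.  No saturation
constants are introduced; consequently all states must remain strictly
positive, and the package enforces this at every entry point.

All constants are dimensionless with default value 1 — the model is a
proof of principle about network *structure*, not a calibrated
physiological simulator.  The optional production terms `k43`
(peripheral deiodinase conversion FT4→FT3), `k42` (TSH-dependent de novo
thyroidal FT3) and `drug3`/`drug4` (constant exogenous T3/T4 production)
default to 0 and are switched on by the variants that study them.

Thirteen variants are registered (`hpt_systems()`).  Each modifies
exactly one mechanism of `sys1`: clamping thyroid-hormone feedback onto
TRH (`sys2`, `sys4`, `sys5`) or TSH (`sys3`, `sys6`, `sys7`), coupling
the two TSH production terms multiplicatively instead of additively
(`sys1mod`), removing the TSH·FT4 feedforward onto FT3 (`sys8`), adding
peripheral conversion (`sys9`), de novo secretion (`sys10`), exogenous
hormone (`sys11`), or a seasonal modulation `ptTSH` of the central drive
(`sys12`).

## Equilibria and the three solution routes

A stable equilibrium represents a physiological steady state (euthyroid
at baseline).  The package computes equilibria three ways and
cross-checks them (`hpt_crosscheck()`):

1. **Root finding** (`hpt_equilibrium()`): a damped Newton iteration on
   the four equilibrium conditions with analytic Jacobians.  Steps are
   projected into the positive orthant by step-halving, and each
   accepted step must reduce the residual max-norm.  Tolerances:
   residual $10^{-10}$, relative step $10^{-12}$.  If the damped
   iteration stalls far from a root (this can happen from the all-ones
   guess at parameter-space corners, e.g. `sys3` with small `k32` and
   `a3`), the solver rides the flow with a stiff integrator for a
   bounded stretch of model time and resumes Newton — legitimate here
   because every studied equilibrium is attracting.
2. **Closed forms** (`hpt_analytic_ft3()`), for `sys1`, `sys1mod`,
   `sys4`, `sys6`, `sys8`, `sys12`.  For the baseline,
   $[\mathrm{FT3}]^2 = k_{423}(a_1 c_2 k_{134} + s_1 k_{21} k_{234}) /
   (a_1 a_2 a_4 k_{134} k_{234})$ — manifestly independent of $k_{32}$
   and $a_3$ ("perfect homeostasis").  For `sys4`/`sys6`, eliminating
   TRH and FT4 from the equilibrium conditions leaves a quadratic in
   $v = (k_{32}/a_3)\,[\mathrm{TSH}]^2$ whose coefficients do not
   involve $k_{32}$ or $a_3$; FT3 $= k_{423} v / a_4$ follows from its
   positive root.  This generalizes the printed unit-parameter formulas
   (e.g. $[\mathrm{FT3}] = (\sqrt{4c^2+1}+1)/(2c)$ for `sys4` with
   clamp level $c$) to arbitrary parameters, and the tests verify the
   generalization against the Newton solver at random parameter draws.
3. **Polynomial roots** (`hpt_polynomial_ft3()`), for `sys2`, `sys3`,
   `sys5`, `sys7`, `sys9`, `sys10`: elimination reduces the equilibrium
   system to a univariate quartic in FT3, valid with the non-free
   constants at 1.  The elimination squares an intermediate relation,
   which introduces a spurious positive root; the admissible root is
   identified by back-substituting the full state and requiring the
   four equilibrium residuals to vanish (filter at $10^{-8}$).  Outside
   the quartics' validity the function refuses and points to the
   Newton solver, which is authoritative.

Stability is assessed from the eigenvalues of the analytic Jacobian at
the equilibrium.  The flag requires every real part below
$-10^{-8}$ rather than $0$, so a numerically zero eigenvalue is never
reported as stable.  Analytic Jacobians are themselves tested against
central finite differences on random positive states.

## Continuation and the homeostasis classification

`hpt_sweep()` continues the equilibrium branch over an increasing
parameter grid (chiefly `k32`, the FT4 production rate constant,
over $[0.3, 3]$), warm-starting each solve from the neighbouring
solution.  Only natural-parameter continuation is implemented: no fold
or Hopf points arise in the studied ranges, so bifurcation-detection
machinery would be dead weight.  The default grid is linear with 100
points; grid density is an artifact choice — the reproduction target is
the branch shape, not any particular grid.

A branch is classified `preserved` when the relative FT3 span
$(\max - \min)/\min$ is below `epsilon = 1e-6`, else `adapted`.  The
threshold sits four orders of magnitude above the numerical invariance
of the analytic cases ($\lesssim 10^{-10}$) and at least four below
genuine adaptation: the smallest adaptive span in the family is `sys10`'s
$\approx 7.7\%$, whose extra TSH-dependent FT3 source partially
compensates the falling FT4 supply — by design, since that is the
rescue mechanism under study — while `sys2`-like broken-feedback
variants drift by well over 10%.  Over $k_{32} \in [0.3, 3]$ the
classification is: preserved for `sys1`, `sys4`, `sys6`, `sys12`;
adapted for `sys1mod`, `sys2`, `sys3`, `sys5`, `sys7`, `sys8`, `sys9`
(with conversion on) and `sys10` (with de novo secretion on).

Two branch facts worth knowing.  First, `sys10`'s FT3 branch at unit
parameters is symmetric under $k_{32} \to 1/k_{32}$ (FT3 at 0.5 and 2
agree to machine precision), with its minimum at $k_{32} = 1$; on the
linear sweep scale the left limb is therefore the sharper one.  Second,
`sys5` and `sys7` produce identical FT3 quartics — clamping FT4
feedback at the hypothalamus or the pituitary is indistinguishable at
equilibrium.

## Time integration

`hpt_integrate()` uses `deSolve::lsoda` (stiff-capable, switching) with
dense output every 0.5 time units, `rtol = 1e-10`, `atol = 1e-12`,
default horizon 200 time units; at all-ones parameters the systems
settle within about 50 units.  The trajectory is truncated at the first
output point whose right-hand-side max-norm falls below the convergence
tolerance ($10^{-9}$ by default).  Initial conditions for the
convergence demonstrations are all-ones — a package choice, recorded in
output metadata, since nothing pins down a canonical starting state.
Any non-positive state in the reported output is an error naming the
failure time.

## Scenario experiments and normalization

`hpt_run_scenario()` packages the named experiments.  Each scenario
sweeps `k32` while the remaining constants are fixed, drawn once per
sample from stated intervals (uniform, seeded — the minimal assumption
for "parameters chosen within ranges"), or stepped through fixed levels:

- `hypothyroid_onset` — `sys10`, `k32` ∈ [0.4, 1.1], `k423` ∈
  [0.2, 0.3], `k43` ∈ [0.7, 0.8], `k42` ∈ [0.1, 0.2]: progressive loss
  of FT4 production with physiologically proportioned FT3 sources.
- `ntis` — `sys10`, `k32` ∈ [0.8, 1.2] with `k423`, `k43`, `k42`,
  `s1`, `c2` simultaneously depressed: non-thyroidal illness.
- `drug` — `sys11` with constant exogenous T3 and/or T4 production.
- `seasonality` — `sys12` at `ptTSH` ∈ {0.5, 1, 1.5}.
- `peripheral_conversion` / `denovo_t3` — `sys9`/`sys10` with
  `k43` ∈ [0, 1] (zero legitimately switches the term off, so zero
  lower bounds are allowed for pure production constants).

Outcomes are reported raw and as percent change,
$100\,(v - v_{\mathrm{ref}})/v_{\mathrm{ref}}$, against a euthyroid
reference configuration.  For most scenarios the reference is the
sample's own parameter draw at `k32 = 1`, so each sample's curves pass
through zero percent at the healthy production rate.  For `ntis` the
reference is instead the healthy parameterization (`k423 = 0.25`,
`k43 = 0.75`, `k42 = 0.15`, `s1 = c2 = 1`, `k32 = 1`): the illness
scenario depresses many constants at once, and comparing it to its own
diseased draws would hide exactly the depression being studied.  With
this normalization the model reproduces the clinical orderings: at
hypothyroid onset FT3 declines far less (in percent) than FT4
(`ft3_protected = TRUE`), while in non-thyroidal illness FT3 falls
relatively more than FT4.

"Protection" is operationalized as the median percent decline at the
low end of the `k32` sweep relative to the same configuration's own
euthyroid reference.  Under this metric the T3 drug (`drug3 = 0.5`) is
more FT3-protective than the T4 drug (`drug4 = 0.8`): with T3 the FT3
level never drops below its euthyroid reference as `k32` collapses
(and its branch is flatter over the whole sweep), whereas with T4 alone
FT3 falls a few percent below it.  Note that the T3 drug raises the
absolute FT3 level above the drug-free baseline — protection here means
guarding against decline, not proximity to the untreated level.

Whether range parameters should co-vary with `k32` is not determined by
the study design; they are drawn once per sample and held fixed along
the sweep, recorded in the scenario metadata.

## The synthetic cohort generator

`hpt_cohort_fixture()` emulates, at the level of normalized
percent-change structure, the kind of cohort a clinical comparison
would use: one `k32` (and one draw of the scenario's range parameters)
per subject, equilibrium FT3/FT4 in percent-change form, plus optional
independent Gaussian noise on the percent scale.  It is synthetic model
output with noise — it reproduces the generating model's envelope by
construction and therefore demonstrates the comparison pipeline, not
clinical validity.  Real cohorts add everything the generator omits:
measurement error structure, assay cross-reactivity, within-subject
temporal variation, medication, and between-subject differences in
constants the model holds fixed.  Passing the cohort-level tests shows
the pipeline is faithful to the model, nothing more.

## Numerical choices, degenerate inputs, limitations

- Tolerances: Newton residual $10^{-10}$; cross-check pass threshold
  $10^{-7}$; homeostasis `epsilon` $10^{-6}$; stability margin
  $10^{-8}$.
- Tie-breaks: if several polynomial roots pass the back-substitution
  filter (not observed in practice), the smallest-residual root wins.
- Degenerate inputs are rejected with typed errors: non-positive
  hormone levels, zero elimination or denominator constants, inverted
  or degenerate sweep intervals, empty vectors in the normalization
  helpers.
- Problem sizes used by the test-suite and reproduction runs: sweeps of
  100 grid points, scenario envelopes of 200 samples on 25-point grids —
  the branch statistics are insensitive to further refinement.
- Not modelled (out of scope by design): transport delays, circadian
  and ultradian pulsatility, stochastic secretion, binding-protein
  kinetics, TSH glycoforms, and any calibration to physical units.
  Two-parameter bifurcation analysis is likewise out of scope; the
  model family exhibits none in the studied ranges.
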