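---
title: "Modeling post-injury synovial inflammation under sex-hormone modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-injury synovial inflammation under sex-hormone modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synovasim)
```

## The model

After an anterior cruciate ligament (ACL) rupture, platelets entering the
joint release TGF-&beta;, which together with TNF-&alpha; recruits
monocytes from the bloodstream into the synovium. The recruited cells
mature into pro-inflammatory M1 macrophages, which secrete cytokines and
matrix metalloproteinases (MMPs); IL-10 drives their conversion into
anti-inflammatory M2 macrophages. The resident synovial fibroblasts (SFs)
produce a baseline tone of the same mediators. `synovasim` represents this
cascade as a 12-state delayed ODE system: four cell pools (platelets `P`,
`M1`, `M2`, `SF`, cells/mL) and eight mediators (IL-1&beta;, TNF-&alpha;,
IL-6, IL-10, TGF-&beta;, TIMP-1, MMP-9, MMP-1, pg/mL).

Cell kinetics:

* platelets decay exponentially, \(dC_P/dt = -k_{d,P} C_P\);
* M1 gains the chemotactic influx
  \(k_{M,in}\,(f_{TGF}(C_{TGF}) + f_{TNF}(C_{TNF}))\), evaluated at
  \(t - \tau\) with \(\tau = 12\) h to account for the time monocytes need
  to transform into M1 cells (the molecular detail of that transformation
  is not modeled), loses \(k_{M1M2} f_{M1M2}(C_{IL10}) C_{M1}\) to
  conversion and decays with \(k_{d,M}\);
* M2 gains the conversion term and decays with the same \(k_{d,M}\);
* SF concentration is constant (\(dC_{SF}/dt = 0\)).

Each mediator \(x\) follows

\[
\frac{dC_x}{dt} = \Big(\prod_j g_{j,x}\Big) k_{x,M1} C_{M1}
  + k_{x,M2} C_{M2}
  + \Big(\prod_n g_{n,x}\Big) k_{x,SF} C_{SF} - k_{d,x} C_x ,
\]

with a platelet source term \(k_{TGF,P} C_P\) for TGF-&beta; only. The
production term structure is deliberately sparse: MMP-9 has no SF term and
MMP-1 no M2 term; this sparsity is what forces the healthy-joint MMP-9
level to be exactly zero (see below). Feedback multipliers take two forms:
down-regulation \(g(C) = a e^{-bC} + c\) (monotone decreasing, bounded in
\((c, a+c]\)) and up-regulation \(g(C) = 1 + a C/(1+C)\) (equal to 1 at
zero regulator, saturating at \(1+a\)). Production coefficients are
defined from in vitro measurements as \(k_{x,y} = C_x / (C_y t)\)
(linear-in-time production) and decay rates from half-lives as
\(k_d = 0.693 / t_{1/2}\), with the two-digit constant kept as
conventionally printed.

Sex hormones enter as feedback multipliers on M1 production only, constant
over a simulation: estrogen up-regulates IL-1&beta; and down-regulates
IL-10 and IL-6; testosterone up-regulates IL-10 and down-regulates
TNF-&alpha;; progesterone down-regulates TNF-&alpha; and IL-6. A hormone
absent from a scenario leaves production unmodulated even when a fitted
down-regulation has \(g(0) \ne 1\); loaded coefficient files are not
forced to satisfy \(a + c = 1\), but the synthetic generator produces
normalised fits by construction.

## Units

Mediators are carried in pg/mL, cells in cells/mL, time in hours. Hormone
scenarios are specified in pM (estrogen, progesterone) and nM
(testosterone). Because each feedback fit has a fixed half-saturation at
one unit of its regulator, every fit declares the unit it was estimated
in, and the evaluator converts (molar to mass via fixed molecular weights
where needed). In the default set, mediator-regulated fits are declared in
ng/mL — placing the feedback transition inside the post-injury
concentration range — except the two MMP-1 induction fits in SFs, which
saturate at pg/mL so MMP-1 remains responsive to the cytokine levels of
the resolving joint; hormone fits are declared in nM.

## Default parameters and calibration

The default set (`default_parameters()`) fixes half-lives of 1-3 h for the
fast cytokines, 10-20 h for TIMP-1/MMP-9/MMP-1, 1.5 h for platelets and
24 h for macrophages, and per-cell M1/M2 production rates of
\(10^{-5}\)–\(10^{-3}\) pg/cell/h. The SF production coefficients are not
free: they are obtained by inverting the SF-only balance
\(k_{x,SF} F_x(C^\ast) C_{SF} = k_{d,x} C^\ast_x\) at published
healthy-joint concentrations (`healthy_reference_concentrations()`), so
the model's computed pre-injury equilibrium reproduces those values; the
forward steady-state solve in the test suite verifies that this closes to
within 5%.

Chemotaxis defaults (`k_M_in` = 2&times;10<sup>4</sup> cells/mL/h, drives
half-saturating at 1 pg/mL) keep the monocyte influx near its ceiling
while platelets persist, producing an M1 pool of ~10<sup>6</sup> cells/mL
that peaks when the platelet gate closes (~day 4.5) and then decays over
weeks — an acute inflammatory peak within the first five days followed by
gradual decline through day 20.

The platelet gating threshold defaults to 10&times;10<sup>-12</sup>
cells/mL. That value is physically implausible (far below one cell per
joint volume) but is retained as the conventional computational guard
against re-initiation of inflammation; it is exposed in the parameter set
rather than silently corrected. Because platelet decay is a pure
exponential, the gate effectively turns the influx off at
\(t = \ln(C_P(0)/\text{thr})/k_{d,P} + \tau\).

## Numerics

Integration uses `deSolve` (`lsoda`, and `dede` when \(\tau > 0\)) with
relative tolerance 10<sup>-8</sup> and per-class absolute tolerances
(10<sup>-6</sup> cells/mL, 10<sup>-12</sup> pg/mL), since concentrations
span ~10 orders of magnitude. Lagged TGF-&beta;/TNF-&alpha; values come
from the integrator's dense history; queries before \(t = 0\) return the
pre-injury state (zero platelets, healthy mediator levels), so influx
starts only at \(t = \tau\). The maximum step is capped at \(\tau/4\) to
keep the history interpolant accurate, and the analytically located
gate-switch time is inserted into the mesh so the solver steps on the
discontinuity instead of chattering across it. The right-hand side
evaluates feedback at `max(state, 0)` to guard against tiny negative
overshoots; reported trajectories clip negatives to zero and warn if the
clipped magnitude exceeds solver resolution. With \(\tau = 0\) the delayed
and undelayed formulations agree within solver tolerance (tested).

The healthy steady state integrates the SF-only subsystem for up to
5,000 h and then polishes the fixed point with a damped Newton iteration,
certifying convergence by a maximum relative derivative below
10<sup>-8</sup>/h. Mediators with no effective SF production term are
pinned to their structural fixed point of exactly 0 rather than left at
integration roundoff.

## Uncertainty analysis

The Latin hypercube scheme assigns each production and decay coefficient
(feedback fits are not perturbed) a row containing an evenly spaced grid
from \(1-f\) to \(1+f\) (\(f = 0.60\) for the hormone-free analysis,
\(0.20\) for the hormone comparison), independently permuted; column
\(i\) is the \(i\)-th parameter set. Marginal stratification is exact by
construction. The default ensemble size is 2000. For each member the
healthy steady state and injured initial condition are recomputed from the
perturbed coefficients, keeping every member internally consistent;
failures are excluded (never imputed) and more than 1% of them aborts the
run. Summaries report the per-time median and quartiles using linear
interpolation between closest ranks (`quantile` type 7).

Hormone conditions use serum ranges for an adult male (E 1.0–106 pM,
T 8.7–38.1 nM), the early follicular phase ("female low E", E 143–673 pM,
T 0.069–1.38 nM) and the ovulatory peak ("female peak E",
E 2266–2797 pM). Estrogen and testosterone are treated as two extra
hypercube rows drawn from the same seeded stream as the coefficient rows,
so the \(i\)-th hormone draw pairs with the \(i\)-th coefficient column.
Hormones are constant in time; cycle dynamics are out of scope.

## Statistics

For each mediator and each day \(d = 1,\dots,20\) (day 0 is excluded —
initial conditions are identical across conditions), per-sample values at
\(t = 24d\) h are compared across the three conditions with
Kruskal–Wallis, followed by the three pairwise two-sided Mann–Whitney U
tests with Bonferroni correction (\(m = 3\), \(p_{adj} = \min(1, 3p)\)).
The U test reports \(U = \min(U_x, U_y)\) with an exact enumeration
p-value when \(n + m \le 12\) without ties and the tie- and
continuity-corrected normal approximation otherwise; the switchover is
fixed so results do not drift with sample size. Fully tied data return
\(H = 0\). Two-sided alternatives are used throughout.

## Synthetic parameter generator

`generate_nominal_parameters()` emits a complete coefficient set with the
exact symbol structure of the model: half-lives log-uniform in
[0.25, 48] h, SF production implied by a log-uniform draw of the healthy
mediator level (0.01–10 pg/mL for cytokines, 10<sup>4</sup>–10<sup>6</sup>
for TIMP-1, 10<sup>2</sup>–10<sup>4</sup> for MMP-1), M1/M2 rates
log-uniform per class, down-regulation triples with \(a + c = 1\) and
\(c \in [0.05, 0.6]\), up-regulation \(a \in [0.2, 5]\), and hormone edges
with the fixed sign structure above. Candidates are rejection-sampled
(cap 1000) until the simulated injury shows an acute peak of IL-1&beta;,
TNF-&alpha; and IL-10 within the first five days with subsequent decline,
every species bounded. Profiles: `stiff` concentrates mediator half-lives
in [0.25, 2] h; `minimal` zeroes all feedback amplitudes, leaving a linear
network (useful for closed-form oracles).

The generator emulates the *structure and scales* of transcribed
coefficient tables, not their values: passing tests demonstrate that the
pipeline's computations are correct on internally consistent inputs, not
that any particular biological coefficient is accurate. Real coefficient
tables can be supplied through `load_parameter_set()` in the documented
CSV dialect.

`generate_pseudo_observations()` adds multiplicative lognormal noise with
a chosen coefficient of variation to nominal trajectories, mimicking
cross-sectional designs (independent subjects per time point); it does not
emulate within-subject correlation, assay detection limits or
non-lognormal outliers seen in real synovial-fluid panels.

## Problem sizes in the test suite

The packaged tests run the hormone comparison at 200 members per condition
with daily output, the identifiability harness on a 10-day horizon, and
toy ensembles of 2–4 members elsewhere; these sizes were chosen so the
full suite completes in minutes while keeping every statistical check
well-powered for the effect sizes the default model produces. Full-scale
runs (2000 members, hourly output) use the same code paths through
`report_ensemble()` / `report_hormone_comparison()`.

## Known limitations

* The model is well-mixed: no spatial structure, no blood–synovium
  transport, no clotting. "Platelets" are a TGF-&beta;-releasing trigger,
  not a clotting model.
* Neutrophils, IL-8, DAMP signalling, resident synovial macrophages and
  donor-sex (XX/XY) cellular effects are outside the network; the healthy
  MMP-9 level of exactly 0 is a direct consequence of omitting resident
  macrophages from the pre-injury state.
* Hormone concentrations are constant; contraceptive formulations and
  post-menopausal profiles are not represented.
* Progesterone's default fits make it essentially inert at physiological
  synovial concentrations (E+P differs from E alone by <1% at 990 pM);
  substantially stronger fitted progesterone effects would need a
  transcribed coefficient table.
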