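---
title: "Cybernetic modeling of eicosanoid enzyme competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cybernetic modeling of eicosanoid enzyme competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyberlipid)
```

## The biological system and the modeling idea

In stimulated macrophages, arachidonic acid (AA, omega-6) and the dietary
omega-3 fatty acids EPA and DHA compete for the same cyclooxygenase (COX)
pool. AA is oxygenated to the unstable endoperoxide PGH2 and onward to
proinflammatory 2-series prostaglandins; EPA yields PGH3 and the
antiinflammatory 3-series prostaglandins; DHA yields a terminal electrophilic
oxo-derivative (PD). How the shared enzyme divides its synthesis and activity
between the competing substrates is regulated at many levels that are not
individually measurable.

The cybernetic framework replaces that unknown regulation with a hypothesis:
the cell allocates enzyme resources to maximize a biological goal, here the
combined consumption of AA and EPA (equivalently the combined production flux
of PGH2 and PGH3, since those are the sole COX products in the network).
Dimensionless control variables implement the allocation:

* activity (matching law): $v_i = \rho_i / \max_j \rho_j$,
* synthesis (proportion law): $u_i = \rho_i / \sum_j \rho_j$,

with $\rho_i = k_i\,[\mathrm{eCOX}]\,[S_i]$ the flux of controlled conversion
$i$. By construction $\sum_i u_i = 1$ and $\max_i v_i = 1$. When every flux
is zero (e.g. at $t = 0$ with no enzyme), we take $u_i = 1/n$, $v_i = 1$, so
the model degenerates to unregulated mass action; the choice only matters on
a measure-zero set and keeps the right-hand side defined everywhere.

Because both conversions share one enzyme pool, the enzyme level cancels from
$v$: `simplified_v()` depends only on substrate levels and rate constants,
and activity dominance transfers exactly at the substrate ratio
$[\mathrm{AA}]/[\mathrm{EPA}] = k_{PGH3}/k_{PGH2}$ (`switch_ratio()`,
`switch_surface()`). That ratio is the model's headline identifiable
quantity.

## The ODE system

States (EPA variant, 13 equations): nine metabolites — PGH2, PGD2, PGE2,
PGJ2, 15-deoxy-PGD2 (`dPGD2`), dhk-PGD2, PGH3, PGD3, PGE3 — and four enzymes
— `eCOX`, `ePtgds`, `ePtges`, `edhkPGD2`. AA, EPA (or DHA) and ATP are
measured *inputs*: their time courses are interpolated (piecewise-linearly,
so interpolation can never produce negative concentrations; constant beyond
the last point) and drive the system. The DHA variant keeps the AA branch and
replaces the 3-series branch by the single controlled conversion
DHA $\to$ PD with no downstream reactions (11 states).

The controlled conversions carry $v$ and an ATP modulation factor
$(1 + k_{ATP}[\mathrm{ATP}])$ — basal COX activity plus the
stimulus-inducible component:

$$\frac{d[\mathrm{PGH_2}]}{dt} =
  v_{PGH2}\,k_{PGH2}[\mathrm{AA}][\mathrm{eCOX}](1 + k_{ATP}[\mathrm{ATP}])
  - g_{PGH2}[\mathrm{PGH_2}]
  - k_{PGD2}[\mathrm{PGH_2}][\mathrm{ePtgds}]
  - k_{PGE2}[\mathrm{PGH_2}][\mathrm{ePtges}]$$

and symmetrically for PGH3 (and PD, which has no downstream terms).
Downstream metabolites follow production − first-order degradation − onward
conversion, with PGD2 additionally dehydrating non-enzymatically (first
order) to PGJ2 and 15-deoxy-PGD2 and oxidizing enzymatically to dhk-PGD2.
The COX balance carries the $u$-weighted Michaelis–Menten induction terms:

$$\frac{d[\mathrm{eCOX}]}{dt} = \alpha
  + u_{PGH2}\,ke_{PGH2}\frac{[\mathrm{AA}]}{Km_{AA} + [\mathrm{AA}]}
  + u_{PGH3}\,ke_{PGH3}\frac{[\mathrm{EPA}]}{Km_{EPA} + [\mathrm{EPA}]}
  - \beta\,[\mathrm{eCOX}]$$

**Design choices where the structure was open.** The downstream enzyme
balances mirror the COX balance without $u$: a constitutive rate, one lumped
induction term driven by the enzyme's substrate pool
($[\mathrm{PGH_2}]+[\mathrm{PGH_3}]$ for `ePtgds`/`ePtges`, $[\mathrm{PGD_2}]$
for `edhkPGD2`), and first-order degradation. `edhkPGD2` carries no
constitutive term — a catabolic activity that only matters once PGD2
accumulates — which lands the default EPA model at exactly 41 free
parameters: 9 rate constants, 9 degradation rates, $k_{ATP}$ and the ATP
decay rate, 7 enzyme synthesis/degradation constants, 10 induction constants,
and 4 initial enzyme levels (`count_parameters()` enumerates them). ATP
itself is modeled as $[\mathrm{ATP}](t) = \mathrm{ATP}_0 e^{-d_{ATP} t}$ with
$\mathrm{ATP}_0$ fixed per condition and $d_{ATP}$ fitted, the simplest shape
consistent with a decaying stimulus.

**Units and identifiability.** Metabolites are in pmol/µg DNA; enzymes are in
arbitrary units, so only the products $k_i\,[\mathrm{e}]$ are identifiable.
The enzyme scale is pinned by bounding the initial enzyme levels in
$[0, 1]$; the ratio $k_{PGH3}/k_{PGH2}$ is scale-free and is the quantity we
report and test for recovery.

## Numerics

Integration uses `deSolve::lsoda` (stiff-capable, automatic switching) at
`rtol = 1e-6`, `atol = 1e-9`. The right-hand side is compiled C for speed; an
R implementation (`assemble_rhs()`, composed of the documented
`compute_fluxes()` / `cybernetic_controls()` / `metabolite_rhs()` /
`enzyme_rhs()` pieces) is the readable reference, and a test asserts the two
engines agree along trajectories. Small negative solver excursions are
clipped to zero for rate evaluation; a zero Michaelis denominator
($Km = 0$ with zero substrate) is a hard error rather than a silent 0/0.

## Estimation

The cost is the scaled fit-error: for every measured species and condition,
$\sum_t (\bar y_{exp} - y_{pred})^2 / \max_t \bar y_{exp}$, summed over
species and conditions. Replicate means are fitted by default (the F-test
below separates replicate scatter from lack of fit; a config switch fits all
replicates). Species weights allow exclusion — weight zero is exactly
equivalent to deleting the species' term — and species whose measurements are
identically zero are dropped with a warning since their scale is undefined.

The unmeasured endoperoxides are assumed to stay below 10 pmol/µg DNA. The
constraint is enforced as a smooth quadratic hinge penalty,
$w \sum_i \max(0, \max_t [I_i](t) - b)^2$ with default weight $10^3$ and
bound $b = 10$, on maxima taken over a dense internal grid (0.1 min): a
smooth penalty keeps the surface usable by the gradient-based refinement
stage, unlike hard rejection.

Optimization is the two-stage hybrid: a seeded mesh pattern search
(`direct_search()`, opportunistic coordinate polling with mesh halving after
failed polls, default budget 2000 evaluations) followed by bounded L-BFGS-B
refinement with numerical gradients (`local_refine()`, default 100
iterations, relative tolerance $10^{-8}$). Both stages operate on the unit
box — each parameter scaled by its bounds — so mesh steps and
finite-difference steps are commensurate across parameters spanning two
orders of magnitude; without this the quasi-Newton stage stalls. Default
bounds are $[0, 100]$ for kinetic constants and $[0, 1]$ for initial enzyme
levels; recovery studies search the ranges the truth was drawn from. The fit
is deterministic given (seed, config, data). Budgets are sized for
desk-scale runs: one default-budget two-condition fit integrates the
13-state system roughly $10^4$ times and takes about a minute.

## Validation

**Lack-of-fit F-test.** Per metabolite,
$F = \frac{\sum_{cond}\sum_t (Y - \bar X)^2 / (n_e n_t)}
         {\sum_{cond}\sum_t\sum_r (X - \bar X)^2 / (n_e n_t (n_r - 1))}$,
the ratio of model-vs-mean error to replicate pure error. The comparison uses
the *lower-tail* critical value — the fit passes when its error is
significantly *below* the experimental scatter ($F < F_{0.05}(df_1, df_2)$;
$F_{0.05}(16, 32) = 0.46$). Degrees of freedom are always computed from the
data at hand ($df_1 = n_e n_t$, $df_2 = n_e n_t (n_r-1)$; the default
7-time-point, 2-condition, 3-replicate design gives (14, 28)).

The suite checks calibration: data regenerated from a fitted model's own
noise model, refit, should pass the test almost always. The refit is a
stage-2 polish from the generating parameters (the null fit) — under the
null, that is the fit the test is about — and the observed pass fraction
over 20 seeded repetitions is above 90%. Note a structural fact: even a
*perfect* fit has $F \approx \tfrac13 F(df_1, df_2)$ in distribution, so
single-species failures at rates around 20% are expected unless the fit
partially tracks the replicate means; passing "all species, always" is not a
statistically reasonable bar at these replicate numbers.

**Leave-one-out-metabolite cross-validation.** `loo_metabolite_cv()` refits
with one metabolite's cost weight set to zero — the metabolite stays in the
kinetics and flux balances — and scores the scaled error of its predicted
trajectory. The suite compares the held-out PGD2 error against the median
error of the fitted species under a refit of matched depth (a polish from
the generating parameters). The matched depth matters: a converged de-novo
fit of 41 parameters against 98 replicate means drives the in-sample errors
far *below* the replicate noise floor (partial overfitting), while the
held-out prediction is bounded below by its own noise floor — which it
attains, i.e. the prediction is as good as the data allow — so a ratio
against overfit in-sample errors would be meaningless.

**Switch analysis.** `switch_surface()` evaluates the simplified activity
variables on an AA × EPA grid; along the ray
$[\mathrm{AA}] = (k_{PGH3}/k_{PGH2})[\mathrm{EPA}]$ both surfaces equal 1,
and on either side one branch dominates — control (high AA, negligible EPA)
sits in the proinflammatory region, EPA supplementation in the
antiinflammatory one.

## The synthetic study emulator

Real measurements for this system (three conditions, 7 sampling times over
60 min, 3 replicates, pmol/µg DNA) are not redistributable, so the package
generates synthetic studies with the same structure (`synthetic_spec()`):

* **Inputs.** AA rises saturatingly, $AA_0 + A\,t/(\tau + t)$
  ($A = 40$, $\tau = 5$ min, baseline 2), plateauing by ~30 min in every
  condition. Supplemented EPA/DHA starts high and decays,
  $E_0 e^{-\lambda t}$ ($E_0 = 40$, $\lambda = 0.02$/min); control EPA is a
  negligible constant (0.3). ATP starts at 10 in all conditions. These are
  the simplest shapes consistent with the qualitative behavior of the
  measured system, with every constant exposed in the spec.
* **Ground truth.** Parameters are drawn uniformly from per-parameter ranges
  chosen so trajectories look like the real system: downstream
  prostaglandins accumulating to tens of pmol/µg DNA, endoperoxides staying
  in the single digits, enzymes of order one in arbitrary units, and
  $k_{PGH3} > k_{PGH2}$ (the omega-3 branch has the larger rate constant).
  Draws whose latent PGH2/PGH3 trajectories would exceed the assumed
  10 pmol/µg DNA bound are rejected and redrawn from a seed-derived
  substream — the synthetic world must satisfy the assumption the estimator
  enforces — so generation stays deterministic per seed.
* **Noise.** Replicates are multiplicative truncated-Gaussian,
  $y(1 + 0.05 z)$ clipped at zero: concentrations are positive and scatter
  grows with level. The true replicate noise structure of the real assay
  (additive vs multiplicative, correlation across times) is unknowable from
  summary descriptions; 5% CV is a deliberately clean default.
* **Emission.** PGH2/PGH3/PD and the enzymes are never emitted — they are
  unmeasurable in the real system too.

`recovery_experiment()` chains truth → data → fit → comparison and reports
the recovered switch ratio, per-species trajectory errors, the fitted
model's intermediate maxima on a dense grid, and the F-test report. At the
default study conditions the switch ratio is typically recovered to ~10%;
the residual error is dominated by the information content of noisy means,
not optimizer failure (fitted costs land below the cost of the truth
itself).

**What passing tests show — and don't.** Green recovery and calibration
tests demonstrate that the estimator is consistent and well-calibrated *when
the model class contains the generating process and the noise is clean,
independent, 5% multiplicative*. Real lipidomics data bring model error,
correlated and larger replicate scatter, and non-stationary inputs; on such
data the F-test and cross-validation are the arbiters, and recovery
precision will be worse than the synthetic figures.

## Known limitations

* Kinetics are irreversible mass action with Michaelis–Menten induction; no
  thermodynamic constraints, no COX-1/COX-2 split (lumped constitutive +
  inducible synthesis), no spatial or cell-population structure.
* The supplement-level downstream wiring (PGJ2/15d-PGD2 branching, downstream
  enzyme balances) is reconstructed from structural cues, not transcribed.
* Rate constants and enzyme levels are only jointly identifiable; compare
  ratios and products, not raw constants.
* The two-stage optimizer is local beyond its pattern-search stage;
  multi-start is available through configuration but is not the default.
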