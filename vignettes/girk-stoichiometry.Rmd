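---
title: "Steady-state modelling of GIRK1/2 gating and G-protein stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state modelling of GIRK1/2 gating and G-protein stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(girkstoich)
library(dplyr)
```

## The biological system and the model

GIRK1/2 is a G protein-gated inwardly rectifying K⁺ channel, a heterotetramer
with four interfacial binding sites for the Gβγ dimer. Gβγ is the channel's
direct activator; the GDP-bound Gα subunit opposes activation indirectly, by
sequestering Gβγ into the Gαβγ heterotrimer. Both the agonist-independent
basal current (I~basal~) and the additional agonist-evoked current
(I~evoked~) therefore report on the pools of Gβγ and Gα^GDP^ that are
physically available to the channel — its *functional stoichiometry*, as
opposed to the limiting (maximal-binding) stoichiometry.

The model is a steady-state equilibrium description with three layers.

**Occupancy.** Gβγ binds the four sites sequentially with identical,
occupancy-independent affinity `K_D` (default 50 nM, from direct biochemical
measurements). The statistical factors of sequential binding (¼, ⅔, 3/2 and
4 times `K_D` for the four steps) make the stationary occupancy distribution
binomial: with $u = [G\beta\gamma]_{free}/K_D$ and $p = u/(1+u)$,

$$\varphi_x = \binom{4}{x} p^x (1-p)^{4-x}, \qquad x = 0 \dots 4 .$$

`occupancy_fractions()` implements this closed form; the test suite checks
it against an explicit linear-system solution of the four mass-action
equilibria plus channel conservation.

**Gating.** All open states are pooled into one per occupancy level. In the
*graded-contribution* variant every occupied state opens at a fixed fraction
of the maximal open probability,

$$P_o = P_{o,max} \sum_{x=1}^{4} f_{p,x}\,\varphi_x,
\qquad f_p = (0.01,\ 0.06,\ 0.26,\ 1),$$

so gating is cooperative even though binding is not. The *concerted* variant
($P_o = P_{o,max}\varphi_4$) opens only the fully occupied channel and is
kept as a cross-check. The *intrinsic-activity* extension adds a
Gβγ-independent floor: $P_o = P_{o,max}(\Phi \sum f_{p,x}\varphi_x +
(1-\Phi))$, where $1-\Phi$ is the intrinsic open probability as a fraction of
$P_{o,max}$.

**G-protein pools.** At rest, free Gβγ is set jointly by channel binding and
by the high-affinity trimer equilibrium
$[G\beta\gamma][G\alpha^{GDP}] = K_{D,trimer}[G\alpha\beta\gamma]$
(default 1.86 nM; the association/dissociation rates are retained only to
check consistency, since the steady state depends only on their ratio).
Under saturating agonist the heterotrimer is taken as fully dissociated, so
the entire Gβγ pool is channel-available. Receptor occupancy is not
modelled: agonist applications are assumed saturating. Direct Gα–channel
binding is also omitted; Gα^GDP^ acts purely through sequestration.

Both states reduce to a single conservation equation in the free Gβγ
concentration, strictly increasing in it, solved by bracketed Brent/bisection
(`stats::uniroot`) on `[0, gbg_total]` with absolute tolerance 1e-12 nM. The
trimer is eliminated analytically (`trimer = ga_total·g/(K_D,trimer+g)`), so
no multidimensional solving is ever needed and convergence is guaranteed.

## Currents, counts and concentrations

Macroscopic currents follow $I = i_{single} P_o N / f_{sc}$, with
`i_single = 2.8 pA` (at 144 mM K⁺), the solution conversion factor
`f_sc = 4.63` mapping patch to whole-cell (24 mM K⁺) conditions, and `N` the
number of functional channels. At saturating coexpressed Gβγ the channel
runs at `P_o,max = 0.105`, which makes the saturating current I~βγ~ a
calibration-free channel counter (`channels_from_ibg()`).

Because Gβγ is membrane-anchored, surface densities are converted to molar
concentrations within a submembrane shell of width `W` via
$C = N/(W \cdot S \cdot A)$; with the default `W = 10 nm` (roughly the size
of the Gβγ–cytosolic-domain complex), 1 molecule/µm² ≈ 166 nM. The factor is
always derived from the geometry, never hard-coded, so width sweeps stay
self-consistent. `normalize_current()` brings oocyte (µA), HEK293 (90 mM K⁺)
and neuronal (−70 mV) recordings to a common pA/pF scale at 24 mM K⁺ and
−80 mV; the holding-potential correction is a linear driving-force scaling
with `E_K = −37 mV`, a documented approximation that ignores rectification
over the 10 mV involved, and the 1 mM difference between 24 and 25 mM K⁺
solutions is ignored.

## The headline computation: inferring the available Gβγ and Gα

```{r inference}
table1 <- read_measurements(girk_example("table1_oocytes.csv"))
est <- infer_stoichiometry(table1)
est %>% select(group, channel_density, gbg_total, gbg_per_channel,
               ga_total, ga_per_channel)
```

The inference is a two-step inversion of the forward model, one group at a
time:

1. channel density from I~βγ~;
2. total available Gβγ from I~total~ — under saturating agonist the whole
   pool is free to act, so the forward evoked-state current is strictly
   increasing in the Gβγ total and the inversion is a bracketed scalar
   root-find (not least squares — uniqueness follows from monotonicity);
3. total available Gα from I~basal~ — the measured current fixes the free
   Gβγ at rest; Gβγ conservation then gives the trimer concentration and
   the trimer equilibrium gives the Gα total in closed form.

Feasibility bounds are explicit: I~total~ must lie below the saturating
current at `P_o,max`, and I~basal~ below the zero-Gα prediction. Violations
raise errors in the low-level functions and are recorded per-row
(`feasible`, `note`) by the pipeline.

The result reproduces the characteristic pattern: 3–4 Gβγ per channel at
every expression level, but a Gα:channel ratio that falls from ~1.4 to ~0.3
as channel density rises — the total Gβγ pool grows with the channel
(recruitment) while the Gα pool stays within the endogenous range.

`sensitivity_sweep()` re-runs the inference over grids of `K_D` (5–100 nM),
shell width (1–20 nm), intrinsic activity (0–10% of `P_o,max`), the assumed
I~βγ~/I~total~ ratio (1.5–3) and `P_o,max` (0.05–0.2); the Gβγ:channel
estimate stays in a narrow band (~3.2–4.2) across the affinity range.

## Scenario simulations

`simulate_gbg_dose_response()` predicts the current while exogenous Gβγ is
titrated in, either on top of the channel-recruited pools inferred from that
cell's own currents or on top of an assumed level of endogenous heterotrimer
only ("classical" null scenario: equal Gα and Gβγ, no recruitment). Added
Gβγ goes to the Gβγ pool only — it is exogenous dimer, not trimer — while in
the endogenous-only mode the starting trimers contribute both subunits
equally. The recruited scenario saturates at far lower doses, because the
starting pool is already close to capacity; both converge to the same
ceiling `i_single·N·P_o,max/f_sc`.

`simulate_ra_vs_ibasal()` reconstructs the inverse relation between the
activation index `R_a = I_total/I_basal` and I~basal~: with a constant
Gβγ:channel ratio (3.5) and a Gα:channel ratio declining hyperbolically with
density, R~a~ decreases strictly and monotonically with I~basal~. The
hyperbola `Gα = y0 + a/x` is fitted by `fit_hyperbolic_ga()` with ordinary
least squares — the model is linear in `1/x`, so `lm()` is exact and
interpolates two points perfectly; the fit is deliberately descriptive, as
the mechanism of the decline is not modelled.

```{r relation}
fit <- fit_hyperbolic_ga(est)
rel <- simulate_ra_vs_ibasal(gbg_ratio = 3.5, ga_curve = fit)
all(diff(rel$r_a[order(rel$i_basal)]) < 0)
```

A fixed stoichiometry (e.g. 4 Gβγ : 2 Gα at every density) fails to
reproduce the inverse relation: the simulated R~a~ is *non-decreasing* in
I~basal~ over the 1–30 channels/µm² range. Note that it is not flat either —
R~a~ rises by roughly a third across the range, because occupancy saturates
faster in the evoked than in the resting state as concentrations grow. The
qualitative contrast with the declining-Gα curve (strictly decreasing,
Spearman −1) is what distinguishes the two hypotheses.

## The synthetic-data generator

`generate_cells()` emulates the study design: groups of cells at set channel
densities, per-cell density drawn lognormally around the group value, pools
assembled from the group ratios, forward solves for the resting, evoked and
saturating states, and independent multiplicative lognormal noise on
I~basal~, I~evoked~ and I~βγ~. I~total~ is recomputed per cell *after*
noising, and R~a~ from each cell's own currents, matching how the
experimental index is computed. Defaults: the three-group oocyte design
(densities 2.74/9.7/21.7, Gβγ ratios 3.74/3.26/3.48, Gα ratios
1.37/0.56/0.33, 50 cells per group), `noise_cv = 0.2` and
`density_spread_cv = 0.3`. The two CVs act on different levels — measurement
noise versus biological spread — and jointly give per-group coefficients of
variation of roughly 0.4–0.7, the range implied by the grouped oocyte data
(SEM·√n/mean). The generator emulates steady-state group structure only: no
oocyte-batch effects, desensitization, endogenous GIRK5 contamination, or
correlated noise between currents, so recovery tests certify the inference
machinery, not robustness to those real-data features.

```{r synthetic}
cells <- generate_cells(synthetic_truth(seed = 7))
recover_from_synthetic(cells) %>% head()
cor(cells$i_basal, cells$r_a, method = "spearman")
```

Because the Gα:channel ratio declines across the groups, per-cell I~basal~
and R~a~ are negatively correlated in the synthetic populations, mirroring
the experimental observation.

## Numerical and design choices

- **Units.** All internal concentrations are nM; molecules/µm² appear only
  at the interfaces and are converted through the slab geometry.
- **Trimer constant.** `kd_trimer = 1.86 nM` is used directly; `koff/kon`
  (1.857 nM) must agree within 5% or construction fails. Whether the
  original analysis used 1.86 or 1.857 is immaterial at the reported
  precision.
- **fp precision.** The fractional open probabilities are known only to the
  two digits quoted (0.01, 0.06, 0.26, 1); they are used verbatim.
- **Degenerate inputs.** `gbg_total = 0` returns the closed, unoccupied
  state exactly; `ga_total = 0` makes the resting and evoked states
  identical; overwhelming Gα drives `P_o → 0`. A measured I~basal~ exactly
  at the zero-Gα bound returns `ga_total = 0` rather than an error.
- **Saturation.** The graded `P_o` approaches `P_o,max` like
  `~4(1-f_{p,3})/u`: the relative gap is ~3·10⁻³ at `u = 10³` and below
  10⁻³ only from `u ≈ 4·10³`.
- **Low-density basal current.** Two I~basal~ means exist for the low
  group (0.73 µA with agonist-series cells, 1.06 µA in the Gβγ series);
  the bundled table uses 0.73 µA in `i_basal` — consistent with how the
  per-group inversion chain is defined — and exposes the alternative as
  the pass-through column `i_basal_no_gbg`.
- **Problem sizes.** Property tests use 60–200 random pools, the grid-search
  oracle refines an 81×81 log-spaced grid for 8 passes, and the synthetic
  recovery study uses 50 cells/group over 20 seed replicates; these sizes
  give stable results while keeping the default test run fast.

## Limitations

Steady state only — no kinetics, desensitization or RGS/PIP₂/Na⁺
modulation; no receptor sub-model (agonist assumed saturating, heterotrimer
dissociation complete); site affinity assumed occupancy-independent; the
neuron normalization rests on the oocyte-derived `P_o,max` and
I~βγ~/I~total~ ratio, which were not measured in neurons. Estimates inherit
the precision of the printed group means used as inputs (about 1–3%).
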