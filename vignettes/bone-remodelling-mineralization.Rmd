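---
title: "Coupled bone remodelling and mineralization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled bone remodelling and mineralization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossify)
```

## The problem

Bone regulates two densities at once. The *apparent* density
$\rho_{app}$ — mineralized wet mass over the whole tissue volume,
pores included — tracks how much matrix there is; the *material* density
$\rho_{mat}$ — mass over the volume of the solid matrix alone — tracks how
mineralized that matrix is. Because remodelling continuously replaces old,
highly mineralized bone with fresh osteoid that mineralizes over years, a
sample of bone is a mosaic of structural units of different tissue ages and
mineral contents, and the two densities are coupled through the kinetics of
resorption. Plotting $\rho_{app}$ against $\rho_{mat}$ across the
cancellous-to-cortical range produces a characteristic boomerang-shaped
curve: high material density at both porosity extremes and a low-density
"nose" in the transition zone.

`ossify` implements a deterministic, daily-resolution continuum model of a
representative bone volume that reproduces this behaviour from one central
hypothesis: **osteoclasts resorb preferentially young, weakly mineralized
bone near the free surface, within a temporal window whose width scales
with the available specific surface** — and therefore with porosity.

## Model

### Composition

A tissue volume $V_t$ splits into bone material $V_b$ and void pores; the
material splits into mineral, organic and water. With volume fractions
$v_b = V_b/V_t$ and (within the material) $v_m + v_o + v_w = 1$, where the
organic fraction is the frozen constant $v_o = 3/7$ and water is replaced
by mineral as tissue mineralizes:

$$\rho_{mat} = \rho_m v_m + \rho_o v_o + \rho_w v_w, \qquad
  \rho_{app} = \rho_{mat}\, v_b,$$

with $\rho_m = 3.2$, $\rho_o = 1.1$, $\rho_w = 1.0$ g/cm³. The ash
fraction $\alpha = \rho_m v_m / (\rho_m v_m + \rho_o v_o)$ and the ash
density $\rho_{ash} = \rho_m v_m v_b$ are derived quantities. Freezing
$v_o$ makes $\rho_{mat}$ affine in $v_m$:
$\rho_{mat} = 1.0429 + 2.2\, v_m$ g/cm³, so material density is a direct
read-out of the mean mineral content.

### Mineralization of a cohort

A piece of bone formed today mineralizes along a three-phase law
(`mineral_law()`): nothing for a lag of $T_{nm} = 12$ d, a linear primary
phase of $T_{prim} = 10$ d up to $v_m^{prim} = 0.121$, then a secondary
exponential approach at rate $\kappa_m = 5\times10^{-4}$/d towards
$v_m^{max} = 0.442$. At the maximum mineralization time
$T_m^{max} = 4000$ d a cohort is *considered* fully mineralized and its
mineral fraction is clamped to exactly $v_m^{max}$; without the clamp the
exponential would still be at $\approx 0.398$ at 4000 d, which would
contradict the convention that the terminal pool is fully mineralized.
The clamp is therefore part of the law, not a numerical shortcut.

### The cohort array

The state of the simulation is a daily age-structured array
$\Delta v_b(i)$, $i = 0..T_m^{max}$: the volume fraction formed $i$ days
ago and still present. Simulations start from an adapted bone of volume
fraction $v_{b0}$ spread uniformly over ages $1..T_m^{max}$. Each day the
array shifts one bin older (the two oldest bins merge into a terminal,
fully mineralized bin), the day's formation enters at age 0, and the day's
resorption is removed according to the strategy:

* **windowed** (the model's hypothesis, "case 3"): equal shares
  $\dot v_r \Delta t / T_{sr}$ from each bin of age
  $T_{nm} .. T_{nm}+T_{sr}-1$. If a bin holds less than its share, the
  deficit spills to successively older bins (osteoclasts digging into
  older, deeper bone), and only if all older bone is exhausted to the
  not-yet-mineralized younger bins — so the amount removed always matches
  the rate unless the bone is fully resorbed, which terminates the run
  with a flag.
* **newest_only** ("case 2"): youngest bone first. The rest of the matrix
  is never touched and mineralizes completely.
* **age_averaged** ("case 1"): proportional removal across all ages —
  the classical non-cohort continuum model, in which osteoclasts reach
  even the fully mineralized core. This is an emulation of that model
  within the cohort bookkeeping (proportional shares are the natural
  cohort translation of age-independent averaged resorption).

The whole-bone mineral fraction is the volume-weighted mean
$v_m = \sum_i \Delta v_b(i)\, v_m^*(i) / v_b$.

The window length co-evolves with porosity $p = 1 - v_b$ through the
specific surface,

$$T_{sr} = \kappa_{sr} S_v(p), \qquad
  S_v = 32.26p - 93.94p^2 + 133.96p^3 - 101.4p^4 + 28.76p^5,$$

recomputed every day: this feedback — more surface, wider window, more
young bone held in a low-mineral state — is the mechanism behind the
boomerang nose. $S_v$ is floored at zero (the printed quintic dips to
$-0.36$ at $p = 1$), and $T_{sr}$ is rounded to whole days with a floor of
one day. A parabolic variant (`sv_variant = "martin"`), matched to the
quintic's peak location and height, is available for sensitivity checks;
$\kappa_{sr}$ (default 200 d, physiologically calibrated range 150–250 d)
sets the window scale. $T_{sr} = \kappa_{sr} S_v$ is taken literally as
days, treating $S_v$ as a normalized surface measure.

### BMU dynamics

Resorption and formation rates come from daily discretizations of the BMU
convolution integrals. With $N(t)$ the daily BMU origination rate and the
living population $L(t') = \sum_{t'-\sigma_L < t'' \le t'} N(t'')$
($\sigma_L = 100$ d lifespan):

$$\dot v_r(t) = \frac{A_{BMU} f_c v_{BMU}}{T_R}
    \sum_{t - T_R < t' \le t} L(t'), \qquad
  \dot v_f(t) = \frac{A_{BMU} f_b v_{BMU}}{T_F}
    \sum_{t - T_R - T_I - T_F < t' \le t - T_R - T_I} L(t'),$$

with $T_R = 24$, $T_I = 8$, $T_F = 64$ d and progression speed
$v_{BMU} = 0.04$ mm/d. Note the formation sum is normalized by its own
window length $T_F$: this is what makes $\dot v_f = \dot v_r$ exact under
a constant history at the reference stimulus, i.e. remodelling
equilibrium. The BMU cross-section $A_{BMU}$ interpolates linearly from
the hemiosteonal $1.9\times10^{-3}$ mm² below $v_b = 0.3$ to the osteonal
$4.3\times10^{-3}$ mm² above $v_b = 0.7$. Histories are pre-filled with
the equilibrium origination rate of the initial state, so the model starts
from an adapted bone rather than empty tissue.

### Mechanoregulation

Three pieces, all functions of the scalar daily stimulus $\xi$ with
reference $\xi^* = 2.5\times10^{-4}$:

1. **Balance.** $f_b/f_c$ is piecewise linear in the unbalanced stimulus,
   fixed by its published range: $0.95$ at $\xi = 0$, $1$ at $\xi = \xi^*$,
   $1.05$ at $\xi = 2\xi^*$, clipped outside. The printed range gives the
   endpoints; the slope between them is the simplest consistent choice.
2. **Activation.** The BMU origination law is
   $N = n_0\, \frac{S_v(p)}{\max S_v}\, \max(1 - \lambda\,\xi/\xi^*,\, 0)$
   with $\lambda = 0.5$: surface-proportional activation under a linear
   inhibitory signal. Disuse cancels the inhibition (doubling activation),
   equilibrium halves the ceiling, and sustained overload at $2\xi^*$
   suppresses origination entirely — resorption becomes unable to reach
   the maturing matrix, which is exactly the "inner parts are less likely
   to be resorbed" densification mechanism. This law is an explicit,
   swappable emulation: the model family it belongs to computes activation
   from a full mechanical (finite-element) stimulus field, which is out of
   scope here, so the activation law must supply the same qualitative
   couplings with one free scale, $n_0$.
3. **Accommodation.** The set point relaxes towards the prevailing
   stimulus, $d\xi^*/dt = (\xi - \xi^*)/\tau_{acc}$ with
   $\tau_{acc} = 250$ d. With the stimulus *prescribed* (no mechanical
   feedback loop), a constant $\pm 5\%$ balance offset would otherwise
   persist indefinitely and no perturbed scenario could re-equilibrate;
   cellular accommodation of the set point is the established lumped
   description of that missing feedback and restores equilibration on the
   observed ~1000-day timescale. Set `tau_acc = Inf` to disable it.

**Calibration of `n0`.** The one free constant of the activation law is
fixed so that the equilibrium turnover at intermediate porosity holds
roughly 60 % of the bone volume inside the remodelling-active (young) age
range at $v_{b0} = 0.5$, $\kappa_{sr} = 200$ — the regime in which the
transition-zone material densities fall in the experimentally observed
1.5–1.7 g/cm³ window. This gives `n0 = 0.12` BMU/(mm³·day); it plays the
same role as $\kappa_{sr}$, shifting the curves to the observed density
levels without affecting their shape.

### Daily step

Within a day, in order: accommodate the set point; append the day's
origination rate to the history; evaluate $\dot v_r, \dot v_f$; advance the
array one day; deposit the formation; remove the resorption through the
current window; re-aggregate $v_m$ and the densities. Formation is
deposited *before* resorption within the day: under the newest-first
strategy the same-day osteoid must be eligible for same-day removal, or a
single one-day-old unmineralized cohort survives forever and blurs the
exact vertical-line limit of case 2 by order $10^{-3}$ g/cm³. For the
windowed and age-averaged strategies the ordering is immaterial (the
window starts at $T_{nm} \ge 1$).

## Steady state and the boomerang

Under equilibrium load the balanced turnover $R = \dot v_r = \dot v_f$
drives the young part of the array to a triangular steady profile that is
consumed exactly at the window's end; the standing young pool holds
$\approx R\,(T_{nm} + T_{sr}/2)$ of low-mineral bone while the remainder
sits in the terminal pool at $v_m^{max}$. Since both $R$ and $T_{sr}$
scale with $S_v(p)$, the young fraction — and hence the depression of
$\rho_{mat}$ — peaks at intermediate porosity: the boomerang nose. At the
porosity extremes the surface is small, turnover concentrates on a few
constantly renewed cohorts, and the interior mineralizes fully — the two
high-$\rho_{mat}$ tails. Larger $\kappa_{sr}$ widens the window and
deepens the nose, which is why the 150/200/250-day family brackets the
experimental scatter.

## Numerical choices

* Time step 1 day; all convolution integrals are daily sums.
* The cohort array has $T_m^{max} + 1$ bins; the terminal bin pools
  everything at or beyond the maximum mineralization age (mass-conserving
  by construction).
* Spillover uses a two-pass greedy: equal in-window shares first, then the
  residual to older bins in ascending age, then (only if the bone older
  than the window is exhausted) to younger bins oldest-first.
* Residuals below $10^{-12}\times$ the day's resorption are float dust and
  do not trigger spillover.
* Full resorption (demand exceeding total bone) empties the array and
  terminates the run with status `"fully_resorbed"` instead of going
  negative.
* Everything is deterministic; reruns are bit-identical.

## What the simulations do and do not show

The sweeps (`sweep_boomerang()`, default grid $v_{b0} = 0.20, 0.25,
\dots, 0.90, 0.94$, horizon 8000 d) reproduce the *shape* and the
*density window* of the observed $\rho_{app}$–$\rho_{mat}$ relationship,
the ordering of the three resorption strategies, the window-size effect,
and the translation of the curve under overload/disuse. They are
single-volume continuum runs: no spatial trabecular geometry, no damage,
no stimulus field from an actual load case, pores are mechanically void,
and the activation law is a calibrated emulation. Exact point-by-point
coordinates of published figures are therefore outside what these runs can
or should match; printed parameter-derived values and the printed density
window are the quantitative anchors. Problem sizes (16-point grids, three
window scalings, 8000-day horizons) keep a full sweep family at a few
minutes on one core.

## Session

```{r}
sessionInfo()
```
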