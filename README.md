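# ossify

Deterministic simulation of coupled bone remodelling and matrix
mineralization in a representative tissue volume.

Bone continuously replaces old, highly mineralized matrix with fresh
osteoid that takes years to mineralize, so every sample is a mosaic of
tissue ages and mineral contents. `ossify` tracks that mosaic explicitly:
bone material is an age-structured **cohort array** Δv_b(i) (one bin per
day of tissue age, up to the maximum mineralization time of 4000 days).
Each simulated day, BMU (basic multicellular unit) population dynamics set
the resorption and formation volume rates through the convolutions

    v̇_r(t) = (A_BMU f_c v_BMU / T_R) Σ_{t' ∈ (t−T_R, t]} L(t')
    v̇_f(t) = (A_BMU f_b v_BMU / T_F) Σ_{t' ∈ formation window} L(t')

(L = living-BMU count, the trailing σ_L-day sum of origination rates),
new bone enters at age 0, and resorption removes bone **preferentially
from young, weakly mineralized cohorts** inside a temporal window of
length T_sr = κ_sr · S_v(p) that scales with the specific surface and
therefore with porosity p = 1 − v_b. Surviving cohorts mineralize along a
three-phase law (12-day lag, 10-day linear primary phase to v_m = 0.121,
exponential secondary phase towards v_m = 0.442). Material and apparent
density follow from the volume fractions:

    ρ_mat = ρ_m v_m + ρ_o v_o + ρ_w v_w,   ρ_app = ρ_mat · v_b

Across initial bone volume fractions 0.20–0.94 this produces the
experimentally observed **boomerang-shaped ρ_app–ρ_mat relationship**:
highly mineralized tails at both porosity extremes and a low-density nose
in the cancellous–cortical transition zone, where the large available
surface keeps a large pool of young bone permanently under-mineralized.
Overload and disuse loading translate the curve right and left.

Intended users: researchers in bone mechanobiology and computational
biomechanics exploring how resorption kinetics shape tissue-level density
relationships (e.g. for CT/QCT density calibration or micro-FE property
assignment).

## Worked example

A transition-zone volume (v_b0 = 0.5) under equilibrium load for 8000
days (about 22 years):

```r
library(ossify)

sim <- run_scenario(scenario(vb0 = 0.5, xi = "equilibrium", horizon = 8000))
glance(sim)
#> # A tibble: 1 × 11
#>     vb0 strategy kappa_sr horizon status days_run   v_b   v_m rho_mat rho_app
#>   <dbl> <chr>       <dbl>   <int> <chr>     <int> <dbl> <dbl>   <dbl>   <dbl>
#> 1   0.5 windowed      200    8000 ok         8000   0.5 0.275    1.65   0.824
#> # ℹ 1 more variable: equilibrium_day <int>
```

Remodelling is balanced (v_b stays at 0.5 to machine precision), yet the
steady turnover holds the mean mineral fraction at 0.275 — well below the
0.442 maximum — giving ρ_mat = 1.65 g/cm³: the depressed material density
of transition-zone bone. The same run under `xi = "overload"` ends at
ρ_mat = 2.015 g/cm³ (activation is suppressed and the matrix mineralizes
fully) and under `xi = "disuse"` at ρ_mat = 1.37 g/cm³ (enhanced
activation churns the matrix faster than it can mineralize).

The boomerang itself is a sweep over initial volume fractions:

```r
sw <- sweep_boomerang(kappa_sr = c(150, 200, 250))
dplyr::slice_min(sw, rho_mat)
#> # A tibble: 1 × 12
#>     vb0 kappa_sr strategy zone         day   v_b   v_m rho_mat rho_app ...
#> 1  0.65      250 windowed transition  8000  0.65 0.224    1.54    0.998
autoplot(sw)   # rho_mat vs rho_app, one curve per kappa_sr
```

The minimum material density over the sweep family — the "nose" of the
boomerang — is 1.54 g/cm³ at v_b0 = 0.65, inside the experimentally
reported 1.5–1.7 g/cm³ window, and smaller resorption windows (lower
κ_sr) shift every point to higher mineralization.

A thin command-line interface wraps the same functions
(`exec/ossify params | run | sweep | compare-cases`), writing traces and
sweeps as CSV with a JSON configuration sidecar.

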