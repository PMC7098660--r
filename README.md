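# schoolsim

Event-driven simulation of burst-and-coast fish schools with selective
neighbor interactions, written for researchers in collective animal
behaviour who want to ask: *how many neighbors, and which ones, must a
fish attend to for a school to form?*

Rummy-nose tetra (*Hemigrammus rhodostomus*) swim in discrete
kick-and-glide cycles: at each "kick" a fish picks a new heading, then
glides passively along a straight line while its speed decays
exponentially (relaxation time τ₀). `schoolsim` implements the
data-driven pairwise interaction model for this swimming mode and lets
every agent combine interactions with a chosen subset of its N − 1
neighbors, re-selected at every kick:

- **nearest** — the k closest neighbors,
- **random** — k neighbors drawn uniformly,
- **most influential** — the k neighbors with the largest influence
  I_ij = |δφ_Att + δφ_Ali|, the absolute pairwise contribution to the
  focal heading change.

## Model

At the n-th kick of agent *i* the heading changes by

    δφᵢⁿ = δφ_w(r_w, θ_w) + δφ_R + Σ_⟨j,i⟩ [ δφ_Att(d,ψ,φ) + δφ_Ali(d,ψ,φ) ]

with wall repulsion `δφ_w = γ_w exp[−(r_w/l_w)²] · β_w sinθ_w (1 + 0.7cos2θ_w)`,
Gaussian heading noise δφ_R, long-range attraction
`F_Att(d) = γ_Att (d/d_Att − 1)/(1 + (d/l_Att)²)` (repulsive below the
balance distance d_Att, optionally truncated at a cut-off d_cut) and
alignment `F_Ali(d) = γ_Ali (d/d_Ali + 1) e^{−(d/l_Ali)²}`, each
modulated by normalized angular functions of the viewing angle ψ and the
heading difference φ. Kick lengths follow a bell-shaped law with mean
7 cm; the glide duration follows from the exponential speed decay,
τ = −τ₀ log(1 − l/(v₀τ₀)). Two parameter presets ship with the package
(`school_params("model")`, `school_params("robots")`).

The package also provides the five collective observables used to
quantify schooling — cohesion C (mean distance to the barycenter),
polarization P, wall distance r_wB and wall angle θ_wB of the
barycenter, and the counter-milling index Q — plus empirical-PDF
comparison by Hellinger distance with l₁-fitted distance rescaling, and
a preprocessing pipeline for 25 Hz tracked trajectories (pixel
conversion, identity reassignment, rest filtering, sequence extraction,
kick detection) with a synthetic tracked-data generator for validating
it.

## Worked example

```r
library(schoolsim)

cfg <- sim_config(
  n_agents    = 5,
  params      = school_params("model"),
  strat       = strategy("influential", k = 1),
  mode        = "bounded",          # circular arena, R = 0.25 m
  total_kicks = 20000,
  seed        = 42
)
sim <- run_simulation(cfg)
sim
#> <school_sim> N = 5, bounded, 20000 kicks over 3355.2 s (83879 frames)

obs <- compute_observables(sim)
dplyr::summarise(obs,
  cohesion_cm      = 100 * mean(cohesion_m),
  polarization     = mean(polarization, na.rm = TRUE),
  wall_distance_cm = 100 * mean(r_wb_m),
  counter_milling  = mean(q, na.rm = TRUE)
)
#> # A tibble: 1 × 4
#>   cohesion_cm polarization wall_distance_cm counter_milling
#>         <dbl>        <dbl>            <dbl>           <dbl>
#> 1        7.10        0.772             9.92           0.318
```

Five agents attending only to their single most influential neighbor
form a compact group (effective radius ≈ 7 cm in a 25 cm tank), swim
strongly polarized (P ≈ 0.77) and travel along the wall about 10 cm from
it. The positive Q under the literal translating-frame formulas reflects
the group's near-rigid circulation along the wall; in the co-rotating
frame (`compute_observables(sim, milling_frame = "co_rotating")`) the
index is negative — individuals rotate about the group center against
the group's own circulation (counter-milling).

Ensembles and sweeps chain the same pieces:

```r
cfg_u <- sim_config(5, strat = strategy("influential", 1),
                    mode = "unbounded", total_kicks = 10000, seed = 1)
run_ensemble(cfg_u, n_runs = 100)
#> <school_ensemble> 100 runs x 10000 kicks (unbounded, influential k = 1)
#>   steady state: <C> = 0.1095 m, <P> = 0.9117

find_critical_cutoff(cfg_u, seq(0.3, 1.5, by = 0.1), statistic = "median")
```

`autoplot()` methods draw trajectories, ensemble time series, cut-off
sweeps and empirical PDFs; `tidy()`/`glance()` return tibble summaries.
A thin command-line front-end lives at `inst/cli/schoolsim.R`.

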