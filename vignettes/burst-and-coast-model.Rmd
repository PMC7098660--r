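---
title: "The burst-and-coast school model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The burst-and-coast school model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolsim)
```

## The model

Rummy-nose tetras swim in a discrete decision cycle: a sudden
acceleration (a *kick*) sets a new heading, a kick length $l$ and a kick
duration $\tau$, after which the fish glides passively along a straight
line while its speed decays exponentially with relaxation time
$\tau_0$. `schoolsim` treats each agent as such a kick-and-glide
swimmer. Positions between kicks follow the glide law: the traveled
fraction of the kick segment after a time $\Delta t$ is

$$f(\Delta t) = \frac{1 - e^{-\Delta t/\tau_0}}{1 - e^{-\tau/\tau_0}},$$

so $f(0)=0$ and $f(\tau)=1$. Kick lengths are drawn from a bell-shaped
law (below); the duration is the time an exponentially decaying glide at
peak speed $v_0$ needs to cover $l$:
$\tau = -\tau_0\log(1 - l/(v_0\tau_0))$. With the model preset
($v_0 = 0.14$ m/s, $\tau_0 = 0.8$ s, mean $l = 7$ cm) the mean glide
duration is about 0.97 s, i.e. roughly one kick per second per fish.

At each kick the heading turns by the sum of independent contributions:

* **wall repulsion** (bounded arena only), a centripetal term
  $\gamma_w e^{-(r_w/l_w)^2}\,\beta_w\sin\theta_w(1+0.7\cos 2\theta_w)$
  in the distance $r_w$ and relative angle $\theta_w$ of the heading to
  the wall;
* **spontaneous noise**, a Gaussian heading fluctuation (see the noise
  convention below);
* **social terms** for each selected neighbor: an attraction
  $F_{Att}(d)\,O_{Att}(\psi)\,E_{Att}(\phi)$ with
  $F_{Att}(d) = \gamma_{Att}\,(d/d_{Att}-1)/(1+(d/l_{Att})^2)$ —
  repulsive below the balance distance $d_{Att}$, long-ranged above it —
  and an alignment $F_{Ali}(d)\,E_{Ali}(\psi)\,O_{Ali}(\phi)$ with a
  Gaussian range $l_{Ali}$. Here $d$ is the pair distance, $\psi$ the
  viewing angle, and $\phi$ the heading difference.

The angular factors are normalized so the mean of their square over
$(-\pi,\pi]$ equals 1; the shipped constants are the published ones and
`angular_normalization()` recomputes them by quadrature as a check. One
constant (the attraction evenness factor, 0.9326) is *not* consistent
with its own rounded series coefficients (quadrature gives about
0.9272); the published value is kept authoritative and the discrepancy
is simply documented.

The *influence* of neighbor $j$ on focal $i$ is
$I_{ij} = |\delta\phi_{Att} + \delta\phi_{Ali}|$. A neighbor-selection
*strategy* (fixed for a whole run) chooses, at every kick of the focal
agent, which $k$ of its $N-1$ neighbors enter the social sum: the $k$
nearest, $k$ at random, or the $k$ most influential. Because attraction
is long-ranged and weak between aligned fish, the most influential
neighbor is frequently *not* the nearest one — that asymmetry is the
scientific heart of the package.

## Tunable parameters

All distances are in meters, times in seconds, angles in radians.
The `"model"` preset (fish-calibrated): $\gamma_R = 0.45$,
$\alpha = 2/3$, $\gamma_w = 0.15$, $l_w = 0.06$, $\gamma_{Att} = 0.12$,
$l_{Att} = 0.20$, $d_{Att} = 0.03$, $\gamma_{Ali} = 0.09$,
$l_{Ali} = 0.20$, $d_{Ali} = 0.06$, $v_0 = 0.14$, $\tau_0 = 0.8$,
mean kick length $0.07$, arena radius $0.25$. The `"robots"` preset
rescales these to a 0.42 m platform with constant kick length (7.4 cm)
and constant kick duration (1.3 s) — wheeled robots do not glide, so the
glide-duration relation is replaced by the constant the controller
enforces. The attraction cut-off `d_cut` (default infinite) truncates
$F_{Att}$ — and only $F_{Att}$ — beyond a pair distance; it exists to
probe how much of group cohesion rests on the long attraction range.

## Numerical and design choices

**Kick-length law.** Only the mean (7 cm) of the empirical bell-shaped
kick-length distribution is published. We use a gamma law with shape 4
truncated to $(0,\,0.99\,v_0\tau_0)$ — physically, no glide can be
longer than $v_0\tau_0$, the distance an exponentially decaying glide
covers in infinite time. Truncating a gamma law lowers its mean, so the
scale is calibrated at construction (by root finding) to make the
*realized* mean exactly `mean_kick_length`. The law is pluggable
(`kick_law = "constant"` reproduces the robots' fixed step).

**Noise convention.** The printed noise term is
$\gamma_R(1-\alpha e^{-(r_w/l_w)^2})\,g$ with $g$ standard normal:
damped to $\gamma_R(1-\alpha)$ at the wall, full strength far from it.
Taken literally, this convention cannot reproduce the published emergent
behavior: simulated polarization saturates near 0.68–0.80 everywhere,
and an unbounded group can never be more polarized than an arena-bound
one (the arena damps noise near the wall). The published results
(unbounded $P\approx0.93$ *above* the arena's $P\approx0.78$; unbounded
$C\approx0.1$ m; arena cohesion and wall distance for several $k$) are
all reproduced when the damping factor is held at its boundary value —
noise s.d. $\gamma_R(1-\alpha) = 0.15$ per kick everywhere, in both
domains. The engine therefore defaults to
`noise_convention = "boundary"`; the literal local form remains
available as `"local"`. The pure function `noise_turn()` keeps the
local $r_w$-dependent form, as its documentation states.

**Boundary handling.** A kick whose straight endpoint would leave the
arena is re-drawn: up to 50 kick-length resamples, then up to 50 noise
redraws (each with 50 length resamples). Length resampling alone cannot
always succeed — an agent may legally end a glide millimeters from the
wall heading outward, where turning inward would need a many-sigma noise
draw — so the terminal fallback reflects the heading specularly off the
wall tangent (deterministic, left/right-symmetric, preserves the
tangential motion component) and, as a last resort, kicks half the free
chord. The fallback triggers rarely (order once per $10^3$–$10^4$
kicks) and leaves the wall-following statistics intact.

**Event loop.** Kicks are processed in increasing order of scheduled
glide-end times, ties broken by agent index; neighbors are
glide-interpolated to the focal kick time ("instantaneous" relative
state). Initial kick phases are staggered inside $[0, \min_i\tau_i)$,
so a budget of $N$ kicks serves every agent exactly once. The social
sum is always accumulated in ascending neighbor index, which makes runs
bit-identical across strategy kinds at $k = N-1$ and the sum exactly
permutation-invariant. All randomness flows through R's RNG, so a run
is reproducible from its seed; negating the noise stream and mirroring
the initial conditions yields the exactly mirrored trajectory set.

**Influence ranking and the cut-off.** The influence used for ranking
is computed with the *untruncated* attraction: the cut-off is applied
when summing turns, not when ranking neighbors, so the ranking stays
well defined beyond the cut-off. A `influence_truncated` switch applies
the cut-off inside the ranking as well.

**Ensembles and steady state.** `run_ensemble()` derives independent
per-run seeds from the configuration seed, and averages cohesion and
polarization per time bin across runs. Steady-state summaries average
the time window holding the last 10% of each run's kicks, then average
across runs. Ensemble observables are sampled at a coarser frame step
(default 0.4 s) than single-run output (0.04 s, the 25 Hz experimental
clock): time averages over minutes are insensitive to the sampling
step, and this keeps large sweeps fast. Acceptance-scale problem
sizes: 100 runs of $10^4$ total kicks for the unbounded steady states;
$1.1\times10^5$ kicks (first 10% discarded) for the arena polarization;
cut-off sweeps with 100 runs of $5\times10^4$ kicks per grid point —
the published 2.7-hour span.

**Critical cut-off estimation.** Below a critical cut-off
$d^*_{cut}$ the group loses cohesion and its members diffuse
($\langle C^2(t)\rangle$ linear in $t$). `find_critical_cutoff()`
classifies each grid value as cohesive or diffusive by comparing a
steady-state cohesion statistic to an escape threshold (0.5 m by
default) and reports the smallest grid value from which all larger
cut-offs are cohesive. Two statistics are offered: the ensemble *mean*
(classical, but at moderate ensemble sizes a single fissioned run —
steady-state cohesion of tens of meters — dominates it) and the
*median*, which classifies the typical run and is the default choice
for desk-scale sweeps in the acceptance protocol.

**Counter-milling frames.** The rotation indices
$\Gamma$ (about the tank center) and $\Gamma_B$ (about the barycenter)
and the index $Q = \Gamma_B\,\mathrm{sign}(\Gamma)$ are computed by
default with the literal translating-barycenter-frame formulas, under
which a group circling the arena in rigid formation scores $Q = +1$.
The verbal definition of counter-milling (a formation of fixed
orientation circling the tank, like fingertips cleaning a window)
corresponds instead to a frame co-rotating with the barycenter heading;
`compute_observables(..., milling_frame = "co_rotating")` subtracts the
orbital rotation rate first, making the window-cleaning motion score
$-1$ and rigid co-rotation 0. Arena simulations score mildly positive
$Q$ in the literal frame and mildly negative (counter-milling) in the
co-rotating frame. Near-zero relative speeds (below $10^{-6}$ m/s)
contribute 0 to $\Gamma_B$.

**Distribution comparison.** Observable distributions are compared by
the discrete Hellinger distance
$D = \sqrt{1-\sum_i\sqrt{F_iG_i}}$ on shared uniform bin edges
(defaults: cohesion on $[0, 0.25]$ m with 100 bins, polarization on
$[0,1]$ with 100, wall distance on $[0,R]$ with 100, wall angle with
72, milling index with 80). Hellinger values depend on the binning, so
reports should state the bin spec. Distance-valued observables can be
rescaled by a multiplier $\lambda$ fitted by $l_1$ grid search between
cohesion PDFs before comparison; mirror symmetrization
(`symmetrize()`) doubles trajectory samples with their $y$-reflection,
which only affects the wall-angle distribution.

## The synthetic tracked-data generator

`generate_fixture()` emulates what a video tracker produces from a real
school: a bounded simulation sampled at 25 Hz, Gaussian position noise
(default s.d. half a pixel, 0.265 mm), persistent identity swaps (the
labels of a random pair exchange from a random frame onward, as
trackers do after a crossing), and rest episodes implemented as
per-agent time freezes (the individual holds position while its own
clock pauses, so its path stays continuous — no teleports). Ground
truth (clean tracks, rest masks, swap events, kick onsets mapped to the
fixture clock) is returned for recovery scoring.

What the generator does *not* emulate: body-shape and occlusion
artifacts, tracker dropouts (missing frames), lighting-dependent noise,
and correlated (non-Gaussian) centroid errors. Pipeline tests passing
on these fixtures show the algorithms recover the corruptions they
model, not that every artifact of real video tracking is handled.

## The preprocessing pipeline

Pixel tables are converted at 0.53 mm/px to tank-centered meters.
Identity reassignment relabels each frame to minimize the total
displacement from the previous frame; the assignment is solved exactly
(enumeration over permutations — globally optimal and cheap for
$N \le 7$) with a greedy fallback for larger groups. The rest filter
flags frames where any individual's net displacement over a 60-frame
window falls below 15.9 mm (mean speed under 6.6 mm/s for 2.4 s);
continuous unflagged runs of at least 20 s become analysis sequences.

Kick detection keeps the published 0.2 s window but locates onsets at
the windowed maximum of the frame-to-frame speed *rise* rather than the
raw speed minimum: the glide-tail minimum is flat (per-frame slope a few
mm/s) and easily displaced by tracking noise, while the burst that ends
it rises by $\sim$9 cm/s within a frame or two. A candidate must show a
rise of at least `min_burst_rise` (default 0.012 m/s, about 9% of the
peak speed) over the two frames after the onset. On clean fixtures the
detected rate is 1.0–1.1 kicks/s per fish, matching the published rate;
onsets are recovered within one frame for 98% of resolvable kicks.
Two kicks of the same fish closer than the detection window cannot be
separated by construction (about 7% of simulated glides are shorter
than 0.2 s), and under heavy tracking noise the detector trades
precision for recall (spurious minima pass the rise gate) — raise
`min_burst_rise` when precision matters more.

## Known limitations

* The kick-length law is a calibrated stand-in for the unpublished
  empirical distribution; observables that depend on the *shape* of the
  inter-kick interval distribution (not just its mean) inherit that
  choice.
* Nearest-neighbor ($k=2$) groups in the unbounded domain show a small
  intrinsic fission rate (order 10% per 2.7 h) even without any
  attraction cut-off; the estimated critical cut-off for that strategy
  sits at 3.0 m under the median classifier, somewhat below the
  published 3.5 m, while the most-influential ($k=1$) and nearest
  ($k=3$) cut-offs land on the published values.
* Tables comparing simulations against the original fish and robot
  recordings cannot be reproduced — those trajectory data were never
  deposited. The Hellinger machinery is exercised on simulated
  reference/candidate pairs instead, where it reproduces the published
  qualitative ranking (most influential best at $k=1$; strategies
  converge by $k=3$).
* Agents are point particles: no body exclusion, no collision handling,
  2D only, and no speed interactions (headings are the only coupled
  degree of freedom).
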