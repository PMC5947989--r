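---
title: "Modelling spatial-coherence selectivity in a looming-sensitive neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial-coherence selectivity in a looming-sensitive neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(loomsel)
```

## The problem

The locust lobula giant movement detector (LGMD) responds selectively to
objects approaching on a collision course. Beyond its classical tuning to
looming kinematics, the neuron discriminates the *spatial coherence* of the
approach: a "coarse" looming stimulus, pixelated at photoreceptor resolution
(2–3° pixels), drives strong firing only when its pixels sit at their true
positions. Scrambling the pixel positions — while leaving every pixel's
luminance time course untouched — collapses the response, even though the
total excitatory drive to the neuron is unchanged. `loomsel` implements the
machinery needed to study this computation end to end: stimulus generation
and a quantitative coherence metric, a conductance-based compartmental model
of the neuron with hyperpolarization-activated (HCN, conductance
$g_H$) and low-threshold inactivating K⁺ (K$_D$-like) channels, the
intracellular electrophysiology analysis tool chain, and synthetic-data
generators that close the loop on every fitting procedure.

## Stimuli and the coherence metric

A looming stimulus is a dark square of half-size $l$ approaching at constant
speed $v<0$; its full angular size is $2\theta(t) = 2\tan^{-1}[l/(vt)]$ with
$t<0$ before collision, so the kinematics are fully characterized by the
ratio $l/|v|$ (50 or 80 ms here). `render_coarse_loom()` pixelates the
stimulus on a regular grid: each coarse pixel's gray level is the background
level plus the luminance step scaled by the covered pixel-area fraction,
quantized to the display's 6-bit resolution, and held at final size after
the stimulus reaches its maximal angle (80° for the restrained-preparation
geometry).

Coherence is degraded by adding a two-dimensional Gaussian jitter (SD
$\sigma$) to each pixel's screen position, drawn once per presentation and
rounded to the nearest free grid cell so pixels never overlap. The percent
coherence of a jittered movie is measured operationally:
in every frame the jittered non-background pixels are matched to reference
pixel positions of equal luminance by a minimum-cost assignment on angular
distance; the per-frame minimal distances are summed over frames, normalized
by the same quantity averaged over 30 uniformly random layouts, and
subtracted from one. An unjittered movie scores exactly 100%, a random
layout ~0%.

Two implementation points matter. First, the assignment is solved exactly
with a Jonker–Volgenant shortest-augmenting-path solver (validated against a
brute-force permutation oracle in the tests). Second, because a darkening
loom's pixel luminances are non-increasing, the large "fully dark" group
only accretes members from frame to frame; the solver therefore reuses the
previous frame's optimal duals and assignment and only augments the newly
darkened pixels, which reduces the per-movie cost from roughly
$\sum_f n_f^3$ to $\sum_f k_f n_f^2$ and makes the full-size metric run in
well under a second per movie.

```{r}
params <- loom_params(l_over_v = 50, max_full_angle = 80)
grid <- coarse_grid(pixel_size = 2)
reference <- render_coarse_loom(params, grid)
jittered <- jitter_layout(reference, sigma = 20, seed = 1)
coherence_percent(jittered, reference, n_draws = 30, seed = 1)
```

## The neuron model

`compartmental_model()` attaches passive properties and channel densities to
a branched morphology and integrates the cable equation with Crank–Nicolson
steps (default `dt = 0.025` ms), a Hines-ordered tree solve, and
Rush–Larsen exponential gate updates — unconditionally stable and
second-order in the voltage. The integrator supports current steps,
arbitrary injected waveforms, an ideal single-electrode voltage clamp
(reported clamp current included), double-exponential synaptic conductance
events, a first-order calcium pool driven by the Ca$_T$ current, and online
spike detection (−15 mV threshold, 2 ms lockout).

The channel complement follows the biology: fast Na⁺ and delayed-rectifier
K⁺ at the spike initiation zone (SIZ) and axon (dendrites carry no fast
Na⁺), an M-type K⁺ conductance peaking at the SIZ, Ca$_T$/K$_{Ca}$ at the
SIZ, and — the core of the mechanism — HCN and K$_D$-like conductances
confined to dendritic field A with density increasing linearly toward the
distal endings (default tip:base ratio 3). HCN kinetics are the
experimentally fitted values: reversal −35 mV, half-activation −77.6 mV,
steepness 13.34 mV (so that 28% of the conductance is open at the −65 mV
resting potential), and a bell-shaped activation time constant peaking at
1.34 s at −83 mV with 20 mV steepness (model default
$\tau_{max}$ = 1.35 s; the minimal time constant, 50 ms, is not printed in
the source data and was chosen so the time constant at rest is ~985 ms).
Ten-fold faster (135/105 ms) and slower (13.5/10.5 s) variants of the HCN
activation and K$_D$ inactivation time constants are selectable.

### The K_D-like conductance

Only fragmentary constraints exist for the K$_D$-like channel: it is a
low-threshold, 4AP-sensitive K⁺ conductance that activates quickly and
inactivates slowly (0.3–2 s) above −70 mV. Within those constraints its
parameters are free, and we chose them to make the channel an effective
*coincidence sensor for sustained, clustered depolarization*: activation is
tonic near rest (half-activation −70 mV, steepness 5 mV, τ = 2 ms), so
brief scattered synaptic events are always taxed by the full shunt, while
the inactivation gate (half −52 mV, steepness 5 mV) only engages where the
membrane is held depolarized for hundreds of milliseconds. Its time
constant is slow near rest (bell peak −65 mV, maximum 1.05 s + 40 ms
offset) — so recovery is slow and resting inactivation tracks the
HCN-maintained resting potential — but drops to ~100–300 ms at depolarized
potentials, matching the dwell time of the looming wavefront on a branch.
A sustained local depolarization therefore *removes* the local K⁺ shunt
with a delay, a slow positive feedback that amplifies exactly the input
pattern a coherent loom produces.

### Retinotopy and synaptic input

`build_facet_map()` embeds the visual field into field A: each primary
branch receives an azimuth sector, and eccentricity from the stimulus focus
maps onto path depth within the branch, so the focus falls on proximal
branch segments and the expanding edge sweeps distally along each branch.
Each facet's drive spreads over its `k` nearest compartments with Gaussian
weights. Each luminance decrement emits a short adapting train of synaptic
events (six sub-events, 80 ms apart, geometrically decaying) whose summed
peak conductance scales with the decrement through a saturating contrast
transform (exponent 0.4) — emulating the sustained, adapting and saturating
response of the presynaptic pathway to a single facet. Synaptic kinetics
are fast nicotinic (rise 0.3 ms, decay 3 ms, reversal 0 mV). Synaptic gain
increases with path distance (tip:base ratio 2.5, mean 1), the
distance-dependent "synaptic democracy" that offsets dendritic attenuation
of distal inputs. Because jitter only relocates pixels, the event *times
and conductances* of a jittered movie are identical to the coherent one:
only their dendritic placement changes, which is precisely the variable the
study isolates. `randomize_locations()` performs the complementary
manipulation, redrawing each event's target uniformly over field A.

### Why the model prefers coherent input

Three ingredients interact. (i) A coherent loom drives each branch as an
orderly proximo-distal wave: the wavefront holds successive compartments
depolarized for a few hundred milliseconds, inactivating the K$_D$-like
conductance along the very path through which all later (more distal) input
must flow to reach the trunk. Scattered input continually meets fresh,
tonically activated K$_D$ shunt instead. (ii) HCN sets the resting
potential (~6 mV depolarized relative to block at full scale) and thereby
the resting inactivation level of K$_D$; blocking $g_H$ hyperpolarizes the
cell, re-arms the shunt everywhere and flattens the coherence preference.
(iii) Opposing both, clustered input loses synaptic driving force
(saturation), which is why a *passive* dendrite responds more strongly to
spatially randomized input — reproduced by the model — and why the full
channel complement is needed to invert that preference.

## Desk-scale study conditions

All simulation experiments run on a synthetic "fan" morphology: 12 field A
branches of 10 compartments (450 µm, diameters tapering 4.5→2.5 µm) plus
trunk, SIZ and axon — 127 compartments in total. Passive properties are
R$_a$ = 300 Ω·cm, C$_m$ = 1 µF/cm², g$_{pas}$ = 10⁻⁴ S/cm² (λ ≈ 500–700 µm,
so a branch spans ~0.8 λ and the arbor is *not* electrotonically compact —
a prerequisite for any spatially selective mechanism). The leak reversal is
calibrated per compartment so −65 mV is the resting state with all channels
at rest. The default coherence sweep uses five jitter levels
(σ = 40, 20, 10, 5, 0°; measured coherences ≈ −1, 39, 71, 87, 100%) with
two jitter draws each, a 30-draw normalization baseline and fixed seeds;
simulated responses are deterministic given the configuration, so a single
run per stimulus suffices. These problem sizes keep a full four-condition
sweep (control, $g_H$ block, K$_D$ block, matched tonic hyperpolarization)
to a few minutes.

```{r}
sweep <- run_coherence_sweep(experiment_config())
sweep$slopes
autoplot(sweep)
```

In this configuration the control model shows a positive coherence
preference (~0.054 spikes per % coherence, Pearson r ≈ 0.98), which drops
by about a quarter after $g_H$ block; K$_D$ block multiplies responses and
flattens the slope relative to the raised counts, with proportionally
larger increases for incoherent stimuli; both the ten-fold faster and the
ten-fold slower kinetics variants reduce the selectivity.
`rall_reduce()` implements the equivalent-cylinder reduction (0.04 λ
electrotonic bins, 3/2-power equivalent diameters over the parallel
unbranched chains crossing each bin, summed electrotonic lengths,
area-weighted densities, synapses transferred to their bin's cylinder); it
preserves input resistance to <0.1% on Rall-consistent trees and conserves
total channel conductance.

## Analysis conventions

The analysis functions implement the measurement definitions used for the
physiological quantities: sag amplitude as peak-to-steady-state
rectification during a hyperpolarizing step, with a single-exponential fit
from 15 ms after the peak to the step end; membrane time constant fitted
from 0.5–13 ms after step onset; HCN activation from voltage-clamp steps
through $g_H(v_2)-g_H(v_1)=\Delta I_H/(v_2-E_H)$ with $E_H=-35$ mV fixed
and $\Delta I_H$ from a single-exponential fit to the clamp current from
15 ms after step onset; simulated EPSP currents
$I(t) = A(1-e^{-t/\tau_1})e^{1-t/\tau_2}$ with $\tau_1$ = 0.3 ms and
$\tau_2$ = 3 ms and summation $(p_5-p_1)/p_1$; the normalized integral
$\int (V-V_{rest})\,dt / \int I\,dt$ in MΩ; firing rates by convolution
with a 20 ms-SD Gaussian on a 1 ms grid (the kernel integrates to one
spike, so the rate integral equals the count); spike counts from stimulus
onset to projected collision; coherence preference as the OLS slope of
count against coherence; the sustained/transient split by the longest
contiguous run of inter-spike intervals above 20 spk/s (1/ISI attached to
each interval, bounding spikes included, earliest run on ties). Nonlinear
fits use Levenberg–Marquardt least squares with log-linear starting values
(500 iterations, tolerance 10⁻¹⁰); sag fits include an offset term.
Population statistics use the BCa bootstrap and a studentized two-sample
bootstrap test of equal means (ASL), both implemented from their standard
constructions.

Every fitting procedure is validated closed-loop against
`gen_clamp_dataset()` and `gen_loom_trains()`, whose ground truth is known
by construction: noiseless recovery to within 2%, and unbiased recovery at
realistic noise (20 pA) over 100 seeds. The spike-train generator draws
from an inhomogeneous Poisson process whose looming-shaped rate template
($\theta'(t-\delta)e^{-\alpha\theta(t-\delta)}$, δ = 30 ms,
α = 0.08 deg⁻¹) is used purely as a plausible test profile; its time
integral is `intercept + slope × coherence`, so the programmed selectivity
slope is recoverable by the analysis chain.

## Numerical choices and degenerate inputs

Gates are clamped-stable for any `dt` (exponential integrator); the passive
solver matches RC and finite-cable closed forms to <1% at the default step,
and halving `dt` leaves the reference looming spike count unchanged.
Voltage clamp is ideal (the measured space-clamp attenuation quantifies the
physical limitation instead). Assignment ties, jitter rounding collisions
(nearest free cell, ties by lowest azimuth then elevation), zero-variance
fits (flagged, `g_max ≈ 0`), degenerate coherence tables (errors) and
empty spike trains (zero rates, all-transient splits) are all handled
explicitly and covered by tests.

## What the synthetic conditions do and do not show

The generators and the fan morphology emulate the *structure* of the
experiments — looming kinematics, coarse pixelation, coherence degradation,
clamp protocols with known ground truth, count statistics linear in
coherence — but not the biological scale: the full reconstruction has 2518
compartments (1266 in field A) versus our 127, and ~15,000 ommatidial
inputs versus 2,080 coarse pixels. Consequently the desk-scale model
reproduces the *directions* of the channel-blockade, randomization,
kinetics and morphology effects, not the published magnitudes (+59%/−61%
randomized-input changes, ~2.5 nA resting HCN current, 95% space clamp,
0.094 inactivation slope), which require the deposited reconstruction and
are exercised by the full-profile entry points only when that SWC file is
supplied. Known desk-scale departures, visible in the package's own
outputs: a complete K$_D$ block depolarizes the resting potential far more
than 4AP does in vivo (the tonic window current that implements the
scattered-input shunt is proportionally larger in a small arbor), pushing
the blocked model into a near-ceiling firing regime; the resting
K$_D$ inactivation level is lower than the full model's; the
K$_D$-versus-Ca$_T$ ordering of the inactivation-coherence slopes is not
resolved at this scale (both are positive, but the stimulus compresses all
spatial structure into the final half-second, diluting the area-averaged
K$_D$ signal); blocking $g_H$ does not increase sEPSP summation — in
the compact fan the local input impedance is dominated by axial current
flow rather than by the HCN-bearing membrane, so the τ_m-mediated
summation effect falls below the opposing contribution of HCN deactivation
tails; and the merged equivalent-cylinder reduction does not abolish the
coherence preference, because the fan's selectivity is carried mostly by
the eccentricity-to-depth wave, which an electrically faithful single
cylinder preserves — only the azimuthal branch-identity dimension is lost,
and with twelve branches it contributes little (the full reconstruction's
genuinely two-dimensional retinotopy is needed for the published
reduction effect). These are limitations of the reduced morphology, not of
the analysis chain, and they are documented rather than tuned away.
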