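# loomsel

Spatial-coherence selectivity of looming-sensitive neurons: stimulus
generation, biophysical modelling and electrophysiology analysis.

The locust lobula giant movement detector (LGMD) fires vigorously to objects
approaching on a collision course and drives escape jumps. Remarkably, its
response depends not only on the looming kinematics but on the *spatial
coherence* of the stimulus: a "coarse" loom pixelated at photoreceptor
resolution (2–3°) loses its efficacy when the pixel positions are scrambled,
even though every pixel keeps its exact luminance time course — so the total
excitatory drive is unchanged and only its spatial arrangement on the
dendrite differs. `loomsel` provides the computational machinery to study
this discrimination:

- **Stimuli.** Looming kinematics `2θ(t) = 2 tan⁻¹[l/(v t)]` (characterized
  by `l/|v|`), coarse pixelation with 6-bit luminance quantization, Gaussian
  position jitter with overlap-free rounding, and the operational coherence
  metric: per-frame minimum-cost assignment (Jonker–Volgenant) of jittered
  pixels onto equal-luminance reference positions, summed over frames and
  normalized by 30 uniformly random layouts —
  `coherence = 100·(1 − d/d_random)`.
- **Neuron model.** A branched compartmental cable solver (Crank–Nicolson,
  Hines-ordered tree solve, Rush–Larsen gates; Rcpp core) with
  Hodgkin–Huxley-style channels: experimentally fitted HCN kinetics
  (`g_H(v) = g_max/(1+exp((v−v_half)/s))`, `v_half = −77.6 mV`,
  `s = 13.34 mV`, reversal −35 mV, bell-shaped τ peaking at 1.34 s near
  −83 mV), a low-threshold inactivating K⁺ conductance (K_D-like) in the
  excitatory dendritic field, fast Na⁺/K_DR spiking at the initiation zone,
  M, Ca_T and K_Ca conductances, current/voltage clamp, space-clamp
  analysis, and Rall equivalent-cylinder reduction (0.04 λ steps, 3/2-power
  diameters).
- **Retinotopic synapses.** Visual facets map onto dendritic branches;
  luminance decrements emit adapting trains of nicotinic conductance
  events; jitter relocates inputs across the arbor while conserving their
  times and total conductance exactly; `randomize_locations()` isolates the
  spatial variable completely.
- **Analysis.** Sag amplitude/τ, membrane τ (0.5–13 ms window), HCN
  activation fits from `ΔI_H/(v₂−E_H)` constraints, sEPSP summation
  `(p₅−p₁)/p₁`, normalized integrals, Gaussian-kernel firing rates (20 ms
  SD), coherence-preference slopes (spikes per % coherence),
  sustained/transient splits, BCa bootstrap and two-sample ASL tests —
  all tibble-in/tibble-out with `tidy()`/`glance()`/`autoplot()` methods.
- **Synthetic data.** Clamp datasets with known Boltzmann/τ ground truth and
  looming-shaped Poisson spike trains with a programmed coherence slope, so
  every fitting procedure is validated closed loop.
- **Experiments.** Scripted in-silico protocols: coherence sweeps under
  channel blockade, retinotopic-vs-randomized input placement, channel
  inactivation tracking, and morphology/kinetics controls.

## Worked example

```r
library(loomsel)

# a coarse loom (l/|v| = 50 ms, 2 deg pixels, 80 deg final size) and a
# moderately jittered version of it
params <- loom_params(l_over_v = 50, max_full_angle = 80)
grid   <- coarse_grid(pixel_size = 2)
ref    <- render_coarse_loom(params, grid)
jit    <- jitter_layout(ref, sigma = 20, seed = 1)
coherence_percent(jit, ref, n_draws = 30, seed = 1)
#> # A tibble: 1 x 4
#>   coherence_percent raw_distance random_baseline_distance n_draws
#>               <dbl>        <dbl>                    <dbl>   <int>
#> 1              26.2      557907.                  755977.      30
```

A σ = 20° jitter leaves about 26% spatial coherence: reconstituting the
reference requires moving the jittered pixels roughly three quarters as
far, in total, as a fully random layout. Sweeping the blockade conditions of the model:

```r
sweep <- run_coherence_sweep(experiment_config())
sweep$slopes[, c("condition", "slope", "pearson_r")]
#> # A tibble: 4 x 3
#>   condition  slope pearson_r
#> 1 control   0.0542     0.984
#> 2 hcn_block 0.0409     0.964
#> 3 holding   0.0415     0.977
#> 4 kd_block  0.0527     0.993
autoplot(sweep)
```

The control model's spike count rises by ~0.054 spikes per percent
coherence (r = 0.98); blocking the HCN conductance (`g_H = 0`, the ZD7288 /
Cs⁺ condition) lowers both the counts and the slope, while blocking the
inactivating K⁺ conductance (4AP condition) multiplies all responses and
flattens the preference relative to them. Presenting identical synaptic
event trains retinotopically versus at random dendritic locations isolates
the mechanism:

```r
run_spatial_randomization(experiment_config())
#>   model   placement   spike_count mean_vm_mV
#> 1 passive retinotopic          80      -61.4
#> 2 passive randomized           86      -60.8
#> 3 hcn     retinotopic          60      -62.3
#> 4 hcn     randomized           65      -61.8
#> 5 full    retinotopic          23      -63.9
#> 6 full    randomized           19      -64.1
```

A passive dendrite prefers the spatially randomized input (less driving
force saturation); adding HCN alone does not change that; only the full
model with both HCN and inactivating K⁺ channels inverts the preference —
the signature reproduced from the physiology.

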