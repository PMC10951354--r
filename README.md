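# cerebsync

Simulation of cerebellar-dependent motor coordination, cast as active
inference.

Rodents synchronise whisking with respiration, and coordinate their limbs
and tail during locomotion; both couplings depend on an intact cerebellum.
`cerebsync` implements a computational account of how that coupling can
arise: the cerebellum is modelled as a Bayesian filter over a **linear
stochastic state-space model**

```
y  = θ_g x + Z          Z ~ N(0, Σ_z)
x' = −x + θ_f v + W     W ~ N(0, Σ_w)
v  = V                  V ~ N(0, Σ_v)
```

whose inversion — a gradient flow of the expectations (μ_x, μ_x′, μ_v) on
the variational free energy

```
F = ½ε_yᵀΠ_z ε_y + ½ε_xᵀΠ_w ε_x + ½ε_vᵀΠ_v ε_v − ½log|Π_z||Π_w||Π_v|,
ε_y = y − θ_g μ_x,   ε_x = μ_x′ + μ_x − θ_f μ_v,   ε_v = μ_v
```

— runs in closed loop with **stochastic Kuramoto oscillators** standing in
for the extra-cerebellar circuits that generate whisking (w = α sin φ_w),
respiration (r = sin φ_r) and limb displacements (l = sin φ). The
oscillators are never coupled to each other directly; each phase only
feels a term `k · sin(x − φ)` involving the filter's estimate of its own
somatic state. When the parallel-fibre connectivity θ_f encodes an
expectation of coordination (an all-ones matrix for whisking–respiration
synchrony; a ±1 pattern pairing diagonal limbs for locomotion), the
estimates are biased toward the coordinated pattern and that bias — fed
back through the coupling terms — synchronises the oscillators. With
θ_f = I (the naive model) the loop provides no coordination and the
behaviours drift apart.

The package provides the filter primitives (`free_energy()`,
`free_energy_gradients()`, `recognition_step()`), the oscillator processes
(`wr_state()`, `quadruped_state()`, regime schedules, perturbations), the
coupled engine (`run_coupled_simulation()`), preset experiments
(`scenario_wr()`, `scenario_locomotion()`), circular and stride-based
metrics, YAML-configured runs and a command-line interface (`cli_main()`,
wrapper script in `inst/scripts/cerebsync`).

## Worked example

```r
library(cerebsync)

# whisking-respiration with an intrinsic angular-velocity offset
res_on  <- scenario_wr("offset", contextualise = TRUE,  seed = 1)
res_off <- scenario_wr("offset", contextualise = FALSE, seed = 1)
print(res_on)
#> <scenario_result> wr-offset
#>   condition: condition = offset, contextualise = TRUE, seed = 1
#>   metrics:
#>      peak_abs_diff = 1
#>      post_transient_max_abs_diff = 1
#>      mean_manifold_distance = 0.1823
#>      mean_tracking_error = 0.16042
res_off$metrics$peak_abs_diff
#> [1] 2
```

With cerebellar contextualisation the whisker–respiration difference never
exceeds 1 a.u. (it touches 1 only during the no-whisk gap of the
behavioural schedule, where |w − r| = |r|; during whisking it stays near
0.6), and the state estimates track the true somatic states to within
0.16 a.u. on average. Without contextualisation the oscillators drift
through full anti-alignment and the difference reaches its theoretical
maximum of 2 a.u.

```r
loc <- scenario_locomotion(contextualise = TRUE, seed = 1)
loc$metrics$plock_fr_hl_conc    # 0.967  diagonal pair phase-locked
loc$metrics$plock_fr_fl_mean    # 3.10   front limbs near antiphase (π)
loc$metrics$tail_symmetry_index # 0.948  tail repeats the same excursion
                                #        every stride
```

The same filter, with the 4-dimensional diagonal-pair θ_f, locks
front-right with hind-left (concentration 0.97) against intrinsic
walk-pattern coupling that would otherwise hold the limbs a quarter-cycle
apart, and makes the stride-averaged tail trajectory reproducible.

From a shell:

```sh
Rscript inst/scripts/cerebsync scenario wr-offset \
    --without-contextualisation --seed 1 --out out/
Rscript inst/scripts/cerebsync list-scenarios
```

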