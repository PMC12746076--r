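# raptormech

Comparative biomechanics of the raptorial ankle: lever mechanics of
dorsiflexion, tendon tensile properties, and phylogenetically informed group
comparisons for birds of prey.

## The problem

Hawks (Accipitridae) and owls (Strigidae) pin, grasp and lift prey with
their hindlimbs. Dorsiflexion of the ankle is driven by the m. tibialis
cranialis, whose tendon inserts on a tubercle on the dorsal face of the
tarsometatarsus. The skeleton sets up a third-class lever about the
intertarsal joint: the **force arm** FA runs from the joint to the tubercle
(inlever) and the **resistance arm** RA from the joint to where the prey's
weight acts at the distal tarsometatarsus (outlever). For a prey item of
mass *m*, the resistance of prey is RP = *m g*, the required muscle force
follows from the lever balance

    F · FA = RP · RA   =>   F = RP · RA / FA,

and the mechanical advantage is MA = FA / RA. Because strigid tubercles sit
proportionally farther down a proportionally shorter, stouter
tarsometatarsus, owls work at a higher MA than hawks and need less muscle
force and torque for the same prey.

The soft-tissue side is measured by incremental cyclic tensile tests: the
tendon is stretched in triangular ramps (five cycles per 2% increment of
resting length, up to 10%, at 50 mm/min, sampled at 50 Hz), giving J-shaped
stress–strain hysteresis loops. From each loop the pipeline extracts
engineering stress σ = F_t / A₀ and strain ε = δ / L₀, regional Young's
moduli (toe, early-linear and late-linear slopes of the rising curve),
trapezoidal loop areas, and resilience (falling-curve area over
rising-curve area — the fraction of strain energy returned).

Because museum series and tensometer traces are not always available, the
package ships a first-class synthetic-data module: Gaussian specimen
populations with configurable species means, closed-form J-curve tensometer
traces whose late-region modulus and resilience are known exactly (so the
whole processing pipeline has an analytic oracle), and Brownian-motion
traits on phylogenies with tunable Pagel's lambda. The phylogenetic module
(Brownian variance–covariance, maximum-likelihood lambda, PGLS ANOVA and
MANOVA with residual-randomization permutation) is implemented from first
principles.

## Worked example

Lever mechanics for the six focal species lifting a 140 g chipmunk:

```r
library(raptormech)
lever_table(focal_lever_geometries(), standard_prey_scenarios()) |>
  format_lever_table() |>
  dplyr::filter(prey == "Tamias striatus")
#>   species            group      RP_N  RA_m   FA_m     MA muscle_force_N torque_Nm
#> 1 Accipiter striatus accipitrid 1.37 0.0514 0.0072  0.14           9.8       0.5
#> 2 Astur cooperii     accipitrid 1.37 0.0669 0.0127  0.19           7.23      0.48
#> 3 Buteo jamaicensis  accipitrid 1.37 0.0823 0.0181  0.22           6.24      0.51
#> 4 Megascops asio     strigid    1.37 0.0312 0.0089  0.29           4.81      0.15
#> 5 Asio otus          strigid    1.37 0.0411 0.0119  0.29           4.74      0.19
#> 6 Bubo virginianus   strigid    1.37 0.0626 0.0213  0.34           4.04      0.25
```

Every strigid MA exceeds every accipitrid MA (which is what drives the
rank-statistic W = 0 in the group comparison), and the sharp-shinned hawk
needs ~2.4× the muscle force of the great horned owl for the same prey.

Processing a synthetic cyclic tensile trace with known ground truth
(resilience 0.75, 1.5 N pre-tension, 0.02 N load noise):

```r
p <- tendon_model_params(a = 0.5, b = 20, eps_max = 0.10, resilience = 0.75,
                         csa = 5, rest_length = 15, pretension = 1.5,
                         noise_sd = 0.02)
res <- process_tensile_trace(generate_tendon_trace(p, seed = 1))
res$summary
#> zero_offset_N final_load_N peak_stress_MPa toe  early late  resilience
#>          1.49         16.0            3.20 13.8 26.6  52.4       0.750
```

The recovered zero offset matches the injected pre-tension, the moduli
order toe < early < late as a J-curve must, and resilience comes back at
the generator's analytic value.

End-to-end demo (all stages, with manifest and CSV/JSON reports):

```r
run_demo(seed = 1, out_dir = "demo_out")
```

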