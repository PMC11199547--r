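# spineload

Estimating lumbar spine loading — compression and anterior–posterior (AP)
shear at the functional spinal units T12/L1 … L5/S1 — from rigid-body trunk
models, and asking how the *degree of morphological individualization* of
those models changes the effects one would attribute to individual
morphology. The package is aimed at musculoskeletal modellers and spine
biomechanics researchers who work with cohort-scale simulation studies.

## What it does

For a synthetic patient cohort whose morphology statistics emulate an
elderly clinical population (n = 93; thoracic kyphosis TK 42.2 ± 11.5°,
lumbar lordosis LL 37.4 ± 12.0°, torso height TH 0.43 ± 0.03 m, torso
weight TW 25.1 ± 5.9 kg, torso centre of mass 0.03 ± 0.01 m anterior and
0.21 ± 0.01 m superior of L5, corr(LL, TK) = 0.4), `spineload` builds three
sagittal-plane trunk models per patient:

| configuration | spine geometry | torso weight & distribution |
|---|---|---|
| `Indiv`    | individual (TK, LL, TH) | individual (TW, CoM) |
| `uniSpine` | uniform (29°, 44°, 0.45 m) | individual |
| `uniTorso` | individual | uniform (23.3 kg, fixed offsets) |

Each model — a lordotic/kyphotic two-arc spine, per-level torso point
masses, generic head–neck and arms, and a 54-fascicle lumbar muscle set —
is simulated under four static tasks (neutral standing; 30° flexion with a
40 % sacral / 60 % lumbar split; lifting 10 kg at 0.25 m or 0.55 m in
front of T3). Muscle forces solve the static optimization

```
min Σ (F_i / PCSA_i)³   s.t.   Σ a_ij F_i = d_j at every lumbar joint,
                               0 ≤ F_i ≤ σ_max · PCSA_i,   σ_max = 1 MPa
```

and the joint reactions are decomposed in the functional-spinal-unit frame
(compression normal to the upper endplate of the lower vertebra; AP shear
orthogonal, positive posterior). The load tables feed signed min–max
scaling, a t-SNE embedding for qualitative pattern inspection, and
standardized multiple regressions per (response × level × load case ×
configuration), whose coefficients β measure effect strengths of the
morphology parameters.

## Worked example

```r
library(spineload)

co <- sample_cohort(93, seed = 1)        # synthetic cohort, Table-scale stats
m  <- assemble_model(co[1, ])            # fully individualized model
simulate_case(m, "neutral")$results
#>    level compression_N shear_AP_N feasible
#> 1 T12/L1      407.3476  163.62442     TRUE
#> 2  L1/L2      489.7246  159.09679     TRUE
#> 3  L2/L3      614.2688  144.85451     TRUE
#> 4  L3/L4      731.1088  108.51422     TRUE
#> 5  L4/L5      800.4626   47.85584     TRUE
#> 6  L5/S1      851.1300  -26.68649     TRUE
```

Patient P001 weighs well above the cohort mean (TW ≈ 33.7 kg), so upright
standing already compresses L4/L5 with ≈ 800 N; the negative L5/S1 shear
means the load there pushes the vertebra anteriorly, as expected on the
steeply tilted lumbosacral endplate.

The full experiment (279 models, 1,116 simulations, under a minute):

```r
rs <- run_experiment(run_config(n = 93, seed = 1))
rs
#> Run: 93 patients, 279 models, 1116 simulations attempted, 1116 feasible

subset(summarize_loads(rs$results),
       level == "L4/L5" & response == "compression" & config == "Indiv")
#>    load_case count   mean   std    min    p25    p50    p75  max
#> 37 flexion30    93 1683.1 266.9 1080.0 1484.0 1681.2 1850.2 2430
#> 38 lift10_25    93 1668.1 223.2 1319.6 1504.0 1611.1 1790.4 2393
#> 39 lift10_55    93 3129.1 301.0 2648.6 2922.6 3071.9 3309.2 4167
#> 40   neutral    93  631.8 146.7  324.5  535.8  599.5  719.3 1079
```

Mean individualized L4/L5 compression is ≈ 0.63 kN standing and ≈ 1.7 kN
in 30° flexion. The regression battery shows what drives it — in uniform-
spine models three torso parameters explain compression almost completely,
with torso weight carrying essentially the whole effect:

```r
reg <- run_regressions(rs$results, rs$cohort)
subset(reg, config == "uniSpine" & level == "L4/L5" &
            response == "compression" & load_case == "neutral")
#>     predictor    beta     se        p stars    r2 n_used
#> 529        TW  1.0000 0.0198 2.17e-67   *** 0.968     93
#> 530    CoM_AP -0.0839 0.0202 7.72e-05   *** 0.968     93
#> 531    CoM_SI  0.0443 0.0196 2.60e-02     * 0.968     93
```

For AP shear in spine-individualized models the dominant predictor is
lumbar lordosis instead (β ≈ −1, p < 0.001): more lordosis tilts the
L4/L5 endplate and shifts load anteriorly. The methods vignette
(`vignettes/lumbar-load-individualization.Rmd`) documents the model,
its parameters and defaults, the numerical choices, and which published
quantities the synthetic conditions can and cannot reproduce.

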