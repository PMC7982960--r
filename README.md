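# artiSSM

Articulating multi-component statistical shape models (SSMs) of jointed
anatomy, with the equine distal limb as the built-in template: nine distal
limb bones plus the hoof capsule, moved by a four-bone kinematic chain
(metacarpus → proximal → middle → distal phalanx; joints MCP, PIP, DIP).

It is aimed at researchers in veterinary biomechanics and anatomical shape
analysis who want a population model of a *jointed* structure: one that
describes inter-subject bone-shape variability while keeping joint spaces
consistent, so every synthesized instance can be posed afterwards.

## The model

After dense correspondence and scale/pose normalization, every subject
becomes one composite shape vector

```
s_i = [ ṽ_i,0 … ṽ_i,M−1 | log_μ1 a_1 … log_μNb a_Nb | c_1 … c_Nb ]
```

— all component vertex coordinates, then one flexion-axis direction and one
joint-center position per skeleton bone. Axis directions live on the unit
sphere, so they enter PCA through the logarithmic map at their intrinsic
(Karcher) mean, the principal-geodesic-analysis treatment. PCA gives
`s(b) = s̄ + E D b` with orthonormal modes `E` and mode standard deviations
`D`; fitting is `b = D⁻¹ Eᵀ (s − s̄)`. Because the skeleton is inside the
shape vector, an instance is reconstructed *with its own* joint axes and
centers and articulated by `T_p R_z(θ) T_p⁻¹` flexion transforms down the
chain.

The pipeline stages, each usable on its own:

- `readMesh()` / `writeMesh()` — vertex-order-preserving PLY/OBJ/STL/VTK I/O
  (vertex order is the correspondence carrier);
- `rigidPrealign()`, `elasticRegister()`, `buildCorrespondences()` —
  similarity ICP plus stiffness-annealed non-rigid ICP with a symmetric
  data term, two-pass mean-reference refinement;
- `normalizeSubjects()` — metacarpal-length scale normalization and
  closed-form single-axis (flexion-only) pose normalization per joint;
- `buildSSM()`, `synthesize()`, `fitShape()`, `sampleInstances()`,
  `reconstructPosed()` — the statistical core;
- `computeBiometric()`, `fitBiometricRegression()`,
  `instanceFromBiometric()`, `biometricCI()`, `correlationTable()` —
  automatic hoof/phalanx biometrics (toe angle, heel angle, frog width,
  joint curvature radii, …) and biometric-driven morphing;
- `compactness()`, `specificity()`, `generalizability()` — standard SSM
  quality metrics;
- `generateReferenceLimb()`, `generatePopulation()` — a synthetic
  articulated-limb generator with exact ground truth, so the entire
  pipeline is testable without any CT data.

## Worked example

```r
library(artiSSM)

ref <- generateReferenceLimb(detail = 0.6)   # synthetic 10-component limb
ref$model
#> LimbModel: 10 components (774 vertices total), 4 skeleton bones

cfg <- syntheticConfig(nSubjects = 12, seed = 7)
run <- runPipeline(runConfig(outDir = "demo-run", synthetic = cfg,
                             reference = ref, detail = 0.6, seed = 7))
ssm <- run$ssm
ssm
#> LimbSSM: 11 modes over 12 training shapes, shape vector length 2346
#>   leading mode sds: 38.3, 21.9, 9.86 (first mode explains 71.7% variance)

head(compactness(ssm), 4)
#>   modes     value
#> 1     1  71.74293
#> 2     2  95.24238
#> 3     3 100.00000
#> 4     4 100.00000
```

The population was generated with three latent modes, and the model finds
exactly three: compactness reaches 100% at mode 3. Morphing by a biometric:

```r
computeBiometric(ssm@reference, ref$schema, "TA")   # toe angle, degrees
#> [1] 52

reg <- fitBiometricRegression(ssm, ref$schema, "TA", n = 300, seed = 1)
round(c(mu = reg$muK, sd = reg$sdK), 2)
#>    mu    sd
#> 51.15  3.19

steep <- reconstructPosed(ssm, instanceFromBiometric(reg, reg$muK + 3 * reg$sdK))
computeBiometric(steep, ref$schema, "TA")
#> [1] 53.46

ci <- biometricCI(ssm, ref$schema, reg, "TA", grid = 15)
round(c(ci$min, ci$max), 3)
#> [1] -7.249  7.885
```

Requesting a toe angle of μ + 3σ ≈ 60.7° produced an instance measuring
53.5°: on this population the toe angle is a distinctly *nonlinear*
function of the mode weights, and the recomputation confidence interval
(−7.2°, +7.9°) reports exactly that. For a biometric that is an affine
functional of the weights the same interval collapses to float precision —
that contrast is what the interval is for. The instance can then be posed:

```r
articulate(steep, c(MCP = 15, PIP = 5, DIP = 3) * pi / 180)
#> LimbModel: 10 components (774 vertices total), 4 skeleton bones
```

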