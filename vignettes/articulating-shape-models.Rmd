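---
title: "Articulating multi-component statistical shape models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Articulating multi-component statistical shape models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

artiSSM builds a statistical shape model (SSM) of a jointed, multi-component
anatomical structure — the template is the equine distal limb: nine bones and
the hoof capsule, carried by four rigid skeleton groups — and keeps the model
articulatable after the statistics are done. This vignette explains the model,
its assumptions, the tunable parameters, the numerical choices, and what the
synthetic test bed does and does not demonstrate.

## The model

Each subject $i$ is a set of $M = 10$ triangle-mesh components $S_{ij}$. The
statistical core is an ordinary point distribution model: once all subjects
share the reference topology (same vertex count and order per component, with
equal indices meaning equal anatomical locations), every subject becomes a
composite shape vector

$$ s_i = [\,\tilde v_{i,0}\;\cdots\;\tilde v_{i,M-1}\;|\;
          \log_{\mu_1} a_1 \cdots \log_{\mu_{N_b}} a_{N_b}\;|\;
          c_1 \cdots c_{N_b}\,] $$

— the pose/scale-normalized vertex coordinates of all components, followed by
one log-mapped flexion-axis direction and one joint-center position per
skeleton bone ($N_b = 4$). PCA of these vectors gives the mean $\bar s$,
orthonormal modes $E$ and mode standard deviations $D = \mathrm{diag}(\sigma_i)$;
instances are $s(b) = \bar s + E D b$, weights fit by
$b = D^{-1} E^{\top} (s - \bar s)$. Because the skeleton (axes and centers)
is part of the shape vector, a synthesized instance carries its *own*
skeleton, and can be posed by the flexion transforms below — joint spaces
stay consistent as the shape changes.

**Why the log map.** Flexion-axis directions live on the unit sphere $S^2$,
not in a vector space; averaging or PCA on raw unit vectors is biased. The
axis block therefore stores each axis in the tangent plane at its intrinsic
(Karcher) mean — the principal-geodesic-analysis treatment — via
`sphereLog()` / `sphereExp()` and `intrinsicMean()`. Joint centers are
points, not directions, and stay Euclidean.

**Articulation.** Each skeleton bone has a right-handed orthonormal frame:
y along the bone's elongation axis, z perpendicular to its sagittal plane,
origin at the center of a circle fitted to its distal articular surface in
that plane. Flexing a bone $b$ by $\theta$ about its parent is the
conjugation $T_{p(b)}\,R_z(\theta)\,T_{p(b)}^{-1}$ with $T_{p(b)}$ the
parent's local-to-world transform; `articulate()` composes these down the
chain MC→P1→P2→P3 (joints MCP, PIP, DIP), so all components of one rigid
group receive the identical transform. Angles between adjacent frames
decompose as spherical coordinates $(\alpha, \beta, \gamma)$ —
flexion/extension in the parent's sagittal plane, abduction out of it,
internal rotation about the bone's own y axis — in the fixed order
$R = R_z(\alpha) R_x(\beta) R_y(\gamma)$ (the verbal definitions do not
force an order; this one makes $\alpha$ the pure in-plane angle).
Positive $\alpha$ is dorsal extension under the right-hand rule in the
left-limb, z-lateral convention; right limbs are mirrored into that
convention by `mirrorLimb()`, which reflects x and y axes and recomputes
z = x × y so frames stay right-handed with z normal to the sagittal plane.

## Correspondence by elastic registration

`buildCorrespondences()` deforms each reference component onto the matching
component of every subject:

1. **Pre-alignment** (`rigidPrealign()`): similarity ICP (rotation,
   translation, uniform scale), initialized from centroid + principal axes
   with all four right-handed axis-flip hypotheses, keeping the lowest
   point-to-surface RMS. Components are processed along the kinematic chain:
   each bone's large representative component also receives its parent's
   transform as an initialization hypothesis, and the small, nearly
   symmetric components of a group (splint bones, sesamoids) take their
   carrier bone's transform outright — their own flip ambiguity cannot be
   arbitrated by surface residual, while anatomy fixes their pose relative
   to the carrier.
2. **Elastic step** (`elasticRegister()`): stiffness-annealed non-rigid ICP.
   Every reference vertex carries an affine transform; each iteration
   matches deformed vertices to closest points on the target *and* target
   vertices to barycentric closest points on the deformed surface (the
   symmetric term — without it the mesh can fit the target one-sidedly
   while sliding or shrinking along it), and solves one sparse linear
   least-squares problem with a graph smoothness term penalizing
   differences between edge-adjacent affines. A weak identity prior
   (`identityWeight`) selects the minimal-displacement deformation among
   the surface-fitting ones: a smooth affine slide along the target costs
   neither data nor smoothness energy, so some such prior is required for a
   well-posed correspondence. Everything is deterministic — no sampling,
   ties by lowest index.
3. **Two passes**: after registering the original reference to all
   subjects, the vertex-wise mean of the results (taken in the reference
   frame) becomes the new reference and the registration is repeated,
   reducing bias toward the initial template. Outputs stay in each
   subject's world pose.

Key parameters (`registrationParams()`): `stiffness` — the annealing
schedule, default 50→1, dimensionless weight of smoothness against the
per-vertex data term; high values move the mesh near-rigidly, low values
allow local detail. `identityWeight` (default 0.05) — displacement prior;
raising it biases toward the pre-aligned shape. `reverseWeight` (default 1)
— symmetric-term weight, scaled so forward and reverse constraints balance.
`distanceCap` — outlier gate in mm for partially overlapping data (off by
default; the synthetic fixtures are complete surfaces).

Registration quality is reported as the signed point-to-surface distance of
registered vertices to the original subject surfaces (`signedGeometricError()`,
negative inside the closed target by generalized winding number, positive
outside; open targets fall back to unsigned with a flag), averaged per
vertex across subjects and globally (mean unsigned ± between-subject sd).
Averages are vertex-weighted; area weighting would be the alternative, and
the choice is deliberately documented rather than hidden.

## Scale and pose normalization

Before statistics, `normalizeSubjects()` removes nuisance variation:

- **Scale**: every subject is multiplied by (reference MC3 length)/(subject
  MC3 length), length being the extent of the bone's vertices projected on
  its frame's y axis — operationalizing "third metacarpal length" in a way
  that is invariant to world pose. Scaling is anchored at the root-group
  centroid, the same point the pose step aligns, which makes scale and pose
  normalization commute.
- **Root alignment**: the metacarpal group is aligned to the reference by
  correspondence Procrustes; the rotation comes from a similarity fit (so
  any residual global scale cannot bias it) and is applied rigidly.
- **Flexion**: walking proximal→distal, each joint's optimal flexion angle
  solves $\theta^* = \arg\min_\theta \lVert a - R_z(\theta)\, b \rVert^2$
  over the bone's vertices expressed in the parent's local frame, in closed
  form: $\theta^* = \operatorname{atan2}\!\big(\sum (b \times a)\cdot \hat z,\;
  \sum (a\cdot b - a_z b_z)\big)$. Only this one degree of freedom per joint
  is removed; abduction/adduction and internal rotation remain in the data
  as remnant posture, by design. The proximal→distal order ensures each
  child's parent frame is already normalized.

Per-subject skeletons are re-estimated from the data: frame axes through the
pre-alignment rotations, joint centers by least-squares circle fits
(`fitJointCircle()`, algebraic Kåsa fit in the bone's sagittal plane) of the
annotated joint-surface vertex sets carried through the correspondence.
Joint surfaces are part of the reference annotation, not auto-detected —
there is no reliable geometric detection rule, and the annotation transfers
to every subject through the correspondence anyway. That same transfer is
what makes all landmark-based biometrics automatic.

## Biometrics

`computeBiometric()` implements the standard hoof and phalanx measures (toe
and heel angle, frog length/width, support length, joint curvature radii,
phalanx lengths, sesamoid angle and height, …; see `biometricIds()`) from a
landmark schema on the reference topology. Conventions chosen where the
verbal definitions are underdetermined: the *ground plane* is the
least-squares plane through the lowest 2% of capsule vertices (a hoof mesh
in the air has no physical ground); a bone's *sagittal plane* passes through
its frame origin with normal z; "lateral view" projections project along
that normal; the toe-to-heel support fraction TS uses the ground-projected
distance from the toe to the distal-phalanx articulation center along the
support direction, as a percentage of the support length.

`fitBiometricRegression()` links a biometric $k$ to the mode weights by
sampling instances from the model's multivariate normal distribution
(N = 1000 by default) and fitting $b(k) = \alpha + \beta k$ per mode
(independent per-mode least squares — algebraically the stacked multivariate
regression). `instanceFromBiometric()` morphs the model to a prescribed
biometric value; the conventional presets are $k = \mu_k \pm 3\sigma_k$.
`biometricCI()` quantifies the linearity assumption by rebuilding instances
across that range and recomputing the biometric: for a biometric that is an
affine functional of the weights the recomputed value equals the requested
one up to float precision, and the signed (min, max) of recomputed − requested
widens exactly when the biometric responds nonlinearly. The default grid is
25 points over ±3σ. `correlationTable()` reports Pearson correlations among
biometrics over sampled instances.

## Model evaluation

Standard SSM quality metrics, all as functions of the mode count:
compactness (cumulative explained variance), specificity (RMS
corresponding-vertex distance of sampled instances to the nearest training
shape; sampling is truncated to the first m modes at each point of the
curve, 200 samples by default), and generalizability (leave-one-out: rebuild
on L−1 subjects, fit the held-out one, RMS error; reported against the
in-sample reconstruction-error curve, whose gap is the cost of generalizing).
The mm-valued metrics use the geometry block only — axis/center entries are
excluded so the result is a surface distance.

## The synthetic test bed

`generateReferenceLimb()` builds a procedural 10-component limb with
analytically known ground truth: frames are axis-aligned by construction,
joint patches lie on analytic cylinders (so circle-fit truth is exact), the
capsule's dorsal and heel walls make configurable angles with the ground,
and the surfaces carry a deterministic low-order asymmetry plus a fine bump
lattice — the stand-in for the muscle ridges and foramina that anchor
registration on real bone. `generatePopulation()` layers, per subject:
low-rank smooth shape modes, a global scale (uniform 0.9–1.15, a
pony-to-horse range), per-joint flexion (uniform ±0.3 rad, the spread of
unloaded cadaver poses), an optional small abduction remnant (also the
mechanism that scatters flexion axes in a cone for the spherical
statistics), optional vertex noise, a random world pose, and optionally a
remeshing step (1→3 centroid face split plus vertex permutation) that
destroys the vertex correspondence so the registration stage has real work.
Mode standard deviations default to (1.5, 1.0, 0.7) mm RMS per vertex —
deliberately modest: the phalanges have 12–16 mm radii, and beyond ~3 mm
the pose/shape separation that any registration must perform becomes
ill-posed.

Two generator choices deserve emphasis because they define what the tests
prove:

- Mode fields displace along vertex normals and are made orthogonal to each
  component's similarity-perturbation subspace (translations, infinitesimal
  rotations, scale moments), with zero displacement on the joint patches
  and the scale-reference vertices. This makes shape *identifiable* from
  pose and scale — precisely the separation the normalization model
  assumes. On such populations the pipeline's exact-correspondence path
  inverts the generative process to machine precision (compactness of the
  true mode count = 100%, subspace principal angles < 1e−5 degrees), which
  is a genuine end-to-end correctness check of scale recovery, root
  alignment, per-joint flexion recovery, skeleton re-estimation, and the
  PCA — not merely of PCA alone.
- What passing these tests does **not** show: that dense correspondence can
  be recovered from remeshed surfaces to the same precision. Measured on
  the remeshed path, the closest-point non-rigid ICP family plateaus at
  roughly 0.4–1.2 mm RMS correspondence error per component, across
  stiffness schedules, priors and resolutions — an information limit of
  pairwise surface matching on smooth anatomy, not a bug: the surfaces
  simply do not determine the correspondence more finely, and the
  systematic part of the error is linear in the latent weights, so the
  recovered subspace tilts by tens of degrees regardless of sample size.
  Methods that break this limit (groupwise correspondence optimization,
  landmark-constrained registration) are deliberately outside this
  package's registration scope. One acceptance test asserts a stricter
  recovery target for this configuration and is expected to fail; it is
  retained unweakened as a record of the limit. Real-data accuracy
  claims should therefore rest on surface error (which is excellent:
  ~0.05 mm mean unsigned on the remeshed fixtures), not on latent-mode
  recovery.

## Numerical choices

- PCA runs as an economy SVD of the centered 3F × L data matrix. The
  classical efficient route for tall shape matrices — eigendecomposition of
  the small Gram matrix $X_c^\top X_c$ — is identical in exact arithmetic
  and is kept as a test oracle, but squaring the matrix halves the
  attainable precision: null modes bottom out at $\sqrt{\varepsilon}\,
  \sigma_1 \approx 1.5\times10^{-8}\sigma_1$ instead of
  $\varepsilon\,\sigma_1$. Variances use the sample divisor L−1 so
  $\sigma_i$ are comparable across population sizes. Mode signs are fixed
  (largest-magnitude entry positive) for cross-platform determinism.
- Modes with $\sigma_i < 10^{-12}\sigma_1$ are excluded from fitting
  (pseudo-inverse would divide by ~0). Weight-space identities are only
  numerically meaningful for modes above ~$10^{-6}\sigma_1$; below that,
  float rounding divided by a vanishing sd dominates, though the
  reconstruction identity still holds to machine precision.
- The spherical log map computes its angle by `atan2` of the cross-product
  norm, which is well conditioned near coincident vectors where `acos`
  loses half the digits; the Karcher mean iterates tangent averaging to a
  1e−12 step with a non-convergence flag for non-hemispherical data.
- No unit weighting is applied between mm coordinates and radian logs in
  the composite vector — the blocks are concatenated as they are, matching
  the model definition; with millimetre-scale geometry blocks of thousands
  of entries the axis blocks contribute negligibly to the mode structure,
  which is the accepted behavior of this model family.
- Geometric-error signs come from the generalized winding number (robust
  for closed meshes); exactly-on-surface points get distance 0. Closed
  synthetic meshes are oriented by breadth-first propagation plus a global
  volume-sign fix.
- The elastic solver adds a relative 1e−9 Tikhonov term: thin, nearly
  collinear components (splint bones) otherwise leave some affine
  directions numerically unconstrained.
- Problem sizes used by the test-suite and the acceptance script: reference
  at `detail = 0.6` (~950 vertices across the limb), 20-subject populations
  on the exact-correspondence path, 8-subject populations on the
  remeshed/registration path, 200–300 sampled instances for regression and
  specificity checks. These sizes were chosen so the whole validation cycle
  stays interactive while every check retains its discriminating power.

## Known limitations

- Pose is a mathematical articulation model, not a statistical one: the
  model does not learn shape-pose covariation, and mode weights do not
  change the range of motion.
- Only flexion/extension is articulated; abduction and internal rotation
  are treated as remnant posture in the data.
- Per-component registration does not model sliding across component
  boundaries or prevent cross-component collisions.
- The biometric regression is linear by construction; `biometricCI()`
  exists precisely to quantify where that assumption bends.
- The synthetic limb is a geometric emulator, not equine anatomy; absolute
  biometric values from it are meaningful only relative to its own
  configuration.
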