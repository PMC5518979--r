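---
title: "Stress-constrained gait simulation: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-constrained gait simulation: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bipedsim` couples three models — multibody dynamics, Hill-type muscle
actuation, and beam-mechanics bone stress — into a single simulation in
which peak bone stress is a *hard* constraint on the gaits an
evolutionary search may use. This vignette documents the models, their
assumptions, every tunable that matters, and the numerical decisions
behind the implementation. It states no empirical result beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## The articulated model

A model is a tree of rigid segments connected by frictionless hinge
joints restricted to the sagittal plane (x forward, y up, angles
counterclockwise, SI units throughout). The planar restriction is the
central simplifying assumption: the main joint actions of a striding
biped are flexion–extension, and a planar controller is vastly easier
to optimise, at the cost of ignoring mediolateral balance entirely.

Segment mass properties come from closed 2-D polygon hulls: the
centroid and second polar moment are computed exactly (Green's-theorem
formulas) for a uniform-density polygon and scaled to the segment's
assigned mass. Segment masses themselves follow a two-stage allocation:

* a power-law regression `m = a·V^b` from convex-hull volume to mass
  (`estimateMassFromHull()`); the shipped full-scale fixture stores the
  hull volumes and the stand-in coefficients (`a = 1214` kg m⁻³,
  `b = 1` — an effective hull density) it was built with, because the
  calibration datasets behind such regressions are published in
  supplements, not in print;
* limb mass fractions of total body mass (`limbMassFractionDefaults()`:
  thigh 0.105, shank 0.048, metatarsal 0.016, pes 0.006 per side),
  documented stand-ins in the style of cursorial-bird data, remainder
  to the trunk. The forelimbs carry no locomotor role here and are
  merged into the trunk segment.

Muscle mass is a single fraction of body mass (default 0.5, the highest
plausible value — results are insensitive to it as long as the
movement is not muscle-limited) distributed over six functional groups
(flexor/extensor × proximal/intermediate/distal,
`muscleMassAllocationDefaults()`) and split equally within a group.

## Muscles

Muscle–tendon units are polyline paths of way-points fixed in segment
frames; no wrapping surfaces. MTU length is the world-frame polyline
length; moment arms are central finite differences `-dL/dθ` with a
1 × 10⁻⁵ rad step (positive arm = counterclockwise moment on the child
segment).

Fibre and tendon-slack lengths are tuned per muscle from the length
sweep across the permitted ranges of every joint the path crosses
(64 grid samples per joint for single-joint muscles; the per-joint
resolution shrinks for multi-joint paths so the full grid stays below
about 4096 poses). With `fibreFraction` f (default 0.5),

* optimal fibre length = f × (max MTU length − min MTU length),
* tendon slack = MTU length at mid-range − fibre length (floored at 0).

This centres each muscle's working range on its force–length optimum.
Maximum isometric force derives from the allocated muscle mass via a
specific tension of 0.3 MPa and a density of 1056 kg m⁻³.

Two force models are provided deliberately:

* `mtuForce()` — the documented series-elastic model: active
  force–length (Gaussian, width 0.45), force–velocity (hyperbolic
  shortening branch reaching zero at 10 optimal fibre lengths s⁻¹,
  saturating lengthening branch at 1.8), passive fibre elasticity, in
  series with a linear tendon (dimensionless stiffness 30, i.e. ~3.3%
  strain at maximum force) that is slack below its slack length; the
  fibre length solves the force-equilibrium equation.
* the engine's inner-loop model — the same active curves with a *stiff*
  tendon (fibre length = MTU length − slack, fibre velocity = MTU
  velocity) and **no passive fibre element**, plus a small fibre
  damping term (1% of `fmax` per unit normalised velocity). Two
  reasons: (i) the fibre/tendon tuning above makes the normalised fibre
  length span roughly [0, 2] across the joint ranges, so any standard
  passive exponential multiplied by the very large `fmax` implied by
  50% muscle mass would rigidly lock every joint near its range ends
  (measured on the toy model: ~29 MPa of spurious standing femoral
  stress, versus ~0.2 MPa true static); (ii) the whole-body simulators
  this engine follows use active-only muscle formulations and represent
  passive joint structures separately. Here that role is played by the
  joint-range torsional springs.

Activation follows first-order dynamics toward the neural excitation
with a 50 ms time constant (exact exponential update per step).

## Contact and joint limits

Ground is the infinite plane y = 0. Contact spheres act as one-sided
spring–dampers: normal force `max(0, k·δ − c·δ̇_sep)`, never tensile, so
feet lift off freely. Friction is regularised Coulomb — tangential
force saturating at μN (μ = 1) with a 0.02 m s⁻¹ regularisation
velocity — to keep the dynamics smooth. Fixture stiffness is chosen so
standing penetration is ~1% of leg length, with damping set near
critical for the foot mass.

Joint ranges are enforced by stiff one-sided torsional spring–dampers
engaging outside the range (stiffness 2 W·L per radian, where W·L is
body weight times leg length), plus a small always-on damping; the
underlying hinge is ideal.

## Dynamics formulation

The equations of motion are assembled in *reduced (joint-space)
coordinates*: a free 3-DOF trunk (or a fixed base for laboratory rigs)
plus one angle per hinge. Welded pairs (used for load recovery)
contribute no coordinate. Per step the engine builds the COM and
angular Jacobians of every body recursively, forms
`M(q) = Σ m_b Jᵀ J + I_b Jw Jwᵀ` and the generalized force vector
(gravity, muscle path forces, contact, joint-limit torques, centripetal
bias), and solves the dense symmetric system.

The practical consequences: hinge anchor residuals are zero by
construction (the 10⁻⁸ m coincidence tolerance is a diagnostic, not a
solver setting), and splitting a segment into welded halves leaves the
equations of motion identical up to round-off — the split/unsplit
equivalence test passes at 10⁻⁶ m over 2 s with observed deviations at
machine precision.

Integration is fixed-step semi-implicit (symplectic) Euler, default
timestep 10⁻⁴ s, chosen for the stiff contact springs. Free fall is
exact at step boundaries; the small-amplitude pendulum period is
reproduced to ~0.07%; passive double-pendulum energy drift is ~0.05%
over 10 s at a 5 × 10⁻⁵ s step (~0.1% at 10⁻⁴ s — the scheme's energy
error is oscillatory, not secular). COM momentum obeys the external
impulse to first order in the step (observed ~3 × 10⁻⁵ m s⁻¹ over
0.3 s of vigorous activation).

A divergence guard terminates a run when the COM speed exceeds
`15·√(g·h₀)` (h₀ = starting hip height) or the solve goes non-finite.
Without it, an *unconstrained* fitness search discovers numerical
blow-ups and reports them as distance; the stress monitor had been
masking this failure mode at finite limits. Guarded termination is
reported as its own cause (`diverged`) and, like any early stop,
truncates the fitness at the distance actually achieved.

## Bone loading and stress

Each monitored segment is split at a cut fraction (default 0.5, the
functional mid-point) perpendicular to its proximal→distal axis. The
hull is clipped at the cut plane so the halves' masses, centroids and
inertias recombine exactly; attached joints, muscle way-points and
contact spheres re-home to the correct half by their position along the
axis. The force and moment transmitted across the weld are recovered by
Newton–Euler summation over the distal subtree — inertial terms
`m(a − g)` and `I·α` minus applied external forces — so muscle, contact
and reaction components are all included. Axial force is resolved along
the bone axis (tension positive), shear transverse, and the out-of-plane
moment maps onto the section's mediolateral axis (`Mx`); `My` is zero
by construction in a planar model.

Cross-sections are hollow: mean external radius R̄ is the mean distance
of the outer boundary from its centroid, wall thickness
t = corticalFraction × R̄, and the inner boundary is the outer boundary
offset uniformly *inward* by t (an offset, not a centroid scaling,
because the datum is a thickness; collapsed vertices are dropped, and
annihilating the section is an error). Area and the second/product
moments come from exact polygon formulas on outer-minus-inner. The
full-scale fixture uses the published cortical fractions — femur 0.38,
tibia 0.35, fibula 0.96, metatarsus 0.60 — on circular outlines with
128 vertices (peak search at boundary vertices needs ≥128 for <0.1%
closed-form agreement).

Peak stress evaluates axial-plus-bending at every outer-boundary vertex
(the extreme fibre of a combined field lies on the outer boundary);
tension is positive and the fail metric is `max(|σmax|, |σmin|)`. Shear
is ignored in the failure metric, bending and compression being the
dominant loading modes. Where a segment carries two bones (tibia +
fibula), each is monitored as a separate beam, with bending moment
shared in proportion to Ix and axial force in proportion to area —
a stiffness-proportional sharing rule adopted because the true
load split is not derivable from the model.

The per-bone peak-stress series is filtered online by a causal
2nd-order Butterworth low-pass at 5 Hz (biquad, state initialised to
the first sample so a constant passes unchanged), compensating for the
absence of soft-tissue cushioning and matching standard gait-analysis
filtering. Filtering is causal because the fail test runs *inside* the
simulation; a zero-phase mode exists for post-hoc plots. The hard fail
triggers at the first step any filtered trace exceeds the limit; with
an infinite limit the monitor is exactly passive (bit-identical
trajectories), and a zero limit fails at the first monitored step.

## Controllers, fitness and the evolutionary search

A controller is a cyclic pattern: N equal phases per cycle (default
N = 8 — enough to express stance/swing asymmetries without bloating the
genome) with one excitation level per muscle per phase, plus the cycle
duration. Left–right symmetry is on by default (right limb = left limb
delayed half a cycle; N must be even), halving the search space.

Fitness is the horizontal COM distance achieved before termination
(duration, fall, stress fail, or divergence) — no extra penalty, early
termination being its own penalty. The fall test is hip height below
50% of its starting value. The optimiser is a generational GA: uniform
crossover (rate 0.7), per-gene Gaussian mutation (rate 0.15, sd 0.2,
clipped to [0, 1]), tournament selection (size 2), elitism 1, fully
seeded. `sweepStressLimits()` optimises limits in descending order,
seeding each search with bounded perturbations of the previous best
(`morphSeed()`) — the staged "gait morphing" re-optimisation strategy.

## The fixtures as study conditions

`makePendulum()`, `makeDropTest()` are closed-form oracles.
`makeToyBiped()` (1 m leg, 80 kg, 6 muscles per limb) is the
optimisable test article: segment length fractions 0.45/0.45/0.10 of
leg length plus a flat pes with heel/toe contact spheres placed
symmetrically about the metatarsophalangeal joint so the standing pose
is a true static equilibrium. `makeTrexLike()` is the same generator at
full scale — 7206.7 kg total, 50% muscle mass, 2.95 m leg — with the
published cortical fractions and stand-in hull volumes; it is a
geometric stand-in (boxes and circles), *not* a laser-scan
reconstruction, and is labelled as such. All fixtures are deterministic
(identical bytes on every build).

What the toy model emulates: the mass budget structure, hollow-bone
stress pipeline, hard-fail-constrained gait search and the
speed-vs-stress-limit trade-off. What it does not: anatomical muscle
routing (6 functional muscles, not 29), 3-D balance, compliant feet,
and real bone-section geometry — so passing tests demonstrate the
*method* behaves correctly, not that the toy's speeds transfer to any
real animal.

The stress limits used for the toy sweep (5, 30, 300 MPa) were chosen
to bracket its regimes once: ~0.5 MPa standing stress, tens of MPa
during vigorous gaits (5 MPa binds almost immediately; 300 MPa never
binds). The test asserts the scientific property — median best speed
non-decreasing in the limit, low strictly below high, over three
independent seed chains with morphing.

## Problem sizes and runtimes

The shipped tests and the acceptance script run the evolutionary
property at a deliberately small scale — population 16, 12 generations,
4 s evaluations at a 5 × 10⁻⁴ s step, 2–3 seed chains over three
limits — sized so the whole suite completes in a few minutes on one
CPU while leaving the property's semantics untouched. The full-model
search behind the original results consumed thousands of core-hours on
a 29-muscle-per-limb model and is explicitly out of scope; nothing at
desk scale reproduces its headline speeds, which is why the package's
checks are property-based (closed forms, conservation laws, invariances,
monotonicity) rather than value-matching.

## Known limitations

* Planar only; no mediolateral mechanics, no torsional bone loading
  (torsion and shear are outside the failure metric by design).
* The stiff-tendon engine muscle ignores series-elastic energy storage;
  gaits that exploit tendon recoil are therefore under-rewarded.
* Spring–damper point contact does not model deformable substrates or
  toe-off rolling.
* The GA at test scale finds locomotion, not optimal locomotion; its
  speeds are lower bounds under the configured budget.
* The legacy-dialect importer does a best-effort planar projection
  (x, z) of 3-D model files and synthesises box hulls; imported models
  generally need curation before simulation.
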