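---
title: "Reference-point distributions and the accuracy of reconstructed jaw relations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-point distributions and the accuracy of reconstructed jaw relations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platealign)
```

## The measurement problem

Reconstructing the intercuspal jaw relation from two *separately* scanned
dental casts requires a common reference. The approach modeled here equips
the articulator mounting plates with hemispherical concave landmarks: a
contact probe measures the concave centers with the casts articulated (the
"standard data", which encodes the true jaw relation), each jaw is then
scanned on its own in an arbitrary pose, the concave centers are recovered
from the scan by sphere fitting (the "fitting data"), and each jaw is
rigidly registered onto the standard data using a chosen subset of the
landmarks. Whatever error that registration leaves shows up as error in the
reconstructed jaw relation.

The question the package answers by simulation: **how does the choice and
spatial distribution of the reference landmarks affect the accuracy of the
reconstruction?** Seven reference-point groups are compared — three-pair
groups 1–3 and four-pair groups 4–7, ranging from perimeter-spanning
(group 4) to front-concentrated (groups 3 and 7) — using the inter-jaw
distances of the *held-out* pairs as the yardstick.

## The model, stage by stage

### Plate geometry

Each plate carries nine concaves of 6 mm diameter, three per face (right
lateral, front, left lateral), FDI-style labels, with every maxillary
concave vertically above its mandibular partner. The actual spacings of a
physical plate are a free design choice, so the layout is fully
parameterized; the defaults are plausible articulator-plate dimensions:

| parameter          | default | unit | meaning                                   |
|--------------------|--------:|------|-------------------------------------------|
| `concave_radius`   | 3       | mm   | hemispherical concave radius (6 mm diameter) |
| `jaw_separation`   | 90      | mm   | vertical distance between concave planes   |
| `face_width`       | 60      | mm   | plate face width                           |
| `lateral_spacing`  | 20      | mm   | spacing of concaves on each lateral face   |
| `front_spacing`    | 15      | mm   | spacing of concaves on the front face      |

Because every number is overridable (and layouts round-trip through JSON),
conclusions can be re-checked for layout sensitivity. The observation
coordinate system is rebuilt from landmarks 12, 0 and 22 exactly as in the
physical protocol: 0 at the origin, the 12–22 line parallel to X, the
12/0/22 plane as XOY, Z normal to it (chosen to point from the mandible
toward the maxilla when both jaws are present), right-handed throughout.

### Noise model

Device accuracy figures are interpreted as 1-σ isotropic Gaussian noise —
per coordinate for the contact probe (0.024 mm) and per surface point for
the scanner (0.059 mm). This is the most conservative simple reading of a
single accuracy number; both σ values are configurable. Contact
measurements are repeated three times and averaged (reducing the variance
by 3); scans are fitted three times and the fitted centers averaged.

### Scan simulation

Each scan session draws a uniformly random rigid pose (uniform rotation via
normalized quaternions, translation uniform in ±50 mm) for the jaw, then
samples each concave as a spherical cap about its opening axis. The cap
half-angle defaults to 75°: a full hemisphere rim is optimistic for real
optical scans, so a slight rim loss is assumed. The three replicate clouds
of a session share the session pose — the physical protocol re-extracts
spheres from repeated scans of one fixture setup, and one pose is the
simplest consistent reading.

The *operator effect* is modeled as independent random subsampling of each
cloud (default fraction 0.7) before fitting, mimicking how differently two
operators delimit the concave region in the scan software. No systematic
inter-operator bias is included by default; the subsampling fractions can
be set per operator to probe reliability (widening the gap between the
operators' fractions degrades inter-operator ICC).

All randomness flows from one master seed through named substreams keyed by
(purpose, jaw, operator, repetition), so any stage can be reproduced in
isolation and identical configurations give bit-identical results.

### Sphere fitting

A two-stage fit, as in standard metrology practice:

1. **Algebraic initialization** — the linear least-squares solution of
   ‖p‖² = 2c·p + (r² − ‖c‖²), exact on noiseless data; rank-deficient
   (coplanar/collinear) clouds are rejected.
2. **Geometric refinement** — damped Gauss–Newton (Levenberg–Marquardt)
   minimization of Σᵢ(‖pᵢ − c‖ − r)². Steps are accepted only when they
   decrease the objective, so the refined fit is never worse than its
   initialization. Convergence: gradient norm below 1e-10 within 100
   iterations; non-convergence is flagged, not fatal. The test suite
   cross-checks the optimum against an independent Levenberg–Marquardt
   implementation.

Free-radius fitting is the default (a generic "best fit spherical
feature"); a fixed-radius variant (the designed 3 mm) is available, since
in simulation the truth is known — Monte-Carlo tests confirm it is never
less accurate for center recovery.

### Registration

Equal-weight rigid landmark alignment by the closed-form Kabsch solution:
centroid subtraction, SVD of the 3×3 cross-covariance, determinant sign
correction. The sign correction guarantees a proper rotation (no
reflection), and the solution is the global optimum of the equal-weight
least-squares objective — verified in tests against a restarted
six-parameter numeric minimizer. No scaling term is estimated: plates and
casts are treated as rigid bodies. Equal weights follow the protocol being
modeled; collinear landmark configurations (second singular value of the
centered source below 1e-9) are reported as errors rather than resolved
arbitrarily, because the optimum is then a continuum.

Each jaw is registered *to the standard data*, never jaw to jaw: the
standard set encodes the articulated relation, so both jaws land in a
common frame and the relation between them is implied.

### Evaluation and statistics

For each (operator, repetition, group) unit, the held-out pairs' distances
D_M are compared with the reference distances D_R taken from the standard
data (a flag switches to the noiseless nominal layout for oracle studies).
Trueness RMSE = √(mean (D_M − D_R)²) per unit; precision RMSE per
repetition = √(mean over pairs (D_M − per-pair repetition mean)²) within
each (operator, group) — the ISO 5725-1 repeatability notion. "Mean ± SD"
summaries aggregate per-unit RMSE values pooled over operators; the
aggregation is a stated, configurable choice since a printed table cannot
reveal it.

The statistical layer implements one-way ANOVA (F = MS_between/MS_within),
Tukey HSD with the Tukey–Kramer standard error at unequal n, and two-way
single-measurement ICC in the two forms used for operator reliability:
absolute agreement (intra-operator, repetitions as raters) and consistency
(inter-operator, operators as raters), with 95% F-based confidence
intervals. All of these are computed from their mean-square decompositions
and verified against independent reference implementations in the test
suite. Zero-variance (constant) inputs raise typed errors rather than
returning NaN; a matrix whose total range is below 1e-9 mm — far below any
physical measurement resolution — counts as constant. Normality and
variance-homogeneity pre-checks (Shapiro–Wilk, Levene) are deliberately not
re-implemented; stock routines (`shapiro.test`, `car::leveneTest`) can be
applied to the `records` data frame directly.

## What the generator does and does not emulate

Emulated: the full study design (9+9 concaves, thrice-averaged contact and
scan measurements, per-jaw arbitrary scanner poses, 15 repetitions × 2
operators × 7 groups = 210 alignment units), device-level Gaussian noise at
the stated accuracies, partial cap capture, and operator-dependent region
selection.

Not emulated: scanner physics (occlusion, specularity, mesh
reconstruction), plaster or print deformation, systematic inter-operator
bias, and any heterogeneity in the true pair distances — in the default
layout every maxillary concave sits exactly above its partner, so all nine
nominal inter-jaw distances equal `jaw_separation`. That last idealization
matters for interpretation: intraclass correlations computed with pairs as
targets draw their between-target variance only from the persistent noise
in the standard data, so synthetic intra-operator ICCs are markedly lower
than those of physical experiments, where pair distances genuinely differ.
The inter-operator consistency ICC is insensitive to this and reproduces
the excellent-reliability pattern. Passing tests therefore demonstrate the
correctness of the pipeline and the *relative* behavior of the groups, not
the absolute accuracy or reliability values of any physical system.

A related caveat applies to the headline numbers: trueness magnitudes
depend on the assumed layout spacings and noise interpretation, so the
package's per-group values should be read as orderings and sensitivities,
not as predictions of a particular physical setup.

## The central finding, in simulation

Under the default layout and noise, the spread four-pair group 4 yields
lower mean trueness than the front-concentrated four-pair group 7, and the
spread three-pair group 1 beats the front-concentrated group 3 — the
leverage effect: held-out pairs far from the reference centroid amplify
registration error. The acceptance suite checks this ordering across 100
independently seeded experiments (run at 4 repetitions × 2 operators each,
a problem size chosen to keep the hundred-experiment study compact while
leaving the per-group means stable), requiring it to hold in at least 95.

## Numerical and testing choices

- Transforms are rotation-matrix based; inputs claiming to be rotations are
  validated (RᵀR = I and det = +1 within 1e-10), never silently
  re-orthogonalized — repair is an explicit flag.
- The degenerate-geometry thresholds: triangle area < 1e-9 mm² for the
  observation frame, second singular value < 1e-9 for alignment,
  QR rank < 4 for the algebraic sphere fit.
- Monte-Carlo test sizes (400–500 replicates for estimator recovery, 100
  experiments for the ordering study, 50 seeds per noise level for
  monotonicity) were chosen to keep sampling error well inside the asserted
  tolerances.
- The sphere-center recovery bound in the acceptance suite (0.024 mm at 300
  points, 75° cap, σ = 0.059 mm) was frozen from an independent
  Levenberg–Marquardt Monte-Carlo oracle with ~25% slack over its measured
  RMSE of 0.019 mm.

## Known limitations

- Only concave landmarks are modeled — no tooth surfaces, so surface-based
  refinement (e.g. iterative closest point) cannot be studied here.
- The equal-weight alignment is the only registration implemented; weighted
  or anisotropic-noise alignment is out of scope.
- No robust (outlier-aware) sphere fitting; real-scan artifacts such as rim
  ghosting would require trimming that the simulation does not need.
- The operator model is deliberately minimal; it produces operator-to-operator
  variation without bias, which is one of several mechanisms consistent
  with the reliability structure of physical data.
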