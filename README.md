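# platealign

Simulation and accuracy evaluation of reference-point registration for the
three-dimensional reconstruction of the intercuspal jaw relation from
separately scanned dental models.

## The problem

Digital dental workflows need the spatial relation between the maxillary and
mandibular casts (the intercuspal position, ICP). One way to recover it
without scanning the articulated pair is to fix each cast to an articulator
mounting plate that carries machined hemispherical concaves, scan each jaw
separately, and register both scans to a contact-measured reference using
the concave centers as landmarks. The accuracy of the reconstructed jaw
relation then depends on **which concaves are used as reference points and
how they are distributed** over the plate.

`platealign` re-creates this evaluation entirely in silico, for researchers
studying landmark-based registration accuracy in dental metrology:

1. **Plate geometry** — paired mounting plates carrying 9 + 9 hemispherical
   concaves (6 mm diameter), named in FDI-style notation
   (`11 12 13 14 0 21 22 23 24` / `41 42 43 44 0' 31 32 33 34`), with the
   nine canonical inter-jaw pairs `11–41 … 24–34` and the observation
   coordinate system built from concaves 12, 0 and 22.
2. **Scan simulation** — contact-probe "standard data" (σ = 0.024 mm,
   thrice-averaged) and optical-scan point clouds (σ = 0.059 mm per point,
   arbitrary rigid scanner pose per jaw, two operators modeled as
   independent cloud subsampling, 15 repetitions each).
3. **Sphere fitting** — each concave center is extracted by an algebraic
   linear least-squares fit refined by geometric (orthogonal-distance)
   Levenberg–Marquardt minimization of Σᵢ(‖pᵢ − c‖ − r)²; three replicate
   fits are averaged into the "fitting data".
4. **Registration** — equal-weight rigid landmark alignment (Kabsch: centroid
   subtraction, SVD of the cross-covariance, determinant sign correction)
   of each jaw's fitting data onto the standard data, for each of seven
   reference-point groups (groups 1–3 use three pairs, groups 4–7 four).
5. **Evaluation** — for the pairs *not* used in alignment, the inter-jaw
   distances D_R (reference, from the standard data) and D_M (measured,
   after alignment) are compared. Per ISO 5725-1, **trueness** is the RMSE
   of D_M − D_R per alignment unit and **precision** the RMSE of D_M about
   its per-pair repetition mean.
6. **Statistics** — one-way ANOVA with Tukey HSD across the seven groups,
   and two-way single-measurement ICC reliability (absolute agreement
   within operator, consistency between operators) with 95% confidence
   intervals.

## Worked example

```r
library(platealign)
cfg <- simulation_config(seed = 1)   # default study design: 15 reps x 2 operators
report <- run_experiment(cfg)
print(report)
```

```
experiment_report: 2 operators x 15 repetitions x 7 groups (210 units)
  per-group accuracy (mm):
   group 1: trueness 0.051 +/- 0.005, precision 0.008 +/- 0.002
   group 2: trueness 0.055 +/- 0.005, precision 0.009 +/- 0.003
   group 3: trueness 0.147 +/- 0.020, precision 0.019 +/- 0.010
   group 4: trueness 0.031 +/- 0.003, precision 0.008 +/- 0.003
   group 5: trueness 0.036 +/- 0.004, precision 0.008 +/- 0.003
   group 6: trueness 0.034 +/- 0.004, precision 0.008 +/- 0.003
   group 7: trueness 0.042 +/- 0.011, precision 0.020 +/- 0.013
```

Each line is one reference-point group: the mean ± sd (over the 30
alignment units) of the trueness RMSE of the held-out inter-jaw distances,
and of the per-repetition precision RMSE. Group 4 — four pairs spread over
the whole plate perimeter — reconstructs the jaw relation most truly
(0.031 mm here), while the front-concentrated groups 3 and 7 are the least
accurate: held-out posterior pairs sit far from the reference centroid and
amplify alignment error by leverage. The spatial spread (homogeneity) of
the reference points, not just their number, drives accuracy.

```r
st <- experiment_statistics(report)
st$anova
#      metric         F df_between df_within             p
#  trueness  557.06946          6       203 3.922411e-123
#  precision  22.13491          6       203  5.549687e-20

icc <- intra_inter_operator_report(report)
head(icc$inter, 3)
#   group   icc ci_low ci_high
#       1 0.994  0.956   0.999
#       2 0.996  0.970   0.999
#       3 0.998  0.989   1.000
```

The group differences are highly significant, and inter-operator
reliability is excellent. `write_report_tables(report, "out/")` writes the
full set of CSV tables (summary, records, ANOVA, 7×7 Tukey matrix, ICC
tables) plus a provenance JSON.

## Documentation

The methods vignette (`vignettes/reference-point-accuracy.Rmd`) describes
the simulation model, its parameters and defaults, the numerical choices in
the sphere fit and alignment, and what the synthetic generator does and
does not capture about physical scan data.
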