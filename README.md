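# limbalign

Statistical shape models of articulated skeletal anatomy confound two
things: the anatomy itself — bone shape and the *neutral alignment* of
bones within a joint — and the *pose* the joint happened to be in at scan
time. Pose loads onto the leading principal components of an articulated
model, inflating its dimensionality and obscuring morphometric signals
such as sexual dimorphism. `limbalign` separates the two for dense
homologous landmark sets of the lower limb (pelvis–femur, femur–tibia,
tibia–foot), and is written for morphometricians and clinical researchers
who work with point-distribution models.

The core idea: fit per-bone **decoupled** models (GPA per bone, pose-free
by construction, `S = S̄ + P b`) and per-joint **articulated** models (GPA
of the whole two-bone construct, pose included); learn a partial least
squares **regressed** model predicting articulated scores from decoupled
scores — since pose is unpredictable from bone shape, the prediction is
the pose-averaged *neutral* alignment; choose the PLS component count by
the left/right dissimilarity error-evolution analysis (extra components
re-introduce pose by overfitting); **recouple** each scan's original bone
geometry into the regressed placement; and learn an **instant** PLS map
from articulated to recoupled scores for one-step denoising of new
constructs. On the pose-free models the package quantifies sex–shape
association by canonical correlation (`r`), PLS-regression explained
variance, amplified male/female effect shapes, and per-landmark
permutation significance with FDR control.

Because no landmark data are distributed, a seeded synthetic generator
produces articulated lower-limb populations with ground-truth neutral
alignment, scanner pose, mirrored left sides, rescan pairs and a planted
sex effect; it doubles as the validation bed (see the methods vignette,
`vignettes/pose-denoising.Rmd`).

## Worked example

```r
library(limbalign)

cfg <- generator_config(n_subjects = 60, seed = 7)
pop <- sample_population(cfg)
pipeline <- build_pipeline(pop)
pipeline
#> <limb_pipeline: 160 scans, bones [pelvis, femur, tibia, foot]>
#>   hip: articulated 12 modes, recoupled 6 modes, k* = 1, instant k = 12
#>   knee: articulated 7 modes, recoupled 5 modes, k* = 1, instant k = 7
#>   ankle: articulated 12 modes, recoupled 9 modes, k* = 1, instant k = 12
```

Each joint's error-evolution analysis selected a single PLS component
(`k* = 1`): neutral alignment rides on the dominant (size) mode, and more
components only reintroduce pose. The pose share of apparent articulated
shape variance — the percentage the pose-free recoupled model cannot
explain — is largest at the hip, where scanner positioning varies most:

```r
sapply(names(pipeline$joints), function(j) estimate_pose_variance(pipeline, j))
#>   hip  knee ankle
#>  6.75  1.36  2.69
```

Denoising one posed hip construct and measuring flexion / abduction /
endorotation (degrees) against the subject's ground-truth neutral
construct:

```r
j <- pop$template$joints$hip
con <- scan_construct(pop$scans$limb[[1]], j)
measure_joint_deviation(con, neutral_control(pop, "S0001", "right", "hip"), j)
#> angles: flexion -1.38, abduction -4.75, endorotation -2.46; rmse 16.8 mm
neutral <- denoise(pipeline, con, "hip")
measure_joint_deviation(neutral, neutral_control(pop, "S0001", "right", "hip"), j)
#> angles: flexion 0.29, abduction 0.51, endorotation -0.50; rmse 2.8 mm
```

The mock validation corrupts model-generated shapes with per-axis
rotations uniform on ±15° through the idealized joint center and reports
deviations before and after correction (here 200 mocks; the study-scale
experiment uses 1000):

```r
mock <- make_mock_set(pipeline$joints$hip$recoupled, j, K = 200, seed = 5)
validate_mock(pipeline, mock, seed = 1)
#>         metric   n before_mean before_sd after_mean after_sd p_value
#>        flexion 200        7.33      4.31    0.00234  0.00260   5e-04
#>      abduction 200        7.78      4.33    0.00751  0.00643   5e-04
#>   endorotation 200        7.42      4.41    0.14476  0.11854   5e-04
#>           rmse 200       39.39     13.75    0.05062  0.03818   5e-04
```

Before correction the mean absolute deviation sits at the analytic value
for a uniform ±15° rotation (7.5° ± 4.33°); after correction it is a
small fraction of a degree, with the reduction significant at the paired
permutation test's resolution. `autoplot()`, `tidy()` and `glance()`
methods render reports, error-evolution curves (`plot_error_evolution()`)
and compactness comparisons (`plot_compactness()`); `sex_shape_analysis()`,
`sex_effect_shapes()` and `landmark_significance()` cover the dimorphism
analysis.

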