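---
title: "Predicting 3D radiotherapy dose with an attention-gated U-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 3D radiotherapy dose with an attention-gated U-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbpdose)
```

## The problem

Inverse planning for head-and-neck IMRT is slow and planner-dependent:
given a CT, contoured targets and organs at risk (OARs), a human planner
iterates objective weights until the dose distribution is clinically
acceptable. Knowledge-based planning (KBP) shortcuts this loop by learning
the anatomy-to-dose mapping from a library of approved plans, so that a new
patient's achievable 3D dose can be predicted in seconds and used as a
planning target, a QA reference, or a decision aid.

`kbpdose` implements a voxelwise dose-regression model for this setting:
simultaneous-integrated-boost head-and-neck plans with up to three nested
prescription levels (70/63/56 Gy in 35 fractions), eight OARs (brainstem,
both parotids, spinal cord, mandible, esophagus, larynx) and an external
body contour, on grids down-sampled to practical sizes (the network
consumes 64^3 crops).

## Input representation

Each plan becomes a 12-channel 64^3 tensor: channel 1 the CT clipped to the
nonnegative [0, 4095] CT-number range and scaled to [0, 1]; channels 2–12
binary masks in a fixed order (PTV_70, PTV_63, PTV_56, brainstem, left
parotid, right parotid, spinal cord, mandible, esophagus, larynx, body).
Structures a plan lacks are represented by all-zero masks, so channel
semantics never depend on what happens to be contoured. Separate channels
per structure avoid label collisions where coarse voxels would let masks
overlap. The ground-truth dose is divided by the 70 Gy prescription for
training; predictions are multiplied back by 70 (and negatives clipped to
zero) before any evaluation, so all reported dosimetry is in Gy.

The crop center is the rounded centroid of the body mask, with the window
clamped inside the grid. This is a deliberate operationalization of
"crop away empty background": it is deterministic, needs no registration,
and degrades gracefully for off-center anatomy. Patients whose anatomy
genuinely exceeds the 64^3 window would be truncated — a known limitation
shared by any fixed-size crop.

## Architecture

The model is a five-level 3D U-Net. Encoder level $l$ applies two
zero-padded 3×3×3 convolutions (stride 1, ReLU) with $16 \cdot 2^{l-1}$
feature maps (16 through 256), dropout after the second convolution with
rate $0.10 + 0.05(l-1)$, and 2×2×2 max-pooling between levels, taking the
grid from 64^3 down to 4^3. The decoder mirrors this with parameter-free
nearest-neighbour ×2 upsampling, concatenation with the (gated) skip
connection, and two 3×3×3 convolutions per level. A final 1×1×1
convolution with linear activation produces the single-channel dose volume
at input resolution. There is no batch normalization anywhere: inputs and
targets are already normalized, and the training recipe relies on dropout
plus early stopping for regularization.

All convolutions that change resolution are pooling or upsampling
operators; the feature convolutions are stride 1. The arithmetic admits no
other reading — four 2× poolings are exactly what takes 64^3 to 4^3, and a
strided final layer could not return an output at input resolution.

### Attention gates

Each skip connection is modulated by an additive attention gate. With
$z_1$ the skip feature volume (C channels, fine grid) and $z_2$ the
coarser decoder feature from the previous hierarchy level (2C channels):

- a 1×1×1 convolution + ReLU projects $z_2$ to a C-channel gating signal;
- a 2×2×2 stride-2 convolution projects $z_1$ down to the gating
  resolution;
- the gating branch passes through a further 1×1×1 and a 3×3×3
  convolution;
- the two branches are added, ReLU-activated, reduced to one channel by a
  1×1×1 convolution, and squashed by a sigmoid into coefficients
  $x_{1,2} \in (0,1)$;
- the coefficients are upsampled to the fine grid and multiply $z_1$
  elementwise; a 1×1×1 output projection follows before concatenation.

The published description pins the gate only loosely (one projection at
stride 1, one at stride 2, addition, ReLU, 1×1×1, sigmoid, multiply), and
the printed stride assignment cannot produce same-shape addends as
written. Two internals — the gate bottleneck width and the upsampling
operator — are therefore fixed by the one hard constraint available: the
exact trainable-parameter total of 6,738,869. The configuration above is
the one that reproduces that integer exactly (gate cost $39C^2 + 6C + 1$
per level, summing to 850,084 over C ∈ {16, 32, 64, 128}, on top of a
5,888,785-parameter gate-free base). The baseline comparison network is
identical with plain concatenations.

```{r params}
count_trainable_parameters(build_attention_unet(model_config()))
count_trainable_parameters(build_baseline_unet())
```

## Training

Training minimizes the voxelwise mean-squared error on the normalized dose
over the full 64^3 grid — no structure masking, matching a cost that sums
over all voxels. Optimization is Adam (learning rate 0.001, $\beta_1 =
0.9$, $\beta_2 = 0.999$, zero decay, $\varepsilon = 10^{-7}$ — the default
of the framework the recipe originates from), batch size 4, at most 120
epochs, early stopping with a 30-epoch patience on the validation loss. An
epoch is one full shuffled pass with the incomplete final batch kept;
Adam steps occur per minibatch and validation is computed once per epoch
(the alternative reading — one parameter update per epoch — would
contradict a batch size of 4). On stopping, the weights of the
best-validation epoch are restored (checkpoint-on-best); this is standard
practice and flag-controllable. Weights are He-initialized (variance
2/fan-in, zero biases), the appropriate scaling for ReLU networks. Every
source of randomness — initialization, shuffling, dropout — is keyed to
explicit seeds.

One numerical safeguard is applied by default: the first 10 Adam steps
run at 1% of the learning rate (`warmup_steps`/`warmup_factor` in
`train_control()`). Adam's bias correction makes its very first step move
*every* parameter by a full learning-rate unit regardless of gradient
magnitude; on a freshly He-initialized 23-convolution network this
coordinated step can overshoot by orders of magnitude, and the resulting
gradient spike inflates the second-moment estimate for thousands of
subsequent steps ($\beta_2 = 0.999$), crippling short training runs. A
brief reduced-rate warmup eliminates the failure mode; in a long
full-cohort run (thousands of steps) ten reduced steps are immaterial, so
the published recipe is otherwise unchanged. The warmup can be disabled
(`warmup_steps = 0`).

The numerical engine is written in the package itself (RcppArmadillo
kernels with hand-derived backpropagation, verified against
finite differences in double precision in the test suite). Convolutions
compute in single precision, the customary precision for training such
networks; `options(kbpdose.double_precision = TRUE)` switches the 3×3×3
kernels to double for verification work.

## Synthetic phantoms

The phantom generator exists so the whole pipeline is testable without
clinical data. Each case has: an ellipsoidal body; spherical targets
(radii 6/5/4 voxels at grid 64) placed with a minimum separation so their
masks are disjoint, with seeded jitter and bounded retries; canonical OARs
(posterior spinal-cord and brainstem cylinders, lateral parotid
ellipsoids, an anterior mandible ellipsoid carrying bone intensity, an
esophagus cylinder, an anterior larynx ellipsoid), all clipped to the
body; a piecewise-constant CT (air 0 / soft tissue 1000 / bone 2800) with
Gaussian noise (SD 60) on the [0, 4095] scale, exercising the clipping
path exactly; and an analytic dose
$D(v) = \max_t P_t \exp(-d_t(v)^2 / 2\sigma^2)$ with $d_t$ the distance to
target $t$'s surface (zero inside, closed-form for spheres), $\sigma = 6$
voxels, clipped to 1.1 × 70 Gy. A configurable fraction of cohort plans
(default 30% per secondary target) lacks PTV_63/PTV_56, emulating the
missing-structure pattern of real cohorts, where only the primary target
is guaranteed.

What the phantom does *not* emulate: beam geometry (no ray effects, no
entrance/exit dose), tissue heterogeneity effects, realistic CT texture,
inter-patient anatomical variability, or the dose spillage patterns of
nine-field IMRT. Passing tests on phantoms therefore demonstrates that the
machinery — preprocessing, network, optimizer, metrics — is correct and
has capacity, not that the model reaches clinical accuracy; the published
cohort-level accuracies require the real multi-institution data and
multi-day training, both out of scope here. Phantom target radii are free
parameters chosen for plausible scale, not calibrated to any cohort.

## Evaluation conventions

- **MAE** per structure in Gy; the global figure uses the body contour as
  the mask.
- **$D_q$** is computed as the $(100-q)$-th percentile of within-mask
  voxel doses with linear interpolation between order statistics, used
  consistently for D99, D2% and D98%.
- **HI** = D2% − D98% on PTV_70, reported in Gy: the magnitudes reported
  for such plans (5–8 on a 70 Gy prescription) are only consistent with
  absolute Gy, not percent; a relative variant (÷ prescription × 100) is
  available behind a flag.
- **CI** = V_RI / TV with the reference isodose defaulting to the full
  prescription (70 Gy), configurable (e.g. 95% of prescription).
- Cohort aggregates are per-plan means ± sample SD; a single-plan cohort
  reports SD 0 by convention, and plans lacking a structure contribute
  nothing to that structure's aggregate (zero-filled masks would otherwise
  be degenerate empty structures).
- DVHs are cumulative: fraction of structure voxels receiving at least
  each binned dose level, from 0 to one bin beyond the maximum dose.

## Numerical and design choices

- Cohort splitting shuffles a canonically sorted id list with a seed and
  rounds the test and validation sizes to nearest (R's ties-to-even); the
  training set takes the remainder. This is the only rounding rule that
  reproduces 340 → 218/54/68 at fractions 0.64/0.16/0.20.
- CT normalization is idempotent: input already inside [0, 1] is left
  untouched, everything else is clipped to [0, 4095] and divided by 4095.
  Signed Hounsfield conventions must be offset upstream.
- The sparse-voxel CSV dialect is row-major (last axis fastest) by
  default with a column-major switch; the convention is pinned here
  because the upstream format leaves it implicit.
- Skip concatenation order is (upsampled decoder, gated skip); the choice
  does not affect the parameter count and is fixed for reproducibility.
- Non-finite training loss aborts with a diagnostic rather than training
  onward from a diverged state.
- Test-suite and acceptance problem sizes (32^3 grids, three-plan
  overfit cohorts, 16^3 pipeline runs) are chosen so a complete run
  finishes in minutes on one core while still exercising every code path
  at full network depth.

## Known limitations

Single-precision convolution arithmetic bounds reproducibility across
BLAS builds (within one machine, runs are bitwise deterministic). Training
at the published cohort scale (hundreds of plans, 120 epochs at 64^3) is
computationally out of reach of a plain CPU build and is not attempted;
the package demonstrates correctness at desk scale. The predicted dose is
a planning aid, not a deliverable plan: converting it into machine
parameters is explicitly out of scope.
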