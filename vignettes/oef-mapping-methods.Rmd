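---
title: "Oxygen extraction fraction mapping from complex mGRE signals: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen extraction fraction mapping from complex mGRE signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmqbold)
```

## The biophysical model

The oxygen extraction fraction, OEF $= 1 - Y/Y_a$, relates the venous oxygen
saturation $Y$ to the arterial saturation $Y_a$ (0.98 by default). `qsmqbold`
estimates $Y$ (and with it OEF) from multi-echo gradient-echo (mGRE) MRI by
modelling the *complex* signal at echo time $t_j$:

$$S_j = F_{qBOLD}(S_0, R_2, Y, v, \chi_n, t_j)\,
        e^{\,i\,\omega_0 t_j\, (d \ast \chi(Y, v, \chi_n))}.$$

The magnitude factor is the qBOLD static-dephasing model

$$F_{qBOLD} = S_0\, e^{-R_2 t_j}\, e^{-v\, f_s(\delta\omega\, t_j)}\, G(t_j),$$

where $v$ is the venous blood volume fraction, $G$ an (optional) macroscopic
attenuation factor, and $\delta\omega$ the characteristic frequency offset
between deoxygenated blood and tissue,

$$\delta\omega = \tfrac{1}{3} \gamma B_0
  \left(\psi_{Hb}\, \Delta\chi_{Hb}\, (1 - Y) + \chi_{ba} - \chi_n\right),$$

with all susceptibilities in ppb (the $10^{-9}$ conversion is applied exactly
once inside `delta_omega()` and once in the phase term). The decay function
$f_s$ of a network of randomly oriented cylinders is the standard integral

$$f_s(x) = \tfrac{1}{3}\int_0^1 (2+u)\sqrt{1-u}\;
           \frac{1 - J_0(1.5\,x\,u)}{u^2}\, du,$$

quadratic ($0.3x^2$) at short times and linear with unit slope at long times.
`fs_quadrature()` evaluates it by adaptive quadrature (absolute tolerance
1e-9); `fs()` memoizes it on a dense grid (0 to 60, cubic spline, linear
asymptotic extension) because the forward model evaluates it millions of
times. The even extension $f_s(x) = f_s(|x|)$ is used throughout; its
derivative is extended as an odd function.

The phase factor couples voxels through the dipole convolution
$d \ast \chi$, computed in k-space with the standard kernel
$D(k) = 1/3 - k_z^2/|k|^2$, $D(0) = 0$ (so a uniform susceptibility produces
no field). The convolution is circular; phantoms therefore keep at least a
25% zero margin around the brain. The voxel-wise susceptibility follows the
mixture

$$\chi = v\left[\frac{\chi_{ba}}{\alpha} +
  \psi_{Hb}\Delta\chi_{Hb}\,\frac{-Y + 1 - (1-\alpha)Y_a}{\alpha}\right]
  + \left(1 - \frac{v}{\alpha}\right)\chi_n,$$

with $\alpha = 0.77$ the venous-to-total blood volume ratio. An alternative
derivation from an explicit three-compartment volume-weighted mixture
(venous blood $v$ at saturation $Y$, arterial blood $v(1-\alpha)/\alpha$ at
saturation $Y_a$, tissue $1 - v/\alpha$) gives a formula whose saturation
weighting differs: it carries $-\alpha Y$ where the model above carries
$-Y$. At typical grey-matter values the two differ by about 6 ppb. The
first form is the model used everywhere in this package;
`chi_qsm_mixture()` exposes the second as a documented cross-check, and the
discrepancy is deliberately surfaced rather than silently resolved.

Constants default to $\gamma = 267.51\times 10^6\,$rad s$^{-1}$T$^{-1}$
(the printed value in common compilations omits the $10^6$),
$\psi_{Hb} = 0.0909$, $\Delta\chi_{Hb} = 12522$ ppb,
$\chi_{ba} = -108.3$ ppb (at hematocrit 0.357). $R_2$ quoted in Hz is
treated as a rate in s$^{-1}$ (no $2\pi$).

```{r forward}
co <- physio_constants()
delta_omega(Y = 0.98, chi_n = 0, co, B0 = 3)   # rad/s
oef_from_Y(0.67)                               # cohort-mean OEF
```

## The synthetic stroke-brain phantom

Real patient-derived ground truth is not redistributable, so the generator
(`make_phantom()`) emulates its published summary statistics: ellipsoidal
brain (semi-axes 36/34/30% of the grid, preserving the convolution margin),
spatially smooth parameter fields built from Gaussian-filtered white noise
(correlation length 6 mm by default, matching the scale of cortical
parameter variation at 2 mm voxels), hard-clipped to the cohort min/max and
iteratively re-centred so the masked sample mean and SD hit the cohort
values: S0 (1.10, 0.04), R2 (19.6, 7.1) s$^{-1}$, Y (0.67, 0.10),
v (0.023, 0.012), $\chi_n$ (-11.6, 37.5) ppb. An ellipsoidal lesion
multiplies Y and v by configurable factors (defaults 0.6 and 0.5) and is
mirrored across the mid-sagittal plane to define the contralateral
reference region. Note that with OEF $= 1 - Y/Y_a$ a *reduced* Y produces
an *elevated*-OEF (penumbra-like) lesion; a subacute low-OEF lesion
corresponds to `Y_scale > 1`. The defaults are placeholders for a
phenotype that is not pinned down by published numbers, not claims.

Noise is injected two ways, mirroring the two modelling philosophies the
package compares. `add_complex_noise()` adds i.i.d. Gaussian noise to the
real and imaginary channels with
$\sigma = \overline{|S_1|}\cdot 10^{-\mathrm{SNR[dB]}/20}$ (amplitude-dB
convention, first-echo masked mean as the signal level); the resulting
magnitudes are Rice-distributed, which is the physical reality the
complex-domain estimator exploits. `add_magnitude_qsm_noise()` instead adds
Gaussian noise directly to the echo magnitudes and to the susceptibility
map (default $\sigma_\chi$ = 10 ppb; the baseline's training corruption
level is not published, so it is a configurable choice) — the baseline
assumption, under which noisy magnitudes can even go negative.

What the phantom does *not* emulate: macroscopic field gradients ($G$ is
accepted as an input and defaults to 1), coil sensitivities, motion,
partial-volume anatomy, or the spatial covariance structure of real
lesions. Tests passing on this phantom therefore validate the estimators
under the stated noise models, not clinical performance.

## Maximum-likelihood inversion

`fit_mcqq_joint()` is the likelihood-faithful reference estimator for the
complex model: it minimizes $\sum_{j,\text{voxels}} |S^{meas} - S^{model}|^2$
with the dipole convolution inside the objective. Two structural facts
shape the solver:

* the dipole kernel vanishes on the magic-angle cone, so the phase
  constrains $\chi$ only up to near-null directions, and
* the qBOLD magnitude is notoriously flat in $Y$ (the $v$–$\delta\omega$
  trade-off), so a plain quasi-Newton descent creeps in those directions.

The solver therefore works in stages: (1) the tissue field is estimated
voxel-wise from the measured phase (temporal unwrapping via phase
increments, magnitude-squared-weighted least-squares slope over echoes);
(2) a Tikhonov-regularized dipole inversion of that field — with the data
term restricted to the observed voxels and the source support restricted to
the object, which makes the operator invertible — alternates with
independent per-voxel fits constrained to the deconvolved susceptibility.
The regularization weight is driven down (0.02, 1e-5, 1e-8) with a
deepening conjugate-gradient budget, so on noiseless data the
susceptibility target of the final sweep is accurate to well below a ppb;
(3) optionally, a joint L-BFGS pass with analytic gradients (the field
pathway pulled back through the self-adjoint convolution) polishes the
exact objective. The polish is off by default: below roughly the
$10^{-3}$-per-voxel objective level the descent directions are the flat
ones, and chasing them trades parameter accuracy for objective decreases
far smaller than any realistic noise level (measured on a 16^3 phantom:
Y-RMSE 0.009 → 0.017 while the objective fell from 0.06 to 3e-4).

Per-voxel subproblems are solved by Levenberg–Marquardt (`minpack.lm`) with
analytic Jacobians in tanh-transformed coordinates
$\theta = lo + (hi-lo)(\tanh u + 1)/2$ — the same smooth squashing the
network uses for its output bounds — with near-zero convergence tolerances,
because the qBOLD valley is flat enough that ordinary step tolerances stop
the solver well before the minimum. Starts are kept 0.5% of the bound range
away from the bounds: a start squashed exactly onto a bound has a saturated
tanh coordinate whose gradient vanishes, freezing that parameter.

Initialization matters in this non-convex landscape and is explicit:
`truth_perturbed` (each map scaled by a uniform ±10% factor) for
self-consistency experiments, `population_mean` (the cohort means) for
blind fits, or custom maps. The per-voxel estimators
(`fit_mcqq_oracle_field()`, with a supplied field and susceptibility
constraint, and `fit_qq_baseline()`, Gaussian residuals on magnitudes plus
susceptibility) share the same machinery; residual blocks are scaled by
their noise SDs, which makes the objectives the respective negative
log-likelihoods. An optional weak Gaussian prior anchored at the
initialization (`prior_sd_frac`) is available for voxels where the
likelihood is uninformative; it is off by default so the default fits are
pure maximum likelihood.

### Identifiability at desk scale — what recovery experiments can show

Noiseless self-consistency on a 24^3 phantom recovers the overwhelming bulk
of voxels exactly (the within-basin error is at the 1e-13 level). Two
structural error sources remain and dominate the RMSE:

* voxels with near-vanishing venous volume carry essentially no information
  about $Y$ (both the dephasing term and the blood susceptibility scale
  with $v$), and about 5% of generated voxels sit at the clipped lower edge
  of the cohort $v$ distribution;
* at a few percent of voxels the eight-echo magnitude curve distinguishes
  the true solution from an alternate local solution only at the
  $10^{-12}$–$10^{-15}$ deviance level — numerically indistinguishable, so
  a local solver started ±10% from the truth occasionally settles in the
  alternate basin. This is the classic poorly-conditioned qBOLD inversion;
  it is also precisely why the field has moved to cluster- and
  network-regularized estimators.

Across phantom seeds this leaves a noiseless whole-mask Y-RMSE of roughly
0.02–0.06 at 24^3 — an honest floor for a voxel-independent
maximum-likelihood reading of the model, reported as-is by the acceptance
machinery rather than masked by additional regularization. Monte-Carlo
consistency in noise behaves accordingly: RMSE of the directly identified
parameters ($S_0$, $R_2$) falls monotonically with SNR, while $Y$, $v$ and
$\chi_n$ are dominated by the flat-valley statistics (the susceptibility
constraint, which anchors $Y$, carries a *fixed* noise level, so its
relative weight in the likelihood falls as the signal SNR rises).

The comparative claim — that the complex-domain estimator (correct
Gaussian likelihood in the complex channels) outperforms the
magnitude-plus-susceptibility Gaussian baseline at low SNR, where
magnitudes are Rician — shows up in two ways with very different
robustness at desk scale. The baseline's signature defect is directly and
robustly demonstrable: under paired noise realizations at 12 dB its fitted
decay tails are systematically biased upward while the complex fit's are
not. Expressed as a pooled OEF root-mean-square error over a few hundred
voxels and a handful of noise seeds, however, the advantage is small
compared with the flat-valley wandering that dominates per-voxel Y errors
in *both* estimators, and its sign can flip between phantom realizations.
A network (or any spatially regularized) estimator suppresses exactly that
wandering, which is why the OEF-level comparison is cleaner at full scale
than for the per-voxel maximum-likelihood reading exercised here.

## Network losses and the scaled-down trainer

The training losses are

* $E_{L1}$: mean absolute difference of the z-scored parameter stacks over
  masked voxels (z-statistics computed once from the training set's masked
  voxels and frozen);
* $E_{Grad}$: L1 difference of the spatial gradient of normalized $Y$
  (forward differences along the three axes, replicate boundary — the
  gradient operator is not printed in loss definitions of this family, so
  the simplest consistent choice is made and its adjoint implemented
  alongside);
* $E_{Model}$: physical-consistency term. The dual-network variant takes
  the mean modulus of the difference of the two complex forward signals
  (modulus of the complex difference, rather than separate real/imaginary
  L1 — the unstated convention adopted here); the baseline variant is the
  per-voxel magnitude L1 plus susceptibility L1 without the convolution.

The total is $E = E_{L1} + 0.1\,E_{Model} + 0.1\,E_{Grad}$. All reductions
are means over masked voxels and channels so the 0.1 weights are
scale-stable across patch sizes.

The model is two 3D U-Net sub-networks — magnitude (8 echo-magnitude
channels in, 5 parameter channels out) and phase (8 echo-phase channels in,
3 out) — whose shared channels ($Y$, $v$, $\chi_n$) are merged by learnable
per-channel scalar weights initialized to 0.5/0.5, merged first and
tanh-squashed second, each output channel mapped into its physiological
bounds ($Y$ 0–1, $v$ 0.005–0.055, the cohort min/max for the rest). At the
reference depth of four pooling levels each sub-network has exactly 18
3×3×3 convolutions, 4 max-poolings, 4 deconvolutions, 4 concatenations and
one 1×1×1 convolution, with zero padding keeping layer outputs at the input
size and channel counts doubling per level (the standard schedule; the
per-level counts are not printed). The engine is written in base R (im2col
gathers plus BLAS matrix products, hand-written backward passes, Adam), so
the whole pipeline runs and trains on one CPU with no deep-learning runtime.

The desk-scale regime is explicit: depth 2, base width 4, 16^3 patches, 20
epochs, Adam at 0.01. The reference regime it is scaled down from uses
depth 4, whole-brain 16×200×200×48 patches, learning rate 1e-4 and 400
epochs; that configuration remains constructible but is not exercised by
the tests. The higher desk learning rate compensates for the small step
count; above ~0.02 the He-scale weights destabilize within 40 steps, and
0.01 sits comfortably below that edge. Each epoch visits the brains in a
freshly shuffled order with a random patch position and a fresh complex
noise instance at 20 dB, so a zero-learning-rate run has a fluctuating loss
history but exactly unchanged parameters. All randomness derives from one
seed; training histories are bit-reproducible. Whole-volume inference
slides patches with configurable overlap (default 30%) and averages
overlapping predictions uniformly; zero padding makes per-patch outputs
vary near patch borders, so constancy under constant input holds patch-wise
rather than voxel-wise.

## Evaluation metrics

`mean_error()` is the signed voxel-mean of truth minus the across-trial
average (accuracy); `mean_std()` the across-trial per-voxel SD with the
*population* divisor $N_t$, averaged over voxels (precision);
`oef_ratio()` the lesion-to-contralateral mean ratio; `ssim_map()` a 3D
SSIM with standard constants ($K_1 = 0.01$, $K_2 = 0.03$), a Gaussian
window (SD 1.5 voxels, applied spectrally) and the dynamic range set to
the pooled masked range; `wilcoxon_signed_rank()` uses the exact null
distribution up to n = 25 (no ties) and the continuity-corrected normal
approximation beyond. OEF maps are stored as fractions and conventionally
displayed in percent.

## Degenerate inputs and numerical choices

* Maps outside the brain mask are zero-filled at construction so the
  convolution is always well-posed; masked losses and metrics ignore them.
* `fs` tolerates any finite argument; non-finite inputs error.
* Tie-breaking in max-pooling is "first index", making training
  deterministic.
* The phase of a voxel with zero signal is taken as 0 by `Arg()`; such
  voxels carry no weight in the field estimate (magnitude-squared weights).
* The simulated echo phases stay well inside ±π at 3 T with the phantom's
  susceptibility range, so temporal unwrapping by increments is exact;
  real-data preparation goes through `compensate_phase()`, which requires
  an explicit field-unit declaration (rad/s or Hz).

## Problem sizes used by the test-suite experiments

Phantoms of 16^3–48^3 voxels at 2 mm, 8 echoes; 500-voxel subsamples and
five paired noise seeds for the estimator comparison; two 24^3 brains and
20 epochs for the training demonstration. These sizes were chosen so each
experiment states its property at a few-minute scale while keeping every
statistical margin it asserts; larger runs change the constants, not the
qualitative conclusions.
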