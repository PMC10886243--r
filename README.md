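# qsmqbold

Oxygen extraction fraction (OEF) mapping from multi-echo gradient-echo
(mGRE) MRI, combining quantitative susceptibility mapping (QSM) of the
signal phase with the qBOLD static-dephasing model of the magnitude — in
the *complex* signal domain, where measurement noise actually is Gaussian.

OEF — the fraction of oxygen that tissue extracts from blood,
OEF = 1 − Y/Yₐ with Y the venous and Yₐ the arterial oxygen saturation —
is a direct marker of tissue viability: elevated OEF flags the salvageable
penumbra in ischemic stroke. The package is aimed at quantitative-MRI
methods researchers who want a fully inspectable, CPU-scale reference
implementation of this model family: the forward physics, the estimators,
the physics-informed network losses, and the evaluation statistics.

## The model

The complex mGRE signal at echo time `t_j` is modelled as

    S_j = F_qBOLD(S0, R2, Y, v, χn, t_j) · exp( i ω0 t_j (d ∗ χ(Y, v, χn)) )

with the qBOLD magnitude

    F_qBOLD = S0 · exp(−R2 t_j) · exp(−v · f_s(δω t_j)) · G(t_j),
    δω = ⅓ γ B0 (ψ_Hb Δχ_Hb (1 − Y) + χ_ba − χn),

`f_s` the static-dephasing decay of randomly oriented vessels (0.3x² at
short times, slope-1 linear at long times), `v` the venous blood volume
fraction, `χn` the non-blood tissue susceptibility, and `d ∗ χ` the dipole
convolution that turns the susceptibility of the blood/tissue mixture into
the tissue field seen by the phase.

The package provides:

* the deterministic forward model (`simulate_signal()`, `f_qbold()`,
  `chi_qsm()`, `dipole_kernel()`, `fs()`);
* a synthetic stroke-brain phantom generator reproducing published cohort
  statistics, with complex-Gaussian or magnitude+susceptibility Gaussian
  noise (`make_phantom()`, `add_complex_noise()`,
  `add_magnitude_qsm_noise()`);
* maximum-likelihood inversion under both noise models
  (`fit_mcqq_joint()`, `fit_mcqq_oracle_field()`, `fit_qq_baseline()`);
* the physics-informed network losses and a configurable dual 3D U-Net
  trainer written in base R (`loss_model_mcqq()`, `build_network()`,
  `train()`, `predict_sliding()`);
* evaluation statistics (`mean_error()`, `mean_std()`, `oef_ratio()`,
  `ssim_map()`, `wilcoxon_signed_rank()`), NIfTI I/O and a CLI
  (`inst/cli/qsmqbold`).

## Worked example

```r
library(qsmqbold)

co  <- physio_constants()
acq <- acq_params(grid_shape = c(24, 24, 24))   # 8 echoes, 4.5/5/39.5 ms, 3 T
ph  <- make_phantom(phantom_config(grid_shape = c(24, 24, 24), seed = 1))

mean(ph$params$Y[ph$params$mask])               # 0.6700001
mean(oef_from_Y(ph$params$Y[ph$params$mask]))   # 0.3163264

clean <- simulate_signal(ph$params, acq, co)
noisy <- add_complex_noise(clean, noise_spec(snr_db = 20, seed = 2),
                           ph$params$mask)
attr(noisy, "sigma")                            # 0.1006668

cfg <- fit_config("mcqq_joint",
                  bounds = list(S0 = c(1.0, 2.2), R2 = c(7, 165),
                                Y = c(0, 1), v = c(0.002, 0.08),
                                chi_n = c(-960, 165)),
                  init = "truth_perturbed", seed = 3)
fit <- fit_mcqq_joint(simulate_signal(ph$params, acq, co), acq, co, cfg,
                      truth = ph$params)
sqrt(mean((fit$params$Y[ph$params$mask] -
           ph$params$Y[ph$params$mask])^2))     # 0.02202557 (noiseless)

oef_ratio(fit$oef, ph$lesion_mask, ph$contralateral_mask)  # 1.372063
```

The phantom's masked mean venous saturation reproduces the cohort value
(0.67); the corresponding mean OEF is 0.316. The noiseless joint fit
recovers the bulk of voxels exactly — the residual Y root-mean-square error
of ~0.02 is concentrated in the few percent of voxels where the qBOLD model
is nearly unidentifiable (vanishing venous volume), an intrinsic property
of the model discussed in the methods vignette. The lesion OEF ratio above
1 reflects the generator's default lesion (reduced venous saturation, i.e.
elevated extraction relative to the mirrored contralateral region).

The same pipeline is available from the shell:

```sh
Rscript inst/cli/qsmqbold simulate --seed 7 --grid 24 --out sim/
Rscript inst/cli/qsmqbold fit --mode mcqq_joint --in sim/ --out fit/
Rscript inst/cli/qsmqbold evaluate --truth sim/truth_Y.nii \
    --trials fit/fit_Y.nii --mask sim/truth_mask.nii --out report.json
```

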