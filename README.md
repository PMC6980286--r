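# tkdce

Tracer-kinetic models as temporal constraints for reconstructing
undersampled brain-tumor DCE-MRI.

## What this package is for

Dynamic contrast-enhanced (DCE) MRI estimates vascular permeability
maps — K<sup>trans</sup> (min⁻¹), v<sub>p</sub>, v<sub>e</sub> — by
fitting tracer-kinetic models to per-pixel contrast concentration-time
curves. Accelerating the acquisition by undersampling (k,t)-space needs a
temporal prior during reconstruction. `tkdce` implements a prior built
from the kinetic model itself:

1. **Library.** Simulate concentration-time profiles
   C(t) over a dense physiological parameter grid, driven by a Parker
   population arterial input function. Patlak model
   (C = K<sup>trans</sup>·∫C<sub>p</sub> + v<sub>p</sub>C<sub>p</sub>):
   4,941 profiles; extended Tofts-Kety model (adds backflux at rate
   K<sup>trans</sup>/v<sub>e</sub>): 494,100 profiles, 50 frames at 5 s.
2. **Dictionary.** Compress the library with k-SVD into r = 100 unit-norm
   temporal basis functions such that every profile is a q-sparse linear
   combination of atoms (q = 2 for Patlak, q = 3 for ETK — the model's
   effective temporal degrees of freedom).
3. **Reconstruction.** Solve
   min<sub>C,U</sub> ‖A C − b‖² s.t. C = U V, ‖u<sub>p</sub>‖₀ ≤ q,
   where A = F<sub>u</sub> S<sub>m</sub> T is the multicoil Cartesian
   sampling chain through the SPGR signal equation, by alternating hard
   k-space data consistency with OMP sparse projection inside an
   iterative multiscale (coarse-to-fine Gaussian filtering) scheme. The
   sparsity level is fixed a priori — no regularization weight to tune.
4. **Estimation & evaluation.** Patlak (linear) and ETK (bounded
   Levenberg-Marquardt) fitting, DESPOT1 T1 mapping, a synthetic
   brain-tumor digital reference object, a temporal-finite-difference
   (tFD) ADMM compressed-sensing baseline, Monte-Carlo bias/uncertainty
   maps, Bland-Altman agreement, and nRMSE.

The methods vignette
(`vignettes/dictionary-constrained-dce-recon.Rmd`) documents the models,
the numerical choices, and the design decisions in detail.

## Worked example

```r
library(tkdce)

grid <- time_grid()                      # 50 frames, 5 s
aif  <- parker_aif(grid)                 # population AIF, hct 0.4
lib  <- build_library("patlak", aif = aif)
#> tk_library (patlak): 4941 profiles x 50 frames

learned <- ksvd_learn(lib, r = 100, q = 2, n_iters = 10, seed = 1)
approximation_errors(lib, learned$dictionary, q = 2)
#> approximation error: mean 3.06e-29 %, max 8.06e-28 % (1 zero rows excluded)
```

Two atoms represent every Patlak curve to the double-precision floor —
the library has numerical rank 2, so q = 2 is exact and the printed
errors are pure floating-point residue.

```r
dro   <- build_dro(c(48, 48), aif, seed = 2, model = "patlak")
coils <- gaussian_coil_maps(c(48, 48), 8)
mask  <- gocart_mask(c(48, 48), grid$n_frames, R = 20, seed = 5)
kt    <- add_noise(apply_forward(dro$conc, dro$tissue, coils, mask),
                   snr = 30, seed = 11)

rec <- reconstruct_dictionary(kt, dro$tissue, coils,
                              recon_config(learned$dictionary, q = 2))
#> tk_recon_result: 48 x 48 pixels, 67 iterations, converged: TRUE

roi  <- as.vector(dro$roi_masks$tumor_rim)
fits <- fit_parameter_maps(rec$C, aif, "patlak", roi = roi)
bland_altman(fits$ktrans[roi], as.vector(dro$ktrans_map)[roi])
#> Bland-Altman: mu = -0.01534, sigma = 0.02276, LoA [-0.05995, 0.02927] (n = 146)
```

From 20-fold-undersampled noisy data (SNR 30), the tumor-rim
K<sup>trans</sup> comes back with a bias of −0.015 min⁻¹ and a spread of
0.023 min⁻¹ against the ground-truth map (rim values 0.05–0.30 min⁻¹) —
with no regularization parameter anywhere in the reconstruction.

A thin command-line wrapper over the same functions ships in
`inst/cli/tkdce` (verbs: `build-library`, `learn-dict`, `make-dro`,
`undersample`, `recon`, `fit`, `evaluate`, `run`), and
`run_experiment()` drives the whole chain from a single validated
configuration (YAML via `read_config()`).

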