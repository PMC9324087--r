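# starmrf

Quantitative T1/T2 mapping from **through-plane accelerated stack-of-stars
MR fingerprinting (MRF)** acquisitions, for MR physicists and image
reconstruction researchers working with radial MRF on systems — such as
low-field MR-guided radiotherapy scanners — where a single k-space spoke is
acquired per MRF frame and scan time scales with the number of slice
(partition) phase-encoding steps.

The package implements the full pipeline in R:

* an **extended-phase-graph (EPG)** simulator for inversion-prepared FISP
  fingerprint trains and the (T1, T2) dictionary, including relaxation
  during the inter-repetition delay;
* the **temporal subspace** Φ ∈ C^(T×K) from the dictionary SVD, and the
  subspace-constrained forward model of the accelerated acquisition with
  an exact adjoint, built on Kaiser–Bessel gridding fused with the
  subspace projection;
* **k-t CAIPIRINHA** sampling: the sampled kz subset alternates from frame
  to frame, imparting known per-frame phases on the aliased slice
  replicates (Fourier shift theorem) that the reconstruction exploits;
* solvers for the inverse problem

  min over α of  ‖ S Θ F Φ C α − y ‖₂² + λ Σᵣ ‖ Rᵣ(α) ‖\*

  — plain conjugate gradients for fully partition-encoded data (R = 1),
  and ADMM with locally-low-rank (LLR) regularization (8×8 patches,
  λ = 1e-4, singular-value soft-thresholding) for accelerated data
  (R = 2), followed by non-local-means denoising of the subspace
  coefficient ("SV") images and exhaustive dot-product dictionary
  matching;
* a **digital sphere phantom** and acquisition simulator (multi-coil,
  noisy, prospective or retrospective undersampling) so the whole pipeline
  is testable without scanner data, plus agreement statistics
  (per-sphere means/SDs, mean absolute percent error, Pearson
  correlation) between unaccelerated and accelerated reconstructions.

## Worked example

Simulate a 2× through-plane accelerated acquisition of the ten-sphere
phantom and reconstruct it (a few minutes on one core):

```r
library(starmrf)

seqp  <- mrf_sequence(default_flip_pattern(256))   # FISP train, TR 12 ms
grid  <- dictionary_grid()                         # 60 x 60 log grid, T2 <= T1
dict  <- build_dictionary(seqp, grid)
sub   <- compute_subspace(dict, rank = 5)

phantom <- make_default_phantom(grid)
truth   <- rasterize_phantom(phantom)
coils   <- simulate_coils(4, n = 64, nz = 8)
samp    <- kt_sampling(256, 8, reduction = 2, readout_samples = 128)
kdata   <- simulate_acquisition(truth, seqp, samp, coils,
                                noise_sd = 0.06, seed = 1)

fit <- mrf_reconstruct(kdata, dict, coils, subspace = sub,
                       voxel_mm = phantom$voxel_mm)
fit
```

```
MRF subspace reconstruction
  64 x 64 x 8 volume, K = 5, R = 2, solver: admm_llr + NLM
Parameter maps: 64 x 64 x 8
  valid voxels: 32768 (100.0%); T1 10-3000 ms, T2 5-1500 ms
```

`coef(fit)` returns the K subspace coefficient images per slice,
`fitted(fit)` the `mrf_maps` object (writable as NIfTI with
`write_maps_nifti()`), `plot(fit)` displays a slice, and
`residuals(fit, kdata)` reports the per-slice-group data-fidelity
residuals.  Per-sphere statistics over the eroded sphere interiors:

```r
stats <- roi_stats(fitted(fit), interior_labels(truth))
head(stats, 5)
```

```
  label n_voxels t1_mean  t1_sd t2_mean   t2_sd
1     1      100   99.43  6.101   19.18  1.6118
2     2       86  180.22  4.894   34.53  0.6184
3     3       86  294.77  0.000   60.29  2.4970
4     4       86  433.93  0.000   90.82  2.5101
5     5       86  639.75 17.866  134.50 10.5784
```

The `t1_mean`/`t2_mean` columns are the per-sphere relaxation-time
estimates in milliseconds (ground truth for spheres 1–5: T1 = 102, 182,
295, 434, 639 ms and T2 = 19, 35, 62, 91, 134 ms); the SD columns measure
within-sphere variability of the accelerated reconstruction.

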