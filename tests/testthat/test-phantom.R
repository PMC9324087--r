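test_that("rasterization assigns sphere values by voxel-center membership", {
  spheres <- data.frame(cx = 0, cy = 0, cz = 0, radius_mm = 3.5,
                        t1_ms = 1000, t2_ms = 100, m0 = 1)
  spec <- phantom_spec(n = 16, nz = 4, voxel_mm = c(2, 2, 2),
                       spheres = spheres)
  truth <- rasterize_phantom(spec)
  inside <- truth$label == 1L
  expect_true(any(inside))
  expect_true(all(truth$t1_ms[inside] == 1000))
  expect_true(all(truth$t2_ms[inside] == 100))
  expect_true(all(truth$t1_ms[!inside] == 0))

  # empty phantom rasterizes to zero volumes
  spec0 <- phantom_spec(n = 8, nz = 2, voxel_mm = c(2, 2, 2),
                        spheres = spheres[0, ])
  truth0 <- rasterize_phantom(spec0)
  expect_equal(max(truth0$m0), 0)

  # overlapping spheres: last listed wins, with a warning
  sp2 <- rbind(spheres, within(spheres, { t1_ms <- 500; t2_ms <- 50 }))
  spec2 <- phantom_spec(n = 16, nz = 4, voxel_mm = c(2, 2, 2), spheres = sp2)
  expect_warning(truth2 <- rasterize_phantom(spec2), "last listed")
  expect_true(all(truth2$t1_ms[truth2$label > 0] == 500))
})

test_that("rasterized sphere volume approximates the analytic volume", {
  spheres <- data.frame(cx = 0, cy = 0, cz = 0, radius_mm = 5.5,
                        t1_ms = 1000, t2_ms = 100, m0 = 1)
  spec <- phantom_spec(n = 32, nz = 32, voxel_mm = c(1, 1, 1),
                       spheres = spheres)
  truth <- rasterize_phantom(spec)
  vol <- sum(truth$label == 1L)
  expect_lt(abs(vol - 4 / 3 * pi * 5.5^3) / (4 / 3 * pi * 5.5^3), 0.1)
})

test_that("the default phantom is physical and on the dictionary grid", {
  grid <- dictionary_grid()
  spec <- make_default_phantom(grid = grid)
  expect_s3_class(spec, "mrf_phantom_spec")
  expect_equal(nrow(spec$spheres), 10L)
  expect_true(all(spec$spheres$t2_ms <= spec$spheres$t1_ms))
  expect_true(all(spec$spheres$t1_ms %in% grid$t1_values_ms))
  expect_true(all(spec$spheres$t2_ms %in% grid$t2_values_ms))
  truth <- rasterize_phantom(spec)
  expect_true(all(sort(unique(truth$label[truth$label > 0])) == 1:10))
})

test_that("simulated coil maps are normalized, smooth and band-limited", {
  co1 <- simulate_coils(1, 16, 2)
  expect_equal(co1$maps, array(1 + 0i, dim = c(16, 16, 2, 1)))

  co <- simulate_coils(4, 32, 2)
  sos <- apply(Mod(co$maps)^2, c(1, 2, 3), sum)
  expect_equal(sos, array(1, dim = c(32, 32, 2)), tolerance = 1e-6)

  fx <- c(0:16, -(15:1)) / 32
  hi <- outer(fx^2, fx^2, `+`) > 0.125^2
  for (c in 1:4) {
    F <- stats::fft(co$maps[, , 1, c])
    expect_lt(sum(Mod(F[hi])^2) / sum(Mod(F)^2), 0.01)
  }
})

test_that("acquisition simulation is reproducible and linear in noise", {
  ms <- mini_setup()
  truth <- rasterize_phantom(ms$spec)
  y1 <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils,
                             noise_sd = 1e-3, seed = 7)
  y2 <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils,
                             noise_sd = 1e-3, seed = 7)
  expect_identical(y1$samples, y2$samples)

  y0 <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils, noise_sd = 0)
  yA <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils,
                             noise_sd = 1e-3, seed = 7)
  yB <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils,
                             noise_sd = 2e-3, seed = 7)
  # same seed: the injected noise scales exactly with sd
  expect_equal(yB$samples - y0$samples, 2 * (yA$samples - y0$samples),
               tolerance = 1e-12)
})

test_that("retrospective decimation reproduces prospective sampling", {
  ms <- mini_setup(R = 1)
  truth <- rasterize_phantom(ms$spec)
  y_full <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils, noise_sd = 0)
  samp2 <- kt_sampling(ms$T_, ms$nz, reduction = 2,
                       readout_samples = ms$samp$readout_samples)
  y_pro <- simulate_acquisition(truth, ms$seq, samp2, ms$coils, noise_sd = 0)
  y_ret <- retrospective_undersample(y_full, 2)
  expect_identical(y_ret$samples, y_pro$samples)
  expect_error(retrospective_undersample(y_pro, 2), "R = 1")
})

test_that("simulated data agree with the subspace forward model of projected truth", {
  ms <- mini_setup(n = 12, nz = 4, T_ = 16, R = 2, K = 3, ncoil = 2)
  truth <- rasterize_phantom(ms$spec)
  y <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils, noise_sd = 0)
  hy <- hybrid_decode(y)
  grp <- slice_groups(ms$samp)
  fused <- combine_gridding_with_subspace(ms$sub, ms$samp, 12)

  # per-voxel projected coefficients of the exact fingerprints
  fps <- list(simulate_fingerprint(ms$seq, 1000, 100),
              simulate_fingerprint(ms$seq, 500, 500))
  resid_max <- 0
  for (g in seq_len(grp$n_groups)) {
    E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = g, fused = fused)
    alpha <- array(0 + 0i, dim = c(12, 12, 3, 2))
    for (j in 1:2) {
      z <- grp$slices[g, j]
      for (i in 1:2) {
        mask <- truth$label[, , z] == i
        ac <- Conj(t(ms$sub$basis)) %*% fps[[i]]
        for (k in 1:3) {
          pl <- alpha[, , k, j]; pl[mask] <- ac[k]; alpha[, , k, j] <- pl
        }
      }
    }
    num <- sqrt(sum(Mod(E$forward(alpha) - hy$groups[[g]])^2))
    den <- sqrt(sum(Mod(hy$groups[[g]])^2))
    if (den > 0) resid_max <- max(resid_max, num / den)
  }
  # the only discrepancy is the off-subspace part of the fingerprints
  sub_resid <- subspace_residual(ms$dict, ms$sub)
  fp_resid <- max(vapply(fps, function(f) {
    pr <- ms$sub$basis %*% (Conj(t(ms$sub$basis)) %*% f)
    sqrt(sum(Mod(f - pr)^2) / sum(Mod(f)^2))
  }, numeric(1)))
  expect_lt(resid_max, max(sub_resid, fp_resid) + 1e-6)
})

test_that("interior labels erode partial-volume edges", {
  spheres <- data.frame(cx = 0, cy = 0, cz = 0, radius_mm = 8,
                        t1_ms = 1000, t2_ms = 100, m0 = 1)
  spec <- phantom_spec(n = 24, nz = 12, voxel_mm = c(2, 2, 2),
                       spheres = spheres)
  truth <- rasterize_phantom(spec)
  inner <- interior_labels(truth)
  expect_true(all(inner[inner > 0] == 1L))
  expect_lt(sum(inner > 0), sum(truth$label > 0))
  # every interior voxel's face neighbors share its label
  idx <- which(inner > 0, arr.ind = TRUE)
  for (r in seq_len(min(nrow(idx), 20))) {
    i <- idx[r, ]
    expect_equal(truth$label[i[1] + 1, i[2], i[3]], 1L)
    expect_equal(truth$label[i[1], i[2], i[3] - 1], 1L)
  }
})
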