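test_that("hybrid decode is unitary and inverts exactly", {
  ms <- mini_setup()
  truth <- rasterize_phantom(ms$spec)
  y <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils, noise_sd = 0)
  hy <- hybrid_decode(y)
  # Parseval: the per-frame kz transform preserves sample energy
  expect_equal(sum(vapply(hy$groups, function(g) sum(Mod(g)^2), numeric(1))),
               sum(Mod(y$samples)^2), tolerance = 1e-10)
  # exact inversion
  back <- hybrid_encode(hy)
  expect_lt(max(Mod(back$samples - y$samples)), 1e-12)
})

test_that("R = 1 decoding reduces to per-slice spoke data", {
  # delta image in one slice: decoded group data equal that slice's spokes
  ms <- mini_setup(R = 1, ncoil = 1)
  n <- ms$n
  truth <- rasterize_phantom(ms$spec)
  truth$t1_ms[] <- 0; truth$t2_ms[] <- 0; truth$m0[] <- 0; truth$label[] <- 0L
  zsel <- 2
  truth$t1_ms[5, 7, zsel] <- 1000; truth$t2_ms[5, 7, zsel] <- 100
  truth$m0[5, 7, zsel] <- 1; truth$label[5, 7, zsel] <- 1L
  y <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils, noise_sd = 0)
  hy <- hybrid_decode(y)
  grp <- slice_groups(ms$samp)
  g <- which(grp$slices[, 1] == zsel)
  others <- setdiff(seq_len(grp$n_groups), g)
  e_other <- sum(vapply(hy$groups[others], function(x) sum(Mod(x)^2), numeric(1)))
  expect_lt(e_other / sum(Mod(hy$groups[[g]])^2), 1e-20)

  # the non-empty group holds the delta's spoke samples times the fingerprint
  fp <- simulate_fingerprint(ms$seq, 1000, 100)
  cmap <- ms$coils$maps[5, 7, zsel, 1]
  xt <- (seq_len(n) - 1) - n / 2
  ref <- complex(0)
  for (t in seq_len(ms$T_)) {
    co <- spoke_coordinates(ms$samp, t)
    ph <- exp(-2i * pi * (co[, 1] * xt[5] + co[, 2] * xt[7]))
    ref <- c(ref, fp[t] * cmap * ph)
  }
  expect_lt(rel_l2(hy$groups[[g]][, 1], ref), 1e-6)
})

test_that("slice-group forward model matches the dense DFT oracle", {
  ms <- mini_setup(n = 12, T_ = 8, R = 2, K = 2, ncoil = 2)
  E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 1)
  alpha <- random_alpha(12, 2, 2, seed = 3)
  y_dir <- direct_group_forward(alpha, ms$sub, ms$coils, ms$samp, 1)
  expect_lt(rel_l2(E$forward(alpha), y_dir), 1e-5)
  # linearity
  expect_equal(E$forward(alpha * 0), y_dir * 0)
  c0 <- 1.7 - 0.4i
  expect_equal(E$forward(c0 * alpha), c0 * E$forward(alpha), tolerance = 1e-12)
})

test_that("adjoint passes the dot test across shapes", {
  for (cfg in list(list(n = 16, R = 1, K = 1), list(n = 16, R = 2, K = 3),
                   list(n = 32, R = 2, K = 5))) {
    ms <- mini_setup(n = cfg$n, nz = 4, T_ = 10, R = cfg$R, K = cfg$K,
                     ncoil = 2)
    E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 1)
    alpha <- random_alpha(cfg$n, cfg$K, cfg$R, seed = cfg$n + cfg$K)
    y <- E$forward(alpha)
    set.seed(99)
    yr <- matrix(complex(real = rnorm(length(y)), imaginary = rnorm(length(y))),
                 nrow(y), ncol(y))
    lhs <- sum(Conj(E$forward(alpha)) * yr)
    rhs <- sum(Conj(alpha) * E$adjoint(yr))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-5)
    expect_equal(E$adjoint(yr * 0), alpha * 0)
  }
})

test_that("adjoint equals the conjugate transpose of the dense matrix", {
  ms <- mini_setup(n = 6, nz = 4, T_ = 6, R = 2, K = 2, ncoil = 2,
                   readout = 8)
  E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 2)
  A <- dense_operator_matrix(E, 6, 2, 2)
  set.seed(4)
  y <- matrix(complex(real = rnorm(E$n_rows * 2),
                      imaginary = rnorm(E$n_rows * 2)), E$n_rows, 2)
  got <- E$adjoint(y)
  ref <- array(Conj(t(A)) %*% as.vector(y), dim = dim(got))
  expect_lt(rel_l2(got, ref), 1e-10)
})

test_that("an alpha confined to one replicate sees only that replicate's phase", {
  ms <- mini_setup(n = 10, nz = 4, T_ = 6, R = 2, K = 2, ncoil = 1)
  grp <- slice_groups(ms$samp)
  fused <- combine_gridding_with_subspace(ms$sub, ms$samp, 10)
  E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 1, fused = fused)
  for (j in 1:2) {
    alpha <- array(0 + 0i, dim = c(10, 10, 2, 2))
    alpha[, , , j] <- random_alpha(10, 2, 1, seed = j)
    z <- grp$slices[1, j]
    kimgs <- alpha[, , , j] * as.vector(ms$coils$maps[, , z, 1])
    single <- fused$forward(kimgs)
    W <- caipi_phase(ms$samp)[, j] * grp$signs[j] / sqrt(2)
    ref <- single * rep(W, each = ms$samp$readout_samples)
    expect_lt(rel_l2(E$forward(alpha)[, 1], ref), 1e-12)
  }
})

test_that("k-space calibration images feed the sensitivity estimator", {
  ms <- mini_setup(n = 16, nz = 4, T_ = 32, R = 1, ncoil = 3)
  truth <- rasterize_phantom(ms$spec)
  y <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils, noise_sd = 0)
  calib <- calibration_images(y, lowpass_frac = 0.4)
  expect_equal(dim(calib), c(16, 16, 4, 3))
  est <- estimate_sensitivities(calib, smooth_sigma = 1)
  # on the object support the estimated magnitudes track the true maps
  z <- 2
  support <- Mod(truth$m0[, , z]) > 0
  expect_gte(sum(support), 10)
  err <- Mod(est$maps[, , z, ])[support] - Mod(ms$coils$maps[, , z, ])[support]
  expect_lt(sqrt(mean(err^2)), 0.15)
  # accelerated data are rejected
  y2 <- retrospective_undersample(y, 2)
  expect_error(calibration_images(y2), "fully partition-encoded")

  # NIfTI export of coil maps
  dir <- tempfile()
  paths <- write_coils_nifti(ms$coils, dir, voxel_mm = c(2, 2, 2))
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
})

test_that("sensitivity estimation recovers smooth maps up to a common phase", {
  # single coil, all-ones calibration: constant modulus-1 map
  est1 <- estimate_sensitivities(array(1 + 0i, dim = c(8, 8, 1)),
                                 smooth_sigma = 0)
  expect_equal(Mod(est1$maps), array(1, dim = c(8, 8, 1, 1)))

  # ground-truth bypass returns the maps untouched
  co <- simulate_coils(3, 16, 2)
  expect_identical(estimate_sensitivities(bypass = co), co)

  # 4 smooth synthetic coils on a smooth phantom: sum-of-squares weighted
  # magnitude recovered within 5%
  co4 <- simulate_coils(4, 32, 1)
  x <- ((seq_len(32) - 1) - 16 + 0.5) / 32
  obj <- exp(-outer(x^2, x^2, `+`) / (2 * 0.25^2))  # smooth object
  calib <- array(0 + 0i, dim = c(32, 32, 4))
  for (c in 1:4) calib[, , c] <- obj * co4$maps[, , 1, c]
  est <- estimate_sensitivities(calib, smooth_sigma = 1)
  support <- obj > 0.3
  err <- abs(Mod(est$maps[, , 1, ])[support] - Mod(co4$maps[, , 1, ])[support])
  expect_lt(sqrt(mean(err^2)), 0.05)
})
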