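test_that("non-local means leaves constants unchanged and averages in the limit", {
  img <- matrix(3 + 2i, 20, 20)
  expect_equal(nlm_denoise(img, 3, 8, strength = 1), img, tolerance = 1e-12)

  # infinite strength: every weight is 1, so the output is the mean of the
  # search window (checked at an interior pixel with a fully valid window)
  set.seed(31)
  img <- matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 20, 20)
  out <- nlm_denoise(img, 3, 8, strength = 1e12)
  win <- img[7:14, 7:14]   # offsets -4..3 around pixel (11, 11)
  expect_equal(out[11, 11], mean(win), tolerance = 1e-6)
})

test_that("non-local means suppresses noise and preserves the mean", {
  set.seed(32)
  sigma <- 0.1
  img <- matrix(complex(real = 1 + rnorm(64^2, 0, sigma),
                        imaginary = rnorm(64^2, 0, sigma)), 64, 64)
  out <- nlm_denoise(img, 3, 32)
  v_in <- stats::var(c(Re(img))) + stats::var(c(Im(img)))
  v_out <- stats::var(c(Re(out))) + stats::var(c(Im(out)))
  expect_gt(v_in / v_out, 4)
  expect_lt(Mod(mean(out) - mean(img)) / Mod(mean(img)), 0.01)
})

test_that("window validation rejects even patches and undersized searches", {
  img <- matrix(0 + 0i, 8, 8)
  expect_error(nlm_denoise(img, 2, 8), "odd")
  expect_error(nlm_denoise(img, 5, 3), "at least")
})

test_that("matching recovers an exact dictionary row with its scale", {
  ms <- mini_setup(T_ = 24, K = 3)
  i <- 7
  sig <- 3.7 * ms$dict$signals[i, ]
  m <- match_dictionary(matrix(sig, 1), ms$dict)
  expect_equal(m$t1_ms[1], unname(ms$grid$entries[i, "t1_ms"]))
  expect_equal(m$t2_ms[1], unname(ms$grid$entries[i, "t2_ms"]))
  expect_equal(Mod(m$m0[1]), 3.7, tolerance = 1e-10)
  expect_equal(m$match_score[1], 1, tolerance = 1e-10)

  # compressed-domain matching of the projected coefficients
  a <- Conj(t(ms$sub$basis)) %*% sig
  mc <- match_dictionary(matrix(a, 1), ms$dict, subspace = ms$sub)
  expect_equal(mc$t1_ms[1], unname(ms$grid$entries[i, "t1_ms"]))
  expect_equal(mc$match_score[1], 1, tolerance = 1e-10)

  # zero signal is flagged invalid
  z <- match_dictionary(matrix(0 + 0i, 1, 24), ms$dict)
  expect_false(z$valid[1])
  expect_true(is.na(z$t1_ms[1]))
  expect_equal(z$match_score[1], 0)

  # unnormalized dictionaries are rejected
  raw <- build_dictionary(ms$seq, ms$grid, normalize = FALSE)
  expect_error(match_dictionary(matrix(sig, 1), raw), "normalized")
})

test_that("matching is robust to noise at SNR 20", {
  seqp <- mrf_sequence(default_flip_pattern(48),
                       n_repetitions_to_steady_cycle = 2)
  grid <- dictionary_grid(
    t1_values_ms = exp(seq(log(100), log(2500), length.out = 20)),
    t2_values_ms = exp(seq(log(20), log(800), length.out = 20)))
  dict <- build_dictionary(seqp, grid)
  set.seed(33)
  ntrial <- 1000
  rows <- sample(nrow(dict$signals), ntrial, replace = TRUE)
  X <- dict$signals[rows, ]
  X <- X + complex(real = rnorm(length(X), 0, 1 / (20 * sqrt(2 * 48))),
                   imaginary = rnorm(length(X), 0, 1 / (20 * sqrt(2 * 48))))
  m <- match_dictionary(X, dict)
  # same or grid-adjacent (t1, t2) in at least 95% of draws
  it1 <- findInterval(m$t1_ms, grid$t1_values_ms)
  jt1 <- findInterval(grid$entries[rows, "t1_ms"], grid$t1_values_ms)
  it2 <- findInterval(m$t2_ms, grid$t2_values_ms)
  jt2 <- findInterval(grid$entries[rows, "t2_ms"], grid$t2_values_ms)
  ok <- abs(it1 - jt1) <= 1 & abs(it2 - jt2) <= 1
  expect_gte(mean(ok), 0.95)
})

test_that("compressed and time-domain matching agree for dictionary signals", {
  ms <- mini_setup(T_ = 32, K = 3)
  set.seed(34)
  rows <- sample(nrow(ms$dict$signals), 200, replace = TRUE)
  scale <- runif(200, 0.5, 2)
  X <- ms$dict$signals[rows, ] * scale
  mt <- match_dictionary(X, ms$dict)
  A <- X %*% Conj(ms$sub$basis)          # voxels x K coefficients
  mc <- match_dictionary(A, ms$dict, subspace = ms$sub)
  agree <- mt$t1_ms == mc$t1_ms & mt$t2_ms == mc$t2_ms
  expect_gte(mean(agree), 0.99)
})

test_that("slice-oversampling crop retains the central prescribed slab", {
  d <- c(4, 4, 40)
  mk <- function() array(runif(prod(d)), d)
  maps <- parameter_maps(mk(), mk(), mk() + 0i, mk(),
                         array(TRUE, d), voxel_mm = c(1.64, 1.64, 5))
  out <- crop_oversampled_slices(maps, 0.25)
  expect_equal(dim(out$t1_ms), c(4, 4, 32))
  expect_equal(out$t1_ms, maps$t1_ms[, , 5:36])   # 4 cut from each side
  expect_identical(crop_oversampled_slices(maps, 0), maps)
  expect_error(crop_oversampled_slices(maps, 0.3), "integer")
})

test_that("maps export to NIfTI with voxel geometry", {
  d <- c(6, 6, 4)
  maps <- parameter_maps(array(1000, d), array(100, d), array(1 + 0i, d),
                         array(1, d), array(TRUE, d),
                         voxel_mm = c(1.64, 1.64, 5))
  dir <- tempfile()
  paths <- write_maps_nifti(maps, dir)
  expect_true(all(file.exists(file.path(dir, c("t1.nii.gz", "t2.nii.gz",
                                               "m0_mag.nii.gz", "score.nii.gz")))))
  img <- RNifti::readNifti(file.path(dir, "t1.nii.gz"))
  expect_equal(dim(img), d)
  expect_equal(RNifti::pixdim(img), c(1.64, 1.64, 5), tolerance = 1e-6)
  expect_equal(max(abs(img - 1000)), 0)
})
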