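test_that("CG recovers the coefficients of consistent, identifiable data", {
  # truth constructed in the operator's row space, so the minimum-norm
  # least-squares solution that CG converges to is the truth itself
  ms <- mini_setup(n = 8, nz = 2, T_ = 24, R = 1, K = 2, ncoil = 2,
                   readout = 16)
  E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 1)
  set.seed(8)
  y0 <- matrix(complex(real = rnorm(E$n_rows * 2),
                       imaginary = rnorm(E$n_rows * 2)), E$n_rows, 2)
  alpha <- E$adjoint(y0)
  alpha <- alpha / sqrt(sum(Mod(alpha)^2))
  y <- E$forward(alpha)
  cfg <- recon_config(n_cg_iters_linear = 200, cg_tolerance = 1e-14)
  got <- cg_linear_recon(y, E, cfg)
  expect_lt(rel_l2(got, alpha), 1e-4)
  # the normal-equation residual trends steadily to zero (its 2-norm can
  # fluctuate locally on an ill-conditioned system, but never regresses
  # above the running minimum by more than a bounded factor)
  r <- attr(got, "cg_resid")
  expect_lt(tail(r, 1), 1e-3 * r[1])
  expect_true(all(r <= 5 * cummin(r)))
  # zero data gives a zero solution
  expect_equal(as.vector(cg_linear_recon(y * 0, E, cfg)),
               rep(0 + 0i, length(alpha)))
})

test_that("llr_prox equals explicit singular-value soft-thresholding", {
  set.seed(21)
  K <- 3; p <- 8
  alpha <- array(complex(real = rnorm(p * p * K * 2),
                         imaginary = rnorm(p * p * K * 2)),
                 dim = c(p, p, K, 2))
  thr <- 0.8
  got <- llr_prox(alpha, thr, p, joint_replicates = TRUE)
  # oracle: one patch covering the image, stacked replicates
  Mp <- matrix(aperm(alpha, c(1, 2, 4, 3)), p * p * 2, K)
  sv <- svd(Mp)
  s <- pmax(sv$d - thr, 0)
  ref <- sv$u %*% (s * Conj(t(sv$v)))
  ref <- aperm(array(ref, dim = c(p, p, 2, K)), c(1, 2, 4, 3))
  expect_lt(max(Mod(got - ref)), 1e-10)

  # threshold 0 is the identity
  expect_identical(llr_prox(alpha, 0, p), alpha)

  # thresholding beyond the largest singular value zeroes the patch
  wiped <- llr_prox(alpha, max(sv$d) + 1, p)
  expect_lt(max(Mod(wiped)), 1e-12)
})

test_that("llr_prox is non-expansive", {
  set.seed(22)
  for (i in 1:5) {
    a <- random_alpha(16, 3, 2, seed = i)
    b <- random_alpha(16, 3, 2, seed = i + 100)
    pa <- llr_prox(a, 0.5, 8)
    pb <- llr_prox(b, 0.5, 8)
    expect_lte(sqrt(sum(Mod(pa - pb)^2)), sqrt(sum(Mod(a - b)^2)) + 1e-12)
  }
})

test_that("ADMM with lambda 0 matches the unregularized CG solution", {
  # both solvers converge to the same minimum-norm least-squares point on
  # consistent data (truth in the row space)
  ms <- mini_setup(n = 10, nz = 4, T_ = 20, R = 1, K = 2, ncoil = 2)
  E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 1)
  set.seed(9)
  y0 <- matrix(complex(real = rnorm(E$n_rows * 2),
                       imaginary = rnorm(E$n_rows * 2)), E$n_rows, 2)
  alpha <- E$adjoint(y0)
  alpha <- alpha / sqrt(sum(Mod(alpha)^2))
  y <- E$forward(alpha)
  ref <- cg_linear_recon(y, E, recon_config(n_cg_iters_linear = 300,
                                            cg_tolerance = 1e-13))
  got <- admm_llr_recon(y, E, recon_config(lambda_llr = 0, admm_rho = 1e-8,
                                           n_admm_iters = 8, n_cg_iters = 60,
                                           cg_tolerance = 1e-13))
  expect_lt(rel_l2(got, ref), 1e-3)

  # zero data with positive regularization gives the zero solution
  z <- admm_llr_recon(y * 0, E, recon_config())
  expect_equal(max(Mod(z)), 0)
  expect_error(recon_config(lambda_llr = -1), "lambda")
})

test_that("ADMM converges and satisfies the objective inequalities", {
  ms <- mini_setup(n = 16, nz = 4, T_ = 16, R = 2, K = 2, ncoil = 2)
  truth <- rasterize_phantom(ms$spec)
  y <- simulate_acquisition(truth, ms$seq, ms$samp, ms$coils,
                            noise_sd = 2e-3, seed = 5)
  hy <- hybrid_decode(y)
  E <- subspace_operator(ms$sub, ms$coils, ms$samp, group = 1)
  cfg <- recon_config(patch_size = 8, lambda_llr = 1e-4)
  x <- admm_llr_recon(hy$groups[[1]], E, cfg)
  log <- attr(x, "admm_log")
  expect_equal(nrow(log), 8L)
  # primal residual shrinks by at least 10x over the iterations
  expect_lt(log$primal_resid[8], log$primal_resid[1] / 10)

  # objective at a converged solution is at least as good as at the zero
  # image and at the unregularized CG solution (run deeper than the
  # standard protocol, since the comparison concerns the minimizer)
  yg <- hy$groups[[1]]
  scale <- max(Mod(E$adjoint(yg)))
  lam_raw <- cfg$lambda_llr * scale   # lambda on the normalized scale
  obj <- function(a) recon_objective(a, yg, E, lam_raw, 8)
  x_deep <- admm_llr_recon(yg, E, recon_config(n_admm_iters = 40,
                                               n_cg_iters = 10))
  f_admm <- obj(x_deep)
  expect_lte(f_admm, obj(x_deep * 0) * (1 + 1e-10))
  cg <- cg_linear_recon(yg, E, recon_config(n_cg_iters_linear = 40))
  expect_lte(f_admm, obj(cg) * (1 + 1e-10))

  # total nuclear norm is non-increasing in lambda
  nn <- numeric(3)
  lams <- c(1e-5, 1e-3, 1e-1)
  for (i in 1:3) {
    xi <- admm_llr_recon(yg, E, recon_config(lambda_llr = lams[i]))
    nn[i] <- starmrf:::llr_nuclear_norm(xi, 8)
  }
  expect_true(all(diff(nn) <= 1e-8 * nn[1]))
})
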