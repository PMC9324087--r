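# Shared small fixtures, built in code.

# A miniature but complete acquisition setup: geometry, dictionary,
# subspace, coils, sampling and a two-sphere phantom.
mini_setup <- function(n = 12, nz = 4, T_ = 16, ncoil = 2, R = 2, K = 2,
                       readout = 2 * n) {
  seqp <- mrf_sequence(default_flip_pattern(T_),
                       n_repetitions_to_steady_cycle = 2)
  grid <- dictionary_grid(t1_values_ms = c(200, 500, 1000, 2000),
                          t2_values_ms = c(50, 100, 300))
  dict <- build_dictionary(seqp, grid)
  sub <- compute_subspace(dict, K)
  coils <- simulate_coils(ncoil, n, nz)
  samp <- kt_sampling(T_, nz, reduction = R, readout_samples = readout)
  # two-sphere layout scaled to the grid so any (n, nz) stays in bounds
  fov <- n * 2
  slab <- nz * 2
  cz <- c(-0.1, 0.1) * slab
  radius <- pmin(0.18 * fov, 0.35 * slab)
  spheres <- data.frame(cx = c(-0.25, 0.2) * fov, cy = c(0.17, -0.12) * fov,
                        cz = cz, radius_mm = radius,
                        t1_ms = c(1000, 500), t2_ms = c(100, 300),
                        m0 = 1)
  spheres$t2_ms <- pmin(spheres$t2_ms, spheres$t1_ms)
  spec <- phantom_spec(n = n, nz = nz, voxel_mm = c(2, 2, 2),
                       spheres = spheres)
  list(seq = seqp, grid = grid, dict = dict, sub = sub, coils = coils,
       samp = samp, spec = spec, n = n, nz = nz, T_ = T_, ncoil = ncoil,
       R = R, K = K)
}

random_alpha <- function(n, K, R, seed = 1) {
  set.seed(seed)
  array(complex(real = stats::rnorm(n * n * K * R),
                imaginary = stats::rnorm(n * n * K * R)),
        dim = c(n, n, K, R))
}
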