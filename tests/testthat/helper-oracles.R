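# Independent oracles used across the test files.

# Isochromat Bloch simulation of the inversion-prepared FISP train: nspins
# uniformly dephased spins per voxel, one spoiler cycle of dephasing per TR
# applied after the readout, relaxation split at the echo time.  Matches the
# package's pulse-phase convention (dF+ = -i sin(a) Z at small angles).
bloch_isochromat <- function(seq, t1, t2, nspins = 256) {
  T_ <- length(seq$flip_angles_deg)
  flip <- seq$flip_angles_deg * pi / 180
  theta <- 2 * pi * ((seq_len(nspins) - 0.5) / nspins)
  M <- matrix(0, 3, nspins); M[3, ] <- 1
  relax <- function(M, dt) {
    e2 <- exp(-dt / t2); e1 <- exp(-dt / t1)
    M[1:2, ] <- M[1:2, ] * e2
    M[3, ] <- M[3, ] * e1 + (1 - e1)
    M
  }
  sig <- complex(T_)
  for (rep in seq_len(seq$n_repetitions_to_steady_cycle)) {
    M[3, ] <- -seq$inversion_efficiency * M[3, ]
    for (t in seq_len(T_)) {
      a <- flip[t]
      My <- M[2, ] * cos(a) - M[3, ] * sin(a)
      Mz <- M[2, ] * sin(a) + M[3, ] * cos(a)
      M[2, ] <- My; M[3, ] <- Mz
      M <- relax(M, seq$te_ms)
      sig[t] <- mean(complex(real = M[1, ], imaginary = M[2, ]))
      M <- relax(M, seq$tr_ms - seq$te_ms)
      Mx <- M[1, ] * cos(theta) - M[2, ] * sin(theta)
      My <- M[1, ] * sin(theta) + M[2, ] * cos(theta)
      M[1, ] <- Mx; M[2, ] <- My
    }
    M <- relax(M, seq$recovery_delay_ms)
  }
  sig
}

# Dense type-2 NUFFT by explicit summation (the DFT oracle).
direct_nufft <- function(coords, img) {
  n <- nrow(img)
  xt <- (seq_len(n) - 1) - n / 2
  out <- complex(nrow(coords))
  for (m in seq_len(nrow(coords))) {
    ph <- exp(-2i * pi * (outer(xt * coords[m, 1], xt * coords[m, 2], `+`)))
    out[m] <- sum(img * ph)
  }
  out
}

# Direct evaluation of the slice-group forward model (sum over replicates of
# CAIPI phase x spoke DFT of the coil-weighted, basis-expanded images).
direct_group_forward <- function(alpha, subspace, coils, sampling, group) {
  n <- dim(coils$maps)[1]
  grp <- slice_groups(sampling)
  R <- sampling$reduction
  K <- subspace$rank
  T_ <- sampling$n_frames
  nread <- sampling$readout_samples
  ncoil <- dim(coils$maps)[4]
  W <- caipi_phase(sampling) * rep(grp$signs, each = T_) / sqrt(R)
  xt <- (seq_len(n) - 1) - n / 2
  y <- matrix(0 + 0i, nread * T_, ncoil)
  for (t in seq_len(T_)) {
    co <- spoke_coordinates(sampling, t)
    rows <- ((t - 1) * nread + 1):(t * nread)
    for (j in seq_len(R)) {
      z <- grp$slices[group, j]
      for (c in seq_len(ncoil)) {
        img <- matrix(0 + 0i, n, n)
        for (k in seq_len(K))
          img <- img + subspace$basis[t, k] * alpha[, , k, j]
        img <- img * coils$maps[, , z, c]
        for (m in seq_len(nread)) {
          ph <- exp(-2i * pi * outer(xt * co[m, 1], xt * co[m, 2], `+`))
          y[rows[m], c] <- y[rows[m], c] + W[t, j] * sum(img * ph)
        }
      }
    }
  }
  y
}

# Explicit matrix of a linear operator on coefficient arrays, one column per
# unit vector (tiny problems only).
dense_operator_matrix <- function(E, n, K, R) {
  nun <- n * n * K * R
  cols <- vector("list", nun)
  for (i in seq_len(nun)) {
    a <- array(0 + 0i, dim = c(n, n, K, R)); a[i] <- 1
    cols[[i]] <- as.vector(E$forward(a))
  }
  do.call(cbind, cols)
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
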