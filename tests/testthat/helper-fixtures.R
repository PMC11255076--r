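# shared fixtures: all synthetic inputs are built in code at test time

# draw a random stable pool parameterization (K > 0, positive damping)
random_stable_pool <- function() {
  repeat {
    p <- pool_params(t1 = runif(1, 0.5, 3), t2 = runif(1, 0.5, 3),
                     C11 = runif(1, 0, 1.8), C12 = runif(1, 0.2, 2),
                     C21 = runif(1, 0.2, 2), C22 = runif(1, 0, 1.5),
                     D = runif(1, 0.5, 5))
    K <- stability_k(p)
    damp <- p$t1 * (1 + p$C22) - p$t2 * (p$C11 - 1)
    if (K <= 0.05 || damp <= 0.05) next
    # keep the slowest mode fast enough that trajectories settle within
    # the simulated horizon
    if (min(abs(Re(eigen(pool_matrix(p))$values))) > 0.2) return(p)
  }
}

# system matrix of the two-pool ODEs, for eigenvalue oracles
pool_matrix <- function(p) {
  rbind(c((p$C11 - 1) / p$t1, -p$C21 / p$t1),
        c(p$C12 / p$t2, -(1 + p$C22) / p$t2))
}

# eigenvalues as a consistently ordered complex pair
eig_pair <- function(M) {
  v <- as.complex(eigen(M)$values)
  v[order(Re(v), Im(v))]
}

# eigenvalues implied by the canonical (wn, zeta) pair
canon_pair <- function(cp) {
  disc <- sqrt(as.complex(cp$zeta^2 - 1))
  v <- cp$wn * (-cp$zeta + c(-1, 1) * disc)
  v[order(Re(v), Im(v))]
}

# noise-free generator configuration (deterministic subjects)
noiseless_config <- function(n_subjects = 1, ...) {
  generator_config(noise_sd_lpm = 0, subject_sd_lpm = 0,
                   pet_noise_sd_mmhg = 0, n_subjects = n_subjects,
                   seed = 1L, ...)
}

# the recovery-segment LTF truth used across pipeline tests
ltf_truth <- function() {
  canonical_params(wn = 0.375, zeta = 0.7, A = 0, B = 9, baseline = 7.6,
                   onset_delay = 2)
}

# pure noiseless LTF curve on the protocol grid (zero outside recovery)
pure_ltf_series <- function(truth = ltf_truth()) {
  grid <- build_protocol(protocol_spec())
  x <- numeric(nrow(grid))
  rec <- grid$segment == "w40_recovery"
  t0 <- min(grid$time_min[rec]) - 0.5
  x[rec] <- step_response(truth, grid$time_min[rec] - t0)
  list(x = x, grid = grid, t0 = t0)
}
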