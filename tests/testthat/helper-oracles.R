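# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written the slow, direct way so it stays
# independent of the package's vectorized implementations.

# Brute-force two-site forward model: propagate the 3-state system with
# Matrix::expm over the same piecewise-constant input schedule as the
# package, but without the closed-form propagator.
oracle_two_site <- function(input_fn, kp, acq, substep = 0.05) {
  A <- matrix(c(-(1 / kp$t1_pyr + kp$k_pl + kp$k_pb), kp$k_pl, kp$k_pb,
                0, -1 / kp$t1_lac, 0,
                0, 0, -1 / kp$t1_bic), 3, 3)
  tt <- timing(acq)$time
  flips <- c(acq$flip_pyr, acq$flip_lac, acq$flip_bic) * pi / 180
  M <- c(0, 0, 0); tcur <- 0
  S <- matrix(0, length(tt), 3)
  for (i in seq_along(tt)) {
    if (tt[i] > tcur) {
      grid <- seq(tcur, tt[i], by = substep)
      if (grid[length(grid)] < tt[i]) grid <- c(grid, tt[i])
      for (k in seq_len(length(grid) - 1)) {
        dt <- grid[k + 1] - grid[k]
        E <- as.matrix(Matrix::expm(A * dt))
        u <- input_fn((grid[k] + grid[k + 1]) / 2)
        M <- as.vector(E %*% M + solve(A, (E - diag(3)) %*% c(u, 0, 0)))
      }
      tcur <- tt[i]
    }
    S[i, ] <- M * sin(flips)
    M <- M * cos(flips)
  }
  S
}

# Exhaustive patch-feature asymmetry oracle on a prepared map: explicit
# loops over every candidate point pair, re-deriving patches and mirrored
# coordinates from first principles.
oracle_asymmetry <- function(prep, w) {
  d <- dim(prep$values)
  s_map <- array(NA_real_, dim = d)
  jmid <- prep$jsum / 2
  patch_ok <- function(s, r, cc) {
    if (r < 2 || r > d[2] - 1 || cc < 2 || cc > d[3] - 1) return(FALSE)
    all(prep$included[s, (r - 1):(r + 1), (cc - 1):(cc + 1)])
  }
  feat <- function(s, r, cc, left) {
    patch <- prep$values[s, (r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (left) patch <- patch[, 3:1]
    mc <- if (left) prep$jsum - cc else cc
    c(as.vector(patch), w * r, w * mc)
  }
  for (s in seq_len(d[1])) {
    pts <- which(prep$included[s, , ], arr.ind = TRUE)
    if (nrow(pts) == 0) next
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; cc <- pts[i, 2]
      if (cc == jmid) next
      if (!patch_ok(s, r, cc)) next
      left <- cc < jmid
      fp <- feat(s, r, cc, left)
      best <- Inf
      for (j in seq_len(nrow(pts))) {
        r2 <- pts[j, 1]; c2 <- pts[j, 2]
        opposite <- if (left) c2 > jmid else c2 < jmid
        if (!opposite || !patch_ok(s, r2, c2)) next
        fq <- feat(s, r2, c2, !left)
        best <- min(best, sqrt(sum((fp - fq)^2)))
      }
      if (is.finite(best)) s_map[s, r, cc] <- best
    }
  }
  s_map
}

# Simpson quadrature on a uniform grid (odd number of points).
simpson <- function(y, h) {
  n <- length(y)
  stopifnot(n %% 2 == 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
             2 * sum(y[seq(3, n - 2, 2)]))
}

# A small all-noise multichannel dataset: zero signal everywhere so every
# frame is available for covariance estimation.
make_noise_raw <- function(cov, n_timepoints = 25, shape = c(8, 10, 10),
                           noise_scale = 1, seed = 99) {
  acq <- acq_params(n_timepoints = n_timepoints)
  phantom <- make_phantom(shape, seed = 1)
  clean <- simulate_dataset(phantom, acq, bolus_params(amplitude = 0))
  prof <- make_coil_profiles(nrow(cov), shape, seed = 2)
  synthesize_multichannel(clean, prof, noise_model(cov, noise_scale),
                          seed = seed)
}

# Default single-voxel noiseless simulation at the reference NAWM rates.
make_reference_sim <- function(k_pl = 0.015, k_pb = 0.003,
                               acq = acq_params(), bolus = bolus_params()) {
  simulate_two_site(bolus, kinetic_params(k_pl = k_pl, k_pb = k_pb), acq)
}
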