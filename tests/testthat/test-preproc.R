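test_that("noise covariance estimation recovers known structure", {
  # white unit-variance noise -> approximately identity
  nraw <- make_noise_raw(diag(4) + 0i, n_timepoints = 40, shape = c(8, 12, 12))
  est <- estimate_noise_covariance(nraw)
  expect_lt(max(Mod(est$channel_covariance - diag(4))), 0.05)
  # known 2x2 covariance recovered within 5% at ~1e5 samples
  cov2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  nraw2 <- make_noise_raw(cov2, n_timepoints = 80, shape = c(8, 12, 12),
                          seed = 7)
  est2 <- estimate_noise_covariance(nraw2)
  expect_lt(max(Mod(est2$channel_covariance - cov2)) / max(Mod(cov2)), 0.05)
  # no designated noise frames -> error
  bad <- nraw
  bad$noise_frames <- integer(0)
  expect_error(estimate_noise_covariance(bad), "noise frames")
})

test_that("a duplicated channel triggers regularization but stays PD", {
  nraw <- make_noise_raw(diag(3) + 0i, n_timepoints = 40, shape = c(8, 12, 12),
                         seed = 11)
  for (m in c("pyr", "lac", "bic")) {
    a <- nraw[[m]]
    a[3, , , , ] <- a[2, , , , ]        # duplicate channel -> singular sample cov
    nraw[[m]] <- a
  }
  est <- estimate_noise_covariance(nraw)
  ev <- eigen(est$channel_covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(Re(ev) > 0))
})

test_that("prewhitening whitens and has the expected closed forms", {
  cov <- diag(c(4, 1)) + 0i
  nraw <- make_noise_raw(cov, n_timepoints = 40, shape = c(8, 12, 12), seed = 3)
  white <- prewhiten(nraw, noise_model(cov))
  # diagonal covariance: channel 1 scaled by 1/2, channel 2 unchanged
  expect_equal(white$pyr[1, , , , ], nraw$pyr[1, , , , ] / 2, tolerance = 1e-12)
  expect_equal(white$pyr[2, , , , ], nraw$pyr[2, , , , ], tolerance = 1e-12)
  # identity covariance leaves data unchanged
  same <- prewhiten(nraw, noise_model(diag(2) + 0i))
  expect_equal(same$pyr, nraw$pyr, tolerance = 1e-12)
  # random SPD covariance: post-hoc covariance of prewhitened noise ~ I
  set.seed(8)
  a <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  spd <- a %*% Conj(t(a)) + diag(4)
  nraw4 <- make_noise_raw(spd, n_timepoints = 80, shape = c(8, 12, 12), seed = 4)
  white4 <- prewhiten(nraw4, noise_model(spd))
  est <- estimate_noise_covariance(white4)
  expect_lt(max(Mod(est$channel_covariance - diag(4))), 0.05)
  expect_error(prewhiten(nraw4, noise_model(diag(2) + 0i)), "dimension")
})

test_that("complex Cholesky factorization is exact", {
  set.seed(5)
  a <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  spd <- a %*% Conj(t(a)) + diag(5)
  L <- hp13c:::chol_complex(spd)
  expect_lt(max(Mod(L %*% Conj(t(L)) - spd)), 1e-10)
  expect_true(all(Mod(L[upper.tri(L)]) == 0))
  expect_error(hp13c:::chol_complex(matrix(c(1, 2, 2, 1) + 0i, 2, 2)),
               "positive-definite")
})

test_that("channel combination is a pyruvate-weighted matched filter", {
  shape <- c(8, 10, 10)
  ph <- make_phantom(shape, seed = 3)
  acq <- acq_params(n_timepoints = 10)
  clean <- simulate_dataset(ph, acq)
  # single channel: combination returns that channel up to unit phase
  prof1 <- make_coil_profiles(1, shape, seed = 2)
  raw1 <- synthesize_multichannel(clean, prof1, noise_model(diag(1) + 0i, 0),
                                  seed = 1)
  comb1 <- combine_channels(raw1)
  vox <- which(ph$nawm_mask, arr.ind = TRUE)[1, ]
  expect_equal(Mod(comb1$pyr[, vox[1], vox[2], vox[3]]),
               Mod(raw1$pyr[1, , vox[1], vox[2], vox[3]]), tolerance = 1e-10)
  # channel with zero sensitivity contributes nothing
  prof2 <- prof1[c(1, 1), , , , drop = FALSE]
  dim(prof2) <- c(2, shape)
  prof2[2, , , ] <- 0
  raw2 <- synthesize_multichannel(clean, prof2, noise_model(diag(2) + 0i, 0),
                                  seed = 1)
  comb2 <- combine_channels(raw2)
  expect_equal(Mod(comb2$pyr[, vox[1], vox[2], vox[3]]),
               Mod(comb1$pyr[, vox[1], vox[2], vox[3]]), tolerance = 1e-10)
  # all-zero pyruvate voxel flagged, output zero
  outside <- which(!ph$brain_mask, arr.ind = TRUE)[1, ]
  expect_true(comb2$undefined_mask[outside[1], outside[2], outside[3]] ||
                all(comb2$pyr[, outside[1], outside[2], outside[3]] == 0))
  # global complex scalar on all channels leaves |combined| invariant
  raw3 <- raw1
  for (m in c("pyr", "lac", "bic")) raw3[[m]] <- raw3[[m]] * exp(1i * 0.7) * 2
  comb3 <- combine_channels(raw3)
  expect_equal(Mod(comb3$pyr), 2 * Mod(comb1$pyr), tolerance = 1e-10)
})

test_that("two equal channels give a sqrt(2) SNR gain", {
  shape <- c(8, 10, 10)
  ph <- make_phantom(shape, seed = 3)
  acq <- acq_params(n_timepoints = 15)
  clean <- simulate_dataset(ph, acq)
  prof1 <- array(1 + 0i, dim = c(1, shape))
  prof2 <- array(1 + 0i, dim = c(2, shape))
  sigma <- 0.05
  raw1 <- synthesize_multichannel(clean, prof1, noise_model(diag(1) + 0i, sigma),
                                  seed = 21)
  raw2 <- synthesize_multichannel(clean, prof2, noise_model(diag(2) + 0i, sigma),
                                  seed = 22)
  s1 <- phase_correct(combine_channels(raw1))
  s2 <- phase_correct(combine_channels(raw2))
  vox <- which(ph$nawm_mask)
  peak1 <- apply(matrix(s1$pyr, dim(s1$pyr)[1])[, vox], 2, max)
  peak2 <- apply(matrix(s2$pyr, dim(s2$pyr)[1])[, vox], 2, max)
  snr_gain <- mean(peak2 / s2$noise_sd) / mean(peak1 / s1$noise_sd)
  expect_equal(snr_gain, sqrt(2), tolerance = 0.05)
})

test_that("phasing removes a constant phase and keeps forward signals positive", {
  shape <- c(8, 10, 10)
  ph <- make_phantom(shape, seed = 3)
  clean <- simulate_dataset(ph, acq_params(n_timepoints = 10))
  prof <- array(exp(1i * pi / 4), dim = c(1, shape))
  raw <- synthesize_multichannel(clean, prof, noise_model(diag(1) + 0i, 0),
                                 seed = 1)
  phased <- phase_correct(combine_channels(raw))
  vox <- which(ph$nawm_mask, arr.ind = TRUE)[1, ]
  expect_equal(phased$pyr[, vox[1], vox[2], vox[3]],
               clean$pyr[, vox[1], vox[2], vox[3]], tolerance = 1e-10)
  expect_true(all(phased$pyr >= -1e-12))
  expect_true(all(phased$lac >= -1e-12))
  # phased noise in the real channel is zero-mean with the expected scale
  nraw <- make_noise_raw(diag(2) + 0i, n_timepoints = 60, shape = c(8, 12, 12),
                         seed = 13)
  ser <- phase_correct(combine_channels(prewhiten(nraw,
                                                  noise_model(diag(2) + 0i))))
  noise_vals <- as.vector(ser$lac)
  expect_lt(abs(mean(noise_vals)), 0.01)
  expect_equal(stats::sd(noise_vals), sqrt(0.5), tolerance = 0.05)
})

test_that("HOSVD reconstruction is exact at full rank and on low-rank input", {
  shape <- c(8, 10, 10)
  ph <- make_phantom(shape, seed = 3)
  clean <- simulate_dataset(ph, acq_params(n_timepoints = 10))
  d4 <- dim(clean$pyr)
  full <- hosvd_denoise(clean, rank_spec = c(d4[2], d4[3], d4[4], d4[1], 3))
  expect_lt(max(abs(full$pyr - clean$pyr)), 1e-10)
  expect_lt(max(abs(full$bic - clean$bic)), 1e-10)
  # exact rank-1 tensor, rank-1 truncation -> exact recovery
  r1 <- clean
  sp <- array(as.vector(outer(outer(sin(1:8), 1:10), rep(1, 10))), dim = shape)
  tr <- exp(-(1:10) / 4)
  for (m in c("pyr", "lac", "bic"))
    r1[[m]] <- outer(tr, sp) * switch(m, pyr = 1, lac = 0.3, bic = 0.1)
  out <- hosvd_denoise(r1, rank_spec = c(1, 1, 1, 1, 1))
  expect_lt(max(abs(out$pyr - r1$pyr)), 1e-10)
  expect_lt(max(abs(out$bic - r1$bic)), 1e-10)
  expect_error(hosvd_denoise(r1, rank_spec = c(99, 1, 1, 1, 1)), "mode dimension")
})

test_that("HOSVD denoising moves noisy low-rank data toward the truth", {
  set.seed(17)
  shape <- c(8, 10, 10)
  ph <- make_phantom(shape, seed = 3)
  truth <- simulate_dataset(ph, acq_params(n_timepoints = 10))
  # rank-2 spatial structure + noise at roughly SNR 5
  noisy <- truth
  sigma <- max(truth$pyr) / 5
  for (m in c("pyr", "lac", "bic"))
    noisy[[m]] <- truth[[m]] + array(rnorm(length(truth[[m]]), sd = sigma),
                                     dim = dim(truth[[m]]))
  den <- hosvd_denoise(noisy, rank_spec = c(3, 3, 3, 3, 3))
  res_pre <- sqrt(mean((noisy$pyr - truth$pyr)^2))
  res_post <- sqrt(mean((den$pyr - truth$pyr)^2))
  expect_lt(res_post, res_pre)
  # truncation error is monotone non-increasing in retained time-mode rank
  errs <- vapply(1:5, function(r) {
    rec <- hosvd_denoise(truth, rank_spec = c(8, 10, 10, r, 3))
    sqrt(mean((rec$pyr - truth$pyr)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("AUC maps apply the strict SNR threshold", {
  shape <- c(8, 10, 10)
  ph <- make_phantom(shape, seed = 3)
  ser <- simulate_dataset(ph, acq_params(n_timepoints = 20))
  ser$noise_sd <- 1
  n <- 20
  vox_out <- which(!ph$brain_mask, arr.ind = TRUE)[1, ]
  # constant trace c over n frames: AUC = n * c
  cval <- 0.9
  ser$pyr[, vox_out[1], vox_out[2], vox_out[3]] <- cval
  # a voxel at exactly SNR 5: excluded by the strict inequality
  vox_edge <- which(!ph$brain_mask, arr.ind = TRUE)[2, ]
  ser$pyr[, vox_edge[1], vox_edge[2], vox_edge[3]] <- 5 * sqrt(n) / n
  maps <- auc_maps(ser, snr_threshold = 5)
  expect_equal(maps$auc$pyr[vox_out[1], vox_out[2], vox_out[3]], n * cval)
  expect_equal(maps$snr$pyr[vox_edge[1], vox_edge[2], vox_edge[3]], 5)
  expect_false(maps$mask$pyr[vox_edge[1], vox_edge[2], vox_edge[3]])
  # all-zero voxel masked out
  vox_zero <- which(!ph$brain_mask, arr.ind = TRUE)[3, ]
  expect_false(maps$mask$pyr[vox_zero[1], vox_zero[2], vox_zero[3]])
  ser2 <- ser
  ser2$noise_sd <- NULL
  expect_error(auc_maps(ser2), "noise_sd")
})
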