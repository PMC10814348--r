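test_that("phantom masks are symmetric, nested and reproducible", {
  ph <- make_phantom(c(8, 16, 16), seed = 1)
  # mirror symmetry of the brain about the column midplane
  expect_identical(ph$brain_mask, ph$brain_mask[, , 16:1])
  # determinism
  ph2 <- make_phantom(c(8, 16, 16), seed = 1)
  expect_identical(ph, ph2)
  ph3 <- make_phantom(c(8, 16, 16), seed = 2)
  expect_false(identical(ph$t2_lesion_mask, ph3$t2_lesion_mask))
  # nesting and NAWM definition
  expect_true(all(ph$nawm_mask <= ph$brain_mask))
  expect_true(all(ph$gm_mask <= ph$brain_mask))
  expect_true(all(ph$t2_lesion_mask <= ph$brain_mask))
  expect_true(all(ph$tumor_mask <= ph$t2_lesion_mask))
  expect_false(any(ph$nawm_mask & ph$t2_lesion_mask))
  expect_false(any(ph$nawm_mask & ph$gm_mask))
  expect_error(make_phantom(c(4, 16, 16)), "dims")
})

test_that("the lesion sits in the left hemisphere and reflects into the brain", {
  for (seed in 1:5) {
    ph <- make_phantom(c(8, 16, 16), seed = seed)
    les <- which(ph$t2_lesion_mask, arr.ind = TRUE)
    expect_gt(nrow(les), 0)
    expect_true(all(les[, 3] <= 8))          # left = low columns
    # explicit index reflection lands in the right hemisphere, inside brain
    refl <- cbind(les[, 1], les[, 2], 16 + 1 - les[, 3])
    expect_true(all(refl[, 3] >= 9))
    expect_true(all(ph$brain_mask[refl]))
  }
})

test_that("gamma-variate bolus has the documented shape", {
  t <- seq(0, 60, by = 0.01)
  bp <- bolus_params(arrival_time = 4, alpha = 2.5, beta = 4, amplitude = 2)
  u <- simulate_bolus(bp, t)
  expect_true(all(u >= 0))
  expect_true(all(u[t <= 4] == 0))
  # calculus oracle: peak at t0 + alpha * beta
  expect_equal(t[which.max(u)], 4 + 2.5 * 4, tolerance = 0.02)
  expect_equal(max(u), 2, tolerance = 1e-6)    # peak-normalized amplitude
  # linearity in amplitude
  u2 <- simulate_bolus(bolus_params(4, 2.5, 4, amplitude = 4), t)
  expect_equal(u2, 2 * u)
  expect_identical(simulate_bolus(bolus_params(amplitude = 0), t),
                   rep(0, length(t)))
  expect_identical(simulate_bolus(bp, numeric(0)), numeric(0))
  expect_error(simulate_bolus(bp, c(3, 1, 2)), "non-decreasing")
  expect_error(bolus_params(alpha = 0))
  expect_error(bolus_params(beta = -1))
})

test_that("forward model obeys its structural limits", {
  acq <- acq_params()
  # no conversion, no initial lactate -> identically zero lactate trace
  sim <- simulate_two_site(bolus_params(), kinetic_params(k_pl = 0, k_pb = 0), acq)
  expect_identical(sim$signals[, "lac"], rep(0, 20))
  expect_identical(sim$signals[, "bic"], rep(0, 20))
  # near-zero conversion, no relaxation, no input, tiny flips: linear growth
  # L(t) ~= k_PL * P0 * t while pyruvate is (almost) undepleted
  k <- 1e-5
  acq_lin <- acq_params(flip_pyr = 1e-3, flip_lac = 1e-3, flip_bic = 1e-3,
                        acquisition_delay = 0)
  kp <- kinetic_params(k_pl = k, k_pb = 0, t1_pyr = Inf, t1_lac = Inf,
                       t1_bic = Inf)
  sim2 <- simulate_two_site(function(t) 0, kp, acq_lin, initial = c(5, 0, 0))
  lac_mag <- sim2$signals[, "lac"] / sin(1e-3 * pi / 180)
  expect_equal(lac_mag, k * 5 * sim2$time, tolerance = 1e-3)
  expect_error(kinetic_params(k_pl = -0.01), "non-negative")
})

test_that("forward model matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  acq <- acq_params(n_timepoints = 8)
  bp <- bolus_params(arrival_time = 3, alpha = 2, beta = 3)
  kp <- kinetic_params(k_pl = 0.02, k_pb = 0.004, t1_pyr = 28, t1_lac = 22,
                       t1_bic = 18)
  sim <- simulate_two_site(bp, kp, acq, substep = 0.25)
  orc <- oracle_two_site(function(t) simulate_bolus(bp, t), kp, acq,
                         substep = 0.25)
  expect_equal(sim$signals, orc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("forward model equals the oracle over random parameter draws", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  acq <- acq_params(n_timepoints = 6, temporal_resolution = 2)
  for (i in 1:100) {
    kp <- kinetic_params(k_pl = runif(1, 0, 0.08), k_pb = runif(1, 0, 0.02),
                         t1_pyr = runif(1, 10, 60), t1_lac = runif(1, 10, 60),
                         t1_bic = runif(1, 10, 60))
    bp <- bolus_params(arrival_time = runif(1, 0, 4), alpha = runif(1, 1, 4),
                       beta = runif(1, 1, 6), amplitude = runif(1, 0.5, 2))
    sim <- simulate_two_site(bp, kp, acq, substep = 0.5)
    orc <- oracle_two_site(function(t) simulate_bolus(bp, t), kp, acq,
                           substep = 0.5)
    expect_equal(sim$signals, orc, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("without losses the lactate terminal value equals k_PL * area(P)", {
  # fine sampling; no relaxation, negligible RF loss, finite bolus
  acq <- acq_params(n_timepoints = 1501, temporal_resolution = 0.02,
                    acquisition_delay = 0,
                    flip_pyr = 1e-4, flip_lac = 1e-4, flip_bic = 1e-4)
  kp <- kinetic_params(k_pl = 0.015, k_pb = 0, t1_pyr = Inf, t1_lac = Inf,
                       t1_bic = Inf)
  bp <- bolus_params(arrival_time = 2, alpha = 2, beta = 2)
  sim <- simulate_two_site(bp, kp, acq, substep = 0.002)
  p_mag <- sim$signals[, "pyr"] / sin(1e-4 * pi / 180)
  l_mag <- sim$signals[, "lac"] / sin(1e-4 * pi / 180)
  area <- simpson(p_mag, 0.02)
  expect_equal(kp$k_pl * area, l_mag[length(l_mag)], tolerance = 1e-6)
})

test_that("multichannel synthesis is seeded with the requested covariance", {
  ph <- make_phantom(c(8, 10, 10), seed = 3)
  acq <- acq_params(n_timepoints = 10)
  clean <- simulate_dataset(ph, acq)
  prof <- make_coil_profiles(4, c(8, 10, 10), seed = 4)
  cov <- matrix(c(1, 0.5, 0, 0, 0.5, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1), 4, 4)
  raw0 <- synthesize_multichannel(clean, prof, noise_model(cov, 0), seed = 5)
  # zero noise: data is exactly profile x signal
  vox <- which(ph$nawm_mask, arr.ind = TRUE)[1, ]
  expect_equal(as.vector(raw0$pyr[2, , vox[1], vox[2], vox[3]]),
               as.vector(prof[2, vox[1], vox[2], vox[3]] *
                           clean$pyr[, vox[1], vox[2], vox[3]]),
               tolerance = 1e-12)
  # pre-arrival frame (t = 2 s < arrival 4 s) is signal-free
  expect_true(1 %in% raw0$noise_frames)
  expect_false(raw0$appended_noise_frame)
  # different seeds give different noise
  raw1 <- synthesize_multichannel(clean, prof, noise_model(cov, 1), seed = 6)
  raw2 <- synthesize_multichannel(clean, prof, noise_model(cov, 1), seed = 7)
  expect_false(identical(raw1$pyr, raw2$pyr))
  expect_identical(raw1$pyr,
                   synthesize_multichannel(clean, prof, noise_model(cov, 1),
                                           seed = 6)$pyr)
  # law of large numbers: empirical covariance of signal-free samples
  nraw <- make_noise_raw(cov, n_timepoints = 30, shape = c(8, 12, 12))
  z <- cbind(matrix(nraw$pyr, 4), matrix(nraw$lac, 4), matrix(nraw$bic, 4))
  emp <- (z %*% Conj(t(z))) / ncol(z)
  expect_lt(max(Mod(emp - cov)), 0.05)
  expect_error(noise_model(matrix(c(1, 2, 2, 1), 2, 2)), "positive-definite")
  expect_error(noise_model(matrix(c(1, 1i, 1i, 1), 2, 2)), "Hermitian")
})

test_that("a dataset with no pre-arrival frames gets an appended noise frame", {
  ph <- make_phantom(c(8, 10, 10), seed = 3)
  acq <- acq_params(n_timepoints = 10, acquisition_delay = 5)
  clean <- simulate_dataset(ph, acq, bolus_params(arrival_time = 1))
  prof <- make_coil_profiles(4, c(8, 10, 10), seed = 4)
  raw <- synthesize_multichannel(clean, prof, noise_model(diag(4) + 0i), seed = 5)
  expect_true(raw$appended_noise_frame)
  expect_identical(raw$noise_frames, 11L)
  expect_equal(dim(raw$pyr)[2], 11L)
})
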