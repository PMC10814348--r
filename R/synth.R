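#' Gamma-variate bolus parameters
#'
#' Parameterizes the synthetic pyruvate input as a gamma-variate,
#' `u(t) = amplitude * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t-t0)/beta)`
#' for `t > t0` and 0 before arrival, normalized so its peak (at
#' `t0 + alpha*beta`) equals `amplitude`. The in-vivo arterial input is not
#' observed by the dynamic acquisition; this smooth unimodal form emulates a
#' 5 mL/s injection followed by a saline flush and cerebral transit. Defaults
#' (arrival 4 s, shape 2.5, scale 4 s) put the magnetization peak near 17 s
#' post injection, typical of adult brain studies.
#'
#' @param arrival_time Bolus arrival time t0 in seconds (default 4).
#' @param alpha Dimensionless gamma shape (> 0, default 2.5).
#' @param beta Gamma scale in seconds (> 0, default 4).
#' @param amplitude Peak input rate in arbitrary signal units (>= 0, default 1).
#' @return An object of class `bolus_params`.
#' @export
bolus_params <- function(arrival_time = 4, alpha = 2.5, beta = 4, amplitude = 1) {
  stopifnot(alpha > 0, beta > 0, amplitude >= 0, is.finite(arrival_time))
  structure(list(arrival_time = arrival_time, alpha = alpha, beta = beta,
                 amplitude = amplitude), class = "bolus_params")
}

#' Evaluate a gamma-variate pyruvate bolus on a time grid
#'
#' @param params A [bolus_params()] object.
#' @param t Non-decreasing numeric vector of times in seconds.
#' @return Numeric vector of input-rate values (>= 0, zero before arrival).
#' @export
simulate_bolus <- function(params, t) {
  stopifnot(inherits(params, "bolus_params"))
  if (length(t) == 0L) return(numeric(0))
  if (is.unsorted(t)) stop("time grid must be non-decreasing")
  u <- t - params$arrival_time
  out <- numeric(length(t))
  pos <- u > 0
  # peak-normalized gamma variate: value 1 at u = alpha*beta
  out[pos] <- params$amplitude *
    (u[pos] / (params$alpha * params$beta))^params$alpha *
    exp(params$alpha - u[pos] / params$beta)
  out
}

#' Kinetic parameters of the two-site exchange model
#'
#' Apparent first-order conversion rates for pyruvate-to-lactate (`k_pl`) and
#' pyruvate-to-bicarbonate (`k_pb`), with longitudinal relaxation times of the
#' three metabolites. Default rates are at the normal-appearing white matter
#' scale (0.015 and 0.003 s^-1). T1 values are assumptions of the synthetic
#' model (30/25/25 s), configurable here and documented in the methods
#' vignette; `Inf` disables relaxation.
#'
#' @param k_pl Pyruvate-to-lactate rate, s^-1 (>= 0).
#' @param k_pb Pyruvate-to-bicarbonate rate, s^-1 (>= 0).
#' @param t1_pyr,t1_lac,t1_bic Longitudinal relaxation times, seconds (> 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_pl = 0.015, k_pb = 0.003,
                           t1_pyr = 30, t1_lac = 25, t1_bic = 25) {
  if (k_pl < 0 || k_pb < 0) stop("conversion rates must be non-negative")
  stopifnot(t1_pyr > 0, t1_lac > 0, t1_bic > 0)
  structure(list(k_pl = k_pl, k_pb = k_pb, t1_pyr = t1_pyr, t1_lac = t1_lac,
                 t1_bic = t1_bic), class = "kinetic_params")
}

# Closed-form matrix exponential of the two-site exchange generator
#   A = [[-(r1p + kpl + kpb), 0, 0], [kpl, -r1l, 0], [kpb, 0, -r1b]]
# exploiting its lower-triangular structure; the near-degenerate eigenvalue
# case falls back to the t*exp(d*t) limit.
exchange_propagator <- function(dt, k_pl, k_pb, r1p, r1l, r1b) {
  d1 <- -(r1p + k_pl + k_pb); d2 <- -r1l; d3 <- -r1b
  e1 <- exp(d1 * dt); e2 <- exp(d2 * dt); e3 <- exp(d3 * dt)
  g21 <- if (abs(d1 - d2) < 1e-12) k_pl * dt * e1 else k_pl * (e1 - e2) / (d1 - d2)
  g31 <- if (abs(d1 - d3) < 1e-12) k_pb * dt * e1 else k_pb * (e1 - e3) / (d1 - d3)
  matrix(c(e1, g21, g31, 0, e2, 0, 0, 0, e3), 3L, 3L)
}

# Exact one-step update of x' = A x + b u with piecewise-constant input u:
# x(dt) = e^{A dt} x + A^{-1} (e^{A dt} - I) b u. A is invertible whenever
# any relaxation or conversion is active; the singular (pure integrator)
# limit is handled by series expansion on the pyruvate row.
exchange_step <- function(x, dt, u, k_pl, k_pb, r1p, r1l, r1b) {
  Ph <- exchange_propagator(dt, k_pl, k_pb, r1p, r1l, r1b)
  if (u == 0) return(as.vector(Ph %*% x))
  A <- matrix(c(-(r1p + k_pl + k_pb), k_pl, k_pb,
                0, -r1l, 0,
                0, 0, -r1b), 3L, 3L)
  rhs <- (Ph - diag(3)) %*% c(u, 0, 0)
  inc <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(inc)) {
    # degenerate generator: integrate the input by fine substeps
    n <- 64L; h <- dt / n; y <- x
    for (i in seq_len(n)) y <- as.vector(exchange_propagator(h, k_pl, k_pb, r1p, r1l, r1b) %*% y) + c(u * h, 0, 0)
    return(y)
  }
  as.vector(Ph %*% x + inc)
}

#' Forward two-site exchange simulation of a dynamic voxel
#'
#' Evolves pyruvate (P), lactate (L) and bicarbonate (B) magnetization under
#' `dP/dt = -(1/T1_P + k_PL + k_PB) P + u(t)`, `dL/dt = k_PL P - L/T1_L`,
#' `dB/dt = k_PB P - B/T1_B` from injection (t = 0), sampling at the frame
#' times of `acq`. At each frame the recorded signal is `S_X = M_X sin(alpha_X)`
#' and the RF loss `M_X <- M_X cos(alpha_X)` is applied once per metabolite
#' per frame (multi-slice sub-timing folded into the effective per-frame
#' angle). Propagation between samples uses the closed-form solution of the
#' linear system with the input held piecewise-constant on a fine internal
#' grid (`substep` seconds).
#'
#' @param input A [bolus_params()] object, a function of time returning the
#'   input rate, or a numeric vector sampled on `input_times`.
#' @param kp A [kinetic_params()] object.
#' @param acq An [acq_params()] object.
#' @param initial Initial `(P, L, B)` magnetization at t = 0 (default zeros).
#' @param substep Internal integration step in seconds (default 0.05).
#' @param input_times Times for a numeric `input` trace (linear interpolation,
#'   zero outside its support).
#' @return Object of class `voxel_sim`: list with `time`, `signals`
#'   (n x 3 matrix, columns pyr/lac/bic), `magnetization` (post-RF, n x 3),
#'   `acq`, `kp`.
#' @export
simulate_two_site <- function(input, kp, acq, initial = c(0, 0, 0),
                              substep = 0.05, input_times = NULL) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(acq, "acq_params"),
            substep > 0, length(initial) == 3L)
  ufun <-
    if (inherits(input, "bolus_params")) function(t) simulate_bolus(input, t)
    else if (is.function(input)) input
    else if (is.numeric(input)) {
      if (is.null(input_times) || length(input_times) != length(input))
        stop("numeric input requires matching input_times")
      function(t) stats::approx(input_times, input, xout = t, rule = 2,
                                yleft = 0, yright = 0)$y
    } else stop("input must be bolus_params, a function, or a numeric trace")
  tt <- timing(acq)$time
  flips <- deg2rad(c(acq$flip_pyr, acq$flip_lac, acq$flip_bic))
  r1 <- c(1 / kp$t1_pyr, 1 / kp$t1_lac, 1 / kp$t1_bic)
  M <- as.numeric(initial)
  n <- length(tt)
  S <- Mout <- matrix(0, n, 3, dimnames = list(NULL, c("pyr", "lac", "bic")))
  tcur <- 0
  for (i in seq_len(n)) {
    if (tt[i] > tcur) {
      grid <- seq(tcur, tt[i], by = substep)
      if (grid[length(grid)] < tt[i]) grid <- c(grid, tt[i])
      for (k in seq_len(length(grid) - 1L)) {
        dt <- grid[k + 1L] - grid[k]
        u <- ufun((grid[k] + grid[k + 1L]) / 2)
        M <- exchange_step(M, dt, u, kp$k_pl, kp$k_pb, r1[1], r1[2], r1[3])
      }
      tcur <- tt[i]
    }
    S[i, ] <- M * sin(flips)
    M <- M * cos(flips)
    Mout[i, ] <- M
  }
  structure(list(time = tt, signals = S, magnetization = Mout,
                 acq = acq, kp = kp), class = "voxel_sim")
}

#' Digital brain phantom with ROI masks
#'
#' Builds a left-right mirror-symmetric elliptical brain mask on a
#' (slice, row, column) grid with nested gray matter (outer rim), NAWM
#' (interior white matter minus lesion), a T2 lesion and a tumor core placed
#' pseudo-randomly in the left hemisphere. NAWM excludes the lesion and gray
#' matter by construction. The mid-sagittal plane is the column-axis midplane
#' (half-integer center for even column counts).
#'
#' @param shape Integer 3-vector (n_slice, n_row, n_col); every dim >= 8.
#' @param seed Integer seed controlling lesion/tumor placement.
#' @param voxel_mm Voxel size in mm (default 15, the 1.5 cm isotropic
#'   resolution of the 13C grid).
#' @return Object of class `phantom_rois`: logical arrays `brain_mask`,
#'   `gm_mask`, `nawm_mask`, `t2_lesion_mask`, `tumor_mask`, plus
#'   `voxel_mm` and `shape`.
#' @export
make_phantom <- function(shape = c(8, 16, 16), seed = 1, voxel_mm = 15) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must have 3 dims, each >= 8")
  ns <- shape[1]; nr <- shape[2]; nc <- shape[3]
  with_seed(seed, {
    # normalized coordinates in [-1, 1] per axis (voxel centers)
    zs <- (seq_len(ns) - (ns + 1) / 2) / (ns / 2)
    ys <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
    xs <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
    R2 <- outer(outer(zs^2 / 0.9^2, ys^2 / 0.85^2, "+"), xs^2 / 0.8^2, "+")
    brain <- R2 <= 1
    interior <- R2 <= 0.62          # inside the gray-matter rim
    gm <- brain & !interior
    # lesion: ellipsoid blob centered in the left hemisphere (low columns)
    les_c <- c(stats::runif(1, -0.35, 0.35),      # slice
               stats::runif(1, -0.35, 0.35),      # row
               stats::runif(1, -0.55, -0.3))      # column strictly left
    les_r <- stats::runif(3, 0.18, 0.28)
    D2 <- outer(outer((zs - les_c[1])^2 / les_r[1]^2,
                      (ys - les_c[2])^2 / les_r[2]^2, "+"),
                (xs - les_c[3])^2 / les_r[3]^2, "+")
    lesion <- (D2 <= 1) & interior
    tumor <- (D2 <= 0.35) & interior
    nawm <- interior & !lesion
    structure(list(brain_mask = brain, gm_mask = gm, nawm_mask = nawm,
                   t2_lesion_mask = lesion, tumor_mask = tumor,
                   voxel_mm = voxel_mm, shape = shape),
              class = "phantom_rois")
  })
}

#' Tissue kinetic presets for synthetic datasets
#'
#' Per-tissue two-site parameters and relative perfusion (bolus amplitude)
#' used by [simulate_dataset()]: NAWM at the reference 0.015/0.003 s^-1
#' scale, gray matter with higher perfusion and conversion, lesion with
#' elevated k_PL and reduced k_PB, tumor with Warburg-shifted kinetics
#' (high k_PL, minimal k_PB).
#'
#' @return Named list of lists with fields `kp` ([kinetic_params()]) and
#'   `amplitude` (relative bolus amplitude).
#' @export
tissue_presets <- function() {
  list(
    nawm   = list(kp = kinetic_params(0.015, 0.003),  amplitude = 1.0),
    gm     = list(kp = kinetic_params(0.020, 0.004),  amplitude = 1.5),
    lesion = list(kp = kinetic_params(0.020, 0.002),  amplitude = 0.8),
    tumor  = list(kp = kinetic_params(0.030, 0.001),  amplitude = 1.2)
  )
}

#' Noiseless synthetic dynamic metabolite volumes
#'
#' Assigns each phantom voxel a tissue class (tumor > lesion > gm > nawm
#' precedence) and fills the dynamic volumes with the corresponding forward
#' two-site traces, scaled by the tissue's relative bolus amplitude. An
#' optional multiplicative hemispheric perturbation raises all left-hemisphere
#' signal amplitudes to break mirror symmetry.
#'
#' @param phantom A [make_phantom()] object.
#' @param acq An [acq_params()] object.
#' @param bolus A [bolus_params()] object.
#' @param tissues Tissue presets as from [tissue_presets()].
#' @param hemi_perturbation Relative increase of k_PL in the left hemisphere
#'   (default 0 = mirror-symmetric kinetics); used to emulate lateralized
#'   metabolic abnormality when testing the asymmetry statistic. Amplitude
#'   scalings are not used because first-order rate estimates are invariant
#'   to them.
#' @return A `metab_series` object: real arrays `pyr`, `lac`, `bic` of shape
#'   (time, slice, row, col), `time`, `acq`, `phantom`, plus a `truth` list of
#'   per-tissue parameters.
#' @export
simulate_dataset <- function(phantom, acq = acq_params(),
                             bolus = bolus_params(),
                             tissues = tissue_presets(),
                             hemi_perturbation = 0) {
  stopifnot(inherits(phantom, "phantom_rois"))
  dims <- phantom$shape
  n <- acq$n_timepoints
  class_map <- array("", dim = dims)
  class_map[phantom$brain_mask] <- "gm"   # default cortical rim
  class_map[phantom$gm_mask] <- "gm"
  class_map[phantom$nawm_mask] <- "nawm"
  class_map[phantom$t2_lesion_mask] <- "lesion"
  class_map[phantom$tumor_mask] <- "tumor"
  trace_for <- function(ts, left) {
    b <- bolus; b$amplitude <- bolus$amplitude * ts$amplitude
    kp <- ts$kp
    if (left && hemi_perturbation != 0)
      kp <- kinetic_params(kp$k_pl * (1 + hemi_perturbation), kp$k_pb,
                           kp$t1_pyr, kp$t1_lac, kp$t1_bic)
    simulate_two_site(b, kp, acq)$signals
  }
  traces <- lapply(tissues, trace_for, left = FALSE)
  traces_left <- if (hemi_perturbation != 0)
    lapply(tissues, trace_for, left = TRUE) else traces
  arr <- function() array(0, dim = c(n, dims))
  out <- list(pyr = arr(), lac = arr(), bic = arr())
  left_cols <- seq_len(floor(dims[3] / 2))
  for (cls in names(tissues)) {
    vox <- which(class_map == cls, arr.ind = TRUE)
    if (nrow(vox) == 0L) next
    for (m in c("pyr", "lac", "bic")) {
      for (r in seq_len(nrow(vox))) {
        tr <- if (vox[r, 3] %in% left_cols) traces_left[[cls]] else traces[[cls]]
        out[[m]][, vox[r, 1], vox[r, 2], vox[r, 3]] <- tr[, m]
      }
    }
  }
  structure(list(pyr = out$pyr, lac = out$lac, bic = out$bic,
                 time = timing(acq)$time, acq = acq, phantom = phantom,
                 noise_sd = NULL,
                 truth = lapply(tissues, function(ts) ts$kp)),
            class = "metab_series")
}

#' Hermitian channel noise model
#'
#' @param channel_covariance Hermitian positive-definite complex matrix
#'   (n_channels x n_channels) of the circular Gaussian channel noise.
#' @param noise_scale Overall noise amplitude multiplier (default 1).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(channel_covariance, noise_scale = 1) {
  cc <- as.matrix(channel_covariance)
  if (!is.complex(cc)) cc <- cc + 0i
  if (nrow(cc) != ncol(cc) || max(Mod(cc - Conj(t(cc)))) > 1e-8 * max(Mod(cc), 1))
    stop("channel covariance must be Hermitian")
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (min(Re(ev)) <= 0) stop("channel covariance must be positive-definite")
  stopifnot(noise_scale >= 0)
  structure(list(channel_covariance = cc, noise_scale = noise_scale),
            class = "noise_model")
}

#' Synthesize multichannel complex dynamic data
#'
#' Multiplies the noiseless metabolite volumes by complex coil sensitivity
#' profiles and adds correlated circular complex Gaussian noise drawn from
#' the channel covariance. Signal-free samples for covariance estimation are
#' the pre-arrival frames when the acquisition starts before bolus arrival;
#' otherwise a dedicated all-noise frame is appended and flagged.
#'
#' @param series A noiseless `metab_series` from [simulate_dataset()].
#' @param coil_profiles Complex array (channel, slice, row, col) of coil
#'   sensitivities.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draw.
#' @return Object of class `raw_dynamic`: complex arrays `pyr`, `lac`, `bic`
#'   of shape (channel, time, slice, row, col), `acq`, `noise_frames`
#'   (indices of signal-free frames), `appended_noise_frame` flag.
#' @export
synthesize_multichannel <- function(series, coil_profiles, noise, seed = 1) {
  stopifnot(inherits(series, "metab_series"), inherits(noise, "noise_model"))
  dims <- dim(series$pyr)            # (t, s, r, c)
  nch <- dim(coil_profiles)[1]
  if (nch != nrow(noise$channel_covariance))
    stop("channel count of profiles must match covariance dimension")
  if (!all(dim(coil_profiles)[-1] == dims[-1]))
    stop("coil profile grid does not match series grid")
  # signal-free frames: no metabolite signal anywhere in the volume
  framesum <- rowSums(abs(matrix(series$pyr, dims[1]))) +
    rowSums(abs(matrix(series$lac, dims[1]))) +
    rowSums(abs(matrix(series$bic, dims[1])))
  noise_frames <- which(framesum == 0)
  appended <- FALSE
  nt <- dims[1]
  if (length(noise_frames) == 0L) {
    nt <- nt + 1L
    noise_frames <- nt
    appended <- TRUE
  }
  L <- chol_complex(noise$channel_covariance)
  nvox <- prod(dims[-1])
  draw <- function(nsamp) {
    w <- matrix(complex(real = stats::rnorm(nch * nsamp, sd = sqrt(0.5)),
                        imaginary = stats::rnorm(nch * nsamp, sd = sqrt(0.5))),
                nch, nsamp)
    noise$noise_scale * (L %*% w)
  }
  out <- with_seed(seed, {
    lapply(list(pyr = series$pyr, lac = series$lac, bic = series$bic), function(vol) {
      sig <- matrix(0 + 0i, nch, nt * nvox)
      prof <- matrix(coil_profiles, nch, nvox)
      vmat <- matrix(vol, dims[1], nvox)       # time x vox
      for (ti in seq_len(dims[1])) {
        idx <- (seq_len(nvox) - 1L) * nt + ti
        sig[, idx] <- prof * rep(vmat[ti, ], each = nch)
      }
      arr <- sig + draw(nt * nvox)
      dim(arr) <- c(nch, nt, dims[-1])
      arr
    })
  })
  structure(list(pyr = out$pyr, lac = out$lac, bic = out$bic,
                 acq = series$acq, noise_frames = noise_frames,
                 appended_noise_frame = appended,
                 phantom = series$phantom, truth = series$truth),
            class = "raw_dynamic")
}

#' Smooth synthetic coil sensitivity profiles
#'
#' Complex profiles with smoothly varying magnitude and phase, one virtual
#' coil element per array entry, peaking at points spread around the volume
#' periphery.
#'
#' @param n_channels Number of channels.
#' @param shape (slice, row, col) grid dimensions.
#' @param seed Seed for element placement.
#' @return Complex array (channel, slice, row, col).
#' @export
make_coil_profiles <- function(n_channels, shape, seed = 1) {
  shape <- as.integer(shape)
  with_seed(seed, {
    prof <- array(0 + 0i, dim = c(n_channels, shape))
    ang <- seq(0, 2 * pi, length.out = n_channels + 1L)[seq_len(n_channels)]
    ctr <- (shape + 1) / 2
    for (ch in seq_len(n_channels)) {
      cz <- ctr[1]
      cy <- ctr[2] + 0.6 * shape[2] / 2 * sin(ang[ch])
      cx <- ctr[3] + 0.6 * shape[3] / 2 * cos(ang[ch])
      phase <- stats::runif(1, -pi, pi)
      for (s in seq_len(shape[1])) for (r in seq_len(shape[2])) for (cc in seq_len(shape[3])) {
        d2 <- ((s - cz) / shape[1])^2 + ((r - cy) / shape[2])^2 + ((cc - cx) / shape[3])^2
        prof[ch, s, r, cc] <- exp(-2 * d2) * exp(1i * (phase + 0.5 * d2))
      }
    }
    prof
  })
}
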