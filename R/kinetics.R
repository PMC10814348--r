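# Voxelwise inputless two-site kinetic modeling of kPL and kPB.

# Predicted product magnetization trace driven by the measured flip-corrected
# pyruvate. Between frames the product decays by cos(alpha) * exp(-dt/T1) and
# gains k_PX * integral of pyruvate. Two discretizations of the integral:
#  - "expweighted" (default): pyruvate piecewise-linear between its post-RF
#    value at frame i and the measured value at frame i+1, convolved exactly
#    with the product's exp(-(t_{i+1}-tau)/T1) relaxation kernel;
#  - "trapezoid": plain trapezoid of the same endpoints, no kernel weighting.
predict_product <- function(k_px, p_mag, t, flip_p, flip_x, t1_x, x0, integral) {
  n <- length(t)
  x <- numeric(n)
  x[1] <- x0
  cp <- cos(flip_p); cx <- cos(flip_x)
  for (i in seq_len(n - 1L)) {
    dt <- t[i + 1L] - t[i]
    E <- exp(-dt / t1_x)
    a <- p_mag[i] * cp
    if (integral == "trapezoid") {
      integ <- dt * (a + p_mag[i + 1L]) / 2
    } else {
      b <- (p_mag[i + 1L] - a) / dt
      integ <- a * t1_x * (1 - E) + b * (t1_x * dt - t1_x^2 * (1 - E))
    }
    x[i + 1L] <- x[i] * cx * E + k_px * integ
  }
  x
}

#' Inputless kinetic fit of a single voxel
#'
#' Jointly fits the pyruvate-to-lactate and pyruvate-to-bicarbonate rate
#' constants by bounded nonlinear least squares on the lactate and
#' bicarbonate signal traces, using the measured flip-corrected pyruvate
#' magnetization (`S_P / sin(alpha_P)`) as the driving input; no arterial
#' input function is required. Rate-constant errors are the standard errors
#' of the estimates, computed from the residual variance and the local
#' curvature (Gauss-Newton `J^T J`) of the fit, expressed as a fraction of
#' the estimate.
#'
#' @param pyr,lac,bic Numeric signal traces on a common time axis.
#' @param acq An [acq_params()] object supplying the time axis and flips; the
#'   time axis can be overridden with `t`.
#' @param t1 A [kinetic_params()] supplying T1 values (its rates are ignored).
#' @param t Optional explicit frame times (seconds).
#' @param integral `"expweighted"` (default) or `"trapezoid"`; see Details.
#' @param initial `"zero"` (default): product magnetization assumed zero at
#'   the first frame, matching the forward-model convention and reproducing
#'   the documented sensitivity to acquisition delay; `"observed"`: initialize
#'   from the first observed flip-corrected signals (delay-robust variant).
#' @param joint Fit both rates simultaneously (default TRUE); otherwise each
#'   product trace is fitted independently (identical estimates, kept for
#'   comparison).
#' @param bounds Rate bounds in s^-1 (default `c(0, 1)`).
#' @param start Starting value for both rates (default 0.01 s^-1).
#' @return Object of class `kinetic_fit`: `k_pl`, `k_pb`, `k_pl_error`,
#'   `k_pb_error` (fractions of the estimates), `fitted_lac`, `fitted_bic`,
#'   `residual_sse`, `converged`.
#' @export
fit_inputless <- function(pyr, lac, bic, acq, t1 = kinetic_params(),
                          t = NULL, integral = c("expweighted", "trapezoid"),
                          initial = c("zero", "observed"), joint = TRUE,
                          bounds = c(0, 1), start = 0.01) {
  integral <- match.arg(integral)
  initial <- match.arg(initial)
  if (is.null(t)) t <- timing(acq)$time
  n <- length(t)
  if (n < 5L) stop("need at least 5 timepoints")
  if (length(pyr) != n || length(lac) != n || length(bic) != n)
    stop("trace lengths must match the time axis")
  if (!all(is.finite(c(pyr, lac, bic)))) stop("traces contain non-finite values")
  if (all(pyr <= 0)) stop("pyruvate trace carries no signal")
  fl <- deg2rad(c(acq$flip_pyr, acq$flip_lac, acq$flip_bic))
  p_mag <- pyr / sin(fl[1])
  x0 <- if (initial == "observed") c(lac[1] / sin(fl[2]), bic[1] / sin(fl[3]))
        else c(0, 0)
  resid_fn <- function(k) {
    lp <- predict_product(k[1], p_mag, t, fl[1], fl[2], t1$t1_lac, x0[1], integral)
    bp <- predict_product(k[2], p_mag, t, fl[1], fl[3], t1$t1_bic, x0[2], integral)
    c(lp * sin(fl[2]) - lac, bp * sin(fl[3]) - bic)
  }
  sse <- function(k) sum(resid_fn(k)^2)
  if (joint) {
    opt <- stats::optim(c(start, start), sse, method = "L-BFGS-B",
                        lower = bounds[1], upper = bounds[2])
    k <- opt$par
    converged <- opt$convergence == 0L
  } else {
    one <- function(j) {
      f <- function(kj) { k <- c(0, 0); k[j] <- kj
        r <- resid_fn(k); sum(r[if (j == 1) seq_len(n) else n + seq_len(n)]^2) }
      stats::optimize(f, interval = bounds)$minimum
    }
    k <- c(one(1), one(2))
    converged <- TRUE
  }
  r0 <- resid_fn(k)
  sse_val <- sum(r0^2)
  eps <- 1e-7
  J <- vapply(1:2, function(j) {
    kk <- k; kk[j] <- kk[j] + eps
    (resid_fn(kk) - r0) / eps
  }, numeric(length(r0)))
  dof <- max(length(r0) - 2L, 1L)
  s2 <- sse_val / dof
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * s2),
                 error = function(e) c(NA_real_, NA_real_))
  frac <- ifelse(k > 0, se / k, Inf)
  lp <- predict_product(k[1], p_mag, t, fl[1], fl[2], t1$t1_lac, x0[1], integral)
  bp <- predict_product(k[2], p_mag, t, fl[1], fl[3], t1$t1_bic, x0[2], integral)
  structure(list(k_pl = k[1], k_pb = k[2],
                 k_pl_error = frac[1], k_pb_error = frac[2],
                 fitted_lac = lp * sin(fl[2]), fitted_bic = bp * sin(fl[3]),
                 residual_sse = sse_val, converged = converged),
            class = "kinetic_fit")
}

#' Voxelwise kinetic maps
#'
#' Runs [fit_inputless()] in every voxel of `mask`; voxels outside the mask,
#' with no pyruvate signal, or whose fit fails to converge are marked invalid.
#'
#' @param series A real `metab_series`.
#' @param mask Logical (slice, row, col) volume of voxels to fit.
#' @param ... Passed to [fit_inputless()].
#' @return Object of class `kinetic_map`: volumes `k_pl`, `k_pb`,
#'   `k_pl_error`, `k_pb_error` and logical `valid_mask`.
#' @export
fit_maps <- function(series, mask, ...) {
  stopifnot(inherits(series, "metab_series"))
  d <- dim(series$pyr)
  if (!all(dim(mask) == d[-1])) stop("mask shape does not match series grid")
  if (!any(mask)) stop("mask selects no voxels")
  vol <- function() array(NA_real_, dim = d[-1])
  out <- list(k_pl = vol(), k_pb = vol(), k_pl_error = vol(),
              k_pb_error = vol(), valid_mask = array(FALSE, dim = d[-1]))
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    s <- idx[r, 1]; ro <- idx[r, 2]; co <- idx[r, 3]
    p <- series$pyr[, s, ro, co]
    if (all(p <= 0)) next
    fit <- tryCatch(
      fit_inputless(p, series$lac[, s, ro, co], series$bic[, s, ro, co],
                    series$acq, t = series$time, ...),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    out$k_pl[s, ro, co] <- fit$k_pl
    out$k_pb[s, ro, co] <- fit$k_pb
    out$k_pl_error[s, ro, co] <- fit$k_pl_error
    out$k_pb_error[s, ro, co] <- fit$k_pb_error
    out$valid_mask[s, ro, co] <- TRUE
  }
  structure(out, class = "kinetic_map")
}

#' Restrict a kinetic map to voxels with acceptable fit errors
#'
#' Keeps voxels whose fractional rate error does not exceed `max_fraction`
#' (boundary retained: a voxel at exactly 25% passes the default filter).
#' The k_PL error is always applied; the k_PB error additionally when
#' `require_bic = TRUE`.
#'
#' @param map A `kinetic_map`.
#' @param max_fraction Maximum fractional error (default 0.25).
#' @param require_bic Also threshold on the k_PB error (default FALSE).
#' @return The map with `valid_mask` restricted.
#' @export
threshold_errors <- function(map, max_fraction = 0.25, require_bic = FALSE) {
  stopifnot(inherits(map, "kinetic_map"))
  keep <- map$valid_mask & !is.na(map$k_pl_error) &
    map$k_pl_error <= max_fraction
  if (require_bic)
    keep <- keep & !is.na(map$k_pb_error) & map$k_pb_error <= max_fraction
  map$valid_mask <- keep & !is.na(keep)
  map$valid_mask[is.na(map$valid_mask)] <- FALSE
  map
}

#' Regional kinetic summary over a partial-volume ROI
#'
#' Averages the rate constants over valid voxels whose ROI volume fraction
#' strictly exceeds `min_fraction` (the >30% normal-appearing-white-matter
#' rule by default).
#'
#' @param map A `kinetic_map`.
#' @param roi_fraction (slice, row, col) volume of per-voxel ROI fractions
#'   in `[0, 1]` (see [roi_fraction()]).
#' @param min_fraction Strict lower bound on the fraction (default 0.30).
#' @return List with `k_pl`, `k_pb` (each mean, sd) and `n`.
#' @export
regional_kinetics <- function(map, roi_fraction, min_fraction = 0.30) {
  stopifnot(inherits(map, "kinetic_map"))
  if (!all(dim(roi_fraction) == dim(map$k_pl)))
    stop("fraction volume does not match map grid")
  sel <- map$valid_mask & roi_fraction > min_fraction
  if (!any(sel)) stop("no voxels qualify at this ROI fraction threshold")
  list(k_pl = c(mean = mean(map$k_pl[sel]), sd = stats::sd(map$k_pl[sel])),
       k_pb = c(mean = mean(map$k_pb[sel]), sd = stats::sd(map$k_pb[sel])),
       n = sum(sel))
}
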