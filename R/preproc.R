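# Multichannel post-processing chain: prewhitening, pyruvate-weighted channel
# combination, zero-order phasing, HOSVD denoising and SNR-thresholded AUC maps.

# Complex Cholesky factorization A = L L^H (L lower triangular).
# base::chol is real-only; channel counts are small so a direct loop is fine.
chol_complex <- function(A) {
  n <- nrow(A)
  L <- matrix(0 + 0i, n, n)
  for (j in seq_len(n)) {
    s <- Re(A[j, j]) - sum(Mod(L[j, seq_len(j - 1L)])^2)
    if (s <= 0) stop("matrix is not positive-definite")
    L[j, j] <- sqrt(s)
    if (j < n) for (i in (j + 1L):n) {
      L[i, j] <- (A[i, j] - sum(L[i, seq_len(j - 1L)] *
                                  Conj(L[j, seq_len(j - 1L)]))) / L[j, j]
    }
  }
  L
}

#' Estimate the channel noise covariance from signal-free samples
#'
#' Pools all voxels of every metabolite at the designated noise frames and
#' forms the sample covariance `Z Z^H / N` across channels. A Hermitian
#' positive-semidefinite estimate that is numerically singular (e.g. from a
#' duplicated channel) is regularized to positive-definite by adding
#' `eps * trace / n` to the diagonal.
#'
#' @param raw A `raw_dynamic` object with designated `noise_frames`.
#' @param eps Diagonal regularization fraction (default 1e-9).
#' @return A [noise_model()] with the estimated covariance.
#' @export
estimate_noise_covariance <- function(raw, eps = 1e-9) {
  stopifnot(inherits(raw, "raw_dynamic"))
  if (length(raw$noise_frames) == 0L)
    stop("no noise frames designated in this dataset")
  nch <- dim(raw$pyr)[1]
  samples <- do.call(cbind, lapply(list(raw$pyr, raw$lac, raw$bic), function(a) {
    d <- dim(a)
    mm <- a
    dim(mm) <- c(d[1], d[2], prod(d[-(1:2)]))   # ch x t x vox
    matrix(mm[, raw$noise_frames, , drop = FALSE], nch)
  }))
  nsamp <- ncol(samples)
  if (nsamp < 10L * nch)
    stop("need at least 10 signal-free samples per channel (have ",
         nsamp, " for ", nch, " channels)")
  mu <- rowMeans(samples)
  zc <- samples - mu
  cc <- (zc %*% Conj(t(zc))) / (nsamp - 1L)
  cc <- (cc + Conj(t(cc))) / 2
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (min(Re(ev)) <= eps * Re(sum(diag(cc))) / nch)
    cc <- cc + diag(eps * Re(sum(diag(cc))) / nch, nch)
  noise_model(cc)
}

#' Prewhiten multichannel data via Cholesky decomposition
#'
#' Left-multiplies the channel dimension by the inverse Cholesky factor
#' `L^-1` (where `cov = L L^H`), so the noise covariance of the output's
#' signal-free samples is the identity.
#'
#' @param raw A `raw_dynamic` object.
#' @param noise A [noise_model()] whose covariance matches the channel count.
#' @return A prewhitened `raw_dynamic`.
#' @export
prewhiten <- function(raw, noise) {
  stopifnot(inherits(raw, "raw_dynamic"), inherits(noise, "noise_model"))
  nch <- dim(raw$pyr)[1]
  if (nrow(noise$channel_covariance) != nch)
    stop("covariance dimension does not match channel count")
  W <- solve(chol_complex(noise$channel_covariance))
  out <- raw
  for (m in c("pyr", "lac", "bic")) {
    d <- dim(raw[[m]])
    mat <- matrix(raw[[m]], nch)
    res <- W %*% mat
    dim(res) <- d
    out[[m]] <- res
  }
  out$prewhitened <- TRUE
  out
}

#' Combine channels with pyruvate-derived complex weights
#'
#' Per voxel, the combination weights are the conjugate of the time-summed
#' complex pyruvate signal of each channel, normalized to unit norm across
#' channels (a matched filter for prewhitened data). The same voxelwise
#' weights are applied to all three metabolites. Voxels whose pyruvate
#' signal is identically zero get zero output and are flagged.
#'
#' @param raw A prewhitened `raw_dynamic`.
#' @return A complex `metab_series` (stage "combined") with arrays of shape
#'   (time, slice, row, col), plus `undefined_mask` for flagged voxels.
#' @export
combine_channels <- function(raw) {
  stopifnot(inherits(raw, "raw_dynamic"))
  d <- dim(raw$pyr)                 # (ch, t, s, r, c)
  nch <- d[1]; nt <- d[2]; nvox <- prod(d[-(1:2)])
  pmat <- matrix(raw$pyr, nch)      # ch x (t*vox), time fastest after ch
  dim(pmat) <- c(nch, nt, nvox)
  wsum <- apply(pmat, c(1, 3), sum)             # ch x vox time-summed pyruvate
  wn <- sqrt(colSums(Mod(wsum)^2))
  undefined <- wn == 0
  w <- Conj(wsum)
  w[, !undefined] <- sweep(w[, !undefined, drop = FALSE], 2,
                           wn[!undefined], "/")
  w[, undefined] <- 0
  combine1 <- function(a) {
    m <- matrix(a, nch)
    dim(m) <- c(nch, nt, nvox)
    out <- matrix(0 + 0i, nt, nvox)
    for (ch in seq_len(nch))
      out <- out + m[ch, , ] * rep(w[ch, ], each = nt)
    dim(out) <- c(nt, d[-(1:2)])
    out
  }
  undef_mask <- array(undefined, dim = d[-(1:2)])
  structure(list(pyr = combine1(raw$pyr), lac = combine1(raw$lac),
                 bic = combine1(raw$bic),
                 time = timing(raw$acq)$time, acq = raw$acq,
                 noise_frames = raw$noise_frames,
                 appended_noise_frame = isTRUE(raw$appended_noise_frame),
                 undefined_mask = undef_mask,
                 phantom = raw$phantom, truth = raw$truth,
                 stage = "combined", noise_sd = NULL),
            class = "metab_series")
}

#' Zero-order phase correction
#'
#' Per voxel, takes the phase of the combined pyruvate signal at its
#' peak-magnitude timepoint, removes it from all metabolites, and keeps the
#' real part. When noise frames are available the per-volume noise standard
#' deviation of the real channel is estimated from them (and any appended
#' noise frame is then dropped from the series).
#'
#' @param series A complex `metab_series` from [combine_channels()].
#' @return A real-valued `metab_series` with `noise_sd` set when noise frames
#'   were available.
#' @export
phase_correct <- function(series) {
  stopifnot(inherits(series, "metab_series"))
  if (!is.complex(series$pyr)) stop("series is already real-valued")
  d <- dim(series$pyr)
  nt <- d[1]; nvox <- prod(d[-1])
  p <- matrix(series$pyr, nt, nvox)
  pk <- max.col(t(Mod(p)), ties.method = "first")
  ph <- Arg(p[cbind(pk, seq_len(nvox))])
  rot <- exp(-1i * ph)
  out <- series
  for (m in c("pyr", "lac", "bic")) {
    mm <- matrix(out[[m]], nt, nvox)
    mm <- Re(sweep(mm, 2, rot, "*"))
    dim(mm) <- d
    out[[m]] <- mm
  }
  nf <- series$noise_frames
  if (length(nf)) {
    vals <- unlist(lapply(c("pyr", "lac", "bic"), function(m) {
      mm <- matrix(out[[m]], nt, nvox)
      as.vector(mm[nf, , drop = FALSE])
    }))
    out$noise_sd <- stats::sd(vals)
  }
  if (isTRUE(series$appended_noise_frame)) {
    keep <- setdiff(seq_len(nt), nf)
    for (m in c("pyr", "lac", "bic")) {
      mm <- out[[m]]
      out[[m]] <- array(mm[keep, , , , drop = FALSE], dim = c(length(keep), d[-1]))
    }
    out$noise_frames <- integer(0)
    out$appended_noise_frame <- FALSE
  }
  out$stage <- "phased"
  out
}

# ---- higher-order SVD --------------------------------------------------

# unfold array along mode k: rows index mode k, columns the rest
unfold <- function(x, k) {
  d <- dim(x)
  perm <- c(k, setdiff(seq_along(d), k))
  matrix(aperm(x, perm), d[k])
}

# fold a mode-k unfolding back into an array of dims d
fold <- function(m, k, d) {
  perm <- c(k, setdiff(seq_along(d), k))
  aperm(array(m, d[perm]), order(perm))
}

# mode-k product of tensor x with matrix U (rows: new mode-k dim)
ttm <- function(x, U, k) {
  d <- dim(x)
  m <- U %*% unfold(x, k)
  d[k] <- nrow(U)
  fold(m, k, d)
}

#' HOSVD denoising of a dynamic multi-metabolite tensor
#'
#' Stacks the metabolite series into a 5-mode tensor
#' (slice, row, col, time, metabolite), computes the higher-order SVD (mode
#' unfoldings factored by ordinary SVD), truncates each mode factor, and
#' reconstructs. Full ranks reproduce the input to numerical precision.
#'
#' Per-mode ranks come from one of three rules:
#' * an explicit integer vector of length 5;
#' * the default noise-floor rule (when the series carries a `noise_sd`
#'   estimate): mode singular values are kept while they exceed the random-
#'   matrix noise edge `noise_sd * (sqrt(m) + sqrt(n))` of the mode's m x n
#'   unfolding. This retains every mode direction with signal above the
#'   noise level, however the signal energy is distributed, and trims the
#'   noise tail;
#' * a scree criterion retaining the smallest leading set of mode singular
#'   vectors covering `energy` of the squared mode spectrum (used when no
#'   noise estimate exists, or when `rank_spec` is a scalar in (0, 1)).
#'   Beware that with a dominant pyruvate component this rule can truncate
#'   the time and metabolite modes to rank 1 and erase kinetic contrast; the
#'   noise-floor rule is preferred whenever a noise estimate is available.
#'
#' @param series A real `metab_series`.
#' @param rank_spec `NULL` (noise-floor rule, falling back to the scree), a
#'   numeric scalar in (0, 1) used as the scree energy threshold, or an
#'   integer vector of length 5 of per-mode ranks.
#' @param energy Mode-energy fraction for the scree fallback (default 0.95).
#' @return A `metab_series` with denoised volumes (same shape and metadata).
#' @export
hosvd_denoise <- function(series, rank_spec = NULL, energy = 0.95) {
  stopifnot(inherits(series, "metab_series"))
  if (is.complex(series$pyr)) stop("denoising expects phased, real-valued data")
  d4 <- dim(series$pyr)             # (t, s, r, c)
  dims <- c(d4[2], d4[3], d4[4], d4[1], 3L)
  x <- array(0, dims)
  for (i in 1:3) {
    m <- c("pyr", "lac", "bic")[i]
    x[, , , , i] <- aperm(series[[m]], c(2, 3, 4, 1))
  }
  use_scree <- FALSE
  if (is.numeric(rank_spec) && length(rank_spec) == 1L &&
      rank_spec > 0 && rank_spec < 1) {
    energy <- rank_spec
    rank_spec <- NULL
    use_scree <- TRUE
  }
  if (!is.null(rank_spec)) {
    rank_spec <- as.integer(rank_spec)
    if (length(rank_spec) != 5L) stop("rank_spec must have one rank per mode")
    if (any(rank_spec < 1L) || any(rank_spec > dims))
      stop("ranks must be between 1 and the mode dimension")
  } else if (!use_scree && is.null(series$noise_sd)) {
    use_scree <- TRUE
  }
  U <- vector("list", 5L)
  for (k in 1:5) {
    m <- unfold(x, k)
    s <- svd(m)
    r <- if (!is.null(rank_spec)) {
      rank_spec[k]
    } else if (use_scree) {
      en <- cumsum(s$d^2) / sum(s$d^2)
      which(en >= energy)[1]
    } else {
      edge <- series$noise_sd * (sqrt(nrow(m)) + sqrt(ncol(m)))
      max(sum(s$d > edge), 1L)
    }
    U[[k]] <- s$u[, seq_len(r), drop = FALSE]
  }
  core <- x
  for (k in 1:5) core <- ttm(core, Conj(t(U[[k]])), k)
  rec <- core
  for (k in 1:5) rec <- ttm(rec, U[[k]], k)
  out <- series
  for (i in 1:3) {
    m <- c("pyr", "lac", "bic")[i]
    out[[m]] <- aperm(rec[, , , , i], c(4, 1, 2, 3))
  }
  out$stage <- "denoised"
  out
}

#' Area-under-the-curve metabolite maps with SNR threshold
#'
#' Sums each metabolite over time and masks voxels whose AUC SNR exceeds the
#' threshold, with `SNR = AUC / (noise_sd * sqrt(n_timepoints))` (the noise
#' standard deviation of a sum of n independent frames). The inequality is
#' strict: a voxel at exactly the threshold is excluded.
#'
#' @param series A real `metab_series` with `noise_sd` estimated.
#' @param snr_threshold Dimensionless threshold (default 5).
#' @return List with `auc`, `snr` and logical `mask`, each a named list over
#'   pyr/lac/bic of (slice, row, col) volumes, plus `noise_sd` and `n_timepoints`.
#' @export
auc_maps <- function(series, snr_threshold = 5) {
  stopifnot(inherits(series, "metab_series"))
  if (is.null(series$noise_sd))
    stop("noise_sd has not been estimated for this series")
  d <- dim(series$pyr)
  n <- d[1]
  denom <- series$noise_sd * sqrt(n)
  res <- lapply(list(pyr = series$pyr, lac = series$lac, bic = series$bic),
                function(a) {
                  auc <- apply(a, c(2, 3, 4), sum)
                  list(auc = auc, snr = auc / denom,
                       mask = auc / denom > snr_threshold)
                })
  list(auc = lapply(res, `[[`, "auc"),
       snr = lapply(res, `[[`, "snr"),
       mask = lapply(res, `[[`, "mask"),
       noise_sd = series$noise_sd, n_timepoints = n)
}
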