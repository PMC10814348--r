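# Patch-based hemispheric asymmetry statistic on kinetic parameter maps.

# bilinear in-plane interpolation of one slice by a factor of 2;
# output index i' maps to input coordinate (i' + 0.5) / 2 (edge-clamped),
# a grid symmetric under left-right reflection of the output indices.
interp2x_slice <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- pmin(pmax((seq_len(2L * nr) + 0.5) / 2, 1), nr)
  xc <- pmin(pmax((seq_len(2L * nc) + 0.5) / 2, 1), nc)
  i0 <- pmin(floor(xr), nr - 1L); fr <- xr - i0
  j0 <- pmin(floor(xc), nc - 1L); fc <- xc - j0
  a <- m[i0, j0, drop = FALSE]; b <- m[i0 + 1L, j0, drop = FALSE]
  cc <- m[i0, j0 + 1L, drop = FALSE]; d <- m[i0 + 1L, j0 + 1L, drop = FALSE]
  Fr <- matrix(fr, 2L * nr, 2L * nc); Fc <- matrix(fc, 2L * nr, 2L * nc, byrow = TRUE)
  a * (1 - Fr) * (1 - Fc) + b * Fr * (1 - Fc) + cc * (1 - Fr) * Fc + d * Fr * Fc
}

interp2x <- function(vol) {
  d <- dim(vol)
  out <- array(0, dim = c(d[1], 2L * d[2], 2L * d[3]))
  for (s in seq_len(d[1])) out[s, , ] <- interp2x_slice(vol[s, , ])
  out
}

# reflect a (slice, row, col) volume about the column index center jsum/2:
# target column j takes the value at column jsum - j (fill outside support)
reflect_cols <- function(vol, jsum, fill = FALSE) {
  d <- dim(vol)
  out <- array(fill, dim = d)
  src <- jsum - seq_len(d[3])
  ok <- src >= 1L & src <= d[3]
  out[, , ok] <- vol[, , src[ok]]
  out
}

#' Prepare a parameter map for asymmetry scoring
#'
#' Applies the map preparation steps: linear interpolation by a factor of 2
#' in-plane; z-normalization to zero mean and unit standard deviation over the
#' analysis region; a symmetric brain mask (brain intersected with its
#' mirror); and exclusion of the T2 lesion and resection cavity together with
#' their midline reflections, so pathology cannot contribute to the score on
#' either side. The midline is the column-axis center of the brain mask's
#' in-plane bounding box on the interpolated grid.
#'
#' @param kpl_map Numeric (slice, row, col) parameter map.
#' @param brain_mask Logical volume on the same grid.
#' @param lesion_mask,cavity_mask Optional logical volumes to exclude.
#' @return Object of class `prepared_map`: z-normalized `values` on the 2x
#'   in-plane grid, logical `symmetric_mask`, `excluded_mask`, `included`
#'   (symmetric minus excluded), `jsum` (reflection index sum), `degenerate`
#'   flag (constant map).
#' @export
prepare_map <- function(kpl_map, brain_mask, lesion_mask = NULL,
                        cavity_mask = NULL) {
  stopifnot(is.array(kpl_map), length(dim(kpl_map)) == 3L)
  stop_if_not_mask(brain_mask, "brain_mask")
  if (!all(dim(brain_mask) == dim(kpl_map)))
    stop("masks must be on the map grid")
  vals <- interp2x(kpl_map)
  brain2 <- interp2x(brain_mask + 0) >= 0.5
  cols <- which(apply(brain2, 3, any))
  if (length(cols) == 0L) stop("brain mask is empty")
  jsum <- min(cols) + max(cols)
  sym <- brain2 & reflect_cols(brain2, jsum)
  excl <- array(FALSE, dim = dim(brain2))
  for (m in list(lesion_mask, cavity_mask)) {
    if (is.null(m)) next
    stop_if_not_mask(m, "exclusion mask")
    if (!all(dim(m) == dim(kpl_map))) stop("masks must be on the map grid")
    m2 <- interp2x(m + 0) >= 0.5
    excl <- excl | m2 | reflect_cols(m2, jsum)
  }
  included <- sym & !excl
  if (!any(included)) stop("no voxels remain after masking")
  mu <- mean(vals[included])
  sdv <- stats::sd(vals[included])
  degenerate <- !is.finite(sdv) || sdv == 0
  vals <- if (degenerate) array(0, dim = dim(vals)) else (vals - mu) / sdv
  structure(list(values = vals, symmetric_mask = sym, excluded_mask = excl,
                 included = included, jsum = jsum, degenerate = degenerate),
            class = "prepared_map")
}

# candidate points of one slice: included, with the full 3x3 in-plane patch
# inside the included set; returns feature matrix [patch(9), w * coords]
slice_features <- function(vals, inc, s, jsum, w, left) {
  nr <- nrow(inc); nc <- ncol(inc)
  ok <- inc
  ok[c(1, nr), ] <- FALSE; ok[, c(1, nc)] <- FALSE
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nr, nc)
    sh[pmax(1, 1 - dr):pmin(nr, nr - dr), pmax(1, 1 - dc):pmin(nc, nc - dc)] <-
      inc[pmax(1, 1 + dr):pmin(nr, nr + dr), pmax(1, 1 + dc):pmin(nc, nc + dc)]
    ok <- ok & sh
  }
  jmid <- jsum / 2
  side <- if (left) col(inc) < jmid else col(inc) > jmid
  pts <- which(ok & side, arr.ind = TRUE)
  if (nrow(pts) == 0L)
    return(list(f = matrix(0, 0, 11L), pts = pts))
  f <- matrix(0, nrow(pts), 11L)
  dcs <- if (left) 1:-1 else -1:1   # flip left patches along columns
  k <- 1L
  for (dc in dcs) for (dr in -1:1) {
    f[, k] <- vals[cbind(pts[, 1] + dr, pts[, 2] + dc)]
    k <- k + 1L
  }
  f[, 10L] <- w * pts[, 1]
  f[, 11L] <- w * (if (left) jsum - pts[, 2] else pts[, 2])
  list(f = f, pts = pts)
}

#' Local hemispheric asymmetry map
#'
#' For every point p in the left point set P_L (and symmetrically for the
#' right set P_R), the local asymmetry `s(p)` is the minimum Euclidean
#' distance between feature vectors `f_p = [patch(p); w * coord(p)]` and
#' `f_q` over all q on the opposite side, where the patch is the 3 x 3
#' in-plane neighborhood of normalized map values and coordinates are
#' expressed in the mirrored frame (so a perfect mirror pair has coordinate
#' distance zero; left patches are read in mirrored column order for the
#' same reason). Points whose patch overlaps excluded or out-of-mask voxels
#' are skipped. The minimum search is restricted to the same slice by
#' default.
#'
#' @param prepared A [prepare_map()] object.
#' @param w Non-negative empirical coordinate weight (default 1.0, in
#'   interpolated-voxel units). Comparisons across datasets must hold w fixed.
#' @param cross_slice Search the opposite hemisphere across all slices
#'   (adds `w * slice` to the feature vector; default FALSE).
#' @return Object of class `asym_map`: `s_map` (NA where not computed) on the
#'   interpolated grid, and `n_points`.
#' @export
local_asymmetry <- function(prepared, w = 1.0, cross_slice = FALSE) {
  stopifnot(inherits(prepared, "prepared_map"))
  if (w < 0) stop("coordinate weight w must be non-negative")
  d <- dim(prepared$values)
  s_map <- array(NA_real_, dim = d)
  slice_ids <- seq_len(d[1])
  feats <- lapply(slice_ids, function(s) list(
    L = slice_features(prepared$values[s, , ], prepared$included[s, , ],
                       s, prepared$jsum, w, left = TRUE),
    R = slice_features(prepared$values[s, , ], prepared$included[s, , ],
                       s, prepared$jsum, w, left = FALSE)))
  get_side <- function(side) {
    fs <- lapply(slice_ids, function(s) {
      f <- feats[[s]][[side]]
      if (cross_slice && nrow(f$f) > 0)
        cbind(f$f, w * s) else f$f
    })
    if (cross_slice) do.call(rbind, fs) else fs
  }
  min_dist <- function(fp, fq) {
    # rows of fp against rows of fq: min Euclidean distance per row of fp.
    # The sum-of-squares expansion locates the argmin; the distance itself is
    # recomputed directly so mirror-identical pairs give an exact zero.
    cross <- fp %*% t(fq)
    d2 <- outer(rowSums(fp^2), rowSums(fq^2), "+") - 2 * cross
    best <- max.col(-d2, ties.method = "first")
    sqrt(rowSums((fp - fq[best, , drop = FALSE])^2))
  }
  for (s in slice_ids) {
    for (side in c("L", "R")) {
      fp <- feats[[s]][[side]]
      if (nrow(fp$f) == 0L) next
      fq <- if (cross_slice) {
        other <- get_side(if (side == "L") "R" else "L")
        other
      } else feats[[s]][[if (side == "L") "R" else "L"]]$f
      fpf <- if (cross_slice) cbind(fp$f, w * s) else fp$f
      if (is.null(dim(fq)) || nrow(fq) == 0L) next
      sv <- min_dist(fpf, fq)
      s_map[cbind(s, fp$pts[, 1], fp$pts[, 2])] <- sv
    }
  }
  structure(list(s_map = s_map, n_points = sum(!is.na(s_map))),
            class = "asym_map")
}

#' Global asymmetry score
#'
#' Arithmetic mean of the local asymmetry over all computed points of both
#' hemispheres, `S = (1/N) * sum s(p)`; `S = 0` indicates perfect left-right
#' correspondence of the included map values, larger values a relative
#' measure of hemispheric asymmetry. Also reported per slice.
#'
#' @param asym An `asym_map` from [local_asymmetry()].
#' @return List with `S`, `n`, and `per_slice` (named numeric, NA for slices
#'   without computable points).
#' @export
global_asymmetry <- function(asym) {
  stopifnot(inherits(asym, "asym_map"))
  vals <- asym$s_map
  if (all(is.na(vals))) stop("no computable asymmetry points (N = 0)")
  per_slice <- apply(vals, 1, function(sl)
    if (all(is.na(sl))) NA_real_ else mean(sl, na.rm = TRUE))
  list(S = mean(vals, na.rm = TRUE), n = sum(!is.na(vals)),
       per_slice = per_slice)
}

#' Hemispheric asymmetry of a parameter map (one call)
#'
#' Convenience wrapper: [prepare_map()], [local_asymmetry()] and
#' [global_asymmetry()].
#'
#' @inheritParams prepare_map
#' @inheritParams local_asymmetry
#' @return List with `S`, `per_slice`, `n`, `s_map` and the `prepared` map.
#' @export
hemispheric_asymmetry <- function(kpl_map, brain_mask, lesion_mask = NULL,
                                  cavity_mask = NULL, w = 1.0,
                                  cross_slice = FALSE) {
  prep <- prepare_map(kpl_map, brain_mask, lesion_mask, cavity_mask)
  la <- local_asymmetry(prep, w = w, cross_slice = cross_slice)
  ga <- global_asymmetry(la)
  list(S = ga$S, per_slice = ga$per_slice, n = ga$n, s_map = la$s_map,
       prepared = prep)
}
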