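# NIfTI / JSON / CSV input-output for series, maps and prescriptions.

acq_to_list <- function(acq) unclass(acq)

acq_from_list <- function(x) do.call(acq_params, x[names(formals(acq_params))])

# (t, s, r, c) internal layout <-> (x=col, y=row, z=slice, t) NIfTI layout
series_to_nifti_array <- function(a) aperm(a, c(4, 3, 2, 1))
nifti_array_to_series <- function(a) aperm(a, c(4, 3, 2, 1))

#' Write a metabolite series as NIfTI volumes with a JSON sidecar
#'
#' One 4-D (x, y, z, t) NIfTI file per metabolite (`<prefix>_pyr.nii` etc.,
#' x = column, y = row, z = slice) plus `<prefix>.json` holding the
#' acquisition parameters, time axis, noise estimate and noise-frame indices.
#'
#' @param series A real `metab_series`.
#' @param prefix Output path prefix.
#' @param voxel_mm Voxel size recorded in the NIfTI header (default 15).
#' @return Invisibly, the written file paths.
#' @export
write_metab_series <- function(series, prefix, voxel_mm = 15) {
  stopifnot(inherits(series, "metab_series"))
  if (is.complex(series$pyr)) stop("write phased (real) series only")
  paths <- character(0)
  for (m in c("pyr", "lac", "bic")) {
    img <- RNifti::asNifti(series_to_nifti_array(series[[m]]),
                           pixdim = c(rep(voxel_mm, 3), series$acq$temporal_resolution))
    p <- paste0(prefix, "_", m, ".nii")
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  side <- list(acq = acq_to_list(series$acq), time = series$time,
               noise_sd = series$noise_sd,
               noise_frames = series$noise_frames)
  jp <- paste0(prefix, ".json")
  jsonlite::write_json(side, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}

#' Read a metabolite series written by [write_metab_series()]
#'
#' @param prefix Path prefix used at write time.
#' @return A real `metab_series`.
#' @export
read_metab_series <- function(prefix) {
  jp <- paste0(prefix, ".json")
  if (!file.exists(jp)) stop("sidecar not found: ", jp)
  side <- jsonlite::read_json(jp, simplifyVector = TRUE)
  acq <- acq_from_list(side$acq)
  vols <- lapply(c("pyr", "lac", "bic"), function(m) {
    p <- paste0(prefix, "_", m, ".nii")
    if (!file.exists(p)) stop("missing volume: ", p)
    nifti_array_to_series(array(RNifti::readNifti(p),
                                dim = dim(RNifti::readNifti(p))))
  })
  names(vols) <- c("pyr", "lac", "bic")
  if (!all(dim(vols$pyr) == dim(vols$lac)) ||
      !all(dim(vols$pyr) == dim(vols$bic)))
    stop("metabolite volumes disagree in shape")
  structure(list(pyr = vols$pyr, lac = vols$lac, bic = vols$bic,
                 time = as.numeric(side$time), acq = acq,
                 noise_sd = if (is.null(side$noise_sd)) NULL else side$noise_sd,
                 noise_frames = as.integer(side$noise_frames %||% integer(0))),
            class = "metab_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a kinetic map as NIfTI volumes
#'
#' Writes `k_pl`, `k_pb`, the fractional error maps and the validity mask as
#' 3-D NIfTI volumes (`<prefix>_kpl.nii`, ...).
#'
#' @param map A `kinetic_map`.
#' @param prefix Output path prefix.
#' @param voxel_mm Voxel size in mm.
#' @return Invisibly, the written file paths.
#' @export
write_kinetic_map <- function(map, prefix, voxel_mm = 15) {
  stopifnot(inherits(map, "kinetic_map"))
  comps <- list(kpl = map$k_pl, kpb = map$k_pb, kpl_error = map$k_pl_error,
                kpb_error = map$k_pb_error, valid = map$valid_mask + 0)
  paths <- vapply(names(comps), function(nm) {
    a <- comps[[nm]]
    a[is.na(a)] <- 0
    img <- RNifti::asNifti(aperm(a, c(3, 2, 1)), pixdim = rep(voxel_mm, 3))
    p <- paste0(prefix, "_", nm, ".nii")
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a kinetic map written by [write_kinetic_map()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `kinetic_map` (voxels outside the validity mask set to NA).
#' @export
read_kinetic_map <- function(prefix) {
  rd <- function(nm) {
    p <- paste0(prefix, "_", nm, ".nii")
    if (!file.exists(p)) stop("missing volume: ", p)
    img <- RNifti::readNifti(p)
    aperm(array(img, dim = dim(img)), c(3, 2, 1))
  }
  valid <- rd("valid") > 0.5
  strip <- function(a) { a[!valid] <- NA_real_; a }
  structure(list(k_pl = strip(rd("kpl")), k_pb = strip(rd("kpb")),
                 k_pl_error = strip(rd("kpl_error")),
                 k_pb_error = strip(rd("kpb_error")),
                 valid_mask = valid),
            class = "kinetic_map")
}

#' Write / read an oriented prescription as JSON
#'
#' Schema: `center_mm` (3), `rotation_rowmajor` (9), `extents_mm` (3).
#'
#' @param volume A [prescription_volume()].
#' @param path JSON file path.
#' @return `write_prescription` invisibly returns `path`;
#'   `read_prescription` returns a validated [prescription_volume()].
#' @export
write_prescription <- function(volume, path) {
  stopifnot(inherits(volume, "prescription_volume"))
  jsonlite::write_json(list(center_mm = volume$center,
                            rotation_rowmajor = as.vector(t(volume$rotation)),
                            extents_mm = volume$extents),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_prescription
#' @export
read_prescription <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("center_mm", "rotation_rowmajor", "extents_mm"))
    if (is.null(x[[f]])) stop("prescription JSON missing field: ", f)
  prescription_volume(x$center_mm,
                      matrix(x$rotation_rowmajor, 3, 3, byrow = TRUE),
                      x$extents_mm)
}
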