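#' Acquisition parameters for dynamic HP-13C EPI
#'
#' Describes the dynamic 2D multi-slice EPI schedule used throughout the
#' package: a metabolite-selective readout sampling pyruvate, lactate and
#' bicarbonate once per temporal frame. Defaults correspond to the standard
#' brain protocol: 20 timepoints at 3 s temporal resolution (60 s total),
#' 16 x 16 in-plane matrix over a 24 cm FOV, 1032 us echo spacing, 8 slices,
#' and the (20, 30, 30) degree flip-angle scheme for (Pyr, Lac, Bic).
#'
#' @param n_timepoints Number of temporal frames (default 20).
#' @param temporal_resolution Frame spacing in seconds (default 3).
#' @param acquisition_delay Post-injection delay of the first frame in
#'   seconds (default 2; the protocol used 2 or 5).
#' @param flip_pyr,flip_lac,flip_bic Flip angles in degrees (defaults 20, 30, 30).
#' @param matrix_n In-plane matrix size per axis (default 16).
#' @param fov Field of view in cm (default 24).
#' @param echo_spacing EPI echo spacing in seconds (default 1032e-6).
#' @param n_slices Number of slices (default 8).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(n_timepoints = 20, temporal_resolution = 3,
                       acquisition_delay = 2,
                       flip_pyr = 20, flip_lac = 30, flip_bic = 30,
                       matrix_n = 16, fov = 24, echo_spacing = 1032e-6,
                       n_slices = 8) {
  stopifnot(n_timepoints >= 1, matrix_n >= 1, n_slices >= 1,
            temporal_resolution > 0, echo_spacing > 0, fov > 0,
            acquisition_delay >= 0)
  flips <- c(pyr = flip_pyr, lac = flip_lac, bic = flip_bic)
  if (any(flips <= 0) || any(flips >= 90))
    stop("flip angles must lie strictly between 0 and 90 degrees")
  structure(list(n_timepoints = as.integer(n_timepoints),
                 temporal_resolution = temporal_resolution,
                 acquisition_delay = acquisition_delay,
                 flip_pyr = flip_pyr, flip_lac = flip_lac, flip_bic = flip_bic,
                 matrix_n = as.integer(matrix_n), fov = fov,
                 echo_spacing = echo_spacing, n_slices = as.integer(n_slices)),
            class = "acq_params")
}

#' Sampling schedule of a dynamic acquisition
#'
#' @param acq An [acq_params()] object.
#' @return List with `time` (frame times in seconds,
#'   `t_i = acquisition_delay + i * temporal_resolution`, i = 0..n-1) and
#'   `duration` (total dynamic duration, `n_timepoints * temporal_resolution`).
#' @export
timing <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  list(time = acq$acquisition_delay +
         (seq_len(acq$n_timepoints) - 1) * acq$temporal_resolution,
       duration = acq$n_timepoints * acq$temporal_resolution)
}

#' Pyruvate center frequency from a urea reference
#'
#' A coil-embedded [13C]urea phantom gives the pyruvate center frequency by a
#' fixed chemical-shift offset: `f0_pyr = f_urea + 270` Hz.
#'
#' @param f_urea Urea resonance frequency in Hz.
#' @return Pyruvate center frequency in Hz.
#' @export
f0_from_urea <- function(f_urea) {
  stopifnot(is.numeric(f_urea), all(is.finite(f_urea)))
  f_urea + 270
}

#' Pyruvate center frequency from the water resonance
#'
#' Applies the empirical 1H-13C gyromagnetic conversion ratio 0.251491899 to
#' the proton water center frequency.
#'
#' @param f_water Water center frequency in Hz; must be positive.
#' @return Pyruvate center frequency in Hz.
#' @export
f0_from_water <- function(f_water) {
  stopifnot(is.numeric(f_water), all(is.finite(f_water)))
  if (any(f_water <= 0)) stop("water frequency must be positive")
  f_water * 0.251491899
}

#' Spectral response of the metabolite-selective excitation pulse
#'
#' Gaussian passband model of the spectral-spatial RF pulse: the achieved
#' fractional transverse magnetization at a frequency offset `df` from the
#' passband center is `Mxy(df) = exp(-4 log(2) df^2 / fwhm^2)`, so that the
#' response is 0.5 at `|df| = fwhm / 2`. This is a model of the pulse's
#' passband parameterized by its printed FWHM, not a measured profile; a
#' measured response can be substituted wherever a function of offset is
#' accepted.
#'
#' @param offset Frequency offset(s) from the passband center, Hz.
#' @param fwhm Full width at half maximum of the passband, Hz (default 130).
#' @return Fractional Mxy in `[0, 1]`.
#' @export
excitation_response <- function(offset, fwhm = 130) {
  stopifnot(fwhm > 0)
  exp(-4 * log(2) * offset^2 / fwhm^2)
}

#' Per-voxel bandwidth along the EPI phase-encode direction
#'
#' `1 / (matrix_n * echo_spacing)`; with the default 16 matrix and 1032 us
#' echo spacing this evaluates to 60.562 Hz.
#'
#' @param matrix_n Matrix size along phase encode.
#' @param echo_spacing Echo spacing in seconds.
#' @return Voxel bandwidth in Hz.
#' @export
voxel_bandwidth <- function(matrix_n, echo_spacing) {
  stopifnot(matrix_n >= 1, echo_spacing > 0)
  1 / (matrix_n * echo_spacing)
}

#' Off-resonance pixel shift in the phase-encode direction
#'
#' A frequency offset displaces the image by `offset / voxel_bw` voxels along
#' phase encode. Shifts whose magnitude exceeds half a voxel (the
#' half-bandwidth criterion) are flagged as needing correction.
#'
#' @param offset Frequency offset in Hz (signed).
#' @param voxel_bw Voxel bandwidth in Hz (see [voxel_bandwidth()]).
#' @return List with `shift` (signed fractional voxels) and
#'   `correction_needed` (`TRUE` when `|shift| > 0.5`).
#' @export
pixel_shift <- function(offset, voxel_bw) {
  stopifnot(voxel_bw > 0)
  shift <- offset / voxel_bw
  list(shift = shift, correction_needed = abs(shift) > 0.5)
}

#' Injection quality-control gate
#'
#' Checks a dissolution QC record against the release tolerances:
#' polarization >= 15%; pyruvate concentration 220-280 mM; EPA (electron
#' paramagnetic agent) concentration <= 3.0 uM; pH 5.0-9.0; temperature
#' 25-37 C; volume strictly > 38 mL; and a passed sterilizing-filter bubble
#' point test. Range bounds are inclusive except the volume, which is strict,
#' mirroring the printed inequality symbols.
#'
#' @param record Named list with fields `polarization` (percent),
#'   `pyruvate_concentration` (mM), `epa_concentration` (uM), `ph`,
#'   `temperature` (C), `volume` (mL), `bubble_point_passed` (logical).
#' @return List with `pass` (logical) and `violations` (character vector of
#'   failing parameter names, empty on pass).
#' @export
qc_check <- function(record) {
  fields <- c("polarization", "pyruvate_concentration", "epa_concentration",
              "ph", "temperature", "volume", "bubble_point_passed")
  missing <- setdiff(fields, names(record))
  if (length(missing))
    stop("QC record missing field(s): ", paste(missing, collapse = ", "))
  num <- unlist(record[setdiff(fields, "bubble_point_passed")])
  if (!all(is.finite(num))) stop("QC record contains non-finite values")
  violations <- character()
  if (record$polarization < 15) violations <- c(violations, "polarization")
  if (record$pyruvate_concentration < 220 || record$pyruvate_concentration > 280)
    violations <- c(violations, "pyruvate_concentration")
  if (record$epa_concentration > 3.0) violations <- c(violations, "epa_concentration")
  if (record$ph < 5.0 || record$ph > 9.0) violations <- c(violations, "ph")
  if (record$temperature < 25 || record$temperature > 37)
    violations <- c(violations, "temperature")
  if (!(record$volume > 38)) violations <- c(violations, "volume")
  if (!isTRUE(record$bubble_point_passed)) violations <- c(violations, "bubble_point")
  list(pass = length(violations) == 0L, violations = violations)
}
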