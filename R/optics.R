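#' Confocal acquisition optics settings
#'
#' @param excitation_wavelength_nm Excitation wavelength in nanometres
#'   (> 0).
#' @param numerical_aperture Objective numerical aperture
#'   (0 < NA <= refractive index).
#' @param refractive_index Immersion refractive index (default 1.52, oil
#'   setting used to match the ~1.49 index of the clearing medium).
#' @return An object of class `optics_settings`.
#' @examples
#' optics_settings(561, 0.75, 1.52)
#' @export
optics_settings <- function(excitation_wavelength_nm, numerical_aperture,
                            refractive_index = 1.52) {
  if (excitation_wavelength_nm <= 0) stop("wavelength must be > 0")
  if (numerical_aperture <= 0) stop("numerical aperture must be > 0")
  if (numerical_aperture > refractive_index) {
    stop("numerical aperture cannot exceed the immersion refractive index")
  }
  structure(list(excitation_wavelength_nm = as.numeric(excitation_wavelength_nm),
                 numerical_aperture = as.numeric(numerical_aperture),
                 refractive_index = as.numeric(refractive_index)),
            class = "optics_settings")
}

#' Theoretical lateral resolution (Rayleigh criterion)
#'
#' `0.61 * lambda / NA`, using the excitation wavelength. Both the raw
#' value and the nearest-nanometre rounding are returned so downstream
#' reports never re-round.
#'
#' @param settings An [optics_settings()].
#' @return List with `nm` (unrounded) and `nm_rounded`.
#' @examples
#' lateral_resolution(optics_settings(561, 0.75))$nm_rounded  # 456
#' @export
lateral_resolution <- function(settings) {
  stopifnot(inherits(settings, "optics_settings"))
  nm <- 0.61 * settings$excitation_wavelength_nm / settings$numerical_aperture
  list(nm = nm, nm_rounded = round(nm))
}

#' Theoretical axial resolution (wide-field formula)
#'
#' `2 * n * lambda / NA^2`, using the immersion refractive index and the
#' excitation wavelength.
#'
#' @param settings An [optics_settings()].
#' @return List with `nm` (unrounded) and `nm_rounded`.
#' @examples
#' axial_resolution(optics_settings(561, 0.75, 1.52))$nm_rounded  # 3032
#' @export
axial_resolution <- function(settings) {
  stopifnot(inherits(settings, "optics_settings"))
  nm <- 2 * settings$refractive_index * settings$excitation_wavelength_nm /
    settings$numerical_aperture^2
  list(nm = nm, nm_rounded = round(nm))
}

#' Does the axial sampling satisfy the Nyquist criterion?
#'
#' TRUE when the z-step is smaller than the theoretical axial resolution.
#'
#' @param settings An [optics_settings()].
#' @param z_step Axial slice spacing in micrometres.
#' @return Logical.
#' @export
nyquist_satisfied <- function(settings, z_step) {
  z_step * 1000 < axial_resolution(settings)$nm
}
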