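#' Optical configuration of the off-axis DHM setup
#'
#' Defaults describe a Mach-Zehnder off-axis transmission DHM: a 632.8 nm
#' HeNe source, a 20x / 0.65 NA microscope objective and an 8-bit camera with
#' 5.2 um pixel pitch. The reference beam arrives at a small tilt, encoded as
#' a spatial carrier frequency in cycles/pixel at the camera; the default
#' (0.25, 0.25) separates the +1 diffraction order from the DC term by more
#' than the NA-limited object bandwidth. The default reference amplitude is
#' 3x the (unit) object amplitude so that the object self-interference term
#' `|O|^2` stays well below the cross term inside the sideband window; this
#' keeps numerical refocusing reliable on dense scenes.
#'
#' @param wavelength_um vacuum wavelength in um
#' @param magnification lateral magnification of the imaging objective
#' @param numerical_aperture objective NA, in (0, 1]
#' @param camera_pixel_um camera pixel pitch in um
#' @param bit_depth detector bit depth (integer)
#' @param carrier_cycles_per_px reference-tilt spatial frequency at the
#'   camera, `c(f_col, f_row)` in cycles/pixel; each axis must be below the
#'   Nyquist limit 0.5 and the carrier must be non-zero overall
#' @param reference_amplitude_ratio reference beam amplitude relative to the
#'   (unit) object beam amplitude
#' @param medium_refractive_index refractive index used by free-space
#'   propagation of the reconstruction (1 for air-equivalent paths)
#' @return an `optical_config` object
#' @examples
#' opt <- optical_config()
#' object_pixel_um(opt)  # 5.2 / 20 = 0.26 um at the object plane
#' @export
optical_config <- function(wavelength_um = 0.6328,
                           magnification = 20,
                           numerical_aperture = 0.65,
                           camera_pixel_um = 5.2,
                           bit_depth = 8L,
                           carrier_cycles_per_px = c(0.25, 0.25),
                           reference_amplitude_ratio = 3,
                           medium_refractive_index = 1) {
  stopifnot(is.numeric(wavelength_um), length(wavelength_um) == 1)
  if (wavelength_um <= 0) stop("optics.wavelength_um must be positive")
  if (magnification <= 0) stop("optics.magnification must be positive")
  if (numerical_aperture <= 0 || numerical_aperture > 1)
    stop("optics.numerical_aperture must lie in (0, 1]")
  if (camera_pixel_um <= 0) stop("optics.camera_pixel_um must be positive")
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 16L)
    stop("optics.bit_depth must be an integer in 1..16")
  carrier_cycles_per_px <- as.numeric(carrier_cycles_per_px)
  if (length(carrier_cycles_per_px) != 2)
    stop("optics.carrier_cycles_per_px must have two components")
  if (any(abs(carrier_cycles_per_px) >= 0.5))
    stop("optics.carrier_cycles_per_px must be below Nyquist (|f| < 0.5)")
  if (all(carrier_cycles_per_px == 0))
    stop("optics.carrier_cycles_per_px must be non-zero (off-axis geometry)")
  if (reference_amplitude_ratio <= 0)
    stop("optics.reference_amplitude_ratio must be positive")
  if (medium_refractive_index < 1)
    stop("optics.medium_refractive_index must be >= 1")
  structure(list(wavelength_um = wavelength_um,
                 magnification = magnification,
                 numerical_aperture = numerical_aperture,
                 camera_pixel_um = camera_pixel_um,
                 bit_depth = bit_depth,
                 carrier_cycles_per_px = carrier_cycles_per_px,
                 reference_amplitude_ratio = reference_amplitude_ratio,
                 medium_refractive_index = medium_refractive_index),
            class = "optical_config")
}

#' Object-plane sampling of an optical configuration
#'
#' @param optics an [optical_config()]
#' @return camera pixel pitch demagnified to the object plane, in um/pixel
#' @export
object_pixel_um <- function(optics) {
  optics$camera_pixel_um / optics$magnification
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> %.4g nm, %gx / NA %.2f, %.3g um pitch (%.3g um object px), %d-bit\n",
    x$wavelength_um * 1000, x$magnification, x$numerical_aperture,
    x$camera_pixel_um, object_pixel_um(x), x$bit_depth))
  cat(sprintf("  carrier (%.3g, %.3g) cycles/px, reference ratio %.3g\n",
              x$carrier_cycles_per_px[1], x$carrier_cycles_per_px[2],
              x$reference_amplitude_ratio))
  invisible(x)
}
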