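# Forward optical model: pure-phase object fields, angular-spectrum
# propagation, and off-axis hologram synthesis with detector noise and
# quantization. This is the physics twin of the reconstruction module; the
# two together form the closed loop every accuracy claim is tested on.

#' Complex scalar optical field
#'
#' @param values 2-D complex matrix, the scalar field U(x, y) at one plane
#' @param sampling_um lateral sampling, um/pixel
#' @param plane_z_um axial position of the plane, um
#' @param wavelength_um vacuum wavelength, um
#' @return a `complex_field`
#' @export
complex_field <- function(values, sampling_um, plane_z_um = 0,
                          wavelength_um = 0.6328) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  if (sampling_um <= 0 || wavelength_um <= 0)
    stop("sampling and wavelength must be positive")
  structure(list(values = values, sampling_um = sampling_um,
                 plane_z_um = plane_z_um, wavelength_um = wavelength_um),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %dx%d px, %.3g um/px, z = %.4g um, lambda = %.4g um\n",
              nrow(x$values), ncol(x$values), x$sampling_um, x$plane_z_um,
              x$wavelength_um))
  invisible(x)
}

#' Pure-phase object field exp(i phi)
#'
#' @param phase a [phase_map] or numeric matrix of phases (radians)
#' @param optics an [optical_config()] supplying the object-plane sampling
#'   and wavelength when `phase` is a bare matrix
#' @return unit-amplitude `complex_field` at z = 0
#' @export
phase_to_field <- function(phase, optics = optical_config()) {
  if (inherits(phase, "phase_map")) {
    vals <- phase$values
    sampling <- phase$sampling_um
  } else {
    vals <- phase
    sampling <- object_pixel_um(optics)
  }
  if (!all(is.finite(vals))) stop("phase must be finite")
  complex_field(exp(1i * vals), sampling_um = sampling, plane_z_um = 0,
                wavelength_um = optics$wavelength_um)
}

#' Angular-spectrum propagation
#'
#' Exact scalar free-space propagation over a distance `dz_um`: the field's
#' 2-D spectrum is multiplied by the transfer function
#' `H = exp(i 2 pi dz sqrt((n/lambda)^2 - fx^2 - fy^2))` for propagating
#' components; evanescent components (negative radicand) are zeroed
#' (band-limited propagation, the default) or exponentially damped.
#' The operation is unitary on the propagating band, so
#' `propagate(dz)` followed by `propagate(-dz)` restores the input to
#' numerical precision.
#'
#' An attribute `aliasing_warning` is set (with a one-time [warning()]) when
#' `|dz|` exceeds the guard distance at which the sampled transfer function
#' aliases over the field's occupied band: for the highest occupied spatial
#' frequency `f_occ`, `dz_max = N px sqrt((n/lambda)^2 - f_occ^2) / (2 f_occ)`
#' (the local fringe rate of `H` must stay below the spectral Nyquist step).
#'
#' @param field a [complex_field()]
#' @param dz_um propagation distance, um (sign = direction)
#' @param evanescent `"zero"` or `"decay"`
#' @return the propagated `complex_field` at `plane_z_um + dz_um`
#' @export
propagate_angular_spectrum <- function(field, dz_um,
                                       evanescent = c("zero", "decay")) {
  stopifnot(inherits(field, "complex_field"))
  evanescent <- match.arg(evanescent)
  if (dz_um == 0) return(field)
  n_med <- attr(field, "medium_refractive_index") %||% 1
  lam <- field$wavelength_um / n_med
  px <- field$sampling_um
  nr <- nrow(field$values); nc <- ncol(field$values)
  fy <- fft_freq(nr, px)  # cycles/um along rows
  fx <- fft_freq(nc, px)  # cycles/um along columns
  f2 <- outer(fy^2, fx^2, `+`)
  arg <- (1 / lam)^2 - f2
  kz <- sqrt(pmax(arg, 0))
  H <- exp(2i * pi * dz_um * kz)
  ev <- arg < 0
  if (any(ev)) {
    if (evanescent == "zero") H[ev] <- 0
    else H[ev] <- exp(-2 * pi * abs(dz_um) * sqrt(-arg[ev]))
  }
  S <- fft2(field$values)
  out <- ifft2(S * H)
  res <- complex_field(out, sampling_um = px,
                       plane_z_um = field$plane_z_um + dz_um,
                       wavelength_um = field$wavelength_um)
  A <- Mod(S)
  occupied <- A > 1e-3 * max(A)
  fmag <- sqrt(f2)
  f_occ <- max(fmag[occupied])
  guard <- if (f_occ > 0)
    min(nr, nc) * px * sqrt(max((1 / lam)^2 - f_occ^2, 0)) / (2 * f_occ)
  else Inf
  if (abs(dz_um) > guard) {
    warning("propagation distance ", dz_um,
            " um exceeds the aliasing guard (", signif(guard, 3), " um)")
    attr(res, "aliasing_warning") <- TRUE
  }
  res
}

#' Detector noise description
#'
#' @param photon_scale expected photon count at the mean intensity; `NULL`
#'   disables shot noise (ideal detector)
#' @param read_noise_sigma Gaussian read noise, in photon-count units
#' @param seed integer seed for the noise draw
#' @return a plain list used by [synthesize_hologram()]
#' @export
noise_meta <- function(photon_scale = NULL, read_noise_sigma = 0, seed = 1L) {
  if (!is.null(photon_scale) && photon_scale <= 0)
    stop("photon_scale must be positive (use NULL to disable shot noise)")
  if (read_noise_sigma < 0) stop("read_noise_sigma must be non-negative")
  list(photon_scale = photon_scale, read_noise_sigma = read_noise_sigma,
       seed = as.integer(seed))
}

#' Synthesize an off-axis hologram
#'
#' Propagates the object field by `defocus_um`, interferes it with a tilted
#' plane-wave reference `R = a exp(i 2 pi (f_col x + f_row y))` at the
#' configured carrier frequency, forms the intensity `|O + R|^2`, applies
#' Poisson shot noise and Gaussian read noise, scales so the noise-free mean
#' intensity maps to half the detector full scale, and quantizes to
#' `bit_depth` integers (clipped; the clipped fraction is recorded).
#'
#' @param object_field a [complex_field()] (use a flat field for
#'   `role = "reference"` frames; see [reference_hologram()])
#' @param optics an [optical_config()]
#' @param defocus_um axial offset applied at synthesis time, um
#' @param noise a [noise_meta()]
#' @param role `"object"` or `"reference"`
#' @return a `hologram_frame`: integer `intensity` matrix plus metadata
#' @export
synthesize_hologram <- function(object_field, optics, defocus_um = 0,
                                noise = noise_meta(), role = "object") {
  stopifnot(inherits(object_field, "complex_field"),
            inherits(optics, "optical_config"))
  role <- match.arg(role, c("object", "reference"))
  U <- if (defocus_um != 0)
    propagate_angular_spectrum(object_field, defocus_um)$values
  else object_field$values
  nr <- nrow(U); nc <- ncol(U)
  fc <- optics$carrier_cycles_per_px  # (f_col, f_row)
  xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
  Rw <- optics$reference_amplitude_ratio *
    exp(2i * pi * (fc[1] * xg + fc[2] * yg))
  I <- Mod(U + Rw)^2
  mean_clean <- mean(I)
  if (!is.null(noise$photon_scale)) {
    I <- withr::with_seed(noise$seed, {
      lam <- I / mean_clean * noise$photon_scale
      counts <- rpois(length(lam), lam)
      if (noise$read_noise_sigma > 0)
        counts <- counts + rnorm(length(lam), 0, noise$read_noise_sigma)
      matrix(counts, nr, nc) / noise$photon_scale * mean_clean
    })
  } else if (noise$read_noise_sigma > 0) {
    stop("read noise without a photon_scale has no count units; set photon_scale")
  }
  full <- 2^optics$bit_depth - 1
  q <- round(I * (full / 2) / mean_clean)
  clipped <- mean(q < 0 | q > full)
  q <- pmin(pmax(q, 0), full)
  structure(list(intensity = matrix(as.integer(q), nr, nc),
                 optics = optics, role = role,
                 axial_offset_um = defocus_um, noise_meta = noise),
            clipped_fraction = clipped,
            class = "hologram_frame")
}

#' Synthesize a reference (empty-field) hologram
#'
#' @param optics an [optical_config()]
#' @param dims field size `c(rows, cols)` in pixels
#' @param defocus_um axial offset, um
#' @param noise a [noise_meta()]
#' @return a `hologram_frame` with `role = "reference"`
#' @export
reference_hologram <- function(optics, dims, defocus_um = 0,
                               noise = noise_meta()) {
  flat <- phase_to_field(matrix(0, dims[1], dims[2]), optics)
  synthesize_hologram(flat, optics, defocus_um, noise, role = "reference")
}

#' @export
print.hologram_frame <- function(x, ...) {
  cat(sprintf("<hologram_frame:%s> %dx%d px, %d-bit, range [%d, %d]\n",
              x$role, nrow(x$intensity), ncol(x$intensity),
              x$optics$bit_depth, min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Write / read holograms as 8/16-bit grayscale TIFF
#'
#' Synthesis metadata (role, defocus, noise, optics) is echoed to a JSON
#' sidecar next to the image.
#'
#' @param holo a `hologram_frame`
#' @param path TIFF path
#' @param optics an [optical_config()] used when reading (the sidecar, if
#'   present, overrides carrier/bit-depth fields)
#' @return invisibly, `path` (write) or a `hologram_frame` (read)
#' @export
write_hologram <- function(holo, path) {
  full <- 2^holo$optics$bit_depth - 1
  tiff::writeTIFF(holo$intensity / full, path,
                  bits.per.sample = if (holo$optics$bit_depth <= 8) 8L else 16L)
  side <- list(role = holo$role, axial_offset_um = holo$axial_offset_um,
               noise_meta = holo$noise_meta,
               optics = unclass(holo$optics))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path, optics = optical_config()) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side_path <- paste0(path, ".json")
  role <- "object"; defocus <- 0
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    optics <- do.call(optical_config, side$optics)
    role <- side$role
    defocus <- side$axial_offset_um
  }
  full <- 2^optics$bit_depth - 1
  structure(list(intensity = matrix(as.integer(round(img * full)),
                                    nrow(img), ncol(img)),
                 optics = optics, role = role, axial_offset_um = defocus,
                 noise_meta = NULL),
            class = "hologram_frame")
}

#' Write a complex field as paired float TIFFs (real, imaginary)
#'
#' @param field a [complex_field()]
#' @param prefix path prefix; writes `<prefix>_re.tif` and `<prefix>_im.tif`
#' @return invisibly, the two paths
#' @export
write_complex_field <- function(field, prefix) {
  p1 <- paste0(prefix, "_re.tif"); p2 <- paste0(prefix, "_im.tif")
  write_image_tiff(Re(field$values), p1)
  write_image_tiff(Im(field$values), p2)
  invisible(c(p1, p2))
}
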