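# Hologram -> 3-D reconstruction: Fourier sideband demodulation, optimal
# reference selection, numerical autofocus, circular median filtering,
# reliability-sorted phase unwrapping, and phase-to-height conversion.

#' Wrapped or unwrapped phase map
#'
#' @param values numeric matrix of phases, radians
#' @param wrapped logical; wrapped maps must lie in `[-pi, pi)`
#' @param sampling_um lateral sampling, um/pixel
#' @return a `phase_map`
#' @export
phase_map <- function(values, wrapped, sampling_um) {
  stopifnot(is.matrix(values), is.logical(wrapped), sampling_um > 0)
  if (wrapped && (min(values) < -pi || max(values) >= pi))
    stop("wrapped phase values must lie in [-pi, pi)")
  structure(list(values = values, wrapped = wrapped,
                 sampling_um = sampling_um),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map:%s> %dx%d px, %.3g um/px, range [%.3g, %.3g] rad\n",
              if (x$wrapped) "wrapped" else "unwrapped",
              nrow(x$values), ncol(x$values), x$sampling_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Physical thickness map
#'
#' @param values numeric matrix of optical thickness, um
#' @param sampling_um lateral sampling, um/pixel
#' @param delta_n refractive-index contrast used for the conversion; carried
#'   with the map because volume claims are only physical when delta_n is the
#'   true cell contrast (otherwise heights are optical-thickness equivalents)
#' @return a `height_map`
#' @export
height_map <- function(values, sampling_um, delta_n) {
  stopifnot(is.matrix(values), sampling_um > 0)
  if (!all(is.finite(values))) stop("height values must be finite")
  if (delta_n <= 0) stop("delta_n must be positive")
  structure(list(values = values, sampling_um = sampling_um,
                 delta_n = delta_n),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %dx%d px, %.3g um/px, delta_n %.3g, max %.3g um\n",
              nrow(x$values), ncol(x$values), x$sampling_um, x$delta_n,
              max(x$values)))
  invisible(x)
}

#' Demodulate the off-axis sideband of a hologram
#'
#' Computes the hologram's 2-D spectrum, locates the strongest peak outside a
#' DC exclusion disc, applies a circular window around it, recenters the
#' windowed sideband to zero frequency and inverse-transforms to recover the
#' complex object field. The search is restricted to the half-plane with
#' positive column frequency (ties to positive row frequency) and the
#' demodulated field is conjugated, which yields `+arg(O)` for the synthesis
#' default of a positive carrier.
#'
#' @param holo a `hologram_frame`
#' @param optics an [optical_config()]; supplies the NA band limit used to
#'   cap the window radius
#' @param window_radius window radius in cycles/pixel; default
#'   `min(0.45 * |carrier|, NA band radius)`
#' @param dc_exclude radius of the DC exclusion disc, cycles/pixel
#' @param snr_threshold minimum ratio of the peak magnitude to the median
#'   spectral magnitude; below it the carrier is declared undetectable
#' @return a `complex_field` at object-plane sampling, with attribute
#'   `carrier_cycles_per_px` (detected `c(f_col, f_row)`)
#' @export
extract_sideband <- function(holo, optics = holo$optics,
                             window_radius = NULL, dc_exclude = 0.05,
                             snr_threshold = 5) {
  stopifnot(inherits(holo, "hologram_frame"))
  I <- holo$intensity
  nr <- nrow(I); nc <- ncol(I)
  S <- fft2(I - mean(I))
  fr <- fft_freq(nr)  # rows, cycles/px
  fc <- fft_freq(nc)  # cols, cycles/px
  fr_g <- matrix(rep(fr, nc), nr, nc)
  fc_g <- matrix(rep(fc, each = nr), nr, nc)
  fmag <- sqrt(fr_g^2 + fc_g^2)
  A <- Mod(S)
  search <- (fmag > dc_exclude) & (fc_g > 0 | (fc_g == 0 & fr_g > 0))
  if (!any(search)) stop("no carrier detected: empty search region")
  A_search <- A
  A_search[!search] <- -Inf
  pk <- arrayInd(which.max(A_search), dim(A))
  if (A[pk] <= 0 || A[pk] < snr_threshold * median(A[search]))
    stop("no carrier detected: strongest off-axis peak below the SNR threshold")
  carrier <- c(fc[pk[2]], fr[pk[1]])
  cdist <- sqrt(sum(carrier^2))
  na_band <- optics$numerical_aperture / optics$wavelength_um *
    object_pixel_um(optics)
  if (is.null(window_radius))
    window_radius <- min(0.45 * cdist, na_band)
  if (window_radius <= max(2 / min(nr, nc), cdist - 0.5 + 1e-12) ||
      cdist <= dc_exclude + 2 / min(nr, nc))
    stop("orders overlap: carrier too close to DC for the sideband window")
  S_shift <- circ_shift_to_origin(S, pk[1], pk[2])
  mask <- outer(fr^2, fc^2, `+`) < window_radius^2
  field <- ifft2(S_shift * mask)
  out <- complex_field(Conj(field), sampling_um = object_pixel_um(optics),
                       plane_z_um = 0, wavelength_um = optics$wavelength_um)
  attr(out, "carrier_cycles_per_px") <- carrier
  attr(out, "window_radius") <- window_radius
  out
}

#' Select the optimal reference field
#'
#' For each candidate reference the wrapped phase difference
#' `arg(O conj(R))` is formed; the winner minimizes the residual background
#' roughness, defined as the circular standard deviation of the 3x3
#' circular-median-filtered difference over the background region (default:
#' the whole field).
#'
#' @param object_field the demodulated object `complex_field`
#' @param candidates list of candidate reference `complex_field`s
#' @param background_mask logical matrix marking background pixels, or `NULL`
#' @return `list(index, phase_diff, roughness)`: the winning candidate index,
#'   its wrapped difference as a [phase_map], and all roughness scores (rad)
#' @export
select_reference <- function(object_field, candidates, background_mask = NULL) {
  stopifnot(inherits(object_field, "complex_field"))
  if (inherits(candidates, "complex_field")) candidates <- list(candidates)
  if (length(candidates) == 0) stop("at least one reference candidate is required")
  dims <- dim(object_field$values)
  rough <- numeric(length(candidates))
  diffs <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    R <- candidates[[k]]
    if (!all(dim(R$values) == dims)) stop("candidate ", k, " shape mismatch")
    d <- Arg(object_field$values * Conj(R$values))
    diffs[[k]] <- d
    z <- exp(1i * d)
    zf <- median_filter_cpp(Re(z), 3L) + 1i * median_filter_cpp(Im(z), 3L)
    df <- Arg(zf)
    rough[k] <- circular_sd(if (is.null(background_mask)) df else df[background_mask])
  }
  best <- which.min(rough)
  list(index = best,
       phase_diff = phase_map(wrap_phase(diffs[[best]]), wrapped = TRUE,
                              sampling_um = object_field$sampling_um),
       roughness = rough)
}

#' Numerical autofocus
#'
#' Propagates the field over a grid of axial positions and evaluates a focus
#' metric; for pure-phase objects the normalized amplitude variance
#' `var(|U|) / mean(|U|)^2` is minimal at focus (a phase object in focus has
#' flat amplitude). The grid optimum is refined by parabolic interpolation of
#' the metric.
#'
#' @param field a `complex_field`
#' @param z_range_um `c(min, max)` search interval, um
#' @param n_steps number of grid points (>= 3)
#' @param metric `"amp_var"` (minimize) or `"tamura"` (minimize
#'   `sd(|U|)/mean(|U|)`; equivalent ordering, kept for comparison)
#' @return `list(z_best_um, focus_curve)` with the curve as a data.frame
#'   `(z_um, metric)`
#' @export
autofocus <- function(field, z_range_um = c(-100, 100), n_steps = 21L,
                      metric = c("amp_var", "tamura")) {
  stopifnot(inherits(field, "complex_field"),
            all(is.finite(z_range_um)), length(z_range_um) == 2)
  metric <- match.arg(metric)
  n_steps <- as.integer(n_steps)
  if (n_steps < 3) stop("n_steps must be >= 3")
  zs <- seq(z_range_um[1], z_range_um[2], length.out = n_steps)
  U0 <- fft2(field$values)
  # propagate in the spectral domain once per z without re-doing the forward FFT
  px <- field$sampling_um
  lam <- field$wavelength_um
  nr <- nrow(field$values); nc <- ncol(field$values)
  arg <- (1 / lam)^2 - outer(fft_freq(nr, px)^2, fft_freq(nc, px)^2, `+`)
  kz <- sqrt(pmax(arg, 0))
  band <- arg >= 0
  vals <- vapply(zs, function(z) {
    H <- exp(2i * pi * z * kz) * band
    A <- Mod(ifft2(U0 * H))
    if (metric == "amp_var") var(as.vector(A)) / mean(A)^2
    else sd(as.vector(A)) / mean(A)
  }, numeric(1))
  if (all(!is.finite(vals))) stop("focus metric non-finite over the whole range")
  i <- which.min(vals)
  z_best <- zs[i]
  if (i > 1 && i < length(zs)) {
    y1 <- vals[i - 1]; y2 <- vals[i]; y3 <- vals[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (is.finite(denom) && denom > 0) {
      delta <- 0.5 * (y1 - y3) / denom
      z_best <- zs[i] + delta * (zs[2] - zs[1])
    }
  }
  list(z_best_um = z_best, focus_curve = data.frame(z_um = zs, metric = vals))
}

#' Median-filter a phase map
#'
#' Square median filter of odd side `kernel_px`. Wrapped inputs are filtered
#' on the complex unit circle (real and imaginary parts of `exp(i phi)` are
#' median-filtered separately and the argument re-taken) so that wrap seams
#' at +-pi do not produce spurious jumps; the wrapped flag is preserved.
#'
#' @param phase a [phase_map]
#' @param kernel_px odd kernel side, pixels (default 3)
#' @return the filtered `phase_map`
#' @export
filter_phase <- function(phase, kernel_px = 3L) {
  stopifnot(inherits(phase, "phase_map"))
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1 || kernel_px %% 2 == 0)
    stop("kernel_px must be a positive odd integer")
  if (kernel_px == 1) return(phase)
  if (phase$wrapped) {
    z <- exp(1i * phase$values)
    zf <- median_filter_cpp(Re(z), kernel_px) +
      1i * median_filter_cpp(Im(z), kernel_px)
    phase_map(wrap_phase(Arg(zf)), wrapped = TRUE,
              sampling_um = phase$sampling_um)
  } else {
    phase_map(median_filter_cpp(phase$values, kernel_px), wrapped = FALSE,
              sampling_um = phase$sampling_um)
  }
}

#' Unwrap a wrapped phase map
#'
#' Reliability-sorted region-growing unwrapping (second-difference pixel
#' reliabilities, most reliable edges merged first). Exact (up to one global
#' 2 pi k) on residue-free inputs. The output is anchored by subtracting the
#' multiple of 2 pi nearest to the background median, which keeps the
#' pixel-wise identity `output - input == 0 (mod 2 pi)` while placing the
#' background near zero; residue count is recorded in attribute `residues`.
#'
#' @param phase a wrapped [phase_map]
#' @param background_mask logical matrix of background pixels used for
#'   anchoring (default: whole field)
#' @return the unwrapped `phase_map` (wrapped = FALSE)
#' @export
unwrap_phase <- function(phase, background_mask = NULL) {
  stopifnot(inherits(phase, "phase_map"))
  if (!phase$wrapped) stop("unwrap_phase expects a wrapped phase map")
  res <- count_residues(phase$values)
  uw <- unwrap_herraez_cpp(phase$values)
  bg <- if (is.null(background_mask)) uw else uw[background_mask]
  uw <- uw - 2 * pi * round(median(bg) / (2 * pi))
  out <- phase_map(uw, wrapped = FALSE, sampling_um = phase$sampling_um)
  attr(out, "residues") <- res
  out
}

#' Convert unwrapped phase to physical thickness
#'
#' `h = phi * lambda / (2 pi delta_n)`: the standard quantitative-phase
#' relation between measured phase and optical path difference
#' `OPD = delta_n * h`.
#'
#' @param phase an unwrapped [phase_map]
#' @param delta_n refractive-index contrast (> 0)
#' @param wavelength_um vacuum wavelength, um
#' @return a [height_map] in um
#' @export
phase_to_height <- function(phase, delta_n, wavelength_um = 0.6328) {
  stopifnot(inherits(phase, "phase_map"))
  if (phase$wrapped) stop("phase must be unwrapped before height conversion")
  if (delta_n <= 0) stop("delta_n must be positive")
  height_map(phase$values * wavelength_um / (2 * pi * delta_n),
             sampling_um = phase$sampling_um, delta_n = delta_n)
}

#' Default reconstruction options
#'
#' @param filter_kernel_px median filter kernel (odd), pixels
#' @param autofocus logical; run the numerical focus search
#' @param autofocus_range_um focus search interval, um
#' @param autofocus_steps focus grid size
#' @param delta_n refractive-index contrast for height conversion
#' @param background_quantile quantile of the unwrapped phase below which
#'   pixels are treated as background for tilt/piston calibration
#' @param window_radius sideband window override, cycles/pixel (or `NULL`)
#' @param dc_exclude DC exclusion radius, cycles/pixel
#' @return named list of options for [reconstruct()]
#' @export
reconstruct_options <- function(filter_kernel_px = 3L,
                                autofocus = TRUE,
                                autofocus_range_um = c(-50, 50),
                                autofocus_steps = 11L,
                                delta_n = 0.05,
                                background_quantile = 0.5,
                                window_radius = NULL,
                                dc_exclude = 0.05) {
  list(filter_kernel_px = filter_kernel_px, autofocus = autofocus,
       autofocus_range_um = autofocus_range_um,
       autofocus_steps = autofocus_steps, delta_n = delta_n,
       background_quantile = background_quantile,
       window_radius = window_radius, dc_exclude = dc_exclude)
}

#' Full hologram-to-height reconstruction
#'
#' Composes the pipeline: sideband demodulation of the object and reference
#' holograms, numerical autofocus (object and references propagated to the
#' same plane), optimal-reference phase differencing, 3x3 circular median
#' filtering, reliability-sorted unwrapping, least-squares tilt/piston
#' removal on the background, and phase-to-height conversion.
#'
#' @param object_holo the object `hologram_frame`
#' @param reference_holos one `hologram_frame` or a list of candidates
#' @param optics an [optical_config()]
#' @param options a [reconstruct_options()] list
#' @return `list(height, phase, qc)`: the [height_map], the unwrapped
#'   [phase_map], and a QC record (carrier, chosen reference, z_best,
#'   residues, background roughness, clipped fraction)
#' @export
reconstruct <- function(object_holo, reference_holos,
                        optics = object_holo$optics,
                        options = reconstruct_options()) {
  options <- modifyList(reconstruct_options(), options)
  if (inherits(reference_holos, "hologram_frame"))
    reference_holos <- list(reference_holos)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  O <- stage("extract_sideband",
             extract_sideband(object_holo, optics,
                              window_radius = options$window_radius,
                              dc_exclude = options$dc_exclude))
  refs <- stage("extract_sideband", lapply(reference_holos, function(h)
    extract_sideband(h, optics, window_radius = options$window_radius,
                     dc_exclude = options$dc_exclude)))
  carrier <- attr(O, "carrier_cycles_per_px")
  z_best <- 0
  if (isTRUE(options$autofocus)) {
    af <- stage("autofocus",
                autofocus(O, options$autofocus_range_um, options$autofocus_steps))
    z_best <- af$z_best_um
    if (abs(z_best) > 1e-9) {
      O <- propagate_angular_spectrum(O, z_best)
      refs <- lapply(refs, propagate_angular_spectrum, dz_um = z_best)
    }
  }
  sel <- stage("select_reference", select_reference(O, refs))
  filt <- stage("filter_phase", filter_phase(sel$phase_diff,
                                             options$filter_kernel_px))
  uw <- stage("unwrap_phase", unwrap_phase(filt))
  residues <- attr(uw, "residues")
  # tilt/piston calibration: robust plane fit anchored on the background
  pf <- remove_plane(uw$values)
  vals <- pf$values
  bg <- vals <= quantile(vals, options$background_quantile)
  vals <- vals - median(vals[bg])
  phase_cal <- phase_map(vals, wrapped = FALSE, sampling_um = uw$sampling_um)
  height <- stage("phase_to_height",
                  phase_to_height(phase_cal, options$delta_n,
                                  optics$wavelength_um))
  qc <- list(carrier_cycles_per_px = carrier %||% optics$carrier_cycles_per_px,
             reference_index = sel$index,
             z_best_um = z_best,
             residue_count = residues,
             background_roughness_rad = min(sel$roughness),
             clipped_fraction = attr(object_holo, "clipped_fraction") %||% 0)
  list(height = height, phase = phase_cal, qc = qc)
}
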