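# Shared numerical helpers: FFT conventions, phase wrapping, plane fits.
#
# Conventions (used by every module): arrays are row-major images with pixel
# (0,0) at the top-left (R matrix element [1,1]); spatial frequencies are in
# cycles/pixel or cycles/um with frequency (0,0) stored at array index [1,1]
# (the unshifted DFT layout).

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' DFT sample frequencies in cycles per sample
#'
#' Frequencies in the unshifted DFT order: 0, 1/n, ..., then the negative
#' branch, matching `stats::fft` output layout.
#'
#' @param n number of samples
#' @param d sample spacing (defaults to 1, giving cycles/pixel)
#' @return numeric vector of length `n`
#' @keywords internal
fft_freq <- function(n, d = 1) {
  f <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  f / (n * d)
}

# circularly shift a matrix so that element (i0, j0) moves to (1, 1)
circ_shift_to_origin <- function(x, i0, j0) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 + (i0 - 1)) %% n) + 1,
    ((seq_len(m) - 1 + (j0 - 1)) %% m) + 1, drop = FALSE]
}

#' Wrap phase values into [-pi, pi)
#'
#' @param x numeric vector/matrix of phase values in radians
#' @return wrapped values in `[-pi, pi)`
#' @export
wrap_phase <- function(x) (x + pi) %% (2 * pi) - pi

# circular (wrap-insensitive) standard deviation of phases, in radians
circular_sd <- function(phi) {
  r <- Mod(mean(exp(1i * phi)))
  r <- min(max(r, 1e-12), 1)
  sqrt(-2 * log(r))
}

# Least-squares plane a + b*col + c*row fitted over `mask` and subtracted.
# With robust > 0, the fit is repeated on the lower-residual half so that
# positive objects (cells) do not drag the background plane up.
remove_plane <- function(values, mask = NULL, robust = 2L) {
  n <- nrow(values); m <- ncol(values)
  rowg <- matrix(rep(seq_len(n), m), n, m)
  colg <- matrix(rep(seq_len(m), each = n), n, m)
  if (is.null(mask)) mask <- matrix(TRUE, n, m)
  fit_once <- function(msk) {
    X <- cbind(1, colg[msk], rowg[msk])
    qr.solve(crossprod(X), crossprod(X, values[msk]))
  }
  msk <- mask
  cf <- fit_once(msk)
  for (k in seq_len(robust)) {
    resid <- values - (cf[1] + cf[2] * colg + cf[3] * rowg)
    cutoff <- stats::quantile(resid[mask], 0.5)
    msk <- mask & (resid <= cutoff)
    if (sum(msk) < 16) break
    cf <- fit_once(msk)
  }
  list(values = values - (cf[1] + cf[2] * colg + cf[3] * rowg),
       coefficients = as.numeric(cf), background = msk)
}

#' Count phase residues in a wrapped phase map
#'
#' Sums wrapped differences around every elementary 2x2 loop; a non-zero loop
#' integral (a residue) marks a local 2*pi inconsistency that no unwrapping
#' path can resolve exactly.
#'
#' @param wrapped matrix of wrapped phases (radians)
#' @return integer residue count
#' @export
count_residues <- function(wrapped) {
  n <- nrow(wrapped); m <- ncol(wrapped)
  if (n < 2 || m < 2) return(0L)
  dx <- wrap_phase(wrapped[, -1, drop = FALSE] - wrapped[, -m, drop = FALSE])
  dy <- wrap_phase(wrapped[-1, , drop = FALSE] - wrapped[-n, , drop = FALSE])
  loops <- dx[-n, , drop = FALSE] + dy[, -1, drop = FALSE] -
    dx[-1, , drop = FALSE] - dy[, -m, drop = FALSE]
  sum(abs(loops) > pi)
}

# write a float image as a [0,1]-scaled 32-bit TIFF plus a JSON sidecar with
# the affine offset/scale (tiff stores float samples faithfully only in [0,1])
write_image_tiff <- function(values, path) {
  lo <- min(values); hi <- max(values)
  scale <- if (hi > lo) hi - lo else 1
  suppressWarnings(tiff::writeTIFF((values - lo) / scale, path,
                                   bits.per.sample = 32L))
  jsonlite::write_json(list(offset = lo, scale = scale, dim = dim(values)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    x <- x * meta$scale + meta$offset
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
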