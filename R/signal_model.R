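# Spin-echo forward model in the complex domain, and noise injection at a
# requested mean SNR. All times are milliseconds, signal in arbitrary units.

#' Tissue parameter triple
#'
#' Bundles the three physical parameters that determine the spin-echo signal
#' of a tissue: proton density `rho` (arbitrary units), spin-lattice
#' relaxation time `t1` (ms) and spin-spin relaxation time `t2` (ms).
#'
#' @param rho Proton density, arbitrary units, `>= 0`.
#' @param t1 Spin-lattice relaxation time in ms, `> 0`.
#' @param t2 Spin-spin relaxation time in ms, `> 0`. Physically `t2 <= t1`;
#'   a violation triggers a warning, not an error.
#' @param name Optional tissue name.
#' @return An object of class `tissue_params`.
#' @examples
#' wm <- tissue_params(2.56, 1389, 72.4, name = "white matter")
#' spin_echo_amplitude(wm, te = 80, tr = 3600)
#' @export
tissue_params <- function(rho, t1, t2, name = NULL) {
  stopifnot(is.numeric(rho), is.numeric(t1), is.numeric(t2),
            length(rho) == 1L, length(t1) == 1L, length(t2) == 1L)
  if (!is.finite(rho) || rho < 0) stop("rho must be finite and >= 0")
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be finite and > 0")
  if (!is.finite(t2) || t2 <= 0) stop("t2 must be finite and > 0")
  if (t2 > t1) warning("t2 > t1 is not physical for tissue; proceeding anyway")
  structure(list(rho = rho, t1 = t1, t2 = t2, name = name),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  nm <- if (is.null(x$name)) "tissue" else x$name
  cat(sprintf("<tissue_params> %s: rho = %g a.u., T1 = %g ms, T2 = %g ms\n",
              nm, x$rho, x$t1, x$t2))
  invisible(x)
}

#' Spin-echo acquisition protocol
#'
#' An ordered list of (TE, TR) pairs, one per acquired image. TE is the echo
#' time and TR the repetition time, both in ms and both operator-chosen.
#'
#' @param te Numeric vector of echo times (ms), all `> 0`.
#' @param tr Numeric vector of repetition times (ms), same length as `te`,
#'   with `te < tr` pairwise.
#' @return An object of class `acquisition_protocol` with fields `te`, `tr`
#'   and `m` (the number of images).
#' @examples
#' acquisition_protocol(te = c(80, 80, 155, 155), tr = c(3600, 500, 3600, 500))
#' @export
acquisition_protocol <- function(te, tr) {
  stopifnot(is.numeric(te), is.numeric(tr))
  if (length(te) != length(tr)) stop("te and tr must have the same length")
  if (length(te) < 1L) stop("at least one (TE, TR) pair is required")
  if (any(!is.finite(te)) || any(te <= 0)) stop("all TE must be finite and > 0")
  if (any(!is.finite(tr)) || any(tr <= 0)) stop("all TR must be finite and > 0")
  if (any(te >= tr)) stop("TE must be smaller than TR in every pair")
  structure(list(te = as.numeric(te), tr = as.numeric(tr),
                 m = length(te)), class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %d image(s)\n", x$m))
  cat(paste0("  (TE, TR) ms: ",
             paste(sprintf("(%g, %g)", x$te, x$tr), collapse = ", "), "\n"))
  invisible(x)
}

#' Reference four-image spin-echo protocol
#'
#' The four (TE, TR) combinations used throughout the package's phantom
#' studies: (80, 3600), (80, 500), (155, 3600), (155, 500) ms. Two echo
#' times to encode T2 decay, two repetition times to encode T1 recovery.
#'
#' @return An [acquisition_protocol] with four pairs.
#' @export
default_acquisition_protocol <- function() {
  acquisition_protocol(te = c(80, 80, 155, 155), tr = c(3600, 500, 3600, 500))
}

# vectorised noise-free amplitude; all arguments recycle like base ops
se_amplitude <- function(rho, t1, t2, te, tr) {
  rho * exp(-te / t2) * (1 - exp(-tr / t1))
}

#' Noise-free spin-echo signal amplitude
#'
#' Evaluates the spin-echo magnitude model
#' `rho * exp(-TE/T2) * (1 - exp(-TR/T1))` for a tissue at one or more
#' (TE, TR) settings. The amplitude is proportional to rho, strictly
#' decreasing in TE and strictly increasing in TR.
#'
#' @param tissue A [tissue_params] object.
#' @param te Echo time(s), ms, `> 0`.
#' @param tr Repetition time(s), ms, `> 0`; recycled against `te`.
#' @return Numeric vector of amplitudes (arbitrary units).
#' @examples
#' wm <- tissue_params(2.56, 1389, 72.4)
#' spin_echo_amplitude(wm, 80, 3600)  # ~0.784
#' @export
spin_echo_amplitude <- function(tissue, te, tr) {
  if (!inherits(tissue, "tissue_params"))
    stop("tissue must be a tissue_params object")
  if (any(te <= 0) || any(tr <= 0)) stop("te and tr must be > 0")
  se_amplitude(tissue$rho, tissue$t1, tissue$t2, te, tr)
}

#' Noise standard deviation for a target mean SNR
#'
#' The mean SNR of a complex-valued acquisition is defined here as the mean
#' squared noise-free amplitude over the foreground mask and all images,
#' divided by the total complex-noise power `2 * sigma^2` (real plus
#' imaginary channel), expressed in dB. Given noise-free amplitude maps and
#' a target SNR this returns the per-channel noise standard deviation
#' `sigma = sqrt(mean(|f|^2) * 10^(-snr_db/10) / 2)`.
#'
#' @param amplitude_maps Numeric array: either a matrix or a 3D array with
#'   the image index on the third dimension, holding noise-free amplitudes.
#' @param snr_db Target mean SNR in dB (finite).
#' @param mask Logical matrix selecting the foreground voxels over which
#'   the mean power is taken. Default: voxels with nonzero amplitude in at
#'   least one image.
#' @return Per-channel noise standard deviation (same units as amplitudes).
#' @examples
#' sigma_for_mean_snr(matrix(1, 10, 10), snr_db = 30)  # sqrt(1e-3/2)
#' @export
sigma_for_mean_snr <- function(amplitude_maps, snr_db, mask = NULL) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db))
    stop("snr_db must be a single finite number")
  a <- amplitude_maps
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (length(dim(a)) != 3L) stop("amplitude_maps must be a matrix or 3D array")
  if (is.null(mask)) mask <- apply(a != 0, c(1, 2), any)
  if (!is.logical(mask) || !all(dim(mask) == dim(a)[1:2]))
    stop("mask must be a logical matrix matching the map shape")
  if (!any(mask)) stop("mask selects no voxels")
  p <- mean(a[rep(mask, dim(a)[3])]^2)
  if (p <= 0) stop("all masked amplitudes are zero: SNR undefined")
  sqrt(p * 10^(-snr_db / 10) / 2)
}

#' Set of complex spin-echo images
#'
#' Container for `m` co-registered complex images and the protocol they
#' were acquired with. Images are stored as a complex `rows x cols x m`
#' array.
#'
#' @param images Complex (or numeric) 3D array, third dimension indexing
#'   the acquisitions, or a list of equal-shape matrices.
#' @param protocol An [acquisition_protocol]; its `m` must match the number
#'   of images.
#' @param noise_sigma Per-channel noise standard deviation (a.u.), `>= 0`;
#'   `NA` when unknown.
#' @return An object of class `complex_image_set`.
#' @export
complex_image_set <- function(images, protocol, noise_sigma = NA_real_) {
  if (!inherits(protocol, "acquisition_protocol"))
    stop("protocol must be an acquisition_protocol")
  if (is.list(images)) {
    dims <- unique(lapply(images, dim))
    if (length(dims) != 1L) stop("all images must share the same shape")
    images <- array(unlist(images), dim = c(dims[[1]], length(images)))
  }
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1L))
  if (length(dim(images)) != 3L) stop("images must form a 3D array")
  if (dim(images)[3] != protocol$m)
    stop(sprintf("got %d images but the protocol lists %d (TE, TR) pairs",
                 dim(images)[3], protocol$m))
  if (!is.na(noise_sigma) && noise_sigma < 0) stop("noise_sigma must be >= 0")
  storage.mode(images) <- "complex"
  structure(list(images = images, protocol = protocol,
                 noise_sigma = noise_sigma), class = "complex_image_set")
}

#' @export
print.complex_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<complex_image_set> %d x %d voxels, %d image(s), sigma = %s\n",
              d[1], d[2], d[3],
              if (is.na(x$noise_sigma)) "unknown" else format(x$noise_sigma)))
  invisible(x)
}

#' Simulate a complex spin-echo acquisition
#'
#' Generates `protocol$m` complex images from per-voxel parameter maps: the
#' noise-free amplitude of each voxel follows the spin-echo model, rotated
#' by the voxel phase, with independent zero-mean Gaussian noise of
#' standard deviation `sigma` added to the real and imaginary channels.
#' One phase per voxel is shared across all images.
#'
#' @param rho_map,t1_map,t2_map Numeric matrices of identical shape holding
#'   proton density (a.u.) and relaxation times (ms). Voxels with
#'   `rho_map == 0` contribute pure noise; their `t1`/`t2` values are
#'   ignored (may be any positive placeholder).
#' @param phase_map Phase in radians, matrix of the same shape or a single
#'   number (default 0).
#' @param protocol An [acquisition_protocol].
#' @param sigma Per-channel noise standard deviation, `>= 0`.
#' @param seed Integer seed; the same seed reproduces the noise exactly.
#' @return A [complex_image_set].
#' @export
simulate_acquisition <- function(rho_map, t1_map, t2_map, phase_map = 0,
                                 protocol = default_acquisition_protocol(),
                                 sigma = 0, seed = 1L) {
  shp <- dim(rho_map)
  if (is.null(shp)) stop("rho_map must be a matrix")
  if (!identical(dim(t1_map), shp) || !identical(dim(t2_map), shp))
    stop("rho, t1 and t2 maps must share the same shape")
  if (length(phase_map) == 1L) phase_map <- matrix(phase_map, shp[1], shp[2])
  if (!identical(dim(phase_map), shp)) stop("phase_map shape mismatch")
  if (sigma < 0) stop("sigma must be >= 0")
  t1s <- pmax(t1_map, .Machine$double.eps)
  t2s <- pmax(t2_map, .Machine$double.eps)
  cube <- array(complex(real = 0), dim = c(shp, protocol$m))
  phasor <- exp(1i * phase_map)
  for (k in seq_len(protocol$m)) {
    amp <- se_amplitude(rho_map, t1s, t2s, protocol$te[k], protocol$tr[k])
    cube[, , k] <- amp * phasor
  }
  if (sigma > 0) {
    n <- length(cube)
    noise <- with_seed(seed, complex(real = rnorm(n, sd = sigma),
                                     imaginary = rnorm(n, sd = sigma)))
    cube <- cube + array(noise, dim = dim(cube))
  }
  complex_image_set(cube, protocol, noise_sigma = sigma)
}

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Empirical mean SNR of an image set
#'
#' Measures `10*log10(mean |noise-free amplitude|^2 / (2 sigma^2))` from a
#' simulated set and its known ground-truth amplitudes; the utility used to
#' verify that [sigma_for_mean_snr()] calibrates correctly.
#'
#' @param amplitude_maps Noise-free amplitude array (rows x cols x m).
#' @param sigma Per-channel noise standard deviation.
#' @param mask Logical foreground matrix (default: nonzero amplitude).
#' @return Mean SNR in dB.
#' @export
mean_snr_db <- function(amplitude_maps, sigma, mask = NULL) {
  a <- amplitude_maps
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (is.null(mask)) mask <- apply(a != 0, c(1, 2), any)
  p <- mean(a[rep(mask, dim(a)[3])]^2)
  10 * log10(p / (2 * sigma^2))
}
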