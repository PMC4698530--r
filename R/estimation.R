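# Voxelwise least-squares relaxometry and Cramer-Rao lower bound
# covariances for the (rho, T1, T2) estimators.

#' Default fit bounds
#'
#' Box constraints for the least-squares fit: rho in (0, 20] a.u.,
#' T1 in [100, 12000] ms, T2 in [5, 3000] ms. Wide enough to hold all
#' brain tissues including CSF (T1 ~ 7.4 s, T2 ~ 300 ms) with margin.
#'
#' @return Named list with `rho_max`, `t1` and `t2` ranges.
#' @export
fit_bounds <- function() {
  list(rho_max = 20, t1 = c(100, 12000), t2 = c(5, 3000))
}

#' Per-voxel parameter estimate maps
#'
#' @param rho_hat,t1_hat,t2_hat,phi_hat,residual Numeric matrices.
#' @param mask Logical matrix of voxels carrying valid fits.
#' @return An object of class `estimate_maps`.
#' @export
estimate_maps <- function(rho_hat, t1_hat, t2_hat, phi_hat, residual, mask) {
  shp <- dim(rho_hat)
  for (m in list(t1_hat, t2_hat, phi_hat, residual, mask))
    if (!identical(dim(m), shp)) stop("all maps must share the same shape")
  if (any(residual[mask] < 0, na.rm = TRUE)) stop("residuals must be >= 0")
  structure(list(rho_hat = rho_hat, t1_hat = t1_hat, t2_hat = t2_hat,
                 phi_hat = phi_hat, residual = residual, mask = mask),
            class = "estimate_maps")
}

#' @export
print.estimate_maps <- function(x, ...) {
  cat(sprintf("<estimate_maps> %d x %d, %d fitted voxels\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Least-squares fit of one voxel
#'
#' Estimates (rho, T1, T2, phi) from the M complex observations of a single
#' voxel by minimising `sum_k |y_k - f_k(theta) exp(i phi)|^2`. The phase
#' and the proton density are concentrated out in closed form (for fixed
#' T1, T2 the optimal phase is the angle of `sum_k y_k f_k` and the optimal
#' rho is a ratio of inner products), leaving a 2D search over (T1, T2)
#' that is solved by a log-spaced grid plus Nelder-Mead refinement from the
#' best grid cells. With two unknown relaxation times, one amplitude and
#' one phase, at least two images are required for identifiability.
#'
#' @param observations Complex vector of length `protocol$m`.
#' @param protocol An [acquisition_protocol] with `m >= 2`.
#' @param bounds Fit box, see [fit_bounds()].
#' @param n_grid Grid resolution per relaxation-time axis.
#' @param n_starts Number of grid cells refined by Nelder-Mead.
#' @return List with `tissue` ([tissue_params]), `phi` (radians),
#'   `residual` (L2 norm of the complex residual vector), `converged` and
#'   `background` flags. All-zero observations are flagged `background`
#'   rather than raising an error.
#' @export
fit_voxel <- function(observations, protocol, bounds = fit_bounds(),
                      n_grid = 16L, n_starts = 3L) {
  if (!inherits(protocol, "acquisition_protocol"))
    stop("protocol must be an acquisition_protocol")
  if (protocol$m < 2L)
    stop("at least 2 images are needed to identify (rho, T1, T2, phi)")
  y <- as.complex(observations)
  if (length(y) != protocol$m)
    stop("observation count does not match the protocol")
  r <- cpp_fit_voxels(matrix(y, nrow = 1), protocol$te, protocol$tr,
                      bounds$rho_max, bounds$t1[1], bounds$t1[2],
                      bounds$t2[1], bounds$t2[2],
                      as.integer(n_grid), as.integer(n_starts),
                      600L, 1e-9)
  if (r$background[1])
    return(list(tissue = NULL, phi = 0, residual = 0,
                converged = TRUE, background = TRUE))
  list(tissue = tissue_params(r$rho[1], r$t1[1], r$t2[1]),
       phi = r$phi[1], residual = r$residual[1],
       converged = r$converged[1], background = FALSE)
}

#' Least-squares fit of every masked voxel
#'
#' Applies the single-voxel estimator independently to every voxel in the
#' mask. Voxels are statistically independent, so the result does not
#' depend on evaluation order. Background voxels (all-zero observations)
#' and non-converged fits are dropped from the output mask.
#'
#' @param images A [complex_image_set].
#' @param mask Logical matrix of voxels to fit; default: voxels whose mean
#'   magnitude exceeds zero.
#' @inheritParams fit_voxel
#' @return An [estimate_maps].
#' @export
fit_maps <- function(images, mask = NULL, bounds = fit_bounds(),
                     n_grid = 16L, n_starts = 3L) {
  stopifnot(inherits(images, "complex_image_set"))
  cube <- images$images
  d <- dim(cube)
  if (is.null(mask)) mask <- apply(Mod(cube), c(1, 2), mean) > 0
  if (!is.logical(mask) || !all(dim(mask) == d[1:2]))
    stop("mask must be a logical matrix matching the image shape")
  if (!any(mask)) stop("mask selects no voxels")
  idx <- which(mask)
  Y <- matrix(cube, d[1] * d[2], d[3])[idx, , drop = FALSE]
  p <- images$protocol
  r <- cpp_fit_voxels(Y, p$te, p$tr, bounds$rho_max,
                      bounds$t1[1], bounds$t1[2], bounds$t2[1], bounds$t2[2],
                      as.integer(n_grid), as.integer(n_starts), 600L, 1e-9)
  blank <- matrix(NA_real_, d[1], d[2])
  rho <- t1 <- t2 <- phi <- resid <- blank
  rho[idx] <- r$rho; t1[idx] <- r$t1; t2[idx] <- r$t2
  phi[idx] <- r$phi; resid[idx] <- r$residual
  ok <- matrix(FALSE, d[1], d[2])
  ok[idx] <- r$converged & !r$background
  estimate_maps(rho, t1, t2, phi, resid, ok)
}

#' Fisher information matrix of the complex spin-echo model
#'
#' For M complex observations `y_k = f_k(theta) exp(i phi) + n_k` with
#' i.i.d. circular Gaussian noise of per-channel standard deviation
#' `noise_sigma`, the Fisher information for the parameter vector
#' (rho, T1, T2, phi) is
#' `J_ij = (1/sigma^2) sum_k Re[ (ds_k/dtheta_i)* (ds_k/dtheta_j) ]`
#' with `s_k = f_k exp(i phi)`. The amplitude partials are analytic:
#' `df/drho = f/rho`, `df/dT1 = -rho exp(-TE/T2) exp(-TR/T1) TR/T1^2`,
#' `df/dT2 = f TE/T2^2`, and `ds/dphi = i s`. The phase block decouples
#' from the amplitude block, so phi acts as a clean nuisance parameter.
#'
#' @param tissue A [tissue_params] with `rho > 0`.
#' @param protocol An [acquisition_protocol].
#' @param noise_sigma Per-channel noise standard deviation, `> 0`.
#' @param phi Common phase (radians); does not affect the result.
#' @return Symmetric 4x4 matrix, parameters ordered (rho, T1, T2, phi).
#' @export
fisher_information <- function(tissue, protocol, noise_sigma, phi = 0) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "acquisition_protocol"))
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  if (tissue$rho == 0)
    stop("rho = 0: the rho-derivative direction is undefined")
  te <- protocol$te; tr <- protocol$tr
  f <- se_amplitude(tissue$rho, tissue$t1, tissue$t2, te, tr)
  d_rho <- f / tissue$rho
  d_t1 <- -tissue$rho * exp(-te / tissue$t2) * exp(-tr / tissue$t1) *
    tr / tissue$t1^2
  d_t2 <- f * te / tissue$t2^2
  # complex partials s_k = f_k e^{i phi}: amplitude partials share the
  # phasor, the phi partial is i*s, so cross terms Re[i f df] vanish
  D <- cbind(d_rho, d_t1, d_t2)
  J <- matrix(0, 4, 4)
  J[1:3, 1:3] <- crossprod(D)
  J[4, 4] <- sum(f^2)
  dimnames(J) <- list(c("rho", "t1", "t2", "phi"),
                      c("rho", "t1", "t2", "phi"))
  J / noise_sigma^2
}

#' CRLB covariance of the (rho, T1, T2) estimators
#'
#' Inverts the 4x4 Fisher information and returns the top-left 3x3 block:
#' the lowest covariance attainable by any unbiased estimator of
#' (rho, T1, T2) when the phase is a nuisance parameter. The least-squares
#' estimator is asymptotically efficient under Gaussian noise, so this
#' matrix doubles as the predicted covariance of the fitted maps, and is
#' what the statistical classifiers use as per-class covariance.
#'
#' @inheritParams fisher_information
#' @return Symmetric positive-definite 3x3 matrix (units a.u., ms, ms).
#' @export
crlb_covariance <- function(tissue, protocol, noise_sigma) {
  J <- fisher_information(tissue, protocol, noise_sigma)
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    vec <- eigen(J, symmetric = TRUE)$vectors[, 4]
    dir <- rownames(J)[which.max(abs(vec))]
    stop(sprintf(
      "Fisher information is singular (deficient direction ~ %s); %s",
      dir, "more distinct (TE, TR) pairs are needed"))
  }
  S <- solve(J)[1:3, 1:3]
  (S + t(S)) / 2
}
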