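# Procedural four-tissue brain-slice phantom and multiplicative
# intensity-inhomogeneity (bias) fields.

#' Reference tissue parameters of the four-tissue brain phantom
#'
#' Literature 3T values for white matter, subcortical white matter, gray
#' matter and cerebrospinal fluid:
#' rho = (2.56, 2.67, 2.14, 4.54) a.u., T1 = (1389, 1593, 1794, 7446) ms,
#' T2 = (72.4, 65.5, 95.2, 302) ms.
#'
#' @return A list of four [tissue_params], in the order WM, scWM, GM, CSF.
#' @export
brain_phantom_tissues <- function() {
  list(tissue_params(2.56, 1389, 72.4, name = "white matter"),
       tissue_params(2.67, 1593, 65.5, name = "subcortical white matter"),
       tissue_params(2.14, 1794, 95.2, name = "gray matter"),
       tissue_params(4.54, 7446, 302, name = "cerebrospinal fluid"))
}

#' Ground-truth label map
#'
#' @param labels Integer matrix; 0 is background, 1..N are tissue classes.
#' @param class_names Character vector of N names.
#' @param class_params List of N [tissue_params], parallel to `class_names`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, class_names, class_params) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  n <- length(class_names)
  if (length(class_params) != n)
    stop("class_params must have one entry per class name")
  if (any(labels < 0L) || any(labels > n))
    stop("labels must lie in 0..", n)
  present <- tabulate(labels[labels > 0L], nbins = n)
  if (any(present == 0L))
    stop("every class must occupy at least one voxel; empty: ",
         paste(class_names[present == 0L], collapse = ", "))
  structure(list(labels = labels, class_names = class_names,
                 class_params = class_params), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cnt <- tabulate(x$labels[x$labels > 0L], nbins = length(x$class_names))
  cat(sprintf("<label_map> %d x %d, %d classes\n", d[1], d[2],
              length(x$class_names)))
  for (i in seq_along(x$class_names))
    cat(sprintf("  %d %-26s %6d voxels\n", i, x$class_names[i], cnt[i]))
  invisible(x)
}

#' Synthetic brain-slice phantom
#'
#' Builds a 2D label map that mimics an axial brain slice: an elliptical
#' head filled with white matter, a sinusoidal cortical gray-matter ribbon,
#' subcortical white-matter nuclei, CSF in an outer rim and two ventricles,
#' a one-to-two voxel wide interhemispheric CSF fissure (a deliberately
#' thin structure) and a sprinkle of single-voxel gray-matter islands.
#' Thin and isolated structures are included on purpose: they are what a
#' spatial regularizer can erase, so they make the phantom a stress test
#' rather than a best case.
#'
#' @param shape Integer vector (rows, cols), each `>= 64`.
#' @param geometry_seed Integer seed controlling the ribbon undulation and
#'   the island placement; identical seeds give identical phantoms.
#' @return A [label_map] with classes WM, scWM, GM, CSF carrying the
#'   [brain_phantom_tissues()] parameters.
#' @export
make_brain_phantom <- function(shape = c(160, 160), geometry_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L))
    stop("shape must be at least 64 x 64")
  nr <- shape[1]; nc <- shape[2]
  with_seed(geometry_seed, {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    b <- 0.47 * nr; a <- 0.44 * nc
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    Y <- (yy - cy) / b; X <- (xx - cx) / a
    r <- sqrt(X^2 + Y^2)
    th <- atan2(Y, X)

    lab <- matrix(0L, nr, nc)
    lab[r <= 1] <- 4L                      # outer CSF rim
    lab[r <= 0.93] <- 3L                   # cortical GM shell
    k_rib <- sample(7:11, 1L)
    ph_rib <- runif(1L, 0, 2 * pi)
    ribbon <- 0.72 + 0.06 * sin(k_rib * th + ph_rib)
    lab[r <= ribbon] <- 1L                 # WM core

    in_ell <- function(x0, y0, ax, ay) {
      ((xx - cx - x0 * a) / (ax * a))^2 + ((yy - cy - y0 * b) / (ay * b))^2 <= 1
    }
    # subcortical WM nuclei, one per hemisphere
    lab[in_ell(-0.33, 0.08, 0.15, 0.12) & lab == 1L] <- 2L
    lab[in_ell(0.33, 0.08, 0.15, 0.12) & lab == 1L] <- 2L
    # lateral ventricles: elongated CSF pockets near the midline
    lab[in_ell(-0.12, -0.05, 0.055, 0.2) & lab != 0L] <- 4L
    lab[in_ell(0.12, -0.05, 0.055, 0.2) & lab != 0L] <- 4L
    # interhemispheric fissure: thin vertical CSF channel from the top rim
    fis <- abs(xx - cx) <= 0.5 & Y < -0.28 & r <= ribbon
    lab[fis] <- 4L
    # isolated single-voxel GM islands inside WM
    wm_idx <- which(lab == 1L & r < 0.5)
    isl <- sample(wm_idx, min(8L, length(wm_idx)))
    lab[isl] <- 3L
    label_map(lab,
              class_names = c("WM", "scWM", "GM", "CSF"),
              class_params = brain_phantom_tissues())
  })
}

#' Per-voxel parameter maps of a label map
#'
#' Expands a [label_map] into piecewise-constant rho, T1 and T2 matrices.
#' Background voxels get `rho = 0` and positive placeholder relaxation
#' times (their signal is zero regardless).
#'
#' @param truth A [label_map].
#' @return List with matrices `rho`, `t1`, `t2` and the logical foreground
#'   `mask`.
#' @export
parameter_maps <- function(truth) {
  stopifnot(inherits(truth, "label_map"))
  lab <- truth$labels
  rho <- vapply(truth$class_params, `[[`, numeric(1), "rho")
  t1 <- vapply(truth$class_params, `[[`, numeric(1), "t1")
  t2 <- vapply(truth$class_params, `[[`, numeric(1), "t2")
  idx <- lab + 1L
  list(rho = matrix(c(0, rho)[idx], nrow(lab), ncol(lab)),
       t1 = matrix(c(1000, t1)[idx], nrow(lab), ncol(lab)),
       t2 = matrix(c(100, t2)[idx], nrow(lab), ncol(lab)),
       mask = lab > 0L)
}

#' Multiplicative intensity-inhomogeneity field
#'
#' @param field Positive matrix of multiplicative factors.
#' @param nonuniformity Fractional nonuniformity, e.g. 0.20 for a field
#'   spanning `[0.90, 1.10]`.
#' @return An object of class `bias_field`.
#' @export
bias_field <- function(field, nonuniformity) {
  if (!is.matrix(field) || any(field <= 0)) stop("field must be positive")
  if (nonuniformity < 0 || nonuniformity >= 1)
    stop("nonuniformity must be in [0, 1)")
  # the mean sits close to, but not exactly at, 1; allow 2% slack
  spread <- (max(field) - min(field)) / mean(field)
  if (spread > nonuniformity * 1.02 + 1e-9)
    stop("field spread exceeds the declared nonuniformity")
  structure(list(field = field, nonuniformity = nonuniformity),
            class = "bias_field")
}

#' Generate a smooth multiplicative bias field
#'
#' A low-order 2D polynomial with seeded random coefficients, dominated by
#' its linear (tilt) terms, rescaled to the range
#' `[1 - nonuniformity/2, 1 + nonuniformity/2]`. This follows the common
#' convention in which a "20% inhomogeneity" means intensities modulated
#' between 90% and 110% of nominal. The field models slowly varying coil
#' sensitivity: it multiplies the noise-free signal, so it scales rho
#' estimates but leaves T1 and T2 estimates untouched.
#'
#' @param shape Integer (rows, cols).
#' @param nonuniformity Fraction in `[0, 1)`; 0 returns a flat field.
#' @param seed Integer seed for the polynomial coefficients.
#' @return A [bias_field].
#' @export
make_bias_field <- function(shape, nonuniformity = 0.2, seed = 1L) {
  shape <- as.integer(shape)
  if (nonuniformity < 0) stop("nonuniformity must be >= 0")
  if (nonuniformity >= 1) stop("nonuniformity must be < 1")
  nr <- shape[1]; nc <- shape[2]
  if (nonuniformity == 0)
    return(bias_field(matrix(1, nr, nc), 0))
  with_seed(seed, {
    u <- matrix(seq(-1, 1, length.out = nr), nr, nc)
    v <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
    c_lin <- runif(2, 0.6, 1) * sample(c(-1, 1), 2, replace = TRUE)
    c_hi <- runif(3, -0.15, 0.15)
    g <- c_lin[1] * u + c_lin[2] * v +
      c_hi[1] * u * v + c_hi[2] * u^2 + c_hi[3] * v^2
    g <- (g - min(g)) / (max(g) - min(g))  # [0, 1]
    f <- 1 - nonuniformity / 2 + nonuniformity * g
    bias_field(f, nonuniformity)
  })
}

#' Apply a bias field to an image set
#'
#' Multiplies every image voxelwise by the field. The intended pipeline
#' order is bias before noise injection (the field models coil
#' sensitivity); applying it to an already noisy set scales the noise too.
#'
#' @param images A [complex_image_set].
#' @param field A [bias_field] of matching shape.
#' @return A [complex_image_set] with modulated images.
#' @export
apply_bias <- function(images, field) {
  stopifnot(inherits(images, "complex_image_set"),
            inherits(field, "bias_field"))
  d <- dim(images$images)
  if (!all(dim(field$field) == d[1:2])) stop("field shape mismatch")
  out <- images$images * array(rep(field$field, d[3]), dim = d)
  complex_image_set(out, images$protocol, images$noise_sigma)
}
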