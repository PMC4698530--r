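# Decision criteria in (rho, T1, T2) space: Euclidean baseline, the
# variance-weighted distance criterion (WDC), the full-covariance
# statistical-correlation criterion (StCC), its spatially regularized
# refinement (SpCC) and a K-means baseline on a scalar composite image.

#' Class model for tissue classification
#'
#' Holds, for each of N tissue classes, the centroid vector
#' (rho, T1, T2) and the 3x3 covariance of the parameter estimators.
#' `rho_weight_inflation` (lambda >= 1) inflates the rho variance of every
#' class: values above 1 tell the classifiers to trust the proton density
#' less, the recommended guard when a multiplicative intensity bias is
#' suspected (the bias scales rho estimates but not T1/T2).
#'
#' @param centroids N x 3 numeric matrix, columns (rho, t1, t2).
#' @param covariances List of N symmetric positive-definite 3x3 matrices.
#' @param names Character vector of N class names.
#' @param rho_weight_inflation Lambda `>= 1`, default 1.
#' @return An object of class `class_model`.
#' @export
class_model <- function(centroids, covariances, names = NULL,
                        rho_weight_inflation = 1) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2L) stop("at least 2 classes are required")
  if (ncol(centroids) != 3L) stop("centroids must have 3 columns")
  if (length(covariances) != n)
    stop("one covariance per class is required")
  if (rho_weight_inflation < 1) stop("rho_weight_inflation must be >= 1")
  for (i in seq_len(n)) {
    S <- covariances[[i]]
    if (!is.matrix(S) || !all(dim(S) == 3L) || max(abs(S - t(S))) > 1e-8)
      stop("covariance ", i, " is not a symmetric 3x3 matrix")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("covariance ", i, " is not positive definite")
  }
  if (is.null(names)) names <- paste0("class", seq_len(n))
  dup <- duplicated(round(centroids, 10))
  if (any(dup))
    warning("identical centroids supplied for classes: ",
            paste(which(dup), collapse = ", "),
            " (indistinguishable classes)")
  structure(list(n_classes = n, names = names, centroids = centroids,
                 covariances = covariances,
                 rho_weight_inflation = rho_weight_inflation),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> %d classes, lambda = %g\n",
              x$n_classes, x$rho_weight_inflation))
  for (i in seq_len(x$n_classes))
    cat(sprintf("  %d %-26s mu = (%g, %g, %g)\n", i, x$names[i],
                x$centroids[i, 1], x$centroids[i, 2], x$centroids[i, 3]))
  invisible(x)
}

#' Build a class model from tissue parameters and the CRLB
#'
#' Centroids are the supplied literature/phantom tissue triples; each class
#' covariance is the CRLB covariance of the estimators evaluated at that
#' centroid under the given protocol and noise level. This ties the
#' decision regions directly to the acquisition: a noisier or less
#' informative protocol automatically widens them.
#'
#' @param tissues List of [tissue_params], one per class.
#' @param protocol An [acquisition_protocol].
#' @param noise_sigma Per-channel noise standard deviation, `> 0`.
#' @param rho_weight_inflation Lambda `>= 1` applied to the rho variance.
#' @return A [class_model].
#' @export
build_class_model <- function(tissues, protocol, noise_sigma,
                              rho_weight_inflation = 1) {
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  cent <- t(vapply(tissues, function(t) c(t$rho, t$t1, t$t2), numeric(3)))
  nms <- vapply(seq_along(tissues), function(i) {
    if (is.null(tissues[[i]]$name)) paste0("class", i) else tissues[[i]]$name
  }, character(1))
  covs <- lapply(seq_along(tissues), function(i) {
    tryCatch(crlb_covariance(tissues[[i]], protocol, noise_sigma),
             error = function(e) stop(sprintf(
               "CRLB covariance is singular for class %d (%s): %s",
               i, nms[i], conditionMessage(e)), call. = FALSE))
  })
  class_model(cent, covs, names = nms,
              rho_weight_inflation = rho_weight_inflation)
}

#' Segmentation result
#'
#' @param labels Integer label matrix (0 = background/unclassified).
#' @param metrics 3D array (rows x cols x N) of per-class decision metrics.
#' @param criterion Name of the producing criterion.
#' @return An object of class `segmentation`.
#' @export
segmentation <- function(labels, metrics, criterion) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, metrics = metrics, criterion = criterion),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s: %d x %d, %d classified voxels\n",
              x$criterion, nrow(x$labels), ncol(x$labels),
              sum(x$labels > 0L)))
  invisible(x)
}

# shared plumbing: (n_fg x 3) feature matrix + bookkeeping
classify_setup <- function(maps, model) {
  stopifnot(inherits(maps, "estimate_maps"), inherits(model, "class_model"))
  idx <- which(maps$mask)
  if (length(idx) == 0L) stop("no voxels to classify: empty mask")
  X <- cbind(maps$rho_hat[idx], maps$t1_hat[idx], maps$t2_hat[idx])
  list(idx = idx, X = X, shape = dim(maps$mask))
}

assemble_segmentation <- function(setup, D, model, criterion) {
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)  # single-voxel mask
  lab <- matrix(0L, setup$shape[1], setup$shape[2])
  lab[setup$idx] <- max.col(-D, ties.method = "first")
  met <- array(NA_real_, dim = c(setup$shape, model$n_classes))
  for (n in seq_len(model$n_classes)) {
    plane <- matrix(NA_real_, setup$shape[1], setup$shape[2])
    plane[setup$idx] <- D[, n]
    met[, , n] <- plane
  }
  segmentation(lab, met, criterion)
}

#' Minimum Euclidean distance classification
#'
#' The classical baseline: each voxel is assigned to the class whose
#' centroid is nearest in unweighted Euclidean distance over
#' (rho, T1, T2). Because T1 spans thousands of ms while rho is of order
#' one, this distance is dominated by T1 — which is exactly the weakness
#' the statistically weighted criteria address. Ties go to the lowest
#' class index.
#'
#' @param maps An [estimate_maps].
#' @param model A [class_model] in the same units as the maps.
#' @return A [segmentation]; metrics hold the Euclidean distances.
#' @export
classify_euclidean <- function(maps, model) {
  s <- classify_setup(maps, model)
  D <- vapply(seq_len(model$n_classes), function(n) {
    sqrt(rowSums(sweep(s$X, 2, model$centroids[n, ])^2))
  }, numeric(nrow(s$X)))
  assemble_segmentation(s, D, model, "euclidean")
}

# per-class variances with the rho inflation applied
model_variances <- function(model) {
  v <- t(vapply(model$covariances, diag, numeric(3)))
  v[, 1] <- v[, 1] * model$rho_weight_inflation
  v
}

#' Weighted distance criterion (WDC)
#'
#' Treats the three estimators as independent Gaussians and maximises the
#' joint likelihood, i.e. minimises over classes n the sum of squared
#' deviations weighted by the inverse estimator variances:
#' `(rho - mu_rho(n))^2 / (2 lambda sigma_rho^2(n)) + ...` for T1 and T2
#' alike (lambda multiplying only the rho variance). With all class
#' variances equal this ranking coincides with the Euclidean one; with
#' lambda large the rho term drops out and only the relaxation times vote.
#'
#' @inheritParams classify_euclidean
#' @return A [segmentation]; metrics hold the weighted squared distances.
#' @export
classify_wdc <- function(maps, model) {
  s <- classify_setup(maps, model)
  v <- model_variances(model)
  if (any(v <= 0)) stop("non-positive estimator variance in model")
  D <- vapply(seq_len(model$n_classes), function(n) {
    rowSums(sweep(s$X, 2, model$centroids[n, ])^2 %*% diag(1 / (2 * v[n, ])))
  }, numeric(nrow(s$X)))
  assemble_segmentation(s, D, model, "wdc")
}

#' Statistical correlation criterion (StCC)
#'
#' Uses the full 3x3 estimator covariance of each class: voxels are
#' assigned by minimal Mahalanobis squared distance
#' `(x - mu_n)^T Sigma_n^{-1} (x - mu_n)`. The inverse covariance is the
#' weighting consistent with the Gaussian likelihood and reduces to the
#' WDC when the covariances are diagonal. Setting `literal_sigma = TRUE`
#' weights by Sigma_n itself instead of its inverse — a form that has
#' appeared in print but that inverts the meaning of "reliable", kept only
#' for comparison.
#'
#' @inheritParams classify_euclidean
#' @param literal_sigma Use Sigma_n instead of Sigma_n^{-1} (default FALSE).
#' @return A [segmentation]; metrics hold the quadratic-form values.
#' @export
classify_stcc <- function(maps, model, literal_sigma = FALSE) {
  s <- classify_setup(maps, model)
  lam <- model$rho_weight_inflation
  D <- vapply(seq_len(model$n_classes), function(n) {
    S <- model$covariances[[n]]
    S[1, 1] <- S[1, 1] * lam
    W <- if (literal_sigma) S else solve(S)
    Z <- sweep(s$X, 2, model$centroids[n, ])
    rowSums((Z %*% W) * Z)
  }, numeric(nrow(s$X)))
  assemble_segmentation(s, D, model, "stcc")
}

# counts of 8-neighbors carrying each label, mask-aware
neighbor_label_counts <- function(lab, mask, n_classes) {
  nr <- nrow(lab); nc <- ncol(lab)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  counts <- array(0L, dim = c(nr, nc, n_classes))
  valid <- matrix(0L, nr, nc)
  for (s in shifts) {
    sr <- s[1]; sc <- s[2]
    r_dst <- max(1, 1 - sr):min(nr, nr - sr)
    c_dst <- max(1, 1 - sc):min(nc, nc - sc)
    r_src <- r_dst + sr; c_src <- c_dst + sc
    m_src <- mask[r_src, c_src, drop = FALSE]
    valid[r_dst, c_dst] <- valid[r_dst, c_dst] + m_src
    l_src <- lab[r_src, c_src, drop = FALSE]
    for (n in seq_len(n_classes)) {
      counts[r_dst, c_dst, n] <- counts[r_dst, c_dst, n] +
        (m_src & l_src == n)
    }
  }
  list(counts = counts, valid = valid)
}

#' Spatial correlation criterion (SpCC)
#'
#' Refines an StCC segmentation with one (or more) regularization passes.
#' For each foreground voxel let `d0` be its minimal StCC metric and
#' `p(n)` the fraction of its 8-connected in-mask neighbors labeled `n` by
#' StCC; the voxel is reassigned to
#' `argmin_n metric_n - p(n) * d0`. The reduction is capped at `d0`, so
#' adjusted metrics stay nonnegative; a voxel whose neighborhood
#' unanimously agrees with its own label can never flip, while isolated
#' disagreements are pulled toward the local consensus. At image borders
#' and mask edges `p(n)` is normalized by the number of valid neighbors; a
#' voxel with no in-mask neighbor keeps its StCC label.
#'
#' @param stcc_result A [segmentation] produced by [classify_stcc()].
#' @param iterations Number of refinement passes (default 1); later passes
#'   recompute the label fractions from the refreshed labels while keeping
#'   the StCC metrics fixed.
#' @return A [segmentation] with criterion `"spcc"`; metrics keep the StCC
#'   quadratic forms (only labels change).
#' @export
spcc_refine <- function(stcc_result, iterations = 1L) {
  stopifnot(inherits(stcc_result, "segmentation"))
  if (!identical(stcc_result$criterion, "stcc"))
    stop("spcc_refine expects the segmentation produced by classify_stcc")
  met <- stcc_result$metrics
  n_classes <- dim(met)[3]
  lab <- stcc_result$labels
  mask <- lab > 0L
  idx <- which(mask)
  Dm <- vapply(seq_len(n_classes), function(n) met[, , n][idx],
               numeric(length(idx)))
  if (is.null(dim(Dm))) Dm <- matrix(Dm, nrow = 1L)
  d0 <- apply(Dm, 1, min)
  for (pass in seq_len(iterations)) {
    nb <- neighbor_label_counts(lab, mask, n_classes)
    valid <- nb$valid[idx]
    newlab <- lab
    P <- vapply(seq_len(n_classes), function(n) nb$counts[, , n][idx],
                numeric(length(idx)))
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    P <- P / pmax(valid, 1L)
    adj <- Dm - P * d0
    pick <- max.col(-adj, ties.method = "first")
    keep <- valid == 0L
    pick[keep] <- lab[idx][keep]
    newlab[idx] <- pick
    if (identical(newlab, lab)) { lab <- newlab; break }
    lab <- newlab
  }
  segmentation(lab, met, "spcc")
}

#' Scalar composite image of the estimate maps
#'
#' Averages the rho, T1 and T2 maps after centring each at its median and
#' scaling by its median absolute deviation over the mask, producing the
#' single gray-level image on which the K-means baseline operates. Robust
#' scaling is used rather than min-max because the CSF T1 (an order of
#' magnitude above the other tissues) would otherwise compress the
#' remaining classes into an unresolvable sliver of the range. The
#' per-channel centres and scales are kept as an attribute so class
#' centroids can be projected into the same composite space.
#'
#' @param maps An [estimate_maps].
#' @return Numeric matrix with `NA` off-mask and attribute `scaling`
#'   (3 x 2 matrix: per-channel median and MAD).
#' @export
composite_image <- function(maps) {
  stopifnot(inherits(maps, "estimate_maps"))
  idx <- which(maps$mask)
  X <- cbind(maps$rho_hat[idx], maps$t1_hat[idx], maps$t2_hat[idx])
  ctr <- apply(X, 2, median)
  scl <- pmax(apply(X, 2, mad), .Machine$double.eps)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out <- matrix(NA_real_, nrow(maps$mask), ncol(maps$mask))
  out[idx] <- rowMeans(Z)
  attr(out, "scaling") <- cbind(center = ctr, scale = scl)
  out
}

#' K-means baseline on a composite image
#'
#' Clusters the foreground values of a scalar composite image with Lloyd's
#' algorithm (multiple seeded restarts) and, when a [class_model] is
#' supplied, relabels the clusters by nearest model centroid projected
#' into composite space — so cluster 2 means the same tissue as class 2 of
#' the model. Without a model, clusters are ordered by increasing center
#' value.
#'
#' @param composite Numeric matrix from [composite_image()] (`NA` =
#'   background).
#' @param k Number of clusters, `>= 2`.
#' @param seed Integer seed; fixed seed gives identical labels.
#' @param model Optional [class_model] used only to align cluster indices.
#' @return A [segmentation] with criterion `"kmeans"`; metrics hold the
#'   absolute distance of each voxel to each (aligned) cluster center.
#' @export
kmeans_baseline <- function(composite, k, seed = 1L, model = NULL) {
  if (k < 2L) stop("k must be >= 2")
  idx <- which(!is.na(composite))
  vals <- composite[idx]
  if (length(unique(vals)) < k)
    stop("k exceeds the number of distinct composite values")
  # some multi-start restarts land on empty clusters and warn; the best
  # restart is still well-defined, so those warnings are noise here
  km <- with_seed(seed, withCallingHandlers(
    kmeans(vals, centers = k, iter.max = 200L, nstart = 10L,
           algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  centers <- as.numeric(km$centers)
  if (!is.null(model)) {
    sc <- attr(composite, "scaling")
    if (is.null(sc)) stop("composite lacks the scaling attribute")
    proj <- rowMeans(sweep(sweep(model$centroids, 2, sc[, 1]), 2,
                           sc[, 2], "/"))
    if (model$n_classes != k)
      stop("model class count must equal k for alignment")
    # greedy one-to-one: closest (cluster, class) pairs first
    map <- integer(k)
    d <- abs(outer(centers, proj, "-"))
    for (step in seq_len(k)) {
      w <- which(d == min(d), arr.ind = TRUE)[1, ]
      map[w[1]] <- w[2]
      d[w[1], ] <- Inf; d[, w[2]] <- Inf
    }
  } else {
    map <- order(order(centers))
  }
  lab <- matrix(0L, nrow(composite), ncol(composite))
  lab[idx] <- map[km$cluster]
  aligned_centers <- numeric(k)
  aligned_centers[map] <- centers
  met <- array(NA_real_, dim = c(dim(composite), k))
  for (n in seq_len(k)) {
    plane <- matrix(NA_real_, nrow(composite), ncol(composite))
    plane[idx] <- abs(vals - aligned_centers[n])
    met[, , n] <- plane
  }
  segmentation(lab, met, "kmeans")
}
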