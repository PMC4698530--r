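# Shared fixtures: the reference tissues/protocol and small builders used
# across the suite. Everything is generated in code; no stored data.

wm_tissue <- function() tissue_params(2.56, 1389, 72.4, name = "WM")

ref_protocol <- function() default_acquisition_protocol()

# noise-free observations of one voxel under the reference protocol
clean_obs <- function(tissue, phi = 0, protocol = ref_protocol()) {
  spin_echo_amplitude(tissue, protocol$te, protocol$tr) * exp(1i * phi)
}

# estimate_maps built directly from matrices (skips fitting) for
# classifier tests
maps_from_matrices <- function(rho, t1, t2, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(rho), ncol(rho))
  z <- matrix(0, nrow(rho), ncol(rho))
  estimate_maps(rho, t1, t2, z, z, mask)
}

# random SPD 3x3 matrix
random_spd <- function(scale = c(0.1, 100, 5)) {
  A <- matrix(rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.5
  D <- diag(scale)
  D %*% S %*% D
}

# random k-class model with controllable covariance structure
random_model <- function(k = 3, covariance = c("spd", "diagonal",
                                               "identity", "equal")) {
  covariance <- match.arg(covariance)
  cent <- cbind(runif(k, 1, 5), runif(k, 500, 5000), runif(k, 30, 300))
  covs <- switch(covariance,
    spd = replicate(k, random_spd(), simplify = FALSE),
    diagonal = replicate(k, diag(c(runif(1, 0.01, 0.2),
                                   runif(1, 100, 5000),
                                   runif(1, 1, 50))), simplify = FALSE),
    identity = replicate(k, diag(3), simplify = FALSE),
    equal = { S <- runif(1, 0.5, 2) * diag(3)  # one shared scalar variance
              replicate(k, S, simplify = FALSE) })
  class_model(cent, covs)
}

# random estimate maps roughly on tissue scales
random_maps <- function(nr = 16, nc = 16) {
  maps_from_matrices(matrix(runif(nr * nc, 1, 5), nr, nc),
                     matrix(runif(nr * nc, 500, 5000), nr, nc),
                     matrix(runif(nr * nc, 30, 300), nr, nc))
}

# connected components of a logical matrix, 8-connectivity (test oracle)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    nr <- nrow(mask)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      i <- (v - 1L) %% nr + 1L; j <- (v - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(mask)) {
          w <- (jj - 1L) * nr + ii
          if (mask[w] && lab[w] == 0L) { lab[w] <- comp; queue <- c(queue, w) }
        }
      }
    }
  }
  comp
}
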