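test_that("noise-free voxels are recovered to optimizer tolerance", {
  p <- ref_protocol()
  for (tis in brain_phantom_tissues()) {
    fit <- fit_voxel(clean_obs(tis), p)
    expect_true(fit$converged)
    expect_lt(abs(fit$tissue$rho / tis$rho - 1), 1e-4)
    expect_lt(abs(fit$tissue$t1 / tis$t1 - 1), 1e-4)
    expect_lt(abs(fit$tissue$t2 / tis$t2 - 1), 1e-4)
    expect_lt(fit$residual, 1e-6)
  }
})

test_that("a common phase is estimated without disturbing the parameters", {
  p <- ref_protocol()
  wm <- wm_tissue()
  fit <- fit_voxel(clean_obs(wm, phi = 1.0), p)
  expect_lt(abs(fit$phi - 1.0), 1e-4)
  expect_lt(abs(fit$tissue$t1 / wm$t1 - 1), 1e-4)
  # phase invariance: rotating all observations shifts phi only
  obs <- clean_obs(wm) + 0.002 * complex(real = c(1, -1, 2, 0),
                                         imaginary = c(0, 1, -1, 1))
  f0 <- fit_voxel(obs, p)
  f1 <- fit_voxel(obs * exp(1i * 0.7), p)
  expect_equal(f1$tissue$t1, f0$tissue$t1, tolerance = 1e-6)
  expect_equal(f1$tissue$rho, f0$tissue$rho, tolerance = 1e-6)
  expect_equal((f1$phi - f0$phi) %% (2 * pi), 0.7, tolerance = 1e-4)
})

test_that("scaling observations rescales rho and nothing else", {
  p <- ref_protocol()
  wm <- wm_tissue()
  obs <- clean_obs(wm) + 0.003 * complex(real = c(1, 2, -1, 1),
                                         imaginary = c(-1, 0, 1, 2))
  f0 <- fit_voxel(obs, p)
  f1 <- fit_voxel(3 * obs, p)
  expect_equal(f1$tissue$rho, 3 * f0$tissue$rho, tolerance = 1e-6)
  expect_equal(f1$tissue$t1, f0$tissue$t1, tolerance = 1e-6)
  expect_equal(f1$tissue$t2, f0$tissue$t2, tolerance = 1e-6)
})

test_that("degenerate voxels are flagged, not fatal", {
  p <- ref_protocol()
  bg <- fit_voxel(complex(real = rep(0, 4)), p)
  expect_true(bg$background)
  expect_null(bg$tissue)
  expect_error(fit_voxel(complex(real = 1), acquisition_protocol(80, 3600)),
               "at least 2")
})

test_that("the returned optimum beats a bounded reference grid", {
  # oracle: the concentrated criterion evaluated on an independent coarse
  # grid must never undercut the optimizer's solution
  p <- ref_protocol()
  b <- fit_bounds()
  crit <- function(obs, t1, t2) {
    g <- exp(-p$te / t2) * (1 - exp(-p$tr / t1))
    S <- sum(obs * g)
    rho <- min(max(Mod(S) / sum(g^2), 0), b$rho_max)
    sum(Mod(obs)^2) + rho^2 * sum(g^2) - 2 * rho * Mod(S)
  }
  set.seed(31)
  for (rep in 1:20) {
    tis <- tissue_params(runif(1, 0.5, 6), runif(1, 300, 8000),
                         runif(1, 20, 400))
    obs <- clean_obs(tis) + 0.01 * complex(real = rnorm(4),
                                           imaginary = rnorm(4))
    fit <- fit_voxel(obs, p)
    f_opt <- crit(obs, fit$tissue$t1, fit$tissue$t2)
    grid <- expand.grid(t1 = exp(seq(log(b$t1[1]), log(b$t1[2]), length = 5)),
                        t2 = exp(seq(log(b$t2[1]), log(b$t2[2]), length = 5)))
    f_grid <- mapply(function(a, c) crit(obs, a, c), grid$t1, grid$t2)
    expect_lte(f_opt, min(f_grid) + 1e-10)
  }
})

test_that("fit_maps reproduces the phantom exactly without noise", {
  ph <- make_brain_phantom(c(64, 64), geometry_seed = 2)
  pm <- parameter_maps(ph)
  set <- simulate_acquisition(pm$rho, pm$t1, pm$t2, sigma = 0)
  maps <- fit_maps(set, mask = pm$mask)
  expect_identical(maps$mask, pm$mask)
  fg <- pm$mask
  expect_lt(max(abs(maps$rho_hat[fg] / pm$rho[fg] - 1)), 1e-4)
  expect_lt(max(abs(maps$t1_hat[fg] / pm$t1[fg] - 1)), 1e-4)
  expect_lt(max(abs(maps$t2_hat[fg] / pm$t2[fg] - 1)), 1e-4)
  expect_true(all(is.na(maps$rho_hat[!fg])))
  expect_error(fit_maps(set, mask = matrix(FALSE, 64, 64)), "no voxels|empty",
               ignore.case = TRUE)
})

test_that("per-tissue medians survive 30 dB noise within 2 percent", {
  sim <- simulate_phantom_study(shape = c(96, 96), snr_db = 30, seed = 5)
  maps <- fit_maps(sim$images, mask = sim$params$mask)
  for (k in 1:4) {
    sel <- sim$truth$labels == k & maps$mask
    tis <- sim$truth$class_params[[k]]
    expect_lt(abs(median(maps$t2_hat[sel]) / tis$t2 - 1), 0.02)
    expect_lt(abs(median(maps$t1_hat[sel]) / tis$t1 - 1), 0.02)
  }
})

test_that("analytic Fisher information matches finite differences", {
  p <- ref_protocol()
  sigma <- 0.01
  phi <- 0.3
  num_fim <- function(tis, phi) {
    # central differences of the complex mean vector s_k(theta)
    s_of <- function(th) {
      se <- th[1] * exp(-p$te / th[3]) * (1 - exp(-p$tr / th[2]))
      se * exp(1i * th[4])
    }
    th0 <- c(tis$rho, tis$t1, tis$t2, phi)
    D <- matrix(0i, p$m, 4)
    for (j in 1:4) {
      h <- 1e-6 * max(abs(th0[j]), 1)
      up <- th0; up[j] <- up[j] + h
      dn <- th0; dn[j] <- dn[j] - h
      D[, j] <- (s_of(up) - s_of(dn)) / (2 * h)
    }
    Re(Conj(t(D)) %*% D) / sigma^2
  }
  for (tis in brain_phantom_tissues()) {
    J <- fisher_information(tis, p, sigma, phi = phi)
    Jn <- num_fim(tis, phi)
    expect_lt(max(abs(J - Jn)) / max(abs(J)), 1e-4)
  }
})

test_that("Fisher information scales as 1/sigma^2 and needs m >= 2", {
  p <- ref_protocol()
  wm <- wm_tissue()
  J1 <- fisher_information(wm, p, 0.01)
  J2 <- fisher_information(wm, p, 0.02)
  expect_equal(J1 / 4, J2, tolerance = 1e-12)
  # one image: 2 real observations cannot identify 4 parameters
  p1 <- acquisition_protocol(80, 3600)
  Js <- fisher_information(wm, p1, 0.01)
  expect_lte(qr(Js)$rank, 2)
  expect_error(crlb_covariance(wm, p1, 0.01), "singular")
  expect_error(fisher_information(tissue_params(0, 1000, 80), p, 0.01),
               "rho = 0")
})

test_that("CRLB covariance is SPD with negatively correlated rho and T2", {
  p <- ref_protocol()
  S <- crlb_covariance(wm_tissue(), p, 0.0098)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_lt(S[1, 3], 0)  # Cov(rho, T2) < 0
  expect_lt(S[1, 3] / sqrt(S[1, 1] * S[3, 3]), -0.5)
})
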