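test_that("Euclidean labels match a per-voxel exhaustive oracle", {
  set.seed(101)
  maps <- random_maps()
  model <- random_model(4, "spd")
  seg <- classify_euclidean(maps, model)
  X <- cbind(as.vector(maps$rho_hat), as.vector(maps$t1_hat),
             as.vector(maps$t2_hat))
  oracle <- apply(X, 1, function(x) {
    which.min(vapply(seq_len(4), function(n)
      sqrt(sum((x - model$centroids[n, ])^2)), numeric(1)))
  })
  expect_identical(as.vector(seg$labels), as.integer(oracle))
})

test_that("ties break toward the lowest class index", {
  maps <- maps_from_matrices(matrix(1, 1, 1), matrix(1000, 1, 1),
                             matrix(80, 1, 1))
  cent <- rbind(c(1, 900, 80), c(1, 1000, 200), c(1, 1100, 80))
  model <- class_model(cent, replicate(3, diag(3), simplify = FALSE))
  seg <- classify_euclidean(maps, model)  # classes 1 and 3 equidistant
  expect_identical(seg$labels[1, 1], 1L)
  # a voxel exactly at a centroid gets that class with metric zero
  maps2 <- maps_from_matrices(matrix(1, 1, 1), matrix(1100, 1, 1),
                              matrix(80, 1, 1))
  seg2 <- classify_euclidean(maps2, model)
  expect_identical(seg2$labels[1, 1], 3L)
  expect_equal(seg2$metrics[1, 1, 3], 0)
})

test_that("WDC reduces to Euclidean under equal variances", {
  set.seed(102)
  for (rep in 1:5) {
    maps <- random_maps(8, 8)
    model <- random_model(3, "equal")
    expect_identical(classify_wdc(maps, model)$labels,
                     classify_euclidean(maps, model)$labels)
  }
})

test_that("WDC evaluates the two-term arithmetic example correctly", {
  maps <- maps_from_matrices(matrix(1, 1, 1), matrix(1000, 1, 1),
                             matrix(80, 1, 1))
  model <- class_model(rbind(c(1.2, 1000, 80), c(1.0, 1200, 80)),
                       list(diag(c(0.01, 1e4, 25)),
                            diag(c(0.04, 1e4, 25))))
  seg <- classify_wdc(maps, model)
  # by hand: d_A = 0.2^2/(2*0.01) = 2; d_B = 200^2/(2*1e4) = 2 -> tie -> A
  expect_equal(seg$metrics[1, 1, 1], 2)
  expect_equal(seg$metrics[1, 1, 2], 2)
  expect_identical(seg$labels[1, 1], 1L)
  # nudge the voxel: now B is closer
  maps2 <- maps_from_matrices(matrix(1, 1, 1), matrix(1050, 1, 1),
                              matrix(80, 1, 1))
  seg2 <- classify_wdc(maps2, model)
  expect_identical(seg2$labels[1, 1], 2L)
})

test_that("a huge rho inflation makes WDC ignore proton density", {
  set.seed(103)
  maps <- random_maps(8, 8)
  model <- random_model(3, "diagonal")
  big <- class_model(model$centroids, model$covariances,
                     rho_weight_inflation = 1e6)
  seg <- classify_wdc(maps, big)
  # oracle: WDC on (T1, T2) only
  X <- cbind(as.vector(maps$t1_hat), as.vector(maps$t2_hat))
  v <- t(vapply(model$covariances, function(S) diag(S)[2:3], numeric(2)))
  oracle <- apply(X, 1, function(x) {
    which.min(vapply(1:3, function(n)
      sum((x - model$centroids[n, 2:3])^2 / (2 * v[n, ])), numeric(1)))
  })
  expect_identical(as.vector(seg$labels), as.integer(oracle))
})

test_that("StCC equals WDC for diagonal and Euclidean for identity Sigma", {
  set.seed(104)
  for (rep in 1:5) {
    maps <- random_maps(8, 8)
    d_model <- random_model(3, "diagonal")
    expect_identical(classify_stcc(maps, d_model)$labels,
                     classify_wdc(maps, d_model)$labels)
    i_model <- random_model(3, "identity")
    seg_i <- classify_stcc(maps, i_model)
    seg_e <- classify_euclidean(maps, i_model)
    expect_identical(seg_i$labels, seg_e$labels)
    # identity covariance: quadratic form is the squared Euclidean metric
    expect_equal(seg_i$metrics, seg_e$metrics^2, tolerance = 1e-9)
  }
})

test_that("StCC matches a direct Mahalanobis oracle to 1e-10", {
  set.seed(105)
  maps <- random_maps()
  model <- random_model(4, "spd")
  seg <- classify_stcc(maps, model)
  X <- cbind(as.vector(maps$rho_hat), as.vector(maps$t1_hat),
             as.vector(maps$t2_hat))
  for (n in 1:4) {
    Sinv <- solve(model$covariances[[n]])
    oracle <- apply(X, 1, function(x) {
      z <- x - model$centroids[n, ]
      as.numeric(t(z) %*% Sinv %*% z)
    })
    expect_equal(as.vector(seg$metrics[, , n]), oracle, tolerance = 1e-10)
  }
})

test_that("class permutation permutes the output labels accordingly", {
  set.seed(106)
  maps <- random_maps(8, 8)
  model <- random_model(4, "spd")
  perm <- c(3L, 1L, 4L, 2L)
  pmodel <- class_model(model$centroids[perm, ],
                        model$covariances[perm],
                        names = model$names[perm])
  seg <- classify_stcc(maps, model)
  pseg <- classify_stcc(maps, pmodel)
  inv <- order(perm)  # original class k now sits at position inv[k]
  expect_identical(as.vector(pseg$labels),
                   as.integer(inv[as.vector(seg$labels)]))
})

test_that("SpCC keeps unanimous interiors and flips isolated disagreements", {
  # hand-built 3x3 instance with identity covariances: metrics are squared
  # distances to mu_A = 0 and mu_B = 2 along rho
  rho <- matrix(2, 3, 3); rho[2, 2] <- 0.95
  maps <- maps_from_matrices(rho, matrix(1000, 3, 3), matrix(80, 3, 3))
  model <- class_model(rbind(c(0, 1000, 80), c(2, 1000, 80)),
                       list(diag(3), diag(3)))
  stcc <- classify_stcc(maps, model)
  expect_identical(stcc$labels[2, 2], 1L)  # d_A = 0.9025 < d_B = 1.1025
  expect_true(all(stcc$labels[-5] == 2L))
  spcc <- spcc_refine(stcc)
  # center: d_B - 1 * d_0 = 0.2 < d_A = 0.9025 -> flips to B
  expect_identical(spcc$labels[2, 2], 2L)
  # corners had unanimous in-label neighborhoods where p favors their own
  # class; none of them flips
  expect_true(all(spcc$labels[-5] == 2L))
})

test_that("SpCC adjusted metrics stay nonnegative and p = 0 never flips", {
  set.seed(107)
  maps <- random_maps()
  model <- random_model(3, "spd")
  stcc <- classify_stcc(maps, model)
  spcc <- spcc_refine(stcc)
  lab <- stcc$labels
  mask <- lab > 0L
  # brute-force neighborhood fractions
  nr <- nrow(lab); nc <- ncol(lab)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nbr <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj])
        nbr <- c(nbr, lab[ii, jj])
    }
    d <- stcc$metrics[i, j, ]
    d0 <- min(d)
    p <- tabulate(nbr, 3) / length(nbr)
    adj <- d - p * d0
    expect_true(all(adj >= -1e-12))
    expect_identical(spcc$labels[i, j], as.integer(which.min(adj)))
    # when no neighbor disagrees constructively, the label is unchanged
    if (all(p[-lab[i, j]] == 0))
      expect_identical(spcc$labels[i, j], lab[i, j])
  }
})

test_that("spcc_refine rejects segmentations from other criteria", {
  maps <- random_maps(4, 4)
  model <- random_model(3, "spd")
  expect_error(spcc_refine(classify_wdc(maps, model)), "classify_stcc")
})

test_that("K-means recovers separated plateaus and is deterministic", {
  comp <- matrix(NA_real_, 12, 12)
  comp[1:4, ] <- 0.1; comp[5:8, ] <- 0.5; comp[9:12, ] <- 0.9
  comp <- comp + matrix(runif(144, -0.02, 0.02), 12, 12)
  seg <- kmeans_baseline(comp, 3, seed = 1)
  expect_identical(seg$labels[1, 1], 1L)
  expect_identical(seg$labels[6, 6], 2L)
  expect_identical(seg$labels[12, 12], 3L)
  expect_equal(length(unique(as.vector(seg$labels[1:4, ]))), 1L)
  seg2 <- kmeans_baseline(comp, 3, seed = 1)
  expect_identical(seg$labels, seg2$labels)
  expect_error(kmeans_baseline(matrix(c(1, 1, 2, 2), 2, 2), 3), "distinct")
})

test_that("build_class_model wires tissues, CRLB and lambda together", {
  p <- ref_protocol()
  model <- build_class_model(brain_phantom_tissues(), p, 0.0098)
  expect_equal(model$n_classes, 4L)
  expect_equal(model$centroids[1, ], c(2.56, 1389, 72.4),
               ignore_attr = TRUE)
  for (S in model$covariances) {
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_true(all(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
  expect_warning(
    build_class_model(list(wm_tissue(), wm_tissue()), p, 0.0098),
    "indistinguishable")
  # lambda plumbing: WDC metrics for class 1 shrink by exactly lambda in
  # the rho term
  m1 <- build_class_model(brain_phantom_tissues(), p, 0.0098)
  m3 <- build_class_model(brain_phantom_tissues(), p, 0.0098,
                          rho_weight_inflation = 3)
  maps <- maps_from_matrices(matrix(3, 1, 1), matrix(1389, 1, 1),
                             matrix(72.4, 1, 1))
  d1 <- classify_wdc(maps, m1)$metrics[1, 1, 1]
  d3 <- classify_wdc(maps, m3)$metrics[1, 1, 1]
  # only the rho deviation contributes here, so the metric divides by 3
  expect_equal(d3, d1 / 3, tolerance = 1e-12)
})
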