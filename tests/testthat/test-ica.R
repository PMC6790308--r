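test_that("PCA whitening is exact on low-rank data and unit-covariance", {
  g <- tiny_grid(dim = c(8, 8, 8), vox = 6)
  tp <- lapply(c(-12, 0, 12), function(x0)
    network_template(paste0("t", x0),
                     list(list(xyz = c(x0, 0, 0), amplitude = 1, sigma = 6))))
  run <- simulate_rest_run(tp, grid = g, n_volumes = 30, noise_sd = 0,
                           seed = 2)
  wh <- pca_whiten(run, 3)
  # whitened spatial series are uncorrelated with unit variance
  C <- tcrossprod(wh$Y) / ncol(wh$Y)
  expect_equal(C, diag(3), tolerance = 1e-6)
  # rank-3 data reconstruct exactly from 3 components
  X <- t(langmapr:::run_matrix(run))
  Xc <- sweep(X, 1, wh$mean)  # centred as in pca_whiten
  recon <- wh$dewhitener %*% wh$Y
  expect_lt(max(abs(recon - Xc)) / max(abs(Xc)), 1e-8)
  expect_equal(wh$explained_variance, 1, tolerance = 1e-10)
  # retained variance equals the eigenvalue ratio computed independently
  run_n <- simulate_rest_run(tp, grid = g, n_volumes = 30, noise_sd = 1,
                             seed = 3)
  wh2 <- pca_whiten(run_n, 2)
  Xn <- t(langmapr:::run_matrix(run_n))
  Xn <- Xn - rowMeans(Xn)
  ev <- svd(Xn)$d^2          # singular-value oracle for the eigenvalues
  expect_equal(wh2$explained_variance, sum(ev[1:2]) / sum(ev),
               tolerance = 1e-6)
  expect_error(pca_whiten(run, 10), "rank")
})

test_that("Infomax separates Laplacian sources and flags Gaussian ones", {
  set.seed(42)
  V <- 5000
  S <- matrix(rexp(2 * V) * sign(runif(2 * V) - 0.5), 2, V)
  A <- matrix(rnorm(4), 2, 2)
  X <- A %*% S
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / V, symmetric = TRUE)
  Y <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% Xc
  um <- infomax_unmix(Y, ica_config(n_components = 2, seed = 1,
                                    max_iter = 3000))
  expect_true(um$converged)
  R <- abs(cor(t(um$W %*% Y), t(S)))
  expect_gt(max(R[1, ]), 0.99)
  expect_gt(max(R[2, ]), 0.99)
  expect_equal(sort(apply(R, 1, which.max)), 1:2)  # distinct sources
  # Gaussian sources: no separation guarantee, near-zero kurtosis reported
  G <- matrix(rnorm(2 * V), 2, V)
  Yg <- {
    Xg <- A %*% G; Xgc <- Xg - rowMeans(Xg)
    egg <- eigen(tcrossprod(Xgc) / V, symmetric = TRUE)
    diag(1 / sqrt(egg$values)) %*% t(egg$vectors) %*% Xgc
  }
  umg <- suppressWarnings(infomax_unmix(Yg, ica_config(n_components = 2,
                                                       seed = 1,
                                                       max_iter = 200)))
  expect_true(all(abs(umg$source_kurtosis) < 0.5))
})

test_that("permuting voxels permutes spatial maps identically", {
  set.seed(9)
  V <- 2000
  S <- matrix(rexp(3 * V) * sign(runif(3 * V) - 0.5), 3, V)
  A <- matrix(rnorm(9), 3, 3)
  X <- A %*% S
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / V, symmetric = TRUE)
  Y <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% Xc
  perm <- sample(V)
  cfg <- ica_config(n_components = 3, seed = 2, max_iter = 3000)
  um1 <- infomax_unmix(Y, cfg)
  um2 <- infomax_unmix(Y[, perm], cfg)
  s1 <- um1$W %*% Y
  s2 <- um2$W %*% Y[, perm]
  expect_equal(s1[, perm], s2, tolerance = 1e-6)
})

test_that("decompositions are z-scored, skew-positive, and seed-deterministic", {
  tpl <- validation_templates()
  g <- validation_grid()
  rest <- simulate_rest_run(tpl, grid = g, n_volumes = 60, noise_sd = 0.5,
                            seed = 11)
  run <- bandpass_bold_run(discard_initial_volumes(rest, 3))
  d1 <- suppressWarnings(decompose_rest(run, ica_config(n_components = 8,
                                                        seed = 11)))
  d2 <- suppressWarnings(decompose_rest(run, ica_config(n_components = 8,
                                                        seed = 11)))
  expect_identical(d1$spatial_maps, d2$spatial_maps)  # bitwise determinism
  expect_identical(d1$time_courses, d2$time_courses)
  msk <- g$mask
  for (m in d1$spatial_maps) {
    v <- m$values[msk]
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(sd(v), 1, tolerance = 1e-6)
    expect_gte(mean(v^3), 0)  # sign convention
  }
  expect_equal(nrow(d1$time_courses), run$n_volumes)
  # requesting more components than the temporal rank fails with the rank
  expect_error(decompose_rest(run, ica_config(n_components = 59, seed = 1)),
               "rank")
})

test_that("component thresholding zeroes subthreshold voxels only", {
  g <- tiny_grid(dim = c(6, 6, 6), vox = 6)
  set.seed(13)
  vals <- array(rnorm(prod(g$dim)), dim = g$dim)
  m <- stat_map(g, vals, kind = "z")
  thr <- threshold_component(m, 2)
  expect_true(all(thr$values[vals <= 2] == 0))
  expect_equal(thr$values[vals > 2], vals[vals > 2])
  expect_equal(threshold_component(m, -Inf)$values, m$values)
  sub <- threshold_component(stat_map(g, array(1, dim = g$dim), kind = "z"), 2)
  expect_true(all(sub$values == 0))
})

test_that("planted networks are recovered from noisy rest runs", {
  # lighter version (3 seeds) of the ten-seed acceptance property
  mins <- vapply(1:3, function(s)
    min(recover_validation_networks(seed = s)$correlation), numeric(1))
  expect_true(all(mins >= 0.85))
  expect_gte(mean(mins), 0.9)
})
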