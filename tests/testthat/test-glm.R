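test_that("the canonical HRF has the double-gamma shape", {
  fine <- canonical_hrf(0.01)
  expect_equal((which.max(fine) - 1) * 0.01, 5, tolerance = 0.02)
  expect_gt(sum(fine) * 0.01, 0)        # positive integral over 32 s
  expect_equal(max(fine), 1)            # peak-normalised
  h <- canonical_hrf(2.28)
  expect_length(h, floor(32 / 2.28) + 1)  # 15 samples
  # sampled kernel peaks at the sample nearest 5 s
  expect_equal((which.max(h) - 1) * 2.28, 4.56)
})

test_that("initial-volume discard shortens runs consistently", {
  g <- tiny_grid(dim = c(5, 5, 5), vox = 6)
  tp <- list(network_template("A", list(list(xyz = c(0, 0, 0),
                                             amplitude = 1, sigma = 10))))
  run <- simulate_rest_run(tp, grid = g, n_volumes = 270, seed = 1)
  out <- discard_initial_volumes(run, 3)
  expect_equal(out$n_volumes, 267)
  expect_equal(nrow(out$ground_truth$time_courses), 267)
  expect_identical(discard_initial_volumes(run, 0), run)
  expect_error(discard_initial_volumes(run, 270), "cannot discard")
})

test_that("design matrices carry HRF-convolved boxcars, DCT drift and intercept", {
  des <- block_design(267, 2.28, 16)
  dm <- build_design(des, 267, 2.28, highpass_cutoff_s = 128)
  # floor(2 * 267 * 2.28 / 128) = 9 drift columns
  expect_equal(sum(grepl("^dct", dm$columns)), 9)
  expect_true("intercept" %in% dm$columns)
  # alternating SG/TL regressors are anti-phased
  expect_lt(cor(dm$X[, "SG"], dm$X[, "TL"]), 0)
  # a run shorter than 128 s gets no drift columns beyond the intercept
  des_s <- block_design(48, 2.28, 16)
  dm_s <- build_design(des_s, 48, 2.28)
  expect_equal(sum(grepl("^dct", dm_s$columns)), 1)  # 48*2.28 = 109 s -> 1
  dm_s2 <- build_design(block_design(24, 2.28, 8), 24, 2.28)
  expect_equal(sum(grepl("^dct", dm_s2$columns)), 0)
  # a design whose conditions collapse to the same regressor is refused
  des_bad <- block_design(60, 2.28, 16)
  des_bad$onsets$TL <- des_bad$onsets$SG
  expect_error(build_design(des_bad, 60, 2.28), "collinear")
})

test_that("GLM recovers a noise-free planted activation exactly", {
  g <- tiny_grid(dim = c(10, 10, 10), vox = 6)
  tp <- network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                        sigma = 10)))
  des <- block_design(80, 2.28)
  run <- simulate_task_run(tp, des, grid = g, n_volumes = 80,
                           effect_size = 1, noise_sd = 0,
                           drift_amplitude = 0, seed = 1)
  fit <- fit_glm(run, build_design(des, 80, 2.28))
  expect_equal(fit$dof, 80 - ncol(fit$design$X))
  planted <- run$ground_truth$maps$active$values
  eff <- fit$beta[, "SG"] - fit$beta[, "TL"]
  expect_equal(eff, planted[g$mask], tolerance = 1e-6)
  # constant run: all non-intercept betas are zero
  cr <- bold_run(g, array(3, dim = c(g$dim, 80)), tr_s = 2.28)
  cfit <- fit_glm(cr, build_design(des, 80, 2.28))
  expect_true(all(abs(cfit$beta[, colnames(cfit$beta) != "intercept"]) < 1e-10))
  expect_error(fit_glm(run, build_design(des, 79, 2.28)), "79")
})

test_that("null-contrast t values follow Student t and t is antisymmetric", {
  g <- tiny_grid(dim = c(10, 10, 10), vox = 6)
  des <- block_design(80, 2.28)
  dm <- build_design(des, 80, 2.28)
  set.seed(21)
  noise <- array(rnorm(prod(g$dim) * 80), dim = c(g$dim, 80))
  fit <- fit_glm(bold_run(g, noise, tr_s = 2.28), dm)
  tmap <- t_contrast(fit, c(SG = 1, TL = -1))
  tv <- tmap$values[tmap$grid$mask]
  ks <- ks.test(pt(tv, df = attr(tmap, "dof")), "punif")
  expect_gt(ks$p.value, 0.01)
  tneg <- t_contrast(fit, c(SG = -1, TL = 1))
  expect_equal(tneg$values, -tmap$values)
  expect_error(t_contrast(fit, c(SG = 1, nosuch = -1)), "unknown regressor")
  # constant voxels (zero residual variance) are masked out, not NaN
  cr <- bold_run(g, array(1, dim = c(g$dim, 80)), tr_s = 2.28)
  ct <- t_contrast(fit_glm(cr, dm))
  expect_equal(sum(ct$grid$mask), 0)
})

test_that("the 128-s high-pass removes slow drift", {
  g <- tiny_grid(dim = c(4, 4, 4), vox = 6)
  des <- block_design(267, 2.28)
  dm <- build_design(des, 267, 2.28)
  t_s <- (0:266) * 2.28
  # a slow scanner-style drift well below the cutoff is removed to < 1%
  drift <- 5 * cos(2 * pi * t_s / 600)
  arr <- array(rep(drift, each = prod(g$dim)), dim = c(g$dim, 267))
  fit <- fit_glm(bold_run(g, arr, tr_s = 2.28), dm)
  expect_lt(max(abs(fit$residuals)), 0.01 * diff(range(drift)))
  # any-phase drifts of period >= 300 s lose >= 99% of their variance
  # (drifts near the 128-s cutoff are only attenuated - filter roll-off)
  for (ph in c(0, pi / 3, pi / 2)) {
    d2 <- cos(2 * pi * t_s / 300 + ph)
    r <- qr.resid(qr(dm$X), d2)
    expect_lt(mean(r^2) / var(d2), 0.01)
  }
})

test_that("t maps are invariant to joint rescaling of data and design", {
  g <- tiny_grid(dim = c(6, 6, 6), vox = 6)
  des <- block_design(60, 2.28)
  tp <- network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                        sigma = 10)))
  run <- simulate_task_run(tp, des, grid = g, n_volumes = 60,
                           effect_size = 1, noise_sd = 0.5, seed = 3)
  dm <- build_design(des, 60, 2.28)
  t1 <- t_contrast(fit_glm(run, dm))
  run2 <- run
  run2$data <- run$data * 7
  t2 <- t_contrast(fit_glm(run2, dm))
  expect_equal(t2$values, t1$values, tolerance = 1e-9)
})

test_that("FWE voxel thresholding is conservative and finds planted signal", {
  g <- tiny_grid(dim = c(10, 10, 10), vox = 6)
  des <- block_design(80, 2.28)
  dm <- build_design(des, 80, 2.28)
  spec <- threshold_spec("FWE_voxel", 0.05)
  # all-zero t map survives nothing
  null_map <- stat_map(g, array(0, dim = g$dim), kind = "t")
  out0 <- apply_threshold(null_map, spec, dof = 70)
  expect_equal(nrow(out0$clusters), 0)
  # modest Monte-Carlo check here; the full 1000-run version is in the
  # acceptance suite
  set.seed(31)
  fp <- 0
  for (i in 1:120) {
    noise <- array(rnorm(prod(g$dim) * 80), dim = c(g$dim, 80))
    thr <- apply_threshold(t_contrast(fit_glm(bold_run(g, noise, tr_s = 2.28),
                                              dm)), spec)
    if (any(thr$map$values > 0)) fp <- fp + 1
  }
  expect_lte(fp / 120, 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
  # planted activation with unit effect and noise survives FWE
  tp <- network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                        sigma = 10)))
  run <- simulate_task_run(tp, des, grid = g, n_volumes = 80,
                           effect_size = 1, noise_sd = 1, seed = 5)
  thr <- apply_threshold(t_contrast(fit_glm(run, dm)), spec)
  expect_gt(nrow(thr$clusters), 0)
  peak <- thr$clusters[1, ]
  expect_lte(sqrt(peak$x^2 + peak$y^2 + peak$z^2), 12)
})

test_that("cluster-level FDR with a permutation null keeps planted clusters only", {
  g <- tiny_grid(dim = c(10, 10, 10), vox = 6)
  des <- block_design(80, 2.28)
  dm <- build_design(des, 80, 2.28)
  tp <- network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                        sigma = 10)))
  run <- simulate_task_run(tp, des, grid = g, n_volumes = 80,
                           effect_size = 1, noise_sd = 1, seed = 6)
  fit <- fit_glm(run, dm)
  tmap <- t_contrast(fit)
  nulls <- perm_null_tmaps(fit, n_perm = 100, seed = 7)
  spec <- threshold_spec("FDR_cluster", alpha = 0.05,
                         cluster_forming_p = 0.001)
  out <- apply_threshold(tmap, spec, null_maps = nulls)
  expect_gt(nrow(out$clusters), 0)
  expect_lte(sqrt(sum(unlist(out$clusters[1, c("x", "y", "z")])^2)), 12)
  # pure-noise map yields nothing at the same spec
  set.seed(8)
  noise <- array(rnorm(prod(g$dim) * 80), dim = c(g$dim, 80))
  nfit <- fit_glm(bold_run(g, noise, tr_s = 2.28), dm)
  nout <- apply_threshold(t_contrast(nfit), spec,
                          null_maps = perm_null_tmaps(nfit, n_perm = 100,
                                                      seed = 9))
  expect_equal(sum(nout$map$values > 0), 0)
})

test_that("fixed-effects pooling of two sessions sharpens the contrast", {
  g <- tiny_grid(dim = c(6, 6, 6), vox = 6)
  des <- block_design(60, 2.28)
  dm <- build_design(des, 60, 2.28)
  tp <- network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                        sigma = 10)))
  fits <- lapply(1:2, function(s)
    fit_glm(simulate_task_run(tp, des, grid = g, n_volumes = 60,
                              effect_size = 1, noise_sd = 1, seed = s), dm))
  tp1 <- t_contrast(fits[[1]])
  tpool <- t_contrast_pooled(fits)
  expect_equal(attr(tpool, "dof"), 2 * fits[[1]]$dof)
  core <- mask_index(g, mni_to_voxel(g, c(0, 0, 0)))
  v <- which(as.vector(g$mask))[core]
  expect_gt(tpool$values[arrayInd(v, g$dim)], 0)
})
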