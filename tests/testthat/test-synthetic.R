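test_that("rendered template maps are sums of Gaussians with maxima at nodes", {
  g <- tiny_grid(dim = c(16, 16, 16), vox = 3)
  tp <- network_template("one", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                          sigma = 6)))
  m <- render_network_map(tp, g)
  peak_vox <- which(m$values == max(m$values), arr.ind = TRUE)
  expect_true(all(abs(voxel_to_mni(g, peak_vox[1, ])) <= g$voxel_size_mm))
  expect_gte(max(m$values), exp(-sum((1.5)^2 * 3) / 72))  # within 1 voxel of 1
  # zero-amplitude nodes give the zero map
  tp0 <- network_template("none", list(list(xyz = c(0, 0, 0), amplitude = 0,
                                            sigma = 6)))
  expect_true(all(render_network_map(tp0, g)$values == 0))
  # node outside the grid box errors
  tpo <- network_template("out", list(list(xyz = c(500, 0, 0), amplitude = 1,
                                           sigma = 6)))
  expect_error(render_network_map(tpo, g), "outside")
})

test_that("the language template's nodes are recovered as local maxima", {
  g <- volume_grid()  # default 3 mm MNI grid
  lang <- default_templates()[["LANG"]]
  m <- render_network_map(lang, g)
  pk <- local_maxima(m, 0.2, min_separation_mm = 8)
  nodes <- t(vapply(lang$nodes, function(n) n$xyz, numeric(3)))
  expect_gte(nrow(pk), nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    d <- sqrt((pk$x - nodes[i, 1])^2 + (pk$y - nodes[i, 2])^2 +
                (pk$z - nodes[i, 3])^2)
    expect_lte(min(d), 3)
  }
})

test_that("band-limited sources keep their power inside the band", {
  tr <- 2.28
  set.seed(5)
  for (i in 1:5) {
    s <- band_limited_series(270, tr, c(0.01, 0.1))
    expect_equal(mean(s), 0, tolerance = 1e-10)
    expect_equal(sd(s), 1, tolerance = 1e-10)
    p <- Mod(fft(s))^2
    f <- c(0, seq_len(269)) / (270 * tr)
    f <- pmin(f, 1 / tr - f)
    inband <- f >= 0.01 & f <= 0.1
    expect_gte(sum(p[inband]) / sum(p), 0.95)
  }
  expect_error(band_limited_series(100, 2.28, c(0.01, 0.5)), "Nyquist")
})

test_that("rest simulation is reproducible and rank-1 per template when noise-free", {
  g <- tiny_grid(dim = c(10, 10, 10), vox = 6)
  tp <- list(network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                             sigma = 10))))
  r1 <- simulate_rest_run(tp, grid = g, n_volumes = 40, noise_sd = 0, seed = 7)
  r2 <- simulate_rest_run(tp, grid = g, n_volumes = 40, noise_sd = 0, seed = 7)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_rest_run(tp, grid = g, n_volumes = 40, noise_sd = 0, seed = 8)
  expect_false(identical(r1$data, r3$data))
  # every in-support voxel time course is an exact multiple of s_1
  s1 <- r1$ground_truth$time_courses[, 1]
  X <- matrix(r1$data, prod(g$dim), 40)
  supp <- which(as.vector(r1$ground_truth$maps[[1]]$values) > 0.5)
  for (v in supp[1:5]) {
    expect_equal(cor(X[v, ], s1), 1, tolerance = 1e-12)
  }
  # generators leave the global RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_rest_run(tp, grid = g, n_volumes = 20, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("block designs tile the run and the task run records its truth", {
  d <- block_design(270, 2.28, 16)
  expect_equal(d$n_epochs, 38)  # floor(270 * 2.28 / 16)
  expect_equal(length(d$onsets$SG), 19)
  expect_equal(length(d$onsets$TL), 19)
  expect_equal(max(d$onsets$TL) + 16, 38 * 16)  # non-overlapping tiling
  expect_error(block_design(5, 2.28, 16), "design longer than run")

  g <- tiny_grid(dim = c(8, 8, 8), vox = 6)
  tp <- network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                        sigma = 10)))
  des <- block_design(60, 2.28)
  run <- simulate_task_run(tp, des, grid = g, n_volumes = 60,
                           effect_size = 1, noise_sd = 0.5, seed = 2)
  expect_equal(length(run$condition_track), 60)
  expect_setequal(unique(run$condition_track), c("SG", "TL", "rest"))
  expect_equal(length(run$ground_truth$regressor), 60)
  # effect 0 gives a pure noise + drift run: no correlation with regressor
  run0 <- simulate_task_run(tp, des, grid = g, n_volumes = 60,
                            effect_size = 0, noise_sd = 0, seed = 2,
                            drift_amplitude = 1)
  X <- matrix(run0$data, prod(g$dim), 60)
  expect_true(all(abs(cor(t(X[1:3, ]), run0$ground_truth$regressor) -
                        cor(X[1, ], run0$ground_truth$regressor)) < 1e-9))
  expect_error(simulate_task_run(tp, block_design(60, 2.28), grid = g,
                                 n_volumes = 30), "longer than run")
})

test_that("temporal band-pass keeps in-band structure and rejects bad bands", {
  g <- tiny_grid(dim = c(6, 6, 6), vox = 6)
  tp <- list(network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                             sigma = 12))))
  run <- simulate_rest_run(tp, grid = g, n_volumes = 80, noise_sd = 1,
                           seed = 3)
  bp <- bandpass_bold_run(run)
  v <- matrix(bp$data, prod(g$dim), 80)[100, ]
  p <- Mod(fft(v))^2
  f <- c(0, seq_len(79)) / (80 * run$tr_s)
  f <- pmin(f, 1 / run$tr_s - f)
  expect_gte(sum(p[f >= 0.01 & f <= 0.1]) / sum(p), 0.999)
  expect_error(bandpass_bold_run(run, c(0.01, 10)), "Nyquist")
})

test_that("BOLD runs round-trip through NIfTI with their sidecar", {
  g <- tiny_grid(dim = c(6, 6, 6), vox = 6)
  tp <- list(network_template("A", list(list(xyz = c(0, 0, 0), amplitude = 1,
                                             sigma = 12))))
  run <- simulate_rest_run(tp, grid = g, n_volumes = 10, seed = 4)
  path <- tempfile(fileext = ".nii.gz")
  write_bold_run(run, path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), c(6, 6, 6, 10))
  expect_equal(as.numeric(img), as.numeric(run$data))
  side <- jsonlite::read_json(sub("\\.nii\\.gz$", ".json", path))
  expect_equal(side$tr_s, 2.28)
  expect_equal(side$seed, 4)
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
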