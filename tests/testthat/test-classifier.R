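test_that("patch extraction copies the exact window and guards borders", {
  sys <- tiny_system()
  set.seed(51)
  vol <- array(rnorm(32 * 32 * sys$L), dim = c(32, 32, sys$L))
  p <- extract_patch(vol, c(11, 11))
  expect_equal(p, vol[1:21, 1:21, , drop = FALSE])
  p2 <- extract_patch(vol, c(15, 20))
  expect_equal(p2, vol[5:25, 10:30, , drop = FALSE])
  ones <- array(1, dim = c(32, 32, sys$L))
  expect_true(all(extract_patch(ones, c(16, 16)) == 1))
  expect_error(extract_patch(vol, c(10, 16)), "range error")
  expect_error(extract_patch(vol, c(16, 23)), "range error")
})

test_that("balanced training sets have the promised size, balance, labels", {
  phantoms <- tiny_phantoms(10)
  sys <- small_system64()
  ds <- build_training_set(phantoms, sys, task = "edge",
                           patches_per_image = 10, seed = 5)
  expect_equal(dim(ds$x)[4], 100L)
  ratio <- sum(ds$y == 1) / sum(ds$y == 0)
  expect_gte(ratio, 0.9); expect_lte(ratio, 1.1)
  # labels agree with a direct truth lookup at the sampled centres
  img_of <- rep(seq_along(phantoms), each = 10)
  for (k in seq(1, 100, by = 7)) {
    truth <- phantoms[[img_of[k]]]$truth
    is_edge <- any(truth$elements$row == ds$centers[k, 1] &
                     truth$elements$col == ds$centers[k, 2])
    expect_equal(ds$y[k], as.numeric(is_edge))
  }
  ds0 <- build_training_set(phantoms, sys, task = 0L,
                            patches_per_image = 10, seed = 6)
  for (k in seq(1, 100, by = 11)) {
    truth <- phantoms[[img_of[k]]]$truth
    has_bin <- any(truth$elements$row == ds0$centers[k, 1] &
                     truth$elements$col == ds0$centers[k, 2] &
                     truth$elements$bin == 0L)
    expect_equal(ds0$y[k], as.numeric(has_bin))
  }
  # patches are the coefficient windows of the normalized image
  vol <- shearlet_transform(normalize_image(phantoms[[1]]$image), sys)
  expect_equal(ds$x[, , , 1], extract_patch(vol, ds$centers[1, ]))
})

test_that("tasks without positive pixels fail loudly", {
  blank <- list(image = matrix(0, 64, 64),
                truth = wavefront_set(NULL, c(64, 64), 4))
  sys <- small_system64()
  expect_error(build_training_set(list(blank, blank), sys, task = 0L),
               "no positive pixels")
})

test_that("constant ensembles produce the degenerate predictions", {
  sys <- small_system64()
  img <- tiny_phantoms(1)[[1]]$image
  off <- constant_ensemble(sys, edge_on = FALSE)
  wf0 <- predict_wavefront_set(img, sys, off)
  expect_equal(nrow(wf0$elements), 0L)
  on <- constant_ensemble(sys, edge_on = TRUE, orientations_on = TRUE)
  wf1 <- predict_wavefront_set(img, sys, on)
  n_int <- 64 - 20
  expect_equal(nrow(wf1$elements), n_int^2 * 4L)
  expect_true(all(wf1$elements$row >= 11 & wf1$elements$row <= 54))
})

test_that("predicted sets from a trained mini ensemble stay in the interior
           and beat noise-labelled truth", {
  phantoms <- tiny_phantoms(12)
  sys <- small_system64()
  ens <- train_wavefront_extractor(
    phantoms[1:10], sys,
    config = train_config(epochs = 3, seed = 7),
    channels = c(4L, 8L, 8L), dense_width = 16L,
    calibration_fraction = 0)
  wf <- predict_wavefront_set(phantoms[[11]]$image, sys, ens)
  if (nrow(wf$elements)) {
    expect_true(all(wf$elements$row >= 11 & wf$elements$row <= 54))
    expect_true(all(wf$elements$col >= 11 & wf$elements$col <= 54))
  }
  truth <- restrict_to_interior(phantoms[[11]]$truth)
  real_mf <- mf_score(wf, truth)
  noise <- truth
  set.seed(1)
  noise$elements$row <- sample(11:54, nrow(noise$elements), TRUE)
  noise$elements$col <- sample(11:54, nrow(noise$elements), TRUE)
  noise <- wavefront_set(noise$elements, truth$dims, truth$n_orientations)
  expect_gte(real_mf, mf_score(wf, noise))
})

test_that("ensembles survive a save/load round trip", {
  phantoms <- tiny_phantoms(4)
  sys <- small_system64()
  ens <- train_wavefront_extractor(
    phantoms, sys, config = train_config(epochs = 1, seed = 8),
    channels = c(2L, 4L), dense_width = 8L, calibration_fraction = 0)
  dir <- file.path(tempdir(), "bundle-test")
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ens2 <- load_ensemble(dir)
  expect_equal(ens2$n_orientations, ens$n_orientations)
  expect_equal(ens2$tau_edge, ens$tau_edge)
  img <- phantoms[[1]]$image
  expect_equal(predict_wavefront_set(img, sys, ens2)$elements,
               predict_wavefront_set(img, sys, ens)$elements)
  unlink(dir, recursive = TRUE)
})
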