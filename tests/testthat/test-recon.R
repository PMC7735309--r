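# small geometries keep the sparse system matrices cheap
recon_geom <- function() {
  fixture("recon_geom", function() lowdose_geometry(9, n_det = 48,
                                                    image_size = 32))
}
recon_A <- function() fixture("recon_A", function()
  shearwf:::ray_matrix(recon_geom()))

test_that("FBP is zero on zero and recovers a disk on full-angle data", {
  geomf <- sinogram_geometry(n_angles = 90, n_det = 192, image_size = 128)
  zero <- structure(list(data = matrix(0, 90, 192), geometry = geomf),
                    class = "sinogram")
  expect_true(all(fbp(zero) == 0))
  img <- rasterize(ellipse(0.1, -0.1, 0.45, 0.45, 0, 1, 0), 128, 4)
  rec <- fbp(ray_transform(img, geomf))
  expect_gte(stats::cor(as.vector(rec), as.vector(img)), 0.95)
})

test_that("an impulse sinogram back-projects to a ridge along its line", {
  geom <- sinogram_geometry(n_angles = 12, n_det = 64, image_size = 64)
  data <- matrix(0, 12, 64)
  ai <- 4; oi <- 40
  data[ai, oi] <- 1
  rec <- fbp(structure(list(data = data, geometry = geom),
                       class = "sinogram"),
             recon_config("fbp", fbp_filter = "hann"))
  th <- geom$angles[ai]; p <- geom$offsets[oi]
  coords <- (2 * (seq_len(64) - 1) + 1) / 64 - 1
  xx <- matrix(coords, 64, 64, byrow = TRUE)
  yy <- matrix(coords, 64, 64)
  dist_line <- abs(xx * cos(th) + yy * sin(th) - p)
  on_line <- dist_line < 2 / 64
  off_line <- dist_line > 10 / 64
  expect_gt(mean(rec[on_line]), 5 * mean(abs(rec[off_line])))
})

test_that("CG Tikhonov matches a dense direct solve on a toy problem", {
  geom <- sinogram_geometry(n_angles = 10, n_det = 24, image_size = 16)
  set.seed(81)
  img <- rasterize(ellipse(0.1, 0, 0.5, 0.35, 0.4, 1, 0), 16, 2)
  sino <- ray_transform(img, geom)
  lambda <- 0.05
  A <- as.matrix(shearwf:::ray_matrix(geom))
  D <- as.matrix(shearwf:::gradient_matrix(16))
  g <- as.vector(t(sino$data))
  direct <- solve(crossprod(A) + lambda * crossprod(D), crossprod(A, g))
  cg <- tikhonov_recon(sino, recon_config("tikhonov", lambda = lambda,
                                          iterations = 400L,
                                          tolerance = 1e-12))
  expect_lt(max(abs(as.vector(cg) - direct)), 1e-4)
})

test_that("Tikhonov flattens with larger lambda and its objective decreases", {
  geom <- recon_geom()
  img <- rasterize(ellipse(0, 0.1, 0.5, 0.3, 0.2, 1, 0), 32, 2)
  sino <- ray_transform(img, geom)
  A <- recon_A()
  D <- shearwf:::gradient_matrix(32)
  grad_norm <- function(lambda) {
    f <- tikhonov_recon(sino, recon_config("tikhonov", lambda = lambda,
                                           iterations = 150L), A = A)
    sqrt(sum(as.vector(D %*% as.vector(f))^2))
  }
  expect_gt(grad_norm(0.001), grad_norm(1))
  g <- as.vector(t(sino$data))
  objective <- function(iters) {
    f <- as.vector(tikhonov_recon(sino, recon_config(
      "tikhonov", lambda = 0.01, iterations = iters, tolerance = 0),
      A = A))
    sum((as.vector(A %*% f) - g)^2) +
      0.01 * sum(as.vector(D %*% f)^2)
  }
  objs <- vapply(c(2L, 5L, 15L, 40L), objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-8))
})

test_that("TV reconstruction reduces total variation and energy over time", {
  geom <- recon_geom()
  img <- rasterize(ellipse(0, 0, 0.55, 0.4, 0, 1, 0), 32, 2)
  sino <- ray_transform(img, geom)
  set.seed(82)
  sino$data <- sino$data + matrix(rnorm(length(sino$data),
                                        sd = 0.03 * max(sino$data)),
                                  nrow(sino$data))
  A <- recon_A()
  D <- shearwf:::gradient_matrix(32)
  tvn <- function(f) {
    gr <- as.vector(D %*% as.vector(f))
    n <- length(f)
    sum(sqrt(gr[seq_len(n)]^2 + gr[n + seq_len(n)]^2))
  }
  rec_tv <- tv_recon(sino, recon_config("tv", lambda = 0.01,
                                        iterations = 150L), A = A)
  rec_fbp <- fbp(sino)
  expect_lt(tvn(rec_tv), tvn(rec_fbp))
  g <- as.vector(t(sino$data))
  obj <- vapply(c(10L, 60L, 150L), function(it)
    shearwf:::tv_objective(as.vector(tv_recon(
      sino, recon_config("tv", lambda = 0.01, iterations = it), A = A)),
      g, A, D, 0.01), numeric(1))
  expect_lt(obj[2], obj[1])
  expect_lte(obj[3], obj[2] + 1e-6)
})

test_that("TV with lambda = 0 approaches the least-squares solution", {
  geom <- sinogram_geometry(n_angles = 40, n_det = 24, image_size = 16)
  img <- rasterize(ellipse(0, 0, 0.5, 0.35, 0.1, 1, 0), 16, 2)
  sino <- ray_transform(img, geom)
  A <- shearwf:::ray_matrix(geom)
  ls <- tikhonov_recon(sino, recon_config("tikhonov", lambda = 1e-10,
                                          iterations = 500L,
                                          tolerance = 1e-12), A = A)
  tv0 <- tv_recon(sino, recon_config("tv", lambda = 0,
                                     iterations = 3000L), A = A)
  expect_lt(norm(tv0 - ls, "F") / norm(ls, "F"), 0.05)
})

test_that("benchmark plumbing handles oracle and empty predictors", {
  sys <- small_system64()
  geom <- lowdose_geometry(6, n_det = 80, image_size = 64)
  cfg <- phantom_config(image_size = 64, n_small = c(1, 2),
                        n_orientations = 4)
  ph <- sample_head_phantom(cfg, seed = 90)
  # all-empty predictors: every route scores the penalty cap
  sys_s <- fixture("sys80", function()
    build_shearlet_system(shearlet_config(80, n_scales = 2)))
  ens_off_i <- constant_ensemble(sys, edge_on = FALSE)
  ens_off_s <- constant_ensemble(sys_s, edge_on = FALSE)
  res <- benchmark_wavefront_recovery(
    ph, geom, ens_off_i, ens_off_s, sys, sys_s,
    configs = list(fbp = recon_config("fbp"),
                   tikhonov = recon_config("tikhonov", lambda = 0.005,
                                           iterations = 10L),
                   tv = recon_config("tv", lambda = 1e-3,
                                     iterations = 20L)),
    penalty_cap = 77, seed = 3)
  expect_equal(res$wavefront_mse, rep(77, 4))
  # oracle sinogram wavefront: the canonical route error is at the
  # digitization scale
  ts <- sinogram_wavefront_truth(ph, geom)
  q <- attr(ts, "q")
  inv <- canonical_inverse(ts$elements$row, ts$elements$col, q, geom, 4)
  pred <- wavefront_set(inv[, c("row", "col", "bin")], c(64, 64), 4)
  truth_vis <- visible_wavefront(restrict_to_interior(ph$truth), geom)
  expect_lt(wavefront_mse(pred, truth_vis, bin_tolerance = 1), 4)
})
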