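test_that("ray transform is zero on zero and matches disk chord lengths", {
  geom <- sinogram_geometry(n_angles = 8, n_det = 181, image_size = 256)
  z <- ray_transform(matrix(0, 256, 256), geom)
  expect_true(all(z$data == 0))
  img <- rasterize(ellipse(0, 0, 0.5, 0.5, 0, 1, 0), 256, 4)
  sg <- ray_transform(img, geom)
  p0 <- which.min(abs(geom$offsets))
  expect_lt(max(abs(sg$data[, p0] - 1)), 0.01)  # chord 2r = 1 at p = 0
  # radially symmetric image: columns constant over angle
  expect_lt(max(apply(sg$data, 2, function(cc) diff(range(cc)))), 1e-2)
})

test_that("ray transform preserves mass per angle within 1%", {
  geom <- sinogram_geometry(n_angles = 5, n_det = 128, image_size = 128)
  img <- rasterize(rbind(ellipse(0.2, -0.1, 0.4, 0.25, 0.4, 1, 0),
                         ellipse(-0.2, 0.2, 0.2, 0.15, 1.2, 0.5, 0.01)),
                   128, 4)
  sg <- ray_transform(img, geom)
  mass <- sum(img) * (2 / 128)^2
  dp <- geom$offsets[2] - geom$offsets[1]
  for (ai in seq_along(geom$angles)) {
    expect_lt(abs(sum(sg$data[ai, ]) * dp - mass) / mass, 0.01)
  }
})

test_that("the sparse system matrix is the exact transform and adjoint", {
  geom <- lowdose_geometry(12, n_det = 48, image_size = 32)
  A <- shearwf:::ray_matrix(geom)
  set.seed(61)
  img <- matrix(rnorm(32 * 32), 32)
  s1 <- ray_transform(img, geom)$data
  s2 <- matrix(as.vector(A %*% as.vector(img)),
               nrow = length(geom$angles), byrow = TRUE)
  expect_lt(max(abs(s1 - s2)), 1e-12)
  v <- rnorm(nrow(A)); w <- rnorm(ncol(A))
  expect_lt(abs(sum((A %*% w) * v) -
                  sum(w * as.vector(Matrix::crossprod(A, v)))), 1e-9)
})

test_that("canonical relations are mutually inverse on the grid", {
  # angles aligned with the bin centres make the round trip exact up to
  # half-grid rounding
  n_or <- 8L
  geom <- sinogram_geometry(image_size = 64, n_det = 96,
                            angles = shearwf:::bin_center_angle(0:7, 8))
  set.seed(62)
  for (i in 1:25) {
    row <- sample(10:55, 1); col <- sample(10:55, 1)
    bin <- sample(0:7, 1)
    fw <- canonical_forward(row, col, bin, n_or, geom)
    expect_equal(nrow(fw), 1L)
    inv <- canonical_inverse(fw$angle_idx, fw$offset_idx, fw$q, geom, n_or)
    expect_lte(abs(inv$row - row), 1)
    expect_lte(abs(inv$col - col), 1)
    expect_equal(inv$bin, bin)
    # grid-aligned element maps forward onto itself
    fw2 <- canonical_forward(inv$row, inv$col, inv$bin, n_or, geom)
    expect_equal(fw2$angle_idx, fw$angle_idx)
    expect_lte(abs(fw2$offset_idx - fw$offset_idx), 1)
  }
})

test_that("canonical forward reproduces circle geometry and the origin", {
  n_or <- 180L
  geom <- sinogram_geometry(n_angles = 180, n_det = 256, image_size = 128)
  # near-origin pixel: p0 ~ 0, q ~ 0
  fw <- canonical_forward(64, 64, 45, n_or, geom)
  expect_lt(abs(fw$p), 2 / 128)
  expect_lt(abs(fw$q), 2 / 128)
  # circle centred at c: boundary point with normal angle alpha has
  # p0 = c . omega(alpha) + r
  cx <- 0.2; cy <- -0.1; r <- 0.4
  wf <- analytic_wavefront_set(ellipse(cx, cy, r, r, 0, 1, 0), 128, n_or)
  e <- wf$elements[seq(1, nrow(wf$elements), by = 23), ]
  for (i in seq_len(nrow(e))) {
    fw <- canonical_forward(e$row[i], e$col[i], e$bin[i], n_or, geom)
    alpha <- fw$theta
    expected_p <- cx * cos(alpha) + cy * sin(alpha) + r
    # the element's normal may point inward: then p0 = c.omega - r
    expect_true(min(abs(fw$p - expected_p),
                    abs(fw$p - (cx * cos(alpha) + cy * sin(alpha) - r)))
                < 0.03)
  }
})

test_that("visibility filtering matches a direct angle-distance oracle", {
  wf <- analytic_wavefront_set(ellipse(0, 0, 0.5, 0.5, 0, 1, 0), 128, 180)
  dense <- sinogram_geometry(n_angles = 180, n_det = 64, image_size = 128)
  expect_equal(nrow(visible_wavefront(wf, dense)$elements),
               nrow(wf$elements))
  sparse <- lowdose_geometry(6, n_det = 64, image_size = 128)
  tol <- 1.5 * pi / 180
  vis <- visible_wavefront(wf, sparse, angle_tolerance = tol)
  centers <- shearwf:::bin_center_angle(wf$elements$bin, 180)
  keep <- vapply(centers, function(a)
    min(shearwf:::angle_dist_mod_pi(sparse$angles, a)) <= tol + 1e-12,
    logical(1))
  expect_equal(nrow(vis$elements), sum(keep))
  # visibility is monotone in the measured angles
  denser <- lowdose_geometry(3, n_det = 64, image_size = 128)
  vis2 <- visible_wavefront(wf, denser, angle_tolerance = tol)
  expect_gte(nrow(vis2$elements), nrow(vis$elements))
  key <- function(w) paste(w$elements$row, w$elements$col, w$elements$bin)
  expect_true(all(key(vis) %in% key(vis2)))
})

test_that("sinogram wavefront truth lies on the sinusoid and inverts back", {
  geom <- lowdose_geometry(6, n_det = 80, image_size = 64)
  cfg <- phantom_config(image_size = 64, n_small = c(0, 0),
                        n_orientations = 8)
  empty <- list(truth = wavefront_set(NULL, c(64, 64), 8))
  expect_equal(nrow(sinogram_wavefront_truth(empty, geom)$elements), 0L)
  # small off-centre dot: sinogram elements concentrate on p = x0.omega
  dot <- ellipse(0.3, -0.2, 0.05, 0.05, 0, 1, 0)
  ph <- list(truth = analytic_wavefront_set(dot, 64, 8))
  ts <- sinogram_wavefront_truth(ph, geom)
  expect_gt(nrow(ts$elements), 0)
  th <- geom$angles[ts$elements$row]
  p_curve <- 0.3 * cos(th) + (-0.2) * sin(th)
  p_elem <- geom$offsets[ts$elements$col]
  dp <- geom$offsets[2] - geom$offsets[1]
  expect_lt(max(abs(p_elem - p_curve)), 0.05 + 2 * dp + dp / 2)
  # mapping truth elements back lands near the image truth
  ph2 <- sample_head_phantom(phantom_config(image_size = 64,
                                            n_small = c(2, 3),
                                            n_orientations = 8), seed = 71)
  ts2 <- sinogram_wavefront_truth(ph2, geom)
  q <- attr(ts2, "q")
  inv <- canonical_inverse(ts2$elements$row, ts2$elements$col, q, geom, 8)
  truth <- ph2$truth$elements
  for (i in seq(1, nrow(inv), by = 17)) {
    d <- sqrt((truth$row - inv$row[i])^2 + (truth$col - inv$col[i])^2)
    bd <- pmin(abs(truth$bin - inv$bin[i]),
               8 - abs(truth$bin - inv$bin[i]))
    expect_true(any(d <= 2 & bd <= 1))
  }
})

test_that("canvas embedding and collapse are inverse and flip-aware", {
  geom <- lowdose_geometry(6, n_det = 64, image_size = 64)
  set.seed(63)
  img <- rasterize(ellipse(0.1, 0.2, 0.3, 0.2, 0.3, 1, 0), 64, 2)
  sg <- ray_transform(img, geom)
  canvas <- sinogram_canvas(sg, 64)
  nA <- length(geom$angles)
  expect_equal(canvas[1:nA, ], sg$data)
  # odd half-turn band is the detector-flipped copy
  expect_equal(canvas[nA + 1, ], rev(sg$data[1, ]))
  wf <- wavefront_set(data.frame(row = c(3, 14), col = c(20, 41),
                                 bin = c(1, 6)), c(nA, 64), 8)
  cv <- canvas_wavefront(wf, 64)
  back <- canvas_to_sinogram(cv, nA, 64)
  expect_equal(back$elements, wf$elements)
})
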