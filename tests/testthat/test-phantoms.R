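test_that("sampling is deterministic and respects the ellipse-count range", {
  cfg <- phantom_config(image_size = 64, n_orientations = 8)
  p1 <- sample_head_phantom(cfg, seed = 3)
  p2 <- sample_head_phantom(cfg, seed = 3)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth$elements, p2$truth$elements)
  cfg0 <- phantom_config(image_size = 64, n_small = c(0, 0))
  expect_equal(nrow(sample_head_phantom(cfg0, seed = 1)$ellipses), 2L)
})

test_that("interior ellipses stay inside the inner skull", {
  cfg <- phantom_config(image_size = 64)
  for (seed in 1:100) {
    el <- shearwf:::with_seed(seed, shearwf:::sample_head_ellipses(cfg))
    inner <- el[2, ]
    small <- el[-(1:2), , drop = FALSE]
    if (!nrow(small)) next
    # every point of each small ellipse inside the inner skull ellipse
    for (k in seq_len(nrow(small))) {
      e <- small[k, ]
      tau <- seq(0, 2 * pi, length.out = 97)
      bx <- e$cx + cos(e$phi) * e$a * cos(tau) - sin(e$phi) * e$b * sin(tau)
      by <- e$cy + sin(e$phi) * e$a * cos(tau) + cos(e$phi) * e$b * sin(tau)
      expect_true(all((bx / inner$a)^2 + (by / inner$b)^2 <= 1 + 1e-9))
    }
  }
})

test_that("rasterization reproduces disk geometry, area and additivity", {
  e <- ellipse(0, 0, 0.5, 0.5, 0, 1, 0)
  img <- rasterize(e, 128, 4)
  expect_equal(img[64, 64], 1)
  expect_equal(img[1, 1], 0)
  area <- pi * 0.5 * 0.5 * 128^2 / 4
  expect_lt(abs(sum(img) - area) / area, 0.005)
  e2 <- ellipse(0.3, -0.2, 0.2, 0.1, 0.7, -0.5, 0)
  both <- rasterize(rbind(e, e2), 64, 2)
  expect_equal(both, rasterize(e, 64, 2) + rasterize(e2, 64, 2))
})

test_that("analytic truth carries the outward normal orientation", {
  # axis-aligned ellipse: at (cx + a, cy) the normal points along +x (bin
  # straddles 0 degrees)
  e <- ellipse(0.1, -0.2, 0.4, 0.2, 0, 1, 0)
  wf <- analytic_wavefront_set(e, 128, 180)
  rr <- round(((-0.2 + 1) * 128 + 1) / 2)
  cc <- round(((0.5 + 1) * 128 + 1) / 2)
  near <- wf$elements[abs(wf$elements$row - rr) <= 1 &
                        abs(wf$elements$col - cc) <= 1, ]
  expect_gt(nrow(near), 0)
  expect_true(all(pmin(near$bin, 180 - near$bin) <= 15))
  # circle: normal orientation at boundary angle alpha is alpha mod 180
  ec <- ellipse(0, 0, 0.5, 0.5, 0, 1, 0)
  wfc <- analytic_wavefront_set(ec, 128, 180)
  M <- 128
  x <- (2 * (wfc$elements$col - 1) + 1) / M - 1
  y <- (2 * (wfc$elements$row - 1) + 1) / M - 1
  alpha <- (atan2(y, x) * 180 / pi) %% 180
  bindist <- abs(wfc$elements$bin + 0.5 - alpha)
  bindist <- pmin(bindist, 180 - bindist)
  expect_lt(max(bindist), 2.5)
})

test_that("truth orientations agree with a super-resolved gradient oracle", {
  # the oracle itself (central differences on the 8x super-resolved ramp)
  # carries ~2 degrees of direction error, so the +-1-bin agreement is
  # checked at a bin width just above that error (72 bins of 2.5 degrees)
  e <- ellipse(-0.1, 0.15, 0.45, 0.35, 0.6, 1, 0.02)
  M <- 64
  nb <- 72L
  wf <- analytic_wavefront_set(e, M, nb)
  S <- 8L
  fine <- rasterize(e, M * S, 1)
  # dense boundary polyline to locate each element's nearest boundary point
  tau <- seq(0, 2 * pi, length.out = 4001)[-4001]
  bx <- e$cx + cos(e$phi) * e$a * cos(tau) - sin(e$phi) * e$b * sin(tau)
  by <- e$cy + sin(e$phi) * e$a * cos(tau) + cos(e$phi) * e$b * sin(tau)
  idx <- seq(1, nrow(wf$elements), length.out = min(40, nrow(wf$elements)))
  for (i in unique(round(idx))) {
    el <- wf$elements[i, ]
    px <- (2 * (el$col - 1) + 1) / M - 1
    py <- (2 * (el$row - 1) + 1) / M - 1
    k <- which.min((bx - px)^2 + (by - py)^2)
    # fine pixel containing the nearest boundary point
    r <- round(((by[k] + 1) * M * S + 1) / 2)
    cc <- round(((bx[k] + 1) * M * S + 1) / 2)
    gx <- (fine[r, cc + 1] - fine[r, cc - 1]) / 2
    gy <- (fine[r + 1, cc] - fine[r - 1, cc]) / 2
    ang <- (atan2(gy, gx) * 180 / pi) %% 180
    oracle_bin <- floor(ang / (180 / nb)) %% nb
    d <- min(abs(el$bin - oracle_bin), nb - abs(el$bin - oracle_bin))
    expect_lte(d, 1)
  }
})

test_that("truth is non-empty iff some ellipse has non-zero intensity", {
  e0 <- ellipse(0, 0, 0.5, 0.3, 0, 0, 0)
  expect_equal(nrow(analytic_wavefront_set(e0, 64, 8)$elements), 0L)
  e1 <- ellipse(0, 0, 0.5, 0.3, 0, 0.4, 0)
  expect_gt(nrow(analytic_wavefront_set(e1, 64, 8)$elements), 0L)
})

test_that("edge mask matches the half-pixel distance rule for a circle", {
  r <- 0.5; M <- 96
  wf <- analytic_wavefront_set(ellipse(0, 0, r, r, 0, 1, 0), M, 8)
  mask <- edge_mask(wf)
  coords <- (2 * (seq_len(M) - 1) + 1) / M - 1
  dist_to_circle <- abs(sqrt(outer(coords^2, coords^2, "+")) - r)
  half <- 1 / M
  # exact rule up to the polyline sampling slack
  expect_true(all(mask[dist_to_circle <= half * 0.95]))
  expect_true(!any(mask[dist_to_circle > half * 1.05]))
})

test_that("circle truth orientations are close to uniform over bins", {
  wf <- analytic_wavefront_set(ellipse(0, 0, 0.6, 0.6, 0, 1, 0), 256, 8)
  h <- tabulate(wf$elements$bin + 1L, 8)
  expect_gt(min(h), 0.8 * mean(h))
  expect_lt(max(h), 1.2 * mean(h))
})
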