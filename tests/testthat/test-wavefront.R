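test_that("constructor validates, deduplicates and derives the edge mask", {
  wf <- wf_from(rbind(c(1, 2, 3), c(1, 2, 3), c(5, 6, 0)))
  expect_equal(nrow(wf$elements), 2L)
  m <- edge_mask(wf)
  expect_true(m[1, 2] && m[5, 6])
  expect_equal(sum(m), 2L)
  expect_error(wf_from(rbind(c(0, 2, 3))), "outside")
  expect_error(wf_from(rbind(c(1, 40, 3))), "outside")
  expect_error(wf_from(rbind(c(1, 2, 9))), "bins")
})

test_that("orientation F-score matches F-measure arithmetic", {
  truth <- wf_from(cbind(seq(2, 29, by = 3), 5, 2))
  expect_equal(orientation_fscore(truth, truth, 2, match_tolerance()), 1)
  empty <- wf_from(matrix(numeric(0), ncol = 3))
  expect_equal(orientation_fscore(empty, truth, 2, match_tolerance()), 0)
  expect_equal(orientation_fscore(empty, empty, 2, match_tolerance()), 1)
  # half of truth predicted, nothing spurious: F = 2 * 0.5 / 1.5 = 2/3
  half <- wf_from(cbind(seq(2, 29, by = 3), 5, 2)[1:5, , drop = FALSE])
  expect_equal(orientation_fscore(half, truth, 2, match_tolerance()), 2 / 3)
})

test_that("MF-score handles identity, disjoint sets and 90-degree rotation", {
  truth <- wf_from(rbind(c(3, 4, 1), c(10, 12, 5), c(20, 8, 1)))
  expect_equal(mf_score(truth, truth), 1)
  far <- wf_from(rbind(c(30, 30, 3)))
  expect_equal(mf_score(far, truth), 0)
  # simultaneous quarter-turn of both sets leaves the score unchanged
  rot <- function(wf) {
    e <- wf$elements
    wf_from(cbind(e$col, 32 + 1 - e$row, (e$bin + 2) %% 8))
  }
  pred <- wf_from(rbind(c(3, 5, 1), c(10, 12, 5), c(25, 25, 2)))
  expect_equal(mf_score(rot(pred), rot(truth)), mf_score(pred, truth))
})

test_that("Hausdorff distance matches a brute-force oracle", {
  expect_equal(hausdorff_distance(wf_from(rbind(c(3, 4, 2))),
                                  wf_from(rbind(c(3, 4, 2)))), 0)
  a <- wf_from(rbind(c(3, 4, 2)))
  b <- wf_from(rbind(c(3, 9, 2)))
  expect_equal(hausdorff_distance(a, b), 5)
  set.seed(9)
  A <- wf_from(cbind(sample(32, 30, TRUE), sample(32, 30, TRUE),
                     sample(0:7, 30, TRUE)))
  B <- wf_from(cbind(sample(32, 25, TRUE), sample(32, 25, TRUE),
                     sample(0:7, 25, TRUE)))
  oracle <- function(p, q, scale = 1) {
    d <- function(i, j) {
      sqrt((p$row[i] - q$row[j])^2 + (p$col[i] - q$col[j])^2) +
        scale * min(abs(p$bin[i] - q$bin[j]),
                    8 - abs(p$bin[i] - q$bin[j]))
    }
    m1 <- max(sapply(seq_len(nrow(p)), function(i)
      min(sapply(seq_len(nrow(q)), function(j) d(i, j)))))
    m2 <- max(sapply(seq_len(nrow(q)), function(j)
      min(sapply(seq_len(nrow(p)), function(i) d(i, j)))))
    max(m1, m2)
  }
  expect_equal(hausdorff_distance(A, B), oracle(A$elements, B$elements))
  expect_equal(hausdorff_distance(A, B, bin_scale = 2.5),
               oracle(A$elements, B$elements, scale = 2.5))
})

test_that("wavefront MSE matches a nearest-neighbour oracle and its caps", {
  truth <- wf_from(rbind(c(3, 4, 2), c(10, 10, 6), c(20, 25, 0)))
  expect_equal(wavefront_mse(truth, truth), 0)
  empty <- wf_from(matrix(numeric(0), ncol = 3))
  expect_equal(wavefront_mse(empty, truth, penalty_cap = 123), 123)
  expect_equal(wavefront_mse(truth, empty), 0)
  set.seed(10)
  P <- wf_from(cbind(sample(32, 20, TRUE), sample(32, 20, TRUE),
                     sample(0:7, 20, TRUE)))
  oracle <- 0
  for (i in seq_len(nrow(truth$elements))) {
    t <- truth$elements[i, ]
    ds <- Inf
    for (j in seq_len(nrow(P$elements))) {
      p <- P$elements[j, ]
      bd <- min(abs(p$bin - t$bin), 8 - abs(p$bin - t$bin))
      if (bd <= 2) {
        ds <- min(ds, (p$row - t$row)^2 + (p$col - t$col)^2)
      }
    }
    oracle <- oracle + min(ds, 1000)
  }
  expect_equal(wavefront_mse(P, truth), oracle / 3)
})

test_that("metrics reject mismatched domains", {
  a <- wf_from(rbind(c(1, 1, 0)))
  b <- wavefront_set(data.frame(row = 1, col = 1, bin = 0), c(16, 16), 8)
  expect_error(mf_score(a, b), "domain")
  expect_error(wavefront_mse(a, b), "domain")
})

test_that("pooled MF aggregates counts across pairs", {
  t1 <- wf_from(rbind(c(3, 4, 1), c(9, 9, 1)))
  t2 <- wf_from(rbind(c(5, 5, 1)))
  # first image fully missed, second fully hit: pooled recall 1/3 for bin 1
  p1 <- wf_from(matrix(numeric(0), ncol = 3))
  p2 <- t2
  pooled <- mf_score_pooled(list(p1, p2), list(t1, t2), bins = 1L)
  expect_equal(pooled, 2 * (1 * 1 / 3) / (1 + 1 / 3))
})
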