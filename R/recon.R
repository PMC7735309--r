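# Classical reconstruction baselines (filtered back-projection, Tikhonov,
# total variation) and the wavefront-recovery benchmark comparing the
# invert-then-extract routes against the canonical-relation route.

#' Reconstruction configuration
#'
#' @param method one of \code{"fbp"}, \code{"tikhonov"}, \code{"tv"}.
#' @param fbp_filter ramp filter window: \code{"ram-lak"} or \code{"hann"}.
#' @param lambda regularization weight (> 0) for tikhonov/tv.
#' @param iterations iteration count of the iterative solvers.
#' @param tolerance relative residual tolerance of the conjugate-gradient
#'   solver.
#' @return object of class \code{recon_config}.
#' @export
recon_config <- function(method = c("fbp", "tikhonov", "tv"),
                         fbp_filter = c("ram-lak", "hann"),
                         lambda = 0.01, iterations = 100L,
                         tolerance = 1e-8) {
  method <- match.arg(method)
  fbp_filter <- match.arg(fbp_filter)
  stopifnot(lambda >= 0, iterations >= 1)
  structure(list(method = method, fbp_filter = fbp_filter, lambda = lambda,
                 iterations = as.integer(iterations), tolerance = tolerance),
            class = "recon_config")
}

#' Filtered back-projection
#'
#' Ramp-filters each projection along the detector axis (optionally with a
#' Hann window) and back-projects with bilinear interpolation over the
#' measured angles.
#'
#' @param sinogram a [ray_transform()] result (or matching list).
#' @param config a [recon_config()] (only the filter choice is used).
#' @return \code{M x M} reconstruction matrix.
#' @export
fbp <- function(sinogram, config = recon_config("fbp")) {
  geom <- sinogram$geometry
  g <- sinogram$data
  nD <- ncol(g)
  dp <- geom$offsets[2] - geom$offsets[1]
  freqs <- fft_freqs(nD) / (nD * dp)
  filt <- abs(freqs)
  if (config$fbp_filter == "hann") {
    filt <- filt * (0.5 + 0.5 * cos(pi * freqs / max(abs(freqs))))
  }
  q <- t(apply(g, 1, function(row)
    Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / nD))
  M <- geom$image_size
  coords <- (2 * (seq_len(M) - 1) + 1) / M - 1
  xx <- matrix(coords, M, M, byrow = TRUE)
  yy <- matrix(coords, M, M)
  dth <- if (length(geom$angles) > 1) mean(diff(geom$angles)) else pi
  rec <- matrix(0, M, M)
  for (ai in seq_along(geom$angles)) {
    th <- geom$angles[ai]
    p <- xx * cos(th) + yy * sin(th)
    fi <- (p - geom$offsets[1]) / dp + 1
    i0 <- floor(fi); d <- fi - i0
    v0 <- ifelse(i0 >= 1 & i0 <= nD, q[ai, pmin(pmax(i0, 1L), nD)], 0)
    v1 <- ifelse(i0 + 1 >= 1 & i0 + 1 <= nD,
                 q[ai, pmin(pmax(i0 + 1L, 1L), nD)], 0)
    rec <- rec + (1 - d) * v0 + d * v1
  }
  rec * dth
}

# sparse forward-difference gradient operator (2 M^2 x M^2), Neumann
# boundary (zero rows at the far edge)
#' @keywords internal
gradient_matrix <- function(M) {
  n <- M * M
  idx <- matrix(seq_len(n), M, M)
  # vertical differences (along rows)
  i1 <- as.vector(idx[-M, ]); i2 <- as.vector(idx[-1, ])
  Dv <- Matrix::sparseMatrix(i = c(seq_along(i1), seq_along(i1)),
                             j = c(i1, i2), x = c(rep(-1, length(i1)),
                                                  rep(1, length(i1))),
                             dims = c(n, n))
  # horizontal differences (along cols)
  j1 <- as.vector(idx[, -M]); j2 <- as.vector(idx[, -1])
  Dh <- Matrix::sparseMatrix(i = c(seq_along(j1), seq_along(j1)),
                             j = c(j1, j2), x = c(rep(-1, length(j1)),
                                                  rep(1, length(j1))),
                             dims = c(n, n))
  rbind(Dv, Dh)
}

#' Tikhonov-regularized reconstruction
#'
#' Minimizes \code{||R f - g||^2 + lambda ||grad f||^2} by conjugate
#' gradients on the normal equations (the objective is the CG quadratic, so
#' it is non-increasing across iterations).
#'
#' @param sinogram a [ray_transform()] result.
#' @param config a [recon_config()] with \code{method = "tikhonov"}.
#' @param A optional precomputed [ray_matrix()] of the geometry.
#' @return \code{M x M} reconstruction matrix.
#' @export
tikhonov_recon <- function(sinogram, config = recon_config("tikhonov"),
                           A = NULL) {
  geom <- sinogram$geometry
  M <- geom$image_size
  if (is.null(A)) A <- ray_matrix(geom)
  D <- gradient_matrix(M)
  g <- as.vector(t(sinogram$data))     # row-major: angle-major rows
  rhs <- as.vector(Matrix::crossprod(A, g))
  apply_op <- function(v) {
    as.vector(Matrix::crossprod(A, A %*% v)) +
      config$lambda * as.vector(Matrix::crossprod(D, D %*% v))
  }
  x <- numeric(M * M)
  r <- rhs
  p <- r
  rs <- sum(r^2)
  rs0 <- rs
  for (it in seq_len(config$iterations)) {
    Ap <- apply_op(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (rs_new < config$tolerance^2 * rs0) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  matrix(x, M, M)
}

#' Total-variation reconstruction
#'
#' Minimizes \code{||R f - g||^2 / 2 + lambda TV(f)} (isotropic TV) with the
#' Chambolle-Pock primal-dual scheme at a fixed iteration count; step sizes
#' come from a power-iteration estimate of the operator norm.
#'
#' @inheritParams tikhonov_recon
#' @param config a [recon_config()] with \code{method = "tv"}.
#' @return \code{M x M} reconstruction matrix.
#' @export
tv_recon <- function(sinogram, config = recon_config("tv", lambda = 1e-3,
                                                     iterations = 200L),
                     A = NULL) {
  geom <- sinogram$geometry
  M <- geom$image_size
  n <- M * M
  if (is.null(A)) A <- ray_matrix(geom)
  D <- gradient_matrix(M)
  g <- as.vector(t(sinogram$data))
  # operator norm of K = [A; D] by power iteration
  v <- rep(1 / sqrt(n), n)
  for (i in 1:12) {
    w <- as.vector(Matrix::crossprod(A, A %*% v)) +
      as.vector(Matrix::crossprod(D, D %*% v))
    v <- w / sqrt(sum(w^2))
  }
  Lnorm <- sqrt(sqrt(sum((as.vector(Matrix::crossprod(A, A %*% v)) +
                            as.vector(Matrix::crossprod(D, D %*% v)))^2)))
  tau <- 0.95 / Lnorm
  sigma <- 0.95 / Lnorm
  x <- numeric(n); xbar <- x
  y1 <- numeric(length(g)); y2 <- numeric(2 * n)
  for (it in seq_len(config$iterations)) {
    y1 <- (y1 + sigma * (as.vector(A %*% xbar) - g)) / (1 + sigma)
    y2 <- y2 + sigma * as.vector(D %*% xbar)
    if (config$lambda > 0) {
      mag <- sqrt(y2[seq_len(n)]^2 + y2[n + seq_len(n)]^2)
      scale <- pmin(1, config$lambda / pmax(mag, 1e-12))
      y2 <- y2 * c(scale, scale)
    } else {
      y2 <- y2 * 0
    }
    x_new <- x - tau * (as.vector(Matrix::crossprod(A, y1)) +
                          as.vector(Matrix::crossprod(D, y2)))
    xbar <- 2 * x_new - x
    x <- x_new
  }
  matrix(x, M, M)
}

#' @keywords internal
tv_objective <- function(x, g, A, D, lambda) {
  n <- length(x)
  grad <- as.vector(D %*% x)
  tv <- sum(sqrt(grad[seq_len(n)]^2 + grad[n + seq_len(n)]^2))
  0.5 * sum((as.vector(A %*% x) - g)^2) + lambda * tv
}

# ---------------------------------------------------------------------------
# sinogram canvases: square, angle-periodic embeddings of a sinogram so the
# shearlet/CNN pipeline (square inputs, patch borders) can classify every
# measured angle. The extension uses g(theta + pi, p) = g(theta, -p).

#' Embed a sinogram in a square angle-periodic canvas
#'
#' Row \code{r} of the canvas holds angle index \code{((r-1) mod nA) + 1};
#' every odd half-turn is detector-flipped (\code{g(theta+pi, p) =
#' g(theta, -p)}). The detector axis is centred (requires
#' \code{n_det <= size}).
#'
#' @param sinogram a [ray_transform()] result.
#' @param size even canvas side length, at least \code{n_det}.
#' @return \code{size x size} matrix.
#' @export
sinogram_canvas <- function(sinogram, size) {
  g <- sinogram$data
  nA <- nrow(g); nD <- ncol(g)
  stopifnot(size >= nD, size %% 2 == 0)
  off <- (size - nD) %/% 2L
  canvas <- matrix(0, size, size)
  for (r in seq_len(size)) {
    h <- (r - 1L) %/% nA
    ai <- (r - 1L) %% nA + 1L
    row <- g[ai, ]
    if (h %% 2L == 1L) row <- rev(row)
    canvas[r, off + seq_len(nD)] <- row
  }
  canvas
}

#' Map a sinogram-domain wavefront set onto the canvas
#'
#' Replicates each element into every half-turn band of the canvas,
#' flipping the detector index and mirroring the orientation bin on odd
#' bands.
#'
#' @param truth a [wavefront_set()] on the (angle, offset) grid.
#' @param size canvas side length.
#' @return a [wavefront_set()] on the \code{size x size} canvas.
#' @export
canvas_wavefront <- function(truth, size) {
  nA <- truth$dims[1]; nD <- truth$dims[2]
  off <- (size - nD) %/% 2L
  n <- truth$n_orientations
  e <- truth$elements
  out <- list()
  h <- 0L
  while (h * nA < size) {
    if (nrow(e)) {
      rows <- e$row + h * nA
      keep <- rows <= size
      if (any(keep)) {
        flip <- h %% 2L == 1L
        cols <- if (flip) nD + 1L - e$col[keep] else e$col[keep]
        bins <- if (flip) (n - 1L - e$bin[keep]) %% n else e$bin[keep]
        out[[length(out) + 1L]] <- data.frame(
          row = rows[keep], col = cols + off, bin = bins)
      }
    }
    h <- h + 1L
  }
  elements <- if (length(out)) do.call(rbind, out) else NULL
  wavefront_set(elements, c(size, size), n)
}

#' Collapse a canvas-domain wavefront set back to the sinogram grid
#'
#' Inverse of [canvas_wavefront()]: maps each canvas element to its
#' original (angle, offset) cell, un-mirroring odd half-turn bands, and
#' deduplicates.
#'
#' @param wf a [wavefront_set()] on the canvas.
#' @param nA,nD angle and detector counts of the original grid.
#' @return a [wavefront_set()] on the \code{nA x nD} grid.
#' @export
canvas_to_sinogram <- function(wf, nA, nD) {
  size <- wf$dims[1]
  off <- (size - nD) %/% 2L
  n <- wf$n_orientations
  e <- wf$elements
  if (nrow(e)) {
    col0 <- e$col - off
    keep <- col0 >= 1L & col0 <= nD
    e <- e[keep, , drop = FALSE]; col0 <- col0[keep]
    h <- (e$row - 1L) %/% nA
    ai <- (e$row - 1L) %% nA + 1L
    flip <- h %% 2L == 1L
    cols <- ifelse(flip, nD + 1L - col0, col0)
    bins <- ifelse(flip, (n - 1L - e$bin) %% n, e$bin)
    e <- data.frame(row = ai, col = cols, bin = bins)
  }
  wavefront_set(e, c(nA, nD), n)
}

# ---------------------------------------------------------------------------

# Dense prediction cache: edge probabilities at every interior pixel plus
# orientation probabilities for every pixel above `tau_floor`, so that
# predictions at any edge threshold >= tau_floor can be assembled without
# re-running the models.
#' @keywords internal
wf_dense_cache <- function(image, system, ensemble, tau_floor = 0.05) {
  M <- ensemble$image_size
  volume <- shearlet_transform(normalize_image(image), system)
  interior <- interior_range(M)
  centers <- as.matrix(expand.grid(row = interior, col = interior))
  edge_p <- predict_patch_probs(ensemble$edge_model$params, volume, centers)
  sel <- which(edge_p > tau_floor)
  probs <- matrix(0, length(sel), ensemble$n_orientations)
  if (length(sel)) {
    ec <- centers[sel, , drop = FALSE]
    for (b in seq_len(ensemble$n_orientations)) {
      probs[, b] <- predict_patch_probs(
        ensemble$orientation_models[[b]]$params, volume, ec)
    }
  }
  list(centers = centers, edge_p = edge_p, sel = sel, probs = probs,
       ensemble = ensemble, dims = c(M, M))
}

#' @keywords internal
wf_from_cache <- function(cache, tau_edge) {
  keep <- cache$edge_p[cache$sel] > tau_edge
  assemble_wavefront(cache$centers[cache$sel[keep], , drop = FALSE],
                     cache$probs[keep, , drop = FALSE],
                     cache$ensemble, cache$dims)
}

# canonical route from a cached canvas prediction
#' @keywords internal
canonical_route_from_cache <- function(cache, tau_edge, geometry,
                                       n_orientations, dims) {
  wf_canvas <- wf_from_cache(cache, tau_edge)
  wf_sino <- canvas_to_sinogram(wf_canvas, nA = length(geometry$angles),
                                nD = length(geometry$offsets))
  e <- wf_sino$elements
  if (!nrow(e)) return(wavefront_set(NULL, dims, n_orientations))
  q <- sinogram_bin_to_q(e$bin, geometry, wf_sino$n_orientations)
  inv <- canonical_inverse(e$row, e$col, q, geometry, n_orientations)
  wavefront_set(inv[, c("row", "col", "bin")], dims, n_orientations)
}

#' Wavefront-recovery benchmark
#'
#' Compares four routes from a (noisy, possibly sparse-angle) sinogram to an
#' image-domain wavefront set, scoring each with [wavefront_mse()] against
#' the visible part of the phantom's analytic truth:
#' \itemize{
#'   \item \code{canonical}: extract the sinogram-domain wavefront set with
#'     the sinogram ensemble and map it back through the inverse canonical
#'     relation (no image reconstruction);
#'   \item \code{fbp}, \code{tikhonov}, \code{tv}: reconstruct the image and
#'     extract its wavefront set with the image ensemble.
#' }
#'
#' @param phantom a [sample_head_phantom()] result.
#' @param geometry a [sinogram_geometry()] (typically [lowdose_geometry()]).
#' @param ensemble_image trained [train_wavefront_extractor()] for images.
#' @param ensemble_sinogram trained ensemble for sinogram canvases.
#' @param system_image,system_sinogram shearlet systems matching the two
#'   ensembles.
#' @param configs named list of [recon_config()]s for \code{fbp},
#'   \code{tikhonov} and \code{tv}.
#' @param noise_sd Gaussian noise level, relative to the sinogram maximum.
#' @param penalty_cap,bin_tolerance passed to [wavefront_mse()]. The
#'   orientation tolerance defaults to one bin: at coarse orientation
#'   resolutions the angle snapping of the canonical relation (up to half
#'   the angular spacing) can legitimately cross one bin boundary.
#' @param seed RNG seed of the noise.
#' @return data frame with columns \code{method} and \code{wavefront_mse},
#'   with the predictions attached as attribute \code{"predictions"} and
#'   the visible truth as attribute \code{"truth"}.
#' @export
benchmark_wavefront_recovery <- function(phantom, geometry, ensemble_image,
                                         ensemble_sinogram, system_image,
                                         system_sinogram,
                                         configs = list(
                                           fbp = recon_config("fbp"),
                                           tikhonov = recon_config(
                                             "tikhonov", lambda = 0.005,
                                             iterations = 60L),
                                           tv = recon_config(
                                             "tv", lambda = 1e-3,
                                             iterations = 200L)),
                                         noise_sd = 0.01,
                                         penalty_cap = 1000,
                                         bin_tolerance = 1L, seed = 1L) {
  sino <- ray_transform(phantom$image, geometry)
  if (noise_sd > 0) {
    sino$data <- sino$data + with_seed(seed, matrix(
      stats::rnorm(length(sino$data), sd = noise_sd * max(abs(sino$data))),
      nrow(sino$data)))
  }
  truth_vis <- visible_wavefront(restrict_to_interior(phantom$truth),
                                 geometry)

  # route (a): canonical relation on the sinogram wavefront set
  size <- ensemble_sinogram$image_size
  canvas <- sinogram_canvas(sino, size)
  tau_s <- ensemble_sinogram$tau_edge
  cache_s <- wf_dense_cache(canvas, system_sinogram, ensemble_sinogram,
                            tau_floor = tau_s)
  preds <- list(canonical = canonical_route_from_cache(
    cache_s, tau_s, geometry, phantom$truth$n_orientations,
    phantom$truth$dims))

  # routes (b-d): reconstruct, then extract
  A <- ray_matrix(geometry)
  recons <- list(
    fbp = fbp(sino, configs$fbp),
    tikhonov = tikhonov_recon(sino, configs$tikhonov, A = A),
    tv = tv_recon(sino, configs$tv, A = A))
  for (m in names(recons)) {
    tau_m <- ensemble_image$tau_edge
    cache <- wf_dense_cache(recons[[m]], system_image, ensemble_image,
                            tau_floor = tau_m)
    preds[[m]] <- wf_from_cache(cache, tau_m)
  }

  res <- data.frame(
    method = c("canonical", "fbp", "tikhonov", "tv"),
    wavefront_mse = vapply(c("canonical", "fbp", "tikhonov", "tv"),
                           function(m) wavefront_mse(
                             preds[[m]], truth_vis,
                             penalty_cap = penalty_cap,
                             bin_tolerance = bin_tolerance), numeric(1)))
  attr(res, "predictions") <- preds
  attr(res, "truth") <- truth_vis
  attr(res, "reconstructions") <- recons
  res
}
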