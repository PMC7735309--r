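# Parallel-beam ray transform on [-1, 1]^2 and the digitized canonical
# relation transferring wavefront elements between image and sinogram
# domains. A line is parameterized by (theta, p): direction normal
# omega(theta) = (cos theta, sin theta), offset p along omega, and the
# integral runs along omega_perp = (-sin theta, cos theta). Image pixel
# (row i, col j) sits at x = (2*(j-1)+1)/M - 1, y = (2*(i-1)+1)/M - 1.

#' Parallel-beam sinogram geometry
#'
#' @param n_angles number of projection angles, equispaced on \code{[0, pi)};
#'   alternatively pass explicit \code{angles}.
#' @param n_det number of detector offsets, equispaced on
#'   \code{[-offset_max, offset_max]}.
#' @param image_size side length M of the image the geometry acts on.
#' @param angles optional explicit increasing angle grid (radians, in
#'   \code{[0, pi)}).
#' @param offset_max half-width of the detector, default \code{sqrt(2)}
#'   (the shadow of the unit square).
#' @return object of class \code{sinogram_geometry} with fields
#'   \code{angles}, \code{offsets}, \code{image_size}.
#' @export
sinogram_geometry <- function(n_angles = 180L, n_det = 128L,
                              image_size = 128L, angles = NULL,
                              offset_max = sqrt(2)) {
  if (is.null(angles)) {
    angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  }
  angles <- as.numeric(angles)
  if (is.unsorted(angles, strictly = TRUE)) {
    stop("invalid geometry: angles must be strictly increasing")
  }
  if (any(angles < 0 | angles >= pi)) {
    stop("invalid geometry: angles must lie in [0, pi)")
  }
  offsets <- seq(-offset_max, offset_max, length.out = n_det)
  structure(list(angles = angles, offsets = offsets,
                 image_size = as.integer(image_size)),
            class = "sinogram_geometry")
}

#' @export
print.sinogram_geometry <- function(x, ...) {
  cat(sprintf(
    "Parallel-beam geometry: %d angles x %d offsets on a %d x %d image\n",
    length(x$angles), length(x$offsets), x$image_size, x$image_size))
  invisible(x)
}

#' Every-n-degrees low-dose geometry
#'
#' Convenience constructor for the sparse-angle setting: angles 0, stride,
#' 2*stride, ... degrees (below 180).
#'
#' @param stride_deg angular stride in degrees (default 6).
#' @inheritParams sinogram_geometry
#' @return a [sinogram_geometry()].
#' @export
lowdose_geometry <- function(stride_deg = 6, n_det = 128L,
                             image_size = 128L) {
  k <- floor((180 - 1e-9) / stride_deg)
  ang <- (0:k) * stride_deg * pi / 180
  sinogram_geometry(n_det = n_det, image_size = image_size, angles = ang)
}

#' Parallel-beam ray transform
#'
#' Line integrals of a square image over the geometry's (angle, offset)
#' grid, computed by sampling each line at half-pixel steps with bilinear
#' interpolation. Linear in the image.
#'
#' @param image \code{M x M} numeric matrix.
#' @param geometry a [sinogram_geometry()] with matching \code{image_size}.
#' @return object of class \code{sinogram}: list with \code{data}
#'   (\code{n_angles x n_det} matrix) and \code{geometry}.
#' @export
ray_transform <- function(image, geometry) {
  stopifnot(inherits(geometry, "sinogram_geometry"))
  M <- geometry$image_size
  if (!is.matrix(image) || nrow(image) != M || ncol(image) != M) {
    stop("shape error: image does not match the geometry")
  }
  step <- 1 / M                       # half a pixel (pixel width 2/M)
  smax <- sqrt(2)
  s <- seq(-smax, smax, by = step)
  data <- matrix(0, length(geometry$angles), length(geometry$offsets))
  for (ai in seq_along(geometry$angles)) {
    th <- geometry$angles[ai]
    w <- c(cos(th), sin(th)); wp <- c(-sin(th), cos(th))
    # sample points for all (offset, s) pairs
    px <- outer(geometry$offsets * w[1], s * wp[1], "+")
    py <- outer(geometry$offsets * w[2], s * wp[2], "+")
    v <- bilinear_lookup(image, px, py, M)
    data[ai, ] <- rowSums(v) * step
  }
  structure(list(data = data, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d angles x %d offsets\n", nrow(x$data),
              ncol(x$data)))
  invisible(x)
}

# bilinear interpolation of image values at domain coordinates (x, y);
# zero outside the grid
#' @keywords internal
bilinear_lookup <- function(image, x, y, M) {
  # fractional (row, col) indices
  fj <- ((x + 1) * M + 1) / 2
  fi <- ((y + 1) * M + 1) / 2
  j0 <- floor(fj); i0 <- floor(fi)
  dj <- fj - j0; di <- fi - i0
  v <- numeric(length(fj))
  at <- function(ii, jj) {
    ok <- ii >= 1 & ii <= M & jj >= 1 & jj <= M
    out <- numeric(length(ii))
    out[ok] <- image[cbind(ii[ok], jj[ok])]
    out
  }
  v <- at(i0, j0) * (1 - di) * (1 - dj) + at(i0 + 1L, j0) * di * (1 - dj) +
    at(i0, j0 + 1L) * (1 - di) * dj + at(i0 + 1L, j0 + 1L) * di * dj
  array(v, dim = dim(x))
}

# Sparse system matrix of the discrete ray transform (rows: angle-major
# (angle, offset) pairs; columns: image pixels in column-major order).
# Shares the sampling rule of ray_transform, so it is its exact
# matrix representation, and its transpose the exact adjoint. Cached on the
# geometry's environment by callers that need repeated products.
#' @keywords internal
ray_matrix <- function(geometry) {
  M <- geometry$image_size
  step <- 1 / M
  smax <- sqrt(2)
  s <- seq(-smax, smax, by = step)
  nA <- length(geometry$angles); nD <- length(geometry$offsets)
  ii <- list(); jj <- list(); vv <- list(); blk <- 0L
  for (ai in seq_len(nA)) {
    th <- geometry$angles[ai]
    w <- c(cos(th), sin(th)); wp <- c(-sin(th), cos(th))
    px <- outer(geometry$offsets * w[1], s * wp[1], "+")
    py <- outer(geometry$offsets * w[2], s * wp[2], "+")
    fj <- ((px + 1) * M + 1) / 2
    fi <- ((py + 1) * M + 1) / 2
    j0 <- floor(fj); i0 <- floor(fi)
    dj <- fj - j0; di <- fi - i0
    row_id <- matrix(rep((ai - 1L) * nD + seq_len(nD), length(s)), nD)
    for (corner in 1:4) {
      ci <- i0 + (corner == 2L | corner == 4L)
      cj <- j0 + (corner >= 3L)
      wgt <- switch(corner,
                    (1 - di) * (1 - dj), di * (1 - dj),
                    (1 - di) * dj, di * dj) * step
      ok <- ci >= 1 & ci <= M & cj >= 1 & cj <= M & wgt > 0
      blk <- blk + 1L
      ii[[blk]] <- row_id[ok]
      jj[[blk]] <- (cj[ok] - 1L) * M + ci[ok]
      vv[[blk]] <- wgt[ok]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(nA * nD, M * M))
}

#' @keywords internal
bin_center_angle <- function(bin, n_orientations) {
  (bin + 0.5) * pi / n_orientations
}

# cyclic angular distance modulo pi
#' @keywords internal
angle_dist_mod_pi <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' Forward canonical relation of the ray transform
#'
#' Maps an image-domain wavefront element (pixel location with normal
#' orientation) to the sinogram-domain element it induces: the singularity
#' at \code{x0} with normal direction \code{theta0} shows up at the measured
#' angle nearest \code{theta0} (within \code{angle_tolerance}, else it is
#' invisible and an empty result is returned), at offset
#' \code{p0 = x0 . omega(theta0)}, with covector direction
#' \code{-q dtheta + dp} where \code{q = x0 . omega_perp(theta0)}.
#'
#' @param row,col 1-based pixel indices of the element.
#' @param bin orientation bin of the normal direction.
#' @param n_orientations number of image-domain orientation bins.
#' @param geometry a [sinogram_geometry()].
#' @param angle_tolerance maximal distance (radians, modulo pi) between the
#'   normal direction and a measured angle; defaults to half the angular
#'   spacing.
#' @return data frame with columns \code{angle_idx}, \code{offset_idx}
#'   (1-based grid indices), \code{theta}, \code{p}, \code{q} (continuous
#'   parameters); zero rows when the element is invisible.
#' @export
canonical_forward <- function(row, col, bin, n_orientations, geometry,
                              angle_tolerance = NULL) {
  stopifnot(inherits(geometry, "sinogram_geometry"))
  M <- geometry$image_size
  if (is.null(angle_tolerance)) {
    angle_tolerance <- angular_spacing(geometry) / 2
  }
  x <- (2 * (col - 1) + 1) / M - 1
  y <- (2 * (row - 1) + 1) / M - 1
  theta0 <- bin_center_angle(bin, n_orientations)
  d <- angle_dist_mod_pi(geometry$angles, theta0)
  ai <- which.min(d)
  if (d[ai] > angle_tolerance + 1e-12) {
    return(data.frame(angle_idx = integer(), offset_idx = integer(),
                      theta = numeric(), p = numeric(), q = numeric()))
  }
  th <- geometry$angles[ai]
  p0 <- x * cos(th) + y * sin(th)
  q <- -x * sin(th) + y * cos(th)
  doff <- abs(geometry$offsets - p0)
  oi <- which.min(doff)
  data.frame(angle_idx = ai, offset_idx = oi, theta = th, p = p0, q = q)
}

#' @keywords internal
angular_spacing <- function(geometry) {
  if (length(geometry$angles) > 1) min(diff(geometry$angles)) else pi
}

#' Inverse canonical relation of the ray transform
#'
#' Recovers the image-domain wavefront element from a sinogram-domain one:
#' \code{x0 = p0 * omega(theta0) + q * omega_perp(theta0)}, with normal
#' orientation bin the bin containing \code{theta0} modulo 180 degrees.
#'
#' @param angle_idx,offset_idx 1-based sinogram grid indices.
#' @param q slope parameter of the sinogram covector (domain units).
#' @param geometry a [sinogram_geometry()].
#' @param n_orientations image-domain orientation bins.
#' @return data frame with \code{row}, \code{col} (1-based, clamped to the
#'   grid), \code{bin}, \code{x}, \code{y}.
#' @export
canonical_inverse <- function(angle_idx, offset_idx, q, geometry,
                              n_orientations) {
  stopifnot(inherits(geometry, "sinogram_geometry"))
  M <- geometry$image_size
  th <- geometry$angles[angle_idx]
  p0 <- geometry$offsets[offset_idx]
  x <- p0 * cos(th) - q * sin(th)
  y <- p0 * sin(th) + q * cos(th)
  col <- pmin(pmax(round(((x + 1) * M + 1) / 2), 1L), M)
  row <- pmin(pmax(round(((y + 1) * M + 1) / 2), 1L), M)
  bin <- floor((th %% pi) / (pi / n_orientations)) %% n_orientations
  data.frame(row = row, col = col, bin = bin, x = x, y = y)
}

#' Visible subset of an image-domain wavefront set
#'
#' Keeps the elements whose normal direction lies within
#' \code{angle_tolerance} (modulo 180 degrees) of a measured projection
#' angle; the rest are invisible for the geometry.
#'
#' @param truth a [wavefront_set()] in the image domain.
#' @param geometry a [sinogram_geometry()].
#' @param angle_tolerance radians; defaults to half the angular spacing.
#' @return a [wavefront_set()].
#' @export
visible_wavefront <- function(truth, geometry, angle_tolerance = NULL) {
  stopifnot(inherits(truth, "wavefront_set"))
  if (is.null(angle_tolerance)) {
    angle_tolerance <- angular_spacing(geometry) / 2
  }
  e <- truth$elements
  if (!nrow(e)) return(truth)
  if (!length(geometry$angles)) {
    return(wavefront_set(NULL, truth$dims, truth$n_orientations))
  }
  th <- bin_center_angle(e$bin, truth$n_orientations)
  keep <- vapply(th, function(t)
    min(angle_dist_mod_pi(geometry$angles, t)) <= angle_tolerance + 1e-12,
    logical(1))
  wavefront_set(e[keep, , drop = FALSE], truth$dims, truth$n_orientations)
}

# orientation bin of a sinogram covector (-q dtheta + dp) on the index grid:
# the direction has components (-q * dtheta_spacing, dp_spacing) in
# (angle index, offset index) units.
#' @keywords internal
sinogram_direction_bin <- function(q, geometry, n_orientations) {
  dth <- angular_spacing(geometry)
  dp <- geometry$offsets[2] - geometry$offsets[1]
  ang <- (atan2(dp, -q * dth) * 180 / pi) %% 180
  floor(ang / (180 / n_orientations)) %% n_orientations
}

#' @keywords internal
sinogram_bin_to_q <- function(bin, geometry, n_orientations) {
  dth <- angular_spacing(geometry)
  dp <- geometry$offsets[2] - geometry$offsets[1]
  ang <- bin_center_angle(bin, n_orientations)  # radians in (0, pi)
  -dp / (tan(ang) * dth)
}

#' Sinogram-domain wavefront truth of a phantom
#'
#' Pushes every element of the phantom's analytic image-domain wavefront set
#' through the forward canonical relation and bins the resulting covector
#' slope into sinogram-domain orientation bins (grid-aware: the
#' \code{dtheta} component is scaled by the angular spacing, \code{dp} by
#' the detector spacing).
#'
#' @param phantom a [sample_head_phantom()] result (or any object with a
#'   \code{truth} wavefront set).
#' @param geometry a [sinogram_geometry()].
#' @param n_orientations sinogram-domain orientation bins (defaults to the
#'   truth's).
#' @param angle_tolerance see [canonical_forward()].
#' @return a [wavefront_set()] on the (angle, offset) grid; rows index
#'   angles, columns offsets. The continuous slopes are attached as
#'   attribute \code{"q"} (one per element).
#' @export
sinogram_wavefront_truth <- function(phantom, geometry,
                                     n_orientations = NULL,
                                     angle_tolerance = NULL) {
  truth <- if (inherits(phantom, "wavefront_set")) phantom else phantom$truth
  if (is.null(n_orientations)) n_orientations <- truth$n_orientations
  e <- truth$elements
  out <- vector("list", nrow(e))
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      fw <- canonical_forward(e$row[i], e$col[i], e$bin[i],
                              truth$n_orientations, geometry,
                              angle_tolerance)
      if (nrow(fw)) {
        out[[i]] <- data.frame(
          row = fw$angle_idx, col = fw$offset_idx,
          bin = sinogram_direction_bin(fw$q, geometry, n_orientations),
          q = fw$q)
      }
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  dims <- c(length(geometry$angles), length(geometry$offsets))
  if (is.null(out)) return(wavefront_set(NULL, dims, n_orientations))
  wf <- wavefront_set(out[, c("row", "col", "bin")], dims, n_orientations)
  # attach median slope per retained (deduplicated) element
  key <- paste(out$row, out$col, out$bin)
  qmed <- tapply(out$q, key, stats::median)
  wf_key <- paste(wf$elements$row, wf$elements$col, wf$elements$bin)
  attr(wf, "q") <- as.numeric(qmed[wf_key])
  wf
}
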