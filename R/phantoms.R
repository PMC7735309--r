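# Random-ellipse head phantoms with analytically known wavefront sets.
# The image models the square [-1, 1]^2; pixel (i, j) (1-based matrix
# indices) has centre coordinates x = (2*(j-1)+1)/M - 1 (along columns) and
# y = (2*(i-1)+1)/M - 1 (along rows). Orientations are measured as the angle
# of the outward normal, atan2(ny, nx) reduced modulo 180 degrees.

# Evaluate code with a private RNG stream so sampling is reproducible
# without disturbing the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Define an ellipse
#'
#' @param cx,cy centre in domain units (the image spans \code{[-1, 1]^2}).
#' @param a,b positive semi-axes in domain units.
#' @param phi rotation of the first axis, radians in \code{[0, pi)}.
#' @param intensity additive intensity contribution \code{Delta}.
#' @param edge_width boundary smoothing width \code{sigma >= 0} in domain
#'   units; 0 gives a sharp jump, positive values a smooth ramp across the
#'   boundary. The analytic wavefront set is the same in both cases.
#' @return one-row data frame; ellipse lists are data frames of such rows.
#' @export
ellipse <- function(cx, cy, a, b, phi = 0, intensity = 1, edge_width = 0) {
  stopifnot(a > 0, b > 0, edge_width >= 0)
  data.frame(cx = cx, cy = cy, a = a, b = b, phi = phi %% pi,
             intensity = intensity, edge_width = edge_width)
}

#' Configuration of the head-phantom sampler
#'
#' Encodes the study conditions of the random head phantoms: two concentric
#' large ellipses form the outer and inner skull, and a random number of
#' small ellipses with random sizes, orientations, intensities and boundary
#' regularities lie strictly inside the inner skull.
#'
#' @param image_size even image side length M.
#' @param n_small integer range \code{c(min, max)} for the number of interior
#'   ellipses.
#' @param size_range range of interior semi-axes, domain units.
#' @param intensity_range range of interior intensity magnitudes (the sign is
#'   chosen at random).
#' @param edge_width_range range of positive boundary widths; each interior
#'   ellipse is sharp with probability \code{sharp_prob}, otherwise its width
#'   is drawn from this range.
#' @param sharp_prob probability of a sharp (width 0) interior boundary.
#' @param n_orientations orientation bins of the analytic truth.
#' @param supersample supersampling factor of the rasterizer.
#' @return an object of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = 256L, n_small = c(5L, 12L),
                           size_range = c(0.04, 0.22),
                           intensity_range = c(0.2, 1),
                           edge_width_range = c(0.005, 0.03),
                           sharp_prob = 0.5, n_orientations = 180L,
                           supersample = 4L) {
  stopifnot(length(n_small) == 2, n_small[1] <= n_small[2], n_small[1] >= 0,
            size_range[1] > 0, size_range[1] <= size_range[2],
            intensity_range[1] > 0,
            intensity_range[1] <= intensity_range[2],
            sharp_prob >= 0, sharp_prob <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_small = as.integer(n_small), size_range = size_range,
                 intensity_range = intensity_range,
                 edge_width_range = edge_width_range,
                 sharp_prob = sharp_prob,
                 n_orientations = as.integer(n_orientations),
                 supersample = as.integer(supersample)),
            class = "phantom_config")
}

#' Sample a random head phantom
#'
#' Draws the skull pair plus interior ellipses, rasterizes the image and
#' derives the analytic digital wavefront set. The same seed reproduces the
#' phantom bitwise.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed fixing the sample.
#' @return an object of class \code{phantom}: list with \code{image}
#'   (\code{M x M} matrix), \code{ellipses} (data frame) and \code{truth}
#'   (a [wavefront_set()]).
#' @export
sample_head_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  ellipses <- with_seed(seed, sample_head_ellipses(config))
  phantom_from_ellipses(ellipses, config)
}

#' @keywords internal
phantom_from_ellipses <- function(ellipses, config) {
  image <- rasterize(ellipses, config$image_size,
                     supersample = config$supersample)
  truth <- analytic_wavefront_set(ellipses, config$image_size,
                                  n_orientations = config$n_orientations)
  structure(list(image = image, ellipses = ellipses, truth = truth,
                 config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Head phantom: %d x %d image, %d ellipses, %d truth elements\n",
              nrow(x$image), ncol(x$image), nrow(x$ellipses),
              nrow(x$truth$elements)))
  invisible(x)
}

#' @keywords internal
sample_head_ellipses <- function(config) {
  # skull: two concentric large ellipses; the ring between them is bright
  oa <- stats::runif(1, 0.65, 0.75)
  ob <- stats::runif(1, 0.88, 0.95)
  ring <- stats::runif(1, 0.04, 0.08)
  outer_int <- stats::runif(1, 0.8, 1)
  inner_int <- -stats::runif(1, 0.6, 0.9) * outer_int
  skull <- rbind(
    ellipse(0, 0, oa, ob, 0, outer_int, 0),
    ellipse(0, 0, oa - ring, ob - ring, 0, inner_int, 0)
  )
  ia <- oa - ring; ib <- ob - ring
  n <- if (config$n_small[1] == config$n_small[2]) config$n_small[1] else
    sample(seq.int(config$n_small[1], config$n_small[2]), 1)
  small <- vector("list", n)
  if (n > 0) {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        a <- stats::runif(1, config$size_range[1], config$size_range[2])
        b <- stats::runif(1, config$size_range[1], config$size_range[2])
        rmax <- max(a, b)
        if (rmax >= min(ia, ib) - 0.02) next
        cx <- stats::runif(1, -(ia - rmax), ia - rmax)
        cy <- stats::runif(1, -(ib - rmax), ib - rmax)
        # conservative containment: bounding circle inside the inner skull
        if ((cx / (ia - rmax))^2 + (cy / (ib - rmax))^2 > 1) next
        phi <- stats::runif(1, 0, pi)
        mag <- stats::runif(1, config$intensity_range[1],
                            config$intensity_range[2])
        sgn <- sample(c(-1, 1), 1)
        ew <- if (stats::runif(1) < config$sharp_prob) 0 else
          stats::runif(1, config$edge_width_range[1],
                       config$edge_width_range[2])
        small[[i]] <- ellipse(cx, cy, a, b, phi, sgn * mag, ew)
        placed <- TRUE
        break
      }
      if (!placed) stop("generation error: could not place interior ellipse")
    }
    small <- do.call(rbind, small)
  } else {
    small <- NULL
  }
  rbind(skull, small)
}

#' Rasterize a list of ellipses
#'
#' Additively renders ellipse contributions on the pixel grid. Sharp
#' ellipses (\code{edge_width = 0}) contribute their intensity times the
#' fractional pixel coverage, estimated by \code{supersample^2}-fold
#' supersampling; smoothed ellipses replace the indicator by a smooth ramp
#' of width \code{edge_width} (measured approximately along the boundary
#' normal) and need no anti-aliasing.
#'
#' @param ellipses data frame of [ellipse()] rows.
#' @param M even image side length.
#' @param supersample supersampling factor (>= 1) for sharp boundaries.
#' @return \code{M x M} numeric matrix.
#' @export
rasterize <- function(ellipses, M, supersample = 4L) {
  M <- as.integer(M)
  supersample <- as.integer(supersample)
  stopifnot(M %% 2L == 0L, supersample >= 1L)
  img <- matrix(0, M, M)
  if (is.null(ellipses) || nrow(ellipses) == 0) return(img)
  coords1 <- (2 * (seq_len(M) - 1) + 1) / M - 1
  for (e in seq_len(nrow(ellipses))) {
    el <- ellipses[e, ]
    if (el$edge_width > 0) {
      yy <- matrix(coords1, M, M)           # rows
      xx <- matrix(coords1, M, M, byrow = TRUE)
      r <- ellipse_radius(xx, yy, el)
      ramp_scale <- min(el$a, el$b) / el$edge_width
      img <- img + el$intensity * meyer_smooth((1 - r) * ramp_scale + 0.5)
    } else {
      S <- supersample
      Mf <- M * S
      cf <- (2 * (seq_len(Mf) - 1) + 1) / Mf - 1
      yy <- matrix(cf, Mf, Mf)
      xx <- matrix(cf, Mf, Mf, byrow = TRUE)
      r <- ellipse_radius(xx, yy, el)
      fine <- matrix(as.numeric(r <= 1), Mf, Mf)
      # average S x S blocks
      cov <- fine
      dim(cov) <- c(S, M, Mf)
      cov <- colSums(cov)
      dim(cov) <- c(M, S, M)
      cov <- colSums(aperm(cov, c(2, 1, 3))) / S^2
      img <- img + el$intensity * cov
    }
  }
  img
}

# Elliptical radius: 1 on the boundary, < 1 inside.
#' @keywords internal
ellipse_radius <- function(x, y, el) {
  dx <- x - el$cx
  dy <- y - el$cy
  u <- cos(el$phi) * dx + sin(el$phi) * dy
  v <- -sin(el$phi) * dx + cos(el$phi) * dy
  sqrt((u / el$a)^2 + (v / el$b)^2)
}

#' Analytic digital wavefront set of an ellipse list
#'
#' For each ellipse boundary, marks every pixel whose centre lies within half
#' a pixel of the boundary curve with the orientation bin of the outward
#' normal at the nearest boundary point, and unions the per-ellipse sets.
#' Cancellation along exactly coincident boundaries is ignored.
#'
#' @param ellipses data frame of [ellipse()] rows.
#' @param M image side length.
#' @param n_orientations number of orientation bins.
#' @return a [wavefront_set()] on the \code{M x M} grid.
#' @export
analytic_wavefront_set <- function(ellipses, M, n_orientations = 180L) {
  M <- as.integer(M)
  n_orientations <- as.integer(n_orientations)
  stopifnot(n_orientations >= 2L)
  all_el <- list()
  half_pixel <- 1 / M                       # pixel width is 2/M
  if (!is.null(ellipses) && nrow(ellipses) > 0) {
    for (e in seq_len(nrow(ellipses))) {
      el <- ellipses[e, ]
      if (el$intensity == 0) next
      # boundary samples, ~20 per pixel of arc length
      per <- pi * (3 * (el$a + el$b) -
                     sqrt((3 * el$a + el$b) * (el$a + 3 * el$b)))
      ns <- max(256L, ceiling(per * (M / 2) * 20))
      tau <- seq(0, 2 * pi, length.out = ns + 1L)[-(ns + 1L)]
      ct <- cos(tau); st <- sin(tau)
      bx <- el$cx + cos(el$phi) * el$a * ct - sin(el$phi) * el$b * st
      by <- el$cy + sin(el$phi) * el$a * ct + cos(el$phi) * el$b * st
      nx <- cos(el$phi) * el$b * ct - sin(el$phi) * el$a * st
      ny <- sin(el$phi) * el$b * ct + cos(el$phi) * el$a * st
      ang <- (atan2(ny, nx) * 180 / pi) %% 180
      bin <- floor(ang / (180 / n_orientations)) %% n_orientations
      # fractional pixel indices of each sample (1-based)
      jf <- ((bx + 1) * M + 1) / 2          # column from x
      if_ <- ((by + 1) * M + 1) / 2         # row from y
      j0 <- round(jf); i0 <- round(if_)
      offs <- expand.grid(di = -1:1, dj = -1:1)
      rows <- rep(i0, nrow(offs)) + rep(offs$di, each = ns)
      cols <- rep(j0, nrow(offs)) + rep(offs$dj, each = ns)
      brow <- rep(if_, nrow(offs)); bcol <- rep(jf, nrow(offs))
      bbin <- rep(bin, nrow(offs))
      keep <- rows >= 1 & rows <= M & cols >= 1 & cols <= M
      rows <- rows[keep]; cols <- cols[keep]
      d <- sqrt((rows - brow[keep])^2 + (cols - bcol[keep])^2)
      bbin <- bbin[keep]
      near <- d <= (half_pixel / (2 / M))   # half a pixel, in pixel units
      if (!any(near)) next
      idx <- (cols[near] - 1L) * M + rows[near]
      o <- order(idx, d[near])
      first <- !duplicated(idx[o])
      sel <- o[first]
      all_el[[length(all_el) + 1L]] <- data.frame(
        row = rows[near][sel], col = cols[near][sel], bin = bbin[near][sel])
    }
  }
  elements <- if (length(all_el)) do.call(rbind, all_el) else NULL
  wavefront_set(elements, dims = c(M, M), n_orientations = n_orientations)
}
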