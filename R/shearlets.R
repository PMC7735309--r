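#' Configuration for a cone-adapted digital shearlet system
#'
#' Describes the digital shearlet filter bank acting on square \code{M x M}
#' images: the number of scales \code{J}, the number of shears per scale
#' \code{K_j} (odd, covering shear indices \code{-k_j .. k_j} with
#' \code{k_j = (K_j - 1)/2}), and the generating windows. The default shear
#' counts \code{K_j = 2^(ceiling(j/2) + 1) + 1} give 5, 5, 9, 9 for four
#' scales and a bank of 49 filters.
#'
#' @param image_size even integer \code{M >= 32}, the side length in pixels.
#' @param n_scales integer \code{J >= 1}, number of shearlet scales
#'   (scale \code{J} is the finest).
#' @param shear_counts integer vector of length \code{n_scales}; each entry
#'   must be odd and \code{>= 3}. Defaults to
#'   \code{2^(ceiling(j/2) + 1) + 1}.
#' @param generator currently only \code{"classical_meyer"}: a Meyer-type
#'   band-limited wavelet along the cone axis combined with a smooth bump in
#'   the shear variable.
#' @return an object of class \code{shearlet_config}.
#' @seealso [build_shearlet_system()]
#' @export
shearlet_config <- function(image_size, n_scales = 4L, shear_counts = NULL,
                            generator = "classical_meyer") {
  if (length(image_size) != 1L || !is.finite(image_size) ||
      image_size != round(image_size)) {
    stop("invalid config: `image_size` must be a single integer")
  }
  image_size <- as.integer(image_size)
  if (image_size < 32L || image_size %% 2L != 0L) {
    stop("invalid config: `image_size` must be even and at least 32")
  }
  n_scales <- as.integer(n_scales)
  if (n_scales < 1L) stop("invalid config: `n_scales` must be >= 1")
  if (is.null(shear_counts)) {
    j <- seq_len(n_scales)
    shear_counts <- as.integer(2^(ceiling(j / 2) + 1) + 1)
  }
  shear_counts <- as.integer(shear_counts)
  if (length(shear_counts) != n_scales) {
    stop("invalid config: `shear_counts` must have one entry per scale")
  }
  if (any(shear_counts < 3L) || any(shear_counts %% 2L == 0L)) {
    stop("invalid config: every shear count must be odd and >= 3")
  }
  generator <- match.arg(generator, "classical_meyer")
  structure(
    list(image_size = image_size, n_scales = n_scales,
         shear_counts = shear_counts, generator = generator),
    class = "shearlet_config"
  )
}

#' Number of filters in a shearlet system
#'
#' The bank holds \code{2 * sum(K_j - 1) + 1} filters: for each scale, both
#' frequency cones contribute \code{K_j} shearlets but the two seam shearlets
#' at the cone boundaries are shared, and a single low-pass filter covers the
#' remaining low frequencies.
#'
#' @param shear_counts integer vector of per-scale shear counts \code{K_j}.
#' @return integer slice count.
#' @export
shearlet_count <- function(shear_counts) {
  as.integer(2L * sum(shear_counts - 1L) + 1L)
}

# Frequencies of an M-point DFT in natural (unshifted) order:
# 0, 1, ..., M/2 - 1, -M/2, ..., -1.
#' @keywords internal
fft_freqs <- function(M) {
  f <- seq_len(M) - 1L
  f[f >= M / 2] <- f[f >= M / 2] - M
  f
}

#' Build a cone-adapted digital shearlet system
#'
#' Constructs the band-limited shearlet filter bank in the frequency domain.
#' Frequency space is split into a horizontal cone (\code{|xi2| <= |xi1|}), a
#' vertical cone and a low-pass region; on each cone, Meyer-type radial
#' windows select dyadic scale bands while shifted bump windows in the slope
#' variable \code{xi2/xi1} (resp. \code{xi1/xi2}) select orientations, so the
#' shearing acts as frequency-variable resampling and the pixel grid is never
#' interpolated. The two boundary shearlets at \code{|k| = k_j} are glued
#' across the cone seam and shared between the cones. After a final pointwise
#' normalization the squared moduli of all filters sum to one at every
#' frequency, making the associated transform a Parseval frame (the adjoint
#' reconstructs exactly).
#'
#' @param config a [shearlet_config()], or an even image size (in which case
#'   the remaining arguments are passed through to [shearlet_config()]).
#' @param ... forwarded to [shearlet_config()] when `config` is numeric.
#' @return an object of class \code{shearlet_system}: a list with the
#'   frequency-domain filter stack \code{filters} (array \code{M x M x L},
#'   DFT ordering with the DC bin first), an \code{index} data frame with
#'   columns \code{slice}, \code{scale}, \code{shear}, \code{cone}
#'   (\code{+1} horizontal, \code{-1} vertical, \code{0} low-pass) and
#'   \code{seam}, the slice count \code{L} and the generating \code{config}.
#' @examples
#' sys <- build_shearlet_system(shearlet_config(64, n_scales = 2))
#' sys$L
#' @export
build_shearlet_system <- function(config, ...) {
  if (!inherits(config, "shearlet_config")) {
    config <- shearlet_config(config, ...)
  }
  M <- config$image_size
  J <- config$n_scales
  K <- config$shear_counts
  L <- shearlet_count(K)

  f <- fft_freqs(M)
  xi1 <- matrix(f, nrow = M, ncol = M)        # varies along rows
  xi2 <- matrix(f, nrow = M, ncol = M, byrow = TRUE)
  rho <- pmax(abs(xi1), abs(xi2)) / (M / 2)   # cone-axis radius in [0, sqrt2]

  horizontal <- abs(xi2) <= abs(xi1) & !(xi1 == 0 & xi2 == 0)
  vertical <- abs(xi2) > abs(xi1)
  u <- matrix(0, M, M)                        # slope within the active cone
  u[horizontal] <- xi2[horizontal] / xi1[horizontal]
  u[vertical] <- xi1[vertical] / xi2[vertical]

  # Squared radial windows: dyadic Meyer bands, with the finest band
  # flattened to 1 from rho = 1/2 out to the grid corners so that the
  # radial windows and the low-pass form an exact partition of unity.
  Wsq <- vector("list", J)
  for (j in seq_len(J)) {
    wj <- psi1_sq(2^(J - j) * rho)
    if (j == J) wj[rho > 0.5] <- 1
    Wsq[[j]] <- wj
  }
  radial_sum <- Reduce(`+`, Wsq)
  lowpass_sq <- pmax(0, 1 - radial_sum)

  filters <- array(0, dim = c(M, M, L))
  index <- data.frame(slice = seq_len(L), scale = NA_integer_,
                      shear = NA_integer_, cone = NA_integer_,
                      seam = FALSE)
  s <- 0L
  for (j in seq_len(J)) {
    sigma <- (K[j] - 1L) / 2L
    for (k in seq.int(-sigma, sigma)) {
      dir_h <- psi2_sq(sigma * u - k) * horizontal
      dir_v <- psi2_sq(sigma * u - k) * vertical
      if (abs(k) < sigma) {
        # interior shearlets live on a single cone
        s <- s + 1L
        filters[, , s] <- sqrt(Wsq[[j]] * dir_h)
        index[s, 2:5] <- list(j, k, 1L, FALSE)
        s <- s + 1L
        filters[, , s] <- sqrt(Wsq[[j]] * dir_v)
        index[s, 2:5] <- list(j, k, -1L, FALSE)
      } else {
        # seam shearlets are glued across the cone boundary and shared
        s <- s + 1L
        filters[, , s] <- sqrt(Wsq[[j]] * (dir_h + dir_v))
        index[s, 2:5] <- list(j, k, 1L, TRUE)
      }
    }
  }
  s <- s + 1L
  filters[, , s] <- sqrt(lowpass_sq)
  index[s, 2:5] <- list(NA_integer_, NA_integer_, 0L, FALSE)
  stopifnot(s == L)

  # Enforce evenness under xi -> -xi (mod M). Away from the Nyquist
  # row/column the filters are already even; at the Nyquist frequencies the
  # slope variable is not, and without this step the real part of the FFT
  # correlation would discard energy. Averaging the squared filters with
  # their reflection preserves the pointwise partition of unity exactly.
  ineg <- c(1L, M:2L)
  for (l in seq_len(L)) {
    f2 <- filters[, , l]^2
    filters[, , l] <- sqrt((f2 + f2[ineg, ineg]) / 2)
  }

  # Parseval normalization: divide out the pointwise frame function.
  total <- matrix(rowSums(matrix(filters^2, ncol = L)), M, M)
  filters <- filters / rep(sqrt(total), L)

  structure(
    list(filters = filters, index = index, L = L, config = config),
    class = "shearlet_system"
  )
}

#' @export
print.shearlet_system <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Digital shearlet system: %d x %d grid, %d scales, %d filters\n",
    cfg$image_size, cfg$image_size, cfg$n_scales, x$L))
  cat(" shears per scale:", paste(cfg$shear_counts, collapse = ", "), "\n")
  invisible(x)
}

#' @keywords internal
system_id <- function(system) {
  cfg <- system$config
  paste0("shearlet:M", cfg$image_size, ":J", cfg$n_scales, ":K",
         paste(cfg$shear_counts, collapse = "."), ":", cfg$generator)
}

#' Digital shearlet transform of a square image
#'
#' Computes, for every filter in the bank, the circular cross-correlation of
#' the image with the filter's impulse response, evaluated with FFTs. Slice
#' \code{l} of the result holds the coefficients \code{<I, T_m psi_l>} for
#' all circular translates \code{m}.
#'
#' @param image real \code{M x M} matrix with finite entries.
#' @param system a [build_shearlet_system()] result with matching size.
#' @return a real array \code{M x M x L} of class
#'   \code{shearlet_coefficients} carrying a \code{system_id} attribute.
#' @export
shearlet_transform <- function(image, system) {
  stopifnot(inherits(system, "shearlet_system"))
  M <- system$config$image_size
  if (!is.matrix(image) || nrow(image) != M || ncol(image) != M) {
    stop("shape error: `image` must be a ", M, " x ", M, " matrix")
  }
  if (!all(is.finite(image))) stop("input error: image has non-finite pixels")
  Ihat <- stats::fft(image)
  out <- array(0, dim = c(M, M, system$L))
  for (l in seq_len(system$L)) {
    out[, , l] <- Re(stats::fft(Ihat * system$filters[, , l],
                                inverse = TRUE)) / M^2
  }
  structure(out, system_id = system_id(system),
            class = c("shearlet_coefficients", "array"))
}

#' Adjoint of the digital shearlet transform
#'
#' For the Parseval-normalized bank, \code{adjoint_transform(shearlet_transform(I))}
#' reproduces \code{I} up to floating point, so the adjoint doubles as the
#' reconstruction operator.
#'
#' @param volume real array \code{M x M x L} of coefficients.
#' @param system the generating [build_shearlet_system()] result.
#' @return real \code{M x M} matrix.
#' @export
adjoint_transform <- function(volume, system) {
  stopifnot(inherits(system, "shearlet_system"))
  M <- system$config$image_size
  d <- dim(volume)
  if (length(d) != 3 || d[1] != M || d[2] != M || d[3] != system$L) {
    stop("shape error: volume does not match the system")
  }
  acc <- matrix(0 + 0i, M, M)
  for (l in seq_len(system$L)) {
    acc <- acc + stats::fft(volume[, , l]) * system$filters[, , l]
  }
  Re(stats::fft(acc, inverse = TRUE)) / M^2
}
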