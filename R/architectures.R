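# Construction and bookkeeping of the semantic edge detection architectures:
# CASENet and DDS on a 101-layer residual backbone, and their shearlet
# variants (shear-CASENet, shear-DDS) whose first convolutional layer takes
# the L shearlet channels and whose fourth backbone stage is removed (the
# "2" variants keep it). The graphs are untrained layer tables used for
# shape propagation and parameter accounting.

#' Architecture specification
#'
#' @param variant one of \code{"casenet"}, \code{"shear_casenet"},
#'   \code{"dds"}, \code{"shear_dds"}.
#' @param n_categories number of semantic categories K.
#' @param input_size side length N of the square input.
#' @param shearlet_channels L, the shearlet slice count fed to the shear
#'   variants (default 49, the four-scale bank).
#' @param include_stage4 keep the fourth backbone stage; defaults to
#'   \code{TRUE} for the non-shear variants and \code{FALSE} for the shear
#'   variants (set \code{TRUE} for the "shear-* 2" variants).
#' @param input_channels channels of the network input; defaults to 3 for
#'   the non-shear variants and \code{shearlet_channels} for the shear ones.
#' @return object of class \code{architecture_spec}.
#' @export
architecture_spec <- function(variant = c("casenet", "shear_casenet",
                                          "dds", "shear_dds"),
                              n_categories = 20L, input_size = 256L,
                              shearlet_channels = 49L,
                              include_stage4 = NULL,
                              input_channels = NULL) {
  variant <- match.arg(variant)
  shear <- variant %in% c("shear_casenet", "shear_dds")
  if (is.null(include_stage4)) include_stage4 <- !shear
  if (is.null(input_channels)) {
    input_channels <- if (shear) shearlet_channels else 3L
  }
  if (shear && input_channels != shearlet_channels) {
    stop("config error: shear variants take the shearlet channels as input")
  }
  structure(list(variant = variant, n_categories = as.integer(n_categories),
                 input_size = as.integer(input_size),
                 shearlet_channels = as.integer(shearlet_channels),
                 include_stage4 = include_stage4,
                 input_channels = as.integer(input_channels)),
            class = "architecture_spec")
}

#' @keywords internal
conv_layer_row <- function(stage, name, in_ch, out_ch, kernel, bias = FALSE,
                           stride = 1L) {
  data.frame(stage = stage, name = name, type = "conv",
             in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
             kernel = as.integer(kernel), bias = bias,
             stride = as.integer(stride),
             weights = as.integer(kernel)^2 * in_ch * out_ch +
               if (bias) out_ch else 0L)
}

# bottleneck residual stage of the 101-layer backbone
#' @keywords internal
residual_stage_rows <- function(stage, n_blocks, in_ch, bottleneck, out_ch) {
  rows <- list()
  cur <- in_ch
  for (b in seq_len(n_blocks)) {
    pre <- sprintf("%s%s", stage, letters[min(b, 26)])
    rows[[length(rows) + 1L]] <- rbind(
      conv_layer_row(stage, paste0(pre, "_1x1a"), cur, bottleneck, 1L),
      conv_layer_row(stage, paste0(pre, "_3x3"), bottleneck, bottleneck, 3L),
      conv_layer_row(stage, paste0(pre, "_1x1b"), bottleneck, out_ch, 1L))
    if (b == 1L) {
      rows[[length(rows) + 1L]] <-
        conv_layer_row(stage, paste0(pre, "_down"), cur, out_ch, 1L)
    }
    cur <- out_ch
  }
  do.call(rbind, rows)
}

#' Build a semantic edge detection network graph
#'
#' Assembles the layer table of the chosen architecture: the first
#' convolution (7x7), the bottleneck residual stages res2 (3 blocks, 256
#' channels), res3 (4 blocks, 512), res4 (23 blocks, 1024; optional) and
#' res5 (3 blocks, 2048), the single-channel side maps of the early stages,
#' the K-channel class activation map of the last stage, and the K-grouped
#' fused classifier. The DDS variants insert a residual information
#' converter behind every supervised side stage.
#'
#' @param spec an [architecture_spec()].
#' @return object of class \code{edge_network}: list with the \code{layers}
#'   data frame, \code{spec}, and the side-output structure.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  dds <- spec$variant %in% c("dds", "shear_dds")
  layers <- list(conv_layer_row("conv1", "conv1", spec$input_channels, 64L,
                                7L, stride = 2L))
  layers[[2]] <- residual_stage_rows("res2", 3L, 64L, 64L, 256L)
  layers[[3]] <- residual_stage_rows("res3", 4L, 256L, 128L, 512L)
  last_ch <- 512L
  if (spec$include_stage4) {
    layers[[4]] <- residual_stage_rows("res4", 23L, 512L, 256L, 1024L)
    last_ch <- 1024L
  }
  layers[[length(layers) + 1L]] <-
    residual_stage_rows("res5", 3L, last_ch, 512L, 2048L)

  K <- spec$n_categories
  side_stages <- c("conv1", "res2", "res3",
                   if (dds && spec$include_stage4) "res4")
  side_ch <- c(conv1 = 64L, res2 = 256L, res3 = 512L, res4 = 1024L)
  heads <- list()
  if (dds) {
    # information converters: residual block (two 3x3 convs) per side stage
    for (s in side_stages) {
      ch <- side_ch[[s]]
      heads[[length(heads) + 1L]] <- rbind(
        conv_layer_row("converter", paste0(s, "_conv_a"), ch, ch, 3L),
        conv_layer_row("converter", paste0(s, "_conv_b"), ch, ch, 3L))
    }
    heads[[length(heads) + 1L]] <-
      conv_layer_row("converter", "res5_conv", 2048L, 2048L, 3L)
  }
  for (s in side_stages) {
    heads[[length(heads) + 1L]] <-
      conv_layer_row("side", paste0("side_", s), side_ch[[s]], 1L, 1L,
                     bias = TRUE)
  }
  heads[[length(heads) + 1L]] <-
    conv_layer_row("side", "side_res5_class", 2048L, K, 1L, bias = TRUE)
  n_side <- length(side_stages)
  # fused classifier: per category, the side maps plus its activation slice
  heads[[length(heads) + 1L]] <-
    conv_layer_row("fuse", "fused_class", n_side + 1L, 1L, 1L,
                   bias = TRUE) |> transform(
                     weights = (n_side + 1L) * K + K, out_ch = K)
  layers <- do.call(rbind, c(layers, heads))
  rownames(layers) <- NULL
  structure(list(layers = layers, spec = spec, n_side = n_side),
            class = "edge_network")
}

#' @export
print.edge_network <- function(x, ...) {
  cat(sprintf("%s graph: %d conv layers, stage 4 %s, input %d channels\n",
              x$spec$variant, nrow(x$layers),
              if (spec_has_stage4(x)) "present" else "removed",
              x$spec$input_channels))
  cat(sprintf(" parameters: %s (weights), %s (paper convention)\n",
              format(count_parameters(x, convention = "weights"),
                     big.mark = ","),
              format(count_parameters(x, convention = "paper"),
                     big.mark = ",")))
  invisible(x)
}

#' @keywords internal
spec_has_stage4 <- function(graph) any(graph$layers$stage == "res4")

#' Output shape of a network on a square input
#'
#' All side and activation maps are upsampled back to the input resolution
#' before fusion, so the fused semantic edge map has one channel per
#' category at full resolution.
#'
#' @param graph a [build_network()] result.
#' @param input_size side length N (defaults to the spec's).
#' @return integer \code{c(K, N, N)}.
#' @export
network_output_shape <- function(graph, input_size = NULL) {
  stopifnot(inherits(graph, "edge_network"))
  if (is.null(input_size)) input_size <- graph$spec$input_size
  c(graph$spec$n_categories, as.integer(input_size),
    as.integer(input_size))
}

#' Count network parameters
#'
#' Two conventions are reported. \code{"weights"} counts the kernel weights
#' (plus biases of the classifier heads; backbone convolutions are
#' bias-free, their affine scaling living in batch normalization) of the
#' constructed graph. \code{"paper"} reproduces the printed accounting of
#' the source architectures: for the non-shear variants it coincides with
#' \code{"weights"}; a shear variant is counted as its non-shear parent
#' minus \code{(128 - L) * N^2} for the removal of the fourth stage combined
#' with the first-layer channel change. The stage-4 activation figure
#' \code{1024 * N^2 / 4} is attached as attribute
#' \code{"stage4_activations"}.
#'
#' @param graph a [build_network()] result.
#' @param convention \code{"paper"} or \code{"weights"}.
#' @param input_size N used by the paper convention (defaults to the
#'   spec's).
#' @return parameter count (numeric scalar with attribute).
#' @export
count_parameters <- function(graph, convention = c("paper", "weights"),
                             input_size = NULL) {
  stopifnot(inherits(graph, "edge_network"))
  convention <- match.arg(convention)
  spec <- graph$spec
  if (is.null(input_size)) input_size <- spec$input_size
  N <- as.numeric(input_size)
  shear <- spec$variant %in% c("shear_casenet", "shear_dds")
  out <- if (convention == "weights" || !shear) {
    sum(graph$layers$weights)
  } else {
    parent_variant <- sub("shear_", "", spec$variant)
    parent <- build_network(architecture_spec(
      parent_variant, n_categories = spec$n_categories,
      input_size = spec$input_size,
      shearlet_channels = spec$shearlet_channels))
    sum(parent$layers$weights) -
      (128 - spec$shearlet_channels) * N^2
  }
  structure(out, stage4_activations = if (spec$include_stage4)
    1024 * N^2 / 4 else 0)
}

#' Compose the shearlet filters with trainable first-layer kernels
#'
#' By associativity of (circular) convolution, running the shearlet
#' transform and then convolving each coefficient channel with a trainable
#' kernel equals a single convolution with the composed kernel
#' \code{psi_l * omega_l}. This lets a shearlet first layer be stored as L
#' composed kernels.
#'
#' @param system a [build_shearlet_system()] result.
#' @param kernels array \code{k x k x L} of trainable kernels (odd k).
#' @return array \code{M x M x L} of composed impulse responses (circular,
#'   aligned so that index (1, 1) is the origin).
#' @export
first_layer_factorization <- function(system, kernels) {
  stopifnot(inherits(system, "shearlet_system"))
  M <- system$config$image_size
  d <- dim(kernels)
  if (length(d) != 3 || d[3] != system$L || d[1] %% 2 != 1 || d[1] != d[2]) {
    stop("kernels must be k x k x L with odd k")
  }
  k <- d[1]; half <- (k - 1L) %/% 2L
  out <- array(0, dim = c(M, M, system$L))
  for (l in seq_len(system$L)) {
    pad <- matrix(0, M, M)
    # embed kernel with its centre at the origin (circular wrap)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        pad[(a - 1L - half) %% M + 1L, (b - 1L - half) %% M + 1L] <-
          kernels[a, b, l]
      }
    }
    out[, , l] <- Re(stats::fft(stats::fft(pad) * system$filters[, , l],
                                inverse = TRUE)) / M^2
  }
  out
}

#' Apply composed first-layer kernels to an image
#'
#' Circular convolution of the image with each composed kernel; numerically
#' identical (to rounding) to [shearlet_transform()] followed by
#' per-channel circular convolution with the trainable kernels.
#'
#' @param image \code{M x M} matrix.
#' @param composed [first_layer_factorization()] output.
#' @return array \code{M x M x L}.
#' @export
apply_composed_kernels <- function(image, composed) {
  M <- nrow(image)
  d <- dim(composed)
  stopifnot(d[1] == M, d[2] == M)
  Ihat <- stats::fft(image)
  out <- array(0, dim = d)
  for (l in seq_len(d[3])) {
    out[, , l] <- Re(stats::fft(Ihat * stats::fft(composed[, , l]),
                                inverse = TRUE)) / M^2
  }
  out
}

#' Storage reduction of the factorized first layer
#'
#' A non-shearlet first stage stores \code{reference} trainable kernels;
#' the factorized shearlet first layer stores L composed kernels plus the L
#' fixed shearlet filters, i.e. \code{reference - 2L} fewer kernels when
#' \code{2L < reference}.
#'
#' @param L shearlet slice count.
#' @param reference kernel budget of the reference first stage (128).
#' @return integer kernel-count reduction.
#' @export
kernel_storage_reduction <- function(L, reference = 128L) {
  as.integer(reference - 2L * as.integer(L))
}
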