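# File I/O, manifests and command-style entry points. Wavefront CSV schema:
# `row,col,orientation_bin` with 0-based indices (row 0 = first matrix row,
# bin 0 = normal along +x, degrees increasing counter-clockwise); R objects
# use 1-based indices internally.

#' Write a wavefront set to CSV
#'
#' @param wf a [wavefront_set()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_wavefront_csv <- function(wf, path) {
  stopifnot(inherits(wf, "wavefront_set"))
  df <- data.frame(row = wf$elements$row - 1L, col = wf$elements$col - 1L,
                   orientation_bin = wf$elements$bin)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wavefront set written by [write_wavefront_csv()]
#'
#' @param path CSV file.
#' @param dims domain dimensions \code{c(rows, cols)}.
#' @param n_orientations orientation bins.
#' @return a [wavefront_set()].
#' @export
read_wavefront_csv <- function(path, dims, n_orientations = 180L) {
  df <- utils::read.csv(path)
  wavefront_set(data.frame(row = df$row + 1L, col = df$col + 1L,
                           bin = df$orientation_bin),
                dims = dims, n_orientations = n_orientations)
}

#' Write a wavefront set to JSON
#'
#' @inheritParams write_wavefront_csv
#' @export
write_wavefront_json <- function(wf, path) {
  stopifnot(inherits(wf, "wavefront_set"))
  jsonlite::write_json(
    list(dims = wf$dims, n_orientations = wf$n_orientations,
         elements = data.frame(row = wf$elements$row - 1L,
                               col = wf$elements$col - 1L,
                               orientation_bin = wf$elements$bin)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Render a wavefront set as a colour-coded PNG
#'
#' Edge pixels are coloured by their normal orientation on the HSV colour
#' wheel (two bins per hue period since orientations live modulo 180
#' degrees); background is black. Pixels with several orientations show the
#' smallest bin.
#'
#' @param wf a [wavefront_set()].
#' @param path output PNG file.
#' @return \code{path}, invisibly.
#' @export
render_wavefront_png <- function(wf, path) {
  stopifnot(inherits(wf, "wavefront_set"))
  img <- array(0, dim = c(wf$dims[1], wf$dims[2], 3))
  e <- wf$elements
  if (nrow(e)) {
    first <- !duplicated(e[, c("row", "col")])
    e <- e[first, ]
    cols <- grDevices::hsv(e$bin / wf$n_orientations, 1, 1)
    rgb <- grDevices::col2rgb(cols) / 255
    img[cbind(e$row, e$col, 1)] <- rgb[1, ]
    img[cbind(e$row, e$col, 2)] <- rgb[2, ]
    img[cbind(e$row, e$col, 3)] <- rgb[3, ]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write a grey-scale image as PNG
#'
#' The image is min-max normalized to \code{[0, 1]} (8-bit grey-scale; use
#' [write_matrix_tsv()] for lossless storage).
#'
#' @param image numeric matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(normalize_image(image), path)
  invisible(path)
}

#' Lossless plain-text matrix export / import
#'
#' @param m numeric matrix.
#' @param path TSV file.
#' @return the path (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @keywords internal
write_manifest <- function(dir, command, config, seed,
                           file = "run_manifest.json") {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("shearwf")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, file),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Generate a phantom dataset directory
#'
#' Writes, for each phantom, the image (lossless TSV plus a preview PNG),
#' the ellipse list (CSV) and the analytic wavefront truth (CSV), alongside
#' a manifest recording configuration and seed.
#'
#' @param out_dir output directory (created).
#' @param n_phantoms number of phantoms.
#' @param config a [phantom_config()].
#' @param seed base seed; phantom i uses \code{seed + i}.
#' @return \code{out_dir}, invisibly.
#' @export
cmd_generate_phantoms <- function(out_dir, n_phantoms = 10L,
                                  config = phantom_config(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_phantoms)) {
    ph <- sample_head_phantom(config, seed = seed + i)
    stem <- file.path(out_dir, sprintf("phantom_%04d", i))
    write_matrix_tsv(ph$image, paste0(stem, ".tsv"))
    write_image_png(ph$image, paste0(stem, ".png"))
    utils::write.csv(ph$ellipses, paste0(stem, "_ellipses.csv"),
                     row.names = FALSE)
    write_wavefront_csv(ph$truth, paste0(stem, "_truth.csv"))
  }
  write_manifest(out_dir, "generate_phantoms",
                 c(unclass(config), n_phantoms = n_phantoms), seed)
  invisible(out_dir)
}

#' Compute and store the shearlet transform of a stored image
#'
#' @param image_path TSV image written by [write_matrix_tsv()].
#' @param out_path output TSV holding the \code{L x (M*M)} coefficient
#'   matrix (one slice per row).
#' @param n_scales,shear_counts system parameters.
#' @return the coefficient volume, invisibly.
#' @export
cmd_transform <- function(image_path, out_path, n_scales = 4L,
                          shear_counts = NULL) {
  image <- read_matrix_tsv(image_path)
  sys <- build_shearlet_system(shearlet_config(nrow(image),
                                               n_scales = n_scales,
                                               shear_counts = shear_counts))
  vol <- shearlet_transform(image, sys)
  write_matrix_tsv(matrix(as.vector(vol), nrow = sys$L, byrow = TRUE),
                   out_path)
  invisible(vol)
}

#' Train a wavefront extraction ensemble from a phantom dataset directory
#'
#' @param dataset_dir directory written by [cmd_generate_phantoms()].
#' @param out_dir model bundle directory.
#' @param n_orientations orientation bins used for the truth.
#' @param n_scales shearlet scales.
#' @param config a [train_config()].
#' @param ... passed to [train_wavefront_extractor()].
#' @return the ensemble, invisibly.
#' @export
cmd_train <- function(dataset_dir, out_dir, n_orientations = 180L,
                      n_scales = 4L, config = train_config(), ...) {
  images <- sort(Sys.glob(file.path(dataset_dir, "phantom_*.tsv")))
  if (!length(images)) stop("no phantoms found in ", dataset_dir)
  M <- NULL
  phantoms <- lapply(images, function(f) {
    img <- read_matrix_tsv(f)
    M <<- nrow(img)
    truth <- read_wavefront_csv(sub("\\.tsv$", "_truth.csv", f),
                                dims = dim(img),
                                n_orientations = n_orientations)
    list(image = img, truth = truth)
  })
  sys <- build_shearlet_system(shearlet_config(M, n_scales = n_scales))
  ens <- train_wavefront_extractor(phantoms, sys, config = config, ...)
  save_ensemble(ens, out_dir)
  write_manifest(out_dir, "train",
                 list(dataset = dataset_dir, n_orientations = n_orientations,
                      n_scales = n_scales, train = unclass(config)),
                 config$seed)
  invisible(ens)
}

#' Predict and store the wavefront set of a stored image
#'
#' @param image_path TSV image.
#' @param bundle_dir ensemble directory from [cmd_train()]/[save_ensemble()].
#' @param out_stem output stem; writes \code{<stem>.csv} and
#'   \code{<stem>.png}.
#' @return the predicted [wavefront_set()], invisibly.
#' @export
cmd_predict <- function(image_path, bundle_dir, out_stem) {
  ens <- load_ensemble(bundle_dir)
  image <- read_matrix_tsv(image_path)
  sys <- build_shearlet_system(ens$system_config)
  wf <- predict_wavefront_set(image, sys, ens)
  write_wavefront_csv(wf, paste0(out_stem, ".csv"))
  render_wavefront_png(wf, paste0(out_stem, ".png"))
  invisible(wf)
}

#' Run the CT wavefront-recovery benchmark and store the results table
#'
#' @param phantom a [sample_head_phantom()] result.
#' @param geometry a [sinogram_geometry()].
#' @param bundle_image,bundle_sinogram ensemble directories.
#' @param out_csv output CSV path.
#' @param ... passed to [benchmark_wavefront_recovery()].
#' @return the benchmark data frame, invisibly.
#' @export
cmd_ct_benchmark <- function(phantom, geometry, bundle_image,
                             bundle_sinogram, out_csv, ...) {
  ens_i <- load_ensemble(bundle_image)
  ens_s <- load_ensemble(bundle_sinogram)
  sys_i <- build_shearlet_system(ens_i$system_config)
  sys_s <- build_shearlet_system(ens_s$system_config)
  res <- benchmark_wavefront_recovery(phantom, geometry, ens_i, ens_s,
                                      sys_i, sys_s, ...)
  utils::write.csv(res, out_csv, row.names = FALSE)
  write_manifest(dirname(out_csv), "ct_benchmark",
                 list(methods = res$method), NA)
  invisible(res)
}
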