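# Patch-based wavefront-set classification: balanced patch datasets drawn
# from shearlet coefficient volumes, one binary CNN per orientation bin plus
# one edge/non-edge CNN, and full-image prediction.

PATCH_HALF <- 10L  # 21 x 21 patches

#' Min-max normalize an image to [0, 1]
#'
#' Applied to every image before its shearlet transform is fed to the
#' classifiers; patches receive no further pre-processing.
#'
#' @param image numeric matrix.
#' @return matrix with range \code{[0, 1]} (all-constant images map to 0).
#' @export
normalize_image <- function(image) {
  rng <- range(image)
  if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
  else image * 0
}

#' Extract a coefficient patch centred at a pixel
#'
#' Copies the \code{21 x 21 x L} window of a shearlet coefficient volume
#' around \code{center}. Centres closer than 10 pixels to the border are
#' rejected: border pixels are unclassifiable by design.
#'
#' @param volume array \code{M x M x L} of shearlet coefficients.
#' @param center integer \code{c(row, col)}, 1-based.
#' @return numeric array \code{21 x 21 x L}.
#' @export
extract_patch <- function(volume, center) {
  d <- dim(volume)
  r <- as.integer(center[1]); c <- as.integer(center[2])
  h <- PATCH_HALF
  if (r < h + 1L || c < h + 1L || r > d[1] - h || c > d[2] - h) {
    stop("range error: patch centre too close to the border")
  }
  volume[(r - h):(r + h), (c - h):(c + h), , drop = FALSE]
}

#' @keywords internal
interior_range <- function(M) (PATCH_HALF + 1L):(M - PATCH_HALF)

#' Restrict a wavefront set to the classifiable interior
#'
#' Drops elements within \code{border} pixels of the domain boundary, where
#' patch-based classification is undefined.
#'
#' @param wf a [wavefront_set()].
#' @param border border width in pixels (default: the patch half-width).
#' @return a [wavefront_set()].
#' @export
restrict_to_interior <- function(wf, border = PATCH_HALF) {
  e <- wf$elements
  keep <- e$row > border & e$row <= wf$dims[1] - border &
    e$col > border & e$col <= wf$dims[2] - border
  wavefront_set(e[keep, , drop = FALSE], wf$dims, wf$n_orientations)
}

# label of a centre pixel for a task: orientation bin i -> truth contains
# bin i there; "edge" -> any orientation present.
#' @keywords internal
task_label_matrix <- function(truth, task) {
  m <- matrix(FALSE, truth$dims[1], truth$dims[2])
  e <- truth$elements
  if (identical(task, "edge")) {
    if (nrow(e)) m[cbind(e$row, e$col)] <- TRUE
  } else {
    bin <- as.integer(task)
    stopifnot(bin >= 0, bin < truth$n_orientations)
    e <- e[e$bin == bin, , drop = FALSE]
    if (nrow(e)) m[cbind(e$row, e$col)] <- TRUE
  }
  m
}

#' Assemble a balanced patch training set for one binary task
#'
#' Samples exactly \code{patches_per_image} distinct patch centres per
#' phantom, targeting a 50/50 split between positive centres (where the
#' analytic truth carries the task's label) and negatives. Images short of
#' positives are compensated by images with spares so the global
#' positive/negative ratio stays within [0.9, 1.1]; if that fails a warning
#' is issued, and an error is raised when positives fall below 10% of the
#' targeted half.
#'
#' @param phantoms list of objects with fields \code{image} and \code{truth}
#'   (e.g. [sample_head_phantom()] results, or sinogram canvases).
#' @param system a [build_shearlet_system()] matching the image size.
#' @param task either an orientation bin (0-based integer) or \code{"edge"}.
#' @param patches_per_image patches drawn per image (default 10).
#' @param seed RNG seed for centre sampling.
#' @param volumes optional list of precomputed coefficient volumes (from
#'   [shearlet_transform()] of the min-max normalized images).
#' @return list with \code{x} (array \code{21 x 21 x L x N}), \code{y}
#'   (0/1 labels) and \code{centers}.
#' @export
build_training_set <- function(phantoms, system, task,
                               patches_per_image = 10L, seed = 1L,
                               volumes = NULL) {
  n_img <- length(phantoms)
  stopifnot(n_img > 0, patches_per_image >= 2)
  M <- nrow(phantoms[[1]]$image)
  interior <- interior_range(M)
  half <- patches_per_image %/% 2L

  pools <- with_seed(seed, lapply(seq_len(n_img), function(i) {
    lab <- task_label_matrix(phantoms[[i]]$truth, task)
    lab <- lab[interior, interior, drop = FALSE]
    pos <- which(lab); neg <- which(!lab)
    list(pos = sample(pos), neg = sample(neg))
  }))
  n_pos_avail <- vapply(pools, function(p) length(p$pos), integer(1))
  take_pos <- pmin(n_pos_avail, half)
  deficit <- sum(half - take_pos)
  if (deficit > 0) {
    spare <- pmin(n_pos_avail - take_pos, patches_per_image - take_pos)
    for (i in order(spare, decreasing = TRUE)) {
      if (deficit <= 0) break
      extra <- min(spare[i], deficit)
      take_pos[i] <- take_pos[i] + extra
      deficit <- deficit - extra
    }
  }
  n_total <- n_img * patches_per_image
  n_pos <- sum(take_pos)
  if (n_pos == 0) stop("no positive pixels available for task ", task)
  ratio <- n_pos / (n_total - n_pos)
  if (ratio < 0.9 || ratio > 1.1) {
    warning(sprintf(
      "undersampling for task %s: positive/negative ratio %.2f", task, ratio))
  }
  if (n_pos < 0.1 * n_total / 2) {
    stop("too few positive pixels for task ", task, " (", n_pos, " of ",
         n_total, " patches)")
  }

  L <- system$L
  x <- array(0, dim = c(2L * PATCH_HALF + 1L, 2L * PATCH_HALF + 1L, L,
                        n_total))
  y <- numeric(n_total)
  centers <- matrix(0L, n_total, 2L)
  k <- 0L
  off <- interior[1] - 1L
  for (i in seq_len(n_img)) {
    vol <- if (!is.null(volumes)) volumes[[i]] else
      shearlet_transform(normalize_image(phantoms[[i]]$image), system)
    np <- take_pos[i]
    nn <- patches_per_image - np
    sel <- c(pools[[i]]$pos[seq_len(np)], pools[[i]]$neg[seq_len(nn)])
    labs <- rep(c(1, 0), c(np, nn))
    ni <- length(interior)
    rows <- (sel - 1L) %% ni + 1L + off
    cols <- (sel - 1L) %/% ni + 1L + off
    for (s in seq_along(sel)) {
      k <- k + 1L
      x[, , , k] <- extract_patch(vol, c(rows[s], cols[s]))
      y[k] <- labs[s]
      centers[k, ] <- c(rows[s], cols[s])
    }
  }
  list(x = x, y = y, centers = centers, task = task)
}

#' Train the wavefront-set extraction ensemble
#'
#' Trains one binary CNN per orientation bin plus one edge/non-edge CNN on
#' balanced shearlet-coefficient patches, optionally calibrating per-model
#' decision thresholds on held-out phantoms. Orientation model \code{i}
#' answers "does the centre pixel carry a singularity with orientation bin
#' i"; the edge model answers "is the centre pixel an edge pixel".
#'
#' @param phantoms list of objects with \code{image} and \code{truth}; their
#'   truths fix the number of orientation bins.
#' @param system [build_shearlet_system()] for the image size.
#' @param config a [train_config()].
#' @param patches_per_image patches per image and task (default 10).
#' @param channels,dense_width architecture of each binary CNN.
#' @param calibration_fraction fraction of phantoms held out to calibrate
#'   decision thresholds (0 disables calibration; thresholds stay at 0.5).
#' @param allow_empty_tasks replace orientation tasks without positive
#'   pixels by a constant-negative model instead of failing. Useful for
#'   sinogram-domain ensembles, where the bounded covector slopes leave the
#'   direction bins near 0/180 degrees unpopulated.
#' @param verbose print progress.
#' @return object of class \code{wf_ensemble}.
#' @export
train_wavefront_extractor <- function(phantoms, system,
                                      config = train_config(),
                                      patches_per_image = 10L,
                                      channels = c(32L, 64L, 128L, 256L),
                                      dense_width = 1024L,
                                      calibration_fraction = 0.1,
                                      allow_empty_tasks = FALSE,
                                      verbose = FALSE) {
  stopifnot(length(phantoms) >= 2)
  n_orient <- phantoms[[1]]$truth$n_orientations
  M <- nrow(phantoms[[1]]$image)
  n_cal <- floor(length(phantoms) * calibration_fraction)
  cal <- if (n_cal > 0) phantoms[seq_len(n_cal)] else list()
  train <- phantoms[setdiff(seq_along(phantoms), seq_len(n_cal))]

  if (verbose) message("computing ", length(train), " coefficient volumes")
  volumes <- lapply(train, function(p)
    shearlet_transform(normalize_image(p$image), system))

  spec <- cnn_spec(c(2L * PATCH_HALF + 1L, 2L * PATCH_HALF + 1L, system$L),
                   channels = channels, dense_width = dense_width)
  tasks <- c(as.list(0:(n_orient - 1L)), list("edge"))
  models <- vector("list", length(tasks))
  for (ti in seq_along(tasks)) {
    task <- tasks[[ti]]
    if (verbose) message("training task ", task)
    ds <- if (allow_empty_tasks) {
      tryCatch(build_training_set(train, system, task,
                                  patches_per_image = patches_per_image,
                                  seed = config$seed + 1000L + ti,
                                  volumes = volumes),
               error = function(e) {
                 if (grepl("positive pixels", conditionMessage(e)))
                   NULL else stop(e)
               })
    } else {
      build_training_set(train, system, task,
                         patches_per_image = patches_per_image,
                         seed = config$seed + 1000L + ti,
                         volumes = volumes)
    }
    cfg <- config
    cfg$seed <- config$seed + ti
    models[[ti]] <- if (is.null(ds)) constant_model(spec, cfg) else
      cnn_train(ds$x, ds$y, spec = spec, config = cfg)
  }
  rm(volumes)

  ens <- structure(
    list(orientation_models = models[seq_len(n_orient)],
         edge_model = models[[n_orient + 1L]],
         tau_edge = 0.5, tau_orientation = rep(0.5, n_orient),
         n_orientations = n_orient, image_size = M,
         system_config = system$config, train_config = config,
         channels = channels, dense_width = dense_width),
    class = "wf_ensemble")
  if (length(cal) > 0) {
    ens <- calibrate_thresholds(ens, cal, system, verbose = verbose)
  }
  ens
}

# constant-negative stand-in for an orientation task without positives
#' @keywords internal
constant_model <- function(spec, config) {
  params <- cnn_init(spec, seed = config$seed)
  params$dense2$W[] <- 0
  params$dense2$b[] <- -20
  structure(list(params = params, spec = spec, config = config,
                 history = NULL, constant = TRUE),
            class = "cnn_model")
}

# Choose decision thresholds on held-out phantoms: the edge threshold
# maximizes the pooled edge F-score under the same greedy one-to-one
# matching (1-pixel tolerance) used by the evaluation metrics; each
# orientation threshold maximizes the pooled per-pixel F-score of its
# binary decision at true edge pixels.
#' @keywords internal
calibrate_thresholds <- function(ensemble, phantoms, system,
                                 grid = seq(0.1, 0.9, by = 0.05),
                                 verbose = FALSE) {
  M <- ensemble$image_size
  interior <- interior_range(M)
  edge_probs <- list(); edge_truth_pts <- list(); edge_centers <- list()
  ori_probs <- list(); ori_lab <- list()
  for (pi in seq_along(phantoms)) {
    p <- phantoms[[pi]]
    vol <- shearlet_transform(normalize_image(p$image), system)
    centers <- as.matrix(expand.grid(row = interior, col = interior))
    probs <- predict_patch_probs(ensemble$edge_model$params, vol, centers)
    edge_probs[[pi]] <- probs
    edge_centers[[pi]] <- centers
    te <- unique(restrict_to_interior(p$truth)$elements[, c("row", "col")])
    edge_truth_pts[[pi]] <- te
    ec <- p$truth$elements
    ec <- unique(ec[, c("row", "col")])
    ec <- ec[ec$row %in% interior & ec$col %in% interior, , drop = FALSE]
    if (nrow(ec)) {
      op <- matrix(0, nrow(ec), ensemble$n_orientations)
      for (b in seq_len(ensemble$n_orientations)) {
        op[, b] <- predict_patch_probs(
          ensemble$orientation_models[[b]]$params, vol, as.matrix(ec))
      }
      ori_probs[[pi]] <- op
      lb <- matrix(FALSE, nrow(ec), ensemble$n_orientations)
      for (b in seq_len(ensemble$n_orientations)) {
        m <- task_label_matrix(p$truth, b - 1L)
        lb[, b] <- m[as.matrix(ec)]
      }
      ori_lab[[pi]] <- lb
    }
  }
  f1 <- function(pred, lab) {
    tp <- sum(pred & lab)
    if (sum(pred) == 0 || sum(lab) == 0) return(0)
    pr <- tp / sum(pred); rc <- tp / sum(lab)
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  matched_f1 <- function(t) {
    tp <- 0; np <- 0; nt <- 0
    for (pi in seq_along(phantoms)) {
      sel <- edge_probs[[pi]] > t
      pe <- as.data.frame(edge_centers[[pi]][sel, , drop = FALSE])
      te <- edge_truth_pts[[pi]]
      tp <- tp + greedy_match_count(pe, te, 1.0)
      np <- np + nrow(pe); nt <- nt + nrow(te)
    }
    if (np == 0 || nt == 0) return(0)
    pr <- tp / np; rc <- tp / nt
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  scores <- vapply(grid, matched_f1, numeric(1))
  ensemble$tau_edge <- grid[which.max(scores)]
  if (length(ori_probs)) {
    op <- do.call(rbind, ori_probs)
    ol <- do.call(rbind, ori_lab)
    for (b in seq_len(ensemble$n_orientations)) {
      sb <- vapply(grid, function(t) f1(op[, b] > t, ol[, b]), numeric(1))
      ensemble$tau_orientation[b] <- grid[which.max(sb)]
    }
  }
  if (verbose) {
    message(sprintf("calibrated tau_edge=%.2f, tau_orientation in [%.2f, %.2f]",
                    ensemble$tau_edge, min(ensemble$tau_orientation),
                    max(ensemble$tau_orientation)))
  }
  ensemble
}

# probabilities of one binary model at a set of patch centres
#' @keywords internal
predict_patch_probs <- function(params, volume, centers, batch = 256L) {
  n <- nrow(centers)
  L <- dim(volume)[3]
  P <- 2L * PATCH_HALF + 1L
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    x <- array(0, dim = c(P, P, L, length(idx)))
    for (s in seq_along(idx)) {
      x[, , , s] <- extract_patch(volume, centers[idx[s], ])
    }
    out[idx] <- cnn_predict_params(params, x)
  }
  out
}

#' @export
print.wf_ensemble <- function(x, ...) {
  cat(sprintf(
    "Wavefront extraction ensemble: %d orientation models + 1 edge model\n",
    x$n_orientations))
  cat(sprintf(" input: %d x %d images, %d shearlet channels, tau_edge %.2f\n",
              x$image_size, x$image_size,
              shearlet_count(x$system_config$shear_counts), x$tau_edge))
  invisible(x)
}

#' Predict the digital wavefront set of an image
#'
#' Runs the edge model at every interior pixel of the (min-max normalized)
#' image's shearlet volume; pixels whose edge probability exceeds the edge
#' threshold receive the orientation bins whose models exceed their
#' thresholds, falling back to the most probable bin when none does.
#'
#' @param image \code{M x M} matrix matching the ensemble's training size.
#' @param system [build_shearlet_system()] matching the ensemble.
#' @param ensemble a [train_wavefront_extractor()] result.
#' @param volume optional precomputed coefficient volume of the normalized
#'   image.
#' @return a [wavefront_set()] supported on interior pixels.
#' @export
predict_wavefront_set <- function(image, system, ensemble, volume = NULL) {
  stopifnot(inherits(ensemble, "wf_ensemble"))
  M <- ensemble$image_size
  if (!is.null(image) && (!is.matrix(image) || nrow(image) != M ||
                          ncol(image) != M)) {
    stop("shape error: image does not match the ensemble")
  }
  if (!identical(system$config$image_size, ensemble$system_config$image_size) ||
      system$L != shearlet_count(ensemble$system_config$shear_counts)) {
    stop("shape error: shearlet system does not match the ensemble")
  }
  if (is.null(volume)) {
    volume <- shearlet_transform(normalize_image(image), system)
  }
  interior <- interior_range(M)
  centers <- as.matrix(expand.grid(row = interior, col = interior))
  edge_p <- predict_patch_probs(ensemble$edge_model$params, volume, centers)
  sel <- which(edge_p > ensemble$tau_edge)
  if (!length(sel)) {
    return(wavefront_set(NULL, c(M, M), ensemble$n_orientations))
  }
  ec <- centers[sel, , drop = FALSE]
  n_orient <- ensemble$n_orientations
  probs <- matrix(0, nrow(ec), n_orient)
  for (b in seq_len(n_orient)) {
    probs[, b] <- predict_patch_probs(
      ensemble$orientation_models[[b]]$params, volume, ec)
  }
  assemble_wavefront(ec, probs, ensemble, c(M, M))
}

# turn per-pixel orientation probabilities into a wavefront set: bins above
# their thresholds, or the argmax bin if none passes
#' @keywords internal
assemble_wavefront <- function(ec, probs, ensemble, dims) {
  if (!nrow(ec)) {
    return(wavefront_set(NULL, dims, ensemble$n_orientations))
  }
  over <- sweep(probs, 2, ensemble$tau_orientation, ">")
  elements <- vector("list", nrow(ec))
  for (s in seq_len(nrow(ec))) {
    bins <- which(over[s, ]) - 1L
    if (!length(bins)) bins <- which.max(probs[s, ]) - 1L
    elements[[s]] <- data.frame(row = rep(ec[s, 1], length(bins)),
                                col = rep(ec[s, 2], length(bins)),
                                bin = bins)
  }
  wavefront_set(do.call(rbind, elements), dims, ensemble$n_orientations)
}

#' Patch-protocol MF-score of an ensemble on held-out phantoms
#'
#' Evaluates every binary classifier on a balanced patch set drawn from
#' held-out phantoms exactly like the training data (10 patches per image by
#' default, positives and negatives balanced) and reports the mean of the
#' per-orientation F-scores (MF) together with the edge classifier's
#' F-score. This mirrors the evaluation protocol of the training procedure:
#' test images enter through their sampled patches.
#'
#' @param ensemble a [train_wavefront_extractor()] result.
#' @param phantoms held-out phantoms (objects with \code{image}, \code{truth}).
#' @param system the matching shearlet system.
#' @param patches_per_image patches drawn per image and task.
#' @param seed RNG seed of the patch sampler.
#' @param threshold decision threshold applied to the probabilities.
#' @return list with \code{mf} (mean orientation F-score),
#'   \code{orientation_fscores}, and \code{edge_fscore}.
#' @export
evaluate_patch_mf <- function(ensemble, phantoms, system,
                              patches_per_image = 10L, seed = 1L,
                              threshold = 0.5) {
  stopifnot(inherits(ensemble, "wf_ensemble"))
  volumes <- lapply(phantoms, function(p)
    shearlet_transform(normalize_image(p$image), system))
  n <- ensemble$n_orientations
  fscore <- function(model, task, task_seed) {
    ds <- build_training_set(phantoms, system, task,
                             patches_per_image = patches_per_image,
                             seed = task_seed, volumes = volumes)
    pred <- cnn_predict_params(model$params, ds$x) > threshold
    tp <- sum(pred & ds$y == 1)
    fscore_from_counts(tp, sum(pred), sum(ds$y == 1))
  }
  ofs <- vapply(seq_len(n), function(b)
    fscore(ensemble$orientation_models[[b]], b - 1L, seed + b), numeric(1))
  efs <- fscore(ensemble$edge_model, "edge", seed + n + 1L)
  list(mf = mean(ofs), orientation_fscores = ofs, edge_fscore = efs)
}

#' Save a trained ensemble to a directory
#'
#' Writes one serialized model per binary classifier plus a JSON manifest
#' with the configuration, thresholds and seeds.
#'
#' @param ensemble a \code{wf_ensemble}.
#' @param dir target directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "wf_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in seq_len(ensemble$n_orientations)) {
    saveRDS(ensemble$orientation_models[[b]],
            file.path(dir, sprintf("orientation_%03d.rds", b - 1L)))
  }
  saveRDS(ensemble$edge_model, file.path(dir, "edge.rds"))
  manifest <- list(
    n_orientations = ensemble$n_orientations,
    image_size = ensemble$image_size,
    tau_edge = ensemble$tau_edge,
    tau_orientation = ensemble$tau_orientation,
    system_config = unclass(ensemble$system_config),
    train_config = unclass(ensemble$train_config),
    channels = ensemble$channels, dense_width = ensemble$dense_width)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param dir directory written by [save_ensemble()].
#' @return a \code{wf_ensemble}.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- as.integer(manifest$n_orientations[[1]])
  models <- lapply(seq_len(n) - 1L, function(b)
    readRDS(file.path(dir, sprintf("orientation_%03d.rds", b))))
  structure(
    list(orientation_models = models,
         edge_model = readRDS(file.path(dir, "edge.rds")),
         tau_edge = manifest$tau_edge,
         tau_orientation = manifest$tau_orientation,
         n_orientations = n, image_size = manifest$image_size,
         system_config = do.call(shearlet_config, manifest$system_config[
           c("image_size", "n_scales", "shear_counts", "generator")]),
         train_config = manifest$train_config,
         channels = manifest$channels, dense_width = manifest$dense_width),
    class = "wf_ensemble")
}
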