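#' Digital wavefront sets
#'
#' A digital wavefront set annotates pixels of a rectangular domain with one
#' or more quantized normal orientations. Orientations live in \code{[0, 180)}
#' degrees (directions are taken modulo half-turns) and are binned into
#' \code{n_orientations} equal bins, bin \code{i} covering
#' \code{[i*180/n, (i+1)*180/n)} degrees, with bin 0 containing the normal
#' pointing along +x. The same container represents sinogram-domain sets,
#' with (angle index, offset index) playing the role of (row, column).
#'
#' @param elements data frame with integer columns \code{row}, \code{col}
#'   (1-based pixel indices) and \code{bin} (0-based orientation bin).
#'   Duplicate triples are dropped.
#' @param dims integer vector \code{c(rows, cols)} of the domain.
#' @param n_orientations number of orientation bins (default 180).
#' @return an object of class \code{wavefront_set}.
#' @export
wavefront_set <- function(elements, dims, n_orientations = 180L) {
  dims <- as.integer(dims)
  n_orientations <- as.integer(n_orientations)
  stopifnot(length(dims) == 2, all(dims > 0), n_orientations >= 2)
  if (is.null(elements) || nrow(as.data.frame(elements)) == 0) {
    elements <- data.frame(row = integer(), col = integer(), bin = integer())
  } else {
    elements <- as.data.frame(elements)[, c("row", "col", "bin")]
    elements$row <- as.integer(elements$row)
    elements$col <- as.integer(elements$col)
    elements$bin <- as.integer(elements$bin)
    if (any(elements$row < 1L | elements$row > dims[1] |
            elements$col < 1L | elements$col > dims[2])) {
      stop("wavefront elements outside the domain")
    }
    if (any(elements$bin < 0L | elements$bin >= n_orientations)) {
      stop("orientation bins must lie in [0, n_orientations)")
    }
    elements <- unique(elements)
    elements <- elements[order(elements$row, elements$col, elements$bin), ]
    rownames(elements) <- NULL
  }
  structure(list(elements = elements, dims = dims,
                 n_orientations = n_orientations),
            class = "wavefront_set")
}

#' @export
print.wavefront_set <- function(x, ...) {
  cat(sprintf(
    "Digital wavefront set: %d elements on %d edge pixels (%d x %d domain, %d orientation bins)\n",
    nrow(x$elements), sum(edge_mask(x)), x$dims[1], x$dims[2],
    x$n_orientations))
  invisible(x)
}

#' @export
as.data.frame.wavefront_set <- function(x, ...) x$elements

#' Edge mask of a wavefront set
#'
#' @param wf a [wavefront_set()].
#' @return logical matrix of the domain dimensions; \code{TRUE} where the set
#'   has at least one orientation.
#' @export
edge_mask <- function(wf) {
  stopifnot(inherits(wf, "wavefront_set"))
  m <- matrix(FALSE, wf$dims[1], wf$dims[2])
  if (nrow(wf$elements)) {
    m[cbind(wf$elements$row, wf$elements$col)] <- TRUE
  }
  m
}

#' Matching tolerance for wavefront comparisons
#'
#' @param max_pixel_distance maximum Euclidean pixel distance between matched
#'   elements (default 1).
#' @param max_bin_distance maximum cyclic orientation-bin distance between an
#'   element's bin and the queried bin (default 2).
#' @return an object of class \code{match_tolerance}.
#' @export
match_tolerance <- function(max_pixel_distance = 1.0, max_bin_distance = 2L) {
  stopifnot(max_pixel_distance >= 0, max_bin_distance >= 0)
  structure(list(max_pixel_distance = max_pixel_distance,
                 max_bin_distance = as.integer(max_bin_distance)),
            class = "match_tolerance")
}

#' @keywords internal
cyclic_bin_distance <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

# Elements of `wf` whose bin is within `tol_bins` (cyclically) of `bin`.
#' @keywords internal
restrict_to_bin <- function(wf, bin, tol_bins) {
  e <- wf$elements
  e[cyclic_bin_distance(e$bin, bin, wf$n_orientations) <= tol_bins, ,
    drop = FALSE]
}

# Greedy one-to-one matching between two point sets, pairing closest pairs
# first among those within `max_dist`. Returns the number of matches.
#' @keywords internal
greedy_match_count <- function(p, q, max_dist) {
  np <- nrow(p); nq <- nrow(q)
  if (np == 0 || nq == 0) return(0L)
  d2 <- outer(p$row, q$row, "-")^2 + outer(p$col, q$col, "-")^2
  ok <- which(d2 <= max_dist^2)
  if (!length(ok)) return(0L)
  ok <- ok[order(d2[ok])]
  used_p <- logical(np); used_q <- logical(nq)
  matches <- 0L
  for (idx in ok) {
    i <- (idx - 1L) %% np + 1L
    j <- (idx - 1L) %/% np + 1L
    if (!used_p[i] && !used_q[j]) {
      used_p[i] <- TRUE; used_q[j] <- TRUE
      matches <- matches + 1L
    }
  }
  matches
}

#' @keywords internal
check_same_domain <- function(pred, truth) {
  stopifnot(inherits(pred, "wavefront_set"), inherits(truth, "wavefront_set"))
  if (!identical(pred$dims, truth$dims) ||
      pred$n_orientations != truth$n_orientations) {
    stop("shape error: wavefront sets live on different domains")
  }
}

# TP / |pred| / |truth| for one orientation bin.
#' @keywords internal
bin_match_counts <- function(pred, truth, bin, tol) {
  p <- restrict_to_bin(pred, bin, tol$max_bin_distance)
  q <- restrict_to_bin(truth, bin, tol$max_bin_distance)
  c(tp = greedy_match_count(p, q, tol$max_pixel_distance),
    npred = nrow(p), ntruth = nrow(q))
}

#' @keywords internal
fscore_from_counts <- function(tp, npred, ntruth) {
  if (npred == 0 && ntruth == 0) return(1)
  if (npred == 0 || ntruth == 0) return(0)
  precision <- tp / npred
  recall <- tp / ntruth
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Per-orientation F-score between two digital wavefront sets
#'
#' Restricts both sets to elements whose orientation bin lies within the bin
#' tolerance of \code{bin}, matches them one-to-one greedily (closest pairs
#' first) within the pixel-distance tolerance, and returns the F-measure
#' \code{2PR/(P+R)} of the matching. Two empty restrictions score 1; an empty
#' restriction against a non-empty one scores 0.
#'
#' @param pred,truth [wavefront_set()] objects on the same domain.
#' @param bin orientation bin to evaluate.
#' @param tol a [match_tolerance()].
#' @return F-score in \code{[0, 1]}.
#' @export
orientation_fscore <- function(pred, truth, bin, tol = match_tolerance()) {
  check_same_domain(pred, truth)
  cnt <- bin_match_counts(pred, truth, bin, tol)
  unname(fscore_from_counts(cnt[["tp"]], cnt[["npred"]], cnt[["ntruth"]]))
}

#' Mean F-score (MF) over orientation bins
#'
#' Arithmetic mean of [orientation_fscore()] over orientation bins. By
#' default the mean runs over the bins present in the union of the two sets;
#' pass \code{bins} explicitly (e.g. \code{0:179}) to average over a fixed
#' set of orientations.
#'
#' @inheritParams orientation_fscore
#' @param bins integer vector of bins to average over, or \code{NULL} for the
#'   bins present in \code{pred} or \code{truth}.
#' @return MF-score in \code{[0, 1]} (1 when both sets are empty).
#' @export
mf_score <- function(pred, truth, tol = match_tolerance(), bins = NULL) {
  check_same_domain(pred, truth)
  if (is.null(bins)) {
    bins <- sort(unique(c(pred$elements$bin, truth$elements$bin)))
  }
  if (!length(bins)) return(1)
  mean(vapply(bins, function(b) orientation_fscore(pred, truth, b, tol),
              numeric(1)))
}

#' Pooled mean F-score over a collection of image pairs
#'
#' Aggregates true-positive / prediction / truth counts per orientation bin
#' across all pairs before forming the per-bin F-scores, then averages over
#' bins (test-set pooling, as opposed to averaging per-image MF-scores).
#'
#' @param preds,truths lists of [wavefront_set()] objects of equal length.
#' @param tol a [match_tolerance()].
#' @param bins bins to average over; default: all bins of the domain.
#' @return pooled MF-score in \code{[0, 1]}.
#' @export
mf_score_pooled <- function(preds, truths, tol = match_tolerance(),
                            bins = NULL) {
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  n <- truths[[1]]$n_orientations
  if (is.null(bins)) bins <- 0:(n - 1L)
  counts <- matrix(0, nrow = length(bins), ncol = 3,
                   dimnames = list(NULL, c("tp", "npred", "ntruth")))
  for (i in seq_along(preds)) {
    check_same_domain(preds[[i]], truths[[i]])
    for (bi in seq_along(bins)) {
      counts[bi, ] <- counts[bi, ] +
        bin_match_counts(preds[[i]], truths[[i]], bins[bi], tol)
    }
  }
  mean(apply(counts, 1, function(r) fscore_from_counts(r[1], r[2], r[3])))
}

#' Hausdorff distance between digital wavefront sets
#'
#' Symmetric Hausdorff distance in the product metric
#' \code{d((p, b), (q, c)) = |p - q|_2 + bin_scale * cyclic(b, c)}, where
#' \code{cyclic} is the cyclic orientation-bin distance.
#'
#' @inheritParams orientation_fscore
#' @param bin_scale weight (in pixels per bin) of the orientation component.
#' @return non-negative distance; \code{Inf} if exactly one set is empty,
#'   0 if both are empty.
#' @export
hausdorff_distance <- function(pred, truth, bin_scale = 1.0) {
  check_same_domain(pred, truth)
  p <- pred$elements; q <- truth$elements
  if (nrow(p) == 0 && nrow(q) == 0) return(0)
  if (nrow(p) == 0 || nrow(q) == 0) return(Inf)
  n <- pred$n_orientations
  d <- sqrt(outer(p$row, q$row, "-")^2 + outer(p$col, q$col, "-")^2) +
    bin_scale * outer(p$bin, q$bin,
                      function(a, b) cyclic_bin_distance(a, b, n))
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

#' Wavefront mean squared error
#'
#' For every truth element, the squared pixel distance to the nearest
#' predicted element with a compatible orientation (cyclic bin distance at
#' most \code{bin_tolerance}) is recorded, capped at \code{penalty_cap};
#' truth elements with no compatible prediction receive the cap. The score
#' is the mean over truth elements.
#'
#' @inheritParams orientation_fscore
#' @param penalty_cap cap (in squared pixels) for unmatched truth elements.
#' @param bin_tolerance maximum cyclic bin distance for a prediction to count
#'   as compatible.
#' @return non-negative mean squared distance; 0 for identical sets and
#'   \code{penalty_cap} when \code{pred} is empty (for non-empty truth).
#' @export
wavefront_mse <- function(pred, truth, penalty_cap = 1000,
                          bin_tolerance = 2L) {
  check_same_domain(pred, truth)
  q <- truth$elements
  if (nrow(q) == 0) return(0)
  p <- pred$elements
  if (nrow(p) == 0) return(penalty_cap)
  n <- truth$n_orientations
  d2 <- outer(q$row, p$row, "-")^2 + outer(q$col, p$col, "-")^2
  compat <- outer(q$bin, p$bin,
                  function(a, b) cyclic_bin_distance(a, b, n)) <= bin_tolerance
  d2[!compat] <- Inf
  best <- apply(d2, 1, min)
  mean(pmin(best, penalty_cap))
}
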