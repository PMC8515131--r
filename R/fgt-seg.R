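#' Fuzzy c-means clustering of intensities
#'
#' Minimizes the weighted FCM objective
#' `J = sum_i w_i sum_k u_ik^m (x_i - c_k)^2` subject to memberships summing
#' to one per sample, by alternating the closed-form membership and centroid
#' updates.  Duplicate values are aggregated into weights internally, which
#' leaves the objective (and hence the solution) mathematically unchanged
#' while making voxel-scale problems cheap.  Initialization places centroids
#' at evenly spaced quantiles, so the algorithm is deterministic; `seed` is
#' accepted for interface stability but not consumed.
#'
#' @param values numeric vector of samples (e.g. voxel intensities).
#' @param c number of clusters (>= 2, and at most the number of distinct
#'   values).
#' @param m fuzzifier exponent (> 1).
#' @param tol convergence tolerance on the relative change in `J` (kept
#'   relative so the fit is exactly equivariant under intensity rescaling).
#' @param max_iter iteration cap.
#' @param weights optional non-negative sample weights (e.g. histogram
#'   counts); default 1 per sample.
#' @param seed unused; present for call-signature stability.
#' @return Object of class `fcm_result`: `centroids` (sorted increasing),
#'   `memberships` (samples x clusters, matching the sorted centroids),
#'   `objective`, `objective_trace`, `iterations`.
#' @export
fuzzy_cmeans <- function(values, c, m = 2, tol = 1e-5, max_iter = 300L,
                         weights = NULL, seed = NULL) {
  if (!all(is.finite(values))) stop("values must be finite")
  if (c < 2) stop("c must be at least 2")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0))
    stop("weights must be non-negative and match values")

  # aggregate duplicates: identical objective, far fewer samples
  agg <- rowsum(weights, group = values)
  x <- as.numeric(rownames(agg))
  w <- as.numeric(agg[, 1])
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) < c) stop("need at least c distinct values")

  cent <- as.numeric(quantile(x, probs = (seq_len(c) - 0.5) / c, names = FALSE))

  # scale-relative guards keep the solution exactly equivariant under x -> k*x
  s2 <- max(x^2, 1e-300)
  trace <- numeric(0)
  J_old <- Inf
  U <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, cent, function(a, b) (a - b)^2)
    zero <- d2 < .Machine$double.eps * s2
    U <- matrix(0, length(x), c)
    any_zero <- rowSums(zero) > 0
    if (any(any_zero)) U[any_zero, ] <- zero[any_zero, , drop = FALSE] /
        rowSums(zero[any_zero, , drop = FALSE])
    if (any(!any_zero)) {
      dd <- d2[!any_zero, , drop = FALSE]
      inv <- dd^(-1 / (m - 1))
      U[!any_zero, ] <- inv / rowSums(inv)
    }
    Um <- U^m
    cent <- colSums(Um * w * x) / colSums(Um * w)
    d2 <- outer(x, cent, function(a, b) (a - b)^2)
    J <- sum(w * rowSums(Um * d2))
    trace <- c(trace, J)
    if (is.finite(J_old) && abs(J_old - J) < tol * max(J, s2 * 1e-12)) break
    J_old <- J
  }
  ord <- order(cent)
  structure(list(centroids = cent[ord],
                 memberships = U[, ord, drop = FALSE],
                 values = x, weights = w,
                 objective = trace[length(trace)],
                 objective_trace = trace,
                 iterations = length(trace)),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d clusters, %d iterations, J = %.6g\n",
              length(x$centroids), x$iterations, x$objective))
  cat("  centroids:", paste(signif(x$centroids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Xie-Beni cluster validity index
#'
#' Compactness over separation: `J_m / (N * min_{k != l} |c_k - c_l|^2)`.
#' Smaller is better.
#'
#' @param fit an `fcm_result`.
#' @return Scalar index value.
#' @keywords internal
xie_beni <- function(fit) {
  d2 <- outer(fit$values, fit$centroids, function(a, b) (a - b)^2)
  J <- sum(fit$weights * rowSums(fit$memberships^2 * d2))
  sep <- min(dist(fit$centroids))^2
  N <- sum(fit$weights)
  J / (N * sep)
}

#' Automatic selection of the cluster number
#'
#' Runs [fuzzy_cmeans()] for each candidate `c` and returns the one
#' minimizing the Xie-Beni validity index.  Near-constant inputs (or fewer
#' distinct values than `c_min`) return `c_min` with a degeneracy warning.
#'
#' @param values numeric samples.
#' @param c_min,c_max candidate range (`c_min >= 2`).
#' @param m,tol,max_iter,weights forwarded to [fuzzy_cmeans()].
#' @return Integer `c*`, with attribute `"index"` holding the per-candidate
#'   Xie-Beni values.
#' @export
select_cluster_number <- function(values, c_min = 2L, c_max = 5L, m = 2,
                                  tol = 1e-5, max_iter = 300L,
                                  weights = NULL) {
  if (c_min < 2) stop("c_min must be at least 2")
  if (c_max < c_min) stop("empty cluster-number range")
  n_distinct <- length(unique(values))
  scale <- max(abs(values), 1e-12)
  if (n_distinct < c_min || sd(values) < 1e-9 * scale) {
    warning("degenerate (near-constant) intensities; returning c_min")
    return(structure(as.integer(c_min), index = NULL))
  }
  cands <- seq.int(c_min, min(c_max, n_distinct))
  idx <- vapply(cands, function(cc) {
    xie_beni(fuzzy_cmeans(values, cc, m = m, tol = tol,
                          max_iter = max_iter, weights = weights))
  }, numeric(1))
  structure(as.integer(cands[which.min(idx)]),
            index = stats::setNames(idx, cands))
}

#' Segment fibroglandular tissue within the breast mask
#'
#' Step 2 of the scheme.  Intensities inside the breast mask are pooled over
#' the full 3D volume, binned into a fixed-width histogram (exact weighted
#' clustering on bin centres), clustered by fuzzy c-means with the cluster
#' number chosen by the Xie-Beni index, and hard-assigned by maximum
#' membership.  Clusters whose centroid exceeds the midpoint of the extreme
#' centroids are labelled FGT (fat suppression renders FGT brighter than
#' fat).  A unimodality guard protects single-tissue (all-fat) breasts: if
#' the intensity histogram shows no valley between the extreme centroids
#' (smoothed density at their midpoint above `valley_ratio` times the
#' smaller flanking peak) the breast is treated as one tissue and an empty
#' FGT mask is returned with flag `"single_tissue"`.
#'
#' @param volume 3D numeric array (pre-contrast).
#' @param breast_mask logical array from [segment_whole_breast()].
#' @param c_min,c_max cluster-number range.
#' @param m fuzzifier.
#' @param n_bins histogram bins used to pool voxel intensities.
#' @param valley_ratio unimodality guard: minimum valley-to-peak density
#'   ratio above which the breast is declared single-tissue.
#' @return Logical FGT mask (always a subset of `breast_mask`), with the
#'   fitted `fcm_result` in attribute `"fit"`.
#' @export
segment_fgt <- function(volume, breast_mask, c_min = 2L, c_max = 5L, m = 2,
                        n_bins = 256L, valley_ratio = 0.5) {
  stopifnot(identical(dim(volume), dim(breast_mask)))
  if (!any(breast_mask)) stop("empty breast mask")
  vals <- volume[breast_mask]
  empty <- array(FALSE, dim(volume))

  if (length(unique(vals)) < 2) return(empty)
  r <- range(vals)
  edges <- seq(r[1], r[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(vals, edges, all.inside = TRUE), 1L), n_bins)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(bin, nbins = n_bins)
  use <- counts > 0
  bx <- centres[use]; bw <- counts[use]

  cstar <- tryCatch(
    select_cluster_number(bx, c_min, c_max, m = m, weights = bw),
    warning = function(w) structure(as.integer(c_min), degenerate = TRUE))
  if (isTRUE(attr(cstar, "degenerate")) || length(unique(bx)) < c_min)
    return(empty)
  fit <- fuzzy_cmeans(bx, as.integer(cstar), m = m, weights = bw)
  hard <- max.col(fit$memberships, ties.method = "first")
  midpoint <- mean(range(fit$centroids))

  # unimodality guard: a real fat/FGT mixture has a density valley between
  # the extreme centroids; a single tissue does not
  smooth <- as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2))
  smooth[is.na(smooth)] <- 0
  bin_of <- function(val) pmin(pmax(findInterval(val, edges, all.inside = TRUE), 1L), n_bins)
  mid_bin <- bin_of(midpoint)
  valley <- mean(smooth[max(1, mid_bin - 2):min(n_bins, mid_bin + 2)])
  peak_low <- max(smooth[seq_len(mid_bin)])
  peak_high <- max(smooth[seq.int(mid_bin, n_bins)])
  if (valley > valley_ratio * min(peak_low, peak_high)) {
    out <- empty
    attr(out, "fit") <- fit
    attr(out, "flag") <- "single_tissue"
    return(out)
  }
  fgt_clusters <- which(fit$centroids > midpoint)
  # map each voxel to its bin's hard cluster
  bin_cluster <- integer(n_bins)
  bin_cluster[use] <- hard
  voxel_is_fgt <- bin_cluster[bin] %in% fgt_clusters

  out <- empty
  out[breast_mask] <- voxel_is_fgt
  attr(out, "fit") <- fit
  out
}
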