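#' Gradient cost map for boundary tracing
#'
#' Cost is `1 - min(g / g_sat, 1)` where `g` is the central-difference
#' gradient magnitude and `g_sat` a noise-adaptive saturation level
#' (`max(4 * 1.4826 * MAD(g), 0.05 * max(g))`).  Every edge clearly above
#' the gradient noise floor therefore costs (near) zero, regardless of its
#' strength — a weak air/fat skin edge competes on equal terms with the
#' strong fat/FGT interface, and the positional terms added by the caller
#' decide between them.  A constant slice has no gradient anywhere and
#' yields a uniform cost map.
#'
#' @param slice_image 2D numeric matrix (rows anterior to posterior).
#' @return Non-negative cost matrix of the same dimension.
#' @export
compute_cost_map <- function(slice_image) {
  if (!is.matrix(slice_image) || !all(is.finite(slice_image)))
    stop("slice_image must be a finite numeric matrix")
  nr <- nrow(slice_image); nc <- ncol(slice_image)
  gy <- matrix(0, nr, nc); gx <- matrix(0, nr, nc)
  if (nr > 2) gy[2:(nr - 1), ] <- (slice_image[3:nr, ] - slice_image[1:(nr - 2), ]) / 2
  if (nr > 1) { gy[1, ] <- slice_image[2, ] - slice_image[1, ]
                gy[nr, ] <- slice_image[nr, ] - slice_image[nr - 1, ] }
  if (nc > 2) gx[, 2:(nc - 1)] <- (slice_image[, 3:nc] - slice_image[, 1:(nc - 2)]) / 2
  if (nc > 1) { gx[, 1] <- slice_image[, 2] - slice_image[, 1]
                gx[, nc] <- slice_image[, nc] - slice_image[, nc - 1] }
  g <- sqrt(gy^2 + gx^2)
  m <- max(g)
  if (m == 0) return(matrix(1, nr, nc))
  g_sat <- max(4 * stats::mad(g, constant = 1.4826), 0.05 * m)
  1 - pmin(g / g_sat, 1)
}

#' Trace a minimum-cost boundary path by dynamic programming
#'
#' Finds the path `r(1..ncol)` (one row per column, steps bounded by
#' `smoothness_limit`) minimizing
#' `sum(cost[r_j, j]) + lambda_smooth * sum(|r_j - r_{j-1}|) +
#'  lambda_prior * sum(|r_j - prior_j|)`.
#' The optimum is global for this objective; ties are broken toward the
#' smallest row index.  The prior path is typically the boundary traced on
#' the adjacent slice, which carries cross-slice continuity through the
#' volume.
#'
#' @param cost_map numeric matrix of non-negative finite costs.
#' @param prior_path optional integer vector (one row per column) from the
#'   previous slice, or `NULL`.
#' @param smoothness_limit maximum allowed row change between adjacent
#'   columns.
#' @param lambda_smooth weight of the step-size penalty.
#' @param lambda_prior weight of the deviation-from-prior penalty (ignored
#'   when `prior_path` is `NULL`).
#' @return Integer vector of row positions, class `boundary_path`, with the
#'   attained objective in attribute `"cost"`.
#' @export
trace_boundary_dp <- function(cost_map, prior_path = NULL,
                              smoothness_limit = 4L,
                              lambda_smooth = 0.15, lambda_prior = 0.02) {
  if (!is.matrix(cost_map) || length(cost_map) == 0)
    stop("cost_map must be a non-empty matrix")
  if (!all(is.finite(cost_map))) stop("cost_map must be finite")
  nr <- nrow(cost_map); nc <- ncol(cost_map)
  s <- as.integer(smoothness_limit)
  if (!is.null(prior_path) && length(prior_path) != nc)
    stop("prior_path length must match ncol(cost_map)")

  local_cost <- cost_map
  if (!is.null(prior_path)) {
    local_cost <- local_cost + lambda_prior *
      abs(outer(seq_len(nr), prior_path, "-"))
  }

  D <- matrix(Inf, nr, nc)
  ptr <- matrix(NA_integer_, nr, nc)
  D[, 1] <- local_cost[, 1]
  rows <- seq_len(nr)
  for (j in seq_len(nc)[-1]) {
    best <- rep(Inf, nr)
    arg <- rep(NA_integer_, nr)
    for (d in seq(-s, s)) {           # predecessor row = r + d, smallest first
      pr <- rows + d
      ok <- pr >= 1L & pr <= nr
      cand <- rep(Inf, nr)
      cand[ok] <- D[pr[ok], j - 1] + lambda_smooth * abs(d)
      upd <- cand < best
      best[upd] <- cand[upd]
      arg[upd] <- pr[upd]
    }
    D[, j] <- best + local_cost[, j]
    ptr[, j] <- arg
  }
  path <- integer(nc)
  path[nc] <- which.min(D[, nc])      # which.min ties -> smallest row
  if (nc > 1) for (j in seq(nc, 2)) path[j - 1] <- ptr[path[j], j]
  structure(path, cost = min(D[, nc]), class = "boundary_path")
}

#' Segment the whole breast from a pre-contrast volume
#'
#' Step 1 of the three-step scheme.  Each 2D slice is processed in sequence:
#' the skin line (anterior air/tissue edge) and the chest wall (posterior
#' tissue/body edge) are traced by [trace_boundary_dp()] on a gradient cost
#' map with a small positional bias disambiguating the two edges; the path
#' found on the previous slice acts as the continuity prior for the next.
#' The breast mask is everything between the two traced boundaries, and is
#' split at the sternum midline (the minimum-foreground column near the
#' volume centre) into left and right breasts.
#'
#' The skin path is steered by a coverage penalty — `beta` times the
#' fraction of foreground (Otsu) voxels a column would leave anterior to
#' the path — so it hugs the first air/tissue transition; the chest-wall
#' path is steered by a posterior positional bias of weight `alpha`, so it
#' settles on the last tissue/body edge.
#'
#' @param volume 3D numeric array, axes (slice, row, column) with rows
#'   running anterior to posterior.
#' @param spacing voxel spacing in mm (unused by the tracer itself; carried
#'   for interface symmetry).
#' @param alpha weight of the posterior bias on the chest-wall cost.
#' @param beta weight of the uncovered-foreground penalty on the skin cost.
#' @param min_thickness minimum skin-to-chest-wall distance (voxels) for a
#'   column to contribute breast tissue; suppresses the zero-thickness
#'   ribbon where both boundaries coincide on the chest wall.
#' @param smoothness_limit,lambda_smooth,lambda_prior DP parameters, see
#'   [trace_boundary_dp()].
#' @return A list with logical arrays `mask` (both breasts), `left`,
#'   `right`, and the integer `midline` column.  An all-background volume
#'   yields empty masks with a warning.
#' @export
segment_whole_breast <- function(volume, spacing = c(1, 1, 1),
                                 alpha = 0.15, beta = 4, min_thickness = 3L,
                                 smoothness_limit = 4L,
                                 lambda_smooth = 0.15, lambda_prior = 0.02) {
  stopifnot(length(dim(volume)) == 3)
  dims <- dim(volume)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  mask <- array(FALSE, dims)

  # two-level Otsu: the first split can lump fat with air when a bright
  # class (FGT/body) dominates the contrast, so re-split the lower mode to
  # find the air/tissue level
  v <- as.vector(volume)
  empty_out <- function() {
    warning("no breast-like foreground found; returning empty mask")
    list(mask = mask, left = mask, right = mask,
         midline = as.integer(round(nx / 2)))
  }
  if (diff(range(v)) == 0) return(empty_out())
  thr1 <- otsu_threshold(v)
  low <- v[v <= thr1]
  thr <- if (length(low) > 1 && diff(range(low)) > 0)
    otsu_threshold(low) else thr1
  fg <- v > thr
  # Otsu separability (between-class / total variance) at the primary
  # split: a single Gaussian noise mode cannot exceed ~0.64 however it is
  # cut, whereas any genuine air/tissue structure scores well above it
  fg1 <- v > thr1
  eta <- if (any(fg1) && any(!fg1)) {
    w <- mean(fg1)
    w * (1 - w) * (mean(v[fg1]) - mean(v[!fg1]))^2 / stats::var(v)
  } else 0
  if (mean(fg) < 0.005 || eta < 0.66) return(empty_out())

  rowbias <- (seq_len(ny) - 1) / max(1, ny - 1)
  bias_cw <- alpha * matrix(1 - rowbias, ny, nx)      # prefer posterior edge

  prev_skin <- NULL; prev_cw <- NULL
  for (z in seq_len(nz)) {
    sl <- volume[z, , ]
    base <- compute_cost_map(sl)
    fg <- sl > thr
    # foreground left anterior to a path at row r, per column (fraction of ny)
    uncovered <- apply(fg, 2, function(col) c(0, cumsum(col))[seq_len(ny)])
    skin <- trace_boundary_dp(base + beta * uncovered / ny, prev_skin,
                              smoothness_limit, lambda_smooth, lambda_prior)
    cw <- trace_boundary_dp(base + bias_cw, prev_cw,
                            smoothness_limit, lambda_smooth, lambda_prior)
    prev_skin <- as.integer(skin); prev_cw <- as.integer(cw)
    thick <- prev_cw - prev_skin
    for (x in which(thick >= min_thickness)) {
      rows_x <- prev_skin[x]:(prev_cw[x] - 1L)
      # air pockets between the paths (inter-breast gap, lateral wedges)
      # are not breast tissue
      mask[z, rows_x, x] <- sl[rows_x, x] > thr
    }
  }

  # sternum midline: minimum-foreground column within the central third
  centre <- seq.int(max(1L, round(nx / 3)), min(nx, round(2 * nx / 3)))
  colsum <- apply(mask[, , centre, drop = FALSE], 3, sum)
  midline <- centre[which.min(colsum)]

  left <- mask; left[, , seq.int(midline, nx)] <- FALSE
  right <- mask; right[, , seq_len(midline)] <- FALSE
  list(mask = mask, left = left, right = right, midline = as.integer(midline))
}
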