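#' Specify a digital breast DCE-MRI phantom
#'
#' Describes a bilateral breast phantom: two hemiellipsoids resting on a flat
#' chest-wall plane, a one-voxel skin shell, a central fibroglandular (FGT)
#' core occupying a prescribed volume fraction of the breast, and a nested
#' set of enhancing FGT voxels per post-contrast phase.  Intensities follow
#' the fat-suppressed T1 convention (air near zero, fat low, FGT high).
#' Enhancement multiplies the post-contrast intensity of enhancing voxels so
#' that the subtraction/original ratio equals `enhancement_ratio_true`
#' exactly, which makes the intensity metric BPE_I analytic.
#'
#' @param grid_shape integer vector (slices, rows, columns); rows run
#'   anterior to posterior.
#' @param voxel_spacing mm per axis, same order as `grid_shape`.
#' @param breast_radius lateral semi-axis of each breast hemiellipsoid, mm.
#'   The anterior and slice-direction semi-axes are 1.5 times this value.
#' @param chest_wall_depth thickness of the posterior body slab, mm.
#' @param fgt_fraction_true target FGT / whole-breast volume fraction.
#' @param enhanced_fraction_true length-3 vector: fraction of FGT voxels
#'   enhancing at 60, 180 and 300 s (the ground truth of BPE_V).
#' @param enhancement_ratio_true length-3 vector: subtraction/original
#'   intensity ratio of enhancing voxels per phase (the ground truth of
#'   BPE_I).
#' @param noise_sigma standard deviation of the additive Gaussian noise added
#'   independently to each acquired volume (intensity units).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param kinetics `"monotone"` enforces non-decreasing enhanced fractions
#'   across phases; `"free"` skips the check.
#' @param intensities named list of tissue intensities
#'   (`air`, `fat`, `fgt`, `skin`, `body`).
#' @param seed integer seed controlling the noise draws.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [true_metrics()]
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_spacing = c(1, 1, 1),
                         breast_radius = 20,
                         chest_wall_depth = 20,
                         fgt_fraction_true = 0.164,
                         enhanced_fraction_true = c(0.305, 0.481, 0.543),
                         enhancement_ratio_true = c(0.265, 0.323, 0.359),
                         noise_sigma = 5,
                         noise_model = c("gaussian", "rician"),
                         kinetics = c("monotone", "free"),
                         intensities = list(air = 10, fat = 60, fgt = 220,
                                            skin = 60, body = 140),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  kinetics <- match.arg(kinetics)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be three positive integers")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  frac <- c(fgt_fraction_true, enhanced_fraction_true)
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
    stop("fractions must lie in [0, 1]")
  if (length(enhanced_fraction_true) != 3L ||
      length(enhancement_ratio_true) != 3L)
    stop("per-phase parameters must have length 3")
  if (any(enhancement_ratio_true < 0))
    stop("enhancement_ratio_true must be non-negative")
  if (kinetics == "monotone" && is.unsorted(enhanced_fraction_true))
    stop("enhanced_fraction_true must be non-decreasing under monotone kinetics")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 breast_radius = breast_radius,
                 chest_wall_depth = chest_wall_depth,
                 fgt_fraction_true = fgt_fraction_true,
                 enhanced_fraction_true = enhanced_fraction_true,
                 enhancement_ratio_true = enhancement_ratio_true,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 kinetics = kinetics,
                 intensities = intensities,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Breast DCE-MRI phantom spec\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "),
      " spacing:", paste(x$voxel_spacing, collapse = " x "), "mm\n")
  cat("  FGT fraction:", x$fgt_fraction_true,
      " enhanced fractions:", paste(x$enhanced_fraction_true, collapse = ", "), "\n")
  cat("  enhancement ratios:", paste(x$enhancement_ratio_true, collapse = ", "),
      " noise sigma:", x$noise_sigma, " seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a phantom DCE-MRI series with ground truth
#'
#' Builds the noiseless tissue-label volume from a [phantom_spec()], realizes
#' one pre-contrast and three post-contrast volumes (phase times 60, 180,
#' 300 s) with independent additive noise, and returns the ground-truth masks
#' and noiseless volumes needed to compute true metrics.  FGT voxels are the
#' innermost fraction of breast voxels under the ellipsoidal distance, and
#' the per-phase enhancing sets are nested by the same ordering, so monotone
#' enhanced fractions yield nested enhancing masks.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `series` (class `mri_series`: `pre`,
#'   `post` (list of 3), `phase_times`, `spacing`) and `gt` (class
#'   `ground_truth`: `breast_mask`, `fgt_mask`, `enhanced_masks`,
#'   noiseless `pre_clean` / `post_clean`, and the true metric values).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  sp <- spec$voxel_spacing
  n <- nz * ny * nx

  Z <- rep_len(seq_len(nz), n)
  Y <- rep(rep(seq_len(ny), each = nz), times = nx)
  X <- rep(seq_len(nx), each = nz * ny)

  y_cw <- ny - max(1L, round(spec$chest_wall_depth / sp[2]))
  ax <- spec$breast_radius / sp[3]
  ay <- 1.5 * spec$breast_radius / sp[2]
  az <- 1.5 * spec$breast_radius / sp[1]
  cz <- (nz + 1) / 2
  cx_l <- 0.27 * nx
  cx_r <- 0.73 * nx

  e_for <- function(cx) {
    ((X - cx) / ax)^2 + ((Y - y_cw) / ay)^2 + ((Z - cz) / az)^2
  }
  E <- pmin(e_for(cx_l), e_for(cx_r))
  anterior <- Y <= y_cw
  breast <- anterior & E <= 1
  shell_delta <- 2 / min(ax, ay, az)
  interior <- anterior & E <= 1 - shell_delta
  shell <- breast & !interior

  n_breast <- sum(breast)
  idx_interior <- which(interior)
  n_fgt <- min(round(spec$fgt_fraction_true * n_breast), length(idx_interior))
  fgt_idx <- if (n_fgt > 0) {
    idx_interior[order(E[idx_interior])[seq_len(n_fgt)]]
  } else integer(0)
  fgt <- logical(n); fgt[fgt_idx] <- TRUE

  # nested enhancing sets: innermost voxels enhance first
  fgt_by_depth <- fgt_idx[order(E[fgt_idx])]
  enhanced_idx <- lapply(spec$enhanced_fraction_true, function(e) {
    fgt_by_depth[seq_len(round(e * n_fgt))]
  })

  ti <- spec$intensities
  pre_clean <- rep(ti$air, n)
  pre_clean[Y > y_cw] <- ti$body
  pre_clean[breast] <- ti$fat
  pre_clean[shell] <- ti$skin
  pre_clean[fgt] <- ti$fgt

  post_clean <- lapply(seq_len(3), function(p) {
    v <- pre_clean
    v[enhanced_idx[[p]]] <- v[enhanced_idx[[p]]] * (1 + spec$enhancement_ratio_true[p])
    v
  })

  add_noise <- function(v) {
    if (spec$noise_sigma == 0) return(v)
    if (spec$noise_model == "rician") {
      sqrt((v + rnorm(n, 0, spec$noise_sigma))^2 + rnorm(n, 0, spec$noise_sigma)^2)
    } else {
      v + rnorm(n, 0, spec$noise_sigma)
    }
  }
  vols <- with_seed(spec$seed, {
    c(list(add_noise(pre_clean)), lapply(post_clean, add_noise))
  })

  as_vol <- function(v) array(v, dim = dims)
  as_mask <- function(m) array(m, dim = dims)

  enhanced_masks <- lapply(enhanced_idx, function(ii) {
    m <- logical(n); m[ii] <- TRUE; as_mask(m)
  })

  series <- structure(list(pre = as_vol(vols[[1]]),
                           post = lapply(vols[-1], as_vol),
                           phase_times = c(60, 180, 300),
                           spacing = sp),
                      class = "mri_series")
  gt <- structure(list(breast_mask = as_mask(breast),
                       fgt_mask = as_mask(fgt),
                       enhanced_masks = enhanced_masks,
                       pre_clean = as_vol(pre_clean),
                       post_clean = lapply(post_clean, as_vol),
                       spacing = sp,
                       midline_column = round((cx_l + cx_r) / 2),
                       true_fgt = if (n_breast > 0) n_fgt / n_breast else NA_real_,
                       true_bpe_v = if (n_fgt > 0)
                         vapply(enhanced_idx, length, 1L) / n_fgt else rep(NA_real_, 3),
                       true_bpe_i = spec$enhancement_ratio_true),
                  class = "ground_truth")
  list(series = series, gt = gt)
}

#' Compute ground-truth metrics from phantom masks
#'
#' Applies the three quantitative formulas directly to the ground-truth masks
#' and noiseless volumes: FGT = V_fgt / V_breast, BPE_V(p) = V_enhanced(p) /
#' V_fgt, and BPE_I(p) = mean over enhancing voxels of subtraction/original
#' intensity.  This is the oracle against which the measurement pipeline is
#' judged.
#'
#' @param gt a `ground_truth` object from [make_phantom()].
#' @return A `quant_result` (see [quant_result()]).
#' @export
true_metrics <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  nb <- sum(gt$breast_mask)
  if (nb == 0) stop("empty breast mask")
  nf <- sum(gt$fgt_mask)
  fgt <- nf / nb
  bpe_v <- rep(NA_real_, 3)
  bpe_i <- rep(NA_real_, 3)
  for (p in 1:3) {
    m <- gt$enhanced_masks[[p]]
    if (nf > 0) bpe_v[p] <- sum(m) / nf
    if (sum(m) > 0) {
      sub <- gt$post_clean[[p]][m] - gt$pre_clean[m]
      bpe_i[p] <- mean(sub / gt$pre_clean[m])
    }
  }
  quant_result(fgt = fgt, bpe_v = bpe_v, bpe_i = bpe_i, side = "combined")
}

#' Container for per-subject quantitative metrics
#'
#' @param fgt FGT volume fraction in \[0, 1\].
#' @param bpe_v length-3 enhanced-FGT volume fractions (phases at 60, 180,
#'   300 s).
#' @param bpe_i length-3 mean subtraction/original intensity ratios.
#' @param side `"left"`, `"right"` or `"combined"`.
#' @param flags character vector of quality flags (e.g. `"empty_fgt"`).
#' @return An object of class `quant_result`.
#' @export
quant_result <- function(fgt, bpe_v, bpe_i, side = "combined",
                         flags = character(0)) {
  structure(list(fgt = fgt, bpe_v = bpe_v, bpe_i = bpe_i,
                 side = side, flags = flags),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Quantitative metrics (%s breast)\n", x$side))
  cat(sprintf("  FGT:   %5.1f%%\n", 100 * x$fgt))
  cat(sprintf("  BPE_V: %s  (60/180/300 s)\n",
              paste(sprintf("%5.1f%%", 100 * x$bpe_v), collapse = " ")))
  cat(sprintf("  BPE_I: %s\n",
              paste(sprintf("%5.3f", x$bpe_i), collapse = " ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
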