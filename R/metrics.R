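#' FGT volume fraction
#'
#' `V_fibroglandular / V_breast`.  With a uniform voxel grid the volume
#' ratio reduces to the voxel-count ratio.
#'
#' @param fgt_mask,breast_mask logical arrays, `fgt_mask` nested in
#'   `breast_mask`.
#' @param spacing voxel spacing (mm); enters only through the common voxel
#'   volume and therefore cancels.
#' @return Fraction in \[0, 1\].
#' @export
compute_fgt_fraction <- function(fgt_mask, breast_mask, spacing = c(1, 1, 1)) {
  nb <- sum(breast_mask)
  if (nb == 0) stop("empty breast mask")
  if (any(fgt_mask & !breast_mask)) stop("fgt_mask must be nested in breast_mask")
  sum(fgt_mask) / nb
}

#' Enhanced-FGT volume fraction (BPE_V)
#'
#' `V_enhanced / V_fibroglandular` for one post-contrast phase.
#'
#' @param enhanced_mask,fgt_mask logical arrays, `enhanced_mask` nested in
#'   `fgt_mask`.
#' @return Fraction in \[0, 1\]; `NA` with an `"undefined"` attribute when
#'   the FGT mask is empty.
#' @export
compute_bpe_v <- function(enhanced_mask, fgt_mask) {
  nf <- sum(fgt_mask)
  if (nf == 0) return(structure(NA_real_, undefined = TRUE))
  if (any(enhanced_mask & !fgt_mask))
    stop("enhanced_mask must be nested in fgt_mask")
  sum(enhanced_mask) / nf
}

#' Mean enhancement intensity ratio (BPE_I)
#'
#' Mean over enhanced voxels of `I_subtraction / I_original`, where
#' `I_original` is the pre-contrast intensity.  Voxels whose pre-contrast
#' intensity falls below 1 percent of the volume's robust intensity scale
#' (the median absolute intensity) are excluded from the mean — the ratio is
#' unstable there; the number excluded is reported in attribute
#' `"n_excluded"`.
#'
#' @param subtraction numeric array of post-minus-pre intensities.
#' @param pre_volume pre-contrast numeric array.
#' @param enhanced_mask logical mask of enhanced FGT voxels.
#' @return Mean ratio (>= 0 for genuinely enhancing tissue); `NA` with an
#'   `"undefined"` attribute when the mask is empty.
#' @export
compute_bpe_i <- function(subtraction, pre_volume, enhanced_mask) {
  n <- sum(enhanced_mask)
  if (n == 0) return(structure(NA_real_, undefined = TRUE))
  i_orig <- pre_volume[enhanced_mask]
  i_sub <- subtraction[enhanced_mask]
  floor_val <- 0.01 * stats::median(abs(pre_volume))
  ok <- i_orig > floor_val
  if (!any(ok)) return(structure(NA_real_, undefined = TRUE, n_excluded = n))
  structure(mean(i_sub[ok] / i_orig[ok]), n_excluded = sum(!ok))
}

#' Apply the laterality selection rule
#'
#' Controls contribute the per-metric arithmetic mean of the two breasts
#' (lesion-free by definition); benign and cancer subjects contribute the
#' breast contralateral to the lesion, untouched, to avoid lesion
#' contamination.
#'
#' @param group `"control"`, `"benign"` or `"cancer"`.
#' @param left,right `quant_result` objects for the two breasts.
#' @param lesion_side `"left"` or `"right"` for lesion groups; ignored for
#'   controls.
#' @return A `quant_result` with `side` set to `"combined"` (controls) or
#'   the contralateral side.
#' @export
select_measurement <- function(group, left, right, lesion_side = NA) {
  stopifnot(inherits(left, "quant_result"), inherits(right, "quant_result"))
  group <- match.arg(group, c("control", "benign", "cancer"))
  if (group == "control") {
    return(quant_result(fgt = mean(c(left$fgt, right$fgt)),
                        bpe_v = (left$bpe_v + right$bpe_v) / 2,
                        bpe_i = (left$bpe_i + right$bpe_i) / 2,
                        side = "combined",
                        flags = union(left$flags, right$flags)))
  }
  if (is.na(lesion_side) || !lesion_side %in% c("left", "right"))
    stop("lesion groups require lesion_side 'left' or 'right'")
  if (lesion_side == "left") right else left
}

#' Quantify one subject's series through the full three-step pipeline
#'
#' Runs whole-breast segmentation on the pre-contrast volume, FGT
#' segmentation inside it, then per-phase subtraction, noise estimation
#' (reference region: breast minus FGT, falling back to the whole breast)
#' and enhanced-FGT thresholding, and assembles per-side metrics.
#'
#' @param series an `mri_series` (see [make_phantom()]).
#' @param k noise-threshold multiplier for enhanced-FGT segmentation.
#' @param c_min,c_max fuzzy c-means cluster-number range.
#' @param ... forwarded to [segment_whole_breast()].
#' @return List with `left` and `right` `quant_result`s and the
#'   segmentation masks (`breast`, `fgt`, `enhanced` per phase).
#' @export
quantify_series <- function(series, k = 3, c_min = 2L, c_max = 5L, ...) {
  stopifnot(inherits(series, "mri_series"))
  seg <- segment_whole_breast(series$pre, series$spacing, ...)
  if (!any(seg$mask)) {
    empty <- quant_result(NA_real_, rep(NA_real_, 3), rep(NA_real_, 3),
                          flags = "empty_breast")
    return(list(left = structure(empty, side = "left"),
                right = structure(empty, side = "right"),
                masks = seg))
  }
  fgt <- segment_fgt(series$pre, seg$mask, c_min = c_min, c_max = c_max)
  enhanced <- vector("list", 3)
  subs <- vector("list", 3)
  for (p in 1:3) {
    subs[[p]] <- subtract_volumes(series$post[[p]], series$pre, phase = p,
                                  phase_time = series$phase_times[p])
    ref <- seg$mask & !fgt
    if (!any(ref)) ref <- seg$mask
    sigma <- estimate_noise_sigma(subs[[p]], ref)
    enhanced[[p]] <- if (any(fgt))
      segment_enhanced_fgt(subs[[p]], fgt, sigma, k = k)
    else array(FALSE, dim(fgt))
  }

  side_result <- function(side_mask, side) {
    if (!any(side_mask)) {
      return(quant_result(NA_real_, rep(NA_real_, 3), rep(NA_real_, 3),
                          side = side, flags = "empty_breast"))
    }
    f <- fgt & side_mask
    flags <- character(0)
    fgt_frac <- compute_fgt_fraction(f, side_mask, series$spacing)
    bv <- rep(NA_real_, 3); bi <- rep(NA_real_, 3)
    if (!any(f)) {
      flags <- "empty_fgt"
    } else {
      for (p in 1:3) {
        e <- enhanced[[p]] & side_mask
        bv[p] <- compute_bpe_v(e, f)
        bi_p <- compute_bpe_i(subs[[p]], series$pre, e)
        bi[p] <- as.numeric(bi_p)
        if (isTRUE(attr(bi_p, "undefined"))) flags <- union(flags, "no_enhancement")
      }
    }
    quant_result(fgt = fgt_frac, bpe_v = bv, bpe_i = bi, side = side,
                 flags = flags)
  }

  list(left = side_result(seg$left, "left"),
       right = side_result(seg$right, "right"),
       masks = list(breast = seg$mask, left = seg$left, right = seg$right,
                    fgt = fgt, enhanced = enhanced))
}
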