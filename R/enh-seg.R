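#' Subtraction volume
#'
#' Voxelwise post-contrast minus pre-contrast difference, with no clipping;
#' negative values are kept (they carry the noise distribution used for
#' threshold calibration).
#'
#' @param post,pre 3D numeric arrays on the same grid.
#' @param phase integer phase index (1-3).
#' @param phase_time acquisition time in seconds (60, 180 or 300).
#' @return Numeric array of class `subtraction_volume` with attributes
#'   `phase` and `phase_time`.
#' @export
subtract_volumes <- function(post, pre, phase = 1L,
                             phase_time = c(60, 180, 300)[phase]) {
  if (!identical(dim(post), dim(pre))) stop("grid mismatch between post and pre")
  if (!phase_time %in% c(60, 180, 300))
    stop("phase_time must be one of 60, 180, 300 s")
  structure(post - pre, phase = as.integer(phase), phase_time = phase_time,
            class = "subtraction_volume")
}

#' Robust noise estimate for a subtraction volume
#'
#' `1.4826 * MAD` of the subtraction values inside a non-enhancing reference
#' region (typically breast-not-FGT, i.e. fat, which should not enhance).
#' The MAD makes the estimate robust to a small fraction of genuinely
#' enhancing voxels contaminating the region.
#'
#' @param subtraction numeric array (from [subtract_volumes()]).
#' @param reference_region logical array selecting the reference voxels.
#' @return Estimated noise standard deviation (>= 0).
#' @export
estimate_noise_sigma <- function(subtraction, reference_region) {
  if (!any(reference_region)) stop("empty reference region")
  v <- subtraction[reference_region]
  stats::mad(v, constant = 1.4826)
}

#' Segment enhanced FGT by noise-calibrated thresholding
#'
#' Step 3 of the scheme: FGT voxels whose subtraction intensity exceeds
#' `k * sigma` are labelled enhanced.  The result is a subset of the FGT
#' mask by construction, and raising `k` can only shrink it.
#'
#' @param subtraction numeric array of post-minus-pre intensities.
#' @param fgt_mask logical FGT mask.
#' @param sigma noise level (>= 0), e.g. from [estimate_noise_sigma()].
#' @param k threshold multiplier (default 3: the conventional noise floor).
#' @return Logical enhanced-FGT mask.
#' @export
segment_enhanced_fgt <- function(subtraction, fgt_mask, sigma, k = 3) {
  if (!any(fgt_mask)) stop("empty FGT mask")
  if (sigma < 0) stop("sigma must be non-negative")
  out <- array(FALSE, dim(fgt_mask))
  out[fgt_mask] <- subtraction[fgt_mask] > k * sigma
  out
}
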