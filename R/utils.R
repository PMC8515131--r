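#' Evaluate code with a temporary RNG state
#'
#' Seeds the generator, runs `code`, then restores the caller's RNG state so
#' that library calls do not perturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Otsu intensity threshold
#'
#' Histogram-based threshold maximizing between-class variance; used to find
#' foreground (tissue) voxels when extracting the volume of interest.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return Threshold value; voxels strictly above it are foreground.
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- hist(x, breaks = seq(r[1], r[2], length.out = n_bins + 1L), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two logical masks of identical shape.
#' Returns 1 when both masks are empty.
#'
#' @param a,b logical arrays of the same dimension.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
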