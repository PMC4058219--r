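# Evaluation metrics: median (or mean) absolute/squared error on magnitude
# images, and the aggregate report.

prep_pair <- function(x, ref, scale) {
  if (!identical(dim(x), dim(ref))) stop("image shapes differ")
  mx <- Mod(x); mr <- Mod(ref)
  if (scale == "0-255") {
    top <- max(mr)
    if (top > 0) {
      f <- 255 / top
      mx <- mx * f; mr <- mr * f
    }
  }
  list(x = mx, ref = mr)
}

#' Median (or mean) absolute error between magnitude images
#'
#' The study's error indicator: the median over pixels of the absolute
#' difference of magnitudes.  With `scale = "0-255"` both images are first
#' rescaled by the same factor that maps the reference maximum to 255, so
#' errors are on the familiar 8-bit intensity scale.
#'
#' @param x reconstructed image (numeric or complex matrix).
#' @param ref reference image of the same shape.
#' @param scale `"none"` (raw units) or `"0-255"`.
#' @param stat `"median"` (the study's definition) or `"mean"`.
#' @return nonnegative scalar.
#' @export
mae <- function(x, ref, scale = c("none", "0-255"),
                stat = c("median", "mean")) {
  scale <- match.arg(scale); stat <- match.arg(stat)
  p <- prep_pair(x, ref, scale)
  d <- abs(p$x - p$ref)
  if (stat == "median") stats::median(d) else mean(d)
}

#' Median (or mean) squared error between magnitude images
#'
#' As [mae()] with squared differences.
#'
#' @inheritParams mae
#' @return nonnegative scalar.
#' @export
mse <- function(x, ref, scale = c("none", "0-255"),
                stat = c("median", "mean")) {
  scale <- match.arg(scale); stat <- match.arg(stat)
  p <- prep_pair(x, ref, scale)
  d <- (p$x - p$ref)^2
  if (stat == "median") stats::median(d) else mean(d)
}

#' Aggregate evaluation report for a reconstruction
#'
#' Bundles the error metrics with the sampling diagnostics: MAE and MSE of
#' the reconstruction against the ground truth (0-255 scale by default),
#' the energy-preserving ratio of the mask on the full k-space, and the
#' image-domain Pearson correlation between reconstruction and truth
#' magnitudes.
#'
#' @param recon reconstructed image matrix.
#' @param truth ground-truth image matrix.
#' @param mask sampling mask (optional; needed for `epr`).
#' @param k_full fully sampled k-space of the truth (optional; needed for
#'   `epr`).
#' @param scale intensity scale for MAE/MSE (default `"0-255"`).
#' @param stat `"median"` or `"mean"`.
#' @param method,sampler optional labels carried into the report.
#' @return one-row data.frame with columns `method, sampler, mae, mse,
#'   epr, corr2d, sampling_ratio`.
#' @export
evaluate <- function(recon, truth, mask = NULL, k_full = NULL,
                     scale = "0-255", stat = "median", method = NA_character_,
                     sampler = NA_character_) {
  ep <- if (!is.null(mask) && !is.null(k_full)) epr(mask, k_full) else NA_real_
  ratio <- if (!is.null(mask)) mean(mask == 1) else NA_real_
  data.frame(method = method, sampler = sampler,
             mae = mae(recon, truth, scale, stat),
             mse = mse(recon, truth, scale, stat),
             epr = ep,
             corr2d = pearson(Mod(recon), Mod(truth)),
             sampling_ratio = ratio,
             stringsAsFactors = FALSE)
}
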