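# Multilevel separable 2D discrete wavelet transform (periodized) and the
# masked Fourier measurement operator.
#
# No wavelet machinery is assumed from outside the package: the transform is
# built here from the standard published filter banks (orthonormal Haar and
# the biorthogonal CDF 9/7 pair known as bior4.4), using circular
# (periodized) boundary handling.  Periodization keeps every subband exactly
# half the size of its parent and makes analysis/synthesis exact inverses
# for biorthogonal filters, which is what the reconstruction algorithms
# rely on.

.wavelet_filters <- list(
  haar = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)
  ),
  bior4.4 = list(
    dec_lo = c(0, 0.03782845550726404, -0.023849465019556843,
               -0.11062440441843718, 0.37740285561283066,
               0.8526986790088938, 0.37740285561283066,
               -0.11062440441843718, -0.023849465019556843,
               0.03782845550726404),
    dec_hi = c(0, -0.06453888262869706, 0.04068941760916406,
               0.41809227322161724, -0.7884856164055829,
               0.41809227322161724, 0.04068941760916406,
               -0.06453888262869706, 0, 0),
    rec_lo = c(0, -0.06453888262869706, -0.04068941760916406,
               0.41809227322161724, 0.7884856164055829,
               0.41809227322161724, -0.04068941760916406,
               -0.06453888262869706, 0, 0),
    rec_hi = c(0, -0.03782845550726404, -0.023849465019556843,
               0.11062440441843718, 0.37740285561283066,
               -0.8526986790088938, 0.37740285561283066,
               0.11062440441843718, -0.023849465019556843,
               -0.03782845550726404)
  )
)

#' Wavelet specification
#'
#' @param family `"haar"` (orthonormal; the phantom-study transform at 3
#'   levels) or `"bior4.4"` (biorthogonal 9/7; the in vivo transform at 6
#'   levels).
#' @param levels decomposition depth (>= 1).
#' @return object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = c("haar", "bior4.4"), levels = 3L) {
  family <- match.arg(family)
  levels <- as.integer(levels)
  if (levels < 1) stop("levels must be at least 1")
  structure(list(family = family, levels = levels), class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("wavelet_spec: %s, %d levels\n", x$family, x$levels))
  invisible(x)
}

# Analysis/synthesis operators for one periodized DWT stage of length n,
# realized as (n/2 x n) and (n x n/2) matrices.  The phase offset
# p = s = L/2 - 1 centers the even-length filters so that synthesis inverts
# analysis exactly (verified to machine precision for both families).
.dwt_cache <- new.env(parent = emptyenv())

dwt_stage <- function(family, n) {
  key <- paste0(family, "|", n)
  hit <- .dwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n %% 2 != 0) stop("periodized DWT needs an even length, got ", n)
  f <- .wavelet_filters[[family]]
  L <- length(f$dec_lo)
  p <- L %/% 2 - 1
  amat <- function(filt) {
    M <- matrix(0, n / 2, n)
    for (k in 0:(n / 2 - 1)) for (m in seq_len(L)) {
      j <- (2 * k + 1 + p - (m - 1)) %% n
      M[k + 1, j + 1] <- M[k + 1, j + 1] + filt[m]
    }
    M
  }
  smat <- function(filt) {
    M <- matrix(0, n, n / 2)
    for (k in 0:(n / 2 - 1)) for (m in seq_len(L)) {
      i <- (2 * k + (m - 1) - p) %% n
      M[i + 1, k + 1] <- M[i + 1, k + 1] + filt[m]
    }
    M
  }
  st <- list(Al = amat(f$dec_lo), Ah = amat(f$dec_hi),
             Sl = smat(f$rec_lo), Sh = smat(f$rec_hi))
  .dwt_cache[[key]] <- st
  st
}

pad_dims <- function(d, levels) {
  blk <- 2^levels
  ceiling(d / blk) * blk
}

reflect_pad <- function(x, nr, nc) {
  if (nrow(x) < nr) {
    extra <- nr - nrow(x)
    x <- rbind(x, x[nrow(x) - seq_len(extra) + 1, , drop = FALSE])
  }
  if (ncol(x) < nc) {
    extra <- nc - ncol(x)
    x <- cbind(x, x[, ncol(x) - seq_len(extra) + 1, drop = FALSE])
  }
  x
}

#' Multilevel 2D wavelet analysis
#'
#' Separable periodized DWT.  The result is a single matrix in the usual
#' quadrant layout: the coarsest approximation band occupies the top-left
#' `(N/2^levels) x (M/2^levels)` block, with detail bands in the remaining
#' quadrants of each level.  Complex inputs are transformed directly (the
#' filters are real, so this equals transforming the real and imaginary
#' channels separately).  Inputs whose dimensions are not divisible by
#' `2^levels` are reflection-padded; [wavelet_synthesis()] undoes the
#' padding exactly.
#'
#' @param img numeric or complex matrix.
#' @param spec a [wavelet_spec()].
#' @return matrix of coefficients of class `wavelet_coeffs`, carrying the
#'   spec and original dimensions as attributes.
#' @export
wavelet_analysis <- function(img, spec) {
  stopifnot(is.matrix(img), inherits(spec, "wavelet_spec"))
  d0 <- dim(img)
  dp <- pad_dims(d0, spec$levels)
  x <- reflect_pad(img, dp[1], dp[2])
  n <- dp[1]; m <- dp[2]
  for (l in seq_len(spec$levels)) {
    sr <- dwt_stage(spec$family, n)
    sc <- dwt_stage(spec$family, m)
    blk <- x[seq_len(n), seq_len(m), drop = FALSE]
    rowpass <- rbind(sr$Al %*% blk, sr$Ah %*% blk)
    x[seq_len(n), seq_len(m)] <- cbind(rowpass %*% t(sc$Al),
                                       rowpass %*% t(sc$Ah))
    n <- n / 2; m <- m / 2
  }
  structure(x, spec = spec, orig_dim = d0,
            class = c("wavelet_coeffs", class(x)))
}

#' Multilevel 2D wavelet synthesis
#'
#' Exact inverse of [wavelet_analysis()]: rebuilds the image from the
#' quadrant-layout coefficient matrix and crops any reflection padding.
#'
#' @param coeffs a `wavelet_coeffs` matrix.
#' @param spec wavelet specification; defaults to the one stored on
#'   `coeffs`.
#' @return matrix with the original image dimensions.
#' @export
wavelet_synthesis <- function(coeffs, spec = attr(coeffs, "spec")) {
  stopifnot(is.matrix(coeffs), inherits(spec, "wavelet_spec"))
  d0 <- attr(coeffs, "orig_dim") %||% dim(coeffs)
  x <- unclass(coeffs)
  attr(x, "spec") <- NULL; attr(x, "orig_dim") <- NULL
  np <- nrow(x); mp <- ncol(x)
  n <- np / 2^(spec$levels - 1); m <- mp / 2^(spec$levels - 1)
  for (l in seq_len(spec$levels)) {
    sr <- dwt_stage(spec$family, n)
    sc <- dwt_stage(spec$family, m)
    blk <- x[seq_len(n), seq_len(m), drop = FALSE]
    h <- n / 2; w <- m / 2
    # undo the column pass, then the row pass
    colpass <- blk[, seq_len(w), drop = FALSE] %*% t(sc$Sl) +
      blk[, w + seq_len(w), drop = FALSE] %*% t(sc$Sh)
    x[seq_len(n), seq_len(m)] <- sr$Sl %*% colpass[seq_len(h), , drop = FALSE] +
      sr$Sh %*% colpass[h + seq_len(h), , drop = FALSE]
    n <- n * 2; m <- m * 2
  }
  x[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
}

#' Dimensions of the coarsest approximation band
#' @noRd
approx_block <- function(coeffs, spec = attr(coeffs, "spec")) {
  c(nrow(coeffs), ncol(coeffs)) / 2^spec$levels
}

#' Largest detail-coefficient magnitude
#'
#' Maximum complex magnitude over all detail bands (the coarsest
#' approximation band is excluded); used to set default threshold
#' schedules.
#'
#' @param coeffs a `wavelet_coeffs` matrix.
#' @return nonnegative scalar.
#' @export
detail_max <- function(coeffs) {
  ab <- approx_block(coeffs)
  m <- Mod(coeffs)
  m[seq_len(ab[1]), seq_len(ab[2])] <- 0
  max(m)
}

#' Masked (undersampled) Fourier transform
#'
#' `to_kspace` followed by entrywise multiplication with the sampling mask;
#' unsampled k-space entries are zero.  This is the measurement operator of
#' the compressed-sensing acquisition model.
#'
#' @param img image matrix.
#' @param mask binary sampling mask of the same shape.
#' @return complex k-space matrix.
#' @export
masked_ft <- function(img, mask) {
  if (!identical(dim(img), dim(mask))) stop("image and mask shapes differ")
  to_kspace(img) * (mask == 1)
}
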