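# Sampling probability maps (ePRESS iPDF/wPDF, variable density, power) and
# their conversion to k-space sampling masks; energy and correlation
# diagnostics.

normalize_pdf <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("probability map has no mass")
  v / s
}

new_mask <- function(values, mode = "point", center_rows = 0L) {
  structure(values, mode = mode, center_rows = as.integer(center_rows),
            class = c("sampling_mask", class(values)))
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("sampling_mask: %d x %d, %d points (ratio %.3f), %s mode\n",
              nrow(x), ncol(x), sum(x), mean(x), attr(x, "mode")))
  invisible(x)
}

#' Number of sampled points in a mask
#' @param mask a sampling mask (binary matrix).
#' @return integer count of ones.
#' @export
mask_points <- function(mask) sum(mask == 1)

#' Initial probability map from reference k-spaces
#'
#' Sums the k-space magnitudes of the reference scans and normalizes to
#' unit total mass (the ePRESS "iPDF").  In `line` mode the map is
#' additionally collapsed along the readout (column, kx) axis to a per-row
#' profile broadcast across all columns, matching 1D line undersampling
#' where whole readout lines are acquired.
#'
#' @param references list of complex k-space matrices, all the same shape.
#' @param mode `"point"` (full 2D map) or `"line"` (row profile).
#' @return nonnegative matrix summing to 1.
#' @export
build_ipdf <- function(references, mode = c("point", "line")) {
  mode <- match.arg(mode)
  if (length(references) == 0) stop("at least one reference is required")
  d <- dim(references[[1]])
  acc <- matrix(0, d[1], d[2])
  for (k in references) {
    if (!identical(dim(k), d)) stop("reference shapes differ")
    acc <- acc + Mod(k)
  }
  if (mode == "line") {
    prof <- rowSums(acc)
    acc <- matrix(prof, d[1], d[2])
  }
  normalize_pdf(acc)
}

#' Power-spectrum probability map
#'
#' Like [build_ipdf()] but accumulates squared magnitudes (the power
#' spectrum), the map driving power-method random sampling.
#'
#' @inheritParams build_ipdf
#' @return nonnegative matrix summing to 1.
#' @export
build_power_pdf <- function(references, mode = c("point", "line")) {
  sq <- lapply(references, function(k) {
    m <- Mod(k)
    matrix(complex(real = m^2), nrow(k), ncol(k))
  })
  build_ipdf(sq, mode)
}

#' Two-dimensional Hamming window
#'
#' Separable product of 1D Hamming factors
#' `0.54 - 0.46 cos(2 pi m / N)` evaluated at indices `m = 0..N-1`
#' (`n = 0..M-1` for the second axis), so the peak value 1 falls on the
#' k-space center index and the corners take the Hamming endpoint value
#' 0.08 per axis.
#'
#' @param N rows, `M` cols (both >= 2).
#' @param M columns; defaults to `N`.
#' @return matrix of values in (0, 1\], symmetric under 180-degree rotation
#'   about the grid center.
#' @export
hamming2d <- function(N, M = N) {
  stopifnot(N >= 2, M >= 2)
  wr <- 0.54 - 0.46 * cos(2 * pi * (seq_len(N) - 1) / N)
  wc <- 0.54 - 0.46 * cos(2 * pi * (seq_len(M) - 1) / M)
  outer(wr, wc)
}

#' Window an iPDF into a wPDF
#'
#' Multiplies the probability map by the Hamming window raised to `alpha`
#' and renormalizes: `wPDF` is proportional to `iPDF * omega^alpha`.  The
#' window apodizes the reference-specific fine structure of the iPDF —
#' smooth taper, peak 1 at the k-space center — so the energy ranking that
#' drives [select_mask()] follows the statistically shared energy
#' distribution rather than incidental detail of individual references;
#' `alpha` sets how strongly the taper acts (`alpha` near 0 leaves the
#' iPDF unchanged).
#'
#' @param ipdf probability map (matrix summing to 1).
#' @param alpha positive window exponent; the study default is 0.8 for
#'   piecewise-constant phantoms and 1.4 for textured in vivo images.
#' @return reweighted probability map summing to 1.
#' @export
apply_window <- function(ipdf, alpha) {
  stopifnot(alpha > 0)
  w <- hamming2d(nrow(ipdf), ncol(ipdf))
  normalize_pdf(ipdf * w^alpha)
}

#' Deterministic energy-ordered mask selection
#'
#' Selects the `n_points` largest wPDF entries (point mode) or the
#' `n_points` rows with the largest summed wPDF (line mode) — the exact
#' limit of lowering a threshold level until the point budget is met.
#' Ties at the cut value are broken by (row, col) order.  The
#' `center_rows` central rows are forced on and counted toward the budget,
#' guaranteeing the symmetric central k-space needed for phase estimation.
#' Selection is nested: enlarging `n_points` only adds points.
#'
#' @param wpdf probability map.
#' @param n_points number of points (point mode) or rows (line mode) to
#'   select.
#' @param mode `"point"` or `"line"`.
#' @param center_rows number of central rows always sampled.
#' @return binary `sampling_mask` matrix.
#' @export
select_mask <- function(wpdf, n_points, mode = c("point", "line"),
                        center_rows = 4L) {
  mode <- match.arg(mode)
  N <- nrow(wpdf); M <- ncol(wpdf)
  crows <- center_row_indices(N, center_rows)
  mask <- matrix(0L, N, M)
  if (mode == "point") {
    if (n_points < 1 || n_points > N * M)
      stop("n_points out of range for point mode")
    if (n_points < length(crows) * M)
      stop("n_points smaller than the forced central-row budget")
    rr <- as.vector(row(wpdf)); cc <- as.vector(col(wpdf))
    forced <- rr %in% crows
    ord <- order(-forced, -as.vector(wpdf), rr, cc)
    mask[cbind(rr[ord[seq_len(n_points)]], cc[ord[seq_len(n_points)]])] <- 1L
  } else {
    if (n_points < 1 || n_points > N)
      stop("n_points (line count) out of range for line mode")
    if (n_points < length(crows))
      stop("n_points smaller than the forced central-row budget")
    score <- rowSums(wpdf)
    forced <- seq_len(N) %in% crows
    ord <- order(-forced, -score, seq_len(N))
    mask[ord[seq_len(n_points)], ] <- 1L
  }
  new_mask(mask, mode, length(crows))
}

#' Variable-density polynomial probability map
#'
#' The classical variable-density law `(1 - r)^p`, with `r` the distance to
#' the k-space center scaled so the farthest grid point has `r = 1`;
#' negative bases are clipped to 0 and the map is normalized to unit mass.
#' `p = 0` gives a uniform map; larger `p` concentrates mass at the center.
#'
#' @param N rows.
#' @param M columns; defaults to `N`.
#' @param p nonnegative decay exponent (study default 10).
#' @return probability map matrix.
#' @export
vd_pdf <- function(N, M = N, p) {
  stopifnot(p >= 0)
  dr <- (seq_len(N) - 1) - N %/% 2
  dc <- (seq_len(M) - 1) - M %/% 2
  r <- sqrt(outer(dr^2, dc^2, `+`))
  r <- r / max(r)
  normalize_pdf(pmax(1 - r, 0)^p)
}

# Inclusion probabilities for a point-vs-threshold random draw: the pdf is
# rescaled to peak 1 and a constant offset is added (bisected, with
# clipping to [0, 1]) until the probabilities sum to the target count —
# the classical calibration used for variable-density mask generation,
# which gives low-probability regions a uniform floor instead of freezing
# the high-probability region into a deterministic block.
capped_inclusion <- function(w, target) {
  n <- length(w)
  if (target == 0) return(numeric(n))
  if (target == n) return(rep(1, n))
  if (sum(w > 0) < target)
    stop("probability map has fewer positive entries than points requested")
  shape <- w / max(w)
  f <- function(off) sum(pmin(pmax(shape + off, 0), 1)) - target
  lo <- -1; hi <- 1
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  pmin(pmax(shape + hi, 0), 1)
}

#' Random mask drawn from a probability map
#'
#' Realizes the point-versus-random-threshold selection rule used for the
#' variable-density and power-method patterns: each grid position's
#' inclusion probability is the map value scaled up and capped at 1, with
#' the scale calibrated so the probabilities sum to `n_points`.  The mask
#' is drawn by systematic probability-proportional-to-size sampling, which
#' realizes exactly those inclusion probabilities while always producing
#' exactly `n_points` points, so acceleration factors are exact.  An
#' optional block of central rows can be forced on (counted toward the
#' budget) so phase estimation remains possible.  Reproducible for a fixed
#' seed.
#'
#' @param pdf probability map.
#' @param n_points exact number of points to sample.
#' @param seed integer seed.
#' @param center_rows central rows forced on (default 0).
#' @return binary `sampling_mask` matrix with exactly `n_points` ones.
#' @export
pdf_random_mask <- function(pdf, n_points, seed, center_rows = 0L) {
  N <- nrow(pdf); M <- ncol(pdf)
  if (n_points < 1 || n_points > N * M) stop("n_points out of range")
  crows <- center_row_indices(N, center_rows)
  mask <- matrix(0L, N, M)
  mask[crows, ] <- 1L
  n_forced <- sum(mask)
  if (n_points < n_forced)
    stop("n_points smaller than the forced central-row budget")
  remaining <- n_points - n_forced
  if (remaining > 0) {
    avail <- which(mask == 0L)
    pii <- capped_inclusion(pdf[avail], remaining)
    # systematic PPS: one uniform start, pick cells where the cumulative
    # inclusion probability crosses successive integers
    u <- with_seed(seed, stats::runif(1))
    cum <- cumsum(pii)
    sel <- which(floor(cum - u) > floor(c(0, cum[-length(cum)]) - u))
    if (length(sel) > remaining)       # guard against cumsum round-off
      sel <- sel[seq_len(remaining)]
    else if (length(sel) < remaining) {
      extra <- setdiff(order(pii, decreasing = TRUE), sel)
      sel <- c(sel, extra[seq_len(remaining - length(sel))])
    }
    mask[avail[sel]] <- 1L
  }
  new_mask(mask, "point", length(crows))
}

#' Low-resolution (central block) mask
#'
#' Selects the `n_points` grid positions nearest the k-space center, ties
#' broken by (row, col) order — plain truncation of high spatial
#' frequencies.  As for [select_mask()], `center_rows` central rows can be
#' forced on (counted toward the budget) so the mask supports phase
#' estimation.
#'
#' @param N rows.
#' @param M columns; defaults to `N`.
#' @param n_points number of points.
#' @param center_rows central rows forced on (default 0).
#' @return binary `sampling_mask` matrix.
#' @export
lowres_mask <- function(N, M = N, n_points, center_rows = 0L) {
  if (n_points < 1 || n_points > N * M) stop("n_points out of range")
  crows <- center_row_indices(N, center_rows)
  if (n_points < length(crows) * M)
    stop("n_points smaller than the forced central-row budget")
  dr <- (seq_len(N) - 1) - N %/% 2
  dc <- (seq_len(M) - 1) - M %/% 2
  r <- sqrt(outer(dr^2, dc^2, `+`))
  rr <- as.vector(row(r)); cc <- as.vector(col(r))
  forced <- rr %in% crows
  ord <- order(-forced, as.vector(r), rr, cc)
  mask <- matrix(0L, N, M)
  mask[cbind(rr[ord[seq_len(n_points)]], cc[ord[seq_len(n_points)]])] <- 1L
  new_mask(mask, "point", length(crows))
}

#' Energy-preserving ratio
#'
#' Fraction of total k-space energy (sum of squared magnitudes) captured by
#' the sampled points.
#'
#' @param mask binary sampling mask.
#' @param k complex k-space matrix of the same shape, not identically zero.
#' @return ratio in \[0, 1\].
#' @export
epr <- function(mask, k) {
  if (!identical(dim(mask), dim(k))) stop("mask and k-space shapes differ")
  e <- Mod(k)^2
  tot <- sum(e)
  if (tot == 0) stop("k-space is identically zero")
  sum(e[mask == 1]) / tot
}

pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0) return(NA_real_)
  sum(da * db) / sqrt(va * vb)
}

#' 2D correlation between a probability map and a k-space magnitude
#'
#' Pearson correlation between the flattened map and `|k|`; `NA` if either
#' side has zero variance.
#'
#' @param map probability map matrix.
#' @param k complex k-space matrix of the same shape.
#' @return correlation coefficient, or `NA` when undefined.
#' @export
correlation_2d <- function(map, k) {
  if (!identical(dim(map), dim(k))) stop("map and k-space shapes differ")
  pearson(map, Mod(k))
}

#' Row-wise correlations between a probability map and a k-space magnitude
#'
#' Per-row Pearson correlations; rows where either side is constant give
#' `NA`.
#'
#' @inheritParams correlation_2d
#' @return numeric vector, one coefficient per row.
#' @export
rowwise_correlation <- function(map, k) {
  if (!identical(dim(map), dim(k))) stop("map and k-space shapes differ")
  m <- Mod(k)
  vapply(seq_len(nrow(map)), function(i) pearson(map[i, ], m[i, ]),
         numeric(1))
}
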