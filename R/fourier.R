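# Centered, unitary 2D Fourier transforms between image space and k-space.
#
# Convention used throughout the package: the DC component sits at the
# 0-based index (floor(N/2), floor(M/2)), i.e. R index (floor(N/2)+1,
# floor(M/2)+1); both directions are normalized by 1/sqrt(N*M) so the
# transform is unitary and energy ratios (EPR, thresholds) are scale-free.

#' Circularly shift a matrix
#' @noRd
circshift2 <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(m) - 1 - dc) %% m) + 1,
    drop = FALSE]
}

fftshift2 <- function(x) circshift2(x, nrow(x) %/% 2, ncol(x) %/% 2)
ifftshift2 <- function(x) circshift2(x, -(nrow(x) %/% 2), -(ncol(x) %/% 2))

#' Image to centered k-space
#'
#' Centered unitary 2D discrete Fourier transform.  The DC component of the
#' result is at index `(floor(N/2)+1, floor(M/2)+1)`; total energy is
#' preserved exactly (Parseval), so [from_kspace()] inverts it to machine
#' precision.
#'
#' @param img numeric or complex matrix (image-space grid).
#' @return complex matrix of the same shape (k-space grid).
#' @seealso [from_kspace()]
#' @export
#' @examples
#' k <- to_kspace(matrix(1, 8, 8))
#' which(Mod(k) > 1e-12)  # single DC entry
to_kspace <- function(img) {
  stopifnot(is.matrix(img))
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(length(img))
}

#' Centered k-space to image
#'
#' Inverse of [to_kspace()]; unitary, so `from_kspace(to_kspace(x))`
#' round-trips to within floating-point error.
#'
#' @param k complex matrix (centered k-space grid).
#' @return complex matrix (image-space grid).
#' @export
from_kspace <- function(k) {
  stopifnot(is.matrix(k))
  fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

#' Indices of the central phase-encode rows
#'
#' The `n` rows centered on the DC row (0-based row floor(N/2)); these are
#' the rows forced into every sampling mask so the symmetric-k-space phase
#' estimate is available.
#'
#' @param N number of rows.
#' @param n number of central rows wanted.
#' @return integer vector of 1-based row indices.
#' @export
center_row_indices <- function(N, n) {
  if (n <= 0) return(integer(0))
  if (n > N) stop("more central rows requested than the grid has")
  dc <- N %/% 2                      # 0-based DC row
  idx <- dc - (n %/% 2) + seq_len(n) - 1
  idx <- idx - min(0, min(idx)) + 0  # clamp into range for tiny N
  idx <- idx - max(0, max(idx) - (N - 1))
  sort(idx) + 1
}
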