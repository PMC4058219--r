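# Randomized Shepp-Logan phantom generation and simulated acquisition.

#' Canonical Shepp-Logan ellipse parameters
#'
#' The classical ten-ellipse head phantom.  Each row gives the additive
#' intensity `A`, semiaxes `a` (horizontal) and `b` (vertical) as fractions
#' of the half field of view, the center `(x0, y0)` in the same units, and
#' the rotation `phi` in degrees (counter-clockwise from the x axis).
#'
#' @return data.frame with columns `A, a, b, x0, y0, phi`, one row per
#'   ellipse.
#' @export
shepp_logan_ellipses <- function() {
  data.frame(
    A   = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023,
            0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023,
            0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

validate_ellipses <- function(ellipses) {
  need <- c("A", "a", "b", "x0", "y0", "phi")
  if (!is.data.frame(ellipses) || !all(need %in% names(ellipses)) ||
      nrow(ellipses) == 0)
    stop("ellipses must be a nonempty data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(ellipses$a <= 0) || any(ellipses$b <= 0))
    stop("invalid ellipse geometry: semiaxes a and b must be positive")
  if (any(abs(ellipses$x0) > 1) || any(abs(ellipses$y0) > 1))
    stop("ellipse centers must lie inside the unit field of view")
  invisible(ellipses)
}

#' Rasterize a Shepp-Logan-style phantom
#'
#' Analytic rasterization on pixel centers of the unit square \[-1, 1\]^2:
#' each pixel value is the sum of `A` over all ellipses containing the pixel
#' center.  Row 1 is the top of the image (y near +1).
#'
#' @param N grid size (N x N image), at least 16.
#' @param ellipses data.frame of ellipse parameters as in
#'   [shepp_logan_ellipses()].
#' @return real-valued N x N matrix.
#' @export
#' @examples
#' img <- shepp_logan(64)
#' range(img)
shepp_logan <- function(N, ellipses = shepp_logan_ellipses()) {
  if (N < 16) stop("grid size N must be at least 16")
  validate_ellipses(ellipses)
  xs <- (-N + 1 + 2 * (seq_len(N) - 1)) / N   # pixel centers in [-1, 1]
  ys <- rev(xs)                               # row 1 at the top
  X <- matrix(xs, N, N, byrow = TRUE)
  Y <- matrix(ys, N, N)
  img <- matrix(0, N, N)
  for (e in seq_len(nrow(ellipses))) {
    th <- ellipses$phi[e] * pi / 180
    xc <- X - ellipses$x0[e]
    yc <- Y - ellipses$y0[e]
    u <- (xc * cos(th) + yc * sin(th)) / ellipses$a[e]
    v <- (-xc * sin(th) + yc * cos(th)) / ellipses$b[e]
    img <- img + ellipses$A[e] * (u^2 + v^2 <= 1)
  }
  img
}

perturb_ellipses_impl <- function(base, variances, max_tries = 100) {
  sds <- sqrt(variances)
  out <- base
  for (e in seq_len(nrow(base))) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      noise <- stats::rnorm(6, mean = 0, sd = sds)
      cand <- as.numeric(base[e, c("A", "a", "b", "x0", "y0", "phi")]) + noise
      if (cand[2] > 0 && cand[3] > 0 && abs(cand[4]) <= 1 &&
          abs(cand[5]) <= 1) {
        out[e, c("A", "a", "b", "x0", "y0", "phi")] <- as.list(cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not draw a valid perturbation for ellipse ", e,
           " after ", max_tries, " tries; reduce the variances")
  }
  out
}

#' Randomly perturb ellipse parameters
#'
#' Adds independent zero-mean Gaussian noise to each of the six parameters
#' of every ellipse, with per-parameter variances
#' `(A, a, b, x0, y0, phi)`.  Draws that would produce a nonpositive
#' semiaxis or push the center outside the field of view are redrawn for
#' that ellipse (bounded retries).  Reproducible for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param base data.frame of ellipse parameters.
#' @param variances numeric vector of 6 nonnegative variances, in the order
#'   `A, a, b, x0, y0, phi` (phi in squared degrees).
#' @param seed integer seed.
#' @param max_tries redraw budget per ellipse.
#' @return data.frame of the same shape as `base`.
#' @export
perturb_ellipses <- function(base, variances, seed, max_tries = 100) {
  validate_ellipses(base)
  if (length(variances) != 6 || any(variances < 0))
    stop("variances must be 6 nonnegative values (A, a, b, x0, y0, phi)")
  with_seed(seed, perturb_ellipses_impl(base, variances, max_tries))
}

#' Default perturbation variances for the phantom study
#'
#' Variances `(A = 0.1, a = 0.05, b = 0.05, x0 = 0.05, y0 = 0.05,
#' phi = 10)`; `phi` is in squared degrees, the rest in the squared
#' phantom units (intensity, fractions of the half field of view).
#'
#' @return numeric vector of length 6.
#' @export
default_variances <- function() c(0.1, 0.05, 0.05, 0.05, 0.05, 10)

#' Generate a randomized phantom dataset
#'
#' Builds `n_ref` reference images plus one held-out test image, each a
#' Shepp-Logan phantom whose ellipse parameters were independently
#' perturbed with [perturb_ellipses()].  A pure function of
#' `(N, n_ref, variances, seed)`.
#'
#' @param N grid size.
#' @param n_ref number of reference images (>= 1).
#' @param variances 6-vector of perturbation variances.
#' @param seed integer seed.
#' @param base ellipse set to perturb.
#' @return object of class `phantom_dataset`: list with `references` (list
#'   of N x N matrices), `test` (N x N matrix), `seed`, `variances`.
#' @export
#' @examples
#' ds <- make_dataset(32, n_ref = 3, variances = default_variances(), seed = 1)
#' length(ds$references)
make_dataset <- function(N, n_ref, variances = default_variances(), seed = 1,
                         base = shepp_logan_ellipses()) {
  if (n_ref < 1) stop("n_ref must be at least 1")
  imgs <- with_seed(seed, lapply(seq_len(n_ref + 1), function(i) {
    shepp_logan(N, perturb_ellipses_impl(base, variances))
  }))
  structure(list(references = imgs[seq_len(n_ref)],
                 test = imgs[[n_ref + 1]],
                 seed = seed, variances = variances),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom_dataset: %d reference + 1 test image, %d x %d, seed %d\n",
              length(x$references), nrow(x$test), ncol(x$test), x$seed))
  invisible(x)
}

#' Impose a smooth synthetic phase on a magnitude image
#'
#' Multiplies the image by `exp(i * phi(x, y))` where `phi` is a random
#' low-order (degree <= 2, no constant term) polynomial field scaled so
#' `max |phi| = strength`.  Makes the object complex so the
#' phase-correction path of the improved cost function can be exercised on
#' synthetic data; the output magnitude equals the input magnitude
#' everywhere.
#'
#' @param img real matrix (magnitude image).
#' @param strength maximum absolute phase, radians (>= 0).
#' @param seed integer seed for the polynomial coefficients.
#' @return complex matrix of the same shape.
#' @export
synth_phase <- function(img, strength, seed = 1) {
  stopifnot(is.matrix(img), strength >= 0)
  if (strength == 0) return(img)
  N <- nrow(img); M <- ncol(img)
  xs <- seq(-1, 1, length.out = M)
  ys <- seq(-1, 1, length.out = N)
  X <- matrix(xs, N, M, byrow = TRUE)
  Y <- matrix(ys, N, M)
  coef <- with_seed(seed, stats::runif(5, -1, 1))
  phi <- coef[1] * X + coef[2] * Y + coef[3] * X^2 + coef[4] * Y^2 +
    coef[5] * X * Y
  m <- max(abs(phi))
  if (m == 0) return(img + 0i)
  phi <- phi * (strength / m)
  img * exp(1i * phi)
}
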