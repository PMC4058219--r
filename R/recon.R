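# Improved-cost-function components (phase correction, region of support)
# and the iterative thresholding (ITA) and FISTA solvers.

#' Linearly decreasing threshold schedule
#'
#' `T(k) = Ti - (Ti - Tf) / (max_iter - 1) * (k - 1)`: starts exactly at
#' `Ti`, ends exactly at `Tf`, strictly decreasing when `Ti > Tf`.
#'
#' @param Ti initial threshold.
#' @param Tf final threshold.
#' @param max_iter iteration budget (>= 1).
#' @return object of class `threshold_schedule`.
#' @export
threshold_schedule <- function(Ti, Tf, max_iter) {
  stopifnot(max_iter >= 1)
  structure(list(Ti = Ti, Tf = Tf, max_iter = as.integer(max_iter)),
            class = "threshold_schedule")
}

#' Threshold at iteration k
#'
#' @param s a [threshold_schedule()].
#' @param k iteration index in `1..max_iter`.
#' @return the threshold value.
#' @export
schedule_value <- function(s, k) {
  stopifnot(inherits(s, "threshold_schedule"))
  if (any(k < 1) || any(k > s$max_iter)) stop("iteration index out of range")
  if (s$max_iter == 1) return(rep(s$Ti, length(k)))
  s$Ti - (s$Ti - s$Tf) / (s$max_iter - 1) * (k - 1)
}

#' Estimate the phase-correction map from central k-space rows
#'
#' Keeps the `n_central` fully sampled rows around the DC row (zeroing the
#' rest of k-space), reconstructs the corresponding low-resolution image
#' `Is`, and returns `P = exp(-i * angle(Is))` — a unit-modulus per-pixel
#' phase estimate.  Multiplying the object by `P` makes it approximately
#' real, which is what lets hard thresholding and support projection act on
#' a real-like image.
#'
#' @param y measured (undersampled) k-space matrix.
#' @param mask sampling mask; its `n_central` central rows must be fully
#'   sampled.
#' @param n_central number of central rows to use (default 4).
#' @return complex matrix with `|P| = 1` everywhere.
#' @export
estimate_phase <- function(y, mask, n_central = 4L) {
  if (!identical(dim(y), dim(mask))) stop("y and mask shapes differ")
  rows <- center_row_indices(nrow(y), n_central)
  if (length(rows) == 0) stop("n_central must be positive")
  if (!all(mask[rows, ] == 1))
    stop("the ", n_central, " central rows are not fully sampled in the mask")
  ks <- matrix(0 + 0i, nrow(y), ncol(y))
  ks[rows, ] <- y[rows, ]
  is_ <- from_kspace(ks)
  exp(-1i * Arg(is_))
}

#' Estimate a region-of-support mask from the acquired k-space
#'
#' Surrogate for the coarse prior scan that defines the region of support
#' (ROS): the acquired k-space samples are apodized with a Hamming window
#' (suppressing truncation ringing), zero-filled and inverse transformed;
#' the magnitude is thresholded at `frac` times its maximum and cleaned
#' with morphological closing and hole filling into a solid region.
#' Pixels outside the ROS are forced to zero during reconstruction.
#'
#' @param y measured (undersampled) k-space matrix.
#' @param mask sampling mask (only its sampled positions are used).
#' @param frac threshold fraction of the coarse-image maximum
#'   (`frac = 0` gives an all-ones, no-op support).
#' @param n_central unused compatibility argument (the estimate uses all
#'   sampled points).
#' @return binary matrix (1 inside the support).
#' @export
estimate_support <- function(y, mask, frac = 0.05, n_central = NULL) {
  if (!identical(dim(y), dim(mask))) stop("y and mask shapes differ")
  stopifnot(frac >= 0)
  if (frac == 0) return(matrix(1L, nrow(y), ncol(y)))
  w <- hamming2d(nrow(y), ncol(y))
  coarse <- Mod(from_kspace(y * (mask == 1) * w))
  s <- coarse >= frac * max(coarse)
  brush <- EBImage::makeBrush(5, shape = "disc")
  s <- EBImage::closing(s * 1, brush)
  s <- EBImage::fillHull(s)
  matrix(as.integer(s > 0.5), nrow(y), ncol(y))
}

#' Hard-threshold wavelet coefficients
#'
#' Keeps a coefficient unchanged iff its complex magnitude exceeds `T`,
#' otherwise sets it to zero (hard, not soft, thresholding).  The coarsest
#' approximation band is exempt by default: zeroing it would destroy DC
#' content that the threshold schedule cannot recover.
#'
#' @param coeffs a `wavelet_coeffs` matrix from [wavelet_analysis()].
#' @param T nonnegative threshold.
#' @param keep_approx exempt the coarsest approximation band (default
#'   `TRUE`).
#' @return thresholded `wavelet_coeffs` matrix.
#' @export
hard_threshold <- function(coeffs, T, keep_approx = TRUE) {
  stopifnot(T >= 0)
  out <- coeffs * (Mod(coeffs) > T)
  if (keep_approx) {
    ab <- approx_block(coeffs)
    out[seq_len(ab[1]), seq_len(ab[2])] <- coeffs[seq_len(ab[1]),
                                                  seq_len(ab[2])]
  }
  out
}

soft_threshold <- function(coeffs, lambda) {
  m <- Mod(coeffs)
  shrink <- pmax(0, 1 - lambda / pmax(m, .Machine$double.xmin))
  coeffs * shrink
}

#' Enforce exact k-space data consistency
#'
#' Transforms the phase-corrected image `P * x` to k-space, overwrites the
#' sampled locations with the measured values `y`, transforms back, and
#' removes the phase correction again (`P^-1 = conj(P)` since `|P| = 1`).
#' Afterwards `to_kspace(P * x')` equals `y` exactly at every sampled
#' location.
#'
#' @param x current image estimate.
#' @param y measured k-space (zero at unsampled locations).
#' @param mask binary sampling mask.
#' @param P unit-modulus phase-correction matrix, or `NULL` for none.
#' @return updated image matrix.
#' @export
data_consistency <- function(x, y, mask, P = NULL) {
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(mask)))
    stop("x, y and mask shapes differ")
  k <- if (is.null(P)) to_kspace(x) else to_kspace(P * x)
  sel <- mask == 1
  k[sel] <- y[sel]
  xr <- from_kspace(k)
  if (is.null(P)) xr else Conj(P) * xr
}

#' Reconstruction configuration
#'
#' Bundles the solver parameters.  `Ti`/`Tf` default to 0.5 and 0.001
#' times the largest detail-coefficient magnitude of the zero-filled
#' starting image; `F` (minimum improvement, Frobenius norm of the image
#' change) defaults to 0, i.e. the solver stops early only at an exact
#' fixpoint — with a slowly moving threshold schedule the iterates pass
#' through quasi-stationary phases early on, so any positive default
#' would stop the annealing prematurely; `I` is the patience in
#' iterations.  `lambda` is the l1 weight of the FISTA baseline,
#' defaulting to 0.01 times the largest detail-coefficient magnitude
#' (the same normalization as `Ti`; the approximation band's large DC
#' coefficient would otherwise set the scale).
#'
#' @param wavelet a [wavelet_spec()].
#' @param Ti,Tf initial/final hard threshold (`NULL` = data-driven
#'   default).
#' @param max_iter iteration budget.
#' @param F minimum improvement amount (`NULL` = data-driven default).
#' @param I patience: stop after this many consecutive iterations with
#'   change below `F`.
#' @param use_phase apply phase correction (improved cost function).
#' @param use_support apply region-of-support projection.
#' @param n_central central rows used for phase/support estimation.
#' @param support_frac threshold fraction for [estimate_support()].
#' @param keep_approx exempt the approximation band from thresholding.
#' @param lambda FISTA l1 weight (`NULL` = data-driven default).
#' @param phase,support optional precomputed phase map / support mask
#'   (otherwise estimated from the data when enabled).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(wavelet = wavelet_spec("haar", 3), Ti = NULL,
                         Tf = NULL, max_iter = 200L, F = NULL, I = 5L,
                         use_phase = FALSE, use_support = FALSE,
                         n_central = 4L, support_frac = 0.05,
                         keep_approx = TRUE, lambda = NULL, phase = NULL,
                         support = NULL) {
  stopifnot(inherits(wavelet, "wavelet_spec"), max_iter >= 1, I >= 1)
  if (!is.null(F) && F < 0) stop("F must be nonnegative")
  structure(list(wavelet = wavelet, Ti = Ti, Tf = Tf,
                 max_iter = as.integer(max_iter), F = F, I = as.integer(I),
                 use_phase = use_phase, use_support = use_support,
                 n_central = as.integer(n_central),
                 support_frac = support_frac, keep_approx = keep_approx,
                 lambda = lambda, phase = phase, support = support),
            class = "recon_config")
}

new_recon_result <- function(image, iterations, stop_reason, change_norms,
                             extra = list()) {
  structure(c(list(image = image, iterations_run = iterations,
                   stop_reason = stop_reason, change_norms = change_norms),
              extra),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result: %d x %d image, %d iterations (%s)\n",
              nrow(x$image), ncol(x$image), x$iterations_run,
              x$stop_reason))
  invisible(x)
}

prepare_phase_support <- function(y, mask, cfg) {
  P <- NULL
  if (cfg$use_phase)
    P <- cfg$phase %||% estimate_phase(y, mask, cfg$n_central)
  S <- NULL
  if (cfg$use_support)
    S <- cfg$support %||% estimate_support(y, mask, cfg$support_frac,
                                           cfg$n_central)
  list(P = P, S = S)
}

#' Iterative thresholding reconstruction (ITA)
#'
#' Solves the improved cost function by alternating, at each iteration k:
#' wavelet hard thresholding at the scheduled level `T(k)`, exact k-space
#' data replacement at sampled locations (with phase correction when
#' enabled), and region-of-support projection.  Starts from the
#' zero-filled inverse transform of `y` and stops when the image change
#' stays below `F` for `I` consecutive iterations or the budget is
#' exhausted.
#'
#' @param y measured k-space matrix (zero at unsampled locations).
#' @param mask binary sampling mask.
#' @param cfg a [recon_config()].
#' @return `recon_result` with the image, iteration count, stop reason,
#'   per-iteration change norms and post-consistency k-space residuals.
#' @export
ita_reconstruct <- function(y, mask, cfg = recon_config()) {
  if (!identical(dim(y), dim(mask))) stop("y and mask shapes differ")
  ps <- prepare_phase_support(y, mask, cfg)
  x <- from_kspace(y)                 # x0: zero-filled inverse transform
  c0 <- wavelet_analysis(x, cfg$wavelet)
  dmax <- detail_max(c0)
  Ti <- cfg$Ti %||% (0.5 * dmax)
  Tf <- cfg$Tf %||% (0.001 * dmax)
  sched <- threshold_schedule(Ti, Tf, cfg$max_iter)
  Fmin <- cfg$F %||% 0
  sel <- mask == 1
  change <- numeric(0)
  resid <- numeric(0)
  stall <- 0L
  reason <- "budget"
  k_iter <- 0L
  for (k in seq_len(cfg$max_iter)) {
    k_iter <- k
    x_prev <- x
    cf <- wavelet_analysis(x, cfg$wavelet)
    cf <- hard_threshold(cf, schedule_value(sched, k), cfg$keep_approx)
    x <- wavelet_synthesis(cf, cfg$wavelet)
    x <- data_consistency(x, y, mask, ps$P)
    kchk <- if (is.null(ps$P)) to_kspace(x) else to_kspace(ps$P * x)
    resid <- c(resid, max(Mod(kchk[sel] - y[sel]), 0))
    if (!is.null(ps$S)) x <- ps$S * x
    dn <- frob(x - x_prev)
    change <- c(change, dn)
    if (dn <= Fmin) stall <- stall + 1L else stall <- 0L
    if (stall >= cfg$I) { reason <- "stalled"; break }
  }
  new_recon_result(x, k_iter, reason, change,
                   list(consistency_residual = resid, schedule = sched,
                        phase = ps$P, support = ps$S))
}

#' FISTA baseline for the conventional cost function
#'
#' Monotone accelerated proximal-gradient iteration on the Lagrangian form
#' `lambda * ||Psi x||_1 + 1/2 * ||Fu x - y||^2` with soft thresholding in
#' the wavelet domain (step size 1: the masked unitary Fourier operator
#' has Lipschitz constant 1).  The monotone (MFISTA) variant is used, so
#' the objective trace is non-increasing.  This is the reference solver
#' for the conventional cost function, without phase correction or support
#' projection.
#'
#' @inheritParams ita_reconstruct
#' @return `recon_result` with the image, iteration count, stop reason,
#'   change norms and the objective trace.
#' @export
fista_reconstruct <- function(y, mask, cfg = recon_config()) {
  if (!identical(dim(y), dim(mask))) stop("y and mask shapes differ")
  sel <- mask == 1
  x <- from_kspace(y)
  c0 <- wavelet_analysis(x, cfg$wavelet)
  lambda <- cfg$lambda %||% (0.01 * detail_max(c0))
  Fmin <- cfg$F %||% 0
  objective <- function(xx) {
    k <- to_kspace(xx)
    lambda * sum(Mod(wavelet_analysis(xx, cfg$wavelet))) +
      0.5 * sum(Mod(k[sel] - y[sel])^2)
  }
  z <- x
  t_k <- 1
  obj_x <- objective(x)
  obj_trace <- numeric(0)
  change <- numeric(0)
  stall <- 0L
  reason <- "budget"
  k_iter <- 0L
  for (k in seq_len(cfg$max_iter)) {
    k_iter <- k
    x_prev <- x
    kz <- to_kspace(z)
    grad_k <- matrix(0 + 0i, nrow(y), ncol(y))
    grad_k[sel] <- kz[sel] - y[sel]
    w <- z - from_kspace(grad_k)
    cand <- wavelet_synthesis(soft_threshold(wavelet_analysis(w, cfg$wavelet),
                                             lambda),
                              cfg$wavelet)
    obj_cand <- objective(cand)
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    if (obj_cand <= obj_x) {
      x <- cand
      obj_x <- obj_cand
    }
    # monotone FISTA momentum: accelerate along the candidate direction
    z <- x + (t_k / t_next) * (cand - x) +
      ((t_k - 1) / t_next) * (x - x_prev)
    t_k <- t_next
    obj_trace <- c(obj_trace, obj_x)
    dn <- frob(x - x_prev)
    change <- c(change, dn)
    if (dn <= Fmin) stall <- stall + 1L else stall <- 0L
    if (stall >= cfg$I) { reason <- "stalled"; break }
  }
  new_recon_result(x, k_iter, reason, change,
                   list(objective = obj_trace, lambda = lambda))
}
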