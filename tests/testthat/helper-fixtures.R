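# Shared fixtures, all built in code.  The full-size study dataset is
# cached per seed because several tests reuse it.

.fixture_cache <- new.env(parent = emptyenv())

study_dataset <- function(seed = 1L, N = 128L, n_ref = 20L) {
  key <- paste0("ds", seed, "_", N, "_", n_ref)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_dataset(N, n_ref, default_variances(), seed)
  .fixture_cache[[key]]
}

study_kspaces <- function(seed = 1L, N = 128L, n_ref = 20L) {
  key <- paste0("ks", seed, "_", N, "_", n_ref)
  if (is.null(.fixture_cache[[key]])) {
    ds <- study_dataset(seed, N, n_ref)
    .fixture_cache[[key]] <- list(refs_k = lapply(ds$references, to_kspace),
                                  test_k = to_kspace(ds$test),
                                  truth = ds$test)
  }
  .fixture_cache[[key]]
}

rand_mat <- function(n, m = n, seed = 1, complex = FALSE) {
  withr::with_seed(seed, {
    re <- matrix(rnorm(n * m), n, m)
    if (complex) re + 1i * matrix(rnorm(n * m), n, m) else re
  })
}

# a single ellipse that covers the whole [-1, 1]^2 field of view
covering_ellipse <- function(A = 1)
  data.frame(A = A, a = 2, b = 2, x0 = 0, y0 = 0, phi = 0)

# scalar point-in-ellipse test, independent of the rasterizer
brute_force_phantom_pixel <- function(ellipses, x, y) {
  val <- 0
  for (e in seq_len(nrow(ellipses))) {
    th <- ellipses$phi[e] * pi / 180
    xc <- x - ellipses$x0[e]; yc <- y - ellipses$y0[e]
    u <- (xc * cos(th) + yc * sin(th)) / ellipses$a[e]
    v <- (-xc * sin(th) + yc * cos(th)) / ellipses$b[e]
    if (u^2 + v^2 <= 1) val <- val + ellipses$A[e]
  }
  val
}

pixel_centers <- function(N) (-N + 1 + 2 * (seq_len(N) - 1)) / N
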