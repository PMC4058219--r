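test_that("threshold schedule interpolates linearly between Ti and Tf", {
  s <- threshold_schedule(10, 0, 11)
  expect_equal(schedule_value(s, 1), 10)
  expect_equal(schedule_value(s, 11), 0)
  expect_equal(schedule_value(s, 6), 5)
  expect_true(all(diff(schedule_value(s, 1:11)) < 0))
  expect_error(schedule_value(s, 0), "out of range")
  expect_error(schedule_value(s, 12), "out of range")
  expect_equal(schedule_value(threshold_schedule(3, 1, 1), 1), 3)
})

test_that("hard thresholding keeps only coefficients above the magnitude cut", {
  base <- wavelet_analysis(matrix(0, 4, 4), wavelet_spec("haar", 1))
  co <- base
  co[1, 3] <- 3; co[3, 1] <- -1; co[3, 3] <- 0.5i; co[4, 4] <- -2.5
  out <- hard_threshold(co, 2)
  expect_equal(out[1, 3], 3 + 0i)
  expect_equal(out[3, 1], 0 + 0i)
  expect_equal(out[3, 3], 0 + 0i)
  expect_equal(out[4, 4], -2.5 + 0i)
  # T = 0 keeps everything (strict inequality: exact zeros stay zero)
  expect_equal(hard_threshold(co, 0)[, ], co[, ])
  # T above the maximum zeroes all detail bands
  big <- hard_threshold(co, 10)
  d <- Mod(big); d[1:2, 1:2] <- 0
  expect_equal(max(d), 0)
  # the approximation band survives unless exempted
  co2 <- base; co2[1, 1] <- 5
  expect_equal(hard_threshold(co2, 10)[1, 1], 5)
  expect_equal(hard_threshold(co2, 10, keep_approx = FALSE)[1, 1], 0)
})

test_that("phase estimation returns a unit-modulus map that re-aligns the object", {
  ds <- study_dataset(1, N = 64, n_ref = 1)
  truth <- ds$test
  obj <- synth_phase(truth, pi / 4, seed = 9)
  y <- to_kspace(obj)
  mask <- matrix(1L, 64, 64)
  P <- estimate_phase(y, mask, 4)
  expect_equal(Mod(P), matrix(1, 64, 64))
  # phase correction re-aligns the object toward the real axis; the
  # alignment sharpens as the central band widens
  im_before <- sqrt(sum(Im(obj)^2))
  im4 <- sqrt(sum(Im(P * obj)^2))
  im8 <- sqrt(sum(Im(estimate_phase(y, mask, 8) * obj)^2))
  expect_lt(im4, im_before)
  expect_lt(im8, 0.5 * im_before)
  expect_lt(im8, im4)
  # a real nonnegative object has small estimated phase on its support
  Pr <- estimate_phase(to_kspace(truth), mask, 4)
  on_obj <- truth > 0.5 * max(truth)
  expect_lt(median(abs(Arg(Pr)[on_obj])), 0.1)
  expect_lt(max(abs(Arg(Pr)[on_obj])), 0.5)
  # unsampled central rows are refused
  empty <- matrix(0L, 64, 64)
  expect_error(estimate_phase(y, empty, 4), "not fully sampled")
})

test_that("support estimation covers the object and acts as an idempotent projector", {
  ks <- study_kspaces(1)
  wpdf <- apply_window(build_ipdf(ks$refs_k), 0.8)
  msk <- select_mask(wpdf, round(0.25 * 128^2), center_rows = 4)
  y <- ks$test_k * (msk == 1)
  S <- estimate_support(y, msk, 0.05)
  truth_sup <- ks$truth > 0
  expect_gte(mean(S[truth_sup]), 0.99)
  expect_true(all(S %in% c(0L, 1L)))
  # idempotent projector that never increases energy
  x <- rand_mat(128, seed = 31, complex = TRUE)
  expect_equal(S * (S * x), S * x)
  expect_lte(sqrt(sum(Mod(S * x)^2)), sqrt(sum(Mod(x)^2)))
  # frac = 0 is the no-op support
  expect_equal(estimate_support(y, msk, 0), matrix(1L, 128, 128))
})

test_that("data consistency restores measured k-space values exactly", {
  x <- rand_mat(16, seed = 41, complex = TRUE)
  truth <- rand_mat(16, seed = 42, complex = TRUE)
  msk <- matrix(as.integer(rand_mat(16, seed = 43) > 0.3), 16, 16)
  y <- to_kspace(truth) * (msk == 1)
  # without phase correction
  xr <- data_consistency(x, y, msk)
  expect_lt(max(Mod(to_kspace(xr)[msk == 1] - y[msk == 1])), 1e-10)
  # with a nontrivial unit-modulus phase map
  P <- exp(1i * Arg(rand_mat(16, seed = 44, complex = TRUE)))
  xp <- data_consistency(x, y, msk, P)
  expect_lt(max(Mod(to_kspace(P * xp)[msk == 1] - y[msk == 1])), 1e-10)
  # full mask: the data replace everything
  full <- matrix(1L, 16, 16)
  yf <- to_kspace(truth)
  expect_equal(data_consistency(x, yf, full), truth)
  expect_equal(data_consistency(x, yf, full, P), Conj(P) * truth)
  # empty mask: x passes through (within round-trip error)
  expect_equal(data_consistency(x, matrix(0i, 16, 16), matrix(0L, 16, 16)), x)
})

test_that("ITA recovers the acquired image exactly under full sampling", {
  truth <- study_dataset(1, N = 64, n_ref = 1)$test
  y <- to_kspace(truth)
  full <- matrix(1L, 64, 64)
  res <- ita_reconstruct(y, full, recon_config(max_iter = 1))
  expect_equal(res$iterations_run, 1L)
  expect_lt(max(Mod(res$image - truth)), 1e-8)
})

test_that("ITA maintains exact consistency and improves with more data", {
  ks <- study_kspaces(1)
  wpdf <- apply_window(build_ipdf(ks$refs_k), 0.8)
  errs <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(r) {
    msk <- select_mask(wpdf, round(r * 128^2), center_rows = 4)
    y <- ks$test_k * (msk == 1)
    res <- ita_reconstruct(y, msk, recon_config(max_iter = 150))
    expect_lt(max(res$consistency_residual), 1e-10)
    mae(Mod(res$image), ks$truth)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))   # error non-increasing in ratio
})

test_that("the improved model beats plain thresholding on phase-corrupted objects", {
  ks <- study_kspaces(1)
  obj <- synth_phase(ks$truth, pi / 4, seed = 51)
  y_full <- to_kspace(obj)
  wpdf <- apply_window(build_ipdf(ks$refs_k), 0.8)
  msk <- select_mask(wpdf, round(0.25 * 128^2), center_rows = 4)
  y <- y_full * (msk == 1)
  sp <- wavelet_spec("bior4.4", 6)
  plain <- ita_reconstruct(y, msk, recon_config(wavelet = sp, max_iter = 150))
  icf <- ita_reconstruct(y, msk, recon_config(wavelet = sp, max_iter = 150,
                                              use_phase = TRUE,
                                              use_support = TRUE))
  expect_lt(mae(Mod(icf$image), ks$truth), mae(Mod(plain$image), ks$truth))
})

test_that("FISTA solves the trivial limits and decreases its objective", {
  truth <- study_dataset(1, N = 32, n_ref = 1)$test
  y <- to_kspace(truth)
  full <- matrix(1L, 32, 32)
  # lambda = 0, full mask: least squares = zero-filled inverse, exact
  r0 <- fista_reconstruct(y, full, recon_config(max_iter = 3, lambda = 0))
  expect_lt(max(Mod(r0$image - truth)), 1e-10)
  # enormous lambda drives the image to zero
  rinf <- fista_reconstruct(y, full, recon_config(max_iter = 5, lambda = 1e9))
  expect_lt(max(Mod(rinf$image)), 1e-8)
  # monotone objective on a random undersampled instance
  msk <- matrix(as.integer(rand_mat(32, seed = 61) > 0.2), 32, 32)
  yr <- to_kspace(rand_mat(32, seed = 62)) * (msk == 1)
  rr <- fista_reconstruct(yr, msk, recon_config(max_iter = 40))
  expect_true(all(diff(rr$objective) <= 1e-12))
})
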