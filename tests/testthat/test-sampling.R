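test_that("build_ipdf accumulates reference magnitudes and normalizes", {
  cst <- matrix(2 + 0i, 4, 4)
  expect_equal(build_ipdf(list(cst)), matrix(1 / 16, 4, 4))
  # duplicating a reference changes nothing after normalization
  k1 <- matrix(complex(real = 1:16, imaginary = 16:1), 4, 4)
  expect_equal(build_ipdf(list(k1, k1)), build_ipdf(list(k1)))

  # hand-worked 4x4 sum of two references
  a <- matrix(c(1, 0, 2, 1,  0, 3, 1, 0,  2, 1, 0, 1,  1, 0, 1, 2), 4, 4)
  b <- matrix(c(0, 1, 1, 2,  1, 0, 2, 1,  0, 2, 1, 0,  2, 1, 0, 1), 4, 4)
  got <- build_ipdf(list(a + 0i, b * 1i))   # magnitudes are a and b
  expect_equal(got, (a + b) / sum(a + b))

  # line mode: constant across each row, row masses follow the profile
  lp <- build_ipdf(list(a + 0i), "line")
  expect_true(all(apply(lp, 1, function(r) diff(range(r)) == 0)))
  expect_equal(rowSums(lp), rowSums(a) / sum(a))

  expect_error(build_ipdf(list()), "at least one")
  expect_error(build_ipdf(list(a + 0i, matrix(0i, 2, 2))), "shapes differ")
})

test_that("hamming2d matches the closed form at every index", {
  w <- hamming2d(128, 128)
  expect_equal(w[1, 1], 0.08 * 0.08)
  expect_equal(w[65, 65], 1.0)      # peak at the DC index
  # brute-force evaluation of the separable closed form
  ref <- matrix(0, 128, 128)
  for (m in 0:127) for (n in 0:127)
    ref[m + 1, n + 1] <- (0.54 - 0.46 * cos(2 * pi * m / 128)) *
      (0.54 - 0.46 * cos(2 * pi * n / 128))
  expect_equal(w, ref)
  # 180-degree rotational symmetry about the grid center
  idx <- 2:128
  expect_equal(w[idx, idx], w[rev(idx), rev(idx)])
  expect_true(all(w > 0))
})

test_that("apply_window tapers the iPDF by the hamming window", {
  ip <- build_ipdf(study_kspaces(1)$refs_k)
  # alpha -> 0 leaves the map unchanged
  expect_equal(apply_window(ip, 1e-9), ip, tolerance = 1e-6)
  # uniform iPDF: the wPDF is the normalized window itself, maximal at center
  u <- matrix(1 / 64^2, 64, 64)
  wp <- apply_window(u, 1)
  expect_equal(which.max(wp), which.max(hamming2d(64, 64)))
  expect_equal(wp, hamming2d(64, 64) / sum(hamming2d(64, 64)))
  # larger alpha concentrates more mass in the central half-radius
  r <- sqrt(outer(((1:128) - 65)^2, ((1:128) - 65)^2, `+`))
  inner <- r <= max(r) / 2
  m1 <- sum(apply_window(ip, 0.8)[inner])
  m2 <- sum(apply_window(ip, 1.4)[inner])
  expect_gt(m2, m1)
  expect_equal(sum(apply_window(ip, 0.8)), 1)
})

test_that("select_mask equals a full-sort top-k oracle with documented tie-breaks", {
  # 8x8 toy instance, 13 points
  w <- rand_mat(8, seed = 5)^2
  m <- select_mask(w / sum(w), 13, "point", center_rows = 0)
  ord <- order(-as.vector(w), as.vector(row(w)), as.vector(col(w)))
  want <- matrix(0L, 8, 8); want[ord[1:13]] <- 1L
  expect_equal(unclass(m)[, ], want[, ], ignore_attr = TRUE)

  # trivial budgets
  expect_equal(sum(select_mask(w / sum(w), 64, center_rows = 0)), 64)
  m1 <- select_mask(w / sum(w), 1, center_rows = 0)
  expect_equal(which(m1 == 1), which.max(w))

  # nesting: enlarging the budget only adds points
  m_small <- select_mask(w / sum(w), 10, center_rows = 1)
  m_big <- select_mask(w / sum(w), 30, center_rows = 1)
  expect_true(all(m_big[m_small == 1] == 1))

  # forced central rows are on and counted against the budget
  mc <- select_mask(w / sum(w), 20, center_rows = 2)
  expect_true(all(mc[center_row_indices(8, 2), ] == 1))
  expect_equal(sum(mc), 20)
  expect_error(select_mask(w / sum(w), 10, center_rows = 4), "central-row")

  # line mode selects whole rows by summed mass
  ml <- select_mask(w / sum(w), 3, "line", center_rows = 0)
  full_rows <- which(apply(ml == 1, 1, all))
  expect_length(full_rows, 3)
  expect_equal(sum(ml), 3 * 8)
  expect_setequal(full_rows, order(-rowSums(w))[1:3])
})

test_that("select_mask matches the sort oracle on 100 random instances", {
  for (i in 1:100) {
    w <- rand_mat(8, seed = 1000 + i)^2
    n <- withr::with_seed(2000 + i, sample(64, 1))
    m <- select_mask(w / sum(w), n, center_rows = 0)
    ord <- order(-as.vector(w), as.vector(row(w)), as.vector(col(w)))
    expect_identical(which(as.vector(m == 1)), sort(ord[seq_len(n)]))
  }
})

test_that("vd_pdf matches brute-force evaluation of the polynomial law", {
  v <- vd_pdf(128, 128, 10)
  expect_equal(which.max(v), (65 - 1) * 128 + 65)   # DC index maximal
  expect_equal(vd_pdf(16, 16, 0), matrix(1 / 256, 16, 16))
  ref <- matrix(0, 128, 128)
  rmax <- sqrt(2 * 64^2)
  for (i in 1:128) for (j in 1:128) {
    r <- sqrt((i - 65)^2 + (j - 65)^2) / rmax
    ref[i, j] <- max(1 - r, 0)^10
  }
  expect_equal(v, ref / sum(ref))
})

test_that("pdf_random_mask draws exact-count reproducible masks with pdf-shaped inclusion", {
  p <- vd_pdf(16, 16, 10)
  m <- pdf_random_mask(p, 60, seed = 3)
  expect_equal(sum(m), 60)
  expect_identical(unclass(pdf_random_mask(p, 60, seed = 3)),
                   unclass(m))
  expect_false(identical(unclass(pdf_random_mask(p, 60, seed = 4)),
                         unclass(m)))
  expect_equal(sum(pdf_random_mask(p, 256, seed = 1)), 256)

  # uniform map: empirical inclusion frequencies are uniform
  u <- matrix(1 / 64, 8, 8)
  freq <- Reduce(`+`, lapply(1:400, function(s)
    unclass(pdf_random_mask(u, 16, seed = s)) * 1))
  # each cell has inclusion probability 1/4; binomial 3-sigma band
  p0 <- 1 / 4
  band <- 3 * sqrt(p0 * (1 - p0) * 400)
  expect_true(all(abs(freq - 400 * p0) <= band))

  # center rows forced
  mc <- pdf_random_mask(p, 100, seed = 2, center_rows = 2)
  expect_true(all(mc[center_row_indices(16, 2), ] == 1))
  expect_equal(sum(mc), 100)

  # degenerate map with too few positive entries
  sparse <- matrix(0, 8, 8); sparse[1:5] <- 1 / 5
  expect_error(pdf_random_mask(sparse, 10, seed = 1), "fewer positive")
})

test_that("lowres_mask selects the points nearest the k-space center", {
  expect_equal(sum(lowres_mask(8, 8, 64)), 64)
  m1 <- lowres_mask(9, 9, 1)
  expect_equal(which(m1 == 1), (5 - 1) * 9 + 5)
  # radius-sort oracle at 16x16, 64 points
  m <- lowres_mask(16, 16, 64)
  r <- sqrt(outer(((1:16) - 9)^2, ((1:16) - 9)^2, `+`))
  ord <- order(as.vector(r), as.vector(row(r)), as.vector(col(r)))
  expect_identical(which(as.vector(m == 1)), sort(ord[1:64]))
})

test_that("epr measures the sampled share of k-space energy", {
  k <- matrix(complex(real = c(1, 2, 0, 1,  0, 3, 1, 0,
                               2, 1, 0, 1,  1, 0, 1, 2)), 4, 4)
  full <- matrix(1L, 4, 4)
  expect_equal(epr(full, k), 1.0)
  expect_equal(epr(matrix(0L, 4, 4), k), 0.0)
  m5 <- matrix(0L, 4, 4); m5[c(1, 6, 9, 11, 16)] <- 1L
  # hand computation: energies 1, 9, 2^2, 0, 2^2 of total sum of squares
  expect_equal(epr(m5, k), (1 + 9 + 4 + 0 + 4) / sum(Mod(k)^2))
  expect_error(epr(full, matrix(0i, 4, 4)), "identically zero")
  # EPR is nondecreasing along nested masks
  ks <- study_kspaces(1)
  w <- apply_window(build_ipdf(ks$refs_k), 0.8)
  es <- vapply(c(1000, 4000, 8000), function(n)
    epr(select_mask(w, n, center_rows = 0), ks$test_k), numeric(1))
  expect_true(all(diff(es) >= 0))
})

test_that("correlation diagnostics handle proportional and degenerate inputs", {
  k <- study_kspaces(1)$test_k
  expect_equal(correlation_2d(Mod(k) / sum(Mod(k)), k), 1.0)
  expect_true(is.na(correlation_2d(matrix(1 / 64, 8, 8),
                                   matrix(2 + 0i, 8, 8))))
  rw <- rowwise_correlation(Mod(k) / sum(Mod(k)), k)
  expect_equal(rw, rep(1, 128), tolerance = 1e-9)
  # constant rows yield the undefined marker, not an error
  mzero <- matrix(1, 4, 4)
  kk <- matrix(complex(real = 1:16), 4, 4)
  expect_true(all(is.na(rowwise_correlation(mzero / 16, kk))))
  expect_error(correlation_2d(matrix(1, 2, 2), kk), "shapes differ")
})

test_that("probability maps are normalized and nonnegative", {
  ks <- study_kspaces(1)
  for (m in list(build_ipdf(ks$refs_k), build_power_pdf(ks$refs_k),
                 apply_window(build_ipdf(ks$refs_k), 0.8),
                 vd_pdf(64, 64, 10), vd_pdf(32, 48, 3))) {
    expect_true(all(m >= 0))
    expect_lt(abs(sum(m) - 1), 1e-9)
  }
})
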