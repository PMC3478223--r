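test_that("flat surfaces give fd = 2 exactly and r2 = 1", {
  m <- mk_disk_mask(8)
  s <- fit_fd(blanket_series(const_nucleus(m, gray = 117L)))
  expect_identical(s$fd, 2)
  expect_identical(s$r2, 1)
  # A(eps) equals the mask pixel count at every radius, V = 2*eps*N
  expect_equal(s$areas, rep(sum(m), 15))
  expect_equal(s$volumes, 2 * (1:15) * sum(m))
})

test_that("a single-pixel mask dilates as a bare cone", {
  g <- matrix(50, 5, 5)
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  s <- blanket_series(g, eps_max = 5, mask = m)
  expect_equal(s$volumes, 2 * (1:5))
  expect_equal(s$areas, rep(1, 5))
})

test_that("blanket volumes grow by at least twice the mask size per step", {
  for (seed in c(2, 12)) {
    n <- random_nucleus(seed = seed)
    s <- blanket_series(n, eps_max = 10)
    expect_true(all(diff(c(0, s$volumes)) >= 2 * sum(n$mask)))
    expect_true(all(diff(s$volumes) > 0))
  }
})

test_that("gray inversion leaves the blanket series unchanged", {
  n <- random_nucleus(seed = 13)
  inv <- nucleus_image(255L - n$gray, n$mask, n$calibration)
  s1 <- fit_fd(blanket_series(n))
  s2 <- fit_fd(blanket_series(inv))
  expect_identical(s1$volumes, s2$volumes)
  expect_identical(s1$fd, s2$fd)
  expect_identical(s1$r2, s2$r2)
})

test_that("fd increases with surface roughness and r2 stays in range", {
  fd_h <- function(h) {
    fit_fd(blanket_series(generate_fbm_surface(h, 128, seed = 21) * 40))$fd
  }
  expect_gt(fd_h(0.3), fd_h(0.7))
  n <- random_nucleus(seed = 14)
  s <- fit_fd(blanket_series(n))
  expect_gte(s$r2, 0); expect_lte(s$r2, 1)
  expect_lt(s$r2, 1) # real, noisy image: never an ideal fractal
  expect_gte(s$fd, 2 - 0.05); expect_lte(s$fd, 3 + 0.05)
})

test_that("blankets equal brute-force cone dilation on small images", {
  for (seed in c(3, 23)) {
    set.seed(seed)
    g <- matrix(sample(0:20, 256, replace = TRUE), 16, 16)
    s <- blanket_series(g, eps_max = 4)
    expect_equal(s$volumes, oracle_blanket_V(g, 4), tolerance = 1e-12)
  }
})

test_that("45-degree rotated-frame R2 equals the direct computation", {
  n <- random_nucleus(seed = 15)
  s <- blanket_series(n)
  expect_equal(fit_fd(s, rotate45 = TRUE)$r2, fit_fd(s)$r2,
               tolerance = 1e-12)
})

test_that("the sausage normalization variant is exposed", {
  n <- random_nucleus(seed = 16)
  s <- blanket_series(n, normalization = "sausage")
  expect_equal(s$areas, s$volumes / (2 * s$epsilons))
  # both normalizations agree exactly on flat surfaces
  m <- mk_disk_mask(8)
  f1 <- fit_fd(blanket_series(const_nucleus(m), normalization = "sausage"))
  expect_identical(f1$fd, 2)
})

test_that("configuration errors are caught", {
  n <- random_nucleus(seed = 17)
  expect_error(blanket_series(n, eps_max = 2), "eps_max")
  expect_error(blanket_series(matrix(1, 4, 4), mask = matrix(FALSE, 4, 4)),
               "empty")
})

test_that("n8 neighborhood is available and dilates at least as fast as n4", {
  n <- random_nucleus(seed = 18)
  v4 <- blanket_series(n, eps_max = 6)$volumes
  v8 <- blanket_series(n, eps_max = 6, neighborhood = "n8")$volumes
  expect_true(all(v8 >= v4))
})
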