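make_stats <- function(counts, Th, R) {
  st <- pair_stats(Th, R)
  st$counts <- counts
  st$n_images <- 1L
  st
}

test_that("ODD kernels are zero-sum, linear in strength, class-balanced", {
  set.seed(21)
  R <- 5L; D <- 2L * R + 1L; Th <- 4L
  off <- seq(-R, R)
  inside <- outer(off^2, off^2, `+`) <= R^2
  rnd <- function() {
    a <- array(runif(D * D * Th * Th), dim = c(D, D, Th, Th))
    for (i in seq_len(Th)) for (j in seq_len(Th)) {
      s <- a[, , j, i]; s[!inside] <- 0; a[, , j, i] <- s
    }
    a
  }
  h <- rnd()
  st_t <- make_stats(h, Th, R)
  st_d <- make_stats(h, Th, R)

  # identical class statistics cancel exactly
  k0 <- odd_kernel(st_t, st_d, strength = 3)
  expect_true(all(abs(k0$canonical) < 1e-12))

  st_d2 <- make_stats(rnd(), Th, R)
  k1 <- odd_kernel(st_t, st_d2, strength = 3)
  expect_lt(abs(sum(k1$canonical)), 1e-9 * 3)
  # every rotated instance inherits the zero sum (rotation conserves mass)
  for (i in seq_len(Th)) {
    expect_lt(abs(sum(k1$rotated[, , , i])), 1e-9 * 3)
  }
  # target part sums to +S, distractor part to -S
  ht <- canonicalize(st_t); hd <- canonicalize(st_d2)
  expect_equal(sum((3 / sum(ht)) * ht), 3, tolerance = 1e-12)
  expect_equal(sum((3 / sum(hd)) * hd), 3, tolerance = 1e-12)

  k2 <- odd_kernel(st_t, st_d2, strength = 6)
  expect_equal(k2$canonical, 2 * k1$canonical, tolerance = 1e-12)
  expect_equal(rescale_kernel(k1, 6)$canonical, k2$canonical,
               tolerance = 1e-12)

  empty <- make_stats(array(0, dim = c(D, D, Th, Th)), Th, R)
  expect_error(odd_kernel(empty, st_d2), "empty pair statistics")
})

test_that("8-bit quantization is symmetric and inverts within half an LSB", {
  set.seed(22)
  k <- toy_kernel(R = 5L, n_orient = 4L)
  # plant exact extremes so the code endpoints are observable
  mx <- max(abs(k$canonical)) * 1.25
  k$canonical[2, 2, 1] <- mx
  k$canonical[3, 3, 1] <- -mx
  kq <- quantize_kernel(k)
  expect_identical(kq$quantized$codes[which(k$canonical == 0)[1]], 128L)
  expect_identical(kq$quantized$codes[2, 2, 1], 255L)
  expect_identical(kq$quantized$codes[3, 3, 1], 1L)
  expect_true(all(kq$quantized$codes >= 0L & kq$quantized$codes <= 255L))
  back <- dequantize_kernel(kq)
  expect_lt(max(abs(back - k$canonical)), mx / 254)

  kz <- k; kz$canonical[] <- 0
  kzq <- quantize_kernel(kz)
  expect_true(all(kzq$quantized$codes == 128L))
  expect_identical(kzq$quantized$scale, 0)
  expect_true(all(dequantize_kernel(kzq) == 0))
})

test_that("bowtie geometry separates excitation and isotropic inhibition", {
  p <- bowtie_params(opening_angle = pi / 2, max_orient_diff = pi / 4,
                     sigma_exc = 8, sigma_inh = 8, strength = 2)
  R <- 16L
  kb <- bowtie_kernel(p, R = R, n_orient = 8L, angle_offset = 0)
  K <- kb$canonical
  ctr <- R + 1L

  # along the axis (dx > 0, dy = 0): excitatory for parallel orientations
  expect_gt(K[ctr, ctr + 6, 1], 0)
  # same offset, orientation difference beyond the limit: inhibitory
  expect_lt(K[ctr, ctr + 6, 4], 0)   # theta_rel = 3 * pi / 8 > pi / 4
  # inhibition is orientation-insensitive at equal |delta|
  expect_equal(K[ctr + 6, ctr, 4], K[ctr + 6, ctr, 5])
  # Gaussian falloff ratio between |d| = sigma and 2 sigma
  v1 <- K[ctr, ctr + 8, 1]; v2 <- K[ctr, ctr + 16, 1]
  expect_equal(v1 / v2, exp(1.5), tolerance = 1e-9)
  # equal-and-opposite normalization
  expect_equal(sum(K[K > 0]), 2, tolerance = 1e-9)
  expect_equal(sum(K), 0, tolerance = 1e-9)
})

test_that("kernels round-trip through serialization", {
  k <- toy_kernel()
  path <- withr::local_tempfile(fileext = ".rds")
  write_kernel(k, path)
  k2 <- read_kernel(path)
  expect_identical(k2$canonical, k$canonical)
  expect_identical(k2$rotated, k$rotated)
  expect_true(file.exists(paste0(path, ".json")))
})
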