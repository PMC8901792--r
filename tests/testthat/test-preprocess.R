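test_that("per-slice equalization preserves ranks and handles degenerate slices", {
  set.seed(1)
  a <- array(0, c(4, 12, 12))
  a[1, , ] <- 0.7                      # constant slice
  a[2, , ] <- matrix(runif(144), 12)   # generic slice
  a[3, , ] <- matrix(sample(a[2, , ]), 12) # same histogram, permuted
  a[4, 5:8, 5:8] <- runif(16) + 1      # slice with background zeros
  v <- equalize_slices(volume(a, 96))
  e <- v$data
  expect_true(all(e[1, , ] == 1))                       # constant maps to a constant
  expect_equal(sort(as.vector(e[2, , ])), sort(as.vector(e[3, , ])),
               tolerance = 1e-12)                       # histogram-determined
  expect_equal(cor(as.vector(a[2, , ]), as.vector(e[2, , ]),
                   method = "spearman"), 1)             # ranks preserved
  expect_equal(cor(as.vector(a[4, , ][a[4, , ] > 0]),
                   as.vector(e[4, , ][a[4, , ] > 0]),
                   method = "spearman"), 1)
  expect_true(all(e[4, , ][a[4, , ] == 0] == 0))        # background untouched
  expect_true(all(e >= 0 & e <= 1))
})

test_that("background suppression zeroes exactly the sub-threshold voxels", {
  a <- array(0, c(3, 3, 3))
  a[] <- seq(0.001, 0.027, by = 0.001) * 370 # max ~ 10
  a[1:5] <- c(0.01, 0.02, 0.05, 0.08, 0.09)  # 5 voxels below 0.01 * max
  v <- volume(a, 96)
  out <- suppress_background(v, 0.01)
  expect_equal(sum(out$data == 0) - sum(a == 0), 5)
  expect_true(all(out$data[out$data > 0] == a[out$data > 0]))
  expect_equal(suppress_background(v, 0)$data, a)        # frac 0 is a no-op
  # idempotence
  expect_equal(suppress_background(out, 0.01)$data, out$data)
  expect_error(suppress_background(volume(array(0, c(2, 2, 2)) + 0, 96)),
               "empty")
})

test_that("binarize thresholds strictly above frac * max and is idempotent", {
  set.seed(2)
  a <- array(runif(1000, 0, 100), c(10, 10, 10))
  v <- volume(a, 96)
  m <- binarize(v, 0.01)
  expect_identical(sort(unique(as.vector(m$data))), c(0, 1))
  expect_equal(sum(m$data), sum(a > 1))            # max 100, frac 0.01
  expect_equal(m$data, array(as.double(a > 0.01 * max(a)), dim(a)))
  m0 <- binarize(v, 0)
  expect_equal(m0$data, array(as.double(a > 0), dim(a)))
  expect_equal(binarize(m, 0.01)$data, m$data)     # idempotent on masks
  expect_error(binarize(volume(array(0, c(2, 2, 2)) + 0, 96)), "empty")
  expect_s3_class(binarize(v, method = "otsu"), "bw_mask")
})

test_that("PCA pre-alignment recovers orientation of ellipsoidal masks", {
  d <- c(48, 48, 48)
  mk <- function(rot = NULL) {
    ctr <- (d + 1) / 2
    idx <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
    p <- sweep(idx, 2, ctr)
    if (!is.null(rot)) p <- p %*% t(rot)
    inside <- (p[, 1] / 20)^2 + (p[, 2] / 12)^2 + (p[, 3] / 8)^2 <= 1
    a <- array(0, d)
    a[idx[inside, ]] <- 1
    v <- volume(a, 96)
    class(v) <- c("bw_mask", class(v))
    v
  }
  m0 <- mk()
  al <- pca_prealign(m0, reference = m0)
  R <- al$transform$rotation
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_equal(abs(R), diag(3), tolerance = 1e-6)  # identity up to signs

  # 30 degrees about Z (mixing y and x): recovered within 1 degree
  th <- 30 * pi / 180
  Rz <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  mr <- mk(rot = Rz) # body rotated by Rz^T in index space
  al2 <- pca_prealign(mr, reference = m0)
  ang <- acos(pmin(1, (sum(diag(al2$transform$rotation %*% t(Rz))) - 1) / 2))
  expect_lt(ang * 180 / pi, 1)
  expect_gt(cor(as.vector(al2$resampled$data), as.vector(m0$data)), 0.95)

  # perfect sphere: degenerate eigenvalues
  sph <- mk()
  idx <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  p <- sweep(idx, 2, (d + 1) / 2)
  a <- array(0, d); a[idx[rowSums(p^2) <= 15^2, ]] <- 1
  sphv <- volume(a, 96)
  expect_error(pca_prealign(sphv), "degenerate")
  expect_silent(pca_prealign(sphv, allow_degenerate = TRUE))
})

test_that("aligned masks return a near-identity transform", {
  m <- binarize(ellipsoid_volume(d = c(40, 40, 40), semi = c(16, 12, 8)),
                0.01)
  al <- pca_prealign(m, reference = m)
  expect_equal(abs(al$transform$rotation), diag(3), tolerance = 1e-6)
})

test_that("LoG contours match a direct spatial convolution on an impulse", {
  d <- c(24, 24, 24)
  a <- array(0, d); a[12, 12, 12] <- 1
  v <- volume(a, 96)
  out <- log_contours(v, radius_vox = 2)
  K <- brainwarp:::log_kernel(2)
  oracle <- abs(K) # impulse response is the kernel itself
  # same normalization as the implementation
  oracle_n <- oracle
  oracle_n[oracle_n < 1e-6 * max(oracle_n)] <- 0
  oracle_n <- oracle_n / mean(oracle_n[oracle_n > 0])
  got <- out$data[4:20, 4:20, 4:20]
  expect_lt(max(abs(got - oracle_n)) / max(oracle_n), 1e-6)
})

test_that("LoG normalization, degenerate cases and equivariance hold", {
  expect_true(all(log_contours(volume(array(1, c(16, 16, 16)), 96),
                               3)$data == 0))      # constant input
  v <- ellipsoid_volume(d = c(28, 28, 28), semi = c(9, 10, 11))
  ct <- log_contours(v, 3)$data
  expect_equal(mean(ct[ct > 0]), 1, tolerance = 1e-9)
  expect_error(log_contours(v, 20), "radius")
  # translation equivariance on interior voxels
  sh <- c(1, 2, 1)
  a2 <- array(0, dim(v$data))
  a2[(1 + sh[1]):28, (1 + sh[2]):28, (1 + sh[3]):28] <-
    v$data[1:(28 - sh[1]), 1:(28 - sh[2]), 1:(28 - sh[3])]
  c1 <- brainwarp:::fft_convolve_same(v$data, brainwarp:::log_kernel(2))
  c2 <- brainwarp:::fft_convolve_same(a2, brainwarp:::log_kernel(2))
  i <- 12:18
  expect_lt(max(abs(c2[i + sh[1], i + sh[2], i + sh[3]] - c1[i, i, i])),
            1e-6)
})

test_that("filtered image is mask plus contours, with provenance", {
  v <- ellipsoid_volume()
  m <- binarize(v, 0.01)
  ct <- log_contours(v, 3)
  f <- compose_filtered(m, ct)
  expect_s3_class(f, "bw_filtered")
  set.seed(3)
  idx <- cbind(sample(32, 100, TRUE), sample(32, 100, TRUE),
               sample(32, 100, TRUE))
  expect_equal(f$data[idx], m$data[idx] + ct$data[idx])
  zero <- as_volume(array(0, dim(v$data)), v)
  expect_equal(compose_filtered(m, zero)$data, m$data)
  expect_equal(compose_filtered(as_volume(zero$data, m), ct)$data, ct$data)
  bad <- as_volume(array(0, c(8, 8, 8)), v)
  expect_error(compose_filtered(m, bad), "shape")
})

test_that("contours sharpen the similarity peak against 1-voxel shifts", {
  # light-sheet stacks are smooth at the working resolution; emulate that by
  # blurring the tiered phantom before comparing raw vs filtered similarity
  v <- make_phantom(phantom_spec(noise_sd = 0), 2, seed = 1)$volume
  sg <- 4; R <- ceiling(3 * sg); gx <- seq(-R, R)
  G <- exp(-outer(outer(gx^2, gx^2, "+"), gx^2, "+") / (2 * sg^2))
  v$data <- brainwarp:::fft_convolve_same(v$data, G / sum(G))
  a2 <- array(0, dim(v$data))
  a2[, , 2:64] <- v$data[, , 1:63]
  v2 <- as_volume(a2, v)
  f1 <- preprocess_volume(v); f2 <- preprocess_volume(v2)
  raw_cor <- pearson_similarity(v, v2)
  filt_cor <- pearson_similarity(f1, f2)
  expect_lt(filt_cor, raw_cor)
})

test_that("preprocessing pipeline output satisfies the filtered-image invariants", {
  f <- preprocess_volume(make_phantom(phantom_spec(), 1, seed = 5)$volume)
  expect_gte(min(f$data), 0)
  expect_s3_class(f, "bw_filtered")
})
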