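test_that("grayscale conversion matches the scalar weighted-average oracle", {
  expect_equal(to_grayscale(array(0.37, c(3, 3, 3))), matrix(0.37, 3, 3))
  rgb <- array(0, c(2, 2, 3)); rgb[, , 1] <- 1
  expect_equal(to_grayscale(rgb), matrix(0.299, 2, 2))

  set.seed(31)
  img <- array(runif(5 * 6 * 3), c(5, 6, 3))
  got <- to_grayscale(img)
  for (i in 1:5) for (j in 1:6) {
    expect_equal(got[i, j],
                 0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] + 0.114 * img[i, j, 3],
                 tolerance = 1e-12)
  }
  expect_error(to_grayscale(img, weights = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("mean filter equals the brute-force windowed mean with reflect padding", {
  expect_equal(mean_filter(matrix(0.8, 10, 10), 7), matrix(0.8, 10, 10))

  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  got <- mean_filter(imp, 7)
  expect_equal(got[8:14, 8:14], matrix(1 / 49, 7, 7))
  expect_equal(got[11, 15], 0)

  set.seed(32)
  img <- matrix(runif(15 * 15), 15, 15)
  k <- 7L; p <- 3L
  idx <- c(p:1, 1:15, 15:(15 - p + 1))       # symmetric reflect padding
  pad <- img[idx, idx]
  oracle <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15)
    oracle[i, j] <- mean(pad[i:(i + k - 1), j:(j + k - 1)])
  expect_equal(mean_filter(img, k), oracle, tolerance = 1e-12)

  expect_error(mean_filter(img, 6), "odd")
  expect_error(mean_filter(matrix(1, 3, 3), 7), "exceeds")
})

test_that("Otsu threshold maximizes between-class variance (exhaustive oracle)", {
  otsu_oracle <- function(v, n_bins = 256L) {
    h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), nbins = n_bins)
    mids <- (seq_len(n_bins) - 0.5) / n_bins
    best <- 0; best_t <- 1
    for (i in seq_len(n_bins - 1L)) {
      w0 <- sum(h[1:i]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(h[1:i] * mids[1:i]) / w0
      m1 <- sum(h[(i + 1):n_bins] * mids[(i + 1):n_bins]) / w1
      bc <- (w0 / sum(h)) * (w1 / sum(h)) * (m0 - m1)^2
      if (bc > best) { best <- bc; best_t <- i / n_bins }
    }
    best_t
  }
  set.seed(33)
  for (rep in 1:5) {
    v <- c(rnorm(200, 0.25, 0.05), rnorm(120, 0.8, 0.06))
    v <- pmin(pmax(v, 0), 1)
    img <- matrix(v, 20)
    expect_equal(otsu_threshold(img), otsu_oracle(v), tolerance = 1e-12)
  }

  # two delta modes: everything at the high mode is foreground
  img <- matrix(rep(c(0.1, 0.9), each = 32), 8)
  m <- binarize(img, "otsu")
  expect_identical(m == 1L, img == 0.9)
})

test_that("binarize applies strict-above thresholding", {
  img <- matrix(c(0.2, 0.8, 0.8, 0.2), 2)
  m <- binarize(img, "fixed", threshold = 0.5)
  expect_identical(m, structure(matrix(c(0L, 1L, 1L, 0L), 2), threshold = 0.5))
  # a constant image has no valid split: empty foreground
  expect_identical(sum(binarize(matrix(0.5, 4, 4), "otsu")), 0L)
  expect_error(binarize(img, "fixed"), "requires")
})

test_that("connected components respect connectivity and minimum area", {
  # two blocks touching only at a corner
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[5:7, 5:7] <- 1L
  expect_length(extract_regions(m, min_area = 1, connectivity = 4), 2L)
  expect_length(extract_regions(m, min_area = 1, connectivity = 8), 1L)

  expect_identical(extract_regions(matrix(0L, 5, 5), min_area = 1), list())

  # area filter drops the single-pixel blob
  m2 <- matrix(0L, 8, 8); m2[2:4, 2:4] <- 1L; m2[7, 7] <- 1L
  expect_length(extract_regions(m2, min_area = 2), 1L)

  # regions come back row-major by centroid
  m3 <- matrix(0L, 12, 12)
  m3[9:10, 2:3] <- 1L   # lower-left
  m3[2:3, 8:9] <- 1L    # upper-right
  m3[2:3, 2:3] <- 1L    # upper-left
  rg <- extract_regions(m3, min_area = 1)
  cents <- t(vapply(rg, `[[`, numeric(2), "centroid"))
  expect_equal(order(cents[, 1], cents[, 2]), 1:3)
  expect_equal(cents[1, ], c(row = 2.5, col = 2.5))
})

test_that("seed cubes are cropped to bbox with off-mask voxels zeroed", {
  d <- c(6L, 20L, 20L)
  wl <- seq(400, 1000, length.out = 6)
  sig <- seq(0.2, 0.7, length.out = 6)
  arr <- array(0.01, d)
  mask <- matrix(0L, 20, 20)
  mask[5:12, 7:15] <- 1L
  for (b in 1:6) {
    plane <- arr[b, , ]
    plane[mask == 1L] <- sig[b]
    arr[b, , ] <- plane
  }
  scene <- hypercube(arr, wl)
  rg <- extract_regions(mask, min_area = 1)
  cubes <- extract_seed_cubes(scene, rg)
  expect_length(cubes, 1L)
  cb <- cubes[[1]]
  expect_identical(dim(cb$data), c(6L, 8L, 9L))
  inside <- rg[[1]]$mask == 1L
  for (b in 1:6)
    expect_equal(mean(cb$data[b, , ][inside]), sig[b])
  expect_true(all(matrix(cb$data, 6)[, !as.vector(inside)] == 0))

  # a region covering the whole scene crops to the scene itself
  full <- extract_seed_cubes(scene, extract_regions(matrix(1L, 20, 20)))[[1]]
  expect_equal(full$data, scene$data)

  bad <- rg
  bad[[1]]$bbox <- c(row0 = 15L, col0 = 15L, row1 = 30L, col1 = 30L)
  expect_error(extract_seed_cubes(scene, bad), "bounds")
})

test_that("standardize pads to square, resizes, and is idempotent", {
  wl <- seq(400, 1000, length.out = 16)

  cube <- hypercube(array(0.4, c(16, 32, 32)), wl)
  expect_identical(standardize(cube, target = c(16, 32, 32))$data, cube$data)

  # constant-valued ellipse: bilinear interpolation preserves the constant
  mask <- vdspec:::ellipse_mask(50, 18, 10)
  arr <- array(0, c(16, 50, 50))
  for (b in 1:16) arr[b, , ] <- 0.6 * mask
  out <- standardize(hypercube(arr, wl), target = c(16, 32, 32))
  expect_identical(dim(out$data), c(16L, 32L, 32L))
  expect_equal(out$data[3, 16, 16], 0.6, tolerance = 1e-9)
  expect_equal(max(out$data), 0.6, tolerance = 1e-9)

  # aspect ratio preserved through pad-to-square: 2:1 ellipse stays 2:1
  tall <- array(0, c(16, 80, 40))
  em <- vdspec:::ellipse_mask(80, 39, 39)[, seq(2, 80, by = 2)]  # 80 x 40 ellipse
  for (b in 1:16) tall[b, , ] <- em
  st <- standardize(hypercube(tall, wl), target = c(16, 32, 32))
  bwm <- st$data[1, , ] > 0.5
  rows <- range(which(rowSums(bwm) > 0))
  cols <- range(which(colSums(bwm) > 0))
  expect_equal(diff(rows) + 1, 2 * (diff(cols) + 1), tolerance = 0.12)

  expect_error(standardize(cube, target = c(20, 32, 32)), "bands")
  rs <- standardize(hypercube(array(0.4, c(16, 32, 32)), wl),
                    target = c(24, 32, 32), spectral_resample = TRUE)
  expect_identical(dim(rs$data), c(24L, 32L, 32L))
  expect_equal(unique(as.vector(rs$data)), 0.4)
})

test_that("full segmentation chain recovers every placed seed", {
  spec <- synthetic_spec(n_classes = 2, bands = 16, seed_patch = 16,
                         rng_seed = 5)
  sc <- make_scene(spec, n_seeds = 6, grid_shape = c(2, 3))
  corrected <- radiometric_correct(sc$scene, sc$refs)
  seg <- segment_scene(corrected, target = c(16, 16, 16), min_area = 10)
  expect_length(seg$samples, 6L)
  expect_true(all(vapply(seg$samples, function(s)
    identical(dim(s$data), c(16L, 16L, 16L)), logical(1))))
})
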