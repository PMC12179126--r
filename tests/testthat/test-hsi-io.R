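test_that("ENVI round trip is bit-exact for every interleave and dtype", {
  tmp <- withr::local_tempdir()
  for (seed in 1:3) {
    cube <- random_cube(d = 5L, h = 4L, w = 3L, seed = seed)
    for (il in c("bsq", "bil", "bip")) {
      path <- file.path(tmp, sprintf("c%d_%s.raw", seed, il))
      write_envi(cube, path, interleave = il, dtype = "float32")
      back <- read_envi(paste0(path, ".hdr"))
      # float32 quantizes; compare at single precision
      expect_equal(back$data, cube$data, tolerance = 1e-7)
      expect_identical(dim(back$data), dim(cube$data))
    }
  }
  # uint16 integer data round-trips exactly, including values above 2^15
  dn <- hypercube(array(sample.int(65535L, 60) - 1L, dim = c(5, 4, 3)),
                  seq(400, 1000, length.out = 5))
  p <- file.path(tmp, "dn.raw")
  write_envi(dn, p, interleave = "bil", dtype = "uint16")
  expect_identical(read_envi(paste0(p, ".hdr"))$data, dn$data)
})

test_that("interleaves agree: one array written three ways reads back identically", {
  tmp <- withr::local_tempdir()
  cube <- random_cube(d = 4L, h = 5L, w = 6L, seed = 9)
  got <- lapply(c("bsq", "bil", "bip"), function(il) {
    path <- file.path(tmp, paste0(il, ".raw"))
    write_envi(cube, path, interleave = il)
    read_envi(paste0(path, ".hdr"))$data
  })
  expect_equal(got[[1]], got[[2]])
  expect_equal(got[[1]], got[[3]])
})

test_that("wavelengths survive the header at full double precision", {
  tmp <- withr::local_tempdir()
  wl <- 400 + cumsum(c(0.31415926535897931, runif(4, 0.9, 1.1)))
  cube <- random_cube(d = 5L, seed = 2, wl = wl)
  path <- file.path(tmp, "wl.raw")
  write_envi(cube, path)
  expect_identical(read_envi(paste0(path, ".hdr"))$wavelengths, wl)
})

test_that("header validation catches missing fields and size mismatches", {
  tmp <- withr::local_tempdir()
  cube <- random_cube(seed = 3)
  path <- file.path(tmp, "bad.raw")
  write_envi(cube, path)
  hdr_path <- paste0(path, ".hdr")

  hdr <- readLines(hdr_path)
  writeLines(hdr[!grepl("^bands", hdr)], hdr_path)
  expect_error(read_envi(hdr_path), "bands")

  # header says 5 bands but binary holds 4 bands' worth of data
  writeLines(hdr, hdr_path)
  bin <- readBin(path, "raw", n = file.size(path))
  writeBin(bin[seq_len(4 * 4 * 3 * 4)], path)
  expect_error(read_envi(hdr_path), "mismatch")
})

test_that("missing wavelength block synthesizes a linear 400-1000 nm axis", {
  tmp <- withr::local_tempdir()
  cube <- random_cube(d = 5L, seed = 4)
  path <- file.path(tmp, "nowl.raw")
  write_envi(cube, path)
  hdr_path <- paste0(path, ".hdr")
  hdr <- readLines(hdr_path)
  writeLines(hdr[!grepl("^wavelength", hdr)], hdr_path)
  expect_warning(back <- read_envi(hdr_path), "wavelength")
  expect_equal(back$wavelengths, seq(400, 1000, length.out = 5))
})

test_that("black/white correction satisfies the calibration identities", {
  d <- c(6L, 5L, 4L)
  set.seed(11)
  wl <- seq(400, 1000, length.out = d[1])
  white <- hypercube(array(2500 + runif(prod(d), 0, 500), d), wl)
  dark <- hypercube(array(90 + runif(prod(d), 0, 20), d), wl)
  refs <- reference_frames(white, dark)

  expect_equal(radiometric_correct(white, refs)$data, array(1, d))
  expect_equal(radiometric_correct(dark, refs)$data, array(0, d))
  for (alpha in c(0.25, 0.5, 0.87)) {
    raw <- hypercube(dark$data + alpha * (white$data - dark$data), wl)
    expect_equal(radiometric_correct(raw, refs)$data, array(alpha, d),
                 tolerance = 1e-12)
  }
})

test_that("degenerate reference voxels are guarded to zero and flagged", {
  d <- c(3L, 4L, 4L)
  wl <- seq(400, 1000, length.out = 3)
  w_arr <- array(1000, d)
  b_arr <- array(100, d)
  w_arr[2, 1, 1] <- b_arr[2, 1, 1]   # dead pixel: W == B
  refs <- reference_frames(hypercube(w_arr, wl), hypercube(b_arr, wl))
  raw <- hypercube(array(600, d), wl)
  out <- radiometric_correct(raw, refs)
  expect_identical(out$data[2, 1, 1], 0)
  expect_identical(out$meta$n_guarded, 1L)
})

test_that("single scan-line references broadcast across scene rows", {
  d <- c(4L, 6L, 5L)
  wl <- seq(400, 1000, length.out = 4)
  set.seed(12)
  line_w <- array(3000 + runif(4 * 5, 0, 100), c(4, 1, 5))
  line_b <- array(100 + runif(4 * 5, 0, 5), c(4, 1, 5))
  full_w <- array(line_w[, rep(1, 6), ], d)
  full_b <- array(line_b[, rep(1, 6), ], d)
  raw <- hypercube(array(runif(prod(d), 200, 2000), d), wl)
  out_line <- radiometric_correct(
    raw, reference_frames(hypercube(line_w, wl), hypercube(line_b, wl)))
  out_full <- radiometric_correct(
    raw, reference_frames(hypercube(full_w, wl), hypercube(full_b, wl)))
  expect_equal(out_line$data, out_full$data)
})

test_that("mismatched or suspect references are rejected or flagged", {
  wl4 <- seq(400, 1000, length.out = 4)
  wl5 <- seq(400, 1000, length.out = 5)
  w4 <- hypercube(array(1000, c(4, 2, 2)), wl4)
  b5 <- hypercube(array(100, c(5, 2, 2)), wl5)
  expect_error(reference_frames(w4, b5), "band counts")

  # white below dark on a quarter of voxels -> flagged with a warning
  b4 <- array(100, c(4, 2, 2))
  b4[, , 1] <- 2000
  expect_warning(refs <- reference_frames(w4, hypercube(b4, wl4)), "flagged")
  expect_true(refs$meta$suspect_reference)

  raw5 <- hypercube(array(500, c(5, 2, 2)), wl5)
  refs4 <- reference_frames(w4, hypercube(array(100, c(4, 2, 2)), wl4))
  expect_error(radiometric_correct(raw5, refs4), "bands")
})

test_that("pseudo-RGB picks nearest bands with lower-wavelength tie-break", {
  set.seed(21)
  planes <- array(runif(6 * 8 * 7), c(6, 8, 7))
  scale01 <- function(m) (m - min(m)) / (max(m) - min(m))

  # axis containing the exact composite wavelengths
  wl <- c(470, 500, 550, 600, 640, 700)
  cube <- hypercube(planes, wl)
  rgb <- pseudo_rgb(cube)
  expect_equal(rgb[, , 1], scale01(planes[5, , ]))  # 640
  expect_equal(rgb[, , 2], scale01(planes[3, , ]))  # 550
  expect_equal(rgb[, , 3], scale01(planes[1, , ]))  # 470

  # 639.4 is nearer to 640 than 640.7; an exact tie goes to the lower band
  wl2 <- c(469, 471, 549.5, 600, 639.4, 640.7)
  rgb2 <- pseudo_rgb(hypercube(planes, wl2))
  expect_equal(rgb2[, , 1], scale01(planes[5, , ]))
  expect_equal(rgb2[, , 3], scale01(planes[1, , ]))  # 469 vs 471: tie -> 469

  expect_error(pseudo_rgb(hypercube(planes[1:3, , ], c(400, 450, 500))),
               "no band within")

  const <- hypercube(array(0.5, c(6, 3, 3)), wl)
  expect_equal(pseudo_rgb(const), array(0, c(3, 3, 3)))
})

test_that("hypercube invariants are enforced", {
  expect_error(hypercube(array(1, c(3, 2, 2)), c(500, 450, 400)), "increasing")
  expect_error(hypercube(array(1, c(3, 2, 2)), c(400, 500)), "3 bands")
  expect_error(hypercube(matrix(1, 2, 2), c(400, 500)), "3-axis")
})
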