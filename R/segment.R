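#' Weighted-average grayscale conversion
#'
#' Collapses a 3-channel composite to grayscale with the ITU-R BT.601 luma
#' weights 0.299/0.587/0.114 by default. Custom weights must sum to 1.
#'
#' @param rgb `H x W x 3` array with channels in \[0, 1\].
#' @param weights length-3 numeric summing to 1 within 1e-9.
#' @return an `H x W` matrix.
#' @export
to_grayscale <- function(rgb, weights = c(0.299, 0.587, 0.114)) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("`rgb` must be an H x W x 3 array")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("grayscale weights must sum to 1")
  weights[1] * rgb[, , 1] + weights[2] * rgb[, , 2] + weights[3] * rgb[, , 3]
}

#' Mean filter with reflect padding
#'
#' Smooths an image with a k x k arithmetic-mean window (default 7 x 7, the
#' standard pre-threshold denoising size). Borders use symmetric (reflect)
#' padding, so the filter is exact at every pixel. Implemented separably via
#' running means along rows then columns.
#'
#' @param img numeric matrix.
#' @param k odd window size, `k <= min(dim(img))`.
#' @return a matrix of the same dimension.
#' @export
mean_filter <- function(img, k = 7L) {
  if (!is.matrix(img)) stop("`img` must be a matrix")
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("mean filter window `k` must be odd")
  if (k > min(dim(img))) stop("`k` exceeds image dimensions")
  p <- (k - 1L) %/% 2L
  run <- function(m) {
    # symmetric padding along rows of m, then centered running mean per column
    if (p > 0L) m <- m[c(p:1, seq_len(nrow(m)), nrow(m):(nrow(m) - p + 1L)), ,
                       drop = FALSE]
    f <- stats::filter(m, rep(1 / k, k), sides = 2)
    matrix(f[(p + 1L):(nrow(m) - p), ], ncol = ncol(m))
  }
  t(run(t(run(img))))
}

#' Otsu threshold from a 256-bin histogram
#'
#' Returns the threshold maximizing between-class variance over the 255
#' interior bin boundaries of a 256-bin histogram of \[0, 1\] intensities.
#' On ties the lowest boundary wins. Pixels are classified foreground when
#' strictly above the threshold, so a constant image yields an empty
#' foreground.
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param n_bins histogram resolution. Default 256.
#' @return the threshold, a scalar in \[0, 1\].
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  if (any(v < 0 | v > 1)) stop("`img` values must lie in [0, 1]")
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), nbins = n_bins)
  n <- length(v)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(h)[-n_bins] / n
  mu0 <- cumsum(h * mids)[-n_bins] / n
  mu_t <- sum(h * mids) / n
  w1 <- 1 - w0
  between <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu0)^2 / (w0 * w1), 0)
  if (max(between) == 0) return(1)  # no valid split (constant image): nothing is foreground
  which.max(between) / n_bins  # boundary of the best split bin
}

#' Binarize a grayscale image
#'
#' Foreground is every pixel strictly above the threshold, found either by
#' [otsu_threshold] (`method = "otsu"`) or supplied directly
#' (`method = "fixed"`).
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold required when `method = "fixed"`.
#' @return an integer 0/1 matrix with attribute `"threshold"`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(img),
    fixed = {
      if (is.null(threshold)) stop("method = 'fixed' requires `threshold`")
      threshold
    })
  mask <- matrix(as.integer(img > thr), nrow = nrow(img))
  attr(mask, "threshold") <- thr
  mask
}

#' Extract seed regions from a binary mask
#'
#' Labels connected foreground components (4- or 8-connectivity), drops
#' components below `min_area` pixels, and returns the survivors sorted
#' row-major by centroid (top-to-bottom, then left-to-right), which gives
#' deterministic per-seed identifiers for tray layouts.
#'
#' @param mask integer 0/1 matrix.
#' @param min_area minimum component area in pixels. Default 50.
#' @param connectivity 4 or 8 (default), the pixel adjacency rule.
#' @return a list of `seed_region` objects with fields `bbox`
#'   (`(row0, col0, row1, col1)`, half-open), `mask` (0/1 patch), `area`,
#'   `centroid`.
#' @export
extract_regions <- function(mask, min_area = 50L, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "integer"
  lab <- .label_components(mask, as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  regions <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    patch <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    patch[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1L
    regions[[length(regions) + 1L]] <- structure(
      list(bbox = c(row0 = r0, col0 = c0, row1 = r1 + 1L, col1 = c1 + 1L),
           mask = patch, area = nrow(idx),
           centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2]))),
      class = "seed_region")
  }
  cents <- t(vapply(regions, `[[`, numeric(2), "centroid"))
  regions[order(cents[, 1], cents[, 2])]
}

#' Crop per-seed hypercubes from a scene
#'
#' For each region, crops all bands to the region's bounding box and zeroes
#' voxels outside the region mask, isolating one seed per cube.
#'
#' @param scene a [hypercube].
#' @param regions list of `seed_region` from [extract_regions].
#' @return a list of [hypercube]s, one per region.
#' @export
extract_seed_cubes <- function(scene, regions) {
  stopifnot(is_hypercube(scene))
  d <- dim(scene$data)
  lapply(regions, function(rg) {
    b <- rg$bbox
    if (b["row0"] < 1L || b["col0"] < 1L || b["row1"] > d[2L] + 1L ||
        b["col1"] > d[3L] + 1L)
      stop("region out of scene bounds")
    crop <- scene$data[, b["row0"]:(b["row1"] - 1L), b["col0"]:(b["col1"] - 1L),
                       drop = FALSE]
    off <- rg$mask == 0L
    if (any(off)) {
      zero <- array(rep(as.vector(off), each = d[1L]), dim = dim(crop))
      crop[zero] <- 0
    }
    hypercube(crop, scene$wavelengths,
              meta = list(bbox = rg$bbox, area = rg$area, centroid = rg$centroid))
  })
}

#' Standardize a seed cube to fixed dimensions
#'
#' Spatially pads each band to a square (seed centered) then bilinearly
#' resizes to the target height/width, preserving the seed's aspect ratio.
#' The band count must already equal the target depth unless
#' `spectral_resample = TRUE`, in which case spectra are first linearly
#' interpolated onto a uniform axis of the target length.
#'
#' @param seed_cube a [hypercube] for a single seed.
#' @param target integer triple `(D, H, W)`. Default `c(462, 100, 100)`, the
#'   conventional standardized sample size at full spectral resolution.
#' @param spectral_resample interpolate along wavelength when the band count
#'   differs from `target[1]`. Default `FALSE`.
#' @return a [hypercube] of dimension `target`.
#' @export
standardize <- function(seed_cube, target = c(462L, 100L, 100L),
                        spectral_resample = FALSE) {
  stopifnot(is_hypercube(seed_cube), length(target) == 3L)
  d <- dim(seed_cube$data)
  x <- seed_cube$data
  wl <- seed_cube$wavelengths
  if (d[1L] != target[1L]) {
    if (!spectral_resample)
      stop(sprintf("cube has %d bands but target depth is %d (set spectral_resample = TRUE to interpolate)",
                   d[1L], target[1L]))
    wl_new <- seq(min(wl), max(wl), length.out = target[1L])
    x <- apply(x, c(2, 3), function(s) stats::approx(wl, s, xout = wl_new)$y)
    wl <- wl_new
    d <- dim(x)
  }
  if (identical(as.integer(d), as.integer(target)))
    return(hypercube(x, wl, meta = seed_cube$meta))
  side <- max(d[2L], d[3L])
  pr <- (side - d[2L]) %/% 2L
  pc <- (side - d[3L]) %/% 2L
  sq <- array(0, dim = c(d[1L], side, side))
  sq[, pr + seq_len(d[2L]), pc + seq_len(d[3L])] <- x
  out <- array(0, dim = as.integer(target))
  for (b in seq_len(d[1L])) {
    out[b, , ] <- EBImage::resize(sq[b, , ], w = target[2L], h = target[3L],
                                  filter = "bilinear")
  }
  hypercube(out, wl, meta = seed_cube$meta)
}

#' Run the full segmentation chain on a corrected scene
#'
#' Pseudo-RGB composite, grayscale, mean filter, threshold, connected
#' components, per-seed crop, standardization — the complete route from a
#' reflectance scene to a list of standardized per-seed cubes.
#'
#' @param scene a corrected reflectance [hypercube].
#' @param target standardized cube dimensions `(D, H, W)`.
#' @param method,threshold thresholding rule, see [binarize].
#' @param k mean-filter window. Default 7.
#' @param min_area,connectivity component filtering, see [extract_regions].
#' @return list with `samples` (standardized [hypercube]s), `regions`,
#'   `mask`, and `threshold`.
#' @export
segment_scene <- function(scene, target = c(n_bands(scene), 100L, 100L),
                          method = "otsu", threshold = NULL, k = 7L,
                          min_area = 50L, connectivity = 8L) {
  rgb <- pseudo_rgb(scene)
  gray <- to_grayscale(rgb)
  smooth <- mean_filter(gray, k = k)
  mask <- binarize(smooth, method = method, threshold = threshold)
  regions <- extract_regions(mask, min_area = min_area,
                             connectivity = connectivity)
  cubes <- extract_seed_cubes(scene, regions)
  samples <- lapply(cubes, standardize, target = target)
  list(samples = samples, regions = regions, mask = mask,
       threshold = attr(mask, "threshold"))
}
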