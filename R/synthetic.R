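#' Synthetic hyperspectral seed-data specification
#'
#' Describes the generator that emulates the statistical structure of a
#' seed-variety hyperspectral dataset: a shared smooth reflectance baseline,
#' class-discriminative Gaussian bumps confined to specific spectral windows
#' (the regions where variety spectra visibly differ, by default 500-550 nm
#' and 600-700 nm), a single multiplicative per-seed intensity scalar as the
#' within-class variation, additive voxel noise, and elliptical seeds on a
#' dark background.
#'
#' Defaults are desk-scale (64 bands, 32 x 32 standardized seeds) so a full
#' train/search experiment runs on one CPU core; 462 x 100 x 100 is
#' supported by overriding `bands` and `seed_patch`.
#'
#' @param n_classes number of varieties. Default 8.
#' @param seeds_per_class seeds generated per variety. Default 100.
#' @param bands spectral bands. Default 64.
#' @param wl_range wavelength range in nm. Default `c(400, 1000)`.
#' @param windows list of per-window `c(center, width)` nm pairs; each class
#'   receives one bump per window at a class-specific center offset.
#' @param amplitude bump amplitude in reflectance units. Default 0.08,
#'   comparable to typical between-variety spectral separation.
#' @param informative_span width of the discriminative signal in contiguous
#'   bands; bumps are truncated to this span around their center. NULL
#'   (default) leaves bumps untruncated.
#' @param intensity_jitter_sd sd of the per-seed multiplicative scalar
#'   (drawn once per seed). Default 0.10.
#' @param noise_sd sd of additive per-voxel noise. Default 0.05.
#' @param seed_patch spatial size of a standardized seed cube. Default 32.
#' @param axes_range range of ellipse semi-axes as a fraction of the patch.
#' @param rng_seed integer generator seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 8L, seeds_per_class = 100L, bands = 64L,
                           wl_range = c(400, 1000),
                           windows = list(c(525, 50), c(650, 100)),
                           amplitude = 0.08, informative_span = NULL,
                           intensity_jitter_sd = 0.10, noise_sd = 0.05,
                           seed_patch = 32L, axes_range = c(0.22, 0.38),
                           rng_seed = 1L) {
  stopifnot(n_classes >= 1L, seeds_per_class >= 1L, bands >= 4L,
            amplitude >= 0, intensity_jitter_sd >= 0, noise_sd >= 0)
  for (w in windows)
    if (w[1] < wl_range[1] || w[1] > wl_range[2])
      stop("window center outside the wavelength range")
  structure(list(n_classes = as.integer(n_classes),
                 seeds_per_class = as.integer(seeds_per_class),
                 bands = as.integer(bands), wl_range = wl_range,
                 windows = windows, amplitude = amplitude,
                 informative_span = informative_span,
                 intensity_jitter_sd = intensity_jitter_sd,
                 noise_sd = noise_sd, seed_patch = as.integer(seed_patch),
                 axes_range = axes_range, rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Wavelength axis of a synthetic spec
#' @param spec a [synthetic_spec].
#' @return numeric vector of band-center wavelengths in nm.
#' @export
spec_wavelengths <- function(spec) {
  seq(spec$wl_range[1], spec$wl_range[2], length.out = spec$bands)
}

#' Per-class reflectance signatures
#'
#' Every class shares a smooth low-order polynomial baseline; class identity
#' enters only as Gaussian bumps inside the configured spectral windows, with
#' class-specific center offsets and signs of spacing so signatures differ in
#' shape, not scale. With `informative_span` set, each bump is zeroed outside
#' the span of contiguous bands around its center, confining all class signal
#' to exactly that many bands per window. Deterministic given the spec.
#'
#' @param spec a [synthetic_spec].
#' @return matrix `n_classes x bands` of reflectance values in (0, 1.2).
#' @export
make_class_signatures <- function(spec) {
  wl <- spec_wavelengths(spec)
  u <- (wl - spec$wl_range[1]) / diff(spec$wl_range)
  baseline <- 0.25 + 0.45 * u - 0.15 * u^2          # smooth rising reflectance
  sig <- matrix(rep(baseline, each = spec$n_classes),
                nrow = spec$n_classes)
  if (spec$amplitude > 0 && spec$n_classes > 1L) {
    step_nm <- diff(spec$wl_range) / (spec$bands - 1L)
    for (wi in seq_along(spec$windows)) {
      ctr <- spec$windows[[wi]][1]
      wid <- spec$windows[[wi]][2]
      for (cl in seq_len(spec$n_classes)) {
        if (is.null(spec$informative_span)) {
          # class-specific center offset inside the window, alternating sign:
          # classes differ in curve shape, emulating distinct variety spectra
          off <- (cl - 1 - (spec$n_classes - 1) / 2) / max(1, spec$n_classes - 1)
          c_nm <- ctr + off * wid * 0.8
          s_nm <- wid / 4
          sgn <- if ((cl + wi) %% 2L == 0L) 1 else -1
          sig[cl, ] <- sig[cl, ] +
            sgn * spec$amplitude * exp(-(wl - c_nm)^2 / (2 * s_nm^2))
        } else {
          # span mode: one shared center, class signal = per-class coefficient
          # on a bump truncated to exactly `informative_span` contiguous bands
          c_nm <- wl[nearest_band(wl, ctr)]
          half <- (spec$informative_span - 1) / 2
          s_nm <- spec$informative_span * step_nm / 4
          bump <- exp(-(wl - c_nm)^2 / (2 * s_nm^2))
          bump[abs(wl - c_nm) > (half + 0.5) * step_nm] <- 0
          coef <- if (spec$n_classes == 1L) 1 else
            2 * (cl - 1) / (spec$n_classes - 1) - 1
          sig[cl, ] <- sig[cl, ] + coef * spec$amplitude * bump
        }
      }
    }
  }
  pmin(pmax(sig, 1e-3), 1.2)
}

# Elliptical 0/1 mask centered in an n x n patch with semi-axes (a, b) in
# pixels and a small rotation.
ellipse_mask <- function(n, a, b, theta = 0) {
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n) - ctr, n, n)
  cc <- t(rr)
  x <- cos(theta) * cc + sin(theta) * rr
  y <- -sin(theta) * cc + cos(theta) * rr
  matrix(as.integer((x / a)^2 + (y / b)^2 <= 1), n, n)
}

#' Generate one standardized synthetic seed sample
#'
#' An elliptical seed (random axes and orientation) on a near-zero
#' background. Inside the mask each voxel's spectrum is the class signature
#' times one per-seed scalar `s ~ Normal(1, intensity_jitter_sd)` (drawn once
#' per seed, encoding intensity-only within-class variation), plus
#' independent `Normal(0, noise_sd)` voxel noise, clipped at 0.
#'
#' @param class_id 0-based class index.
#' @param spec a [synthetic_spec].
#' @param signatures optional precomputed [make_class_signatures] matrix.
#' @return a sample list: `cube` ([hypercube]), `label`, `source`, `scale`.
#' @export
make_seed_cube <- function(class_id, spec, signatures = NULL) {
  stopifnot(class_id >= 0L, class_id < spec$n_classes)
  if (is.null(signatures)) signatures <- make_class_signatures(spec)
  n <- spec$seed_patch
  ax <- stats::runif(2, spec$axes_range[1], spec$axes_range[2]) * n
  mask <- ellipse_mask(n, ax[1], ax[2], stats::runif(1, 0, pi))
  s <- 1 + stats::rnorm(1, 0, spec$intensity_jitter_sd)
  cube <- array(0, dim = c(spec$bands, n, n))
  inside <- which(mask == 1L)
  sigv <- signatures[class_id + 1L, ] * s
  vox <- matrix(sigv, spec$bands, length(inside)) +
    if (spec$noise_sd > 0)
      matrix(stats::rnorm(spec$bands * length(inside), 0, spec$noise_sd),
             spec$bands, length(inside))
    else 0
  flat <- matrix(cube, spec$bands, n * n)
  flat[, inside] <- pmax(vox, 0)
  cube <- array(flat, dim = c(spec$bands, n, n))
  list(cube = hypercube(cube, spec_wavelengths(spec),
                        meta = list(synthetic = TRUE)),
       label = as.integer(class_id), source = "synthetic", scale = s,
       mask = mask)
}

#' Generate a full labeled synthetic dataset
#'
#' `n_classes x seeds_per_class` standardized seed samples, bit-reproducible
#' given `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec].
#' @return list of samples as produced by [make_seed_cube].
#' @export
make_dataset <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$rng_seed)
  signatures <- make_class_signatures(spec)
  out <- vector("list", spec$n_classes * spec$seeds_per_class)
  i <- 0L
  for (cl in seq_len(spec$n_classes) - 1L) {
    for (s in seq_len(spec$seeds_per_class)) {
      i <- i + 1L
      out[[i]] <- make_seed_cube(cl, spec, signatures)
      out[[i]]$source <- sprintf("synthetic/class%d/seed%d", cl, s)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Generate a tray scene with calibration frames
#'
#' Places seeds at disjoint grid cells (random sub-cell offsets) on a dark
#' background, then encodes the reflectance scene as raw digital numbers
#' `I0 = B + R (W - B)` using a white frame with a mild smooth spatial
#' gradient and a noisy low dark frame, so that [radiometric_correct]
#' recovers the reflectance exactly.
#'
#' @param spec a [synthetic_spec]; `seed_patch` sets the grid cell size.
#' @param n_seeds total seeds to place, class-balanced round-robin.
#' @param grid_shape `c(rows, cols)` of cells; capacity must cover `n_seeds`.
#' @return list with `scene` (raw-DN [hypercube]), `refs`
#'   ([reference_frames]), `reflectance` (ground-truth [hypercube]),
#'   `truth` (data.frame of bbox, class, area per placed seed), and
#'   `truth_mask` (H x W integer matrix labeling each seed's pixels by its
#'   seed index).
#' @export
make_scene <- function(spec, n_seeds = 8L, grid_shape = c(2L, 4L)) {
  if (n_seeds > prod(grid_shape)) stop("grid capacity below n_seeds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$rng_seed)
  cell <- spec$seed_patch + 8L            # margin keeps seeds separated
  Hs <- grid_shape[1] * cell
  Ws <- grid_shape[2] * cell
  refl <- array(pmax(stats::rnorm(spec$bands * Hs * Ws, 0.02, 0.005), 0),
                dim = c(spec$bands, Hs, Ws))
  signatures <- make_class_signatures(spec)
  truth <- NULL
  truth_mask <- matrix(0L, Hs, Ws)   # 0 = background, i = seed index i
  cells <- expand.grid(gr = seq_len(grid_shape[1]), gc = seq_len(grid_shape[2]))
  for (i in seq_len(n_seeds)) {
    cl <- (i - 1L) %% spec$n_classes
    sm <- make_seed_cube(cl, spec, signatures)
    patch <- sm$cube$data
    np <- spec$seed_patch
    r0 <- (cells$gr[i] - 1L) * cell + sample.int(cell - np, 1L)
    c0 <- (cells$gc[i] - 1L) * cell + sample.int(cell - np, 1L)
    sel <- sm$mask == 1L
    block <- refl[, r0 + seq_len(np), c0 + seq_len(np)]
    keep <- array(rep(as.vector(sel), each = spec$bands), dim = dim(patch))
    block[keep] <- patch[keep]
    refl[, r0 + seq_len(np), c0 + seq_len(np)] <- block
    truth_mask[r0 + seq_len(np), c0 + seq_len(np)][sel] <- i
    truth <- rbind(truth, data.frame(
      row0 = r0 + 1L, col0 = c0 + 1L, row1 = r0 + np + 1L, col1 = c0 + np + 1L,
      class = cl, area = sum(sel), seed_index = i))
  }
  wl <- spec_wavelengths(spec)
  # white: flat high DN with a smooth +-5% spatial gradient; dark: low noisy DN
  grad <- outer(seq(0.95, 1.05, length.out = Hs),
                seq(0.97, 1.03, length.out = Ws))
  white <- array(0, dim = c(spec$bands, Hs, Ws))
  for (b in seq_len(spec$bands)) white[b, , ] <- 3000 * grad
  dark <- array(100 + stats::rnorm(spec$bands * Hs * Ws, 0, 2),
                dim = c(spec$bands, Hs, Ws))
  scene_dn <- dark + refl * (white - dark)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(scene = hypercube(scene_dn, wl, meta = list(synthetic = TRUE, units = "DN")),
       refs = reference_frames(hypercube(white, wl), hypercube(dark, wl)),
       reflectance = hypercube(refl, wl),
       truth = truth, truth_mask = truth_mask)
}
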