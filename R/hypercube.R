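#' Construct a hyperspectral cube
#'
#' A `hypercube` is the package's in-memory representation of a hyperspectral
#' image: a band-major numeric array of dimension `(D, H, W)` (spectral bands,
#' image rows, image columns) with a strictly increasing per-band wavelength
#' axis in nanometres. Band-major layout keeps the spectral axis contiguous,
#' which is the axis the variable-depth convolution slides along.
#'
#' @param data numeric array with `dim` of length 3, ordered (bands, rows, cols).
#' @param wavelengths numeric vector of length `dim(data)[1]`, strictly
#'   increasing, in nanometres.
#' @param meta named list of free-form acquisition metadata (interleave,
#'   dtype tag, description, processing flags).
#' @return an object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-axis array (bands, rows, cols)")
  storage.mode(data) <- "double"
  d <- dim(data)
  if (any(d < 1L)) stop("all cube dimensions must be >= 1")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != d[1L])
    stop(sprintf("wavelength axis has length %d but cube has %d bands",
                 length(wavelengths), d[1L]))
  if (d[1L] > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d bands x %d rows x %d cols, %.1f-%.1f nm\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Number of spectral bands of a hypercube
#' @param cube a `hypercube`.
#' @return integer band count.
#' @export
n_bands <- function(cube) dim(cube$data)[1L]

is_hypercube <- function(x) inherits(x, "hypercube")

#' Bundle white and dark calibration frames
#'
#' The white frame is a scan of a standard reflectance panel, the dark frame a
#' lens-capped acquisition capturing dark current. Both must share the target
#' cube's band count; spatially they may be full frames or a single scan line
#' (rows = 1) that is broadcast across the scene during correction. If the
#' white frame does not exceed the dark frame on at least 99% of voxels the
#' pair is flagged (`meta$suspect_reference`) with a warning, since such
#' references produce unstable reflectance.
#'
#' @param white a `hypercube`, the standard-white calibration scan.
#' @param dark a `hypercube`, the dark-field calibration scan.
#' @return an object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  stopifnot(is_hypercube(white), is_hypercube(dark))
  if (n_bands(white) != n_bands(dark))
    stop("white and dark references have different band counts")
  if (!isTRUE(all.equal(white$wavelengths, dark$wavelengths)))
    stop("white and dark references have different wavelength axes")
  suspect <- FALSE
  if (identical(dim(white$data), dim(dark$data))) {
    frac_ok <- mean(white$data >= dark$data)
    if (frac_ok < 0.99) {
      warning(sprintf("white < dark on %.1f%% of voxels; reference pair flagged",
                      100 * (1 - frac_ok)))
      suspect <- TRUE
    }
  }
  structure(list(white = white, dark = dark,
                 meta = list(suspect_reference = suspect)),
            class = "reference_frames")
}
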