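#' Black/white radiometric correction
#'
#' Converts raw digital numbers to relative reflectance using a standard-white
#' panel scan W and a dark-current scan B:
#' \deqn{I = (I_0 - B) / (W - B)}
#' applied element-wise. Voxels where `|W - B| < guard` (dead or saturated
#' reference pixels) are set to 0 and their count is recorded in
#' `meta$n_guarded` rather than raising an error.
#'
#' References may be full frames matching the scene spatially, or single scan
#' lines (rows = 1, same column count) which are replicated across scene rows,
#' as produced by line-scan calibration.
#'
#' @param raw a [hypercube] of raw digital numbers.
#' @param refs a [reference_frames] pair sharing the scene's band axis.
#' @param guard small positive number below which the denominator is treated
#'   as degenerate. Default `1e-6`.
#' @return a reflectance [hypercube], typically valued in \[0, ~1.1\].
#' @export
radiometric_correct <- function(raw, refs, guard = 1e-6) {
  stopifnot(is_hypercube(raw), inherits(refs, "reference_frames"))
  d <- dim(raw$data)
  if (n_bands(refs$white) != d[1L])
    stop(sprintf("reference has %d bands but scene has %d",
                 n_bands(refs$white), d[1L]))
  w <- expand_reference(refs$white$data, d)
  b <- expand_reference(refs$dark$data, d)
  denom <- w - b
  bad <- abs(denom) < guard
  denom[bad] <- 1
  out <- (raw$data - b) / denom
  out[bad] <- 0
  hypercube(out, raw$wavelengths,
            meta = c(raw$meta, list(corrected = TRUE, n_guarded = sum(bad))))
}

# Broadcast a reference frame to scene dims: accepts a full (D,H,W) frame or
# a single scan line (D,1,W).
expand_reference <- function(ref, d) {
  rd <- dim(ref)
  if (identical(rd, d)) return(ref)
  if (rd[1L] == d[1L] && rd[2L] == 1L && rd[3L] == d[3L]) {
    return(array(ref[, rep(1L, d[2L]), , drop = FALSE], dim = d))
  }
  stop(sprintf(
    "reference dims (%s) are neither the scene dims (%s) nor a single scan line",
    paste(rd, collapse = "x"), paste(d, collapse = "x")))
}

#' Pseudo-RGB composite from a hypercube
#'
#' Builds the 3-channel composite used for seed segmentation by picking, for
#' each target wavelength, the band nearest to it (ties broken toward the
#' lower wavelength). The defaults 640/550/470 nm are the conventional ENVI
#' true-colour composite bands. Each channel is min-max scaled to \[0, 1\]
#' over the scene; a constant channel scales to all zeros.
#'
#' @param cube a [hypercube].
#' @param targets_nm length-3 numeric, target wavelengths for the R, G, B
#'   channels in that order.
#' @param max_offset_nm maximum tolerated distance between a target and its
#'   nearest band before erroring. Default 25 nm.
#' @return an `H x W x 3` array with values in \[0, 1\].
#' @export
pseudo_rgb <- function(cube, targets_nm = c(640, 550, 470), max_offset_nm = 25) {
  stopifnot(is_hypercube(cube), length(targets_nm) == 3L)
  idx <- vapply(targets_nm, function(t) nearest_band(cube$wavelengths, t),
                integer(1))
  off <- abs(cube$wavelengths[idx] - targets_nm)
  if (any(off > max_offset_nm))
    stop(sprintf("no band within %g nm of target %g nm (nearest: %g nm)",
                 max_offset_nm, targets_nm[which.max(off)],
                 cube$wavelengths[idx[which.max(off)]]))
  d <- dim(cube$data)
  out <- array(0, dim = c(d[2L], d[3L], 3L))
  for (ch in 1:3) {
    plane <- cube$data[idx[ch], , ]
    rng <- range(plane)
    out[, , ch] <- if (rng[2] > rng[1]) (plane - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out
}

# Index of the band nearest to target; on an exact distance tie the lower
# wavelength wins (which.min picks the first of an increasing axis).
nearest_band <- function(wavelengths, target) {
  which.min(abs(wavelengths - target))
}
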