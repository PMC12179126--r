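#' Read an ENVI-format hyperspectral cube
#'
#' Parses the ASCII `.hdr` file and the raw binary companion and returns a
#' band-major [hypercube] regardless of the on-disk interleave (`bsq`, `bil`
#' or `bip`). Supported data types are ENVI code 4 (32-bit float) and 12
#' (unsigned 16-bit integer). When the header carries no `wavelength` block a
#' linear 400-1000 nm axis is synthesized with a warning, matching the usual
#' VNIR acquisition range.
#'
#' @param header_path path to the `.hdr` file. The binary companion is the
#'   same path without the `.hdr` extension (or `.raw`/`.dat`/`.img` beside it).
#' @return a [hypercube].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- parse_envi_header(header_path)
  for (f in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(hdr[[f]]))
      stop(sprintf("ENVI header missing mandatory field '%s'", f))
  }
  samples <- as.integer(hdr$samples)   # image columns
  lines   <- as.integer(hdr$lines)     # image rows
  bands   <- as.integer(hdr$bands)
  dtype   <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", interleave)
  bin_path <- envi_binary_path(header_path)
  if (is.null(bin_path)) stop("companion binary file not found for ", header_path)

  n <- as.double(samples) * lines * bands
  bytes <- switch(as.character(dtype), "4" = 4L, "12" = 2L,
                  stop("unsupported ENVI data type code: ", dtype))
  actual <- file.size(bin_path)
  if (actual != n * bytes)
    stop(sprintf("binary size mismatch: header implies %.0f bytes, file has %.0f",
                 n * bytes, actual))
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- if (dtype == 4L) {
    readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  } else {
    readBin(con, what = "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  }
  # Reorder on-disk layout -> (bands, rows, cols).
  arr <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines, bands)), c(3, 2, 1)),
    bil = aperm(array(v, dim = c(samples, bands, lines)), c(2, 3, 1)),
    bip = aperm(array(v, dim = c(bands, samples, lines)), c(1, 3, 2)))
  wl <- hdr$wavelength
  if (is.null(wl)) {
    warning("header has no wavelength block; synthesizing a linear 400-1000 nm axis")
    wl <- seq(400, 1000, length.out = bands)
  } else {
    wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
    if (length(wl) != bands)
      stop("wavelength block length does not match band count")
  }
  hypercube(arr, wl, meta = list(interleave = interleave, dtype = dtype,
                                 description = hdr$description))
}

#' Write a hypercube as an ENVI header + binary pair
#'
#' Round-trips exactly with [read_envi] for the supported data types: 32-bit
#' float (`dtype = "float32"`, lossless for data already stored at single
#' precision and for integer-valued DNs) and unsigned 16-bit integer
#' (`dtype = "uint16"`, requires integer-valued data in \[0, 65535\]).
#'
#' @param cube a [hypercube].
#' @param path output path of the binary file; the header is `<path>.hdr`.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param dtype `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       dtype = c("float32", "uint16")) {
  stopifnot(is_hypercube(cube))
  interleave <- match.arg(interleave)
  dtype <- match.arg(dtype)
  d <- dim(cube$data)
  a <- switch(interleave,
    bsq = aperm(cube$data, c(3, 2, 1)),
    bil = aperm(cube$data, c(3, 1, 2)),
    bip = aperm(cube$data, c(1, 3, 2)))
  v <- as.vector(a)
  con <- file(path, "wb")
  if (dtype == "float32") {
    writeBin(v, con, size = 4L, endian = "little")
    code <- 4L
  } else {
    if (any(v < 0 | v > 65535 | v != round(v))) {
      close(con)
      stop("uint16 output requires integer values in [0, 65535]")
    }
    writeBin(as.integer(v), con, size = 2L, endian = "little")
    code <- 12L
  }
  close(con)
  hdr <- c(
    "ENVI",
    "description = {written by vdspec}",
    sprintf("samples = %d", d[3]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[1]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, digits = 17, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# ENVI headers are "key = value" lines; values in {...} may span lines.
parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list()
  pat <- gregexpr("(?m)^[ \t]*([a-zA-Z][a-zA-Z0-9 _]*?)[ \t]*=[ \t]*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)[[1]]
  if (pat[1] == -1) return(out)
  starts <- as.integer(pat)
  lens <- attr(pat, "match.length")
  cstarts <- attr(pat, "capture.start")
  clens <- attr(pat, "capture.length")
  for (i in seq_along(starts)) {
    key <- tolower(trimws(substr(txt, cstarts[i, 1], cstarts[i, 1] + clens[i, 1] - 1)))
    val <- trimws(substr(txt, cstarts[i, 2], cstarts[i, 2] + clens[i, 2] - 1))
    out[[key]] <- val
  }
  out
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  cands <- c(base, paste0(base, c(".raw", ".dat", ".img")))
  for (p in cands) if (file.exists(p) && !identical(p, header_path)) return(p)
  NULL
}
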