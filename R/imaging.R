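#' Hyperspectral image cube
#'
#' A rows x cols x bands reflectance array with its wavelength grid. The
#' imaging spectrometer emulated here delivers 300 channels over 400-1000 nm
#' at about 2.1 nm resolution; reflectance is dimensionless in \[0, 1\].
#'
#' @param reflectance 3-D numeric array (rows, cols, bands), non-negative.
#' @param wavelengths Strictly ascending band centers (nm), length equal to
#'   the third array dimension.
#' @return Object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(reflectance, wavelengths) {
  if (length(dim(reflectance)) != 3L)
    stop2("cube: reflectance must be a rows x cols x bands array")
  if (dim(reflectance)[3] != length(wavelengths))
    stop2("cube: number of bands must match length(wavelengths)")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop2("cube: wavelengths must be strictly increasing")
  if (any(reflectance < 0))
    stop2("cube: negative reflectance after ingestion")
  structure(list(reflectance = reflectance,
                 wavelengths = as.numeric(wavelengths)),
            class = "hyperspectral_cube")
}

#' @export
wavelengths.hyperspectral_cube <- function(x) x$wavelengths

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("Hyperspectral cube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

nearest_band <- function(wl, target) which.min(abs(wl - target))

## ---------------------------------------------------------------------------
## ENVI container: flat binary cube + text header. Header keys follow the
## standard: samples (cols), lines (rows), bands, data type (4 = float32,
## 5 = float64), interleave (bsq/bil/bip), byte order (0 little, 1 big),
## wavelength = { ... }.
## ---------------------------------------------------------------------------

#' Write a cube in ENVI format
#'
#' @param cube A [hyperspectral_cube()].
#' @param header_path Path of the `.hdr` header file; the binary goes to the
#'   same path without the `.hdr` extension.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return The header path, invisibly.
#' @export
write_envi_cube <- function(cube, header_path, interleave = c("bsq", "bil", "bip"),
                            data_type = 5) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4, 5)) stop2("envi: data type must be 4 or 5")
  d <- dim(cube$reflectance)
  rows <- d[1]; cols <- d[2]; bands <- d[3]
  data_path <- sub("\\.hdr$", "", header_path)
  if (identical(data_path, header_path)) data_path <- paste0(header_path, ".dat")
  # reorder to the requested interleave; fastest-varying dimension first
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vec <- as.vector(aperm(cube$reflectance, perm))
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(vec, con, size = if (data_type == 4) 4L else 8L, endian = "little")
  hdr <- c(
    "ENVI",
    "description = { synthetic maize leaf cube }",
    paste0("samples = ", cols),
    paste0("lines = ", rows),
    paste0("bands = ", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = Nanometers"),
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                 collapse = ", "), " }")
  )
  writeLines(hdr, header_path)
  invisible(header_path)
}

parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else m[2]
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave") %||% "bsq"),
    byte_order = as.integer(get_scalar("byte order") %||% "0"),
    offset = as.integer(get_scalar("header offset") %||% "0"),
    wavelength = {
      blk <- get_block("wavelength")
      if (is.null(blk)) NULL
      else as.numeric(strsplit(gsub("\\s", "", blk), ",")[[1]])
    }
  )
}

#' Read an ENVI cube
#'
#' Accepts BSQ, BIL and BIP interleaves, float32/float64 data, either byte
#' order. The wavelength list must be present in the header: without it the
#' cube is unusable downstream (NDVI band lookup, band selection), so its
#' absence is a format error.
#'
#' @param header_path Path to the `.hdr` file; the binary is looked up at the
#'   same path without `.hdr` (or with `.dat` appended).
#' @return A [hyperspectral_cube()].
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path)) stop2("envi: header not found: ", header_path)
  h <- parse_envi_header(header_path)
  if (is.null(h$wavelength))
    stop2("envi: header lacks the wavelength field")
  if (anyNA(c(h$samples, h$lines, h$bands)))
    stop2("envi: header lacks samples/lines/bands")
  if (!h$data_type %in% c(4L, 5L))
    stop2("envi: unsupported data type ", h$data_type)
  if (length(h$wavelength) != h$bands)
    stop2("envi: wavelength list length does not match bands")
  data_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(data_path)) data_path <- paste0(header_path, ".dat")
  if (!file.exists(data_path)) stop2("envi: binary file not found")
  n <- h$samples * h$lines * h$bands
  size <- if (h$data_type == 4L) 4L else 8L
  expected <- h$offset + n * size
  if (file.info(data_path)$size < expected)
    stop2("envi: binary smaller than header-implied shape")
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", h$offset)
  vec <- readBin(con, "numeric", n = n, size = size,
                 endian = if (h$byte_order == 1L) "big" else "little")
  if (length(vec) != n) stop2("envi: interleave/shape mismatch")
  arr <- switch(h$interleave,
    bsq = aperm(array(vec, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vec, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vec, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stop2("envi: unknown interleave ", h$interleave)
  )
  hyperspectral_cube(arr, h$wavelength)
}

#' NDVI map of a cube
#'
#' Per pixel, `NDVI = (r_nir - r_red) / (r_nir + r_red)` with the reflectance
#' taken at the channels nearest to the requested near-infrared and red
#' wavelengths (780 and 660 nm by default; the 2.1 nm grid has no exact
#' channel at either). Pixels with `r_nir + r_red == 0` are defined as 0:
#' fully dark pixels are never leaf.
#'
#' @param cube A [hyperspectral_cube()].
#' @param nir_nm,red_nm Requested wavelengths (nm).
#' @return Object of class `ndvi_map`: `values` (rows x cols, in \[-1, 1\]),
#'   `nir_band_index`, `red_band_index`.
#' @export
ndvi_map <- function(cube, nir_nm = 780, red_nm = 660) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  wl <- cube$wavelengths
  if (length(wl) < 2) stop2("ndvi: cube has too few bands")
  rng <- range(wl)
  if (nir_nm < rng[1] || nir_nm > rng[2] || red_nm < rng[1] || red_nm > rng[2])
    warning("ndvi: requested wavelength outside the grid; using nearest channel")
  i_nir <- nearest_band(wl, nir_nm)
  i_red <- nearest_band(wl, red_nm)
  d <- dim(cube$reflectance)
  nir <- matrix(cube$reflectance[, , i_nir], d[1], d[2])
  red <- matrix(cube$reflectance[, , i_red], d[1], d[2])
  denom <- nir + red
  vals <- ifelse(denom == 0, 0, (nir - red) / denom)
  structure(list(values = vals, nir_band_index = i_nir,
                 red_band_index = i_red),
            class = "ndvi_map")
}

#' Segment leaf pixels by NDVI threshold
#'
#' Keeps pixels with NDVI strictly above the threshold (default 0); ties are
#' background.
#'
#' @param ndvi An [ndvi_map()].
#' @param threshold NDVI cutoff.
#' @return Object of class `leaf_mask`: `keep` (logical matrix), `n_pixels`.
#' @export
segment_leaf <- function(ndvi, threshold = 0) {
  stopifnot(inherits(ndvi, "ndvi_map"))
  keep <- ndvi$values > threshold
  structure(list(keep = keep, n_pixels = sum(keep)), class = "leaf_mask")
}

#' Mean leaf spectrum over a mask
#'
#' Per-band arithmetic mean of the reflectance over the masked pixels; this
#' is the spectrum a leaf sample contributes to the modeling table. An empty
#' mask signals a failed acquisition and is an error.
#'
#' @param cube A [hyperspectral_cube()].
#' @param mask A [segment_leaf()] mask (or logical matrix).
#' @return Numeric vector, one mean reflectance per band.
#' @export
extract_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  keep <- if (inherits(mask, "leaf_mask")) mask$keep else mask
  d <- dim(cube$reflectance)
  if (!identical(dim(keep), d[1:2]))
    stop2("extract_mean_spectrum: mask shape does not match cube")
  if (!any(keep))
    stop2("extract_mean_spectrum: empty segmentation (no leaf pixels)")
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  colMeans(flat[as.vector(keep), , drop = FALSE])
}

#' Export a leaf mask as plain text
#'
#' Writes the mask as an ASCII grid of 0/1 for quick visual inspection.
#'
#' @param mask A [segment_leaf()] mask.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mask_ascii <- function(mask, path) {
  stopifnot(inherits(mask, "leaf_mask"))
  lines <- apply(mask$keep, 1, function(r) paste(as.integer(r), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
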