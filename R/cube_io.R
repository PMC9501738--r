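#' Construct a spectral cube
#'
#' A spectral cube is a rows x cols x bands numeric array with a strictly
#' increasing wavelength axis (nm) and a `kind` flag saying whether the
#' values are raw sensor counts or calibrated reflectance.
#'
#' @param values 3-D numeric array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   length equal to `dim(values)[3]`, strictly increasing and finite.
#' @param kind `"raw_counts"` or `"reflectance"`.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths,
                          kind = c("raw_counts", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    stopf("wavelength axis length (%d) does not match band count (%d)",
          length(wavelengths), dim(values)[3L])
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stopf("wavelengths must be finite")
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths = wavelengths, kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

# ENVI dialect used throughout: ASCII ".hdr" with samples/lines/bands/
# interleave/data type/byte order/wavelength keys; little-endian flat
# binary. data type 12 = unsigned 16-bit, 4 = 32-bit float.
envi_dtypes <- list(`4`  = list(what = "numeric", size = 4L),
                    `12` = list(what = "integer", size = 2L))

#' Write a cube as an ENVI-style header + flat binary pair
#'
#' @param cube a [spectral_cube()].
#' @param header_path path of the `.hdr` file; the binary is written next to
#'   it with the `.hdr` extension stripped (or `.img` appended).
#' @param interleave `"bil"`, `"bip"` or `"bsq"`.
#' @param data_type ENVI data-type code: 4 (32-bit float) or 12 (unsigned
#'   16-bit integer). Values are truncated to integers for type 12.
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bil", "bip", "bsq"),
                       data_type = 4L) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, "spectral_cube"))
  dt <- envi_dtypes[[as.character(data_type)]]
  if (is.null(dt)) stopf("unsupported ENVI data type %s", data_type)
  d <- dim(cube$values)           # rows (lines), cols (samples), bands
  bin_path <- envi_binary_path(header_path, must_exist = FALSE)
  # file order, fastest index first:
  #   bsq: sample, line, band ; bil: sample, band, line ; bip: band, sample, line
  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),
                 bil = c(2L, 3L, 1L),
                 bip = c(3L, 2L, 1L))
  v <- as.vector(aperm(cube$values, perm))
  if (data_type == 12L) {
    if (any(v < 0 | v > 65535))
      stopf("values outside [0, 65535] cannot be stored as unsigned 16-bit")
    writeBin(as.integer(round(v)), bin_path, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), bin_path, size = 4L, endian = "little")
  }
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength units = nm"),
           sprintf("wavelength = { %s }",
                   paste(format(cube$wavelengths, trim = TRUE), collapse = ", ")))
  writeLines(hdr, header_path)
  invisible(header_path)
}

envi_binary_path <- function(header_path, must_exist = TRUE) {
  stem <- sub("\\.hdr$", "", header_path)
  candidates <- c(stem, paste0(stem, ".img"), paste0(stem, ".dat"))
  if (!must_exist) return(candidates[1L])
  hit <- candidates[file.exists(candidates)]
  if (!length(hit)) stopf("no binary file found next to header '%s'", header_path)
  hit[1L]
}

parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*(\\S+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(m) < 2)
    stopf("header '%s' has no wavelength block", header_path)
  wl <- as.numeric(strsplit(m[2], "[,\n]")[[1]])
  wl <- wl[!is.na(wl)]
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type")),
       interleave = tolower(get_scalar("interleave")),
       byte_order = as.integer(get_scalar("byte order")),
       wavelengths = wl)
}

#' Read an ENVI-style cube
#'
#' Supports BIL/BIP/BSQ interleaves, data types 4 (float32) and 12 (uint16),
#' little-endian byte order, and requires a `wavelength = { ... }` block in
#' the header. `read_envi(write_envi(cube))` is the identity for supported
#' types.
#'
#' @param header_path path to the `.hdr` file.
#' @param kind value kind of the stored cube (not recorded by the format).
#' @return A [spectral_cube()].
#' @export
read_envi <- function(header_path, kind = c("raw_counts", "reflectance")) {
  kind <- match.arg(kind)
  h <- parse_envi_header(header_path)
  if (anyNA(c(h$samples, h$lines, h$bands)))
    stopf("header '%s' is missing samples/lines/bands", header_path)
  if (!h$interleave %in% c("bil", "bip", "bsq"))
    stopf("unsupported interleave '%s'", h$interleave)
  dt <- envi_dtypes[[as.character(h$data_type)]]
  if (is.null(dt)) stopf("unsupported ENVI data type %s", h$data_type)
  if (length(h$wavelengths) != h$bands)
    stopf("header declares %d bands but lists %d wavelengths",
          h$bands, length(h$wavelengths))
  n <- h$samples * h$lines * h$bands
  bin_path <- envi_binary_path(header_path)
  expect_bytes <- n * dt$size
  if (file.info(bin_path)$size != expect_bytes)
    stopf("binary '%s' has %d bytes, header implies %d (corrupt pair?)",
          bin_path, file.info(bin_path)$size, expect_bytes)
  v <- readBin(bin_path, what = dt$what, n = n, size = dt$size,
               signed = dt$size > 2L, endian = "little")
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines))
  perm <- switch(h$interleave,
                 bsq = c(2L, 1L, 3L),
                 bil = c(3L, 1L, 2L),
                 bip = c(3L, 2L, 1L))
  arr <- aperm(array(as.numeric(v), dims), perm)
  spectral_cube(arr, h$wavelengths, kind = kind)
}

# Broadcast a reference frame to the cube's rows x cols x bands shape.
# Accepted shapes: length-bands vector (flat-field reference), cols x bands
# matrix (line-scan per-column reference), or a full 3-D frame.
broadcast_ref <- function(ref, dims, name) {
  if (inherits(ref, "spectral_cube")) ref <- ref$values
  if (is.null(dim(ref))) {
    if (length(ref) != dims[3L])
      stopf("`%s` vector length %d does not match %d bands",
            name, length(ref), dims[3L])
    return(aperm(array(ref, dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L)))
  }
  if (length(dim(ref)) == 2L) {
    if (!all(dim(ref) == dims[2:3]))
      stopf("`%s` matrix must be cols x bands (%d x %d)",
            name, dims[2L], dims[3L])
    return(aperm(array(ref, c(dims[2L], dims[3L], dims[1L])), c(3L, 1L, 2L)))
  }
  if (length(dim(ref)) == 3L) {
    if (!all(dim(ref) == dims))
      stopf("`%s` 3-D frame shape does not match the cube", name)
    return(ref)
  }
  stopf("`%s` must be a vector, matrix or 3-D array", name)
}

#' White/dark reflectance calibration
#'
#' Converts raw counts to relative reflectance with the standard two-point
#' correction \deqn{I_C = (I_{raw} - I_{dark}) / (I_{white} - I_{dark})}
#' where the white reference is a near-100%-reflectance tile and the dark
#' reference is acquired with the lens capped. Output is clipped to
#' \[0, 1.5\] (specular pixels can legitimately exceed 1).
#'
#' @param raw a [spectral_cube()] of kind `"raw_counts"`.
#' @param white,dark reference frames: a length-bands vector, a
#'   cols x bands matrix (line-scan references), or a full 3-D array;
#'   broadcast across the missing axes.
#' @param clip upper clipping bound for reflectance.
#' @return A [spectral_cube()] of kind `"reflectance"` with the same
#'   wavelength axis.
#' @export
calibrate <- function(raw, white, dark, clip = 1.5) {
  stopifnot(inherits(raw, "spectral_cube"))
  if (raw$kind != "raw_counts")
    stopf("`raw` must be a raw_counts cube, got kind '%s'", raw$kind)
  d <- dim(raw$values)
  w <- broadcast_ref(white, d, "white")
  k <- broadcast_ref(dark, d, "dark")
  denom <- w - k
  if (any(denom <= 0)) {
    bad <- sort(unique(which(denom <= 0, arr.ind = TRUE)[, 3L]))
    stopf("white - dark is not positive in band(s) %s (0-based: %s)",
          paste(bad, collapse = ", "), paste(bad - 1L, collapse = ", "))
  }
  refl <- (raw$values - k) / denom
  refl[refl < 0] <- 0
  refl[refl > clip] <- clip
  spectral_cube(refl, raw$wavelengths, kind = "reflectance")
}
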