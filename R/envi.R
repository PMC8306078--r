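# ENVI header + flat-binary and multi-page TIFF cube I/O.
#
# ENVI layout conventions: `samples` = image columns, `lines` = rows;
# binary order is BSQ (sample, line, band), BIL (sample, band, line) or
# BIP (band, sample, line), fastest index first. In memory the package
# always stores rows x cols x bands.

envi_dtype <- function(code) {
  switch(as.character(code),
    "4" = list(what = "numeric", size = 4L, signed = TRUE),
    "5" = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported ENVI data type code: ", code,
         " (supported: 4 float32, 5 float64, 12 uint16)")
  )
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header: ", path)
  fields <- list()
  # match either key = { possibly multi-line block } or key = value
  pat <- "(?m)^([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- trimws(sub("=.*$", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[tolower(key)]] <- val
  }
  fields
}

envi_brace_numbers <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Write a hyperspectral cube
#'
#' `dialect = "ENVI"` writes a text header (`<path>.hdr`) plus a flat
#' binary file in the requested interleave and data type. `dialect =
#' "TIFF"` writes a multi-page 32-bit float TIFF with the wavelength grid
#' in a plain-text sidecar (`<path>.wavelengths.txt`).
#'
#' @param cube A [hypercube()].
#' @param path Output path for the binary/TIFF file.
#' @param dialect `"ENVI"` or `"TIFF"`.
#' @param interleave ENVI interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 (float32), 5 (float64,
#'   lossless for R doubles) or 12 (uint16; values must already be
#'   integers in 0..65535).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("ENVI", "TIFF"),
                       interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  dialect <- match.arg(dialect)
  d <- dim(cube$data)
  if (dialect == "TIFF") {
    pages <- lapply(seq_len(d[3]), function(j) cube$data[, , j])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    wl_path <- paste0(path, ".wavelengths.txt")
    writeLines(c(paste("region", cube$region),
                 format(cube$wavelengths, trim = TRUE)), wl_path)
    return(invisible(path))
  }
  interleave <- match.arg(interleave)
  dt <- envi_dtype(data_type)
  perm <- switch(interleave,
    bsq = c(2, 1, 3), bil = c(2, 3, 1), bip = c(3, 2, 1)
  )
  vals <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    if (any(vals < 0 | vals > 65535)) {
      stop("uint16 output requires values in 0..65535")
    }
    # writeBin has no unsigned 16-bit mode; reinterpret via two bytes
    writeBin(as.integer(vals), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = { hyperpls cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("region = %s", cube$region),
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read a hyperspectral cube
#'
#' Accepts the ENVI interleaves BSQ, BIL and BIP and normalises them to
#' the in-memory `rows x cols x bands` layout. The header must declare a
#' wavelength list whose length matches the band count.
#'
#' @param path Path to the ENVI binary (with `<path>.hdr` alongside) or
#'   the TIFF file (with `<path>.wavelengths.txt` alongside).
#' @param dialect `"ENVI"` or `"TIFF"`.
#' @return A [hypercube()].
#' @export
read_cube <- function(path, dialect = c("ENVI", "TIFF")) {
  dialect <- match.arg(dialect)
  if (dialect == "TIFF") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    wl_path <- paste0(path, ".wavelengths.txt")
    if (!file.exists(wl_path)) {
      stop("missing wavelength metadata: ", wl_path)
    }
    lines <- readLines(wl_path)
    region <- sub("^region\\s+", "", lines[1])
    wl <- as.numeric(lines[-1])
    if (length(wl) != length(pages)) {
      stop(sprintf(
        "TIFF has %d pages but %d wavelengths are listed",
        length(pages), length(wl)
      ))
    }
    data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (j in seq_along(pages)) data[, , j] <- pages[[j]]
    return(hypercube(data, wl, region))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- need[!need %in% names(h)]
  if (length(miss)) {
    stop("ENVI header lacks fields: ", paste(miss, collapse = ", "))
  }
  cols <- as.integer(h[["samples"]]); rows <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header declares no wavelength list; cannot build a cube")
  }
  wl <- envi_brace_numbers(h[["wavelength"]])
  if (length(wl) != bands) {
    stop(sprintf(
      "header declares %d bands but lists %d wavelengths",
      bands, length(wl)
    ))
  }
  dt <- envi_dtype(h[["data type"]])
  n <- rows * cols * bands
  expected_bytes <- n * dt$size
  found_bytes <- file.size(path)
  if (found_bytes != expected_bytes) {
    stop(sprintf(
      "binary size mismatch: expected %d bytes (%d x %d x %d, %d bytes/value), found %d",
      expected_bytes, rows, cols, bands, dt$size, found_bytes
    ))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- if (dt$what == "integer") {
    as.numeric(readBin(con, integer(), n = n, size = dt$size,
                       signed = dt$signed, endian = "little"))
  } else {
    readBin(con, numeric(), n = n, size = dt$size, endian = "little")
  }
  interleave <- tolower(h[["interleave"]])
  data <- switch(interleave,
    bsq = aperm(array(vals, dim = c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(bands, cols, rows)), c(3, 2, 1)),
    stop("unknown interleave: ", interleave)
  )
  region <- if (!is.null(h[["region"]])) h[["region"]] else "VIS-NIR"
  hypercube(data, wl, region)
}

#' Write / read a fruit mask
#'
#' Masks travel as PNG (black background, white fruit).
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
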