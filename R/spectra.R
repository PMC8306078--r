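#' Construct an evenly spaced wavelength grid
#'
#' Builds the inclusive arithmetic grid `start, start + step, ..., stop`
#' used to index spectra and hyperspectral cubes. The two push-broom sensor
#' grids used throughout the package are `make_wavelength_grid(400, 1000, 5)`
#' (VIS-NIR, 121 variables) and `make_wavelength_grid(900, 1700, 5)`
#' (NIR, 161 variables).
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm); must exceed `start`.
#' @param step Grid spacing (nm); `stop - start` must be an integer
#'   multiple of `step`.
#' @return Numeric vector of wavelengths of length `(stop - start)/step + 1`.
#' @examples
#' length(make_wavelength_grid(400, 1000, 5)) # 121
#' length(make_wavelength_grid(900, 1700, 5)) # 161
#' @export
make_wavelength_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (stop <= start) stop("`stop` must be greater than `start`")
  if (step <= 0) stop("`step` must be positive")
  n_steps <- (stop - start) / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop(sprintf(
      "wavelength range %g-%g nm is not divisible by step %g nm",
      start, stop, step
    ))
  }
  seq(start, stop, by = step)
}

#' Sample-by-wavelength spectrum collection
#'
#' Thin wrapper around a numeric matrix (rows = samples, columns =
#' wavelengths) carrying its wavelength grid and a sensor-region tag.
#' All model fitting functions accept either a `spectrum_set` or a plain
#' matrix plus a wavelength vector.
#'
#' @param x Numeric matrix, samples in rows.
#' @param wavelengths Numeric vector, one entry per column of `x`,
#'   strictly increasing.
#' @param region Sensor region tag, `"VIS-NIR"` or `"NIR"` (free text
#'   is tolerated for non-standard instruments).
#' @return A matrix of class `spectrum_set` with attributes `wavelengths`
#'   and `region`.
#' @export
spectrum_set <- function(x, wavelengths, region = "VIS-NIR") {
  x <- as.matrix(x)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(x) != length(wavelengths)) {
    stop(sprintf(
      "matrix has %d columns but %d wavelengths were supplied",
      ncol(x), length(wavelengths)
    ))
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  colnames(x) <- format(wavelengths, trim = TRUE)
  structure(x,
    wavelengths = wavelengths, region = region,
    class = c("spectrum_set", class(x))
  )
}

#' Wavelength grid of a spectrum set or cube
#' @param x A `spectrum_set` or `hypercube`.
#' @return Numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(x) {
  if (inherits(x, "hypercube")) return(x$wavelengths)
  w <- attr(x, "wavelengths")
  if (is.null(w)) stop("object carries no wavelength grid")
  w
}

#' @export
print.spectrum_set <- function(x, ...) {
  w <- attr(x, "wavelengths")
  cat(sprintf(
    "<spectrum_set> %d samples x %d wavelengths (%g-%g nm, %s)\n",
    nrow(x), ncol(x), min(w), max(w), attr(x, "region")
  ))
  invisible(x)
}

# Subsetting keeps the wavelength grid in step with the columns.
#' @export
`[.spectrum_set` <- function(x, i, j, ..., drop = FALSE) {
  w <- attr(x, "wavelengths")
  region <- attr(x, "region")
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) {
    wj <- if (missing(j)) w else w[j]
    return(spectrum_set(y, wj, region))
  }
  y
}

# Internal: accept spectrum_set or matrix + wavelengths, return plain list.
as_spectra <- function(x, wl = NULL) {
  if (inherits(x, "spectrum_set")) {
    list(x = unclass(x), wavelengths = attr(x, "wavelengths"),
         region = attr(x, "region"))
  } else {
    x <- as.matrix(x)
    if (is.null(wl)) wl <- seq_len(ncol(x))
    list(x = x, wavelengths = as.numeric(wl), region = NA_character_)
  }
}
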