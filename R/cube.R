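#' Hyperspectral cube container
#'
#' A reflectance cube is stored as a `rows x cols x bands` array with the
#' band index on the last axis and a strictly increasing wavelength grid.
#'
#' @param data Numeric array `rows x cols x bands`, finite.
#' @param wavelengths Numeric vector, length equal to the band count.
#' @param region Sensor region tag.
#' @param mask Optional logical `rows x cols` matrix (fruit = TRUE).
#' @return A list of class `hypercube` with elements `data`,
#'   `wavelengths`, `region`, `mask`.
#' @export
hypercube <- function(data, wavelengths, region = "VIS-NIR", mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("cube data must be a 3-d array")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths)) {
    stop(sprintf(
      "cube has %d bands but %d wavelengths were supplied",
      dim(data)[3], length(wavelengths)
    ))
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (!all(is.finite(data))) stop("cube data must be finite")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(data)[1:2])) {
      stop("mask shape must match the cube's spatial shape")
    }
    storage.mode(mask) <- "logical"
  }
  structure(
    list(data = data, wavelengths = wavelengths, region = region,
         mask = mask),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d pixels, %d bands (%g-%g nm, %s)%s\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$region,
    if (is.null(x$mask)) "" else sprintf(", mask: %d px", sum(x$mask))
  ))
  invisible(x)
}

#' Render one sample of a synthetic batch as a hyperspectral cube
#'
#' Places an elliptical fruit on a dark background. Fruit pixels carry the
#' sample's Beer-Lambert spectrum modulated by a smooth radial
#' concentration field (core-to-skin gradient) whose spatial mean over the
#' fruit mask equals the sample's nominal concentration exactly; all
#' constituent concentrations share the field. Background pixels carry
#' low-reflectance sensor noise. The ground-truth mask and per-pixel
#' concentration fields are stored for parameter-recovery tests.
#'
#' @param batch A `synthetic_batch` from [mix_spectra()].
#' @param sample Row index of the sample to render.
#' @param shape Integer vector `c(rows, cols)`.
#' @param axes Ellipse semi-axes in pixels, `c(row_semi_axis,
#'   col_semi_axis)`; the ellipse must fit inside the frame.
#' @param center Ellipse center `c(row, col)`; defaults to the frame
#'   center.
#' @param modulation Relative amplitude of the radial concentration field
#'   (0 = spatially uniform fruit).
#' @param background_reflectance Mean reflectance of the dark background.
#' @return A [hypercube()] with `mask` set to the ground-truth fruit mask
#'   and an extra element `truth` holding the per-pixel concentration
#'   field (named list of `rows x cols` matrices), the nominal
#'   concentrations and the noiseless sample spectrum.
#' @export
generate_cube <- function(batch, sample = 1L,
                          shape = c(48L, 64L), axes = c(14, 20),
                          center = NULL, modulation = 0.15,
                          background_reflectance = 0.02) {
  stopifnot(inherits(batch, "synthetic_batch"))
  cfg <- batch$config
  grid <- wavelengths(batch$spectra)
  p <- length(grid)
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  if (is.null(center)) center <- c((rows + 1) / 2, (cols + 1) / 2)
  b_ax <- axes[1]; a_ax <- axes[2] # row / col semi-axes
  if (center[1] - b_ax < 1 || center[1] + b_ax > rows ||
      center[2] - a_ax < 1 || center[2] + a_ax > cols) {
    stop(sprintf(
      "ellipse with semi-axes (%g, %g) at center (%g, %g) exceeds the %d x %d frame",
      b_ax, a_ax, center[1], center[2], rows, cols
    ))
  }
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  rho2 <- ((rr - center[1]) / b_ax)^2 + ((cc - center[2]) / a_ax)^2
  mask <- rho2 <= 1

  # zero-mean radial shape over the mask -> spatial mean equals nominal
  g <- -rho2
  g[!mask] <- 0
  g[mask] <- g[mask] - mean(g[mask])
  field <- 1 + modulation * g

  cons <- cfg$constituents
  c_nom <- as.numeric(batch$concentrations[sample, cons])
  names(c_nom) <- cons
  D <- batch$truth$design
  bg <- batch$truth$background
  base <- as.numeric(baseline_basis(grid) %*% batch$truth$baseline_coef[sample, ])

  n_fruit <- sum(mask)
  # per-pixel absorbance for fruit pixels: scaled concentrations
  A_px <- (field[mask] %o% as.numeric(D %*% c_nom)) +
    matrix(bg + base, n_fruit, p, byrow = TRUE)
  R_fruit <- 10^(-A_px)

  set.seed(cfg$seed + 1000L + as.integer(sample))
  data <- array(0, dim = c(rows, cols, p))
  noise <- if (cfg$noise_sd > 0) {
    array(stats::rnorm(rows * cols * p, 0, cfg$noise_sd),
          dim = c(rows, cols, p))
  } else {
    array(0, dim = c(rows, cols, p))
  }
  flat_mask <- which(mask)
  for (j in seq_len(p)) {
    band <- matrix(background_reflectance, rows, cols)
    band[flat_mask] <- R_fruit[, j]
    data[, , j] <- band
  }
  data <- pmin(pmax(data + noise, 1e-6), 1)

  cube <- hypercube(data, grid, cfg$region, mask = mask)
  fields <- lapply(cons, function(nm) {
    f <- matrix(NA_real_, rows, cols)
    f[mask] <- c_nom[[nm]] * field[mask]
    f
  })
  names(fields) <- cons
  cube$truth <- list(
    mask = mask, concentration_field = fields, nominal = c_nom,
    sample_spectrum = as.numeric(batch$spectra[sample, , drop = TRUE]),
    noiseless_pixels = R_fruit
  )
  cube
}
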