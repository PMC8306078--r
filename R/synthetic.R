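#' Reference population statistics for fruit constituents
#'
#' Per-constituent minimum, maximum, mean and standard deviation used as
#' default targets by the synthetic generator. Values describe fresh goji
#' berries pooled over four maturity stages; units are grams per kilogram
#' fresh weight except where noted.
#'
#' @return A data.frame with columns `constituent`, `unit`, `min`, `max`,
#'   `mean`, `sd`.
#' @export
constituent_stats <- function() {
  data.frame(
    constituent = c(
      "vitamin_c", "ascorbic_acid", "dhaa", "antioxidant",
      "phenols", "anthocyanin", "ssc", "ta"
    ),
    unit = c(
      "g/kg", "g/kg", "g/kg", "g TE/kg",
      "g GA/kg", "mg/cm2", "%", "%"
    ),
    min  = c(0.13, 0.02, 0.04, 1.63, 2.09, 0.67, 6.50, 0.11),
    max  = c(0.65, 0.48, 0.18, 3.29, 3.37, 1.35, 25.90, 0.92),
    mean = c(0.31, 0.20, 0.11, 2.31, 2.62, 1.05, 21.62, 0.56),
    sd   = c(0.14, 0.12, 0.04, 0.41, 0.32, 0.17, 3.48, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Default absorption-band library
#'
#' Gaussian absorption bands assigned to each constituent, placed at
#' literature positions: vitamin C correlates with peaks at 850, 1000,
#' 1210, 1360, 1460, 1580 and 1650 nm; phenolics (dominated by ferulic
#' acid) absorb in the visible around 450 nm; sugar/starch features sit
#' near 880-920 nm; organic-acid information concentrates in 900-1000 nm.
#' `width` is the Gaussian sigma in nm and `strength` the peak decadic
#' absorbance contributed per concentration unit.
#'
#' @return A data.frame with columns `constituent`, `center`, `width`,
#'   `strength`.
#' @export
default_band_library <- function() {
  data.frame(
    constituent = c(
      rep("vitamin_c", 7),
      "phenols", "phenols",
      "ssc", "ssc",
      "ta", "ta"
    ),
    center = c(
      850, 1000, 1210, 1360, 1460, 1580, 1650,
      450, 480,
      880, 910,
      950, 995
    ),
    width = c(
      15, 18, 20, 22, 20, 20, 18,
      22, 28,
      12, 14,
      12, 16
    ),
    strength = c(
      0.45, 0.35, 0.40, 0.40, 0.25, 0.35, 0.30,
      0.085, 0.055,
      0.004, 0.005,
      0.28, 0.22
    ),
    stringsAsFactors = FALSE
  )
}

#' Validate a single absorption band definition
#'
#' @param constituent Constituent name.
#' @param center Band center (nm), inside the joint sensor range 400-1700.
#' @param width Gaussian sigma (nm), positive.
#' @param strength Peak absorbance per concentration unit, positive.
#' @return A one-row data.frame compatible with [default_band_library()].
#' @export
component_band <- function(constituent, center, width, strength) {
  if (center < 400 || center > 1700) {
    stop("band center must lie within the 400-1700 nm sensor union")
  }
  if (width <= 0) stop("band width must be positive")
  if (strength <= 0) stop("band strength must be positive")
  data.frame(
    constituent = constituent, center = center,
    width = width, strength = strength, stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic batch generator
#'
#' @param n_samples Number of samples (>= 2).
#' @param region `"VIS-NIR"` (400-1000 nm) or `"NIR"` (900-1700 nm).
#' @param constituents Constituent names to simulate; defaults to the
#'   constituents of [default_band_library()] that own at least one band
#'   inside the chosen region.
#' @param stats Data.frame of target population statistics in the format
#'   of [constituent_stats()].
#' @param noise_sd Additive sensor noise on reflectance (default 0.005).
#' @param baseline_amp Standard deviation of per-sample smooth baseline
#'   drift coefficients, in absorbance units (default 0.005).
#' @param n_stages Number of maturity stages (default 4).
#' @param stage_shift Named vector of per-stage mean shifts in units of the
#'   within-stage standard deviation; unnamed constituents get 0. Riper
#'   stages carry more soluble solids, acidity and vitamin C, so those
#'   default to 1.
#' @param seed Integer RNG seed; every generator call is reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 100,
                             region = c("VIS-NIR", "NIR"),
                             constituents = NULL,
                             stats = constituent_stats(),
                             noise_sd = 0.005,
                             baseline_amp = 0.005,
                             n_stages = 4,
                             stage_shift = c(vitamin_c = 1, ssc = 1, ta = 1),
                             seed = 1L) {
  region <- match.arg(region)
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (baseline_amp < 0) stop("baseline_amp must be non-negative")
  if (n_stages < 1) stop("n_stages must be at least 1")
  grid <- region_grid(region)
  if (is.null(constituents)) {
    bl <- default_band_library()
    inreg <- bl$center >= min(grid) & bl$center <= max(grid)
    constituents <- unique(bl$constituent[inreg])
  }
  missing_stats <- setdiff(constituents, stats$constituent)
  if (length(missing_stats)) {
    stop("no population statistics for: ", paste(missing_stats, collapse = ", "))
  }
  st <- stats[match(constituents, stats$constituent), ]
  bad <- st$min > st$mean | st$mean > st$max | st$sd < 0
  if (any(bad)) {
    stop("stats must satisfy min <= mean <= max and sd >= 0 (violated for ",
         paste(st$constituent[bad], collapse = ", "), ")")
  }
  shift <- stats::setNames(rep(0, length(constituents)), constituents)
  keep <- intersect(names(stage_shift), constituents)
  shift[keep] <- stage_shift[keep]
  structure(list(
    n_samples = as.integer(n_samples), region = region,
    constituents = constituents, stats = st,
    noise_sd = noise_sd, baseline_amp = baseline_amp,
    n_stages = as.integer(n_stages), stage_shift = shift,
    seed = as.integer(seed)
  ), class = "generator_config")
}

region_grid <- function(region) {
  switch(region,
    "VIS-NIR" = make_wavelength_grid(400, 1000, 5),
    "NIR" = make_wavelength_grid(900, 1700, 5),
    stop("unknown region: ", region)
  )
}

# Exact truncated-normal machinery (inverse-CDF sampling, analytic moments).
rtrunc_norm <- function(n, mean, sd, a, b) {
  if (sd == 0) return(rep(pmin(pmax(mean, a), b), n))
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  u <- stats::runif(n, lo, hi)
  stats::qnorm(u, mean, sd)
}

trunc_norm_moments <- function(mean, sd, a, b) {
  if (sd == 0) return(c(mean = pmin(pmax(mean, a), b), var = 0))
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m <- mean + sd * dphi / z
  v <- sd^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z -
                 (dphi / z)^2)
  c(mean = m, var = max(v, 0))
}

# Solve for the latent (mu0, sigma_w) so that the stage-shifted, truncated
# mixture reproduces the target population mean and sd. Stage offsets are
# delta * sigma_w * (s - (S+1)/2); fixed-point iteration converges in a
# handful of steps for all Table-like inputs.
calibrate_stage_mixture <- function(target_mean, target_sd, a, b,
                                    delta, n_stages) {
  s_idx <- seq_len(n_stages) - (n_stages + 1) / 2
  if (target_sd == 0) {
    return(list(mu0 = target_mean, sigma_w = 0, offsets = 0 * s_idx))
  }
  spread <- sqrt(1 + delta^2 * mean(s_idx^2))
  mu0 <- target_mean
  sigma_w <- target_sd / spread
  for (it in 1:100) {
    off <- delta * sigma_w * s_idx
    mom <- vapply(off, function(o) {
      trunc_norm_moments(mu0 + o, sigma_w, a, b)
    }, numeric(2))
    pop_mean <- mean(mom["mean", ])
    pop_var <- mean(mom["var", ] + (mom["mean", ] - pop_mean)^2)
    if (abs(pop_mean - target_mean) < 1e-12 * max(1, abs(target_mean)) &&
        abs(sqrt(pop_var) - target_sd) < 1e-12 * target_sd) break
    mu0 <- mu0 + (target_mean - pop_mean)
    sigma_w <- sigma_w * target_sd / sqrt(pop_var)
  }
  list(mu0 = mu0, sigma_w = sigma_w, offsets = delta * sigma_w * s_idx)
}

#' Draw a synthetic constituent concentration table
#'
#' Concentrations are drawn per maturity stage from truncated normal
#' distributions on the configured `[min, max]` interval. A monotone
#' stage effect shifts the per-stage means (riper fruit carry more
#' soluble solids, acidity and vitamin C); the latent within-stage mean
#' and spread are calibrated analytically so the pooled population
#' reproduces the configured mean and sd.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `sample_id`, `stage`, then one column
#'   per constituent.
#' @export
sample_concentrations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_samples
  stage <- rep(seq_len(config$n_stages), length.out = n)
  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    stage = stage, stringsAsFactors = FALSE
  )
  for (k in seq_along(config$constituents)) {
    nm <- config$constituents[k]
    st <- config$stats[k, ]
    cal <- calibrate_stage_mixture(
      st$mean, st$sd, st$min, st$max,
      config$stage_shift[[nm]], config$n_stages
    )
    vals <- numeric(n)
    for (s in seq_len(config$n_stages)) {
      idx <- which(stage == s)
      vals[idx] <- rtrunc_norm(
        length(idx), cal$mu0 + cal$offsets[s], cal$sigma_w,
        st$min, st$max
      )
    }
    out[[nm]] <- vals
  }
  out
}

# Per-unit-concentration absorbance design matrix on a wavelength grid:
# one column per constituent, summing that constituent's Gaussian bands.
band_design <- function(grid, bands, constituents) {
  D <- matrix(0, length(grid), length(constituents),
              dimnames = list(NULL, constituents))
  for (i in seq_len(nrow(bands))) {
    k <- match(bands$constituent[i], constituents)
    if (is.na(k)) next
    D[, k] <- D[, k] + bands$strength[i] *
      exp(-0.5 * ((grid - bands$center[i]) / bands$width[i])^2)
  }
  D
}

# Fixed water/background absorbance: broad water bands at 970 and 1450 nm
# plus a flat pedestal keeping fruit reflectance near 0.5.
water_background <- function(grid, pedestal = 0.25, amplitude = 0.4) {
  pedestal +
    amplitude * exp(-0.5 * ((grid - 970) / 35)^2) +
    amplitude * exp(-0.5 * ((grid - 1450) / 45)^2)
}

baseline_basis <- function(grid) {
  u <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  cbind(1, u, u^2)
}

#' Simulate a batch of reflectance spectra by Beer-Lambert mixing
#'
#' The forward model is additive in decadic absorbance:
#' `A(lambda) = sum_k c_k * eps_k(lambda) + water background + baseline`,
#' where `eps_k` sums the constituent's Gaussian bands. Reflectance is
#' `R = 10^-A` plus additive Gaussian sensor noise, clipped to (0, 1].
#'
#' @param concentrations Data.frame as produced by
#'   [sample_concentrations()] (columns `sample_id`, `stage`, constituents).
#' @param bands Band library data.frame; defaults to
#'   [default_band_library()].
#' @param config A [generator_config()].
#' @return A `synthetic_batch`: list with elements `spectra`
#'   (a [spectrum_set()] of reflectance), `concentrations`, `stage`, and
#'   `truth` (band library, per-unit design matrix, noiseless absorbance,
#'   background and baseline used).
#' @export
mix_spectra <- function(concentrations, bands = default_band_library(),
                        config) {
  stopifnot(inherits(config, "generator_config"))
  grid <- region_grid(config$region)
  cons <- config$constituents
  miss <- setdiff(cons, bands$constituent)
  if (length(miss)) stop("no bands defined for: ", paste(miss, collapse = ", "))
  inreg <- bands$center >= min(grid) & bands$center <= max(grid)
  for (nm in cons) {
    if (!any(inreg & bands$constituent == nm)) {
      stop(sprintf(
        "constituent '%s' has no absorption band inside the %s grid (%g-%g nm); it would be unlearnable",
        nm, config$region, min(grid), max(grid)
      ))
    }
  }
  C <- as.matrix(concentrations[, cons, drop = FALSE])
  n <- nrow(C)
  D <- band_design(grid, bands[inreg, , drop = FALSE], cons)
  bg <- water_background(grid)
  set.seed(config$seed + 1L)
  bb <- baseline_basis(grid)
  bcoef <- matrix(stats::rnorm(n * ncol(bb), 0, config$baseline_amp),
                  n, ncol(bb))
  A <- C %*% t(D) + matrix(bg, n, length(grid), byrow = TRUE) +
    bcoef %*% t(bb)
  R <- 10^(-A)
  if (config$noise_sd > 0) {
    R <- R + matrix(stats::rnorm(n * length(grid), 0, config$noise_sd),
                    n, length(grid))
  }
  R <- pmin(pmax(R, 1e-6), 1)
  spectra <- spectrum_set(R, grid, config$region)
  rownames(spectra) <- concentrations$sample_id
  structure(list(
    spectra = spectra,
    concentrations = concentrations,
    stage = concentrations$stage,
    config = config,
    truth = list(
      bands = bands[inreg, , drop = FALSE], design = D,
      absorbance = A, background = bg, baseline_coef = bcoef
    )
  ), class = "synthetic_batch")
}

#' Generate a complete synthetic batch
#'
#' Convenience wrapper: draws concentrations with
#' [sample_concentrations()] and mixes spectra with [mix_spectra()].
#'
#' @inheritParams mix_spectra
#' @param config A [generator_config()].
#' @return A `synthetic_batch`; see [mix_spectra()].
#' @export
simulate_batch <- function(config = generator_config(),
                           bands = default_band_library()) {
  conc <- sample_concentrations(config)
  mix_spectra(conc, bands, config)
}

#' @export
print.synthetic_batch <- function(x, ...) {
  cat(sprintf(
    "<synthetic_batch> %d samples, %s region, constituents: %s\n",
    nrow(x$spectra), x$config$region,
    paste(x$config$constituents, collapse = ", ")
  ))
  invisible(x)
}

#' Noise-equivalent concentration error of a synthetic batch
#'
#' Propagates the generator's reflectance noise through the Beer-Lambert
#' forward model to the best achievable per-sample concentration error:
#' the standard error of the generalised least-squares estimator that
#' knows the true absorptivity spectra and fits concentrations jointly
#' with the smooth-baseline nuisance basis. Used to judge whether the
#' calibration pipeline extracts close to all the information the data
#' contain.
#'
#' @param batch A `synthetic_batch`.
#' @return Named numeric vector, one noise-equivalent RMSE per
#'   constituent, in concentration units.
#' @export
noise_equivalent_error <- function(batch) {
  stopifnot(inherits(batch, "synthetic_batch"))
  cfg <- batch$config
  cons <- cfg$constituents
  if (cfg$noise_sd == 0) {
    return(stats::setNames(rep(0, length(cons)), cons))
  }
  grid <- wavelengths(batch$spectra)
  D <- batch$truth$design
  # nuisance: pedestal + drift polynomial (water bands are constant across
  # samples and absorbed by the pedestal column)
  N <- baseline_basis(grid)
  G <- cbind(D, N)
  Rbar <- 10^(-colMeans(batch$truth$absorbance))
  sigma_A <- cfg$noise_sd / (log(10) * Rbar)
  Gw <- G / sigma_A
  info <- crossprod(Gw)
  cov <- solve(info)
  stats::setNames(sqrt(diag(cov)[seq_along(cons)]), cons)
}

#' Write / read a concentration table as CSV
#'
#' Plain CSV with header `sample_id, stage, <constituent columns>`.
#'
#' @param x Concentration data.frame.
#' @param path File path.
#' @return `read_concentrations` returns the data.frame.
#' @export
write_concentrations <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentrations
#' @export
read_concentrations <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("concentration table lacks columns: ", paste(miss, collapse = ", "))
  }
  out
}
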