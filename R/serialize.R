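#' Save / load a fitted calibration
#'
#' A `pls_calibration` is stored as a single self-describing JSON file:
#' chain definition (steps, window, polynomial order, fitted column
#' means), PLS state (weights, loadings, coefficients, centering
#' statistics, chosen latent variables, retained-variable index) and the
#' wavelength grid. Numeric payloads are written at full precision, so a
#' reloaded model predicts identically.
#'
#' @param object A [pls_calibration()] fit.
#' @param path Output file path (`.json`).
#' @return `load_calibration` returns the restored `pls_calibration`
#'   (without the cross-validation record, which is not needed for
#'   prediction).
#' @export
save_calibration <- function(object, path) {
  stopifnot(inherits(object, "pls_calibration"))
  m <- object$model
  payload <- list(
    format = "hyperpls_calibration",
    version = 1L,
    constituent = object$constituent,
    region = object$region,
    wavelengths = object$wavelengths,
    lv = object$lv,
    columns = object$columns,
    metrics = object$metrics,
    chain = list(
      steps = object$chain$steps,
      window = object$chain$window,
      polyorder = object$chain$polyorder,
      log_base = object$chain$log_base,
      column_means = object$chain$column_means
    ),
    model = list(
      coefficients = m$coefficients, intercept = m$intercept,
      W = m$W, P = m$P, q = m$q,
      x_means = m$x_means, y_mean = m$y_mean,
      n_lv = m$n_lv, n = m$n, p = m$p,
      wavelengths = m$wavelengths
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "columnmajor")
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "hyperpls_calibration")) {
    stop("not a serialized calibration: ", path)
  }
  chain <- parse_chain(
    if (length(p$chain$steps)) paste(p$chain$steps, collapse = " + ")
    else "none",
    window = p$chain$window, polyorder = p$chain$polyorder,
    log_base = p$chain$log_base
  )
  chain$column_means <- p$chain$column_means
  chain$wavelengths <- p$wavelengths
  model <- structure(list(
    coefficients = p$model$coefficients, intercept = p$model$intercept,
    W = as.matrix(p$model$W), P = as.matrix(p$model$P), q = p$model$q,
    x_means = p$model$x_means, y_mean = p$model$y_mean,
    n_lv = p$model$n_lv, n = p$model$n, p = p$model$p,
    columns = p$columns, wavelengths = p$model$wavelengths
  ), class = "pls1")
  structure(list(
    chain = chain, model = model, cv = NULL, lv = p$lv,
    metrics = p$metrics, columns = p$columns,
    wavelengths = p$wavelengths, region = p$region, y = NULL,
    constituent = p$constituent
  ), class = "pls_calibration")
}

#' Read a generator configuration from a YAML file
#'
#' Plain-text mirror of [generator_config()]: top-level keys match the
#' constructor arguments; `stats` may override individual constituents
#' as a mapping of `name: [min, max, mean, sd]`.
#'
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  stats <- constituent_stats()
  if (!is.null(y$stats)) {
    for (nm in names(y$stats)) {
      v <- as.numeric(y$stats[[nm]])
      if (length(v) != 4) {
        stop("stats entry for '", nm, "' must be [min, max, mean, sd]")
      }
      i <- match(nm, stats$constituent)
      if (is.na(i)) {
        stats <- rbind(stats, data.frame(
          constituent = nm, unit = "", min = v[1], max = v[2],
          mean = v[3], sd = v[4], stringsAsFactors = FALSE
        ))
      } else {
        stats[i, c("min", "max", "mean", "sd")] <- as.list(v)
      }
    }
  }
  args <- list(stats = stats)
  for (key in c("n_samples", "region", "constituents", "noise_sd",
                "baseline_amp", "n_stages", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$stage_shift)) {
    args$stage_shift <- unlist(y$stage_shift)
  }
  do.call(generator_config, args)
}
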