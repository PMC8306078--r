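#' Fit a full spectral calibration for one constituent
#'
#' The package's central model object: a pretreatment chain fitted on the
#' calibration spectra, a PLS1 regression on the transformed variables,
#' and a leave-one-out cross-validation record from which the
#' latent-variable count is chosen by the PRESS-ratio rule (see
#' [select_lv()]). All centering statistics are learned on the
#' calibration rows only, so the object can be applied verbatim to
#' external spectra and to image pixels.
#'
#' @param x Raw reflectance spectra ([spectrum_set()] or matrix),
#'   calibration samples in rows.
#' @param y Constituent concentrations, length `nrow(x)`.
#' @param chain Pretreatment chain code (see [parse_chain()]) or a
#'   `pretreatment_chain` object. Default `"SM + MC"`.
#' @param wl Wavelength grid when `x` is a plain matrix.
#' @param columns Optional retained-variable index into the wavelength
#'   grid (e.g. from [modified_ipls()]); pretreatment runs on the full
#'   grid, the regression on the retained columns.
#' @param lv Latent-variable count; `NULL` (default) selects it from the
#'   cross-validation PRESS curve.
#' @param max_lv Candidate bound for cross-validation (default
#'   `min(20, I - 2, variables)`).
#' @param prob_threshold PRESS-ratio probability threshold.
#' @param constituent Optional constituent name carried into reports.
#' @return An object of class `pls_calibration` with components `chain`
#'   (fitted), `model` ([fit_pls()] object), `cv` ([loo_cv()] record),
#'   `lv`, `metrics` (calibration and cross-validation [fit_metrics()]),
#'   `columns`, `wavelengths`, `y`, `constituent`.
#' @examples
#' cfg <- generator_config(n_samples = 40, seed = 7)
#' batch <- simulate_batch(cfg)
#' cal <- pls_calibration(batch$spectra, batch$concentrations$ssc,
#'                        chain = "SM + MC", constituent = "ssc")
#' print(cal)
#' @export
pls_calibration <- function(x, y, chain = "SM + MC", wl = NULL,
                            columns = NULL, lv = NULL, max_lv = NULL,
                            prob_threshold = 0.75, constituent = NULL) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "pretreatment_chain"))
  s <- as_spectra(x, wl)
  y <- as.numeric(y)
  fa <- fit_apply(chain, s$x, s$wavelengths)
  cv <- suppressWarnings(
    loo_cv(fa$x, y, max_lv = max_lv, columns = columns)
  )
  if (is.null(lv)) lv <- select_lv(cv, prob_threshold)
  model <- fit_pls(fa$x, y, n_lv = lv, columns = columns)
  cal_m <- fit_metrics(y, model$fitted_values)
  cv_m <- fit_metrics(y, cv$predictions[, lv])
  structure(list(
    chain = fa$chain, model = model, cv = cv, lv = as.integer(lv),
    metrics = list(
      r2_cal = cal_m$r2, rmsec = cal_m$rmse,
      r2_cv = cv_m$r2, rmsecv = cv_m$rmse
    ),
    columns = columns,
    wavelengths = s$wavelengths,
    region = s$region,
    y = y,
    constituent = constituent,
    call = match.call()
  ), class = "pls_calibration")
}

#' @export
print.pls_calibration <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<pls_calibration>%s chain: %s | %d LV | %d samples, %d variables\n",
    if (is.null(x$constituent)) "" else paste0(" ", x$constituent, " |"),
    format(x$chain), x$lv, x$model$n, x$model$p
  ))
  cat(sprintf(
    "  R2cal %.3f  RMSEC %.4g  |  R2cv %.3f  RMSECV %.4g\n",
    m$r2_cal, m$rmsec, m$r2_cv, m$rmsecv
  ))
  invisible(x)
}

#' @export
summary.pls_calibration <- function(object, ...) {
  print(object)
  press <- object$cv$press
  cat("  PRESS by LV:\n")
  print(stats::setNames(signif(press, 4), seq_along(press)))
  if (!is.null(object$columns)) {
    cat(sprintf("  retained variables: %d of %d\n",
                length(object$columns), length(object$wavelengths)))
  }
  invisible(object)
}

#' @export
coef.pls_calibration <- function(object, ...) coef(object$model)

#' @export
fitted.pls_calibration <- function(object, ...) object$model$fitted_values

#' @export
residuals.pls_calibration <- function(object, ...) {
  object$y - object$model$fitted_values
}

#' Predict from a fitted spectral calibration
#'
#' New raw reflectance spectra are passed through the fitted pretreatment
#' chain (using the stored calibration centering statistics) and the PLS
#' regression.
#'
#' @param object A [pls_calibration()] fit.
#' @param newdata Raw spectra on the calibration wavelength grid.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations.
#' @export
predict.pls_calibration <- function(object, newdata, ...) {
  xt <- chain_apply(object$chain, newdata, object$wavelengths)
  predict(object$model, xt)
}

#' Predicted-versus-measured plot for a spectral calibration
#'
#' @param x A [pls_calibration()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pls_calibration <- function(x, ...) {
  y <- x$y
  yf <- x$model$fitted_values
  ycv <- x$cv$predictions[, x$lv]
  rng <- range(c(y, yf, ycv))
  graphics::plot(y, yf, xlim = rng, ylim = rng,
                 xlab = "measured", ylab = "predicted",
                 pch = 19, col = "grey30", ...)
  graphics::points(y, ycv, pch = 1, col = "steelblue")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("calibration", "cross-validation"),
                   pch = c(19, 1), col = c("grey30", "steelblue"),
                   bty = "n")
  invisible(x)
}

#' Refine a calibration by wavelength elimination and outlier removal
#'
#' Mirrors the refinement stage of the study workflow: backward
#' interval-PLS on the pretreated calibration spectra discards intervals
#' whose removal improves RMSECV, then the cross-validation outlier
#' statistic iteratively removes aberrant samples, and the final model is
#' refitted (pretreatment chain included) on the cleaned samples and
#' retained wavelengths.
#'
#' @param object A [pls_calibration()] fit (fitted on the full grid).
#' @param x,y The raw calibration spectra and responses used to fit
#'   `object`.
#' @param n_intervals Number of elimination intervals (default 20).
#' @param alpha Outlier flagging level (default 0.01).
#' @param floor_frac Minimum retained sample fraction (default 0.8).
#' @param max_lv,prob_threshold As in [pls_calibration()].
#' @return A list: `calibration` (the refined [pls_calibration()]),
#'   `scheme` (retained [make_intervals()] scheme), `ipls_trace`,
#'   `removed` (original row indices of removed samples),
#'   `removal_log`, `keep` (logical row filter).
#' @export
refine_calibration <- function(object, x, y, n_intervals = 20,
                               alpha = 0.01, floor_frac = 0.8,
                               max_lv = NULL, prob_threshold = 0.75) {
  stopifnot(inherits(object, "pls_calibration"))
  s <- as_spectra(x, object$wavelengths)
  y <- as.numeric(y)
  xt <- chain_apply(object$chain, s$x, s$wavelengths)
  scheme <- make_intervals(s$wavelengths, n_intervals)
  ip <- modified_ipls(xt, y, scheme, max_lv = max_lv,
                      prob_threshold = prob_threshold)
  orr <- remove_outliers_refit(xt, y, alpha = alpha,
                               floor_frac = floor_frac, max_lv = max_lv,
                               columns = ip$columns,
                               prob_threshold = prob_threshold)
  keep <- orr$keep
  fresh_chain <- parse_chain(format(object$chain),
                             window = object$chain$window,
                             polyorder = object$chain$polyorder,
                             log_base = object$chain$log_base)
  refined <- pls_calibration(
    s$x[keep, , drop = FALSE], y[keep], chain = fresh_chain,
    wl = s$wavelengths, columns = ip$columns, max_lv = max_lv,
    prob_threshold = prob_threshold, constituent = object$constituent
  )
  list(
    calibration = refined, scheme = ip$scheme, ipls_trace = ip$trace,
    removed = which(!keep), removal_log = orr$log, keep = keep
  )
}
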