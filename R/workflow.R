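#' Stratified calibration/prediction split
#'
#' Seeded random split, stratified by maturity stage. The total
#' calibration size is `ceiling(fraction * n)` (rounding toward
#' calibration) and is apportioned to the strata by largest remainder,
#' capped so both partitions stay non-empty in every stratum.
#'
#' @param stage Per-sample stratum labels (maturity stage).
#' @param fraction Calibration fraction, strictly between 0 and 1
#'   (default 0.70).
#' @param seed Integer RNG seed.
#' @return A list with integer index vectors `calibration` and
#'   `prediction` (disjoint, exhaustive).
#' @export
split_samples <- function(stage, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  stage <- as.character(stage)
  strata <- unique(stage)
  n_s <- vapply(strata, function(s) sum(stage == s), integer(1))
  if (any(n_s < 2)) {
    bad <- strata[which(n_s < 2)[1]]
    stop(sprintf(
      "stratum '%s' has %d sample(s); need at least 2 for a split",
      bad, sum(stage == bad)
    ))
  }
  total_cal <- ceiling(fraction * length(stage))
  quota <- fraction * n_s
  alloc <- floor(quota)
  rem <- total_cal - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, decreasing = TRUE) # ties: stratum order
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  alloc <- pmin(pmax(alloc, 1L), n_s - 1L)
  set.seed(as.integer(seed))
  cal <- integer(0)
  for (k in seq_along(strata)) {
    idx <- which(stage == strata[k])
    cal <- c(cal, sort(sample(idx, alloc[k])))
  }
  cal <- sort(cal)
  list(calibration = cal,
       prediction = setdiff(seq_along(stage), cal))
}

empty_report <- function() {
  data.frame(
    parameter = character(0), region = character(0),
    pretreatment = character(0),
    effective_wavelength_range_nm = character(0),
    n_sample = integer(0), n_variables = integer(0), lvs = integer(0),
    r2_cal = numeric(0), rmsec = numeric(0),
    r2_cv = numeric(0), rmsecv = numeric(0),
    r2_pred = numeric(0), rmsep = numeric(0),
    removed_samples = character(0), refined = logical(0),
    error = character(0), stringsAsFactors = FALSE
  )
}

report_row <- function(parameter, region, pretreatment, wl_range,
                       n_sample, n_variables, lvs, cal, pred,
                       removed = "", refined = FALSE, error = NA_character_) {
  data.frame(
    parameter = parameter, region = region, pretreatment = pretreatment,
    effective_wavelength_range_nm = wl_range,
    n_sample = n_sample, n_variables = n_variables, lvs = lvs,
    r2_cal = cal$r2_cal, rmsec = cal$rmsec,
    r2_cv = cal$r2_cv, rmsecv = cal$rmsecv,
    r2_pred = pred$r2, rmsep = pred$rmse,
    removed_samples = removed, refined = refined, error = error,
    stringsAsFactors = FALSE
  )
}

#' Run the pretreatment-by-constituent calibration grid
#'
#' For each (constituent, pretreatment chain) pair: stratified 70/30
#' split on the samples with a measured value, chain fitting and PLS1
#' calibration with LOO cross-validation and PRESS-ratio LV selection on
#' the calibration partition, then external evaluation on the prediction
#' partition. Optionally, the best full-spectrum row per constituent
#' (lowest RMSEP) is refined by backward interval-PLS and outlier
#' removal ([refine_calibration()]) and re-evaluated externally.
#' Failures of individual configurations are recorded in the row's
#' `error` field rather than aborting the grid.
#'
#' @param spectra Raw reflectance [spectrum_set()] (all samples).
#' @param concentrations Data.frame with columns `sample_id`, `stage` and
#'   one column per constituent (missing values allowed; each
#'   constituent uses its complete cases).
#' @param constituents Constituent column names to model.
#' @param chains Character vector of pretreatment chain codes.
#' @param fraction Calibration fraction (default 0.70).
#' @param seed Split seed.
#' @param refine `"best"` (default: refine the lowest-RMSEP chain per
#'   constituent), `"none"`, or `"all"`.
#' @param n_intervals,alpha,floor_frac Refinement settings (see
#'   [refine_calibration()]).
#' @param max_lv,prob_threshold Model settings (see
#'   [pls_calibration()]).
#' @return A `model_report` data.frame, one row per fitted
#'   configuration; refined rows carry `refined = TRUE`, the retained
#'   wavelength ranges and the removed sample ids. The fitted
#'   [pls_calibration()] objects are attached as attribute `"models"`
#'   (named `parameter|pretreatment[|refined]`).
#' @export
run_grid <- function(spectra, concentrations, constituents, chains,
                     fraction = 0.7, seed = 1L,
                     refine = c("best", "none", "all"),
                     n_intervals = 20, alpha = 0.01, floor_frac = 0.8,
                     max_lv = NULL, prob_threshold = 0.75) {
  refine <- match.arg(refine)
  if (inherits(spectra, "synthetic_batch")) {
    # convenience: run_grid(batch, constituents, chains, ...)
    if (!missing(concentrations) && is.character(concentrations)) {
      if (missing(chains)) chains <- constituents
      constituents <- concentrations
    }
    concentrations <- spectra$concentrations
    spectra <- spectra$spectra
  }
  s <- as_spectra(spectra)
  region <- ifelse(is.na(s$region), "VIS-NIR", s$region)
  miss <- setdiff(constituents, names(concentrations))
  if (length(miss)) {
    stop("constituent column(s) absent: ", paste(miss, collapse = ", "))
  }
  for (code in chains) parse_chain(code) # fail fast on unparseable codes
  full_range <- sprintf("%g-%g", min(s$wavelengths), max(s$wavelengths))
  rows <- list()
  models <- list()
  for (cons in constituents) {
    yy <- concentrations[[cons]]
    ok <- which(!is.na(yy))
    sp <- split_samples(concentrations$stage[ok], fraction, seed)
    cal_i <- ok[sp$calibration]
    pred_i <- ok[sp$prediction]
    x_cal <- s$x[cal_i, , drop = FALSE]
    x_pred <- s$x[pred_i, , drop = FALSE]
    y_cal <- yy[cal_i]
    y_pred <- yy[pred_i]
    cons_rows <- list()
    cons_cals <- list()
    for (code in chains) {
      res <- tryCatch({
        cal <- pls_calibration(x_cal, y_cal, chain = code,
                               wl = s$wavelengths, max_lv = max_lv,
                               prob_threshold = prob_threshold,
                               constituent = cons)
        pm <- fit_metrics(y_pred, predict(cal, x_pred))
        list(cal = cal, row = report_row(
          cons, region, code, full_range,
          length(cal_i) + length(pred_i), length(s$wavelengths), cal$lv,
          cal$metrics, pm
        ))
      }, error = function(e) {
        list(cal = NULL, row = report_row(
          cons, region, code, full_range,
          length(cal_i) + length(pred_i), length(s$wavelengths),
          NA_integer_,
          list(r2_cal = NA_real_, rmsec = NA_real_,
               r2_cv = NA_real_, rmsecv = NA_real_),
          list(r2 = NA_real_, rmse = NA_real_),
          error = conditionMessage(e)
        ))
      })
      cons_rows[[code]] <- res$row
      cons_cals[[code]] <- res$cal
      models[[paste(cons, code, sep = "|")]] <- res$cal
    }
    cons_report <- do.call(rbind, cons_rows)
    if (refine != "none") {
      todo <- if (refine == "all") {
        which(!is.na(cons_report$rmsep))
      } else {
        valid <- cons_report[!is.na(cons_report$rmsep), , drop = FALSE]
        if (nrow(valid)) {
          which(cons_report$pretreatment ==
                  select_best(valid)$pretreatment)[1]
        } else {
          integer(0)
        }
      }
      for (ri in todo) {
        code <- cons_report$pretreatment[ri]
        base_cal <- cons_cals[[code]]
        if (is.null(base_cal)) next
        ref <- tryCatch({
          rf <- refine_calibration(base_cal, x_cal, y_cal,
                                   n_intervals = n_intervals,
                                   alpha = alpha,
                                   floor_frac = floor_frac,
                                   max_lv = max_lv,
                                   prob_threshold = prob_threshold)
          pm <- fit_metrics(y_pred, predict(rf$calibration, x_pred))
          removed_ids <- concentrations$sample_id[cal_i[rf$removed]]
          row <- report_row(
            cons, region, code, format_intervals(rf$scheme),
            sum(rf$keep) + length(pred_i),
            length(rf$calibration$columns), rf$calibration$lv,
            rf$calibration$metrics, pm,
            removed = paste(removed_ids, collapse = ";"),
            refined = TRUE
          )
          models[[paste(cons, code, "refined", sep = "|")]] <-
            rf$calibration
          row
        }, error = function(e) {
          report_row(
            cons, region, code, "", NA_integer_, NA_integer_,
            NA_integer_,
            list(r2_cal = NA_real_, rmsec = NA_real_,
                 r2_cv = NA_real_, rmsecv = NA_real_),
            list(r2 = NA_real_, rmse = NA_real_),
            refined = TRUE, error = conditionMessage(e)
          )
        })
        cons_report <- rbind(cons_report, ref)
      }
    }
    rows[[cons]] <- cons_report
  }
  report <- do.call(rbind, c(list(empty_report()), rows))
  rownames(report) <- NULL
  class(report) <- c("model_report", class(report))
  attr(report, "models") <- models
  report
}

#' Select the best model row of a report
#'
#' Primary key: lowest RMSEP; ties broken by highest predictive R2,
#' then fewest latent variables, then fewest variables, then stable
#' order.
#'
#' @param reports A `model_report` data.frame with prediction metrics.
#' @return The selected row (one-row data.frame).
#' @export
select_best <- function(reports) {
  ok <- which(!is.na(reports$rmsep))
  if (!length(ok)) stop("no rows with prediction metrics to select from")
  r <- reports[ok, , drop = FALSE]
  ord <- order(r$rmsep, -r$r2_pred, r$lvs, r$n_variables)
  r[ord[1], , drop = FALSE]
}

#' Write a model report as CSV
#'
#' `style = "table"` writes the prediction-table column layout:
#' parameter, effective wavelength range, sample count, variable count,
#' then `LVs, R2_Cal, RMSEC, R2_CV, RMSECV, R2_pred, RMSEP`.
#' `style = "full"` keeps every internal column.
#'
#' @param reports A `model_report`.
#' @param path Output CSV path.
#' @param style `"full"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, style = c("full", "table")) {
  style <- match.arg(style)
  out <- as.data.frame(reports)
  if (style == "table") {
    out <- out[, c("parameter", "effective_wavelength_range_nm",
                   "n_sample", "n_variables", "lvs",
                   "r2_cal", "rmsec", "r2_cv", "rmsecv",
                   "r2_pred", "rmsep")]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pixel-wise constituent prediction map
#'
#' Every masked pixel's spectrum is passed through the calibration's
#' fitted pretreatment chain (stored centering statistics, no refitting)
#' and the PLS model; background pixels are `NA`.
#'
#' @param cube A [hypercube()] on the calibration's wavelength grid.
#' @param calibration A [pls_calibration()] fit.
#' @param mask Logical matrix; defaults to `cube$mask`.
#' @return An object of class `prediction_map`: `values` (rows x cols
#'   raster, `NA` off-mask), `mask`, `constituent`.
#' @export
predict_map <- function(cube, calibration, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"),
            inherits(calibration, "pls_calibration"))
  if (!isTRUE(all.equal(cube$wavelengths, calibration$wavelengths))) {
    stop("cube wavelength grid does not match the calibration grid")
  }
  if (is.null(mask)) stop("no mask supplied and cube carries none")
  shape <- dim(cube$data)[1:2]
  values <- matrix(NA_real_, shape[1], shape[2])
  if (any(mask)) {
    px <- pixel_spectra(cube, mask)
    values[px$index] <- predict(calibration, px$x)
  }
  structure(list(
    values = values, mask = as.matrix(mask),
    constituent = calibration$constituent
  ), class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<prediction_map>%s %d x %d, %d fruit px, range %.4g-%.4g\n",
    if (is.null(x$constituent)) "" else paste0(" ", x$constituent, ":"),
    nrow(x$values), ncol(x$values), length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA
  ))
  invisible(x)
}

#' @export
plot.prediction_map <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, , drop = FALSE]),
                  axes = FALSE, asp = nrow(x$values) / ncol(x$values),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
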