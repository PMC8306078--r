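#' Partition a wavelength grid into contiguous intervals
#'
#' Near-equal contiguous blocks; when the variable count is not divisible
#' by `n_intervals`, the earlier intervals receive the extra variable.
#'
#' @param grid Wavelength vector (or an integer variable count).
#' @param n_intervals Number of intervals, `1 <= n_intervals <= length(grid)`.
#' @return An object of class `interval_scheme`: `bounds` (n x 2 matrix
#'   of first/last variable indices), `retained` (logical flags),
#'   `grid` (the wavelength vector, or indices when a count was given).
#' @export
make_intervals <- function(grid, n_intervals) {
  if (length(grid) == 1 && grid == round(grid) && grid > 1) {
    grid <- seq_len(grid)
  }
  p <- length(grid)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1) stop("n_intervals must be at least 1")
  if (n_intervals > p) stop("more intervals than variables")
  base <- p %/% n_intervals
  extra <- p %% n_intervals
  sizes <- rep(base, n_intervals) + rep(c(1L, 0L), c(extra, n_intervals - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  structure(list(
    bounds = cbind(start = starts, end = ends),
    retained = rep(TRUE, n_intervals),
    grid = as.numeric(grid)
  ), class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf(
    "<interval_scheme> %d intervals over %d variables, %d retained\n",
    nrow(x$bounds), length(x$grid), sum(x$retained)
  ))
  invisible(x)
}

# variable indices of the currently retained intervals
scheme_columns <- function(scheme, retained = scheme$retained) {
  idx <- integer(0)
  for (j in which(retained)) {
    idx <- c(idx, scheme$bounds[j, "start"]:scheme$bounds[j, "end"])
  }
  idx
}

#' Report retained intervals as wavelength ranges
#'
#' @param scheme An `interval_scheme`.
#' @return Character scalar like `"1475-1495, 1525-1545, 1600-1650"`:
#'   maximal runs of contiguous retained variables, endpoints inclusive.
#' @export
format_intervals <- function(scheme) {
  cols <- sort(scheme_columns(scheme))
  if (!length(cols)) return("")
  breaks <- which(diff(cols) > 1)
  run_start <- cols[c(1, breaks + 1)]
  run_end <- cols[c(breaks, length(cols))]
  paste(sprintf("%g-%g", scheme$grid[run_start], scheme$grid[run_end]),
        collapse = ", ")
}

# RMSECV of the model restricted to `columns`, with LV count re-selected
# by the PRESS-ratio rule. Returns the RMSECV at the chosen LV.
interval_rmsecv <- function(X, y, columns, max_lv, prob_threshold) {
  ml <- min(max_lv, length(columns))
  cv <- suppressWarnings(loo_cv(X, y, max_lv = ml, columns = columns))
  k <- select_lv(cv, prob_threshold)
  list(rmsecv = cv$rmsecv[k], lv = k)
}

#' Backward interval-PLS wavelength elimination
#'
#' The retained spectral range is divided into contiguous intervals; at
#' each round, every retained interval is tentatively removed, the model
#' on the remaining variables is re-cross-validated (with the
#' latent-variable count re-selected each time), and the single interval
#' whose removal most improves RMSECV is permanently discarded. The
#' procedure stops when no removal improves RMSECV or one interval
#' remains, so the final retained RMSECV never exceeds the full-spectrum
#' RMSECV. Ties are broken toward the interval starting at the lower
#' wavelength.
#'
#' @param x Pretreated calibration spectra.
#' @param y Response vector.
#' @param scheme An [make_intervals()] scheme; with a single interval
#'   the procedure is a no-op.
#' @param max_lv Candidate latent-variable bound per evaluation.
#' @param prob_threshold PRESS-ratio probability threshold for
#'   [select_lv()].
#' @return A list: `scheme` (with updated `retained` flags), `trace`
#'   (data.frame of round, candidate interval, RMSECV, chosen LV,
#'   removed flag), `rmsecv` (final), `lv` (final chosen LV count),
#'   `columns` (retained variable indices).
#' @export
modified_ipls <- function(x, y, scheme, max_lv = NULL,
                          prob_threshold = 0.75) {
  stopifnot(inherits(scheme, "interval_scheme"))
  s <- as_spectra(x)
  X <- s$x
  y <- as.numeric(y)
  if (is.null(max_lv)) max_lv <- min(20L, nrow(X) - 2L, ncol(X))
  retained <- scheme$retained
  cur <- interval_rmsecv(X, y, scheme_columns(scheme, retained),
                         max_lv, prob_threshold)
  trace <- list()
  round_i <- 0L
  while (sum(retained) > 1) {
    round_i <- round_i + 1L
    cand <- which(retained)
    res <- lapply(cand, function(j) {
      r <- retained; r[j] <- FALSE
      interval_rmsecv(X, y, scheme_columns(scheme, r), max_lv,
                      prob_threshold)
    })
    rmse_cand <- vapply(res, `[[`, numeric(1), "rmsecv")
    lv_cand <- vapply(res, `[[`, integer(1), "lv")
    best <- which.min(rmse_cand) # ties -> lowest start wavelength (first)
    removed_flag <- rmse_cand[best] < cur$rmsecv
    trace[[round_i]] <- data.frame(
      round = round_i, interval = cand,
      start_nm = scheme$grid[scheme$bounds[cand, "start"]],
      end_nm = scheme$grid[scheme$bounds[cand, "end"]],
      rmsecv = rmse_cand, lv = lv_cand,
      removed = seq_along(cand) == best & removed_flag
    )
    if (!removed_flag) break
    retained[cand[best]] <- FALSE
    cur <- res[[best]]
  }
  scheme$retained <- retained
  list(
    scheme = scheme,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(round = integer(0), interval = integer(0),
                 start_nm = numeric(0), end_nm = numeric(0),
                 rmsecv = numeric(0), lv = integer(0),
                 removed = logical(0)),
    rmsecv = cur$rmsecv, lv = cur$lv,
    columns = sort(scheme_columns(scheme, retained))
  )
}

#' Cross-validation outlier statistic
#'
#' For each sample, the squared deviation of its left-out prediction
#' from its nominal value is compared against the summed squared
#' deviations of all other samples:
#' `F_y(i) = (I - 1) * (yhat_i - y_i)^2 / sum_{j != i} (yhat_j - y_j)^2`,
#' an F statistic with `(1, I - 1)` degrees of freedom. Samples whose
#' upper-tail probability falls below `alpha` are flagged as outliers
#' (their nominal analyte value deviates significantly from what the
#' model predicts when they are left out).
#'
#' @param cv A [loo_cv()] record.
#' @param lv Latent-variable count at which to take the left-out
#'   predictions; default: [select_lv()] on `cv`.
#' @param alpha Flagging significance level (default 0.01).
#' @return A data.frame of class `outlier_record` with columns `sample`,
#'   `f_value`, `numerator`, `denominator`, `p_value`, `flag`; degrees
#'   of freedom in attributes `df1`, `df2`.
#' @export
outlier_scores <- function(cv, lv = NULL, alpha = 0.01) {
  stopifnot(inherits(cv, "pls_cv"))
  I <- cv$I
  if (I < 3) stop("outlier statistic needs at least 3 samples")
  if (is.null(lv)) lv <- select_lv(cv)
  e2 <- (cv$predictions[, lv] - cv$y)^2
  denom <- sum(e2) - e2
  f_val <- (I - 1) * e2 / denom
  p_val <- stats::pf(f_val, 1, I - 1, lower.tail = FALSE)
  out <- data.frame(
    sample = seq_len(I), f_value = f_val,
    numerator = e2, denominator = denom,
    p_value = p_val, flag = p_val < alpha
  )
  attr(out, "df1") <- 1L
  attr(out, "df2") <- I - 1L
  attr(out, "alpha") <- alpha
  class(out) <- c("outlier_record", class(out))
  out
}

#' Iterative cross-validation outlier removal
#'
#' Repeatedly drops the single most significant flagged sample (highest
#' `F_y`), refits the leave-one-out cross-validation and recomputes the
#' scores, until no sample is flagged, `max_rounds` is reached, or the
#' sample count would fall below `floor_frac` of the initial count.
#'
#' @param x Pretreated calibration spectra.
#' @param y Response vector.
#' @param alpha Flagging level (default 0.01).
#' @param max_rounds Maximum removals (default unlimited up to the
#'   floor); `0` returns the input unchanged.
#' @param floor_frac Minimum retained fraction of the initial sample
#'   count (default 0.8).
#' @param max_lv Candidate latent-variable bound for each refit.
#' @param columns Optional retained-variable index.
#' @param prob_threshold PRESS-ratio threshold for LV re-selection.
#' @return A list: `keep` (logical index into the original rows),
#'   `log` (data.frame of round, removed sample, F value, p value),
#'   `cv` (final [loo_cv()] record), `lv` (final chosen LV count).
#' @export
remove_outliers_refit <- function(x, y, alpha = 0.01, max_rounds = Inf,
                                  floor_frac = 0.8, max_lv = NULL,
                                  columns = NULL, prob_threshold = 0.75) {
  s <- as_spectra(x)
  X <- s$x
  y <- as.numeric(y)
  I0 <- nrow(X)
  keep <- rep(TRUE, I0)
  floor_n <- ceiling(floor_frac * I0)
  log_rows <- list()
  round_i <- 0L
  cv <- lv <- NULL
  repeat {
    idx <- which(keep)
    cv <- suppressWarnings(
      loo_cv(X[idx, , drop = FALSE], y[idx], max_lv = max_lv,
             columns = columns)
    )
    lv <- select_lv(cv, prob_threshold)
    if (round_i >= max_rounds) break
    sc <- outlier_scores(cv, lv = lv, alpha = alpha)
    if (!any(sc$flag)) break
    if (length(idx) - 1 < floor_n) break
    worst <- sc$sample[which.max(ifelse(sc$flag, sc$f_value, -Inf))]
    round_i <- round_i + 1L
    log_rows[[round_i]] <- data.frame(
      round = round_i, sample = idx[worst],
      f_value = sc$f_value[worst], p_value = sc$p_value[worst]
    )
    keep[idx[worst]] <- FALSE
  }
  list(
    keep = keep,
    log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(round = integer(0), sample = integer(0),
                 f_value = numeric(0), p_value = numeric(0)),
    cv = cv, lv = lv
  )
}
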