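#' Fit a single-response PLS regression (PLS1, NIPALS deflation)
#'
#' Sequential latent-variable extraction: each component's weight vector
#' is proportional to the covariance `X'y` of the deflated blocks, the
#' score is `t = Xw`, loadings follow by least squares, and both blocks
#' are deflated by the score. X and y are centered internally (so the
#' intercept equals `mean(y)` when prediction rows are all-zero after
#' mean centering). The regression vector in the original (pretreated)
#' variable space is `b = W (P'W)^-1 q`.
#'
#' @param x Numeric matrix or [spectrum_set()] of pretreated calibration
#'   spectra (samples x variables).
#' @param y Numeric response (one constituent), length `nrow(x)`.
#' @param n_lv Number of latent variables, `1 <= n_lv <=
#'   min(nrow - 1, ncol)`.
#' @param columns Optional integer index of retained variables (into the
#'   wavelength grid); the model records it and `predict()` subsets new
#'   spectra accordingly.
#' @return An object of class `pls1`: weights `W`, loadings `P`,
#'   y-loadings `q`, coefficient vector `coefficients`, `intercept`,
#'   centering statistics, `n_lv` (possibly truncated when the residual
#'   covariance vanishes), and the retained-variable index.
#' @export
fit_pls <- function(x, y, n_lv, columns = NULL) {
  s <- as_spectra(x)
  X <- s$x
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (stats::sd(y) == 0) stop("y has zero variance; nothing to calibrate")
  max_rank <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > max_rank) {
    stop(sprintf("n_lv must lie in 1..%d (rows - 1, variables)", max_rank))
  }
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  scores <- matrix(0, n, n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sum(abs(yc)))) break # residual signal exhausted
    w <- w / nw
    t_a <- as.numeric(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-300) break
    p_a <- crossprod(Xc, t_a)[, 1] / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    scores[, a] <- t_a
    a_used <- a
  }
  if (a_used == 0L) stop("no usable latent variable (X'y is numerically zero)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  scores <- scores[, seq_len(a_used), drop = FALSE]
  structure(list(
    coefficients = b,
    intercept = ybar - sum(xbar * b),
    fitted_values = ybar + as.numeric(scores %*% q),
    y = y,
    W = W, P = P, q = q, scores = scores,
    x_means = xbar, y_mean = ybar,
    n_lv = a_used, n_lv_requested = as.integer(n_lv),
    columns = columns, n = n, p = p,
    wavelengths = if (is.null(columns)) s$wavelengths else s$wavelengths[columns]
  ), class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf(
    "<pls1> %d latent variables, %d variables, %d calibration samples\n",
    x$n_lv, x$p, x$n
  ))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$coefficients,
                    format(object$wavelengths, trim = TRUE)))
}

#' Predict constituent concentrations from a fitted PLS1 model
#'
#' @param object A [fit_pls()] model.
#' @param newdata Matrix or [spectrum_set()] of pretreated spectra. When
#'   the model was fitted on a retained-variable subset, `newdata` may be
#'   either the full grid (it is subset by the stored index) or already
#'   restricted to the retained variables.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  X <- as_spectra(newdata)$x
  p_fit <- length(object$coefficients)
  if (!is.null(object$columns) && ncol(X) != p_fit) {
    if (max(object$columns) > ncol(X)) {
      stop(sprintf(
        "newdata has %d columns; cannot apply retained-variable index up to %d",
        ncol(X), max(object$columns)
      ))
    }
    X <- X[, object$columns, drop = FALSE]
  }
  if (ncol(X) != p_fit) {
    stop(sprintf("newdata has %d variables, model expects %d",
                 ncol(X), p_fit))
  }
  as.numeric(X %*% object$coefficients) + object$intercept
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted_values

#' @export
residuals.pls1 <- function(object, ...) object$y - object$fitted_values

# Coefficient path: regression vector and intercept for every component
# count 1..n_lv of a fitted model (triangular system reuse).
pls_coef_path <- function(fit) {
  K <- fit$n_lv
  B <- matrix(0, length(fit$coefficients), K)
  icpt <- numeric(K)
  PtW <- crossprod(fit$P, fit$W)
  for (k in seq_len(K)) {
    bk <- fit$W[, 1:k, drop = FALSE] %*%
      solve(PtW[1:k, 1:k, drop = FALSE], fit$q[1:k])
    B[, k] <- bk
    icpt[k] <- fit$y_mean - sum(fit$x_means * bk)
  }
  list(B = B, intercept = icpt)
}

#' Leave-one-out cross-validation of a PLS1 calibration
#'
#' For every sample, the model (including its centering statistics) is
#' refitted on the remaining `I - 1` rows with `1..max_lv` latent
#' variables, and the left-out row is predicted. Returns the PRESS curve
#' and the full matrix of left-out predictions, the inputs to
#' latent-variable selection and to the cross-validation outlier
#' statistic.
#'
#' @param x Pretreated calibration spectra (matrix or [spectrum_set()]).
#' @param y Response vector.
#' @param max_lv Largest candidate latent-variable count; clipped with a
#'   warning when infeasible for `I - 1` training rows. Default
#'   `min(20, I - 2, variables)`.
#' @param columns Optional retained-variable index (see [fit_pls()]).
#' @return An object of class `pls_cv`: `press` (PRESS per LV),
#'   `rmsecv` (`sqrt(PRESS/I)`), `predictions` (I x max_lv matrix of
#'   left-out predictions), `y`, `I`, `max_lv`.
#' @export
loo_cv <- function(x, y, max_lv = NULL, columns = NULL) {
  s <- as_spectra(x)
  X <- s$x
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  y <- as.numeric(y)
  I <- nrow(X)
  if (I < 3) stop("leave-one-out cross-validation needs at least 3 samples")
  feasible <- min(I - 2L, ncol(X))
  if (is.null(max_lv)) max_lv <- min(20L, feasible)
  if (max_lv > feasible) {
    warning(sprintf("max_lv clipped from %d to %d (I - 2, variables bound)",
                    max_lv, feasible))
    max_lv <- feasible
  }
  preds <- matrix(NA_real_, I, max_lv)
  for (i in seq_len(I)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], max_lv)
    path <- pls_coef_path(fit)
    pr <- as.numeric(X[i, ] %*% path$B) + path$intercept
    if (fit$n_lv < max_lv) { # degenerate tail: curve flattens
      pr <- c(pr, rep(pr[fit$n_lv], max_lv - fit$n_lv))
    }
    preds[i, ] <- pr
  }
  press <- colSums((preds - y)^2)
  structure(list(
    press = press, rmsecv = sqrt(press / I),
    predictions = preds, y = y, I = I, max_lv = as.integer(max_lv)
  ), class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  k <- which.min(x$press)
  cat(sprintf(
    "<pls_cv> I = %d, LV 1..%d; min PRESS %.4g at %d LV (RMSECV %.4g)\n",
    x$I, x$max_lv, x$press[k], k, x$rmsecv[k]
  ))
  invisible(x)
}

#' Select the latent-variable count from a PRESS curve
#'
#' Implements the parsimonious PRESS-ratio rule: the ratio
#' `PRESS(k)/min(PRESS)` is treated as a variance ratio (an F statistic
#' with `(I, I)` degrees of freedom), and the chosen model is the one
#' with the fewest latent variables whose PRESS is not significantly
#' worse than the minimum — i.e. the smallest `k <= argmin` whose ratio
#' has F-distribution probability below `prob_threshold` (default 0.75).
#' With `method = "ratio"` the F distribution is bypassed and the raw
#' ratio is compared against `ratio_max`.
#'
#' @param cv A [loo_cv()] record (or any list with `press` and `I`).
#' @param prob_threshold Probability threshold of the F rule (default
#'   0.75).
#' @param method `"f_test"` (default) or `"ratio"`.
#' @param ratio_max Raw-ratio bound used when `method = "ratio"`.
#' @return The chosen latent-variable count (integer).
#' @export
select_lv <- function(cv, prob_threshold = 0.75,
                      method = c("f_test", "ratio"), ratio_max = 1.25) {
  method <- match.arg(method)
  press <- cv$press
  I <- cv$I
  k_star <- which.min(press)
  ratio <- press / press[k_star]
  ok <- if (method == "f_test") {
    stats::pf(ratio, I, I) < prob_threshold
  } else {
    ratio <= ratio_max
  }
  candidates <- which(ok[seq_len(k_star)])
  as.integer(candidates[1])
}

#' Goodness-of-fit metrics
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`; `R2 = 1 - SSres/SStot` with `SStot`
#' about the mean of `y_true`. The squared Pearson correlation is also
#' returned (`r2_corr`) since some chemometric toolboxes report that
#' convention for cross-validation.
#'
#' @param y_true Observed values.
#' @param y_hat Predicted values.
#' @return A list with `rmse`, `r2`, `r2_corr` (`r2` is `NA` when
#'   `y_true` has zero variance).
#' @export
fit_metrics <- function(y_true, y_hat) {
  y_true <- as.numeric(y_true); y_hat <- as.numeric(y_hat)
  if (length(y_true) != length(y_hat) || length(y_true) < 2) {
    stop("y_true and y_hat must have equal length >= 2")
  }
  res <- y_true - y_hat
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  r2_corr <- if (ss_tot == 0 || stats::sd(y_hat) == 0) {
    NA_real_
  } else {
    stats::cor(y_true, y_hat)^2
  }
  list(rmse = rmse, r2 = r2, r2_corr = r2_corr)
}
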