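#' Parse a pretreatment chain code
#'
#' Chain codes are `" + "`-separated sequences of the tokens `SM`
#' (Savitzky-Golay smoothing), `Log` (decadic absorbance transform,
#' `A = -log10(R)`), `1st Dev` / `2nd Dev` (Savitzky-Golay derivatives)
#' and `MC` (mean centering), applied in the listed order — e.g.
#' `"SM + Log + 1st Dev + MC"`. Constraints: at most one derivative step;
#' `MC`, if present, must be last.
#'
#' @param code Chain code string. `"none"` or `""` gives an empty chain.
#' @param window Savitzky-Golay window length (odd, > `polyorder`).
#' @param polyorder Savitzky-Golay polynomial order.
#' @param log_base `10` for decadic absorbance (default) or `exp(1)` for
#'   natural log.
#' @return A list of class `pretreatment_chain`.
#' @export
parse_chain <- function(code, window = 7L, polyorder = 2L, log_base = 10) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  code <- trimws(code)
  steps <- if (code == "" || tolower(code) == "none") {
    character(0)
  } else {
    trimws(strsplit(code, "\\+")[[1]])
  }
  known <- c("SM", "Log", "1st Dev", "2nd Dev", "MC")
  bad <- setdiff(steps, known)
  if (length(bad)) {
    stop("unknown pretreatment token(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  n_dev <- sum(steps %in% c("1st Dev", "2nd Dev"))
  if (n_dev > 1) stop("a chain may contain at most one derivative step")
  if ("MC" %in% steps && match("MC", steps) != length(steps)) {
    stop("MC (mean centering) must be the last step of a chain")
  }
  structure(list(
    steps = steps, window = window, polyorder = polyorder,
    log_base = log_base, column_means = NULL, wavelengths = NULL
  ), class = "pretreatment_chain")
}

#' @export
print.pretreatment_chain <- function(x, ...) {
  cat(sprintf(
    "<pretreatment_chain> %s (window %d, polyorder %d)%s\n",
    if (length(x$steps)) paste(x$steps, collapse = " + ") else "identity",
    x$window, x$polyorder,
    if (is.null(x$column_means)) "" else " [fitted]"
  ))
  invisible(x)
}

#' Format a chain back to its code string
#' @param x A `pretreatment_chain`.
#' @param ... Unused.
#' @return The chain code, e.g. `"SM + 1st Dev + MC"`.
#' @export
format.pretreatment_chain <- function(x, ...) {
  if (!length(x$steps)) "none" else paste(x$steps, collapse = " + ")
}

apply_step <- function(step, x, wl, chain) {
  step_nm <- diff(wl)
  if (length(step_nm) && max(abs(step_nm - step_nm[1])) > 1e-8) {
    stop("pretreatment requires a uniform wavelength step")
  }
  h <- if (length(step_nm)) step_nm[1] else 1
  sg <- function(m) {
    if (chain$window > ncol(x)) {
      stop(sprintf(
        "Savitzky-Golay window (%d) exceeds the band count (%d)",
        chain$window, ncol(x)
      ))
    }
    t(apply(x, 1, function(row) {
      signal::sgolayfilt(row, p = chain$polyorder, n = chain$window,
                         m = m, ts = h)
    }))
  }
  switch(step,
    "SM" = sg(0L),
    "1st Dev" = sg(1L),
    "2nd Dev" = sg(2L),
    "Log" = {
      if (any(x <= 0)) {
        stop("Log transform requires strictly positive reflectance")
      }
      -log(x, base = chain$log_base)
    },
    "MC" = x, # handled by caller (needs fitted means)
    stop("unknown step: ", step)
  )
}

chain_core <- function(chain, x, wl) {
  for (step in chain$steps[chain$steps != "MC"]) {
    x <- apply_step(step, x, wl, chain)
  }
  x
}

#' Fit a pretreatment chain and transform the calibration spectra
#'
#' Applies the chain's operators in order. Smoothing and derivatives use
#' a Savitzky-Golay filter whose edge values come from the local
#' polynomial fit, so the wavelength grid is fully retained; derivatives
#' are scaled by the grid step (units per nm, per nm squared). If the
#' chain contains `MC`, the column means of the (otherwise transformed)
#' calibration spectra are stored in the returned chain for later use on
#' prediction data.
#'
#' @param chain A [parse_chain()] result.
#' @param x A [spectrum_set()] or numeric matrix (samples x wavelengths).
#' @param wl Wavelength grid; taken from `x` when it is a `spectrum_set`.
#' @return A list with elements `x` (transformed [spectrum_set()]) and
#'   `chain` (the fitted chain).
#' @export
fit_apply <- function(chain, x, wl = NULL) {
  stopifnot(inherits(chain, "pretreatment_chain"))
  s <- as_spectra(x, wl)
  if ("MC" %in% chain$steps && nrow(s$x) < 2) {
    stop("mean centering requires at least 2 calibration spectra")
  }
  out <- chain_core(chain, s$x, s$wavelengths)
  chain$wavelengths <- s$wavelengths
  if ("MC" %in% chain$steps) {
    chain$column_means <- colMeans(out)
    out <- sweep(out, 2, chain$column_means)
  }
  list(
    x = spectrum_set(out, s$wavelengths,
                     ifelse(is.na(s$region), "VIS-NIR", s$region)),
    chain = chain
  )
}

#' Apply a fitted pretreatment chain to new spectra
#'
#' Identical operators to [fit_apply()], except that `MC` subtracts the
#' column means stored at fitting time (no information flows from the
#' new spectra into the transform).
#'
#' @param chain A fitted `pretreatment_chain` (from [fit_apply()]).
#' @param x New spectra on the same wavelength grid.
#' @param wl Wavelength grid if `x` is a plain matrix.
#' @return Transformed [spectrum_set()].
#' @export
chain_apply <- function(chain, x, wl = NULL) {
  stopifnot(inherits(chain, "pretreatment_chain"))
  s <- as_spectra(x, wl)
  if ("MC" %in% chain$steps && is.null(chain$column_means)) {
    stop("chain contains MC but has not been fitted; use fit_apply() first")
  }
  if (!is.null(chain$wavelengths) &&
      !isTRUE(all.equal(chain$wavelengths, s$wavelengths))) {
    stop("wavelength grid of the new spectra does not match the fitted grid")
  }
  out <- chain_core(chain, s$x, s$wavelengths)
  if ("MC" %in% chain$steps) {
    out <- sweep(out, 2, chain$column_means)
  }
  spectrum_set(out, s$wavelengths,
               ifelse(is.na(s$region), "VIS-NIR", s$region))
}
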