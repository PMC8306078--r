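# Fruit/background segmentation and per-object mean-spectrum extraction.

# 8-connectivity connected-component labeling by iterative minimum-label
# propagation. Masks here are small (a few thousand pixels), so the
# fixed-point sweep is cheap and keeps the dependency surface flat
# (installed labelers use 4-connectivity).
label_components <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  idx <- matrix(seq_len(nr * nc), nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  repeat {
    changed <- FALSE
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]; dc <- shifts$dc[s]
      r_src <- max(1, 1 - dr):min(nr, nr - dr)
      c_src <- max(1, 1 - dc):min(nc, nc - dc)
      r_dst <- r_src + dr; c_dst <- c_src + dc
      src <- lab[r_src, c_src, drop = FALSE]
      dst <- lab[r_dst, c_dst, drop = FALSE]
      upd <- src > 0L & dst > 0L & dst < src
      if (any(upd)) {
        src[upd] <- dst[upd]
        lab[r_src, c_src] <- src
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # relabel 1..K ordered by centroid (row-major)
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  cent <- t(vapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- matrix(0L, nr, nc)
  for (new_k in seq_along(ord)) out[lab == ids[ord[new_k]]] <- new_k
  out
}

# drop connected components smaller than min_size pixels
remove_small_objects <- function(mask, min_size) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Segment fruit pixels from the background
#'
#' Thresholds a single band of the cube: foreground is reflectance above
#' the threshold. With `method = "otsu"` the threshold is computed from
#' the band histogram (Otsu's criterion via `EBImage::otsu`); with
#' `method = "fixed"` it must be supplied. Components smaller than
#' `min_size` pixels are removed.
#'
#' @param cube A [hypercube()].
#' @param method `"otsu"` or `"fixed"`.
#' @param band Band position in nm (matched to the nearest grid point).
#'   Default: the band nearest 800 nm (VIS-NIR) or 1100 nm (NIR), where
#'   fruit/background contrast is typically maximal.
#' @param threshold Reflectance threshold, required for `method =
#'   "fixed"`.
#' @param min_size Minimum connected-object size in pixels (default 20).
#' @return Logical `rows x cols` mask.
#' @export
build_mask <- function(cube, method = c("otsu", "fixed"), band = NULL,
                       threshold = NULL, min_size = 20L) {
  stopifnot(inherits(cube, "hypercube"))
  method <- match.arg(method)
  wl <- cube$wavelengths
  if (is.null(band)) {
    band <- if (identical(cube$region, "NIR")) 1100 else 800
    band <- min(max(band, min(wl)), max(wl))
  }
  j <- which.min(abs(wl - band))
  slice <- cube$data[, , j]
  if (method == "otsu") {
    rng <- range(slice)
    if (diff(rng) <= 0) {
      stop(sprintf("band %g nm is constant; cannot threshold", wl[j]))
    }
    threshold <- EBImage::otsu(slice, range = rng)
  } else if (is.null(threshold)) {
    stop("method = 'fixed' requires a threshold")
  }
  fg <- slice > threshold
  fg <- remove_small_objects(fg, min_size)
  if (!any(fg)) {
    stop(sprintf(
      "empty foreground: no pixels above threshold %.4g at band %g nm",
      threshold, wl[j]
    ))
  }
  fg
}

#' Extract per-object mean spectra
#'
#' Labels the mask's connected components (8-connectivity) and computes
#' each object's unweighted mean spectrum over its pixels. Objects are
#' numbered by centroid in row-major order.
#'
#' @param cube A [hypercube()].
#' @param mask Logical matrix; defaults to `cube$mask`.
#' @return A list of class `object_spectra` with elements `id`,
#'   `pixel_count`, `centroid` (n x 2 matrix of row/col), and `spectra`
#'   (a [spectrum_set()], one row per object).
#' @export
extract_object_spectra <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(mask)) stop("no mask supplied and cube carries none")
  mask <- as.matrix(mask)
  if (!any(mask)) stop("mask is empty")
  lab <- label_components(mask)
  k <- max(lab)
  p <- dim(cube$data)[3]
  flat <- matrix(cube$data, ncol = p) # pixel-major, band columns
  means <- matrix(0, k, p)
  counts <- integer(k)
  cent <- matrix(0, k, 2, dimnames = list(NULL, c("row", "col")))
  for (obj in seq_len(k)) {
    w <- which(lab == obj)
    counts[obj] <- length(w)
    means[obj, ] <- colMeans(flat[w, , drop = FALSE])
    rc <- which(lab == obj, arr.ind = TRUE)
    cent[obj, ] <- c(mean(rc[, 1]), mean(rc[, 2]))
  }
  structure(list(
    id = seq_len(k), pixel_count = counts, centroid = cent,
    spectra = spectrum_set(means, cube$wavelengths, cube$region)
  ), class = "object_spectra")
}

#' @export
print.object_spectra <- function(x, ...) {
  cat(sprintf("<object_spectra> %d objects, %d bands\n",
              length(x$id), ncol(x$spectra)))
  invisible(x)
}

# Flattened masked pixel spectra: matrix (n_masked x bands) plus linear
# indices, used for pixel-wise prediction maps.
pixel_spectra <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(mask)) stop("no mask supplied and cube carries none")
  p <- dim(cube$data)[3]
  flat <- matrix(cube$data, ncol = p)
  idx <- which(as.vector(mask))
  list(x = flat[idx, , drop = FALSE], index = idx,
       shape = dim(cube$data)[1:2])
}
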