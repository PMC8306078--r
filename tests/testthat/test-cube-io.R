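make_test_cube <- function(rows = 7, cols = 9, region = "VIS-NIR",
                           seed = 5) {
  set.seed(seed)
  wl <- make_wavelength_grid(400, 450, 5)
  hypercube(array(runif(rows * cols * length(wl)),
                  dim = c(rows, cols, length(wl))), wl, region)
}

test_that("ENVI round-trip is bit-identical for every interleave", {
  cube <- make_test_cube()
  for (il in c("bsq", "bil", "bip")) {
    path <- withr::local_tempfile(fileext = ".dat")
    write_cube(cube, path, "ENVI", interleave = il, data_type = 5)
    back <- read_cube(path, "ENVI")
    expect_identical(back$data, cube$data, label = paste("interleave", il))
    expect_equal(back$wavelengths, cube$wavelengths)
    expect_equal(back$region, cube$region)
  }
})

test_that("float32 and uint16 ENVI payloads survive within precision", {
  cube <- make_test_cube()
  path <- withr::local_tempfile(fileext = ".dat")
  write_cube(cube, path, "ENVI", data_type = 4)
  expect_equal(read_cube(path)$data, cube$data, tolerance = 1e-6)
  counts <- cube
  counts$data <- round(cube$data * 10000)
  path2 <- withr::local_tempfile(fileext = ".dat")
  write_cube(counts, path2, "ENVI", data_type = 12)
  expect_identical(read_cube(path2)$data, counts$data)
})

test_that("TIFF round-trip preserves data and wavelength metadata", {
  cube <- make_test_cube()
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path, "TIFF")
  back <- read_cube(path, "TIFF")
  expect_equal(back$data, cube$data, tolerance = 1e-6)
  expect_equal(back$wavelengths, cube$wavelengths)
})

test_that("inconsistent or incomplete headers are rejected", {
  cube <- make_test_cube()
  path <- withr::local_tempfile(fileext = ".dat")
  write_cube(cube, path, "ENVI")
  hdr <- readLines(paste0(path, ".hdr"))

  # band count disagreeing with the wavelength list
  bad <- sub("^bands = .*", "bands = 10", hdr)
  writeLines(bad, paste0(path, ".hdr"))
  expect_error(read_cube(path), "declares 10 bands but lists 11")

  # missing wavelength list
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "no wavelength list")

  # dims disagreeing with the binary payload, both sizes reported
  bad <- sub("^lines = .*", "lines = 12", hdr)
  writeLines(bad, paste0(path, ".hdr"))
  expect_error(read_cube(path), "expected .* found")
})

test_that("fixed-threshold masking recovers the ground truth exactly", {
  b <- tiny_batch(n = 2, noise_sd = 0, seed = 23)
  cube <- generate_cube(b, 1, shape = c(40, 40), axes = c(10, 12),
                        modulation = 0)
  # fruit reflectance ~0.2-0.6, background 0.02: threshold in between
  mask <- build_mask(cube, method = "fixed", threshold = 0.1, min_size = 1)
  expect_identical(mask, cube$truth$mask)
  # masking is idempotent: same parameters, same mask
  expect_identical(build_mask(cube, "fixed", threshold = 0.1, min_size = 1),
                   mask)
})

test_that("otsu masking agrees with ground truth on noisy cubes", {
  b <- tiny_batch(n = 2, noise_sd = 0.01, seed = 29)
  cube <- generate_cube(b, 1, shape = c(40, 50), axes = c(11, 14))
  mask <- build_mask(cube, method = "otsu")
  agreement <- mean(mask == cube$truth$mask)
  expect_gte(agreement, 0.99)
})

test_that("an all-background cube raises an empty-foreground error", {
  wl <- make_wavelength_grid(400, 450, 5)
  dark <- hypercube(array(0.01, dim = c(10, 10, length(wl))), wl)
  expect_error(build_mask(dark, "fixed", threshold = 0.5),
               "empty foreground")
})

test_that("object spectra match a literal per-pixel loop", {
  b <- tiny_batch(n = 2, noise_sd = 0.005, seed = 31)
  cube <- generate_cube(b, 2, shape = c(30, 36), axes = c(7, 9))
  obj <- extract_object_spectra(cube)
  expect_length(obj$id, 1)
  # brute-force oracle
  px <- which(cube$mask, arr.ind = TRUE)
  acc <- 0
  for (r in seq_len(nrow(px))) {
    acc <- acc + cube$data[px[r, 1], px[r, 2], ]
  }
  expect_equal(as.numeric(obj$spectra[1, , drop = TRUE]),
               as.numeric(acc / nrow(px)), tolerance = 1e-12)
  expect_equal(obj$pixel_count, nrow(px))
})

test_that("zero-modulation object mean equals the injected spectrum", {
  b <- tiny_batch(n = 2, noise_sd = 0, seed = 37)
  cube <- generate_cube(b, 1, shape = c(30, 30), axes = c(8, 8),
                        modulation = 0)
  obj <- extract_object_spectra(cube)
  expect_equal(as.numeric(obj$spectra[1, , drop = TRUE]),
               as.numeric(b$spectra[1, , drop = TRUE]), tolerance = 1e-9)
})

test_that("disjoint fruits are labeled as separate 8-connected objects", {
  wl <- make_wavelength_grid(400, 420, 5)
  data <- array(0.01, dim = c(20, 20, length(wl)))
  data[3:6, 3:6, ] <- 0.8
  data[12:16, 10:15, ] <- 0.7
  cube <- hypercube(data, wl)
  mask <- build_mask(cube, "fixed", threshold = 0.4, min_size = 1)
  obj <- extract_object_spectra(cube, mask)
  expect_length(obj$id, 2)
  # row-major centroid ordering
  expect_lt(obj$centroid[1, "row"], obj$centroid[2, "row"])
  # diagonal contact joins components under 8-connectivity
  data2 <- array(0.01, dim = c(10, 10, length(wl)))
  data2[2:4, 2:4, ] <- 0.8
  data2[5, 5, ] <- 0.8 # touches (4,4) only diagonally
  cube2 <- hypercube(data2, wl)
  obj2 <- extract_object_spectra(
    cube2, build_mask(cube2, "fixed", threshold = 0.4, min_size = 1)
  )
  expect_length(obj2$id, 1)
})

test_that("mask PNG round-trips", {
  m <- matrix(FALSE, 8, 9)
  m[3:5, 4:7] <- TRUE
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
})
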