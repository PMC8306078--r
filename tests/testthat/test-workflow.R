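test_that("stratified splits follow the 70/30 design", {
  stage <- rep(1:4, each = 25)
  sp <- split_samples(stage, fraction = 0.7, seed = 5)
  expect_length(sp$calibration, 70)
  expect_length(sp$prediction, 30)
  per_stage <- table(stage[sp$calibration])
  expect_true(all(per_stage >= 17))
  # disjoint and exhaustive
  expect_length(intersect(sp$calibration, sp$prediction), 0)
  expect_setequal(c(sp$calibration, sp$prediction), seq_along(stage))
  # same seed reproduces the partition
  expect_identical(split_samples(stage, 0.7, seed = 5), sp)
  # rounding toward calibration: 97 samples in one stratum -> 68/29
  sp97 <- split_samples(rep(1, 97), 0.7, seed = 2)
  expect_length(sp97$calibration, 68)
  expect_length(sp97$prediction, 29)
  expect_error(split_samples(c(1, 1, 2), 0.7), "stratum '2'")
  expect_error(split_samples(stage, 1.2), "strictly between")
})

test_that("the model grid produces one populated row per configuration", {
  b <- tiny_batch(n = 40, noise_sd = 0.004, seed = 89, baseline_amp = 0.003)
  chains <- c("MC", "SM + MC", "SM + 1st Dev + MC")
  rep <- run_grid(b, "ssc", chains, seed = 3, refine = "none")
  expect_equal(nrow(rep), 3)
  expect_equal(rep$pretreatment, chains)
  for (col in c("lvs", "r2_cal", "rmsec", "r2_cv", "rmsecv",
                "r2_pred", "rmsep")) {
    expect_true(all(!is.na(rep[[col]])), label = col)
  }
  expect_true(all(is.na(rep$error)))
})

test_that("noiseless synthetic data is calibrated almost perfectly", {
  b <- tiny_batch(n = 40, noise_sd = 0, seed = 97)
  rep <- run_grid(b, c("ssc", "ta"), "SM + MC", seed = 3, refine = "none")
  expect_true(all(rep$r2_cal >= 0.99))
})

test_that("per-constituent missing values shrink the sample base", {
  b <- tiny_batch(n = 40, noise_sd = 0.004, seed = 101)
  b$concentrations$ssc[1:6] <- NA
  rep <- run_grid(b, c("ssc", "ta"), "SM + MC", seed = 3, refine = "none")
  expect_equal(rep$n_sample[rep$parameter == "ssc"], 34)
  expect_equal(rep$n_sample[rep$parameter == "ta"], 40)
})

test_that("failed configurations are recorded per-row, not fatally", {
  b <- tiny_batch(n = 40, noise_sd = 0.004, seed = 103)
  b$concentrations$ta <- 1 # zero variance: calibration must fail
  rep <- run_grid(b, c("ssc", "ta"), "SM + MC", seed = 3, refine = "none")
  ssc_row <- rep[rep$parameter == "ssc", ]
  ta_row <- rep[rep$parameter == "ta", ]
  expect_true(is.na(ssc_row$error))
  expect_match(ta_row$error, "zero variance")
  expect_true(is.na(ta_row$r2_pred))
})

test_that("best-model selection applies the RMSEP-first tie chain", {
  base <- empty <- data.frame(
    parameter = "x", region = "VIS-NIR", pretreatment = c("a", "b", "c"),
    effective_wavelength_range_nm = "", n_sample = 90L,
    n_variables = c(121L, 121L, 121L), lvs = c(5L, 4L, 6L),
    r2_cal = 0.9, rmsec = 0.1, r2_cv = 0.8, rmsecv = 0.2,
    r2_pred = c(0.90, 0.80, 0.91), rmsep = c(0.05, 0.04, 0.04),
    removed_samples = "", refined = FALSE, error = NA_character_,
    stringsAsFactors = FALSE
  )
  expect_equal(select_best(base)$pretreatment, "c") # lowest RMSEP, best R2
  single <- base[2, ]
  expect_equal(select_best(single)$pretreatment, "b")
  ties <- base
  ties$rmsep <- 0.04; ties$r2_pred <- 0.9; ties$lvs <- 5L
  expect_equal(select_best(ties)$pretreatment, "a") # stable order
  expect_error(select_best(transform(base, rmsep = NA_real_)),
               "no rows")
})

test_that("report CSVs use the prediction-table column order", {
  b <- tiny_batch(n = 30, noise_sd = 0.004, seed = 107)
  rep <- run_grid(b, "ssc", "SM + MC", seed = 3, refine = "none")
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, path, style = "table")
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", header), c(
    "parameter", "effective_wavelength_range_nm", "n_sample",
    "n_variables", "lvs", "r2_cal", "rmsec", "r2_cv", "rmsecv",
    "r2_pred", "rmsep"
  ))
})

test_that("refinement rows carry retained ranges and removed samples", {
  b <- tiny_batch(n = 45, noise_sd = 0.004, seed = 109, baseline_amp = 0.003)
  rep <- run_grid(b, "ta", c("SM + MC"), seed = 3, refine = "best",
                  n_intervals = 6)
  refined <- rep[rep$refined, ]
  expect_equal(nrow(refined), 1)
  expect_true(is.na(refined$error))
  expect_match(refined$effective_wavelength_range_nm, "^[0-9]+-[0-9]+")
  # refined RMSECV cannot exceed the full-spectrum RMSECV of its chain
  full <- rep[!rep$refined & rep$pretreatment == refined$pretreatment, ]
  expect_lte(refined$rmsecv, full$rmsecv + 1e-12)
})

test_that("pixel maps equal object-mean predictions for linear chains", {
  b <- tiny_batch(n = 25, noise_sd = 0, seed = 113)
  cal <- pls_calibration(b$spectra, b$concentrations$ssc, chain = "MC",
                         constituent = "ssc")
  cube <- generate_cube(b, 3, shape = c(30, 34), axes = c(8, 10),
                        modulation = 0)
  map <- predict_map(cube, cal)
  obj <- extract_object_spectra(cube)
  obj_pred <- predict(cal, obj$spectra)
  px_vals <- map$values[cube$mask]
  expect_equal(px_vals, rep(obj_pred, length(px_vals)), tolerance = 1e-9)
  # linearity of the full map: mean of pixel predictions equals the
  # prediction of the mean spectrum even with spatial structure
  cube2 <- generate_cube(b, 4, shape = c(30, 34), axes = c(8, 10),
                         modulation = 0.2)
  map2 <- predict_map(cube2, cal)
  obj2 <- extract_object_spectra(cube2)
  expect_equal(mean(map2$values[cube2$mask]),
               predict(cal, obj2$spectra)[1], tolerance = 1e-9)
})

test_that("pixel maps recover the injected concentration field", {
  b <- tiny_batch(n = 30, noise_sd = 0, seed = 127)
  cal <- pls_calibration(b$spectra, b$concentrations$ta, chain = "MC",
                         constituent = "ta")
  cube <- generate_cube(b, 5, shape = c(32, 36), axes = c(9, 11),
                        modulation = 0.15)
  map <- predict_map(cube, cal)
  truth <- cube$truth$concentration_field$ta
  err <- map$values[cube$mask] - truth[cube$mask]
  rng <- diff(range(truth[cube$mask]))
  expect_lte(sqrt(mean(err^2)), 0.01 * rng + 0.02 * sd(b$concentrations$ta))
})

test_that("degenerate map inputs are handled per contract", {
  b <- tiny_batch(n = 20, noise_sd = 0, seed = 131)
  cal <- pls_calibration(b$spectra, b$concentrations$ssc, chain = "MC")
  cube <- generate_cube(b, 1, shape = c(20, 20), axes = c(5, 6))
  empty_mask <- matrix(FALSE, 20, 20)
  map <- predict_map(cube, cal, mask = empty_mask)
  expect_true(all(is.na(map$values)))
  nir <- tiny_batch(n = 20, noise_sd = 0, seed = 131, region = "NIR")
  cube_nir <- generate_cube(nir, 1, shape = c(20, 20), axes = c(5, 6))
  expect_error(predict_map(cube_nir, cal), "grid")
})

test_that("identical configuration and seed give byte-identical reports", {
  b1 <- simulate_batch(generator_config(n_samples = 30, seed = 11))
  b2 <- simulate_batch(generator_config(n_samples = 30, seed = 11))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_report(run_grid(b1, "ta", c("MC", "SM + MC"), seed = 7,
                        refine = "none"), p1)
  write_report(run_grid(b2, "ta", c("MC", "SM + MC"), seed = 7,
                        refine = "none"), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("calibration accessors behave like a standard model object", {
  b <- tiny_batch(n = 30, noise_sd = 0.004, seed = 137)
  cal <- pls_calibration(b$spectra, b$concentrations$ssc,
                         chain = "SM + MC", constituent = "ssc")
  expect_s3_class(cal, "pls_calibration")
  expect_length(coef(cal), ncol(b$spectra) + 1)
  expect_equal(length(fitted(cal)), 30)
  expect_equal(residuals(cal), b$concentrations$ssc - fitted(cal))
  expect_output(print(cal), "R2cal")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(cal))
})
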