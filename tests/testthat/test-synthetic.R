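test_that("sampled concentrations hit the target population moments", {
  cfg <- generator_config(n_samples = 1000, seed = 7)
  cc <- sample_concentrations(cfg)
  for (k in seq_along(cfg$constituents)) {
    nm <- cfg$constituents[k]
    st <- cfg$stats[k, ]
    expect_true(all(cc[[nm]] >= st$min & cc[[nm]] <= st$max),
                label = paste(nm, "within configured range"))
    # pooled moments within 10% of targets
    expect_lt(abs(mean(cc[[nm]]) - st$mean), 0.10 * st$mean)
    expect_lt(abs(sd(cc[[nm]]) - st$sd), 0.10 * st$sd)
    # documented vitamin C example: mean within 3 sd / sqrt(n)
    if (nm == "vitamin_c") {
      expect_lt(abs(mean(cc[[nm]]) - 0.31), 3 * 0.14 / sqrt(1000))
    }
  }
})

test_that("riper stages carry higher soluble solids and vitamin C", {
  cfg <- generator_config(n_samples = 2000, seed = 21)
  cc <- sample_concentrations(cfg)
  for (nm in c("ssc", "vitamin_c", "ta")) {
    stage_means <- tapply(cc[[nm]], cc$stage, mean)
    expect_true(all(diff(stage_means) > 0),
                label = paste(nm, "stage means increase"))
  }
})

test_that("degenerate sd = 0 collapses every stage to its mean", {
  st <- constituent_stats()
  st$sd <- 0
  cfg <- generator_config(n_samples = 20, stats = st, seed = 5)
  cc <- sample_concentrations(cfg)
  for (nm in cfg$constituents) {
    expect_equal(length(unique(cc[[nm]])), 1)
  }
})

test_that("equal seeds give bit-identical batches", {
  b1 <- simulate_batch(generator_config(n_samples = 15, seed = 33))
  b2 <- simulate_batch(generator_config(n_samples = 15, seed = 33))
  expect_identical(b1$concentrations, b2$concentrations)
  expect_identical(unclass(b1$spectra), unclass(b2$spectra))
})

test_that("reflectance is bounded in (0, 1] and absorbance non-negative", {
  b <- tiny_batch(n = 30, noise_sd = 0.01, seed = 9, baseline_amp = 0.005)
  expect_true(all(b$spectra > 0))
  expect_true(all(b$spectra <= 1))
  expect_true(all(-log10(b$spectra) >= 0))
})

test_that("noiseless absorbance is exactly linear in concentrations", {
  cfg <- generator_config(n_samples = 8, noise_sd = 0, baseline_amp = 0,
                          seed = 13)
  b <- simulate_batch(cfg)
  # independent oracle: direct matrix product of the stored design
  C <- as.matrix(b$concentrations[, cfg$constituents])
  A_oracle <- C %*% t(b$truth$design) +
    matrix(b$truth$background, nrow(C), length(b$truth$background),
           byrow = TRUE)
  expect_equal(b$truth$absorbance, A_oracle, tolerance = 1e-12)
  expect_equal(unclass(b$spectra), 10^(-A_oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("absorbance at a band center increases with concentration", {
  st <- constituent_stats()
  st <- st[st$constituent == "ta", ]
  cfg <- generator_config(
    n_samples = 10, constituents = "ta", stats = st,
    noise_sd = 0, baseline_amp = 0, stage_shift = c(ta = 0), seed = 3
  )
  bands <- component_band("ta", 950, 12, 0.28)
  b <- mix_spectra(sample_concentrations(cfg), bands, cfg)
  grid <- wavelengths(b$spectra)
  j <- which.min(abs(grid - 950))
  A_center <- -log10(b$spectra[, j])
  ord <- order(b$concentrations$ta)
  expect_true(all(diff(A_center[ord]) > 0))
})

test_that("identical concentrations give identical noiseless spectra", {
  cfg <- generator_config(n_samples = 2, noise_sd = 0, baseline_amp = 0,
                          seed = 17)
  stopifnot(cfg$baseline_amp == 0) # per-sample drift off: spectra must match
  cc <- sample_concentrations(cfg)
  cc[2, cfg$constituents] <- cc[1, cfg$constituents]
  b <- mix_spectra(cc, config = cfg)
  expect_equal(b$spectra[1, , drop = TRUE], b$spectra[2, , drop = TRUE])
})

test_that("a constituent without an in-region band is rejected", {
  st <- constituent_stats()
  cfg <- generator_config(
    n_samples = 5, region = "NIR",
    constituents = c("vitamin_c", "phenols"),
    stats = st, seed = 1
  )
  expect_error(mix_spectra(sample_concentrations(cfg), config = cfg),
               "phenols.*no absorption band")
})

test_that("synthetic cubes honor geometry and field constraints", {
  b <- tiny_batch(n = 3, noise_sd = 0, seed = 41)
  cube <- generate_cube(b, sample = 2, shape = c(50, 60),
                        axes = c(12, 18), modulation = 0.2)
  # mask pixel count close to the ellipse area a*b*pi
  area <- pi * 12 * 18
  expect_lt(abs(sum(cube$mask) - area) / area, 0.05)
  # spatial mean of each per-pixel concentration field equals nominal
  for (nm in names(cube$truth$concentration_field)) {
    f <- cube$truth$concentration_field[[nm]]
    expect_equal(mean(f[cube$mask]), unname(cube$truth$nominal[[nm]]),
                 tolerance = 1e-9)
  }
  # ellipse exceeding the frame is rejected
  expect_error(
    generate_cube(b, 1, shape = c(20, 20), axes = c(15, 15)),
    "exceeds"
  )
})

test_that("zero radial modulation makes every fruit pixel the sample spectrum", {
  b <- tiny_batch(n = 2, noise_sd = 0, seed = 19)
  cube <- generate_cube(b, sample = 1, shape = c(30, 30), axes = c(8, 10),
                        modulation = 0)
  px <- which(cube$mask, arr.ind = TRUE)
  ref <- as.numeric(b$spectra[1, , drop = TRUE])
  for (r in sample(nrow(px), 5)) {
    expect_equal(as.numeric(cube$data[px[r, 1], px[r, 2], ]), ref,
                 tolerance = 1e-9)
  }
})
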