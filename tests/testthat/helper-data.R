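# Shared fixtures, all generated in code.

# small synthetic batch (noiseless unless stated) for cube / io tests
tiny_batch <- function(n = 6, noise_sd = 0, seed = 101, region = "VIS-NIR",
                       baseline_amp = 0) {
  cfg <- generator_config(
    n_samples = n, region = region, noise_sd = noise_sd,
    baseline_amp = baseline_amp, seed = seed
  )
  simulate_batch(cfg)
}

# small random regression problem with known linear structure
tiny_regression <- function(I = 12, p = 6, seed = 1, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(I * p), I, p)
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta + rnorm(I, 0, noise))
  list(X = X, y = y, beta = beta)
}

# literal leave-one-out PRESS oracle: refits I times from scratch,
# independent of loo_cv's internals
press_oracle <- function(X, y, max_lv) {
  I <- nrow(X)
  preds <- matrix(NA_real_, I, max_lv)
  for (i in seq_len(I)) {
    for (k in seq_len(max_lv)) {
      fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_lv = k)
      preds[i, k] <- predict(fit, X[i, , drop = FALSE])
    }
  }
  colSums((preds - y)^2)
}
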