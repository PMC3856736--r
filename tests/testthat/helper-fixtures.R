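# Programmatic fixtures shared across test files.

# Pixel table whose covariates are draws from a 4-D Gaussian with the
# default correlation; the first `n_nests` rows of each location are nests.
mvn_pixels <- function(name, n, n_nests, seed) {
  with_seed(seed, {
    z <- matrix(rnorm(n * 4), n, 4) %*% chol(default_correlation())
    data.frame(location = name, row = seq_len(n), col = 1L,
               cosasp = z[, 1] * 0.3, dnbr = 400 + z[, 2] * 150,
               loccc = 0.5 + z[, 3] * 0.1, landcc = 0.5 + z[, 4] * 0.1,
               in_unit = 1L, nest = rep(c(1L, 0L), c(n_nests, n - n_nests)),
               stringsAsFactors = FALSE)
  })
}

# Three-location Gaussian calibration table (no spatial structure).
mvn_study_table <- function(n = 1500, n_nests = 60, seed = 1) {
  rbind(mvn_pixels("a", n, n_nests, derive_seed(seed, "a")),
        mvn_pixels("b", n, n_nests, derive_seed(seed, "b")),
        mvn_pixels("c", n, n_nests, derive_seed(seed, "c")))
}

# Small simulated landscape for quick model fits.
quick_location <- function(seed = 1, n_nests = 30, side = 60) {
  simulate_location(location_spec("quick", side, side, n_nests = n_nests),
                    truth_model(), seed = seed)
}

# Compact full-study config for pipeline tests.
quick_config <- function(seed = 1, side = 60, mahal_iters = 25,
                         n_application = 2) {
  shifts <- c(2, 3)[seq_len(n_application)]
  run_config(
    study = study_spec(default_calibration_specs(side, side),
                       default_application_specs(side, side,
                                                 dnbr_shift_sd = shifts),
                       seed = seed),
    seed = seed, mahal_iters = mahal_iters, n_available = 3000,
    distance_per_location = 1000)
}

run_quietly <- function(cfg) {
  suppressMessages(run_study(cfg, verbose = FALSE))
}

# Brute-force AUC by exhaustive pair counting (independent oracle).
auc_brute <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Brute-force predictive-gain scan (independent oracle).
max_gain_brute <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  cand <- c(cand, max(cand) + 1)
  gains <- vapply(cand, function(t) mean(pos >= t) - mean(neg >= t), 0)
  best <- min(cand[gains >= max(gains) - 1e-12])
  list(threshold = best, gain = max(gains))
}
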