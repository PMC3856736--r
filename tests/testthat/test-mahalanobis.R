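# Partitioned Mahalanobis D2: eigenstructure, oracle equivalence at k_max,
# chi-square rescaling, the subsample-CV harness and Pareto selection.

test_that("bivariate correlation 0.9 yields eigenvalues 0.1 and 1.9", {
  with_seed(31, {
    z <- matrix(rnorm(4000), 2000, 2)
    r <- matrix(c(1, .9, .9, 1), 2)
    x <- z %*% chol(r)
    nest <- data.frame(cosasp = x[, 1], dnbr = x[, 2],
                       loccc = runif(2000), landcc = runif(2000),
                       location = "x", row = 1, col = 1, in_unit = 1, nest = 1)
    rep1 <- fit_replicate(nest, mahal_partition_spec(c("cosasp", "dnbr"), 1))
    expect_equal(rep1$values, c(0.1, 1.9), tolerance = 0.05)
    expect_equal(crossprod(rep1$vectors), diag(2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
})

test_that("k_max partition equals the classical Mahalanobis oracle", {
  for (s in 1:5) {
    nest <- mvn_pixels("m", 60, 60, seed = 300 + s)
    px <- mvn_pixels("p", 40, 0, seed = 400 + s)
    r <- fit_replicate(nest, mahal_partition_spec(covariate_names(), 4))
    d2 <- d2_partition(r, px)
    oracle <- mahalanobis(as.matrix(px[, covariate_names()]),
                          colMeans(as.matrix(nest[, covariate_names()])),
                          cov(as.matrix(nest[, covariate_names()])))
    expect_equal(d2, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("D2 is zero at the nest mean and ignores excluded components", {
  nest <- mvn_pixels("m", 80, 80, seed = 33)
  r1 <- fit_replicate(nest, mahal_partition_spec(covariate_names(), 1))
  centre <- nest[1, ]
  centre[covariate_names()] <- as.list(r1$center)
  expect_equal(d2_partition(r1, centre), 0, tolerance = 1e-12)
  # moving along an excluded (highest-variance) component leaves D2 fixed
  v_excl <- r1$vectors[, 4]                      # ascending order: last = max
  shifted <- centre
  shifted[covariate_names()] <-
    as.list(r1$center + 2 * r1$scale * v_excl)
  expect_equal(d2_partition(r1, shifted), 0, tolerance = 1e-10)
})

test_that("chi-square rescaling hits its closed forms", {
  expect_equal(hsi_from_d2(0, 3), 1)
  expect_equal(hsi_from_d2(2 * log(2), 2), 0.5)
  expect_lt(hsi_from_d2(1e6, 4), 1e-12)
  d2 <- seq(0, 10, by = 0.5)
  expect_true(all(diff(hsi_from_d2(d2, 2)) < 0))
})

test_that("identity-correlation D2 at one SD along each axis is the
           dimension count", {
  with_seed(35, {
    n <- 50000
    nest <- data.frame(cosasp = rnorm(n), dnbr = rnorm(n),
                       loccc = rnorm(n), landcc = rnorm(n))
    r <- fit_replicate(nest[, 1:2], mahal_partition_spec(c("cosasp", "dnbr"), 2))
    probe <- data.frame(cosasp = r$center[1] + r$scale[1],
                        dnbr = r$center[2] + r$scale[2])
    expect_equal(d2_partition(r, probe), 2, tolerance = 0.05)
  })
})

test_that("the averaged fit is deterministic, balanced and bounded", {
  tab <- mvn_study_table(n = 400, n_nests = 40, seed = 37)
  sp <- mahal_partition_spec(covariate_names(), 4)
  f1 <- fit_mahal(tab, sp, n_iter = 10, per_location_nests = 28, seed = 41)
  f2 <- fit_mahal(tab, sp, n_iter = 10, per_location_nests = 28, seed = 41)
  expect_equal(f1$replicates, f2$replicates)
  expect_length(f1$replicates, 10)
  h <- predict(f1, tab[1:200, ])
  expect_true(all(h >= 0 & h <= 1))
  single <- f1; single$replicates <- f1$replicates[1]
  expect_equal(predict(single, tab[1:50, ]),
               hsi_from_d2(d2_partition(f1$replicates[[1]], tab[1:50, ]), 4))
})

test_that("too few nests per location is a named error", {
  tab <- mvn_study_table(n = 200, n_nests = 10, seed = 43)
  expect_error(fit_mahal(tab, mahal_partition_spec(covariate_names(), 4),
                         per_location_nests = 28), "fewer than 28")
})

test_that("the CV harness returns iter x fold replicates and a PIT-consistent
           null", {
  tab <- mvn_study_table(n = 600, n_nests = 120, seed = 47)
  sp <- mahal_partition_spec(covariate_names(), 4)
  ev <- subsample_cv_evaluate(tab, sp, n_iter = 2, per_location_nests = 30,
                              folds = 5, n_available = 600, seed = 51)
  expect_equal(nrow(ev$replicates), 10)
  ev2 <- subsample_cv_evaluate(tab, sp, n_iter = 2, per_location_nests = 30,
                               folds = 5, n_available = 600, seed = 51)
  expect_equal(ev$replicates, ev2$replicates)
  # nests and available pixels share one distribution: AUC near 1/2 and
  # (at this subsample size) median nest HSI moderately below 1/2
  ev3 <- subsample_cv_evaluate(tab, sp, n_iter = 10,
                               per_location_nests = 100, folds = 5,
                               n_available = 900, seed = 53)
  expect_lt(abs(ev3$auc - 0.5), 0.06)
  expect_lt(abs(ev3$median_nest_hsi - 0.5), 0.07)
})

test_that("spec constraints are enforced", {
  expect_error(mahal_partition_spec(c("cosasp", "loccc")), "dnbr")
  expect_error(mahal_partition_spec(c("dnbr"), 2), "k")
  specs <- suppressMessages(enumerate_mahal_specs())
  expect_length(specs, 10)
})

test_that("Pareto selection keeps exactly the nondominated candidates", {
  m <- data.frame(model = c("a", "b", "c", "d"),
                  median_nest_hsi = c(0.5, 0.4, 0.3, 0.35),
                  auc = c(0.6, 0.7, 0.8, 0.62))
  sel <- select_mahal_models(m)
  # brute-force dominance check
  dom <- function(i, j) all(c(m$median_nest_hsi[j] >= m$median_nest_hsi[i],
                              m$auc[j] >= m$auc[i])) &&
    (m$median_nest_hsi[j] > m$median_nest_hsi[i] || m$auc[j] > m$auc[i])
  front <- which(!vapply(1:4, function(i)
    any(vapply(1:4, function(j) dom(i, j), logical(1))), logical(1)))
  expect_setequal(sel$model, m$model[front])
  # a dominated point is out, extremes are in
  expect_false("d" %in% sel$model)
  expect_true(all(c("a", "c") %in% sel$model))
  # ties are both retained
  t2 <- data.frame(model = c("x", "y"), median_nest_hsi = c(.4, .4),
                   auc = c(.7, .7))
  expect_equal(nrow(select_mahal_models(t2)), 2)
})
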