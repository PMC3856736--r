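# Ensemble counts, agreement proportions, environmental distance and the
# novelty diagnostics.

make_fit_with_threshold <- function(tab, covs, thr_data, seed = 1) {
  fit <- fit_wlr(tab[tab$nest == 1, ],
                 tab[tab$nest == 0 & tab$in_unit == 1, ][1:100, ], covs)
  set_threshold(fit, threshold_max_gain(
    predict(fit, tab[tab$nest == 1, ]), predict(fit, thr_data)))
}

test_that("classification uses the >= rule and matches scalar comparisons", {
  tab <- quick_location(seed = 101, n_nests = 30)
  f1 <- make_fit_with_threshold(tab, "dnbr", tab)
  f2 <- make_fit_with_threshold(tab, c("dnbr", "loccc"), tab)
  cls <- classify_all(list(a = f1, b = f2), tab[1:500, ])
  expect_identical(dim(cls), c(500L, 2L))
  expect_identical(cls[, "a"],
                   as.integer(predict(f1, tab[1:500, ]) >= f1$threshold))
  expect_identical(cls[, "b"],
                   as.integer(predict(f2, tab[1:500, ]) >= f2$threshold))
  # boundary pixel: exactly at threshold classifies suitable
  nofit <- f1; nofit$threshold <- NA_real_
  expect_error(classify_all(list(x = nofit), tab[1:5, ]), "threshold")
})

test_that("ensemble counts are row sums with the right bounds", {
  m <- rbind(c(1, 0, 1, 1, 0, 0, 1, 1), rep(1, 8), rep(0, 8))
  expect_identical(ensemble_count(m), c(5L, 8L, 0L))
  expect_error(ensemble_count(matrix(2, 2, 2)), "binary")
})

test_that("location proportions match direct counting and obey inclusion", {
  counts <- 0:8
  loc <- rep("z", 9)
  pr <- location_proportions(counts, loc, 8)
  expect_equal(pr$liberal, 8 / 9)
  expect_equal(pr$conservative, 1 / 9)
  expect_equal(pr$agreement, 2 / 9)
  pr3 <- location_proportions(rep(3, 10), rep("w", 10), 8)
  expect_equal(pr3$liberal, 1)
  expect_equal(pr3$conservative, 0)
  expect_equal(pr3$agreement, 0)
  # liberal >= conservative and agreement complement
  with_seed(103, {
    cs <- sample(0:8, 500, replace = TRUE)
    ls <- sample(c("p", "q"), 500, replace = TRUE)
    pr2 <- location_proportions(cs, ls, 8)
    expect_true(all(pr2$liberal >= pr2$conservative))
    mid <- vapply(c("p", "q"), function(l)
      mean(cs[ls == l] >= 1 & cs[ls == l] <= 7), 0)
    expect_equal(pr2$agreement + mid[pr2$location], rep(1, 2),
                 ignore_attr = TRUE)
  })
  # survey-unit exclusion
  iu <- rep(c(1, 0), 250)
  pr4 <- location_proportions(cs <- sample(0:8, 500, TRUE), rep("r", 500), 8,
                              in_unit = iu, exclude_survey_units = TRUE)
  expect_equal(pr4$n_pixels, 250)
})

test_that("nest rate by count recovers degenerate and null patterns", {
  counts <- rep(0:8, each = 50)
  nest <- as.integer(counts == 8 & seq_along(counts) %% 5 == 0)
  res <- nest_rate_by_count(counts, nest, 8)
  expect_equal(res$table$proportion[1:8], rep(0, 8))
  expect_gt(res$table$proportion[9], 0)
  expect_gt(res$pearson_r, 0)
  with_seed(105, {
    # independence: slope within 3 SE of zero most of the time
    slopes <- replicate(10, {
      cs <- sample(0:8, 3000, replace = TRUE)
      ns <- rbinom(3000, 1, 0.02)
      r <- nest_rate_by_count(cs, ns, 8)
      f <- lm(proportion ~ level, data = r$table)
      abs(coef(f)[2]) < 3 * summary(f)$coefficients[2, 2]
    })
    expect_gte(mean(slopes), 0.8)
  })
})

test_that("environmental distance matches hand quadratic forms and the
           mahalanobis oracle", {
  ref <- list(mean = c(cosasp = 0, dnbr = 0, loccc = 0, landcc = 0),
              cov = diag(c(4, 1, 1, 1)))
  px <- data.frame(cosasp = 2, dnbr = 1, loccc = 0, landcc = 0)
  expect_equal(environmental_distance(ref, px), sqrt(2))
  px0 <- data.frame(cosasp = 0, dnbr = 0, loccc = 0, landcc = 0)
  expect_equal(environmental_distance(ref, px0), 0)
  # identity covariance, unit offset
  ref2 <- list(mean = ref$mean, cov = diag(4))
  expect_equal(environmental_distance(ref2,
                                      data.frame(cosasp = 1, dnbr = 0,
                                                 loccc = 0, landcc = 0)), 1)
  # oracle on a fitted reference
  tab <- mvn_study_table(n = 400, n_nests = 30, seed = 107)
  dr <- distance_reference(tab, per_location = 200, seed = 109)
  d <- environmental_distance(dr, tab[1:50, ])
  oracle <- sqrt(mahalanobis(as.matrix(tab[1:50, covariate_names()]),
                             dr$mean, dr$cov))
  expect_equal(d, oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("distance is invariant to affine covariate rescaling when the
           reference is recomputed", {
  tab <- mvn_study_table(n = 300, n_nests = 30, seed = 111)
  dr1 <- distance_reference(tab, per_location = 150, seed = 1)
  tab2 <- tab
  tab2$dnbr <- tab2$dnbr / 100 + 3
  tab2$loccc <- tab2$loccc * 5
  dr2 <- distance_reference(tab2, per_location = 150, seed = 1)
  expect_equal(environmental_distance(dr1, tab[1:40, ]),
               environmental_distance(dr2, tab2[1:40, ]), tolerance = 1e-6)
})

test_that("median-unbiased distance summaries match known quantiles", {
  expect_equal(median_distance_summary(rep(2.5, 10)),
               c(median = 2.5, lower = 2.5, upper = 2.5))
  expect_equal(median_distance_summary(1:100)[["median"]], 50.5)
  with_seed(113, {
    # chi distribution with 4 df: compare with analytic quantiles
    d <- sqrt(stats::rchisq(2e5, df = 4))
    s <- median_distance_summary(d)
    expect_equal(s[["median"]], sqrt(stats::qchisq(0.5, 4)), tolerance = 0.01)
    expect_equal(s[["lower"]], sqrt(stats::qchisq(0.025, 4)), tolerance = 0.02)
    expect_equal(s[["upper"]], sqrt(stats::qchisq(0.975, 4)), tolerance = 0.02)
  })
})

test_that("agreement-distance regression recovers exact and null patterns", {
  d <- c(1, 2, 3, 4, 5)
  a <- 0.9 - 0.1 * d
  res <- suppressWarnings(agreement_vs_distance(a, d))  # exact-fit lm warning
  expect_equal(res$pearson_r, -1)
  expect_equal(res$slope, -0.1)
  expect_error(agreement_vs_distance(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(agreement_vs_distance(rep(0.5, 4), 1:4), "zero variance")
})

test_that("dose-response profiles are flat for constant scores and monotone
           for a dnbr-only model", {
  tab <- quick_location(seed = 115, n_nests = 30)
  fit <- fit_wlr(tab[tab$nest == 1, ],
                 tab[tab$nest == 0 & tab$in_unit == 1, ][1:100, ], "dnbr")
  prof <- dose_response_profile(fit, tab, "dnbr", n_bins = 8)
  expect_equal(nrow(prof), 8)
  med <- prof$median[!is.na(prof$median)]
  if (coef(fit)["dnbr"] > 0) expect_true(all(diff(med) >= 0))
  expect_error(dose_response_profile(fit, tab[1:3, ], "dnbr", n_bins = 8),
               "distinct")
})
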