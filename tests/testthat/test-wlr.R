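# Weighted logistic regression: AICc arithmetic, oracle equivalences,
# selection behaviour and prediction.

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(0, 0, 10), 0)
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  expect_equal(aicc(-5, 1, 1e9), -2 * -5 + 2, tolerance = 1e-6)
  expect_error(aicc(-5, 3, 4), "undefined")
})

test_that("equal class sizes reproduce the unweighted ML fit exactly", {
  set.seed(13)
  n <- 120
  d <- data.frame(cosasp = rnorm(n), dnbr = rnorm(n, 330, 230),
                  loccc = runif(n), landcc = runif(n))
  y <- rbinom(n, 1, plogis(scale(d$dnbr) * 0.8))
  used <- d[y == 1, ]; avail <- d[y == 0, ][seq_len(sum(y)), ]
  fit <- fit_wlr(used, avail, c("dnbr", "loccc"))
  oracle <- glm(rep(c(1, 0), c(nrow(used), nrow(avail))) ~ dnbr + loccc,
                family = binomial, data = rbind(used, avail))
  expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
})

test_that("null data give slope coefficients near zero", {
  set.seed(17)
  n <- 4000
  pool <- data.frame(cosasp = rnorm(n), dnbr = rnorm(n, 330, 230),
                     loccc = runif(n), landcc = runif(n))
  fit <- fit_wlr(pool[1:500, ], pool[501:n, ], covariate_names())
  # standardized coefficients ~ N(0, se); 3 SE on this n is well under 0.35
  expect_true(all(abs(fit$coefficients_std[-1]) < 0.35))
})

test_that("the weighted fit is invariant to rescaling all weights", {
  # equalized class weights are what makes available-sample size arbitrary:
  # doubling the available sample from the same distribution must not move
  # the coefficients systematically (same data, duplicated availables)
  set.seed(19)
  n <- 600
  d <- data.frame(cosasp = rnorm(n), dnbr = rnorm(n, 330, 230),
                  loccc = runif(n), landcc = runif(n))
  used <- d[1:100, ]; avail <- d[101:350, ]
  f1 <- fit_wlr(used, avail, "dnbr")
  f2 <- fit_wlr(used, rbind(avail, avail), "dnbr")
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-6)
})

test_that("a strong generating slope is recovered within 15 percent", {
  slopes <- vapply(1:25, function(s) with_seed(s, {
    N <- 30000; z <- rnorm(N)
    y <- rbinom(N, 1, plogis(-4 + 0.8 * z))
    used <- data.frame(dnbr = z[y == 1][1:200])
    avail <- data.frame(dnbr = sample(z[y == 0], 2000))
    coef(fit_wlr(used, avail, "dnbr"))[["dnbr"]]
  }), 0)
  expect_lt(abs(mean(slopes) - 0.8) / 0.8, 0.15)
  expect_true(all(slopes > 0))
})

test_that("all-subsets selection fits 16 models and ranks by AICc", {
  tab <- quick_location(seed = 23, n_nests = 40)
  used <- tab[tab$nest == 1, ]
  avail <- tab[tab$nest == 0 & tab$in_unit == 1, ][1:100, ]
  sel <- all_subsets_aicc(used, avail, covariate_names())
  expect_equal(nrow(sel$table), 16)
  expect_true("(intercept only)" %in% sel$table$model)
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_true(!is.unsorted(sel$table$aicc))
  # ranking invariant to covariate ordering
  sel2 <- all_subsets_aicc(used, avail, rev(covariate_names()))
  norm_lab <- function(x) vapply(strsplit(x, "+", fixed = TRUE),
                                 function(p) paste(sort(p), collapse = "+"),
                                 "")
  expect_identical(norm_lab(sel$table$model), norm_lab(sel2$table$model))
})

test_that("selection finds the generating covariate", {
  # strong dnbr-only truth: the chosen subset should contain dnbr
  tr <- truth_model(coefficients = c(cosasp = 0, dnbr = 1.5, loccc = 0,
                                     landcc = 0))
  hits <- vapply(1:10, function(s) {
    tab <- simulate_location(location_spec("sel", 60, 60, n_nests = 40),
                             tr, seed = 600 + s)
    used <- tab[tab$nest == 1, ]
    avail <- tab[tab$nest == 0 & tab$in_unit == 1, ][1:150, ]
    "dnbr" %in% all_subsets_aicc(used, avail)$best$covariates
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("constant covariates and perfect separation are flagged", {
  d <- data.frame(cosasp = rnorm(40), dnbr = rep(1, 40),
                  loccc = runif(40), landcc = runif(40))
  expect_error(fit_wlr(d[1:20, ], d[21:40, ], "dnbr"), "constant")
  sep <- data.frame(dnbr = c(rnorm(20, 10), rnorm(20, -10)),
                    cosasp = 0, loccc = 0, landcc = 0)
  fit <- fit_wlr(sep[1:20, ], sep[21:40, ], "dnbr")
  expect_true(fit$separated)
})

test_that("prediction is the inverse-logit of the linear predictor", {
  tab <- quick_location(seed = 29, n_nests = 30)
  fit <- fit_wlr(tab[tab$nest == 1, ],
                 tab[tab$nest == 0 & tab$in_unit == 1, ][1:80, ], "dnbr")
  px <- tab[1:50, ]
  expect_equal(predict(fit, px),
               plogis(coef(fit)[1] + coef(fit)["dnbr"] * px$dnbr),
               ignore_attr = TRUE)
  # monotone in dnbr by coefficient sign
  grid <- tab[rep(1, 20), ]
  grid$dnbr <- seq(0, 900, length.out = 20)
  h <- predict(fit, grid)
  if (coef(fit)["dnbr"] > 0) expect_true(all(diff(h) > 0))
  expect_error(predict(fit, grid[, "loccc", drop = FALSE]), "lacks")
})
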