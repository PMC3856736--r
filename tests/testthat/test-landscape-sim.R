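# Synthetic landscape generator: determinism, marginal and correlation
# fidelity, nest placement and validation.

test_that("identical spec and seed reproduce the identical table", {
  sp <- location_spec("det", 50, 50, n_nests = 10)
  t1 <- simulate_location(sp, truth_model(), seed = 11)
  t2 <- simulate_location(sp, truth_model(), seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_location(sp, truth_model(), seed = 12)
  expect_false(identical(t1, t3))
})

test_that("empirical dNBR mean matches the spec mean within 3 SE", {
  sp <- location_spec("fid", 100, 100,
                      mean_vector = c(0, 327.8, 0.63, 0.59),
                      sd_vector = c(0.69, 235.2, 0.42, 0.19), n_nests = 0)
  tab <- simulate_location(sp, truth_model(), seed = 21)
  se <- 235.2 / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$dnbr) - 327.8), 3 * se)
})

test_that("bounded covariates stay in range and track their spec moments", {
  sp <- location_spec("fid2", 100, 100, n_nests = 0)
  ok_mean <- 0
  for (s in 1:10) {
    tab <- simulate_location(sp, truth_model(), seed = 30 + s)
    expect_true(all(tab$cosasp >= -1 & tab$cosasp <= 1))
    expect_true(all(tab$loccc >= 0 & tab$loccc <= 1))
    expect_true(all(tab$landcc >= 0 & tab$landcc <= 1))
    ok_mean <- ok_mean +
      (abs(mean(tab$loccc) - 0.63) < 3 * 0.42 / 100) +
      (abs(mean(tab$landcc) - 0.59) < 3 * 0.19 / 100)
  }
  # clip noise on a spatially smoothed field makes single-seed 3-SE checks
  # fail occasionally by design; require a clear majority of passes
  expect_gte(ok_mean / 20, 0.8)
})

test_that("local/landscape canopy correlation is within 0.1 of spec", {
  sp <- location_spec("corfid", 100, 100, n_nests = 0)
  for (s in 1:5) {
    tab <- simulate_location(sp, truth_model(), seed = 40 + s)
    expect_lt(abs(cor(tab$loccc, tab$landcc) - 0.635), 0.1)
  }
})

test_that("nests enrich the favored covariate under a monotone truth", {
  # dnbr-only positive truth; nests should sit higher in dnbr than the
  # survey unit background (Mann-Whitney over a seed batch)
  tr <- truth_model(coefficients = c(cosasp = 0, dnbr = 1.2, loccc = 0,
                                     landcc = 0))
  sp <- location_spec("enrich", 60, 60, n_nests = 30)
  diffs <- p_vals <- numeric(20)
  for (s in 1:20) {
    tab <- simulate_location(sp, tr, seed = 50 + s)
    nests <- tab$dnbr[tab$nest == 1]
    bg <- tab$dnbr[tab$nest == 0 & tab$in_unit == 1]
    diffs[s] <- mean(nests) - mean(bg)
    p_vals[s] <- wilcox.test(nests, bg, alternative = "greater")$p.value
  }
  expect_true(all(diffs > 0))
  expect_lt(median(p_vals), 0.01)
})

test_that("nest pixels are distinct, inside the unit, and exact in count", {
  tab <- quick_location(seed = 5, n_nests = 25)
  expect_equal(sum(tab$nest), 25)
  expect_true(all(tab$in_unit[tab$nest == 1] == 1))
  expect_equal(anyDuplicated(tab[, c("row", "col")]), 0)
})

test_that("invalid specs are rejected with informative errors", {
  bad_cor <- matrix(0.99, 4, 4); diag(bad_cor) <- 1
  bad_cor[1, 2] <- -0.99            # asymmetric
  expect_error(location_spec("bad", 50, 50, correlation = bad_cor),
               "symmetric")
  sing <- diag(4); sing[1, 2] <- sing[2, 1] <- 1  # not PD
  expect_error(location_spec("bad2", 50, 50, correlation = sing),
               "positive definite")
  expect_error(location_spec("bad3", 50, 50, sd_vector = c(0, 1, 1, 1) * 0.1,
                             mean_vector = c(0, 300, .5, .5))
               , "SD")
  expect_error(
    simulate_location(location_spec("toomany", 20, 20, n_nests = 200,
                                    survey_fraction = 0.2), truth_model(), 1),
    "exceeds the survey-unit pixel count")
})

test_that("study concatenation keeps location ids and strips app nests", {
  st <- study_spec(
    list(location_spec("c1", 30, 30, n_nests = 5),
         location_spec("c2", 30, 30, n_nests = 5),
         location_spec("c3", 30, 30, n_nests = 5)),
    list(location_spec("a1", 30, 30, n_nests = 5),
         location_spec("a2", 30, 30)), seed = 3)
  tab <- simulate_study(st)
  expect_setequal(unique(tab$location), c("c1", "c2", "c3", "a1", "a2"))
  expect_equal(sum(tab$nest[tab$location %in% c("a1", "a2")]), 0)
  # zero application locations -> calibration-only concatenation
  st0 <- study_spec(st$calibration, list(), seed = 3)
  tab0 <- simulate_study(st0)
  expect_identical(tab0, tab[tab$location %in% c("c1", "c2", "c3"), ])
})

test_that("duplicate location names are rejected", {
  expect_error(study_spec(list(location_spec("x", 30, 30),
                               location_spec("x", 30, 30))),
               "duplicate")
})

test_that("a shifted application location is farther in environmental
           distance than every calibration location", {
  st <- study_spec(default_calibration_specs(60, 60),
                   default_application_specs(60, 60, dnbr_shift_sd = 2),
                   seed = 9)
  tab <- simulate_study(st)
  calib <- tab[tab$location %in% c("calib_wa", "calib_or", "calib_id"), ]
  ref <- distance_reference(calib, per_location = 1000, seed = 1)
  med <- vapply(unique(tab$location), function(l) {
    median(environmental_distance(ref, tab[tab$location == l, ]))
  }, 0)
  expect_gt(med[["novel_1"]], max(med[c("calib_wa", "calib_or", "calib_id")]))
})

test_that("pixel table CSV round trip is faithful", {
  tab <- quick_location(seed = 2, n_nests = 8, side = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pixel_table(tab, path)
  back <- read_pixel_table(path)
  expect_equal(back$dnbr, tab$dnbr, tolerance = 1e-12)
  expect_identical(back$nest, tab$nest)
  expect_identical(back$location, tab$location)
})
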