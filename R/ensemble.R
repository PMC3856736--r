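# Ensemble combination of binary model classifications, agreement
# diagnostics and environmental-novelty analysis.

#' Binary classification matrix from a set of thresholded models
#'
#' Entry (i, j) is 1 iff model j scores pixel i at or above its stored
#' threshold.
#'
#' @param models Named list of fitted models, each with a threshold set via
#'   [set_threshold()].
#' @param pixels Pixel table.
#' @return Integer 0/1 matrix, one column per model.
#' @export
classify_all <- function(models, pixels) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("'models' must be a named list")
  }
  out <- vapply(names(models), function(m) {
    fit <- models[[m]]
    if (is.null(fit$threshold) || is.na(fit$threshold)) {
      stop("model '", m, "' has no classification threshold")
    }
    as.integer(predict(fit, pixels) >= fit$threshold)
  }, integer(nrow(pixels)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(pixels))
  colnames(out) <- names(models)
  out
}

#' Per-pixel ensemble count
#'
#' Number of models classifying each pixel highly suitable (row sums of the
#' binary classification matrix).
#'
#' @param classification Binary matrix from [classify_all()].
#' @return Integer vector in 0..ncol(classification).
#' @export
ensemble_count <- function(classification) {
  stopifnot(is_binary01(classification))
  as.integer(rowSums(classification))
}

#' Per-location ensemble proportions and agreement
#'
#' For each location: the liberal suitability proportion (count >= 1), the
#' conservative proportion (count = number of models) and the agreement
#' proportion (count 0 or all).  For calibration locations the convention is
#' to compile these outside survey-unit boundaries
#' (`exclude_survey_units = TRUE`).
#'
#' @param counts Ensemble counts from [ensemble_count()].
#' @param location Location id per pixel.
#' @param n_models Number of models in the ensemble.
#' @param in_unit Optional 0/1 survey-unit flag per pixel.
#' @param exclude_survey_units If `TRUE` and `in_unit` is given, survey-unit
#'   pixels are dropped before computing proportions.
#' @return Data frame: location, n_pixels, liberal, conservative, agreement.
#' @export
location_proportions <- function(counts, location, n_models,
                                 in_unit = NULL,
                                 exclude_survey_units = FALSE) {
  stopifnot(length(counts) == length(location),
            all(counts >= 0), all(counts <= n_models))
  keep <- rep(TRUE, length(counts))
  if (exclude_survey_units) {
    if (is.null(in_unit)) stop("in_unit required to exclude survey units")
    keep <- in_unit == 0
  }
  locs <- unique(location)
  rows <- lapply(locs, function(l) {
    sel <- keep & location == l
    n <- sum(sel)
    if (n == 0) {
      warning("location '", l, "' has no pixels after exclusion")
      return(data.frame(location = l, n_pixels = 0L, liberal = NA_real_,
                        conservative = NA_real_, agreement = NA_real_,
                        stringsAsFactors = FALSE))
    }
    cs <- counts[sel]
    data.frame(location = l, n_pixels = n,
               liberal = mean(cs >= 1),
               conservative = mean(cs == n_models),
               agreement = mean(cs == 0 | cs == n_models),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nest occurrence rate by ensemble level
#'
#' Over surveyed pixels only: the proportion of pixels containing nests at
#' each ensemble level 0..n_models, with the Pearson correlation and simple
#' linear regression of proportion on level (levels with at least one pixel).
#'
#' @param counts Ensemble counts over surveyed pixels.
#' @param nest 0/1 nest flags aligned with `counts`.
#' @param n_models Number of models.
#' @return List: `table` (level, n_pixels, n_nests, proportion), `pearson_r`,
#'   `slope`, `r_squared`.
#' @export
nest_rate_by_count <- function(counts, nest, n_models) {
  stopifnot(length(counts) == length(nest), is_binary01(nest))
  lv <- 0:n_models
  tab <- data.frame(level = lv,
                    n_pixels = vapply(lv, function(k) sum(counts == k), 0),
                    n_nests = vapply(lv, function(k)
                      sum(nest[counts == k]), 0))
  tab$proportion <- ifelse(tab$n_pixels > 0, tab$n_nests / tab$n_pixels,
                           NA_real_)
  use <- tab$n_pixels > 0
  if (sum(use) < 3) {
    warning("fewer than 3 occupied ensemble levels; correlation unreliable")
  }
  dropped <- lv[!use]
  if (length(dropped)) {
    message("nest_rate_by_count: level(s) without pixels omitted: ",
            paste(dropped, collapse = ", "))
  }
  fit <- lm(proportion ~ level, data = tab[use, ])
  r <- cor(tab$level[use], tab$proportion[use])
  list(table = tab, pearson_r = r, slope = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Reference distribution for environmental distance
#'
#' Mean vector and covariance matrix of the four covariates over a balanced
#' sample of survey-unit pixels from the calibration locations.
#'
#' @param data Pixel table covering the calibration locations.
#' @param per_location Pixels sampled per location (default 5000, capped at
#'   what each survey unit contains).
#' @param seed Integer seed.
#' @return Object of class `distance_reference`: `mean`, `cov`, `n`.
#' @export
distance_reference <- function(data, per_location = 5000, seed = 1L) {
  check_pixel_table(data)
  unit <- data[data$in_unit == 1, , drop = FALSE]
  locs <- unique(unit$location)
  samp <- with_seed(seed, {
    do.call(rbind, lapply(locs, function(l) {
      pool <- which(unit$location == l)
      unit[sample(pool, min(per_location, length(pool))), , drop = FALSE]
    }))
  })
  x <- as.matrix(samp[, covariate_names()])
  sig <- stats::cov(x)
  ok <- tryCatch({ solve(sig); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop("singular covariance matrix (condition number ",
         signif(kappa(sig), 3), "); cannot define environmental distance")
  }
  structure(list(mean = colMeans(x), cov = sig, n = nrow(x),
                 sample = x),
            class = "distance_reference")
}

#' Environmental distance from the surveyed environmental space
#'
#' D = sqrt((x - mu)' Sigma^-1 (x - mu)) with mu, Sigma from a
#' [distance_reference()]; zero at the reference mean.
#'
#' @param reference A [distance_reference()], or a list with `mean` and
#'   `cov`.
#' @param pixels Pixel table with the four covariates.
#' @return Nonnegative distance per pixel.
#' @export
environmental_distance <- function(reference, pixels) {
  x <- as.matrix(pixels[, covariate_names(), drop = FALSE])
  d2 <- mahalanobis(x, reference$mean, reference$cov)
  sqrt(pmax(d2, 0))
}

#' Median and 95% interval of a distance sample
#'
#' Median-unbiased quantiles (type 8): the median with the 2.5th and 97.5th
#' percentiles.
#'
#' @param distances Nonempty numeric vector.
#' @return Named vector `c(median, lower, upper)`.
#' @export
median_distance_summary <- function(distances) {
  stopifnot(length(distances) > 0)
  q <- mu_quantile(distances, c(0.5, 0.025, 0.975))
  c(median = q[1], lower = q[2], upper = q[3])
}

#' Relate location-level model agreement to environmental distance
#'
#' Pearson correlation and least-squares regression of agreement on median
#' environmental distance across locations.
#'
#' @param agreement Per-location agreement proportions.
#' @param median_distance Per-location median environmental distances.
#' @return List: `pearson_r`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
agreement_vs_distance <- function(agreement, median_distance) {
  stopifnot(length(agreement) == length(median_distance))
  if (length(agreement) < 3) stop("need at least 3 locations")
  if (sd(agreement) == 0 || sd(median_distance) == 0) {
    warning("zero variance; correlation undefined")
    return(list(pearson_r = NA_real_, slope = NA_real_,
                intercept = NA_real_, r_squared = NA_real_,
                n = length(agreement)))
  }
  fit <- lm(agreement ~ median_distance)
  list(pearson_r = cor(median_distance, agreement),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = length(agreement))
}

#' Dose-response profile of a model along one covariate
#'
#' Equal-width bins over the covariate's observed range; per-bin median and
#' 25th/75th median-unbiased percentiles of the model's HSI.  Bins with
#' fewer than 5 pixels are flagged.
#'
#' @param fit Fitted model with a `predict` method.
#' @param pixels Pixel table.
#' @param covariate Covariate name.
#' @param n_bins Number of bins (default 10).
#' @return Data frame: bin midpoint, n, HSI quartiles, `sparse` flag.
#' @export
dose_response_profile <- function(fit, pixels, covariate, n_bins = 10) {
  x <- pixels[[covariate]]
  if (length(unique(x)) < n_bins) {
    stop("covariate '", covariate, "' has fewer than ", n_bins,
         " distinct values")
  }
  hsi <- predict(fit, pixels)
  brk <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- cut(x, brk, include.lowest = TRUE, labels = FALSE)
  mid <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  rows <- lapply(seq_len(n_bins), function(b) {
    h <- hsi[bin == b]
    if (!length(h)) {
      return(data.frame(mid = mid[b], n = 0L, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_, sparse = TRUE))
    }
    q <- mu_quantile(h, c(0.25, 0.5, 0.75))
    data.frame(mid = mid[b], n = length(h), q25 = q[1], median = q[2],
               q75 = q[3], sparse = length(h) < 5)
  })
  do.call(rbind, rows)
}
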