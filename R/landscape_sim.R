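# Synthetic post-fire landscape generator.
#
# Produces multi-location pixel tables with spatially autocorrelated
# covariate fields, a contiguous survey unit per location, and nest pixels
# placed according to a known suitability truth, so the whole modelling
# pipeline can be exercised and validated without field data.

#' Specify one synthetic wildfire location
#'
#' A location is a rectangular grid of 30-m pixels with four covariate
#' fields (`cosasp`, `dnbr`, `loccc`, `landcc`), a contiguous rectangular
#' survey unit and a number of nest pixels to place inside it.
#'
#' Covariates are generated as correlated, spatially smoothed Gaussian
#' fields.  For the bounded covariates (`cosasp` in \[-1,1\], `loccc` and
#' `landcc` in \[0,1\]) the latent Gaussian moments are solved so that the
#' *clipped* field matches `mean_vector` / `sd_vector`; see
#' [simulate_location()].
#'
#' @param name Location identifier (unique within a study).
#' @param grid_rows,grid_cols Pixel grid dimensions.
#' @param mean_vector,sd_vector Numeric length-4 vectors of covariate means
#'   and SDs, in the order of [covariate_names()].
#' @param correlation 4x4 symmetric positive-definite correlation matrix.
#' @param smoothing_range_px Spatial autocorrelation range in pixels (SD of
#'   the Gaussian smoothing kernel is half this value).
#' @param survey_fraction Fraction of pixels inside the survey unit, in (0,1].
#' @param n_nests Number of distinct nest pixels to place in the survey unit.
#' @return An object of class `location_spec`.
#' @export
#' @examples
#' location_spec("toy", 40, 40, n_nests = 10)
location_spec <- function(name, grid_rows, grid_cols,
                          mean_vector = c(0, 327.8, 0.63, 0.59),
                          sd_vector = c(0.69, 235.2, 0.42, 0.19),
                          correlation = default_correlation(),
                          smoothing_range_px = 4,
                          survey_fraction = 0.35,
                          n_nests = 28) {
  covs <- covariate_names()
  mean_vector <- setNames(as.numeric(mean_vector), covs)
  sd_vector <- setNames(as.numeric(sd_vector), covs)
  if (any(sd_vector <= 0)) stop("all covariate SDs must be > 0")
  correlation <- as.matrix(correlation)
  dimnames(correlation) <- list(covs, covs)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)) ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    stop("correlation matrix for location '", name,
         "' must be symmetric with unit diagonal")
  }
  ok <- tryCatch({ chol(correlation); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop("correlation matrix for location '", name,
         "' is not positive definite")
  }
  if (survey_fraction <= 0 || survey_fraction > 1) {
    stop("survey_fraction must be in (0, 1]")
  }
  stopifnot(grid_rows >= 4, grid_cols >= 4, n_nests >= 0)
  structure(list(name = as.character(name),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 mean_vector = mean_vector, sd_vector = sd_vector,
                 correlation = correlation,
                 smoothing_range_px = smoothing_range_px,
                 survey_fraction = survey_fraction,
                 n_nests = as.integer(n_nests)),
            class = "location_spec")
}

#' Default covariate correlation matrix
#'
#' Unit-diagonal correlation with a strong local/landscape canopy cover
#' correlation (0.635) and all remaining intercorrelations at or below 0.3.
#'
#' @return 4x4 correlation matrix named by [covariate_names()].
#' @export
default_correlation <- function() {
  covs <- covariate_names()
  r <- diag(4)
  dimnames(r) <- list(covs, covs)
  r["loccc", "landcc"] <- r["landcc", "loccc"] <- 0.635
  r["dnbr", "loccc"] <- r["loccc", "dnbr"] <- 0.20
  r["dnbr", "landcc"] <- r["landcc", "dnbr"] <- 0.15
  r["cosasp", "dnbr"] <- r["dnbr", "cosasp"] <- 0.10
  r["cosasp", "loccc"] <- r["loccc", "cosasp"] <- 0.10
  r["cosasp", "landcc"] <- r["landcc", "cosasp"] <- 0.10
  r
}

#' Specify the suitability truth used to place nests
#'
#' A monotone (or unimodal) map from covariates to the true nest-placement
#' probability.  Covariates are standardized internally against `center` /
#' `scale` so coefficients are on a per-SD scale.
#'
#' @param form `"linear-logistic"` (probability is inverse-logit of a linear
#'   predictor in standardized covariates) or `"unimodal-gaussian"`
#'   (inverse-logit of a negative quadratic, peaking at `optimum`).
#' @param intercept Intercept of the linear predictor (controls prevalence).
#' @param coefficients Named per-SD coefficients for the four covariates.
#' @param optimum Standardized optimum per covariate (unimodal form only).
#' @param center,scale Standardization reference (defaults: landscape-wide
#'   available-pixel means and SDs).
#' @return An object of class `truth_model`.
#' @export
#' @examples
#' tr <- truth_model()
#' p <- truth_prob(tr, data.frame(cosasp = 0, dnbr = 600, loccc = .8, landcc = .6))
truth_model <- function(form = c("linear-logistic", "unimodal-gaussian"),
                        intercept = -4,
                        coefficients = c(cosasp = 0.45, dnbr = 0.85,
                                         loccc = 0.50, landcc = 0.35),
                        optimum = c(cosasp = 0, dnbr = 0, loccc = 0, landcc = 0),
                        center = c(cosasp = 0, dnbr = 327.8,
                                   loccc = 0.63, landcc = 0.59),
                        scale = c(cosasp = 0.69, dnbr = 235.2,
                                  loccc = 0.42, landcc = 0.19)) {
  form <- match.arg(form)
  covs <- covariate_names()
  structure(list(form = form, intercept = intercept,
                 coefficients = coefficients[covs],
                 optimum = optimum[covs],
                 center = center[covs], scale = scale[covs]),
            class = "truth_model")
}

#' True nest-placement probability for pixels
#'
#' @param truth A [truth_model()].
#' @param pixels Data frame with the four covariate columns.
#' @return Probability vector in (0, 1).
#' @export
truth_prob <- function(truth, pixels) {
  stopifnot(inherits(truth, "truth_model"))
  covs <- covariate_names()
  z <- sweep(sweep(as.matrix(pixels[, covs]), 2, truth$center), 2,
             truth$scale, "/")
  eta <- if (truth$form == "linear-logistic") {
    truth$intercept + drop(z %*% truth$coefficients)
  } else {
    truth$intercept -
      drop(sweep(z, 2, truth$optimum)^2 %*% abs(truth$coefficients))
  }
  plogis(eta)
}

#' Specify a complete synthetic study
#'
#' @param calibration List of [location_spec()]s where nests are placed and
#'   models are calibrated (at least one).
#' @param application List of [location_spec()]s to which models are applied;
#'   no nests are placed there regardless of their `n_nests`.
#' @param truth A [truth_model()].
#' @param seed Integer study seed; per-location child seeds are derived from
#'   it with [derive_seed()].
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(calibration, application = list(),
                       truth = truth_model(), seed = 1L) {
  if (inherits(calibration, "location_spec")) calibration <- list(calibration)
  if (inherits(application, "location_spec")) application <- list(application)
  stopifnot(length(calibration) >= 1)
  nm <- vapply(c(calibration, application), `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate location names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(list(calibration = calibration, application = application,
                 truth = truth, seed = as.integer(seed)),
            class = "study_spec")
}

#' Default calibration location specs
#'
#' Three environmentally distinct calibration locations whose pooled
#' covariate distribution matches landscape-wide available-pixel summaries
#' (pooled dNBR about 330 +/- 235, pooled canopy-cover proportions about
#' 0.63 / 0.59), with nest sample sizes of 28, 44 and 36 pixels.
#'
#' @param grid_rows,grid_cols Grid size per location.
#' @return List of three [location_spec()]s.
#' @export
default_calibration_specs <- function(grid_rows = 120, grid_cols = 120) {
  list(
    location_spec("calib_wa", grid_rows, grid_cols,
                  mean_vector = c(0.05, 300, 0.55, 0.55),
                  n_nests = 28),
    location_spec("calib_or", grid_rows, grid_cols,
                  mean_vector = c(-0.05, 380, 0.70, 0.62),
                  sd_vector = c(0.69, 180, 0.42, 0.19),
                  n_nests = 44),
    location_spec("calib_id", grid_rows, grid_cols,
                  mean_vector = c(0.00, 310, 0.63, 0.60),
                  n_nests = 36)
  )
}

#' Default application (novel-environment) location specs
#'
#' Locations emulating fires outside the calibration region that burned more
#' severely than any calibration location: the dNBR mean is shifted upward by
#' `dnbr_shift_sd` landscape SDs (235.2 units per SD), with slightly sparser
#' landscape canopy.  No nests are placed at application locations.
#'
#' @param grid_rows,grid_cols Grid size per location.
#' @param dnbr_shift_sd Upward dNBR mean shift per location, in SD units.
#' @return List of [location_spec()]s.
#' @export
default_application_specs <- function(grid_rows = 120, grid_cols = 120,
                                      dnbr_shift_sd = c(2, 2.5, 3, 3.5)) {
  lapply(seq_along(dnbr_shift_sd), function(i) {
    location_spec(paste0("novel_", i), grid_rows, grid_cols,
                  mean_vector = c(0, 327.8 + dnbr_shift_sd[i] * 235.2,
                                  0.55, 0.50),
                  n_nests = 0L)
  })
}

#' Default full study spec
#'
#' @param seed Study seed.
#' @param grid_rows,grid_cols Grid size applied to every location.
#' @param truth Suitability truth (default [truth_model()]).
#' @return A [study_spec()].
#' @export
default_study <- function(seed = 1L, grid_rows = 120, grid_cols = 120,
                          truth = truth_model()) {
  study_spec(default_calibration_specs(grid_rows, grid_cols),
             default_application_specs(grid_rows, grid_cols),
             truth = truth, seed = seed)
}

# --- internal field machinery ----------------------------------------------

# 1-D convolution with edge replication.
conv_edge <- function(x, k) {
  h <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

# Spatially smoothed standard-normal field (marginals ~ N(0,1) before the
# exact empirical standardization applied by the caller).
gaussian_field <- function(nr, nc, range_px) {
  m <- matrix(rnorm(nr * nc), nr, nc)
  if (range_px > 0) {
    sigma <- range_px / 2
    half <- max(1L, ceiling(3 * sigma))
    k <- dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    m <- apply(m, 2, conv_edge, k = k)
    m <- t(apply(m, 1, conv_edge, k = k))
  }
  m
}

# Mean and SD of clip(X, a, b) for X ~ N(mu, sigma).
clipped_moments <- function(mu, sigma, a, b) {
  al <- if (is.finite(a)) (a - mu) / sigma else -Inf
  be <- if (is.finite(b)) (b - mu) / sigma else Inf
  Pa <- pnorm(al); Pb <- pnorm(be)
  pa <- dnorm(al); pb <- dnorm(be)
  dP <- Pb - Pa
  xphi <- function(z, p) if (is.finite(z)) z * p else 0
  m1 <- (if (is.finite(a)) a * Pa else 0) +
    (if (is.finite(b)) b * (1 - Pb) else 0) +
    mu * dP - sigma * (pb - pa)
  m2 <- (if (is.finite(a)) a^2 * Pa else 0) +
    (if (is.finite(b)) b^2 * (1 - Pb) else 0) +
    mu^2 * dP + 2 * mu * sigma * (pa - pb) +
    sigma^2 * (dP - (xphi(be, pb) - xphi(al, pa)))
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Latent Gaussian (mu, sigma) whose clipped moments match the target.
latent_clip_params <- function(target_mean, target_sd, a, b) {
  target_mean <- unname(target_mean); target_sd <- unname(target_sd)
  if (!is.finite(a) && !is.finite(b)) {
    return(c(mu = target_mean, sigma = target_sd))
  }
  obj <- function(p) {
    m <- clipped_moments(p[1], exp(p[2]), a, b)
    (m["mean"] - target_mean)^2 / max(target_sd, 1e-6)^2 +
      (m["sd"] - target_sd)^2 / max(target_sd, 1e-6)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# --- simulation -------------------------------------------------------------

#' Simulate one location's pixel table
#'
#' Generates four spatially autocorrelated covariate fields with exactly the
#' requested empirical cross-correlation structure (independent smoothed
#' fields are empirically orthonormalized and mixed through the Cholesky
#' factor of the correlation matrix), rescales them to the requested
#' moments, clips bounded covariates to their ranges (with latent moments
#' moment-matched so post-clip mean/SD still hit the spec), carves out a
#' centred rectangular survey unit, and places `n_nests` distinct nest
#' pixels inside it, sampled without replacement with probability
#' proportional to the suitability truth.
#'
#' @param spec A [location_spec()].
#' @param truth A [truth_model()].
#' @param seed Integer seed; the same (spec, seed) pair always reproduces
#'   the identical table.
#' @return A pixel-table data frame with columns `location`, `row`, `col`,
#'   the four covariates, `in_unit` and `nest` (0/1 flags).
#' @export
#' @examples
#' tab <- simulate_location(location_spec("toy", 40, 40, n_nests = 5),
#'                          truth_model(), seed = 1)
#' sum(tab$nest)
simulate_location <- function(spec, truth = truth_model(), seed = 1L) {
  stopifnot(inherits(spec, "location_spec"), inherits(truth, "truth_model"))
  covs <- covariate_names()
  nr <- spec$grid_rows; nc <- spec$grid_cols
  n <- nr * nc
  with_seed(seed, {
    z <- vapply(seq_along(covs),
                function(i) as.vector(gaussian_field(nr, nc,
                                                     spec$smoothing_range_px)),
                numeric(n))
    z <- sweep(z, 2, colMeans(z))
    q <- qr.Q(qr(z)) * sqrt(n - 1)          # exact sd 1, exact zero cross-cor
    bounds <- covariate_bounds()
    lat <- lapply(covs, function(j) {
      b <- bounds[[j]]
      latent_clip_params(spec$mean_vector[j], spec$sd_vector[j],
                         ifelse(is.na(b[1]), -Inf, b[1]),
                         ifelse(is.na(b[2]), Inf, b[2]))
    })
    names(lat) <- covs
    # First-order (Hermite) attenuation of each covariate's correlation by
    # clipping: c_j = sigma_latent * P(in range) / sd(clipped).  Inflate the
    # latent correlation so the *post-clip* correlation matches the spec.
    atten <- vapply(covs, function(j) {
      b <- bounds[[j]]; p <- lat[[j]]
      a <- ifelse(is.na(b[1]), -Inf, b[1])
      bb <- ifelse(is.na(b[2]), Inf, b[2])
      pin <- pnorm((bb - p[["mu"]]) / p[["sigma"]]) -
        pnorm((a - p[["mu"]]) / p[["sigma"]])
      min(p[["sigma"]] * pin / spec$sd_vector[[j]], 1)
    }, 0)
    rlat <- spec$correlation / outer(atten, atten)
    rlat[rlat > 0.99] <- 0.99
    rlat[rlat < -0.99] <- -0.99
    diag(rlat) <- 1
    ev <- eigen(rlat, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {            # floor eigenvalues, renormalize
      v <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
      rlat <- v / sqrt(outer(diag(v), diag(v)))
    }
    x <- q %*% chol(rlat)
    colnames(x) <- covs
    vals <- matrix(NA_real_, n, length(covs), dimnames = list(NULL, covs))
    for (j in covs) {
      b <- bounds[[j]]
      p <- lat[[j]]
      v <- p[["mu"]] + p[["sigma"]] * x[, j]
      if (!is.na(b[1])) v <- pmax(v, b[1])
      if (!is.na(b[2])) v <- pmin(v, b[2])
      vals[, j] <- v
    }
    rows <- rep(seq_len(nr), times = nc)
    cols <- rep(seq_len(nc), each = nr)
    # centred rectangular survey unit covering ~survey_fraction of pixels
    rh <- max(1L, round(nr * sqrt(spec$survey_fraction)))
    cw <- max(1L, round(nc * sqrt(spec$survey_fraction)))
    r0 <- (nr - rh) %/% 2L + 1L
    c0 <- (nc - cw) %/% 2L + 1L
    in_unit <- as.integer(rows >= r0 & rows < r0 + rh &
                            cols >= c0 & cols < c0 + cw)
    tab <- data.frame(location = spec$name, row = rows, col = cols,
                      vals, in_unit = in_unit, nest = 0L,
                      stringsAsFactors = FALSE)
    unit_idx <- which(in_unit == 1L)
    if (spec$n_nests > length(unit_idx)) {
      stop("location '", spec$name, "': n_nests (", spec$n_nests,
           ") exceeds the survey-unit pixel count (", length(unit_idx), ")")
    }
    if (spec$n_nests > 0) {
      p <- truth_prob(truth, tab[unit_idx, ])
      nest_idx <- sample(unit_idx, spec$n_nests, replace = FALSE, prob = p)
      tab$nest[nest_idx] <- 1L
    }
    tab
  })
}

#' Simulate a complete multi-location study
#'
#' Concatenates per-location tables generated with deterministically derived
#' child seeds.  Application locations never receive nest flags.
#'
#' @param study A [study_spec()].
#' @return Pixel-table data frame covering all locations.
#' @export
#' @examples
#' st <- study_spec(list(location_spec("a", 30, 30, n_nests = 5)),
#'                  list(location_spec("b", 30, 30)), seed = 7)
#' table(simulate_study(st)$location)
simulate_study <- function(study) {
  stopifnot(inherits(study, "study_spec"))
  sim_one <- function(spec, is_app) {
    if (is_app && spec$n_nests > 0) spec$n_nests <- 0L
    simulate_location(spec, study$truth,
                      seed = derive_seed(study$seed, spec$name))
  }
  tabs <- c(lapply(study$calibration, sim_one, is_app = FALSE),
            lapply(study$application, sim_one, is_app = TRUE))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Read / write a pixel table as CSV
#'
#' The on-disk layout has columns `location`, `row`, `col`, `cosasp`,
#' `dnbr`, `loccc`, `landcc`, `in_unit`, `nest`.
#'
#' @param x Pixel table.
#' @param path File path.
#' @return `read_pixel_table` returns the validated data frame;
#'   `write_pixel_table` returns `path` invisibly.
#' @export
write_pixel_table <- function(x, path) {
  check_pixel_table(x)
  write.csv(x[, c("location", "row", "col", covariate_names(),
                  "in_unit", "nest")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pixel_table
#' @export
read_pixel_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_pixel_table(x)
  x
}

#' @export
print.location_spec <- function(x, ...) {
  cat("Location spec '", x$name, "': ", x$grid_rows, " x ", x$grid_cols,
      " pixels, survey fraction ", x$survey_fraction,
      ", nests ", x$n_nests, "\n", sep = "")
  m <- rbind(mean = x$mean_vector, sd = x$sd_vector)
  print(round(m, 3))
  invisible(x)
}

#' @export
print.study_spec <- function(x, ...) {
  cat("Study spec:", length(x$calibration), "calibration +",
      length(x$application), "application location(s), seed", x$seed, "\n")
  cat("  calibration:",
      paste(vapply(x$calibration, `[[`, "", "name"), collapse = ", "), "\n")
  if (length(x$application)) {
    cat("  application:",
        paste(vapply(x$application, `[[`, "", "name"), collapse = ", "), "\n")
  }
  invisible(x)
}
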