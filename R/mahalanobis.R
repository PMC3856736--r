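# Partitioned Mahalanobis D2 habitat models.
#
# Principal components are extracted from the correlation matrix of
# nest-pixel covariates and ordered by *ascending* eigenvalue; partition k
# sums the squared standardized component scores of the k smallest-variance
# components divided by their eigenvalues.  Small-variance components
# represent the most consistent multivariate requirements of nest sites, so
# low-k partitions emphasize the conditions nests share.  At k = k_max the
# statistic equals the classical Mahalanobis distance squared.  D2 is
# rescaled to a 0-1 HSI with the chi-square upper-tail probability at k
# degrees of freedom, giving HSI = 1 exactly at the nest multivariate mean.

#' Specify a partitioned Mahalanobis model
#'
#' @param covariates Covariate set; must include `dnbr` (models are
#'   constrained to include burn severity).
#' @param k Partition index in 1..length(covariates); `k = k_max` gives the
#'   unpartitioned (classical) D2 model.
#' @return Object of class `mahal_partition_spec`.
#' @export
#' @examples
#' mahal_partition_spec(c("cosasp", "dnbr"), k = 2)
mahal_partition_spec <- function(covariates, k = length(covariates)) {
  covariates <- as.character(covariates)
  if (!"dnbr" %in% covariates) {
    stop("Mahalanobis models must include burn severity ('dnbr')")
  }
  stopifnot(all(covariates %in% covariate_names()),
            k >= 1, k <= length(covariates))
  structure(list(covariates = covariates, k = as.integer(k)),
            class = "mahal_partition_spec")
}

#' Enumerate candidate partitioned-D2 model specs
#'
#' Burn severity is always included; cosine aspect and the prefire
#' canopy-cover block (`loccc` + `landcc`, which enter together) are added
#' in all combinations, and each covariate set is crossed with every
#' feasible partition index.  This yields the standard 10-model candidate
#' set (1 + 2 + 3 + 4 over the 1-, 2-, 3- and 4-variable sets); the count
#' is reported via `message()` rather than hard-coded.
#'
#' @return List of [mahal_partition_spec()]s.
#' @export
enumerate_mahal_specs <- function() {
  blocks <- list(character(0), "cosasp", c("loccc", "landcc"),
                 c("cosasp", "loccc", "landcc"))
  specs <- list()
  for (s in blocks) {
    covs <- intersect(covariate_names(), c(s, "dnbr"))
    for (k in seq_along(covs)) {
      specs[[length(specs) + 1L]] <- mahal_partition_spec(covs, k)
    }
  }
  message("enumerated ", length(specs), " candidate partitioned-D2 models")
  specs
}

#' Fit one D2 replicate to nest pixels
#'
#' Standardizes the covariates by the nest-sample mean/SD, eigendecomposes
#' the nest correlation matrix and orders components by ascending
#' eigenvalue.
#'
#' @param nest_rows Pixel-table rows of nest pixels.
#' @param spec A [mahal_partition_spec()].
#' @return Object of class `mahal_replicate` storing the centre, scale,
#'   eigenvectors, eigenvalues and partition index.
#' @export
fit_replicate <- function(nest_rows, spec) {
  stopifnot(inherits(spec, "mahal_partition_spec"))
  covs <- spec$covariates
  if (nrow(nest_rows) < length(covs) + 2) {
    stop("need at least ", length(covs) + 2, " nest rows")
  }
  x <- as.matrix(nest_rows[, covs, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    stop("constant covariate in nest sample: ",
         paste(covs[scl == 0], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ev <- eigen(cor(z), symmetric = TRUE)
  ord <- order(ev$values)                  # ascending variance
  values <- ev$values[ord]
  vectors <- ev$vectors[, ord, drop = FALSE]
  if (any(values[seq_len(spec$k)] < 1e-10)) {
    stop("zero eigenvalue within the selected partition (k = ", spec$k, ")")
  }
  structure(list(covariates = covs, k = spec$k, center = ctr, scale = scl,
                 values = values, vectors = vectors),
            class = "mahal_replicate")
}

#' Partitioned D2 for pixels
#'
#' Sum over the k smallest-variance components of
#' (component score)^2 / eigenvalue.  Nonnegative; zero exactly at the nest
#' multivariate mean; at k = k_max equals the classical Mahalanobis
#' distance squared.
#'
#' @param replicate A [fit_replicate()] result.
#' @param pixels Pixel table with the replicate's covariates.
#' @return Nonnegative numeric vector.
#' @export
d2_partition <- function(replicate, pixels) {
  stopifnot(inherits(replicate, "mahal_replicate"))
  z <- sweep(sweep(as.matrix(pixels[, replicate$covariates, drop = FALSE]),
                   2, replicate$center), 2, replicate$scale, "/")
  scores <- z %*% replicate$vectors
  sel <- seq_len(replicate$k)
  as.numeric(scores[, sel, drop = FALSE]^2 %*% (1 / replicate$values[sel]))
}

#' Rescale D2 to a 0-1 habitat suitability index
#'
#' HSI = upper-tail chi-square probability with `k` degrees of freedom at
#' `d2`: strictly decreasing in D2, equal to 1 at D2 = 0.
#'
#' @param d2 Nonnegative D2 values.
#' @param k Degrees of freedom (the partition index).
#' @return HSI vector in \[0, 1\].
#' @export
#' @examples
#' hsi_from_d2(2 * log(2), 2)   # 0.5
hsi_from_d2 <- function(d2, k) {
  stopifnot(all(d2 >= -1e-12), k >= 1)
  pchisq(pmax(d2, 0), df = k, lower.tail = FALSE)
}

#' Fit a partitioned Mahalanobis habitat model
#'
#' Fits `n_iter` replicates, each to an equal-representation subsample of
#' `per_location_nests` nest pixels drawn without replacement from every
#' calibration location; predictions average the replicate HSIs.
#'
#' @param data Pixel table covering the calibration locations.
#' @param spec A [mahal_partition_spec()].
#' @param n_iter Number of subsample replicates (default 100).
#' @param per_location_nests Nest pixels drawn per location per replicate
#'   (default 28).
#' @param seed Integer seed.
#' @return Object of class `c("mahal_fit", "hsi_fit")`.
#' @export
fit_mahal <- function(data, spec, n_iter = 100, per_location_nests = 28,
                      seed = 1L) {
  check_pixel_table(data)
  stopifnot(inherits(spec, "mahal_partition_spec"))
  nests <- data[data$nest == 1, , drop = FALSE]
  locs <- unique(nests$location)
  short <- locs[vapply(locs, function(l) sum(nests$location == l),
                       0) < per_location_nests]
  if (length(short)) {
    stop("location(s) with fewer than ", per_location_nests,
         " nest pixels: ", paste(short, collapse = ", "))
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      idx <- unlist(lapply(locs, function(l) {
        sample(which(nests$location == l), per_location_nests)
      }))
      fit_replicate(nests[idx, , drop = FALSE], spec)
    })
  })
  structure(list(spec = spec, replicates = reps, n_iter = n_iter,
                 per_location_nests = per_location_nests,
                 threshold = NA_real_),
            class = c("mahal_fit", "hsi_fit"))
}

#' Predict HSI from a partitioned Mahalanobis fit
#'
#' Mean over replicates of the chi-square rescaled partitioned D2.
#'
#' @param object A `mahal_fit`.
#' @param newdata Pixel table.
#' @param ... Unused.
#' @return HSI vector in \[0, 1\].
#' @export
predict.mahal_fit <- function(object, newdata, ...) {
  stopifnot(length(object$replicates) >= 1)
  h <- 0
  for (r in object$replicates) {
    h <- h + hsi_from_d2(d2_partition(r, newdata), r$k)
  }
  h / length(object$replicates)
}

#' @export
print.mahal_fit <- function(x, ...) {
  cat("Partitioned Mahalanobis D2 habitat model\n")
  cat("  covariates:", paste(x$spec$covariates, collapse = ", "),
      "| partition k =", x$spec$k, "of", length(x$spec$covariates), "\n")
  cat("  replicates:", length(x$replicates),
      "(", x$per_location_nests, "nests/location each )\n")
  if (!is.na(x$threshold)) cat("  HSI threshold =", round(x$threshold, 4), "\n")
  invisible(x)
}

#' Subsample + cross-validated evaluation of a partitioned-D2 spec
#'
#' For each of `n_iter` iterations: draw the equal-representation nest
#' subsample and an available-pixel sample (an equal share from each
#' calibration location's survey unit); split nests into `folds` folds; fit
#' on the training nests and score the withheld nests and the available
#' pixels, recording the median withheld-nest HSI and the AUC of withheld
#' nests against available pixels.  `n_iter * folds` validation replicates
#' in total.
#'
#' @inheritParams fit_mahal
#' @param folds Cross-validation folds (default 5).
#' @param n_available Total available pixels per iteration (default 10000,
#'   capped at what the survey units contain).
#' @return List with `median_nest_hsi`, `auc` (means over replicates),
#'   `median_nest_hsi_sd`, `auc_sd`, and the per-replicate values.
#' @export
subsample_cv_evaluate <- function(data, spec, n_iter = 100,
                                  per_location_nests = 28, folds = 5,
                                  n_available = 10000, seed = 1L) {
  check_pixel_table(data)
  nests <- data[data$nest == 1, , drop = FALSE]
  unit <- data[data$in_unit == 1, , drop = FALSE]
  locs <- unique(nests$location)
  short <- locs[vapply(locs, function(l) sum(nests$location == l),
                       0) < per_location_nests]
  if (length(short)) {
    stop("location(s) with fewer than ", per_location_nests,
         " nest pixels: ", paste(short, collapse = ", "))
  }
  per_loc_avail <- ceiling(n_available / length(locs))
  med <- a <- numeric(0)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- unlist(lapply(locs, function(l) {
        sample(which(nests$location == l), per_location_nests)
      }))
      sub <- nests[idx, , drop = FALSE]
      avail <- do.call(rbind, lapply(locs, function(l) {
        pool <- which(unit$location == l)
        unit[sample(pool, min(per_loc_avail, length(pool))), , drop = FALSE]
      }))
      fold <- kfold_split(nrow(sub), folds, seed = NULL)
      for (f in seq_len(folds)) {
        train <- sub[fold != f, , drop = FALSE]
        test <- sub[fold == f, , drop = FALSE]
        rep_f <- fit_replicate(train, spec)
        hsi_test <- hsi_from_d2(d2_partition(rep_f, test), rep_f$k)
        hsi_av <- hsi_from_d2(d2_partition(rep_f, avail), rep_f$k)
        med <- c(med, median(hsi_test))
        a <- c(a, auc(hsi_test, hsi_av))
      }
    }
  })
  list(median_nest_hsi = mean(med), auc = mean(a),
       median_nest_hsi_sd = sd(med), auc_sd = sd(a),
       replicates = data.frame(median_nest_hsi = med, auc = a))
}

#' Pareto-front selection over (median nest HSI, AUC)
#'
#' Returns the candidates not dominated in both metrics, annotated so the
#' final manual choice among front members can be replicated.
#'
#' @param metrics Data frame with columns `median_nest_hsi` and `auc` (one
#'   row per candidate; extra columns are carried through).
#' @return The input rows on the Pareto front, with a logical
#'   `pareto_front` column added to the full table in attribute `"all"`.
#' @export
select_mahal_models <- function(metrics) {
  stopifnot(all(c("median_nest_hsi", "auc") %in% names(metrics)))
  n <- nrow(metrics)
  dominated <- vapply(seq_len(n), function(i) {
    any(metrics$median_nest_hsi >= metrics$median_nest_hsi[i] &
          metrics$auc >= metrics$auc[i] &
          (metrics$median_nest_hsi > metrics$median_nest_hsi[i] |
             metrics$auc > metrics$auc[i]))
  }, logical(1))
  metrics$pareto_front <- !dominated
  out <- metrics[!dominated, , drop = FALSE]
  attr(out, "all") <- metrics
  out
}
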