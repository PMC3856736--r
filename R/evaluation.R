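# Model-agnostic performance machinery: rank-based AUC, sensitivity /
# specificity, predictive-gain threshold optimization, k-fold utilities and
# model-by-location performance reporting.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Fraction of (positive, negative) score pairs in which the positive scores
#' higher, ties counted one half; computed from rank sums.
#'
#' @param pos_scores Scores of positive (nest) cases.
#' @param neg_scores Scores of negative (available) cases.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.4, 0.7), c(0.5, 0.3))   # 5/6
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stop("both score vectors must be nonempty")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity and specificity at an HSI threshold
#'
#' A pixel is classified highly suitable when HSI >= threshold.
#' Sensitivity is the fraction of nest scores at or above the threshold;
#' specificity is the fraction of available scores below it.
#'
#' @param threshold Classification threshold.
#' @param nest_scores,available_scores Score vectors.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec_at <- function(threshold, nest_scores, available_scores) {
  stopifnot(is.finite(threshold))
  c(sensitivity = mean(nest_scores >= threshold),
    specificity = mean(available_scores < threshold))
}

#' Threshold maximizing predictive gain
#'
#' Scans every candidate threshold (the distinct pooled scores plus one
#' value above the maximum) and returns the one maximizing predictive gain =
#' sensitivity - (1 - specificity), the true skill statistic.  Ties are
#' broken toward the smallest threshold, i.e. toward sensitivity.
#'
#' @param nest_scores Nest-pixel scores pooled across calibration locations.
#' @param available_scores Available-pixel scores pooled the same way.
#' @return Object of class `threshold_result`: list with `threshold`,
#'   `sensitivity`, `specificity`, `gain`, `n_nest`, `n_available`.
#' @export
#' @examples
#' threshold_max_gain(c(0.8, 0.6, 0.9), c(0.1, 0.5, 0.7, 0.2))
threshold_max_gain <- function(nest_scores, available_scores) {
  stopifnot(length(nest_scores) > 0, length(available_scores) > 0)
  all_scores <- c(nest_scores, available_scores)
  if (length(unique(all_scores)) == 1L) {
    warning("all scores identical; returning zero gain at that value")
    t0 <- all_scores[1]
    ss <- sens_spec_at(t0, nest_scores, available_scores)
    return(structure(list(threshold = t0, sensitivity = ss[[1]],
                          specificity = ss[[2]], gain = 0,
                          n_nest = length(nest_scores),
                          n_available = length(available_scores)),
                     class = "threshold_result"))
  }
  cand <- sort(unique(all_scores))
  cand <- c(cand, cand[length(cand)] + 1)
  # sens(t) = P(nest >= t); 1 - spec(t) = P(avail >= t).
  # findInterval(..., left.open = TRUE) counts scores < t in a sorted vector.
  sn <- sort(nest_scores); sa <- sort(available_scores)
  sens <- 1 - findInterval(cand, sn, left.open = TRUE) / length(sn)
  fpr <- 1 - findInterval(cand, sa, left.open = TRUE) / length(sa)
  gain <- sens - fpr
  gmax <- max(gain)
  best <- min(cand[gain >= gmax - 1e-12])
  ss <- sens_spec_at(best, nest_scores, available_scores)
  structure(list(threshold = best, sensitivity = ss[[1]],
                 specificity = ss[[2]], gain = ss[[1]] + ss[[2]] - 1,
                 n_nest = length(nest_scores),
                 n_available = length(available_scores)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("HSI threshold", round(x$threshold, 4),
      ": sensitivity", round(x$sensitivity, 3),
      ", specificity", round(x$specificity, 3),
      ", predictive gain", round(x$gain, 3), "\n")
  invisible(x)
}

#' Random k-fold assignment
#'
#' Partitions `n` items into `k` folds whose sizes differ by at most one.
#'
#' @param n Number of items (must be >= k).
#' @param k Number of folds.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Integer vector of fold labels 1..k, length n.
#' @export
kfold_split <- function(n, k = 5, seed = NULL) {
  if (n < k) stop("n (", n, ") must be at least k (", k, ")")
  draw <- function() sample(rep(seq_len(k), length.out = n))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Model-by-location performance table
#'
#' For every model and location: AUC of nest versus available (survey-unit)
#' pixels, and sensitivity / specificity at the model's stored pooled
#' threshold.  Cells with AUC at or below the 0.6 usefulness bar are
#' flagged.  Locations without nests get `NA` metrics.
#'
#' @param models Named list of fitted models (each with a `threshold` set).
#' @param data Pixel table covering the locations to evaluate.
#' @param locations Locations to report (default: all with nest pixels).
#' @return Data frame with columns `model`, `location`, `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `gain`, `useful`.
#' @export
performance_table <- function(models, data, locations = NULL) {
  check_pixel_table(data)
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("'models' must be a named list")
  }
  if (is.null(locations)) {
    locations <- unique(data$location[data$nest == 1])
  }
  rows <- list()
  for (m in names(models)) {
    fit <- models[[m]]
    thr <- fit$threshold
    if (is.na(thr)) stop("model '", m, "' has no threshold set")
    for (l in locations) {
      d <- data[data$location == l & data$in_unit == 1, , drop = FALSE]
      nests <- d[d$nest == 1, , drop = FALSE]
      if (nrow(nests) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, location = l, auc = NA_real_, sensitivity = NA_real_,
          specificity = NA_real_, threshold = thr, gain = NA_real_,
          useful = NA, stringsAsFactors = FALSE)
        next
      }
      hsi_nest <- predict(fit, nests)
      hsi_avail <- predict(fit, d)
      a <- auc(hsi_nest, hsi_avail)
      ss <- sens_spec_at(thr, hsi_nest, hsi_avail)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, location = l, auc = a, sensitivity = ss[[1]],
        specificity = ss[[2]], threshold = thr,
        gain = ss[[1]] + ss[[2]] - 1, useful = a > 0.6,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Set the classification threshold on a fitted model
#'
#' @param fit A fitted model (`wlr_fit`, `mahal_fit` or `maxent_fit`).
#' @param threshold HSI threshold, or a [threshold_max_gain()] result.
#' @return The fit with its `threshold` element set.
#' @export
set_threshold <- function(fit, threshold) {
  stopifnot(inherits(fit, "hsi_fit"))
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  fit$threshold <- threshold
  fit
}
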