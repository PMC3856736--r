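# Weighted logistic regression resource-selection models with all-subsets
# AICc selection.  Nest (used) pixels get weight 1 and available pixels get
# weight n_used/n_available so the two classes carry equal total weight,
# which removes the influence of the arbitrary available-sample size on the
# fitted selection coefficients.

#' Small-sample corrected AIC
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik Maximized log-likelihood.
#' @param k_params Number of estimated parameters.
#' @param n_eff Effective sample size (rows, not summed weights).
#' @return Numeric AICc value.
#' @export
#' @examples
#' aicc(-10, 2, 100)   # 24 + 12/97
aicc <- function(loglik, k_params, n_eff) {
  if (n_eff <= k_params + 1) {
    stop("AICc undefined: n_eff (", n_eff, ") must exceed k_params + 1 (",
         k_params + 1, ")")
  }
  -2 * loglik + 2 * k_params + 2 * k_params * (k_params + 1) /
    (n_eff - k_params - 1)
}

#' Fit a weighted logistic regression habitat model
#'
#' Maximizes the case-weighted binomial log-likelihood in which used (nest)
#' rows carry weight 1 and available rows carry weight
#' `n_used / n_available`, so both classes contribute equal total weight.
#' Covariates are z-scored internally on the pooled sample for optimizer
#' stability; reported coefficients are on the original covariate scale.
#' With equal class sizes the fit reduces exactly to ordinary logistic
#' regression.
#'
#' @param used Pixel-table rows for nest pixels.
#' @param available Pixel-table rows for available (non-nest) pixels.
#' @param covariates Character vector, subset of [covariate_names()]
#'   (may be empty for the intercept-only model).
#' @param location Optional location label stored on the fit.
#' @return Object of class `c("wlr_fit", "hsi_fit")` with elements
#'   `coefficients` (original scale, intercept first), `loglik`, `aicc`,
#'   `n_used`, `n_available`, `separated` flag and `threshold` (NA until
#'   set).
#' @export
#' @examples
#' tab <- simulate_location(location_spec("toy", 50, 50, n_nests = 30),
#'                          truth_model(), seed = 2)
#' fit <- fit_wlr(tab[tab$nest == 1, ], tab[tab$nest == 0 & tab$in_unit == 1, ],
#'                c("dnbr", "loccc"))
#' coef(fit)
fit_wlr <- function(used, available, covariates = covariate_names(),
                    location = NULL) {
  stopifnot(nrow(used) >= 1, nrow(available) >= 1)
  covariates <- as.character(covariates)
  dat <- rbind(used[, covariates, drop = FALSE],
               available[, covariates, drop = FALSE])
  y <- c(rep(1, nrow(used)), rep(0, nrow(available)))
  n1 <- nrow(used); n0 <- nrow(available)
  w <- c(rep(1, n1), rep(n1 / n0, n0))
  if (length(covariates)) {
    xm <- as.matrix(dat)
    csd <- apply(xm, 2, sd)
    if (any(csd == 0)) {
      stop("constant covariate(s): ",
           paste(covariates[csd == 0], collapse = ", "))
    }
    cmu <- colMeans(xm)
    xs <- sweep(sweep(xm, 2, cmu), 2, csd, "/")
    X <- cbind(`(Intercept)` = 1, xs)
  } else {
    cmu <- csd <- numeric(0)
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  fit <- glm.fit(X, y, weights = w, family = quasibinomial())
  beta_std <- coef(fit)
  p <- fitted(fit)
  eps <- 1e-12
  loglik <- sum(w * (y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))))
  separated <- !fit$converged || any(abs(beta_std) > 15) ||
    all(p[y == 1] > 1 - 1e-8) && all(p[y == 0] < 1e-8)
  # back-transform to the original covariate scale
  if (length(covariates)) {
    slopes <- beta_std[-1] / csd
    intercept <- beta_std[1] - sum(beta_std[-1] * cmu / csd)
    beta <- c(`(Intercept)` = unname(intercept), slopes)
  } else {
    beta <- c(`(Intercept)` = unname(beta_std[1]))
  }
  k <- length(beta)
  n_eff <- n1 + n0
  structure(list(location = location, covariates = covariates,
                 coefficients = beta, coefficients_std = beta_std,
                 loglik = loglik, n_used = n1, n_available = n0,
                 n_eff = n_eff, k_params = k,
                 aicc = aicc(loglik, k, n_eff),
                 separated = separated, threshold = NA_real_),
            class = c("wlr_fit", "hsi_fit"))
}

#' All-subsets AICc model selection for WLR
#'
#' Fits every subset of the candidate covariates (including the
#' intercept-only model) and ranks them by AICc.  Subsets whose fit is
#' flagged as separated are excluded from the ranking with a message.
#'
#' @inheritParams fit_wlr
#' @return List with `table` (data frame: model, k, loglik, aicc, delta_aicc,
#'   ranked ascending), `fits` (list of [fit_wlr()] objects in the same
#'   order) and `best` (the top-ranked fit).
#' @export
all_subsets_aicc <- function(used, available, covariates = covariate_names(),
                             location = NULL) {
  stopifnot(length(covariates) <= 4)
  subsets <- list(character(0))
  for (k in seq_along(covariates)) {
    cmb <- utils::combn(covariates, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  fits <- list(); labels <- character(0)
  for (s in subsets) {
    lab <- if (length(s)) paste(s, collapse = "+") else "(intercept only)"
    f <- tryCatch(fit_wlr(used, available, s, location = location),
                  error = function(e) e)
    if (inherits(f, "error")) {
      message("subset '", lab, "' failed: ", conditionMessage(f))
      next
    }
    if (f$separated) {
      message("subset '", lab, "' excluded: perfect separation flagged")
      next
    }
    fits[[length(fits) + 1L]] <- f
    labels <- c(labels, lab)
  }
  if (!length(fits)) stop("no subset could be fitted")
  aiccs <- vapply(fits, `[[`, 0, "aicc")
  ord <- order(aiccs)
  fits <- fits[ord]; labels <- labels[ord]; aiccs <- aiccs[ord]
  tab <- data.frame(model = labels,
                    k = vapply(fits, `[[`, 0, "k_params"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aicc = aiccs, delta_aicc = aiccs - aiccs[1],
                    stringsAsFactors = FALSE)
  list(table = tab, fits = fits, best = fits[[1]])
}

#' Predict HSI from a WLR fit
#'
#' Inverse-logit of the fitted linear predictor, in (0, 1).
#'
#' @param object A `wlr_fit`.
#' @param newdata Pixel table with the fit's covariates.
#' @param ... Unused.
#' @return Numeric HSI vector.
#' @export
predict.wlr_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) {
    stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "))
  }
  eta <- rep(object$coefficients[1], nrow(newdata))
  for (j in object$covariates) {
    eta <- eta + object$coefficients[j] * newdata[[j]]
  }
  plogis(eta)
}

#' @export
coef.wlr_fit <- function(object, ...) object$coefficients

#' @export
print.wlr_fit <- function(x, ...) {
  cat("Weighted logistic regression habitat model",
      if (!is.null(x$location)) paste0("(", x$location, ")"), "\n")
  cat("  covariates:", if (length(x$covariates))
    paste(x$covariates, collapse = ", ") else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  cat("  n_used =", x$n_used, ", n_available =", x$n_available,
      ", logLik =", round(x$loglik, 2), ", AICc =", round(x$aicc, 2), "\n")
  if (!is.na(x$threshold)) cat("  HSI threshold =", round(x$threshold, 4), "\n")
  invisible(x)
}

#' @export
summary.wlr_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, aicc = object$aicc,
              loglik = object$loglik, n_used = object$n_used,
              n_available = object$n_available, separated = object$separated)
  class(out) <- "summary.wlr_fit"
  out
}

#' @export
print.summary.wlr_fit <- function(x, ...) {
  cat("WLR fit summary\n")
  print(round(x$coefficients, 4))
  cat("logLik", round(x$loglik, 3), "| AICc", round(x$aicc, 3),
      "| n =", x$n_used, "+", x$n_available,
      if (x$separated) "| SEPARATION FLAGGED", "\n")
  invisible(x)
}
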