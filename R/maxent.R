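# Presence-background maximum-entropy habitat model.
#
# The fit maximizes the concave penalized log-likelihood
#   mean_presence(lambda . f) - log(mean_background exp(lambda . f))
#     - sum_j beta_j |lambda_j|
# over feature weights lambda by cyclic coordinate ascent with
# soft-thresholding; beta_j follows the published default regularization
# schema beta_j = beta_multiplier * s_class * sd_bg(f_j) / sqrt(n_presence)
# with class constants s = 1.0 for linear/quadratic and 1.2 for product
# features.  The fitted distribution over background pixels is
# q_i = exp(lambda . f_i) / Z; the logistic output at prevalence 0.5 is
# HSI(x) = q(x) e^H / (1 + q(x) e^H) with H the entropy of q over the
# background, so an uninformative (all-zero) model scores 0.5 everywhere.

#' Build a scaled Maxent feature specification from background pixels
#'
#' Features are min-max scaled to \[0,1\] using background bounds: linear =
#' scaled covariate, quadratic = scaled square, product = scaled pairwise
#' product.  Constant covariates are dropped with a warning.
#'
#' @param background Pixel-table rows defining the available environment.
#' @param covariates Covariates to use.
#' @param classes Feature classes among `"linear"`, `"quadratic"`,
#'   `"product"`.
#' @return Object of class `maxent_features`: per-feature name, class,
#'   variables and raw min/max bounds.
#' @export
maxent_features <- function(background, covariates = covariate_names(),
                            classes = c("linear", "quadratic", "product")) {
  classes <- match.arg(classes, several.ok = TRUE)
  keep <- covariates[vapply(covariates,
                            function(j) sd(background[[j]]) > 0, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warning("constant covariate(s) dropped from features: ",
            paste(dropped, collapse = ", "))
  }
  feats <- list()
  add <- function(name, class, vars, raw) {
    rng <- range(raw)
    if (!(rng[2] > rng[1])) return()
    feats[[length(feats) + 1L]] <<- list(name = name, class = class,
                                         vars = vars, min = rng[1],
                                         max = rng[2])
  }
  for (j in keep) {
    if ("linear" %in% classes) add(j, "linear", j, background[[j]])
    if ("quadratic" %in% classes) {
      add(paste0(j, "^2"), "quadratic", j, background[[j]]^2)
    }
  }
  if ("product" %in% classes && length(keep) >= 2) {
    prs <- utils::combn(keep, 2, simplify = FALSE)
    for (p in prs) {
      add(paste(p, collapse = "*"), "product", p,
          background[[p[1]]] * background[[p[2]]])
    }
  }
  structure(list(features = feats, covariates = keep, classes = classes),
            class = "maxent_features")
}

# Raw (unscaled) feature values for a pixel table.
maxent_raw_feature <- function(f, pixels) {
  switch(f$class,
         linear = pixels[[f$vars]],
         quadratic = pixels[[f$vars]]^2,
         product = pixels[[f$vars[1]]] * pixels[[f$vars[2]]])
}

#' Evaluate the scaled feature matrix for pixels
#'
#' Values are clamped to \[0,1\] for pixels outside the background bounds;
#' the number of clamped entries is reported with `message()` when nonzero.
#'
#' @param spec A [maxent_features()] object.
#' @param pixels Pixel table.
#' @return Numeric matrix, one column per feature.
#' @export
build_features <- function(spec, pixels) {
  stopifnot(inherits(spec, "maxent_features"))
  n_clamp <- 0L
  cols <- lapply(spec$features, function(f) {
    v <- (maxent_raw_feature(f, pixels) - f$min) / (f$max - f$min)
    n_clamp <<- n_clamp + sum(v < 0 | v > 1)
    pmin(pmax(v, 0), 1)
  })
  if (n_clamp > 0) {
    message("build_features: clamped ", n_clamp,
            " feature value(s) outside background bounds")
  }
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(spec$features, `[[`, "", "name")
  m
}

#' Fit an L1-regularized maximum-entropy habitat model
#'
#' @param presence Pixel-table rows of nest (presence) pixels.
#' @param background Pixel-table rows of available (background) pixels.
#' @param covariates Covariates to use.
#' @param classes Feature classes (see [maxent_features()]).
#' @param beta_multiplier Global multiplier on the default per-feature
#'   regularization (1 = defaults; 0 = unregularized).
#' @param max_iter Maximum coordinate-ascent sweeps.
#' @param tol Convergence tolerance on the penalized objective.
#' @return Object of class `c("maxent_fit", "hsi_fit")` with elements
#'   `lambda` (feature coefficients), `log_partition` (log sum over the
#'   training background of exp(lambda.f)), `entropy` (H of the fitted
#'   background distribution), `beta` (per-feature penalties), `features`.
#' @export
#' @examples
#' tab <- simulate_location(location_spec("toy", 50, 50, n_nests = 30),
#'                          truth_model(), seed = 3)
#' fit <- fit_maxent(tab[tab$nest == 1, ], tab[tab$in_unit == 1, ],
#'                   covariates = "dnbr", classes = "linear")
#' range(predict(fit, tab))
fit_maxent <- function(presence, background,
                       covariates = covariate_names(),
                       classes = c("linear", "quadratic", "product"),
                       beta_multiplier = 1.0, max_iter = 5000, tol = 1e-9) {
  stopifnot(nrow(presence) >= 2, nrow(background) >= nrow(presence))
  spec <- maxent_features(background, covariates, classes)
  Fb <- build_features(spec, background)
  Fp <- build_features(spec, presence)
  m <- nrow(Fp); nb <- nrow(Fb)
  p_mean <- colMeans(Fp)
  s_class <- c(linear = 1.0, quadratic = 1.0, product = 1.2)
  cls <- vapply(spec$features, `[[`, "", "class")
  beta <- beta_multiplier * s_class[cls] * apply(Fb, 2, sd) / sqrt(m)
  nf <- ncol(Fb)
  lambda <- numeric(nf)
  eta <- rep(0, nb)
  objective <- function(lambda, eta) {
    mx <- max(eta)
    lse <- mx + log(mean(exp(eta - mx)))
    sum(lambda * p_mean) - lse - sum(beta * abs(lambda))
  }
  obj <- objective(lambda, eta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (j in seq_len(nf)) {
      mx <- max(eta)
      w <- exp(eta - mx); w <- w / sum(w)
      Eq <- sum(w * Fb[, j])
      Vq <- max(sum(w * Fb[, j]^2) - Eq^2, 1e-8)
      g <- p_mean[j] - Eq
      z <- Vq * lambda[j] + g
      lam_new <- sign(z) * max(abs(z) - beta[j], 0) / Vq
      step <- lam_new - lambda[j]
      if (step == 0) next
      # damped update: halve the step until the objective does not decrease
      repeat {
        cand <- lambda[j] + step
        eta_cand <- eta + step * Fb[, j]
        lam_try <- lambda; lam_try[j] <- cand
        o <- objective(lam_try, eta_cand)
        if (o >= obj - 1e-12 || abs(step) < 1e-14) {
          lambda[j] <- cand; eta <- eta_cand; obj <- o
          break
        }
        step <- step / 2
      }
    }
    o_new <- obj
    obj_settled <- it > 1 && abs(o_new - o_prev) < tol
    o_prev <- o_new
    if (obj_settled) {
      # require the KKT conditions, not just a flat objective:
      # |gap_j| <= beta_j for inactive features, equality for active ones
      mx <- max(eta)
      w <- exp(eta - mx); w <- w / sum(w)
      gaps <- p_mean - colSums(w * Fb)
      viol <- ifelse(lambda == 0, pmax(abs(gaps) - beta, 0),
                     abs(abs(gaps) - beta))
      if (max(viol) < 1e-8) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    mx <- max(eta); w <- exp(eta - mx); w <- w / sum(w)
    grad <- p_mean - colSums(w * Fb)
    stop("maxent fit did not converge in ", max_iter,
         " sweeps (gradient norm ", signif(sqrt(sum(grad^2)), 3), ")")
  }
  mx <- max(eta)
  log_partition <- mx + log(sum(exp(eta - mx)))
  q <- exp(eta - log_partition)
  entropy <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(features = spec, lambda = setNames(lambda, colnames(Fb)),
                 beta = beta, log_partition = log_partition,
                 entropy = entropy, n_presence = m, n_background = nb,
                 beta_multiplier = beta_multiplier,
                 objective = obj, threshold = NA_real_),
            class = c("maxent_fit", "hsi_fit"))
}

#' Predict logistic-output HSI from a Maxent fit
#'
#' With q(x) the background-normalized raw score and H the fitted entropy,
#' HSI = q e^H / (1 + q e^H): strictly increasing in q, equal to 0.5
#' everywhere for an all-zero model.
#'
#' @param object A `maxent_fit`.
#' @param newdata Pixel table.
#' @param ... Unused.
#' @return HSI vector in (0, 1).
#' @export
predict.maxent_fit <- function(object, newdata, ...) {
  Fm <- build_features(object$features, newdata)
  eta <- drop(Fm %*% object$lambda)
  log_qeh <- eta - object$log_partition + object$entropy
  plogis(log_qeh)
}

#' @export
coef.maxent_fit <- function(object, ...) object$lambda

#' @export
print.maxent_fit <- function(x, ...) {
  cat("Maximum-entropy habitat model (", length(x$lambda), " features, ",
      sum(x$lambda != 0), " active)\n", sep = "")
  print(round(x$lambda[x$lambda != 0], 4))
  cat("  entropy H =", round(x$entropy, 4),
      "| presence n =", x$n_presence,
      "| background n =", x$n_background, "\n")
  if (!is.na(x$threshold)) cat("  HSI threshold =", round(x$threshold, 4), "\n")
  invisible(x)
}

#' Percent variable contributions by permutation importance
#'
#' For each covariate, its values are permuted jointly across the presence
#' and background rows, features are rebuilt with the stored background
#' bounds, and the drop in (unpenalized) training gain is recorded; drops
#' are averaged over `n_perm` permutations, floored at zero and normalized
#' to sum to 100.
#'
#' @param fit A [fit_maxent()] result.
#' @param presence,background The fitting data.
#' @param n_perm Permutations per covariate (default 10).
#' @param seed Integer seed.
#' @return Named percentage vector summing to 100 (all-`NA` if the model
#'   has no active feature).
#' @export
variable_contribution <- function(fit, presence, background, n_perm = 10,
                                  seed = 1L) {
  stopifnot(inherits(fit, "maxent_fit"))
  covs <- fit$features$covariates
  if (all(fit$lambda == 0)) {
    warning("all-zero model: contributions undefined")
    return(setNames(rep(NA_real_, length(covs)), covs))
  }
  gain_of <- function(pres, bg) {
    Fp <- build_features(fit$features, pres)
    Fb <- build_features(fit$features, bg)
    etap <- drop(Fp %*% fit$lambda)
    etab <- drop(Fb %*% fit$lambda)
    mx <- max(etab)
    mean(etap) - (mx + log(mean(exp(etab - mx))))
  }
  g0 <- gain_of(presence, background)
  np <- nrow(presence)
  pooled <- rbind(presence[, covs, drop = FALSE],
                  background[, covs, drop = FALSE])
  drops <- with_seed(seed, {
    vapply(covs, function(j) {
      d <- numeric(n_perm)
      for (r in seq_len(n_perm)) {
        perm <- pooled
        perm[[j]] <- sample(perm[[j]])
        d[r] <- g0 - gain_of(perm[seq_len(np), , drop = FALSE],
                             perm[-seq_len(np), , drop = FALSE])
      }
      mean(d)
    }, 0)
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) return(setNames(rep(0, length(covs)), covs))
  100 * drops / sum(drops)
}

#' Backward variable exclusion monitored by cross-validated AUC
#'
#' Starting from a fit on all covariates, iteratively removes the
#' lowest-contribution covariate (among those contributing less than
#' `contribution_floor_pct`) as long as the mean `folds`-fold validation AUC
#' does not drop by more than `auc_tolerance`; halts otherwise.
#'
#' @inheritParams fit_maxent
#' @param contribution_floor_pct Only covariates below this percent
#'   contribution are candidates for removal (default 10).
#' @param folds Cross-validation folds (default 5).
#' @param auc_tolerance Maximum tolerated drop in mean CV AUC (default
#'   0.005).
#' @param seed Integer seed (fold assignment and permutations).
#' @return List with `covariates` (the retained set) and `trace` (data
#'   frame: step, candidate, removed, cv_auc).
#' @export
exclude_minimal_variables <- function(presence, background,
                                      covariates = covariate_names(),
                                      classes = c("linear", "quadratic",
                                                  "product"),
                                      beta_multiplier = 1.0,
                                      contribution_floor_pct = 10,
                                      folds = 5, auc_tolerance = 0.005,
                                      seed = 1L) {
  cv_auc <- function(covs, fold_seed) {
    fp <- kfold_split(nrow(presence), folds, seed = fold_seed)
    fb <- kfold_split(nrow(background), folds,
                      seed = derive_seed(fold_seed, "bg"))
    mean(vapply(seq_len(folds), function(f) {
      fit <- fit_maxent(presence[fp != f, , drop = FALSE],
                        background[fb != f, , drop = FALSE],
                        covs, classes, beta_multiplier)
      auc(predict(fit, presence[fp == f, , drop = FALSE]),
          predict(fit, background[fb == f, , drop = FALSE]))
    }, 0))
  }
  covs <- covariates
  stage_seed <- function(tag) derive_seed(seed, paste0("exclude_minimal_", tag))
  auc_now <- cv_auc(covs, stage_seed("cv0"))
  trace <- data.frame(step = 0L, candidate = NA_character_, removed = NA,
                      cv_auc = auc_now, stringsAsFactors = FALSE)
  step <- 0L
  while (length(covs) > 1) {
    step <- step + 1L
    fit <- fit_maxent(presence, background, covs, classes, beta_multiplier)
    contrib <- variable_contribution(fit, presence, background,
                                     seed = stage_seed(paste0("perm", step)))
    contrib <- contrib[covs]
    low <- names(which.min(contrib))
    if (contrib[low] >= contribution_floor_pct) break
    auc_without <- cv_auc(setdiff(covs, low), stage_seed(paste0("cv", step)))
    ok <- auc_without >= auc_now - auc_tolerance
    trace <- rbind(trace, data.frame(step = step, candidate = low,
                                     removed = ok, cv_auc = auc_without,
                                     stringsAsFactors = FALSE))
    if (!ok) break
    covs <- setdiff(covs, low)
    auc_now <- auc_without
  }
  list(covariates = covs, trace = trace)
}
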