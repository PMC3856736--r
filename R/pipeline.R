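# End-to-end orchestration: simulate (or load) a study, fit the 8-model
# roster, select thresholds, evaluate, build ensemble summaries and
# diagnostics, and optionally write all artifacts to a run directory.

#' Configuration for a full study run
#'
#' @param study A [study_spec()] (simulate mode), or `NULL` with `data`
#'   supplied.
#' @param data Optional pre-built pixel table (file mode); overrides
#'   simulation.
#' @param seed Global seed; every stage seed is derived from it.
#' @param wlr_locations Calibration locations to fit WLR models for
#'   (`NULL` = all locations with nests; `character(0)` = no WLR models).
#' @param wlr_n_available Available (non-nest, in-unit) pixels sampled per
#'   calibration location for WLR fitting, recycled over locations
#'   (defaults 68, 100, 47).
#' @param mahal_specs List of [mahal_partition_spec()]s (default: the 2-,
#'   3- and 4-variable sets at k = k_max).
#' @param mahal_iters Mahalanobis subsample replicates (default 100).
#' @param mahal_nests Nest pixels per location per replicate (default 28).
#' @param maxent_variants Named list; each element is
#'   `list(covariates=, classes=)` (default: the 3-variable
#'   linear/quadratic/product model and the dNBR-only linear model).
#' @param n_available Total available pixels for threshold selection and
#'   Maxent background (default 10000, capped by survey-unit size).
#' @param distance_per_location Pixels per location for the distance
#'   reference and per-location distance samples (default 5000).
#' @param output_dir Optional directory to write artifacts to.
#' @return Object of class `run_config`.
#' @export
run_config <- function(study = default_study(seed), data = NULL, seed = 1L,
                       wlr_locations = NULL,
                       wlr_n_available = c(68, 100, 47),
                       mahal_specs = list(
                         mahal_partition_spec(c("cosasp", "dnbr"), 2),
                         mahal_partition_spec(c("dnbr", "loccc", "landcc"), 3),
                         mahal_partition_spec(covariate_names(), 4)),
                       mahal_iters = 100, mahal_nests = 28,
                       maxent_variants = list(
                         maxent_3var = list(
                           covariates = c("cosasp", "dnbr", "loccc"),
                           classes = c("linear", "quadratic", "product")),
                         maxent_dnbr = list(covariates = "dnbr",
                                            classes = "linear")),
                       n_available = 10000,
                       distance_per_location = 5000,
                       output_dir = NULL) {
  cfg <- list(study = study, data = data, seed = as.integer(seed),
              wlr_locations = wlr_locations,
              wlr_n_available = wlr_n_available, mahal_specs = mahal_specs,
              mahal_iters = mahal_iters, mahal_nests = mahal_nests,
              maxent_variants = maxent_variants, n_available = n_available,
              distance_per_location = distance_per_location,
              output_dir = output_dir)
  if (is.null(cfg$study) && is.null(cfg$data)) {
    stop("run_config needs either a study spec or a pixel table")
  }
  roster_empty <- !length(cfg$mahal_specs) && !length(cfg$maxent_variants) &&
    (!is.null(cfg$wlr_locations) && !length(cfg$wlr_locations))
  if (roster_empty) stop("model roster is empty")
  structure(cfg, class = "run_config")
}

#' Validate a pixel table (or study spec) for the pipeline
#'
#' Report-only checks: covariate ranges, 0/1 flag encoding, per-location
#' nest counts against the Mahalanobis subsample size, and location
#' consistency.
#'
#' @param x Pixel table or [study_spec()].
#' @param mahal_nests Required nests per calibration location (default 28).
#' @return Data frame of checks with columns `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(x, mahal_nests = 28) {
  if (inherits(x, "study_spec")) x <- simulate_study(x)
  check_pixel_table(x)
  res <- list()
  add <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(check = check, pass = pass,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  add("cosasp range", all(abs(x$cosasp) <= 1),
      if (!all(abs(x$cosasp) <= 1)) "values outside [-1, 1]" else "")
  add("canopy proportions", all(x$loccc >= 0 & x$loccc <= 1 &
                                  x$landcc >= 0 & x$landcc <= 1))
  add("flags binary", is_binary01(x$in_unit) && is_binary01(x$nest))
  add("nests inside units", all(x$in_unit[x$nest == 1] == 1),
      "nest pixels must lie in survey units")
  dup <- anyDuplicated(x[, c("location", "row", "col")])
  add("pixels unique", dup == 0)
  nest_locs <- unique(x$location[x$nest == 1])
  for (l in nest_locs) {
    n <- sum(x$nest == 1 & x$location == l)
    add(paste0("nest count (", l, ")"), n >= mahal_nests,
        paste0(n, " nests, need >= ", mahal_nests))
  }
  do.call(rbind, res)
}

#' Run the full ensemble habitat suitability study
#'
#' Stages, in order: data snapshot (simulate or ingest); per-calibration-
#' location WLR with all-subsets AICc selection; partitioned Mahalanobis
#' models on equal-representation subsamples; Maxent variants; pooled
#' predictive-gain thresholds; model-by-location performance table;
#' predictions and binary classifications for every location; ensemble
#' counts, per-location liberal/conservative/agreement proportions
#' (outside survey units at calibration locations); nest rate by ensemble
#' level (surveyed pixels); environmental distances and the
#' agreement-vs-distance regression.  All randomness derives from
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @param verbose Print stage messages (default TRUE).
#' @return Object of class `hsi_study` holding the data, fitted models,
#'   thresholds, performance table and ensemble summaries.
#' @export
run_study <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[firehsi] ", ...)
  t0 <- Sys.time()

  say("stage 1/6: data")
  data <- if (!is.null(config$data)) config$data else simulate_study(config$study)
  check_pixel_table(data)
  calib_locs <- unique(data$location[data$nest == 1])
  if (!length(calib_locs)) stop("stage data: no calibration nests found")
  all_locs <- unique(data$location)
  unit <- data[data$in_unit == 1, , drop = FALSE]

  wlr_locs <- if (is.null(config$wlr_locations)) calib_locs else
    intersect(config$wlr_locations, calib_locs)
  say("stage 2/6: weighted logistic regressions (", length(wlr_locs),
      " locations)")
  n_avail <- rep_len(config$wlr_n_available, max(length(wlr_locs), 1))
  wlr_fits <- list()
  for (i in seq_along(wlr_locs)) {
    l <- wlr_locs[i]
    used <- data[data$location == l & data$nest == 1, , drop = FALSE]
    pool <- which(unit$location == l & unit$nest == 0)
    avail <- with_seed(derive_seed(config$seed, paste0("wlr_", l)), {
      unit[sample(pool, min(n_avail[i], length(pool))), , drop = FALSE]
    })
    sel <- all_subsets_aicc(used, avail, covariate_names(), location = l)
    wlr_fits[[paste0("wlr_", l)]] <- sel$best
  }

  say("stage 3/6: partitioned Mahalanobis models (",
      length(config$mahal_specs), " specs)")
  mahal_fits <- list()
  for (i in seq_along(config$mahal_specs)) {
    sp <- config$mahal_specs[[i]]
    nm <- paste0("mahal_", length(sp$covariates), "var_k", sp$k)
    mahal_fits[[nm]] <- fit_mahal(
      data, sp, n_iter = config$mahal_iters,
      per_location_nests = config$mahal_nests,
      seed = derive_seed(config$seed, paste0("mahal_", i)))
  }

  say("stage 4/6: maxent models (", length(config$maxent_variants),
      " variants)")
  nests_all <- data[data$nest == 1, , drop = FALSE]
  nest_counts <- table(nests_all$location)[calib_locs]
  bg_quota <- round(config$n_available * as.numeric(nest_counts) /
                      sum(nest_counts))
  background <- with_seed(derive_seed(config$seed, "maxent_bg"), {
    do.call(rbind, lapply(seq_along(calib_locs), function(i) {
      pool <- which(unit$location == calib_locs[i])
      unit[sample(pool, min(bg_quota[i], length(pool))), , drop = FALSE]
    }))
  })
  maxent_fits <- list()
  for (nm in names(config$maxent_variants)) {
    v <- config$maxent_variants[[nm]]
    maxent_fits[[nm]] <- fit_maxent(nests_all, background,
                                    covariates = v$covariates,
                                    classes = v$classes)
  }

  models <- c(wlr_fits, mahal_fits, maxent_fits)

  say("stage 5/6: thresholds and performance")
  avail_thr <- with_seed(derive_seed(config$seed, "threshold_avail"), {
    per_loc <- ceiling(config$n_available / length(calib_locs))
    do.call(rbind, lapply(calib_locs, function(l) {
      pool <- which(unit$location == l)
      unit[sample(pool, min(per_loc, length(pool))), , drop = FALSE]
    }))
  })
  thresholds <- list()
  for (nm in names(models)) {
    thr <- threshold_max_gain(predict(models[[nm]], nests_all),
                              predict(models[[nm]], avail_thr))
    thresholds[[nm]] <- thr
    models[[nm]] <- set_threshold(models[[nm]], thr)
  }
  perf <- performance_table(models, data, locations = calib_locs)

  say("stage 6/6: ensemble summaries and diagnostics")
  classification <- classify_all(models, data)
  counts <- ensemble_count(classification)
  n_models <- length(models)
  is_calib <- data$location %in% calib_locs
  # Table-5 convention: outside survey units at calibration locations,
  # whole locations elsewhere
  keep <- ifelse(is_calib, data$in_unit == 0, TRUE)
  props <- location_proportions(counts[keep], data$location[keep], n_models)
  props <- props[match(all_locs, props$location), ]
  surveyed <- data$in_unit == 1 & is_calib
  nest_rate <- nest_rate_by_count(counts[surveyed], data$nest[surveyed],
                                  n_models)
  ref <- distance_reference(data[is_calib, , drop = FALSE],
                            per_location = config$distance_per_location,
                            seed = derive_seed(config$seed, "distance_ref"))
  dist_rows <- list(); med_dist <- numeric(0)
  all_dist <- numeric(0)
  for (l in all_locs) {
    pool <- which(data$location == l & keep)
    samp_idx <- with_seed(derive_seed(config$seed, paste0("dist_", l)), {
      sample(pool, min(config$distance_per_location, length(pool)))
    })
    d <- environmental_distance(ref, data[samp_idx, , drop = FALSE])
    s <- median_distance_summary(d)
    med_dist <- c(med_dist, s[["median"]])
    all_dist <- c(all_dist, d)
    dist_rows[[l]] <- data.frame(location = l, n = length(d),
                                 median = s[["median"]], lower = s[["lower"]],
                                 upper = s[["upper"]],
                                 stringsAsFactors = FALSE)
  }
  dist_tab <- do.call(rbind, dist_rows)
  rownames(dist_tab) <- NULL
  agr <- agreement_vs_distance(props$agreement, med_dist)
  ref_dist <- environmental_distance(ref, as.data.frame(ref$sample))
  out <- structure(list(
    config = config, data = data, models = models, thresholds = thresholds,
    performance = perf, classification = classification, counts = counts,
    location_summary = cbind(props,
                             median_distance = med_dist,
                             calibration = all_locs %in% calib_locs),
    nest_rate = nest_rate, agreement_distance = agr,
    distance_table = dist_tab,
    distance_reference = ref,
    surveyed_distance_summary = median_distance_summary(ref_dist),
    applied_distance_summary = median_distance_summary(all_dist),
    calibration_locations = calib_locs,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "hsi_study")
  if (!is.null(config$output_dir)) write_study_artifacts(out,
                                                         config$output_dir)
  out
}

# Write CSV artifacts and a plain-text manifest for a finished run.
write_study_artifacts <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pixel_table(study$data, file.path(dir, "data_snapshot.csv"))
  write.csv(study$performance, file.path(dir, "performance.csv"),
            row.names = FALSE)
  write.csv(study$location_summary, file.path(dir, "ensemble_locations.csv"),
            row.names = FALSE)
  write.csv(study$nest_rate$table, file.path(dir, "nest_rate.csv"),
            row.names = FALSE)
  write.csv(study$distance_table, file.path(dir, "agreement_distance.csv"),
            row.names = FALSE)
  thr <- data.frame(model = names(study$thresholds),
                    threshold = vapply(study$thresholds, `[[`, 0,
                                       "threshold"),
                    gain = vapply(study$thresholds, `[[`, 0, "gain"))
  write.csv(thr, file.path(dir, "thresholds.csv"), row.names = FALSE)
  manifest <- c(
    paste0("package: firehsi ",
           as.character(utils::packageVersion("firehsi"))),
    paste0("seed: ", study$config$seed),
    paste0("n_models: ", length(study$models)),
    paste0("models: ", paste(names(study$models), collapse = ", ")),
    paste0("locations: ",
           paste(unique(study$data$location), collapse = ", ")),
    paste0("config_checksum: ", config_checksum(study$config)))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

# Simple deterministic checksum of the deparsed config (ignoring output_dir).
config_checksum <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  txt <- paste(deparse(cfg), collapse = "\n")
  cp <- utf8ToInt(txt)
  h <- 0
  for (i in seq_along(cp)) h <- (h * 131 + cp[i]) %% 2147483629
  sprintf("%010d", h)
}

#' @export
print.hsi_study <- function(x, ...) {
  cat("Ensemble habitat suitability study\n")
  cat("  ", length(x$calibration_locations), "calibration +",
      length(unique(x$data$location)) - length(x$calibration_locations),
      "application location(s),", nrow(x$data), "pixels\n")
  cat("  ", length(x$models), "models:",
      paste(names(x$models), collapse = ", "), "\n")
  cat("  mean calibration AUC:",
      round(mean(x$performance$auc, na.rm = TRUE), 3), "\n")
  cat("  nest rate vs ensemble level: Pearson r =",
      round(x$nest_rate$pearson_r, 3), "\n")
  cat("  agreement vs distance: Pearson r =",
      round(x$agreement_distance$pearson_r, 3), "\n")
  invisible(x)
}

#' @export
summary.hsi_study <- function(object, ...) {
  cat("Performance (model x location):\n")
  print(object$performance, digits = 3)
  cat("\nLocation ensemble summary:\n")
  print(object$location_summary, digits = 3)
  cat("\nNest rate by ensemble level:\n")
  print(object$nest_rate$table, digits = 3)
  invisible(object)
}

#' Plot study diagnostics
#'
#' `type = "agreement"`: location-level model agreement against median
#' environmental distance with the fitted regression line.
#' `type = "nest_rate"`: nest occurrence proportion against ensemble level.
#'
#' @param x An `hsi_study`.
#' @param type Which diagnostic to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hsi_study <- function(x, type = c("agreement", "nest_rate"), ...) {
  type <- match.arg(type)
  if (type == "agreement") {
    ls <- x$location_summary
    plot(ls$median_distance, ls$agreement,
         xlab = "median environmental distance",
         ylab = "model agreement",
         pch = ifelse(ls$calibration, 19, 1), ...)
    abline(x$agreement_distance$intercept, x$agreement_distance$slope,
           lty = 2)
    legend("topright", pch = c(19, 1),
           legend = c("calibration", "application"), bty = "n")
  } else {
    tb <- x$nest_rate$table
    plot(tb$level, tb$proportion, type = "b",
         xlab = "ensemble level (models classifying suitable)",
         ylab = "proportion of pixels with nests", ...)
  }
  invisible(x)
}
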