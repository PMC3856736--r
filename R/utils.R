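#' Names of the four model covariates
#'
#' Column names used throughout the package for the pixel covariates:
#' cosine aspect (`cosasp`, unitless in \[-1,1\]), delta normalized burn
#' ratio (`dnbr`, unitless burn-severity index), and local- / landscape-scale
#' prefire canopy cover (`loccc`, `landcc`, proportions in \[0,1\]).
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' covariate_names()
covariate_names <- function() c("cosasp", "dnbr", "loccc", "landcc")

# Hard range limits per covariate; NA = unbounded.
covariate_bounds <- function() {
  list(cosasp = c(-1, 1), dnbr = c(NA_real_, NA_real_),
       loccc = c(0, 1), landcc = c(0, 1))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions taking a `seed` argument do not disturb
#' the global random number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a child seed from a parent seed and a key
#'
#' Deterministic derivation of per-stage / per-location seeds from one study
#' seed, stable when locations are added (the child depends only on the
#' parent seed and the key, not on list position).
#'
#' @param seed Integer parent seed.
#' @param key Character or integer key (e.g. a location name or stage name).
#' @return An integer in \[1, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(42, "tripod")
derive_seed <- function(seed, key) {
  cp <- utf8ToInt(as.character(key))
  h <- 0
  for (i in seq_along(cp)) h <- (h * 131 + cp[i]) %% 2147483629
  v <- ((as.numeric(seed) %% 2147483629) * 48271 + h) %% 2147483629
  as.integer(v) + 1L
}

# Validate that a data frame is a usable pixel table.
check_pixel_table <- function(x, require_covariates = covariate_names()) {
  stopifnot(is.data.frame(x))
  needed <- c("location", "row", "col", require_covariates, "in_unit", "nest")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("pixel table is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(x)
}

is_binary01 <- function(x) all(x %in% c(0, 1))

# Quantile convention used for all "median-unbiased" summaries
# (Hyndman-Fan type 8, alpha = beta = 1/3).
mu_quantile <- function(x, probs) {
  quantile(x, probs = probs, type = 8, names = FALSE)
}
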