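# Covariate derivation from raw grids: cosine aspect, square and circular
# moving-window means, canopy-cover binarize-then-average, and Grid <->
# pixel-table conversion.

#' Construct a single-covariate raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus pixel size and a nodata
#' sentinel.  Cells equal to `nodata` (or `NA`) are treated as missing.
#'
#' @param values Numeric matrix.
#' @param pixel_size_m Pixel edge length in metres (default 30).
#' @param nodata Nodata sentinel value (default -9999).
#' @return Object of class `hsi_grid`.
#' @export
#' @examples
#' g <- hsi_grid(matrix(1:9, 3, 3))
hsi_grid <- function(values, pixel_size_m = 30, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), pixel_size_m > 0)
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(list(values = values, pixel_size_m = pixel_size_m,
                 nodata = nodata),
            class = "hsi_grid")
}

#' @export
print.hsi_grid <- function(x, ...) {
  cat("hsi_grid: ", nrow(x$values), " x ", ncol(x$values), " cells, ",
      x$pixel_size_m, " m pixels, ", sum(is.na(x$values)),
      " nodata cell(s)\n", sep = "")
  invisible(x)
}

#' Cosine-transform slope aspect
#'
#' Maps aspect in degrees clockwise from north to the north-south
#' orientation index: +1 for north-facing, -1 for south-facing, 0 for
#' east/west.  Nodata (`NA`) propagates.
#'
#' @param aspect_deg Aspect in degrees, in \[0, 360).
#' @return Numeric vector in \[-1, 1\].
#' @export
#' @examples
#' cosine_aspect(c(0, 90, 180))
cosine_aspect <- function(aspect_deg) {
  bad <- !is.na(aspect_deg) & (aspect_deg < 0 | aspect_deg >= 360)
  if (any(bad)) stop("aspect values must lie in [0, 360)")
  cospi(aspect_deg / 180)
}

# Shift-and-accumulate focal mean over an arbitrary offset kernel.
# Nodata cells are excluded; at edges the window shrinks to available cells;
# windows with no valid cell yield nodata.
focal_mean_offsets <- function(grid, offsets) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  vz <- v; vz[!valid] <- 0
  sums <- matrix(0, nr, nc)
  cnts <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets[i, 1]; dc <- offsets[i, 2]
    if (abs(dr) >= nr || abs(dc) >= nc) next
    sr <- max(1, 1 - dr):min(nr, nr - dr)   # target rows
    sc <- max(1, 1 - dc):min(nc, nc - dc)
    sums[sr, sc] <- sums[sr, sc] + vz[sr + dr, sc + dc, drop = FALSE]
    cnts[sr, sc] <- cnts[sr, sc] + valid[sr + dr, sc + dc, drop = FALSE]
  }
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  hsi_grid(out, grid$pixel_size_m, grid$nodata)
}

#' Square moving-window mean
#'
#' Mean over the (2h+1) x (2h+1) window centred on each cell.  At edges the
#' window shrinks to the cells that exist; nodata cells are excluded from
#' the mean, and a window with no valid cell yields nodata.
#'
#' @param grid An [hsi_grid()].
#' @param half_width_px Window half-width in pixels (default 1, i.e. the
#'   1-ha 3x3 window at 30-m pixels).
#' @return An [hsi_grid()].
#' @export
#' @examples
#' g <- hsi_grid(matrix(1:9, 3, 3, byrow = TRUE))
#' focal_mean_square(g)$values[2, 2]   # 5
focal_mean_square <- function(grid, half_width_px = 1L) {
  stopifnot(inherits(grid, "hsi_grid"), half_width_px >= 0)
  h <- as.integer(half_width_px)
  offsets <- as.matrix(expand.grid(dr = -h:h, dc = -h:h))
  focal_mean_offsets(grid, offsets)
}

# Offsets of cells whose centres lie within radius_m of the focal centre.
circle_offsets <- function(radius_m, pixel_size_m) {
  r_px <- radius_m / pixel_size_m
  h <- floor(r_px)
  g <- expand.grid(dr = -h:h, dc = -h:h)
  keep <- sqrt(g$dr^2 + g$dc^2) <= r_px + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Circular moving-window mean
#'
#' Mean over all cells whose centres lie within `radius_m` of the focal cell
#' centre (the focal cell always included).  Edge and nodata policy as in
#' [focal_mean_square()].  The realized interior kernel cell count is
#' reported with `message()` so the neighbourhood definition can be audited.
#'
#' @param grid An [hsi_grid()].
#' @param radius_m Window radius in metres (default 1000, the landscape-scale
#'   314-ha window).
#' @return An [hsi_grid()].
#' @export
focal_mean_circle <- function(grid, radius_m = 1000) {
  stopifnot(inherits(grid, "hsi_grid"), radius_m > 0)
  offsets <- circle_offsets(radius_m, grid$pixel_size_m)
  message("focal_mean_circle: kernel of ", nrow(offsets),
          " cells at radius ", radius_m, " m / ",
          grid$pixel_size_m, " m pixels")
  focal_mean_offsets(grid, offsets)
}

#' Canopy-cover proportion covariates from a percent-canopy grid
#'
#' Binarizes canopy cover at strictly greater than `threshold_pct`, then
#' averages over the local 3x3 window (`loccc_from_canopy`) or the circular
#' landscape window (`landcc_from_canopy`), yielding the proportion of the
#' neighbourhood with moderate-to-high canopy cover, in \[0,1\].
#'
#' @param canopy An [hsi_grid()] of percent canopy cover in \[0, 100\].
#' @param threshold_pct Strict binarization threshold (default 40).
#' @param radius_m Landscape window radius in metres (landcc only).
#' @return An [hsi_grid()] of proportions.
#' @export
loccc_from_canopy <- function(canopy, threshold_pct = 40) {
  focal_mean_square(binarize_canopy(canopy, threshold_pct), 1L)
}

#' @rdname loccc_from_canopy
#' @export
landcc_from_canopy <- function(canopy, threshold_pct = 40, radius_m = 1000) {
  focal_mean_circle(binarize_canopy(canopy, threshold_pct), radius_m)
}

binarize_canopy <- function(canopy, threshold_pct) {
  stopifnot(inherits(canopy, "hsi_grid"))
  v <- canopy$values
  if (any(v < 0 | v > 100, na.rm = TRUE)) {
    stop("canopy values must be percentages in [0, 100] or nodata")
  }
  hsi_grid((v > threshold_pct) * 1, canopy$pixel_size_m, canopy$nodata)
}

#' Convert covariate grids to a pixel table and back
#'
#' `grids_to_pixel_table` stacks one grid per covariate (all the same shape)
#' into the tabular layout used by the models; cells that are nodata in any
#' covariate are omitted.  `pixel_table_to_grid` restores a single covariate
#' to its grid, filling unobserved cells with nodata; the round trip is
#' lossless for valid cells.
#'
#' @param location Location identifier.
#' @param grids Named list of [hsi_grid()]s, one per entry of
#'   [covariate_names()].
#' @param unit_mask,nest_mask Logical/0-1 matrices of the grid shape
#'   (default: all outside the unit, no nests).
#' @return A pixel-table data frame / an [hsi_grid()].
#' @export
grids_to_pixel_table <- function(location, grids, unit_mask = NULL,
                                 nest_mask = NULL) {
  covs <- covariate_names()
  missing <- setdiff(covs, names(grids))
  if (length(missing)) {
    stop("missing grid(s): ", paste(missing, collapse = ", "))
  }
  dims <- dim(grids[[covs[1]]]$values)
  for (j in covs) {
    if (!identical(dim(grids[[j]]$values), dims)) {
      stop("grid '", j, "' has shape ", paste(dim(grids[[j]]$values),
                                              collapse = "x"),
           ", expected ", paste(dims, collapse = "x"))
    }
  }
  nr <- dims[1]; nc <- dims[2]
  if (is.null(unit_mask)) unit_mask <- matrix(0L, nr, nc)
  if (is.null(nest_mask)) nest_mask <- matrix(0L, nr, nc)
  tab <- data.frame(location = as.character(location),
                    row = rep(seq_len(nr), times = nc),
                    col = rep(seq_len(nc), each = nr),
                    stringsAsFactors = FALSE)
  for (j in covs) tab[[j]] <- as.vector(grids[[j]]$values)
  tab$in_unit <- as.integer(as.vector(unit_mask) != 0)
  tab$nest <- as.integer(as.vector(nest_mask) != 0)
  keep <- stats::complete.cases(tab[, covs])
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @rdname grids_to_pixel_table
#' @param table Pixel table.
#' @param covariate One of [covariate_names()].
#' @param pixel_size_m,nodata Grid metadata for the result.
#' @export
pixel_table_to_grid <- function(table, covariate, pixel_size_m = 30,
                                nodata = -9999) {
  check_pixel_table(table)
  stopifnot(covariate %in% c(covariate_names(), "in_unit", "nest"))
  nr <- max(table$row); nc <- max(table$col)
  v <- matrix(NA_real_, nr, nc)
  v[cbind(table$row, table$col)] <- table[[covariate]]
  hsi_grid(v, pixel_size_m, nodata)
}
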