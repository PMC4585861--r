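# Classification of EI grids, per-class area accounting, scenario
# comparison (stress change, class transitions) and occurrence overlay.

EARTH_RADIUS_KM <- 6371.0088

#' Suitability class labels
#'
#' Ordered from least to most suitable; integer codes 0-3 in raster output.
#'
#' @return character vector of the four class labels.
#' @export
suitability_levels <- function() {
  c("unsuitable", "marginal", "suitable", "highly_suitable")
}

#' Classify Ecoclimatic Index values
#'
#' Maps EI to the four suitability classes: `EI < 1` unsuitable,
#' `1 <= EI < 10` marginal, `10 <= EI <= 20` suitable (able to support
#' substantial populations), `EI > 20` highly suitable. Classification uses
#' the unrounded double-precision EI.
#'
#' @param ei numeric EI values in [0, 100] (NA passes through).
#' @return ordered factor over [suitability_levels()].
#' @export
classify_ei <- function(ei) {
  ok <- is.na(ei) | (ei >= 0 & ei <= 100)
  if (!all(ok)) {
    stop("EI out of [0, 100]: ", paste(utils::head(ei[!ok]), collapse = ", "),
         call. = FALSE)
  }
  code <- ifelse(ei < 1, 0L, ifelse(ei < 10, 1L, ifelse(ei <= 20, 2L, 3L)))
  factor(suitability_levels()[code + 1L], levels = suitability_levels(),
         ordered = TRUE)
}

#' Spherical area of a grid cell
#'
#' Area of a lon/lat cell as a spherical zone section:
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with
#' `R = 6371.0088 km`.
#'
#' @param lat_center cell-center latitude(s), degrees.
#' @param cell_size cell edge, degrees.
#' @return area(s) in km^2.
#' @export
cell_area <- function(lat_center, cell_size) {
  half <- cell_size / 2
  if (any(abs(lat_center) + half > 90 + 1e-9)) {
    stop("cell extends beyond +/-90 degrees latitude", call. = FALSE)
  }
  top <- pmin(90, lat_center + half) * pi / 180
  bot <- pmax(-90, lat_center - half) * pi / 180
  EARTH_RADIUS_KM^2 * (cell_size * pi / 180) * (sin(top) - sin(bot))
}

result_class_factor <- function(result) {
  factor(suitability_levels()[result$class_code + 1L],
         levels = suitability_levels(), ordered = TRUE)
}

#' Per-class area accounting
#'
#' Sums spherical cell areas over the valid mask by suitability class,
#' giving one row of the scenario-by-class area table. Totals over classes
#' are a fixed-mask invariant: every scenario on the same grid and mask sums
#' to the same regional total.
#'
#' @param result an `annual_result` from [run_grid()].
#' @param scenario label for the row.
#' @return data frame with columns `scenario`, the four class areas (km^2),
#'   and `total`.
#' @export
area_table <- function(result, scenario = "current") {
  stopifnot(inherits(result, "annual_result"))
  areas <- matrix(rep(cell_area(grid_lats(result$grid),
                                result$grid$cell_size),
                      result$grid$n_lon),
                  nrow = result$grid$n_lat)
  cls <- result$class_code[result$mask]
  a <- areas[result$mask]
  by_class <- vapply(0:3, function(k) sum(a[cls == k]), 0)
  out <- data.frame(scenario = scenario,
                    t(stats::setNames(by_class, suitability_levels())),
                    total = sum(a), check.names = FALSE)
  rownames(out) <- NULL
  out
}

check_same_footprint <- function(run_a, run_b) {
  if (!same_grid(run_a$grid, run_b$grid)) {
    stop("grid mismatch between runs", call. = FALSE)
  }
  if (!identical(run_a$mask, run_b$mask)) {
    stop("mask mismatch between runs", call. = FALSE)
  }
}

#' Per-cell change between two runs
#'
#' `stress_change()` returns the cellwise arithmetic difference `b - a` of
#' the named stress (or of `EI`); `class_transitions()` cross-tabulates the
#' suitability classes of the two runs (area-weighted km^2, or cell counts).
#' Both require identical grids and masks.
#'
#' @param run_a,run_b `annual_result` objects on the same grid and mask.
#' @param which one of `"CS"`, `"HS"`, `"DS"`, `"WS"`, `"EI"`.
#' @return `stress_change()`: list with `delta` (matrix, `NA` off-mask),
#'   `which`, `grid`, `mask` (class `change_map`). `class_transitions()`: a
#'   4x4 matrix, rows = classes in `run_a`, columns = classes in `run_b`.
#' @export
stress_change <- function(run_a, run_b, which = c("CS", "HS", "DS", "WS", "EI")) {
  which <- match.arg(which)
  check_same_footprint(run_a, run_b)
  structure(list(delta = run_b[[which]] - run_a[[which]], which = which,
                 grid = run_a$grid, mask = run_a$mask),
            class = "change_map")
}

#' @rdname stress_change
#' @param weighted if `TRUE` (default) entries are km^2; otherwise cell
#'   counts.
#' @export
class_transitions <- function(run_a, run_b, weighted = TRUE) {
  check_same_footprint(run_a, run_b)
  grid <- run_a$grid
  w <- if (weighted) {
    matrix(rep(cell_area(grid_lats(grid), grid$cell_size), grid$n_lon),
           nrow = grid$n_lat)[run_a$mask]
  } else {
    rep(1, sum(run_a$mask))
  }
  a <- run_a$class_code[run_a$mask]
  b <- run_b$class_code[run_b$mask]
  m <- matrix(0, 4L, 4L, dimnames = list(from = suitability_levels(),
                                         to = suitability_levels()))
  for (k in seq_along(a)) m[a[k] + 1L, b[k] + 1L] <- m[a[k] + 1L, b[k] + 1L] + w[k]
  m
}

#' Overlay occurrence points on a suitability grid
#'
#' Looks up the suitability class of each point by nearest cell center (no
#' interpolation; categorical map semantics). Points outside the grid or on
#' masked cells are flagged `off_grid` and excluded from the counts.
#'
#' @param points data frame with columns `lon`, `lat`.
#' @param result an `annual_result` from [run_grid()].
#' @return list with `points` (the input plus `EI`, `class`, `off_grid`),
#'   `class_counts` (named counts over on-grid points), and `fraction_ei_pos`
#'   (fraction of on-grid points with EI > 0).
#' @export
overlay_occurrences <- function(points, result) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  grid <- result$grid
  j <- round((points$lon - grid$lon_origin) / grid$cell_size) + 1L
  i <- round((grid$lat_origin - points$lat) / grid$cell_size) + 1L
  inside <- i >= 1L & i <= grid$n_lat & j >= 1L & j <= grid$n_lon
  on_mask <- inside
  on_mask[inside] <- result$mask[cbind(i[inside], j[inside])]
  ei <- rep(NA_real_, nrow(points))
  cls <- rep(NA_integer_, nrow(points))
  ei[on_mask] <- result$EI[cbind(i[on_mask], j[on_mask])]
  cls[on_mask] <- result$class_code[cbind(i[on_mask], j[on_mask])]
  pts <- cbind(points,
               EI = ei,
               class = factor(suitability_levels()[cls + 1L],
                              levels = suitability_levels(), ordered = TRUE),
               off_grid = !on_mask)
  counts <- table(pts$class[!pts$off_grid])
  frac <- if (any(!pts$off_grid)) mean(ei[on_mask] > 0) else NA_real_
  list(points = pts, class_counts = counts, fraction_ei_pos = frac)
}

#' Write result layers as ASCII rasters
#'
#' Writes the EI surface (float) and the class surface (integer codes 0-3)
#' of a run as ESRI ASCII grids; the conventional map legend is
#' white/blue/yellow/red for codes 0/1/2/3.
#'
#' @param result an `annual_result`.
#' @param dir output directory.
#' @param label scenario label used in file names (`ei_<label>.asc`,
#'   `class_<label>.asc`).
#' @return invisibly, the written file paths.
#' @export
write_result_rasters <- function(result, dir, label = "current") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ei_path <- file.path(dir, sprintf("ei_%s.asc", label))
  cls_path <- file.path(dir, sprintf("class_%s.asc", label))
  write_asc(result$EI, result$grid, ei_path)
  cls <- result$class_code
  storage.mode(cls) <- "double"
  write_asc(cls, result$grid, cls_path, digits = 1)
  invisible(c(ei_path, cls_path))
}
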