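# Gridded and station monthly climatologies: containers, plain-text I/O,
# and scenario perturbation. Coordinates are WGS84 lon/lat, cell-center
# registered, latitudes stored north -> south, longitudes west -> east.

CLIM_VARS <- c("tmin", "tmax", "ptotal", "rh0900", "rh1500")

#' Define a regular geographic grid
#'
#' Cell-center registration: `lon_origin`/`lat_origin` are the center of the
#' north-west cell; row `i` has center latitude
#' `lat_origin - (i-1) * cell_size` (north to south) and column `j` has center
#' longitude `lon_origin + (j-1) * cell_size` (west to east).
#'
#' @param lon_origin,lat_origin center of the north-west cell, degrees.
#' @param cell_size cell edge, degrees (default 1/6 degree = 10 arcmin).
#' @param n_lon,n_lat number of columns / rows.
#' @return a `grid_definition` object.
#' @export
grid_definition <- function(lon_origin, lat_origin, cell_size = 1 / 6,
                            n_lon, n_lat) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            n_lon >= 1L, n_lat >= 1L)
  west <- lon_origin - cell_size / 2
  east <- lon_origin + (n_lon - 1) * cell_size + cell_size / 2
  north <- lat_origin + cell_size / 2
  south <- lat_origin - (n_lat - 1) * cell_size - cell_size / 2
  if (west < -180 - 1e-9 || east > 180 + 1e-9) {
    stop("grid exceeds [-180, 180] longitude", call. = FALSE)
  }
  if (south < -90 - 1e-9 || north > 90 + 1e-9) {
    stop("grid exceeds [-90, 90] latitude", call. = FALSE)
  }
  structure(
    list(lon_origin = as.numeric(lon_origin),
         lat_origin = as.numeric(lat_origin),
         cell_size = as.numeric(cell_size),
         n_lon = as.integer(n_lon), n_lat = as.integer(n_lat)),
    class = "grid_definition"
  )
}

#' @rdname grid_definition
#' @param grid a `grid_definition`.
#' @return `grid_lons()` / `grid_lats()` return the vectors of cell-center
#'   longitudes (west to east) and latitudes (north to south).
#' @export
grid_lons <- function(grid) grid$lon_origin + (seq_len(grid$n_lon) - 1L) * grid$cell_size

#' @rdname grid_definition
#' @export
grid_lats <- function(grid) grid$lat_origin - (seq_len(grid$n_lat) - 1L) * grid$cell_size

same_grid <- function(a, b, tol = 1e-9) {
  a$n_lon == b$n_lon && a$n_lat == b$n_lat &&
    abs(a$lon_origin - b$lon_origin) < tol &&
    abs(a$lat_origin - b$lat_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Assemble a monthly climatology
#'
#' Bundles the five input variables — average monthly minimum and maximum
#' temperature (degC), monthly precipitation total (mm), and relative
#' humidity at 09:00 and 15:00 (percent) — on a shared grid with a shared
#' land/valid mask. Each variable is an `n_lat x n_lon x 12` array (or a
#' length-12 vector for a single-cell climatology). Cells with any missing
#' value in any variable are masked out.
#'
#' @param grid a [grid_definition].
#' @param tmin,tmax,ptotal,rh0900,rh1500 `n_lat x n_lon x 12` arrays.
#' @param mask optional logical `n_lat x n_lon` matrix of valid cells;
#'   defaults to all cells with complete data.
#' @return a `monthly_climatology` object.
#' @export
monthly_climatology <- function(grid, tmin, tmax, ptotal, rh0900, rh1500,
                                mask = NULL) {
  stopifnot(inherits(grid, "grid_definition"))
  shape <- c(grid$n_lat, grid$n_lon, 12L)
  vars <- list(tmin = tmin, tmax = tmax, ptotal = ptotal,
               rh0900 = rh0900, rh1500 = rh1500)
  vars <- lapply(vars, function(v) {
    if (is.vector(v) && length(v) == 12L) v <- array(v, dim = c(1L, 1L, 12L))
    if (!is.array(v) || !identical(dim(v), as.integer(shape))) {
      stop("each climatology variable must be an n_lat x n_lon x 12 array ",
           "matching the grid (", paste(shape, collapse = " x "), ")",
           call. = FALSE)
    }
    storage.mode(v) <- "double"
    v
  })
  complete <- Reduce(`&`, lapply(vars, function(v) {
    apply(is.finite(v), c(1, 2), all)
  }))
  if (is.null(mask)) {
    mask <- complete
  } else {
    stopifnot(is.logical(mask), identical(dim(mask), as.integer(shape[1:2])))
    mask <- mask & complete
  }

  idx <- which(rep(mask, times = 12L))
  if (any(vars$tmin[idx] > vars$tmax[idx] + 1e-9)) {
    stop("tmin > tmax in some cell-months", call. = FALSE)
  }
  if (any(vars$ptotal[idx] < 0)) {
    stop("negative monthly precipitation", call. = FALSE)
  }
  rh <- c(vars$rh0900[idx], vars$rh1500[idx])
  if (any(rh < 0 | rh > 100)) {
    stop("relative humidity outside [0, 100]", call. = FALSE)
  }
  structure(c(list(grid = grid), vars, list(mask = mask)),
            class = "monthly_climatology")
}

#' @export
print.monthly_climatology <- function(x, ...) {
  g <- x$grid
  cat("<monthly_climatology> ", g$n_lat, "x", g$n_lon, " cells @ ",
      signif(g$cell_size, 4), " deg, ", sum(x$mask), " valid\n", sep = "")
  invisible(x)
}

# Long-form data frame of valid cells: row/col/lon/lat + 12 monthly values.
clim_var_table <- function(clim, var) {
  idx <- which(clim$mask, arr.ind = TRUE)
  lon <- grid_lons(clim$grid)[idx[, 2]]
  lat <- grid_lats(clim$grid)[idx[, 1]]
  vals <- matrix(clim[[var]][cbind(rep(idx[, 1], 12L), rep(idx[, 2], 12L),
                                   rep(1:12, each = nrow(idx)))],
                 nrow = nrow(idx))
  colnames(vals) <- sprintf("m%02d", 1:12)
  cbind(data.frame(lon = lon, lat = lat), as.data.frame(vals))
}

#' Read and write monthly climatologies
#'
#' The gridded on-disk form is a directory of five wide CSV files
#' (`tmin.csv`, `tmax.csv`, `ptotal.csv`, `rh0900.csv`, `rh1500.csv`), one
#' row per valid cell with columns `lon, lat, m01 ... m12`. All five files
#' must share a single regular grid; a cell missing from any file is masked.
#' A single CSV file is read as a station table: one row per month, columns
#' `tmin, tmax, ptotal, rh0900, rh1500` (plus optional constant `lon`,
#' `lat`), yielding a one-cell climatology.
#'
#' @param path directory (gridded) or CSV file (station).
#' @param cell_size cell size in degrees used when reconstructing a grid
#'   that has only one cell in some dimension; ignored otherwise.
#' @return a [monthly_climatology].
#' @export
read_climatology <- function(path, cell_size = 1 / 6) {
  if (dir.exists(path)) {
    read_climatology_dir(path, cell_size)
  } else if (file.exists(path)) {
    read_station_csv(path, cell_size = cell_size)
  } else {
    stop("no such climatology path: ", path, call. = FALSE)
  }
}

read_climatology_dir <- function(path, cell_size) {
  files <- file.path(path, paste0(CLIM_VARS, ".csv"))
  missing_files <- !file.exists(files)
  if (any(missing_files)) {
    stop("missing climatology file(s): ",
         paste(basename(files[missing_files]), collapse = ", "), call. = FALSE)
  }
  tabs <- lapply(files, utils::read.csv)
  names(tabs) <- CLIM_VARS
  mcols <- sprintf("m%02d", 1:12)
  for (v in CLIM_VARS) {
    need <- c("lon", "lat", mcols)
    if (!all(need %in% names(tabs[[v]]))) {
      stop("climatology file ", v, ".csv lacks columns: ",
           paste(setdiff(need, names(tabs[[v]])), collapse = ", "),
           call. = FALSE)
    }
  }
  axis_of <- function(u, ascending) {
    u <- sort(unique(u), decreasing = !ascending)
    if (length(u) > 1L) {
      d <- abs(diff(u))
      if (max(d) - min(d) > 1e-6 * mean(d)) {
        stop("grid mismatch: irregular coordinate spacing", call. = FALSE)
      }
    }
    u
  }
  lons <- axis_of(unlist(lapply(tabs, `[[`, "lon")), ascending = TRUE)
  lats <- axis_of(unlist(lapply(tabs, `[[`, "lat")), ascending = FALSE)
  step <- c(if (length(lons) > 1L) diff(lons)[1], if (length(lats) > 1L) -diff(lats)[1])
  if (length(step) == 2L && abs(step[1] - step[2]) > 1e-6 * step[1]) {
    stop("grid mismatch: longitude and latitude spacing differ", call. = FALSE)
  }
  cs <- if (length(step) >= 1L) step[1] else cell_size
  grid <- grid_definition(lons[1], lats[1], cs, length(lons), length(lats))

  shape <- c(grid$n_lat, grid$n_lon, 12L)
  arrs <- lapply(tabs, function(tab) {
    a <- array(NA_real_, dim = shape)
    i <- match(round(tab$lat / cs), round(lats / cs))
    j <- match(round(tab$lon / cs), round(lons / cs))
    if (anyNA(i) || anyNA(j)) {
      stop("grid mismatch: coordinates off the common grid", call. = FALSE)
    }
    for (m in 1:12) a[cbind(i, j, m)] <- tab[[mcols[m]]]
    a
  })
  monthly_climatology(grid, arrs$tmin, arrs$tmax, arrs$ptotal,
                      arrs$rh0900, arrs$rh1500)
}

#' @rdname read_climatology
#' @param lon,lat station coordinates, used if the CSV has no `lon`/`lat`
#'   columns.
#' @export
read_station_csv <- function(path, lon = 0, lat = 0, cell_size = 1 / 6) {
  tab <- utils::read.csv(path)
  if (!all(CLIM_VARS %in% names(tab))) {
    stop("station CSV lacks columns: ",
         paste(setdiff(CLIM_VARS, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) != 12L) {
    stop("station CSV must have 12 rows (one per month); got ", nrow(tab),
         call. = FALSE)
  }
  if ("lon" %in% names(tab)) lon <- tab$lon[1]
  if ("lat" %in% names(tab)) lat <- tab$lat[1]
  grid <- grid_definition(lon, lat, cell_size, 1L, 1L)
  to_arr <- function(v) array(v, dim = c(1L, 1L, 12L))
  monthly_climatology(grid, to_arr(tab$tmin), to_arr(tab$tmax),
                      to_arr(tab$ptotal), to_arr(tab$rh0900),
                      to_arr(tab$rh1500))
}

#' @rdname read_climatology
#' @param clim a [monthly_climatology].
#' @export
write_climatology <- function(clim, path) {
  stopifnot(inherits(clim, "monthly_climatology"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (v in CLIM_VARS) {
    utils::write.csv(clim_var_table(clim, v),
                     file.path(path, paste0(v, ".csv")), row.names = FALSE)
  }
  invisible(path)
}

#' Perturb a climatology with a climate-change delta
#'
#' Applies a uniform or spatially varying scenario perturbation: temperatures
#' are shifted by `dT` (degC), precipitation is scaled by `P_scale`
#' (dimensionless, > 0), and both humidity fields are shifted by `dRH`
#' (percentage points) then clamped to [0, 100]. The mask is preserved.
#' Full replacement climatologies (e.g. downscaled GCM output read with
#' [read_climatology()]) are the alternative entry path for future climates.
#'
#' @param base a [monthly_climatology].
#' @param dT,P_scale,dRH scalars or `n_lat x n_lon` matrices.
#' @return a perturbed [monthly_climatology] on the same grid and mask.
#' @export
apply_scenario_delta <- function(base, dT = 0, P_scale = 1, dRH = 0) {
  stopifnot(inherits(base, "monthly_climatology"))
  as_field <- function(x, name) {
    if (length(x) == 1L) {
      array(x, dim = dim(base$tmin))
    } else if (is.matrix(x) && identical(dim(x), dim(base$mask))) {
      array(rep(x, 12L), dim = dim(base$tmin))
    } else {
      stop(name, " must be a scalar or an n_lat x n_lon matrix", call. = FALSE)
    }
  }
  dT <- as_field(dT, "dT")
  P_scale <- as_field(P_scale, "P_scale")
  dRH <- as_field(dRH, "dRH")
  if (any(P_scale <= 0)) stop("P_scale must be > 0 everywhere", call. = FALSE)
  clamp01 <- function(x) pmin(pmax(x, 0), 100)
  monthly_climatology(
    base$grid,
    tmin = base$tmin + dT,
    tmax = base$tmax + dT,
    ptotal = base$ptotal * P_scale,
    rh0900 = clamp01(base$rh0900 + dRH),
    rh1500 = clamp01(base$rh1500 + dRH),
    mask = base$mask
  )
}

#' Read and write occurrence points
#'
#' Occurrence points are (lon, lat) pairs, read from a two-column CSV
#' (columns `lon`, `lat`) or a GeoJSON FeatureCollection / MultiPoint of
#' point geometries.
#'
#' @param path input file (`.csv`, `.json` or `.geojson`).
#' @return a data frame with columns `lon` and `lat`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    coords <- if (identical(gj$type, "FeatureCollection")) {
      lapply(gj$features, function(f) f$geometry$coordinates)
    } else if (identical(gj$type, "MultiPoint")) {
      gj$coordinates
    } else {
      stop("unsupported GeoJSON type: ", gj$type, call. = FALSE)
    }
    data.frame(lon = vapply(coords, function(p) as.numeric(p[[1]]), 0),
               lat = vapply(coords, function(p) as.numeric(p[[2]]), 0))
  } else {
    tab <- utils::read.csv(path)
    if (!all(c("lon", "lat") %in% names(tab))) {
      stop("occurrence CSV needs columns lon, lat", call. = FALSE)
    }
    tab[, c("lon", "lat")]
  }
}

#' @rdname read_occurrences
#' @param points data frame with columns `lon`, `lat`.
#' @param format `"csv"` or `"geojson"`; default inferred from the file
#'   extension.
#' @export
write_occurrences <- function(points, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) "geojson" else "csv"
  }
  if (format == "geojson") {
    features <- lapply(seq_len(nrow(points)), function(i) {
      list(type = "Feature", properties = stats::setNames(list(), character(0)),
           geometry = list(type = "Point",
                           coordinates = c(points$lon[i], points$lat[i])))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(points[, c("lon", "lat")], path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write single-band rasters as ESRI ASCII grid
#'
#' Plain-text raster interchange for EI, class and stress-change layers
#' (readable by QGIS/ArcGIS/GDAL). Values are written row-major from the
#' northern row down, matching the package's internal matrix orientation.
#'
#' @param mat numeric `n_lat x n_lon` matrix (NA = nodata).
#' @param grid a [grid_definition].
#' @param path output file.
#' @param nodata nodata sentinel written for NA cells.
#' @param digits significant digits to print.
#' @return `read_asc()` returns `list(values = matrix, grid = grid_definition)`.
#' @export
write_asc <- function(mat, grid, path, nodata = -9999, digits = 10) {
  stopifnot(is.matrix(mat), identical(dim(mat),
                                      c(grid$n_lat, grid$n_lon)))
  hdr <- c(
    sprintf("ncols %d", grid$n_lon),
    sprintf("nrows %d", grid$n_lat),
    sprintf("xllcorner %.10g", grid$lon_origin - grid$cell_size / 2),
    sprintf("yllcorner %.10g", grid$lat_origin -
              (grid$n_lat - 0.5) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(mat, 1L, function(row) {
    row[!is.finite(row)] <- nodata
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  mat <- do.call(rbind, vals)
  mat[mat == hdr$nodata_value] <- NA_real_
  grid <- grid_definition(
    lon_origin = hdr$xllcorner + hdr$cellsize / 2,
    lat_origin = hdr$yllcorner + (hdr$nrows - 0.5) * hdr$cellsize,
    cell_size = hdr$cellsize, n_lon = hdr$ncols, n_lat = hdr$nrows
  )
  list(values = mat, grid = grid)
}
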