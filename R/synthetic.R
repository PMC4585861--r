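# Seeded generators for tropical-like monthly climatologies, scenario
# testbeds, fuzzing inputs and occurrence samples. All randomness in the
# package lives here; the model core is deterministic.

#' Specify a synthetic monthly climatology
#'
#' Describes an idealised tropical-to-temperate climate field: maximum /
#' minimum temperature decline linearly with absolute latitude
#' (`lapse` degC per degree), the seasonal cycle is sinusoidal with
#' amplitude `t_amp + t_amp_per_deg * |lat|` (peaking in July north of the
#' equator, January south of it), precipitation follows a 12-month
#' von-Mises-shaped monsoon profile with concentration `monsoon_kappa`
#' normalised to `annual_rain` (mm), and humidity is constant at the stated
#' morning/afternoon baselines. Gaussian noise with the given per-variable
#' standard deviations is added when `noise_sd > 0`; `seed` fixes all
#' randomness.
#'
#' @param n_lon,n_lat grid shape.
#' @param lon_origin,lat_origin north-west cell-center, degrees.
#' @param cell_size cell edge, degrees (default 0.5 keeps testbeds fast;
#'   10-arcmin grids are supported by setting `1/6`).
#' @param t_max_eq,t_min_eq equatorial baselines, degC (defaults 31 / 22,
#'   the ideal maxima/minima for a lowland humid-tropics crop).
#' @param lapse temperature decline per degree of absolute latitude.
#' @param t_amp,t_amp_per_deg seasonal semi-amplitude, degC, and its growth
#'   per degree of latitude.
#' @param annual_rain annual precipitation, mm (default 2250, the middle of
#'   the ideal 2000-2500 mm band).
#' @param monsoon_kappa concentration of the monsoon profile (0 = uniform).
#' @param monsoon_peak_month month of peak rain (antiphase in the south).
#' @param rh0900_base,rh1500_base humidity baselines, percent.
#' @param noise_sd named list of per-variable noise standard deviations
#'   (names among `tmin`, `tmax`, `ptotal`, `rh`); `0` = deterministic.
#' @param seed integer seed fixing all randomness.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_lon = 36L, n_lat = 36L,
                           lon_origin = 95, lat_origin = 8.75,
                           cell_size = 0.5,
                           t_max_eq = 31, t_min_eq = 22,
                           lapse = 0.35,
                           t_amp = 0.5, t_amp_per_deg = 0.28,
                           annual_rain = 2250,
                           monsoon_kappa = 0.3, monsoon_peak_month = 12,
                           rh0900_base = 90, rh1500_base = 70,
                           noise_sd = list(), seed = 1L) {
  stopifnot(annual_rain >= 0, t_amp >= 0, t_amp_per_deg >= 0,
            monsoon_kappa >= 0, lapse >= 0)
  sd_def <- list(tmin = 0, tmax = 0, ptotal = 0, rh = 0)
  unknown <- setdiff(names(noise_sd), names(sd_def))
  if (length(unknown)) {
    stop("unknown noise_sd name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sd_def[names(noise_sd)] <- noise_sd
  structure(list(n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
                 lon_origin = lon_origin, lat_origin = lat_origin,
                 cell_size = cell_size,
                 t_max_eq = t_max_eq, t_min_eq = t_min_eq, lapse = lapse,
                 t_amp = t_amp, t_amp_per_deg = t_amp_per_deg,
                 annual_rain = annual_rain,
                 monsoon_kappa = monsoon_kappa,
                 monsoon_peak_month = monsoon_peak_month,
                 rh0900_base = rh0900_base, rh1500_base = rh1500_base,
                 noise_sd = sd_def, seed = as.integer(seed)),
            class = "synthetic_spec")
}

monsoon_profile <- function(kappa, peak_month) {
  w <- exp(kappa * cos(2 * pi * ((1:12) - peak_month) / 12))
  w / sum(w)
}

#' Generate a synthetic monthly climatology
#'
#' Deterministic given the spec's seed; satisfies all
#' [monthly_climatology()] invariants by construction (noise is clipped so
#' that `tmin < tmax`, precipitation stays non-negative by renormalisation,
#' humidity is clamped to [0, 100]).
#'
#' @param spec a [synthetic_spec].
#' @return a [monthly_climatology].
#' @export
make_climatology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- grid_definition(spec$lon_origin, spec$lat_origin, spec$cell_size,
                          spec$n_lon, spec$n_lat)
  lats <- grid_lats(grid)
  nl <- grid$n_lat; nn <- grid$n_lon
  shape <- c(nl, nn, 12L)

  lat_arr <- array(rep(lats, times = nn * 12L), dim = shape)
  # seasonal phase: peak July in the north, January in the south
  month_arr <- array(rep(1:12, each = nl * nn), dim = shape)
  season <- cos(2 * pi * (month_arr - 7) / 12)
  season <- season * sign(lat_arr + 1e-12)
  amp <- spec$t_amp + spec$t_amp_per_deg * abs(lat_arr)

  tmax <- spec$t_max_eq - spec$lapse * abs(lat_arr) + amp * season
  tmin <- spec$t_min_eq - spec$lapse * abs(lat_arr) + amp * season

  prof <- monsoon_profile(spec$monsoon_kappa, spec$monsoon_peak_month)
  prof_s <- monsoon_profile(spec$monsoon_kappa,
                            ((spec$monsoon_peak_month + 5) %% 12) + 1)
  ptotal <- array(0, dim = shape)
  for (m in 1:12) {
    ptotal[, , m] <- spec$annual_rain *
      ifelse(lats >= 0, prof[m], prof_s[m])
  }

  rh0900 <- array(spec$rh0900_base, dim = shape)
  rh1500 <- array(spec$rh1500_base, dim = shape)

  sd <- spec$noise_sd
  if (any(unlist(sd) > 0)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    if (sd$tmax > 0) tmax <- tmax + stats::rnorm(length(tmax), 0, sd$tmax)
    if (sd$tmin > 0) tmin <- tmin + stats::rnorm(length(tmin), 0, sd$tmin)
    tmin <- pmin(tmin, tmax - 0.1)
    if (sd$ptotal > 0) {
      ptotal <- pmax(ptotal + stats::rnorm(length(ptotal), 0, sd$ptotal), 0)
      # renormalise each cell back to the spec'd annual total
      ann <- apply(ptotal, c(1, 2), sum)
      ann[ann == 0] <- 1
      for (m in 1:12) {
        ptotal[, , m] <- ptotal[, , m] * spec$annual_rain / ann
      }
    }
    if (sd$rh > 0) {
      rh0900 <- pmin(pmax(rh0900 + stats::rnorm(length(rh0900), 0, sd$rh), 0), 100)
      rh1500 <- pmin(pmax(rh1500 + stats::rnorm(length(rh1500), 0, sd$rh), 0), 100)
    }
  }
  tmin <- pmin(tmin, tmax - 0.1)

  monthly_climatology(grid, tmin, tmax, ptotal, rh0900, rh1500)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' An "ideal tropical" single-cell climatology
#'
#' The reference cell used to calibrate the evapotranspiration coefficient:
#' mean temperature 26 degC year-round (`t_min` 22 / `t_max` 30), relative
#' humidity 80 percent morning and afternoon, and 2250 mm annual rain spread
#' evenly over the months by day length.
#'
#' @param lon,lat cell-center coordinates.
#' @return a one-cell [monthly_climatology].
#' @export
ideal_tropical_cell <- function(lon = 101.75, lat = 2.75) {
  grid <- grid_definition(lon, lat, 1 / 6, 1L, 1L)
  arr <- function(v) array(v, dim = c(1L, 1L, 12L))
  monthly_climatology(
    grid,
    tmin = arr(22), tmax = arr(30),
    ptotal = arr(2250 * MONTH_DAYS / YEAR_DAYS),
    rh0900 = arr(80), rh1500 = arr(80)
  )
}

#' A latitudinal gradient testbed with a known class pattern
#'
#' Builds a deterministic strip grid from the equator to 35 degrees latitude
#' whose suitability under the bundled oil-palm preset declines monotonically
#' poleward — highly suitable at the equator through suitable and marginal to
#' unsuitable where mean temperatures sit below the development threshold
#' year-round — driven by the temperature response, cold stress and the
#' degree-day gate. Rainfall in the strip tracks the local annual
#' evapotranspiration demand so soil moisture stays near the optimum and the
#' gradient stays thermally limited; one easternmost "arid" column gets only
#' 200 mm per year and is dry-stress limited instead.
#'
#' @param n_lat rows (default 36, 1-degree cells from 0.5 to 35.5 S).
#' @param n_lon columns (default 4: three humid columns plus the arid one).
#' @param p parameter set used to scale rainfall to demand.
#' @return list with `clim` (a [monthly_climatology]), `arid_col` (column
#'   index of the arid strip), and `expected` — the expected ordered class
#'   sequence constraint (character vector of length `n_lat` of class labels
#'   for the humid columns, `NA` where unpinned).
#' @export
make_gradient_testbed <- function(n_lat = 36L, n_lon = 4L,
                                  p = oil_palm_params()) {
  grid <- grid_definition(lon_origin = 110, lat_origin = -0.5, cell_size = 1,
                          n_lon = n_lon, n_lat = n_lat)
  lats <- grid_lats(grid)
  nl <- grid$n_lat; nn <- grid$n_lon
  shape <- c(nl, nn, 12L)

  # Mean temperature declines at 0.55 degC per degree of latitude; the
  # seasonal semi-amplitude peaks mid-strip (continental interior) and is
  # small at both the equatorial and the poleward (maritime) ends, so cold
  # stress builds gradually with latitude while the far end is cold
  # year-round.
  lapse <- 0.55
  amp_max <- 14
  lat_arr <- array(rep(abs(lats), times = nn * 12L), dim = shape)
  month_arr <- array(rep(1:12, each = nl * nn), dim = shape)
  # southern hemisphere: summer peaks in January
  season <- cos(2 * pi * (month_arr - 1) / 12)
  amp <- amp_max * sin(pi * lat_arr / 36)
  tmax <- 31 - lapse * lat_arr + amp * season
  tmin <- 22 - lapse * lat_arr + amp * season
  rh <- 80

  # monthly rain proportional to the month's ET demand (temperature times
  # saturation deficit), scaled to annual demand; keeps sm near SM1
  tavg <- (tmax + tmin) / 2
  demand <- pmax(tavg, 0) * (1 - rh / 100) * p$k_et *
    array(rep(MONTH_DAYS, each = nl * nn), dim = shape)
  ptotal <- demand
  arid_col <- nn
  ann_arid <- apply(ptotal[, arid_col, , drop = FALSE], 1L, sum)
  for (m in 1:12) {
    ptotal[, arid_col, m] <- ptotal[, arid_col, m] * 200 /
      pmax(ann_arid, 1e-9)
  }

  clim <- monthly_climatology(grid, tmin, tmax, ptotal,
                              array(rh, shape), array(rh, shape))

  expected <- rep(NA_character_, nl)
  expected[abs(lats) <= 5] <- "highly_suitable"
  expected[abs(lats) >= 8] <- "unsuitable"
  list(clim = clim, arid_col = arid_col, expected = expected)
}

#' Randomized weekly climate series for fuzzing
#'
#' Draws `n` independent weekly climate series spanning extreme conditions —
#' temperatures from polar to hyper-arid-hot, rainfall from none to
#' perhumid, humidity over the full range — used to fuzz the per-cell
#' pipeline (e.g. verifying EI stays within [0, 100]).
#'
#' @param n number of series (rows).
#' @param seed integer seed.
#' @return a [weekly_climate] with `n` rows.
#' @export
random_weekly_climate <- function(n, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  base_t <- stats::runif(n, -30, 40)
  amp <- stats::runif(n, 0, 20)
  phase <- stats::runif(n, 0, 2 * pi)
  wk_frac <- (1:52) / 52
  t_avg <- outer(base_t, rep(1, 52)) +
    outer(amp, rep(1, 52)) * cos(outer(phase, 2 * pi * wk_frac, `+`)) +
    matrix(stats::rnorm(n * 52, 0, 1.5), n, 52)
  spread <- matrix(stats::runif(n * 52, 1, 12), n, 52)
  t_min <- t_avg - spread / 2
  t_max <- t_avg + spread / 2
  annual_rain <- stats::runif(n, 0, 6000)
  conc <- stats::runif(n, 0, 3)
  rain_w <- exp(outer(conc, rep(1, 52)) *
                  cos(outer(phase, 2 * pi * wk_frac, `+`)))
  rain_w <- rain_w / rowSums(rain_w) * annual_rain
  rh <- matrix(stats::runif(n * 52, 5, 100), n, 52)
  weekly_climate(t_min, t_max, rain_w, rh)
}

#' Sample synthetic occurrence points from a suitability class
#'
#' Draws `n` points uniformly (with replacement) over the cell centers of
#' the cells in the requested class; deterministic given `seed`. Supports
#' the occurrence-overlay validation pattern: points sampled from highly
#' suitable cells must overlay as 100 percent highly suitable.
#'
#' @param result an `annual_result` from [run_grid()].
#' @param n number of points.
#' @param class_filter class label (default `"highly_suitable"`).
#' @param seed integer seed.
#' @return data frame with columns `lon`, `lat`.
#' @export
sample_occurrences <- function(result, n, class_filter = "highly_suitable",
                               seed = 1L) {
  stopifnot(inherits(result, "annual_result"))
  code <- match(class_filter, suitability_levels()) - 1L
  if (is.na(code)) stop("unknown class: ", class_filter, call. = FALSE)
  cells <- which(result$mask & result$class_code == code, arr.ind = TRUE)
  if (nrow(cells) == 0L) {
    stop("no cells in class ", class_filter, call. = FALSE)
  }
  if (n == 0L) return(data.frame(lon = numeric(0), lat = numeric(0)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n, replace = TRUE), , drop = FALSE]
  data.frame(lon = grid_lons(result$grid)[pick[, 2]],
             lat = grid_lats(result$grid)[pick[, 1]])
}
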