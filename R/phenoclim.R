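# Monthly -> weekly conversion and the single-bucket soil moisture balance.
#
# Year structure: 365.25 days split into 52 weeks (weeks 1-51 of 7 days,
# week 52 of 8.25 days) and 12 calendar months (February carries the leap
# quarter-day). Weeks and months both tile [0, 365.25] exactly, so
# day-overlap apportionment conserves annual precipitation totals to
# rounding error.

MONTH_DAYS <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
YEAR_DAYS <- 365.25

#' Week lengths of the model year
#'
#' @return numeric vector of 52 week lengths in days (51 x 7 plus one 8.25).
#' @export
week_lengths <- function() c(rep(7, 51), YEAR_DAYS - 51 * 7)

month_bounds <- function() c(0, cumsum(MONTH_DAYS))
month_midpoints <- function() month_bounds()[1:12] + MONTH_DAYS / 2
week_bounds <- function() c(0, cumsum(week_lengths()))
week_midpoints <- function() {
  b <- week_bounds()
  (b[1:52] + b[2:53]) / 2
}

# 12 x 52 weights interpolating month-midpoint values to week midpoints,
# linear and periodic in the year. W_weekly = M_monthly %*% interp.
monthly_to_weekly_interp <- function() {
  mm <- month_midpoints()
  wm <- week_midpoints()
  A <- matrix(0, 12L, 52L)
  for (w in 1:52) {
    d <- wm[w]
    if (d < mm[1]) {
      lo <- 12L; hi <- 1L
      frac <- (d - (mm[12] - YEAR_DAYS)) / (mm[1] - (mm[12] - YEAR_DAYS))
    } else if (d >= mm[12]) {
      lo <- 12L; hi <- 1L
      frac <- (d - mm[12]) / (mm[1] + YEAR_DAYS - mm[12])
    } else {
      lo <- max(which(mm <= d))
      hi <- lo + 1L
      frac <- (d - mm[lo]) / (mm[hi] - mm[lo])
    }
    A[lo, w] <- A[lo, w] + (1 - frac)
    A[hi, w] <- A[hi, w] + frac
  }
  A
}

# 12 x 52 apportionment of monthly totals to weeks by day overlap; each row
# sums to 1 so annual totals are conserved.
monthly_to_weekly_overlap <- function() {
  mb <- month_bounds()
  wb <- week_bounds()
  O <- matrix(0, 12L, 52L)
  for (m in 1:12) {
    for (w in 1:52) {
      ov <- min(mb[m + 1], wb[w + 1]) - max(mb[m], wb[w])
      if (ov > 0) O[m, w] <- ov / MONTH_DAYS[m]
    }
  }
  O
}

#' Construct a weekly climate series
#'
#' Container for 52-week series of minimum, maximum and mean temperature
#' (degC), precipitation (mm per week) and mean relative humidity (percent),
#' for one or more cells (one row per cell). Usually produced by
#' [to_weekly()]; the constructor is exported so weekly series can also be
#' built directly (e.g. fuzzing the index kernels).
#'
#' @param t_min,t_max,precip,rh_mean numeric `n_cells x 52` matrices (or
#'   length-52 vectors for one cell).
#' @param t_avg optional; defaults to `(t_min + t_max) / 2`.
#' @param grid,mask optional provenance (a [grid_definition] and the logical
#'   valid-cell matrix whose `which(mask)` ordering matches rows).
#' @return a `weekly_climate` object.
#' @export
weekly_climate <- function(t_min, t_max, precip, rh_mean, t_avg = NULL,
                           grid = NULL, mask = NULL) {
  as_m <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    storage.mode(x) <- "double"
    x
  }
  t_min <- as_m(t_min); t_max <- as_m(t_max)
  precip <- as_m(precip); rh_mean <- as_m(rh_mean)
  if (is.null(t_avg)) t_avg <- (t_min + t_max) / 2 else t_avg <- as_m(t_avg)
  dims <- lapply(list(t_min, t_max, t_avg, precip, rh_mean), dim)
  if (length(unique(dims)) != 1L || dims[[1]][2] != 52L) {
    stop("weekly series must be n_cells x 52 and share dimensions",
         call. = FALSE)
  }
  if (any(t_min > t_max + 1e-9)) stop("t_min > t_max in weekly series", call. = FALSE)
  if (any(precip < 0)) stop("negative weekly precipitation", call. = FALSE)
  if (any(rh_mean < 0 | rh_mean > 100)) {
    stop("weekly rh_mean outside [0, 100]", call. = FALSE)
  }
  structure(list(t_min = t_min, t_max = t_max, t_avg = t_avg,
                 precip = precip, rh_mean = rh_mean,
                 days = week_lengths(), grid = grid, mask = mask),
            class = "weekly_climate")
}

#' Interpolate a monthly climatology to 52 weeks
#'
#' Temperatures and humidity are interpolated linearly and periodically
#' between month midpoints and sampled at week midpoints. Monthly
#' precipitation totals are apportioned to weeks proportionally to the
#' day overlap of week and month, which conserves the annual total exactly.
#' Weekly mean temperature is `(t_min + t_max) / 2` and weekly humidity is
#' the mean of the 09:00 and 15:00 fields.
#'
#' @param clim a [monthly_climatology].
#' @return a [weekly_climate] with one row per valid (masked-in) cell, in
#'   `which(clim$mask)` order.
#' @export
to_weekly <- function(clim) {
  stopifnot(inherits(clim, "monthly_climatology"))
  idx <- which(clim$mask)
  n <- length(idx)
  if (n == 0L) stop("climatology has no valid cells", call. = FALSE)
  monthly_mat <- function(v) {
    m <- matrix(clim[[v]], ncol = 12L)[idx, , drop = FALSE]
    m
  }
  A <- monthly_to_weekly_interp()
  O <- monthly_to_weekly_overlap()
  t_min <- monthly_mat("tmin") %*% A
  t_max <- monthly_mat("tmax") %*% A
  rh <- ((monthly_mat("rh0900") + monthly_mat("rh1500")) / 2) %*% A
  # interpolation is convex so bounds are preserved, but guard rounding
  rh <- pmin(pmax(rh, 0), 100)
  precip <- monthly_mat("ptotal") %*% O
  weekly_climate(t_min, t_max, precip, rh, grid = clim$grid, mask = clim$mask)
}

K_ET_DEFAULT <- 2250 / (365.25 * 26 * 0.2)

#' Weekly single-bucket soil moisture balance
#'
#' Runs the water balance
#' `sm_w = clamp(sm_(w-1) + (precip_w - pet_w) / soil_capacity, 0, sm_cap)`
#' with a bulk temperature-humidity potential evapotranspiration
#' `pet_w = k_et * max(0, t_avg_w) * (1 - rh_mean_w / 100) * days_w` (mm per
#' week, `days_w` the week length in days). Soil moisture is a fraction of
#' `soil_capacity`; values above 1 denote surplus beyond nominal capacity,
#' capped at `sm_cap`. The annual cycle is iterated from `init` until the
#' series is periodic (max weekly change between cycles below `tol`) or
#' `max_cycles` is reached; the converged year is returned.
#'
#' @param wk a [weekly_climate].
#' @param p a [climex_params] (uses `soil_capacity` and `k_et`).
#' @param init spin-up initial soil moisture fraction (default `p$SM1`).
#' @param sm_cap hard cap on the soil moisture fraction; must exceed `SM3`
#'   so wet stress can accumulate above `SMWS`.
#' @param tol,max_cycles spin-up convergence tolerance and cycle budget.
#' @return a `soil_moisture_series`: list with `sm` (`n_cells x 52` matrix),
#'   `cycles` (per-cell cycles to convergence), `converged` (logical per
#'   cell), and `sm_cap`.
#' @export
soil_moisture_balance <- function(wk, p, init = p$SM1, sm_cap = 2.5,
                                  tol = 1e-6, max_cycles = 100L) {
  stopifnot(inherits(wk, "weekly_climate"), inherits(p, "climex_params"))
  if (sm_cap <= p$SM3) {
    warning("sm_cap <= SM3: wet stress can never accumulate")
  }
  pet <- sweep(p$k_et * pmax(wk$t_avg, 0) * (1 - wk$rh_mean / 100),
               2L, wk$days, `*`)
  delta <- (wk$precip - pet) / p$soil_capacity
  n <- nrow(delta)
  sm <- matrix(0, n, 52L)
  prev <- matrix(Inf, n, 52L)
  s <- rep(as.numeric(init), length.out = n)
  cycles <- rep(NA_integer_, n)
  for (cyc in seq_len(max_cycles)) {
    for (w in 1:52) {
      s <- pmin(sm_cap, pmax(0, s + delta[, w]))
      sm[, w] <- s
    }
    d <- abs(sm - prev)
    changed <- d[cbind(seq_len(n), max.col(d, ties.method = "first"))]
    newly <- is.na(cycles) & changed < tol
    cycles[newly] <- cyc
    if (!anyNA(cycles)) break
    prev[] <- sm
  }
  converged <- !is.na(cycles)
  cycles[!converged] <- max_cycles
  structure(list(sm = sm, cycles = cycles, converged = converged,
                 sm_cap = sm_cap),
            class = "soil_moisture_series")
}
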