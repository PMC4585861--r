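# Independent literal-loop reference implementations used as oracles.
# These deliberately mirror the written definitions week by week in plain
# scalar code, sharing nothing with the package's vectorized kernels.

oracle_stresses <- function(t_min, t_max, t_avg, sm, dd, p) {
  cs1 <- 0; cs2 <- 0; hs <- 0; ds <- 0; ws <- 0
  for (w in 1:52) {
    if (t_min[w] < p$TTCS) cs1 <- cs1 + (p$TTCS - t_min[w])
    if (dd[w] < p$DTCS) cs2 <- cs2 + (p$DTCS - dd[w])
    if (t_max[w] > p$TTHS) hs <- hs + (t_max[w] - p$TTHS)
    if (sm[w] < p$SMDS) ds <- ds + (p$SMDS - sm[w])
    if (sm[w] > p$SMWS) ws <- ws + (sm[w] - p$SMWS)
  }
  list(
    CS = min(100, max(min(100, 100 * abs(p$THCS) * cs1),
                      min(100, 100 * abs(p$DHCS) * cs2))),
    HS = min(100, 100 * p$THHS * hs),
    DS = min(100, 100 * abs(p$HDS) * ds),
    WS = min(100, 100 * p$HWS * ws)
  )
}

oracle_growth <- function(t_avg, sm, p) {
  tot <- 0
  for (w in 1:52) {
    ti <- if (t_avg[w] <= p$DV0 || t_avg[w] >= p$DV3) 0
      else if (t_avg[w] < p$DV1) (t_avg[w] - p$DV0) / (p$DV1 - p$DV0)
      else if (t_avg[w] <= p$DV2) 1
      else (p$DV3 - t_avg[w]) / (p$DV3 - p$DV2)
    mi <- if (sm[w] <= p$SM0 || sm[w] >= p$SM3) 0
      else if (sm[w] < p$SM1) (sm[w] - p$SM0) / (p$SM1 - p$SM0)
      else if (sm[w] <= p$SM2) 1
      else (p$SM3 - sm[w]) / (p$SM3 - p$SM2)
    tot <- tot + ti * mi
  }
  100 * tot / 52
}

oracle_soil_balance <- function(precip, t_avg, rh, p, init, sm_cap = 2.5,
                                cycles = 100) {
  days <- c(rep(7, 51), 8.25)
  sm <- numeric(52)
  s <- init
  for (cyc in 1:cycles) {
    prev <- sm
    for (w in 1:52) {
      pet <- p$k_et * max(0, t_avg[w]) * (1 - rh[w] / 100) * days[w]
      s <- s + (precip[w] - pet) / p$soil_capacity
      s <- min(sm_cap, max(0, s))
      sm[w] <- s
    }
    if (cyc > 1 && max(abs(sm - prev)) < 1e-9) break
  }
  sm
}

# Dense daily interpolation oracle for the monthly -> weekly conversion:
# sample the periodic linear interpolant at 0.01-day resolution and average
# nothing — read it off at the week midpoint.
oracle_weekly_temps <- function(monthly) {
  month_days <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mids <- cumsum(c(0, month_days))[1:12] + month_days / 2
  xs <- c(mids[12] - 365.25, mids, mids[1] + 365.25)
  ys <- c(monthly[12], monthly, monthly[1])
  wb <- c(0, cumsum(c(rep(7, 51), 8.25)))
  wm <- (wb[1:52] + wb[2:53]) / 2
  stats::approx(xs, ys, xout = wm)$y
}

# A small deterministic monthly climatology grid for I/O and mapping tests.
toy_climatology <- function(n_lat = 3L, n_lon = 4L, mask_out = NULL) {
  grid <- grid_definition(100, 5, 1, n_lon, n_lat)
  shape <- c(n_lat, n_lon, 12L)
  base <- array(rep(1:12, each = n_lat * n_lon), dim = shape)
  tmin <- 20 + 0.1 * base
  tmax <- 29 + 0.2 * base
  ptotal <- array(150, shape) + 2 * base
  rh09 <- array(88, shape)
  rh15 <- array(72, shape)
  mask <- matrix(TRUE, n_lat, n_lon)
  if (!is.null(mask_out)) mask[mask_out] <- FALSE
  monthly_climatology(grid, tmin, tmax, ptotal, rh09, rh15, mask = mask)
}

# Constant-conditions single-cell weekly series.
constant_weekly <- function(t_min = 22, t_max = 30, precip = 43.125,
                            rh = 80) {
  weekly_climate(rep(t_min, 52), rep(t_max, 52), rep(precip, 52),
                 rep(rh, 52))
}
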