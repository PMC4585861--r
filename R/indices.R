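# The model core: weekly growth indices, annual stress accumulators, the
# degree-day establishment gate, and the annual Ecoclimatic Index.
#
# All stress accumulators are linear in the weekly threshold exceedance,
# additive over weeks, and clamped at 100; rates keep their printed per-week
# semantics and enter through their magnitudes.

trapezoid <- function(x, lo, opt_lo, opt_hi, hi) {
  out <- numeric(length(x))
  up <- x > lo & x < opt_lo
  out[up] <- (x[up] - lo) / (opt_lo - lo)
  out[x >= opt_lo & x <= opt_hi] <- 1
  down <- x > opt_hi & x < hi
  out[down] <- (hi - x[down]) / (hi - opt_hi)
  dim(out) <- dim(x)
  out
}

#' Weekly growth indices
#'
#' `temperature_index()` is the trapezoidal weekly temperature response: 0 at
#' or below `DV0` and at or above `DV3`, 1 on the optimal plateau
#' `[DV1, DV2]`, linear in between. `moisture_index()` is the analogous
#' trapezoid on soil moisture over `[SM0, SM1, SM2, SM3]`. The weekly growth
#' index is their product.
#'
#' @param t_avg weekly mean temperature(s), degC.
#' @param sm weekly soil moisture fraction(s).
#' @param p a [climex_params].
#' @return values in [0, 1], same shape as the input.
#' @export
temperature_index <- function(t_avg, p) {
  trapezoid(t_avg, p$DV0, p$DV1, p$DV2, p$DV3)
}

#' @rdname temperature_index
#' @export
moisture_index <- function(sm, p) {
  trapezoid(sm, p$SM0, p$SM1, p$SM2, p$SM3)
}

#' Weekly degree-days above the development threshold
#'
#' `dd_w = max(0, t_avg_w - DV0) * days_w` with `days_w` the week length in
#' days; the annual sum gates establishment against `PDD`.
#'
#' @param t_avg `n_cells x 52` matrix (or length-52 vector) of weekly mean
#'   temperatures, degC.
#' @inheritParams temperature_index
#' @return matrix of weekly degree-days (degC days).
#' @export
degree_days <- function(t_avg, p) {
  if (is.null(dim(t_avg))) t_avg <- matrix(t_avg, nrow = 1L)
  sweep(pmax(t_avg - p$DV0, 0), 2L, week_lengths(), `*`)
}

#' Annual growth index
#'
#' The annual growth index is the year-mean weekly growth index scaled to
#' 0-100: `GIA = 100 * sum(GI_w) / 52`.
#'
#' @param gi `n_cells x 52` matrix (or length-52 vector) of weekly growth
#'   indices in [0, 1].
#' @return numeric vector, 0-100.
#' @export
annual_growth_index <- function(gi) {
  if (is.null(dim(gi))) gi <- matrix(gi, nrow = 1L)
  stopifnot(ncol(gi) == 52L)
  100 * rowSums(gi) / 52
}

row_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x

#' Annual stress accumulators
#'
#' Each stress is the annual sum of weekly exceedances beyond its threshold,
#' scaled by the magnitude of its weekly accumulation rate and by 100, and
#' clamped to [0, 100]:
#' * cold stress combines two mechanisms by maximum — weekly minimum
#'   temperature below `TTCS` at rate `|THCS|`, and weekly degree-days below
#'   `DTCS` at rate `|DHCS|` (both mechanisms bound the same process, so
#'   summing would double-count);
#' * heat stress accumulates weekly maximum temperature above `TTHS` at rate
#'   `THHS`;
#' * dry stress accumulates soil moisture below `SMDS` at rate `|HDS|`;
#' * wet stress accumulates soil moisture above `SMWS` at rate `HWS`.
#'
#' @param wk a [weekly_climate].
#' @param dd `n_cells x 52` weekly degree-days from [degree_days()].
#' @param sm a `soil_moisture_series` from [soil_moisture_balance()], or an
#'   `n_cells x 52` soil moisture matrix.
#' @param p a [climex_params].
#' @return numeric vector of stress values, 0-100.
#' @export
cold_stress <- function(wk, dd, p) {
  cs1 <- 100 * abs(p$THCS) * rowSums(pmax(p$TTCS - wk$t_min, 0))
  cs2 <- 100 * abs(p$DHCS) * rowSums(pmax(p$DTCS - row_mat(dd), 0))
  pmin(100, pmax(pmin(100, cs1), pmin(100, cs2)))
}

#' @rdname cold_stress
#' @export
heat_stress <- function(wk, p) {
  pmin(100, 100 * p$THHS * rowSums(pmax(wk$t_max - p$TTHS, 0)))
}

sm_matrix <- function(sm) {
  if (inherits(sm, "soil_moisture_series")) sm$sm else row_mat(sm)
}

#' @rdname cold_stress
#' @export
dry_stress <- function(sm, p) {
  pmin(100, 100 * abs(p$HDS) * rowSums(pmax(p$SMDS - sm_matrix(sm), 0)))
}

#' @rdname cold_stress
#' @export
wet_stress <- function(sm, p) {
  pmin(100, 100 * p$HWS * rowSums(pmax(sm_matrix(sm) - p$SMWS, 0)))
}

#' Combine growth and stress into the Ecoclimatic Index
#'
#' `EI = GIA * (1 - CS/100) * (1 - HS/100) * (1 - DS/100) * (1 - WS/100)`,
#' set to 0 wherever the annual degree-day sum falls short of `PDD` (hard
#' establishment gate), then clamped to [0, 100].
#'
#' @param gia annual growth index, 0-100.
#' @param cs,hs,ds,ws annual stresses, 0-100.
#' @param annual_dd annual degree-day sum above `DV0`.
#' @param p a [climex_params].
#' @return EI values in [0, 100].
#' @export
ecoclimatic_index <- function(gia, cs, hs, ds, ws, annual_dd, p) {
  ei <- gia * (1 - cs / 100) * (1 - hs / 100) * (1 - ds / 100) * (1 - ws / 100)
  ei[annual_dd < p$PDD] <- 0
  pmin(100, pmax(0, ei))
}

#' Run the full per-cell pipeline from weekly series
#'
#' Soil moisture balance, weekly indices, stress accumulators, degree-day
#' gate and EI for every row (cell) of a weekly climate.
#'
#' @param wk a [weekly_climate].
#' @param p a [climex_params].
#' @param ... passed to [soil_moisture_balance()] (e.g. `sm_cap`, `init`).
#' @return a data frame with one row per cell: `GIA`, `CS`, `HS`, `DS`, `WS`,
#'   `annual_dd`, `EI`, `class` (ordered factor), `sm_cycles`,
#'   `sm_converged`.
#' @export
run_weekly <- function(wk, p, ...) {
  stopifnot(inherits(wk, "weekly_climate"), inherits(p, "climex_params"))
  sms <- soil_moisture_balance(wk, p, ...)
  ti <- temperature_index(wk$t_avg, p)
  mi <- moisture_index(sms$sm, p)
  gi <- ti * mi
  dd <- degree_days(wk$t_avg, p)
  gia <- annual_growth_index(gi)
  cs <- cold_stress(wk, dd, p)
  hs <- heat_stress(wk, p)
  ds <- dry_stress(sms, p)
  ws <- wet_stress(sms, p)
  annual_dd <- rowSums(dd)
  ei <- ecoclimatic_index(gia, cs, hs, ds, ws, annual_dd, p)
  data.frame(GIA = gia, CS = cs, HS = hs, DS = ds, WS = ws,
             annual_dd = annual_dd, EI = ei, class = classify_ei(ei),
             sm_cycles = sms$cycles, sm_converged = sms$converged)
}

#' Run the model over a climatology
#'
#' `run_grid()` composes monthly-to-weekly interpolation, the soil moisture
#' balance, the index kernels and classification over every valid cell of a
#' gridded climatology; masked cells propagate as `NA`. `run_cell()` is the
#' single-cell convenience (a one-cell climatology or a one-row result).
#'
#' @param clim a [monthly_climatology].
#' @param p a [climex_params].
#' @param ... passed to [soil_moisture_balance()].
#' @return `run_grid()` returns an `annual_result`: list with the
#'   [grid_definition] `grid`, logical `mask`, matrices `EI`, `GIA`, `CS`,
#'   `HS`, `DS`, `WS`, `annual_dd` (`NA` off-mask) and integer `class_code`
#'   matrix (0 unsuitable ... 3 highly suitable). `run_cell()` returns the
#'   one-row data frame of [run_weekly()].
#' @export
run_grid <- function(clim, p, ...) {
  stopifnot(inherits(clim, "monthly_climatology"))
  wk <- to_weekly(clim)
  res <- run_weekly(wk, p, ...)
  shape <- dim(clim$mask)
  lift <- function(v) {
    m <- matrix(NA_real_, shape[1], shape[2])
    m[which(clim$mask)] <- v
    m
  }
  cls <- matrix(NA_integer_, shape[1], shape[2])
  cls[which(clim$mask)] <- as.integer(res$class) - 1L
  structure(list(grid = clim$grid, mask = clim$mask,
                 EI = lift(res$EI), GIA = lift(res$GIA),
                 CS = lift(res$CS), HS = lift(res$HS),
                 DS = lift(res$DS), WS = lift(res$WS),
                 annual_dd = lift(res$annual_dd),
                 class_code = cls),
            class = "annual_result")
}

#' @rdname run_grid
#' @export
run_cell <- function(clim, p, ...) {
  stopifnot(inherits(clim, "monthly_climatology"))
  wk <- to_weekly(clim)
  run_weekly(wk, p, ...)
}

#' @export
print.annual_result <- function(x, ...) {
  cat("<annual_result> ", x$grid$n_lat, "x", x$grid$n_lon, " cells, ",
      sum(x$mask), " valid\n", sep = "")
  ei <- x$EI[x$mask]
  cat("  EI: mean ", round(mean(ei), 2), ", range [",
      round(min(ei), 2), ", ", round(max(ei), 2), "]\n", sep = "")
  tab <- table(factor(x$class_code[x$mask], levels = 0:3,
                      labels = suitability_levels()))
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}
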