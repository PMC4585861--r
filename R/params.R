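# Species parameter sets: the 19 kernel parameters governing the growth
# trapezoids, the four stress accumulators and the degree-day gate, plus the
# soil bucket capacity and evapotranspiration coefficient.

PARAM_KEYS <- c(
  "DV0", "DV1", "DV2", "DV3",
  "SM0", "SM1", "SM2", "SM3",
  "TTCS", "THCS", "DTCS", "DHCS",
  "TTHS", "THHS",
  "SMDS", "HDS",
  "SMWS", "HWS",
  "PDD"
)

OPTIONAL_PARAM_KEYS <- c("soil_capacity", "k_et")

#' Construct and validate a species parameter set
#'
#' A `climex_params` object holds the full kernel parameter set of the
#' ecoclimatic model: the temperature trapezoid (`DV0 < DV1 <= DV2 < DV3`,
#' degrees C), the soil-moisture trapezoid (`SM0 < SM1 <= SM2 < SM3`, fraction
#' of soil water-holding capacity), the cold (`TTCS`/`THCS` on weekly minimum
#' temperature and `DTCS`/`DHCS` on weekly degree-days), heat (`TTHS`/`THHS`),
#' dry (`SMDS`/`HDS`) and wet (`SMWS`/`HWS`) stress thresholds and weekly
#' accumulation rates, and the minimum annual degree-day sum `PDD` required
#' for establishment.
#'
#' Rates are stored signed exactly as conventionally printed (cold and dry
#' rates negative, heat and wet rates positive); the stress kernels use their
#' magnitudes, so published parameter tables can be transcribed verbatim.
#'
#' @param ... named numeric scalars: all 19 kernel parameters (see
#'   [oil_palm_params()] for the full key list), optionally `soil_capacity`
#'   (bucket water-holding capacity, mm; default 100) and `k_et`
#'   (evapotranspiration coefficient, mm per degree C per day per unit
#'   saturation deficit fraction; see [soil_moisture_balance()]).
#' @return an object of class `climex_params` (a named list).
#' @examples
#' p <- oil_palm_params()
#' p$DV0
#' @export
climex_params <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1]]) && is.null(names(vals))) {
    vals <- vals[[1]]
  }
  validate_params(vals)
}

#' @rdname climex_params
#' @param p a named list or `climex_params` object to validate.
#' @export
validate_params <- function(p) {
  p <- as.list(p)
  nm <- names(p)
  unknown <- setdiff(nm, c(PARAM_KEYS, OPTIONAL_PARAM_KEYS))
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_keys <- setdiff(PARAM_KEYS, nm)
  if (length(missing_keys) > 0L) {
    stop("missing parameter key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(p$soil_capacity)) p$soil_capacity <- 100
  if (is.null(p$k_et)) p$k_et <- K_ET_DEFAULT
  for (k in names(p)) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter ", k, " must be a finite numeric scalar", call. = FALSE)
    }
    p[[k]] <- as.numeric(v)
  }

  ord <- function(a, b, strict, sa, sb) {
    bad <- if (strict) p[[sa]] >= p[[sb]] else p[[sa]] > p[[sb]]
    if (bad) {
      stop("parameter ordering violated: require ", sa,
           if (strict) " < " else " <= ", sb,
           " (got ", sa, "=", p[[sa]], ", ", sb, "=", p[[sb]], ")",
           call. = FALSE)
    }
  }
  ord(strict = TRUE,  sa = "DV0", sb = "DV1")
  ord(strict = FALSE, sa = "DV1", sb = "DV2")
  ord(strict = TRUE,  sa = "DV2", sb = "DV3")
  ord(strict = TRUE,  sa = "SM0", sb = "SM1")
  ord(strict = FALSE, sa = "SM1", sb = "SM2")
  ord(strict = TRUE,  sa = "SM2", sb = "SM3")
  ord(strict = FALSE, sa = "TTCS", sb = "DV0")
  ord(strict = FALSE, sa = "DV2",  sb = "TTHS")
  ord(strict = FALSE, sa = "SMDS", sb = "SM0")
  ord(strict = FALSE, sa = "SM2",  sb = "SMWS")

  sign_check <- function(key, expected) {
    v <- p[[key]]
    if (expected == "negative" && v > 0) {
      stop("parameter ", key, " must be <= 0 (stored as printed, a negative ",
           "weekly rate); got ", v, call. = FALSE)
    }
    if (expected == "positive" && v < 0) {
      stop("parameter ", key, " must be >= 0; got ", v, call. = FALSE)
    }
  }
  sign_check("THCS", "negative")
  sign_check("DHCS", "negative")
  sign_check("HDS",  "negative")
  sign_check("THHS", "positive")
  sign_check("HWS",  "positive")
  if (p$PDD < 0) stop("parameter PDD must be >= 0; got ", p$PDD, call. = FALSE)
  if (p$DTCS < 0) stop("parameter DTCS must be >= 0; got ", p$DTCS, call. = FALSE)
  if (p$soil_capacity <= 0) {
    stop("parameter soil_capacity must be > 0; got ", p$soil_capacity,
         call. = FALSE)
  }
  if (p$k_et <= 0) stop("parameter k_et must be > 0; got ", p$k_et, call. = FALSE)

  p <- p[c(PARAM_KEYS, OPTIONAL_PARAM_KEYS)]
  class(p) <- "climex_params"
  p
}

#' The published oil palm parameter set
#'
#' Returns the fitted parameter set for oil palm (*Elaeis guineensis*):
#' growth limited below 19 and above 36 degrees C with the optimum on
#' 24-28 degrees C, soil-moisture optimum on 0.6-1.6 of bucket capacity, two
#' cold-stress mechanisms (weekly minimum temperature below 15 degrees C at
#' 0.005 per week, and weekly degree-day sums below 20 degree-days at 0.0005
#' per week), heat stress above 36 degrees C, dry stress below soil moisture
#' 0.4, wet stress above soil moisture 2, and a 1500 degree-day annual
#' establishment threshold.
#'
#' The same values ship as a plain-text config at
#' `system.file("extdata", "oil_palm.params", package = "ecoclimex")`.
#'
#' @return a [climex_params] object.
#' @export
oil_palm_params <- function() {
  climex_params(
    DV0 = 19, DV1 = 24, DV2 = 28, DV3 = 36,
    SM0 = 0.4, SM1 = 0.6, SM2 = 1.6, SM3 = 2,
    TTCS = 15, THCS = -0.005,
    DTCS = 20, DHCS = -0.0005,
    TTHS = 36, THHS = 0.001,
    SMDS = 0.4, HDS = -0.007,
    SMWS = 2, HWS = 0.0023,
    PDD = 1500
  )
}

#' Read and write parameter files
#'
#' Parameter files are flat `key = value` text tables, one species per file,
#' keyed by the standard mnemonics (`DV0` ... `PDD`, plus `soil_capacity` and
#' `k_et`). Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return `read_climex_params()` returns a validated [climex_params] object;
#'   `write_climex_params()` writes `p` and returns `path` invisibly.
#' @examples
#' preset <- system.file("extdata", "oil_palm.params", package = "ecoclimex")
#' p <- read_climex_params(preset)
#' p$PDD
#' @export
read_climex_params <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("unparseable line(s) in ", path, ": ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 3L)))
  if (anyNA(vals)) {
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  validate_params(stats::setNames(as.list(vals), keys))
}

#' @rdname read_climex_params
#' @param p a [climex_params] object.
#' @export
write_climex_params <- function(p, path) {
  stopifnot(inherits(p, "climex_params"))
  lines <- sprintf("%s = %s", names(p),
                   vapply(unclass(p), format, character(1), digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.climex_params <- function(x, ...) {
  cat("<climex_params>\n")
  cat("  temperature trapezoid (degC):", x$DV0, x$DV1, x$DV2, x$DV3, "\n")
  cat("  moisture trapezoid (frac)  :", x$SM0, x$SM1, x$SM2, x$SM3, "\n")
  cat("  cold stress  : TTCS", x$TTCS, "degC @", x$THCS, "/wk; DTCS",
      x$DTCS, "degC-days @", x$DHCS, "/wk\n")
  cat("  heat stress  : TTHS", x$TTHS, "degC @", x$THHS, "/wk\n")
  cat("  dry stress   : SMDS", x$SMDS, "@", x$HDS, "/wk\n")
  cat("  wet stress   : SMWS", x$SMWS, "@", x$HWS, "/wk\n")
  cat("  degree-day gate PDD:", x$PDD, "degC-days above DV0\n")
  cat("  bucket:", x$soil_capacity, "mm; k_et:", x$k_et, "\n")
  invisible(x)
}
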