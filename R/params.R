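#' Crop parameter set for the rape growth engine
#'
#' Builds the full parameter set driving [run_simulation()].  Defaults are
#' the single-point rape calibration means where published values exist
#' (temperature sums, initial dry weight, specific pod area, leaf span,
#' conversion efficiencies, dry-matter partition tables, initial available
#' water); the remaining engine parameters (emergence sums, leaf-area
#' dynamics, light-response and respiration coefficients, root partitioning)
#' carry standard WOFOST-style winter-rape values and are all overridable.
#'
#' Scalar parameters (units in parentheses):
#' \describe{
#'   \item{TSUMEM, TBASEM}{degree-days sowing to emergence and its base
#'     temperature (C d, C).}
#'   \item{TSUM1, TSUM2}{degree-days emergence to flowering and flowering to
#'     maturity (C d).}
#'   \item{TDWI}{initial total crop dry weight at emergence (kg/ha).}
#'   \item{LAIEM}{leaf area index at emergence (ha/ha).}
#'   \item{RGRLAI}{maximum relative growth rate of LAI during the juvenile
#'     phase (1/(C d)).}
#'   \item{SPA}{specific pod area: pod area index per unit storage-organ dry
#'     mass (ha/kg).}
#'   \item{SPAN}{leaf life span at reference temperature (physiological d).}
#'   \item{TBASE}{base temperature for development and leaf ageing (C).}
#'   \item{CVL, CVO, CVR, CVS}{assimilate-to-dry-matter conversion
#'     efficiencies for leaves, storage organs, roots, stems (kg/kg).}
#'   \item{RML, RMO, RMR, RMS}{maintenance respiration coefficients
#'     (kg CH2O/kg/d) at the reference temperature.}
#'   \item{Q10}{relative respiration increase per 10 C (dimensionless).}
#'   \item{WAV}{initial available soil water (cm).}
#'   \item{SOIL_CAP}{bucket capacity of the one-layer soil (cm).}
#' }
#' AFGEN tables over DVS: \code{SLATB} (specific leaf area, ha/kg),
#' \code{KDIFTB} (diffuse-light extinction), \code{AMAXTB} (maximum leaf CO2
#' assimilation, kg/ha/h), \code{FLTB}, \code{FSTB}, \code{FOTB} (shoot
#' dry-matter partition fractions, constrained to sum to 1 at every shared
#' breakpoint), \code{FRTB} (root fraction of total assimilate).  Over
#' temperature: \code{EFFTB} (initial light-use efficiency,
#' (kg/ha/h)/(J/m2/s)) and \code{TMPFTB} (temperature reduction of AMAX).
#'
#' @param ... Named overrides of any default, e.g. \code{SPA = 5e-4} or
#'   \code{SLATB = afgen(c(0, 2), c(0.002, 0.0018))}.
#' @param sowing_date Sowing date (\code{Date} or ISO string).
#' @return An object of class \code{crop_params} (named list).
#' @examples
#' p <- crop_params()
#' p$SPA
#' p2 <- crop_params(SPA = 0.0004, TSUM1 = 650)
#' @export
crop_params <- function(..., sowing_date = as.Date("2020-10-10")) {
  # Partition means renormalized so FL + FS + FO = 1 exactly at every
  # breakpoint (the raw DVS-0.7 means sum to 1.01).
  dvs8 <- c(0, 0.3, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0)
  fl <- c(0.94, 0.90, 0.34, 0.16, 0.04, 0.00, 0.00, 0.00)
  fo <- c(0.06, 0.10, 0.66, 0.59, 0.23, 0.04, 0.00, 0.00)
  fs <- c(0.00, 0.00, 0.01, 0.25, 0.73, 0.96, 1.00, 1.00)
  tot <- fl + fs + fo
  fl <- fl / tot; fs <- fs / tot; fo <- fo / tot

  p <- list(
    TSUMEM = 20, TBASEM = 3,
    TSUM1 = 701, TSUM2 = 737,
    TDWI = 8.9, LAIEM = 0.25, RGRLAI = 0.012,
    SPA = 0.00065, SPAN = 37.4, TBASE = 0,
    CVL = 0.439, CVO = 0.612, CVR = 0.526, CVS = 0.350,
    RML = 0.030, RMO = 0.010, RMR = 0.010, RMS = 0.015,
    Q10 = 2,
    WAV = 42, SOIL_CAP = 55,
    SLATB  = afgen(c(0, 2), c(0.0022, 0.0018)),
    KDIFTB = afgen(c(0, 2), c(0.60, 0.75)),
    EFFTB  = afgen(c(0, 40), c(0.45, 0.45)),
    AMAXTB = afgen(c(0, 1, 2), c(35, 35, 28)),
    TMPFTB = afgen(c(0, 3, 10, 15, 20, 30, 35, 40),
                   c(0.01, 0.05, 0.75, 1, 1, 0.95, 0.70, 0.30)),
    FLTB = afgen(dvs8, fl),
    FSTB = afgen(dvs8, fs),
    FOTB = afgen(dvs8, fo),
    FRTB = afgen(c(0, 1.3, 2), c(0.4, 0, 0)),
    sowing_date = as.Date(sowing_date),
    emergence_mode = "tsum"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown crop parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  class(p) <- "crop_params"
  validate_crop_params(p)
  p
}

validate_crop_params <- function(p) {
  for (cv in c("CVL", "CVO", "CVR", "CVS"))
    if (p[[cv]] <= 0 || p[[cv]] > 1)
      stop(cv, " must lie in (0, 1]", call. = FALSE)
  if (p$TSUM1 <= 0 || p$TSUM2 <= 0)
    stop("TSUM1 and TSUM2 must be positive", call. = FALSE)
  if (p$SPAN <= 0) stop("SPAN must be positive", call. = FALSE)
  if (p$SPA < 0) stop("SPA must be non-negative", call. = FALSE)
  xs <- p$FLTB$x
  if (!identical(xs, p$FSTB$x) || !identical(xs, p$FOTB$x))
    stop("FLTB, FSTB and FOTB must share DVS breakpoints", call. = FALSE)
  s <- p$FLTB$y + p$FSTB$y + p$FOTB$y
  if (any(abs(s - 1) > 1e-6))
    stop("FLTB + FSTB + FOTB must equal 1 at every DVS breakpoint ",
         "(max deviation ", format(max(abs(s - 1))), ")", call. = FALSE)
  invisible(p)
}

#' @export
print.crop_params <- function(x, ...) {
  cat("Crop parameter set (", length(x), " entries)\n", sep = "")
  sc <- names(x)[vapply(x, is.numeric, logical(1))]
  cat("  scalars: ", paste0(sc, "=", vapply(x[sc], format, "")), "\n")
  cat("  tables:  ",
      paste(names(x)[vapply(x, is_afgen, logical(1))], collapse = ", "), "\n")
  cat("  sowing:  ", format(x$sowing_date), "\n")
  invisible(x)
}

# ---- symbol access -------------------------------------------------------
# Calibration and sensitivity address parameters by field symbols such as
# "SPA" (scalar) or "KDIFTB2.00" / "FSTB1.70" (table ordinate at the given
# breakpoint).

parse_symbol <- function(symbol) {
  m <- regmatches(symbol, regexec("^([A-Za-z0-9_]+?)([0-9]+\\.[0-9]+)?$",
                                  symbol))[[1]]
  if (!length(m)) stop("cannot parse parameter symbol: ", symbol,
                       call. = FALSE)
  list(name = m[2], at = if (nzchar(m[3])) as.numeric(m[3]) else NA_real_)
}

#' Get or set a parameter by field symbol
#'
#' Symbols follow the field convention: a bare name addresses a scalar
#' (\code{"SPA"}); a name with a numeric suffix addresses one ordinate of an
#' AFGEN table at that breakpoint (\code{"KDIFTB2.00"}, \code{"FSTB1.70"}).
#' Setting a member of the FLTB/FSTB/FOTB partition triplet renormalizes the
#' other two members at that breakpoint so the three still sum to 1 (the
#' remainder is shared in proportion to their current values; if both are
#' zero it goes to FOTB, or to FSTB when FOTB itself is being set).
#'
#' @param params A \code{crop_params} object.
#' @param symbol Character symbol.
#' @param value Replacement value (for \code{set_param}).
#' @return \code{get_param}: the numeric value. \code{set_param}: the
#'   modified parameter set.
#' @export
get_param <- function(params, symbol) {
  s <- parse_symbol(symbol)
  obj <- params[[s$name]]
  if (is.null(obj)) stop("unknown parameter: ", s$name, call. = FALSE)
  if (is.na(s$at)) {
    if (is_afgen(obj)) stop(symbol, " is a table; give a breakpoint suffix",
                            call. = FALSE)
    return(obj)
  }
  i <- match(s$at, obj$x)
  if (is.na(i)) stop("no breakpoint ", s$at, " in table ", s$name,
                     call. = FALSE)
  obj$y[i]
}

#' @rdname get_param
#' @param renormalize Logical; renormalize the partition triplet after
#'   setting one of its members (default TRUE).  Callers that write all
#'   three members of an already-constrained triplet set it to FALSE.
#' @export
set_param <- function(params, symbol, value, renormalize = TRUE) {
  s <- parse_symbol(symbol)
  obj <- params[[s$name]]
  if (is.null(obj)) stop("unknown parameter: ", s$name, call. = FALSE)
  if (is.na(s$at)) {
    params[[s$name]] <- value
    if (s$name %in% c("TSUM1", "TSUM2", "SPAN") && value <= 0)
      stop(s$name, " must be positive", call. = FALSE)
    return(params)
  }
  i <- match(s$at, obj$x)
  if (is.na(i)) stop("no breakpoint ", s$at, " in table ", s$name,
                     call. = FALSE)
  obj$y[i] <- value
  params[[s$name]] <- obj
  if (renormalize && s$name %in% c("FLTB", "FSTB", "FOTB"))
    params <- renorm_partition(params, s$name, i)
  params
}

renorm_partition <- function(params, changed, i) {
  members <- c("FLTB", "FSTB", "FOTB")
  others <- setdiff(members, changed)
  v <- min(max(params[[changed]]$y[i], 0), 1)
  params[[changed]]$y[i] <- v
  rest <- 1 - v
  o1 <- params[[others[1]]]$y[i]; o2 <- params[[others[2]]]$y[i]
  if (o1 + o2 > 0) {
    params[[others[1]]]$y[i] <- rest * o1 / (o1 + o2)
    params[[others[2]]]$y[i] <- rest * o2 / (o1 + o2)
  } else {
    sink <- if (changed == "FOTB") "FSTB" else "FOTB"
    params[[sink]]$y[i] <- rest
    params[[setdiff(others, sink)]]$y[i] <- 0
  }
  params
}

# ---- bounds registry -----------------------------------------------------

#' Parameter bounds for calibration and sensitivity analysis
#'
#' Returns the lower/upper bounds for a vector of parameter symbols.  Where
#' a symbol appears in the single-point calibration table its [min, max]
#' range is used; otherwise the generic model-documentation bounds for its
#' family apply (e.g. KDIFTB in [0, 1], SPA in [0, 0.01]).
#'
#' @param symbols Character vector of parameter symbols.
#' @return Data frame with columns \code{symbol}, \code{lower}, \code{upper}.
#' @export
param_bounds <- function(symbols) {
  t4 <- calib_bounds_table()
  generic <- c(TSUMEM = NA, TBASEM = NA, TSUM1 = NA, TSUM2 = NA,
               TDWI = NA, LAIEM = NA, RGRLAI = NA, SLATB = NA, SPA = NA,
               SPAN = NA, TBASE = NA, KDIFTB = NA, EFFTB = NA, AMAXTB = NA,
               TMPFTB = NA, CVL = NA, CVO = NA, CVR = NA, CVS = NA,
               RML = NA, RMO = NA, RMR = NA, RMS = NA,
               FLTB = NA, FOTB = NA, FSTB = NA)
  glo <- c(0, 0, 500, 500, 0.01, 1e-4, 1e-4, 0, 0, 20, -10, 0, 0, 0, 0,
           0.2, 0.2, 0.2, 0.2, 0, 0, 0, 0, 0, 0, 0)
  ghi <- c(30, 30, 1000, 1000, 10, 1, 1, 0.01, 0.01, 50, 10, 1, 1, 60, 1,
           1, 1, 1, 1, 0.1, 0.1, 0.1, 0.1, 1, 1, 1)
  names(glo) <- names(ghi) <- names(generic)
  out <- data.frame(symbol = symbols, lower = NA_real_, upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(symbols)) {
    sym <- symbols[k]
    j <- match(sym, t4$symbol)
    if (!is.na(j) && t4$upper[j] > t4$lower[j]) {
      out$lower[k] <- t4$lower[j]; out$upper[k] <- t4$upper[j]
    } else {
      base <- parse_symbol(sym)$name
      if (!base %in% names(glo))
        stop("no bounds known for parameter ", sym, call. = FALSE)
      out$lower[k] <- glo[[base]]; out$upper[k] <- ghi[[base]]
    }
  }
  out
}

# Single-point calibration ranges (mean / min / max) for the symbols with
# published field-derived values; shipped in code so no data file is needed.
calib_bounds_table <- function() {
  txt <- "symbol mean lower upper
WAV 42 25 55
TSUM1 701 550 860
TSUM2 737 650 850
TDWI 8.9 4.0 13.0
SPA 0.00065 0.00020 0.00090
SPAN 37.4 31.5 49.5
CVL 0.439 0.220 0.700
CVO 0.612 0.350 0.950
CVR 0.526 0.290 0.700
CVS 0.350 0.200 0.595
FLTB0.00 0.94 0.90 1.00
FLTB0.30 0.90 0.70 1.00
FLTB0.70 0.34 0.18 0.60
FLTB1.00 0.16 0.00 0.32
FLTB1.30 0.04 0.00 0.15
FLTB1.50 0.00 0.00 0.00
FLTB1.70 0.00 0.00 0.00
FLTB2.00 0.00 0.00 0.00
FOTB0.00 0.06 0.00 0.10
FOTB0.30 0.10 0.00 0.30
FOTB0.70 0.66 0.40 0.82
FOTB1.00 0.59 0.45 0.85
FOTB1.30 0.23 0.05 0.45
FOTB1.50 0.04 0.00 0.10
FOTB1.70 0.00 0.00 0.00
FOTB2.00 0.00 0.00 0.00
FSTB0.00 0.00 0.00 0.00
FSTB0.30 0.00 0.00 0.00
FSTB0.70 0.01 0.00 0.10
FSTB1.00 0.25 0.00 0.48
FSTB1.30 0.73 0.50 0.90
FSTB1.50 0.96 0.90 1.00
FSTB1.70 1.00 1.00 1.00
FSTB2.00 1.00 1.00 1.00"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# ---- YAML persistence ----------------------------------------------------

#' Read or write a crop parameter set as YAML
#'
#' Scalars are stored as-is; AFGEN tables as two parallel lists \code{x},
#' \code{y}.
#'
#' @param params A \code{crop_params} object.
#' @param path File path.
#' @return \code{read_params_yaml} returns a \code{crop_params} object;
#'   \code{write_params_yaml} returns \code{path} invisibly.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "crop_params"))
  out <- lapply(unclass(params), function(v) {
    if (is_afgen(v)) list(x = v$x, y = v$y)
    else if (inherits(v, "Date")) format(v)
    else v
  })
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- lapply(raw[setdiff(names(raw), c("sowing_date", "emergence_mode"))],
                 function(v) {
                   if (is.list(v) && all(c("x", "y") %in% names(v)))
                     afgen(unlist(v$x), unlist(v$y))
                   else v
                 })
  args$sowing_date <- as.Date(raw$sowing_date)
  do.call(crop_params, args)
}
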