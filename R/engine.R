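#' WOFOST-style daily growth engine with pod-area canopy
#'
#' Re-implementation of the potential-production core of the WOFOST scheme:
#' degree-day phenology, canopy gross CO2 assimilation by three-point
#' Gaussian integration over canopy depth and over the daylight period,
#' Q10 maintenance respiration, DVS-dependent dry-matter partitioning with
#' per-organ conversion efficiencies, leaf cohorts with physiological-age
#' senescence, and a pod area index PAI = SPA * W_so that joins the leaves
#' in light interception (TPAI = LAI + PAI).  A one-layer water bucket
#' provides an optional water-limited mode.
#'
#' @name growth_engine
NULL

gauss3_x <- c(0.1127016653792583, 0.5, 0.8872983346207417)
gauss3_w <- c(0.2777777777777778, 0.4444444444444444, 0.2777777777777778)

#' Advance crop development stage by one day
#'
#' Effective temperature max(0, Tmean - TBASE) accumulates into the
#' pre-flowering sum until it reaches TSUM1 (DVS = sum/TSUM1), then into the
#' post-flowering sum (DVS = 1 + sum2/TSUM2), capped at 2.
#'
#' @param state Engine state list with \code{tsum1}, \code{tsum2}.
#' @param params \code{crop_params}.
#' @param tmean Daily mean temperature, C.
#' @return Updated state with new \code{DVS}, \code{tsum1}, \code{tsum2}.
#' @export
phenology_step <- function(state, params, tmean) {
  if (params$TSUM1 <= 0 || params$TSUM2 <= 0)
    stop("TSUM1 and TSUM2 must be positive", call. = FALSE)
  eff <- max(0, tmean - params$TBASE)
  if (state$tsum1 < params$TSUM1) {
    state$tsum1 <- state$tsum1 + eff
    if (state$tsum1 > params$TSUM1) {
      state$tsum2 <- state$tsum2 + (state$tsum1 - params$TSUM1)
      state$tsum1 <- params$TSUM1
    }
  } else {
    state$tsum2 <- state$tsum2 + eff
  }
  state$DVS <- min(state$tsum1 / params$TSUM1 +
                     state$tsum2 / params$TSUM2, 2)
  state
}

# Instantaneous canopy gross assimilation (kg CO2 ha-1 h-1) for a given
# photosynthetic area index and PAR flux (J m-2 s-1): diffuse-light profile
# with extinction kdif, leaf-level negative-exponential light response.
canopy_assim_instant <- function(pai_total, par, amax, eff, kdif) {
  if (pai_total <= 0 || par <= 0 || amax <= 0) return(0)
  laic <- pai_total * gauss3_x
  absorbed <- kdif * par * exp(-kdif * laic)   # per unit area at depth
  fgl <- amax * (1 - exp(-absorbed * eff / amax))
  sum(gauss3_w * fgl) * pai_total
}

# Daily assimilation core on precomputed solar geometry (kg CH2O ha-1 d-1).
daily_assim_core <- function(pai_total, amax, eff, kdif, avrad,
                             daylength, sinld, cosld, dsinbe) {
  if (pai_total <= 0 || avrad <= 0 || amax <= 0 || eff <= 0) return(0)
  dtga <- 0
  for (i in 1:3) {
    hour <- 12 + 0.5 * daylength * gauss3_x[i]
    sinb <- max(0, sinld + cosld * cos(2 * pi * (hour + 12) / 24))
    par <- 0.5 * avrad * sinb * (1 + 0.4 * sinb) / dsinbe
    dtga <- dtga + gauss3_w[i] *
      canopy_assim_instant(pai_total, par, amax, eff, kdif)
  }
  dtga * daylength * 30 / 44   # kg CO2 -> kg CH2O
}

# Water-bucket core on precomputed extraterrestrial radiation.
water_core <- function(soil_water, tpai, cap, tmean, trange, angot_kj,
                       precip_mm) {
  ra_mm <- angot_kj / 2450
  et0 <- max(0, 0.0023 * (tmean + 17.8) * sqrt(max(trange, 0)) * ra_mm)
  cover <- 1 - exp(-0.75 * tpai)
  demand_cm <- et0 * (cover + 0.5 * (1 - cover)) / 10
  rain_cm <- precip_mm / 10
  loss_cm <- min(soil_water + rain_cm, demand_cm)
  sw <- soil_water + rain_cm - loss_cm
  drain_cm <- max(0, sw - cap)
  sw <- sw - drain_cm
  list(soil_water = sw, stress = min(1, max(0, sw / cap / 0.5)),
       rain_cm = rain_cm, loss_cm = loss_cm, drain_cm = drain_cm)
}

#' Daily canopy gross assimilation
#'
#' Integrates instantaneous canopy photosynthesis over the daylight period
#' (three-point Gauss) with irradiance distributed over the day following
#' solar elevation.  Light is attenuated over the total photosynthetic area
#' index, so pods contribute to interception and assimilation.
#'
#' @param pai_total Photosynthetic area index used for interception (TPAI,
#'   or LAI in leaf-only mode).
#' @param params \code{crop_params} (uses AMAXTB, EFFTB, TMPFTB, KDIFTB).
#' @param dvs Current development stage.
#' @param weather_day One-row weather record with \code{date}, \code{tmin},
#'   \code{tmax}, \code{radiation} (kJ m-2 d-1).
#' @param lat Latitude, decimal degrees.
#' @return Gross assimilation, kg CH2O ha-1 d-1.
#' @export
daily_gross_assimilation <- function(pai_total, params, dvs, weather_day,
                                     lat) {
  rad <- weather_day$radiation
  if (is.null(rad) || is.na(rad))
    stop("weather day lacks radiation", call. = FALSE)
  if (rad < 0) stop("negative radiation", call. = FALSE)
  if (pai_total <= 0 || rad == 0) return(0)
  tmean <- (weather_day$tmin + weather_day$tmax) / 2
  tday <- (weather_day$tmax + tmean) / 2
  amax <- afgen_eval(params$AMAXTB, dvs) * afgen_eval(params$TMPFTB, tday)
  eff <- afgen_eval(params$EFFTB, tday)
  kdif <- afgen_eval(params$KDIFTB, dvs)
  geo <- solar_geometry(weather_day$date, lat)
  daily_assim_core(pai_total, amax, eff, kdif, rad * 1000,
                   geo$daylength, geo$sinld, geo$cosld, geo$dsinbe)
}

#' Maintenance respiration
#'
#' Sum of per-organ coefficients times living mass, scaled by
#' Q10^((Tmean - 25)/10) and capped at the day's gross assimilation.
#'
#' @param state Engine state (living masses \code{W_leaf}, \code{W_stem},
#'   \code{W_so}, \code{W_root}).
#' @param params \code{crop_params}.
#' @param tmean Daily mean temperature, C.
#' @param gross Day's gross assimilation (cap), kg CH2O ha-1 d-1.
#' @return Maintenance respiration, kg CH2O ha-1 d-1.
#' @export
maintenance_respiration <- function(state, params, tmean, gross = Inf) {
  rm25 <- params$RML * state$W_leaf + params$RMS * state$W_stem +
    params$RMO * state$W_so + params$RMR * state$W_root
  min(rm25 * params$Q10^((tmean - 25) / 10), gross)
}

#' Partition net assimilate and grow organs
#'
#' The root fraction FRTB(DVS) is taken off the top; the shoot share is
#' split by FLTB/FSTB/FOTB(DVS) (which must sum to 1 within 1e-6 at the
#' current DVS); each organ converts its allocation with its own
#' efficiency, so gross - maintenance = sum(dW/CV) holds exactly.
#'
#' @param params \code{crop_params}.
#' @param dvs Current development stage.
#' @param net Net assimilate (gross - maintenance), kg CH2O ha-1 d-1.
#' @return List with per-organ dry-mass increments \code{dW_leaf},
#'   \code{dW_stem}, \code{dW_so}, \code{dW_root}.
#' @export
partition_and_grow <- function(params, dvs, net) {
  if (net < 0) stop("net assimilate must be non-negative", call. = FALSE)
  fl <- afgen_eval(params$FLTB, dvs)
  fs <- afgen_eval(params$FSTB, dvs)
  fo <- afgen_eval(params$FOTB, dvs)
  if (abs(fl + fs + fo - 1) > 1e-6)
    stop("partition fractions sum to ", format(fl + fs + fo),
         " at DVS ", format(dvs), call. = FALSE)
  fr <- min(max(afgen_eval(params$FRTB, dvs), 0), 1)
  shoot <- net * (1 - fr)
  list(dW_leaf = params$CVL * fl * shoot,
       dW_stem = params$CVS * fs * shoot,
       dW_so   = params$CVO * fo * shoot,
       dW_root = params$CVR * fr * net)
}

#' Leaf cohort dynamics
#'
#' New leaf mass enters as a cohort whose area is the mass times the current
#' specific leaf area; during the juvenile phase (DVS < 0.3) area growth is
#' exponential at RGRLAI per effective degree-day, capped by that source
#' supply.  Cohorts age by (Tmean - TBASE)/(35 - TBASE) physiological days
#' (clamped at 0) and die when older than SPAN, moving their mass to
#' \code{W_leaf_dead} and removing their area.
#'
#' @param state Engine state (cohort vectors, \code{LAI}, \code{DVS}).
#' @param params \code{crop_params}.
#' @param tmean Daily mean temperature, C.
#' @param dW_leaf Leaf dry-mass increment, kg ha-1.
#' @return Updated state.
#' @export
leaf_dynamics <- function(state, params, tmean, dW_leaf) {
  if (params$SPAN <= 0) stop("SPAN must be positive", call. = FALSE)
  if (dW_leaf < 0) stop("leaf growth must be non-negative", call. = FALSE)
  sla <- afgen_eval(params$SLATB, state$DVS)
  eff <- max(0, tmean - params$TBASE)
  # ageing and senescence of existing cohorts
  aging <- eff / (35 - params$TBASE)
  state$cohort_age <- state$cohort_age + max(0, aging)
  dead <- state$cohort_age > params$SPAN
  if (any(dead)) {
    state$W_leaf_dead <- state$W_leaf_dead + sum(state$cohort_mass[dead])
    state$W_leaf <- state$W_leaf - sum(state$cohort_mass[dead])
    state$cohort_mass <- state$cohort_mass[!dead]
    state$cohort_area <- state$cohort_area[!dead]
    state$cohort_age <- state$cohort_age[!dead]
  }
  lai_live <- sum(state$cohort_area)
  # new growth
  darea <- dW_leaf * sla
  if (state$DVS < 0.3 && lai_live > 0)
    darea <- min(lai_live * (exp(params$RGRLAI * eff) - 1), darea)
  if (dW_leaf > 0) {
    state$cohort_mass <- c(state$cohort_mass, dW_leaf)
    state$cohort_area <- c(state$cohort_area, darea)
    state$cohort_age <- c(state$cohort_age, 0)
    state$W_leaf <- state$W_leaf + dW_leaf
  }
  state$LAI <- sum(state$cohort_area)
  state
}

#' Pod area index update
#'
#' PAI = SPA * W_so once pods exist (DVS >= 1); before flowering the pod
#' area is 0.  TPAI = LAI + PAI always.
#'
#' @param state Engine state.
#' @param params \code{crop_params}.
#' @return Updated state with \code{PAI} and \code{TPAI}.
#' @export
pod_area_update <- function(state, params) {
  if (params$SPA < 0) stop("SPA must be non-negative", call. = FALSE)
  state$PAI <- if (state$DVS >= 1) params$SPA * state$W_so else 0
  state$TPAI <- state$LAI + state$PAI
  state
}

#' One-layer soil water bucket
#'
#' The bucket gains precipitation and loses crop transpiration plus soil
#' evaporation, both scaled from a Hargreaves-type reference evaporation by
#' canopy cover.  The water-stress factor is 1 above half of bucket
#' capacity and declines linearly to 0 at empty.
#'
#' @param state Engine state (\code{soil_water}, \code{TPAI}).
#' @param params \code{crop_params} (uses SOIL_CAP).
#' @param weather_day One-row weather record.
#' @param lat Latitude, decimal degrees.
#' @return Updated state with \code{soil_water}, \code{stress},
#'   \code{rain_cm}, \code{loss_cm}, \code{drain_cm} for the day.
#' @export
water_balance_step <- function(state, params, weather_day, lat) {
  tmean <- (weather_day$tmin + weather_day$tmax) / 2
  wb <- water_core(state$soil_water, state$TPAI, params$SOIL_CAP, tmean,
                   weather_day$tmax - weather_day$tmin,
                   solar_geometry(weather_day$date, lat)$angot_kj,
                   weather_day$precip)
  state[names(wb)] <- wb
  state
}

#' Run the growth engine over a weather series
#'
#' Orchestrates the daily steps in a fixed order (phenology, assimilation,
#' maintenance respiration, partitioning, leaf and pod dynamics, water
#' balance) from sowing to maturity (DVS = 2) or the end of the window.
#'
#' @param params A \code{crop_params} object.
#' @param weather A \code{weather_series} covering the window (radiation is
#'   derived from sunshine where absent).
#' @param window Optional \code{Date} vector of length 2 (start, end);
#'   defaults to sowing date through the end of the weather series.
#' @param mode \code{"potential"} (no water stress, default) or
#'   \code{"water-limited"}.
#' @param interception \code{"tpai"} (pods intercept light, default) or
#'   \code{"lai"} (leaf-only baseline).
#' @return A \code{crop_trace}: data frame with one row per simulated day
#'   (date, DVS, LAI, PAI, TPAI, TWSO, TAGP, organ masses, carbon and water
#'   ledger columns), with the parameter set and run settings as attributes.
#' @examples
#' \donttest{
#' wx <- generate_weather(weather_gen_spec(seed = 1))
#' tr <- run_simulation(crop_params(), wx)
#' tail(tr[, c("date", "DVS", "LAI", "TPAI", "TWSO", "TAGP")])
#' }
#' @export
run_simulation <- function(params, weather, window = NULL,
                           mode = c("potential", "water-limited"),
                           interception = c("tpai", "lai")) {
  mode <- match.arg(mode)
  interception <- match.arg(interception)
  stopifnot(inherits(params, "crop_params"),
            inherits(weather, "weather_series"))
  validate_crop_params(params)
  weather <- ensure_radiation(weather)
  lat <- attr(weather, "station")$lat
  if (is.null(window))
    window <- c(params$sowing_date, max(weather$date))
  window <- as.Date(window)
  days <- seq(window[1], window[2], by = "day")
  idx <- match(days, weather$date)
  if (anyNA(idx))
    stop("weather does not cover the simulation window (missing ",
         format(days[which(is.na(idx))[1]]), ")", call. = FALSE)
  tminv <- weather$tmin[idx]; tmaxv <- weather$tmax[idx]
  radv <- weather$radiation[idx]; precipv <- weather$precip[idx]
  if (any(radv < 0)) stop("negative radiation", call. = FALSE)
  geo <- solar_geometry(days, lat)

  n <- length(days)
  # per-day quantities depending on temperature only, vectorized up front
  tmeanv <- (tminv + tmaxv) / 2
  tdayv <- (tmaxv + tmeanv) / 2
  effday <- afgen_eval_vec(params$EFFTB, tdayv)
  tmpfday <- afgen_eval_vec(params$TMPFTB, tdayv)
  q10f <- params$Q10^((tmeanv - 25) / 10)
  efft <- pmax(0, tmeanv - params$TBASE)
  aging_day <- efft / (35 - params$TBASE)

  # DVS-indexed tables merged onto one refined breakpoint grid so the daily
  # loop does one bracketing search instead of seven (exact for
  # piecewise-linear tables)
  dvs_tabs <- c("FLTB", "FSTB", "FOTB", "FRTB", "SLATB", "KDIFTB", "AMAXTB")
  grid <- sort(unique(c(0, 2, unlist(lapply(params[dvs_tabs],
                                            function(tb) tb$x)))))
  grid <- grid[grid >= 0 & grid <= 2]
  Ytab <- vapply(params[dvs_tabs], afgen_eval_vec, numeric(length(grid)),
                 at = grid)
  ng <- length(grid)
  dvs_vals <- function(dvs) {
    i <- findInterval(dvs, grid, all.inside = TRUE)
    w <- (dvs - grid[i]) / (grid[i + 1L] - grid[i])
    Ytab[i, ] + w * (Ytab[i + 1L, ] - Ytab[i, ])
  }

  RML <- params$RML; RMS <- params$RMS; RMO <- params$RMO
  RMR <- params$RMR
  CVL <- params$CVL; CVS <- params$CVS; CVO <- params$CVO
  CVR <- params$CVR
  SPA <- params$SPA; SPAN <- params$SPAN; RGRLAI <- params$RGRLAI
  SOIL_CAP <- params$SOIL_CAP

  cols <- c("DVS", "LAI", "PAI", "TPAI", "TWSO", "TAGP",
            "W_leaf", "W_leaf_dead", "W_stem", "W_so", "W_root",
            "gross", "maint", "dW_leaf", "dW_stem", "dW_so", "dW_root",
            "soil_water", "stress", "rain_cm", "loss_cm", "drain_cm")
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  last <- n

  # scalar state (kept out of a list so the daily loop does not copy)
  DVS <- 0; ts1 <- 0; ts2 <- 0; tsem <- 0; emerged <- FALSE
  W_leaf <- 0; W_stem <- 0; W_so <- 0; W_root <- 0; W_leaf_dead <- 0
  LAI <- 0; PAI <- 0; TPAI <- 0
  soil_water <- params$WAV; stress <- 1
  co_mass <- numeric(n); co_area <- numeric(n); co_age <- numeric(n)
  co_lo <- 1L; co_hi <- 0L   # live cohort window
  tpai_mode <- interception == "tpai"
  wlim <- mode == "water-limited"
  TSUM1 <- params$TSUM1; TSUM2 <- params$TSUM2

  for (t in seq_len(n)) {
    tmean <- tmeanv[t]
    gross <- 0; maint <- 0
    dwl <- 0; dws <- 0; dwo <- 0; dwr <- 0

    if (!emerged) {
      tsem <- tsem + max(0, tmean - params$TBASEM)
      if (tsem >= params$TSUMEM) {
        emerged <- TRUE
        fr0 <- min(max(afgen_eval(params$FRTB, 0), 0), 1)
        shoot <- params$TDWI * (1 - fr0)
        W_root <- params$TDWI * fr0
        W_leaf <- shoot * afgen_eval(params$FLTB, 0)
        W_stem <- shoot * afgen_eval(params$FSTB, 0)
        W_so <- shoot * afgen_eval(params$FOTB, 0)
        co_hi <- 1L
        co_mass[1L] <- W_leaf; co_area[1L] <- params$LAIEM
        co_age[1L] <- 0
        LAI <- params$LAIEM
        PAI <- 0; TPAI <- LAI
      }
    } else if (DVS < 2) {
      # phenology
      if (ts1 < TSUM1) {
        ts1 <- ts1 + efft[t]
        if (ts1 > TSUM1) { ts2 <- ts2 + (ts1 - TSUM1); ts1 <- TSUM1 }
      } else ts2 <- ts2 + efft[t]
      DVS <- min(ts1 / TSUM1 + ts2 / TSUM2, 2)
      tb <- dvs_vals(DVS)  # FLTB FSTB FOTB FRTB SLATB KDIFTB AMAXTB
      # assimilation over the photosynthetic canopy
      pai_int <- if (tpai_mode) TPAI else LAI
      gross <- daily_assim_core(pai_int, tb[7L] * tmpfday[t], effday[t],
                                tb[6L],
                                radv[t] * 1000, geo$daylength[t],
                                geo$sinld[t], geo$cosld[t], geo$dsinbe[t])
      if (wlim) gross <- gross * stress
      maint <- min((RML * W_leaf + RMS * W_stem + RMO * W_so +
                      RMR * W_root) * q10f[t], gross)
      net <- gross - maint
      # partition
      fl <- tb[1L]; fs <- tb[2L]; fo <- tb[3L]
      if (abs(fl + fs + fo - 1) > 1e-6)
        stop("partition fractions sum to ", format(fl + fs + fo),
             " at DVS ", format(DVS), call. = FALSE)
      fr <- min(max(tb[4L], 0), 1)
      shoot <- net * (1 - fr)
      dwl <- CVL * fl * shoot
      dws <- CVS * fs * shoot
      dwo <- CVO * fo * shoot
      dwr <- CVR * fr * net
      W_stem <- W_stem + dws; W_so <- W_so + dwo; W_root <- W_root + dwr
      # leaf cohorts: age, senesce, grow
      if (co_hi >= co_lo) {
        rng <- co_lo:co_hi
        co_age[rng] <- co_age[rng] + max(0, aging_day[t])
        while (co_lo <= co_hi && co_age[co_lo] > SPAN) {
          W_leaf_dead <- W_leaf_dead + co_mass[co_lo]
          W_leaf <- W_leaf - co_mass[co_lo]
          co_lo <- co_lo + 1L
        }
      }
      lai_live <- if (co_hi >= co_lo) sum(co_area[co_lo:co_hi]) else 0
      darea <- dwl * tb[5L]
      if (DVS < 0.3 && lai_live > 0)
        darea <- min(lai_live * (exp(RGRLAI * efft[t]) - 1), darea)
      if (dwl > 0) {
        co_hi <- co_hi + 1L
        co_mass[co_hi] <- dwl; co_area[co_hi] <- darea; co_age[co_hi] <- 0
        W_leaf <- W_leaf + dwl
      }
      LAI <- if (co_hi >= co_lo) sum(co_area[co_lo:co_hi]) else 0
      # pod area
      PAI <- if (DVS >= 1) SPA * W_so else 0
      TPAI <- LAI + PAI
    }
    wb <- water_core(soil_water, TPAI, SOIL_CAP, tmean,
                     tmaxv[t] - tminv[t], geo$angot_kj[t], precipv[t])
    soil_water <- wb$soil_water; stress <- wb$stress

    out[t, ] <- c(DVS, LAI, PAI, TPAI, W_so,
                  W_leaf + W_leaf_dead + W_stem + W_so,
                  W_leaf, W_leaf_dead, W_stem, W_so, W_root,
                  gross, maint, dwl, dws, dwo, dwr,
                  soil_water, stress, wb$rain_cm, wb$loss_cm, wb$drain_cm)
    if (DVS >= 2) { last <- t; break }
  }

  trace <- data.frame(date = days[seq_len(last)],
                      out[seq_len(last), , drop = FALSE])
  structure(trace, params = params, mode = mode,
            interception = interception, lat = lat,
            maturity_date = if (DVS >= 2) days[last] else as.Date(NA),
            class = c("crop_trace", "data.frame"))
}

#' @export
print.crop_trace <- function(x, ...) {
  cat("Crop growth trace: ", nrow(x), " days ", format(min(x$date)), " .. ",
      format(max(x$date)), "  [", attr(x, "mode"), ", ",
      attr(x, "interception"), " interception]\n", sep = "")
  cat(sprintf("  final DVS %.3f, max TPAI %.2f, TWSO %.0f kg/ha, TAGP %.0f kg/ha\n",
              x$DVS[nrow(x)], max(x$TPAI), x$TWSO[nrow(x)],
              x$TAGP[nrow(x)]))
  invisible(x)
}

#' @export
`[.crop_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' Write a simulation trace as tidy CSV
#'
#' @param trace A \code{crop_trace}.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)[, c("date", "DVS", "LAI", "PAI", "TPAI",
                                 "TWSO", "TAGP", "soil_water")]
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
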