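#' Seeded synthetic weather generator
#'
#' Generates a daily weather series with the seasonal statistics of the
#' study region (southern-Hunan winter rape season): sinusoidal seasonal
#' temperature with AR(1) day-to-day noise, Bernoulli-gamma precipitation,
#' truncated-normal sunshine bounded by day length, and near-constant
#' vapour pressure and wind.  The seasonal temperature shape is centred so
#' that the window mean equals the requested mean.
#'
#' @param tmin_mean,tmax_mean Window-mean daily minimum / maximum
#'   temperature, C (defaults: the Hengyang station means 9.87 / 16.89).
#' @param temp_amplitude Seasonal half-amplitude, C.
#' @param ar1 AR(1) coefficient of the temperature noise.
#' @param temp_sd Innovation SD of the temperature noise, C.
#' @param precip_mean Mean daily precipitation, mm (default 1.92).
#' @param wet_prob Probability of a wet day.
#' @param sunshine_mean Mean daily sunshine, h (default 3.08).
#' @param sunshine_sd SD of daily sunshine, h.
#' @param vap_mean Mean vapour pressure, kPa (default 1.60).
#' @param vap_sd Day-to-day SD of vapour pressure, kPa.
#' @param wind_mean Mean wind speed, m/s (default 2.33).
#' @param wind_sd Day-to-day SD of wind speed, m/s.
#' @param start,end Window dates (default 2020-10-01 .. 2021-05-31).
#' @param station Station metadata (default: the Hengyang coordinates).
#' @param seed Integer seed; the series is a pure function of the spec.
#' @return A \code{weather_gen_spec} list, or (from [generate_weather()]) a
#'   \code{weather_series}.
#' @export
weather_gen_spec <- function(tmin_mean = 9.87, tmax_mean = 16.89,
                             temp_amplitude = 6, ar1 = 0.6, temp_sd = 1.5,
                             precip_mean = 1.92, wet_prob = 0.35,
                             sunshine_mean = 3.08, sunshine_sd = 2,
                             vap_mean = 1.60, vap_sd = 0.1,
                             wind_mean = 2.33, wind_sd = 0.5,
                             start = "2020-10-01", end = "2021-05-31",
                             station = list(name = "synthetic-hengyang",
                                            lon = 112.37, lat = 26.98),
                             seed = 1L) {
  stopifnot(temp_amplitude >= 0, wet_prob >= 0, wet_prob <= 1,
            tmax_mean >= tmin_mean)
  spec <- as.list(environment())
  class(spec) <- "weather_gen_spec"
  spec
}

#' @rdname weather_gen_spec
#' @param spec A \code{weather_gen_spec}.
#' @export
generate_weather <- function(spec) {
  stopifnot(inherits(spec, "weather_gen_spec"))
  dates <- seq(as.Date(spec$start), as.Date(spec$end), by = "day")
  n <- length(dates)
  if (n < 30) stop("weather window shorter than 30 days", call. = FALSE)
  doy <- as.integer(strftime(dates, "%j"))
  # coldest around mid-January (doy 15); centred over the window
  shape <- -cos(2 * pi * (doy - 15) / 365.25)
  shape <- shape - mean(shape)
  seas <- spec$temp_amplitude * shape

  rng <- local_rng(spec$seed)
  noise <- numeric(n)
  z <- rng$norm(n)
  if (spec$temp_sd > 0) {
    noise[1] <- z[1] * spec$temp_sd / sqrt(1 - spec$ar1^2)
    for (t in seq_len(n)[-1])
      noise[t] <- spec$ar1 * noise[t - 1] + z[t] * spec$temp_sd
    noise <- noise - mean(noise)
  }
  tmin <- spec$tmin_mean + seas + noise
  spread <- pmax(0.5, (spec$tmax_mean - spec$tmin_mean) +
                   rng$norm(n) * spec$temp_sd * 0.5)
  spread <- spread - mean(spread) + (spec$tmax_mean - spec$tmin_mean)
  tmax <- tmin + pmax(spread, 0.2)

  wet <- rng$unif(n) < spec$wet_prob
  amount <- if (spec$wet_prob > 0)
    rng$gamma(n, shape = 0.8) * (spec$precip_mean / spec$wet_prob / 0.8)
  else numeric(n)
  precip <- ifelse(wet, amount, 0)
  # recentre the realized wet-day totals so the window mean matches the
  # spec (daily precipitation is too skewed for a 200-day mean to land
  # close on its own)
  if (any(precip > 0) && spec$precip_mean > 0)
    precip <- precip * spec$precip_mean / mean(precip)

  dl <- day_length(dates, spec$station$lat)
  sun <- spec$sunshine_mean + rng$norm(n) * spec$sunshine_sd
  sunshine <- pmin(pmax(sun, 0), dl)

  vap <- pmax(0.1, spec$vap_mean + rng$norm(n) * spec$vap_sd)
  wind <- pmax(0.1, spec$wind_mean + rng$norm(n) * spec$wind_sd)

  ws <- weather_series(data.frame(date = dates, tmin = tmin, tmax = tmax,
                                  precip = precip, vap = vap, wind = wind,
                                  sunshine = sunshine),
                       station = spec$station)
  dev <- c(tmin = mean(ws$tmin) - spec$tmin_mean,
           tmax = mean(ws$tmax) - spec$tmax_mean)
  ref <- c(spec$tmin_mean, spec$tmax_mean)
  if (any(abs(dev) > 0.1 * pmax(abs(ref), 1)))
    stop("generated window means deviate more than 10% from the spec",
         call. = FALSE)
  ws
}

# Seed-local RNG so generators never disturb the caller's RNG stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(norm = with_state(stats::rnorm),
       unif = with_state(stats::runif),
       gamma = with_state(function(n, shape) stats::rgamma(n, shape = shape)),
       lnorm = with_state(stats::rlnorm))
}

#' Draw a parameter-truth set
#'
#' With \code{draw = FALSE} (default) returns the published single-point
#' calibration means verbatim (SPA 0.00065, TSUM1 701, ...).  With
#' \code{draw = TRUE} each scalar with a published range is drawn uniformly
#' within [min, max] and the partition tables are rebuilt from per-breakpoint
#' draws renormalized so FL + FS + FO = 1 everywhere.
#'
#' @param seed Integer seed (used only when \code{draw = TRUE}).
#' @param draw Draw from the ranges instead of returning the means.
#' @param ... Extra overrides forwarded to [crop_params()].
#' @return A \code{crop_params} object.
#' @export
generate_truth <- function(seed = 1L, draw = FALSE, ...) {
  if (!draw) return(crop_params(...))
  tb <- calib_bounds_table()
  rng <- local_rng(seed)
  vals <- tb$lower + rng$unif(nrow(tb)) * (tb$upper - tb$lower)
  names(vals) <- tb$symbol
  scalars <- c("WAV", "TSUM1", "TSUM2", "TDWI", "SPA", "SPAN",
               "CVL", "CVO", "CVR", "CVS")
  args <- as.list(vals[scalars])
  dvs8 <- c(0, 0.3, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0)
  key <- sprintf("%.2f", dvs8)
  fl <- vals[paste0("FLTB", key)]
  fo <- vals[paste0("FOTB", key)]
  fs <- vals[paste0("FSTB", key)]
  tot <- fl + fs + fo
  tot[tot == 0] <- 1
  args$FLTB <- afgen(dvs8, unname(fl / tot))
  args$FSTB <- afgen(dvs8, unname(fs / tot))
  args$FOTB <- afgen(dvs8, unname(fo / tot))
  do.call(crop_params, c(args, list(...)))
}

#' Generate a synthetic observation campaign
#'
#' Runs the growth engine with a known truth and samples LAI, SAI, TPAI,
#' TWSO and TAGP at five development-stage triggers (the seedling, budding,
#' flowering, milky and maturity campaigns), optionally with multiplicative
#' lognormal noise.  Stages before flowering (DVS < 1) have SAI = 0 and
#' TPAI = LAI, matching how pods are absent from the first three field
#' campaigns.
#'
#' @param truth A \code{crop_params} truth set.
#' @param weather A \code{weather_series}.
#' @param stage_dvs DVS triggers of the five campaigns.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   observation noise (0 = noise-free).
#' @param seed Integer seed for the noise draws.
#' @param mode,interception Engine settings used for the truth run.
#' @return An \code{obs_campaign}: data frame (stage, date, dvs, lai, sai,
#'   tpai, twso, tagp, siliques_present) with attributes \code{sowing},
#'   \code{harvest} (maturity date), \code{truth} and \code{trace}.
#' @export
generate_campaign <- function(truth, weather,
                              stage_dvs = c(0.2, 0.6, 1.0, 1.5, 1.9),
                              noise_cv = 0.05, seed = 1L,
                              mode = "potential", interception = "tpai") {
  stopifnot(length(stage_dvs) >= 2, all(diff(stage_dvs) > 0),
            noise_cv >= 0)
  tr <- run_simulation(truth, weather, mode = mode,
                       interception = interception)
  if (tr$DVS[nrow(tr)] < 2)
    stop("truth run did not reach maturity within the weather window ",
         "(final DVS ", format(tr$DVS[nrow(tr)]), ")", call. = FALSE)
  stage_names <- c("Seedling", "Budding", "Flowering", "Milky", "Maturity")
  if (length(stage_dvs) != 5)
    stage_names <- paste0("Stage", seq_along(stage_dvs))
  # each campaign samples the last day still within its DVS trigger, so
  # the flowering campaign (trigger 1.0) is visited just before pods
  # emerge and carries SAI = 0, like the field protocol's first three
  # pod-free campaigns
  rows <- vapply(stage_dvs, function(d) {
    ok <- which(tr$DVS <= d & tr$DVS > 0)
    if (!length(ok)) NA_integer_ else max(ok)
  }, 0L)
  if (anyNA(rows) || any(diff(rows) <= 0))
    stop("stage triggers outside the simulated DVS range", call. = FALSE)

  rng <- local_rng(seed)
  jitter <- function(x) {
    if (noise_cv == 0) return(x)
    sdlog <- sqrt(log(1 + noise_cv^2))
    x * rng$lnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  lai <- jitter(tr$LAI[rows])
  pods <- tr$DVS[rows] >= 1
  sai <- ifelse(pods, jitter(tr$PAI[rows]), 0)
  obs <- data.frame(stage = stage_names,
                    date = tr$date[rows],
                    dvs = tr$DVS[rows],
                    lai = lai, sai = sai, tpai = lai + sai,
                    twso = jitter(tr$TWSO[rows]),
                    tagp = jitter(tr$TAGP[rows]),
                    siliques_present = pods,
                    stringsAsFactors = FALSE)
  structure(obs, sowing = truth$sowing_date,
            harvest = attr(tr, "maturity_date"), truth = truth, trace = tr,
            class = c("obs_campaign", "data.frame"))
}

#' @export
print.obs_campaign <- function(x, ...) {
  cat("Observation campaign: ", nrow(x), " stages, sown ",
      format(attr(x, "sowing")), ", harvest ", format(attr(x, "harvest")),
      "\n", sep = "")
  print(as.data.frame(x)[, c("stage", "date", "lai", "sai", "tpai",
                             "twso", "tagp")], digits = 4)
  invisible(x)
}

#' Read / write an observation campaign CSV
#'
#' Columns: stage, date, lai, sai, tpai, twso, tagp, siliques_present; the
#' sowing and harvest dates travel as comment-free extra columns repeated on
#' each row.
#'
#' @param campaign An \code{obs_campaign}.
#' @param path File path.
#' @export
write_campaign_csv <- function(campaign, path) {
  df <- as.data.frame(campaign)
  df$date <- format(df$date)
  df$sowing <- format(attr(campaign, "sowing"))
  df$harvest <- format(attr(campaign, "harvest"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_campaign_csv
#' @export
read_campaign_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sowing <- as.Date(df$sowing[1]); harvest <- as.Date(df$harvest[1])
  df$sowing <- NULL; df$harvest <- NULL
  df$date <- as.Date(df$date)
  validate_campaign(structure(df, sowing = sowing, harvest = harvest,
                              class = c("obs_campaign", "data.frame")))
}

validate_campaign <- function(campaign) {
  stopifnot(all(c("stage", "date", "lai", "sai", "tpai", "twso", "tagp",
                  "siliques_present") %in% names(campaign)))
  if (any(diff(as.integer(campaign$date)) <= 0))
    stop("campaign dates must be strictly increasing", call. = FALSE)
  if (any(abs(campaign$tpai - campaign$lai - campaign$sai) > 1e-8))
    stop("campaign must satisfy tpai = lai + sai", call. = FALSE)
  if (any(campaign$sai[!campaign$siliques_present] != 0))
    stop("pre-silique stages must have sai = 0", call. = FALSE)
  campaign
}
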