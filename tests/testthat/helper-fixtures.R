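# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_weather <- function(seed = 1L) {
  key <- paste0("wx", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_weather(weather_gen_spec(seed = seed))
  .fx[[key]]
}

fx_trace <- function(seed = 1L, ...) {
  key <- paste0("tr", seed, paste(c(...), collapse = "_"))
  if (is.null(.fx[[key]]))
    .fx[[key]] <- run_simulation(crop_params(...), fx_weather(seed))
  .fx[[key]]
}

# constant-temperature weather with fixed radiation-friendly sunshine
const_weather <- function(tmin, tmax, days = 250,
                          start = "2020-10-10", lat = 26.98,
                          sunshine = 3, precip = 2) {
  dates <- seq(as.Date(start), by = "day", length.out = days)
  weather_series(
    data.frame(date = dates, tmin = tmin, tmax = tmax, precip = precip,
               vap = 1.6, wind = 2.3, sunshine = sunshine),
    station = list(name = "const", lon = 112.37, lat = lat))
}

# carbon-ledger residual of a trace (relative to gross where gross > 0)
carbon_residual <- function(tr, p) {
  lhs <- tr$gross - tr$maint
  rhs <- tr$dW_leaf / p$CVL + tr$dW_stem / p$CVS + tr$dW_so / p$CVO +
    tr$dW_root / p$CVR
  err <- abs(lhs - rhs)
  rel <- err[tr$gross > 0] / tr$gross[tr$gross > 0]
  max(c(rel, err[tr$gross == 0]))
}

# minimal hand-built campaign around given stage dates
manual_campaign <- function(dates, sowing, harvest,
                            lai = rep(2, length(dates)),
                            sai = rep(0, length(dates)),
                            twso = rep(1000, length(dates)),
                            tagp = rep(3000, length(dates)),
                            stages = c("Seedling", "Budding", "Flowering",
                                       "Milky", "Maturity")) {
  structure(
    data.frame(stage = stages[seq_along(dates)], date = as.Date(dates),
               dvs = NA_real_, lai = lai, sai = sai, tpai = lai + sai,
               twso = twso, tagp = tagp, siliques_present = sai > 0,
               stringsAsFactors = FALSE),
    sowing = as.Date(sowing), harvest = as.Date(harvest),
    class = c("obs_campaign", "data.frame"))
}
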