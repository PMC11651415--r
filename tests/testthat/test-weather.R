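test_that("weather CSV survives a write/read round trip field for field", {
  ws <- fx_weather(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(ws, path)
  back <- read_weather_csv(path, station = attr(ws, "station"))
  expect_equal(as.data.frame(back), as.data.frame(ws), tolerance = 1e-12)

  small <- data.frame(date = as.Date("2021-03-01") + 0:2,
                      tmin = c(5, 6, 7), tmax = c(12, 13, 11),
                      precip = c(0, 2.5, 0), vap = 1.5, wind = 2,
                      sunshine = c(3, 0, 8))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(weather_series(small), p2)
  rt <- read_weather_csv(p2)
  expect_equal(nrow(rt), 3)
  expect_true(all(diff(rt$date) == 1))
})

test_that("weather validation rejects physical impossibilities", {
  base <- data.frame(date = as.Date("2021-03-01") + 0:2,
                     tmin = c(5, 6, 7), tmax = c(12, 5, 11),
                     precip = 0, vap = 1.5, wind = 2, sunshine = 3)
  expect_error(weather_series(base), "row 2")
  base$tmax <- c(12, 13, 11)
  dup <- base; dup$date[2] <- dup$date[1]
  expect_error(weather_series(dup), "duplicate|increasing")
  gap <- base; gap$date[3] <- gap$date[3] + 5
  expect_error(weather_series(gap), "gap")
  neg <- base; neg$precip <- c(0, -1, 0)
  expect_error(weather_series(neg), "precip")
  sun <- base; sun$sunshine <- c(3, 25, 3)
  expect_error(weather_series(sun), "sunshine")
})

test_that("Angstrom radiation hits its clear-sky and overcast limits", {
  d <- as.Date("2021-03-15"); lat <- 26.98
  N <- day_length(d, lat)
  r0 <- angstrom_radiation(0, d, lat)
  rN <- angstrom_radiation(N, d, lat)
  expect_equal(rN / r0, (0.25 + 0.5) / 0.25, tolerance = 1e-12)
  expect_error(angstrom_radiation(N + 1, d, lat), "day length")
  expect_error(angstrom_radiation(-1, d, lat), "non-negative")
})

test_that("Angstrom radiation agrees with an independent solar-geometry
          formulation", {
  # FAO-56 style oracle with its own declination and day-length forms
  fao_ra_kj <- function(doy, lat_deg) {
    phi <- lat_deg * pi / 180
    dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
    dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
    ws <- acos(pmin(pmax(-tan(phi) * tan(dec), -1), 1))
    ra <- 24 * 60 / pi * 0.0820 * dr *
      (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))  # MJ
    ra * 1000
  }
  d <- as.Date("2021-03-15"); lat <- 26.98; n <- 3.3
  doy <- as.integer(strftime(d, "%j"))
  ws_fao <- acos(-tan(lat * pi / 180) *
                   tan(0.409 * sin(2 * pi * doy / 365 - 1.39)))
  N_fao <- 24 / pi * ws_fao
  expected <- (0.25 + 0.5 * n / N_fao) * fao_ra_kj(doy, lat)
  got <- angstrom_radiation(n, d, lat)
  expect_equal(got, expected, tolerance = 0.03)
})

test_that("IDW reproduces hand-computed weights and degenerate cases", {
  # single source
  expect_equal(idw_interpolate(list(lon = 0, lat = 0),
                               data.frame(lon = 1, lat = 1, value = 7)), 7)
  # two equidistant sources bracket the target symmetrically
  src <- data.frame(lon = c(0, 0), lat = c(0.5, -0.5), value = c(10, 20))
  expect_equal(idw_interpolate(list(lon = 0, lat = 0), src), 15,
               tolerance = 1e-9)
  # distances 1 km and 2 km along a meridian, power 2:
  # (10/1 + 40/4) / (1 + 1/4) = 16
  km <- 1 / 111.195  # degrees latitude per km (haversine sphere)
  src2 <- data.frame(lon = c(0, 0), lat = c(km, 2 * km),
                     value = c(10, 40))
  expect_equal(idw_interpolate(list(lon = 0, lat = 0), src2, power = 2),
               16, tolerance = 1e-4)
  # exact positional match short-circuits
  src3 <- data.frame(lon = c(0, 3), lat = c(0, 3), value = c(42, 7))
  expect_equal(idw_interpolate(list(lon = 0, lat = 0), src3), 42)
  expect_error(idw_interpolate(list(lon = 0, lat = 0),
                               data.frame(lon = numeric(), lat = numeric(),
                                          value = numeric())),
               "at least one")
})

test_that("IDW is bounded by its sources and scale-invariant in distance", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    src <- data.frame(lon = runif(k, -1, 1), lat = runif(k, -1, 1),
                      value = runif(k, 0, 100))
    pw <- runif(1, 0.5, 4)
    v <- idw_interpolate(list(lon = 0.2, lat = -0.1), src, power = pw)
    expect_gte(v, min(src$value))
    expect_lte(v, max(src$value))
  }
  # doubling all offsets (small angles: distances scale uniformly)
  src <- data.frame(lon = c(0.01, -0.02), lat = c(0.015, 0.005),
                    value = c(3, 9))
  big <- src; big$lon <- 2 * big$lon; big$lat <- 2 * big$lat
  expect_equal(idw_interpolate(list(lon = 0, lat = 0), src),
               idw_interpolate(list(lon = 0, lat = 0), big),
               tolerance = 1e-6)
})

test_that("whole-series IDW interpolation preserves tmax >= tmin", {
  s1 <- fx_weather(1); s2 <- fx_weather(2)
  out <- idw_weather(list(name = "mid", lon = 112.6, lat = 26.8),
                     list(s1, s2))
  expect_true(all(out$tmax >= out$tmin))
  expect_equal(nrow(out), nrow(s1))
  # target collocated with a station returns that station's series
  here <- idw_weather(attr(s1, "station"), list(s1, s2))
  expect_equal(here$tmin, s1$tmin, tolerance = 1e-12)
})
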