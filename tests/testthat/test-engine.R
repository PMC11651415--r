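test_that("AFGEN tables interpolate linearly and clamp at the ends", {
  tb <- afgen(c(0, 2), c(0, 2))
  expect_equal(afgen_eval(tb, 1), 1)
  expect_equal(afgen_eval(tb, -5), 0)
  expect_equal(afgen_eval(tb, 9), 2)
  expect_error(afgen(c(0, 0), c(1, 2)), "increasing")
  expect_error(afgen(1, 1), ">= 2")

  # brute-force segment-search oracle on random tables
  brute <- function(x, y, at) {
    if (at <= x[1]) return(y[1])
    n <- length(x)
    if (at >= x[n]) return(y[n])
    for (i in seq_len(n - 1))
      if (at <= x[i + 1])
        return(y[i] + (y[i + 1] - y[i]) * (at - x[i]) / (x[i + 1] - x[i]))
  }
  set.seed(6)
  for (r in 1:25) {
    x <- sort(runif(sample(2:8, 1), -5, 5))
    while (any(diff(x) == 0)) x <- sort(runif(5, -5, 5))
    y <- rnorm(length(x))
    tb <- afgen(x, y)
    at <- runif(1, -7, 7)
    expect_equal(afgen_eval(tb, at), brute(x, y, at), tolerance = 1e-12)
  }
})

test_that("degree-day phenology crosses flowering exactly at TSUM1", {
  p <- crop_params(TSUM1 = 700, TSUM2 = 700, TBASE = 0)
  st <- list(DVS = 0, tsum1 = 0, tsum2 = 0)
  # constant effective 10 C d: DVS reaches 1 on day 70
  for (d in 1:69) st <- phenology_step(st, p, 10)
  expect_lt(st$DVS, 1)
  st <- phenology_step(st, p, 10)
  expect_equal(st$DVS, 1)
  # at the base temperature development stalls
  st0 <- list(DVS = 0, tsum1 = 0, tsum2 = 0)
  for (d in 1:50) st0 <- phenology_step(st0, p, p$TBASE)
  expect_equal(st0$DVS, 0)
  q <- crop_params(); q$TSUM1 <- -1
  expect_error(phenology_step(st, q, 10), "positive")
})

test_that("daily assimilation vanishes without light or canopy and is
          linear in light when AMAX is unbounded", {
  p <- crop_params()
  wd <- list(date = as.Date("2021-03-01"), tmin = 8, tmax = 16,
             radiation = 0)
  expect_equal(daily_gross_assimilation(3, p, 1, wd, 26.98), 0)
  wd$radiation <- 12000
  expect_equal(daily_gross_assimilation(0, p, 1, wd, 26.98), 0)
  expect_error(daily_gross_assimilation(3, p, 1,
                                        within(wd, radiation <- -1), 26.98),
               "negative")

  # AMAX -> Inf: leaf response becomes EFF * absorbed light; compare the
  # Gaussian canopy integral against the exact exponential-profile integral
  tpai <- 0.5; kdif <- 0.6; eff <- 0.45
  pbig <- crop_params(AMAXTB = afgen(c(0, 2), c(1e9, 1e9)),
                      TMPFTB = afgen(c(0, 40), c(1, 1)),
                      EFFTB = afgen(c(0, 40), c(eff, eff)),
                      KDIFTB = afgen(c(0, 2), c(kdif, kdif)))
  got <- daily_gross_assimilation(tpai, pbig, 1, wd, 26.98)
  geo <- tpaicrop:::solar_geometry(wd$date, 26.98)
  exact <- 0
  xg <- c(0.1127016653792583, 0.5, 0.8872983346207417)
  wg <- c(0.2777777777777778, 0.4444444444444444, 0.2777777777777778)
  for (i in 1:3) {
    hour <- 12 + 0.5 * geo$daylength * xg[i]
    sinb <- max(0, geo$sinld + geo$cosld * cos(2 * pi * (hour + 12) / 24))
    par <- 0.5 * wd$radiation * 1000 * sinb * (1 + 0.4 * sinb) / geo$dsinbe
    exact <- exact + wg[i] * eff * par * (1 - exp(-kdif * tpai))
  }
  exact <- exact * geo$daylength * 30 / 44
  expect_equal(got, exact, tolerance = 0.01)
})

test_that("maintenance respiration scales with mass, temperature and cap", {
  p <- crop_params(RML = 0.03, RMO = 0, RMR = 0, RMS = 0)
  st <- list(W_leaf = 1000, W_stem = 0, W_so = 0, W_root = 0)
  expect_equal(maintenance_respiration(st, p, 25), 30)
  expect_equal(maintenance_respiration(st, p, 35), 60)   # Q10 = 2
  expect_equal(maintenance_respiration(st, p, 25, gross = 10), 10)
  st0 <- list(W_leaf = 0, W_stem = 0, W_so = 0, W_root = 0)
  expect_equal(maintenance_respiration(st0, p, 25), 0)
})

test_that("partitioning conserves assimilate through the conversion step", {
  p <- crop_params()
  dW <- partition_and_grow(p, 0.5, 100)
  expect_equal(dW$dW_leaf / p$CVL + dW$dW_stem / p$CVS +
                 dW$dW_so / p$CVO + dW$dW_root / p$CVR, 100,
               tolerance = 1e-12)
  # degenerate storage-only partition sends all shoot growth to pods
  po <- crop_params(FLTB = afgen(c(0, 2), c(0, 0)),
                    FSTB = afgen(c(0, 2), c(0, 0)),
                    FOTB = afgen(c(0, 2), c(1, 1)),
                    FRTB = afgen(c(0, 2), c(0, 0)))
  dWo <- partition_and_grow(po, 1.2, 50)
  expect_equal(dWo$dW_so, po$CVO * 50)
  expect_equal(dWo$dW_leaf + dWo$dW_stem + dWo$dW_root, 0)
  # a broken partition table is refused
  bad <- crop_params()
  bad$FOTB$y[3] <- bad$FOTB$y[3] + 0.2
  expect_error(partition_and_grow(bad, 0.7, 10), "sum")
  expect_error(partition_and_grow(p, 0.5, -1), "non-negative")
})

test_that("lossless conversion makes dry-matter gain equal net assimilate", {
  p <- crop_params(CVL = 1, CVO = 1, CVR = 1, CVS = 1)
  tr <- run_simulation(p, fx_weather(1))
  gain <- tr$dW_leaf + tr$dW_stem + tr$dW_so + tr$dW_root
  expect_equal(gain, tr$gross - tr$maint, tolerance = 1e-12)
})

test_that("leaf cohorts conserve mass between living and dead pools", {
  p <- crop_params()
  tr <- fx_trace(1)
  k <- nrow(tr)
  first <- which(tr$W_leaf > 0)[1]
  init_leaf <- tr$W_leaf[first] - tr$dW_leaf[first]
  expect_equal(tr$W_leaf[k] + tr$W_leaf_dead[k],
               init_leaf + sum(tr$dW_leaf), tolerance = 1e-9)
  expect_true(any(tr$W_leaf_dead > 0) || max(tr$DVS) < 2)
  # stasis: no growth, young cohorts -> LAI unchanged
  st <- list(DVS = 0.5, cohort_mass = c(10, 5), cohort_area = c(0.02, 0.01),
             cohort_age = c(1, 2), W_leaf = 15, W_leaf_dead = 0, LAI = 0.03)
  st2 <- leaf_dynamics(st, p, 10, 0)
  expect_equal(st2$LAI, 0.03)
  expect_equal(st2$W_leaf_dead, 0)
  # a cohort aged past SPAN moves to the dead pool the same day
  st$cohort_age <- c(p$SPAN + 0.5, 2)
  st3 <- leaf_dynamics(st, p, 10, 0)
  expect_equal(st3$W_leaf_dead, 10)
  expect_equal(st3$W_leaf, 5)
  expect_equal(st3$LAI, 0.01)
})

test_that("pod area follows SPA * storage mass once pods exist", {
  p <- crop_params(SPA = 0.00065)
  st <- list(DVS = 1.4, W_so = 4000, LAI = 2)
  st <- pod_area_update(st, p)
  expect_equal(st$PAI, 2.6)
  expect_equal(st$TPAI, 4.6)
  st$DVS <- 0.8
  expect_equal(pod_area_update(st, p)$PAI, 0)
  # PAI never decreases while storage mass accumulates
  tr <- fx_trace(1)
  grow <- diff(tr$W_so) >= 0
  expect_true(all(diff(tr$PAI)[grow] >= 0))
})

test_that("the engine closes its carbon and water ledgers daily", {
  for (s in 1:5) {
    p <- generate_truth(seed = s, draw = TRUE)
    tr <- run_simulation(p, fx_weather(s))
    expect_lt(carbon_residual(tr, p), 1e-9)
    expect_true(all(diff(tr$DVS) >= 0))
    expect_equal(tr$TPAI, tr$LAI + tr$PAI)
    expect_true(all(tr$TWSO <= tr$TAGP + 1e-9))
    expect_true(all(as.matrix(tr[, c("LAI", "PAI", "TWSO", "TAGP",
                                     "W_root", "soil_water")]) >= 0))
    dsw <- diff(tr$soil_water)
    bal <- (tr$rain_cm - tr$loss_cm - tr$drain_cm)[-1]
    expect_equal(dsw, bal, tolerance = 1e-9)
  }
})

test_that("with SPA = 0 the engine collapses to the leaf-only model", {
  p0 <- crop_params(SPA = 0)
  tr <- run_simulation(p0, fx_weather(1))
  expect_equal(tr$PAI, rep(0, nrow(tr)))
  expect_equal(tr$TPAI, tr$LAI)
  tr_lai <- run_simulation(p0, fx_weather(1), interception = "lai")
  expect_equal(tr$TWSO, tr_lai$TWSO, tolerance = 1e-12)
  expect_equal(tr$LAI, tr_lai$LAI, tolerance = 1e-12)
})

test_that("identical inputs give bit-identical traces and SPA raises yield", {
  a <- run_simulation(crop_params(), fx_weather(4))
  b <- run_simulation(crop_params(), fx_weather(4))
  expect_identical(as.data.frame(a), as.data.frame(b))
  twso <- vapply(c(0.0002, 0.00065, 0.0009), function(spa) {
    tr <- run_simulation(crop_params(SPA = spa), fx_weather(4))
    tr$TWSO[nrow(tr)]
  }, 0)
  expect_true(all(diff(twso) >= 0))
})

test_that("water-limited mode responds to drought while potential ignores it", {
  dry <- const_weather(12, 22, days = 250, precip = 0, sunshine = 6)
  p <- crop_params(WAV = 20, SOIL_CAP = 55)
  pot <- run_simulation(p, dry, mode = "potential")
  expect_true(all(pot$stress <= 1))
  wet <- run_simulation(p, dry, mode = "water-limited")
  # zero rain and positive demand: storage drains monotonically to the floor
  sw <- wet$soil_water
  expect_true(all(diff(sw) <= 1e-12))
  expect_lt(min(wet$stress), 1)
  expect_lte(wet$TWSO[nrow(wet)], pot$TWSO[nrow(pot)])
})

test_that("a weather gap inside the window is refused", {
  wx <- fx_weather(1)
  expect_error(run_simulation(crop_params(), wx,
                              window = c(min(wx$date),
                                         max(wx$date) + 30)),
               "cover")
})
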