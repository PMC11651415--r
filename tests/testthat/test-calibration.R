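test_that("phenology calibration recovers temperature sums from stage dates", {
  # constant Tmean 10 C, bases 0/3: emergence after ceiling(20/7) = 3 days,
  # flowering 70 days later gives TSUM1 = 700
  wx <- const_weather(5, 15, days = 250)
  sow <- as.Date("2020-10-10")
  emergence <- sow + 2              # cumulative 7, 14, 21 >= TSUMEM = 20
  dates <- emergence + c(10, 30, 70, 100, 130)
  camp <- manual_campaign(dates, sowing = sow, harvest = emergence + 140,
                          sai = c(0, 0, 0, 1, 1))
  p <- calibrate_phenology(camp, wx, crop_params())
  # the estimate is centred within the crossing day, so it can differ from
  # the plain sum by at most one day's effective temperature (10 C d)
  expect_lte(abs(p$TSUM1 - 700), 5)
  expect_lte(abs(p$TSUM2 - 700), 10)

  # degenerate interval: flowering coincides with emergence
  camp0 <- manual_campaign(emergence + c(-2, -1, 0, 30, 60),
                           sowing = sow, harvest = emergence + 100,
                           sai = c(0, 0, 0, 1, 1))
  expect_error(calibrate_phenology(camp0, wx, crop_params()),
               "follow emergence")
  # missing flowering stage
  camp1 <- camp; camp1$stage[3] <- "Podding"
  expect_error(calibrate_phenology(camp1, wx, crop_params()),
               "Flowering")
})

test_that("phenology round-trips through the engine within a day's warmth", {
  truth <- crop_params()
  wx <- fx_weather(5)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 5)
  p <- calibrate_phenology(obs, wx, crop_params())
  tmean <- (wx$tmin + wx$tmax) / 2
  max_eff <- max(pmax(0, tmean - truth$TBASE))
  expect_lt(abs(p$TSUM1 - truth$TSUM1), max_eff)
  expect_lt(abs(p$TSUM2 - truth$TSUM2), max_eff)
})

test_that("the quadratic anchor fit interpolates exactly", {
  mk_trace <- function(dates, lai, tpai = lai)
    data.frame(date = as.Date(dates), LAI = lai, TPAI = tpai)
  # anchors (0, 0), (1, 1), (2, 4) -> y = t^2
  d0 <- as.Date("2021-01-01")
  # LAI peaks on the first day; the TPAI there is the first anchor value 0
  tr <- mk_trace(d0 + 0:2, lai = c(0.5, 0.1, 0.05),
                 tpai = c(0, 0.1, 0.05))
  camp <- manual_campaign(d0 + 1:2, sowing = d0 - 100, harvest = d0 + 3,
                          lai = c(0, 0), sai = c(1, 4),
                          stages = c("Milky", "Maturity"))
  cv <- fit_tpai_quadratic(tr, camp)
  expect_equal(unname(attr(cv, "coef")), c(0, 0, 1))
  expect_equal(cv$tpai, c(0, 1, 4))

  # collinear anchors recover a line (zero curvature)
  camp2 <- manual_campaign(d0 + 1:2, sowing = d0 - 100, harvest = d0 + 3,
                           lai = c(0, 0), sai = c(1, 2),
                           stages = c("Milky", "Maturity"))
  cv2 <- fit_tpai_quadratic(tr, camp2)
  expect_equal(unname(attr(cv2, "coef"))[3], 0, tolerance = 1e-12)

  # random distinct anchors: the curve passes through all three to 1e-10
  set.seed(8)
  for (r in 1:20) {
    tt <- sort(sample(0:40, 3))
    while (anyDuplicated(tt)) tt <- sort(sample(0:40, 3))
    y <- runif(3, 0.5, 6)
    trc <- mk_trace(d0 + c(tt[1], tt[1] + 41), c(y[1], y[1] - 1),
                    c(y[1], y[1] - 1))
    cr <- manual_campaign(d0 + tt[2:3], sowing = d0 - 100,
                          harvest = d0 + 60,
                          lai = c(0, 0), sai = y[2:3],
                          stages = c("Milky", "Maturity"))
    cvr <- fit_tpai_quadratic(trc, cr)
    a <- attr(cvr, "anchors")
    got <- cvr$tpai[match(a$t, cvr$date)]
    expect_lt(max(abs(got - pmax(a$y, 0))), 1e-10)
  }
})

test_that("baseline LAI calibration is self-consistent on its own output", {
  truth <- crop_params()
  wx <- fx_weather(6)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 6,
                           interception = "lai")
  fit <- calibrate_crop(obs, wx, method = "lai")
  expect_s3_class(fit, "crop_calibration")
  expect_lt(fit$objective, 0.05)
  # fitted parameters respect their declared bounds
  b <- param_bounds(fit$free)
  v <- vapply(fit$free, function(s) get_param(fit$params, s), 0)
  expect_true(all(v >= b$lower - 1e-12 & v <= b$upper + 1e-12))
})

test_that("a single perturbed specific-leaf-area scale is recovered", {
  truth <- crop_params()
  truth$SLATB$y[1] <- truth$SLATB$y[1] * 1.25
  wx <- fx_weather(6)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 9,
                           interception = "lai")
  fit <- calibrate_crop(obs, wx, method = "lai", free = "SLATB0.00",
                        control = list(maxit = 60, factr = 1e8))
  expect_lt(abs(get_param(fit$params, "SLATB0.00") - truth$SLATB$y[1]) /
              truth$SLATB$y[1], 0.05)
})

test_that("TPAI-SPA recovers the specific pod area in a twin experiment", {
  truth <- crop_params()          # SPA = 0.00065
  wx <- fx_weather(7)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 7)
  fit <- calibrate_crop(obs, wx, method = "tpai-spa")
  expect_lt(abs(get_param(fit$params, "SPA") - 0.00065), 5e-4)
  # the line search only ever accepts improving steps
  expect_true(all(diff(fit$spa_search$objective) <= 1e-12))
  # a campaign with no pod-bearing stage cannot drive the SPA search
  cw <- const_weather(5, 15, days = 250)
  sow <- as.Date("2020-10-10")
  nopods <- manual_campaign(sow + c(15, 40, 75, 105, 135), sowing = sow,
                            harvest = sow + 145)
  expect_error(calibrate_crop(nopods, cw, method = "tpai-spa"),
               "pod-bearing")
})

test_that("a truth at the preset SPA needs no line-search steps", {
  truth <- crop_params(SPA = 0.007)
  wx <- fx_weather(8)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 8)
  fit <- calibrate_crop(obs, wx, method = "tpai-spa",
                        control = list(maxit = 4))
  expect_equal(fit$spa_search$spa[1], 0.007)
  expect_lte(nrow(fit$spa_search), 2)
})

test_that("TPAI-Curve matches an engine-generated calibration curve", {
  truth <- crop_params()
  wx <- fx_weather(7)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 7)
  tr <- attr(obs, "trace")
  sel <- tr$DVS >= 0.9 & tr$DVS <= 2
  cv <- structure(data.frame(date = tr$date[sel], tpai = tr$TPAI[sel]),
                  class = c("tpai_curve", "data.frame"))
  fit <- calibrate_crop(obs, wx, method = "tpai-curve", curve = cv,
                        control = list(maxit = 60, factr = 1e8))
  expect_lt(fit$objective, 0.02)
  expect_lt(abs(get_param(fit$params, "SPA") - 0.00065), 5e-4)
})

test_that("calibration objects expose the standard modelling interface", {
  truth <- crop_params()
  wx <- fx_weather(7)
  obs <- generate_campaign(truth, wx, noise_cv = 0, seed = 7)
  fit <- calibrate_crop(obs, wx, method = "tpai-spa",
                        control = list(maxit = 6))
  expect_named(coef(fit), c("TSUM1", "TSUM2", fit$free))
  s <- summary(fit)
  expect_true(all(c("TPAI", "TWSO", "TAGP") %in% rownames(s$metrics)))
  tr <- predict(fit)
  expect_s3_class(tr, "crop_trace")
  r <- residuals(fit)
  expect_equal(nrow(r), nrow(obs))
  expect_equal(r$tpai, fit$residuals$tpai_obs - fit$residuals$tpai_sim)
  f <- fitted(fit)
  expect_equal(nrow(f), nrow(obs))
  expect_output(print(fit), "TPAI-SPA")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
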