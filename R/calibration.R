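#' Calibrate the rape growth model against an observation campaign
#'
#' Fits crop parameters to stage-dated field (or synthetic) observations by
#' one of three strategies:
#' \describe{
#'   \item{\code{"lai"}}{the traditional baseline: phenology from the stage
#'     dates, then bounded least squares on the free parameters against the
#'     LAI observations, with the engine in leaf-only interception mode.
#'     Pod photosynthesis is ignored, which is what underestimates yield
#'     for a pod-bearing crop.}
#'   \item{\code{"tpai-spa"}}{phenology, then a line search on the specific
#'     pod area SPA (preset 0.007, steps of 0.0005 by default, direction
#'     set by the sign of the TPAI misfit at the pod-bearing stages,
#'     stopping when the misfit stops improving), then bounded least
#'     squares of the free set against the TPAI observations at every
#'     stage.}
#'   \item{\code{"tpai-curve"}}{phenology and an LAI-matching step as for
#'     the baseline (with pod interception active), then a quadratic TPAI
#'     calibration curve anchored at the simulated-LAI peak, the highest
#'     later TPAI observation and the final pre-harvest observation, then
#'     bounded least squares matching the simulated TPAI to that curve
#'     daily over the anchor span plus the pre-peak LAI residuals.}
#' }
#'
#' @param campaign An \code{obs_campaign} (see [generate_campaign()] /
#'   [read_campaign_csv()]).
#' @param weather A \code{weather_series} covering sowing to harvest.
#' @param params0 Starting \code{crop_params} (defaults to
#'   [crop_params()]).
#' @param method \code{"lai"}, \code{"tpai-spa"} or \code{"tpai-curve"}.
#' @param free Character vector of free parameter symbols; default is the
#'   sensitivity top set \code{KDIFTB2.00, EFFTB0.00, SPA, FSTB1.70, CVO,
#'   EFFTB40.00, SLATB0.00} (SPA dropped for the \code{"lai"} baseline,
#'   where it has no effect on light interception).
#' @param curve Optional \code{tpai_curve} to calibrate against (method
#'   \code{"tpai-curve"}); when supplied the anchored-quadratic
#'   construction is skipped.
#' @param control List of optimizer settings: \code{maxit} (default 20),
#'   \code{spa_preset} (0.007), \code{spa_step} (0.0005, the finer end of
#'   the documented 0.0005--0.001 range), \code{factr} (1e12).
#' @param mode Production mode passed to the engine.
#' @return An object of class \code{crop_calibration} with components
#'   \code{method}, \code{params} (fitted set), \code{params0},
#'   \code{objective} (RMSE in index units), \code{free}, \code{residuals}
#'   (per-stage observed/simulated table), \code{iterations} (log), and
#'   supporting data.  Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{plot}.
#' @examples
#' \donttest{
#' wx <- generate_weather(weather_gen_spec(seed = 7))
#' obs <- generate_campaign(crop_params(), wx, noise_cv = 0, seed = 7)
#' fit <- calibrate_crop(obs, wx, method = "tpai-spa")
#' coef(fit)["SPA"]
#' }
#' @export
calibrate_crop <- function(campaign, weather, params0 = crop_params(),
                           method = c("lai", "tpai-spa", "tpai-curve"),
                           free = NULL, curve = NULL, control = list(),
                           mode = "potential") {
  method <- match.arg(method)
  validate_campaign(campaign)
  weather <- ensure_radiation(weather)
  ctl <- utils::modifyList(list(maxit = 20, spa_preset = 0.007,
                                spa_step = 5e-4, factr = 1e12), control)
  if (is.null(free)) {
    free <- c("KDIFTB2.00", "EFFTB0.00", "SPA", "FSTB1.70", "CVO",
              "EFFTB40.00", "SLATB0.00")
    if (method == "lai") free <- setdiff(free, "SPA")
  }
  fit <- switch(method,
    "lai" = calibrate_baseline_lai(campaign, weather, params0, free, ctl),
    "tpai-spa" = tpai_spa_calibrate(campaign, weather, params0, free, ctl),
    "tpai-curve" = tpai_curve_calibrate(campaign, weather, params0, free,
                                        ctl, curve = curve))
  fit$campaign <- campaign
  fit$weather <- weather
  fit$mode <- mode
  tr <- run_simulation(fit$params, weather,
                       interception = fit$interception, mode = mode)
  fit$trace <- tr
  rows <- match(campaign$date, tr$date)
  rows[is.na(rows)] <- nrow(tr)   # dates past maturity: final state
  fit$residuals <- data.frame(
    stage = campaign$stage, date = campaign$date,
    lai_obs = campaign$lai, lai_sim = tr$LAI[rows],
    tpai_obs = campaign$tpai, tpai_sim = tr$TPAI[rows],
    twso_obs = campaign$twso, twso_sim = tr$TWSO[rows],
    tagp_obs = campaign$tagp, tagp_sim = tr$TAGP[rows])
  class(fit) <- "crop_calibration"
  fit
}

# ---- building blocks -----------------------------------------------------

#' Phenology calibration from stage dates
#'
#' Recovers the temperature sums from the campaign calendar: TSUM1 is the
#' effective temperature (base TBASE) accumulated from emergence (sowing
#' plus TSUMEM degree-days over TBASEM) to the flowering-stage date, TSUM2
#' from flowering to the harvest/maturity date (the recorded harvest date
#' when present, else the maturity-stage date).  Estimates falling outside
#' the published calibration ranges are clamped with a warning.
#'
#' @param campaign An \code{obs_campaign}.
#' @param weather A \code{weather_series}.
#' @param params A \code{crop_params} (supplies TBASE, TBASEM, TSUMEM).
#' @return The parameter set with fitted \code{TSUM1}, \code{TSUM2}.
#' @export
calibrate_phenology <- function(campaign, weather, params) {
  flower <- campaign$date[campaign$stage == "Flowering"]
  if (!length(flower))
    stop("campaign has no Flowering stage", call. = FALSE)
  maturity <- attr(campaign, "harvest")
  if (is.null(maturity) || is.na(maturity))
    maturity <- campaign$date[campaign$stage == "Maturity"]
  if (!length(maturity) || is.na(maturity))
    stop("campaign has no Maturity stage or harvest date", call. = FALSE)
  sowing <- attr(campaign, "sowing")
  if (is.null(sowing) || is.na(sowing))
    stop("campaign has no sowing date", call. = FALSE)
  d <- weather$date
  tmean <- (weather$tmin + weather$tmax) / 2
  em_sum <- cumsum(ifelse(d >= sowing, pmax(0, tmean - params$TBASEM), 0))
  emergence <- d[which(em_sum >= params$TSUMEM)[1]]
  if (is.na(emergence))
    stop("emergence not reached within the weather series", call. = FALSE)
  if (flower <= emergence)
    stop("flowering date does not follow emergence", call. = FALSE)
  if (maturity <= flower)
    stop("maturity date does not follow flowering", call. = FALSE)
  eff <- pmax(0, tmean - params$TBASE)
  # the stage calendar brackets each crossing within one day; centring the
  # estimate half a day into the crossing day keeps the simulated stage
  # strictly pre-flowering on the flowering-visit date
  eff_next <- eff[match(flower + 1, d)]
  if (is.na(eff_next)) eff_next <- mean(eff[d > emergence & d <= flower])
  eff_mat <- eff[match(maturity, d)]
  if (is.na(eff_mat)) eff_mat <- eff_next
  tsum1 <- sum(eff[d > emergence & d <= flower]) + eff_next / 2
  tsum2 <- sum(eff[d > flower & d <= maturity]) - eff_next / 2 -
    eff_mat / 2
  b <- calib_bounds_table()
  clamp <- function(v, sym) {
    k <- match(sym, b$symbol)
    if (v < b$lower[k] || v > b$upper[k]) {
      warning(sym, " estimate ", round(v), " outside [", b$lower[k], ", ",
              b$upper[k], "]; clamped", call. = FALSE)
      v <- min(max(v, b$lower[k]), b$upper[k])
    }
    v
  }
  params$TSUM1 <- clamp(tsum1, "TSUM1")
  params$TSUM2 <- clamp(tsum2, "TSUM2")
  params
}

# Bounded least squares over `free` on the unit box via L-BFGS-B.
# objective_fn(params) must return an RMSE-type scalar.
fit_free_set <- function(params, free, objective_fn, ctl) {
  b <- param_bounds(free)
  x0 <- vapply(seq_along(free), function(k) {
    v <- get_param(params, free[k])
    (min(max(v, b$lower[k]), b$upper[k]) - b$lower[k]) /
      (b$upper[k] - b$lower[k])
  }, 0)
  apply_x <- function(x) {
    pr <- params
    for (k in seq_along(free))
      pr <- set_param(pr, free[k],
                      b$lower[k] + x[k] * (b$upper[k] - b$lower[k]))
    pr
  }
  evals <- new.env(); evals$log <- list()
  fn <- function(x) {
    val <- objective_fn(apply_x(x))
    evals$log[[length(evals$log) + 1L]] <- c(x, val)
    val
  }
  ndeps <- if (is.null(ctl$ndeps)) 1e-3 else ctl$ndeps
  opt <- stats::optim(x0, fn, method = "L-BFGS-B",
                      lower = rep(0, length(free)),
                      upper = rep(1, length(free)),
                      control = list(maxit = ctl$maxit, factr = ctl$factr,
                                     ndeps = rep(ndeps, length(free))))
  list(params = apply_x(opt$par), objective = opt$value,
       convergence = opt$convergence, n_eval = length(evals$log))
}

# One engine run per evaluation; returns simulated LAI/TPAI/TWSO/TAGP at
# the campaign dates (dates past maturity carry the final value forward).
sim_at_stages <- function(params, weather, dates, interception) {
  tr <- run_simulation(params, weather, interception = interception)
  idx <- match(dates, tr$date)
  pick <- function(var) {
    v <- tr[[var]][idx]
    v[is.na(v)] <- tr[[var]][nrow(tr)]
    v
  }
  list(trace = tr, LAI = pick("LAI"), TPAI = pick("TPAI"),
       TWSO = pick("TWSO"), TAGP = pick("TAGP"))
}

# Stage TWSO/TAGP residuals as relative errors expressed in TPAI units, so
# the yield information the field campaigns carry can enter an index-scale
# objective on an even footing.
yield_residuals <- function(sim, campaign) {
  scale <- mean(campaign$tpai)
  c((sim$TWSO - campaign$twso) / mean(campaign$twso),
    (sim$TAGP - campaign$tagp) / mean(campaign$tagp)) * scale
}

calibrate_baseline_lai <- function(campaign, weather, params0, free, ctl) {
  params <- calibrate_phenology(campaign, weather, params0)
  obj <- function(pr)
    rmse(campaign$lai,
         sim_at_stages(pr, weather, campaign$date, "lai")$LAI)
  ls <- fit_free_set(params, free, obj, ctl)
  list(method = "lai", params = ls$params, params0 = params0,
       objective = ls$objective, free = free, interception = "lai",
       convergence = ls$convergence,
       iterations = data.frame(step = "lai-ls",
                               objective = ls$objective))
}

tpai_spa_calibrate <- function(campaign, weather, params0, free, ctl) {
  params <- calibrate_phenology(campaign, weather, params0)
  pod <- campaign$siliques_present
  if (!any(pod))
    stop("TPAI-SPA needs at least one pod-bearing stage", call. = FALSE)
  # step a adjusted the development-period parameters above (phenology
  # from the stage calendar); the yield-based adjustment of allocation and
  # conversion parameters happens in the step-c refinement objective.

  # step b: SPA line search from the preset, clamped to (0, 0.01];
  # direction from the sign of the TPAI misfit at the pod-bearing stages
  spa_lo <- 0; spa_hi <- 0.01
  spa <- min(max(ctl$spa_preset, spa_lo), spa_hi)
  step <- ctl$spa_step
  pod_misfit <- function(s) {
    sim <- sim_at_stages(set_param(params, "SPA", s), weather,
                         campaign$date[pod], "tpai")
    sim$TPAI - campaign$tpai[pod]
  }
  m0 <- pod_misfit(spa)
  cur <- sqrt(mean(m0^2))
  dir <- if (mean(m0) > 0) -1 else 1
  log <- data.frame(step = "spa-search", spa = spa, objective = cur)
  repeat {
    cand <- spa + dir * step
    if (cand < spa_lo || cand > spa_hi) break
    val <- sqrt(mean(pod_misfit(cand)^2))
    if (val >= cur) break
    spa <- cand; cur <- val
    log <- rbind(log, data.frame(step = "spa-search", spa = spa,
                                 objective = cur))
  }
  params <- set_param(params, "SPA", spa)

  # step c: refinement of the full free set against the TPAI observations
  # (yield residuals retained so SPA x W_so stays identified)
  obj_c <- function(pr) {
    sim <- sim_at_stages(pr, weather, campaign$date, "tpai")
    sqrt(mean(c(sim$TPAI - campaign$tpai,
                yield_residuals(sim, campaign))^2))
  }
  ls <- fit_free_set(params, free, obj_c, ctl)
  sim <- sim_at_stages(ls$params, weather, campaign$date, "tpai")
  obj_tpai <- rmse(campaign$tpai, sim$TPAI)
  list(method = "tpai-spa", params = ls$params, params0 = params0,
       objective = obj_tpai, free = free, interception = "tpai",
       convergence = ls$convergence, spa_search = log,
       iterations = rbind(log,
                          data.frame(step = "tpai-ls", spa = spa,
                                     objective = obj_tpai)))
}

#' Quadratic TPAI calibration curve from three anchors
#'
#' Builds the TPAI calibration curve of the curve-matching method: the
#' first anchor is the peak of the step-a simulated LAI curve (earliest day
#' on ties), the second the highest observed TPAI after that peak, the
#' third the last observation before harvest.  The unique quadratic through
#' the three anchors is sampled daily over the anchor span and clamped at
#' zero.
#'
#' @param lai_trace A \code{crop_trace} from the LAI-matching step.
#' @param campaign An \code{obs_campaign}.
#' @return A \code{tpai_curve}: data frame (date, tpai) with an
#'   \code{anchors} attribute.
#' @export
fit_tpai_quadratic <- function(lai_trace, campaign) {
  i1 <- which.max(lai_trace$LAI)       # earliest maximum
  t1 <- lai_trace$date[i1]
  # the anchor value is the canopy's TPAI at the LAI peak: identical to the
  # LAI peak value whenever pods are still absent there (the construction's
  # premise), and still a matchable TPAI anchor when they are not
  y1 <- lai_trace$TPAI[i1]
  later <- which(campaign$date > t1)
  if (!length(later))
    stop("no TPAI observation after the simulated LAI peak", call. = FALSE)
  t3 <- campaign$date[max(later)]      # last observation before harvest
  y3 <- campaign$tpai[max(later)]
  mid <- later[campaign$date[later] < t3]
  if (!length(mid)) {
    # late LAI peak: fall back to the latest earlier observation that
    # still leaves a middle anchor available
    idx3 <- max(later)
    if (idx3 >= 3) {
      t1 <- campaign$date[idx3 - 2L]
      i1 <- which(lai_trace$date == t1)
      if (!length(i1)) i1 <- nrow(lai_trace)
      y1 <- lai_trace$TPAI[i1]
      later <- which(campaign$date > t1)
      mid <- later[campaign$date[later] < t3]
    }
  }
  if (!length(mid))
    stop("need an observation between the LAI peak and the final stage",
         call. = FALSE)
  i2 <- mid[which.max(campaign$tpai[mid])]
  t2 <- campaign$date[i2]
  y2 <- campaign$tpai[i2]
  tt <- as.numeric(c(t1, t2, t3) - t1)
  if (anyDuplicated(tt))
    stop("degenerate anchors: anchor times must be distinct", call. = FALSE)
  cf <- solve(cbind(1, tt, tt^2), c(y1, y2, y3))
  dates <- seq(t1, t3, by = "day")
  x <- as.numeric(dates - t1)
  structure(data.frame(date = dates,
                       tpai = pmax(cf[1] + cf[2] * x + cf[3] * x^2, 0)),
            anchors = data.frame(t = c(t1, t2, t3), y = c(y1, y2, y3)),
            coef = cf, class = c("tpai_curve", "data.frame"))
}

tpai_curve_calibrate <- function(campaign, weather, params0, free, ctl,
                                 curve = NULL) {
  params <- calibrate_phenology(campaign, weather, params0)
  # step a: match the simulated LAI to the observed LAI at the stages
  obj_lai <- function(pr)
    rmse(campaign$lai,
         sim_at_stages(pr, weather, campaign$date, "tpai")$LAI)
  step_a <- fit_free_set(params, setdiff(free, "SPA"), obj_lai, ctl)
  params <- step_a$params
  if (is.null(curve)) {
    lai_trace <- run_simulation(params, weather, interception = "tpai")
    curve <- fit_tpai_quadratic(lai_trace, campaign)
  }
  t1 <- curve$date[1]
  pre <- campaign$date < t1
  # step e: align the simulated TPAI with the calibration curve day by day
  # (pre-peak LAI stage residuals and stage yields retained)
  obj_curve <- function(pr) {
    sim <- sim_at_stages(pr, weather, campaign$date, "tpai")
    tr <- sim$trace
    daily <- tr$TPAI[match(curve$date, tr$date)]
    daily[is.na(daily)] <- tr$TPAI[nrow(tr)]
    yres <- yield_residuals(sim, campaign)
    # weight the handful of stage-yield residuals so their block carries
    # weight comparable to the dense daily-curve block
    yres <- yres * sqrt(length(daily) / length(yres))
    res <- c(daily - curve$tpai,
             if (any(pre)) sim$LAI[pre] - campaign$lai[pre],
             yres)
    sqrt(mean(res^2))
  }
  # the temperature sums are polished here on top of the date-based
  # phenology estimate: the daily curve pins development finer than the
  # stage calendar can
  ls <- fit_free_set(params, unique(c(free, "TSUM1", "TSUM2")),
                     obj_curve, ctl)
  tr <- run_simulation(ls$params, weather, interception = "tpai")
  daily <- tr$TPAI[match(curve$date, tr$date)]
  daily[is.na(daily)] <- tr$TPAI[nrow(tr)]
  obj_daily <- sqrt(mean((daily - curve$tpai)^2))
  list(method = "tpai-curve", params = ls$params, params0 = params0,
       objective = obj_daily, free = free, interception = "tpai",
       convergence = ls$convergence, curve = curve,
       iterations = data.frame(step = c("lai-ls", "curve-ls"),
                               objective = c(step_a$objective,
                                             obj_daily)))
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.crop_calibration <- function(x, ...) {
  cat("Crop model calibration (", toupper(x$method), " method)\n", sep = "")
  cat("  objective (RMSE): ", format(x$objective, digits = 4),
      "  [", x$convergence, if (x$convergence == 0) " = converged", "]\n",
      sep = "")
  cat("  fitted: ", paste0(names(coef(x)), " = ",
                           signif(coef(x), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.crop_calibration <- function(object, ...) {
  syms <- c("TSUM1", "TSUM2", object$free)
  vapply(syms, function(s) get_param(object$params, s), 0)
}

#' @export
#' @method summary crop_calibration
summary.crop_calibration <- function(object, ...) {
  r <- object$residuals
  met <- function(obs, sim)
    c(R2 = r_squared(obs, sim), RMSE = rmse(obs, sim),
      NRMSE = nrmse(obs, sim), bias_rate = estimation_bias_rate(obs, sim))
  tab <- rbind(TPAI = met(r$tpai_obs, r$tpai_sim),
               TWSO = met(r$twso_obs, r$twso_sim),
               TAGP = met(r$tagp_obs, r$tagp_sim))
  out <- list(method = object$method, objective = object$objective,
              coef = coef(object), metrics = tab, residuals = r)
  class(out) <- "summary.crop_calibration"
  out
}

#' @export
print.summary.crop_calibration <- function(x, ...) {
  cat("Calibration summary (", toupper(x$method), " method)\n", sep = "")
  cat("  objective (RMSE):", format(x$objective, digits = 4), "\n")
  cat("  stage metrics (observed vs simulated):\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' @export
predict.crop_calibration <- function(object, weather = NULL, ...) {
  if (is.null(weather)) weather <- object$weather
  run_simulation(object$params, weather,
                 interception = object$interception, mode = object$mode)
}

#' @export
fitted.crop_calibration <- function(object, ...) {
  object$residuals[, c("stage", "date", "lai_sim", "tpai_sim", "twso_sim",
                       "tagp_sim")]
}

#' @export
residuals.crop_calibration <- function(object, ...) {
  r <- object$residuals
  data.frame(stage = r$stage, date = r$date,
             lai = r$lai_obs - r$lai_sim,
             tpai = r$tpai_obs - r$tpai_sim,
             twso = r$twso_obs - r$twso_sim,
             tagp = r$tagp_obs - r$tagp_sim)
}

#' @export
plot.crop_calibration <- function(x, which = c("tpai", "twso"), ...) {
  which <- match.arg(which)
  tr <- x$trace; r <- x$residuals
  if (which == "tpai") {
    graphics::plot(tr$date, tr$TPAI, type = "l", xlab = "date",
                   ylab = "TPAI", ...)
    graphics::lines(tr$date, tr$LAI, lty = 2)
    graphics::points(r$date, r$tpai_obs, pch = 19, col = 2)
    if (!is.null(x$curve))
      graphics::lines(x$curve$date, x$curve$tpai, col = 4, lty = 3)
    graphics::legend("topleft", c("simulated TPAI", "simulated LAI",
                                  "observed TPAI"),
                     lty = c(1, 2, NA), pch = c(NA, NA, 19),
                     col = c(1, 1, 2), bty = "n")
  } else {
    graphics::plot(tr$date, tr$TWSO, type = "l", xlab = "date",
                   ylab = "TWSO (kg/ha)", ...)
    graphics::points(r$date, r$twso_obs, pch = 19, col = 2)
  }
  invisible(x)
}
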