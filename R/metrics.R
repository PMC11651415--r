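#' Accuracy metrics for paired observed/simulated series
#'
#' The evaluation metrics used throughout the toolkit: coefficient of
#' determination, root mean square error, normalized RMSE (percent of the
#' observed mean by default) and the aggregate estimation-bias rate
#' (positive values indicate underestimation by the simulation).
#'
#' @param observed,simulated Equal-length numeric vectors (length >= 2 for
#'   \code{r_squared}).
#' @name metrics
NULL

check_pair <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("observed and simulated must have equal length", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(simulated)))
    stop("metrics require finite values", call. = FALSE)
}

#' @rdname metrics
#' @param variant \code{"determination"} (1 - SS_res/SS_tot, default) or
#'   \code{"pearson2"} (squared Pearson correlation).
#' @return \code{r_squared}: dimensionless, <= 1 for the determination form.
#' @export
r_squared <- function(observed, simulated,
                      variant = c("determination", "pearson2")) {
  variant <- match.arg(variant)
  check_pair(observed, simulated)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed series has zero variance; R2 undefined", call. = FALSE)
  if (variant == "pearson2") return(stats::cor(observed, simulated)^2)
  1 - sum((observed - simulated)^2) / ss_tot
}

#' @rdname metrics
#' @return \code{rmse}: same units as the series.
#' @export
rmse <- function(observed, simulated) {
  check_pair(observed, simulated)
  sqrt(mean((observed - simulated)^2))
}

#' @rdname metrics
#' @param normalizer \code{"mean"} (default) or \code{"range"} of the
#'   observed series.
#' @return \code{nrmse}: percent.
#' @export
nrmse <- function(observed, simulated, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  check_pair(observed, simulated)
  den <- if (normalizer == "mean") mean(observed) else diff(range(observed))
  if (den == 0)
    stop("observed ", normalizer, " is zero; NRMSE undefined", call. = FALSE)
  100 * rmse(observed, simulated) / den
}

#' @rdname metrics
#' @return \code{estimation_bias_rate}: percent; positive when the
#'   simulation underestimates the observations on average.
#' @export
estimation_bias_rate <- function(observed, simulated) {
  check_pair(observed, simulated)
  if (mean(observed) == 0)
    stop("observed mean is zero; bias rate undefined", call. = FALSE)
  100 * (mean(observed) - mean(simulated)) / mean(observed)
}
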