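#' Field formulas: organ geometry to canopy indices
#'
#' Helpers that convert caliper measurements and quadrat counts into the
#' quantities used to calibrate the growth model: single-organ areas, the
#' leaf/silique area-index regressions, the total photosynthetic area index
#' (TPAI), plant density, water content and thousand-seed weight.
#'
#' @name canopy_indices
NULL

#' Single leaf area from length and width
#'
#' Rape leaves are treated as ellipses, so area = pi/4 * length * width.
#'
#' @param length,width Leaf dimensions, cm.
#' @return Area, cm^2 (vectorized).
#' @examples
#' leaf_area(10, 4)  # 10 * pi
#' @export
leaf_area <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("leaf length and width must be positive", call. = FALSE)
  pi / 4 * length * width
}

#' Silique surface area from length and diameter
#'
#' Siliques are elongated pods measured by length and diameter; the lateral
#' surface of a cylinder (pi * d * l) is the default closed form.  A prolate
#' spheroid of the same length and equatorial diameter is available via
#' \code{shape = "spheroid"} for comparison.
#'
#' @param length Silique length, cm.
#' @param diameter Silique diameter, cm.
#' @param shape \code{"cylinder"} (default) or \code{"spheroid"}.
#' @return Surface area, cm^2 (vectorized).
#' @examples
#' silique_surface_area(5, 0.4)                      # 2 * pi
#' silique_surface_area(5, 0.4, shape = "spheroid")  # smaller, closed pod
#' @export
silique_surface_area <- function(length, diameter,
                                 shape = c("cylinder", "spheroid")) {
  shape <- match.arg(shape)
  if (any(length <= 0) || any(diameter <= 0))
    stop("silique length and diameter must be positive", call. = FALSE)
  if (shape == "cylinder") return(pi * diameter * length)
  # prolate spheroid: semi-axes a = diameter/2 (equatorial), c = length/2
  a <- diameter / 2; cc <- length / 2
  e <- sqrt(pmax(1 - a^2 / cc^2, 0))
  ifelse(e < 1e-12, 4 * pi * a^2,
         2 * pi * a^2 * (1 + cc / (a * e) * asin(e)))
}

#' Area-index regression (aggregate organ area to index)
#'
#' Linear regression linking aggregated organ area to an optically measured
#' area index; the published leaf fit is index = 0.005 * area + 1.318, and
#' the same relation is reused for silique area.
#'
#' @param slope,intercept Regression coefficients.
#' @return Object of class \code{area_index_regression}.
#' @export
area_index_regression <- function(slope = 0.005, intercept = 1.318) {
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = NA_real_, rmse = NA_real_, nrmse = NA_real_),
            class = "area_index_regression")
}

#' @export
print.area_index_regression <- function(x, ...) {
  cat("Area-index regression: index = ", format(x$slope), " * area + ",
      format(x$intercept), "\n", sep = "")
  if (!is.na(x$r_squared))
    cat("  fit: R2 = ", format(x$r_squared, digits = 4), ", RMSE = ",
        format(x$rmse, digits = 4), ", NRMSE = ",
        format(x$nrmse, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' LAI from aggregated leaf area
#'
#' @param S_L Aggregated estimated leaf area (cm^2, in the aggregation that
#'   produced the regression).
#' @param reg An [area_index_regression()] (defaults to the published fit).
#' @return LAI, dimensionless.
#' @examples
#' lai_from_leaf_area(0)    # intercept 1.318
#' lai_from_leaf_area(100)  # 1.818
#' @export
lai_from_leaf_area <- function(S_L, reg = area_index_regression()) {
  if (any(S_L < 0)) stop("leaf area must be non-negative", call. = FALSE)
  reg$slope * S_L + reg$intercept
}

#' SAI from aggregated silique area
#'
#' Before silique emergence the silique area index is 0 by definition,
#' whatever the regression intercept; \code{siliques_present} gates that.
#'
#' @param S_P Aggregated estimated silique surface area (cm^2).
#' @param reg An [area_index_regression()].
#' @param siliques_present Logical; \code{FALSE} forces SAI = 0.
#' @return SAI, dimensionless.
#' @export
sai_from_silique_area <- function(S_P, reg = area_index_regression(),
                                  siliques_present = TRUE) {
  if (any(S_P < 0)) stop("silique area must be non-negative", call. = FALSE)
  ifelse(rep_len(siliques_present, length(S_P)),
         reg$slope * S_P + reg$intercept, 0)
}

#' Total photosynthetic area index
#'
#' @param lai,sai Leaf and silique area indices (non-negative).
#' @return TPAI = LAI + SAI.
#' @export
tpai <- function(lai, sai) {
  if (any(lai < 0) || any(sai < 0))
    stop("lai and sai must be non-negative", call. = FALSE)
  lai + sai
}

#' Plant (or silique) density from a quadrat count
#'
#' density = 1e4 * n_a / side^2 individuals per m^2; with the default
#' 100-cm quadrat this reduces to the count itself.
#'
#' @param n_a Count within the quadrat.
#' @param quadrat_side Quadrat side, cm (default 100).
#' @return Density, individuals m-2.
#' @export
plant_density <- function(n_a, quadrat_side = 100) {
  if (any(quadrat_side <= 0))
    stop("quadrat side must be positive", call. = FALSE)
  if (any(n_a < 0)) stop("count must be non-negative", call. = FALSE)
  1e4 * n_a / quadrat_side^2
}

#' Plant water content from dry and wet weight
#'
#' theta = 1 - m_d / m_w.
#'
#' @param m_d Dry weight, g.
#' @param m_w Wet weight, g (positive, >= m_d).
#' @return Water content fraction in [0, 1].
#' @export
water_content <- function(m_d, m_w) {
  if (any(m_w <= 0)) stop("wet weight must be positive", call. = FALSE)
  if (any(m_d < 0)) stop("dry weight must be non-negative", call. = FALSE)
  if (any(m_d > m_w))
    stop("dry weight exceeds wet weight", call. = FALSE)
  1 - m_d / m_w
}

#' Thousand-seed weight from a unit-plot yield sample
#'
#' N = m_b / n_b * 1000.
#'
#' @param m_b Seed mass per unit plot, g.
#' @param n_b Seed count per unit plot (positive).
#' @return Thousand-seed weight, g.
#' @export
thousand_seed_weight <- function(m_b, n_b) {
  if (any(n_b <= 0)) stop("seed count must be positive", call. = FALSE)
  m_b / n_b * 1000
}

#' Fit the area-to-index regression by ordinary least squares
#'
#' @param area Numeric vector of aggregated organ areas (cm^2).
#' @param index Numeric vector of measured area indices.
#' @return An \code{area_index_regression} with fit statistics
#'   (\code{r_squared}, \code{rmse}, \code{nrmse} in percent of the
#'   observed-index mean).
#' @export
fit_area_index_regression <- function(area, index) {
  stopifnot(length(area) == length(index))
  if (length(unique(area)) < 2)
    stop("need >= 2 distinct area values to fit a line", call. = FALSE)
  fit <- stats::lm(index ~ area)
  reg <- area_index_regression(slope = unname(stats::coef(fit)[2]),
                               intercept = unname(stats::coef(fit)[1]))
  pred <- stats::fitted(fit)
  reg$r_squared <- r_squared(index, pred)
  reg$rmse <- rmse(index, pred)
  reg$nrmse <- nrmse(index, pred)
  reg
}
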