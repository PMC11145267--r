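#' Default income and price index series
#'
#' Small editable series used to update the value of statistical life from
#' its 2014 base to 2022 dollars and income levels: real median earnings
#' growth of 10% and a GDP-deflator ratio chosen so the combined update
#' factor is exactly 12.4/9.3. The exact official series are not shipped;
#' the 2022 endpoint is pinned to the $12.4M target.
#' @name valuation-indexes
#' @keywords internal
default_income_index <- function() c("2014" = 1.0, "2022" = 1.10)

default_price_deflator <- function() {
  c("2014" = 1.0, "2022" = (12.4 / 9.3) / 1.10)
}

#' Valuation parameters
#'
#' Willingness-to-pay values and discounting constants used to monetize
#' health impacts: a value per statistical life (VSL) at a base year with
#' income and price indexes for updating, a value per statistical case (VSC)
#' of childhood asthma, and the health discount rate.
#'
#' @param vsl_base VSL in base-year dollars (default $9.3M, 2014).
#' @param base_year,target_year Years for VSL updating.
#' @param elasticity Income elasticity of the VSL (default 1.0).
#' @param income_index,price_deflator Named year-to-index vectors.
#' @param vsc Value per statistical case of childhood asthma (2022 USD).
#' @param discount_rate Annual health discount rate (default 3%).
#' @return Object of class `valuation_params`.
#' @export
valuation_params <- function(vsl_base = 9.3e6, base_year = 2014,
                             target_year = 2022, elasticity = 1.0,
                             income_index = default_income_index(),
                             price_deflator = default_price_deflator(),
                             vsc = 610000, discount_rate = 0.03) {
  stopifnot(all(income_index > 0), all(price_deflator > 0), discount_rate >= 0)
  structure(list(vsl_base = vsl_base, base_year = base_year,
                 target_year = target_year, elasticity = elasticity,
                 income_index = income_index, price_deflator = price_deflator,
                 vsc = vsc, discount_rate = discount_rate),
            class = "valuation_params")
}

#' Update the value of statistical life to a target year
#'
#' `vsl_base x (income_t / income_b)^elasticity x (deflator_t / deflator_b)`:
#' real income growth enters through the income elasticity, inflation through
#' the price deflator.
#'
#' @param params A `valuation_params`.
#' @param target_year Year to update to (default the params' target year).
#' @return VSL in target-year dollars and income levels.
#' @export
update_vsl <- function(params, target_year = params$target_year) {
  by <- as.character(params$base_year); ty <- as.character(target_year)
  if (!by %in% names(params$income_index) || !ty %in% names(params$income_index) ||
      !by %in% names(params$price_deflator) || !ty %in% names(params$price_deflator))
    stop("income/deflator index missing for year ", by, " or ", ty)
  params$vsl_base *
    (params$income_index[[ty]] / params$income_index[[by]])^params$elasticity *
    (params$price_deflator[[ty]] / params$price_deflator[[by]])
}

#' Cessation-lag weights for mortality benefits
#'
#' A reduction in PM2.5 exposure does not avert all deaths immediately: 30%
#' of the mortality benefit accrues in the first year, 50% uniformly over
#' years 2-5, and the remaining 20% uniformly over years 6-20. Weights sum
#' to 1 exactly.
#'
#' @return Object of class `cessation_lag`: `horizon_years` (20) and
#'   `weights` (length 20).
#' @export
lag_weights <- function() {
  w <- c(0.30, rep(0.50 / 4, 4), rep(0.20 / 15, 15))
  structure(list(horizon_years = 20L, weights = w), class = "cessation_lag")
}

#' Present-value factor of the cessation-lag distribution
#'
#' `sum_t w_t (1 + rate)^-(t-1)`: benefits in the exposure year are
#' undiscounted. Equals 1 at rate 0, decreases in the rate, and tends to the
#' first-year share as the rate grows.
#'
#' @param lag A [lag_weights()] object.
#' @param rate Annual discount rate.
#' @return Scalar in (0, 1].
#' @export
discounted_lag_factor <- function(lag = lag_weights(), rate = 0.03) {
  if (rate < 0) stop("discount rate must be >= 0")
  t <- seq_along(lag$weights)
  sum(lag$weights * (1 + rate)^-(t - 1))
}

#' Monetize an impact breakdown
#'
#' Mortality is valued at the updated VSL with the cessation-lag discount
#' factor applied; asthma onset is valued at the VSC in the exposure year
#' (the cessation lag describes the mortality response only).
#'
#' @param impacts Either an `impact_breakdown` or a named list/vector with
#'   elements `mortality` and/or `asthma_onset` giving case counts.
#' @param params A `valuation_params`.
#' @param lag A [lag_weights()] object.
#' @return List: `mortality_usd`, `asthma_usd`, `total_usd`, `vsl`,
#'   `lag_factor`, `mortality_share`.
#' @export
monetize_impacts <- function(impacts, params = valuation_params(),
                             lag = lag_weights()) {
  if (inherits(impacts, "impact_breakdown") || is.data.frame(impacts)) {
    tot <- stats::aggregate(impacts["cases"], impacts["outcome"], sum)
    counts <- stats::setNames(tot$cases, tot$outcome)
  } else {
    counts <- unlist(impacts)
  }
  deaths <- if ("mortality" %in% names(counts)) counts[["mortality"]] else 0
  asthma <- if ("asthma_onset" %in% names(counts)) counts[["asthma_onset"]] else 0
  vsl <- update_vsl(params)
  lf <- discounted_lag_factor(lag, params$discount_rate)
  mort_usd <- deaths * vsl * lf
  asth_usd <- asthma * params$vsc
  total <- mort_usd + asth_usd
  list(mortality_usd = mort_usd, asthma_usd = asth_usd, total_usd = total,
       vsl = vsl, lag_factor = lf,
       mortality_share = if (total > 0) mort_usd / total else NA_real_)
}

#' Present-value multiplier for a uniform flow over the vehicle lifetime
#'
#' Per-vehicle results spread a constant per-mile benefit uniformly over the
#' lifetime (13 full years plus a half-weighted 14th year for the default
#' 13.5) and discount each year back to purchase. The mid-year convention
#' discounts year `t` by `(1 + rate)^-(t - 0.5)`; start-of-year by
#' `(1 + rate)^-(t - 1)`.
#'
#' @param years Lifetime in years (default 13.5).
#' @param rate Annual discount rate.
#' @param convention `"mid-year"` (default) or `"start-of-year"`.
#' @return Scalar in (0, 1]; 1 at rate 0.
#' @export
lifetime_discount_multiplier <- function(years = 13.5, rate = 0.03,
                                         convention = c("mid-year", "start-of-year")) {
  convention <- match.arg(convention)
  if (years <= 0) stop("lifetime must be positive")
  if (rate < 0) stop("discount rate must be >= 0")
  full <- floor(years)
  fracwt <- years - full
  shift <- if (convention == "mid-year") 0.5 else 1
  t <- seq_len(full)
  s <- sum((1 + rate)^-(t - shift))
  if (fracwt > 0) s <- s + fracwt * (1 + rate)^-(full + 1 - shift)
  s / years
}
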