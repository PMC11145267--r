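#' Log-linear slope from a hazard ratio per IQR
#'
#' Epidemiologic cohorts often report a hazard ratio per interquartile range
#' of exposure; under a log-linear concentration-response model the implied
#' slope per ug/m^3 is `ln(HR) / IQR`.
#'
#' @param hr Hazard ratio (> 0).
#' @param iqr Interquartile range of exposure, ug/m^3 (> 0).
#' @return Slope per ug/m^3.
#' @export
slope_from_hazard_ratio <- function(hr, iqr) {
  if (!is.finite(hr) || !is.finite(iqr) || hr <= 0 || iqr <= 0)
    stop("hazard ratio and IQR must be positive")
  log(hr) / iqr
}

#' Concentration-response function
#'
#' Log-linear relationship between a chronic PM2.5 increment and outcome
#' risk, with age-specific slopes and an optional threshold (default 0: a
#' no-threshold model). If a (hazard ratio, IQR) provenance pair is given,
#' the slope is derived from it via [slope_from_hazard_ratio()].
#'
#' @param outcome `"mortality"` or `"asthma_onset"`.
#' @param beta Slope per ug/m^3; either a scalar applied to every relevant
#'   age bin or a named vector by age bin. Ignored when `source_hr` is given.
#' @param threshold Concentration below which no effect accrues (ug/m^3).
#' @param source_hr Optional `c(hr, iqr)` pair.
#' @return Object of class `concentration_response`.
#' @export
concentration_response <- function(outcome = c("mortality", "asthma_onset"),
                                   beta, threshold = 0, source_hr = NULL) {
  outcome <- match.arg(outcome)
  if (!is.null(source_hr)) beta <- slope_from_hazard_ratio(source_hr[1], source_hr[2])
  if (any(beta < 0) || threshold < 0) stop("beta and threshold must be >= 0")
  structure(list(outcome = outcome, beta = beta, threshold = threshold,
                 source_hr = source_hr), class = "concentration_response")
}

#' Default childhood-asthma concentration-response function
#'
#' Asthma onset among at-risk children aged 0-17, log-linear with slope
#' derived from a cohort hazard ratio of 1.33 per 6.53 ug/m^3 IQR
#' (about a 4.4% risk increase per ug/m^3), no threshold.
#' @return A `concentration_response`.
#' @export
default_asthma_crf <- function() {
  concentration_response("asthma_onset", source_hr = c(1.33, 6.53))
}

#' Default adult-mortality concentration-response function
#'
#' Nonaccidental adult (25+) mortality from chronic PM2.5 exposure,
#' log-linear. The default slope of 0.0077 per ug/m^3 (about RR 1.08 per
#' 10 ug/m^3) is a repository-supplied mid-range value for pooled
#' multi-cohort chronic-exposure models; supply cohort-specific or
#' age-specific slopes to override, or use [gemm_slope()] to evaluate the
#' pooled-cohort functional form at an ambient level.
#' @param beta Slope(s) per ug/m^3.
#' @return A `concentration_response`.
#' @export
default_mortality_crf <- function(beta = 0.0077) {
  concentration_response("mortality", beta = beta)
}

#' Local slope of the pooled-cohort (GEMM-style) hazard function
#'
#' The pooled multi-cohort mortality model has hazard
#' `exp(theta * log(1 + z/alpha) * omega(z))` with
#' `omega(z) = 1 / (1 + exp(-(z - mu)/nu))` and `z = max(C - cf, 0)` the
#' exposure above the counterfactual. This returns the derivative of the log
#' hazard at ambient concentration `ambient` - the local log-linear slope to
#' plug into [default_mortality_crf()]. All shape parameters are
#' user-supplied; no published parameter set ships with the package.
#'
#' @param ambient Ambient PM2.5, ug/m^3.
#' @param theta,alpha,mu,nu Shape parameters.
#' @param counterfactual Counterfactual concentration, ug/m^3.
#' @return Slope per ug/m^3 at `ambient`.
#' @export
gemm_slope <- function(ambient, theta, alpha, mu, nu, counterfactual = 2.4) {
  z <- max(ambient - counterfactual, 0)
  om <- 1 / (1 + exp(-(z - mu) / nu))
  dom <- om * (1 - om) / nu
  theta * (om / (alpha + z) + log(1 + z / alpha) * dom)
}

#' Per-cell, per-age population health table
#'
#' Expands a domain into one row per (cell, age bin) with population and the
#' baseline rates the burden calculations need.
#'
#' @param domain A `bus_domain`.
#' @return data.frame: `cell_id`, `county_id`, `age_bin`, `population`,
#'   `mortality_rate`, `asthma_incidence`, `asthma_prevalence`, `is_child`,
#'   `is_adult`.
#' @export
population_health_table <- function(domain) {
  cells <- domain$cells
  rates <- domain$rates
  bins <- rates$age_bin
  out <- data.frame(
    cell_id = rep(cells$cell_id, times = length(bins)),
    county_id = rep(cells$county_id, times = length(bins)),
    age_bin = rep(bins, each = nrow(cells)),
    population = as.vector(domain$pop_age[, bins]),
    stringsAsFactors = FALSE
  )
  out <- merge(out, rates, by = "age_bin", sort = FALSE)
  out[order(out$cell_id, match(out$age_bin, bins)), c(
    "cell_id", "county_id", "age_bin", "population", "mortality_rate",
    "asthma_incidence", "asthma_prevalence", "is_child", "is_adult")]
}

#' At-risk children: those not currently with asthma
#'
#' @param table A [population_health_table()].
#' @return Child-bin rows with an `at_risk` column,
#'   `population * (1 - prevalence)`.
#' @export
at_risk_population <- function(table) {
  kids <- table[table$is_child, , drop = FALSE]
  kids$at_risk <- kids$population * (1 - kids$asthma_prevalence)
  kids
}

# slope for an age bin: scalar beta recycled, or named lookup
beta_for_bin <- function(beta, bin) {
  if (length(beta) == 1L && is.null(names(beta))) return(unname(beta))
  if (!bin %in% names(beta)) stop("no slope for age bin ", bin)
  unname(beta[[bin]])
}

#' Attributable cases from a concentration-change field
#'
#' For each receptor cell and age bin the attributable burden is
#' `baseline_rate * exposed_population * (1 - exp(-beta * max(dC - threshold, 0)))`
#' - the at-risk child population with asthma incidence for asthma onset, the
#' adult (25+) population with baseline mortality for mortality. By default
#' each pollutant channel's concentration change is run through the
#' attributable fraction separately (the per-species decomposition used
#' throughout); `attribution = "proportional"` instead applies the
#' attributable fraction to the summed concentration and splits it across
#' pollutants in proportion to their concentration contributions.
#'
#' @param delta_c data.frame from [apply_srm()]: `cell_id`, `pollutant`,
#'   `delta_c` (>= 0).
#' @param crf A `concentration_response`.
#' @param table A [population_health_table()].
#' @param attribution `"channel"` (default) or `"proportional"`.
#' @return data.frame of class `impact_breakdown`: `outcome`, `pollutant`,
#'   `cell_id`, `county_id`, `cases`; attribute `toxicity_multiplier` = 1.
#' @export
attributable_cases <- function(delta_c, crf, table,
                               attribution = c("channel", "proportional")) {
  attribution <- match.arg(attribution)
  stopifnot(inherits(crf, "concentration_response"))
  if (any(delta_c$delta_c < 0)) stop("concentration changes must be >= 0")

  if (crf$outcome == "asthma_onset") {
    exp_tab <- at_risk_population(table)
    exp_tab$exposed <- exp_tab$at_risk
    exp_tab$rate <- exp_tab$asthma_incidence
  } else {
    exp_tab <- table[table$is_adult, , drop = FALSE]
    exp_tab$exposed <- exp_tab$population
    exp_tab$rate <- exp_tab$mortality_rate
  }
  # collapse ages: cases are additive over age bins at a common dC, and with a
  # scalar-slope CRF the rate*pop products can be pre-summed per cell
  cases_for_dc <- function(dc_by_cell) {
    tot <- numeric(length(dc_by_cell$cell_id))
    for (bin in unique(exp_tab$age_bin)) {
      b <- beta_for_bin(crf$beta, bin)
      sub <- exp_tab[exp_tab$age_bin == bin, ]
      idx <- match(dc_by_cell$cell_id, sub$cell_id)
      rp <- (sub$rate * sub$exposed)[idx]
      rp[is.na(rp)] <- 0
      eff <- pmax(dc_by_cell$dc - crf$threshold, 0)
      tot <- tot + rp * (1 - exp(-b * eff))
    }
    tot
  }

  cellinfo <- unique(table[, c("cell_id", "county_id")])
  if (attribution == "channel") {
    out <- do.call(rbind, lapply(unique(delta_c$pollutant), function(p) {
      sub <- delta_c[delta_c$pollutant == p, ]
      data.frame(outcome = crf$outcome, pollutant = p, cell_id = sub$cell_id,
                 cases = cases_for_dc(list(cell_id = sub$cell_id, dc = sub$delta_c)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    tot_dc <- stats::aggregate(delta_c ~ cell_id, delta_c, sum)
    joint <- cases_for_dc(list(cell_id = tot_dc$cell_id, dc = tot_dc$delta_c))
    out <- do.call(rbind, lapply(unique(delta_c$pollutant), function(p) {
      sub <- delta_c[delta_c$pollutant == p, ]
      idx <- match(sub$cell_id, tot_dc$cell_id)
      share <- ifelse(tot_dc$delta_c[idx] > 0, sub$delta_c / tot_dc$delta_c[idx], 0)
      data.frame(outcome = crf$outcome, pollutant = p, cell_id = sub$cell_id,
                 cases = joint[idx] * share, stringsAsFactors = FALSE)
    }))
  }
  out$county_id <- cellinfo$county_id[match(out$cell_id, cellinfo$cell_id)]
  out <- out[, c("outcome", "pollutant", "cell_id", "county_id", "cases")]
  attr(out, "toxicity_multiplier") <- 1
  class(out) <- c("impact_breakdown", "data.frame")
  out
}

#' Total cases in an impact breakdown
#' @param impacts An `impact_breakdown`.
#' @param by Optional grouping columns (e.g. `"pollutant"`).
#' @return Total cases (scalar) or a data.frame of group totals.
#' @export
total_cases <- function(impacts, by = NULL) {
  if (is.null(by)) return(sum(impacts$cases))
  stats::aggregate(impacts["cases"], impacts[by], sum)
}

#' Attributable cases per metric ton emitted at one source cell
#'
#' Runs a unit 1 t/yr emission of one pollutant at `source_cell` through the
#' source-receptor matrix and the attributable-burden step. In the
#' small-exposure limit this approaches
#' `beta x pseudo intake fraction x population-weighted baseline rate x population`.
#'
#' @param source_cell Source cell id.
#' @param pollutant One of [POLLUTANTS].
#' @param crf A `concentration_response`.
#' @param table A [population_health_table()].
#' @param srm A `bus_srm`.
#' @return Cases per (t/yr) emitted.
#' @export
marginal_damage_per_ton <- function(source_cell, pollutant, crf, table, srm) {
  field <- data.frame(cell_id = source_cell, pollutant = pollutant,
                      tons_per_year = 1)
  class(field) <- c("emission_field", "data.frame")
  dc <- apply_srm(field, srm)
  sum(attributable_cases(dc[dc$pollutant == pollutant, ], crf, table)$cases)
}

#' Scale the primary-PM2.5 channel by a toxicity multiplier
#'
#' Sensitivity analysis treating carbonaceous primary PM2.5 from combustion
#' as `m` times more toxic by mass than the ambient mix: the primary-PM2.5
#' channel is scaled by `m`, other channels are unchanged.
#'
#' @param impacts An `impact_breakdown`.
#' @param m Multiplier (>= 1 in the intended use; must be >= 0).
#' @return The rescaled `impact_breakdown`; attribute `toxicity_multiplier`
#'   records `m`.
#' @export
apply_toxicity_multiplier <- function(impacts, m) {
  if (!is.finite(m) || m < 0) stop("toxicity multiplier must be >= 0")
  sel <- impacts$pollutant == "PM25_primary"
  impacts$cases[sel] <- impacts$cases[sel] * m
  attr(impacts, "toxicity_multiplier") <- m
  impacts
}

#' Default grid-emission projection scalers, 2023-2036
#'
#' Combined NOx/SO2 damage intensity of grid generation relative to the 2018
#' base year, declining linearly from 0.40 to 0.17 (mean about 0.29,
#' emulating reference-case projections in which NOx and SO2 emission rates
#' fall roughly 3x and 4x below 2018 levels over the bus lifetime).
#'
#' @param years Projection years.
#' @return Named numeric vector of scalers.
#' @export
default_grid_scalers <- function(years = 2023:2036) {
  s <- seq(0.40, 0.17, length.out = length(years))
  stats::setNames(s, years)
}

#' Per-mile health impacts of electricity for bus charging
#'
#' Converts electricity consumption at the wheel into generation (dividing
#' out charging and transmission losses), applies a base-year attributable
#' mortality rate per TWh generated scaled by per-year grid-emission
#' projections, and transfers an asthma-to-mortality ratio taken from the
#' diesel side of the same run.
#'
#' @param kwh_per_mile Consumption at the wheel (kWh/mile).
#' @param grid_loss,charging_loss Fractional losses in `[0, 1)`.
#' @param deaths_per_twh_base Attributable deaths per TWh generated in the
#'   base year.
#' @param projection_scalers Per-year damage scalers relative to the base
#'   year (> 0), see [default_grid_scalers()].
#' @param asthma_ratio Asthma-onset cases per attributable death, computed
#'   from the diesel-side totals of the same run.
#' @return List: `generation_kwh_per_mile`, `deaths_per_mile_by_year`,
#'   `deaths_per_mile` (lifetime mean), `asthma_per_mile`.
#' @export
electric_grid_impacts <- function(kwh_per_mile = 1.54, grid_loss = 0.048,
                                  charging_loss = 0.10,
                                  deaths_per_twh_base = 2.2,
                                  projection_scalers = default_grid_scalers(),
                                  asthma_ratio = 0) {
  if (grid_loss < 0 || grid_loss >= 1 || charging_loss < 0 || charging_loss >= 1)
    stop("losses must be in [0, 1)")
  if (any(projection_scalers <= 0)) stop("projection scalers must be > 0")
  gen <- kwh_per_mile / ((1 - charging_loss) * (1 - grid_loss))
  deaths_by_year <- gen * 1e-9 * deaths_per_twh_base * projection_scalers
  deaths <- mean(deaths_by_year)
  list(generation_kwh_per_mile = gen,
       deaths_per_mile_by_year = deaths_by_year,
       deaths_per_mile = deaths,
       asthma_per_mile = deaths * asthma_ratio)
}
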