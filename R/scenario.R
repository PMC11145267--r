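#' Define a bus replacement scenario
#'
#' Which emission-factor set is taken off the road, what replaces it
#' (an electric bus or another diesel set), where the miles are driven, and
#' the lifetime/cost assumptions.
#'
#' @param replaced `source_label` of the emission-factor set being replaced.
#' @param replacement `"electric"` or another diesel `source_label`.
#' @param region A county id (integer), an urban-rural class from
#'   [URBAN_CLASSES], or `"all"`.
#' @param annual_vmt Miles driven per year by the replaced bus; defaults to
#'   `lifetime_miles / lifetime_years`.
#' @param lifetime_miles,lifetime_years Lifetime assumptions (defaults
#'   190,134 miles over 13.5 years).
#' @param toxicity_multiplier Primary-PM2.5 toxicity multiplier (default 1).
#' @param cost_differential Lifetime cost premium of the electric bus, USD
#'   (default 156,000).
#' @return Object of class `replacement_scenario`.
#' @export
replacement_scenario <- function(replaced, replacement = "electric",
                                 region = "all", annual_vmt = NULL,
                                 lifetime_miles = 190134, lifetime_years = 13.5,
                                 toxicity_multiplier = 1,
                                 cost_differential = 156000) {
  if (is.null(annual_vmt)) annual_vmt <- lifetime_miles / lifetime_years
  if (annual_vmt <= 0) stop("annual VMT must be positive")
  structure(list(replaced = replaced, replacement = replacement,
                 region = region, annual_vmt = annual_vmt,
                 lifetime_miles = lifetime_miles,
                 lifetime_years = lifetime_years,
                 toxicity_multiplier = toxicity_multiplier,
                 cost_differential = cost_differential),
            class = "replacement_scenario")
}

# Resolve a region spec to county ids
region_counties <- function(domain, region) {
  if (identical(region, "all")) return(domain$counties$county_id)
  if (is.numeric(region)) {
    if (!all(region %in% domain$counties$county_id))
      stop("region not in domain: ", paste(setdiff(region, domain$counties$county_id),
                                           collapse = ", "))
    return(as.integer(region))
  }
  if (is.character(region) && all(region %in% URBAN_CLASSES)) {
    ids <- domain$counties$county_id[domain$counties$urban_class %in% region]
    if (length(ids) == 0L) stop("no counties of class ", paste(region, collapse = ","),
                                " in domain")
    return(ids)
  }
  stop("region must be county id(s), an urban-rural class, or \"all\"")
}

# Default concentration-response set
default_crfs <- function() {
  list(mortality = default_mortality_crf(), asthma = default_asthma_crf())
}

#' Per-mile health impacts of a diesel emission-factor set in a region
#'
#' Distributes one bus-year of driving (`annual_vmt` miles) over the
#' region's counties in proportion to population, converts g/mile emission
#' factors to t/yr, runs them through the source-receptor matrix and the
#' attributable-burden step, and normalizes to cases per mile.
#'
#' @param ef Named g/mile vector over [POLLUTANTS] (see [ef_vector()]).
#' @param region County id(s), urban class, or `"all"`.
#' @param domain,srm Domain and source-receptor matrix.
#' @param crfs List with elements `mortality` and `asthma`.
#' @param table A [population_health_table()]; computed if `NULL`.
#' @param annual_vmt Miles per year driven in the region.
#' @param toxicity_multiplier Primary-PM2.5 multiplier.
#' @return List: `breakdown` (annual `impact_breakdown`, both outcomes),
#'   `cases_per_mile` (named: mortality, asthma_onset),
#'   `usd_by_pollutant_per_mile` filled in by the monetizing caller.
#' @export
diesel_impacts_per_mile <- function(ef, region, domain, srm,
                                    crfs = default_crfs(), table = NULL,
                                    annual_vmt = 14084,
                                    toxicity_multiplier = 1) {
  if (is.null(table)) table <- population_health_table(domain)
  counties <- region_counties(domain, region)
  cpop <- domain$counties$population[match(counties, domain$counties$county_id)]
  vmt_share <- if (sum(cpop) > 0) cpop / sum(cpop) else rep(1 / length(cpop), length(cpop))
  county_emissions <- do.call(rbind, lapply(seq_along(counties), function(i) {
    data.frame(county_id = counties[i], pollutant = names(ef),
               tons_per_year = unname(ef) * annual_vmt * vmt_share[i] * 1e-6,
               stringsAsFactors = FALSE)
  }))
  field <- allocate_county_emissions(county_emissions, domain)
  dc <- apply_srm(field, srm)
  mort <- attributable_cases(dc, crfs$mortality, table)
  asth <- attributable_cases(dc, crfs$asthma, table)
  breakdown <- rbind(mort, asth)
  class(breakdown) <- c("impact_breakdown", "data.frame")
  attr(breakdown, "toxicity_multiplier") <- 1
  if (toxicity_multiplier != 1)
    breakdown <- apply_toxicity_multiplier(breakdown, toxicity_multiplier)
  tot <- total_cases(breakdown, by = "outcome")
  cpm <- stats::setNames(tot$cases / annual_vmt, tot$outcome)
  for (o in c("mortality", "asthma_onset")) if (!o %in% names(cpm)) cpm[o] <- 0
  list(breakdown = breakdown, cases_per_mile = cpm, annual_vmt = annual_vmt)
}

# Monetize per-mile cases: mortality with VSL x lag factor, asthma with VSC
monetize_per_mile <- function(cases_per_mile, valuation, lag = lag_weights()) {
  vsl <- update_vsl(valuation)
  lf <- discounted_lag_factor(lag, valuation$discount_rate)
  mort <- cases_per_mile[["mortality"]] * vsl * lf
  asth <- cases_per_mile[["asthma_onset"]] * valuation$vsc
  c(mortality = mort, asthma_onset = asth, total = mort + asth)
}

#' Per-mile benefit of a replacement scenario
#'
#' Health benefit per mile = monetized per-mile impacts of the replaced bus
#' minus those of the replacement, computed on the same receptor set. An
#' electric replacement's impacts come from grid generation via
#' [electric_grid_impacts()], with the asthma-to-mortality ratio transferred
#' from the diesel side of the same run. Replacing a bus with an identical
#' one yields exactly zero; negative benefits are reported, not clipped.
#'
#' @param scenario A `replacement_scenario`.
#' @param domain,srm Domain and source-receptor matrix.
#' @param efs An `ef_table`.
#' @param crfs Concentration-response set, see [default_crfs()].
#' @param valuation A `valuation_params`.
#' @param grid List of arguments forwarded to [electric_grid_impacts()].
#' @return Object of class `bus_benefit` (per-mile fields filled).
#' @export
per_mile_benefit <- function(scenario, domain, srm, efs,
                             crfs = default_crfs(),
                             valuation = valuation_params(),
                             grid = list()) {
  stopifnot(inherits(scenario, "replacement_scenario"))
  table <- population_health_table(domain)
  replaced <- diesel_impacts_per_mile(
    ef_vector(efs, scenario$replaced), scenario$region, domain, srm, crfs,
    table, scenario$annual_vmt, scenario$toxicity_multiplier)
  replaced$usd_per_mile <- monetize_per_mile(replaced$cases_per_mile, valuation)

  if (identical(scenario$replacement, "electric")) {
    ratio <- if (replaced$cases_per_mile[["mortality"]] > 0)
      replaced$cases_per_mile[["asthma_onset"]] / replaced$cases_per_mile[["mortality"]]
    else 0
    gi <- do.call(electric_grid_impacts, c(grid, list(asthma_ratio = ratio)))
    cpm <- c(mortality = gi$deaths_per_mile, asthma_onset = gi$asthma_per_mile)
    replacement <- list(breakdown = NULL, cases_per_mile = cpm, grid = gi)
  } else {
    replacement <- diesel_impacts_per_mile(
      ef_vector(efs, scenario$replacement), scenario$region, domain, srm, crfs,
      table, scenario$annual_vmt, scenario$toxicity_multiplier)
  }
  replacement$usd_per_mile <- monetize_per_mile(replacement$cases_per_mile, valuation)

  structure(list(
    scenario = scenario, valuation = valuation,
    replaced = replaced, replacement = replacement,
    benefit_per_mile_usd = unname(replaced$usd_per_mile[["total"]] -
                                    replacement$usd_per_mile[["total"]]),
    benefit_per_mile_by_outcome = replaced$usd_per_mile[c("mortality", "asthma_onset")] -
      replacement$usd_per_mile[c("mortality", "asthma_onset")]
  ), class = "bus_benefit")
}

#' Per-bus (lifetime present-value) fields of a benefit result
#'
#' Health: per-mile benefit x lifetime miles x the uniform-flow discount
#' multiplier ([lifetime_discount_multiplier()]). Climate: present value of
#' the lifetime CO2 flows under the social-cost schedule. Net benefit
#' subtracts the scenario's cost differential (electric replacements only).
#'
#' @param benefit A `bus_benefit` from [per_mile_benefit()].
#' @param climate A `climate_params`.
#' @param schedule An `scc_schedule`.
#' @param convention Driving-year discounting convention for the health side.
#' @return The `bus_benefit` with `per_bus` fields added.
#' @export
per_bus_benefit <- function(benefit, climate = climate_params(),
                            schedule = build_scc_schedule(),
                            convention = c("mid-year", "start-of-year")) {
  convention <- match.arg(convention)
  stopifnot(inherits(benefit, "bus_benefit"))
  sc <- benefit$scenario
  mult <- lifetime_discount_multiplier(sc$lifetime_years,
                                       benefit$valuation$discount_rate,
                                       convention)
  health <- benefit$benefit_per_mile_usd * sc$lifetime_miles * mult
  is_electric <- identical(sc$replacement, "electric")
  climate_usd <- if (is_electric) climate_benefit_per_bus(climate, schedule) else {
    # diesel-for-diesel swaps change tailpipe CO2 only through fuel economy,
    # which the scenario holds fixed: no climate term
    0
  }
  ghg_t <- if (is_electric) lifetime_ghg_reduction(climate) else 0
  benefit$per_bus <- list(
    health_usd = health, climate_usd = climate_usd, ghg_reduction_t = ghg_t,
    total_usd = health + climate_usd,
    net_benefit_usd = health + climate_usd -
      if (is_electric) sc$cost_differential else 0,
    lifetime_multiplier = mult, convention = convention
  )
  benefit
}

#' Evaluate a scenario end to end
#'
#' @inheritParams per_mile_benefit
#' @inheritParams per_bus_benefit
#' @return A `bus_benefit` with per-mile and per-bus fields.
#' @export
evaluate_scenario <- function(scenario, domain, srm, efs,
                              crfs = default_crfs(),
                              valuation = valuation_params(),
                              climate = climate_params(),
                              schedule = build_scc_schedule(),
                              grid = list(),
                              convention = c("mid-year", "start-of-year")) {
  pm <- per_mile_benefit(scenario, domain, srm, efs, crfs, valuation, grid)
  per_bus_benefit(pm, climate, schedule, convention)
}

#' @export
print.bus_benefit <- function(x, ...) {
  sc <- x$scenario
  cat("Replacement scenario:", sc$replaced, "->", sc$replacement,
      "| region:", paste(sc$region, collapse = ","), "\n")
  cat(sprintf("  Health benefit: $%.4f per mile\n", x$benefit_per_mile_usd))
  if (!is.null(x$per_bus)) {
    pb <- x$per_bus
    cat(sprintf("  Per bus: health $%s, climate $%s, GHG %.1f t, net $%s\n",
                format(round(pb$health_usd), big.mark = ","),
                format(round(pb$climate_usd), big.mark = ","),
                pb$ghg_reduction_t,
                format(round(pb$net_benefit_usd), big.mark = ",")))
  }
  invisible(x)
}

#' @export
summary.bus_benefit <- function(object, ...) {
  x <- object
  out <- data.frame(
    side = c("replaced", "replacement"),
    mortality_per_mile = c(x$replaced$cases_per_mile[["mortality"]],
                           x$replacement$cases_per_mile[["mortality"]]),
    asthma_per_mile = c(x$replaced$cases_per_mile[["asthma_onset"]],
                        x$replacement$cases_per_mile[["asthma_onset"]]),
    usd_per_mile = c(x$replaced$usd_per_mile[["total"]],
                     x$replacement$usd_per_mile[["total"]])
  )
  print(x)
  cat("\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Annual burden of a fleet across regions
#'
#' Sums per-mile impacts weighted by vehicle miles traveled per county and
#' reports annual attributable deaths and asthma-onset cases plus rates per
#' 100 million miles. Linear in VMT.
#'
#' @param vmt_by_county data.frame: `county_id`, `vmt` (miles/yr, >= 0).
#' @param ef Named g/mile vector applied in every county (a fleet-average
#'   set), or a function(county_id) returning one.
#' @param domain,srm,crfs,table As elsewhere.
#' @param toxicity_multiplier Primary-PM2.5 multiplier.
#' @return List: `deaths_per_year`, `asthma_per_year`,
#'   `deaths_per_100M_miles`, `asthma_per_100M_miles`, `total_vmt`,
#'   `breakdown`.
#' @export
fleet_burden <- function(vmt_by_county, ef, domain, srm,
                         crfs = default_crfs(), table = NULL,
                         toxicity_multiplier = 1) {
  if (any(vmt_by_county$vmt < 0)) stop("VMT must be >= 0")
  if (is.null(table)) table <- population_health_table(domain)
  get_ef <- if (is.function(ef)) ef else function(county_id) ef
  county_emissions <- do.call(rbind, lapply(seq_len(nrow(vmt_by_county)), function(i) {
    e <- get_ef(vmt_by_county$county_id[i])
    data.frame(county_id = vmt_by_county$county_id[i], pollutant = names(e),
               tons_per_year = unname(e) * vmt_by_county$vmt[i] * 1e-6,
               stringsAsFactors = FALSE)
  }))
  total_vmt <- sum(vmt_by_county$vmt)
  if (total_vmt == 0 || all(county_emissions$tons_per_year == 0)) {
    return(list(deaths_per_year = 0, asthma_per_year = 0,
                deaths_per_100M_miles = NA_real_,
                asthma_per_100M_miles = NA_real_,
                total_vmt = total_vmt, breakdown = NULL))
  }
  field <- allocate_county_emissions(county_emissions, domain)
  dc <- apply_srm(field, srm)
  mort <- attributable_cases(dc, crfs$mortality, table)
  asth <- attributable_cases(dc, crfs$asthma, table)
  breakdown <- rbind(mort, asth)
  class(breakdown) <- c("impact_breakdown", "data.frame")
  attr(breakdown, "toxicity_multiplier") <- 1
  if (toxicity_multiplier != 1)
    breakdown <- apply_toxicity_multiplier(breakdown, toxicity_multiplier)
  deaths <- sum(breakdown$cases[breakdown$outcome == "mortality"])
  asthma <- sum(breakdown$cases[breakdown$outcome == "asthma_onset"])
  list(deaths_per_year = deaths, asthma_per_year = asthma,
       deaths_per_100M_miles = deaths / (total_vmt / 1e8),
       asthma_per_100M_miles = asthma / (total_vmt / 1e8),
       total_vmt = total_vmt, breakdown = breakdown)
}

#' VMT-weighted aggregation of county results by urban-rural class
#'
#' @param county_values data.frame: `county_id`, `value`.
#' @param domain A `bus_domain` (supplies each county's class).
#' @param weights data.frame: `county_id`, `weight` (e.g. VMT); equal
#'   weights if `NULL`.
#' @return data.frame: `urban_class`, `value` (weighted mean), `weight`
#'   (class total), `total` (weight x mean; class totals sum to the
#'   fleet-wide total).
#' @export
aggregate_by_class <- function(county_values, domain, weights = NULL) {
  cls <- domain$counties$urban_class[match(county_values$county_id,
                                           domain$counties$county_id)]
  if (anyNA(cls)) stop("unclassified county in results")
  if (is.null(weights)) {
    w <- rep(1, nrow(county_values))
  } else {
    w <- weights$weight[match(county_values$county_id, weights$county_id)]
    if (anyNA(w)) stop("missing weight for some county")
  }
  agg <- lapply(split(seq_along(cls), cls), function(idx) {
    data.frame(value = stats::weighted.mean(county_values$value[idx], w[idx]),
               weight = sum(w[idx]),
               total = sum(county_values$value[idx] * w[idx]))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(urban_class = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(match(out$urban_class, URBAN_CLASSES)), ]
}

#' Map county results to school districts through a population crosswalk
#'
#' Each county's value is split across the districts it intersects using
#' block-group-population weights; per-county weights must sum to 1, so
#' totals are conserved.
#'
#' @param county_values data.frame: `county_id`, `value`.
#' @param crosswalk data.frame: `county_id`, `district_id`, `weight` (>= 0,
#'   summing to 1 within each county to 1e-9).
#' @return data.frame: `district_id`, `value`.
#' @export
map_to_districts <- function(county_values, crosswalk) {
  if (any(crosswalk$weight < 0)) stop("crosswalk weights must be >= 0")
  sums <- tapply(crosswalk$weight, crosswalk$county_id, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("crosswalk weights must sum to 1 within each county")
  v <- county_values$value[match(crosswalk$county_id, county_values$county_id)]
  if (anyNA(v)) stop("crosswalk references county absent from results")
  contrib <- v * crosswalk$weight
  out <- stats::aggregate(list(value = contrib),
                          list(district_id = crosswalk$district_id), sum)
  out[order(out$district_id), ]
}

#' Share of impacts accruing to the source region
#'
#' The fraction of an impact breakdown's cases whose receptor lies in the
#' given source counties (or in counties of the same urban class); shares
#' over a partition of receptors sum to 1.
#'
#' @param impacts An `impact_breakdown` (receptor `county_id` column).
#' @param source_region County id(s) or an urban class.
#' @param domain Needed when `source_region` is a class.
#' @return Fraction in `[0, 1]`.
#' @export
local_share <- function(impacts, source_region, domain = NULL) {
  total <- sum(impacts$cases)
  if (total == 0) return(NA_real_)
  if (is.character(source_region) && !is.null(domain)) {
    ids <- region_counties(domain, source_region)
  } else ids <- source_region
  sum(impacts$cases[impacts$county_id %in% ids]) / total
}

#' Net benefit after the replacement cost differential
#'
#' @param result A `bus_benefit` with per-bus fields, or a numeric total
#'   benefit in USD.
#' @param cost_differential USD; defaults to the scenario's value for a
#'   `bus_benefit`.
#' @return Health + climate benefits minus the cost differential, USD.
#' @export
net_benefit <- function(result, cost_differential = NULL) {
  if (inherits(result, "bus_benefit")) {
    if (is.null(result$per_bus)) stop("compute per-bus fields first")
    total <- result$per_bus$total_usd
    if (is.null(cost_differential))
      cost_differential <- result$scenario$cost_differential
  } else {
    total <- result
    if (is.null(cost_differential)) stop("cost differential required")
  }
  total - cost_differential
}
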